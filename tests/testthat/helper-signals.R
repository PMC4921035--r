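# Shared fixtures built in code.

design <- load_design()
analysis_design <- apply_exclusions(design)

# A signal_table from per-control named signal vectors (log2 scale), one
# value per pool in design order.
st <- function(..., platform = "array", replicate = 1L) {
  vals <- list(...)
  rows <- do.call(rbind, lapply(names(vals), function(id) {
    data.frame(control_id = id, pool = pool_order(), replicate = replicate,
               signal = vals[[id]])
  }))
  signal_table(rows, platform)
}

pool_order <- function() c("12", "13", "14", "15")

# Noiseless array signals for every analysis-set control (log2 of the
# Langmuir intensity at its nominal abundance), plus background rows.
noiseless_array <- function(k_d = 1e4, i_max = 2^14, bg = 2^5) {
  simulate_microarray(design,
                      array_sim_config(k_d = k_d, i_max = i_max, bg = bg,
                                       noise_sd = 0, seed = 1),
                      no_anomalies())
}

# Spearman's rho via the d^2 formula (valid for distinct values) -- the
# independent oracle for the monotonicity screen.
rho_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
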