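#' Microarray simulation settings
#'
#' Defaults are the conditions the analysis is designed around: saturation
#' at Imax = 2^14 with Kd = 10^4 placing roughly the upper quarter of the
#' 2^20 ladder in compression, an additive background of 2^5 (about the
#' level a bead-array background probe reports), log2-additive Gaussian
#' noise of 0.1 (multiplicative ~7 % intensity noise, the visual spread of
#' single-channel array dose-response panels), and a 0.3 % wt/wt spike
#' fraction carried as metadata (a uniform rescaling of concentration is
#' absorbed into Kd).
#'
#' @param k_d Dissociation constant, relative-abundance units.
#' @param i_max Saturation intensity, linear scale.
#' @param bg Additive background, linear scale (>= 0).
#' @param noise_sd SD of Gaussian noise added to log2 signal.
#' @param spike_fraction Percent wt/wt, metadata only.
#' @param n_replicates Replicates per (control, pool).
#' @param seed RNG seed; fixes the full output.
#' @return List of class \code{array_sim_config}.
#' @export
array_sim_config <- function(k_d = 1e4, i_max = 2^14, bg = 2^5,
                             noise_sd = 0.1, spike_fraction = 0.3,
                             n_replicates = 1L, seed = 1L) {
  stopifnot(k_d > 0, i_max > 0, bg >= 0, noise_sd >= 0, n_replicates >= 1L)
  structure(list(k_d = k_d, i_max = i_max, bg = bg, noise_sd = noise_sd,
                 spike_fraction = spike_fraction,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "array_sim_config")
}

#' RNA-Seq simulation settings
#'
#' Counts are Poisson ("shot noise" of counting technical replicates) with
#' expectation proportional to depth x abundance x transcript length,
#' normalized within each pool; reported as RPKM with a 0.01 reporting
#' floor. Default depth 10^7 aligned reads per sample; transcript lengths
#' default to a deterministic synthetic assignment spanning 250-2000 nt.
#'
#' @param depth Expected aligned reads per sample.
#' @param lengths Optional named numeric vector of transcript lengths (nt)
#'   by control_id; missing controls get the synthetic default.
#' @param floor RPKM reporting floor; values at or below it are unreported.
#' @param n_replicates Replicates (libraries) per pool.
#' @param seed RNG seed; fixes the full output.
#' @return List of class \code{rnaseq_sim_config}.
#' @export
rnaseq_sim_config <- function(depth = 1e7, lengths = NULL, floor = 0.01,
                              n_replicates = 1L, seed = 1L) {
  stopifnot(depth > 0, floor >= 0, n_replicates >= 1L)
  structure(list(depth = depth, lengths = lengths, floor = floor,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "rnaseq_sim_config")
}

#' Anomaly specification for the simulators
#'
#' Injected departures from the nominal design, mimicking the failure modes
#' the assessment is built to catch: subpool mis-assignment (a control
#' prepared into the wrong subpool, so its true mixing proportions follow
#' another row of the Latin square), dropouts (controls yielding no signal),
#' and per-control log2 offsets (a concentration/mixing error that shifts a
#' whole dose-response curve).
#'
#' The default injects the canonical mis-assignment pattern: ERCC-00113
#' labeled subpool E but truly prepared in subpool C.
#'
#' @param misassigned Named character vector, control_id -> true subpool.
#' @param dropouts Character vector of controls forced undetected.
#' @param offset_controls Named numeric vector, control_id -> log2 offset.
#' @return List of class \code{anomaly_spec}.
#' @export
anomaly_spec <- function(misassigned = c("ERCC-00113" = "C"),
                         dropouts = character(),
                         offset_controls = numeric()) {
  structure(list(misassigned = misassigned, dropouts = dropouts,
                 offset_controls = offset_controls),
            class = "anomaly_spec")
}

#' No injected anomalies
#' @return An empty \code{anomaly_spec}.
#' @export
no_anomalies <- function() {
  anomaly_spec(misassigned = character(), dropouts = character(),
               offset_controls = numeric())
}

check_anomalies <- function(anomalies, design) {
  targets <- c(names(anomalies$misassigned), anomalies$dropouts,
               names(anomalies$offset_controls))
  unknown <- setdiff(targets, design$records$control_id)
  if (length(unknown)) {
    stop("anomaly targets not in the design: ",
         paste(unknown, collapse = ", "))
  }
}

# Evaluate fn with a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# True subpool of a control in the simulation: anomaly override, else the
# ORIGINAL labeled subpool (a recorded reassignment is a diagnosis made by
# the analysis, not part of the simulated truth).
true_subpool <- function(record, anomalies) {
  id <- record$control_id
  if (id %in% names(anomalies$misassigned)) anomalies$misassigned[[id]]
  else record$subpool
}

#' Simulate a microarray signal table
#'
#' Forward simulation of the Langmuir response: for each control and pool,
#' concentration is the nominal abundance under the control's true subpool,
#' intensity follows I = Imax C / (Kd + C) + bg, and the reported log2
#' intensity gets additive Gaussian noise. The omitted control (ERCC-00073)
#' and the seven antisense controls (which cannot hybridize sense probes)
#' report background-level intensity; dropout controls emit no rows;
#' offset anomalies shift a control's log2 signal.
#'
#' Deterministic under a fixed seed.
#'
#' @param design An \code{ercc_design} (the full design, before exclusions).
#' @param config An \code{array_sim_config}.
#' @param anomalies An \code{anomaly_spec}.
#' @return A \code{signal_table} (platform "array") with the config and
#'   anomalies attached as attributes \code{sim_config} / \code{sim_anomalies}.
#' @export
simulate_microarray <- function(design, config = array_sim_config(),
                                anomalies = anomaly_spec()) {
  check_anomalies(anomalies, design)
  rec <- design$records
  with_seed(config$seed, function() {
    rows <- lapply(seq_len(nrow(rec)), function(i) {
      id <- rec$control_id[i]
      if (id %in% anomalies$dropouts) return(NULL)
      at_background <- rec$subpool[i] == "omitted" || rec$antisense[i]
      if (at_background && config$bg <= 0) return(NULL)
      per_pool <- lapply(design$pools, function(p) {
        mu <- if (at_background) {
          log2(config$bg)
        } else {
          sp <- true_subpool(rec[i, ], anomalies)
          c_nom <- rec$base_abundance[i] * proportion_of(design, sp, p) / 10
          log2(langmuir_intensity(c_nom, config$i_max, config$k_d, config$bg))
        }
        if (id %in% names(anomalies$offset_controls)) {
          mu <- mu + anomalies$offset_controls[[id]]
        }
        data.frame(control_id = id, pool = p,
                   replicate = seq_len(config$n_replicates),
                   signal = mu + stats::rnorm(config$n_replicates,
                                              sd = config$noise_sd))
      })
      do.call(rbind, per_pool)
    })
    out <- signal_table(do.call(rbind, rows), "array",
                        spike_fraction = config$spike_fraction)
    attr(out, "sim_config") <- config
    attr(out, "sim_anomalies") <- anomalies
    out
  })
}

# Deterministic synthetic transcript length for a control (250-2000 nt).
synthetic_length <- function(control_id) {
  num <- as.integer(sub("ERCC-", "", control_id))
  250 + (num * 37L) %% 1751L
}

#' Simulate an RNA-Seq signal table
#'
#' Per control, pool and replicate: the expected count is the pool's depth
#' apportioned by abundance x transcript length (normalized over the pool's
#' sense-strand controls), the observed count is Poisson, and the reported
#' signal is RPKM = count / (length_kb x reads_M), truncated at the
#' reporting floor. Controls whose counts all fall at or below the floor in
#' a pool have no rows there, so low-ladder controls come out partially
#' detected or undetected at modest depth. Antisense controls (absent from
#' a sense-strand reference) and the omitted control emit no rows.
#'
#' Deterministic under a fixed seed.
#'
#' @param design An \code{ercc_design} (the full design, before exclusions).
#' @param config An \code{rnaseq_sim_config}.
#' @param anomalies An \code{anomaly_spec}.
#' @return A \code{signal_table} (platform "rnaseq", log2 RPKM) with
#'   attributes \code{sim_config} / \code{sim_anomalies}.
#' @export
simulate_rnaseq <- function(design, config = rnaseq_sim_config(),
                            anomalies = anomaly_spec()) {
  check_anomalies(anomalies, design)
  rec <- design$records
  active <- !(rec$subpool == "omitted" | rec$antisense |
              rec$control_id %in% anomalies$dropouts)
  ids <- rec$control_id[active]
  lengths <- vapply(ids, function(id) {
    if (!is.null(config$lengths) && id %in% names(config$lengths)) {
      config$lengths[[id]]
    } else {
      synthetic_length(id)
    }
  }, numeric(1))
  # pool-independent normalizer: pools are spiked at the same mass
  # fraction, so between-pool ratios must not be distorted by per-pool
  # renormalization of the expected counts
  pool_weights <- lapply(design$pools, function(p) {
    ab <- vapply(which(active), function(i) {
      sp <- true_subpool(rec[i, ], anomalies)
      rec$base_abundance[i] * proportion_of(design, sp, p) / 10
    }, numeric(1))
    ab * lengths
  })
  names(pool_weights) <- design$pools
  normalizer <- mean(vapply(pool_weights, sum, numeric(1)))
  with_seed(config$seed, function() {
    rows <- lapply(design$pools, function(p) {
      lambda <- config$depth * pool_weights[[p]] / normalizer
      per_rep <- lapply(seq_len(config$n_replicates), function(r) {
        counts <- stats::rpois(length(lambda), lambda)
        rpkm <- counts / ((lengths / 1000) * (config$depth / 1e6))
        if (length(anomalies$offset_controls)) {
          j <- match(names(anomalies$offset_controls), ids)
          ok <- !is.na(j)
          rpkm[j[ok]] <- rpkm[j[ok]] * 2^unlist(anomalies$offset_controls)[ok]
        }
        keep <- rpkm > config$floor
        data.frame(control_id = ids[keep], pool = p, replicate = r,
                   signal = log2(rpkm[keep]))
      })
      do.call(rbind, per_rep)
    })
    out <- signal_table(do.call(rbind, rows), "rnaseq")
    attr(out, "sim_config") <- config
    attr(out, "sim_anomalies") <- anomalies
    out
  })
}
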