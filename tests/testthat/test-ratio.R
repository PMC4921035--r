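test_that("Bland-Altman points encode M, A, and the design ratio", {
  tab <- st("ERCC-00128" = c(6, 6, 8, 9),     # B: pools 12,13,14,15
            "ERCC-00060" = c(9, 9, 9, 9))     # A: 1-to-1
  ba <- bland_altman(tab, analysis_design, "12", "13")
  b <- ba[ba$control_id == "ERCC-00128", ]
  expect_equal(b$m_value, 0)                  # equal signals
  a <- ba[ba$control_id == "ERCC-00060", ]
  expect_equal(a$nominal_log2_ratio, 0)       # constant subpool

  ba2 <- bland_altman(tab, analysis_design, "15", "12")
  expect_equal(ba2$m_value[ba2$control_id == "ERCC-00128"], 3)
  expect_equal(ba2$nominal_log2_ratio[ba2$control_id == "ERCC-00128"], 2)

  # Si = 4 Sj in linear signal is M = 2
  tab4 <- st("ERCC-00128" = log2(c(64, 16, 16, 16)))
  ba4 <- bland_altman(tab4, analysis_design, "12", "13")
  expect_equal(ba4$m_value[1], 2)
  # literal Bland-Altman abscissa: log of the linear mean
  bam <- bland_altman(tab4, analysis_design, "12", "13", ma = FALSE)
  expect_equal(bam$a_value[1], log2((64 + 16) / 2))
  expect_equal(ba4$a_value[1], (6 + 4) / 2)
})

test_that("swapping the pool pair negates M and preserves A", {
  sim <- simulate_microarray(design, array_sim_config(seed = 9))
  for (pair in list(c("12", "14"), c("13", "15"), c("12", "13"))) {
    fwd <- bland_altman(sim, analysis_design, pair[1], pair[2])
    rev <- bland_altman(sim, analysis_design, pair[2], pair[1])
    m <- match(fwd$control_id, rev$control_id)
    expect_equal(fwd$m_value, -rev$m_value[m])
    expect_equal(fwd$a_value, rev$a_value[m])
    expect_equal(fwd$nominal_log2_ratio, -rev$nominal_log2_ratio[m])
  }
})

test_that("all six pool pairs reproduce the designed fold multiset", {
  sim <- noiseless_array()
  pairs <- unique(enumerate_pool_pairs(analysis_design)[, c("pool_i", "pool_j")])
  folds <- unlist(lapply(seq_len(nrow(pairs)), function(k) {
    ba <- bland_altman(sim, analysis_design, pairs$pool_i[k], pairs$pool_j[k])
    round(2^abs(ba$nominal_log2_ratio), 1)
  }))
  expect_equal(sort(unique(folds)), c(1.0, 1.5, 1.6, 1.7, 2.5, 2.7, 4.0))
})

test_that("expected ratio curves compress at both extremes of the range", {
  fit <- structure(list(i_max = 2^14, k_d = 1e4, bg = 2^5, residual_sd = 0.1,
                        ci_level = 0.99, n = 10, platform_class = "array"),
                   class = c("langmuir_fit", "dose_response_fit"))
  for (fold in c(1.5, 2.5, 4)) {
    curve <- expected_ratio_curve(fit, fold, abundance_range = c(1e-6, 1e14))
    expect_equal(curve$a_value, sort(curve$a_value))
    expect_lt(abs(curve$m_value[1]), 1e-3)                    # bg floor
    expect_lt(abs(curve$m_value[nrow(curve)]), 1e-3)          # saturation
    expect_lt(max(curve$m_value), log2(fold))                 # never exceeds
    # interior approaches the nominal ratio when bg and saturation are remote
    free <- fit; free$bg <- 0; free$k_d <- 1e10
    lin <- expected_ratio_curve(free, fold, abundance_range = c(1, 1e4))
    expect_equal(max(lin$m_value), log2(fold), tolerance = 1e-3)
  }
  # RNA-Seq: no saturation, constant expected ratio
  rfit <- structure(list(intercept = -3, slope = 1, residual_sd = 0.1,
                         ci_level = 0.99, n = 10, platform_class = "rnaseq"),
                    class = c("unit_slope_fit", "dose_response_fit"))
  rc <- expected_ratio_curve(rfit, 2.5)
  expect_true(all(rc$m_value == log2(2.5)))
})

test_that("ratio recovery is summarized by region and nominal fold", {
  region <- structure(list(lower_log2_abundance = 4,
                           upper_log2_abundance = 13),
                      class = "linear_region")

  # noiseless linear-regime data: zero error inside the region
  sim <- simulate_microarray(design,
                             array_sim_config(k_d = 1e12, bg = 0,
                                              noise_sd = 0, seed = 1),
                             no_anomalies())
  labels_design <- apply_exclusions(design, honor_reassignment = FALSE)
  ba <- bland_altman(sim, labels_design, "12", "14")
  rs <- ratio_recovery_summary(ba, region)
  inside <- rs[rs$location == "inside", ]
  expect_true(all(inside$median_abs_error < 1e-9))
  expect_equal(sum(inside$n) + sum(rs$n[rs$location == "outside"]), nrow(ba))
  # the 1-to-1 subpool recovers M = 0
  expect_equal(rs$median_m[rs$nominal_log2_ratio == 0 &
                             rs$location == "inside"], 0)

  # with saturation, in-region ratios beat out-of-region ratios
  sat <- noiseless_array()
  basat <- bland_altman(sat, labels_design, "12", "14")
  rssat <- ratio_recovery_summary(basat, region)
  for (f in unique(rssat$nominal_log2_ratio[rssat$nominal_log2_ratio != 0])) {
    err_in <- rssat$median_abs_error[rssat$nominal_log2_ratio == f &
                                       rssat$location == "inside"]
    err_out <- rssat$median_abs_error[rssat$nominal_log2_ratio == f &
                                        rssat$location == "outside"]
    if (length(err_in) && length(err_out)) expect_lt(err_in, err_out)
  }
})

test_that("sequencing ratio noise shrinks as shot noise, 1 over sqrt(lambda)", {
  set.seed(101)
  sd_m_at <- function(lambda, n = 1000) {
    x <- rpois(n, lambda); y <- rpois(n, lambda)
    keep <- x > 0 & y > 0
    sd(log2(x[keep]) - log2(y[keep]))
  }
  s100 <- sd_m_at(100)
  s10k <- sd_m_at(10000)
  expect_equal(s100 / s10k, 10, tolerance = 0.15)
  # matches the analytic delta-method scale sqrt(2)/(ln 2 sqrt(lambda))
  expect_equal(s100, sqrt(2) / (log(2) * sqrt(100)), tolerance = 0.1)
})
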