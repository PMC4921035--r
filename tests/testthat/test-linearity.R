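test_that("per-control slopes recover ideal, flat, and compressed responses", {
  id <- "ERCC-00128"  # subpool B, base 16
  ab <- log2(nominal_abundance(analysis_design, id, pool_order()))
  ideal <- list(ab + 3); names(ideal) <- id
  s <- control_slope(do.call(st, ideal), analysis_design, id)
  expect_true(s$defined)
  expect_equal(s$slope, 1)

  flat <- list(rep(7, 4)); names(flat) <- id
  expect_equal(control_slope(do.call(st, flat), analysis_design, id)$slope, 0)

  # constant-abundance subpool A: slope undefined
  a <- control_slope(do.call(st, flat), analysis_design, "ERCC-00060")
  expect_false(is.finite(a$slope) && a$defined)
  expect_false(a$defined)

  # deep saturation compresses the slope toward zero
  sim <- noiseless_array()
  top <- control_slope(sim, analysis_design, "ERCC-00024")  # top rung, E
  expect_lt(top$slope, 0.05)
  mid <- control_slope(sim, analysis_design, "ERCC-00085")  # base 256, B
  expect_gt(mid$slope, 0.9)
})

test_that("Spearman screen matches the rank-covariance oracle exhaustively", {
  id <- "ERCC-00128"
  props <- c(10, 15, 25, 40)  # subpool B over pools 12..15
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  expect_equal(nrow(perms), 24L)
  seen_rho <- numeric(0)
  for (k in seq_len(nrow(perms))) {
    sig <- as.numeric(perms[k, ]) + 5   # signal ranks = permutation
    vals <- list(sig); names(vals) <- id
    m <- spearman_monotonicity(do.call(st, vals), analysis_design, id)
    expect_equal(m$rho, rho_d2(props, sig))
    expect_equal(m$monotonic, all(diff(sig) > 0))
    seen_rho <- c(seen_rho, m$rho)
  }
  # only the strictly increasing permutation certifies monotonicity
  expect_equal(sum(seen_rho == 1), 1L)

  # the mis-assignment fingerprint: lowest-proportion pool gives the highest
  # signal, the rest increase; exactly one permutation shows it with rho=-0.2
  hits <- perms[apply(perms, 1, function(r)
    abs(rho_d2(props, r) + 0.2) < 1e-12 && r[1] == 4), ]
  expect_equal(nrow(hits), 1L)
  expect_equal(as.numeric(hits[1, ]), c(4, 1, 2, 3))

  # strictly decreasing
  dec <- list(c(9, 8, 7, 6)); names(dec) <- id
  expect_equal(spearman_monotonicity(do.call(st, dec),
                                     analysis_design, id)$rho, -1)

  # ties are conservatively non-monotonic
  tie <- list(c(5, 5, 6, 7)); names(tie) <- id
  mt <- spearman_monotonicity(do.call(st, tie), analysis_design, id)
  expect_lt(mt$rho, 1)
  expect_false(mt$monotonic)

  expect_error(spearman_monotonicity(do.call(st, dec), analysis_design,
                                     "ERCC-00060"), "constant subpool")
})

test_that("the expected slope curve matches its finite-difference oracle", {
  sim <- noiseless_array()
  cen <- compute_centroids(sim, analysis_design)
  fit <- fit_langmuir(cen, 2^14, 2^5)

  # analytic limits
  fit0 <- fit_langmuir(cen, 2^14, 2^5)
  fit0$bg <- 0
  expect_equal(expected_slope_curve(fit0, log2(fit0$k_d) - 15), 1,
               tolerance = 1e-4)
  expect_lt(expected_slope_curve(fit, log2(fit$k_d) + 15), 1e-3)

  grid <- seq(-3, 23, by = 0.01)
  analytic <- expected_slope_curve(fit, grid)
  numeric_m <- diff(predict_log2(fit, grid)) / 0.01
  centered <- (numeric_m[-1] + numeric_m[-length(numeric_m)]) / 2
  expect_lt(max(abs(analytic[c(-1, -length(analytic))] - centered)), 1e-4)
})

test_that("linear-region bounds match a brute-force grid and move with bg", {
  mkfit <- function(bg, k_d = 1e4, i_max = 2^14) {
    structure(list(i_max = i_max, k_d = k_d, bg = bg, residual_sd = 0.1,
                   ci_level = 0.99, n = 10, platform_class = "array"),
              class = c("langmuir_fit", "dose_response_fit"))
  }
  fit <- mkfit(bg = 2^5)
  region <- linear_region(fit)
  expect_lt(region$lower_log2_abundance, region$upper_log2_abundance)

  # oracle: sign changes of the second difference on a 0.001-step grid
  grid <- seq(log2(1) - log2(10), log2(4 * 2^20) + log2(10), by = 0.001)
  m <- expected_slope_curve(fit, grid)
  s <- sign(diff(m, differences = 2))
  idx <- which(s[-length(s)] * s[-1] < 0)
  bounds <- (grid[idx + 1] + grid[idx + 2]) / 2
  expect_lt(abs(region$lower_log2_abundance - bounds[1]), 0.002)
  expect_lt(abs(region$upper_log2_abundance - bounds[length(bounds)]), 0.002)

  # slope at the interior peak exceeds the slope at both bounds
  interior <- expected_slope_curve(fit, mean(c(region$lower_log2_abundance,
                                               region$upper_log2_abundance)))
  expect_gt(interior,
            expected_slope_curve(fit, region$lower_log2_abundance))
  expect_gt(interior,
            expected_slope_curve(fit, region$upper_log2_abundance))

  # no additive background, no lower inflection
  expect_error(linear_region(mkfit(bg = 0)), class = "region_undefined")

  # the lower bound rises monotonically with background
  lowers <- vapply(c(2^3, 2^5, 2^7), function(bg)
    linear_region(mkfit(bg))$lower_log2_abundance, numeric(1))
  expect_true(all(diff(lowers) > 0))
})

test_that("non-monotonic flagging honors the linear region by platform", {
  mono <- data.frame(control_id = c("low", "mid", "high"),
                     subpool = "B", rho = c(0.8, 0.8, 1),
                     monotonic = c(FALSE, FALSE, TRUE))
  cen <- data.frame(control_id = c("low", "mid", "high"), subpool = "B",
                    mean_log2_abundance = c(1, 9, 12),
                    mean_log2_signal = c(5, 9, 12))
  region <- structure(list(lower_log2_abundance = 4,
                           upper_log2_abundance = 13),
                      class = "linear_region")
  fl <- flag_nonmonotonic_outliers(mono, cen, region, platform = "array")
  expect_equal(fl$is_outlier, c(FALSE, TRUE, FALSE))
  expect_equal(fl$sub_range, c(TRUE, FALSE, FALSE))
  expect_equal(fl$position, c("below", "inside", "inside"),
               ignore_attr = TRUE)

  fl2 <- flag_nonmonotonic_outliers(mono, cen, NULL, platform = "rnaseq")
  expect_equal(fl2$is_outlier, c(TRUE, TRUE, FALSE))
  expect_false(any(fl2$sub_range))
})

test_that("mis-assignment diagnosis recovers the true subpool", {
  # truth C, labeled E: the canonical preparation-error pattern
  sim <- simulate_microarray(design, array_sim_config(seed = 2),
                             anomaly_spec(misassigned = c("ERCC-00113" = "C")))
  diagd <- apply_exclusions(design, honor_reassignment = FALSE)
  cen <- compute_centroids(sim, diagd)
  fit <- fit_langmuir(cen, estimate_imax(sim, diagd),
                      estimate_background(sim))
  m <- spearman_monotonicity(sim, diagd, "ERCC-00113")
  expect_lt(m$rho, 1)
  d <- best_fit_subpool(sim, diagd, fit, "ERCC-00113")
  expect_equal(d$original_subpool, "E")
  expect_equal(d$suggested_subpool, "C")
  expect_false(d$tie)

  # a correctly labeled monotone control suggests its own subpool
  d2 <- best_fit_subpool(sim, diagd, fit, "ERCC-00085")
  expect_equal(d2$suggested_subpool, "B")

  # all-equal signals are ambiguous: original assignment with a tie flag
  flat <- list(rep(8, 4)); names(flat) <- "ERCC-00128"
  d3 <- best_fit_subpool(do.call(st, flat), analysis_design, fit,
                         "ERCC-00128")
  expect_true(d3$tie)
  expect_equal(d3$suggested_subpool, d3$original_subpool)
})

test_that("slope estimates shrink as controls pass the dissociation constant", {
  sim <- simulate_microarray(design,
                             array_sim_config(bg = 0, noise_sd = 0, seed = 1),
                             no_anomalies())
  # original labels so simulated truth and analyzed subpool agree
  labels_design <- apply_exclusions(design, honor_reassignment = FALSE)
  sl <- control_slopes(sim, labels_design)
  # one subpool: distinct base abundances, no exact ties between controls
  sl <- sl[sl$defined & sl$subpool == "B", ]
  sl <- sl[order(sl$mean_log2_abundance), ]
  above <- sl[sl$mean_log2_abundance > log2(1e4), ]
  expect_true(all(diff(above$slope) < 0))
  expect_lt(min(above$slope), 0.5)
  below <- sl[sl$mean_log2_abundance < log2(1e4) - 6, ]
  expect_true(all(below$slope > 0.9))
})
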