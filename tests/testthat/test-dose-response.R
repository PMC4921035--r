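test_that("centroids average log2 abundance and log2 signal over the pools", {
  # ERCC-00128: subpool B, base 16 -> abundances {16, 24, 40, 64}
  tab <- st("ERCC-00128" = c(5, 5.5, 6, 6.5),
            "ERCC-00060" = c(9, 9, 9, 9))       # subpool A, base 1024
  cen <- compute_centroids(tab, analysis_design)
  b <- cen[cen$control_id == "ERCC-00128", ]
  expect_equal(b$mean_log2_abundance, 4.976723, tolerance = 1e-6)
  expect_equal(b$mean_log2_signal, 5.75)
  a <- cen[cen$control_id == "ERCC-00060", ]
  expect_equal(a$mean_log2_abundance, 10)        # constant abundance, exact
  expect_equal(a$subpool, "A")

  # identity response puts every centroid on the identity line
  ids <- c("ERCC-00128", "ERCC-00085", "ERCC-00086")
  vals <- lapply(ids, function(id)
    log2(nominal_abundance(analysis_design, id, pool_order())))
  names(vals) <- ids
  cen2 <- compute_centroids(do.call(st, vals), analysis_design)
  expect_equal(cen2$mean_log2_signal, cen2$mean_log2_abundance)
})

test_that("anchors are derived from the top controls and the omitted control", {
  # most abundant control per pool: E, D, C, B top rungs in pools 12..15
  tops <- c("ERCC-00024", "ERCC-00016", "ERCC-00018", "ERCC-00002")
  flat <- lapply(tops, function(id) rep(NA_real_, 4))
  names(flat) <- tops
  for (i in seq_along(tops)) flat[[i]] <- c(10, 10, 10, 10)
  for (i in seq_along(tops)) flat[[i]][i] <- 14
  low <- list("ERCC-00128" = c(5, 5, 5, 5))
  tab <- do.call(st, c(flat, low))
  expect_equal(estimate_imax(tab, analysis_design), 2^14)

  for (i in seq_along(tops)) flat[[i]][i] <- c(14, 14, 15, 15)[i]
  tab2 <- do.call(st, c(flat, low))
  expect_equal(estimate_imax(tab2, analysis_design), 24576)

  # deep-saturation anchor approaches Imax + bg on simulated data
  sim <- noiseless_array()
  expect_equal(estimate_imax(sim, analysis_design), 2^14 + 2^5,
               tolerance = 0.005)

  # background from the omitted control; rnaseq has no bg term
  bgtab <- st("ERCC-00073" = rep(5.81, 4), "ERCC-00128" = c(6, 7, 8, 9))
  expect_equal(estimate_background(bgtab), 2^5.81)
  rseq <- simulate_rnaseq(design, rnaseq_sim_config(seed = 1))
  expect_equal(estimate_background(rseq), 0)
  expect_equal(estimate_background(bgtab, bg_override = 0), 0)
  no_bg <- st("ERCC-00128" = c(6, 7, 8, 9))
  expect_error(estimate_background(no_bg), "bg_override")
})

test_that("the Langmuir fit recovers Kd and honors the model limits", {
  # centroids placed exactly on the curve: recovery is exact
  oncurve <- data.frame(control_id = sprintf("c%02d", 1:30), subpool = "B",
                        mean_log2_abundance = seq(0, 22, length.out = 30))
  oncurve$mean_log2_signal <-
    log2(2^14 * 2^oncurve$mean_log2_abundance /
           (1e4 + 2^oncurve$mean_log2_abundance) + 2^5)
  fit_exact <- fit_langmuir(oncurve, i_max = 2^14, bg = 2^5)
  expect_equal(fit_exact$k_d, 1e4, tolerance = 1e-6)
  expect_lt(fit_exact$residual_sd, 1e-6)

  # through the simulator: the centroid averages log2 signal over four
  # abundances, so the curve's bends leave a small but nonzero residual
  sim <- noiseless_array()
  cen <- compute_centroids(sim, analysis_design)
  fit <- fit_langmuir(cen, i_max = 2^14, bg = 2^5)
  expect_equal(fit$k_d, 1e4, tolerance = 1e-3)
  expect_lt(fit$residual_sd, 0.05)

  # midpoint and saturation limits of the fitted curve
  expect_equal(2^predict_log2(fit, log2(fit$k_d)) - fit$bg, fit$i_max / 2,
               tolerance = 1e-6)
  expect_equal(2^predict_log2(fit, 40), fit$i_max + fit$bg, tolerance = 1e-3)

  # fitted curve is strictly increasing across the full ladder
  grid <- seq(-4, 24, by = 0.05)
  expect_true(all(diff(predict_log2(fit, grid)) > 0))

  expect_error(fit_langmuir(cen[1:2, ], 2^14, 2^5), "at least 3")
})

test_that("the analytic Kd matches a dense grid-search oracle", {
  for (seed in 1:3) {
    sim <- simulate_microarray(design,
                               array_sim_config(noise_sd = 0.1, seed = seed),
                               no_anomalies())
    cen <- compute_centroids(sim, analysis_design)
    i_max <- estimate_imax(sim, analysis_design)
    bg <- estimate_background(sim)
    fit <- fit_langmuir(cen, i_max, bg)

    grid <- seq(-2, 8, by = 0.001)
    c_lin <- 2^cen$mean_log2_abundance
    ssr <- vapply(grid, function(g) {
      pred <- log2(i_max * c_lin / (10^g + c_lin) + bg)
      sum((cen$mean_log2_signal - pred)^2)
    }, numeric(1))
    expect_lt(abs(log10(fit$k_d) - grid[which.min(ssr)]), 0.001 + 1e-9)
  }
})

test_that("the unit-slope fit equals its closed form and translates exactly", {
  cen <- data.frame(control_id = c("a", "b", "c"), subpool = "B",
                    mean_log2_abundance = c(2, 5, 9),
                    mean_log2_signal = c(5, 8, 12))
  fit <- fit_linear_unit_slope(cen)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$residual_sd, 0)

  cen2 <- data.frame(control_id = c("a", "b"), subpool = "B",
                     mean_log2_abundance = c(0, 0),
                     mean_log2_signal = c(1, -1))
  fit2 <- fit_linear_unit_slope(cen2)
  expect_equal(fit2$intercept, 0)
  expect_equal(fit2$residual_sd, sqrt(2))

  # independent route: intercept-only least squares on the offsets
  sim <- simulate_rnaseq(design, rnaseq_sim_config(seed = 5))
  cen3 <- compute_centroids(sim, apply_exclusions(design))
  fit3 <- fit_linear_unit_slope(cen3)
  lmfit <- lm(I(mean_log2_signal - mean_log2_abundance) ~ 1, data = cen3)
  expect_equal(fit3$intercept, unname(coef(lmfit)[1]))

  shifted <- cen3
  shifted$mean_log2_signal <- shifted$mean_log2_signal + 2.5
  expect_equal(fit_linear_unit_slope(shifted)$intercept, fit3$intercept + 2.5)
  expect_equal(fit_linear_unit_slope(shifted)$residual_sd, fit3$residual_sd)
})

test_that("response outliers are flagged outside the t-based band", {
  cen <- data.frame(control_id = sprintf("c%02d", 1:40), subpool = "B",
                    mean_log2_abundance = seq(1, 14, length.out = 40))
  set.seed(11)
  cen$mean_log2_signal <- cen$mean_log2_abundance + 2 +
    rnorm(40, sd = 0.05)
  fit0 <- fit_linear_unit_slope(cen)

  # all-zero residuals: nothing flagged
  clean <- cen
  clean$mean_log2_signal <- clean$mean_log2_abundance + 2
  flags0 <- flag_response_outliers(fit_linear_unit_slope(clean), clean)
  expect_false(any(flags0$is_outlier))

  # a single control pushed 10 residual SDs off the curve is the only flag
  bumped <- cen
  bumped$mean_log2_signal[17] <- bumped$mean_log2_signal[17] +
    10 * fit0$residual_sd
  fitb <- fit_linear_unit_slope(bumped)
  flags <- flag_response_outliers(fitb, bumped)
  expect_equal(flags$control_id[flags$is_outlier], "c17")

  # confidence band is narrower than the prediction band by sqrt(n)
  fp <- flag_response_outliers(fitb, bumped, band = "prediction")
  fc <- flag_response_outliers(fitb, bumped, band = "confidence")
  expect_equal(attr(fp, "half_width") / attr(fc, "half_width"),
               sqrt(fitb$n))
})
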