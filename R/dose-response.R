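#' Per-control centroids (dose-response mid-points)
#'
#' The mid-point of each control's dose-response curve: the average over the
#' four pools of log2 nominal abundance against the average of log2 signal.
#' These centroids, one per detected control, are the points the platform
#' dose-response model is fit to.
#'
#' @param signals A \code{signal_table}.
#' @param design An \code{ercc_design}, normally with exclusions applied.
#' @param include_subpool_a Include the constant (1-to-1) subpool-A controls;
#'   their centroid abundance is their single abundance. Default \code{TRUE}.
#' @return data.frame with control_id, subpool, mean_log2_abundance,
#'   mean_log2_signal, one row per detected control.
#' @export
compute_centroids <- function(signals, design, include_subpool_a = TRUE) {
  collapsed <- collapse_replicates(signals)
  rec <- design$records[design$records$subpool != "omitted", ]
  if (!include_subpool_a) rec <- rec[rec$subpool != "A", ]
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    id <- rec$control_id[i]
    if (detection_status(signals, id, design$pools) != "detected") return(NULL)
    ab <- nominal_abundance(design, id, design$pools)
    sig <- collapsed$mean_log2_signal[collapsed$control_id == id]
    sig <- sig[match(design$pools,
                     collapsed$pool[collapsed$control_id == id])]
    data.frame(control_id = id, subpool = rec$subpool[i],
               mean_log2_abundance = mean(log2(ab)),
               mean_log2_signal = mean(sig))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(control_id = character(), subpool = character(),
                      mean_log2_abundance = numeric(),
                      mean_log2_signal = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Saturation-intensity anchor
#'
#' Experimental anchor for the saturation plateau: in each pool, take the
#' detected control with the highest nominal abundance, convert its mean
#' log2 signal to linear intensity, and average the four linear values.
#' Deep in saturation this approaches Imax + bg.
#'
#' @inheritParams compute_centroids
#' @return Linear-scale intensity anchor (scalar).
#' @export
estimate_imax <- function(signals, design) {
  collapsed <- collapse_replicates(signals)
  rec <- design$records[design$records$subpool != "omitted", ]
  tops <- vapply(design$pools, function(p) {
    sub <- collapsed[collapsed$pool == p &
                     collapsed$control_id %in% rec$control_id, ]
    if (nrow(sub) == 0L) {
      stop("pool ", p, " has no detected controls; cannot anchor Imax")
    }
    ab <- vapply(sub$control_id, function(id)
      nominal_abundance(design, id, p), numeric(1))
    2^sub$mean_log2_signal[which.max(ab)]
  }, numeric(1))
  mean(tops)
}

#' Background anchor from the omitted control
#'
#' ERCC-00073 is left out of every pool, so on arrays its probe reports pure
#' background; the anchor is the mean of its linear-scale signal across
#' pools and replicates. Sequencing has no additive background term (an
#' absent transcript simply yields zero counts), so the anchor is 0.
#'
#' @param signals A \code{signal_table}.
#' @param bg_override Optional fixed background (linear scale), e.g. 0 to
#'   fit arrays without a background term.
#' @param omitted_id Identifier of the omitted control.
#' @return Linear-scale background anchor (scalar).
#' @export
estimate_background <- function(signals, bg_override = NULL,
                                omitted_id = "ERCC-00073") {
  if (!is.null(bg_override)) return(bg_override)
  if (platform_class(signals) == "rnaseq") return(0)
  rows <- signals$signal[signals$control_id == omitted_id]
  if (length(rows) == 0L) {
    stop("no ", omitted_id, " rows in the array signal table; ",
         "supply bg_override to set the background anchor explicitly")
  }
  mean(2^rows)
}

langmuir_intensity <- function(abundance, i_max, k_d, bg) {
  i_max * abundance / (k_d + abundance) + bg
}

#' Fit the Langmuir dose-response model (arrays)
#'
#' Hybridization signal saturates with analyte concentration following a
#' Langmuir isotherm, I = Imax * C / (Kd + C) + bg. Imax and bg are fixed at
#' their experimentally derived anchors; the dissociation constant Kd is the
#' single free parameter, chosen to minimize the sum of squared log2
#' residuals over the centroids. Fitting in log2 space weights the 2^20
#' abundance range evenly.
#'
#' @param centroids Output of \code{\link{compute_centroids}} (>= 3 rows).
#' @param i_max,bg Linear-scale anchors (see \code{\link{estimate_imax}},
#'   \code{\link{estimate_background}}).
#' @param ci_level Interval level used downstream for outlier flagging.
#' @param log10_kd_range Search bracket for log10 Kd.
#' @return Object of class \code{c("langmuir_fit", "dose_response_fit")}:
#'   list with i_max, k_d, bg, residual_sd (RMS log2 residual, df = n - 1),
#'   ci_level, n.
#' @export
fit_langmuir <- function(centroids, i_max, bg, ci_level = 0.99,
                         log10_kd_range = c(-2, 8)) {
  if (nrow(centroids) < 3L) stop("need at least 3 centroids to fit Kd")
  c_lin <- 2^centroids$mean_log2_abundance
  s_log2 <- centroids$mean_log2_signal
  objective <- function(log10_kd) {
    pred <- log2(langmuir_intensity(c_lin, i_max, 10^log10_kd, bg))
    sum((s_log2 - pred)^2)
  }
  opt <- stats::optimize(objective, interval = log10_kd_range, tol = 1e-7)
  at_edge <- min(abs(opt$minimum - log10_kd_range)) < 1e-3
  if (at_edge) {
    stop(sprintf(paste0("Langmuir fit did not converge inside the bracket: ",
                        "log10 Kd = %.3f at bracket [%g, %g], SSR = %.4g"),
                 opt$minimum, log10_kd_range[1], log10_kd_range[2],
                 opt$objective))
  }
  k_d <- 10^opt$minimum
  n <- nrow(centroids)
  structure(
    list(i_max = i_max, k_d = k_d, bg = bg,
         residual_sd = sqrt(opt$objective / (n - 1)),
         ci_level = ci_level, n = n, platform_class = "array"),
    class = c("langmuir_fit", "dose_response_fit")
  )
}

#' Fit the unit-slope linear model (RNA-Seq)
#'
#' Sequencing signal is proportional to concentration over its whole range,
#' so the dose-response model is a line of slope 1 in log2-log2 space with
#' a fitted intercept: the closed-form least-squares intercept is the mean
#' of (log2 signal - log2 abundance) over the centroids.
#'
#' @param centroids Output of \code{\link{compute_centroids}} (>= 2 rows).
#' @param ci_level Interval level used downstream for outlier flagging.
#' @return Object of class \code{c("unit_slope_fit", "dose_response_fit")}:
#'   list with intercept, slope (always 1), residual_sd (df = n - 1),
#'   ci_level, n.
#' @export
fit_linear_unit_slope <- function(centroids, ci_level = 0.99) {
  if (nrow(centroids) < 2L) stop("need at least 2 centroids")
  offsets <- centroids$mean_log2_signal - centroids$mean_log2_abundance
  intercept <- mean(offsets)
  n <- length(offsets)
  structure(
    list(intercept = intercept, slope = 1,
         residual_sd = sqrt(sum((offsets - intercept)^2) / (n - 1)),
         ci_level = ci_level, n = n, platform_class = "rnaseq"),
    class = c("unit_slope_fit", "dose_response_fit")
  )
}

#' Fitted log2 signal at given log2 abundances
#'
#' @param fit A \code{dose_response_fit}.
#' @param log2_abundance Numeric vector of log2 nominal abundances.
#' @return Numeric vector of predicted log2 signals.
#' @export
predict_log2 <- function(fit, log2_abundance) UseMethod("predict_log2")

#' @export
predict_log2.langmuir_fit <- function(fit, log2_abundance) {
  log2(langmuir_intensity(2^log2_abundance, fit$i_max, fit$k_d, fit$bg))
}

#' @export
predict_log2.unit_slope_fit <- function(fit, log2_abundance) {
  log2_abundance + fit$intercept
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("Langmuir dose-response fit (array)\n")
  cat(sprintf("  Imax = %.4g  Kd = %.4g  bg = %.4g (linear scale)\n",
              x$i_max, x$k_d, x$bg))
  cat(sprintf("  residual SD = %.4f log2 units over %d centroids (CI %.0f%%)\n",
              x$residual_sd, x$n, 100 * x$ci_level))
  invisible(x)
}

#' @export
print.unit_slope_fit <- function(x, ...) {
  cat("Unit-slope linear dose-response fit (RNA-Seq)\n")
  cat(sprintf("  intercept = %.4f (slope fixed at 1)\n", x$intercept))
  cat(sprintf("  residual SD = %.4f log2 units over %d centroids (CI %.0f%%)\n",
              x$residual_sd, x$n, 100 * x$ci_level))
  invisible(x)
}

#' Flag response-curve outliers
#'
#' A control is an outlier when its centroid falls outside the fit's
#' interval: |log2 residual| greater than t(1 - (1-ci)/2, df = n - 1) times
#' the residual SD. The default is a prediction-style band on individual
#' controls; \code{band = "confidence"} shrinks the half-width by sqrt(n)
#' to a band on the mean curve.
#'
#' @param fit A \code{dose_response_fit}.
#' @param centroids Centroids to assess (need not be the fitting set).
#' @param ci_level Interval level; defaults to the fit's.
#' @param band \code{"prediction"} (default) or \code{"confidence"}.
#' @return data.frame with control_id, signed_residual (log2), is_outlier,
#'   and the band half_width as an attribute.
#' @export
flag_response_outliers <- function(fit, centroids, ci_level = fit$ci_level,
                                   band = c("prediction", "confidence")) {
  band <- match.arg(band)
  resid <- centroids$mean_log2_signal -
    predict_log2(fit, centroids$mean_log2_abundance)
  half_width <- stats::qt(1 - (1 - ci_level) / 2, df = fit$n - 1) *
    fit$residual_sd
  if (band == "confidence") half_width <- half_width / sqrt(fit$n)
  out <- data.frame(
    control_id = centroids$control_id,
    signed_residual = resid,
    is_outlier = abs(resid) > half_width
  )
  attr(out, "half_width") <- half_width
  out
}
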