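#' Bland-Altman (MA) points for a pool pair
#'
#' For every control detected in both pools, M is the log2 ratio of its
#' (replicate-collapsed) signals and A the average of the two log2 signals
#' -- the MA-plot convention. Setting \code{ma = FALSE} gives the literal
#' Bland-Altman abscissa, the log2 of the mean of the linear signals.
#' The design's nominal log2 ratio for the control's subpool rides along
#' for comparison: titrated subpools contribute fold changes up to 4, the
#' constant subpool A the 1-to-1 component.
#'
#' @param signals A \code{signal_table}.
#' @param design An \code{ercc_design} (exclusions applied).
#' @param pool_i,pool_j Distinct pool labels; M is pool_i over pool_j.
#' @param ma Use mean-of-logs for A (default) rather than log-of-means.
#' @return data.frame with control_id, subpool, m_value, a_value,
#'   nominal_log2_ratio, mean_log2_abundance (average of the control's two
#'   nominal log2 abundances, used to place the point in the dynamic range).
#' @export
bland_altman <- function(signals, design, pool_i, pool_j, ma = TRUE) {
  pool_i <- as.character(pool_i); pool_j <- as.character(pool_j)
  if (identical(pool_i, pool_j)) stop("pool_i and pool_j must differ")
  collapsed <- collapse_replicates(signals)
  rec <- design$records[design$records$subpool != "omitted", ]
  rows <- lapply(seq_len(nrow(rec)), function(k) {
    id <- rec$control_id[k]
    sub <- collapsed[collapsed$control_id == id, ]
    si <- sub$mean_log2_signal[sub$pool == pool_i]
    sj <- sub$mean_log2_signal[sub$pool == pool_j]
    if (length(si) != 1L || length(sj) != 1L) return(NULL)
    sp <- rec$subpool[k]
    a <- if (ma) (si + sj) / 2 else log2((2^si + 2^sj) / 2)
    ab <- nominal_abundance(design, id, c(pool_i, pool_j))
    data.frame(control_id = id, subpool = sp,
               m_value = si - sj, a_value = a,
               nominal_log2_ratio = log2(pairwise_ratio(design, sp,
                                                        pool_i, pool_j)),
               mean_log2_abundance = mean(log2(ab)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(control_id = character(), subpool = character(),
                      m_value = numeric(), a_value = numeric(),
                      nominal_log2_ratio = numeric(),
                      mean_log2_abundance = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Model-derived expected ratio curve
#'
#' For a nominal fold change f, trace (A, M) parametrically over
#' concentration using the fitted dose-response model: M(C) = log2 I(fC) -
#' log2 I(C) and A(C) = (log2 I(fC) + log2 I(C)) / 2. For the Langmuir
#' model the curve shows the characteristic ratio compression: M tends to 0
#' at low A (the additive background enters both signals) and at high A
#' (both signals saturate), reaching log2 f only in the linear interior.
#' For the unit-slope RNA-Seq model there is no saturation and the expected
#' curve is the constant M = log2 f.
#'
#' @param fit A \code{dose_response_fit}.
#' @param fold Nominal fold change (> 0); f = 1 traces the 1-to-1 curve.
#' @param abundance_range Linear-scale concentration range to trace.
#' @param n Number of grid points (log2-spaced).
#' @return data.frame with columns log2_abundance, a_value, m_value,
#'   sorted by a_value; attribute \code{fold}.
#' @export
expected_ratio_curve <- function(fit, fold, abundance_range = c(1e-2, 1e8),
                                 n = 2000L) {
  UseMethod("expected_ratio_curve")
}

#' @export
expected_ratio_curve.langmuir_fit <- function(fit, fold,
                                              abundance_range = c(1e-2, 1e8),
                                              n = 2000L) {
  x <- seq(log2(abundance_range[1]), log2(abundance_range[2]),
           length.out = n)
  hi <- predict_log2(fit, x + log2(fold))
  lo <- predict_log2(fit, x)
  out <- data.frame(log2_abundance = x,
                    a_value = (hi + lo) / 2,
                    m_value = hi - lo)
  out <- out[order(out$a_value), ]
  rownames(out) <- NULL
  attr(out, "fold") <- fold
  out
}

#' @export
expected_ratio_curve.unit_slope_fit <- function(fit, fold,
                                                abundance_range = c(1e-2, 1e8),
                                                n = 2000L) {
  x <- seq(log2(abundance_range[1]), log2(abundance_range[2]),
           length.out = n)
  out <- data.frame(log2_abundance = x,
                    a_value = predict_log2(fit, x) + log2(fold) / 2,
                    m_value = rep(log2(fold), n))
  attr(out, "fold") <- fold
  out
}

#' Ratio recovery summary per nominal fold
#'
#' How closely observed ratios approach the design's target ratios, split
#' by whether a control lies inside the linear region (by its pair-average
#' nominal abundance) or outside it: per nominal fold, the median observed
#' M and the median absolute deviation of M from log2 f.
#'
#' @param points Output of \code{\link{bland_altman}}.
#' @param region A \code{linear_region}, or NULL to summarize without the
#'   inside/outside split (RNA-Seq).
#' @return data.frame with nominal_log2_ratio, location
#'   (\code{"inside"}/\code{"outside"}/\code{"all"}), n, median_m,
#'   median_abs_error.
#' @export
ratio_recovery_summary <- function(points, region = NULL) {
  if (is.null(region)) {
    points$location <- "all"
  } else {
    inside <- points$mean_log2_abundance >= region$lower_log2_abundance &
      points$mean_log2_abundance <= region$upper_log2_abundance
    points$location <- ifelse(inside, "inside", "outside")
  }
  groups <- split(points, list(points$nominal_log2_ratio, points$location),
                  drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(nominal_log2_ratio = g$nominal_log2_ratio[1],
               location = g$location[1],
               n = nrow(g),
               median_m = stats::median(g$m_value),
               median_abs_error = stats::median(abs(g$m_value -
                                                    g$nominal_log2_ratio[1])))
  }))
  out <- out[order(out$nominal_log2_ratio, out$location), ]
  rownames(out) <- NULL
  out
}
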