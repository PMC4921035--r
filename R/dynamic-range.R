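#' Range from per-sample extremes
#'
#' The arithmetic behind a dynamic-range row: range = max - min, with the
#' range's uncertainty combined from the min and max SDs in quadrature,
#' sd = sqrt(sd_min^2 + sd_max^2).
#'
#' @param min_mean,min_sd Mean and SD (across samples) of the per-sample
#'   minimum log2 signal.
#' @param max_mean,max_sd Same for the per-sample maximum.
#' @return List with range_mean, range_sd.
#' @export
range_from_extremes <- function(min_mean, min_sd, max_mean, max_sd) {
  list(range_mean = max_mean - min_mean,
       range_sd = sqrt(min_sd^2 + max_sd^2))
}

#' Dynamic-range coverage summary
#'
#' For each sample (pool), the minimum and maximum log2 signal over the
#' detected members of a subset of transcripts (the spike-in controls, or
#' an endogenous background set supplied as its own signal table); reported
#' as mean +/- SD across the samples, with the range derived by
#' \code{\link{range_from_extremes}}. On arrays the omitted control's level
#' (pure background) is summarized alongside.
#'
#' @param signals A \code{signal_table}.
#' @param controls Optional character vector restricting the subset; default
#'   all controls present except the omitted one.
#' @param subset_label Label carried into the output ("ERCC", "BKGD", ...).
#' @param omitted_id Identifier of the omitted control (arrays); its rows are
#'   excluded from the min/max and summarized separately when present.
#' @return List of class \code{range_summary}: subset, n_samples,
#'   min_mean/min_sd, max_mean/max_sd, range_mean/range_sd,
#'   omitted_mean/omitted_sd (NA when the omitted control is absent).
#' @export
range_summary <- function(signals, controls = NULL, subset_label = "ERCC",
                          omitted_id = "ERCC-00073") {
  collapsed <- collapse_replicates(signals)
  omitted_rows <- collapsed[collapsed$control_id == omitted_id, ]
  collapsed <- collapsed[collapsed$control_id != omitted_id, ]
  if (!is.null(controls)) {
    collapsed <- collapsed[collapsed$control_id %in% controls, ]
  }
  if (nrow(collapsed) == 0L) stop("empty subset: no signals to summarize")
  pools <- sort(unique(collapsed$pool))
  mins <- vapply(pools, function(p)
    min(collapsed$mean_log2_signal[collapsed$pool == p]), numeric(1))
  maxs <- vapply(pools, function(p)
    max(collapsed$mean_log2_signal[collapsed$pool == p]), numeric(1))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  rng <- range_from_extremes(mean(mins), sd0(mins), mean(maxs), sd0(maxs))
  structure(list(
    subset = subset_label,
    n_samples = length(pools),
    min_mean = mean(mins), min_sd = sd0(mins),
    max_mean = mean(maxs), max_sd = sd0(maxs),
    range_mean = rng$range_mean, range_sd = rng$range_sd,
    omitted_mean = if (nrow(omitted_rows)) mean(omitted_rows$mean_log2_signal)
                   else NA_real_,
    omitted_sd = if (nrow(omitted_rows) > 1L)
                   stats::sd(omitted_rows$mean_log2_signal) else
                   if (nrow(omitted_rows) == 1L) 0 else NA_real_
  ), class = "range_summary")
}

#' @export
print.range_summary <- function(x, ...) {
  cat(sprintf("Dynamic range coverage [%s], %d samples\n",
              x$subset, x$n_samples))
  if (!is.na(x$omitted_mean)) {
    cat(sprintf("  omitted control: %.2f +/- %.2f\n",
                x$omitted_mean, x$omitted_sd))
  }
  cat(sprintf("  min %.2f +/- %.2f   max %.2f +/- %.2f   range %.2f +/- %.2f\n",
              x$min_mean, x$min_sd, x$max_mean, x$max_sd,
              x$range_mean, x$range_sd))
  invisible(x)
}

#' Range summary as a one-row data.frame
#' @param x A \code{range_summary}.
#' @param ... Unused.
#' @return data.frame mirroring the dynamic-range table columns.
#' @export
as.data.frame.range_summary <- function(x, ...) {
  data.frame(subset = x$subset, n_samples = x$n_samples,
             omitted_mean = x$omitted_mean, omitted_sd = x$omitted_sd,
             min_mean = x$min_mean, min_sd = x$min_sd,
             max_mean = x$max_mean, max_sd = x$max_sd,
             range_mean = x$range_mean, range_sd = x$range_sd)
}
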