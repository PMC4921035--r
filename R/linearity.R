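#' Per-control dose-response slope
#'
#' Ordinary least-squares slope of log2 signal against log2 nominal
#' abundance over a control's (up to) four pool measurements. A slope of 1
#' is the ideal proportional response; slopes shrink toward 0 as a control
#' approaches the additive-background floor or hybridization saturation.
#' Subpool-A controls sit at a single abundance, so their slope is
#' undefined.
#'
#' @param signals A \code{signal_table}.
#' @param design An \code{ercc_design} (exclusions applied).
#' @param control_id ERCC identifier of a detected control.
#' @return List with control_id, slope, defined.
#' @export
control_slope <- function(signals, design, control_id) {
  ab <- log2(nominal_abundance(design, control_id, design$pools))
  if (length(unique(ab)) == 1L) {
    return(list(control_id = control_id, slope = NA_real_, defined = FALSE))
  }
  collapsed <- collapse_replicates(signals)
  sub <- collapsed[collapsed$control_id == control_id, ]
  sig <- sub$mean_log2_signal[match(design$pools, sub$pool)]
  keep <- !is.na(sig)
  slope <- stats::cov(ab[keep], sig[keep]) / stats::var(ab[keep])
  list(control_id = control_id, slope = slope, defined = TRUE)
}

#' Slopes for every detected control
#'
#' @inheritParams control_slope
#' @return data.frame with control_id, subpool, mean_log2_abundance,
#'   slope, defined.
#' @export
control_slopes <- function(signals, design) {
  rec <- design$records[design$records$subpool != "omitted", ]
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    id <- rec$control_id[i]
    if (detection_status(signals, id, design$pools) != "detected") return(NULL)
    s <- control_slope(signals, design, id)
    data.frame(control_id = id, subpool = rec$subpool[i],
               mean_log2_abundance =
                 mean(log2(nominal_abundance(design, id, design$pools))),
               slope = s$slope, defined = s$defined)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman monotonicity of a titrated control
#'
#' Signal from a titrated (subpool B-E) control should increase strictly
#' with its pool mixing proportion, 10 % < 15 % < 25 % < 40 %. Monotonicity
#' is certified by Spearman's rho between proportion and signal over the
#' four pools: rho = 1 means strictly monotone; any inversion or tie gives
#' rho < 1. With n = 4 no formal test is attempted -- rho is a screen, not
#' a statistic with a null distribution.
#'
#' @param signals A \code{signal_table}.
#' @param design An \code{ercc_design} (exclusions applied).
#' @param control_id A detected, titrated control (subpool A is excluded:
#'   constant proportion has no rank order).
#' @param subpool Optional subpool label to evaluate the control under
#'   (used when diagnosing mis-assignment); default its design subpool.
#' @return List with control_id, rho, monotonic.
#' @export
spearman_monotonicity <- function(signals, design, control_id,
                                  subpool = NULL) {
  i <- match(control_id, design$records$control_id)
  if (is.na(i)) stop("unknown control: ", control_id)
  if (is.null(subpool)) {
    subpool <- effective_subpool(design$records[i, ])
  }
  if (subpool == "A") {
    stop(control_id, " is in the constant subpool; monotonicity is undefined")
  }
  props <- vapply(design$pools, function(p)
    proportion_of(design, subpool, p), numeric(1))
  collapsed <- collapse_replicates(signals)
  sub <- collapsed[collapsed$control_id == control_id, ]
  sig <- sub$mean_log2_signal[match(design$pools, sub$pool)]
  rho <- suppressWarnings(stats::cor(props, sig, method = "spearman"))
  list(control_id = control_id, rho = rho,
       monotonic = isTRUE(rho == 1))
}

#' Monotonicity for every detected titrated control
#'
#' @inheritParams spearman_monotonicity
#' @return data.frame with control_id, subpool, rho, monotonic.
#' @export
monotonicity_table <- function(signals, design) {
  rec <- design$records[!design$records$subpool %in% c("omitted", "A"), ]
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    id <- rec$control_id[i]
    if (detection_status(signals, id, design$pools) != "detected") return(NULL)
    m <- spearman_monotonicity(signals, design, id)
    data.frame(control_id = id, subpool = rec$subpool[i],
               rho = m$rho, monotonic = m$monotonic)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected slope curve from the Langmuir model
#'
#' The first derivative of the fitted model in log2-log2 space,
#' m(C) = d log2 I / d log2 C = (C / I) * Imax * Kd / (Kd + C)^2,
#' is the slope an ideally behaving control at abundance C should show:
#' near 1 in the linear regime, falling to 0 in saturation, and (with an
#' additive background) also falling to 0 at low abundance.
#'
#' @param fit A \code{langmuir_fit}.
#' @param log2_abundance Grid of log2 abundances.
#' @return Numeric vector of expected slopes.
#' @export
expected_slope_curve <- function(fit, log2_abundance) {
  c_lin <- 2^log2_abundance
  i <- langmuir_intensity(c_lin, fit$i_max, fit$k_d, fit$bg)
  (c_lin / i) * fit$i_max * fit$k_d / (fit$k_d + c_lin)^2
}

#' Demarcate the linear region of the dynamic range
#'
#' The expected-slope curve rises from 0 (background-dominated), peaks, and
#' falls back to 0 (saturation). Its two inflection points -- sign changes
#' of the second difference of m(log2 C) on a dense grid -- bound the
#' region where a linear response can be expected. The grid covers the
#' design ladder extended one decade on each side, at step 0.01 in log2 C,
#' refined to 0.001 around each sign change.
#'
#' With bg = 0 the low-abundance side has no inflection (the curve is a
#' falling logistic) and the region is undefined; an error of class
#' \code{region_undefined} is raised.
#'
#' @param fit A \code{langmuir_fit}.
#' @param abundance_range Linear-scale abundance range of the design ladder;
#'   default 1 to 4 * 2^20 (lowest rung to highest rung at 40 %).
#' @param step Coarse grid step in log2 C.
#' @return Object of class \code{linear_region}: list with
#'   lower_log2_abundance, upper_log2_abundance.
#' @export
linear_region <- function(fit, abundance_range = c(1, 4 * 2^20),
                          step = 0.01) {
  lo <- log2(abundance_range[1]) - log2(10)
  hi <- log2(abundance_range[2]) + log2(10)
  grid <- seq(lo, hi, by = step)
  changes <- slope_curvature_changes(fit, grid)
  if (length(changes) < 2L) {
    stop(structure(
      class = c("region_undefined", "error", "condition"),
      list(message = sprintf(paste0(
        "linear region undefined: %d curvature sign change(s) on the grid ",
        "(an additive background is required for the lower inflection)"),
        length(changes)), call = sys.call(-1))))
  }
  bounds <- vapply(c(changes[1], changes[length(changes)]), function(x0) {
    fine <- seq(x0 - 2 * step, x0 + 2 * step, by = step / 10)
    fc <- slope_curvature_changes(fit, fine)
    if (length(fc)) fc[which.min(abs(fc - x0))] else x0
  }, numeric(1))
  structure(list(lower_log2_abundance = bounds[1],
                 upper_log2_abundance = bounds[2]),
            class = "linear_region")
}

# Grid locations (midpoints) where the second difference of the expected
# slope changes sign.
slope_curvature_changes <- function(fit, grid) {
  m <- expected_slope_curve(fit, grid)
  d2 <- diff(m, differences = 2)
  s <- sign(d2)
  idx <- which(s[-length(s)] * s[-1] < 0)
  # second difference d2[i] is centered on grid[i + 1]
  (grid[idx + 1] + grid[idx + 2]) / 2
}

#' @export
print.linear_region <- function(x, ...) {
  cat(sprintf("linear region: log2 abundance in [%.2f, %.2f] (span %.2f)\n",
              x$lower_log2_abundance, x$upper_log2_abundance,
              x$upper_log2_abundance - x$lower_log2_abundance))
  invisible(x)
}

#' Flag non-monotonic controls as outliers
#'
#' On arrays, a non-monotonic control is only an outlier if it lies inside
#' the linear region, where a monotone response was to be expected;
#' non-monotonic controls below the lower bound merely mark the detection
#' floor and are listed as \code{sub_range}, not as outliers. On RNA-Seq
#' there is no saturation model and every non-monotonic control is flagged.
#'
#' @param monotonicity Output of \code{\link{monotonicity_table}}.
#' @param centroids Output of \code{\link{compute_centroids}} (supplies each
#'   control's position in the dynamic range).
#' @param region A \code{linear_region} (arrays) or NULL (rnaseq).
#' @param platform \code{"array"} or \code{"rnaseq"}.
#' @param rule \code{"centroid"} places a control by its centroid abundance;
#'   \code{"any-point"} treats it as inside the region if any of its four
#'   abundances falls inside.
#' @param design,signals Needed for \code{rule = "any-point"}.
#' @return data.frame with control_id, rho, monotonic, position
#'   (\code{"inside"}, \code{"below"}, \code{"above"}, or \code{NA} for
#'   rnaseq), is_outlier, sub_range.
#' @export
flag_nonmonotonic_outliers <- function(monotonicity, centroids, region,
                                       platform = c("array", "rnaseq"),
                                       rule = c("centroid", "any-point"),
                                       design = NULL, signals = NULL) {
  platform <- match.arg(platform)
  rule <- match.arg(rule)
  out <- monotonicity
  out <- out[out$control_id %in% centroids$control_id, ]
  if (platform == "rnaseq") {
    out$position <- NA_character_
    out$is_outlier <- !out$monotonic
    out$sub_range <- FALSE
    return(out)
  }
  position_of <- function(id) {
    if (rule == "centroid") {
      x <- centroids$mean_log2_abundance[match(id, centroids$control_id)]
      lo <- x; hi <- x
    } else {
      ab <- log2(nominal_abundance(design, id, design$pools))
      lo <- min(ab); hi <- max(ab)
    }
    if (hi < region$lower_log2_abundance) "below"
    else if (lo > region$upper_log2_abundance) "above"
    else "inside"
  }
  out$position <- vapply(out$control_id, position_of, character(1))
  out$is_outlier <- !out$monotonic & out$position == "inside"
  out$sub_range <- !out$monotonic & out$position == "below"
  out
}

#' Diagnose a suspected subpool mis-assignment
#'
#' A control whose signal pattern contradicts its labeled subpool (the
#' hallmark: the lowest-proportion pool yields the highest signal, giving
#' rho = -0.2) may have been prepared into a different subpool. For each
#' candidate subpool B-E, the control's rho is recomputed under that
#' subpool's mixing proportions and its squared log2 residuals against the
#' platform fit are summed over the four pools; the suggested assignment
#' maximizes rho, with ties broken by the smaller residual sum. When every
#' candidate ties (e.g. all-equal signals), the original assignment is
#' returned with \code{tie = TRUE}.
#'
#' @param signals A \code{signal_table}.
#' @param design An \code{ercc_design} (exclusions applied).
#' @param fit A \code{dose_response_fit} for the platform.
#' @param control_id A detected titrated control.
#' @return List with control_id, original_subpool, suggested_subpool, tie,
#'   and an evidence data.frame (subpool, rho, residual_ss).
#' @export
best_fit_subpool <- function(signals, design, fit, control_id) {
  i <- match(control_id, design$records$control_id)
  if (is.na(i)) stop("unknown control: ", control_id)
  original <- effective_subpool(design$records[i, ])
  base <- design$records$base_abundance[i]
  collapsed <- collapse_replicates(signals)
  sub <- collapsed[collapsed$control_id == control_id, ]
  sig <- sub$mean_log2_signal[match(design$pools, sub$pool)]
  candidates <- c("B", "C", "D", "E")
  evidence <- do.call(rbind, lapply(candidates, function(sp) {
    props <- vapply(design$pools, function(p)
      proportion_of(design, sp, p), numeric(1))
    ab <- base * props / 10
    rho <- suppressWarnings(stats::cor(props, sig, method = "spearman"))
    resid <- sig - predict_log2(fit, log2(ab))
    data.frame(subpool = sp, rho = rho, residual_ss = sum(resid^2))
  }))
  if (all(is.na(evidence$rho))) {
    return(list(control_id = control_id, original_subpool = original,
                suggested_subpool = original, tie = TRUE,
                evidence = evidence))
  }
  best_rho <- max(evidence$rho, na.rm = TRUE)
  top <- evidence[!is.na(evidence$rho) & evidence$rho == best_rho, ]
  tie <- nrow(top) > 1L
  suggested <- top$subpool[which.min(top$residual_ss)]
  list(control_id = control_id, original_subpool = original,
       suggested_subpool = suggested, tie = tie, evidence = evidence)
}
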