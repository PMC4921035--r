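#' Assessment run configuration
#'
#' @param platform \code{"array"} or \code{"rnaseq"}; selects the
#'   dose-response model (Langmuir vs unit-slope linear) and the
#'   non-monotonic flagging rule.
#' @param signals A \code{signal_table}, or a path read via
#'   \code{\link{read_signals}}.
#' @param design An \code{ercc_design}; default the packaged design.
#' @param rpkm_floor Reporting floor applied when reading sequencing input.
#' @param ci_level Outlier interval level, in (0, 1). Default 0.99.
#' @param band Interval construction for response outliers
#'   (\code{"prediction"} or \code{"confidence"}).
#' @param region_rule How a control is placed relative to the linear region
#'   (\code{"centroid"} or \code{"any-point"}).
#' @param honor_reassignment Analyze recorded subpool reassignments (e.g.
#'   ERCC-00113 under subpool C) rather than original labels. Set
#'   \code{FALSE} to re-diagnose. Default \code{TRUE}.
#' @param drop_non_srm Drop ERCC-00114 from the analysis set.
#' @param include_subpool_a Include 1-to-1 controls in the model fit.
#' @param bg_override Optional fixed background anchor (linear scale).
#' @param outdir Optional output directory for the report bundle.
#' @return List of class \code{assessment_config}.
#' @export
assessment_config <- function(platform = c("array", "rnaseq"), signals,
                              design = NULL, rpkm_floor = 0.01,
                              ci_level = 0.99,
                              band = c("prediction", "confidence"),
                              region_rule = c("centroid", "any-point"),
                              honor_reassignment = TRUE,
                              drop_non_srm = FALSE,
                              include_subpool_a = TRUE,
                              bg_override = NULL, outdir = NULL) {
  platform <- match.arg(platform)
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  structure(list(platform = platform, signals = signals, design = design,
                 rpkm_floor = rpkm_floor, ci_level = ci_level,
                 band = match.arg(band), region_rule = match.arg(region_rule),
                 honor_reassignment = honor_reassignment,
                 drop_non_srm = drop_non_srm,
                 include_subpool_a = include_subpool_a,
                 bg_override = bg_override, outdir = outdir),
            class = "assessment_config")
}

#' Run the composite assessment
#'
#' Orchestrates the full scheme: design validation and exclusions,
#' detection flagging, dose-response model fit, response-curve outlier
#' flags at the configured interval, per-control slopes and Spearman
#' monotonicity, linear-region demarcation (arrays), mis-assignment
#' diagnosis for flagged non-monotonic controls, the six pairwise
#' Bland-Altman tables with ratio-recovery summaries, and the dynamic-range
#' summary. When \code{config$outdir} is set, the bundle is written as TSVs
#' with a JSON fit sidecar and a plain-text decision log; on failure any
#' partial outputs are removed.
#'
#' @param config An \code{assessment_config}.
#' @return List of class \code{spike_assessment} with elements design,
#'   detection, centroids, fit, region, per_control, response_outliers,
#'   slopes, monotonicity, nonmono_flags, diagnoses, ratios (list of six
#'   data.frames), ratio_summary, range, log.
#' @export
run_assessment <- function(config) {
  stopifnot(inherits(config, "assessment_config"))
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  design <- if (is.null(config$design)) load_design() else config$design
  validate_design(design)
  signals <- config$signals
  if (is.character(signals)) {
    signals <- read_signals(signals, config$platform, config$rpkm_floor)
  }
  if (platform_class(signals) != config$platform) {
    stop("signal table platform (", platform_class(signals),
         ") does not match config platform (", config$platform, ")")
  }

  analysis <- apply_exclusions(design, drop_non_srm = config$drop_non_srm,
                               honor_reassignment = config$honor_reassignment)
  note("analysis set: %d controls (%d excluded: %d antisense, %d omitted%s)",
       nrow(analysis$records), nrow(analysis$excluded),
       sum(analysis$excluded$antisense),
       sum(analysis$excluded$subpool == "omitted"),
       if (config$drop_non_srm) ", non-SRM dropped" else "")
  if (config$honor_reassignment &&
      any(nzchar(design$records$reassigned_subpool))) {
    note("reassignments honored: %s",
         paste(design$records$control_id[
           nzchar(design$records$reassigned_subpool)], collapse = ", "))
  }

  detection <- detection_table(signals, analysis)
  note("detection: %d detected, %d partial, %d undetected",
       sum(detection$status == "detected"),
       sum(detection$status == "partial"),
       sum(detection$status == "undetected"))

  centroids <- compute_centroids(signals, analysis,
                                 include_subpool_a = config$include_subpool_a)

  if (config$platform == "array") {
    i_max <- estimate_imax(signals, analysis)
    bg <- estimate_background(signals, bg_override = config$bg_override)
    fit <- fit_langmuir(centroids, i_max, bg, ci_level = config$ci_level)
    note("Langmuir fit: Imax = %.4g, Kd = %.4g, bg = %.4g, residual SD = %.4f",
         fit$i_max, fit$k_d, fit$bg, fit$residual_sd)
    region <- tryCatch(linear_region(fit), region_undefined = function(e) {
      note("linear region undefined: %s", conditionMessage(e))
      NULL
    })
    if (!is.null(region)) {
      note("linear region: log2 abundance in [%.2f, %.2f]",
           region$lower_log2_abundance, region$upper_log2_abundance)
    }
  } else {
    fit <- fit_linear_unit_slope(centroids, ci_level = config$ci_level)
    note("unit-slope fit: intercept = %.4f, residual SD = %.4f",
         fit$intercept, fit$residual_sd)
    region <- NULL
  }

  response <- flag_response_outliers(fit, centroids,
                                     ci_level = config$ci_level,
                                     band = config$band)
  slopes <- control_slopes(signals, analysis)
  mono <- monotonicity_table(signals, analysis)
  nonmono <- if (config$platform == "array" && is.null(region)) {
    note("non-monotonic flagging skipped: no linear region")
    NULL
  } else {
    flag_nonmonotonic_outliers(mono, centroids, region,
                               platform = config$platform,
                               rule = config$region_rule,
                               design = analysis, signals = signals)
  }

  diag_ids <- if (is.null(nonmono)) character() else
    nonmono$control_id[nonmono$is_outlier]
  diagnoses <- lapply(diag_ids, function(id)
    best_fit_subpool(signals, analysis, fit, id))
  names(diagnoses) <- diag_ids
  for (d in diagnoses) {
    if (d$suggested_subpool != d$original_subpool && !d$tie) {
      note("%s (labeled %s) is more consistent with subpool %s",
           d$control_id, d$original_subpool, d$suggested_subpool)
    }
  }

  per_control <- build_per_control(analysis, detection, centroids, response,
                                   slopes, mono, nonmono)
  pairs <- unique(enumerate_pool_pairs(analysis)[, c("pool_i", "pool_j")])
  ratios <- lapply(seq_len(nrow(pairs)), function(k)
    bland_altman(signals, analysis, pairs$pool_i[k], pairs$pool_j[k]))
  names(ratios) <- paste0(pairs$pool_i, "_vs_", pairs$pool_j)
  ratio_summary <- do.call(rbind, lapply(names(ratios), function(nm) {
    s <- ratio_recovery_summary(ratios[[nm]], region)
    s$pair <- nm
    s
  }))
  range <- range_summary(signals)

  result <- structure(
    list(design = analysis, detection = detection, centroids = centroids,
         fit = fit, region = region, per_control = per_control,
         response_outliers = response, slopes = slopes, monotonicity = mono,
         nonmono_flags = nonmono, diagnoses = diagnoses, ratios = ratios,
         ratio_summary = ratio_summary, range = range, log = log_lines),
    class = "spike_assessment")
  if (!is.null(config$outdir)) write_assessment(result, config$outdir)
  result
}

# One row per analysis-set control, with a definite outlier_class.
build_per_control <- function(analysis, detection, centroids, response,
                              slopes, mono, nonmono) {
  rec <- analysis$records
  out <- data.frame(control_id = rec$control_id, subpool = rec$subpool)
  out$status <- detection$status[match(out$control_id, detection$control_id)]
  m <- match(out$control_id, centroids$control_id)
  out$mean_log2_abundance <- centroids$mean_log2_abundance[m]
  out$mean_log2_signal <- centroids$mean_log2_signal[m]
  out$residual <- response$signed_residual[match(out$control_id,
                                                 response$control_id)]
  out$response_outlier <- response$is_outlier[match(out$control_id,
                                                    response$control_id)]
  out$slope <- slopes$slope[match(out$control_id, slopes$control_id)]
  out$rho <- mono$rho[match(out$control_id, mono$control_id)]
  out$monotonic <- mono$monotonic[match(out$control_id, mono$control_id)]
  if (!is.null(nonmono)) {
    mm <- match(out$control_id, nonmono$control_id)
    out$in_linear_region <- nonmono$position[mm] == "inside"
    out$nonmono_outlier <- nonmono$is_outlier[mm]
    out$sub_range <- nonmono$sub_range[mm]
  } else {
    out$in_linear_region <- NA
    out$nonmono_outlier <- NA
    out$sub_range <- NA
  }
  resp <- !is.na(out$response_outlier) & out$response_outlier
  nm <- !is.na(out$nonmono_outlier) & out$nonmono_outlier
  sr <- !is.na(out$sub_range) & out$sub_range
  out$outlier_class <- ifelse(out$status != "detected", "not_assessed",
    ifelse(resp & nm, "both",
      ifelse(resp, "response_curve",
        ifelse(nm, "non_monotonic",
          ifelse(sr, "sub_range", "none")))))
  out
}

#' Write an assessment report bundle
#'
#' TSVs for the per-control table, outlier census (grouped by criterion),
#' six pairwise ratio tables, ratio-recovery and dynamic-range summaries; a
#' JSON sidecar with the fit parameters and region bounds; and the decision
#' log. Reruns with identical inputs produce byte-identical files. Partial
#' outputs are removed if any write fails.
#'
#' @param x A \code{spike_assessment}.
#' @param outdir Output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_assessment <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
  }
  tryCatch({
    emit(x$per_control, "per_control.tsv")
    census <- x$per_control[x$per_control$outlier_class %in%
                              c("response_curve", "non_monotonic", "both"),
                            c("control_id", "subpool", "mean_log2_abundance",
                              "outlier_class")]
    emit(census, "outlier_census.tsv")
    sub_range <- x$per_control[!is.na(x$per_control$sub_range) &
                                 x$per_control$sub_range,
                               c("control_id", "subpool",
                                 "mean_log2_abundance")]
    emit(sub_range, "sub_range_controls.tsv")
    for (nm in names(x$ratios)) {
      emit(x$ratios[[nm]], paste0("ratio_", nm, ".tsv"))
    }
    emit(x$ratio_summary, "ratio_summary.tsv")
    emit(as.data.frame(x$range), "range_summary.tsv")
    sidecar <- list(
      platform = x$fit$platform_class,
      ci_level = x$fit$ci_level,
      n_centroids = x$fit$n,
      residual_sd = x$fit$residual_sd
    )
    if (inherits(x$fit, "langmuir_fit")) {
      sidecar$i_max <- x$fit$i_max
      sidecar$k_d <- x$fit$k_d
      sidecar$bg <- x$fit$bg
    } else {
      sidecar$intercept <- x$fit$intercept
      sidecar$slope <- x$fit$slope
    }
    if (!is.null(x$region)) {
      sidecar$linear_region <- list(
        lower_log2_abundance = x$region$lower_log2_abundance,
        upper_log2_abundance = x$region$upper_log2_abundance)
    }
    sidecar_path <- file.path(outdir, "fit.json")
    jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, sidecar_path)
    log_path <- file.path(outdir, "assessment_log.txt")
    writeLines(x$log, log_path)
    written <- c(written, log_path)
  }, error = function(e) {
    unlink(written)
    stop("failed writing assessment bundle: ", conditionMessage(e))
  })
  invisible(outdir)
}

#' @export
print.spike_assessment <- function(x, ...) {
  cat("Composite spike-in assessment (", x$fit$platform_class, ")\n", sep = "")
  print(x$fit)
  if (!is.null(x$region)) print(x$region)
  tab <- table(x$per_control$outlier_class)
  cat("  outlier classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
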