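#' Construct a signal table
#'
#' A signal table holds one measurement per (control, pool, replicate):
#' log2 fluorescence intensity for hybridization arrays, or log2 FPKM/RPKM
#' for sequencing. Platform class and spike fraction travel as attributes.
#'
#' @param data data.frame with columns \code{control_id}, \code{pool},
#'   \code{replicate}, \code{signal} (log2 scale).
#' @param platform_class \code{"array"} or \code{"rnaseq"}.
#' @param spike_fraction Spike-in mass fraction, percent wt/wt of pool per
#'   total RNA (metadata).
#' @return data.frame of class \code{signal_table}.
#' @export
signal_table <- function(data, platform_class = c("array", "rnaseq"),
                         spike_fraction = NA_real_) {
  platform_class <- match.arg(platform_class)
  required <- c("control_id", "pool", "replicate", "signal")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("signal table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data <- data[, required]
  data$control_id <- as.character(data$control_id)
  data$pool <- as.character(data$pool)
  data$replicate <- as.integer(data$replicate)
  if (nrow(data) && !is.numeric(data$signal)) {
    stop("signal column must be numeric")
  }
  if (nrow(data) && any(!is.finite(data$signal))) {
    stop("non-finite signal values after transformation")
  }
  key <- paste(data$control_id, data$pool, data$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (control, pool, replicate) key: ",
         key[duplicated(key)][1])
  }
  structure(data,
            platform_class = platform_class,
            spike_fraction = spike_fraction,
            class = c("signal_table", "data.frame"))
}

#' Platform class of a signal table
#' @param signals A \code{signal_table}.
#' @return \code{"array"} or \code{"rnaseq"}.
#' @export
platform_class <- function(signals) attr(signals, "platform_class")

#' Read a long-format signal file
#'
#' Reads TSV or CSV (sniffed from the header line) with columns
#' \code{control_id}, \code{pool}, \code{replicate}, \code{signal}. Array
#' signals are taken as already log2 intensities. Sequencing signals are
#' linear FPKM/RPKM: values at or below the reporting floor (pipelines
#' truncate reported RPKM, conventionally at 0.01) are treated as missing
#' -- a floored value carries no quantitative information -- and the rest
#' are log2-transformed. Zero or missing entries are dropped: absence of a
#' row is how "not detected in this pool" is represented.
#'
#' @param path File path.
#' @param platform_class \code{"array"} or \code{"rnaseq"}.
#' @param rpkm_floor Reporting floor for sequencing input. Default 0.01.
#' @param spike_fraction Optional metadata, percent wt/wt.
#' @return A \code{signal_table}.
#' @export
read_signals <- function(path, platform_class = c("array", "rnaseq"),
                         rpkm_floor = 0.01, spike_fraction = NA_real_) {
  platform_class <- match.arg(platform_class)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    return(signal_table(
      data.frame(control_id = character(), pool = character(),
                 replicate = integer(), signal = numeric()),
      platform_class, spike_fraction))
  }
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("control_id", "pool", "replicate", "signal")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) && !is.numeric(df$signal)) {
    stop(path, ": non-numeric signal values")
  }
  df <- df[!is.na(df$signal), , drop = FALSE]
  if (platform_class == "rnaseq") {
    df <- df[df$signal > rpkm_floor, , drop = FALSE]
    df$signal <- log2(df$signal)
  }
  signal_table(df, platform_class, spike_fraction)
}

#' Write a signal table
#'
#' Emits the same long-format dialect \code{\link{read_signals}} reads.
#' Array tables are written as stored (log2); sequencing tables are written
#' as linear FPKM/RPKM so the file round-trips through the reading floor and
#' transform.
#'
#' @param signals A \code{signal_table}.
#' @param path Output path; extension \code{.csv} selects comma separation,
#'   anything else tab.
#' @return \code{path}, invisibly.
#' @export
write_signals <- function(signals, path) {
  out <- as.data.frame(signals)
  if (platform_class(signals) == "rnaseq") out$signal <- 2^out$signal
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detection status of a control
#'
#' A control is \code{detected} when it has signal in every pool,
#' \code{undetected} when it has signal in none, and \code{partial}
#' otherwise. Partially detected and undetected controls are excluded from
#' model fitting (they have no complete dose-response curve) but are kept
#' for display at their target abundance.
#'
#' @param signals A \code{signal_table}.
#' @param control_id ERCC identifier.
#' @param pools Pool labels defining "every pool"; default the design's four.
#' @return Character scalar: \code{"detected"}, \code{"partial"} or
#'   \code{"undetected"}.
#' @export
detection_status <- function(signals, control_id, pools = pool_labels()) {
  present <- unique(signals$pool[signals$control_id == control_id])
  n <- sum(pools %in% present)
  if (n == length(pools)) "detected" else if (n == 0L) "undetected" else "partial"
}

#' Detection status for every control in the analysis set
#'
#' @param signals A \code{signal_table}.
#' @param design An \code{ercc_design} (exclusions applied or not; omitted
#'   controls are skipped).
#' @return data.frame with control_id and status.
#' @export
detection_table <- function(signals, design) {
  ids <- design$records$control_id[design$records$subpool != "omitted"]
  data.frame(
    control_id = ids,
    status = vapply(ids, detection_status, character(1),
                    signals = signals, pools = design$pools),
    row.names = NULL
  )
}

#' Collapse replicates to per-(control, pool) summaries
#'
#' Mean and sample SD of the log2 signal across replicates; SD is 0 for a
#' single replicate.
#'
#' @param signals A \code{signal_table}.
#' @return data.frame with control_id, pool, mean_log2_signal, sd_log2_signal,
#'   n_replicates; platform class preserved as an attribute.
#' @export
collapse_replicates <- function(signals) {
  if (nrow(signals) == 0L) {
    out <- data.frame(control_id = character(), pool = character(),
                      mean_log2_signal = numeric(), sd_log2_signal = numeric(),
                      n_replicates = integer())
  } else {
    key <- interaction(signals$control_id, signals$pool, drop = TRUE)
    split_sig <- split(signals$signal, key)
    ids <- do.call(rbind, strsplit(names(split_sig), ".", fixed = TRUE))
    out <- data.frame(
      control_id = ids[, 1],
      pool = ids[, 2],
      mean_log2_signal = vapply(split_sig, mean, numeric(1)),
      sd_log2_signal = vapply(split_sig, function(x)
        if (length(x) > 1L) stats::sd(x) else 0, numeric(1)),
      n_replicates = vapply(split_sig, length, integer(1)),
      row.names = NULL
    )
    out <- out[order(out$control_id, out$pool), ]
    rownames(out) <- NULL
  }
  attr(out, "platform_class") <- platform_class(signals)
  out
}
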