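#' Load the modified Latin square pool design
#'
#' Reads the packaged (or a user-supplied) design table describing how ERCC
#' controls are distributed among five subpools and how the subpools are
#' mixed by volume into Pools 12-15. Subpool A enters every pool at a
#' constant 10 % (giving 1-to-1 comparisons); subpools B-E rotate through
#' proportions 10/15/25/40 % in a Latin square, so that each titrated
#' control is measured at four relative abundances spanning a 4-fold range,
#' and pairwise pool comparisons carry known fold changes.
#'
#' Within each subpool the controls sit on a relative-abundance ladder
#' spanning \eqn{2^{20}} from the least to the most abundant member.
#'
#' @param path Path to a design CSV with columns
#'   \code{control_id,subpool,base_abundance,antisense,non_srm,reassigned_subpool}.
#'   Defaults to the fixture shipped with the package.
#' @return An object of class \code{ercc_design}: a list with
#'   \describe{
#'     \item{records}{data.frame of per-control rows (one per control).}
#'     \item{square}{data.frame of mixing proportions, subpool x pool.}
#'     \item{pools}{character vector of pool labels, \code{"12".."15"}.}
#'   }
#'   The design is validated on load; violations of the design invariants
#'   (Latin square closure, ladder span, exclusion counts) raise an error
#'   before any analysis can run.
#' @examples
#' design <- load_design()
#' sum(design$records$antisense)   # 7 antisense controls
#' @export
load_design <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ercc_latin_square_design.csv",
                        package = "spikeqc", mustWork = TRUE)
  }
  records <- utils::read.csv(path, colClasses = "character")
  required <- c("control_id", "subpool", "base_abundance", "antisense",
                "non_srm", "reassigned_subpool")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("design fixture is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records$base_abundance <- suppressWarnings(as.numeric(records$base_abundance))
  records$antisense <- as.logical(records$antisense)
  records$non_srm <- as.logical(records$non_srm)
  records$reassigned_subpool[is.na(records$reassigned_subpool)] <- ""
  bad <- which(is.na(records$base_abundance) | is.na(records$antisense) |
                 is.na(records$non_srm))
  if (length(bad)) {
    stop("design fixture row ", bad[1], " (", records$control_id[bad[1]],
         "): non-numeric abundance or non-logical flag")
  }
  bad <- which(!records$subpool %in% c("A", "B", "C", "D", "E", "omitted"))
  if (length(bad)) {
    stop("design fixture row ", bad[1], " (", records$control_id[bad[1]],
         "): unknown subpool '", records$subpool[bad[1]], "'")
  }
  if (anyDuplicated(records$control_id)) {
    stop("design fixture: duplicated control_id ",
         records$control_id[duplicated(records$control_id)][1])
  }
  design <- structure(
    list(records = records, square = latin_square(), pools = pool_labels()),
    class = "ercc_design"
  )
  validate_design(design)
  design
}

# Mixing proportions (percent) of each subpool in each pool. Cyclic Latin
# square over B-E; subpool A is pinned at 10 % everywhere.
latin_square <- function() {
  data.frame(
    subpool = c("A", "B", "C", "D", "E"),
    `12` = c(10, 10, 15, 25, 40),
    `13` = c(10, 15, 25, 40, 10),
    `14` = c(10, 25, 40, 10, 15),
    `15` = c(10, 40, 10, 15, 25),
    check.names = FALSE
  )
}

pool_labels <- function() c("12", "13", "14", "15")

#' Validate a pool design
#'
#' Checks the structural invariants of the modified Latin square: subpool A
#' constant at 10 %, subpools B-E each taking every proportion in
#' \{10, 15, 25, 40\} exactly once, column sums of 100 %, exactly one omitted
#' control, exactly seven antisense controls, every base abundance on its
#' subpool's ladder, and a \eqn{2^{20}} min-to-max span per subpool.
#'
#' @param design An \code{ercc_design}.
#' @return The design, invisibly; errors on the first violated invariant.
#' @export
validate_design <- function(design) {
  sq <- design$square
  pools <- design$pools
  if (!all(sq[sq$subpool == "A", pools] == 10)) {
    stop("design invariant violated: subpool A must be 10 % in every pool")
  }
  for (sp in c("B", "C", "D", "E")) {
    props <- as.numeric(sq[sq$subpool == sp, pools])
    if (!setequal(props, c(10, 15, 25, 40)) || length(props) != 4) {
      stop("design invariant violated: subpool ", sp,
           " proportions are not a permutation of {10,15,25,40}")
    }
  }
  if (!all(colSums(sq[, pools]) == 100)) {
    stop("design invariant violated: pool proportions must sum to 100 %")
  }
  rec <- design$records
  if (sum(rec$subpool == "omitted") != 1 ||
      rec$control_id[rec$subpool == "omitted"] != "ERCC-00073") {
    stop("design invariant violated: exactly ERCC-00073 must be omitted")
  }
  if (sum(rec$antisense) != 7) {
    stop("design invariant violated: expected exactly 7 antisense controls, got ",
         sum(rec$antisense))
  }
  for (sp in c("A", "B", "C", "D", "E")) {
    base <- rec$base_abundance[rec$subpool == sp]
    if (!all(base %in% subpool_ladder(sp))) {
      stop("design invariant violated: subpool ", sp,
           " has base abundances off the ladder")
    }
    if (max(base) / min(base) != 2^20) {
      stop("design invariant violated: subpool ", sp,
           " ladder does not span 2^20")
    }
  }
  invisible(design)
}

# The relative-abundance ladder of a subpool. 19 SRM slots at
# {2^0..2^16, 2^18, 2^20}; subpool A additionally carries the non-SRM
# control at 2^17.
subpool_ladder <- function(subpool) {
  base <- c(2^(0:16), 2^18, 2^20)
  if (subpool == "A") sort(c(base, 2^17)) else base
}

#' @export
print.ercc_design <- function(x, ...) {
  rec <- x$records
  cat("Modified Latin square ERCC pool design\n")
  cat("  controls:", nrow(rec),
      sprintf("(%d antisense, %d omitted, %d non-SRM)\n",
              sum(rec$antisense), sum(rec$subpool == "omitted"),
              sum(rec$non_srm)))
  cat("  pools:", paste(x$pools, collapse = ", "), "\n")
  cat("  subpool sizes:",
      paste(sprintf("%s=%d", c("A", "B", "C", "D", "E"),
                    table(factor(rec$subpool, c("A", "B", "C", "D", "E")))),
            collapse = " "), "\n")
  invisible(x)
}

# Mixing proportion (percent) of a subpool in a pool.
proportion_of <- function(design, subpool, pool) {
  pool <- as.character(pool)
  if (!pool %in% design$pools) stop("unknown pool: ", pool)
  row <- match(subpool, design$square$subpool)
  if (is.na(row)) stop("unknown subpool: ", subpool)
  design$square[row, pool]
}

# Effective subpool of a control: the reassigned label when present and
# honored, otherwise the original.
effective_subpool <- function(record, honor_reassignment = TRUE) {
  if (honor_reassignment && !is.na(record$reassigned_subpool) &&
      nzchar(record$reassigned_subpool)) {
    record$reassigned_subpool
  } else {
    record$subpool
  }
}

#' Nominal relative abundance of a control in a pool
#'
#' The design's ground truth: base ladder abundance scaled by the subpool's
#' mixing proportion in the pool, relative to the 10 % reference (so a
#' subpool-B control with base 1 is at 4 in pool 15, where B enters at 40 %).
#'
#' @param design An \code{ercc_design}.
#' @param control_id ERCC identifier; must be present and not omitted.
#' @param pool Pool label ("12".."15"); vectorized over pools.
#' @param honor_reassignment Use the reassigned subpool (e.g. ERCC-00113
#'   under subpool C) when one is recorded. Default \code{TRUE}.
#' @return Numeric vector of nominal relative abundances, one per pool.
#' @export
nominal_abundance <- function(design, control_id, pool,
                              honor_reassignment = TRUE) {
  i <- match(control_id, design$records$control_id)
  if (is.na(i)) stop("unknown control: ", control_id)
  record <- design$records[i, ]
  if (record$subpool == "omitted") {
    stop(control_id, " is omitted from the pools; it has no nominal abundance")
  }
  sp <- effective_subpool(record, honor_reassignment)
  vapply(as.character(pool),
         function(p) record$base_abundance * proportion_of(design, sp, p) / 10,
         numeric(1))
}

#' Nominal abundance matrix (controls x pools)
#'
#' @inheritParams nominal_abundance
#' @param controls Controls to include; default all non-omitted controls.
#' @return data.frame with control_id, subpool and one column per pool.
#' @export
nominal_abundance_matrix <- function(design, controls = NULL,
                                     honor_reassignment = TRUE) {
  rec <- design$records
  rec <- rec[rec$subpool != "omitted", ]
  if (!is.null(controls)) rec <- rec[rec$control_id %in% controls, ]
  out <- data.frame(
    control_id = rec$control_id,
    subpool = vapply(seq_len(nrow(rec)), function(i)
      effective_subpool(rec[i, ], honor_reassignment), character(1))
  )
  for (p in design$pools) {
    out[[p]] <- vapply(seq_len(nrow(rec)), function(i)
      nominal_abundance(design, rec$control_id[i], p, honor_reassignment),
      numeric(1))
  }
  out
}

#' Nominal fold change between two pools for a subpool
#'
#' Ratio of mixing proportions, the known "truth" a platform should recover
#' for every titrated control of the subpool. Stored exact; round at the
#' reporting layer (e.g. 40/15 prints as 2.7).
#'
#' @param design An \code{ercc_design}.
#' @param subpool Subpool label A-E.
#' @param pool_i,pool_j Distinct pool labels; the ratio is pool_i over pool_j.
#' @return The exact proportion quotient.
#' @export
pairwise_ratio <- function(design, subpool, pool_i, pool_j) {
  if (as.character(pool_i) == as.character(pool_j)) {
    stop("pool_i and pool_j must differ")
  }
  proportion_of(design, subpool, pool_i) / proportion_of(design, subpool, pool_j)
}

#' Enumerate the six pairwise pool comparisons
#'
#' Each unordered pool pair carries four titrated fold changes (one per
#' subpool B-E, in both "up" and "down" directions) plus the 1-to-1
#' comparison from subpool A. Across all six pairs the rounded fold changes
#' are exactly \{1.5, 1.6, 1.7, 2.5, 2.7, 4.0\}.
#'
#' @param design An \code{ercc_design}.
#' @return data.frame with one row per (pair, subpool): pool_i, pool_j,
#'   subpool, ratio (exact, pool_i over pool_j), fold (rounded magnitude,
#'   one decimal).
#' @export
enumerate_pool_pairs <- function(design) {
  pools <- design$pools
  pairs <- utils::combn(pools, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    pi <- pairs[1, k]; pj <- pairs[2, k]
    data.frame(
      pool_i = pi, pool_j = pj,
      subpool = c("A", "B", "C", "D", "E"),
      ratio = vapply(c("A", "B", "C", "D", "E"),
                     function(sp) pairwise_ratio(design, sp, pi, pj),
                     numeric(1))
    )
  }))
  rownames(out) <- NULL
  out$fold <- round(pmax(out$ratio, 1 / out$ratio), 1)
  out
}

#' Apply the analysis exclusions
#'
#' Drops the seven antisense controls (arrays probe the sense strand, and
#' the sequencing reference is sense, so they yield no signal) and the
#' omitted control (needed only for background estimation) from the analysis
#' set, keeping them in a side list. Reassigned subpools (ERCC-00113 under
#' subpool C) are applied to the analysis records when
#' \code{honor_reassignment} is \code{TRUE}.
#'
#' Idempotent: applying twice equals applying once.
#'
#' @param design An \code{ercc_design}.
#' @param drop_non_srm Also drop the non-SRM control ERCC-00114 (it is absent
#'   from sequencing references). Default \code{FALSE}.
#' @param honor_reassignment See \code{\link{nominal_abundance}}.
#' @return An \code{ercc_design} whose \code{records} are the analysis set
#'   (with subpool replaced by the effective subpool) and with an
#'   \code{excluded} data.frame of the removed rows.
#' @export
apply_exclusions <- function(design, drop_non_srm = FALSE,
                             honor_reassignment = TRUE) {
  rec <- design$records
  drop <- rec$antisense | rec$subpool == "omitted"
  if (drop_non_srm) drop <- drop | rec$non_srm
  excluded <- rbind(design$excluded, rec[drop, ])
  rec <- rec[!drop, ]
  rec$subpool <- vapply(seq_len(nrow(rec)), function(i)
    effective_subpool(rec[i, ], honor_reassignment), character(1))
  # subpool now holds the effective label; blank the reassignment column so
  # downstream lookups cannot re-apply (or, in diagnosis mode, apply) it
  rec$reassigned_subpool <- ""
  design$records <- rec
  design$excluded <- excluded
  design
}
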