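#' @title Target-decoy FDR accounting and ROC utilities
#' @name evaluation
#' @description
#' Standard target-decoy accounting at a score threshold, FDR-controlled
#' acceptance, ROC points and set-overlap (Venn) summaries. The FDR
#' estimate is \eqn{FDR = 2 \cdot FP/(FP + TP)} with FP the number of
#' accepted decoys and \eqn{FP + TP} the number of accepted targets.
NULL

#' Target-decoy report at a fixed score threshold
#'
#' Accepts every PSM with score at or above `t`. `FP` is the accepted decoy
#' count, `TP` the accepted target count minus `FP`, and the estimated
#' false discovery rate is \eqn{2 \cdot FP / (FP + TP)} (0 when no targets
#' are accepted). A per-digest-type breakdown of accepted targets is
#' included.
#'
#' @param scores Score per PSM.
#' @param coll The `psm_collection`.
#' @param t Score threshold.
#' @return A list of class `"acceptance_report"`.
#' @export
fdr_at_threshold <- function(scores, coll, t) {
  stopifnot(length(scores) == nrow(coll))
  acc <- scores >= t
  acc_t <- acc & !coll$is_decoy
  fp <- sum(acc & coll$is_decoy)
  n_targets <- sum(acc_t)
  tp <- n_targets - fp
  fdr <- if (n_targets > 0) 2 * fp / n_targets else 0
  by_type <- vapply(c(full = 2, half = 1, none = 0),
                    function(code) sum(acc_t & coll$digest_type == code),
                    integer(1))
  structure(list(threshold = t, n_accepted_targets = n_targets,
                 n_accepted_decoys = fp, tp_estimate = tp, fdr = fdr,
                 accepted_targets_by_type = by_type),
            class = "acceptance_report")
}

#' @export
print.acceptance_report <- function(x, ...) {
  cat(sprintf(
    "threshold %.6g: %d targets (TP+FP), TP = %d, FP = %d, FDR = %.4f\n",
    x$threshold, x$n_accepted_targets, x$tp_estimate, x$n_accepted_decoys,
    x$fdr))
  cat(sprintf("  accepted targets by digest type: full %d, half %d, none %d\n",
              x$accepted_targets_by_type["full"],
              x$accepted_targets_by_type["half"],
              x$accepted_targets_by_type["none"]))
  if (isTRUE(x$warning_flag))
    cat("  warning: no threshold met the requested FDR level\n")
  invisible(x)
}

#' Accept PSMs at a target FDR level
#'
#' Scans every distinct observed score as a candidate threshold and returns
#' the report of the lowest (most permissive) threshold whose estimated FDR
#' is at or below `level` while accepting at least one target (the empty
#' acceptance is vacuous). If no threshold qualifies, the report of the
#' strictest threshold is returned with `warning_flag = TRUE`.
#'
#' @param scores Score per PSM.
#' @param coll The `psm_collection`.
#' @param level FDR level in (0, 1].
#' @return An `"acceptance_report"`.
#' @export
select_at_fdr <- function(scores, coll, level) {
  stopifnot(level > 0, level <= 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  reports <- lapply(thresholds, function(t) fdr_at_threshold(scores, coll, t))
  ok <- vapply(reports, function(r)
    r$fdr <= level && r$n_accepted_targets > 0, logical(1))
  if (any(ok)) {
    rep <- reports[[max(which(ok))]]   # lowest qualifying threshold
    rep$warning_flag <- FALSE
  } else {
    rep <- reports[[1L]]
    rep$warning_flag <- TRUE
    warning("no score threshold achieves FDR <= ", level)
  }
  rep
}

#' ROC points over all distinct score thresholds
#'
#' At each distinct score `t` (descending): \eqn{TPR = TP/(TP+FN)} and
#' \eqn{FPR = FP/(FP+TN)}, where positives/negatives with score >= `t`
#' count as TP/FP.
#'
#' @param scores Score per PSM.
#' @param positives,negatives Disjoint index sets (for synthetic data:
#'   truth-true targets vs truth-false targets plus decoys; for real data:
#'   targets vs decoys).
#' @return Data frame with columns `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(scores, positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("both classes must be nonempty")
  if (length(intersect(positives, negatives)) > 0L)
    stop("positives and negatives must be disjoint")
  thresholds <- sort(unique(scores[c(positives, negatives)]),
                     decreasing = TRUE)
  tpr <- vapply(thresholds,
                function(t) mean(scores[positives] >= t), numeric(1))
  fpr <- vapply(thresholds,
                function(t) mean(scores[negatives] >= t), numeric(1))
  data.frame(threshold = thresholds, tpr = tpr, fpr = fpr)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the [roc_points()] curve with the origin
#' prepended.
#'
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, positives, negatives) {
  pts <- roc_points(scores, positives, negatives)
  x <- c(0, pts$fpr); y <- c(0, pts$tpr)
  if (x[length(x)] < 1) { x <- c(x, 1); y <- c(y, 1) }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Venn region counts for 2 or 3 named sets
#'
#' @param sets Named list of 2 or 3 index vectors over the same universe.
#' @return Named integer vector of all Venn region cardinalities
#'   (exclusive regions, pairwise-only intersections, and for 3 sets the
#'   center).
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L),
            !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) member <- matrix(member, nrow = 1L,
                                        dimnames = list(NULL, nm))
  key <- apply(member, 1L, function(row) paste(nm[row], collapse = "&"))
  regions <- if (length(sets) == 2L) {
    c(nm[1], nm[2], paste(nm, collapse = "&"))
  } else {
    c(nm, paste(nm[1], nm[2], sep = "&"), paste(nm[1], nm[3], sep = "&"),
      paste(nm[2], nm[3], sep = "&"), paste(nm, collapse = "&"))
  }
  counts <- vapply(regions, function(r) sum(key == r), integer(1))
  names(counts) <- regions
  counts
}
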