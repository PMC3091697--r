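#' Two-channel expression dataset
#'
#' Container for a reporter-by-array experiment: log2 sample/reference ratios
#' `M`, per-spot mean log2 intensities `A`, a per-spot confidence flag
#' (`TRUE` = reliable quantification), and the sample design mapping each
#' array to a condition (`depleted` or `control`), a time point in days, and
#' a replicate index.
#'
#' @param M,A numeric matrices (reporters x arrays), same dimensions.
#' @param confidence logical matrix, same dimensions; `TRUE` = confident.
#' @param design data frame with columns `array_id`, `condition`, `time`,
#'   `replicate`; each array id must appear exactly once and match a column.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(M, A, confidence, design) {
  if (!identical(dim(M), dim(A)) || !identical(dim(M), dim(confidence)))
    stopf("M, A and confidence must share dimensions")
  need <- c("array_id", "condition", "time", "replicate")
  if (!all(need %in% names(design))) stopf("design lacks columns: %s",
    paste(setdiff(need, names(design)), collapse = ", "))
  if (anyDuplicated(design$array_id)) stopf("duplicate array ids in design")
  if (!setequal(colnames(M), design$array_id) ||
      nrow(design) != ncol(M))
    stopf("design array ids must match the matrix columns")
  if (!all(design$condition %in% c("depleted", "control")))
    stopf("condition must be 'depleted' or 'control'")
  M <- M[, design$array_id, drop = FALSE]
  A <- A[, design$array_id, drop = FALSE]
  confidence <- confidence[, design$array_id, drop = FALSE]
  structure(list(M = M, A = A, confidence = confidence, design = design,
                 retained = NULL),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$M), "reporters x", ncol(x$M), "arrays;",
      length(unique(x$design$time)), "time points,",
      sprintf("%.1f%% spots flagged low-confidence%s\n",
              100 * mean(!x$confidence),
              if (is.null(x$retained)) "" else "; filtered"))
  invisible(x)
}

#' MA transform of two-channel intensities
#'
#' Converts red (sample) and green (reference) channel intensities to
#' `M = log2(R/G)` and `A = (log2 R + log2 G)/2`. Non-positive or missing
#' intensities in either channel yield `NA` in both outputs.
#'
#' @param red,green positive numeric matrices (or vectors) of identical shape.
#' @return list with matrices `M` and `A`.
#' @export
compute_ma <- function(red, green) {
  if (!identical(dim(red) %||% length(red), dim(green) %||% length(green)))
    stopf("red and green intensities must share shape")
  bad <- !is.finite(red) | !is.finite(green) | red <= 0 | green <= 0
  lr <- log2(red); lg <- log2(green)
  lr[bad] <- NA_real_; lg[bad] <- NA_real_
  list(M = lr - lg, A = (lr + lg) / 2)
}

#' Lowess normalization of log ratios against intensity
#'
#' Removes intensity-dependent dye bias by subtracting from each `M` the
#' lowess fit of `M` on `A` (robust locally weighted regression,
#' [stats::lowess()]). Missing values propagate and never enter the fit.
#'
#' @param M,A numeric vectors of equal length (one array).
#' @param span lowess smoother span in (0, 1].
#' @param iter robustness iterations.
#' @return normalized `M` with attribute `"fitted"` (the subtracted trend).
#' @export
lowess_normalize <- function(M, A, span = 0.3, iter = 3L) {
  if (length(M) != length(A)) stopf("M and A must have equal length")
  if (span <= 0 || span > 1) stopf("'span' must be in (0, 1]")
  ok <- is.finite(M) & is.finite(A)
  if (sum(ok) < 10)
    stopf("fewer than 10 complete (M, A) points; skip normalization instead")
  fit <- lowess(A[ok], M[ok], f = span, iter = iter)
  fitted <- rep(NA_real_, length(M))
  fitted[ok] <- approx(fit$x, fit$y, xout = A[ok], rule = 2, ties = mean)$y
  out <- M - fitted
  attr(out, "fitted") <- fitted
  out
}

#' Lowess-normalize every array of a dataset
#'
#' @param dataset an [expression_dataset()].
#' @inheritParams lowess_normalize
#' @return the dataset with normalized `M`; per-array fit summaries (median
#'   absolute trend removed) in `attr(, "norm_summary")`.
#' @export
normalize_dataset <- function(dataset, span = 0.3, iter = 3L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  summaries <- numeric(ncol(dataset$M))
  for (j in seq_len(ncol(dataset$M))) {
    out <- lowess_normalize(dataset$M[, j], dataset$A[, j], span, iter)
    summaries[j] <- median(abs(attr(out, "fitted")), na.rm = TRUE)
    attributes(out) <- NULL
    dataset$M[, j] <- out
  }
  attr(dataset, "norm_summary") <- data.frame(
    array_id = colnames(dataset$M), median_abs_trend = summaries)
  dataset
}

#' Apply confidence and minimum-replicate filters
#'
#' Spots flagged low-confidence are set to missing. A reporter is retained
#' for the comparison at a given time point only when both the depleted and
#' the control group have at least `min_replicates` non-missing values there;
#' the retained set is recorded per time point and consumed by
#' [call_regulated()].
#'
#' @param dataset an [expression_dataset()].
#' @param min_replicates minimum non-missing replicates per group (>= 2 for
#'   the t-test; the analysis default is 3).
#' @return the dataset with low-confidence spots masked and a logical
#'   `retained` matrix (reporter x time point).
#' @export
filter_expressed <- function(dataset, min_replicates = 3L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  min_replicates <- check_count(min_replicates, "min_replicates")
  if (min_replicates < 2)
    stopf("'min_replicates' must be >= 2 (t-test needs two values per group)")
  dataset$M[!dataset$confidence] <- NA_real_
  tps <- sort(unique(dataset$design$time))
  retained <- matrix(FALSE, nrow(dataset$M), length(tps),
                     dimnames = list(rownames(dataset$M), as.character(tps)))
  for (i in seq_along(tps)) {
    dep <- dataset$design$array_id[dataset$design$time == tps[i] &
                                     dataset$design$condition == "depleted"]
    ctl <- dataset$design$array_id[dataset$design$time == tps[i] &
                                     dataset$design$condition == "control"]
    n_dep <- rowSums(!is.na(dataset$M[, dep, drop = FALSE]))
    n_ctl <- rowSums(!is.na(dataset$M[, ctl, drop = FALSE]))
    retained[, i] <- n_dep >= min_replicates & n_ctl >= min_replicates
  }
  dataset$retained <- retained
  dataset
}
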