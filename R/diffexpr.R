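#' Two-sample t-test with explicit degenerate conventions
#'
#' Welch unequal-variance t-test (the default) or pooled-variance Student
#' t-test between two groups, with two conventions for zero-variance data:
#' both groups constant and equal means gives `p = 1`; both constant with
#' unequal means gives `p = 0` and is flagged degenerate.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 non-missing values.
#' @param var_equal pool the variances (classical Student t) instead of
#'   Welch-Satterthwaite.
#' @return list with `t`, `p` (two-sided), `df`, and `degenerate`.
#' @export
welch_t_test <- function(group_a, group_b, var_equal = FALSE) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stopf("each group needs >= 2 non-missing values")
  v1 <- stats::var(a); v2 <- stats::var(b)
  d <- mean(a) - mean(b)
  if (v1 == 0 && v2 == 0) {
    if (d == 0) return(list(t = 0, p = 1, df = NA_real_, degenerate = FALSE))
    return(list(t = sign(d) * Inf, p = 0, df = NA_real_, degenerate = TRUE))
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- d / sqrt(se2)
  list(t = t, p = 2 * pt(-abs(t), df), df = df, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; missing p-values propagate as `NA` and do not
#' enter the family size.
#'
#' @param pvalues numeric vector in \[0, 1\] (NAs allowed).
#' @return adjusted values (q-values), original order preserved.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- p.adjust(pvalues[ok], method = "BH")
  q
}

#' Signed fold change from group means of log2 ratios
#'
#' The linear ratio `r = 2^(mean(depleted) - mean(control))` is reported as
#' `+r` when `r >= 1` and `-1/r` otherwise, so that +/-1.8 is a symmetric
#' threshold and identical means give +1.
#'
#' @param depleted,control numeric vectors of log2 ratios (>= 1 value each).
#' @return signed fold change.
#' @export
signed_fold_change <- function(depleted, control) {
  depleted <- depleted[!is.na(depleted)]; control <- control[!is.na(control)]
  if (!length(depleted) || !length(control)) stopf("empty group")
  r <- 2^(mean(depleted) - mean(control))
  if (r >= 1) r else -1 / r
}

# Vectorised per-row two-sample test over matrices (NA-aware); returns a
# data frame with diff of means, t, p, df. Degenerate zero-variance rows
# follow the welch_t_test conventions.
row_t_stats <- function(X1, X2, var_equal = FALSE) {
  n1 <- rowSums(!is.na(X1)); n2 <- rowSums(!is.na(X2))
  m1 <- rowMeans(X1, na.rm = TRUE); m2 <- rowMeans(X2, na.rm = TRUE)
  v1 <- rowSums((X1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((X2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  d <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / pmax(n1 - 1, 1) + (v2 / n2)^2 / pmax(n2 - 1, 1))
  }
  t <- d / sqrt(se2)
  p <- 2 * pt(-abs(t), df)
  deg <- se2 == 0
  p[deg & d == 0] <- 1; t[deg & d == 0] <- 0
  p[deg & d != 0] <- 0; t[deg & d != 0] <- sign(d[deg & d != 0]) * Inf
  df[deg] <- NA_real_
  data.frame(diff = d, t = t, p = p, df = df, degenerate = deg & d != 0)
}

#' Call differentially expressed reporters per time point
#'
#' For every reporter retained by [filter_expressed()] at a time point,
#' compares depleted vs control log2 ratios by t-test, adjusts p-values by
#' Benjamini-Hochberg within that time point, and calls a reporter regulated
#' when both `|FC| > fc_threshold` and `q < fdr_threshold` (strict
#' inequalities).
#'
#' @param dataset a filtered [expression_dataset()] (see
#'   [filter_expressed()]).
#' @param fc_threshold linear fold-change threshold (default 1.8).
#' @param fdr_threshold adjusted-p threshold controlling the FDR (default
#'   0.1).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data frame of class `de_calls`: `reporter`, `time`, `fc`, `p`,
#'   `q`, `direction` (`up`/`down`/`none`), `called`.
#' @export
call_regulated <- function(dataset, fc_threshold = 1.8, fdr_threshold = 0.1,
                           var_equal = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$retained))
    stopf("dataset is unfiltered; run filter_expressed() first")
  if (fc_threshold <= 0 || fdr_threshold <= 0)
    stopf("thresholds must be positive")
  tps <- as.numeric(colnames(dataset$retained))
  out <- vector("list", length(tps))
  for (i in seq_along(tps)) {
    keep <- dataset$retained[, i]
    if (!any(keep)) next
    dep <- dataset$design$array_id[dataset$design$time == tps[i] &
                                     dataset$design$condition == "depleted"]
    ctl <- dataset$design$array_id[dataset$design$time == tps[i] &
                                     dataset$design$condition == "control"]
    st <- row_t_stats(dataset$M[keep, dep, drop = FALSE],
                      dataset$M[keep, ctl, drop = FALSE], var_equal)
    r <- 2^st$diff
    fc <- ifelse(r >= 1, r, -1 / r)
    q <- bh_adjust(st$p)
    called <- abs(fc) > fc_threshold & q < fdr_threshold
    out[[i]] <- data.frame(
      reporter = rownames(dataset$M)[keep], time = tps[i],
      fc = fc, p = st$p, q = q,
      direction = ifelse(!called, "none", ifelse(fc > 0, "up", "down")),
      called = called, row.names = NULL)
  }
  calls <- do.call(rbind, out)
  class(calls) <- c("de_calls", "data.frame")
  calls
}

#' Temporal summary of differential-expression calls
#'
#' Per-time-point up/down counts, overall percentages of up- and
#' down-regulation events (each called reporter x time point is one event),
#' and the list of persistent-direction reporters: called with the same sign
#' at every time point covered by the calls table.
#'
#' @param calls a `de_calls` table from [call_regulated()].
#' @return list with `per_time` (data frame `time`, `n_up`, `n_down`,
#'   `n_total`), `pct_up`/`pct_down` (NA when there are no events),
#'   `n_events`, and `persistent` (character vector).
#' @export
temporal_summary <- function(calls) {
  stopifnot(is.data.frame(calls))
  tps <- sort(unique(calls$time))
  per <- data.frame(time = tps,
    n_up = vapply(tps, function(t) sum(calls$time == t & calls$direction == "up"),
                  integer(1)),
    n_down = vapply(tps, function(t) sum(calls$time == t & calls$direction == "down"),
                    integer(1)))
  per$n_total <- per$n_up + per$n_down
  n_events <- sum(per$n_total)
  called <- calls[calls$called, , drop = FALSE]
  persistent <- character(0)
  if (nrow(called)) {
    by_gene <- split(called, called$reporter)
    persistent <- names(by_gene)[vapply(by_gene, function(g) {
      length(unique(g$time)) == length(tps) && length(unique(g$direction)) == 1
    }, logical(1))]
  }
  list(per_time = per,
       pct_up = if (n_events) 100 * sum(per$n_up) / n_events else NA_real_,
       pct_down = if (n_events) 100 * sum(per$n_down) / n_events else NA_real_,
       n_events = n_events,
       persistent = sort(persistent))
}
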