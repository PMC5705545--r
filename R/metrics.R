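# Screening performance metrics: ROC AUC, power metric, accumulated-actives
# curves, robust summaries and distribution comparisons.

check_labels <- function(labels) {
  if (!all(labels %in% c("active", "inactive")))
    stop("every entry must be labeled active or inactive")
  n_act <- sum(labels == "active")
  if (n_act == 0L || n_act == length(labels))
    stop("metric needs at least one active and one inactive")
  invisible(n_act)
}

#' ROC AUC of a ranked list
#'
#' The probability that a randomly chosen active outranks a randomly chosen
#' inactive, computed from the rank statistic (Mann-Whitney formulation);
#' score ties count one half.
#'
#' @param ranked data frame with columns `score` and `label`
#'   (`active`/`inactive`), as produced by [rank_database()]. Row order is
#'   irrelevant: the statistic depends on scores only.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(ranked) {
  labels <- ranked$label
  n_act <- check_labels(labels)
  n_inact <- length(labels) - n_act
  r <- rank(ranked$score, ties.method = "average")
  (sum(r[labels == "active"]) - n_act * (n_act + 1) / 2) / (n_act * n_inact)
}

#' Power metric at the top x% of a ranked list
#'
#' `PM = TPR / (TPR + FPR)` with both rates evaluated over the top
#' `ceil(x% * n)` entries (never fewer than one). The power metric is an
#' early-retrieval measure robust to the threshold and to the active/total
#' ratio: 1 when the prefix holds only actives, 0 when it holds none.
#'
#' @param ranked ranked list (data frame, ordered by descending score, with
#'   `label`).
#' @param x_percent threshold as a percentage of the database, in (0, 100].
#' @return PM in \[0, 1\].
#' @export
power_metric <- function(ranked, x_percent = 10) {
  stopifnot(x_percent > 0, x_percent <= 100)
  labels <- ranked$label
  n_act <- check_labels(labels)
  n_inact <- length(labels) - n_act
  k <- max(1L, ceiling(x_percent / 100 * length(labels)))
  top <- labels[seq_len(k)]
  tpr <- sum(top == "active") / n_act
  fpr <- sum(top == "inactive") / n_inact
  tpr / (tpr + fpr)
}

#' Accumulated-actives curve
#'
#' Walking down the ranked list, point `k` is `(k, number of actives among
#' the first k entries)`; the final value is the total number of actives.
#'
#' @param ranked ranked list with `label`.
#' @return Data frame curve with columns `x` (rank) and `y` (actives so
#'   far).
#' @export
accumulated_actives <- function(ranked) {
  labels <- ranked$label
  data.frame(x = seq_along(labels), y = cumsum(labels == "active"))
}

#' Median and median absolute deviation
#'
#' The raw MAD, `median(|v - median(v)|)`, without the Gaussian consistency
#' constant: the value used for median +/- MAD summaries of metric
#' distributions. Even-length medians are the mean of the central pair.
#'
#' @param values non-empty numeric vector.
#' @return Named numeric vector `c(median = ..., mad = ...)`.
#' @export
median_and_mad <- function(values) {
  if (!length(values)) stop("empty value list")
  m <- stats::median(values)
  c(median = m, mad = stats::median(abs(values - m)))
}

#' Pointwise median of curves on a shared x grid
#'
#' @param curves list of curves (data frames with `x`, `y`) all sharing the
#'   same x grid.
#' @return A single curve with the pointwise median of the y values (mean of
#'   the central pair for an even number of curves).
#' @export
median_curve <- function(curves) {
  stopifnot(length(curves) > 0L)
  x <- curves[[1L]]$x
  for (cv in curves)
    if (!isTRUE(all.equal(cv$x, x))) stop("curves on mismatched x grids")
  ys <- do.call(cbind, lapply(curves, `[[`, "y"))
  data.frame(x = x, y = apply(ys, 1L, stats::median))
}

#' Empirical CDF curve of a metric distribution
#'
#' Sorted values against the fraction of values less than or equal to each;
#' duplicated values collapse into taller steps.
#'
#' @param values non-empty numeric vector (e.g. AUCs over repetitions).
#' @return Data frame curve `x` (distinct sorted values), `y` (cumulative
#'   fraction).
#' @export
cdf_curve <- function(values) {
  if (!length(values)) stop("empty value list")
  x <- sort(unique(values))
  data.frame(x = x, y = stats::ecdf(values)(x))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` with the standard asymptotic two-sample
#' p-value; two metric distributions are flagged as not significantly
#' different when `p >= 0.05`.
#'
#' @param a,b non-empty numeric samples.
#' @return List with `statistic`, `p_value` and the logical
#'   `not_significantly_different`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic),
       p_value = unname(kt$p.value),
       not_significantly_different = unname(kt$p.value) >= 0.05)
}
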