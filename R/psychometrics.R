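#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Rank test for a location difference between two independent groups, using
#' mid-ranks for ties. The headline statistic `u` follows the smaller-side
#' convention `min(U1, U2)` (so that when cases score higher than controls,
#' `u` is small). The orientation-specific statistic
#' `u_cases_lower = #\{x < y\} + ties/2` (with `x` as cases) is also
#' returned; it is the statistic linked to the ROC area by
#' `AUC = 1 - u_cases_lower / (n1 * n2)`.
#'
#' The z deviate uses the normal approximation with tie-corrected variance
#' and no continuity correction; `p` is the two-sided normal probability and
#' `r = |z| / sqrt(n1 + n2)` the rank effect size.
#'
#' @param x Numeric scores of group 1 (cases, by convention).
#' @param y Numeric scores of group 2 (controls).
#' @return A list of class `group_comparison`: `n1`, `n2`, `u`,
#'   `u_cases_lower`, `u_cases_higher`, `z`, `p`, `r`.
#' @examples
#' mann_whitney(c(4, 5, 6), c(1, 2, 3))$u # 0: complete separation
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty", call. = FALSE)
  pooled <- c(x, y)
  rk <- rank(pooled) # mid-ranks
  r1 <- sum(rk[seq_len(n1)])
  # u_higher counts pairs where a case outranks a control (ties half)
  u_higher <- r1 - n1 * (n1 + 1) / 2
  u_lower <- n1 * n2 - u_higher
  u <- min(u_higher, u_lower)
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    z <- 0
  } else {
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  }
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  structure(
    list(n1 = n1, n2 = n2, u = u, u_cases_lower = u_lower,
         u_cases_higher = u_higher, z = z, p = p,
         r = effect_size_r(z, n)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), z = %.2f, p = %.3g, r = %.2f\n",
              x$u, x$n1, x$n2, x$z, x$p, x$r))
  invisible(x)
}

#' Rank-test effect size r
#'
#' Converts a rank-test normal deviate to a correlation-scale effect size,
#' `r = |z| / sqrt(N)` with N the total number of observations. Values of
#' 0.1, 0.3 and 0.5 are conventionally read as small, medium and large.
#'
#' @param z Normal deviate from the rank test.
#' @param N Total sample size across both groups.
#' @return Nonnegative effect size.
#' @examples
#' effect_size_r(-8.6, 146) # 0.71
#' @export
effect_size_r <- function(z, N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("N must be a count >= 1", call. = FALSE)
  }
  abs(z) / sqrt(N)
}

# Coerce labels + positive class into a logical case indicator.
case_indicator <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  labels == positive
}

#' Empirical ROC curve
#'
#' Sweeps the decision rule "score >= t" over every distinct score (plus
#' sentinels at -Inf and +Inf), recording sensitivity (true-positive rate
#' among cases) and specificity (true-negative rate among controls), and
#' integrates the curve by the trapezoidal rule over (1 - specificity,
#' sensitivity). With mid-rank tie handling this area equals the
#' Mann-Whitney identity `1 - u_cases_lower / (n1 * n2)` exactly.
#'
#' @param scores Numeric scores.
#' @param labels Case/control labels (logical, or compared to `positive`).
#' @param positive Label value denoting a case.
#' @return A list of class `roc_result`: `thresholds` (increasing),
#'   `sensitivity`, `specificity`, `auc`, `n_cases`, `n_controls`.
#' @export
empirical_roc <- function(scores, labels, positive = TRUE) {
  is_case <- case_indicator(labels, positive)
  keep <- !is.na(scores) & !is.na(is_case)
  scores <- scores[keep]; is_case <- is_case[keep]
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 == 0L || n2 == 0L) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[is_case] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!is_case] < t), numeric(1))
  # integrate with thresholds descending so x = 1 - spec runs 0 -> 1
  ord <- rev(seq_along(thr))
  xs <- 1 - spec[ord]; ys <- sens[ord]
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, n_cases = n1, n_controls = n2),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds (%d cases, %d controls): AUC = %.3f\n",
              length(x$thresholds), x$n_cases, x$n_controls, x$auc))
  invisible(x)
}

#' Area under the ROC curve from the Mann-Whitney statistic
#'
#' The empirical AUC equals `1 - U / (n1 * n2)` where U is the
#' cases-lower Mann-Whitney statistic (`u_cases_lower` from
#' [mann_whitney()], i.e. the number of case-control pairs in which the
#' control outscores the case, ties counted half).
#'
#' @param U Cases-lower Mann-Whitney statistic.
#' @param n1,n2 Group sizes.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_from_u(467.5, 77, 69) # 0.912
#' @export
auc_from_u <- function(U, n1, n2) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1", call. = FALSE)
  if (U < 0 || U > n1 * n2) {
    stop("U must lie in [0, n1*n2]", call. = FALSE)
  }
  1 - U / (n1 * n2)
}

#' Sensitivity and specificity at a threshold
#'
#' Sensitivity is the fraction of cases with `score >= threshold`;
#' specificity the fraction of controls with `score < threshold`. A class
#' that is absent yields NA for its rate.
#'
#' @param scores Numeric scores.
#' @param labels Case/control labels.
#' @param threshold Decision threshold (score at or above = positive).
#' @param positive Label value denoting a case.
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
operating_point <- function(scores, labels, threshold, positive = TRUE) {
  is_case <- case_indicator(labels, positive)
  keep <- !is.na(scores) & !is.na(is_case)
  scores <- scores[keep]; is_case <- is_case[keep]
  sens <- if (any(is_case)) mean(scores[is_case] >= threshold) else NA_real_
  spec <- if (any(!is_case)) mean(scores[!is_case] < threshold) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Select a screening cut-off under a sensitivity constraint
#'
#' Scans integer thresholds from `min(scores)` to `max(scores) + 1` and
#' keeps those whose sensitivity (fraction of cases at or above the
#' threshold) meets `min_sensitivity`. Under the default
#' `rule = "highest"` the largest qualifying threshold is returned: the
#' most specific cut-off still retaining the required true-positive rate,
#' the rule that selects 14 for the RAADS-14 total at 93% sensitivity.
#' `rule = "lowest"` returns the smallest qualifying threshold instead
#' (trivially the scale minimum, retained for completeness).
#'
#' @param scores Numeric scores.
#' @param labels Case/control labels.
#' @param min_sensitivity Required true-positive rate (default 0.93).
#' @param positive Label value denoting a case.
#' @param rule "highest" (default) or "lowest" qualifying threshold.
#' @return Integer threshold.
#' @export
select_cutoff <- function(scores, labels, min_sensitivity = 0.93,
                          positive = TRUE, rule = c("highest", "lowest")) {
  rule <- match.arg(rule)
  is_case <- case_indicator(labels, positive)
  keep <- !is.na(scores) & !is.na(is_case)
  scores <- scores[keep]; is_case <- is_case[keep]
  if (!any(is_case)) stop("case group is empty", call. = FALSE)
  cases <- scores[is_case]
  candidates <- seq(floor(min(scores)), ceiling(max(scores)) + 1)
  sens <- vapply(candidates, function(t) mean(cases >= t), numeric(1))
  qual <- candidates[sens >= min_sensitivity]
  if (!length(qual)) {
    # always nonempty in practice: sensitivity is 1 at the scale minimum
    stop("no threshold attains the required sensitivity", call. = FALSE)
  }
  as.integer(if (rule == "highest") max(qual) else min(qual))
}

#' Cronbach's alpha and corrected item-total correlations
#'
#' Internal-consistency reliability of a sum score,
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`, with the
#' corrected item-total correlation of each item against the sum of the
#' remaining items.
#'
#' @param item_matrix Numeric matrix or data.frame, subjects x items.
#' @return A list of class `reliability_result`: `alpha`, `item_total`
#'   (named per item), `n_items`, `n_subjects`. `alpha` is NA (with a
#'   warning) when the total score has zero variance.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100), 50, 2)
#' x[, 2] <- x[, 1] + rnorm(50) # correlated pair
#' cronbach_alpha(x)$alpha
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  storage.mode(m) <- "numeric"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m); n <- nrow(m)
  if (k < 2L) stop("need at least 2 items", call. = FALSE)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  total <- rowSums(m)
  vt <- stats::var(total)
  if (!is.finite(vt) || vt <= 0) {
    warning("total score has zero variance; alpha undefined")
    alpha <- NA_real_
  } else {
    alpha <- k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
  }
  item_total <- vapply(seq_len(k), function(j) {
    rest <- total - m[, j]
    if (stats::sd(m[, j]) == 0 || stats::sd(rest) == 0) return(NA_real_)
    stats::cor(m[, j], rest)
  }, numeric(1))
  names(item_total) <- colnames(m) %||% paste0("item_", seq_len(k))
  structure(list(alpha = alpha, item_total = item_total,
                 n_items = k, n_subjects = n),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.2f (%d items, %d subjects)\n",
              x$alpha, x$n_items, x$n_subjects))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discrimination index of an item
#'
#' The item-selection score used to abridge an item bank: the product of the
#' point-biserial correlation between the item score and the case indicator
#' (the Pearson effect size of the group difference) and the corrected
#' item-total correlation of the item within its domain.
#'
#' @param item Numeric item scores.
#' @param groups Case/control labels aligned with `item`.
#' @param domain_matrix Subjects x items matrix of all items in the item's
#'   domain, including the item itself as column `item_col`.
#' @param item_col Column of `domain_matrix` holding this item.
#' @param positive Label value denoting a case.
#' @return A list of class `discrimination_score`: `r_pb`, `r_it`, `index`
#'   (all NA, with `degenerate = TRUE`, when the item has zero variance).
#' @export
discrimination_index <- function(item, groups, domain_matrix, item_col,
                                 positive = TRUE) {
  is_case <- case_indicator(groups, positive)
  dm <- as.matrix(domain_matrix)
  if (stats::sd(item) == 0) {
    return(structure(list(r_pb = NA_real_, r_it = NA_real_, index = NA_real_,
                          degenerate = TRUE),
                     class = "discrimination_score"))
  }
  r_pb <- stats::cor(item, as.numeric(is_case))
  rest <- rowSums(dm) - dm[, item_col]
  r_it <- if (stats::sd(rest) == 0) NA_real_ else stats::cor(dm[, item_col], rest)
  structure(list(r_pb = r_pb, r_it = r_it, index = r_pb * r_it,
                 degenerate = FALSE),
            class = "discrimination_score")
}

#' @export
print.discrimination_score <- function(x, ...) {
  cat(sprintf("discrimination index = %.3f (r_pb = %.3f, r_it = %.3f)\n",
              x$index, x$r_pb, x$r_it))
  invisible(x)
}
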