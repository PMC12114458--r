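# Method-comparison statistics: categorical and essential agreement between
# cytometric and suspension-test MBC determinations, ROC threshold analysis
# with Youden-index cut-off selection, pooled percentages, and the
# auxiliary Welch / Kruskal-Wallis tests.

#' Round half-up
#'
#' Decimal rounding where ties go away from zero (so 91.45 -> 91.5 at one
#' decimal), matching how agreement percentages are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Categorical agreement between paired classifications
#'
#' @param fcm_label,std_label aligned vectors of
#'   `"above_or_MBC"` / `"not_MBC"` labels from the cytometric and the
#'   standard method.
#' @return list with `n_concordant`, `n_total`, `percent` (one decimal,
#'   half-up).
#' @export
categorical_agreement <- function(fcm_label, std_label) {
  stopifnot(length(fcm_label) == length(std_label))
  if (length(fcm_label) == 0) stop("no paired results", call. = FALSE)
  n_conc <- sum(fcm_label == std_label)
  list(n_concordant = n_conc, n_total = length(fcm_label),
       percent = round_half_up(100 * n_conc / length(fcm_label), 1))
}

#' Essential agreement within k doubling dilutions
#'
#' Two MBC determinations agree essentially when they differ by at most
#' `k` two-fold dilution steps: `|log2(fcm / std)| <= k` (with a 1e-9
#' slack for floating-point ladders). Censored calls (`NA`) are excluded
#' from the denominator and counted separately.
#'
#' @param fcm_mbc,std_mbc aligned MBC concentrations; `NA` marks a censored
#'   call.
#' @param k allowed number of doubling dilutions.
#' @return list with `n_within_k`, `n_evaluable`, `n_censored`, `percent`.
#' @export
essential_agreement <- function(fcm_mbc, std_mbc, k = 1) {
  stopifnot(length(fcm_mbc) == length(std_mbc), k >= 0)
  ok <- !is.na(fcm_mbc) & !is.na(std_mbc)
  f <- fcm_mbc[ok]; s <- std_mbc[ok]
  if (any(f <= 0) || any(s <= 0)) {
    stop("MBC concentrations must be positive", call. = FALSE)
  }
  within <- abs(log2(f / s)) <= k + 1e-9
  list(n_within_k = sum(within), n_evaluable = sum(ok),
       n_censored = sum(!ok),
       percent = if (sum(ok) > 0)
         round_half_up(100 * sum(within) / sum(ok), 1) else NA_real_)
}

#' ROC analysis of normalized counts against reference kill status
#'
#' The score is the normalized count and the positive class is
#' `above_or_MBC` (bactericidal by the reference method); a sample is
#' predicted positive when its score falls below the threshold -- note the
#' inverted orientation, since low counts indicate kill. The curve is built
#' over all distinct score thresholds with ties grouped; AUC by the
#' trapezoid rule (equal to the normalized Mann-Whitney U statistic). The
#' operating threshold maximizes the Youden index J = sensitivity +
#' specificity - 1, with ties resolved toward higher specificity.
#'
#' @param scores normalized counts.
#' @param truth reference labels: logical (TRUE = kill) or
#'   `"above_or_MBC"` / `"not_MBC"`.
#' @return list with `roc_points` (data.frame threshold/fpr/tpr), `auc`,
#'   `chosen_threshold`, `sensitivity`, `specificity`, `confusion`
#'   (2x2 matrix at the chosen threshold).
#' @export
roc_analysis <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth) == "above_or_MBC"
  }
  stopifnot(length(scores) == length(truth), is.logical(truth),
            all(scores >= 0))
  if (all(truth) || !any(truth)) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  pos <- scores[truth]; neg <- scores[!truth]
  thresholds <- c(sort(unique(scores)), Inf)
  tpr <- vapply(thresholds, function(t) mean(pos < t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  roc <- data.frame(threshold = c(-Inf, thresholds),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))
  best <- best[which.min(roc$fpr[best])]  # tie -> higher specificity
  chosen <- roc$threshold[best]
  pred <- scores < chosen
  confusion <- matrix(c(sum(pred & truth), sum(pred & !truth),
                        sum(!pred & truth), sum(!pred & !truth)),
                      nrow = 2, byrow = TRUE,
                      dimnames = list(predicted = c("above_or_MBC", "not_MBC"),
                                      reference = c("above_or_MBC", "not_MBC")))
  list(roc_points = roc, auc = auc, chosen_threshold = chosen,
       sensitivity = roc$tpr[best], specificity = 1 - roc$fpr[best],
       confusion = confusion)
}

#' Pool per-group concordance counts into one percentage
#'
#' @param numerators,denominators aligned non-negative counts; the pooled
#'   percentage is `100 * sum(numerators) / sum(denominators)` rounded
#'   half-up to one decimal.
#' @return the pooled percentage.
#' @export
pooled_percentage <- function(numerators, denominators) {
  stopifnot(length(numerators) == length(denominators),
            all(denominators > 0), all(numerators >= 0),
            all(numerators <= denominators))
  round_half_up(100 * sum(numerators) / sum(denominators), 1)
}

#' Welch's unequal-variance t test
#'
#' Wrapper around [stats::t.test()] with Satterthwaite degrees of freedom;
#' degenerate constant-data cases (both variances zero) are handled
#' explicitly: equal means give t = 0 with p = 1, unequal means give an
#' infinite statistic with p = 0.
#'
#' @param x,y numeric samples (n >= 2 each). For `sides = "one"` the
#'   alternative is `mean(x) > mean(y)`.
#' @param sides `"two"` or `"one"`.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y, sides = c("two", "one")) {
  sides <- match.arg(sides)
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  alt <- if (sides == "two") "two.sided" else "greater"
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    t <- sign(d) * Inf
    p <- if (sides == "two") 0 else if (d > 0) 0 else 1
    return(list(t = t, df = length(x) + length(y) - 2, p = p))
  }
  ht <- stats::t.test(x, y, alternative = alt, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Wrapper around [stats::kruskal.test()] with tie correction and the
#' chi-square approximation (df = number of groups - 1). When every
#' observation is identical the statistic is 0 and p = 1.
#'
#' @param groups list of numeric samples (>= 2 groups, total n >= 3).
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 1),
            sum(vapply(groups, length, integer(1))) >= 3)
  allv <- unlist(groups)
  if (length(unique(allv)) == 1) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  ht <- stats::kruskal.test(groups)
  list(H = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
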