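#' Classify references by an average-Tau cutoff
#'
#' Splits a reference universe into high-connectivity (`tau > cutoff`,
#' strict) and the rest.  Query compounds (e.g. the statins themselves)
#' should be excluded from the universe beforehand via `exclude`.
#'
#' @param avg_tau Named numeric vector of average Tau per reference.
#' @param cutoff Threshold in \[-100, 100\] (default 90).
#' @param exclude Reference names to remove from the universe before
#'   classification.
#' @return List with `high` and `low` character vectors partitioning the
#'   universe.
#' @export
threshold_classify <- function(avg_tau, cutoff = 90, exclude = character(0)) {
  stopifnot(cutoff >= -100, cutoff <= 100)
  avg_tau <- avg_tau[setdiff(names(avg_tau), exclude)]
  list(high = names(avg_tau)[avg_tau > cutoff],
       low = names(avg_tau)[avg_tau <= cutoff])
}

#' Build the 2x2 class-by-connectivity table
#'
#' @param high Character vector of high-connectivity references.
#' @param universe All references under consideration.
#' @param class_members References belonging to the drug class of
#'   interest.
#' @return Named list `a` (class & high), `b` (class & not high),
#'   `c` (non-class & high), `d` (non-class & not high).
#' @export
enrichment_table <- function(high, universe, class_members) {
  high <- intersect(high, universe)
  class_members <- intersect(class_members, universe)
  a <- length(intersect(class_members, high))
  b <- length(class_members) - a
  c_ <- length(high) - a
  d <- length(universe) - length(class_members) - c_
  list(a = a, b = b, c = c_, d = d)
}

#' Chi-square test for drug-class enrichment
#'
#' Pearson chi-square test (1 df) on the 2x2 table of class membership
#' against high connectivity, with the odds ratio `ad / bc`.  The
#' default is the uncorrected statistic; Yates continuity correction and
#' Fisher's exact test are available as options.
#'
#' @param table List or vector with counts `a` (class & high), `b`
#'   (class & not high), `c` (non-class & high), `d` (non-class & not
#'   high); all margins must be positive.
#' @param correction `"none"` (default) or `"yates"`.
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return List with `chi2`, `p`, `odds_ratio` (and `method`).
#' @export
class_enrichment_test <- function(table, correction = c("none", "yates"),
                                  method = c("chisq", "fisher")) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  a <- table[["a"]]; b <- table[["b"]]; c_ <- table[["c"]]; d <- table[["d"]]
  cnt <- c(a, b, c_, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("cell counts must be non-negative integers")
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) stop("all margins of the 2x2 table must be positive")
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  if (method == "fisher") {
    ft <- fisher.test(matrix(cnt, 2, byrow = TRUE))
    return(list(chi2 = NA_real_, p = ft$p.value, odds_ratio = or,
                method = "fisher"))
  }
  # Pearson chi-square with 1 df, optional Yates continuity correction
  expct <- outer(c(a + b, c_ + d), c(a + c_, b + d)) / n
  obs <- matrix(cnt, 2, byrow = TRUE)
  dev <- abs(obs - expct)
  if (correction == "yates") dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expct)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       odds_ratio = or, method = paste0("chisq_", correction))
}
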