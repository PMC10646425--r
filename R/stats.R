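#' One-way analysis of variance across groups
#'
#' Standard between/within decomposition via [stats::aov()]. Groups are
#' supplied as a named list of numeric vectors (e.g. per-animal pooled
#' myocardial T1 at each imaging timepoint).
#'
#' @param groups named list of numeric vectors; >= 2 groups, each with
#'   >= 2 values.
#' @return list with \code{F}, \code{dfBetween}, \code{dfWithin}, \code{p},
#'   \code{msWithin}, \code{groupMeans}, \code{groupN}.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least two values")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  # aov warns on a perfect fit; the zero-variance case becomes our error
  tab <- suppressWarnings(stats::anova(stats::aov(value ~ group, data = df)))
  msw <- tab["Residuals", "Mean Sq"]
  if (msw == 0) stop("zero within-group variance: F is undefined")
  list(F = tab["group", "F value"],
       dfBetween = tab["group", "Df"],
       dfWithin = tab["Residuals", "Df"],
       p = tab["group", "Pr(>F)"],
       msWithin = msw,
       groupMeans = vapply(groups, mean, numeric(1)),
       groupN = vapply(groups, length, integer(1)))
}

#' Fisher's Least Significant Difference post-hoc test
#'
#' Unadjusted pairwise t tests using the ANOVA pooled within-group
#' variance: t = (m_i - m_j) / sqrt(MSW (1/n_i + 1/n_j)) on the ANOVA
#' residual degrees of freedom. By construction LSD applies no multiplicity
#' correction beyond the pooled variance itself. Pairs are flagged
#' significant at P < 0.05.
#'
#' @param groups the named list of groups the ANOVA was computed on.
#' @param anovaRes result of [oneWayAnova()] on the same groups.
#' @return data.frame with one row per unordered pair: \code{group1},
#'   \code{group2}, \code{meanDiff}, \code{t}, \code{p},
#'   \code{significant}.
#' @export
fisherLSD <- function(groups, anovaRes) {
  nms <- names(groups)
  m <- anovaRes$groupMeans
  n <- anovaRes$groupN
  msw <- anovaRes$msWithin
  dfw <- anovaRes$dfWithin
  pairs <- utils::combn(seq_along(nms), 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- m[i] - m[j]
    tval <- d / sqrt(msw * (1 / n[i] + 1 / n[j]))
    p <- 2 * stats::pt(-abs(tval), dfw)
    data.frame(group1 = nms[i], group2 = nms[j], meanDiff = unname(d),
               t = unname(tval), p = unname(p), significant = p < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Combined ANOVA + LSD analysis
#'
#' @param groups named list of numeric vectors (see [oneWayAnova()]).
#' @return A [StatsResult-class].
#' @export
anovaLSD <- function(groups) {
  a <- oneWayAnova(groups)
  new("StatsResult", anova = a, lsd = fisherLSD(groups, a))
}
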