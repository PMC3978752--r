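# Two-sample and contingency tests used by the response analysis and
# the cross-tabulation reports.  Implemented directly (exact enumeration
# / closed forms) so the package's p-values are self-contained.

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration of the Mann-Whitney U distribution when the smaller
#' sample has at most 8 observations and there are no ties; otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `statistic` (U for `x`), `p`, and `method`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) lb_stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(nx, ny) <= 8L && !ties) {
    # exact: U distribution over all C(N, nx) rank assignments
    combos <- utils::combn(N, nx)
    u_all <- colSums(combos) - nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= U), mean(u_all >= U)))
    return(list(statistic = U, p = p, method = "exact"))
  }
  mu <- nx * ny / 2
  tab <- table(c(x, y))
  tie_adj <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_adj)
  if (sigma2 <= 0) return(list(statistic = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(statistic = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Two-sided 2x2 contingency test
#'
#' `chi2_cc` is the chi-square test with Yates continuity correction on
#' one degree of freedom; `fisher` is the exact hypergeometric test
#' (two-sided p = sum of table probabilities no larger than the observed
#' one).  A zero margin makes the chi-square statistic undefined, in
#' which case the function falls back to Fisher with a warning.
#'
#' @param tab 2x2 matrix (or coercible) of nonnegative integer counts.
#' @param method `"chi2_cc"` (default) or `"fisher"`.
#' @return list with `p`, `method`, and for chi-square the `statistic`.
#' @export
contingency_test <- function(tab, method = c("chi2_cc", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) lb_stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) lb_stop("counts must be nonnegative integers")
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (method == "chi2_cc" && (any(rs == 0) || any(cs == 0))) {
    lb_warn("zero margin: falling back to Fisher's exact test")
    method <- "fisher"
  }
  if (method == "chi2_cc") {
    E <- outer(rs, cs) / n
    adj <- pmin(0.5, abs(tab - E))
    stat <- sum((abs(tab - E) - adj)^2 / E)
    return(list(statistic = stat,
                p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                method = "chi2_cc"))
  }
  # Fisher: condition on margins, enumerate over the (1,1) cell
  k <- 0:min(rs[1], cs[1])
  probs <- stats::dhyper(k, cs[1], cs[2], rs[1])
  p_obs <- stats::dhyper(tab[1, 1], cs[1], cs[2], rs[1])
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(p = p, method = "fisher")
}
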