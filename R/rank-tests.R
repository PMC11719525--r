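# Nonparametric tests used by the coverage comparisons.

#' Exact Wilcoxon signed-rank test (two-sided)
#'
#' Paired differences `d = x - y`; zero differences are dropped, `|d|` is
#' ranked (midranks on ties) and the statistic is the sum of
#' positively-signed ranks. With `n <= max_exact` untied differences, the
#' p-value is exact over the `2^n` equiprobable sign assignments, computed
#' by the standard convolution of the rank-sum distribution (identical to
#' full enumeration): `p = P(|W - mu| >= |w - mu|)` with `mu = n(n+1)/4`.
#' With ties or larger `n`, a normal approximation with tie-corrected
#' variance and continuity correction is used instead, and `method` records
#' which path was taken.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param max_exact largest `n` for the exact distribution.
#' @return list: `statistic` (W), `n` (non-zero pairs), `p_value`, `method`.
#' @export
exact_wilcoxon_signed_rank <- function(x, y, max_exact = 25L) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, n = 0L, p_value = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  has_ties <- anyDuplicated(abs(d)) > 0L
  if (!has_ties && n <= max_exact) {
    # distribution of W over all sign assignments: polynomial convolution
    counts <- 1
    for (ri in seq_len(n)) {
      shifted <- c(rep(0, ri), counts)
      counts <- c(counts, rep(0, ri)) + shifted
    }
    wvals <- seq(0, n * (n + 1) / 2)
    p <- sum(counts[abs(wvals - mu) >= abs(w - mu) - 1e-9]) / 2^n
    return(list(statistic = w, n = n, p_value = min(1, p),
                method = "exact"))
  }
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24
  if (has_ties) {
    tab <- table(r)
    sigma2 <- sigma2 - sum(tab^3 - tab) / 48
  }
  if (sigma2 <= 0) {
    return(list(statistic = w, n = n, p_value = 1,
                method = "normal-degenerate"))
  }
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(statistic = w, n = n, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal-approx")
}

#' Steel-Dwass all-pairs comparison
#'
#' For every pair of groups, the pooled pair is midranked, the rank sum of
#' the first group is standardised with the tie-corrected two-sample
#' variance, and `|t| * sqrt(2)` is referred to the studentized-range
#' distribution with `k` groups and infinite degrees of freedom — the
#' classical Steel-Dwass procedure, which controls the family-wise error
#' over all pairs.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each `n >= 2`).
#' @return data.frame with one row per unordered pair: `group1`, `group2`,
#'   `statistic` (standardised rank-sum `t`), `p_value`.
#' @export
steel_dwass <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2)) stopf("each group needs n >= 2")
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(pr) {
    gi <- groups[[pr[1]]]; gj <- groups[[pr[2]]]
    ni <- length(gi); nj <- length(gj); N <- ni + nj
    pooled <- c(gi, gj)
    r <- rank(pooled)
    Ri <- sum(r[seq_len(ni)])
    E <- ni * (N + 1) / 2
    V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    if (V <= 0) return(c(statistic = 0, p_value = 1))
    t_stat <- (Ri - E) / sqrt(V)
    p <- stats::ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    c(statistic = t_stat, p_value = min(1, p))
  })
  data.frame(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    statistic = res["statistic", ],
    p_value = res["p_value", ],
    stringsAsFactors = FALSE)
}
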