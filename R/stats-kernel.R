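## Shared statistical primitives. Every Spearman correlation in the package
## (screen, link filter, ATAC coupling) goes through spearman_test() /
## spearman_screen_matrix() so that identical vectors always yield identical
## rho, as the downstream stages assume.

rank_rows <- function(m) {
  stopifnot(is.matrix(m))
  r <- t(apply(m, 1L, rank, ties.method = "average", na.last = "keep"))
  dimnames(r) <- dimnames(m)
  r
}

#' Spearman correlation with t-approximation p-value
#'
#' Average-rank Spearman rho between two vectors with a two-sided p-value
#' from the t approximation on n - 2 degrees of freedom. Pairs are restricted
#' to complete observations and re-ranked on that subset. A constant vector
#' (zero rank variance) yields `rho = NA`, `p = NA`: undefined pairs can
#' never be flagged significant downstream.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p`, and `n` (complete pairs used).
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = spearman_p(rho, n), n = n)
}

## two-sided p from the t approximation; rho exactly +/-1 gives p = 0
spearman_p <- function(rho, n) {
  r <- pmin(1, pmax(-1, rho))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  tt[abs(r) >= 1] <- Inf * sign(r[abs(r) >= 1])
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[n < 3] <- NA_real_
  p
}

#' Matrix Spearman screen kernel
#'
#' Rank-transforms the rows of both matrices and computes all pairwise
#' Pearson correlations on ranks (`nrow(a)` x `nrow(b)` result), with a
#' matching matrix of two-sided t-approximation p-values. Missing cells use
#' pairwise-complete observations; rows with zero rank variance give NA.
#'
#' @param a,b numeric matrices with samples in columns (identical column
#'   order).
#' @return list of matrices `rho`, `p`, `n`.
#' @keywords internal
spearman_screen_matrix <- function(a, b) {
  stopifnot(ncol(a) == ncol(b))
  dn <- list(rownames(a), rownames(b))
  rho <- matrix(NA_real_, nrow(a), nrow(b), dimnames = dn)
  p <- rho
  npair <- matrix(ncol(a), nrow(a), nrow(b), dimnames = dn)
  na_a <- rowSums(is.na(a)) > 0L
  na_b <- rowSums(is.na(b)) > 0L
  if (any(!na_a) && any(!na_b)) {
    ra <- rank_rows(a[!na_a, , drop = FALSE])
    rb <- rank_rows(b[!na_b, , drop = FALSE])
    r <- suppressWarnings(stats::cor(t(ra), t(rb)))
    rho[!na_a, !na_b] <- r
    pp <- spearman_p(as.vector(r), ncol(a))
    pp[is.na(as.vector(r))] <- NA_real_
    p[!na_a, !na_b] <- pp
  }
  # rows with missing cells take the exact pairwise path (re-ranked on the
  # complete subset, matching spearman_test)
  slow <- which(outer(na_a, rep(TRUE, nrow(b)), "&") |
                  outer(rep(TRUE, nrow(a)), na_b, "&"), arr.ind = TRUE)
  for (k in seq_len(nrow(slow))) {
    i <- slow[k, 1L]
    j <- slow[k, 2L]
    st <- spearman_test(a[i, ], b[j, ])
    rho[i, j] <- st$rho
    p[i, j] <- st$p
    npair[i, j] <- st$n
  }
  list(rho = rho, p = p, n = npair)
}

#' One-sided Mann-Whitney U test (first group greater)
#'
#' Rank-sum test that values in `x` tend to exceed values in `y`. The exact
#' null distribution is enumerated when `min(n1, n2) <= 8` and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `U` (statistic for `x`) and `p` (one-sided).
#' @export
mwu_greater <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    return(list(U = NA_real_, p = NA_real_))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- stats::wilcox.test(x, y, alternative = "greater",
                           exact = exact, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Hypergeometric upper tail P(X >= k)
#'
#' Tail probability of drawing at least `k` marked elements when `draws`
#' elements are sampled without replacement from a universe of
#' `universe` elements of which `marked` are marked. This is the one-sided
#' Fisher p-value for enrichment.
#'
#' @param k observed overlap.
#' @param marked number of marked elements in the universe.
#' @param universe universe size.
#' @param draws number of draws.
#' @return numeric p-value in \[0, 1\].
#' @export
hyper_tail <- function(k, marked, universe, draws) {
  stopifnot(universe >= marked, universe >= draws, k >= 0)
  stats::phyper(k - 1, marked, universe - marked, draws, lower.tail = FALSE)
}
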