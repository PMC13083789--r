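#' Significance stars
#'
#' Annotation convention used throughout the figures: `****` for
#' `p < 0.0001`, `***` for `p < 0.001`, `**` for `p < 0.01`, `*` for
#' `p < 0.05`, `"ns"` otherwise.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Character vector of annotations.
#' @examples
#' significance_stars(c(0.03, 0.5, 0.0005))
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.0001, "****",
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "ns"))))
}

new_test_result <- function(method, statistic, p_value, n,
                            exact, degenerate = FALSE) {
  structure(
    list(method = method, statistic = statistic,
         p_value = p_value, n = n, stars = significance_stars(p_value),
         exact = exact, degenerate = degenerate),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (%s)%s\n",
              x$method, x$statistic, x$p_value, x$stars,
              if (x$exact) " [exact]" else " [normal approx.]"))
  if (x$degenerate) cat("  degenerate: all paired differences were zero\n")
  invisible(x)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired test on `x - y`. Zero differences are dropped (the
#' common convention); absolute differences are mid-ranked under ties. For
#' 25 or fewer nonzero pairs the p-value is exact — the full null
#' distribution of the positive-rank sum `W+` over all `2^n` sign
#' assignments is enumerated (by dynamic programming over the doubled
#' ranks, which handles mid-ranks exactly) and the two-sided p is
#' `min(1, 2 * min(P(W+ <= w), P(W+ >= w)))`. Above 25 pairs a normal
#' approximation with tie correction is used, without continuity
#' correction.
#'
#' @param x,y Paired numeric vectors of equal length (`>= 1`).
#' @return A `test_result` with fields `method`, `statistic` (`W+`),
#'   `p_value`, `n` (nonzero pairs used), `stars`, `exact`, `degenerate`.
#'   If every difference is zero the result is degenerate with `p = 1`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(2, 3, 4))  # W+ = 0, p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L) {
    stop("`x` and `y` must be paired vectors of equal length >= 1",
         call. = FALSE)
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(new_test_result("wilcoxon_signed_rank", statistic = 0,
                           p_value = 1, n = 0L, exact = TRUE,
                           degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))  # doubled mid-ranks are integers
    # counts[s + 1] = number of sign assignments with doubled W+ == s
    counts <- numeric(sum(r2) + 1L)
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(length(counts) - rr)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * w))
    total <- 2^n
    p_le <- sum(counts[seq_len(w2 + 1L)]) / total
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- 2 * pnorm(-abs(w - mu) / sqrt(sigma2))
    exact <- FALSE
  }
  new_test_result("wilcoxon_signed_rank", statistic = w, p_value = p,
                  n = n, exact = exact)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided unpaired test. For combined sample sizes of 16 or fewer the
#' p-value is exact: the null distribution of the Mann-Whitney `U`
#' statistic is enumerated over all `choose(n1 + n2, n1)` assignments of
#' the pooled mid-ranks to the first sample (a permutation distribution
#' conditional on the observed values, so ties are handled exactly), and
#' the two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))`. For larger
#' samples a tie-corrected normal approximation is used, without
#' continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A `test_result` with `statistic` = `U` for the first sample.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("`x` and `y` must both be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= 16L) {
    subsets <- combn(n, n1)
    base <- n1 * (n1 + 1) / 2
    us <- colSums(matrix(r[subsets], nrow = n1)) - base
    eps <- 1e-9
    p_le <- mean(us <= u + eps)
    p_ge <- mean(us >= u - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- 2 * pnorm(-abs(u - mu) / sqrt(sigma2))
    exact <- FALSE
  }
  new_test_result("mann_whitney", statistic = u, p_value = p,
                  n = c(n1 = n1, n2 = n2), exact = exact)
}
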