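# Statistical machinery: permutation tests for regression slopes, slope
# differences and mean differences, a normality gate, and rank tests.

#' Number of permutations as a function of sample size
#'
#' 10^4 permutations for n < 500, 10^5 for n >= 500. Permutation subsets are
#' sampled uniformly with replacement from the permutation group, and p-values
#' carry an add-one correction so they are always strictly positive.
#'
#' @param n sample size.
#' @return integer number of permutations.
#' @export
perm_count <- function(n) if (n < 500) 1e4L else 1e5L

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Permutation test of a regression slope against zero
#'
#' The null distribution is built by refitting the slope on random pairings of
#' x and y; the two-sided p-value is the add-one-corrected fraction of null
#' slopes at least as extreme as the observed one.
#'
#' @param x,y data (n >= 3).
#' @param n_perm number of permutations (default from [perm_count()]).
#' @param seed optional integer seed.
#' @return list `slope`, `p`, `n_perm`.
#' @export
perm_test_slope_zero <- function(x, y, n_perm = NULL, seed = NULL) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  if (var(x) == 0) stop("constant x")
  n_perm <- n_perm %||% perm_count(n)
  obs <- ols_slope(x, y)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm),
                   function(i) ols_slope(x, y[sample.int(n)]), 1)
    p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
    list(slope = obs, p = p, n_perm = n_perm)
  })
}

#' Permutation test for the difference of two regression slopes
#'
#' Observations are randomly reassigned to the two samples (keeping the
#' sample sizes); the statistic is `slope1 - slope2`.
#'
#' @param x1,y1,x2,y2 the two samples (n >= 3 each).
#' @param n_perm number of permutations (default from [perm_count()] of the
#'   pooled size).
#' @param seed optional integer seed.
#' @return list `slope1`, `slope2`, `diff`, `p`, `n_perm`.
#' @export
perm_test_slope_difference <- function(x1, y1, x2, y2, n_perm = NULL,
                                       seed = NULL) {
  stopifnot(length(x1) >= 3, length(x2) >= 3)
  n1 <- length(x1)
  x <- c(x1, x2); y <- c(y1, y2)
  n <- length(x)
  n_perm <- n_perm %||% perm_count(n)
  s1 <- ols_slope(x1, y1); s2 <- ols_slope(x2, y2)
  obs <- s1 - s2
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      a <- idx[seq_len(n1)]; b <- idx[-seq_len(n1)]
      ols_slope(x[a], y[a]) - ols_slope(x[b], y[b])
    }, 1)
    p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
    list(slope1 = s1, slope2 = s2, diff = obs, p = p, n_perm = n_perm)
  })
}

#' Permutation test for the difference of two means
#'
#' Independent-type permutation: observations are pooled and reassigned to
#' the two groups.
#'
#' @param a,b numeric samples.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list `diff`, `p`, `n_perm`.
#' @export
perm_test_mean_difference <- function(a, b, n_perm = NULL, seed = NULL) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n_perm <- n_perm %||% perm_count(length(a) + length(b))
  pool <- c(a, b)
  na <- length(a)
  obs <- mean(a) - mean(b)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pool))
      mean(pool[idx[seq_len(na)]]) - mean(pool[idx[-seq_len(na)]])
    }, 1)
    p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
    list(diff = obs, p = p, n_perm = n_perm)
  })
}

#' Mann-Whitney rank test (two-sided)
#' @param a,b numeric samples.
#' @return p-value.
#' @export
rank_test <- function(a, b) {
  wilcox.test(a, b, exact = FALSE)$p.value
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness z-test (Johnson SU approximation) and the kurtosis
#' z-test (Anscombe-Glynn) into `K2 = Zs^2 + Zk^2 ~ chi^2(2)`.
#'
#' @param x numeric sample, n >= 20.
#' @return list `statistic`, `p`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 20) stop("D'Agostino-Pearson requires n >= 20")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  # skewness
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- zs^2 + zk^2
  list(statistic = k2, p = pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Normality gate
#'
#' Shapiro-Wilk for small samples (n < 50), D'Agostino-Pearson otherwise;
#' selects the Wald vs permutation path in [radial_trend()].
#'
#' @param x numeric sample.
#' @param alpha significance threshold.
#' @return list `normal` (logical), `p`, `test`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("too few observations for a normality test")
  if (length(x) < 50) {
    p <- shapiro.test(x)$p.value
    test <- "shapiro-wilk"
  } else {
    p <- dagostino_pearson(x)$p
    test <- "dagostino-pearson"
  }
  list(normal = p >= alpha, p = p, test = test)
}
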