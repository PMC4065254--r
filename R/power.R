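#' Query describing one kindred progeny test
#'
#' Bundles the parameters of the per-kindred test of "no modifier": the
#' baseline negative binomial (mean `mu`, shape `k`), the fold effect `f`
#' carried (heterozygously, hence segregating to half the progeny), the
#' number of phenotyped progeny `n`, the significance level and sidedness.
#'
#' @param mu baseline mean tumor count.
#' @param k negative-binomial shape (overdispersion) parameter.
#' @param f multiplicative fold effect of the modifier (`f = 1` means none).
#' @param n number of Min/+ progeny phenotyped in the kindred.
#' @param alpha significance level of the test.
#' @param sidedness `"two"` (default) or `"one"` (direction taken from `f`).
#' @param segregation_prob probability a progeny inherits the modifier.
#' @return An object of class `design_query`.
#' @examples
#' design_query(f = 2, n = 20)
#' @export
design_query <- function(mu = 99.8, k = 9.8, f = 1, n = 20L, alpha = 0.05,
                         sidedness = c("two", "one"), segregation_prob = 0.5) {
  sidedness <- match.arg(sidedness)
  stopifnot(mu > 0, k > 0, f > 0, alpha > 0, alpha < 1,
            segregation_prob > 0, segregation_prob <= 1,
            n >= 0, n == floor(n))
  structure(list(mu = mu, k = k, f = f, n = as.integer(n), alpha = alpha,
                 sidedness = sidedness, segregation_prob = segregation_prob),
            class = "design_query")
}

#' Normal approximation to the within-kindred mean tumor count
#'
#' Under the null the kindred mean of `n` animals is approximately
#' `Normal(mu, (mu + mu^2/k)/n)`. Under the alternative (fold `f`,
#' segregating to half the progeny) the mean is `mu (1 + f)/2` and the
#' variance adds the between-genotype term:
#' `[ (mu f + (mu f)^2/k)/2 + (mu + mu^2/k)/2 + mu^2 (f - 1)^2/4 ] / n`.
#'
#' @param q a [design_query()].
#' @param under_alternative if `FALSE`, the null (no-modifier) distribution.
#' @return Named numeric `c(mean, sd)`.
#' @examples
#' kindred_mean_distribution(design_query(f = 2, n = 1), under_alternative = FALSE)
#' @export
kindred_mean_distribution <- function(q, under_alternative = TRUE) {
  stopifnot(inherits(q, "design_query"))
  if (q$n < 1L) stop("n must be at least 1")
  v0 <- nb_variance(q$mu, q$k)
  if (!under_alternative)
    return(c(mean = q$mu, sd = sqrt(v0 / q$n)))
  s <- q$segregation_prob
  mu1 <- q$mu * q$f
  m <- (1 - s) * q$mu + s * mu1
  v <- (s * nb_variance(mu1, q$k) + (1 - s) * v0 +
          s * (1 - s) * (mu1 - q$mu)^2) / q$n
  c(mean = m, sd = sqrt(v))
}

reject_bounds <- function(q) {
  sd0 <- sqrt(nb_variance(q$mu, q$k) / q$n)
  if (q$sidedness == "two") {
    z <- qnorm(1 - q$alpha / 2)
    c(lo = q$mu - z * sd0, hi = q$mu + z * sd0)
  } else if (q$f >= 1) {
    c(lo = -Inf, hi = q$mu + qnorm(1 - q$alpha) * sd0)
  } else {
    c(lo = q$mu - qnorm(1 - q$alpha) * sd0, hi = Inf)
  }
}

#' Power of the kindred progeny test
#'
#' Power of the normal-approximation test of the null "this kindred carries
#' no modifier" at level `alpha`, for a kindred segregating a fold-`f`
#' modifier to `n` progeny. The rejection region comes from the null normal
#' approximation of the kindred mean; the alternative is evaluated by
#' conditioning on the binomial number of carriers (normal within each
#' carrier stratum), which keeps the approximation accurate down to small
#' `n` where the carrier-count lumpiness matters.
#'
#' @param q a [design_query()].
#' @return Rejection probability. Equals `alpha` at `f = 1`.
#' @examples
#' kindred_power(design_query(f = 2, n = 20))
#' @export
kindred_power <- function(q) {
  stopifnot(inherits(q, "design_query"))
  if (q$n < 1L) stop("n must be at least 1")
  b <- reject_bounds(q)
  cs <- 0:q$n
  w <- dbinom(cs, q$n, q$segregation_prob)
  m <- (cs * q$f * q$mu + (q$n - cs) * q$mu) / q$n
  v <- (cs * nb_variance(q$f * q$mu, q$k) +
          (q$n - cs) * nb_variance(q$mu, q$k)) / q$n^2
  sdv <- sqrt(v)
  sum(w * (pnorm(b[["lo"]], m, sdv) +
             pnorm(b[["hi"]], m, sdv, lower.tail = FALSE)))
}

#' Progeny needed to reach a target power
#'
#' Smallest `n` such that [kindred_power()] reaches `power_target`.
#'
#' @param q a [design_query()]; its `n` is ignored. `f` must differ from 1.
#' @param power_target required power (default 0.9).
#' @param n_max search cap.
#' @return Integer number of progeny.
#' @examples
#' progeny_for_power(design_query(f = 2), power_target = 0.9)
#' @export
progeny_for_power <- function(q, power_target = 0.9, n_max = 10000L) {
  stopifnot(inherits(q, "design_query"),
            power_target > 0, power_target < 1)
  if (q$f == 1) stop("f = 1: the null is true and the target power is unreachable")
  pow_at <- function(n) { q$n <- as.integer(n); kindred_power(q) }
  # bracket by doubling, then bisect on the monotone power curve
  lo <- 1L; hi <- 1L
  while (pow_at(hi) < power_target) {
    lo <- hi; hi <- hi * 2L
    if (hi > n_max) stop("required progeny exceeds n_max = ", n_max)
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pow_at(mid) >= power_target) hi <- mid else lo <- mid
  }
  if (pow_at(lo) >= power_target) lo else hi
}

#' Rank-sum test of phenotypic neutrality
#'
#' Two-sided Wilcoxon rank-sum comparison of tumor-count distributions,
#' e.g. progeny of a candidate mapping-partner line versus controls sired
#' by the same males. Exact p-values are used when sample sizes permit and
#' there are no ties.
#'
#' @param counts_a,counts_b tumor-count vectors (both non-empty).
#' @return Two-sided p-value.
#' @examples
#' neutrality_test(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
neutrality_test <- function(counts_a, counts_b) {
  if (length(counts_a) == 0L || length(counts_b) == 0L)
    stop("both samples must be non-empty")
  suppressWarnings(
    wilcox.test(counts_a, counts_b, alternative = "two.sided")$p.value)
}
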