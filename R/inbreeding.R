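#' Residual heterozygosity under repeated brother-sister mating
#'
#' For a locus heterozygous in the founding pair, the expected fraction of
#' loci still heterozygous after `t` generations of full-sib mating follows
#' the classical recurrence
#' \deqn{H_t = \tfrac12 H_{t-1} + \tfrac14 H_{t-2}, \quad H_0 = H_1 = 1.}
#' `1 - H_t` is the full-sib inbreeding coefficient. At F10 the residual
#' heterozygosity is 14% (and 11% one generation later); asymptotically
#' `H_{t+1}/H_t` tends to `(1 + sqrt(5))/4`, about 0.809.
#'
#' @param t vector of non-negative integer generation indices (`t = 0` is the
#'   founding generation).
#' @return Numeric vector of expected heterozygous fractions.
#' @examples
#' heterozygosity_remaining(0:12)
#' round(100 * heterozygosity_remaining(10))  # 14
#' @export
heterozygosity_remaining <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0) || any(t != floor(t)))
    stop("t must be a vector of non-negative integers")
  tmax <- max(t, 1)
  H <- numeric(tmax + 1L)
  H[1:2] <- 1  # H_0, H_1
  if (tmax >= 2) for (g in 2:tmax) H[g + 1L] <- H[g] / 2 + H[g - 1L] / 4
  H[t + 1L]
}

#' Generations of sib mating needed to reach a heterozygosity threshold
#'
#' @param threshold target residual heterozygosity in `(0, 1]`.
#' @return Smallest integer `t` with `H_t <= threshold`.
#' @examples
#' generations_until(0.15)  # 10
#' @export
generations_until <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  t <- 0L
  H <- c(1, 1)  # H_{t-1}, H_t rolling pair
  while (H[2] > threshold) {
    t <- t + 1L
    if (t == 1L) next  # H_1 = 1
    H <- c(H[2], H[2] / 2 + H[1] / 4)
  }
  t
}

#' Tabulate the heterozygosity series
#'
#' @param generations last generation index to report.
#' @return data.frame with columns `generation`, `heterozygosity`,
#'   `inbreeding_coefficient`.
#' @examples
#' heterozygosity_series(10)
#' @export
heterozygosity_series <- function(generations) {
  H <- heterozygosity_remaining(0:generations)
  data.frame(generation = 0:generations, heterozygosity = H,
             inbreeding_coefficient = 1 - H)
}
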