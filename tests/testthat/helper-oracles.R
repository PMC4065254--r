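# Shared fixtures and independent oracles used across test files.

toy_chrom_sizes <- function() c(chrA = 5e7, chrB = 3e7)

rdirichlet1 <- function(k) { g <- rgamma(k, 1); g / sum(g) }

# Exhaustive-enumeration oracle for the kindred likelihood: sums over all
# 2^n carrier configurations for every (class, fold) atom. Independent of
# the package's logsumexp/marginalisation path.
brute_kindred_loglik <- function(x, weights, sup_tab, enh_tab, mu, size,
                                 segregation = 0.5) {
  dens <- function(xx, f) dnbinom(xx, mu = f * mu, size = size)
  class_lik <- function(tab) {
    tot <- 0
    for (j in seq_along(tab$fold)) {
      s <- 0
      for (cfg in 0:(2^length(x) - 1)) {
        bits <- as.integer(intToBits(cfg))[seq_along(x)]
        w_cfg <- prod(ifelse(bits == 1, segregation, 1 - segregation))
        s <- s + w_cfg * prod(dens(x, ifelse(bits == 1, tab$fold[j], 1)))
      }
      tot <- tot + tab$prob[j] * s
    }
    tot
  }
  log(weights[1] * prod(dens(x, 1)) +
        (if (weights[2] > 0) weights[2] * class_lik(sup_tab) else 0) +
        (if (weights[3] > 0) weights[3] * class_lik(enh_tab) else 0))
}

# Monte-Carlo power of the kindred z-test with exact NB sampling and
# Mendelian segregation (independent of kindred_power's normal strata).
mc_kindred_power <- function(f, n, mu = 99.8, k = 9.8, alpha = 0.05,
                             reps = 4e4) {
  carrier <- matrix(runif(reps * n) < 0.5, nrow = n)
  x <- matrix(rnbinom(reps * n, mu = ifelse(carrier, f * mu, mu), size = k),
              nrow = n)
  xbar <- colMeans(x)
  z <- (xbar - mu) / sqrt((mu + mu^2 / k) / n)
  mean(abs(z) > qnorm(1 - alpha / 2))
}

# A small variant table with known structure for panel tests.
toy_variant_table <- function() {
  rec <- data.frame(
    line_id = c("g", "g", "g", "h", "h", "b", "b", "g", "h", "b"),
    chrom   = c("chrA", "chrA", "chrB", "chrA", "chrB", "chrA", "chrB",
                "chrA", "chrA", "chrA"),
    pos     = c(1e6, 2e6, 5e5, 2e6, 5e5, 3e6, 1e6, 4.5e7, 4.5e7, 4.5e7),
    ref     = c("A", "A", "T", "A", "T", "G", "C", "A", "A", "A"),
    alt     = c("T", "G", "A", "G", "A", "A", "T", "C", "C", "C"),
    depth   = c(5L, 4L, 6L, 5L, 4L, 7L, 3L, 5L, 5L, 5L),
    genotype_quality = c(99L, 99L, 99L, 99L, 99L, 99L, 99L, 99L, 99L, 99L),
    zygosity = "hom",
    flank_seq = "ACGTACGTACGTACGTACGT",
    stringsAsFactors = FALSE)
  # site chrA:2e6 A>G shared by the g/h pair; chrB:5e5 T>A shared by g/h;
  # chrA:4.5e7 A>C present in g, h AND b (remainder); others line-specific
  line_variant_table(rec, lines = data.frame(
    line_id = c("g", "h", "b"), mean_coverage = c(6, 6, 6),
    stringsAsFactors = FALSE))
}
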