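#' Screen design under the FDR-nonempty-list criterion
#'
#' A screen of `N` kindreds, each progeny-tested with `n` animals, reports
#' the kindreds whose Benjamini-Hochberg adjusted p-values fall below
#' `fdr_q`. The design criterion asks that this reported list contain at
#' least one kindred truly carrying a modifier beyond a stated fold
#' threshold, with probability at least `discovery_prob`.
#' `discovery_probability()` estimates that probability by Monte Carlo;
#' [screen_size_for_discovery()] inverts it for the smallest `N`.
#'
#' Kindred data are simulated exactly: the kindred's (class, fold) is drawn
#' from the mixture, the number of carriers is binomial, and tumor-count
#' sums are negative binomial; each kindred's p-value comes from the
#' normal-approximation test of the no-modifier null. Common random numbers
#' are used across values of `N` (the screen of `N` kindreds is the first
#' `N` columns of one simulated pool), so estimated curves are directly
#' comparable.
#'
#' @param classes a [modifier_class_params()], or a data.frame
#'   `(class, fold, prob)` giving the kindred effect mixture directly.
#' @param N integer vector of screen sizes to evaluate.
#' @param n progeny phenotyped per kindred.
#' @param effect_threshold fold defining a discovery worth making (`> 1`
#'   enhancer side, `< 1` suppressor side).
#' @param colony a [colony_model()] for the baseline negative binomial.
#' @param fdr_q Benjamini-Hochberg false discovery rate of the reported list.
#' @param alpha unused by BH itself; kept for the per-kindred p-value side
#'   convention (`sidedness`).
#' @param sidedness sidedness of the per-kindred test.
#' @param mc_reps Monte-Carlo replicates (at least 1000 for design use).
#' @param seed master seed.
#' @return `discovery_probability()`: data.frame `(N, prob)`.
#' @examples
#' \donttest{
#' discovery_probability(modifier_class_params(), N = c(10, 20), n = 20,
#'                       effect_threshold = 2, mc_reps = 200, seed = 1)
#' }
#' @export
discovery_probability <- function(classes, N, n, effect_threshold,
                                  colony = colony_model(), fdr_q = 0.05,
                                  alpha = 0.05, sidedness = "two",
                                  mc_reps = 2000L, seed = 1L) {
  tab <- as_effect_table(classes)
  pool <- screen_pool(tab, max(N), n, colony, sidedness, mc_reps, seed,
                      effect_threshold)
  data.frame(N = N,
             prob = vapply(N, function(nn)
               discovery_prob_from_pool(pool, nn, fdr_q), numeric(1)))
}

as_effect_table <- function(classes, n_grid = 40L) {
  if (inherits(classes, "modifier_class_params"))
    return(class_effect_table(classes, n_grid = n_grid))
  stopifnot(is.data.frame(classes), all(c("fold", "prob") %in% names(classes)))
  classes$prob <- classes$prob / sum(classes$prob)
  classes
}

# One pooled simulation: mc_reps x N_pool matrices of per-kindred p-values
# and "carries an effect beyond the threshold" flags. Kindreds are i.i.d.,
# so a screen of N kindreds is the first N columns.
screen_pool <- function(tab, N_pool, n, colony, sidedness, mc_reps, seed,
                        effect_threshold, segregation = 0.5, stream = "screen_pool") {
  stopifnot(effect_threshold > 0, effect_threshold != 1)
  beyond <- if (effect_threshold > 1) tab$fold >= effect_threshold
            else tab$fold <= effect_threshold
  if (sum(tab$prob[beyond]) == 0)
    stop("the mixture has zero modifier mass beyond the effect threshold")
  mu <- colony$mean_tumor_count; k <- colony$nb_shape
  tot <- as.integer(mc_reps) * as.integer(N_pool)
  with_substream(seed, stream, {
    atom <- sample.int(nrow(tab), tot, replace = TRUE, prob = tab$prob)
    f <- tab$fold[atom]
    C <- rbinom(tot, n, segregation)
    # sum of C iid NB(f mu, k) is NB(C f mu, C k); likewise the non-carriers
    s_car <- s_non <- numeric(tot)
    i <- C > 0
    s_car[i] <- rnbinom(sum(i), mu = (C * f * mu)[i], size = (C * k)[i])
    j <- C < n
    s_non[j] <- rnbinom(sum(j), mu = ((n - C) * mu)[j], size = ((n - C) * k)[j])
    xbar <- (s_car + s_non) / n
    z <- (xbar - mu) / sqrt(nb_variance(mu, k) / n)
    pval <- if (sidedness == "two") 2 * pnorm(-abs(z)) else pnorm(-z)
    list(pval = matrix(pval, nrow = mc_reps),
         large = matrix(beyond[atom], nrow = mc_reps),
         mc_reps = mc_reps, N_pool = N_pool)
  })
}

discovery_prob_from_pool <- function(pool, N, fdr_q) {
  stopifnot(N <= pool$N_pool)
  hits <- vapply(seq_len(pool$mc_reps), function(r) {
    p <- pool$pval[r, seq_len(N)]
    any(p.adjust(p, method = "BH") <= fdr_q & pool$large[r, seq_len(N)])
  }, logical(1))
  mean(hits)
}

#' Smallest screen size meeting the discovery criterion
#'
#' Finds the smallest number of kindreds `N` such that the BH-reported list
#' at `fdr_q` contains a true modifier beyond `effect_threshold` with
#' probability at least `discovery_prob`, by doubling then bisection on the
#' common-random-number Monte-Carlo curve.
#'
#' @inheritParams discovery_probability
#' @param discovery_prob required probability of a nonempty true-discovery
#'   list.
#' @param N_max search cap.
#' @return Integer `N`, with attribute `prob` (the MC estimate at `N`).
#' @examples
#' \donttest{
#' screen_size_for_discovery(modifier_class_params(), n = 20,
#'                           effect_threshold = 2, mc_reps = 1000, seed = 1)
#' }
#' @export
screen_size_for_discovery <- function(classes, n, effect_threshold,
                                      colony = colony_model(), fdr_q = 0.05,
                                      discovery_prob = 0.95,
                                      sidedness = "two", mc_reps = 2000L,
                                      seed = 1L, N_max = 4096L) {
  if (mc_reps < 1000L)
    warning("mc_reps below 1000 gives unstable design sizes")
  tab <- as_effect_table(classes)
  N_pool <- 16L
  pool <- screen_pool(tab, N_pool, n, colony, sidedness, mc_reps, seed,
                      effect_threshold)
  phat <- discovery_prob_from_pool(pool, N_pool, fdr_q)
  while (phat < discovery_prob) {
    if (N_pool >= N_max)
      stop("no screen of size <= ", N_max, " meets the discovery criterion ",
           sprintf("(estimated probability %.3f at N = %d)", phat, N_pool))
    N_new <- min(2L * N_pool, N_max)
    extra <- screen_pool(tab, N_new - N_pool, n, colony, sidedness, mc_reps,
                         seed, effect_threshold,
                         stream = paste0("screen_pool_ext", N_new))
    pool$pval <- cbind(pool$pval, extra$pval)
    pool$large <- cbind(pool$large, extra$large)
    pool$N_pool <- N_new
    N_pool <- N_new
    phat <- discovery_prob_from_pool(pool, N_pool, fdr_q)
  }
  lo <- 0L; hi <- N_pool  # smallest N with phat(N) >= target in (lo, hi]
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (discovery_prob_from_pool(pool, mid, fdr_q) >= discovery_prob)
      hi <- mid else lo <- mid
  }
  structure(hi, prob = discovery_prob_from_pool(pool, hi, fdr_q))
}

#' Screen design with extreme-kindred preselection
#'
#' Two-stage design: kindreds are first screened with small clusters for
#' multiple extreme animals (the [selection_rule()]), and only selected
#' kindreds enter the full progeny test. Selection reweights the modifier
#' mixture toward large effects (see [extreme_selection_enrichment()]), so
#' far fewer deeply tested kindreds are needed. The progeny number per
#' selected kindred is sized by [progeny_for_power()] at the target fold,
#' and the number of selected kindreds by [screen_size_for_discovery()] on
#' the enriched mixture.
#'
#' @inheritParams screen_size_for_discovery
#' @param rule a [selection_rule()]; `min_extreme = 0` reduces to the
#'   unselected design.
#' @param power_target per-kindred power used to size the progeny test.
#' @param alpha per-kindred significance level for the progeny sizing.
#' @param progeny optional fixed progeny number (skips the power sizing).
#' @return List with `n_kindreds`, `progeny_per_kindred`, `enrichment`,
#'   `p_selected` (probability a kindred passes preselection) and
#'   `discovery_prob_attained`.
#' @examples
#' \donttest{
#' preselected_design(modifier_class_params(), selection_rule(2, 10),
#'                    effect_threshold = 2, mc_reps = 1000, seed = 1)
#' }
#' @export
preselected_design <- function(classes, rule, effect_threshold,
                               colony = colony_model(), fdr_q = 0.05,
                               discovery_prob = 0.95, power_target = 0.9,
                               alpha = 0.05, sidedness = "two",
                               progeny = NULL, mc_reps = 2000L, seed = 1L,
                               N_max = 4096L) {
  stopifnot(inherits(classes, "modifier_class_params"),
            inherits(rule, "selection_rule"))
  enr <- extreme_selection_enrichment(classes, rule, effect_threshold, colony)
  tab_sel <- selected_effect_table(classes, rule, colony)
  if (is.null(progeny)) {
    q <- design_query(mu = colony$mean_tumor_count, k = colony$nb_shape,
                      f = effect_threshold, alpha = alpha,
                      sidedness = sidedness,
                      segregation_prob = classes$segregation_prob)
    progeny <- progeny_for_power(q, power_target = power_target)
  }
  N <- screen_size_for_discovery(tab_sel, n = progeny,
                                 effect_threshold = effect_threshold,
                                 colony = colony, fdr_q = fdr_q,
                                 discovery_prob = discovery_prob,
                                 sidedness = sidedness, mc_reps = mc_reps,
                                 seed = seed, N_max = N_max)
  list(n_kindreds = as.integer(N), progeny_per_kindred = as.integer(progeny),
       enrichment = as.numeric(enr),
       p_selected = attr(enr, "p_selected"),
       discovery_prob_attained = attr(N, "prob"))
}
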