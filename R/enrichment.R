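#' Extreme-kindred selection rule
#'
#' A kindred is flagged for follow-up when at least `min_extreme` of its
#' `cluster_size` phenotyped animals fall in the extreme tail of the
#' baseline phenotype distribution. `extreme_quantile` is the tail mass
#' defining "extreme" (default the 5th/95th baseline percentile);
#' `tail = "upper"` flags high tumor counts (short-lived kindreds, the
#' enhancer side), `tail = "lower"` flags low counts (long-lived kindreds,
#' the suppressor side). `min_extreme = 0` is the vacuous rule that selects
#' every kindred.
#'
#' @param min_extreme minimum number of extreme animals (`0 <= m <= c`).
#' @param cluster_size number of animals phenotyped in the first pass.
#' @param extreme_quantile tail probability in `(0, 0.5)` defining an
#'   extreme animal against the baseline.
#' @param tail which phenotype tail counts as extreme.
#' @return An object of class `selection_rule`.
#' @examples
#' selection_rule(min_extreme = 2, cluster_size = 10)
#' @export
selection_rule <- function(min_extreme = 2L, cluster_size = 10L,
                           extreme_quantile = 0.05,
                           tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(min_extreme >= 0, cluster_size >= 1,
            min_extreme <= cluster_size,
            extreme_quantile > 0, extreme_quantile < 0.5)
  structure(list(min_extreme = as.integer(min_extreme),
                 cluster_size = as.integer(cluster_size),
                 extreme_quantile = extreme_quantile, tail = tail),
            class = "selection_rule")
}

# P(single animal is extreme | kindred fold f): carriers (probability s)
# have NB(f mu, shape), the rest baseline. The count threshold is the
# baseline quantile; both analytic and Monte-Carlo paths use the same
# threshold so discreteness is treated identically.
extreme_count_threshold <- function(rule, colony) {
  if (rule$tail == "upper")
    qnbinom(1 - rule$extreme_quantile, mu = colony$mean_tumor_count,
            size = colony$nb_shape)
  else
    qnbinom(rule$extreme_quantile, mu = colony$mean_tumor_count,
            size = colony$nb_shape)
}

p_animal_extreme <- function(fold, rule, colony, segregation = 0.5) {
  thr <- extreme_count_threshold(rule, colony)
  tail_prob <- function(f) {
    if (rule$tail == "upper")
      pnbinom(thr, mu = f * colony$mean_tumor_count, size = colony$nb_shape,
              lower.tail = FALSE)
    else
      pnbinom(thr, mu = f * colony$mean_tumor_count, size = colony$nb_shape)
  }
  segregation * vapply(fold, tail_prob, numeric(1)) +
    (1 - segregation) * tail_prob(1)
}

p_kindred_selected <- function(fold, rule, colony, segregation = 0.5) {
  p <- p_animal_extreme(fold, rule, colony, segregation)
  if (rule$min_extreme == 0L) return(rep(1, length(p)))
  pbinom(rule$min_extreme - 1L, rule$cluster_size, p, lower.tail = FALSE)
}

#' Enrichment in large modifier effects from extreme-kindred selection
#'
#' Selecting kindreds with multiple extreme animals enriches the follow-up
#' set for large-effect modifiers. This computes
#' `P(effect beyond threshold | selected) / P(effect beyond threshold)`
#' by integrating the class/effect mixture over the selection event: for
#' each (class, fold) atom of the mixture the probability that an animal is
#' extreme is the segregation-weighted tail probability of the fold-shifted
#' negative binomial, and the kindred is selected when a binomial
#' `(cluster_size, p_extreme)` reaches `min_extreme`.
#'
#' @param classes a [modifier_class_params()].
#' @param rule a [selection_rule()].
#' @param large_effect_threshold fold defining a "large" effect: `> 1`
#'   (enhancer side, effects `>= threshold` count) or `< 1` (suppressor
#'   side, effects `<= threshold` count).
#' @param colony a [colony_model()] supplying the baseline negative binomial.
#' @param n_grid fold-grid resolution for the mixture integral.
#' @return Enrichment factor (scalar `>= 0`), with attributes
#'   `p_selected` (marginal selection probability) and `p_large`
#'   (marginal large-effect probability).
#' @examples
#' extreme_selection_enrichment(modifier_class_params(),
#'                              selection_rule(2, 10, 0.05, "upper"), 2)
#' @export
extreme_selection_enrichment <- function(classes, rule, large_effect_threshold,
                                         colony = colony_model(), n_grid = 40L) {
  stopifnot(inherits(classes, "modifier_class_params"),
            inherits(rule, "selection_rule"),
            large_effect_threshold > 0, large_effect_threshold != 1)
  tab <- class_effect_table(classes, n_grid = n_grid)
  beyond <- if (large_effect_threshold > 1)
    tab$fold >= large_effect_threshold else tab$fold <= large_effect_threshold
  p_large <- sum(tab$prob[beyond])
  if (p_large == 0)
    stop("no effect mass beyond the threshold: enrichment undefined ",
         "(P(large effect) = 0)")
  psel <- p_kindred_selected(tab$fold, rule, colony, classes$segregation_prob)
  p_selected <- sum(tab$prob * psel)
  if (p_selected == 0)
    stop("selection event has probability zero under this rule; ",
         "relax min_extreme, cluster_size or extreme_quantile")
  enr <- sum(tab$prob[beyond] * psel[beyond]) / p_selected / p_large
  structure(enr, p_selected = p_selected, p_large = p_large)
}

# Mixture of (class, fold) atoms conditional on a kindred passing the
# selection rule; feeds the preselected screen design.
selected_effect_table <- function(classes, rule, colony = colony_model(),
                                  n_grid = 40L) {
  tab <- class_effect_table(classes, n_grid = n_grid)
  psel <- p_kindred_selected(tab$fold, rule, colony, classes$segregation_prob)
  w <- tab$prob * psel
  if (sum(w) == 0) stop("selection event has probability zero under this rule")
  tab$prob <- w / sum(w)
  attr(tab, "p_selected") <- sum(w)  # marginal selection probability
  tab
}
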