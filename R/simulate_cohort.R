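#' Simulate an unmodified control cohort of Min/+ animals
#'
#' Tumor counts are drawn i.i.d. from the colony's negative binomial,
#' lifespans from the log-linear survival link. Output is deterministic per
#' seed.
#'
#' @param colony a [colony_model()].
#' @param n_animals number of animals (`>= 0`).
#' @param seed master seed.
#' @return A data.frame with one row per animal: `kindred_id` (`"control"`),
#'   `animal_id`, `carrier` (all `FALSE`), `tumor_count`, `lifespan_days`.
#' @examples
#' head(simulate_control_cohort(colony_model(), 5, seed = 1))
#' @export
simulate_control_cohort <- function(colony, n_animals, seed) {
  stopifnot(inherits(colony, "colony_model"))
  if (!is.numeric(n_animals) || length(n_animals) != 1L || n_animals < 0 ||
      n_animals != floor(n_animals))
    stop("n_animals must be a non-negative integer")
  n_animals <- as.integer(n_animals)
  with_substream(seed, "control_cohort", {
    counts <- rnbinom(n_animals, mu = colony$mean_tumor_count,
                      size = colony$nb_shape)
    data.frame(
      kindred_id = rep("control", n_animals),
      animal_id = if (n_animals) sprintf("C%05d", seq_len(n_animals)) else character(),
      carrier = rep(FALSE, n_animals),
      tumor_count = counts,
      lifespan_days = draw_lifespan(counts, colony),
      stringsAsFactors = FALSE
    )
  })
}

draw_lifespan <- function(counts, colony) {
  sl <- colony$survival_link
  exp(sl[["intercept"]] - sl[["slope"]] * log(counts + 1) +
        rnorm(length(counts), 0, sl[["noise_sd"]]))
}

#' Simulate kindred cohorts under the segregating three-component mixture
#'
#' Each kindred (the progeny cluster of one first-generation founder) is
#' assigned a latent class by the mixture weights. Modifier kindreds draw a
#' fold effect from their class's effect distribution; each progeny then
#' carries the modifier independently with the segregation probability, and
#' carriers' tumor counts are NB with mean multiplied by the fold (shape
#' unchanged). Unaffected kindreds and non-carriers follow the baseline
#' colony model.
#'
#' @param colony a [colony_model()].
#' @param classes a [modifier_class_params()].
#' @param n_kindreds,progeny_per_kindred non-negative integers.
#' @param seed master seed.
#' @return A list of class `kindred_cohort` with components
#'   `kindreds` (data.frame: `kindred_id`, `latent_class`, `fold_effect`) and
#'   `animals` (data.frame: `kindred_id`, `animal_id`, `carrier`,
#'   `tumor_count`, `lifespan_days`).
#' @examples
#' ch <- simulate_kindreds(colony_model(), modifier_class_params(),
#'                         n_kindreds = 4, progeny_per_kindred = 3, seed = 1)
#' ch$kindreds
#' @export
simulate_kindreds <- function(colony, classes, n_kindreds, progeny_per_kindred,
                              seed) {
  stopifnot(inherits(colony, "colony_model"),
            inherits(classes, "modifier_class_params"))
  for (v in c(n_kindreds, progeny_per_kindred))
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != floor(v))
      stop("n_kindreds and progeny_per_kindred must be non-negative integers")
  n_kindreds <- as.integer(n_kindreds)
  m <- as.integer(progeny_per_kindred)
  with_substream(seed, "kindred_cohort", {
    cls <- sample(c("none", "suppressor", "enhancer"), n_kindreds,
                  replace = TRUE, prob = classes$weights)
    fold <- rep(1, n_kindreds)
    fold[cls == "suppressor"] <-
      draw_fold(classes$suppressor, sum(cls == "suppressor"))
    fold[cls == "enhancer"] <-
      draw_fold(classes$enhancer, sum(cls == "enhancer"))
    kindreds <- data.frame(
      kindred_id = sprintf("K%04d", seq_len(n_kindreds)),
      latent_class = cls, fold_effect = fold, stringsAsFactors = FALSE)

    n_tot <- n_kindreds * m
    kid <- rep(kindreds$kindred_id, each = m)
    carrier <- rep(cls != "none", each = m) &
      (runif(n_tot) < classes$segregation_prob)
    mu_i <- ifelse(carrier, rep(fold, each = m), 1) * colony$mean_tumor_count
    counts <- rnbinom(n_tot, mu = mu_i, size = colony$nb_shape)
    animals <- data.frame(
      kindred_id = kid,
      animal_id = if (n_tot) paste0(kid, sprintf("-%02d", rep(seq_len(m), n_kindreds))) else character(),
      carrier = carrier,
      tumor_count = counts,
      lifespan_days = draw_lifespan(counts, colony),
      stringsAsFactors = FALSE)
    structure(list(kindreds = kindreds, animals = animals),
              class = "kindred_cohort")
  })
}

# Truncated log-normal fold effects are drawn by inverse-CDF so that no
# rejection loop perturbs the random stream.
draw_fold <- function(effect, n) {
  if (n == 0L) return(numeric())
  if (effect$dist == "point")
    return(effect$folds[sample.int(length(effect$folds), n, replace = TRUE,
                                   prob = effect$probs)])
  p1 <- plnorm(1, effect$meanlog, effect$sdlog)
  u <- if (effect$side == "suppressor") runif(n, 0, p1) else runif(n, p1, 1)
  qlnorm(u, effect$meanlog, effect$sdlog)
}

#' @export
print.kindred_cohort <- function(x, ...) {
  cat(sprintf("Kindred cohort: %d kindreds, %d animals\n",
              nrow(x$kindreds), nrow(x$animals)))
  print(table(x$kindreds$latent_class))
  invisible(x)
}
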