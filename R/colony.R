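#' Baseline colony model for the tumor-multiplicity phenotype
#'
#' Describes the unmodified phenotype of a closed Min colony: tumor counts
#' follow a negative binomial distribution with mean `mean_tumor_count` and
#' overdispersion shape `nb_shape` (variance `mu + mu^2/shape`), and lifespan
#' is linked to tumor burden on the log scale,
#' `log(lifespan) = intercept - slope * log(count + 1) + Normal(0, noise_sd)`,
#' so that heavier tumor burdens shorten life.
#'
#' Defaults are the colony estimates used throughout the package: a mean of
#' 99.8 tumors per animal with shape 9.8. The survival link is a stand-in
#' with realistic scale (about 120 days of life at 100 tumors); only its
#' sign (more tumors, shorter life) is relied upon.
#'
#' @param mean_tumor_count positive mean tumor count per Min/+ animal.
#' @param nb_shape positive negative-binomial shape (overdispersion) parameter.
#' @param survival_link numeric vector `c(intercept, slope, noise_sd)` of the
#'   log-lifespan regression on log tumor count; `slope >= 0`, `noise_sd >= 0`.
#' @return An object of class `colony_model`.
#' @examples
#' cm <- colony_model()
#' cm$mean_tumor_count
#' @export
colony_model <- function(mean_tumor_count = 99.8, nb_shape = 9.8,
                         survival_link = c(intercept = log(600),
                                           slope = 0.35, noise_sd = 0.2)) {
  stopifnot(is.numeric(mean_tumor_count), length(mean_tumor_count) == 1L,
            mean_tumor_count > 0,
            is.numeric(nb_shape), length(nb_shape) == 1L, nb_shape > 0,
            is.numeric(survival_link), length(survival_link) == 3L)
  survival_link <- setNames(as.numeric(survival_link),
                            c("intercept", "slope", "noise_sd"))
  if (survival_link[["slope"]] < 0 || survival_link[["noise_sd"]] < 0)
    stop("survival_link slope and noise_sd must be non-negative")
  structure(list(mean_tumor_count = mean_tumor_count,
                 nb_shape = nb_shape,
                 survival_link = survival_link),
            class = "colony_model")
}

#' @export
print.colony_model <- function(x, ...) {
  cat("Colony model: tumor counts ~ NB(mu =", x$mean_tumor_count,
      ", shape =", x$nb_shape, ")\n")
  cat("  variance:", round(nb_variance(x$mean_tumor_count, x$nb_shape), 1), "\n")
  cat("  log(lifespan) =", round(x$survival_link[["intercept"]], 3), "-",
      x$survival_link[["slope"]], "* log(count + 1) + N(0,",
      x$survival_link[["noise_sd"]], ")\n")
  invisible(x)
}

nb_variance <- function(mu, shape) mu + mu^2 / shape

#' Fold-effect distributions for modifier classes
#'
#' A modifier multiplies the carrier's expected tumor count by a fold effect
#' `f`: suppressors have `f` in (0, 1), enhancers `f > 1`. `effect_lognormal()`
#' specifies a log-normal distribution of `f` truncated to the class's side of
#' 1; `effect_points()` specifies an explicit finite set of fold effects with
#' probabilities (used both for degenerate single-effect models and as the
#' grid representation inside the likelihood machinery).
#'
#' @param median median fold effect (on the natural scale).
#' @param log_sd standard deviation of `log(f)` before truncation.
#' @param side `"suppressor"` (support (0, 1)) or `"enhancer"` (support (1, Inf)).
#' @return An object of class `effect_dist`.
#' @examples
#' effect_lognormal(0.6, 0.2, "suppressor")
#' effect_points(2, 1)
#' @export
effect_lognormal <- function(median, log_sd, side = c("suppressor", "enhancer")) {
  side <- match.arg(side)
  stopifnot(median > 0, log_sd > 0)
  if (side == "suppressor" && median >= 1)
    stop("suppressor median fold must be < 1")
  if (side == "enhancer" && median <= 1)
    stop("enhancer median fold must be > 1")
  structure(list(dist = "lognormal", meanlog = log(median), sdlog = log_sd,
                 side = side),
            class = "effect_dist")
}

#' @param folds vector of positive fold effects (all on one side of 1).
#' @param probs probabilities, recycled to length of `folds`; normalised to 1.
#' @rdname effect_lognormal
#' @export
effect_points <- function(folds, probs = 1) {
  stopifnot(is.numeric(folds), all(folds > 0), !any(folds == 1))
  probs <- rep_len(probs, length(folds))
  stopifnot(all(probs >= 0), sum(probs) > 0)
  if (any(folds < 1) && any(folds > 1))
    stop("point-mass effect distribution must lie on one side of 1")
  side <- if (all(folds < 1)) "suppressor" else "enhancer"
  o <- order(folds)
  structure(list(dist = "point", folds = folds[o],
                 probs = probs[o] / sum(probs), side = side),
            class = "effect_dist")
}

#' @export
print.effect_dist <- function(x, ...) {
  if (x$dist == "lognormal") {
    cat(sprintf("%s fold effect ~ logNormal(median %.3g, log-sd %.3g), truncated to %s\n",
                x$side, exp(x$meanlog), x$sdlog,
                if (x$side == "suppressor") "(0, 1)" else "(1, Inf)"))
  } else {
    cat(sprintf("%s fold effect: point masses at %s\n", x$side,
                paste(signif(x$folds, 3), collapse = ", ")))
  }
  invisible(x)
}

# Discretize an effect distribution onto a fixed log-spaced grid of fold
# effects, returning data.frame(fold, prob). Point distributions pass
# through unchanged. The grid edges stay fixed across EM iterations, which
# makes per-kindred likelihood terms precomputable.
effect_grid <- function(effect, n_grid = 25L,
                        range_suppressor = c(0.05, 0.995),
                        range_enhancer = c(1.005, 20)) {
  stopifnot(inherits(effect, "effect_dist"))
  if (effect$dist == "point")
    return(data.frame(fold = effect$folds, prob = effect$probs))
  rng <- if (effect$side == "suppressor") range_suppressor else range_enhancer
  edges <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_grid + 1L))
  mass <- lognormal_bin_mass(edges, effect$meanlog, effect$sdlog)
  data.frame(fold = sqrt(edges[-1] * edges[-(n_grid + 1L)]), prob = mass)
}

lognormal_bin_mass <- function(edges, meanlog, sdlog) {
  p <- plnorm(edges, meanlog, sdlog)
  mass <- diff(p)
  tot <- sum(mass)
  if (tot <= 0) stop("effect distribution has no mass on the grid")
  mass / tot
}

#' Class mixture of modifier effects across kindreds
#'
#' The three-component mixture over kindreds: a kindred is unaffected with
#' probability `weights["none"]`, carries a dominant suppressor with
#' probability `weights["suppressor"]`, or a dominant enhancer with
#' probability `weights["enhancer"]`. Within a modifier kindred the founder
#' is heterozygous, so each progeny inherits the modifier with probability
#' `segregation_prob` (default 1/2, Mendelian segregation).
#'
#' The default weights are the estimates from the outcross survival screen
#' (39% of mutagenized kindreds free of modifiers, 41% suppressor, 20%
#' enhancer), with log-normal fold effects of median 0.6 (suppressor) and
#' 1.8 (enhancer), log-sd 0.2.
#'
#' @param weights probability triple (`none`, `suppressor`, `enhancer`);
#'   must sum to 1 within `1e-9`.
#' @param suppressor,enhancer [effect_lognormal()] / [effect_points()]
#'   objects on the corresponding side of 1.
#' @param segregation_prob probability that a progeny of a carrier founder
#'   inherits the modifier.
#' @return An object of class `modifier_class_params`.
#' @examples
#' modifier_class_params()
#' modifier_class_params(weights = c(none = 1, suppressor = 0, enhancer = 0))
#' @export
modifier_class_params <- function(weights = c(none = 0.39, suppressor = 0.41,
                                              enhancer = 0.20),
                                  suppressor = effect_lognormal(0.6, 0.2, "suppressor"),
                                  enhancer = effect_lognormal(1.8, 0.2, "enhancer"),
                                  segregation_prob = 0.5) {
  stopifnot(is.numeric(weights), length(weights) == 3L,
            all(weights >= 0), all(weights <= 1))
  if (abs(sum(weights) - 1) > 1e-9)
    stop("class weights must sum to 1 (tolerance 1e-9)")
  weights <- setNames(as.numeric(weights), c("none", "suppressor", "enhancer"))
  stopifnot(inherits(suppressor, "effect_dist"), suppressor$side == "suppressor",
            inherits(enhancer, "effect_dist"), enhancer$side == "enhancer",
            segregation_prob > 0, segregation_prob <= 1)
  structure(list(weights = weights, suppressor = suppressor,
                 enhancer = enhancer, segregation_prob = segregation_prob),
            class = "modifier_class_params")
}

#' @export
print.modifier_class_params <- function(x, ...) {
  cat("Kindred modifier mixture:\n")
  cat(sprintf("  weights: none %.3f, suppressor %.3f, enhancer %.3f\n",
              x$weights[1], x$weights[2], x$weights[3]))
  print(x$suppressor); print(x$enhancer)
  cat("  segregation probability:", x$segregation_prob, "\n")
  invisible(x)
}

# Canonical flattened representation used by enrichment and screen-design
# Monte Carlo: one row per (class, fold) atom, probabilities summing to 1.
class_effect_table <- function(classes, n_grid = 25L) {
  stopifnot(inherits(classes, "modifier_class_params"))
  w <- classes$weights
  out <- data.frame(class = "none", fold = 1, prob = w[["none"]])
  for (cl in c("suppressor", "enhancer")) {
    if (w[[cl]] > 0) {
      g <- effect_grid(classes[[cl]], n_grid = n_grid)
      out <- rbind(out, data.frame(class = cl, fold = g$fold,
                                   prob = w[[cl]] * g$prob))
    }
  }
  out <- out[out$prob > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
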