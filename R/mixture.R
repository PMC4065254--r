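#' Baseline phenotype densities for the mixture model
#'
#' The mixture likelihood is written against a baseline (unmodified)
#' phenotype density and its fold-shifted version for modifier carriers.
#' Two channels are supported behind one interface:
#'
#' * `baseline_nb(mu, size)` — tumor counts, negative binomial. A carrier of
#'   fold `f` has counts `NB(f * mu, size)` (the shape is unchanged by the
#'   modifier).
#' * `baseline_loglifespan(meanlog, sdlog, link_slope)` — log lifespans,
#'   normal. Through the survival link a fold `f` on tumor burden shifts the
#'   mean log lifespan by `-link_slope * log(f)` (enhancers shorten life).
#'
#' @param mu,size negative-binomial mean and shape of the unmodified counts.
#' @return An object of class `phenotype_baseline`.
#' @examples
#' baseline_nb(99.8, 9.8)
#' @export
baseline_nb <- function(mu = 99.8, size = 9.8) {
  stopifnot(mu > 0, size > 0)
  structure(list(channel = "count", mu = mu, size = size),
            class = "phenotype_baseline")
}

#' @param meanlog,sdlog mean and sd of log lifespan in the unmodified colony.
#' @param link_slope magnitude of the log-log survival link slope
#'   (see [colony_model()]).
#' @rdname baseline_nb
#' @export
baseline_loglifespan <- function(meanlog, sdlog, link_slope = 0.35) {
  stopifnot(sdlog > 0, link_slope >= 0)
  structure(list(channel = "lifespan", meanlog = meanlog, sdlog = sdlog,
                 link_slope = link_slope),
            class = "phenotype_baseline")
}

#' @export
print.phenotype_baseline <- function(x, ...) {
  if (x$channel == "count")
    cat(sprintf("Baseline counts ~ NB(mu = %.4g, shape = %.4g)\n", x$mu, x$size))
  else
    cat(sprintf("Baseline log-lifespan ~ N(%.4g, %.4g), link slope %.3g\n",
                x$meanlog, x$sdlog, x$link_slope))
  invisible(x)
}

#' Estimate the baseline from a control cohort
#'
#' Fits the negative binomial to control tumor counts by maximum likelihood
#' (via [MASS::fitdistr()]), or the normal to log lifespans.
#'
#' @param x control phenotype vector (counts or lifespans in days).
#' @param channel `"count"` or `"lifespan"`.
#' @param link_slope survival-link slope, kept with the lifespan baseline.
#' @return A `phenotype_baseline`.
#' @examples
#' ctl <- simulate_control_cohort(colony_model(), 500, seed = 1)
#' estimate_baseline(ctl$tumor_count)
#' @export
estimate_baseline <- function(x, channel = c("count", "lifespan"),
                              link_slope = 0.35) {
  channel <- match.arg(channel)
  if (channel == "count") {
    stopifnot(all(x >= 0), all(x == floor(x)))
    fit <- MASS::fitdistr(x, "negative binomial")
    baseline_nb(mu = unname(fit$estimate["mu"]),
                size = unname(fit$estimate["size"]))
  } else {
    stopifnot(all(x > 0))
    baseline_loglifespan(mean(log(x)), sd(log(x)), link_slope)
  }
}

check_phenotype <- function(x, baseline) {
  if (length(x) < 1L) stop("at least one animal is required")
  if (baseline$channel == "count") {
    if (any(x < 0) || any(x != floor(x)))
      stop("tumor counts must be non-negative integers")
  } else if (any(x <= 0)) stop("lifespans must be positive")
  invisible(x)
}

# Matrix of log densities: rows = animals, cols = fold effects.
log_dens_matrix <- function(baseline, x, folds) {
  if (baseline$channel == "count") {
    outer(x, folds, function(xx, ff)
      dnbinom(xx, mu = ff * baseline$mu, size = baseline$size, log = TRUE))
  } else {
    outer(log(x), folds, function(lx, ff)
      dnorm(lx, baseline$meanlog - baseline$link_slope * log(ff),
            baseline$sdlog, log = TRUE))
  }
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Per-kindred log evidence at each candidate fold: the carrier mixture
# 1/2 f(x | fold) + 1/2 f(x | baseline) applied per animal, multiplied over
# the kindred. Returns list(base = scalar, per_fold = vector over folds).
kindred_fold_loglik <- function(x, baseline, folds, segregation = 0.5) {
  ld <- log_dens_matrix(baseline, x, c(1, folds))
  ld0 <- ld[, 1L]
  ldf <- ld[, -1L, drop = FALSE]
  # log(s * exp(ldf) + (1 - s) * exp(ld0)), columnwise, numerically stable
  m <- pmax(ldf, ld0)
  mix <- m + log(segregation * exp(ldf - m) +
                   (1 - segregation) * exp(ld0 - m))
  list(base = sum(ld0), per_fold = colSums(mix))
}

#' Mixture parameter bundle
#'
#' Collects the parameters the kindred likelihood needs: class weights,
#' per-class effect distributions, baseline density and segregation
#' probability.
#'
#' @param weights probability triple (`none`, `suppressor`, `enhancer`).
#' @param suppressor,enhancer [effect_points()] / [effect_lognormal()]
#'   objects (log-normals are discretized onto a fold grid inside the
#'   likelihood), or `NULL` when the class weight is zero.
#' @param baseline a `phenotype_baseline`.
#' @param segregation_prob carrier probability per progeny.
#' @param n_grid grid resolution used to discretize log-normal effects.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(weights, suppressor = NULL, enhancer = NULL,
                           baseline = baseline_nb(), segregation_prob = 0.5,
                           n_grid = 25L) {
  stopifnot(length(weights) == 3L, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  weights <- setNames(as.numeric(weights), c("none", "suppressor", "enhancer"))
  if (weights[["suppressor"]] > 0 && is.null(suppressor))
    stop("suppressor effect distribution required when its weight is positive")
  if (weights[["enhancer"]] > 0 && is.null(enhancer))
    stop("enhancer effect distribution required when its weight is positive")
  grids <- list(
    suppressor = if (!is.null(suppressor)) effect_grid(suppressor, n_grid),
    enhancer = if (!is.null(enhancer)) effect_grid(enhancer, n_grid))
  structure(list(weights = weights, suppressor = grids$suppressor,
                 enhancer = grids$enhancer, baseline = baseline,
                 segregation_prob = segregation_prob),
            class = "mixture_params")
}

#' Log-likelihood of one kindred under the segregating mixture
#'
#' Computes `log sum_class pi_class E_f [ prod_i ( s f(x_i | fold f) +
#' (1 - s) f(x_i | baseline) ) ]`, where the expectation is over the class's
#' fold-effect distribution, `s` is the segregation probability, and the
#' carrier mixture applies only in modifier classes. For point-mass effect
#' distributions the value is exact (it equals the exhaustive sum over all
#' `2^n` carrier configurations).
#'
#' @param x phenotype vector of the kindred's animals (counts or lifespans,
#'   matching the baseline's channel).
#' @param params a [mixture_params()] (or a fitted [fit_mixture()] object).
#' @return The kindred log-likelihood (scalar).
#' @examples
#' p <- mixture_params(c(1, 0, 0), baseline = baseline_nb(99.8, 9.8))
#' kindred_loglik(c(90, 110, 101), p)
#' @export
kindred_loglik <- function(x, params) {
  params <- as_mixture_params(params)
  check_phenotype(x, params$baseline)
  log_lik_classes(x, params)$total
}

log_lik_classes <- function(x, params) {
  w <- params$weights
  folds <- c(if (!is.null(params$suppressor)) params$suppressor$fold,
             if (!is.null(params$enhancer)) params$enhancer$fold)
  kl <- kindred_fold_loglik(x, params$baseline, folds, params$segregation_prob)
  ns <- if (is.null(params$suppressor)) 0L else nrow(params$suppressor)
  per_class <- c(none = kl$base, suppressor = -Inf, enhancer = -Inf)
  if (ns > 0)
    per_class[["suppressor"]] <-
      logsumexp(log(params$suppressor$prob) + kl$per_fold[seq_len(ns)])
  if (!is.null(params$enhancer))
    per_class[["enhancer"]] <-
      logsumexp(log(params$enhancer$prob) + kl$per_fold[-seq_len(ns)])
  lw <- ifelse(w > 0, log(w), -Inf)
  list(per_class = per_class, total = logsumexp(lw + per_class))
}

as_mixture_params <- function(params) {
  if (inherits(params, "mixture_params")) return(params)
  if (inherits(params, "mixture_fit")) return(params$params)
  stop("params must be a mixture_params or mixture_fit object")
}

#' Posterior class probabilities for a kindred
#'
#' Bayes' rule on the fitted mixture: the posterior probability that a
#' kindred is unaffected, carries a suppressor, or carries an enhancer,
#' given its phenotypes.
#'
#' @param x phenotype vector of the kindred.
#' @param fit a [fit_mixture()] result (or [mixture_params()]).
#' @return Named probability triple summing to 1.
#' @export
posterior_class <- function(x, fit) {
  params <- as_mixture_params(fit)
  check_phenotype(x, params$baseline)
  ll <- log_lik_classes(x, params)
  lw <- ifelse(params$weights > 0, log(params$weights), -Inf)
  lp <- lw + ll$per_class
  p <- exp(lp - logsumexp(lp))
  setNames(p / sum(p), c("none", "suppressor", "enhancer"))
}

#' Maximum-likelihood fit of the three-component segregating mixture
#'
#' Estimates the class weights (the modifier induction rate is
#' `1 - weight["none"]`) and the per-class fold-effect distributions from a
#' cohort of phenotyped kindreds, by an EM ascent. The continuous log-normal
#' effect distributions are represented on a fixed log-spaced fold grid
#' (suppressor nodes below 1, enhancer nodes above 1, so component labels
#' cannot swap); the E step computes responsibilities over (class, fold
#' node), the M step updates the weights in closed form and the log-normal
#' (location, scale) per class by numerical maximisation of the expected
#' complete-data log-likelihood. The observed-data log-likelihood is
#' non-decreasing across iterations; the best of `n_restarts` starts
#' (method-of-moments plus random perturbations) is returned.
#'
#' @param cohort a `kindred_cohort` from [simulate_kindreds()], or an animals
#'   data.frame with columns `kindred_id` and `tumor_count` (or
#'   `lifespan_days` for the lifespan channel).
#' @param baseline a `phenotype_baseline`; supply colony estimates or an
#'   [estimate_baseline()] result from controls.
#' @param n_restarts number of EM starts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param seed master seed for the random restarts.
#' @param channel phenotype channel; must match the baseline.
#' @param segregation_prob carrier probability per progeny.
#' @param n_grid fold-grid resolution per class.
#' @return An object of class `mixture_fit` with elements `weights`,
#'   `suppressor` / `enhancer` (lists with `meanlog`, `sdlog`, `median`),
#'   `params` (a [mixture_params()] for downstream use), `log_likelihood`,
#'   `loglik_trace`, `n_iterations`, `converged`, `n_kindreds`.
#' @examples
#' \donttest{
#' ch <- simulate_kindreds(colony_model(), modifier_class_params(),
#'                         n_kindreds = 200, progeny_per_kindred = 10, seed = 1)
#' fit <- fit_mixture(ch, baseline_nb(99.8, 9.8), n_restarts = 2, seed = 1)
#' fit$weights
#' }
#' @export
fit_mixture <- function(cohort, baseline = baseline_nb(), n_restarts = 5L,
                        tol = 1e-8, max_iter = 2000L, seed = 1L,
                        channel = c("count", "lifespan"),
                        segregation_prob = 0.5, n_grid = 25L) {
  channel <- match.arg(channel)
  stopifnot(inherits(baseline, "phenotype_baseline"),
            baseline$channel == channel, n_restarts >= 1L)
  animals <- if (inherits(cohort, "kindred_cohort")) cohort$animals else cohort
  col <- if (channel == "count") "tumor_count" else "lifespan_days"
  stopifnot(is.data.frame(animals), all(c("kindred_id", col) %in% names(animals)))
  xs <- split(animals[[col]], animals$kindred_id)
  if (length(xs) < 2L) stop("at least 2 kindreds are required")
  for (x in xs) check_phenotype(x, baseline)

  # fixed fold grids (log-spaced); only the masses move during EM
  sup_edges <- exp(seq(log(0.05), log(0.995), length.out = n_grid + 1L))
  enh_edges <- exp(seq(log(1.005), log(20), length.out = n_grid + 1L))
  sup_nodes <- sqrt(sup_edges[-1] * sup_edges[-(n_grid + 1L)])
  enh_nodes <- sqrt(enh_edges[-1] * enh_edges[-(n_grid + 1L)])

  # precompute per-kindred evidence at every node (the expensive part)
  K <- length(xs)
  pf <- vapply(xs, function(x)
    kindred_fold_loglik(x, baseline, c(sup_nodes, enh_nodes), segregation_prob)$per_fold,
    numeric(2L * n_grid))
  Ms <- t(pf[seq_len(n_grid), , drop = FALSE])        # K x n_grid
  Me <- t(pf[n_grid + seq_len(n_grid), , drop = FALSE])
  b0 <- vapply(xs, function(x)
    sum(log_dens_matrix(baseline, x, 1)), numeric(1L))

  inits <- em_inits(xs, baseline, n_restarts, seed)
  best <- NULL
  for (ini in inits) {
    run <- em_run(ini, b0, Ms, Me, sup_edges, enh_edges, tol, max_iter)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  # EM's geometric tail can stall short of the optimum when components
  # overlap; finish the ascent with a quasi-Newton polish of the same
  # discretized likelihood (accepted only if it improves).
  best <- polish_run(best, b0, Ms, Me, sup_edges, enh_edges)

  sup <- list(meanlog = best$theta_s[1], sdlog = best$theta_s[2],
              median = exp(best$theta_s[1]))
  enh <- list(meanlog = best$theta_e[1], sdlog = best$theta_e[2],
              median = exp(best$theta_e[1]))
  params <- mixture_params(
    best$pi,
    suppressor = effect_lognormal(min(sup$median, 0.999), max(sup$sdlog, 1e-3),
                                  "suppressor"),
    enhancer = effect_lognormal(max(enh$median, 1.001), max(enh$sdlog, 1e-3),
                                "enhancer"),
    baseline = baseline, segregation_prob = segregation_prob, n_grid = n_grid)
  structure(list(weights = setNames(best$pi, c("none", "suppressor", "enhancer")),
                 suppressor = sup, enhancer = enh, baseline = baseline,
                 params = params, segregation_prob = segregation_prob,
                 log_likelihood = best$loglik, loglik_trace = best$trace,
                 n_iterations = best$iter, converged = best$converged,
                 channel = channel, n_kindreds = K, n_restarts = n_restarts),
            class = "mixture_fit")
}

# Method-of-moments start: classify kindreds by the z score of their mean
# against the baseline, back out a crude fold per flagged kindred
# (observed mean ratio ~ (1 + f) / 2 under segregation), then jitter for
# the random restarts.
em_inits <- function(xs, baseline, n_restarts, seed) {
  if (baseline$channel == "count") {
    mu0 <- baseline$mu
    v0 <- nb_variance(baseline$mu, baseline$size)
    mns <- vapply(xs, mean, numeric(1))
    z <- (mns - mu0) / sqrt(v0 / lengths(xs))
    r <- mns / mu0
  } else {
    mns <- vapply(xs, function(x) mean(log(x)), numeric(1))
    z <- (mns - baseline$meanlog) / (baseline$sdlog / sqrt(lengths(xs)))
    # on the lifespan channel long-lived = suppressor, so flip the sign
    z <- -z
    sl <- max(baseline$link_slope, 1e-6)
    r <- exp(-(mns - baseline$meanlog) / sl)  # implied count-scale ratio
  }
  lab <- cut(z, c(-Inf, -1.5, 1.5, Inf),
             labels = c("suppressor", "none", "enhancer"))
  pi0 <- pmax(prop.table(table(factor(lab, c("none", "suppressor", "enhancer")))), 0.05)
  pi0 <- as.numeric(pi0 / sum(pi0))
  fold_of <- function(rr) pmin(pmax(2 * rr - 1, 0.06), 18)
  ml_s <- if (any(lab == "suppressor"))
    mean(log(pmin(fold_of(r[lab == "suppressor"]), 0.95))) else log(0.7)
  ml_e <- if (any(lab == "enhancer"))
    mean(log(pmax(fold_of(r[lab == "enhancer"]), 1.05))) else log(1.5)
  base <- list(pi = pi0, theta_s = c(ml_s, 0.3), theta_e = c(ml_e, 0.3))
  inits <- list(base)
  if (n_restarts > 1L) {
    with_substream(seed, "em_restarts", {
      for (i in seq_len(n_restarts - 1L)) {
        p <- abs(base$pi + rnorm(3, 0, 0.15)); p <- p / sum(p)
        inits[[i + 1L]] <- list(
          pi = p,
          theta_s = c(min(base$theta_s[1] + rnorm(1, 0, 0.25), -0.01),
                      exp(log(0.3) + rnorm(1, 0, 0.4))),
          theta_e = c(max(base$theta_e[1] + rnorm(1, 0, 0.25), 0.01),
                      exp(log(0.3) + rnorm(1, 0, 0.4))))
      }
    })
  }
  inits
}

em_run <- function(init, b0, Ms, Me, sup_edges, enh_edges, tol, max_iter) {
  K <- length(b0)
  pi <- init$pi; th_s <- init$theta_s; th_e <- init$theta_e
  trace <- numeric(0)
  ll_old <- -Inf; converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    ws <- lognormal_bin_mass(sup_edges, th_s[1], th_s[2])
    we <- lognormal_bin_mass(enh_edges, th_e[1], th_e[2])
    As <- row_logsumexp(sweep(Ms, 2, log(ws), "+"))
    Ae <- row_logsumexp(sweep(Me, 2, log(we), "+"))
    L <- cbind(b0, As, Ae)
    lw <- ifelse(pi > 0, log(pi), -Inf)
    lj <- sweep(L, 2, lw, "+")
    mx <- apply(lj, 1, max)
    R <- exp(lj - mx)
    rs <- rowSums(R)
    ll <- sum(mx + log(rs))
    R <- R / rs
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
    pi <- pmax(colMeans(R), 0)
    pi <- pi / sum(pi)
    th_s <- mstep_effect(R[, 2], Ms, log(ws), th_s, sup_edges)
    th_e <- mstep_effect(R[, 3], Me, log(we), th_e, enh_edges)
  }
  list(pi = pi, theta_s = th_s, theta_e = th_e, loglik = ll,
       trace = trace, iter = iter, converged = converged)
}

mixture_obs_loglik <- function(pi, th_s, th_e, b0, Ms, Me, sup_edges, enh_edges) {
  ws <- lognormal_bin_mass(sup_edges, th_s[1], th_s[2])
  we <- lognormal_bin_mass(enh_edges, th_e[1], th_e[2])
  L <- cbind(b0,
             row_logsumexp(sweep(Ms, 2, log(ws), "+")),
             row_logsumexp(sweep(Me, 2, log(we), "+")))
  lw <- ifelse(pi > 0, log(pi), -Inf)
  sum(row_logsumexp(sweep(L, 2, lw, "+")))
}

polish_run <- function(run, b0, Ms, Me, sup_edges, enh_edges) {
  pi0 <- pmax(run$pi, 1e-8); pi0 <- pi0 / sum(pi0)
  start <- c(log(pi0[2] / pi0[1]), log(pi0[3] / pi0[1]),
             run$theta_s[1], log(run$theta_s[2]),
             run$theta_e[1], log(run$theta_e[2]))
  unpack <- function(p) {
    pi <- exp(c(0, p[1], p[2])); pi <- pi / sum(pi)
    list(pi = pi, th_s = c(min(p[3], -1e-4), min(max(exp(p[4]), 1e-3), 3)),
         th_e = c(max(p[5], 1e-4), min(max(exp(p[6]), 1e-3), 3)))
  }
  nll <- function(p) {
    q <- unpack(p)
    v <- tryCatch(
      -mixture_obs_loglik(q$pi, q$th_s, q$th_e, b0, Ms, Me, sup_edges, enh_edges),
      error = function(e) Inf)
    if (!is.finite(v)) abs(run$loglik) + 1e6 + sum(p^2) else v
  }
  best_opt <- NULL
  for (method in c("BFGS", "Nelder-Mead")) {
    opt <- tryCatch(optim(start, nll, method = method,
                          control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best_opt) || opt$value < best_opt$value))
      best_opt <- opt
  }
  if (is.null(best_opt) || -best_opt$value <= run$loglik) return(run)
  q <- unpack(best_opt$par)
  run$pi <- q$pi; run$theta_s <- q$th_s; run$theta_e <- q$th_e
  run$loglik <- -best_opt$value
  run$trace <- c(run$trace, run$loglik)
  run
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Weighted log-normal refit on the fixed grid: maximise sum_j N_j log w_j(theta)
# where N_j are expected node counts from the E step. Started from the current
# theta, so the expected complete-data objective (hence the observed
# log-likelihood) cannot decrease.
mstep_effect <- function(resp, M, log_w, theta, edges) {
  if (sum(resp) < 1e-10) return(theta)
  q <- sweep(M, 2, log_w, "+")
  q <- exp(q - apply(q, 1, max))
  q <- q / rowSums(q)
  Nj <- colSums(resp * q)
  obj <- function(par) {
    sl <- exp(par[2])
    if (sl < 1e-3 || sl > 3) return(1e10)
    -sum(Nj * log(lognormal_bin_mass(edges, par[1], sl)))
  }
  start <- c(theta[1], log(theta[2]))
  opt <- tryCatch(optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 200)),
                  error = function(e) NULL)
  if (is.null(opt) || opt$value > obj(start) + 1e-12) return(theta)
  c(opt$par[1], exp(opt$par[2]))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Segregating three-component mixture fit (", x$channel, " channel)\n", sep = "")
  cat(sprintf("  kindreds: %d   log-likelihood: %.3f   converged: %s (%d iterations)\n",
              x$n_kindreds, x$log_likelihood, x$converged, x$n_iterations))
  cat(sprintf("  weights: none %.3f, suppressor %.3f, enhancer %.3f\n",
              x$weights[1], x$weights[2], x$weights[3]))
  cat(sprintf("  modifier induction rate: %.3f\n", 1 - x$weights[[1]]))
  cat(sprintf("  suppressor fold: median %.3f (log-sd %.3f)\n",
              x$suppressor$median, x$suppressor$sdlog))
  cat(sprintf("  enhancer fold:   median %.3f (log-sd %.3f)\n",
              x$enhancer$median, x$enhancer$sdlog))
  invisible(x)
}
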