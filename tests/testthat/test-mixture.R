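test_that("kindred likelihood equals exhaustive carrier-configuration
           enumeration for kindreds of up to 4 animals", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(1:4, 1)
    x <- rnbinom(n, mu = 99.8, size = 9.8)
    w <- as.numeric(rdirichlet1(3))
    sup <- effect_points(sort(runif(2, 0.2, 0.9)), runif(2))
    enh <- effect_points(sort(runif(2, 1.2, 4)), runif(2))
    p <- mixture_params(w, sup, enh, baseline_nb(99.8, 9.8))
    expect_equal(kindred_loglik(x, p),
                 brute_kindred_loglik(x, w,
                                      data.frame(fold = sup$folds, prob = sup$probs),
                                      data.frame(fold = enh$folds, prob = enh$probs),
                                      99.8, 9.8),
                 tolerance = 1e-10)
  }
})

test_that("degenerate all-none mixture reduces to the baseline
           log-density and permuting animals changes nothing", {
  p <- mixture_params(c(1, 0, 0), baseline = baseline_nb(99.8, 9.8))
  x <- c(70, 120, 99, 101)
  expect_equal(kindred_loglik(x, p),
               sum(dnbinom(x, mu = 99.8, size = 9.8, log = TRUE)))
  p2 <- mixture_params(c(0.4, 0.3, 0.3), effect_points(0.5, 1),
                       effect_points(2, 1), baseline_nb(99.8, 9.8))
  expect_identical(kindred_loglik(x, p2), kindred_loglik(rev(x), p2))
  expect_error(kindred_loglik(c(-1, 5), p2), "non-negative")
  expect_error(kindred_loglik(numeric(), p2), "at least one")
})

test_that("posterior class probabilities follow Bayes rule", {
  p0 <- mixture_params(c(1, 0, 0), baseline = baseline_nb(99.8, 9.8))
  expect_equal(unname(posterior_class(c(80, 120), p0)), c(1, 0, 0))
  p <- mixture_params(c(0.39, 0.41, 0.20),
                      effect_lognormal(0.6, 0.2, "suppressor"),
                      effect_lognormal(1.8, 0.2, "enhancer"),
                      baseline_nb(99.8, 9.8))
  for (x in list(c(60, 80), c(300, 250, 280), rnbinom(5, mu = 99.8, size = 9.8)))
    expect_equal(sum(posterior_class(x, p)), 1, tolerance = 1e-12)
  # a strong enhancer kindred is confidently identified at 10 progeny
  cl10 <- modifier_class_params(weights = c(0, 0, 1),
                                enhancer = effect_points(10, 1))
  ch <- simulate_kindreds(colony_model(), cl10, 1, 10, seed = 21)
  post <- posterior_class(ch$animals$tumor_count, p)
  expect_gt(post[["enhancer"]], 0.9)
})

test_that("null-simulated data is assigned almost entirely to the
           unaffected class", {
  ch <- simulate_kindreds(colony_model(), modifier_class_params(c(1, 0, 0)),
                          500, 10, seed = 13)
  fit <- fit_mixture(ch, baseline_nb(99.8, 9.8), n_restarts = 2, seed = 1)
  expect_gte(fit$weights[["none"]], 0.95)
})

test_that("EM log-likelihood trace is non-decreasing and labels cannot
           swap sides", {
  ch <- simulate_kindreds(colony_model(), modifier_class_params(),
                          300, 8, seed = 17)
  fit <- fit_mixture(ch, baseline_nb(99.8, 9.8), n_restarts = 3, seed = 2)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_lt(fit$suppressor$median, 1)
  expect_gt(fit$enhancer$median, 1)
  expect_true(fit$converged)
  expect_error(fit_mixture(list(), baseline_nb()), "data.frame")
})

test_that("weights are recovered without material bias across replicates", {
  # scaled-down replicate study; the full-size recovery check (2000
  # kindreds x 10 progeny) runs in the acceptance suite
  reps <- 8
  truth <- c(0.39, 0.41, 0.20)
  est <- t(vapply(seq_len(reps), function(r) {
    ch <- simulate_kindreds(colony_model(), modifier_class_params(),
                            800, 10, seed = 3000 + r)
    fit <- fit_mixture(ch, baseline_nb(99.8, 9.8), n_restarts = 2, seed = r)
    as.numeric(fit$weights)
  }, numeric(3)))
  bias <- colMeans(est) - truth
  rmse <- sqrt(colMeans((est - matrix(truth, reps, 3, byrow = TRUE))^2))
  expect_true(all(abs(bias) < 0.04))
  expect_true(all(rmse < 0.07))
})

test_that("lifespan channel recovers a strong suppressor signal", {
  co <- colony_model()
  cl <- modifier_class_params(weights = c(0.5, 0.5, 0),
                              suppressor = effect_points(0.3, 1))
  ch <- simulate_kindreds(co, cl, 400, 10, seed = 23)
  ctl <- simulate_control_cohort(co, 2000, seed = 24)
  bl <- estimate_baseline(ctl$lifespan_days, channel = "lifespan",
                          link_slope = co$survival_link[["slope"]])
  fit <- fit_mixture(ch, bl, n_restarts = 2, seed = 3, channel = "lifespan")
  expect_equal(fit$weights[["suppressor"]], 0.5, tolerance = 0.12)
  expect_lt(fit$suppressor$median, 0.7)
})
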