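test_that("control cohorts have the stated NB moments and pass a GOF check", {
  ctl <- simulate_control_cohort(colony_model(), 1e5, seed = 42)
  mu <- 99.8; k <- 9.8
  expect_equal(mean(ctl$tumor_count), mu, tolerance = 0.01)
  expect_equal(var(ctl$tumor_count), mu + mu^2 / k, tolerance = 0.03)
  # chi-square goodness of fit against the NB pmf, alpha = 0.01
  breaks <- c(-Inf, quantile(qnbinom(seq(0.05, 0.95, by = 0.1), mu = mu, size = k)), Inf)
  breaks <- unique(breaks)
  obs <- table(cut(ctl$tumor_count, breaks))
  pr <- diff(pnbinom(c(-1, breaks[-c(1, length(breaks))], Inf), mu = mu, size = k))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr / sum(pr)))
  expect_gt(gof$p.value, 0.01)
})

test_that("control cohort edge cases and determinism", {
  expect_identical(nrow(simulate_control_cohort(colony_model(), 0, seed = 1)), 0L)
  expect_error(simulate_control_cohort(colony_model(), -1, seed = 1),
               "non-negative")
  a <- simulate_control_cohort(colony_model(), 50, seed = 7)
  b <- simulate_control_cohort(colony_model(), 50, seed = 7)
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_control_cohort(colony_model(), 50, seed = 8)))
})

test_that("lifespan is negatively linked to tumor burden when slope > 0", {
  ctl <- simulate_control_cohort(colony_model(), 5000, seed = 11)
  expect_lt(cor(ctl$tumor_count, ctl$lifespan_days, method = "spearman"), 0)
  flat <- colony_model(survival_link = c(log(300), 0, 0.2))
  ctl0 <- simulate_control_cohort(flat, 5000, seed = 11)
  expect_lt(abs(cor(ctl0$tumor_count, ctl0$lifespan_days,
                    method = "spearman")), 0.05)
})

test_that("degenerate mixture weights give all-none kindreds at fold 1", {
  cl <- modifier_class_params(weights = c(1, 0, 0))
  ch <- simulate_kindreds(colony_model(), cl, 50, 5, seed = 2)
  expect_true(all(ch$kindreds$latent_class == "none"))
  expect_true(all(ch$kindreds$fold_effect == 1))
  expect_true(all(!ch$animals$carrier))
})

test_that("pure-enhancer cohort at fixed fold 2 matches segregation and
           carrier-mean expectations", {
  cl <- modifier_class_params(weights = c(0, 0, 1),
                              enhancer = effect_points(2, 1))
  ch <- simulate_kindreds(colony_model(), cl, 10000, 10, seed = 5)
  expect_true(all(ch$kindreds$fold_effect == 2))
  carrier_frac <- mean(ch$animals$carrier)
  expect_equal(carrier_frac, 0.5, tolerance = 0.01)
  carr_mean <- mean(ch$animals$tumor_count[ch$animals$carrier])
  expect_equal(carr_mean, 2 * 99.8, tolerance = 0.02)
  non_mean <- mean(ch$animals$tumor_count[!ch$animals$carrier])
  expect_equal(non_mean, 99.8, tolerance = 0.02)
})

test_that("kindred class frequencies recover the mixture weights", {
  cl <- modifier_class_params()  # 39 / 41 / 20
  ch <- simulate_kindreds(colony_model(), cl, 10000, 2, seed = 9)
  freq <- table(factor(ch$kindreds$latent_class,
                       c("none", "suppressor", "enhancer"))) / 10000
  se <- sqrt(cl$weights * (1 - cl$weights) / 10000)
  expect_true(all(abs(as.numeric(freq) - cl$weights) < 4 * se))
  # fold supports respect the class sides
  expect_true(all(ch$kindreds$fold_effect[ch$kindreds$latent_class == "suppressor"] < 1))
  expect_true(all(ch$kindreds$fold_effect[ch$kindreds$latent_class == "enhancer"] > 1))
})

test_that("mixture weights must sum to one", {
  expect_error(modifier_class_params(weights = c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("variant-line simulation has Poisson counts, the requested
           spectrum, and shared sites in the related pair only", {
  sizes <- c(chr1 = 1e9, chr2 = 1e9)
  tbl <- simulate_variant_lines(sizes, rate_per_bp = 1.1e-6, n_lines = 1,
                                line_ids = "solo", related_pair = NULL,
                                seed = 3)
  lambda <- 1.1e-6 * 2e9
  expect_lt(abs(nrow(tbl$records) - lambda), 3 * sqrt(lambda))
  # spectrum shares within Monte-Carlo error
  sp <- mutation_spectrum(tbl$records)
  expect_true(all(abs(sp$percent / 100 - enu_spectrum()$prob) <
                    4 * sqrt(enu_spectrum()$prob / nrow(tbl$records)) + 0.005))

  tbl2 <- simulate_variant_lines(sizes, rate_per_bp = 2e-6, n_lines = 4,
                                 line_ids = c("a", "b", "g", "h"),
                                 related_pair = c("g", "h"),
                                 shared_fraction = 0.3, seed = 4)
  part <- partition_line_specific(tbl2, related_pair = c("g", "h"))
  expect_gt(nrow(part$shared), 0)
  expect_identical(nrow(part$remainder), 0L)
  # shared fraction of the pair's sites is near the requested value
  g_tot <- sum(tbl2$records$line_id == "g")
  expect_equal(nrow(part$shared) / g_tot, 0.3, tolerance = 0.1)
  # residual heterozygosity rate
  expect_equal(mean(tbl2$records$zygosity == "het"), 0.14, tolerance = 0.03)
})

test_that("zero mutation rate gives an empty table; generators are
           seed-deterministic", {
  tbl <- simulate_variant_lines(toy_chrom_sizes(), rate_per_bp = 0,
                                n_lines = 2, related_pair = NULL, seed = 1)
  expect_identical(nrow(tbl$records), 0L)
  a <- simulate_variant_lines(toy_chrom_sizes(), rate_per_bp = 1e-5,
                              n_lines = 2, related_pair = NULL, seed = 6)
  b <- simulate_variant_lines(toy_chrom_sizes(), rate_per_bp = 1e-5,
                              n_lines = 2, related_pair = NULL, seed = 6)
  expect_identical(a, b)
})

test_that("published per-line summary counts are internally consistent", {
  counts <- snv_line_chromosome_counts()
  expect_identical(colSums(counts[-1]),
                   c(B6.SNVb = 3246, B6.SNVc = 2932, B6.SNVe = 2051,
                     B6.SNVf = 1198, B6.SNVg = 1225, B6.SNVh = 2520,
                     shared_gh = 792))
  expect_equal(sum(enu_spectrum_counts()$n), 13172)
})
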