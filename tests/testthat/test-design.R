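test_that("certain large effects are discovered with a single kindred", {
  certain <- data.frame(class = "enhancer", fold = 10, prob = 1)
  N <- screen_size_for_discovery(certain, n = 30, effect_threshold = 2,
                                 mc_reps = 1000, seed = 1)
  expect_identical(as.integer(N), 1L)
  expect_gte(attr(N, "prob"), 0.95)
})

test_that("discovery probability is non-decreasing in screen size under
           common random numbers", {
  cl <- modifier_class_params()
  curve <- discovery_probability(cl, N = c(5, 10, 20, 40, 80), n = 20,
                                 effect_threshold = 2, mc_reps = 800,
                                 seed = 3)
  expect_true(all(diff(curve$prob) >= 0))
})

test_that("thinning the large-effect mass never shrinks the required
           screen", {
  rich <- data.frame(class = c("none", "enhancer"), fold = c(1, 3),
                     prob = c(0.5, 0.5))
  poor <- data.frame(class = c("none", "enhancer"), fold = c(1, 3),
                     prob = c(0.75, 0.25))
  N_rich <- screen_size_for_discovery(rich, n = 15, effect_threshold = 2,
                                      mc_reps = 1000, seed = 5)
  N_poor <- screen_size_for_discovery(poor, n = 15, effect_threshold = 2,
                                      mc_reps = 1000, seed = 5)
  expect_gte(as.integer(N_poor), as.integer(N_rich))
})

test_that("Benjamini-Hochberg keeps the all-null discovery list honest", {
  set.seed(19)
  # empirical FDR on all-null uniform p-values is at most q
  fdp <- replicate(2000, {
    rej <- p.adjust(runif(50), method = "BH") <= 0.05
    any(rej)  # with no true effects, any rejection is a false discovery
  })
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
  # and the mixture has to contain mass beyond the threshold
  expect_error(screen_size_for_discovery(
    data.frame(class = "none", fold = 1, prob = 1), n = 10,
    effect_threshold = 2, mc_reps = 1000, seed = 1), "zero modifier mass")
})

test_that("extreme-kindred preselection reduces the kindreds needed, and
           selecting the wrong tail backfires", {
  cl <- modifier_class_params()
  base_N <- screen_size_for_discovery(cl, n = 20, effect_threshold = 2,
                                      mc_reps = 1000, seed = 7)
  right <- preselected_design(cl, selection_rule(2, 10, 0.05, "upper"),
                              effect_threshold = 2, progeny = 20,
                              mc_reps = 1000, seed = 7)
  wrong <- preselected_design(cl, selection_rule(2, 10, 0.05, "lower"),
                              effect_threshold = 2, progeny = 20,
                              mc_reps = 1000, seed = 7)
  expect_lte(right$n_kindreds, as.integer(base_N))
  expect_gt(wrong$n_kindreds, right$n_kindreds)
  expect_gt(right$enrichment, 1)
  expect_lt(wrong$enrichment, 1)
  # vacuous selection reproduces the unselected design
  vac <- preselected_design(cl, selection_rule(0, 10, 0.05, "upper"),
                            effect_threshold = 2, progeny = 20,
                            mc_reps = 1000, seed = 7)
  expect_identical(vac$n_kindreds, as.integer(base_N))
  expect_equal(vac$enrichment, 1)
})

test_that("analytic enrichment matches Monte-Carlo selection frequencies
           and is monotone in the required number of extreme animals", {
  cl <- modifier_class_params()
  co <- colony_model()
  rule <- selection_rule(2, 10, 0.05, "upper")
  enr <- extreme_selection_enrichment(cl, rule, 2, co)
  # Monte-Carlo oracle: simulate kindred first-pass clusters directly
  set.seed(41)
  tab <- minscreen:::class_effect_table(cl, 40)
  n <- 4e4
  atom <- sample.int(nrow(tab), n, TRUE, tab$prob)
  f <- tab$fold[atom]
  thr <- qnbinom(0.95, mu = co$mean_tumor_count, size = co$nb_shape)
  extreme <- vapply(seq_len(10), function(j) {
    carrier <- runif(n) < 0.5
    x <- rnbinom(n, mu = ifelse(carrier, f, 1) * co$mean_tumor_count,
                 size = co$nb_shape)
    x > thr
  }, logical(n))
  sel <- rowSums(extreme) >= 2
  mc <- mean(f[sel] >= 2) / mean(f >= 2)
  expect_lt(abs(as.numeric(enr) - mc) / mc, 0.05)
  # enrichment grows with the number of extreme animals demanded
  enrs <- vapply(0:4, function(m)
    as.numeric(extreme_selection_enrichment(
      cl, selection_rule(m, 10, 0.05, "upper"), 2, co)), numeric(1))
  expect_true(all(diff(enrs) >= 0))
  expect_equal(enrs[1], 1)
  # a mixture containing only large effects cannot be enriched further
  only_large <- modifier_class_params(weights = c(0, 0, 1),
                                      enhancer = effect_points(c(3, 5), c(0.5, 0.5)))
  expect_equal(as.numeric(extreme_selection_enrichment(only_large, rule, 2, co)), 1)
  expect_error(extreme_selection_enrichment(
    modifier_class_params(c(1, 0, 0)), rule, 2, co), "no effect mass")
})
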