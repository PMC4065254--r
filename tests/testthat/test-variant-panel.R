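test_that("depth filtering keeps [min_depth, mult x coverage]", {
  tbl <- line_variant_table(
    data.frame(line_id = "a", chrom = "chrA", pos = 1:4, ref = "A", alt = "T",
               depth = c(2L, 3L, 15L, 16L)),
    lines = data.frame(line_id = "a", mean_coverage = 6))
  kept <- filter_calls(tbl)$records
  expect_identical(kept$depth, c(3L, 15L))  # 2 < 3 and 16 > 2.5 * 6 = 15
  # missing metadata is an error
  tbl$lines <- data.frame(line_id = "b", mean_coverage = 6)
  expect_error(filter_calls(tbl), "mean-coverage metadata")
  # empty table passes through
  e <- line_variant_table(minscreen:::empty_variant_records(),
                          lines = data.frame(line_id = character(),
                                             mean_coverage = numeric()))
  expect_identical(nrow(filter_calls(e)$records), 0L)
})

test_that("line-specificity partition is exhaustive, disjoint and
           order-invariant", {
  tbl <- toy_variant_table()
  part <- partition_line_specific(tbl, related_pair = c("g", "h"))
  n_sites <- length(unique(minscreen:::site_key(tbl$records)))
  expect_identical(length(unique(minscreen:::site_key(part$exclusive))) +
                     nrow(part$shared) + nrow(part$remainder), n_sites)
  keys <- list(minscreen:::site_key(part$exclusive),
               minscreen:::site_key(part$shared),
               minscreen:::site_key(part$remainder))
  expect_identical(length(intersect(keys[[1]], keys[[2]])), 0L)
  expect_identical(length(intersect(keys[[1]], keys[[3]])), 0L)
  # the triple-line site lands in the remainder
  expect_identical(part$remainder$pos, 4.5e7)
  expect_identical(nrow(part$shared), 2L)
  # shuffling record order leaves the summary unchanged
  tbl2 <- tbl
  set.seed(1)
  tbl2$records <- tbl2$records[sample(nrow(tbl2$records)), ]
  part2 <- partition_line_specific(tbl2, related_pair = c("g", "h"))
  s1 <- summarize_partition(part, chrom_order = c("chrA", "chrB"))
  s2 <- summarize_partition(part2, chrom_order = c("chrA", "chrB"))
  expect_identical(s1, s2)
  # single line: everything is exclusive
  solo <- line_variant_table(tbl$records[tbl$records$line_id == "g", ],
                             lines = tbl$lines[tbl$lines$line_id == "g", ])
  psolo <- partition_line_specific(solo)
  expect_identical(nrow(psolo$exclusive), sum(tbl$records$line_id == "g"))
})

test_that("partition bookkeeping reproduces the published per-line totals", {
  tbl <- variant_table_from_counts(snv_line_chromosome_counts(), seed = 2)
  part <- partition_line_specific(tbl, related_pair = c("B6.SNVg", "B6.SNVh"))
  summ <- summarize_partition(part, chrom_order = paste0("chr", c(1:19, "X")))
  tot <- summ[summ$chrom == "Total", ]
  expect_equal(tot$B6.SNVb, 3246)
  expect_equal(tot$shared, 792)
  expect_equal(attr(summ, "line_specific_total"), 13172)
  expect_equal(unlist(tot[c("B6.SNVb", "B6.SNVc", "B6.SNVe", "B6.SNVf",
                            "B6.SNVg", "B6.SNVh")], use.names = FALSE),
               c(3246, 2932, 2051, 1198, 1225, 2520))
})

test_that("mutation spectrum percentages are consistent and guarded", {
  sp <- mutation_spectrum(data.frame(ref = rep(c("A", "C", "G", "T"), each = 3),
                                     alt = c("C", "G", "T", "A", "G", "T",
                                             "A", "C", "T", "A", "C", "G")))
  expect_equal(sum(sp$percent), 100)
  expect_true(all(abs(sp$percent - 100 / 12) < 1e-9))
  expect_error(mutation_spectrum(data.frame(ref = "AT", alt = "A")),
               "single-nucleotide")
  # published spectrum: AT<->TA transversion share
  sc <- enu_spectrum_counts()
  fake <- data.frame(ref = rep(sc$ref, sc$n), alt = rep(sc$alt, sc$n))
  expect_equal(at_ta_percent(mutation_spectrum(fake)), 18.7, tolerance = 0.005)
  expect_equal(at_ta_percent(spontaneous_at_ta_counts()), 9, tolerance = 0.01)
})

test_that("per-bp rate reporting", {
  expect_equal(per_bp_rate(1.3e4, 6 * 2e9), 1.1e-6)
  expect_identical(per_bp_rate(0, 1e9), 0)
  expect_identical(per_bp_rate(100, 1e6), per_bp_rate(200, 2e6))
  expect_error(per_bp_rate(10, 0), "positive")
})

test_that("candidate ranking applies quality, repeat and preference rules", {
  cand <- data.frame(
    chrom = "chrA", pos = c(10, 20, 30, 40, 50),
    ref = c("A", "A", "G", "A", "A"),
    alt = c("T", "G", "A", "T", "T"),
    genotype_quality = c(99L, 99L, 99L, 98L, 99L),
    flank_seq = c("ACGT", "ACGT", "ACGT", "ACGT", strrep("A", 10)),
    specificity = c("single-line", "related-pair-only", "related-pair-only",
                    "related-pair-only", "related-pair-only"),
    stringsAsFactors = FALSE)
  r <- rank_candidates(cand)
  expect_identical(nrow(r), 3L)            # quality 98 and AAAA... excluded
  expect_identical(r$pos, c(20, 30, 10))   # pair A>G, pair G>A, then single A>T
  # an A>T candidate outranks an A>G one, all else equal
  two <- data.frame(chrom = "chrA", pos = c(1, 2), ref = "A",
                    alt = c("G", "T"), genotype_quality = 99L,
                    flank_seq = "ACGT", specificity = "single-line",
                    stringsAsFactors = FALSE)
  expect_identical(rank_candidates(two)$alt, c("T", "G"))
})

test_that("repeat predicate flags homopolymers and dinucleotide tandems", {
  expect_identical(flank_has_repeat(c("ACGTACGT", strrep("T", 8),
                                      paste0("GG", strrep("CA", 4), "T"),
                                      strrep("CA", 3))),
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("panel selection fills three bins per autosome with documented
           tie-breaks", {
  sizes <- c(chr1 = 9e6, chr2 = 9e6, chrX = 9e6)
  cand <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chrX"),
    pos = c(1e6, 4e6, 4.8e6, 8e6, 4e6, 5e5),
    ref = "A", alt = "T", genotype_quality = 99L, flank_seq = "ACGT",
    specificity = "related-pair-only", stringsAsFactors = FALSE)
  r <- rank_candidates(cand)
  sel <- select_panel(r, sizes)
  p <- sel$panel
  expect_identical(nrow(p), 4L)  # chr1 x3 + chr2 middle; X excluded
  # equal-rank candidates in chr1's middle bin (3e6, 6e6]: 4.8e6 is nearer
  # the midpoint 4.5e6 than 4e6
  expect_identical(p$pos[p$chrom == "chr1" & p$bin == "middle"], 4.8e6)
  expect_identical(nrow(sel$unfilled), 2L)  # chr2 proximal + distal
  # full coverage gives 3 markers for every autosome
  dense <- data.frame(chrom = rep(paste0("chr", 1:19), each = 3),
                      pos = rep(c(1e6, 4e6, 8e6), 19),
                      ref = "A", alt = "T", genotype_quality = 99L,
                      flank_seq = "ACGT", specificity = "single-line",
                      stringsAsFactors = FALSE)
  sizes19 <- setNames(rep(9e6, 20), c(paste0("chr", 1:19), "chrX"))
  sel19 <- select_panel(rank_candidates(dense), sizes19)
  expect_identical(nrow(sel19$panel), 57L)
  expect_identical(nrow(sel19$unfilled), 0L)
  # selection is idempotent/deterministic
  expect_identical(select_panel(r, sizes)$panel, p)
})

test_that("relaxation admits lower-preference candidates only where the
           strict criteria leave a bin empty", {
  sizes <- c(chr1 = 9e6)
  cand <- data.frame(
    chrom = "chr1", pos = c(1e6, 5e6),
    ref = c("A", "C"), alt = c("T", "G"),  # C>G is outside the preferred set
    genotype_quality = 99L, flank_seq = "ACGT",
    specificity = "related-pair-only", stringsAsFactors = FALSE)
  r <- rank_candidates(cand)
  strict <- select_panel(r, sizes, relax = FALSE)
  relaxed <- select_panel(r, sizes, relax = TRUE)
  expect_identical(nrow(strict$panel), 1L)
  expect_identical(nrow(relaxed$panel), 2L)
  expect_true(relaxed$panel$relaxed[relaxed$panel$pos == 5e6])
})

test_that("intermarker distances pool within-chromosome adjacent gaps", {
  d <- intermarker_distances(data.frame(chrom = "c1", pos = c(100, 200, 400)))
  expect_equal(unname(d[["50%"]]), 150)
  expect_identical(attr(d, "n_distances"), 2L)
  # equally spaced sites have zero IQR width
  eq <- intermarker_distances(data.frame(chrom = "c1", pos = seq(0, 1e6, 1e5)))
  expect_equal(unname(eq[["75%"]] - eq[["25%"]]), 0)
  # order of input rows is irrelevant; distances never span chromosomes
  sc <- data.frame(chrom = rep(c("c1", "c2"), each = 3),
                   pos = c(10, 30, 60, 1000, 1010, 1030))
  expect_identical(intermarker_distances(sc),
                   intermarker_distances(sc[sample(6), ]))
  expect_error(intermarker_distances(data.frame(chrom = "c1", pos = 1)),
               "at least two")
})

test_that("gap finder reports site-free intervals including chromosome
           ends", {
  g <- find_gaps(data.frame(chrom = "c", pos = c(1e6, 4e7)), c(c = 5e7),
                 min_gap = 3e7)
  expect_identical(nrow(g), 1L)
  expect_equal(g$start, 1e6)
  expect_equal(g$length, 4e7 - 1 - 1e6)
  # dense sites leave no gap
  dense <- data.frame(chrom = "c", pos = seq(1e6, 4.9e7, 1e6))
  expect_identical(nrow(find_gaps(dense, c(c = 5e7), min_gap = 3e7)), 0L)
  # an empty chromosome is one full-length gap
  empty <- find_gaps(data.frame(chrom = character(), pos = numeric()),
                     c(c = 5e7), min_gap = 3e7)
  expect_equal(empty$length, 5e7)
  expect_error(find_gaps(data.frame(chrom = "zz", pos = 1), c(c = 5e7)),
               "unknown chromosome")
})

test_that("gap finder agrees with a lattice-occupancy oracle on random
           fixtures", {
  set.seed(55)
  for (rep in 1:5) {
    L <- 1e7
    pos <- sort(sample.int(L / 1e3, sample(3:12, 1))) * 1e3
    gaps <- find_gaps(data.frame(chrom = "c", pos = pos), c(c = L),
                      min_gap = 2e6)
    # oracle: occupancy vector at 1-kb resolution (positions are on the
    # lattice, so runs translate exactly)
    occ <- logical(L / 1e3)
    occ[pos / 1e3] <- TRUE
    runs <- rle(occ)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths
    free <- !runs$values & runs$lengths * 1e3 >= 2e6
    oracle <- data.frame(start = starts[free] * 1e3, end = ends[free] * 1e3)
    # lattice cell [i] covers (i-1)*1e3 .. i*1e3; a site at pos p occupies
    # the single bp [p-1, p), so oracle intervals overcount by up to 1 kb
    expect_identical(nrow(gaps), nrow(oracle))
    if (nrow(gaps)) {
      expect_true(all(abs(gaps$start - oracle$start) < 1e3))
      expect_true(all(abs(gaps$end - oracle$end) < 1e3))
    }
  }
})
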