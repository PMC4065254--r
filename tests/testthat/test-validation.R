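mk_calls <- function(ref = character(), line = character(), f1 = character()) {
  data.frame(
    sample_id = sprintf("s%02d", seq_len(length(ref) + length(line) + length(f1))),
    group = rep(c("reference_colony", "snv_line", "f1"),
                c(length(ref), length(line), length(f1))),
    genotype = c(ref, line, f1), stringsAsFactors = FALSE)
}

test_that("classification rules fire in the documented order", {
  expect_identical(classify_site(mk_calls(rep("no-call", 3), rep("no-call", 2),
                                          rep("no-call", 4))),
                   "assay_failure")
  expect_identical(classify_site(mk_calls("ref/alt", "alt/alt", "ref/alt")),
                   "reference_divergence")
  expect_identical(classify_site(mk_calls("ref/ref", rep("ref/ref", 3),
                                          "ref/ref")),
                   "call_error")
  expect_identical(classify_site(mk_calls("ref/ref", c("alt/alt", "ref/alt"),
                                          "ref/alt")),
                   "residual_heterozygous")
  expect_identical(classify_site(mk_calls("ref/ref", c("alt/alt", "ref/ref"),
                                          "ref/alt")),
                   "residual_heterozygous")
  expect_identical(classify_site(mk_calls("ref/ref", "alt/alt", "ref/alt")),
                   "validated_homozygous")
  # partial no-calls classify on the called subset
  expect_identical(classify_site(mk_calls(c("no-call", "ref/ref"), "alt/alt",
                                          "no-call")),
                   "validated_homozygous")
  # all SNV-line samples missing cannot be adjudicated
  expect_identical(classify_site(mk_calls("ref/ref", "no-call", "ref/alt")),
                   "assay_failure")
  expect_error(classify_site(mk_calls("AA", "alt/alt", "ref/alt")),
               "unknown genotype")
})

test_that("validation summary is a partition of the input sites", {
  labs <- c(rep("validated_homozygous", 5), rep("assay_failure", 2),
            "call_error")
  s <- summarize_validation(labs)
  expect_identical(sum(s), 8L)
  expect_identical(s[["validated_homozygous"]], 5L)
  expect_identical(s[["reference_divergence"]], 0L)
  expect_identical(sum(summarize_validation(character())), 0L)
})

test_that("genotyping fixtures round-trip through the classifier exactly", {
  req <- c(assay_failure = 8, reference_divergence = 5, call_error = 1,
           residual_heterozygous = 11, validated_homozygous = 123)
  fx <- simulate_genotyping_fixture(req, seed = 7)
  expect_identical(nrow(fx$sites), 148L)
  got <- summarize_validation(classify_sites(fx$calls))
  expect_identical(as.integer(got[names(req)]), as.integer(req))
  # randomized category mixes round-trip too
  set.seed(12)
  for (rep in 1:3) {
    req2 <- setNames(as.integer(sample(0:6, 5, TRUE)),
                     c("assay_failure", "reference_divergence", "call_error",
                       "residual_heterozygous", "validated_homozygous"))
    fx2 <- simulate_genotyping_fixture(req2, seed = 100 + rep)
    got2 <- summarize_validation(classify_sites(fx2$calls))
    expect_identical(as.integer(got2[names(req2)]), as.integer(req2))
  }
  # empty and singleton cases
  expect_identical(nrow(simulate_genotyping_fixture(
    c(validated_homozygous = 0), seed = 1)$calls), 0L)
  one <- simulate_genotyping_fixture(c(validated_homozygous = 1), seed = 2)
  expect_identical(classify_sites(one$calls)$classification,
                   "validated_homozygous")
  expect_identical(simulate_genotyping_fixture(req, seed = 7),
                   simulate_genotyping_fixture(req, seed = 7))
})

test_that("panel map export writes matching BED and TSV tracks and
           round-trips", {
  fx <- simulate_genotyping_fixture(c(validated_homozygous = 20,
                                      residual_heterozygous = 4), seed = 3)
  cls <- classify_sites(fx$calls)
  sites <- merge(fx$sites, cls, by = "site_id")
  sites$status <- sites$classification
  dir <- withr::local_tempdir()
  paths <- export_panel_map(sites, dir = dir)
  val_bed <- read.delim(paths[["validated_bed"]], header = FALSE)
  het_bed <- read.delim(paths[["heterozygous_bed"]], header = FALSE)
  expect_identical(nrow(val_bed), 20L)
  expect_identical(nrow(het_bed), 4L)
  expect_true(all(val_bed$V3 - val_bed$V2 == 1))
  back <- ms_read_tsv(paths[["validated_tsv"]])
  expect_setequal(back$site_id, sites$site_id[sites$status == "validated_homozygous"])
  expect_equal(back$pos,
               sites$pos[match(back$site_id, sites$site_id)])
  # a site beyond its chromosome is rejected
  bad <- sites[1, ]; bad$pos <- mouse_chrom_sizes()[[bad$chrom]] + 10
  expect_error(export_panel_map(bad, dir = dir), "outside")
})
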