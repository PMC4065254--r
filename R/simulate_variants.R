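#' Mouse chromosome sizes (mm9/NCBIm37)
#'
#' Lengths in bp of the 19 mouse autosomes plus X, matching the assembly the
#' SNV lines were called against. Positions throughout the package are
#' 1-based inclusive.
#'
#' @return Named numeric vector of chromosome lengths.
#' @examples
#' mouse_chrom_sizes()[c("chr1", "chrX")]
#' @export
mouse_chrom_sizes <- function() {
  c(chr1 = 197195432, chr2 = 181748087, chr3 = 159599783, chr4 = 155630120,
    chr5 = 152537259, chr6 = 149517037, chr7 = 152524553, chr8 = 131738871,
    chr9 = 124076172, chr10 = 129993255, chr11 = 121843856, chr12 = 121257530,
    chr13 = 120284312, chr14 = 125194864, chr15 = 103494974, chr16 = 98319150,
    chr17 = 95272651, chr18 = 90772031, chr19 = 61342430, chrX = 166650296)
}

check_chrom_sizes <- function(chrom_sizes) {
  stopifnot(is.numeric(chrom_sizes), length(chrom_sizes) > 0,
            !is.null(names(chrom_sizes)), all(chrom_sizes > 0))
  chrom_sizes
}

#' Published summaries of the six B6.SNV mapping-partner lines
#'
#' `snv_line_chromosome_counts()` returns the per-chromosome counts of
#' candidate SNVs found in exactly one of the six inbred B6.SNV lines
#' (columns `B6.SNVb` ... `B6.SNVh`), plus the sites found in the related
#' pair B6.SNVg/B6.SNVh and no other line (`shared_gh`). Line-specific sites
#' total 13,172 and the related-pair-shared set 792.
#'
#' `enu_spectrum_counts()` returns the 12-category mutation spectrum of the
#' 13,172 line-specific candidates, and `spontaneous_at_ta_counts()` the
#' AT-to-TA transversion share among spontaneous B6 SNVs across 18 strains
#' (the comparison point for the elevated ENU AT-to-TA fraction).
#'
#' These summaries serve as inputs for fixture construction and for the
#' bookkeeping checks in the test-suite and analysis scripts.
#'
#' @return Data frames (or a named vector for
#'   `spontaneous_at_ta_counts()`); see Details.
#' @examples
#' colSums(snv_line_chromosome_counts()[-1])
#' @export
snv_line_chromosome_counts <- function() {
  df <- data.frame(
    chrom = paste0("chr", c(1:19, "X")),
    B6.SNVb = c(300, 206, 244, 348, 95, 175, 187, 179, 132, 114, 159, 149,
                120, 114, 92, 163, 138, 92, 54, 185),
    B6.SNVc = c(300, 232, 198, 215, 246, 108, 57, 84, 63, 216, 71, 121, 185,
                103, 69, 57, 180, 111, 89, 227),
    B6.SNVe = c(89, 51, 144, 254, 110, 54, 127, 78, 108, 115, 76, 119, 57,
                158, 117, 42, 85, 39, 75, 153),
    B6.SNVf = c(108, 53, 56, 174, 104, 49, 57, 46, 33, 62, 34, 43, 40, 26,
                59, 35, 97, 48, 6, 68),
    B6.SNVg = c(52, 121, 47, 36, 82, 96, 46, 81, 106, 79, 75, 34, 31, 36,
                29, 43, 47, 61, 36, 87),
    B6.SNVh = c(81, 78, 263, 105, 218, 56, 236, 138, 42, 127, 37, 122, 104,
                221, 67, 160, 113, 136, 51, 165),
    shared_gh = c(9, 19, 54, 21, 46, 49, 102, 92, 12, 73, 5, 10, 70, 23, 15,
                  98, 54, 7, 11, 22),
    stringsAsFactors = FALSE)
  df
}

#' @rdname snv_line_chromosome_counts
#' @export
enu_spectrum_counts <- function() {
  data.frame(
    mutation_type = rep(c("transition", "transversion"), c(4, 8)),
    ref = c("A", "T", "C", "G", "A", "T", "C", "G", "A", "T", "C", "G"),
    alt = c("G", "C", "T", "A", "C", "G", "A", "T", "T", "A", "G", "C"),
    n = c(2142, 2497, 1540, 1435, 516, 598, 683, 649, 1114, 1352, 332, 314),
    stringsAsFactors = FALSE)
}

#' @rdname snv_line_chromosome_counts
#' @export
spontaneous_at_ta_counts <- function() {
  c(at_ta = 14849300, total = 164137670)
}

#' Default ENU mutation spectrum as category probabilities
#'
#' The 12 ordered ref-to-alt single-nucleotide categories with probabilities
#' proportional to the line-specific candidate counts of
#' [enu_spectrum_counts()].
#'
#' @return data.frame with columns `ref`, `alt`, `prob`.
#' @export
enu_spectrum <- function() {
  sc <- enu_spectrum_counts()
  data.frame(ref = sc$ref, alt = sc$alt, prob = sc$n / sum(sc$n),
             stringsAsFactors = FALSE)
}

#' Simulate multi-line SNV tables with ENU-like structure
#'
#' Generates per-line candidate variant calls with the statistical structure
#' of resequenced mutagenized inbred lines: per-line variant counts are
#' Poisson with mean `rate_per_bp` times the genome length, positions are
#' uniform along chromosomes (no hotspots), ref/alt categories follow the
#' mutation `spectrum`, a designated related pair of lines shares a fraction
#' of its variants (common founder), a fraction of sites is still
#' heterozygous (residual heterozygosity after inbreeding), and read depths
#' are Poisson around each line's mean sequencing coverage.
#'
#' @param chrom_sizes named vector of chromosome lengths (1-based positions).
#' @param rate_per_bp per-bp candidate mutation rate (default `1.1e-6`).
#' @param spectrum data.frame `(ref, alt, prob)`; probabilities sum to 1.
#' @param n_lines number of lines (ignored when `line_ids` is given).
#' @param line_ids line identifiers; default the six B6.SNV-style lines.
#' @param related_pair character pair of `line_ids` sharing variants, or
#'   `NULL` for fully independent lines.
#' @param shared_fraction fraction of a related line's variants shared with
#'   its sibling; default the observed ratio of pair-shared to
#'   pair-specific-plus-shared sites, `792 / (792 + 1225 + 2520)`.
#' @param residual_het_rate fraction of sites flagged heterozygous
#'   (default 0.14, the F10 sib-mating expectation).
#' @param mean_coverage mean sequencing coverage, recycled across lines.
#' @param flank_width flanking sequence length kept on each side of a site.
#' @param seed master seed.
#' @return A [line_variant_table()].
#' @examples
#' sizes <- c(chr1 = 5e6, chr2 = 4e6)
#' tbl <- simulate_variant_lines(sizes, rate_per_bp = 1e-5, n_lines = 3,
#'                               related_pair = NULL, seed = 1)
#' nrow(tbl$records)
#' @export
simulate_variant_lines <- function(chrom_sizes = mouse_chrom_sizes(),
                                   rate_per_bp = 1.1e-6,
                                   spectrum = enu_spectrum(),
                                   n_lines = 6L,
                                   line_ids = NULL,
                                   related_pair = c("B6.SNVg", "B6.SNVh"),
                                   shared_fraction = 792 / (792 + 1225 + 2520),
                                   residual_het_rate = 0.14,
                                   mean_coverage = 5.7,
                                   flank_width = 50L,
                                   seed = 1L) {
  check_chrom_sizes(chrom_sizes)
  stopifnot(rate_per_bp >= 0, residual_het_rate >= 0, residual_het_rate <= 1,
            shared_fraction >= 0, shared_fraction < 1)
  if (abs(sum(spectrum$prob) - 1) > 1e-8)
    stop("spectrum probabilities must sum to 1")
  if (is.null(line_ids)) {
    # the six inbred lines are b, c, e, f, g, h (d was lost to a recessive
    # lethal during inbreeding)
    pool <- paste0("B6.SNV", c("b", "c", "e", "f", "g", "h"))
    line_ids <- if (n_lines <= 6L) pool[seq_len(n_lines)] else
      paste0("B6.SNV", letters[seq_len(n_lines) + 1L])
  }
  if (!is.null(related_pair)) {
    related_pair <- as.character(related_pair)
    if (!all(related_pair %in% line_ids) || length(related_pair) != 2L)
      stop("related_pair must name two of the line_ids")
  }
  genome_bp <- sum(chrom_sizes)
  coverage <- rep_len(mean_coverage, length(line_ids))
  names(coverage) <- line_ids

  with_substream(seed, "variant_lines", {
    draw_sites <- function(n_sites, line_id, cov) {
      if (n_sites == 0L)
        return(empty_variant_records())
      chrom <- sample(names(chrom_sizes), n_sites, replace = TRUE,
                      prob = chrom_sizes / genome_bp)
      pos <- floor(runif(n_sites) * chrom_sizes[chrom]) + 1
      cat_i <- sample.int(nrow(spectrum), n_sites, replace = TRUE,
                          prob = spectrum$prob)
      data.frame(line_id = line_id, chrom = chrom, pos = pos,
                 ref = spectrum$ref[cat_i], alt = spectrum$alt[cat_i],
                 depth = rpois(n_sites, cov),
                 genotype_quality = sample(c(99L, 30:98), n_sites,
                                           replace = TRUE,
                                           prob = c(0.85, rep(0.15 / 69, 69))),
                 zygosity = ifelse(runif(n_sites) < residual_het_rate,
                                   "het", "hom"),
                 flank_seq = random_flanks(n_sites, flank_width),
                 stringsAsFactors = FALSE)
    }
    recs <- list()
    for (ln in line_ids) {
      in_pair <- !is.null(related_pair) && ln %in% related_pair
      lambda <- rate_per_bp * genome_bp * if (in_pair) 1 - shared_fraction else 1
      recs[[ln]] <- draw_sites(rpois(1, lambda), ln, coverage[[ln]])
    }
    if (!is.null(related_pair)) {
      shared <- draw_sites(rpois(1, rate_per_bp * genome_bp * shared_fraction),
                           related_pair[1], coverage[[related_pair[1]]])
      if (nrow(shared)) {
        twin <- shared
        twin$line_id <- related_pair[2]
        twin$depth <- rpois(nrow(twin), coverage[[related_pair[2]]])
        recs$shared <- rbind(shared, twin)
      }
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    records <- records[!duplicated(records[c("line_id", "chrom", "pos")]), ,
                       drop = FALSE]
    records <- records[order(records$line_id, records$chrom, records$pos), ,
                       drop = FALSE]
    line_variant_table(records,
                       lines = data.frame(line_id = line_ids,
                                          mean_coverage = as.numeric(coverage),
                                          stringsAsFactors = FALSE))
  })
}

empty_variant_records <- function() {
  data.frame(line_id = character(), chrom = character(), pos = numeric(),
             ref = character(), alt = character(), depth = integer(),
             genotype_quality = integer(), zygosity = character(),
             flank_seq = character(), stringsAsFactors = FALSE)
}

random_flanks <- function(n, width) {
  if (n == 0L) return(character())
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 2L * width, replace = TRUE),
          collapse = ""), character(1))
}

#' Rebuild a variant table from per-chromosome summary counts
#'
#' Constructs a synthetic [line_variant_table()] whose line-specific and
#' pair-shared per-chromosome site counts equal a given summary table (the
#' published per-line counts by default). Positions are deterministic per
#' seed and distinct within a chromosome, so the partition bookkeeping of
#' [partition_line_specific()] recovers the input counts exactly.
#'
#' @param counts data.frame like [snv_line_chromosome_counts()]: a `chrom`
#'   column, one count column per line, and optionally a `shared_gh` column
#'   of sites present in the final two lines only.
#' @param chrom_sizes named chromosome lengths covering `counts$chrom`.
#' @param mean_coverage per-line mean coverage recorded in the metadata.
#' @param seed master seed.
#' @return A [line_variant_table()].
#' @examples
#' tbl <- variant_table_from_counts(snv_line_chromosome_counts(), seed = 1)
#' nrow(tbl$records)
#' @export
variant_table_from_counts <- function(counts = snv_line_chromosome_counts(),
                                      chrom_sizes = mouse_chrom_sizes(),
                                      mean_coverage = 5.7, seed = 1L) {
  check_chrom_sizes(chrom_sizes)
  stopifnot(is.data.frame(counts), "chrom" %in% names(counts),
            all(counts$chrom %in% names(chrom_sizes)))
  has_shared <- "shared_gh" %in% names(counts)
  line_cols <- setdiff(names(counts), c("chrom", "shared_gh"))
  if (has_shared && length(line_cols) < 2L)
    stop("shared_gh requires at least two line columns")
  spec <- enu_spectrum()
  with_substream(seed, "table_fixture", {
    recs <- list()
    for (ci in seq_len(nrow(counts))) {
      chrom <- counts$chrom[ci]
      n_cells <- sum(as.numeric(counts[ci, line_cols])) +
        if (has_shared) counts$shared_gh[ci] else 0
      pos_all <- sort(sample.int(chrom_sizes[[chrom]], n_cells))
      cat_i <- sample.int(nrow(spec), n_cells, replace = TRUE, prob = spec$prob)
      used <- 0L
      take <- function(k) {
        idx <- used + seq_len(k); used <<- used + k
        list(pos = pos_all[idx], ref = spec$ref[cat_i[idx]],
             alt = spec$alt[cat_i[idx]])
      }
      for (ln in line_cols) {
        k <- counts[[ln]][ci]
        if (k == 0) next
        s <- take(k)
        recs[[paste(chrom, ln)]] <- data.frame(
          line_id = ln, chrom = chrom, pos = s$pos, ref = s$ref, alt = s$alt,
          depth = 4L, genotype_quality = 99L, zygosity = "hom",
          flank_seq = "", stringsAsFactors = FALSE)
      }
      if (has_shared && counts$shared_gh[ci] > 0) {
        s <- take(counts$shared_gh[ci])
        pair <- utils::tail(line_cols, 2L)
        for (ln in pair)
          recs[[paste(chrom, "shared", ln)]] <- data.frame(
            line_id = ln, chrom = chrom, pos = s$pos, ref = s$ref, alt = s$alt,
            depth = 4L, genotype_quality = 99L, zygosity = "hom",
            flank_seq = "", stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    line_variant_table(records,
                       lines = data.frame(line_id = line_cols,
                                          mean_coverage = mean_coverage,
                                          stringsAsFactors = FALSE))
  })
}
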