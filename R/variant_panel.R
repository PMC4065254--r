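#' Multi-line SNV call table
#'
#' Container for candidate single-nucleotide variant calls across a set of
#' resequenced lines: a `records` data.frame (one row per call, columns
#' `line_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `depth`,
#' `genotype_quality`, `zygosity`, `flank_seq`) and a `lines` data.frame of
#' per-line metadata (`line_id`, `mean_coverage`). `(line_id, chrom, pos)`
#' must be unique.
#'
#' @param records variant call data.frame; missing optional columns
#'   (`depth`, `genotype_quality`, `zygosity`, `flank_seq`) are filled with
#'   defaults.
#' @param lines per-line metadata with `line_id` and `mean_coverage`.
#' @return An object of class `line_variant_table`.
#' @export
line_variant_table <- function(records, lines) {
  stopifnot(is.data.frame(records),
            all(c("line_id", "chrom", "pos", "ref", "alt") %in% names(records)))
  if (is.null(records$depth)) records$depth <- NA_integer_
  if (is.null(records$genotype_quality)) records$genotype_quality <- NA_integer_
  if (is.null(records$zygosity)) records$zygosity <- "hom"
  if (is.null(records$flank_seq)) records$flank_seq <- ""
  if (nrow(records)) {
    stopifnot(all(records$pos >= 1),
              all(records$ref != records$alt),
              all(nchar(records$ref) == 1L), all(nchar(records$alt) == 1L))
    if (anyDuplicated(records[c("line_id", "chrom", "pos")]))
      stop("(line_id, chrom, pos) must be unique")
  }
  if (missing(lines))
    lines <- data.frame(line_id = unique(records$line_id),
                        mean_coverage = NA_real_, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(lines),
            all(c("line_id", "mean_coverage") %in% names(lines)))
  structure(list(records = records, lines = lines),
            class = "line_variant_table")
}

#' @export
print.line_variant_table <- function(x, ...) {
  cat(sprintf("Line variant table: %d calls across %d lines\n",
              nrow(x$records), nrow(x$lines)))
  print(table(x$records$line_id))
  invisible(x)
}

#' Depth-filter variant calls
#'
#' Keeps calls whose read depth is at least `min_depth` and no more than
#' `max_coverage_mult` times the line's mean sequencing coverage; the upper
#' cut culls copy-number or efficiency artifacts that pile up reads.
#'
#' @param table a [line_variant_table()].
#' @param min_depth minimum read depth (default 3).
#' @param max_coverage_mult maximum depth as a multiple of the line's mean
#'   coverage (default 2.5).
#' @return A filtered [line_variant_table()].
#' @examples
#' tbl <- line_variant_table(
#'   data.frame(line_id = "a", chrom = "chr1", pos = 1:3,
#'              ref = "A", alt = "T", depth = c(2, 3, 16)),
#'   lines = data.frame(line_id = "a", mean_coverage = 6))
#' nrow(filter_calls(tbl)$records)  # only depth 3 survives
#' @export
filter_calls <- function(table, min_depth = 3, max_coverage_mult = 2.5) {
  stopifnot(inherits(table, "line_variant_table"))
  miss <- setdiff(unique(table$records$line_id), table$lines$line_id)
  if (length(miss))
    stop("no mean-coverage metadata for line(s): ", paste(miss, collapse = ", "))
  cov <- setNames(table$lines$mean_coverage, table$lines$line_id)
  if (anyNA(cov[unique(table$records$line_id)]))
    stop("mean coverage is NA for some lines; cannot apply the upper depth cut")
  cap <- max_coverage_mult * cov[table$records$line_id]
  keep <- table$records$depth >= min_depth & table$records$depth <= cap
  table$records <- table$records[keep, , drop = FALSE]
  rownames(table$records) <- NULL
  table
}

site_key <- function(df) paste(df$chrom, df$pos, df$alt, sep = ":")

#' Partition sites by line specificity
#'
#' A site -- keyed on `(chrom, pos, alt)`, zygosity ignored -- is
#' *line-specific* when it is called in exactly one line (evidence of an
#' induced, post-split mutation), *pair-shared* when called in exactly the
#' two related lines (a mutation in their common founder), and *remainder*
#' otherwise (shared ancestry or artifacts).
#'
#' @param table a [line_variant_table()].
#' @param related_pair character pair of related line ids, or `NULL`.
#' @return An object of class `variant_partition`: list with `exclusive`
#'   (site records of line-specific calls, with `line_id` the owning line),
#'   `shared` (one record per pair-shared site), `remainder` (one record per
#'   other site, with `n_lines`), and `related_pair`.
#' @export
partition_line_specific <- function(table, related_pair = NULL) {
  stopifnot(inherits(table, "line_variant_table"))
  rec <- table$records
  if (!is.null(related_pair)) {
    related_pair <- as.character(related_pair)
    stopifnot(length(related_pair) == 2L)
  }
  if (nrow(rec) == 0L)
    return(structure(list(exclusive = rec, shared = rec[0, ],
                          remainder = cbind(rec[0, ], n_lines = integer()),
                          related_pair = related_pair),
                     class = "variant_partition"))
  key <- site_key(rec)
  # lines carrying each site, as a sorted collapsed string
  lines_by_site <- tapply(rec$line_id, key,
                          function(l) paste(sort(unique(l)), collapse = "|"))
  n_by_site <- lengths(strsplit(lines_by_site, "|", fixed = TRUE))
  site_lines <- lines_by_site[key]
  site_n <- n_by_site[key]
  pair_key <- if (is.null(related_pair)) NA_character_ else
    paste(sort(related_pair), collapse = "|")
  excl <- rec[site_n == 1L, , drop = FALSE]
  shared_rec <- rec[!is.na(pair_key) & site_lines == pair_key, , drop = FALSE]
  shared <- shared_rec[!duplicated(site_key(shared_rec)), , drop = FALSE]
  rem_rec <- rec[site_n > 1L &
                   (is.na(pair_key) | site_lines != pair_key), , drop = FALSE]
  remainder <- rem_rec[!duplicated(site_key(rem_rec)), , drop = FALSE]
  if (nrow(remainder))
    remainder$n_lines <- as.integer(n_by_site[site_key(remainder)])
  else remainder$n_lines <- integer()
  rownames(excl) <- rownames(shared) <- rownames(remainder) <- NULL
  structure(list(exclusive = excl, shared = shared, remainder = remainder,
                 related_pair = related_pair),
            class = "variant_partition")
}

#' @export
print.variant_partition <- function(x, ...) {
  cat(sprintf("Variant partition: %d line-specific, %d pair-shared, %d other sites\n",
              nrow(x$exclusive), nrow(x$shared), nrow(x$remainder)))
  invisible(x)
}

#' Per-chromosome summary of a line-specificity partition
#'
#' @param partition a [partition_line_specific()] result.
#' @param chrom_order optional chromosome ordering for the rows.
#' @return data.frame: `chrom`, one line-specific count column per line,
#'   `shared` (pair-shared sites, if a related pair was given), and a final
#'   `Total` row; attribute `line_specific_total` carries the grand total.
#' @export
summarize_partition <- function(partition, chrom_order = NULL) {
  stopifnot(inherits(partition, "variant_partition"))
  ex <- partition$exclusive
  chroms <- if (!is.null(chrom_order)) chrom_order else
    unique(c(ex$chrom, partition$shared$chrom))
  lines <- sort(unique(ex$line_id))
  out <- data.frame(chrom = chroms, stringsAsFactors = FALSE)
  for (ln in lines)
    out[[ln]] <- vapply(chroms, function(ch)
      sum(ex$line_id == ln & ex$chrom == ch), numeric(1))
  if (!is.null(partition$related_pair))
    out$shared <- vapply(chroms, function(ch)
      sum(partition$shared$chrom == ch), numeric(1))
  totals <- c(list(chrom = "Total"), as.list(colSums(out[, -1, drop = FALSE])))
  out <- rbind(out, as.data.frame(totals, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "line_specific_total") <- sum(vapply(lines, function(ln)
    sum(ex$line_id == ln), numeric(1)))
  out
}

#' Mutation spectrum of single-nucleotide variants
#'
#' Counts and percentages of the 12 ordered ref-to-alt categories.
#'
#' @param variants a [line_variant_table()], a [partition_line_specific()]
#'   result (its line-specific sites are used), or a data.frame with `ref`
#'   and `alt` columns.
#' @return data.frame of class `spectrum_table`: `mutation_type`, `ref`,
#'   `alt`, `n`, `percent` (percentages sum to 100 up to rounding).
#' @examples
#' sp <- mutation_spectrum(data.frame(ref = c("A", "T"), alt = c("T", "A")))
#' sum(sp$percent)
#' @export
mutation_spectrum <- function(variants) {
  df <- if (inherits(variants, "line_variant_table")) variants$records
        else if (inherits(variants, "variant_partition")) variants$exclusive
        else variants
  stopifnot(is.data.frame(df), all(c("ref", "alt") %in% names(df)))
  bases <- c("A", "C", "G", "T")
  if (nrow(df) &&
      (!all(df$ref %in% bases) || !all(df$alt %in% bases) ||
       any(df$ref == df$alt)))
    stop("mutation_spectrum requires single-nucleotide ref/alt records")
  cats <- enu_spectrum_counts()[c("mutation_type", "ref", "alt")]
  cats$n <- mapply(function(r, a) sum(df$ref == r & df$alt == a),
                   cats$ref, cats$alt)
  cats$percent <- if (sum(cats$n) > 0) 100 * cats$n / sum(cats$n) else 0
  class(cats) <- c("spectrum_table", "data.frame")
  cats
}

#' Share of AT-to-TA transversions in a spectrum
#'
#' ENU mutagenesis elevates A>T / T>A transversions well above their share
#' among spontaneous mutations, which is the basis for preferring them as
#' genotyping markers.
#'
#' @param spectrum a `spectrum_table` from [mutation_spectrum()], or a
#'   two-element count vector `c(at_ta, total)` such as
#'   [spontaneous_at_ta_counts()].
#' @return Percentage (0-100).
#' @examples
#' at_ta_percent(spontaneous_at_ta_counts())
#' @export
at_ta_percent <- function(spectrum) {
  if (is.numeric(spectrum) && length(spectrum) == 2L)
    return(100 * spectrum[[1]] / spectrum[[2]])
  stopifnot(inherits(spectrum, "spectrum_table"))
  idx <- (spectrum$ref == "A" & spectrum$alt == "T") |
    (spectrum$ref == "T" & spectrum$alt == "A")
  100 * sum(spectrum$n[idx]) / sum(spectrum$n)
}

#' Per-base-pair mutation rate
#'
#' @param n_variants number of candidate variants.
#' @param genome_bp base pairs covered (e.g. number of lines times genome
#'   length).
#' @param digits significant digits of the reported rate (default 2, the
#'   convention used for such rates).
#' @return Rate per bp.
#' @examples
#' per_bp_rate(1.3e4, 6 * 2e9)  # 1.1e-06
#' @export
per_bp_rate <- function(n_variants, genome_bp, digits = 2) {
  if (!is.numeric(genome_bp) || genome_bp <= 0)
    stop("genome_bp must be positive")
  stopifnot(n_variants >= 0)
  signif(n_variants / genome_bp, digits)
}
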