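#' Flanking-sequence repeat predicates
#'
#' "No significant repeats in the flanking sequence" is operationalized as:
#' no homopolymer run of `min_run` or more identical bases, and no tandem
#' dinucleotide repeat of `min_units` or more units, anywhere in the stored
#' flank. Both thresholds are configurable.
#'
#' @param flank_seq character vector of flanking sequences.
#' @param min_run homopolymer run length that disqualifies (default 8).
#' @param min_units tandem dinucleotide units that disqualify (default 4).
#' @return Logical vector: `TRUE` when the flank contains a significant
#'   repeat.
#' @examples
#' flank_has_repeat(c("ACGTACGTAC", strrep("A", 10), strrep("AC", 5)))
#' @export
flank_has_repeat <- function(flank_seq, min_run = 8L, min_units = 4L) {
  homo <- sprintf("([ACGTN])\\1{%d,}", min_run - 1L)
  dinuc <- sprintf("([ACGT]{2})\\1{%d,}", min_units - 1L)
  grepl(homo, flank_seq) | grepl(dinuc, flank_seq)
}

# Mutation-type preference for genotyping assays: AT<->TA transversions
# first (elevated by ENU, hence most likely true induced mutations), then
# A>G / T>C, then G>A / C>T transitions; everything else last.
mutation_type_rank <- function(ref, alt) {
  key <- paste0(ref, ">", alt)
  rank <- rep(4L, length(key))
  rank[key %in% c("A>T", "T>A")] <- 1L
  rank[key %in% c("A>G", "T>C")] <- 2L
  rank[key %in% c("G>A", "C>T")] <- 3L
  rank
}

#' Assemble marker candidates for one focal line
#'
#' Collects the sites usable as genotyping markers for `line`: its
#' line-specific sites plus (when the focal line belongs to the related
#' pair) the pair-shared sites, each tagged with its specificity class.
#'
#' @param table a [line_variant_table()] (supplies depth/quality/flank).
#' @param partition matching [partition_line_specific()] result.
#' @param line focal line id.
#' @return data.frame of candidate records with a `specificity` column
#'   (`"related-pair-only"` or `"single-line"`).
#' @export
marker_candidates <- function(table, partition, line) {
  stopifnot(inherits(table, "line_variant_table"),
            inherits(partition, "variant_partition"))
  own <- partition$exclusive[partition$exclusive$line_id == line, , drop = FALSE]
  if (nrow(own)) own$specificity <- "single-line"
  shared <- partition$shared
  if (!is.null(partition$related_pair) && line %in% partition$related_pair &&
      nrow(shared)) {
    # use the focal line's own call record for each shared site
    rec <- table$records[table$records$line_id == line, , drop = FALSE]
    shared <- rec[site_key(rec) %in% site_key(partition$shared), , drop = FALSE]
    if (nrow(shared)) shared$specificity <- "related-pair-only"
  } else shared <- own[0, , drop = FALSE]
  out <- rbind(shared, own)
  rownames(out) <- NULL
  out
}

#' Rank marker candidates for genotyping validation
#'
#' Applies the assay-candidate criteria: a Phred genotyping quality of 99 is
#' required, flanks with significant repeats are excluded, and the survivors
#' are ordered by specificity class (related-pair-shared sites first, since
#' their presence in both sibling lines but no other confirms an induced
#' founder mutation), then mutation-type preference (A>T / T>A, then
#' A>G / T>C, then G>A / C>T), then chromosome and position. Candidates
#' whose mutation type falls outside the preferred three classes are kept in
#' the order (flagged `strict = FALSE`) so that selection can relax onto
#' them where mutations are sparse.
#'
#' @param candidates data.frame from [marker_candidates()] (needs `chrom`,
#'   `pos`, `ref`, `alt`, `genotype_quality`, `flank_seq`, `specificity`).
#' @param quality_required required Phred genotyping quality (default 99).
#' @param min_run,min_units repeat-rule thresholds, see [flank_has_repeat()].
#' @return The eligible candidates ordered by preference, with columns
#'   `type_rank`, `specificity_rank`, `preference_rank` (1 = best) and
#'   `strict`.
#' @export
rank_candidates <- function(candidates, quality_required = 99L,
                            min_run = 8L, min_units = 4L) {
  stopifnot(is.data.frame(candidates),
            all(c("chrom", "pos", "ref", "alt", "genotype_quality",
                  "flank_seq", "specificity") %in% names(candidates)))
  keep <- candidates$genotype_quality >= quality_required &
    !flank_has_repeat(candidates$flank_seq, min_run, min_units)
  out <- candidates[keep, , drop = FALSE]
  out$type_rank <- mutation_type_rank(out$ref, out$alt)
  out$specificity_rank <- match(out$specificity,
                                c("related-pair-only", "single-line", "other"))
  o <- order(out$specificity_rank, out$type_rank, out$chrom, out$pos)
  out <- out[o, , drop = FALSE]
  out$preference_rank <- seq_len(nrow(out))
  out$strict <- out$specificity_rank == 1L & out$type_rank <= 3L
  rownames(out) <- NULL
  out
}

chrom_bins <- function(len, per_chrom = 3L) {
  edges <- seq(0, len, length.out = per_chrom + 1L)
  data.frame(bin = c("proximal", "middle", "distal")[seq_len(per_chrom)],
             start = edges[-length(edges)], end = edges[-1])
}

#' Select a genome-wide marker panel
#'
#' Splits each autosome into `per_autosome` equal physical thirds (proximal
#' / middle / distal -- mouse chromosomes are acrocentric, so the proximal
#' bin abuts the centromere) and picks the best-ranked candidate in each
#' bin. Within a bin, candidates are compared by specificity class, then
#' mutation-type preference, then distance to the bin midpoint, then lower
#' position. With `relax = TRUE` (default) a bin with no candidate meeting
#' the strict criteria falls back first to lower-preference mutation types,
#' then to single-line sites, mirroring the relaxation needed where
#' mutations are sparse; with `relax = FALSE` such bins stay unfilled. The
#' X chromosome is excluded.
#'
#' @param ranked a [rank_candidates()] result.
#' @param chrom_sizes named chromosome lengths; autosomes are every
#'   chromosome except `chrX`/`X`.
#' @param per_autosome bins (and markers) per autosome, default 3.
#' @param relax admit lower-preference candidates in sparse bins.
#' @return List of class `marker_panel`: `panel` (selected markers with
#'   `bin` and `relaxed` flag) and `unfilled` (autosome/bin pairs with no
#'   candidate).
#' @export
select_panel <- function(ranked, chrom_sizes = mouse_chrom_sizes(),
                         per_autosome = 3L, relax = TRUE) {
  check_chrom_sizes(chrom_sizes)
  autosomes <- setdiff(names(chrom_sizes), c("chrX", "X"))
  sel <- list(); unfilled <- list()
  for (ch in autosomes) {
    bins <- chrom_bins(chrom_sizes[[ch]], per_autosome)
    on_ch <- ranked[ranked$chrom == ch, , drop = FALSE]
    for (bi in seq_len(nrow(bins))) {
      inb <- on_ch[on_ch$pos > bins$start[bi] & on_ch$pos <= bins$end[bi], ,
                   drop = FALSE]
      if (!relax) inb <- inb[inb$strict, , drop = FALSE]
      if (nrow(inb) == 0L) {
        unfilled[[paste(ch, bi)]] <- data.frame(
          chrom = ch, bin = bins$bin[bi], stringsAsFactors = FALSE)
        next
      }
      mid <- (bins$start[bi] + bins$end[bi]) / 2
      o <- order(inb$specificity_rank, inb$type_rank, abs(inb$pos - mid),
                 inb$pos)
      pick <- inb[o[1L], , drop = FALSE]
      pick$bin <- bins$bin[bi]
      pick$relaxed <- !pick$strict
      sel[[paste(ch, bi)]] <- pick
    }
  }
  panel <- if (length(sel)) do.call(rbind, sel) else
    cbind(ranked[0, , drop = FALSE], bin = character(), relaxed = logical())
  unf <- if (length(unfilled)) do.call(rbind, unfilled) else
    data.frame(chrom = character(), bin = character(), stringsAsFactors = FALSE)
  rownames(panel) <- rownames(unf) <- NULL
  structure(list(panel = panel, unfilled = unf), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("Marker panel: %d markers selected, %d bins unfilled\n",
              nrow(x$panel), nrow(x$unfilled)))
  invisible(x)
}

#' Quantiles of distances between adjacent marker sites
#'
#' Distances are computed between neighbouring sites within each chromosome
#' (never across chromosome ends) and pooled before taking quantiles.
#'
#' @param sites data.frame with `chrom` and `pos`.
#' @param probs quantile probabilities (default quartiles).
#' @return Named numeric vector of quantiles with attribute `n_distances`.
#' @examples
#' intermarker_distances(data.frame(chrom = "chr1", pos = c(100, 200, 400)))
#' @export
intermarker_distances <- function(sites, probs = c(0.25, 0.5, 0.75)) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  d <- unlist(lapply(split(sites$pos, sites$chrom),
                     function(p) if (length(p) >= 2L) diff(sort(p)) else numeric()),
              use.names = FALSE)
  if (length(d) == 0L)
    stop("need at least two sites on some chromosome to measure distances")
  structure(quantile(d, probs = probs), n_distances = length(d))
}

#' Find marker-free gaps along the genome
#'
#' Reports the maximal intervals of length at least `min_gap` containing no
#' site, including the stretches from each chromosome start to its first
#' site and from the last site to the chromosome end. Chromosomes with no
#' site at all yield one full-length gap. Intervals are 0-based half-open
#' (BED convention); a site at 1-based position `p` occupies `[p-1, p)`.
#'
#' @param sites data.frame with `chrom` and `pos` (1-based), possibly empty.
#' @param chrom_sizes named chromosome lengths; all are scanned.
#' @param min_gap minimum reported gap length in bp (default 3e7).
#' @return data.frame `chrom`, `start`, `end`, `length` (0-based half-open).
#' @examples
#' find_gaps(data.frame(chrom = "c", pos = c(1e6, 4e7)),
#'           c(c = 5e7), min_gap = 3e7)
#' @export
find_gaps <- function(sites, chrom_sizes, min_gap = 3e7) {
  check_chrom_sizes(chrom_sizes)
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  bad <- setdiff(unique(sites$chrom), names(chrom_sizes))
  if (length(bad))
    stop("sites on unknown chromosome(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (ch in names(chrom_sizes)) {
    L <- chrom_sizes[[ch]]
    p <- sort(unique(sites$pos[sites$chrom == ch]))
    # boundaries of site-free intervals in 0-based half-open coordinates
    starts <- c(0, p)
    ends <- c(p - 1, L)
    len <- ends - starts
    keep <- len >= min_gap
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], length = len[keep],
                              stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               length = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
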