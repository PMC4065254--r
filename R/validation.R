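#' Classify a candidate site from genotyping-assay results
#'
#' Validation of a candidate marker site genotypes three sample groups: the
#' reference colony (expected ref/ref), the SNV line the candidate came from
#' (expected alt/alt if the induced mutation is fixed) and F1 hybrids
#' (expected ref/alt). The classification rules are applied in order:
#'
#' 1. every call is a no-call: `assay_failure`;
#' 2. any reference-colony sample carries the alt allele:
#'    `reference_divergence` (the local colony differs from the reference
#'    assembly at this position, or the assembly is wrong -- the assay
#'    cannot distinguish the two);
#' 3. the SNV-line samples are all ref/ref: `call_error` (the sequencing
#'    call was wrong -- the site does not vary);
#' 4. the SNV-line samples are mixed (at least one alt allele alongside a
#'    ref/ref or ref/alt sample): `residual_heterozygous` (the site still
#'    segregates in the inbred line);
#' 5. otherwise (SNV line alt/alt, reference ref/ref, F1 heterozygous):
#'    `validated_homozygous`.
#'
#' Sites where only some samples fail are classified on the called subset;
#' a site whose SNV-line samples are all no-calls cannot be adjudicated and
#' is treated as an assay failure.
#'
#' @param calls data.frame of one site's calls: columns `sample_id`,
#'   `group` (`reference_colony`, `snv_line`, `f1`) and `genotype`
#'   (`ref/ref`, `ref/alt`, `alt/alt`, `no-call`).
#' @return Single classification string.
#' @examples
#' classify_site(data.frame(sample_id = 1:3,
#'                          group = c("reference_colony", "snv_line", "f1"),
#'                          genotype = c("ref/ref", "alt/alt", "ref/alt")))
#' @export
classify_site <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("group", "genotype") %in% names(calls)), nrow(calls) > 0)
  ok_geno <- c("ref/ref", "ref/alt", "alt/alt", "no-call")
  ok_grp <- c("reference_colony", "snv_line", "f1")
  if (!all(calls$genotype %in% ok_geno))
    stop("unknown genotype value(s): ",
         paste(setdiff(calls$genotype, ok_geno), collapse = ", "))
  if (!all(calls$group %in% ok_grp))
    stop("unknown sample group(s): ",
         paste(setdiff(calls$group, ok_grp), collapse = ", "))
  called <- calls[calls$genotype != "no-call", , drop = FALSE]
  if (nrow(called) == 0L) return("assay_failure")
  ref_g <- called$genotype[called$group == "reference_colony"]
  line_g <- called$genotype[called$group == "snv_line"]
  if (any(ref_g %in% c("ref/alt", "alt/alt"))) return("reference_divergence")
  if (length(line_g) == 0L) return("assay_failure")
  if (all(line_g == "ref/ref")) return("call_error")
  if (any(line_g != "alt/alt")) return("residual_heterozygous")
  "validated_homozygous"
}

site_classifications <- function() {
  c("assay_failure", "reference_divergence", "call_error",
    "residual_heterozygous", "validated_homozygous")
}

#' Classify every site of a genotyping result table
#'
#' @param calls data.frame of calls across sites: `site_id`, `sample_id`,
#'   `group`, `genotype`.
#' @return data.frame `site_id`, `classification`.
#' @export
classify_sites <- function(calls) {
  stopifnot(is.data.frame(calls), "site_id" %in% names(calls))
  ids <- unique(calls$site_id)
  data.frame(site_id = ids,
             classification = vapply(split(calls, calls$site_id)[as.character(ids)],
                                     classify_site, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tally site classifications
#'
#' @param classifications a [classify_sites()] result, or a character vector
#'   of classification labels.
#' @return Named integer vector over the five outcome categories; sums to
#'   the number of sites.
#' @export
summarize_validation <- function(classifications) {
  lab <- if (is.data.frame(classifications)) classifications$classification
         else classifications
  table(factor(lab, levels = site_classifications()))
}

#' Simulate a genotyping-assay fixture with known outcome counts
#'
#' Generates assay call records whose classification by [classify_site()]
#' reproduces a requested count per outcome category exactly -- the
#' round-trip property used to test the validation accounting. Sample-group
#' sizes default to the validation layout (31 reference-colony, 7 SNV-line,
#' 41 F1 samples). Within the constraints of each category the genotype
#' patterns are randomized (e.g. how many SNV-line samples are heterozygous
#' at a residually heterozygous site).
#'
#' @param category_counts named non-negative integer vector over (a subset
#'   of) the categories `assay_failure`, `reference_divergence`,
#'   `call_error`, `residual_heterozygous`, `validated_homozygous`.
#' @param n_reference,n_line,n_f1 sample-group sizes.
#' @param chrom_sizes chromosome lengths used to place the sites.
#' @param seed master seed.
#' @return List of class `genotyping_fixture`: `sites` (data.frame
#'   `site_id`, `chrom`, `pos`, `ref`, `alt`, `truth`) and `calls`
#'   (data.frame `site_id`, `sample_id`, `group`, `genotype`).
#' @examples
#' fx <- simulate_genotyping_fixture(c(validated_homozygous = 3,
#'                                     residual_heterozygous = 1), seed = 1)
#' summarize_validation(classify_sites(fx$calls))
#' @export
simulate_genotyping_fixture <- function(category_counts,
                                        n_reference = 31L, n_line = 7L,
                                        n_f1 = 41L,
                                        chrom_sizes = mouse_chrom_sizes(),
                                        seed = 1L) {
  stopifnot(!is.null(names(category_counts)),
            all(names(category_counts) %in% site_classifications()),
            all(category_counts >= 0),
            all(category_counts == floor(category_counts)))
  counts <- setNames(integer(5L), site_classifications())
  counts[names(category_counts)] <- as.integer(category_counts)
  n_sites <- sum(counts)
  truth <- rep(names(counts), counts)
  if (n_sites == 0L)
    return(structure(list(
      sites = data.frame(site_id = character(), chrom = character(),
                         pos = numeric(), ref = character(),
                         alt = character(), truth = character(),
                         stringsAsFactors = FALSE),
      calls = data.frame(site_id = character(), sample_id = character(),
                         group = character(), genotype = character(),
                         stringsAsFactors = FALSE)),
      class = "genotyping_fixture"))
  spec <- enu_spectrum()
  with_substream(seed, "genotyping_fixture", {
    truth <- sample(truth)  # shuffle category order across site ids
    chrom <- sample(names(chrom_sizes), n_sites, replace = TRUE,
                    prob = chrom_sizes / sum(chrom_sizes))
    cat_i <- sample.int(nrow(spec), n_sites, replace = TRUE, prob = spec$prob)
    sites <- data.frame(site_id = sprintf("S%03d", seq_len(n_sites)),
                        chrom = chrom,
                        pos = floor(runif(n_sites) * chrom_sizes[chrom]) + 1,
                        ref = spec$ref[cat_i], alt = spec$alt[cat_i],
                        truth = truth, stringsAsFactors = FALSE)
    groups <- rep(c("reference_colony", "snv_line", "f1"),
                  c(n_reference, n_line, n_f1))
    sample_id <- c(sprintf("REF%02d", seq_len(n_reference)),
                   sprintf("LINE%02d", seq_len(n_line)),
                   sprintf("F1_%02d", seq_len(n_f1)))
    calls <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
      g <- fixture_genotypes(truth[i], groups)
      data.frame(site_id = sites$site_id[i], sample_id = sample_id,
                 group = groups, genotype = g, stringsAsFactors = FALSE)
    }))
    rownames(calls) <- NULL
    structure(list(sites = sites, calls = calls),
              class = "genotyping_fixture")
  })
}

fixture_genotypes <- function(truth, groups) {
  n <- length(groups)
  ref_i <- groups == "reference_colony"
  line_i <- groups == "snv_line"
  f1_i <- groups == "f1"
  g <- character(n)
  g[ref_i] <- "ref/ref"
  g[line_i] <- "alt/alt"
  g[f1_i] <- "ref/alt"
  switch(truth,
    assay_failure = rep("no-call", n),
    reference_divergence = {
      k <- sample.int(sum(ref_i), 1L)
      g[which(ref_i)[seq_len(k)]] <-
        sample(c("ref/alt", "alt/alt"), k, replace = TRUE)
      g
    },
    call_error = {
      g[line_i] <- "ref/ref"
      g[f1_i] <- "ref/ref"
      g
    },
    residual_heterozygous = {
      nl <- sum(line_i)
      k <- sample.int(nl - 1L, 1L)  # heterozygous or ref/ref line samples
      g[which(line_i)[seq_len(k)]] <-
        sample(c("ref/alt", "ref/ref"), k, replace = TRUE,
               prob = c(0.8, 0.2))
      if (all(g[line_i] %in% c("ref/ref")))  # keep at least one alt allele
        g[which(line_i)[nl]] <- "alt/alt"
      g
    },
    validated_homozygous = {
      # sporadic single-sample dropouts leave the classification unchanged
      if (runif(1) < 0.3) g[sample.int(n, 1L)] <- "no-call"
      g
    },
    stop("unknown truth category: ", truth))
}

#' Export the validated mapping-panel map
#'
#' Writes the validated homozygous sites and the residually heterozygous
#' sites as separate BED (0-based half-open) and TSV tracks -- the map a
#' mapping cross against the SNV line would use.
#'
#' @param sites data.frame with `site_id`, `chrom`, `pos` (1-based) and a
#'   `status` column containing `validated_homozygous` /
#'   `residual_heterozygous`.
#' @param chrom_sizes named chromosome lengths; positions must not exceed
#'   them.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of paths written
#'   (`validated_bed`, `validated_tsv`, `heterozygous_bed`,
#'   `heterozygous_tsv`).
#' @export
export_panel_map <- function(sites, chrom_sizes = mouse_chrom_sizes(),
                             dir = ".", prefix = "panel_map") {
  check_chrom_sizes(chrom_sizes)
  stopifnot(is.data.frame(sites),
            all(c("site_id", "chrom", "pos", "status") %in% names(sites)))
  bad <- setdiff(unique(sites$chrom), names(chrom_sizes))
  if (length(bad)) stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  if (nrow(sites) && any(sites$pos > chrom_sizes[sites$chrom] | sites$pos < 1))
    stop("site position outside its chromosome")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tracks <- list(validated = sites[sites$status == "validated_homozygous", ,
                                   drop = FALSE],
                 heterozygous = sites[sites$status == "residual_heterozygous", ,
                                      drop = FALSE])
  paths <- character()
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    bed <- data.frame(chrom = tr$chrom, start = tr$pos - 1, end = tr$pos,
                      name = tr$site_id)
    pb <- file.path(dir, paste0(prefix, "_", nm, ".bed"))
    pt <- file.path(dir, paste0(prefix, "_", nm, ".tsv"))
    write.table(bed, pb, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    ms_write_tsv(tr[c("site_id", "chrom", "pos", "status")], pt,
                 meta = c(track = nm))
    paths[paste0(nm, "_bed")] <- pb
    paths[paste0(nm, "_tsv")] <- pt
  }
  invisible(paths)
}
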