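#' Write and read provenance-stamped TSV files
#'
#' All tabular outputs use tab-separated text with a short `#` comment
#' header carrying the package version and any key=value metadata supplied
#' (never a timestamp, so outputs are bit-reproducible given a seed).
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param meta optional named character vector recorded in the header.
#' @return `ms_write_tsv()` returns `path` invisibly; `ms_read_tsv()` the
#'   data.frame.
#' @export
ms_write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# minscreen %s", as.character(packageVersion("minscreen"))),
             con)
  if (length(meta))
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ms_write_tsv
#' @export
ms_read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Phenotype cohort TSV interchange
#'
#' Cohorts are exchanged as TSV with columns `kindred_id`, `animal_id`,
#' `carrier`, `tumor_count`, `lifespan_days`.
#'
#' @param animals animals data.frame (e.g. `$animals` of a
#'   [simulate_kindreds()] cohort, or a [simulate_control_cohort()] result).
#' @param path file path.
#' @param meta optional metadata for the provenance header.
#' @return `read_cohort_tsv()` returns the animals data.frame.
#' @export
write_cohort_tsv <- function(animals, path, meta = character()) {
  cols <- c("kindred_id", "animal_id", "carrier", "tumor_count",
            "lifespan_days")
  stopifnot(all(cols %in% names(animals)))
  ms_write_tsv(animals[cols], path, meta)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- ms_read_tsv(path)
  cols <- c("kindred_id", "animal_id", "carrier", "tumor_count",
            "lifespan_days")
  if (!all(cols %in% names(df)))
    stop("not a cohort TSV: expected columns ", paste(cols, collapse = ", "))
  df$carrier <- as.logical(df$carrier)
  df
}

#' Chromosome-sizes TSV interchange
#'
#' Two columns, `chrom` and `length`, tab separated.
#'
#' @param chrom_sizes named numeric vector of lengths.
#' @param path file path.
#' @return `read_chrom_sizes()` returns the named vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  check_chrom_sizes(chrom_sizes)
  write.table(data.frame(chrom = names(chrom_sizes),
                         length = as.numeric(chrom_sizes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                   comment.char = "#", stringsAsFactors = FALSE)
  check_chrom_sizes(setNames(as.numeric(df$length), df$chrom))
}

#' Variant-table interchange (VCF 4.2 and TSV dialects)
#'
#' `write_variants_vcf()` emits a minimal VCF 4.2 with one record per
#' (line, site) call: positions 1-based, `INFO` fields `LINE`, `DP`, `GQ`,
#' `ZYG`, `FLANK`, and per-line mean coverage in `##LINE=` header lines.
#' `write_variants_tsv()` writes the flat records table (with a
#' `mean_coverage` column) as TSV. `read_variants()` reads either dialect
#' back into a [line_variant_table()]; VCF records whose REF or ALT is not
#' a single nucleotide are skipped with a warning, and unknown INFO keys
#' are ignored.
#'
#' @param table a [line_variant_table()].
#' @param path file path.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return `read_variants()` returns a [line_variant_table()]; the writers
#'   return `path` invisibly.
#' @export
write_variants_vcf <- function(table, path) {
  stopifnot(inherits(table, "line_variant_table"))
  rec <- table$records
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=minscreen_%s", as.character(packageVersion("minscreen"))),
    sprintf("##LINE=<ID=%s,MEANCOV=%s>", table$lines$line_id,
            table$lines$mean_coverage),
    "##INFO=<ID=LINE,Number=1,Type=String,Description=\"Line carrying the call\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=GQ,Number=1,Type=Integer,Description=\"Phred genotyping quality\">",
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"hom or het\">",
    "##INFO=<ID=FLANK,Number=1,Type=String,Description=\"Flanking sequence\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(rec)) {
    o <- order(rec$chrom, rec$pos, rec$line_id)
    rec <- rec[o, , drop = FALSE]
    info <- sprintf("LINE=%s;DP=%d;GQ=%d;ZYG=%s%s", rec$line_id,
                    as.integer(rec$depth), as.integer(rec$genotype_quality),
                    rec$zygosity,
                    ifelse(nzchar(rec$flank_seq),
                           paste0(";FLANK=", rec$flank_seq), ""))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", rec$chrom,
                       as.integer(rec$pos), rec$ref, rec$alt, info), con)
  }
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
write_variants_tsv <- function(table, path) {
  stopifnot(inherits(table, "line_variant_table"))
  rec <- table$records
  cov <- setNames(table$lines$mean_coverage, table$lines$line_id)
  rec$mean_coverage <- as.numeric(cov[rec$line_id])
  ms_write_tsv(rec, path)
}

#' @rdname write_variants_vcf
#' @export
read_variants <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- ms_read_tsv(path)
    need <- c("line_id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(df)))
      stop("not a variant TSV: expected columns ", paste(need, collapse = ", "))
    lines <- unique(df[intersect(c("line_id", "mean_coverage"), names(df))])
    if (is.null(lines$mean_coverage)) lines$mean_coverage <- NA_real_
    df$mean_coverage <- NULL
    return(line_variant_table(df, lines = lines))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    tab <- empty_variant_records()
  } else {
    snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
      fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
    if (any(!snv))
      warning(sum(!snv), " non-SNV record(s) skipped: line(s) ",
              paste(which(!snv), collapse = ", "))
    fix <- fix[snv, , drop = FALSE]
    info_get <- function(key) vcfR::extract.info(vcf, element = key)[snv]
    tab <- data.frame(
      line_id = info_get("LINE"), chrom = fix$CHROM,
      pos = as.numeric(fix$POS), ref = fix$REF, alt = fix$ALT,
      depth = as.integer(info_get("DP")),
      genotype_quality = as.integer(info_get("GQ")),
      zygosity = info_get("ZYG"), flank_seq = info_get("FLANK"),
      stringsAsFactors = FALSE)
    tab$flank_seq[is.na(tab$flank_seq)] <- ""
  }
  meta <- vcf@meta
  line_meta <- regmatches(meta, regexec("^##LINE=<ID=([^,>]+),MEANCOV=([^>]+)>", meta))
  line_meta <- line_meta[lengths(line_meta) == 3L]
  lines <- if (length(line_meta))
    data.frame(line_id = vapply(line_meta, `[`, character(1), 2L),
               mean_coverage = as.numeric(vapply(line_meta, `[`, character(1), 3L)),
               stringsAsFactors = FALSE)
  else data.frame(line_id = unique(tab$line_id),
                  mean_coverage = rep(NA_real_, length(unique(tab$line_id))),
                  stringsAsFactors = FALSE)
  line_variant_table(tab, lines = lines)
}

#' Run configuration
#'
#' A run configuration collects the colony, mixture, design and panel
#' parameters plus a master seed, with defaults matching the values used
#' throughout (baseline mean 99.8, shape 9.8, alpha 0.05, FDR q 0.05,
#' power target 0.9, discovery probability 0.95, depth filter >= 3 and
#' <= 2.5x coverage, genotyping quality 99, gap threshold 30 Mbp).
#' `read_run_config()` merges a YAML file over the defaults and validates
#' every field's range.
#'
#' @param path YAML file path.
#' @return A validated nested list of class `run_config`.
#' @examples
#' cfg <- default_run_config()
#' cfg$design$fdr_q
#' @export
default_run_config <- function() {
  validate_run_config(list(
    seed = 1L,
    colony = list(mean_tumor_count = 99.8, nb_shape = 9.8,
                  survival_intercept = log(600), survival_slope = 0.35,
                  survival_noise_sd = 0.2),
    mixture = list(weight_none = 0.39, weight_suppressor = 0.41,
                   weight_enhancer = 0.20, suppressor_median = 0.6,
                   enhancer_median = 1.8, effect_log_sd = 0.2,
                   segregation_prob = 0.5),
    design = list(alpha = 0.05, fdr_q = 0.05, power_target = 0.9,
                  discovery_prob = 0.95),
    panel = list(min_depth = 3, max_coverage_mult = 2.5,
                 genotyping_quality = 99, min_gap = 3e7,
                 rate_per_bp = 1.1e-6, residual_het_rate = 0.14)))
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_run_config(), user)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid config: ", msg)
  chk(is.numeric(cfg$seed) && cfg$seed == floor(cfg$seed), "seed must be an integer")
  chk(cfg$colony$mean_tumor_count > 0, "mean_tumor_count must be positive")
  chk(cfg$colony$nb_shape > 0, "nb_shape must be positive")
  w <- with(cfg$mixture, c(weight_none, weight_suppressor, weight_enhancer))
  chk(all(w >= 0) && abs(sum(w) - 1) < 1e-9, "mixture weights must sum to 1")
  chk(cfg$mixture$suppressor_median > 0 && cfg$mixture$suppressor_median < 1,
      "suppressor_median must be in (0, 1)")
  chk(cfg$mixture$enhancer_median > 1, "enhancer_median must exceed 1")
  chk(cfg$mixture$segregation_prob > 0 && cfg$mixture$segregation_prob <= 1,
      "segregation_prob must be in (0, 1]")
  for (f in c("alpha", "fdr_q", "power_target", "discovery_prob"))
    chk(cfg$design[[f]] > 0 && cfg$design[[f]] < 1,
        paste(f, "must be in (0, 1)"))
  chk(cfg$panel$min_depth >= 0, "min_depth must be non-negative")
  chk(cfg$panel$max_coverage_mult > 0, "max_coverage_mult must be positive")
  chk(cfg$panel$min_gap > 0, "min_gap must be positive")
  chk(cfg$panel$rate_per_bp >= 0, "rate_per_bp must be non-negative")
  chk(cfg$panel$residual_het_rate >= 0 && cfg$panel$residual_het_rate <= 1,
      "residual_het_rate must be in [0, 1]")
  structure(cfg, class = c("run_config", "list"))
}

as_colony <- function(cfg) {
  colony_model(cfg$colony$mean_tumor_count, cfg$colony$nb_shape,
               c(cfg$colony$survival_intercept, cfg$colony$survival_slope,
                 cfg$colony$survival_noise_sd))
}

as_classes <- function(cfg) {
  m <- cfg$mixture
  modifier_class_params(
    weights = c(m$weight_none, m$weight_suppressor, m$weight_enhancer),
    suppressor = effect_lognormal(m$suppressor_median, m$effect_log_sd,
                                  "suppressor"),
    enhancer = effect_lognormal(m$enhancer_median, m$effect_log_sd,
                                "enhancer"),
    segregation_prob = m$segregation_prob)
}

#' Build model objects from a run configuration
#'
#' @param cfg a `run_config`.
#' @return `config_colony()` a [colony_model()]; `config_classes()` a
#'   [modifier_class_params()].
#' @export
config_colony <- function(cfg) as_colony(cfg)

#' @rdname config_colony
#' @export
config_classes <- function(cfg) as_classes(cfg)
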