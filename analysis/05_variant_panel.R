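#!/usr/bin/env Rscript
# Isogenic mapping-panel construction: simulate six resequenced SNV lines
# at the observed mutation rate and spectrum, apply the depth filters,
# partition sites by line specificity, summarize spectrum and rate, rank
# genotyping candidates for the phenotypically neutral focal line, select
# the three-markers-per-autosome panel, and report marker spacing and
# marker-free gaps. Writes VCF/TSV/BED artifacts under results/.

suppressPackageStartupMessages(library(minscreen))

seed <- 20140417
dir.create("results", showWarnings = FALSE)
cfg <- default_run_config()
sizes <- mouse_chrom_sizes()

tbl <- simulate_variant_lines(sizes, rate_per_bp = cfg$panel$rate_per_bp,
                              residual_het_rate = cfg$panel$residual_het_rate,
                              seed = seed)
write_variants_vcf(tbl, "results/snv_lines.vcf")
message("Simulated calls: ", nrow(tbl$records), " across 6 lines (",
        "rate ", cfg$panel$rate_per_bp, "/bp)")

kept <- filter_calls(tbl, min_depth = cfg$panel$min_depth,
                     max_coverage_mult = cfg$panel$max_coverage_mult)
message("After depth filters (>= ", cfg$panel$min_depth, ", <= ",
        cfg$panel$max_coverage_mult, "x coverage): ", nrow(kept$records),
        " calls")

part <- partition_line_specific(kept, related_pair = c("B6.SNVg", "B6.SNVh"))
summ <- summarize_partition(part, chrom_order = names(sizes))
ms_write_tsv(summ, "results/line_specific_summary.tsv")
message("Line-specific sites: ", attr(summ, "line_specific_total"),
        "; pair-shared: ", nrow(part$shared))

sp <- mutation_spectrum(part)
ms_write_tsv(sp, "results/mutation_spectrum.tsv")
message(sprintf("AT<->TA transversion share: %.1f%% (spontaneous %.1f%%)",
                at_ta_percent(sp), at_ta_percent(spontaneous_at_ta_counts())))
message("Realized per-bp rate: ",
        per_bp_rate(nrow(kept$records), 6 * sum(sizes)))

cand <- marker_candidates(kept, part, line = "B6.SNVg")
ranked <- rank_candidates(cand, quality_required = cfg$panel$genotyping_quality)
panel <- select_panel(ranked, sizes)
ms_write_tsv(panel$panel[c("chrom", "pos", "ref", "alt", "specificity",
                           "bin", "relaxed")], "results/marker_panel.tsv")
write.table(data.frame(panel$panel$chrom, panel$panel$pos - 1,
                       panel$panel$pos,
                       paste0(panel$panel$ref, ">", panel$panel$alt)),
            "results/marker_panel.bed", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
message("Panel: ", nrow(panel$panel), " markers (",
        sum(panel$panel$relaxed), " via relaxed criteria); ",
        nrow(panel$unfilled), " unfilled bins")

g_sites <- part$exclusive[part$exclusive$line_id == "B6.SNVg",
                          c("chrom", "pos")]
g_sites <- rbind(g_sites, part$shared[c("chrom", "pos")])
d <- intermarker_distances(g_sites)
message(sprintf("Inter-SNV distances in the focal line: median %s bp, IQR %s-%s",
                format(d[["50%"]], big.mark = ","),
                format(d[["25%"]], big.mark = ","),
                format(d[["75%"]], big.mark = ",")))

gaps <- find_gaps(g_sites, sizes, min_gap = cfg$panel$min_gap)
write.table(gaps[c("chrom", "start", "end")], "results/marker_gaps.bed",
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
message("Marker-free gaps over ", cfg$panel$min_gap / 1e6, " Mbp: ",
        nrow(gaps))
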