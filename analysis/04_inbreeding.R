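#!/usr/bin/env Rscript
# Residual heterozygosity under repeated brother-sister mating: the series
# H_t = H_{t-1}/2 + H_{t-2}/4 that sets how many induced variants still
# segregate in an inbred SNV line after t generations.

suppressPackageStartupMessages(library(minscreen))

dir.create("results", showWarnings = FALSE)
series <- heterozygosity_series(15)
ms_write_tsv(series, "results/heterozygosity_series.tsv")

message(sprintf("Residual heterozygosity: F10 %.1f%%, F11 %.1f%%",
                100 * series$heterozygosity[series$generation == 10],
                100 * series$heterozygosity[series$generation == 11]))
message("Generations to reach 15%: ", generations_until(0.15))
message(sprintf("Asymptotic per-generation retention: %.4f (limit (1+sqrt(5))/4 = %.4f)",
                series$heterozygosity[16] / series$heterozygosity[15],
                (1 + sqrt(5)) / 4))
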