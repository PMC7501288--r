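#!/usr/bin/env Rscript

# Stage 3: harmonize the two absolute layers.
#
# Filters: unique hits >= 1, log10(+1) transform, minimum expression
# thresholds (10^5 transcripts, 10^8 proteins), then matching of ORFs that
# are singleton ORF-groups in both layers and replicate averaging per
# time point.

suppressPackageStartupMessages(library(absomics))

data <- read_dataset("results/data")
mt_abs <- read_table("results/mt_absolute.tsv", table_schema("mt_absolute"))
mp_abs <- read_table("results/mp_absolute.tsv", table_schema("mp_absolute"))
# re-attach unique-hit support from the raw observation tables
mt_abs <- merge(mt_abs, data$mt_reads[, c("orfg_id", "sample_id",
                                          "unique_hits")],
                by = c("orfg_id", "sample_id"))
mp_abs <- merge(mp_abs, data$mp_lfq[, c("orfg_id", "sample_id",
                                        "unique_peptides")],
                by = c("orfg_id", "sample_id"))

res <- integrate_layers(mt_abs, mp_abs, data$orf_catalog, data$samples)

write_table(res$paired, "results/paired_expression.tsv")
write_table(res$filter_report, "results/filter_report.tsv")

cat("filter report:\n")
print(res$filter_report)
cat(sprintf("%d ORF x time pairs across %d MAGs retained\n",
            nrow(res$paired), length(unique(res$paired$mag_id))))
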