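#!/usr/bin/env Rscript

# Stage 2: absolute quantification of both omic layers.
#
# MT: spike-in internal standard -> transcriptome size -> RPKM inversion
# -> transcript molecules per 60 ml sample (aliquot factor 10).
# MP: Bradford total mass -> detected-mass correction from the peak table
# -> LFQ fractions -> protein copy numbers per sample.

suppressPackageStartupMessages(library(absomics))

data <- read_dataset("results/data")

mt <- quantify_mt(data$mt_reads, data$spikein, data$orf_catalog,
                  aliquot_factor = 10)
mp <- quantify_mp(data$mp_lfq, data$peaks, data$bradford, data$orf_catalog)

write_table(mt$mt_absolute[, c("orfg_id", "sample_id", "rpkm",
                               "molecules_sample")],
            "results/mt_absolute.tsv")
write_table(mt$sample_summary, "results/mt_sample_summary.tsv")
write_table(mp$mp_absolute[, c("orfg_id", "sample_id", "copy_number")],
            "results/mp_absolute.tsv")
write_table(mp$sample_summary, "results/mp_sample_summary.tsv")

cat(sprintf("transcripts per sample: mean %.3g (range %.3g - %.3g)\n",
            mean(mt$sample_summary$total_molecules),
            min(mt$sample_summary$total_molecules),
            max(mt$sample_summary$total_molecules)))
cat(sprintf("proteins per sample:    mean %.3g (range %.3g - %.3g)\n",
            mean(mp$sample_summary$total_copies),
            min(mp$sample_summary$total_copies),
            max(mp$sample_summary$total_copies)))
cat(sprintf("detected/total protein mass: %.2f - %.2f\n",
            min(mp$sample_summary$detected_mass_g /
                  mp$sample_summary$total_mass_g),
            max(mp$sample_summary$detected_mass_g /
                  mp$sample_summary$total_mass_g)))
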