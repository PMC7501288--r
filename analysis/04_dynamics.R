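#!/usr/bin/env Rscript

# Stage 4: protein/RNA dynamics.
#
# Protein-to-RNA ratio distributions per MAG at 18 h (around exponential
# growth), gene-wise RNA-protein Pearson correlations over time,
# per-time-point monomial fits protein = a * RNA^k, cubic k(t)
# trajectories per MAG, and cross-layer Kendall rank preservation of KO
# functional categories (MG/MT/MP).

suppressPackageStartupMessages(library(absomics))

data <- read_dataset("results/data")
paired <- read_table("results/paired_expression.tsv", table_schema("paired"))
mt_abs <- read_table("results/mt_absolute.tsv", table_schema("mt_absolute"))
mp_abs <- read_table("results/mp_absolute.tsv", table_schema("mp_absolute"))

domains <- with(unique(data$orf_catalog[, c("mag_id", "domain_tag")]),
                setNames(domain_tag, mag_id))

ratios <- protein_rna_ratios(paired, time_h = 18, domains = domains)
write_table(ratios$summary, "results/ratios.tsv")
cat("protein-to-RNA ratio medians at 18 h:\n")
print(ratios$summary[, c("mag_id", "n_genes", "median")])

pcc <- genewise_pcc(paired)
write_table(pcc$records, "results/pcc.tsv")
cat(sprintf("gene-wise RNA-protein PCC: median %.2f over %d ORFs\n",
            pcc$median_pcc, sum(!is.na(pcc$records$pcc))))

fits <- fit_monomial_all(paired, min_points = 30)
write_table(fits, "results/monomial_fits.tsv")

ktraj <- do.call(rbind, lapply(split(fits, fits$mag_id), function(d) {
  if (nrow(d) < 4) return(NULL)
  tr <- fit_k_trajectory(d$time_h, d$k, mag_id = d$mag_id[1])
  data.frame(mag_id = tr$mag_id, t(tr$coefficients),
             time_min = tr$time_range[1], time_max = tr$time_range[2])
}))
write_table(ktraj, "results/k_trajectories.tsv")
cat(sprintf("monomial fits: %d MAG x time cells; k range %.2f - %.2f\n",
            nrow(fits), min(fits$k), max(fits$k)))

mg <- ko_category_abundance(data$orf_catalog)
mt_ko <- ko_category_abundance(data$orf_catalog, mt_abs,
                               "molecules_sample", "orfg_id_mt")
mp_ko <- ko_category_abundance(data$orf_catalog, mp_abs,
                               "copy_number", "orfg_id_mp")
shared <- Reduce(intersect, list(names(mg), names(mt_ko), names(mp_ko)))
rank_agreement <- rbind(
  kendall_rank_preservation(mg[shared], mt_ko[shared], c("MG", "MT")),
  kendall_rank_preservation(mt_ko[shared], mp_ko[shared], c("MT", "MP")),
  kendall_rank_preservation(mg[shared], mp_ko[shared], c("MG", "MP")))
write_table(rank_agreement, "results/rank_agreement.tsv")
cat("KO category rank preservation (Kendall tau-b):\n")
print(rank_agreement)
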