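#!/usr/bin/env Rscript

# Stage 1: generate the ground-truthed synthetic community.
#
# Seven populations (six bacterial, one archaeal methanogen), 150 ORFs
# each, seven time points (13-43 h) in triplicate. Transcript copies are
# log-normal per ORF; protein copies follow protein = a * RNA^k with
# population- and time-specific linearity k. The dataset (read counts with
# spike-in, LFQ intensities with peak table and Bradford masses) is
# written under results/data/ together with the ground truth.

suppressPackageStartupMessages(library(absomics))

config <- simulation_config(mags = default_community(n_orfs = 150), seed = 20260921)
community <- generate_community(config)
mt_obs <- simulate_mt_observation(community)
mp_obs <- simulate_mp_observation(community)

write_dataset(community, mt_obs, mp_obs, "results/data")

n_groups_mt <- length(unique(community$catalog$orfg_id_mt))
cat(sprintf("simulated %d ORFs in %d MAGs; %d MT ORF-groups; %d samples\n",
            nrow(community$catalog), config$n_mags, n_groups_mt,
            nrow(community$samples)))
cat(sprintf("true transcriptome size per sample: %.3g - %.3g nt\n",
            min(community$truth$true_transcriptome_nt),
            max(community$truth$true_transcriptome_nt)))
cat("wrote results/data/\n")
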