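test_that("config and MAG spec invariants are enforced", {
  expect_error(mag_spec("M", n_orfs = 1), "n_orfs")
  expect_error(mag_spec("M", true_k_per_timepoint = c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(mag_spec("M", median_ratio_target = 0), "> 0")
  expect_error(simulation_config(detect_fraction_mp = 0), "detect_fraction_mp")
  expect_error(simulation_config(identified_peak_fraction = 1.4),
               "identified_peak_fraction")
  expect_error(simulation_config(mt_noise_sd = -1), "noise")
  expect_error(simulation_config(aliquot_factor_mt = 0.5), "aliquot_factor")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 123)
  c1 <- generate_community(cfg)
  c2 <- generate_community(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$catalog, c2$catalog)
  o1 <- simulate_mt_observation(c1)
  o2 <- simulate_mt_observation(c2)
  expect_identical(o1, o2)
  p1 <- simulate_mp_observation(c1)
  p2 <- simulate_mp_observation(c2)
  expect_identical(p1, p2)
  # written files are byte-identical too
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_dataset(c1, o1, p1, d1)
  write_dataset(c2, o2, p2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  md5 <- function(d, f) unname(tools::md5sum(file.path(d, f)))
  expect_identical(md5(d1, f1), md5(d2, f1))
})

test_that("noiseless coupling gives protein = a x RNA^k exactly", {
  cfg <- simulation_config(
    mags = list(mag_spec("M1", n_orfs = 30,
                         true_k_per_timepoint = rep(1, 2),
                         true_a_log10 = log10(1000))),
    n_timepoints = 2, n_replicates = 2,
    mt_noise_sd = 0, mp_noise_sd = 0, emit_sequences = FALSE, seed = 5)
  comm <- generate_community(cfg)
  expect_equal(comm$truth$true_protein_molecules,
               1000 * comm$truth$true_rna_molecules, tolerance = 1e-12)
})

test_that("median protein-to-RNA ratio tracks the target regime", {
  cfg <- simulation_config(
    mags = list(mag_spec("A1", "archaeal", n_orfs = 500,
                         true_k_per_timepoint = 1,
                         median_ratio_target = 1e4)),
    n_timepoints = 1, n_replicates = 1,
    mt_noise_sd = 0, mp_noise_sd = 0.3, emit_sequences = FALSE, seed = 17)
  comm <- generate_community(cfg)
  med <- median(comm$truth$true_protein_molecules[, 1] /
                  comm$truth$true_rna_molecules[, 1])
  expect_gt(med, 10^3.5)
  expect_lt(med, 10^4.5)
})

test_that("transcriptome nucleotide totals are conserved", {
  comm <- generate_community(tiny_config(seed = 29))
  expect_equal(
    colSums(comm$truth$true_rna_molecules * comm$catalog$length_nt),
    comm$truth$true_transcriptome_nt)
})

test_that("spike-in reads match the closed-form multinomial mean", {
  cfg <- tiny_config(seed = 41, seq_depth = 1e6)
  comm <- generate_community(cfg)
  nt_aliquot <- comm$truth$true_transcriptome_nt / cfg$aliquot_factor_mt
  spike_nt <- cfg$spike_molecules * cfg$spike_length_nt
  expected_IR <- cfg$seq_depth * spike_nt / (spike_nt + nt_aliquot)
  # exact under expectation-mode allocation
  cfg0 <- tiny_config(seed = 41, seq_depth = 1e6, count_noise = FALSE)
  comm0 <- generate_community(cfg0)
  obs0 <- simulate_mt_observation(comm0)
  expect_equal(obs0$spikein$I_R,
               unname(cfg$seq_depth * spike_nt /
                        (spike_nt + comm0$truth$true_transcriptome_nt /
                           cfg$aliquot_factor_mt)),
               tolerance = 1e-12)
  # multinomial draws scatter around the mean (few-percent tolerance)
  obs <- simulate_mt_observation(comm)
  expect_equal(obs$spikein$I_R, unname(expected_IR), tolerance = 0.05)
  # single ORF: read share equals nucleotide-mass share
  cfg1 <- simulation_config(
    mags = list(mag_spec("M1", n_orfs = 2,
                         true_k_per_timepoint = rep(0.5, 1))),
    n_timepoints = 1, n_replicates = 1, seq_depth = 1e5,
    mt_noise_sd = 0, mp_noise_sd = 0, count_noise = FALSE,
    dup_orf_fraction = 0, emit_sequences = FALSE, seed = 3)
  comm1 <- generate_community(cfg1)
  obs1 <- simulate_mt_observation(comm1)
  nt1 <- comm1$truth$true_rna_molecules[, 1] * comm1$catalog$length_nt /
    cfg1$aliquot_factor_mt
  total_mass <- sum(nt1) + cfg1$spike_molecules * cfg1$spike_length_nt
  expect_equal(sort(obs1$mt_reads$reads),
               sort(unname(1e5 * nt1 / total_mass)), tolerance = 1e-12)
  cfg_zero <- cfg1
  cfg_zero$seq_depth <- 0
  expect_error(simulate_mt_observation(comm1, cfg_zero), "seq_depth")
})

test_that("halving protein copies halves the Bradford mass", {
  cfg <- tiny_config(seed = 59, emit_sequences = FALSE)
  comm <- generate_community(cfg)
  mp1 <- simulate_mp_observation(comm)
  comm2 <- comm
  comm2$truth$true_protein_molecules <- comm$truth$true_protein_molecules / 2
  mp2 <- simulate_mp_observation(comm2)
  expect_equal(mp2$bradford$conc_g_per_l, mp1$bradford$conc_g_per_l / 2)
})

test_that("peak tables encode the identified mass share exactly", {
  cfg <- tiny_config(seed = 67, detect_fraction_mp = 0.5,
                     identified_peak_fraction = 0.8,
                     emit_sequences = FALSE)
  comm <- generate_community(cfg)
  obs <- simulate_mp_observation(comm)
  sid <- obs$bradford$sample_id[1]
  pk <- obs$peaks[obs$peaks$sample_id == sid, ]
  lfq <- obs$mp_lfq[obs$mp_lfq$sample_id == sid, ]
  orfg_mass <- tapply(comm$catalog$mw_g_per_mol *
                        comm$truth$true_protein_molecules[, sid],
                      comm$catalog$orfg_id_mp, sum)
  det_share <- sum(orfg_mass[lfq$orfg_id[lfq$lfq > 0]]) / sum(orfg_mass)
  w <- pk$base_peak_intensity * pk$mass_da
  expect_equal(sum(w[pk$identified == 1]) / sum(w),
               0.8 * det_share, tolerance = 1e-12)
})

test_that("recovered copy numbers degrade gracefully with LFQ noise", {
  run_mp <- function(sd) {
    cfg <- simulation_config(
      mags = list(mag_spec("M1", n_orfs = 500,
                           true_k_per_timepoint = rep(0.7, 1))),
      n_timepoints = 1, n_replicates = 1, lfq_noise_sd = sd,
      mt_noise_sd = 0, mp_noise_sd = 0, detect_fraction_mp = 1,
      identified_peak_fraction = 1, count_noise = FALSE,
      dup_orf_fraction = 0, emit_sequences = FALSE, seed = 3)
    comm <- generate_community(cfg)
    obs <- simulate_mp_observation(comm)
    res <- quantify_mp(obs$mp_lfq, obs$peaks, obs$bradford, comm$catalog)
    truth <- comm$truth$true_protein_molecules[, 1]
    rec <- stats::setNames(res$mp_absolute$copy_number,
                           res$mp_absolute$orfg_id)[names(truth)]
    median(abs(rec - truth) / truth)
  }
  # multiplicative log10 noise of sd s yields a median relative deviation
  # of roughly |10^eps / E 10^eps - 1|; ~16% at sd 0.1, ~31% at sd 0.2
  expect_lt(run_mp(0.15), 0.25)
  expect_lt(run_mp(0.2), 0.35)
  expect_gt(run_mp(0.2), run_mp(0.1))
})

test_that("datasets round-trip through disk and FASTA lengths agree", {
  cfg <- tiny_config(n_orfs = 15, seed = 83)
  comm <- generate_community(cfg)
  mt_obs <- simulate_mt_observation(comm)
  mp_obs <- simulate_mp_observation(comm)
  dir <- file.path(tempdir(), "roundtrip")
  write_dataset(comm, mt_obs, mp_obs, dir)
  back <- read_dataset(dir)
  expect_equal(back$mt_reads$reads, mt_obs$mt_reads$reads)
  expect_equal(back$spikein$I_R, mt_obs$spikein$I_R)
  expect_equal(back$mp_lfq$lfq, mp_obs$mp_lfq$lfq, tolerance = 1e-12)
  expect_equal(back$bradford$conc_g_per_l, mp_obs$bradford$conc_g_per_l,
               tolerance = 1e-12)
  expect_equal(back$samples, comm$samples)
  # sequence-derived lengths equal the catalog lengths
  expect_equal(unname(nchar(back$nt_sequences[comm$catalog$orf_id])),
               comm$catalog$length_nt)
  expect_equal(unname(nchar(back$aa_sequences[comm$catalog$orf_id])),
               comm$catalog$length_nt / 3 - 1)
  expect_error(write_dataset(comm, mt_obs, mp_obs, ""), "empty")
})
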