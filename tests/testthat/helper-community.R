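# Small community configurations shared across test files.

tiny_config <- function(n_orfs = 40, seed = 101, seq_depth = 5e5, ...) {
  simulation_config(
    mags = list(
      BACT1 = mag_spec("BACT1", "bacterial", n_orfs = n_orfs,
                       true_k_per_timepoint = c(0.8, 0.7, 0.6),
                       median_ratio_target = 1e3),
      ARCH1 = mag_spec("ARCH1", "archaeal", n_orfs = n_orfs,
                       true_k_per_timepoint = c(0.7, 0.65, 0.6),
                       median_ratio_target = 1e4)
    ),
    n_timepoints = 3, n_replicates = 2, seq_depth = seq_depth,
    seed = seed, ...
  )
}

noiseless_config <- function(n_orfs = 40, seed = 101, ...) {
  tiny_config(n_orfs = n_orfs, seed = seed,
              mt_noise_sd = 0, mp_noise_sd = 0, lfq_noise_sd = 0,
              detect_fraction_mp = 1, identified_peak_fraction = 1,
              count_noise = FALSE, ...)
}

# Wide orfg x sample matrix from a long absolute table.
wide_values <- function(tab, value_col) {
  w <- stats::xtabs(stats::as.formula(paste(value_col, "~ orfg_id + sample_id")),
                    data = tab)
  matrix(as.numeric(w), nrow = nrow(w), dimnames = dimnames(w))
}
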