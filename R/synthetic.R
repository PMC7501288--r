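#' Specification of one simulated MAG (population)
#'
#' Encodes the population-level parameters the simulator needs: how many
#' ORFs the genome carries, the log-normal transcript abundance
#' distribution, the per-time-point linearity k of the protein-RNA
#' coupling, and the target median protein-to-RNA ratio (around 10^3 for
#' bacteria, 10^4 for archaea).
#'
#' @param mag_id Population label.
#' @param domain_tag `"bacterial"` or `"archaeal"`.
#' @param n_orfs Number of ORFs (>= 2).
#' @param true_k_per_timepoint Linearity values in `[0, 1]`, one per time
#'   point (recycled/validated at generation time).
#' @param true_a_log10 Optional log10 of the monomial scale constant a. If
#'   `NULL` (default), a is derived per time point from
#'   `median_ratio_target` so the median protein/RNA ratio hits the target
#'   whatever k is.
#' @param rna_abundance_log10_mean,rna_abundance_log10_sd Log10 mean / sd
#'   of per-ORF transcript copies per sample.
#' @param median_ratio_target Target median protein molecules per RNA
#'   molecule.
#' @return A `mag_spec` list.
#' @export
mag_spec <- function(mag_id, domain_tag = c("bacterial", "archaeal"),
                     n_orfs = 500,
                     true_k_per_timepoint = NULL,
                     true_a_log10 = NULL,
                     rna_abundance_log10_mean = 8,
                     rna_abundance_log10_sd = 0.8,
                     median_ratio_target = 1e3) {
  domain_tag <- match.arg(domain_tag)
  if (n_orfs < 2) stop("n_orfs must be >= 2", call. = FALSE)
  if (!is.null(true_k_per_timepoint) &&
      (any(true_k_per_timepoint < 0) || any(true_k_per_timepoint > 1))) {
    stop("k must lie in [0, 1] at every time point", call. = FALSE)
  }
  if (median_ratio_target <= 0) {
    stop("median_ratio_target must be > 0", call. = FALSE)
  }
  structure(list(
    mag_id = mag_id, domain_tag = domain_tag, n_orfs = n_orfs,
    true_k_per_timepoint = true_k_per_timepoint,
    true_a_log10 = true_a_log10,
    rna_abundance_log10_mean = rna_abundance_log10_mean,
    rna_abundance_log10_sd = rna_abundance_log10_sd,
    median_ratio_target = median_ratio_target
  ), class = "mag_spec")
}

#' Default simulated community
#'
#' Seven populations modeled on a minimal cellulose-degrading consortium:
#' six bacteria (median protein-to-RNA ratio target 10^3) and one
#' methanogenic archaeon (target 10^4), each with its own k(t) trajectory
#' over seven time points — fast decliners, slow decliners, and flat/rising
#' populations.
#'
#' @param n_orfs ORFs per MAG (default 500).
#' @return List of [mag_spec()] objects.
#' @export
default_community <- function(n_orfs = 500) {
  k <- list(
    RCLO1 = c(0.78, 0.74, 0.70, 0.66, 0.62, 0.58, 0.55),
    CLOS1 = c(0.80, 0.75, 0.70, 0.65, 0.60, 0.56, 0.53),
    TISS1 = c(0.85, 0.68, 0.50, 0.36, 0.29, 0.26, 0.25),
    TEPI1 = c(0.55, 0.56, 0.57, 0.58, 0.58, 0.59, 0.60),
    TEPI2 = c(0.35, 0.38, 0.42, 0.46, 0.50, 0.53, 0.55),
    COPR1 = c(0.80, 0.62, 0.45, 0.34, 0.28, 0.25, 0.24),
    METH1 = c(0.75, 0.71, 0.67, 0.63, 0.60, 0.57, 0.55)
  )
  mags <- lapply(names(k), function(id) {
    mag_spec(id,
             domain_tag = if (id == "METH1") "archaeal" else "bacterial",
             n_orfs = n_orfs,
             true_k_per_timepoint = k[[id]],
             median_ratio_target = if (id == "METH1") 1e4 else 1e3)
  })
  stats::setNames(mags, names(k))
}

#' Simulation configuration
#'
#' Study-geometry defaults mirror the experimental design the pipeline is
#' built for: 60 ml samples over 7 time points (13-43 h, 5 h steps) in
#' triplicate, the transcript internal standard added to a 6 ml aliquot
#' (aliquot factor 10), and Bradford protein mass referenced to the full
#' 60 ml.
#'
#' @param mags List of [mag_spec()] objects (default [default_community()]).
#' @param n_timepoints Number of time points (default 7; times are 13 h +
#'   5 h steps).
#' @param n_replicates Replicates per time point (default 3: A, B, C).
#' @param seq_depth Transcriptome reads per sample (default 2e6).
#' @param spike_molecules Internal-standard molecules added per aliquot
#'   (I_M, default 1e10).
#' @param spike_length_nt Internal-standard length (I_Nt, default 994 nt).
#' @param spike_mass_fraction Optional target fraction of read mass drawn
#'   by the spike-in; when given, `spike_molecules` is derived from it.
#' @param lfq_noise_sd Multiplicative log10 noise on LFQ intensities.
#' @param mt_noise_sd Log10 observation noise on per-sample transcript
#'   copies.
#' @param mp_noise_sd Log10 noise on the protein-RNA coupling.
#' @param detect_fraction_mp Probability an expressed protein group is
#'   detected by MS.
#' @param identified_peak_fraction Fraction of the detected-mass peak
#'   signal that carries a peptide identification.
#' @param aliquot_factor_mt Sample/aliquot volume ratio for MT (default 10).
#' @param sample_volume_l Sample volume in liters (default 0.060).
#' @param dup_orf_fraction Fraction of ORFs that are exact duplicates of
#'   another ORF (creating multi-member ORF-groups; default 0.05).
#' @param count_noise If TRUE (default) reads are sampled multinomially;
#'   FALSE emits expected fractional read counts (noise-free allocation).
#' @param emit_sequences If TRUE (default) generate nucleotide and
#'   amino-acid sequences and derive molecular weights from them; FALSE
#'   uses a mean-residue-mass approximation (faster for large sweeps).
#' @param seed Integer seed; every simulation stage derives its stream
#'   from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(mags = default_community(),
                              n_timepoints = 7,
                              n_replicates = 3,
                              seq_depth = 2e6,
                              spike_molecules = 1e10,
                              spike_length_nt = 994,
                              spike_mass_fraction = NULL,
                              lfq_noise_sd = 0.2,
                              mt_noise_sd = 0.2,
                              mp_noise_sd = 0.3,
                              detect_fraction_mp = 0.6,
                              identified_peak_fraction = 0.7,
                              aliquot_factor_mt = 10,
                              sample_volume_l = 0.060,
                              dup_orf_fraction = 0.05,
                              count_noise = TRUE,
                              emit_sequences = TRUE,
                              seed = 1) {
  stopifnot(length(mags) >= 1, n_timepoints >= 1, n_replicates >= 1,
            seq_depth >= 0, spike_molecules > 0, spike_length_nt > 0)
  if (any(c(lfq_noise_sd, mt_noise_sd, mp_noise_sd) < 0)) {
    stop("noise sds must be >= 0", call. = FALSE)
  }
  if (detect_fraction_mp <= 0 || detect_fraction_mp > 1) {
    stop("detect_fraction_mp must be in (0, 1]", call. = FALSE)
  }
  if (identified_peak_fraction <= 0 || identified_peak_fraction > 1) {
    stop("identified_peak_fraction must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(spike_mass_fraction) &&
      (spike_mass_fraction <= 0 || spike_mass_fraction >= 1)) {
    stop("spike_mass_fraction must be in (0, 1)", call. = FALSE)
  }
  if (aliquot_factor_mt < 1) stop("aliquot_factor_mt must be >= 1", call. = FALSE)
  if (dup_orf_fraction < 0 || dup_orf_fraction >= 1) {
    stop("dup_orf_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(list(
    mags = mags, n_mags = length(mags),
    n_timepoints = n_timepoints, n_replicates = n_replicates,
    seq_depth = seq_depth, spike_molecules = spike_molecules,
    spike_length_nt = spike_length_nt,
    spike_mass_fraction = spike_mass_fraction,
    lfq_noise_sd = lfq_noise_sd, mt_noise_sd = mt_noise_sd,
    mp_noise_sd = mp_noise_sd,
    detect_fraction_mp = detect_fraction_mp,
    identified_peak_fraction = identified_peak_fraction,
    aliquot_factor_mt = aliquot_factor_mt,
    sample_volume_l = sample_volume_l,
    dup_orf_fraction = dup_orf_fraction,
    count_noise = count_noise,
    emit_sequences = emit_sequences,
    seed = as.integer(seed)
  ), class = "sim_config")
}

.sample_frame <- function(config) {
  reps <- LETTERS[seq_len(config$n_replicates)]
  grid <- expand.grid(replicate = reps,
                      tindex = seq_len(config$n_timepoints),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = paste0("t", grid$tindex, grid$replicate),
    time_h = 13 + 5 * (grid$tindex - 1),
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
}

.codons61 <- {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

.random_orf_nt <- function(aa_len) {
  paste0("ATG",
         paste(sample(.codons61, aa_len - 1, replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

#' Generate a ground-truthed synthetic community
#'
#' Draws ORF lengths (log-normal, median ~900 nt), per-ORF transcript
#' copies (log-normal per MAG), and protein copies through the monomial
#' coupling protein = a * RNA^k with multiplicative log10 noise. A
#' configurable fraction of ORFs are exact sequence duplicates, creating
#' multi-member ORF-groups as real assemblies do.
#'
#' @param config A [simulation_config()].
#' @return List with `catalog` (ORF catalog data frame, including
#'   `nt_sequence` / `aa_sequence` columns when sequences are emitted),
#'   `truth` (matrices `true_rna_molecules`, `true_protein_molecules`
#'   (ORF x sample), `true_transcriptome_nt`, `true_k`, `true_a_log10`
#'   (MAG x time)), and `samples` (sample metadata).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  samples <- .sample_frame(config)
  n_samp <- nrow(samples)
  times <- sort(unique(samples$time_h))

  ko_pool <- sprintf("K%05d", 1:15)
  ko_weights <- stats::rexp(length(ko_pool)) + 0.2

  cat_list <- list()
  rna_list <- list()
  prot_list <- list()
  true_k <- matrix(NA_real_, config$n_mags, config$n_timepoints,
                   dimnames = list(vapply(config$mags, `[[`, "", "mag_id"),
                                   paste0("t", seq_len(config$n_timepoints))))
  true_a <- true_k

  for (mi in seq_along(config$mags)) {
    mag <- config$mags[[mi]]
    n <- mag$n_orfs
    k_t <- mag$true_k_per_timepoint
    if (is.null(k_t)) k_t <- rep(0.7, config$n_timepoints)
    if (length(k_t) != config$n_timepoints) {
      stop("MAG ", mag$mag_id, ": true_k_per_timepoint must have length ",
           config$n_timepoints, call. = FALSE)
    }
    if (any(k_t < 0) || any(k_t > 1)) {
      stop("MAG ", mag$mag_id, ": k outside [0, 1]", call. = FALSE)
    }
    a_t <- if (is.null(mag$true_a_log10)) {
      log10(mag$median_ratio_target) +
        (1 - k_t) * mag$rna_abundance_log10_mean
    } else {
      rep(mag$true_a_log10, config$n_timepoints)
    }
    true_k[mi, ] <- k_t
    true_a[mi, ] <- a_t

    orf_ids <- sprintf("%s_orf%04d", mag$mag_id, seq_len(n))
    aa_len <- pmax(30L, round(stats::rlnorm(n, log(900), 0.45) / 3) - 1L)
    # duplicate pairs: ORF 2j copies ORF 2j-1
    n_dup_pairs <- floor(config$dup_orf_fraction * n / 2)
    dup_to <- integer(0)
    if (n_dup_pairs > 0) {
      dup_to <- 2 * seq_len(n_dup_pairs)        # copies
      aa_len[dup_to] <- aa_len[dup_to - 1L]
    }
    length_nt <- 3L * (aa_len + 1L)

    nt_seq <- aa_seq <- rep(NA_character_, n)
    if (config$emit_sequences) {
      nt_seq <- vapply(aa_len, .random_orf_nt, character(1))
      if (length(dup_to) > 0) nt_seq[dup_to] <- nt_seq[dup_to - 1L]
      aa_seq <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(substr(nt_seq, 1, nchar(nt_seq) - 3)),
        no.init.codon = TRUE))
      mw <- vapply(aa_seq, compute_mw, numeric(1), USE.NAMES = FALSE)
    } else {
      mw <- aa_len * mean(.aa_residue_mass) + .water_mass
    }

    base <- stats::rnorm(n, mag$rna_abundance_log10_mean,
                         mag$rna_abundance_log10_sd)
    rna <- matrix(0, n, n_samp, dimnames = list(orf_ids, samples$sample_id))
    prot <- rna
    for (s in seq_len(n_samp)) {
      ti <- match(samples$time_h[s], times)
      lr <- base + stats::rnorm(n, 0, config$mt_noise_sd)
      rna[, s] <- 10^lr
      prot[, s] <- 10^(a_t[ti] + k_t[ti] * lr +
                         stats::rnorm(n, 0, config$mp_noise_sd))
    }

    ko <- sample(ko_pool, n, replace = TRUE, prob = ko_weights)
    cat_list[[mi]] <- data.frame(
      orf_id = orf_ids, mag_id = mag$mag_id,
      domain_tag = mag$domain_tag,
      length_nt = length_nt, mw_g_per_mol = mw,
      ko_terms = ko, nt_sequence = nt_seq, aa_sequence = aa_seq,
      stringsAsFactors = FALSE
    )
    rna_list[[mi]] <- rna
    prot_list[[mi]] <- prot
  }

  catalog <- do.call(rbind, cat_list)
  rownames(catalog) <- NULL
  # ORF-group membership: identical nucleotide sequence for MT, identical
  # amino-acid sequence for MP; without sequences the planted duplicate
  # structure is used directly (duplicates share length and MW).
  if (config$emit_sequences) {
    catalog$orfg_id_mt <- collapse_identical_orfs(
      stats::setNames(catalog$nt_sequence, catalog$orf_id))$orfg_id
    catalog$orfg_id_mp <- collapse_identical_orfs(
      stats::setNames(catalog$aa_sequence, catalog$orf_id))$orfg_id
  } else {
    orfg <- catalog$orf_id
    idx <- match(catalog$orf_id, catalog$orf_id)
    num <- as.integer(sub(".*_orf", "", catalog$orf_id))
    n_per_mag <- vapply(config$mags, `[[`, 0, "n_orfs")
    for (mi in seq_along(config$mags)) {
      n <- config$mags[[mi]]$n_orfs
      n_dup_pairs <- floor(config$dup_orf_fraction * n / 2)
      if (n_dup_pairs > 0) {
        mag_rows <- which(catalog$mag_id == config$mags[[mi]]$mag_id)
        copies <- mag_rows[num[mag_rows] %in% (2 * seq_len(n_dup_pairs))]
        orfg[copies] <- catalog$orf_id[copies - 1L]
      }
    }
    catalog$orfg_id_mt <- orfg
    catalog$orfg_id_mp <- orfg
  }

  rna <- do.call(rbind, rna_list)
  prot <- do.call(rbind, prot_list)
  tnt <- colSums(rna * catalog$length_nt)

  list(
    catalog = catalog,
    truth = list(
      true_rna_molecules = rna,
      true_protein_molecules = prot,
      true_transcriptome_nt = tnt,
      true_k = true_k,
      true_a_log10 = true_a
    ),
    samples = samples,
    config = config
  )
}

#' Simulate the metatranscriptomic observation layer
#'
#' Inverse of the spike-in quantification: 1/aliquot_factor of each
#' sample's RNA is measured together with the internal standard, and reads
#' are allocated across ORFs and spike in proportion to nucleotide mass
#' (molecules x length) — multinomially when `count_noise` is on, as exact
#' expectations otherwise. ORF reads are then summed per MT ORF-group.
#'
#' @param community Output of [generate_community()].
#' @param config Optional override of `community$config`.
#' @return List with `mt_reads` (orfg_id, sample_id, reads, unique_hits)
#'   and `spikein` (sample_id, I_M, I_Nt, I_R).
#' @export
simulate_mt_observation <- function(community, config = community$config) {
  if (config$seq_depth <= 0) stop("seq_depth must be > 0", call. = FALSE)
  set.seed(config$seed + 1L)
  catalog <- community$catalog
  rna <- community$truth$true_rna_molecules
  samples <- community$samples

  I_Nt <- config$spike_length_nt
  nt_mass <- rna / config$aliquot_factor_mt * catalog$length_nt
  I_M <- config$spike_molecules
  if (!is.null(config$spike_mass_fraction)) {
    f <- config$spike_mass_fraction
    I_M <- f / (1 - f) * mean(colSums(nt_mass)) / I_Nt
  }
  spike_mass <- I_M * I_Nt

  orfg <- factor(catalog$orfg_id_mt)
  reads_list <- vector("list", nrow(samples))
  spike_list <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    mass <- c(nt_mass[, s], spike = spike_mass)
    probs <- mass / sum(mass)
    counts <- if (config$count_noise) {
      as.numeric(stats::rmultinom(1, config$seq_depth, probs))
    } else {
      config$seq_depth * probs
    }
    I_R <- counts[length(counts)]
    if (I_R <= 0) {
      stop("no spike-in reads sampled in ", samples$sample_id[s],
           ": spike mass fraction too small for this depth", call. = FALSE)
    }
    orf_reads <- counts[-length(counts)]
    grp <- as.numeric(tapply(orf_reads, orfg, sum))
    reads_list[[s]] <- data.frame(
      orfg_id = levels(orfg), sample_id = samples$sample_id[s],
      reads = grp, unique_hits = grp, stringsAsFactors = FALSE)
    spike_list[[s]] <- data.frame(
      sample_id = samples$sample_id[s], I_M = I_M, I_Nt = I_Nt, I_R = I_R,
      stringsAsFactors = FALSE)
  }
  list(mt_reads = do.call(rbind, reads_list),
       spikein = do.call(rbind, spike_list))
}

#' Simulate the metaproteomic observation layer
#'
#' LFQ intensity per detected ORF-group is proportional to protein mass
#' (molecules x MW) with multiplicative log10 noise; undetected groups get
#' 0. Bradford total mass is exact (sum of molecules x MW / N_A over all
#' ORFs). The per-sample peak table is constructed so the identified
#' intensity-mass share equals `identified_peak_fraction` times the
#' detected-protein mass share, which is what the detected-mass correction
#' inverts.
#'
#' @param community Output of [generate_community()].
#' @param config Optional override of `community$config`.
#' @param n_peaks Peaks per sample in the synthetic peak table.
#' @return List with `mp_lfq`, `peaks`, `bradford` data frames.
#' @export
simulate_mp_observation <- function(community, config = community$config,
                                    n_peaks = 200) {
  if (config$detect_fraction_mp <= 0 || config$detect_fraction_mp > 1) {
    stop("detect_fraction_mp must be in (0, 1]", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  catalog <- community$catalog
  prot <- community$truth$true_protein_molecules
  samples <- community$samples

  orfg <- factor(catalog$orfg_id_mp)
  orfg_ids <- levels(orfg)
  mw_orfg <- as.numeric(tapply(catalog$mw_g_per_mol, orfg, mean))

  lfq_list <- vector("list", nrow(samples))
  peak_list <- vector("list", nrow(samples))
  brad_list <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    p_orfg <- as.numeric(tapply(prot[, s], orfg, sum))
    mass_orfg_g <- p_orfg * mw_orfg / N_AVOGADRO
    total_mass <- sum(catalog$mw_g_per_mol * prot[, s]) / N_AVOGADRO

    detected <- stats::runif(length(p_orfg)) <= config$detect_fraction_mp
    if (!any(detected)) {
      stop("no protein detected in sample ", sid, call. = FALSE)
    }
    lfq <- ifelse(
      detected,
      p_orfg * mw_orfg *
        10^stats::rnorm(length(p_orfg), 0, config$lfq_noise_sd),
      0)
    upep <- ifelse(detected, 1 + stats::rpois(length(p_orfg), 4), 0)
    lfq_list[[s]] <- data.frame(
      orfg_id = orfg_ids, sample_id = sid, lfq = lfq,
      unique_peptides = upep, stringsAsFactors = FALSE)

    det_share <- sum(mass_orfg_g[detected]) / sum(mass_orfg_g)
    r <- config$identified_peak_fraction * det_share
    peak_list[[s]] <- .make_peak_table(sid, n_peaks, r)

    brad_list[[s]] <- data.frame(
      sample_id = sid,
      conc_g_per_l = total_mass / config$sample_volume_l,
      volume_l = config$sample_volume_l, stringsAsFactors = FALSE)
  }
  list(mp_lfq = do.call(rbind, lfq_list),
       peaks = do.call(rbind, peak_list),
       bradford = do.call(rbind, brad_list))
}

# Build n peaks whose identified intensity-mass share is exactly r.
.make_peak_table <- function(sample_id, n, r) {
  stopifnot(r >= 0, r <= 1)
  bpi <- stats::rlnorm(n, log(1e6), 1)
  mass <- stats::runif(n, 500, 3500)
  if (r >= 1) {
    identified <- rep(1L, n)
  } else if (r <= 0) {
    identified <- rep(0L, n)
  } else {
    n_id <- max(1L, min(n - 1L, round(r * n)))
    identified <- c(rep(1L, n_id), rep(0L, n - n_id))
    w <- bpi * mass
    scale <- r * sum(w[identified == 0]) / ((1 - r) * sum(w[identified == 1]))
    bpi[identified == 1] <- bpi[identified == 1] * scale
  }
  data.frame(sample_id = sample_id,
             peak_id = sprintf("%s_pk%03d", sample_id, seq_len(n)),
             base_peak_intensity = bpi, mass_da = mass,
             identified = identified, stringsAsFactors = FALSE)
}

#' Write a simulated dataset to a directory
#'
#' Emits the file set the pipeline readers expect: `orfs.fna` / `orfs.faa`
#' (when sequences were generated), `orf_catalog.tsv`, `mt_reads.tsv`,
#' `spikein.tsv`, `mp_lfq.tsv`, `peaks.tsv`, `bradford.tsv`, `samples.tsv`,
#' and the ground truth under `truth/`.
#'
#' @param community Output of [generate_community()].
#' @param mt_obs Output of [simulate_mt_observation()].
#' @param mp_obs Output of [simulate_mp_observation()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(community, mt_obs, mp_obs, dir) {
  if (is.null(dir) || !nzchar(dir)) {
    stop("output directory path is empty", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  catalog <- community$catalog
  comments <- paste0("seed: ", community$config$seed)

  if (!anyNA(catalog$nt_sequence)) {
    write_fasta(stats::setNames(catalog$nt_sequence, catalog$orf_id),
                file.path(dir, "orfs.fna"))
    write_fasta(stats::setNames(catalog$aa_sequence, catalog$orf_id),
                file.path(dir, "orfs.faa"))
  }
  cat_cols <- c("orf_id", "mag_id", "domain_tag", "orfg_id_mt",
                "orfg_id_mp", "length_nt", "mw_g_per_mol", "ko_terms")
  write_table(catalog[, cat_cols], file.path(dir, "orf_catalog.tsv"),
              comments)
  write_table(mt_obs$mt_reads, file.path(dir, "mt_reads.tsv"), comments)
  write_table(mt_obs$spikein, file.path(dir, "spikein.tsv"), comments)
  write_table(mp_obs$mp_lfq, file.path(dir, "mp_lfq.tsv"), comments)
  write_table(mp_obs$peaks, file.path(dir, "peaks.tsv"), comments)
  write_table(mp_obs$bradford, file.path(dir, "bradford.tsv"), comments)
  write_table(community$samples, file.path(dir, "samples.tsv"), comments)

  truth <- community$truth
  long <- function(mat, value) {
    data.frame(orf_id = rep(rownames(mat), ncol(mat)),
               sample_id = rep(colnames(mat), each = nrow(mat)),
               value = as.vector(mat), stringsAsFactors = FALSE,
               check.names = FALSE) |>
      stats::setNames(c("orf_id", "sample_id", value))
  }
  write_table(long(truth$true_rna_molecules, "rna_molecules"),
              file.path(dir, "truth", "true_rna.tsv"), comments)
  write_table(long(truth$true_protein_molecules, "protein_molecules"),
              file.path(dir, "truth", "true_protein.tsv"), comments)
  write_table(data.frame(sample_id = names(truth$true_transcriptome_nt),
                         transcriptome_nt = truth$true_transcriptome_nt),
              file.path(dir, "truth", "true_transcriptome.tsv"), comments)
  times <- 13 + 5 * (seq_len(ncol(truth$true_k)) - 1)
  kdf <- data.frame(
    mag_id = rep(rownames(truth$true_k), ncol(truth$true_k)),
    time_h = rep(times, each = nrow(truth$true_k)),
    true_k = as.vector(truth$true_k),
    true_a_log10 = as.vector(truth$true_a_log10))
  write_table(kdf, file.path(dir, "truth", "true_k.tsv"), comments)
  invisible(dir)
}

#' Read a simulated dataset back from a directory
#'
#' @param dir Directory written by [write_dataset()].
#' @return List of typed data frames keyed by table name.
#' @export
read_dataset <- function(dir) {
  read1 <- function(file, schema) {
    read_table(file.path(dir, file), table_schema(schema))
  }
  out <- list(
    orf_catalog = read1("orf_catalog.tsv", "orf_catalog"),
    mt_reads = read1("mt_reads.tsv", "mt_reads"),
    spikein = read1("spikein.tsv", "spikein"),
    mp_lfq = read1("mp_lfq.tsv", "mp_lfq"),
    peaks = read1("peaks.tsv", "peaks"),
    bradford = read1("bradford.tsv", "bradford"),
    samples = read1("samples.tsv", "samples")
  )
  fna <- file.path(dir, "orfs.fna")
  if (file.exists(fna)) {
    out$nt_sequences <- read_fasta(fna)
    out$aa_sequences <- read_fasta(file.path(dir, "orfs.faa"))
  }
  out
}
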