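#' Estimate total transcriptome size from the spike-in internal standard
#'
#' Read yield is proportional to the nucleotide mass of the starting
#' material, so the known spike-in dose anchors the unknown transcriptome:
#' total transcriptome nucleotides = I_M x I_Nt x (total transcript reads /
#' spike-in reads).
#'
#' @param I_M Molecules of internal standard added to the aliquot.
#' @param I_Nt Length of the internal standard transcript, nt.
#' @param total_transcript_reads Reads mapping to the transcriptome (spike-in
#'   and rRNA reads excluded).
#' @param I_R Reads mapping to the internal standard.
#' @return Estimated transcriptome size in nucleotides (aliquot scale).
#' @export
estimate_transcriptome_size <- function(I_M, I_Nt, total_transcript_reads, I_R) {
  stopifnot(I_M > 0, I_Nt > 0, total_transcript_reads >= 0)
  if (any(I_R <= 0)) {
    stop("no spike-in reads detected (I_R = 0): transcriptome size undefined",
         call. = FALSE)
  }
  I_M * I_Nt * total_transcript_reads / I_R
}

#' Reads per kilobase per million mapped reads
#'
#' @param reads Per-feature read counts.
#' @param length_nt Feature lengths in nucleotides.
#' @param total_transcript_reads Denominator: transcriptome-mapped reads in
#'   the sample (spike-in excluded).
#' @return RPKM values, same length as `reads`.
#' @export
compute_rpkm <- function(reads, length_nt, total_transcript_reads) {
  stopifnot(length(reads) == length(length_nt))
  if (any(length_nt <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  if (any(reads < 0)) stop("read counts must be >= 0", call. = FALSE)
  if (total_transcript_reads <= 0) {
    stop("total transcript reads must be > 0 to compute RPKM", call. = FALSE)
  }
  reads * 1e9 / (length_nt * total_transcript_reads)
}

#' Absolute transcript molecules from RPKM and transcriptome size
#'
#' T_M = RPKM / 1e9 x (total transcriptome nt). RPKM is a fraction of
#' nucleotide mass per kilobase; multiplying by the absolute transcriptome
#' size converts it to molecules.
#'
#' @param rpkm Per-feature RPKM.
#' @param transcriptome_nt Estimated transcriptome size in nucleotides
#'   (same aliquot scale as the reads used for `rpkm`).
#' @return Transcript molecules per feature, aliquot scale.
#' @export
molecules_per_orfg <- function(rpkm, transcriptome_nt) {
  if (any(rpkm < 0)) stop("RPKM must be >= 0", call. = FALSE)
  if (any(transcriptome_nt < 0)) {
    stop("transcriptome size must be >= 0", call. = FALSE)
  }
  rpkm / 1e9 * transcriptome_nt
}

#' Scale aliquot-level molecule counts to the full sample
#'
#' The internal standard is added to a fixed aliquot of each sample (6 ml of
#' 60 ml by default), so aliquot counts are multiplied by the aliquot factor
#' to reconstruct the whole-sample count.
#'
#' @param molecules_aliquot Molecule counts at aliquot scale.
#' @param aliquot_factor Dimensionless factor >= 1 (default 10).
#' @return Molecule counts per full sample.
#' @export
scale_to_sample <- function(molecules_aliquot, aliquot_factor = 10) {
  if (aliquot_factor < 1) stop("aliquot factor must be >= 1", call. = FALSE)
  molecules_aliquot * aliquot_factor
}

#' Absolute metatranscriptome quantification for a read table
#'
#' Runs the full spike-in inversion per sample: transcriptome size from the
#' internal standard, RPKM per ORF-group, molecules per ORF-group, and
#' scaling from aliquot to sample.
#'
#' @param mt_reads Data frame with columns `orfg_id`, `sample_id`, `reads`,
#'   `unique_hits`.
#' @param spikein Data frame with columns `sample_id`, `I_M`, `I_Nt`, `I_R`.
#' @param catalog ORF catalog data frame (`orf_id`, `orfg_id_mt`,
#'   `length_nt`, ...). ORF-group length is the mean of member lengths.
#' @param aliquot_factor Aliquot-to-sample factor (default 10).
#' @return List with `mt_absolute` (orfg_id, sample_id, reads, rpkm,
#'   molecules_aliquot, molecules_sample) and `sample_summary` (sample_id,
#'   total_reads, spike_reads, transcriptome_nt, total_molecules; aliquot
#'   scale for transcriptome_nt, sample scale for total_molecules).
#' @export
quantify_mt <- function(mt_reads, spikein, catalog, aliquot_factor = 10) {
  stopifnot(all(c("orfg_id", "sample_id", "reads") %in% names(mt_reads)),
            all(c("sample_id", "I_M", "I_Nt", "I_R") %in% names(spikein)))
  orfg_len <- tapply(catalog$length_nt, catalog$orfg_id_mt, mean)
  unknown <- setdiff(unique(mt_reads$orfg_id), names(orfg_len))
  if (length(unknown) > 0) {
    stop("ORF-groups absent from catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  out <- vector("list", nrow(spikein))
  summ <- vector("list", nrow(spikein))
  for (i in seq_len(nrow(spikein))) {
    sid <- spikein$sample_id[i]
    tab <- mt_reads[mt_reads$sample_id == sid, , drop = FALSE]
    if (nrow(tab) == 0) next
    total_reads <- sum(tab$reads)
    tnt <- estimate_transcriptome_size(spikein$I_M[i], spikein$I_Nt[i],
                                       total_reads, spikein$I_R[i])
    rpkm <- compute_rpkm(tab$reads, as.numeric(orfg_len[tab$orfg_id]),
                         total_reads)
    mol_aliquot <- molecules_per_orfg(rpkm, tnt)
    mol_sample <- scale_to_sample(mol_aliquot, aliquot_factor)
    out[[i]] <- data.frame(
      orfg_id = tab$orfg_id, sample_id = sid,
      reads = tab$reads,
      unique_hits = if ("unique_hits" %in% names(tab)) tab$unique_hits else tab$reads,
      rpkm = rpkm,
      molecules_aliquot = mol_aliquot,
      molecules_sample = mol_sample,
      stringsAsFactors = FALSE
    )
    summ[[i]] <- data.frame(
      sample_id = sid, total_reads = total_reads,
      spike_reads = spikein$I_R[i], transcriptome_nt = tnt,
      total_molecules = sum(mol_sample), stringsAsFactors = FALSE
    )
  }
  list(mt_absolute = do.call(rbind, out),
       sample_summary = do.call(rbind, summ))
}
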