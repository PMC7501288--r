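#' Avogadro constant, 1/mol
#' @export
N_AVOGADRO <- 6.02214076e23

# Average (isotope-abundance weighted) residue masses, g/mol, for proteins
# in water-loss (residue) form. Ambiguity codes B/Z are candidate means,
# X is a generic 110 Da residue.
.aa_residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.05192, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.aa_ambiguous_mass <- c(
  B = (114.1038 + 115.0886) / 2,
  Z = (129.1155 + 128.1307) / 2,
  X = 110.0
)
.water_mass <- 18.01528

#' Protein molecular weight from an amino-acid sequence
#'
#' Sum of average residue masses plus one water (18.01528 g/mol). Average,
#' not monoisotopic, masses are used because the total protein approach
#' works at whole-protein mass scale; no post-translational mass shifts.
#'
#' @param aa_sequence Amino-acid string (one-letter IUPAC codes). A trailing
#'   `*` (stop) is tolerated and ignored.
#' @param ambiguous Policy for B/Z/X codes: `"average"` uses the mean of the
#'   candidate residue masses (X = 110 Da); `"error"` rejects them.
#' @return Molecular weight in g/mol.
#' @export
compute_mw <- function(aa_sequence, ambiguous = c("average", "error")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(is.character(aa_sequence), length(aa_sequence) == 1)
  seq <- toupper(sub("\\*$", "", aa_sequence))
  if (nchar(seq) == 0) stop("empty amino-acid sequence", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  masses <- .aa_residue_mass[chars]
  if (ambiguous == "average") {
    amb <- is.na(masses) & chars %in% names(.aa_ambiguous_mass)
    masses[amb] <- .aa_ambiguous_mass[chars[amb]]
  }
  if (anyNA(masses)) {
    pos <- which(is.na(masses))[1]
    stop(sprintf("unknown amino-acid code '%s' at position %d",
                 chars[pos], pos), call. = FALSE)
  }
  sum(masses) + .water_mass
}

#' Total protein mass per sample from the Bradford assay
#'
#' @param conc_g_per_l Bradford protein concentration, g/l.
#' @param volume_l Sample volume, liters (0.060 l for a 60 ml sample).
#' @return Total protein mass in grams.
#' @export
bradford_total_mass <- function(conc_g_per_l, volume_l) {
  if (any(conc_g_per_l < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (any(volume_l <= 0)) stop("volume must be > 0", call. = FALSE)
  conc_g_per_l * volume_l
}

#' LFQ intensities to mass fractions of total detected protein
#'
#' Total protein_i = LFQ_i / sum(LFQ). Zero-LFQ (undetected) entries get
#' fraction 0; detected fractions sum to one.
#'
#' @param lfq Per-protein LFQ intensities for one sample.
#' @return Mass fractions, same length as `lfq`.
#' @export
total_protein_fractions <- function(lfq) {
  if (any(lfq < 0)) stop("LFQ intensities must be >= 0", call. = FALSE)
  total <- sum(lfq)
  if (total <= 0) {
    stop("all LFQ intensities are zero: no detected protein in sample",
         call. = FALSE)
  }
  lfq / total
}

#' Mass fractions to molar fractions
#'
#' Protein concentration_i = Total protein_i / MW_i, in mol per gram of
#' total protein.
#'
#' @param fraction Mass fractions (dimensionless).
#' @param mw_g_per_mol Molecular weights, g/mol.
#' @param ids Optional identifiers used in error messages.
#' @return Molar fractions, mol/g.
#' @export
molar_fractions <- function(fraction, mw_g_per_mol, ids = NULL) {
  stopifnot(length(fraction) == length(mw_g_per_mol))
  bad <- which(mw_g_per_mol <= 0)
  if (length(bad) > 0) {
    lab <- if (!is.null(ids)) ids[bad[1]] else paste("entry", bad[1])
    stop("non-positive molecular weight for ", lab, call. = FALSE)
  }
  fraction / mw_g_per_mol
}

#' Detected protein mass from the MS peak table
#'
#' The Bradford assay measures all protein in the sample, but only the
#' identified fraction of the MS signal is quantified. The correction
#' allocates total mass by intensity x mass over peaks:
#' detected = total x sum(BPI_i x Mass_i over identified peaks) /
#' sum(BPI_j x Mass_j over all peaks).
#'
#' @param total_mass_g Total protein mass in grams (Bradford).
#' @param base_peak_intensity Per-peak base peak intensities.
#' @param mass_da Per-peak masses, Da.
#' @param identified Logical (or 0/1) flag: peak has an associated amino-acid
#'   sequence.
#' @return Detected protein mass in grams, in `[0, total_mass_g]`.
#' @export
detected_protein_mass <- function(total_mass_g, base_peak_intensity, mass_da,
                                  identified) {
  if (length(base_peak_intensity) == 0) {
    stop("empty peak table", call. = FALSE)
  }
  stopifnot(length(base_peak_intensity) == length(mass_da),
            length(mass_da) == length(identified))
  if (any(base_peak_intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (any(mass_da <= 0)) stop("peak masses must be > 0", call. = FALSE)
  w <- base_peak_intensity * mass_da
  denom <- sum(w)
  if (denom <= 0) stop("zero total peak signal", call. = FALSE)
  total_mass_g * sum(w[as.logical(identified)]) / denom
}

#' Copy numbers from molar fractions and detected protein mass
#'
#' Copy number_i = molar fraction_i x detected mass x N_A.
#'
#' @param molar_fraction Molar fractions, mol/g.
#' @param detected_mass_g Detected protein mass, grams.
#' @return Protein molecules per sample.
#' @export
copy_numbers <- function(molar_fraction, detected_mass_g) {
  if (any(molar_fraction < 0) || any(detected_mass_g < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  molar_fraction * detected_mass_g * N_AVOGADRO
}

#' Absolute metaproteome quantification (total protein approach)
#'
#' Per sample: Bradford total mass, detected-mass correction from the peak
#' table, LFQ fractions over detected ORF-groups, molar fractions through
#' molecular weight, copy numbers through Avogadro's number. ORF-group
#' molecular weight is the mean of member ORF weights. Undetected (zero-LFQ)
#' entries receive copy number 0.
#'
#' @param mp_lfq Data frame with columns `orfg_id`, `sample_id`, `lfq`.
#' @param peaks Data frame with columns `sample_id`, `base_peak_intensity`,
#'   `mass_da`, `identified`.
#' @param bradford Data frame with columns `sample_id`, `conc_g_per_l`,
#'   `volume_l`.
#' @param catalog ORF catalog (`orf_id`, `orfg_id_mp`, `mw_g_per_mol`, ...).
#' @return List with `mp_absolute` (orfg_id, sample_id, lfq, copy_number)
#'   and `sample_summary` (sample_id, total_mass_g, detected_mass_g,
#'   total_copies).
#' @export
quantify_mp <- function(mp_lfq, peaks, bradford, catalog) {
  stopifnot(all(c("orfg_id", "sample_id", "lfq") %in% names(mp_lfq)),
            all(c("sample_id", "conc_g_per_l", "volume_l") %in% names(bradford)))
  orfg_mw <- tapply(catalog$mw_g_per_mol, catalog$orfg_id_mp, mean)
  unknown <- setdiff(unique(mp_lfq$orfg_id), names(orfg_mw))
  if (length(unknown) > 0) {
    stop("ORF-groups absent from catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  out <- vector("list", nrow(bradford))
  summ <- vector("list", nrow(bradford))
  for (i in seq_len(nrow(bradford))) {
    sid <- bradford$sample_id[i]
    tab <- mp_lfq[mp_lfq$sample_id == sid, , drop = FALSE]
    pk <- peaks[peaks$sample_id == sid, , drop = FALSE]
    if (nrow(tab) == 0) next
    total_mass <- bradford_total_mass(bradford$conc_g_per_l[i],
                                      bradford$volume_l[i])
    det_mass <- detected_protein_mass(total_mass, pk$base_peak_intensity,
                                      pk$mass_da, pk$identified)
    frac <- total_protein_fractions(tab$lfq)
    molar <- molar_fractions(frac, as.numeric(orfg_mw[tab$orfg_id]),
                             ids = tab$orfg_id)
    cn <- copy_numbers(molar, det_mass)
    out[[i]] <- data.frame(
      orfg_id = tab$orfg_id, sample_id = sid, lfq = tab$lfq,
      unique_peptides = if ("unique_peptides" %in% names(tab)) tab$unique_peptides else NA_real_,
      copy_number = cn, stringsAsFactors = FALSE
    )
    summ[[i]] <- data.frame(
      sample_id = sid, total_mass_g = total_mass,
      detected_mass_g = det_mass, total_copies = sum(cn),
      stringsAsFactors = FALSE
    )
  }
  list(mp_absolute = do.call(rbind, out),
       sample_summary = do.call(rbind, summ))
}
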