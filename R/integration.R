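#' Collapse ORFs with identical sequences into ORF-groups
#'
#' ORFs with byte-identical sequences cannot be resolved by reads or
#' peptides and are grouped; everything else stays a singleton. The group
#' id is the lexicographically smallest member id, so grouping is invariant
#' to input order.
#'
#' @param sequences Named character vector of sequences (names = orf ids).
#' @return Data frame with columns `orf_id`, `orfg_id`.
#' @export
collapse_identical_orfs <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "")) {
    stop("sequences must be named by orf_id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate orf_ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  grp <- match(sequences, unique(sequences))
  rep_id <- vapply(split(ids, grp), min, character(1))
  out <- data.frame(orf_id = ids,
                    orfg_id = unname(rep_id[as.character(grp)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Drop rows without unique read/peptide support
#'
#' Expression estimates backed by zero unique hits are unreliable and are
#' removed before any downstream analysis.
#'
#' @param table Data frame with a `unique_hits` (or `unique_peptides`)
#'   column.
#' @param min_unique_hits Minimum unique hits to retain a row (default 1).
#' @param column Name of the unique-hit column.
#' @return Filtered data frame; the number of removed rows is attached as
#'   attribute `"n_removed"`.
#' @export
filter_unique_hits <- function(table, min_unique_hits = 1,
                               column = "unique_hits") {
  if (!column %in% names(table)) {
    stop("missing column '", column, "'", call. = FALSE)
  }
  keep <- table[[column]] >= min_unique_hits
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Log10 transform with a pseudocount
#'
#' @param values Non-negative values (molecule counts).
#' @param pseudocount Added before the log (default 1, so 0 maps to 0).
#' @return `log10(values + pseudocount)`.
#' @export
log_transform <- function(values, pseudocount = 1) {
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  log10(values + pseudocount)
}

#' Minimum-expression threshold on the log10 scale
#'
#' Entries below the layer's minimum expression are treated as noise:
#' threshold 5 for transcripts (log10 molecules) and 8 for proteins, both
#' boundary-inclusive.
#'
#' @param log_values Log10-transformed expression values.
#' @param layer `"MT"` or `"MP"`.
#' @param thresholds Named numeric vector of per-layer thresholds.
#' @return Logical vector: TRUE where the entry is retained.
#' @export
threshold_filter <- function(log_values, layer,
                             thresholds = c(MT = 5, MP = 8)) {
  if (!layer %in% names(thresholds)) {
    stop("unknown layer '", layer, "'; expected one of: ",
         paste(names(thresholds), collapse = ", "), call. = FALSE)
  }
  log_values >= thresholds[[layer]]
}

#' Screen samples for outliers with PCA
#'
#' Samples are projected onto the first two principal components of their
#' standardized log-scale expression profiles; a sample whose robust
#' z-distance (per-PC median/MAD standardization) exceeds `pc_sd_cutoff` is
#' flagged. Manual overrides are always flagged, whatever the PCA says —
#' the automated rule assists, it does not replace, a judgement call.
#'
#' @param mat Numeric matrix, samples in rows, features (log-scale
#'   expression) in columns. Row names are sample ids.
#' @param pc_sd_cutoff Robust-SD cutoff in PC1-PC2 space (default 3).
#' @param manual Character vector of sample ids flagged unconditionally.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
screen_outlier_samples <- function(mat, pc_sd_cutoff = 3,
                                   manual = character(0)) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 3) {
    stop("need at least 3 samples to screen for outliers", call. = FALSE)
  }
  keep_feat <- apply(mat, 2, stats::sd) > 0
  flagged <- character(0)
  if (sum(keep_feat) >= 2) {
    pcs <- stats::prcomp(mat[, keep_feat, drop = FALSE],
                         center = TRUE, scale. = TRUE)$x
    npc <- min(2L, ncol(pcs))
    z <- vapply(seq_len(npc), function(j) {
      s <- stats::mad(pcs[, j])
      if (s == 0) s <- stats::sd(pcs[, j])
      if (s == 0) return(rep(0, nrow(pcs)))
      (pcs[, j] - stats::median(pcs[, j])) / s
    }, numeric(nrow(pcs)))
    d <- sqrt(rowSums(z^2))
    flagged <- rownames(mat)[d > pc_sd_cutoff]
  }
  union(flagged, intersect(manual, rownames(mat)))
}

#' Match singleton ORF-groups across the transcript and protein layers
#'
#' Direct RNA-protein comparison is only meaningful for ORFs that are
#' unambiguous in both layers, i.e. belong to a single-member ORF-group in
#' MT and in MP. Retained ORFs are joined per sample and averaged over
#' replicates per time point (linear scale by default).
#'
#' @param mt_absolute Data frame `orfg_id`, `sample_id`, `molecules_sample`
#'   (already filtered).
#' @param mp_absolute Data frame `orfg_id`, `sample_id`, `copy_number`
#'   (already filtered).
#' @param catalog ORF catalog with `orf_id`, `mag_id`, `orfg_id_mt`,
#'   `orfg_id_mp`.
#' @param samples Data frame `sample_id`, `time_h`, `replicate`.
#' @param log_scale_mean If TRUE, replicates are averaged on the log10
#'   scale (geometric mean) instead of the linear scale.
#' @return Data frame `orf_id`, `mag_id`, `time_h`, `rna_molecules`,
#'   `protein_molecules`; attribute `"pair_counts"` holds per-MAG matched
#'   ORF counts. Empty intersection yields a warning and an empty frame.
#' @export
match_singletons <- function(mt_absolute, mp_absolute, catalog, samples,
                             log_scale_mean = FALSE) {
  mt_sizes <- table(catalog$orfg_id_mt)
  mp_sizes <- table(catalog$orfg_id_mp)
  singleton <- catalog[mt_sizes[catalog$orfg_id_mt] == 1 &
                         mp_sizes[catalog$orfg_id_mp] == 1, , drop = FALSE]

  mt <- merge(singleton[, c("orf_id", "mag_id", "orfg_id_mt")],
              mt_absolute[, c("orfg_id", "sample_id", "molecules_sample")],
              by.x = "orfg_id_mt", by.y = "orfg_id")
  mp <- merge(singleton[, c("orf_id", "orfg_id_mp")],
              mp_absolute[, c("orfg_id", "sample_id", "copy_number")],
              by.x = "orfg_id_mp", by.y = "orfg_id")
  both <- merge(mt[, c("orf_id", "mag_id", "sample_id", "molecules_sample")],
                mp[, c("orf_id", "sample_id", "copy_number")],
                by = c("orf_id", "sample_id"))
  if (nrow(both) == 0) {
    warning("no singleton ORFs shared between the MT and MP layers")
    out <- data.frame(orf_id = character(0), mag_id = character(0),
                      time_h = numeric(0), rna_molecules = numeric(0),
                      protein_molecules = numeric(0))
    attr(out, "pair_counts") <- integer(0)
    return(out)
  }
  both <- merge(both, samples[, c("sample_id", "time_h")], by = "sample_id")

  avg <- if (log_scale_mean) {
    function(x) 10^mean(log10(x))
  } else {
    mean
  }
  agg <- stats::aggregate(
    cbind(rna_molecules = both$molecules_sample,
          protein_molecules = both$copy_number),
    by = list(orf_id = both$orf_id, mag_id = both$mag_id,
              time_h = both$time_h),
    FUN = avg
  )
  agg <- agg[order(agg$orf_id, agg$time_h), ]
  rownames(agg) <- NULL
  pair_counts <- table(singleton$mag_id[singleton$orf_id %in% agg$orf_id])
  attr(agg, "pair_counts") <- pair_counts
  agg
}

#' Integrate absolute MT and MP tables into paired expression
#'
#' Applies the full harmonization pipeline in order: unique-hit filter on
#' both layers, log10(+1) transform, minimum-expression thresholds (5 MT, 8
#' MP, inclusive), PCA outlier screen on the MT layer with manual
#' overrides, singleton matching and replicate averaging.
#'
#' @param mt_absolute,mp_absolute Output tables of [quantify_mt()] /
#'   [quantify_mp()] (with `unique_hits` / `unique_peptides` columns).
#' @param catalog ORF catalog data frame.
#' @param samples Sample metadata (`sample_id`, `time_h`, `replicate`).
#' @param min_unique_hits Minimum unique hits (default 1).
#' @param thresholds Named log10 thresholds, default `c(MT = 5, MP = 8)`.
#' @param pseudocount Pseudocount for the log transform (default 1).
#' @param drop_samples Manual outlier sample ids (e.g. `"t7C"`).
#' @param pc_sd_cutoff PCA screen cutoff in robust SDs; `NA` disables the
#'   automated screen so only `drop_samples` is honored (the default
#'   policy: the screen assists a manual call).
#' @param log_scale_mean Passed to [match_singletons()].
#' @return List with `paired` (the paired-expression frame),
#'   `dropped_samples`, and `filter_report` (stage, rows_in, rows_out).
#' @export
integrate_layers <- function(mt_absolute, mp_absolute, catalog, samples,
                             min_unique_hits = 1,
                             thresholds = c(MT = 5, MP = 8),
                             pseudocount = 1,
                             drop_samples = character(0),
                             pc_sd_cutoff = NA,
                             log_scale_mean = FALSE) {
  report <- list()
  note <- function(stage, n_in, n_out) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, rows_in = n_in, rows_out = n_out,
      stringsAsFactors = FALSE)
  }

  n0 <- nrow(mt_absolute)
  mt <- filter_unique_hits(mt_absolute, min_unique_hits, "unique_hits")
  note("mt_unique_hits", n0, nrow(mt))
  n0 <- nrow(mp_absolute)
  mp_col <- if ("unique_peptides" %in% names(mp_absolute)) "unique_peptides" else "unique_hits"
  mp <- filter_unique_hits(mp_absolute, min_unique_hits, mp_col)
  note("mp_unique_hits", n0, nrow(mp))

  keep_mt <- threshold_filter(log_transform(mt$molecules_sample, pseudocount),
                              "MT", thresholds)
  n0 <- nrow(mt); mt <- mt[keep_mt, , drop = FALSE]
  note("mt_threshold", n0, nrow(mt))
  keep_mp <- threshold_filter(log_transform(mp$copy_number, pseudocount),
                              "MP", thresholds)
  n0 <- nrow(mp); mp <- mp[keep_mp, , drop = FALSE]
  note("mp_threshold", n0, nrow(mp))

  dropped <- character(0)
  if (!is.na(pc_sd_cutoff) || length(drop_samples) > 0) {
    if (!is.na(pc_sd_cutoff)) {
      wide <- stats::xtabs(log_transform(molecules_sample, pseudocount) ~
                             sample_id + orfg_id, data = mt)
      mat <- matrix(as.numeric(wide), nrow = nrow(wide),
                    dimnames = dimnames(wide))
      dropped <- screen_outlier_samples(mat, pc_sd_cutoff, manual = drop_samples)
    } else {
      dropped <- intersect(drop_samples,
                           union(mt$sample_id, mp$sample_id))
    }
    n0 <- nrow(mt); mt <- mt[!mt$sample_id %in% dropped, , drop = FALSE]
    note("mt_outlier_samples", n0, nrow(mt))
    n0 <- nrow(mp); mp <- mp[!mp$sample_id %in% dropped, , drop = FALSE]
    note("mp_outlier_samples", n0, nrow(mp))
  }

  paired <- match_singletons(mt, mp, catalog, samples,
                             log_scale_mean = log_scale_mean)
  note("match_singletons", nrow(mt) + nrow(mp), nrow(paired))

  list(paired = paired,
       dropped_samples = dropped,
       filter_report = do.call(rbind, report))
}
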