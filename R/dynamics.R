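#' Protein-to-RNA ratio distributions per population
#'
#' Per-ORF ratios of replicate-averaged protein to RNA molecules at one
#' time point, summarized per MAG (median, quartiles, n). When a domain
#' map is supplied, a pooled `all_bacteria` summary over bacterial MAGs is
#' appended, mirroring the community-wide estimate usually quoted next to
#' per-population medians.
#'
#' @param paired Paired-expression frame (`orf_id`, `mag_id`, `time_h`,
#'   `rna_molecules`, `protein_molecules`).
#' @param time_h Time point, hours.
#' @param domains Optional named character vector mapping mag_id to
#'   `"bacterial"` / `"archaeal"`.
#' @return List with `summary` (mag_id, time_h, n_genes, q25, median, q75)
#'   and `ratios` (orf_id, mag_id, ratio).
#' @export
protein_rna_ratios <- function(paired, time_h, domains = NULL) {
  sub <- paired[paired$time_h == time_h, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no paired expression at time ", time_h, " h", call. = FALSE)
  }
  if (any(sub$rna_molecules <= 0)) {
    stop("non-positive RNA values present; filter before computing ratios",
         call. = FALSE)
  }
  ratio <- sub$protein_molecules / sub$rna_molecules
  ratios <- data.frame(orf_id = sub$orf_id, mag_id = sub$mag_id,
                       ratio = ratio, stringsAsFactors = FALSE)

  summarize <- function(r, label) {
    q <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(mag_id = label, time_h = time_h, n_genes = length(r),
               q25 = q[1], median = q[2], q75 = q[3],
               stringsAsFactors = FALSE)
  }
  by_mag <- split(ratio, sub$mag_id)
  summ <- do.call(rbind, Map(function(r, label) summarize(r, label),
                             by_mag, names(by_mag)))
  if (!is.null(domains)) {
    bact <- sub$mag_id %in% names(domains)[domains == "bacterial"]
    if (any(bact)) {
      summ <- rbind(summ, summarize(ratio[bact], "all_bacteria"))
    }
  }
  rownames(summ) <- NULL
  list(summary = summ, ratios = ratios)
}

#' Gene-wise Pearson correlation of RNA and protein over time
#'
#' Pearson r per ORF between log10 RNA and log10 protein replicate means
#' across time points. ORFs with fewer than `min_timepoints` shared time
#' points are skipped and counted; zero-variance series give `NA` (the
#' correlation is undefined), never a forced +/-1.
#'
#' @param paired Paired-expression frame.
#' @param min_timepoints Minimum time points per ORF (default 3).
#' @param log_scale Correlate log10 values (default TRUE, matching how
#'   expression levels are displayed and modeled).
#' @return List with `records` (orf_id, pcc, n_timepoints), `median_pcc`,
#'   `n_skipped`, `n_undefined`.
#' @export
genewise_pcc <- function(paired, min_timepoints = 3, log_scale = TRUE) {
  parts <- split(paired, paired$orf_id)
  rec <- lapply(parts, function(d) {
    n <- nrow(d)
    if (n < min_timepoints) {
      return(data.frame(orf_id = d$orf_id[1], pcc = NA_real_,
                        n_timepoints = n, usable = FALSE))
    }
    x <- d$rna_molecules
    y <- d$protein_molecules
    if (log_scale) {
      x <- log10(x)
      y <- log10(y)
    }
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
    data.frame(orf_id = d$orf_id[1], pcc = r, n_timepoints = n,
               usable = TRUE)
  })
  rec <- do.call(rbind, rec)
  rownames(rec) <- NULL
  usable <- rec[rec$usable, , drop = FALSE]
  list(records = rec[, c("orf_id", "pcc", "n_timepoints")],
       median_pcc = stats::median(usable$pcc, na.rm = TRUE),
       n_skipped = sum(!rec$usable),
       n_undefined = sum(rec$usable & is.na(rec$pcc)))
}

#' Fit the monomial RNA-protein model Protein = a * RNA^k
#'
#' Expression spans orders of magnitude, so the monomial is fitted as the
#' linear model log10(protein) = a_log10 + k * log10(RNA) by ordinary least
#' squares. The slope k is the linearity: k = 1 means protein scales
#' proportionally with RNA, smaller k means a change in RNA is damped at
#' the protein level.
#'
#' @param rna,protein Positive molecule counts, matched per ORF.
#' @param mag_id,time_h Optional labels stored in the result.
#' @return Data frame row: mag_id, time_h, a_log10, k, n_points, r_squared,
#'   residual_sd. `a = 10^a_log10`.
#' @export
fit_monomial <- function(rna, protein, mag_id = NA_character_,
                         time_h = NA_real_) {
  stopifnot(length(rna) == length(protein))
  if (length(rna) < 3) {
    stop("need at least 3 RNA-protein pairs to fit the monomial model",
         call. = FALSE)
  }
  if (any(rna <= 0) || any(protein <= 0)) {
    stop("RNA and protein values must be > 0 on the log scale", call. = FALSE)
  }
  x <- log10(rna)
  y <- log10(protein)
  if (stats::sd(x) == 0) {
    stop("zero variance in RNA: slope undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # exact power-law inputs are legitimate; summary()'s perfect-fit warning
  # is not informative here
  s <- suppressWarnings(summary(fit))
  data.frame(
    mag_id = mag_id, time_h = time_h,
    a_log10 = unname(stats::coef(fit)[1]),
    k = unname(stats::coef(fit)[2]),
    n_points = length(x),
    r_squared = s$r.squared,
    residual_sd = s$sigma,
    stringsAsFactors = FALSE
  )
}

#' Monomial fits for every MAG x time point
#'
#' @param paired Paired-expression frame.
#' @param min_points Minimum matched ORFs per MAG x time cell (default 30;
#'   smaller cells are skipped).
#' @param mags Optional subset of MAG ids to fit.
#' @return Data frame of [fit_monomial()] rows.
#' @export
fit_monomial_all <- function(paired, min_points = 30, mags = NULL) {
  if (!is.null(mags)) paired <- paired[paired$mag_id %in% mags, , drop = FALSE]
  cells <- split(paired, list(paired$mag_id, paired$time_h), drop = TRUE)
  fits <- lapply(cells, function(d) {
    if (nrow(d) < min_points) return(NULL)
    fit_monomial(d$rna_molecules, d$protein_molecules,
                 mag_id = d$mag_id[1], time_h = d$time_h[1])
  })
  out <- do.call(rbind, fits)
  if (is.null(out)) {
    return(data.frame(mag_id = character(0), time_h = numeric(0),
                      a_log10 = numeric(0), k = numeric(0),
                      n_points = integer(0), r_squared = numeric(0),
                      residual_sd = numeric(0)))
  }
  out <- out[order(out$mag_id, out$time_h), ]
  rownames(out) <- NULL
  out
}

#' Predicted protein fold change for an RNA fold change under linearity k
#'
#' Under Protein = a * RNA^k, an RNA fold change f maps to a protein fold
#' change f^k: at k = 1 a doubling of RNA doubles protein, at k = 0.5 it
#' yields sqrt(2), about a 40 percent increase.
#'
#' @param k Linearity exponent.
#' @param rna_fold_change Positive fold change in RNA.
#' @return Protein fold change `rna_fold_change^k`.
#' @export
predict_protein_change <- function(k, rna_fold_change) {
  if (any(rna_fold_change <= 0)) {
    stop("fold change must be > 0", call. = FALSE)
  }
  rna_fold_change^k
}

#' Cubic trajectory of the linearity k over time
#'
#' Degree-3 polynomial least squares of k on time (hours); three
#' coefficients of curvature allow up to two bends. Defined only within
#' the observed time range — extrapolation is refused.
#'
#' @param time_h Time points, hours (>= 4 distinct values).
#' @param k Fitted linearity values at those times.
#' @param mag_id Optional label.
#' @return List with `mag_id`, `coefficients` (c0..c3), `fitted`,
#'   `residuals`, `time_range`, and `predict(t)` (errors outside the range).
#' @export
fit_k_trajectory <- function(time_h, k, mag_id = NA_character_) {
  stopifnot(length(time_h) == length(k))
  if (length(unique(time_h)) < 4) {
    stop("need at least 4 time points for a cubic fit", call. = FALSE)
  }
  fit <- stats::lm(k ~ poly(time_h, 3, raw = TRUE))
  coefs <- stats::setNames(unname(stats::coef(fit)),
                           c("c0", "c1", "c2", "c3"))
  rng <- range(time_h)
  list(
    mag_id = mag_id,
    coefficients = coefs,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    time_range = rng,
    predict = function(t) {
      if (any(t < rng[1] | t > rng[2])) {
        stop("refusing to extrapolate k(t) outside [",
             rng[1], ", ", rng[2], "] h", call. = FALSE)
      }
      coefs[1] + coefs[2] * t + coefs[3] * t^2 + coefs[4] * t^3
    }
  )
}

#' Rank preservation of functional categories between omic layers
#'
#' Kendall tau-b (tie-corrected) between the abundance rankings of the same
#' functional (KO) categories in two layers, e.g. genome ORF counts vs
#' summed absolute transcript molecules. tau = 1 is total agreement in
#' ranking, -1 the opposite ranking.
#'
#' @param x,y Named numeric vectors of category abundances; names must be
#'   the same category set.
#' @param layers Optional length-2 labels (e.g. `c("MG", "MT")`).
#' @return Data frame: layer_x, layer_y, kendall_tau, p_value, n_categories.
#' @export
kendall_rank_preservation <- function(x, y, layers = c("x", "y")) {
  if (is.null(names(x)) || is.null(names(y))) {
    stop("category vectors must be named", call. = FALSE)
  }
  diff_xy <- setdiff(names(x), names(y))
  diff_yx <- setdiff(names(y), names(x))
  if (length(diff_xy) > 0 || length(diff_yx) > 0) {
    stop("category sets differ; only in x: {",
         paste(diff_xy, collapse = ", "), "}; only in y: {",
         paste(diff_yx, collapse = ", "), "}", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 categories", call. = FALSE)
  y <- y[names(x)]
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  data.frame(layer_x = layers[1], layer_y = layers[2],
             kendall_tau = unname(ct$estimate),
             p_value = ct$p.value,
             n_categories = length(x),
             stringsAsFactors = FALSE)
}

#' Marker-gene transcript profiles per pathway
#'
#' Sums absolute transcript molecules over a pathway's marker ORF-groups,
#' per MAG and time point (replicate means), and overlays a cubic
#' polynomial smoothing of the log10 sums for display.
#'
#' @param mt_absolute Absolute MT table (`orfg_id`, `sample_id`,
#'   `molecules_sample`).
#' @param markers Named list: pathway label -> character vector of marker
#'   orfg ids.
#' @param catalog ORF catalog (for MAG assignment of ORF-groups).
#' @param samples Sample metadata (`sample_id`, `time_h`).
#' @return Data frame: pathway, mag_id, time_h, molecules (summed replicate
#'   means), smooth_log10 (cubic fit of log10 molecules, NA when < 4 time
#'   points). Unknown marker ids raise a warning and are counted in
#'   attribute `"n_unknown_markers"`.
#' @export
aggregate_pathway_markers <- function(mt_absolute, markers, catalog, samples) {
  orfg_mag <- tapply(catalog$mag_id, catalog$orfg_id_mt,
                     function(m) m[1])
  tab <- merge(mt_absolute, samples[, c("sample_id", "time_h")],
               by = "sample_id")
  n_unknown <- 0L
  out <- list()
  for (pw in names(markers)) {
    ids <- markers[[pw]]
    known <- ids %in% names(orfg_mag)
    if (any(!known)) {
      n_unknown <- n_unknown + sum(!known)
      warning(sum(!known), " unknown marker id(s) for pathway '", pw,
              "' skipped")
      ids <- ids[known]
    }
    if (length(ids) == 0) next
    sub <- tab[tab$orfg_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0) next
    sub$mag_id <- as.character(orfg_mag[sub$orfg_id])
    # replicate mean per ORFG x time, then sum over markers
    rep_mean <- stats::aggregate(
      list(molecules = sub$molecules_sample),
      by = list(orfg_id = sub$orfg_id, mag_id = sub$mag_id,
                time_h = sub$time_h),
      FUN = mean)
    prof <- stats::aggregate(
      list(molecules = rep_mean$molecules),
      by = list(mag_id = rep_mean$mag_id, time_h = rep_mean$time_h),
      FUN = sum)
    prof$pathway <- pw
    prof <- prof[order(prof$mag_id, prof$time_h), ]
    prof$smooth_log10 <- NA_real_
    for (mag in unique(prof$mag_id)) {
      idx <- which(prof$mag_id == mag)
      if (length(idx) >= 4) {
        t <- prof$time_h[idx]
        yl <- log10(prof$molecules[idx] + 1)
        cf <- stats::lm(yl ~ poly(t, 3, raw = TRUE))
        prof$smooth_log10[idx] <- unname(stats::fitted(cf))
      }
    }
    out[[pw]] <- prof[, c("pathway", "mag_id", "time_h", "molecules",
                          "smooth_log10")]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(pathway = character(0), mag_id = character(0),
                      time_h = numeric(0), molecules = numeric(0),
                      smooth_log10 = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "n_unknown_markers") <- n_unknown
  res
}
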