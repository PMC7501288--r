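#' Functional-category abundance per omic layer
#'
#' For the metagenome layer the abundance of a KO category is its ORF
#' count in the catalog; for the transcript or protein layer it is the sum
#' of absolute molecules over ORF-groups annotated with the category
#' (an ORF-group inherits the union of its members' terms).
#'
#' @param catalog ORF catalog with `ko_terms` (semicolon-separated).
#' @param abs_table Optional absolute table; `NULL` returns ORF counts
#'   (the MG layer).
#' @param value_col Column holding molecule counts
#'   (`"molecules_sample"` or `"copy_number"`).
#' @param orfg_col Catalog column naming the layer's ORF-group id.
#' @return Named numeric vector of category abundances.
#' @export
ko_category_abundance <- function(catalog, abs_table = NULL,
                                  value_col = "molecules_sample",
                                  orfg_col = "orfg_id_mt") {
  split_terms <- function(x) strsplit(x, ";", fixed = TRUE)
  if (is.null(abs_table)) {
    terms <- unlist(split_terms(catalog$ko_terms))
    terms <- terms[nzchar(terms)]
    tab <- table(terms)
    return(stats::setNames(as.numeric(tab), names(tab)))
  }
  orfg_terms <- tapply(catalog$ko_terms, catalog[[orfg_col]], function(x) {
    unique(unlist(split_terms(x)))
  })
  per_orfg <- tapply(abs_table[[value_col]], abs_table$orfg_id, sum)
  acc <- new.env(parent = emptyenv())
  for (g in names(per_orfg)) {
    for (term in orfg_terms[[g]]) {
      if (!nzchar(term)) next
      prev <- if (is.null(acc[[term]])) 0 else acc[[term]]
      acc[[term]] <- prev + per_orfg[[g]]
    }
  }
  vals <- unlist(as.list(acc))
  vals[order(names(vals))]
}

#' Run the full absolute multi-omics pipeline on a simulated community
#'
#' Orchestrates simulate -> quantify MT -> quantify MP -> integrate ->
#' dynamics and writes every stage table plus a run manifest under
#' `out_dir`. Outputs are bit-reproducible under a fixed seed (the
#' manifest timestamp aside).
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @param ratio_time_h Time point for the ratio summary (default 18 h,
#'   around exponential growth).
#' @param drop_samples Manual outlier sample ids for the integration step.
#' @param min_points Minimum matched ORFs per MAG x time cell for the
#'   monomial fits.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, ratio_time_h = 18,
                         drop_samples = character(0), min_points = 30) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  community <- run_stage("simulate", generate_community(config))
  mt_obs <- run_stage("simulate", simulate_mt_observation(community))
  mp_obs <- run_stage("simulate", simulate_mp_observation(community))
  data_dir <- file.path(out_dir, "data")
  run_stage("simulate", write_dataset(community, mt_obs, mp_obs, data_dir))

  mt <- run_stage("quantify-mt",
                  quantify_mt(mt_obs$mt_reads, mt_obs$spikein,
                              community$catalog,
                              aliquot_factor = config$aliquot_factor_mt))
  mp <- run_stage("quantify-mp",
                  quantify_mp(mp_obs$mp_lfq, mp_obs$peaks, mp_obs$bradford,
                              community$catalog))

  integ <- run_stage("integrate",
                     integrate_layers(mt$mt_absolute, mp$mp_absolute,
                                      community$catalog, community$samples,
                                      drop_samples = drop_samples))

  domains <- stats::setNames(
    vapply(split(community$catalog$domain_tag, community$catalog$mag_id),
           `[`, character(1), 1),
    names(split(community$catalog$domain_tag, community$catalog$mag_id)))

  dyn <- run_stage("dynamics", {
    ratios <- protein_rna_ratios(integ$paired, ratio_time_h,
                                 domains = domains)
    pcc <- genewise_pcc(integ$paired)
    fits <- fit_monomial_all(integ$paired, min_points = min_points)
    ktraj <- lapply(split(fits, fits$mag_id), function(d) {
      if (nrow(d) < 4) return(NULL)
      tr <- fit_k_trajectory(d$time_h, d$k, mag_id = d$mag_id[1])
      data.frame(mag_id = tr$mag_id, t(tr$coefficients),
                 time_min = tr$time_range[1], time_max = tr$time_range[2])
    })
    ktraj <- do.call(rbind, ktraj)
    mg <- ko_category_abundance(community$catalog)
    mt_ko <- ko_category_abundance(community$catalog, mt$mt_absolute,
                                   "molecules_sample", "orfg_id_mt")
    mp_ko <- ko_category_abundance(community$catalog, mp$mp_absolute,
                                   "copy_number", "orfg_id_mp")
    shared <- Reduce(intersect, list(names(mg), names(mt_ko), names(mp_ko)))
    rank_agree <- rbind(
      kendall_rank_preservation(mg[shared], mt_ko[shared], c("MG", "MT")),
      kendall_rank_preservation(mt_ko[shared], mp_ko[shared], c("MT", "MP")),
      kendall_rank_preservation(mg[shared], mp_ko[shared], c("MG", "MP")))
    list(ratios = ratios, pcc = pcc, fits = fits, ktraj = ktraj,
         rank_agreement = rank_agree)
  })

  comments <- c(paste0("absomics version: ",
                       as.character(utils::packageVersion("absomics"))),
                paste0("seed: ", config$seed))
  write_table(mt$mt_absolute[, c("orfg_id", "sample_id", "rpkm",
                                 "molecules_sample")],
              file.path(out_dir, "mt_absolute.tsv"), comments)
  write_table(mt$sample_summary, file.path(out_dir, "mt_sample_summary.tsv"),
              comments)
  write_table(mp$mp_absolute[, c("orfg_id", "sample_id", "copy_number")],
              file.path(out_dir, "mp_absolute.tsv"), comments)
  write_table(mp$sample_summary, file.path(out_dir, "mp_sample_summary.tsv"),
              comments)
  write_table(integ$paired, file.path(out_dir, "paired_expression.tsv"),
              comments)
  write_table(integ$filter_report, file.path(out_dir, "filter_report.tsv"),
              comments)
  write_table(dyn$ratios$summary, file.path(out_dir, "ratios.tsv"), comments)
  write_table(dyn$pcc$records, file.path(out_dir, "pcc.tsv"), comments)
  write_table(dyn$fits, file.path(out_dir, "monomial_fits.tsv"), comments)
  if (!is.null(dyn$ktraj)) {
    write_table(dyn$ktraj, file.path(out_dir, "k_trajectories.tsv"), comments)
  }
  write_table(dyn$rank_agreement, file.path(out_dir, "rank_agreement.tsv"),
              comments)

  manifest <- run_manifest(config, out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(community = community, mt = mt, mp = mp,
                 integration = integ, dynamics = dyn, manifest = manifest))
}

#' Build the run manifest for a pipeline output directory
#'
#' @param config The simulation/pipeline configuration.
#' @param out_dir Directory holding the stage outputs.
#' @return List: tool version, config hash, seed, per-file checksums and
#'   row counts, timestamp.
#' @export
run_manifest <- function(config, out_dir) {
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "mags")],
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  files <- list.files(out_dir, pattern = "\\.tsv$", recursive = TRUE,
                      full.names = TRUE)
  rows <- vapply(files, function(f) {
    sum(!startsWith(readLines(f, warn = FALSE), "#")) - 1L
  }, integer(1))
  list(
    tool = "absomics",
    version = as.character(utils::packageVersion("absomics")),
    seed = config$seed,
    config_hash = cfg_hash,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       rows = unname(rows)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
}
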