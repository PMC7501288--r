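#' Read a tab-separated table with schema validation
#'
#' Strict TSV reader used for every tabular file the pipeline touches.
#' Files are UTF-8, tab-delimited, "." decimal, with an optional block of
#' `#`-prefixed comment lines before the header (run metadata written by
#' [write_table()]).
#'
#' @param path Path to a TSV file.
#' @param schema Optional named character vector mapping required column
#'   names to types (`"character"`, `"numeric"`, `"integer"`, `"logical"`).
#'   Missing required columns are an error; extra columns are kept as
#'   character.
#' @return A `data.frame` with typed columns, row order preserved.
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  n_comment <- 0L
  while (n_comment < length(lines) && startsWith(lines[n_comment + 1L], "#")) {
    n_comment <- n_comment + 1L
  }
  df <- utils::read.delim(
    path,
    sep = "\t", header = TRUE, comment.char = "#",
    colClasses = "character", check.names = FALSE,
    stringsAsFactors = FALSE, na.strings = NULL,
    quote = "", fileEncoding = "UTF-8"
  )
  if (!is.null(schema)) {
    missing_cols <- setdiff(names(schema), names(df))
    if (length(missing_cols) > 0) {
      stop("missing required column(s) in ", path, ": ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (col in names(schema)) {
      df[[col]] <- .coerce_column(df[[col]], schema[[col]], col, path,
                                  line_offset = n_comment + 1L)
    }
  }
  df
}

.coerce_column <- function(x, type, col, path, line_offset) {
  out <- switch(type,
    character = x,
    numeric   = suppressWarnings(as.numeric(x)),
    integer   = suppressWarnings(as.integer(as.numeric(x))),
    logical   = suppressWarnings(as.logical(as.integer(x))),
    stop("unknown schema type: ", type, call. = FALSE)
  )
  bad <- which(is.na(out) & !(x %in% c("NA", "")))
  if (length(bad) > 0) {
    stop(sprintf("cannot parse column '%s' as %s in %s (line %d: '%s')",
                 col, type, path, bad[1] + line_offset, x[bad[1]]),
         call. = FALSE)
  }
  out
}

#' Write a tab-separated table with a comment header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param comments Optional character vector written as `# `-prefixed lines
#'   before the header (tool version, seed, config hash, ...).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, comments = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments) > 0) {
    writeLines(paste0("# ", comments), con)
  }
  utils::write.table(format(df, digits = 15, scientific = NA, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased. Duplicate ids are an error.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (any(is.na(ids)) || any(ids == "")) {
    stop("FASTA record with empty id in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty FASTA record in ", path, call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

# Column schemas for every file the pipeline reads or writes.
.schemas <- list(
  orf_catalog = c(orf_id = "character", mag_id = "character",
                  orfg_id_mt = "character", orfg_id_mp = "character",
                  length_nt = "numeric", mw_g_per_mol = "numeric",
                  ko_terms = "character"),
  mt_reads    = c(orfg_id = "character", sample_id = "character",
                  reads = "numeric", unique_hits = "numeric"),
  spikein     = c(sample_id = "character", I_M = "numeric",
                  I_Nt = "numeric", I_R = "numeric"),
  mp_lfq      = c(orfg_id = "character", sample_id = "character",
                  lfq = "numeric", unique_peptides = "numeric"),
  peaks       = c(sample_id = "character", peak_id = "character",
                  base_peak_intensity = "numeric", mass_da = "numeric",
                  identified = "integer"),
  bradford    = c(sample_id = "character", conc_g_per_l = "numeric",
                  volume_l = "numeric"),
  samples     = c(sample_id = "character", time_h = "numeric",
                  replicate = "character"),
  mt_absolute = c(orfg_id = "character", sample_id = "character",
                  rpkm = "numeric", molecules_sample = "numeric"),
  mp_absolute = c(orfg_id = "character", sample_id = "character",
                  copy_number = "numeric"),
  paired      = c(orf_id = "character", mag_id = "character",
                  time_h = "numeric", rna_molecules = "numeric",
                  protein_molecules = "numeric")
)

#' Table schema registry
#'
#' @param name One of the pipeline's table names (e.g. `"orf_catalog"`,
#'   `"mt_reads"`, `"spikein"`, `"mp_lfq"`, `"peaks"`, `"bradford"`,
#'   `"samples"`, `"mt_absolute"`, `"mp_absolute"`, `"paired"`).
#' @return Named character vector mapping column names to types.
#' @export
table_schema <- function(name) {
  if (!name %in% names(.schemas)) {
    stop("unknown table schema: ", name, call. = FALSE)
  }
  .schemas[[name]]
}
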