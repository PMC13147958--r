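#' Read a FASTA file of nucleotide sequences
#'
#' Strictly validated FASTA reader for spike-in references and feature
#' representative sequences. Sequences are uppercased and restricted to the
#' alphabet A, C, G, T, N; record ids are the token before the first
#' whitespace in the header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) sq_stop("io_error", "FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (anyDuplicated(ids))
    sq_stop("io_error", "duplicate FASTA id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    sq_stop("io_error", "empty sequence for record(s): %s",
            paste(ids[!nzchar(seqs)], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    sq_stop("io_error", "non-ACGTN character in record(s): %s",
            paste(ids[bad], collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a feature-by-sample count table
#'
#' The atomic container of the pipeline: a numeric matrix with unique feature
#' ids as rownames and unique sample ids as colnames, all entries
#' non-negative and finite. Counts read from disk are integers; the
#' simulator's diagnostic "expected" mode may hold non-integer expected
#' counts.
#'
#' @param counts Numeric matrix (features x samples) with dimnames.
#' @return A `feature_table` (a validated matrix).
#' @export
feature_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    sq_stop("validation_error", "feature table needs feature and sample ids")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    sq_stop("validation_error", "feature table needs >=1 feature and >=1 sample")
  if (anyDuplicated(rownames(counts)))
    sq_stop("validation_error", "duplicate feature ids: %s",
            paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                  collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    sq_stop("validation_error", "duplicate sample ids: %s",
            paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                  collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    sq_stop("validation_error", "counts must be finite and non-negative")
  class(counts) <- c("feature_table", class(counts))
  counts
}

#' Read a feature-by-sample count table from TSV
#'
#' Expects a tab-delimited file whose header row holds the sample ids and
#' whose first column holds the feature ids; `#` comment lines are ignored.
#' Every cell must parse as a non-negative integer; a non-integer or negative
#' cell is a hard error naming its row and column.
#'
#' @param path Path to the TSV file.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) sq_stop("io_error", "feature table not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, colClasses = "character",
                   quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    sq_stop("io_error", "feature table needs a feature-id column plus >=1 sample")
  fids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  ok <- grepl("^[0-9]+$", cells)
  if (!all(ok)) {
    bad <- arrayInd(which(!ok)[1L], dim(cells))
    sq_stop("io_error",
            "non-integer or negative count '%s' at feature '%s', sample '%s'",
            cells[bad[1L, 1L], bad[1L, 2L]], fids[bad[1L, 1L]],
            colnames(cells)[bad[1L, 2L]])
  }
  counts <- matrix(as.numeric(cells), nrow = nrow(cells),
                   dimnames = list(fids, colnames(cells)))
  feature_table(counts)
}

#' Write a feature/abundance matrix to TSV
#'
#' @param x Matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param id_col Header label for the id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_col = "feature_id") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse taxonomy lineage strings into the 7 canonical ranks
#'
#' Accepts both the prefixed dialect (`k__Bacteria;p__Firmicutes;...`) and
#' bare labels (`Bacteria;Firmicutes;...`). Prefixes are stripped, empty
#' slots become `"Unassigned"`, and every lineage is padded to exactly 7
#' ranks (domain, phylum, class, order, family, genus, species).
#'
#' @param lineages Character vector of `;`-separated lineage strings.
#' @return Character matrix with 7 columns named by rank.
#' @export
parse_lineage <- function(lineages) {
  out <- matrix("Unassigned", nrow = length(lineages), ncol = 7L,
                dimnames = list(NULL, TAX_RANKS))
  parts <- strsplit(lineages, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[A-Za-z]__", "", p)
    p[!nzchar(p)] <- "Unassigned"
    if (length(p) > 7L)
      sq_stop("validation_error", "lineage %d has %d ranks (max 7)", i, length(p))
    if (length(p)) out[i, seq_along(p)] <- p
  }
  out
}

#' Read a feature taxonomy table from TSV
#'
#' Two tab-separated columns: feature id and `;`-separated lineage string.
#'
#' @param path Path to the TSV file.
#' @return A `taxonomy_table` data.frame: `feature_id` plus the 7 ranks.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) sq_stop("io_error", "taxonomy file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, colClasses = "character",
                   quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    sq_stop("io_error", "taxonomy needs feature_id and lineage columns")
  taxonomy_table(df[[1L]], df[[2L]])
}

#' Build a taxonomy table from feature ids and lineage strings
#'
#' @param feature_id Character vector of feature ids.
#' @param lineage Character vector of lineage strings (same length).
#' @return A `taxonomy_table` data.frame.
#' @export
taxonomy_table <- function(feature_id, lineage) {
  if (anyDuplicated(feature_id))
    sq_stop("validation_error", "duplicate feature id(s) in taxonomy")
  out <- data.frame(feature_id = feature_id, parse_lineage(lineage),
                    stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

metadata_required_cols <- c("sample_id", "dose_id", "input_amount",
                            "input_unit", "elution_ul", "template_ul")

#' Read sample metadata from TSV
#'
#' Required columns: `sample_id`, `dose_id` (which spike-in dose was added),
#' `input_amount` and `input_unit` (`g` or `mL` of starting material),
#' `elution_ul` (DNA elution volume), `template_ul` (template volume carried
#' into PCR). Optional: `group` (experimental group label). Enforces
#' `input_amount > 0`, positive volumes, and `template_ul <= elution_ul`.
#'
#' @param path Path to the TSV file.
#' @return A `sample_metadata` data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) sq_stop("io_error", "metadata file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, quote = "", stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Validate a sample metadata data.frame
#'
#' @param df data.frame with the columns documented in [read_metadata()].
#' @return A validated `sample_metadata` data.frame.
#' @export
sample_metadata <- function(df) {
  missing <- setdiff(metadata_required_cols, colnames(df))
  if (length(missing))
    sq_stop("io_error", "metadata is missing required column(s): %s",
            paste(missing, collapse = ", "))
  for (col in c("input_amount", "elution_ul", "template_ul"))
    df[[col]] <- as.numeric(df[[col]])
  if (anyDuplicated(df$sample_id))
    sq_stop("validation_error", "duplicate sample id(s) in metadata")
  if (!all(df$input_unit %in% c("g", "mL")))
    sq_stop("validation_error", "input_unit must be 'g' or 'mL'")
  if (any(!is.finite(df$input_amount)) || any(df$input_amount <= 0))
    sq_stop("validation_error", "input_amount must be > 0")
  if (any(df$elution_ul <= 0) || any(df$template_ul <= 0))
    sq_stop("validation_error", "elution and template volumes must be > 0")
  bad <- df$template_ul > df$elution_ul
  if (any(bad))
    sq_stop("validation_error",
            "template_ul exceeds elution_ul for sample(s): %s",
            paste(df$sample_id[bad], collapse = ", "))
  if (is.null(df$group)) df$group <- NA_character_
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read a capillary-electrophoresis peak table from TSV
#'
#' Columns: `sample_id`, `peak_label` (`target` or `indicator`), `size_bp`,
#' `area`.
#'
#' @param path Path to the TSV file.
#' @return data.frame of peaks.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) sq_stop("io_error", "peak table not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, quote = "", stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "peak_label", "size_bp", "area"),
                     colnames(df))
  if (length(missing))
    sq_stop("io_error", "peak table is missing column(s): %s",
            paste(missing, collapse = ", "))
  if (!all(df$peak_label %in% c("target", "indicator")))
    sq_stop("validation_error", "peak_label must be 'target' or 'indicator'")
  df$size_bp <- as.numeric(df$size_bp)
  df$area <- as.numeric(df$area)
  if (any(!is.finite(df$area)) || any(df$area < 0))
    sq_stop("validation_error", "peak areas must be non-negative")
  df
}

write_tsv_df <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the full result bundle of a pipeline run
#'
#' Emits, under `out_dir`: the assignment report, the per-sample standard
#' curve table, absolute and relative feature tables, per-rank aggregated
#' tables, per-sample totals, the concordance report (when groups are
#' present) and the QC report as both TSV and JSON.
#'
#' @param res Result bundle from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- function(f) file.path(out_dir, f)
  write_tsv_df(res$assignment$assignments, p("assignment.tsv"))
  write_tsv_df(format_num_df(curve_table(res$curves)), p("standard_curves.tsv"))
  write_feature_table(format_num(res$absolute$copies), p("absolute_features.tsv"))
  write_feature_table(format_num(res$relative), p("relative_features.tsv"))
  totals <- data.frame(sample_id = colnames(res$absolute$copies),
                       total_reads = colSums(res$assignment$bio_table),
                       total_copies = format_num(colSums(res$absolute$copies)),
                       unit = res$absolute$unit, stringsAsFactors = FALSE)
  write_tsv_df(totals, p("totals.tsv"))
  if (!is.null(res$taxonomy)) {
    for (rank in TAX_RANKS) {
      write_feature_table(
        format_num(aggregate_rank(res$absolute$copies, res$taxonomy, rank)),
        p(sprintf("absolute_%s.tsv", rank)), id_col = "lineage")
      write_feature_table(
        format_num(aggregate_rank(res$relative, res$taxonomy, rank)),
        p(sprintf("relative_%s.tsv", rank)), id_col = "lineage")
    }
  }
  if (!is.null(res$concordance))
    write_tsv_df(format_num_df(res$concordance), p("concordance.tsv"))
  write_tsv_df(format_num_df(res$qc), p("qc_report.tsv"))
  jsonlite::write_json(res$qc, p("qc_report.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(list.files(out_dir, full.names = TRUE))
}

# deterministic decimal formatting so identical runs are byte-identical
format_num <- function(x) {
  if (is.matrix(x)) {
    out <- matrix(format_num(as.vector(x)), nrow = nrow(x),
                  dimnames = dimnames(x))
    return(out)
  }
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 12))
}

format_num_df <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_num)
  df
}
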