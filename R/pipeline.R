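#' Run the full absolute-quantification pipeline on input files
#'
#' Thin orchestration of the module functions: read and validate inputs,
#' assign features to spike-ins, fit per-sample standard curves, convert
#' the biological table to absolute copies, build relative and per-rank
#' aggregated tables, cross-validate relative vs absolute trends when
#' group labels are present, evaluate QC, and write the output bundle.
#' Samples whose calibration fails are flagged and emitted as missing
#' values; if no sample can be calibrated the run aborts with a classed
#' `pipeline_error`.
#'
#' @param table_path Feature-by-sample count TSV.
#' @param reps_path FASTA of feature representative sequences.
#' @param spikeins_path FASTA of spike-in reference sequences.
#' @param mix_path,dose_path Spike-in mix and dose definition TSVs.
#' @param metadata_path Sample metadata TSV.
#' @param taxonomy_path Optional taxonomy TSV.
#' @param out_dir Output directory.
#' @param threshold Assignment identity threshold (default 0.97).
#' @param min_reads Minimum reads for a calibration point (default 1).
#' @param thresholds QC thresholds from [qc_thresholds()].
#' @param exclude Optional feature ids to drop before calibration (host
#'   removal stand-in).
#' @param correct Apply the volumetric/mass correction from metadata
#'   (default TRUE); with FALSE values stay copies per template.
#' @return The result bundle, invisibly: assignment, curves, absolute,
#'   relative, taxonomy, concordance, qc, and written file paths.
#' @export
run_pipeline <- function(table_path, reps_path, spikeins_path, mix_path,
                         dose_path, metadata_path, taxonomy_path = NULL,
                         out_dir, threshold = 0.97, min_reads = 1,
                         thresholds = qc_thresholds(), exclude = NULL,
                         correct = TRUE) {
  table <- read_feature_table(table_path)
  reps <- read_fasta(reps_path)
  refs <- spikein_refs(read_fasta(spikeins_path),
                       identity_threshold = threshold)
  doses <- read_doses(mix_path, dose_path)
  meta <- read_metadata(metadata_path)
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path)

  assignment <- assign_features(reps, refs, table, threshold = threshold,
                                exclude = exclude)
  sample_dose <- setNames(meta$dose_id, meta$sample_id)
  curves <- fit_sample_curves(assignment$spike_counts, doses, sample_dose,
                              min_reads = min_reads)
  ok <- !vapply(curves, inherits, logical(1), "calibration_failure")
  if (!any(ok))
    sq_stop("pipeline_error",
            "no calibration points: no sample produced a usable standard curve")

  abs_tab <- absolute_table(assignment$bio_table, curves,
                            meta = if (correct) meta)
  rel_tab <- relative_table(assignment$bio_table)
  qc <- qc_report(curves, assignment, abs_tab, thresholds)

  conc <- NULL
  groups <- setNames(meta$group, meta$sample_id)
  if (sum(!is.na(unique(groups))) >= 2L) {
    use <- colnames(rel_tab)[!is.na(groups[colnames(rel_tab)]) &
                               colnames(rel_tab) %in%
                               setdiff(colnames(rel_tab), abs_tab$failed)]
    if (length(unique(groups[use])) >= 2L)
      conc <- concordance(rel_tab[, use, drop = FALSE],
                          abs_tab$copies[, use, drop = FALSE],
                          groups[use],
                          support = assignment$bio_table[, use, drop = FALSE])
  }

  res <- list(assignment = assignment, curves = curves, absolute = abs_tab,
              relative = rel_tab, taxonomy = taxonomy, concordance = conc,
              qc = qc, groups = groups)
  res$files <- write_outputs(res, out_dir)
  invisible(res)
}
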