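#' Default QC thresholds for calibration gating
#'
#' @param r2_warn Curve R-squared below which a sample is warned (0.95).
#' @param r2_fail Curve R-squared below which a sample fails (0.80).
#' @param min_points Minimum usable calibration points (3).
#' @param spike_fraction_range Acceptable window for the fraction of a
#'   sample's reads that are spike-in derived; outside it the dose was
#'   mismatched to the sample's biomass (default `[0.005, 0.30]`).
#' @param max_extrapolated Warn when more than this fraction of features
#'   fall outside the curve's calibrated read range (0.2).
#' @return List of thresholds.
#' @export
qc_thresholds <- function(r2_warn = 0.95, r2_fail = 0.80, min_points = 3L,
                          spike_fraction_range = c(0.005, 0.30),
                          max_extrapolated = 0.2) {
  list(r2_warn = r2_warn, r2_fail = r2_fail, min_points = min_points,
       spike_fraction_range = spike_fraction_range,
       max_extrapolated = max_extrapolated)
}

#' Evaluate one sample's calibration quality
#'
#' Pure function of its inputs: fail on calibration failure, low
#' R-squared, or too few points; warn on moderate R-squared, a spike-in
#' read fraction outside the configured window, or excessive extrapolation;
#' pass otherwise. Every reason is listed.
#'
#' @param curve A `standard_curve` or `calibration_failure`.
#' @param sample_id Sample identifier.
#' @param spike_fraction Spike-in reads / total reads for this sample.
#' @param extrapolated_fraction Fraction of biological features whose read
#'   count lies outside the curve's read range.
#' @param thresholds From [qc_thresholds()].
#' @return One-row data.frame (sample_id, status, r_squared, n_points,
#'   spike_read_fraction, dynamic_range_orders, extrapolated_feature_fraction,
#'   reasons).
#' @export
qc_evaluate <- function(curve, sample_id, spike_fraction,
                        extrapolated_fraction,
                        thresholds = qc_thresholds()) {
  reasons <- character(0)
  status <- "pass"
  warn <- function(msg) {
    reasons <<- c(reasons, msg)
    if (status == "pass") status <<- "warn"
  }
  fail <- function(msg) {
    reasons <<- c(reasons, msg)
    status <<- "fail"
  }
  r2 <- NA_real_; npts <- 0L; dyn <- NA_real_
  if (inherits(curve, "calibration_failure")) {
    fail(if (grepl("usable calibration point", curve$reason))
      "insufficient calibration points" else curve$reason)
  } else {
    r2 <- curve$r_squared
    npts <- curve$n_points
    dyn <- log10(curve$read_range[2L] / curve$read_range[1L])
    if (npts < thresholds$min_points) fail("insufficient calibration points")
    if (r2 < thresholds$r2_fail) fail(sprintf("r_squared %.3f below fail threshold", r2))
    else if (r2 < thresholds$r2_warn) warn(sprintf("r_squared %.3f below warn threshold", r2))
    if (!is.na(extrapolated_fraction) &&
        extrapolated_fraction > thresholds$max_extrapolated)
      warn(sprintf("%.0f%% of features extrapolated beyond curve range",
                   100 * extrapolated_fraction))
  }
  if (is.finite(spike_fraction) &&
      (spike_fraction < thresholds$spike_fraction_range[1L] ||
       spike_fraction > thresholds$spike_fraction_range[2L]))
    warn(sprintf("spike-in read fraction %.4f outside [%g, %g]",
                 spike_fraction, thresholds$spike_fraction_range[1L],
                 thresholds$spike_fraction_range[2L]))
  data.frame(sample_id = sample_id, status = status, r_squared = r2,
             n_points = npts, spike_read_fraction = spike_fraction,
             dynamic_range_orders = dyn,
             extrapolated_feature_fraction = extrapolated_fraction,
             reasons = paste(reasons, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' QC report over all samples of a run
#'
#' @param curves From [fit_sample_curves()].
#' @param assignment From [assign_features()].
#' @param abs_tab From [absolute_table()] (supplies extrapolation
#'   fractions); may be NULL.
#' @param thresholds From [qc_thresholds()].
#' @return data.frame with one row per sample.
#' @export
qc_report <- function(curves, assignment, abs_tab = NULL,
                      thresholds = qc_thresholds()) {
  spike_tot <- colSums(assignment$spike_counts)
  bio_tot <- colSums(assignment$bio_table)
  frac <- spike_tot / (spike_tot + bio_tot)
  rows <- lapply(names(curves), function(s) {
    ef <- if (!is.null(abs_tab)) abs_tab$extrapolated[[s]] else NA_real_
    qc_evaluate(curves[[s]], s, frac[[s]], ef, thresholds)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
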