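#' Fit a per-sample standard curve from spike-in reads and known copies
#'
#' Ordinary least squares of `log10(known copies)` on `log10(observed
#' reads)` over the spike-ins with at least `min_reads` reads. Regressing
#' copies on reads (rather than the reverse) makes the curve directly
#' predictive: converting a read count to copies needs no inversion.
#' Zero-read spike-ins are excluded, never imputed with pseudocounts, and
#' their ids are recorded.
#'
#' @param spike_reads Named numeric: spike-in id -> observed reads.
#' @param known_copies Named numeric: spike-in id -> copies added.
#' @param sample_id Sample identifier carried into the curve.
#' @param min_reads Minimum reads for a usable calibration point (default 1).
#' @return A `standard_curve`: `sample_id`, `slope`, `intercept`,
#'   `r_squared`, `n_points`, `read_range`, `excluded`, `min_reads`.
#'   Fewer than 3 usable points, or no spread in reads, raises a classed
#'   `calibration_error` so callers can flag the sample rather than lose it.
#' @export
fit_standard_curve <- function(spike_reads, known_copies, sample_id = NA,
                               min_reads = 1) {
  common <- intersect(names(spike_reads), names(known_copies))
  reads <- spike_reads[common]
  copies <- known_copies[common]
  used <- names(reads)[reads >= min_reads]
  excluded <- setdiff(common, used)
  if (length(used) < 3L)
    sq_stop("calibration_error",
            "sample %s: %d usable calibration point(s), need >= 3",
            sample_id, length(used))
  x <- log10(as.numeric(reads[used]))
  y <- log10(as.numeric(copies[used]))
  if (length(unique(x)) < 2L)
    sq_stop("calibration_error",
            "sample %s: all spike-in read counts identical, no curve",
            sample_id)
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res < 1e-20)
  structure(list(
    sample_id = sample_id,
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = r2,
    n_points = length(used),
    read_range = c(min(reads[used]), max(reads[used])),
    excluded = excluded,
    min_reads = min_reads), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve [%s]: log10(copies) = %.4f * log10(reads) + %.4f\n",
    x$sample_id, x$slope, x$intercept))
  cat(sprintf("  R^2 = %.6f over %d points, reads %g..%g\n",
              x$r_squared, x$n_points, x$read_range[1L], x$read_range[2L]))
  invisible(x)
}

#' Fit standard curves for every sample of a spike-in count matrix
#'
#' Calibration failures (too few usable points) do not abort: the failing
#' sample gets a `calibration_failure` record in the returned list so
#' downstream steps can emit missing values and the QC report can flag it.
#'
#' @param spike_counts Spike-in-by-sample read count matrix
#'   (from [assign_features()]).
#' @param doses Named list of `spikein_dose` (from [read_doses()]).
#' @param sample_dose Named character: sample id -> dose id.
#' @param min_reads Passed to [fit_standard_curve()].
#' @return Named list per sample: `standard_curve` or `calibration_failure`.
#' @export
fit_sample_curves <- function(spike_counts, doses, sample_dose,
                              min_reads = 1) {
  samples <- colnames(spike_counts)
  missing <- setdiff(samples, names(sample_dose))
  if (length(missing))
    sq_stop("validation_error", "no dose recorded for sample(s): %s",
            paste(missing, collapse = ", "))
  out <- lapply(samples, function(s) {
    dose <- doses[[sample_dose[[s]]]]
    if (is.null(dose))
      sq_stop("validation_error", "sample %s references unknown dose %s",
              s, sample_dose[[s]])
    tryCatch(
      fit_standard_curve(spike_counts[, s], dose$known_copies,
                         sample_id = s, min_reads = min_reads),
      calibration_error = function(e)
        structure(list(sample_id = s, reason = conditionMessage(e)),
                  class = "calibration_failure"))
  })
  setNames(out, samples)
}

#' Convert read counts to copy numbers through a standard curve
#'
#' Zero reads map to zero copies; positive reads map to
#' `10^(slope * log10(reads) + intercept)`. Predictions for read counts
#' outside the curve's calibrated read range are extrapolations and are
#' flagged in the `"extrapolated"` attribute of the result.
#'
#' @param curve A `standard_curve`.
#' @param reads Non-negative numeric vector of read counts.
#' @return Numeric vector of copies with a logical `"extrapolated"`
#'   attribute of the same length.
#' @export
predict_copies <- function(curve, reads) {
  if (!inherits(curve, "standard_curve"))
    sq_stop("validation_error", "predict_copies needs a standard_curve")
  if (any(reads < 0)) sq_stop("validation_error", "reads must be >= 0")
  copies <- ifelse(reads > 0,
                   10^(curve$slope * log10(reads) + curve$intercept), 0)
  extrap <- reads > 0 &
    (reads < curve$read_range[1L] | reads > curve$read_range[2L])
  attr(copies, "extrapolated") <- extrap
  copies
}

#' Volumetric/mass correction of template copy numbers
#'
#' A standard curve yields copies in the PCR template. Scaling by the
#' fraction of the DNA elution that went into the template and dividing by
#' the input material gives copies per gram (or per milliliter):
#' `copies * (elution_ul / template_ul) / input_amount`.
#'
#' @param copies Copies in the amplified template.
#' @param meta One row of a [sample_metadata()] data.frame.
#' @return Corrected copies with a `"unit"` attribute (`copies/g` or
#'   `copies/mL`).
#' @export
correct_concentration <- function(copies, meta) {
  if (!is.finite(meta$input_amount) || meta$input_amount <= 0)
    sq_stop("validation_error", "input_amount must be > 0")
  out <- copies * (meta$elution_ul / meta$template_ul) / meta$input_amount
  attr(out, "unit") <- paste0("copies/", meta$input_unit)
  out
}

#' Tabulate a list of per-sample curves and failures
#'
#' @param curves Result of [fit_sample_curves()].
#' @return data.frame with one row per sample (sample_id, slope, intercept,
#'   r_squared, n_points, min_reads_used, read_min, read_max, status).
#' @export
curve_table <- function(curves) {
  rows <- lapply(curves, function(cv) {
    if (inherits(cv, "calibration_failure"))
      data.frame(sample_id = cv$sample_id, slope = NA_real_,
                 intercept = NA_real_, r_squared = NA_real_,
                 n_points = 0L, min_reads_used = NA_real_,
                 read_min = NA_real_, read_max = NA_real_,
                 status = "failed", stringsAsFactors = FALSE)
    else
      data.frame(sample_id = cv$sample_id,
                 slope = cv$slope,
                 intercept = cv$intercept,
                 r_squared = cv$r_squared,
                 n_points = cv$n_points,
                 min_reads_used = cv$min_reads,
                 read_min = cv$read_range[1L], read_max = cv$read_range[2L],
                 status = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
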