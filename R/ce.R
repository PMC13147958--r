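#' Construct a capillary-electrophoresis peak set for one sample
#'
#' @param sample_id Sample identifier.
#' @param label Character vector, each `"target"` (sample amplicon) or
#'   `"indicator"` (spike-in amplicon).
#' @param size_bp Peak sizes in bases.
#' @param area Peak areas (arbitrary fluorescence units, >= 0).
#' @return A `peak_set` data.frame.
#' @export
peak_set <- function(sample_id, label, size_bp, area) {
  if (!all(label %in% c("target", "indicator")))
    sq_stop("validation_error", "peak labels must be 'target' or 'indicator'")
  if (any(!is.finite(area)) || any(area < 0))
    sq_stop("validation_error", "peak areas must be non-negative")
  out <- data.frame(sample_id = sample_id, peak_label = label,
                    size_bp = size_bp, area = area,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_set", "data.frame")
  out
}

ce_areas <- function(peaks, per_base = FALSE) {
  a <- peaks$area
  if (per_base) a <- a / peaks$size_bp
  c(indicator = sum(a[peaks$peak_label == "indicator"]),
    target = sum(a[peaks$peak_label == "target"]))
}

#' Spike-in proportion from CE peak areas
#'
#' Peak areas on a capillary instrument reflect molar quantities, so the
#' spike-in (indicator) proportion of the library is estimated directly as
#' `sum(indicator areas) / sum(all areas)`, with no length normalization by
#' default. `per_base = TRUE` divides each area by its peak size first, for
#' instruments whose signal scales with fragment mass instead of molarity.
#'
#' @param peaks A [peak_set()] with at least one indicator and one target
#'   peak.
#' @param per_base Normalize areas by peak size before ratioing.
#' @return Fraction in `[0, 1]`.
#' @export
spikein_proportion <- function(peaks, per_base = FALSE) {
  if (!any(peaks$peak_label == "indicator"))
    sq_stop("validation_error", "no indicator peak in peak set")
  if (!any(peaks$peak_label == "target"))
    sq_stop("validation_error", "no target peak in peak set")
  a <- ce_areas(peaks, per_base)
  if (sum(a) <= 0) sq_stop("validation_error", "all peak areas are zero")
  unname(a["indicator"] / sum(a))
}

#' Estimate target copies from the target-to-indicator peak ratio
#'
#' With the indicator (spike-in) amplicon at a known copy number, the
#' molar peak-area ratio converts directly:
#' `target_copies = indicator_copies * sum(target areas) / sum(indicator
#' areas)`.
#'
#' @param peaks A [peak_set()].
#' @param indicator_copies Known copies of the indicator amplicon (> 0).
#' @param per_base See [spikein_proportion()].
#' @return Estimated target copies.
#' @export
estimate_target_copies <- function(peaks, indicator_copies,
                                   per_base = FALSE) {
  if (!is.finite(indicator_copies) || indicator_copies <= 0)
    sq_stop("validation_error", "indicator_copies must be > 0")
  a <- ce_areas(peaks, per_base)
  if (a["indicator"] <= 0)
    sq_stop("validation_error", "indicator peak area is zero")
  unname(indicator_copies * a["target"] / a["indicator"])
}

#' Per-sample CE estimates from a peak table
#'
#' @param peak_df Peak table as read by [read_peak_table()].
#' @param indicator_copies Known indicator copies (recycled per sample).
#' @param per_base See [spikein_proportion()].
#' @return data.frame: sample_id, spikein_proportion, target_copies.
#' @export
ce_estimates <- function(peak_df, indicator_copies, per_base = FALSE) {
  rows <- lapply(split(peak_df, peak_df$sample_id), function(d) {
    ps <- peak_set(d$sample_id[1L], d$peak_label, d$size_bp, d$area)
    data.frame(sample_id = d$sample_id[1L],
               spikein_proportion = spikein_proportion(ps, per_base),
               target_copies = estimate_target_copies(ps, indicator_copies,
                                                      per_base),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
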