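#' Validated spike-in reference set
#'
#' Wraps a named vector of synthetic standard sequences. Lengths must fall in
#' the configured amplicon range; pairs of spike-ins whose mutual identity
#' reaches the assignment threshold are reported with a warning because they
#' could not be told apart during read assignment.
#'
#' @param seqs Named character vector of spike-in sequences.
#' @param min_len,max_len Allowed sequence length range in bases.
#' @param identity_threshold Assignment identity threshold used for the
#'   distinctness check.
#' @return A `spikein_refs` object (named character vector).
#' @export
spikein_refs <- function(seqs, min_len = 50L, max_len = 2000L,
                         identity_threshold = 0.97) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    sq_stop("validation_error", "spike-in ids must be present and unique")
  lens <- nchar(seqs)
  bad <- lens < min_len | lens > max_len
  if (any(bad))
    sq_stop("validation_error", "spike-in length outside [%d, %d] for: %s",
            min_len, max_len, paste(names(seqs)[bad], collapse = ", "))
  if (length(seqs) > 1L) {
    prs <- combn(length(seqs), 2L)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1L, j]; b <- prs[2L, j]
      if (seq_identity(seqs[[a]], seqs[[b]]) >= identity_threshold)
        warning(sprintf("spike-ins %s and %s are >= %.2f identical",
                        names(seqs)[a], names(seqs)[b], identity_threshold))
    }
  }
  structure(seqs, class = "spikein_refs")
}

#' Bundled synthetic spike-in reference set
#'
#' Six synthetic sequences (312-446 bases, GC 45-55%, pairwise identity
#' ~0.5) generated once with a fixed seed and shipped with the package. They
#' are a structural stand-in for a proprietary bacterial spike-in standard
#' mixture, not published reference sequences.
#'
#' @return A [spikein_refs()] object of 6 sequences.
#' @export
bundled_spikeins <- function() {
  path <- system.file("extdata", "spikein_refs_synthetic.fasta",
                      package = "spikequant", mustWork = TRUE)
  spikein_refs(read_fasta(path))
}

#' Define a spike-in mixture
#'
#' A mixture is a stock formulation (copies per microliter of each spike-in)
#' together with a dilution factor; the effective concentration of a mix is
#' `copies_per_ul / dilution_factor`, so a 10-fold serial dilution series
#' shares one stock formulation.
#'
#' @param mix_id Identifier.
#' @param copies_per_ul Named numeric vector, stock copies per microliter.
#' @param dilution_factor Positive number; 1 = undiluted stock.
#' @return A `spikein_mix` object.
#' @export
spikein_mix <- function(mix_id, copies_per_ul, dilution_factor = 1) {
  if (is.null(names(copies_per_ul)) || anyDuplicated(names(copies_per_ul)))
    sq_stop("validation_error", "mix concentrations need unique spike-in ids")
  if (any(!is.finite(copies_per_ul)) || any(copies_per_ul <= 0))
    sq_stop("validation_error", "all concentrations must be > 0")
  if (!is.finite(dilution_factor) || dilution_factor <= 0)
    sq_stop("validation_error", "dilution_factor must be > 0")
  structure(list(mix_id = mix_id, copies_per_ul = copies_per_ul,
                 dilution_factor = dilution_factor),
            class = "spikein_mix")
}

#' Effective concentration of a (possibly diluted) mix
#'
#' @param mix A [spikein_mix()].
#' @return Named numeric vector of copies per microliter after dilution.
#' @export
effective_concentration <- function(mix) {
  mix$copies_per_ul / mix$dilution_factor
}

#' Build a serial dilution series from a stock mix
#'
#' Step `k` has every effective concentration divided by `factor^k`; mix ids
#' are suffixed `_d<k>` deterministically.
#'
#' @param stock A [spikein_mix()].
#' @param n_steps Number of dilution steps (>= 1).
#' @param factor Fold dilution per step (> 1); 10 for a 10-fold series.
#' @return List of `spikein_mix`, one per step.
#' @export
build_serial_dilution <- function(stock, n_steps, factor = 10) {
  if (n_steps < 1L) sq_stop("validation_error", "n_steps must be >= 1")
  if (!is.finite(factor) || factor <= 1)
    sq_stop("validation_error", "dilution factor must be > 1")
  lapply(seq_len(n_steps), function(k) {
    spikein_mix(sprintf("%s_d%d", stock$mix_id, k), stock$copies_per_ul,
                dilution_factor = stock$dilution_factor * factor^k)
  })
}

#' Known copies delivered by adding a mix volume to a sample
#'
#' `known_copies[s] = copies_per_ul[s] * volume_ul / dilution_factor`,
#' exactly.
#'
#' @param mix A [spikein_mix()].
#' @param volume_ul Volume added, microliters (> 0).
#' @param dose_id Identifier; defaults to `<mix_id>_v<volume>`.
#' @return A `spikein_dose` with `known_copies` and their total.
#' @export
dose_for_sample <- function(mix, volume_ul,
                            dose_id = sprintf("%s_v%g", mix$mix_id, volume_ul)) {
  if (!is.finite(volume_ul) || volume_ul <= 0)
    sq_stop("validation_error", "volume_ul must be > 0")
  known <- effective_concentration(mix) * volume_ul
  structure(list(dose_id = dose_id, mix_id = mix$mix_id,
                 volume_ul = volume_ul, known_copies = known,
                 total_copies = sum(known)),
            class = "spikein_dose")
}

#' Read spike-in mix and dose definition tables
#'
#' The mix table has columns `mix_id`, `spikein_id`, `copies_per_ul`,
#' `dilution_factor`; the dose table has `dose_id`, `mix_id`, `volume_ul`.
#' Returns the known copies actually delivered by each dose.
#'
#' @param mix_path,dose_path Paths to the two TSV files.
#' @return Named list: `dose_id` -> [dose_for_sample()] result.
#' @export
read_doses <- function(mix_path, dose_path) {
  mixes_df <- read.delim(mix_path, sep = "\t", comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  doses_df <- read.delim(dose_path, sep = "\t", comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  need_m <- setdiff(c("mix_id", "spikein_id", "copies_per_ul",
                      "dilution_factor"), colnames(mixes_df))
  need_d <- setdiff(c("dose_id", "mix_id", "volume_ul"), colnames(doses_df))
  if (length(need_m) || length(need_d))
    sq_stop("io_error", "mix/dose table missing column(s): %s",
            paste(c(need_m, need_d), collapse = ", "))
  mixes <- lapply(split(mixes_df, mixes_df$mix_id), function(d) {
    if (length(unique(d$dilution_factor)) != 1L)
      sq_stop("validation_error", "mix %s has inconsistent dilution_factor",
              d$mix_id[1L])
    spikein_mix(d$mix_id[1L], setNames(d$copies_per_ul, d$spikein_id),
                d$dilution_factor[1L])
  })
  out <- lapply(seq_len(nrow(doses_df)), function(i) {
    m <- mixes[[doses_df$mix_id[i]]]
    if (is.null(m))
      sq_stop("validation_error", "dose %s references unknown mix %s",
              doses_df$dose_id[i], doses_df$mix_id[i])
    dose_for_sample(m, doses_df$volume_ul[i], dose_id = doses_df$dose_id[i])
  })
  setNames(out, doses_df$dose_id)
}

#' Write mix/dose definition tables for a set of doses
#'
#' @param doses Named list of `spikein_dose` objects.
#' @param mixes Named list of the `spikein_mix` objects they reference.
#' @param mix_path,dose_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_doses <- function(doses, mixes, mix_path, dose_path) {
  mix_rows <- do.call(rbind, lapply(mixes, function(m)
    data.frame(mix_id = m$mix_id, spikein_id = names(m$copies_per_ul),
               copies_per_ul = format_num(m$copies_per_ul),
               dilution_factor = format_num(as.double(m$dilution_factor)),
               stringsAsFactors = FALSE)))
  dose_rows <- do.call(rbind, lapply(doses, function(d)
    data.frame(dose_id = d$dose_id, mix_id = d$mix_id,
               volume_ul = format_num(as.double(d$volume_ul)),
               stringsAsFactors = FALSE)))
  write_tsv_df(mix_rows, mix_path)
  write_tsv_df(dose_rows, dose_path)
  invisible(c(mix_path, dose_path))
}
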