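#' Pairwise sequence identity
#'
#' Identity between two sequences is `1 - levenshtein(a, b) / max(len)`, the
#' edit distance normalized by the longer sequence, so it lies in `[0, 1]`
#' and equals 1 only for identical sequences.
#'
#' @param a,b Non-empty nucleotide sequences.
#' @return Identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b))
    sq_stop("validation_error", "sequences must be non-empty")
  1 - as.numeric(adist(a, b)) / max(nchar(a), nchar(b))
}

# k-mer count profile of one sequence
kmer_profile <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(table(character(0)))
  table(substring(seq, 1:(n - k + 1L), k:n))
}

# Lower bound on edit distance from k-mer profiles: one edit destroys at
# most k k-mers and creates at most k, so the L1 profile distance is <= 2k
# per edit and dist >= L1 / (2k). Used only to prove identity < threshold.
kmer_lower_bound <- function(prof_a, prof_b, k = 8L) {
  keys <- union(names(prof_a), names(prof_b))
  ca <- as.numeric(prof_a[keys]); ca[is.na(ca)] <- 0
  cb <- as.numeric(prof_b[keys]); cb[is.na(cb)] <- 0
  sum(abs(ca - cb)) / (2 * k)
}

#' Partition a feature table into spike-in and biological features
#'
#' Each feature's representative sequence is compared against every spike-in
#' reference; the feature is assigned to the spike-in of maximal identity
#' when that identity reaches `threshold` (ties broken by lexicographically
#' smallest spike-in id), otherwise it is biological. Reads of all features
#' assigned to a spike-in are summed into a spike-in-by-sample count matrix.
#' An optional exclusion list (e.g. host-derived features) removes features
#' from both partitions before calibration.
#'
#' @param reps Named character vector: feature id -> representative sequence.
#' @param refs A [spikein_refs()] set.
#' @param table A [feature_table()].
#' @param threshold Identity threshold in `(0.5, 1]`; default 0.97, the
#'   conventional OTU radius.
#' @param exclude Optional character vector of feature ids to drop (host
#'   removal stand-in).
#' @param prefilter Use the k-mer lower bound to skip alignments that
#'   provably cannot reach `threshold` (identical results, faster).
#' @return An `assignment_result`: `assignments` data.frame (feature_id,
#'   spikein_id, identity, disposition), `spike_counts` matrix,
#'   `bio_table`, and `excluded` (matrix or NULL).
#' @export
assign_features <- function(reps, refs, table, threshold = 0.97,
                            exclude = NULL, prefilter = TRUE) {
  if (threshold <= 0.5 || threshold > 1)
    sq_stop("validation_error", "threshold must be in (0.5, 1]")
  fids <- rownames(table)
  missing <- setdiff(fids, names(reps))
  if (length(missing))
    sq_stop("validation_error", "feature(s) without representative: %s",
            paste(missing, collapse = ", "))
  exclude <- intersect(exclude %||% character(0), fids)
  work <- setdiff(fids, exclude)
  ref_ids <- sort(names(refs))
  ref_seqs <- unclass(refs)[ref_ids]

  assigned <- setNames(rep(NA_character_, length(work)), work)
  identity <- setNames(rep(NA_real_, length(work)), work)
  k <- 8L
  ref_profs <- if (prefilter) lapply(ref_seqs, kmer_profile, k = k) else NULL
  for (f in work) {
    seq <- reps[[f]]
    cand <- ref_ids
    if (prefilter) {
      prof <- kmer_profile(seq, k = k)
      keep <- vapply(ref_ids, function(r) {
        maxlen <- max(nchar(seq), nchar(ref_seqs[[r]]))
        kmer_lower_bound(prof, ref_profs[[r]], k = k) <=
          (1 - threshold) * maxlen
      }, logical(1))
      cand <- ref_ids[keep]
    }
    if (!length(cand)) next
    d <- as.numeric(adist(seq, unlist(ref_seqs[cand])))
    ident <- 1 - d / pmax(nchar(seq), nchar(unlist(ref_seqs[cand])))
    best <- max(ident)
    if (best >= threshold) {
      # ties: candidates already in lexicographic order, take the first
      assigned[f] <- cand[which(ident == best)[1L]]
      identity[f] <- best
    }
  }

  spike_feats <- work[!is.na(assigned)]
  bio_feats <- work[is.na(assigned)]
  if (!length(bio_feats))
    sq_stop("validation_error", "no biological features remain after assignment")
  spike_counts <- matrix(0, nrow = length(ref_ids), ncol = ncol(table),
                         dimnames = list(ref_ids, colnames(table)))
  for (f in spike_feats)
    spike_counts[assigned[f], ] <- spike_counts[assigned[f], ] + table[f, ]

  disposition <- setNames(rep("biological", length(fids)), fids)
  disposition[spike_feats] <- "spikein"
  disposition[exclude] <- "excluded"
  assignments <- data.frame(
    feature_id = fids,
    spikein_id = ifelse(fids %in% work, assigned[fids], NA_character_),
    identity = ifelse(fids %in% work, identity[fids], NA_real_),
    disposition = disposition[fids],
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(
    assignments = assignments,
    spike_counts = spike_counts,
    bio_table = feature_table(table[bio_feats, , drop = FALSE]),
    excluded = if (length(exclude)) table[exclude, , drop = FALSE] else NULL,
    threshold = threshold), class = "assignment_result")
}
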