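#' Convert a biological feature table to absolute copy numbers
#'
#' Each cell is pushed through its sample's standard curve with
#' [predict_copies()]; when metadata is supplied the volumetric/mass
#' correction [correct_concentration()] is applied so the unit becomes
#' copies per gram (or per milliliter) of input material, otherwise values
#' stay as copies in the PCR template. Samples whose calibration failed
#' yield columns of `NA` — never zeros, which would silently claim absence.
#'
#' @param bio_table Biological [feature_table()] (spike-ins removed).
#' @param curves Named list from [fit_sample_curves()] covering every sample.
#' @param meta Optional [sample_metadata()]; must cover every sample when
#'   given.
#' @return An `absolute_table`: `copies` matrix, `unit`, per-sample
#'   `totals`, `extrapolated` fraction per sample, and `failed` sample ids.
#' @export
absolute_table <- function(bio_table, curves, meta = NULL) {
  samples <- colnames(bio_table)
  missing <- setdiff(samples, names(curves))
  if (length(missing))
    sq_stop("validation_error", "no curve or failure record for sample(s): %s",
            paste(missing, collapse = ", "))
  if (!is.null(meta)) {
    absent <- setdiff(samples, meta$sample_id)
    if (length(absent))
      sq_stop("validation_error", "sample(s) missing from metadata: %s",
              paste(absent, collapse = ", "))
  }
  copies <- matrix(NA_real_, nrow = nrow(bio_table), ncol = ncol(bio_table),
                   dimnames = dimnames(bio_table))
  extrap_frac <- setNames(rep(NA_real_, length(samples)), samples)
  unit <- "copies/template"
  for (s in samples) {
    cv <- curves[[s]]
    if (inherits(cv, "calibration_failure")) next
    vals <- predict_copies(cv, bio_table[, s])
    extrap_frac[s] <- mean(attr(vals, "extrapolated"))
    if (!is.null(meta)) {
      row <- meta[meta$sample_id == s, , drop = FALSE]
      vals <- correct_concentration(as.numeric(vals), row)
      unit <- attr(vals, "unit")
    }
    copies[, s] <- as.numeric(vals)
  }
  failed <- samples[vapply(curves[samples], inherits, logical(1),
                           "calibration_failure")]
  structure(list(copies = copies, unit = unit,
                 totals = colSums(copies),
                 extrapolated = extrap_frac,
                 failed = failed), class = "absolute_table")
}

#' Per-sample relative abundance
#'
#' @param bio_table A [feature_table()].
#' @return Matrix of per-sample fractions; every column sums to 1.
#' @export
relative_table <- function(bio_table) {
  tot <- colSums(bio_table)
  zero <- tot == 0
  if (any(zero))
    sq_stop("validation_error", "sample(s) with zero total reads: %s",
            paste(colnames(bio_table)[zero], collapse = ", "))
  sweep(unclass(bio_table), 2L, tot, "/")
}

#' Aggregate a feature-level table to one taxonomic rank
#'
#' Features sharing the full lineage prefix up to `rank` are summed; the
#' row id is that prefix joined with `;`, so two genera with the same name
#' under different families stay separate. A feature absent from the
#' taxonomy gets a fully Unassigned lineage with a warning rather than
#' being dropped, so per-sample sums are conserved at every rank.
#'
#' @param mat Feature-by-sample matrix (counts, copies, or fractions).
#' @param taxonomy A [taxonomy_table()].
#' @param rank One of domain, phylum, class, order, family, genus, species.
#' @return Aggregated matrix with lineage-prefix rownames.
#' @export
aggregate_rank <- function(mat, taxonomy, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  depth <- match(rank, TAX_RANKS)
  lin <- as.matrix(taxonomy[, TAX_RANKS, drop = FALSE])
  rownames(lin) <- taxonomy$feature_id
  fids <- rownames(mat)
  absent <- setdiff(fids, taxonomy$feature_id)
  if (length(absent)) {
    warning(sprintf("%d feature(s) missing from taxonomy, kept as Unassigned",
                    length(absent)))
    lin <- rbind(lin, matrix("Unassigned", nrow = length(absent), ncol = 7L,
                             dimnames = list(absent, TAX_RANKS)))
  }
  key <- apply(lin[fids, seq_len(depth), drop = FALSE], 1L, paste,
               collapse = ";")
  groups <- split(fids, key)
  out <- do.call(rbind, lapply(groups, function(f)
    colSums(mat[f, , drop = FALSE])))
  colnames(out) <- colnames(mat)
  out[order(rownames(out)), , drop = FALSE]
}

#' Cross-validate relative against absolute trends between groups
#'
#' For every taxon and ordered pair of group labels, the direction of the
#' between-group change (log2 fold change of arithmetic group means, with
#' `|log2FC| < flat_band` coded "flat") is computed in relative and in
#' absolute space. A taxon whose relative data call a direction that the
#' absolute data contradict is a compositional false positive and is
#' flagged `discordant`; a change visible only in absolute space is coded
#' `absolute_only` (the added value of spike-in calibration, not a false
#' positive); matching directions are `concordant`. When a read-count
#' `support` matrix is given, taxa with mean support below `min_support`
#' reads in either group are coded `low_support` and never flagged, since
#' their fold changes carry too much sampling noise for a direction call.
#'
#' @param rel Relative abundance matrix (taxa x samples).
#' @param absolute Absolute abundance matrix, same rows/columns.
#' @param groups Named character: sample id -> group label (>= 2 groups).
#' @param flat_band Half-width of the "flat" zone on the log2 scale.
#' @param support Optional read-count matrix matching `rel`.
#' @param min_support Minimum mean reads per sample per group for a
#'   direction call (used only when `support` is given).
#' @return A `concordance_report` data.frame, discordant taxa first.
#' @export
concordance <- function(rel, absolute, groups, flat_band = 0.25,
                        support = NULL, min_support = 20) {
  samples <- colnames(rel)
  if (!identical(colnames(absolute), samples) || !identical(rownames(absolute),
                                                       rownames(rel)))
    sq_stop("validation_error", "relative/absolute tables must align")
  groups <- groups[samples]
  if (any(is.na(groups)))
    sq_stop("validation_error", "every sample needs a group label")
  lv <- sort(unique(groups))
  if (length(lv) < 2L) sq_stop("validation_error", "need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < 1L)) sq_stop("validation_error", "empty group")

  direction <- function(l2fc) {
    ifelse(is.na(l2fc) | abs(l2fc) < flat_band, "flat",
           ifelse(l2fc > 0, "up", "down"))
  }
  gmean <- function(mat, g) rowMeans(mat[, groups == g, drop = FALSE])
  l2fc <- function(m1, m2) {
    out <- log2(m2 / m1)
    out[m1 == 0 & m2 == 0] <- 0          # absent in both: flat
    out
  }

  prs <- combn(lv, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    ga <- prs[1L, j]; gb <- prs[2L, j]
    rfc <- l2fc(gmean(rel, ga), gmean(rel, gb))
    afc <- l2fc(gmean(absolute, ga), gmean(absolute, gb))
    rd <- direction(rfc)
    ad <- direction(afc)
    status <- ifelse(rd == ad, "concordant",
                     ifelse(rd == "flat", "absolute_only", "discordant"))
    if (!is.null(support)) {
      sup_ok <- pmin(gmean(support, ga), gmean(support, gb)) >= min_support
      status[!sup_ok] <- "low_support"
    }
    data.frame(taxon = rownames(rel), group_a = ga, group_b = gb,
               rel_log2fc = rfc, abs_log2fc = afc,
               rel_direction = rd, abs_direction = ad,
               concordant = rd == ad, status = status,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$status != "discordant", out$taxon, out$group_a), ]
  rownames(out) <- NULL
  class(out) <- c("concordance_report", "data.frame")
  out
}
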