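#' Simulation configuration for the mock-community generator
#'
#' The generator emulates the data a spike-in calibrated amplicon run
#' produces: a log-normal mock community with optional per-group
#' multiplicative effects, a 10-fold serial-ladder spike-in dose added to
#' every sample, per-sequence capture efficiencies, and multinomial
#' sampling of each sample to a fixed read depth.
#'
#' @param n_taxa Number of biological taxa (default 200).
#' @param n_per_group Samples per group (default 6).
#' @param n_groups Number of groups (default 2).
#' @param depth Reads per sample (default 1e5).
#' @param mu,sigma Log-normal parameters of per-taxon template copies
#'   (default `log(1e4)`, 1.5).
#' @param n_spikeins Spike-ins in the ladder (default 6).
#' @param spike_base Copies of the lowest ladder rung per dose (1e3).
#' @param spike_fold Fold step between rungs (10).
#' @param sigma_eff Log-normal sd of per-sequence capture efficiency;
#'   0 means unbiased capture.
#' @param group_effects Optional `n_taxa x n_groups` matrix of
#'   multiplicative effects on copies (default: none).
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 200L, n_per_group = 6L, n_groups = 2L,
                       depth = 1e5, mu = log(1e4), sigma = 1.5,
                       n_spikeins = 6L, spike_base = 1e3, spike_fold = 10,
                       sigma_eff = 0, group_effects = NULL, seed) {
  if (missing(seed)) sq_stop("validation_error", "a seed is mandatory")
  vals <- c(n_taxa, n_per_group, n_groups, depth, sigma, n_spikeins,
            spike_base, spike_fold)
  if (any(!is.finite(vals)) || any(vals <= 0))
    sq_stop("validation_error", "all simulation sizes must be positive")
  if (sigma_eff < 0) sq_stop("validation_error", "sigma_eff must be >= 0")
  structure(list(n_taxa = as.integer(n_taxa),
                 n_per_group = as.integer(n_per_group),
                 n_groups = as.integer(n_groups), depth = depth, mu = mu,
                 sigma = sigma, n_spikeins = as.integer(n_spikeins),
                 spike_base = spike_base, spike_fold = spike_fold,
                 sigma_eff = sigma_eff, group_effects = group_effects,
                 seed = as.integer(seed)), class = "sim_config")
}

sim_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# nested hierarchy: species unique per taxon, 40 genera, 20 families, ...
sim_taxonomy <- function(taxa_ids) {
  n <- length(taxa_ids)
  genus <- ((seq_len(n) - 1L) %% 40L) + 1L
  family <- ((genus - 1L) %/% 2L) + 1L
  order <- ((family - 1L) %/% 2L) + 1L
  class <- ((order - 1L) %/% 2L) + 1L
  phylum <- ((class - 1L) %/% 2L) + 1L
  lineage <- sprintf(
    "k__Bacteria;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%02d;g__Genus%02d;s__Species%04d",
    phylum, class, order, family, genus, seq_len(n))
  taxonomy_table(taxa_ids, lineage)
}

#' Draw the ground truth of a simulated experiment
#'
#' Generates per-taxon template copies (log-normal, times any group
#' effect), the spike-in ladder dose, per-sequence efficiencies, sequences,
#' taxonomy and metadata — everything except the read counts. Deterministic
#' given the config seed.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list; see Details in [simulate_dataset()].
#' @export
sim_truth <- function(config) {
  sim_seed(config$seed)
  n <- config$n_taxa
  taxa_ids <- sprintf("ASV_%04d", seq_len(n))
  samples <- sprintf("S%03d", seq_len(config$n_per_group * config$n_groups))
  groups <- setNames(rep(sprintf("G%d", seq_len(config$n_groups)),
                         each = config$n_per_group), samples)

  base <- rlnorm(n, config$mu, config$sigma)
  eff_mat <- config$group_effects %||%
    matrix(1, nrow = n, ncol = config$n_groups)
  gidx <- match(groups, sort(unique(groups)))
  copies <- vapply(seq_along(samples),
                   function(i) base * eff_mat[, gidx[i]], numeric(n))
  dimnames(copies) <- list(taxa_ids, samples)

  bundled <- unclass(bundled_spikeins())
  if (config$n_spikeins <= length(bundled)) {
    spike_seqs <- bundled[seq_len(config$n_spikeins)]
  } else {
    extra <- config$n_spikeins - length(bundled)
    more <- setNames(vapply(seq_len(extra), function(i) random_seq(380L),
                            character(1)),
                     sprintf("SYNSPIKE%02d", length(bundled) + seq_len(extra)))
    spike_seqs <- c(bundled, more)
  }
  spike_ids <- names(spike_seqs)
  spike_copies <- setNames(
    config$spike_base * config$spike_fold^(seq_len(config$n_spikeins) - 1L),
    spike_ids)

  taxa_seqs <- setNames(vapply(seq_len(n), function(i) random_seq(300L),
                               character(1)), taxa_ids)
  efficiency <- setNames(
    if (config$sigma_eff > 0)
      rlnorm(n + config$n_spikeins, 0, config$sigma_eff)
    else rep(1, n + config$n_spikeins),
    c(taxa_ids, spike_ids))

  metadata <- sample_metadata(data.frame(
    sample_id = samples, dose_id = "D1", input_amount = 0.25,
    input_unit = "g", elution_ul = 100, template_ul = 2,
    group = unname(groups), stringsAsFactors = FALSE))

  structure(list(config = config, taxa_ids = taxa_ids,
                 spike_ids = spike_ids, sample_ids = samples,
                 groups = groups, copies = copies,
                 spike_copies = spike_copies, efficiency = efficiency,
                 taxa_seqs = taxa_seqs, spike_seqs = spike_seqs,
                 taxonomy = sim_taxonomy(taxa_ids), metadata = metadata),
            class = "sim_truth")
}

#' Scale one group's total biomass while a focal taxon stays fixed
#'
#' Constructs a ground-truth compositional artifact: every taxon of the
#' chosen group except the focal one is multiplied by `factor`. With
#' `factor < 1` the focal taxon's absolute abundance is unchanged but its
#' relative abundance rises — the discordance that spike-in calibration is
#' meant to expose. `factor = 1` leaves the truth untouched.
#'
#' @param truth A [sim_truth()].
#' @param group Group label whose biomass is scaled.
#' @param factor Positive scale factor.
#' @param focal Focal taxon id; default the taxon of largest mean copies
#'   (dominant taxa are where compositional artifacts bite).
#' @return Modified `sim_truth` with attributes `focal_taxon` and
#'   `biomass_factor`.
#' @export
inject_discordance <- function(truth, group, factor, focal = NULL) {
  if (!is.finite(factor) || factor <= 0)
    sq_stop("validation_error", "factor must be > 0")
  if (!group %in% truth$groups)
    sq_stop("validation_error", "unknown group '%s'", group)
  focal <- focal %||% truth$taxa_ids[which.max(rowMeans(truth$copies))]
  if (!focal %in% truth$taxa_ids)
    sq_stop("validation_error", "unknown focal taxon '%s'", focal)
  cols <- names(truth$groups)[truth$groups == group]
  rows <- setdiff(truth$taxa_ids, focal)
  truth$copies[rows, cols] <- truth$copies[rows, cols] * factor
  attr(truth, "focal_taxon") <- focal
  attr(truth, "biomass_factor") <- factor
  truth
}

#' Sample read counts from a simulation truth
#'
#' Per sample, reads are drawn multinomially over taxa plus spike-ins with
#' probabilities proportional to `copies x efficiency`, so column sums
#' equal the configured depth exactly. `mode = "expected"` returns the
#' (non-integer) expected counts `depth x p` instead — the noiseless
#' diagnostic regime in which calibration must recover copies exactly.
#' Spike-ins appear in the table as features named `SPKFEAT_*` whose
#' representative sequences equal the reference sequences.
#'
#' @param truth A [sim_truth()] (possibly after [inject_discordance()]).
#' @param mode `"multinomial"` (default) or `"expected"`.
#' @return A [feature_table()] over taxa and spike-in features.
#' @export
sim_counts <- function(truth, mode = c("multinomial", "expected")) {
  mode <- match.arg(mode)
  cfg <- truth$config
  if (cfg$depth <= 0) sq_stop("validation_error", "depth must be > 0")
  sim_seed(cfg$seed + 1L)
  spike_feats <- sub("^SYNSPIKE", "SPKFEAT_", truth$spike_ids)
  counts <- matrix(0, nrow = cfg$n_taxa + cfg$n_spikeins,
                   ncol = length(truth$sample_ids),
                   dimnames = list(c(truth$taxa_ids, spike_feats),
                                   truth$sample_ids))
  for (s in truth$sample_ids) {
    w <- c(truth$copies[, s], truth$spike_copies) * truth$efficiency
    p <- w / sum(w)
    counts[, s] <- if (mode == "multinomial")
      rmultinom(1L, size = cfg$depth, prob = p)
    else cfg$depth * p
  }
  feature_table(counts)
}

#' Simulate a complete spike-in calibrated dataset with ground truth
#'
#' Composes [sim_truth()] and [sim_counts()] and packages every input the
#' pipeline consumes: the count table (taxa plus spike-in features),
#' representative sequences, spike-in reference set, mix/dose definitions,
#' metadata, taxonomy, and the truth itself.
#'
#' @param config A [sim_config()].
#' @param mode Passed to [sim_counts()].
#' @return List with elements `truth`, `table`, `reps`, `refs`, `mix`,
#'   `dose`, `metadata`, `taxonomy`.
#' @export
simulate_dataset <- function(config, mode = "multinomial") {
  truth <- sim_truth(config)
  table <- sim_counts(truth, mode = mode)
  spike_feats <- sub("^SYNSPIKE", "SPKFEAT_", truth$spike_ids)
  reps <- c(truth$taxa_seqs,
            setNames(unname(truth$spike_seqs), spike_feats))
  volume_ul <- 2
  mix <- spikein_mix("MIX1", truth$spike_copies / volume_ul, 1)
  dose <- dose_for_sample(mix, volume_ul, dose_id = "D1")
  list(truth = truth, table = table, reps = reps,
       refs = spikein_refs(truth$spike_seqs), mix = mix, dose = dose,
       metadata = truth$metadata, taxonomy = truth$taxonomy)
}

#' Write a simulated dataset as the pipeline's input files
#'
#' @param sim From [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
sim_write <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "feature_table.tsv"),
             reps = file.path(dir, "rep_seqs.fasta"),
             spikeins = file.path(dir, "spikein_refs.fasta"),
             mix = file.path(dir, "spikein_mix.tsv"),
             dose = file.path(dir, "spikein_doses.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"))
  counts <- round(unclass(sim$table))
  storage.mode(counts) <- "integer"
  write_feature_table(counts, paths["table"])
  write_fasta(sim$reps, paths["reps"])
  write_fasta(unclass(sim$refs), paths["spikeins"])
  write_doses(list(D1 = sim$dose), list(MIX1 = sim$mix),
              paths["mix"], paths["dose"])
  meta <- sim$metadata
  meta$input_amount <- format_num(meta$input_amount)
  write_tsv_df(meta, paths["metadata"])
  tax <- data.frame(
    feature_id = sim$taxonomy$feature_id,
    lineage = apply(sim$taxonomy[, TAX_RANKS], 1L, paste, collapse = ";"),
    stringsAsFactors = FALSE)
  write_tsv_df(tax, paths["taxonomy"])
  invisible(paths)
}
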