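# Independent oracles used across tests. These deliberately avoid the code
# paths they check: edit distance is a plain dynamic program, least squares
# uses the closed-form sums.

# full DP Levenshtein distance; rows loop over `a`, columns vectorized over
# `b` with a cummin trick for the insertion closure
dp_edit_distance <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- 0:length(B)
  for (i in seq_along(A)) {
    subst <- prev[-length(prev)] + (A[i] != B)
    dele <- prev[-1] + 1
    v <- c(i, pmin(subst, dele))
    idx <- seq_along(v)
    v <- cummin(v - idx) + idx   # v[j] = min(v[j], v[j-1] + 1), left to right
    prev <- v
  }
  prev[length(prev)]
}

dp_identity <- function(a, b) 1 - dp_edit_distance(a, b) / max(nchar(a), nchar(b))

# closed-form simple linear regression of y on x
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = sxy^2 / (sxx * syy))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# small simulated dataset used by several suites
small_sim <- function(seed = 11L, ...) {
  simulate_dataset(sim_config(n_taxa = 40L, n_per_group = 3L, depth = 2e4,
                              seed = seed, ...))
}

# run assignment + calibration + quantification on a simulate_dataset() result
quantify_sim <- function(sim, meta = NULL) {
  a <- assign_features(sim$reps, sim$refs, sim$table)
  cv <- fit_sample_curves(a$spike_counts, list(D1 = sim$dose),
                          setNames(sim$metadata$dose_id,
                                   sim$metadata$sample_id))
  list(assignment = a, curves = cv,
       absolute = absolute_table(a$bio_table, cv, meta = meta),
       relative = relative_table(a$bio_table))
}
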