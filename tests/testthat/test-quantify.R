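curve_1_2 <- function(sample_id) {
  fit_standard_curve(c(A = 10, B = 100, C = 1000),
                     c(A = 1e3, B = 1e4, C = 1e5), sample_id = sample_id)
}

test_that("absolute_table composes prediction and correction per cell", {
  bio <- feature_table(matrix(c(50, 0), 2, 1,
                              dimnames = list(c("f1", "f2"), "s1")))
  abst <- absolute_table(bio, list(s1 = curve_1_2("s1")))
  expect_equal(abst$copies["f1", "s1"], 5000)
  expect_equal(abst$copies["f2", "s1"], 0)
  expect_identical(abst$unit, "copies/template")
  expect_equal(abst$totals[["s1"]], 5000)

  meta <- sample_metadata(data.frame(
    sample_id = "s1", dose_id = "D1", input_amount = 0.25, input_unit = "g",
    elution_ul = 100, template_ul = 2))
  abst_g <- absolute_table(bio, list(s1 = curve_1_2("s1")), meta = meta)
  expect_equal(abst_g$copies["f1", "s1"], 5000 * (100 / 2) / 0.25)
  expect_identical(abst_g$unit, "copies/g")
})

test_that("failed-curve samples yield missing values, never zeros", {
  bio <- feature_table(matrix(c(50, 20, 7, 3), 2, 2,
                              dimnames = list(c("f1", "f2"), c("s1", "s2"))))
  curves <- list(s1 = curve_1_2("s1"),
                 s2 = structure(list(sample_id = "s2", reason = "too few"),
                                class = "calibration_failure"))
  abst <- absolute_table(bio, curves)
  expect_true(all(is.na(abst$copies[, "s2"])))
  expect_false(anyNA(abst$copies[, "s1"]))
  expect_identical(abst$failed, "s2")
  expect_error(absolute_table(bio, curves["s1"]), "s2",
               class = "validation_error")
})

test_that("quantified copies preserve the within-sample feature ranking", {
  sim <- small_sim(seed = 19)
  q <- quantify_sim(sim)
  for (s in colnames(q$absolute$copies))
    expect_identical(order(q$absolute$copies[, s]),
                     order(q$assignment$bio_table[, s]))
})

test_that("relative_table normalizes columns to exactly 1", {
  bio <- feature_table(matrix(c(25, 75, 10, 0), 2, 2,
                              dimnames = list(c("f1", "f2"), c("s1", "s2"))))
  rel <- relative_table(bio)
  expect_equal(rel[, "s1"], c(f1 = 0.25, f2 = 0.75))
  expect_equal(rel["f1", "s2"], 1.0)
  set.seed(3)
  big <- feature_table(matrix(rpois(600, 7) + 1, 60, 10,
                              dimnames = list(sprintf("f%02d", 1:60),
                                              sprintf("s%02d", 1:10))))
  expect_true(all(abs(colSums(relative_table(big)) - 1) < 1e-12))
  zero <- feature_table(matrix(c(1, 0), 1, 2,
                               dimnames = list("f1", c("a", "b"))))
  expect_error(relative_table(zero), "b", class = "validation_error")
})

test_that("rank aggregation groups by lineage prefix and conserves sums", {
  tax <- taxonomy_table(
    c("f1", "f2", "f3"),
    c("k__B;p__F;c__X;o__O;f__L;g__Lactobacillus;s__a",
      "k__B;p__F;c__X;o__O;f__L;g__Lactobacillus;s__b",
      "k__B;p__F;c__X;o__O;f__L;g__Streptococcus;s__c"))
  m <- matrix(c(100, 200, 50), 3, 1, dimnames = list(c("f1","f2","f3"), "s1"))
  gen <- aggregate_rank(m, tax, "genus")
  expect_equal(gen[grep("Lactobacillus", rownames(gen)), "s1"], 300)
  expect_equal(colSums(gen), colSums(m))

  # species-level aggregation then summing equals the feature-level sum
  expect_equal(colSums(aggregate_rank(m, tax, "species")), colSums(m))

  # a feature missing from taxonomy is kept as Unassigned, with a warning
  m2 <- rbind(m, f4 = 10)
  expect_warning(ph <- aggregate_rank(m2, tax, "phylum"), "Unassigned")
  expect_equal(colSums(ph), colSums(m2))
  expect_true("Unassigned;Unassigned" %in% rownames(ph))
  expect_equal(ph["Unassigned;Unassigned", "s1"], 10)
})

test_that("aggregation conserves per-sample sums at all 7 ranks on random tables", {
  sim <- small_sim(seed = 23)
  q <- quantify_sim(sim)
  for (rank in c("domain", "phylum", "class", "order", "family", "genus",
                 "species")) {
    agg_c <- aggregate_rank(unclass(q$assignment$bio_table), sim$taxonomy, rank)
    expect_equal(colSums(agg_c), colSums(q$assignment$bio_table))
    agg_a <- aggregate_rank(q$absolute$copies, sim$taxonomy, rank)
    expect_equal(colSums(agg_a), q$absolute$totals, tolerance = 1e-9)
  }
})

test_that("concordance codes the compositional artifact analytically", {
  # group B: total biomass halves while minor taxon t1 stays constant
  taxa <- c("t1", "t2", "t3")
  absA <- c(50, 475, 475); absB <- c(50, 237.5, 237.5)
  mabs <- cbind(a1 = absA, a2 = absA, b1 = absB, b2 = absB)
  rownames(mabs) <- taxa
  mrel <- sweep(mabs, 2, colSums(mabs), "/")
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  rep_ <- concordance(mrel, mabs, groups)
  r1 <- rep_[rep_$taxon == "t1", ]
  expect_identical(r1$rel_direction, "up")
  expect_identical(r1$abs_direction, "flat")
  expect_identical(r1$status, "discordant")
  expect_false(r1$concordant)
  # the scaled taxa change in absolute space only
  expect_identical(rep_[rep_$taxon == "t2", "status"], "absolute_only")
  # discordant rows come first
  expect_identical(rep_$status[1], "discordant")
})

test_that("equal total biomass makes every taxon concordant", {
  set.seed(13)
  mabs <- matrix(rlnorm(40, 5, 1), 10, 4,
                 dimnames = list(paste0("t", 1:10), paste0("s", 1:4)))
  mabs <- sweep(mabs, 2, colSums(mabs), "/") * 1e6   # equal totals
  mrel <- sweep(mabs, 2, colSums(mabs), "/")
  groups <- setNames(c("A", "A", "B", "B"), colnames(mabs))
  rep_ <- concordance(mrel, mabs, groups)
  expect_true(all(rep_$concordant))
  expect_true(all(rep_$status == "concordant"))
  expect_error(concordance(mrel, mabs, groups[1:2]), class = "validation_error")
})

test_that("relative is scale-invariant and absolute is spike-equivariant", {
  sim <- small_sim(seed = 29)
  q <- quantify_sim(sim)
  # uniform scaling of a sample's counts leaves its relative column unchanged
  scaled <- unclass(q$assignment$bio_table)
  scaled[, 1] <- scaled[, 1] * 7
  expect_equal(relative_table(feature_table(scaled))[, 1], q$relative[, 1])
  # scaling all known spike copies by c scales recovered copies by c
  dose10 <- sim$dose
  dose10$known_copies <- dose10$known_copies * 10
  cv10 <- fit_sample_curves(q$assignment$spike_counts, list(D1 = dose10),
                            setNames(sim$metadata$dose_id,
                                     sim$metadata$sample_id))
  abs10 <- absolute_table(q$assignment$bio_table, cv10)
  expect_equal(abs10$copies, q$absolute$copies * 10, tolerance = 1e-9)
})
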