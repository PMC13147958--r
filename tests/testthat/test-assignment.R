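test_that("sequence identity matches hand values and the DP oracle", {
  expect_equal(seq_identity("ACGT", "ACGT"), 1.0)
  expect_equal(seq_identity("ACGT", "ACGA"), 0.75)
  expect_error(seq_identity("", "ACGT"), "non-empty",
               class = "validation_error")

  set.seed(31)
  for (i in 1:10) {
    a <- rand_seq(300)
    # two-substitution mutant: identity 1 - 2/300
    pos <- sample(300, 2)
    b <- strsplit(a, "")[[1]]
    for (p in pos) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
    b <- paste(b, collapse = "")
    expect_equal(seq_identity(a, b), 1 - 2 / 300)
    expect_equal(seq_identity(a, b), dp_identity(a, b))
  }
  # indel mutants against the DP oracle
  for (i in 1:10) {
    a <- rand_seq(80)
    b <- rand_seq(77)
    expect_equal(seq_identity(a, b), dp_identity(a, b))
  }
})

make_tbl <- function(fids, nsample = 2) {
  feature_table(matrix(seq_len(length(fids) * nsample) * 10,
                       nrow = length(fids), ncol = nsample,
                       dimnames = list(fids, paste0("s", seq_len(nsample)))))
}

test_that("features at or above threshold go to the best spike-in, ties to the smallest id", {
  set.seed(41)
  r1 <- rand_seq(300); r2 <- rand_seq(300)
  refs <- spikein_refs(c(S2 = r2, S1 = r1))
  mut <- function(s, k) {       # k substitutions
    v <- strsplit(s, "")[[1]]
    for (p in sample(length(v), k)) v[p] <- setdiff(c("A","C","G","T"), v[p])[1]
    paste(v, collapse = "")
  }
  reps <- c(f_exact = r1, f_near = mut(r2, 3), f_far = mut(r1, 90),
            f_bio = rand_seq(300))
  tbl <- make_tbl(names(reps))
  res <- assign_features(reps, refs, tbl, threshold = 0.97)
  asg <- setNames(res$assignments$spikein_id, res$assignments$feature_id)
  expect_identical(asg[["f_exact"]], "S1")
  expect_identical(asg[["f_near"]], "S2")
  expect_true(is.na(asg[["f_far"]]))       # ~0.70 identity: biological
  expect_true(is.na(asg[["f_bio"]]))
  expect_equal(res$assignments$identity[res$assignments$feature_id == "f_exact"], 1.0)

  # exact tie: rep identical to two identical-length refs
  refs_tie <- spikein_refs(c(SB = r1, SA = r1),
                           identity_threshold = 1.01)  # silence pair warning
  res_tie <- assign_features(c(f1 = r1, f_bio = reps[["f_bio"]]), refs_tie,
                             make_tbl(c("f1", "f_bio")))
  expect_identical(
    res_tie$assignments$spikein_id[res_tie$assignments$feature_id == "f1"],
    "SA")
})

test_that("assignment errors on missing representatives and conserves reads", {
  set.seed(43)
  refs <- spikein_refs(setNames(replicate(2, rand_seq(310)), c("S1", "S2")))
  tbl <- make_tbl(c("f1", "f2", "f3"), nsample = 3)
  reps <- c(f1 = unclass(refs)[["S1"]], f2 = rand_seq(300), f3 = rand_seq(300))
  expect_error(assign_features(reps[1:2], refs, tbl), "f3",
               class = "validation_error")

  res <- assign_features(reps, refs, tbl)
  expect_equal(colSums(res$spike_counts) + colSums(res$bio_table),
               colSums(tbl))
  # every feature appears exactly once across the partition
  expect_setequal(
    c(res$assignments$feature_id[res$assignments$disposition == "spikein"],
      rownames(res$bio_table)),
    rownames(tbl))

  # exclusion list removes features but keeps accounting explicit
  res_ex <- assign_features(reps, refs, tbl, exclude = "f2")
  expect_identical(rownames(res_ex$excluded), "f2")
  expect_equal(colSums(res_ex$spike_counts) + colSums(res_ex$bio_table) +
                 colSums(res_ex$excluded), colSums(tbl))
})

test_that("k-mer prefilter never changes the assignment", {
  set.seed(47)
  refs <- spikein_refs(setNames(replicate(3, rand_seq(320)), c("S1", "S2", "S3")))
  reps <- c(setNames(replicate(8, rand_seq(300)), paste0("b", 1:8)),
            hit = unclass(refs)[["S2"]])
  tbl <- make_tbl(names(reps))
  with_pf <- assign_features(reps, refs, tbl, prefilter = TRUE)
  without <- assign_features(reps, refs, tbl, prefilter = FALSE)
  expect_identical(with_pf$assignments, without$assignments)
})

test_that("raising the threshold never assigns more features", {
  set.seed(53)
  refs <- spikein_refs(setNames(replicate(3, rand_seq(300)), c("S1", "S2", "S3")))
  mutn <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (p in sample(length(v), k)) v[p] <- setdiff(c("A","C","G","T"), v[p])[1]
    paste(v, collapse = "")
  }
  reps <- setNames(c(sapply(c(0, 2, 5, 9, 15, 40), function(k)
    mutn(unclass(refs)[["S1"]], k)), rand_seq(300)), paste0("f", 1:7))
  tbl <- make_tbl(names(reps))
  n_assigned <- sapply(c(0.9, 0.95, 0.97, 0.99, 1.0), function(th)
    sum(assign_features(reps, refs, tbl, threshold = th)$assignments$disposition
        == "spikein"))
  expect_true(all(diff(n_assigned) <= 0))
})
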