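test_that("exact log-linear points give slope 1, intercept 2, R^2 1", {
  cv <- fit_standard_curve(c(A = 10, B = 100, C = 1000),
                           c(A = 1e3, B = 1e4, C = 1e5), sample_id = "s")
  expect_equal(cv$slope, 1.0)
  expect_equal(cv$intercept, 2.0)
  expect_equal(cv$r_squared, 1.0)
  expect_equal(cv$n_points, 3L)
  expect_equal(cv$read_range, c(10, 1000))
})

test_that("too few usable points or degenerate reads raise calibration_error", {
  expect_error(fit_standard_curve(c(A = 10, B = 100), c(A = 1e3, B = 1e4)),
               "need >= 3", class = "calibration_error")
  # zero-read spike-ins are excluded, not imputed
  expect_error(
    fit_standard_curve(c(A = 10, B = 100, C = 0), c(A = 1e3, B = 1e4, C = 1e5)),
    class = "calibration_error")
  expect_error(
    fit_standard_curve(c(A = 7, B = 7, C = 7), c(A = 1e3, B = 1e4, C = 1e5)),
    "identical", class = "calibration_error")
  cv <- fit_standard_curve(c(A = 10, B = 100, C = 1000, D = 0),
                           c(A = 1e3, B = 1e4, C = 1e5, D = 1e6))
  expect_identical(cv$excluded, "D")
  expect_equal(cv$n_points, 3L)
})

test_that("fit agrees with the closed-form least-squares oracle on noisy points", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    reads <- sort(10^runif(n, 0.5, 5))
    copies <- 10^(runif(1, 0.8, 1.2) * log10(reads) + runif(1, 1, 3) +
                    rnorm(n, 0, 0.1))
    names(reads) <- names(copies) <- paste0("S", seq_len(n))
    cv <- fit_standard_curve(reads, copies)
    o <- ols_oracle(log10(reads), log10(copies))
    expect_equal(cv$slope, o$slope, tolerance = 1e-10)
    expect_equal(cv$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(cv$r_squared, o$r_squared, tolerance = 1e-10)
  }
})

test_that("fit is invariant to the insertion order of spike-in points", {
  reads <- c(A = 12, B = 130, C = 900, D = 11000, E = 98000)
  copies <- c(A = 1e3, B = 1e4, C = 1e5, D = 1e6, E = 1e7)
  cv1 <- fit_standard_curve(reads, copies)
  perm <- c("D", "A", "E", "C", "B")
  cv2 <- fit_standard_curve(reads[perm], copies[perm])
  expect_equal(cv1$slope, cv2$slope)
  expect_equal(cv1$intercept, cv2$intercept)
  expect_equal(cv1$r_squared, cv2$r_squared)
})

test_that("predict_copies maps reads through the curve and flags extrapolation", {
  cv <- fit_standard_curve(c(A = 10, B = 100, C = 1000),
                           c(A = 1e3, B = 1e4, C = 1e5))
  p <- predict_copies(cv, 50)
  expect_equal(as.numeric(p), 5000)
  expect_false(attr(p, "extrapolated"))

  p0 <- predict_copies(cv, 0)
  expect_equal(as.numeric(p0), 0)
  expect_false(attr(p0, "extrapolated"))

  phi <- predict_copies(cv, 5000)   # above read_range max
  expect_true(attr(phi, "extrapolated"))
  plo <- predict_copies(cv, 2)
  expect_true(attr(plo, "extrapolated"))

  # strictly increasing in reads for positive slope
  reads <- c(0, 1, 3, 10, 400, 1e4)
  expect_true(all(diff(as.numeric(predict_copies(cv, reads))) > 0))
})

test_that("perfectly proportional reads recover copies exactly", {
  copies <- c(A = 1e3, B = 1e4, C = 1e5, D = 1e6, E = 1e7, F = 1e8)
  reads <- copies * 8.3e-4
  cv <- fit_standard_curve(reads, copies)
  expect_equal(cv$slope, 1.0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1.0, tolerance = 1e-12)
  back <- as.numeric(predict_copies(cv, reads))
  expect_equal(back, unname(copies), tolerance = 1e-9)
})

test_that("volumetric/mass correction scales as elution/template/input", {
  meta <- sample_metadata(data.frame(
    sample_id = "s", dose_id = "D", input_amount = 0.25, input_unit = "g",
    elution_ul = 100, template_ul = 2))
  out <- correct_concentration(1e6, meta)
  expect_equal(as.numeric(out), 2e8)
  expect_identical(attr(out, "unit"), "copies/g")

  ident <- sample_metadata(data.frame(
    sample_id = "s", dose_id = "D", input_amount = 1, input_unit = "mL",
    elution_ul = 50, template_ul = 50))
  expect_equal(as.numeric(correct_concentration(123.4, ident)), 123.4)

  # doubling template volume halves the result
  meta2 <- meta; meta2$template_ul <- 4
  expect_equal(as.numeric(correct_concentration(1e6, meta2)),
               as.numeric(correct_concentration(1e6, meta)) / 2)
})

test_that("fit_sample_curves records failures instead of dropping samples", {
  spike_counts <- matrix(c(10, 100, 1000, 5, 0, 0),
                         nrow = 3, dimnames = list(c("A", "B", "C"),
                                                   c("good", "bad")))
  dose <- dose_for_sample(spikein_mix("M", c(A = 500, B = 5000, C = 50000)), 2,
                          dose_id = "D1")
  cvs <- fit_sample_curves(spike_counts, list(D1 = dose),
                           c(good = "D1", bad = "D1"))
  expect_s3_class(cvs$good, "standard_curve")
  expect_s3_class(cvs$bad, "calibration_failure")
  tab <- curve_table(cvs)
  expect_identical(tab$status, c("ok", "failed"))
})
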