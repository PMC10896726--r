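test_that("reference scaling is the identity for a single batch", {
  meta <- toy_meta(n_batches = 1)
  m <- toy_study_matrix(meta)
  out <- reference_scale_normalize(m, meta, reference_scheme("batch_mean"))
  expect_equal(out$values, m$values, tolerance = 1e-12)
})

test_that("reference scaling removes a pure multiplicative batch factor exactly", {
  # one peak; batch1 = {1, 3}, batch2 = {3, 9}: R = 4, C1 = 2, C2 = 6
  meta <- sample_meta(data.frame(
    sample_id = c("b1s1", "b1s2", "b2s1", "b2s2"),
    batch = c("B1", "B1", "B2", "B2"),
    timepoint_days = c(0, 5, 0, 5), replicate = 1, role = "treated"))
  v <- matrix(c(1, 3, 3, 9), 1, 4,
              dimnames = list("peak", meta$sample_id))
  out <- reference_scale_normalize(omics_matrix(v, "metabolite", "raw"), meta,
                                   reference_scheme("batch_mean"))
  expect_equal(unname(out$values[1, ]), c(2, 6, 2, 6))
})

test_that("reference scaling is homogeneous of degree one", {
  meta <- toy_meta()
  m <- toy_study_matrix(meta)
  base <- reference_scale_normalize(m, meta, reference_scheme("batch_mean"))
  k <- 3.7
  scaled <- reference_scale_normalize(
    omics_matrix(k * m$values, "metabolite", "raw"), meta,
    reference_scheme("batch_mean"))
  expect_equal(scaled$values, k * base$values, tolerance = 1e-12)
})

test_that("baseline and qc schemes resolve their reference samples", {
  st <- benchmark_study()
  injected <- inject_batch_effects(st$metabolome, st$meta, st$truth)
  for (kind in c("baseline", "qc")) {
    out <- reference_scale_normalize(injected, st$meta, reference_scheme(kind))
    expect_true(all(out$values > 0))
  }
  meta_noqc <- st$meta[st$meta$role != "qc", ]
  sub <- omics_matrix(injected$values[, meta_noqc$sample_id], "metabolite", "raw")
  expect_error(reference_scale_normalize(sub, meta_noqc, reference_scheme("qc")),
               "no reference samples")
})

test_that("quantile normalization equalizes the column distributions", {
  m <- toy_matrix(matrix(c(1, 2, 3, 4, 5, 6), 3, 2), scale = "log")
  out <- quantile_normalize(m)
  expect_equal(unname(out$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 3.5, 4.5))
  two <- toy_matrix(matrix(c(5, 1, 9, 5, 1, 9), 3, 2), scale = "log")
  expect_equal(quantile_normalize(two)$values, two$values)
  set.seed(91)
  r <- toy_matrix(matrix(rnorm(60), 10, 6), scale = "log")
  qn <- quantile_normalize(r)
  expect_equal(diff(range(colMeans(qn$values))), 0, tolerance = 1e-12)
})

test_that("EB adjustment removes an additive batch shift and keeps one batch intact", {
  set.seed(101)
  meta <- toy_meta(n_batches = 2, timepoints = c(0, 3, 7), replicates = 2)
  # noiseless construction: every sample of a batch repeats the feature mean,
  # batch 2 shifted by a per-feature constant
  base <- matrix(rnorm(20, 10, 1), 20, 12,
                 dimnames = list(sprintf("f%02d", 1:20), meta$sample_id))
  delta <- rnorm(20, 0, 1.5)
  shifted <- base
  shifted[, meta$sample_id[meta$batch == "B2"]] <-
    shifted[, meta$sample_id[meta$batch == "B2"]] + delta
  adj <- eb_location_scale_adjust(omics_matrix(shifted, "metabolite", "log"),
                                  meta, estimate_on = "all")
  b1 <- rowMeans(adj$values[, meta$sample_id[meta$batch == "B1"]])
  b2 <- rowMeans(adj$values[, meta$sample_id[meta$batch == "B2"]])
  expect_lt(max(abs(b1 - b2)), 1e-6)
  # single batch: identity
  meta1 <- toy_meta(n_batches = 1)
  m1 <- log_transform(toy_study_matrix(meta1))
  expect_equal(eb_location_scale_adjust(m1, meta1)$values, m1$values)
  # estimation role must exist in every batch
  meta_nb <- meta
  meta_nb$role[meta_nb$batch == "B2"] <- "treated"
  expect_error(eb_location_scale_adjust(omics_matrix(shifted, "metabolite", "log"),
                                        meta_nb, estimate_on = "baseline"), "B2")
})

test_that("EB adjustment agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  set.seed(111)
  meta <- toy_meta(n_batches = 3, timepoints = c(0, 3, 7), replicates = 2)
  x <- matrix(rnorm(40 * 18, 8, 1), 40, 18,
              dimnames = list(sprintf("f%02d", 1:40), meta$sample_id))
  gam <- matrix(rnorm(40 * 3, 0, 0.8), 40, 3)
  x <- x + gam[, match(meta$batch, unique(meta$batch))]
  mine <- eb_location_scale_adjust(omics_matrix(x, "metabolite", "log"), meta,
                                   estimate_on = "all")
  ref <- suppressMessages(sva::ComBat(dat = x, batch = meta$batch))
  expect_equal(mine$values, ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("EB adjustment commutes with feature reordering", {
  set.seed(121)
  meta <- toy_meta(n_batches = 2, timepoints = c(0, 3, 7), replicates = 2)
  x <- matrix(rnorm(30 * 12, 8, 1), 30, 12,
              dimnames = list(sprintf("f%02d", 1:30), meta$sample_id))
  m <- omics_matrix(x, "metabolite", "log")
  perm <- sample(feature_ids(m))
  direct <- eb_location_scale_adjust(m, meta)$values[perm, ]
  reordered <- eb_location_scale_adjust(
    omics_matrix(x[perm, ], "metabolite", "log"), meta)$values
  expect_equal(direct, reordered, tolerance = 1e-12)
})

test_that("r.s.d. matches hand values and is scale invariant", {
  meta <- sample_meta(data.frame(
    sample_id = paste0("b", 1:3), batch = paste0("B", 1:3),
    timepoint_days = 0, replicate = 1, role = "treated"))
  m <- toy_matrix(matrix(c(1, 2, 2, 2, 3, 2), 2, 3), samples = meta$sample_id)
  out <- rsd(m, meta)
  expect_equal(out$rsd[out$feature_id == "F01"], 0.5)  # {1,2,3}
  expect_equal(out$rsd[out$feature_id == "F02"], 0)    # {2,2,2}
  scaled <- rsd(omics_matrix(7 * m$values, "metabolite", "raw"), meta)
  expect_equal(scaled$rsd, out$rsd, tolerance = 1e-12)
})

test_that("repeatability matches hand values and stays within [0, 1]", {
  meta <- sample_meta(data.frame(
    sample_id = c("b1r1", "b2r1", "b1r2", "b2r2"),
    batch = c("B1", "B2", "B1", "B2"),
    timepoint_days = c(0, 0, 7, 7), replicate = 1, role = "treated"))
  # perfect: identities {1,1} and {3,3}; noisy: {0,2} and {1,3}
  v <- matrix(c(1, 1, 3, 3, 0, 2, 1, 3), 2, 4, byrow = TRUE,
              dimnames = list(c("perfect", "noisy"), meta$sample_id))
  out <- repeatability(toy_matrix(v, scale = "log", samples = meta$sample_id,
                                  features = c("perfect", "noisy")), meta)
  expect_equal(out$repeatability[out$feature_id == "perfect"], 1)
  expect_equal(out$repeatability[out$feature_id == "noisy"], 0.2)
  set.seed(131)
  st <- benchmark_study()
  rp <- repeatability(st$metabolome, st$meta)
  expect_true(all(rp$repeatability >= 0 & rp$repeatability <= 1, na.rm = TRUE))
})

test_that("added noise lowers expected repeatability monotonically", {
  set.seed(141)
  meta <- toy_meta(n_batches = 3, timepoints = c(0, 3, 7, 10), replicates = 1)
  clean <- matrix(rep(rnorm(4, 10, 2), each = 1), 1, 4)[, rep(1:4, 3)]
  clean <- matrix(clean, 1, 12, dimnames = list("f", meta$sample_id))
  grid <- c(0.1, 0.7, 2)
  reps <- vapply(grid, function(ns) {
    mean(vapply(1:40, function(i) {
      noisy <- omics_matrix(abs(clean + rnorm(12, 0, ns)) + 1e-6,
                            "metabolite", "raw")
      repeatability(noisy, meta)$repeatability
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(reps) < 0))
})

test_that("Bhattacharyya distance: zero at identity, exact 1-D closed form", {
  set.seed(151)
  x <- matrix(rnorm(40), 20, 2)
  expect_equal(bhattacharyya_distance(x, x), 0, tolerance = 1e-12)
  # supplied exact moments: mu-difference 2, sigma^2 = 1 -> 0.5
  expect_equal(bhattacharyya_moments(0, 1, 2, 1), 0.5, tolerance = 1e-9)
  # equal covariances kill the determinant term in any dimension
  s <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3)
  mu1 <- c(1, 0, -1); mu2 <- c(0, 2, 1)
  expect_equal(bhattacharyya_moments(mu1, s, mu2, s),
               as.numeric((mu1 - mu2) %*% solve(s) %*% (mu1 - mu2)) / 8,
               tolerance = 1e-9)
})

test_that("Bhattacharyya distance is symmetric and non-negative", {
  set.seed(161)
  for (i in 1:100) {
    d <- sample(1:3, 1)
    x1 <- matrix(rnorm((d + 3) * d, 0, runif(1, 0.5, 2)), d + 3, d)
    x2 <- matrix(rnorm((d + 4) * d, runif(1, -2, 2), runif(1, 0.5, 2)), d + 4, d)
    db12 <- bhattacharyya_distance(x1, x2)
    expect_gte(db12, 0)
    expect_equal(db12, bhattacharyya_distance(x2, x1), tolerance = 1e-10)
  }
})

test_that("pulling clusters apart increases the Bhattacharyya distance", {
  set.seed(171)
  x1 <- matrix(rnorm(60), 30, 2)
  seps <- c(0, 1, 2, 4)
  db <- vapply(seps, function(s)
    bhattacharyya_distance(x1, sweep(x1, 2, c(s, 0), `+`)), numeric(1))
  expect_true(all(diff(db) > 0))
})

test_that("the printed-form determinant variant differs from the standard form", {
  set.seed(181)
  x1 <- matrix(rnorm(40, 0, 1), 20, 2)
  x2 <- matrix(rnorm(40, 1, 2), 20, 2)
  std <- bhattacharyya_distance(x1, x2)
  printed <- bhattacharyya_distance(x1, x2, printed_form = TRUE)
  expect_false(isTRUE(all.equal(std, printed)))
})

test_that("benchmark report always includes the uncorrected input", {
  st <- benchmark_study()
  injected <- inject_batch_effects(st$metabolome, st$meta, st$truth)
  rep_ <- benchmark_methods(injected, st$meta, methods = c("batch_mean", "eb"))
  expect_true("none" %in% rep_$summary$method)
  expect_setequal(rep_$summary$method, c("none", "batch_mean", "eb"))
  expect_true(all(rep_$summary$median_rsd >= 0))
  expect_length(rep_$errors, 0)
})

test_that("with unit batch factors all methods tie with the uncorrected input", {
  st <- benchmark_study()   # clean matrices: factors never injected
  rep_ <- benchmark_methods(st$metabolome, st$meta,
                            methods = c("batch_mean", "baseline", "qc", "quantile"))
  s <- rep_$summary
  none <- s$median_rsd[s$method == "none"]
  expect_true(all(abs(s$median_rsd - none) < 0.05))
})

test_that("a failing method is recorded while the others proceed", {
  st <- default_study()   # no QC samples: the qc scheme must fail
  injected <- inject_batch_effects(st$metabolome, st$meta, st$truth)
  rep_ <- benchmark_methods(injected, st$meta, methods = c("batch_mean", "qc"))
  expect_true("qc" %in% names(rep_$errors))
  expect_true(all(c("none", "batch_mean") %in% rep_$summary$method))
})
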