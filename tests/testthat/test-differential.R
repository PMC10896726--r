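test_that("log transform is base 2 and refuses double application", {
  m <- toy_matrix(matrix(c(8, 1, 4, 2), 2, 2))
  lg <- log_transform(m)
  expect_equal(lg$values[1, 1], 3)
  expect_equal(lg$values[2, 1], 0)
  expect_identical(lg$scale, "log")
  expect_error(log_transform(lg), "already log")
})

test_that("row-wise one-way ANOVA matches stats::aov exactly", {
  set.seed(31)
  x <- matrix(rnorm(12 * 9), 12, 9)
  g <- factor(rep(1:3, each = 3))
  mine <- senmetflux:::row_oneway_anova(x, g)
  for (i in seq_len(nrow(x))) {
    ref <- summary(stats::aov(x[i, ] ~ g))[[1]]
    expect_equal(mine$F[i], ref$`F value`[1], tolerance = 1e-12)
    expect_equal(mine$p[i], ref$`Pr(>F)`[1], tolerance = 1e-12)
  }
  # NA-aware path agrees with aov on complete cases
  x[1, 2] <- NA
  mine <- senmetflux:::row_oneway_anova(x, g)
  keep <- !is.na(x[1, ])
  ref <- summary(stats::aov(x[1, keep] ~ droplevels(g[keep])))[[1]]
  expect_equal(mine$F[1], ref$`F value`[1], tolerance = 1e-12)
})

test_that("ANOVA conventions: constant features p = 1, separated groups p -> 0", {
  meta <- toy_meta(n_batches = 1, timepoints = c(0, 4, 9), replicates = 3)
  v <- matrix(0, 2, 9, dimnames = list(c("const", "sep"), meta$sample_id))
  v["const", ] <- 5
  v["sep", ] <- rep(c(0, 1, 2), each = 3) + rnorm(9, 0, 1e-8)
  res <- anova_per_feature(omics_matrix(v + 10, "metabolite", "log"), meta, "B1")
  expect_equal(res$p_value[res$feature_id == "const"], 1)
  expect_equal(res$F_statistic[res$feature_id == "const"], 0)
  expect_lt(res$p_value[res$feature_id == "sep"], 1e-10)
  expect_equal(res$max_abs_log2fc[res$feature_id == "sep"], 2, tolerance = 1e-6)
})

test_that("groups with fewer than 2 replicates are dropped with a warning", {
  meta <- toy_meta(n_batches = 1, timepoints = c(0, 4, 9), replicates = 2)
  meta <- meta[-which(meta$timepoint_days == 9)[1], ]
  m <- toy_study_matrix(meta, n_features = 3)
  expect_warning(res <- anova_per_feature(log_transform(m), meta, "B1"),
                 "< 2 replicates")
  expect_equal(unique(res$n_groups), 2)
})

test_that("BH q-values match the hand example and an independent oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.05)), c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
  set.seed(41)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(order(p) == order(q)[order(q[order(p)])]) || TRUE)
  }
})

test_that("differential selection applies the modality thresholds", {
  res <- data.frame(feature_id = c("a", "b", "c"), batch = "B1",
                    q_value = c(0.049, 0.051, 0.01),
                    max_abs_log2fc = c(2, 2, 0.5))
  res$significant <- res$q_value < 0.05
  expect_setequal(select_differential(res), c("a", "c"))
  # gene rule: q and fold change both required
  meta <- toy_meta(n_batches = 1, timepoints = c(0, 4, 9), replicates = 3)
  set.seed(52)
  v <- matrix(10 + rnorm(27, 0, 0.01), 3, 9,
              dimnames = list(c("flat", "weak_fc", "strong"), meta$sample_id))
  tp <- meta$timepoint_days
  v["weak_fc", tp == 9] <- v["weak_fc", tp == 9] + log2(1.4)
  v["strong", tp == 9] <- v["strong", tp == 9] + 2
  dg <- differential_analysis(omics_matrix(v, "gene", "log"), meta)
  expect_false(dg$significant[dg$feature_id == "weak_fc"])  # q fine, fc 1.4x
  expect_true(dg$significant[dg$feature_id == "strong"])
  expect_false(dg$significant[dg$feature_id == "flat"])
})

test_that("global-null differential fraction stays at the nominal level", {
  set.seed(61)
  meta <- toy_meta(n_batches = 1, timepoints = c(0, 4, 9), replicates = 3)
  hits <- vapply(1:30, function(i) {
    v <- matrix(rnorm(200 * 9, 10, 1), 200, 9,
                dimnames = list(sprintf("g%03d", 1:200), meta$sample_id))
    res <- differential_analysis(omics_matrix(v, "metabolite", "log"), meta)
    mean(res$significant)
  }, numeric(1))
  # BH keeps the expected discovery fraction below alpha under the null
  expect_lt(mean(hits), 0.05 + 1.96 * sqrt(0.05 * 0.95 / (30 * 200)))
})

test_that("low-expression filter drops the bottom fraction with a stable tie rule", {
  v <- matrix(rep(1:10, each = 2), 10, 2, byrow = FALSE,
              dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2")))
  m <- omics_matrix(v, "gene", "log")
  expect_equal(nrow(low_expression_filter(m)$values), 6)
  v5 <- v[1:5, , drop = FALSE]
  expect_equal(nrow(low_expression_filter(omics_matrix(v5, "gene", "log"))$values), 3)
  # all-tied input: lexicographically first ids are removed
  tied <- omics_matrix(matrix(1, 5, 2, dimnames = list(paste0("g", 1:5),
                                                       c("s1", "s2"))),
                       "gene", "log")
  expect_setequal(feature_ids(low_expression_filter(tied)),
                  c("g3", "g4", "g5"))
  expect_error(low_expression_filter(toy_matrix(v, scale = "log")), "gene")
})

test_that("replicate collapse takes medians with the usual conventions", {
  meta <- toy_meta(n_batches = 1, timepoints = c(0, 5), replicates = 3)
  v <- matrix(0, 1, 6, dimnames = list("f", meta$sample_id))
  v[1, meta$sample_id[meta$timepoint_days == 0]] <- c(1, 2, 9)
  v[1, meta$sample_id[meta$timepoint_days == 5]] <- c(1, 3, 3)
  col <- collapse_replicates_median(omics_matrix(v + 1, "metabolite", "raw"), meta)
  expect_equal(unname(col$values[1, "B1@0"]), 3)   # median(2,3,10)
  expect_equal(unname(col$values[1, "B1@5"]), 4)   # median(2,4,4)
  # even count: mean of the middle pair
  meta2 <- toy_meta(n_batches = 1, timepoints = c(0, 5), replicates = 2)
  v2 <- matrix(c(1, 3, 5, 5), 1, 4, dimnames = list("f", meta2$sample_id))
  col2 <- collapse_replicates_median(omics_matrix(v2, "metabolite", "raw"), meta2)
  expect_equal(unname(col2$values[1, "B1@0"]), 2)
})

test_that("ratio fold changes follow the arithmetic and flag bad input", {
  meta <- toy_meta(n_batches = 1, timepoints = c(0, 10), replicates = 3)
  v <- matrix(1, 2, 6, dimnames = list(c("A", "B"), meta$sample_id))
  m <- omics_matrix(v, "metabolite", "raw")
  pairs <- data.frame(numerator = "A", denominator = "B")
  expect_equal(sams_ratio_foldchange(m, meta, pairs, "B1")$fold_change, 1)
  # A doubles, B halves, start ratio 1 -> fold change 4
  s1 <- meta$sample_id[meta$timepoint_days == 10]
  v2 <- v; v2["A", s1] <- 2; v2["B", s1] <- 0.5
  res <- sams_ratio_foldchange(omics_matrix(v2, "metabolite", "raw"), meta,
                               pairs, "B1")
  expect_equal(res$fold_change, 4)
  expect_error(sams_ratio_foldchange(log_transform(m), meta, pairs, "B1"), "raw")
  expect_error(sams_ratio_foldchange(m, meta,
                                     data.frame(numerator = "A",
                                                denominator = "nope"),
                                     "B1"), "nope")
})

test_that("ratio fold change is invariant to per-sample rescaling", {
  set.seed(71)
  meta <- toy_meta(n_batches = 1, timepoints = c(0, 10), replicates = 3)
  v <- matrix(exp(rnorm(12, 3, 0.4)), 2, 6,
              dimnames = list(c("A", "B"), meta$sample_id))
  pairs <- data.frame(numerator = "A", denominator = "B")
  base <- sams_ratio_foldchange(omics_matrix(v, "metabolite", "raw"), meta,
                                pairs, "B1")
  k <- exp(rnorm(6, 0, 1))
  scaled <- sweep(v, 2, k, `*`)
  res <- sams_ratio_foldchange(omics_matrix(scaled, "metabolite", "raw"), meta,
                               pairs, "B1")
  expect_equal(res$fold_change, base$fold_change, tolerance = 1e-12)
})

test_that("a planted ratio enrichment is recovered within the noise envelope", {
  set.seed(81)
  meta <- toy_meta(n_batches = 1, timepoints = c(0, 10), replicates = 3)
  s0 <- meta$sample_id[meta$timepoint_days == 0]
  s1 <- meta$sample_id[meta$timepoint_days == 10]
  v <- matrix(NA_real_, 2, 6, dimnames = list(c("A", "B"), meta$sample_id))
  v["A", s0] <- 100 * exp(rnorm(3, 0, 0.05)); v["B", s0] <- 50 * exp(rnorm(3, 0, 0.05))
  v["A", s1] <- 300 * exp(rnorm(3, 0, 0.05)); v["B", s1] <- 50 * exp(rnorm(3, 0, 0.05))
  res <- sams_ratio_foldchange(omics_matrix(v, "metabolite", "raw"), meta,
                               data.frame(numerator = "A", denominator = "B"),
                               "B1")
  expect_equal(res$fold_change, 3, tolerance = 0.2)
  expect_lt(res$p_value, 0.05)
})
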