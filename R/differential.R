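#' Base-2 log transform of a raw intensity matrix
#'
#' First analysis step for both modalities. Requires a raw-scale matrix with
#' strictly positive values (impute with [impute_missing()] first); applying
#' it twice is an error.
#'
#' @param x a raw-scale [omics_matrix()].
#' @return An `omics_matrix` on the log scale (base 2).
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$scale != "raw") stopf("matrix is already log scale")
  if (any(x$values <= 0, na.rm = TRUE))
    stopf("non-positive value(s) present; impute before log transform")
  omics_matrix(log2(x$values), x$modality, "log")
}

# vectorised one-way ANOVA across the columns of x grouped by g (a factor);
# NA-aware. Returns F, p and the group means.
row_oneway_anova <- function(x, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  if (k < 2) stopf("one-way ANOVA needs >= 2 groups")
  ind <- stats::model.matrix(~ g - 1)              # samples x groups
  obs <- !is.na(x)
  xz <- x; xz[!obs] <- 0
  n_g <- obs %*% ind                               # features x groups counts
  sum_g <- xz %*% ind
  mean_g <- sum_g / n_g
  n_tot <- rowSums(n_g)
  grand <- rowSums(sum_g) / n_tot
  ssb <- rowSums(n_g * (mean_g - grand)^2)
  sst <- rowSums((xz - grand)^2 * obs)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1
  df2 <- n_tot - k
  msb <- ssb / df1
  msw <- ssw / df2
  f <- msb / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # constant features: zero between- and within-variance -> F = 0, p = 1
  const <- sst < 1e-12 * pmax(abs(grand), 1)^2 | sst == 0
  f[const] <- 0; p[const] <- 1
  untestable <- rowSums(n_g >= 1) < 2 | df2 < 1
  f[untestable] <- NA; p[untestable] <- NA
  list(F = f, p = p, group_means = mean_g, df1 = df1, df2 = df2)
}

#' Per-feature one-way ANOVA across timepoints within a batch
#'
#' Tests, for each feature, whether the mean log intensity differs across
#' timepoint groups of one batch (the only within-batch design variable).
#' QC samples are excluded. Timepoint groups with fewer than 2 replicates
#' are dropped with a warning. Also reports the maximum absolute log2 fold
#' change of any timepoint versus the batch's first timepoint.
#'
#' @param x a log-scale [omics_matrix()].
#' @param meta the study [sample_meta()].
#' @param batch batch id to analyse.
#' @return Data frame with `feature_id`, `batch`, `F_statistic`, `p_value`,
#'   `max_abs_log2fc` and `n_groups`.
#' @export
anova_per_feature <- function(x, meta, batch) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$scale != "log") stopf("anova_per_feature() expects a log-scale matrix")
  meta <- sample_meta(meta)
  m <- meta[meta$batch == batch & meta$role != "qc", ]
  if (nrow(m) == 0) stopf("no samples for batch '%s'", batch)
  counts <- table(m$timepoint_days)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warnf("batch %s: dropping timepoint group(s) with < 2 replicates: %s",
          batch, paste(small, collapse = ", "))
    m <- m[!(as.character(m$timepoint_days) %in% small), ]
  }
  if (length(unique(m$timepoint_days)) < 2)
    stopf("batch %s: fewer than 2 testable timepoint groups", batch)
  v <- x$values[, m$sample_id, drop = FALSE]
  res <- row_oneway_anova(v, m$timepoint_days)
  t0 <- as.character(min(m$timepoint_days))
  gm <- res$group_means
  colnames(gm) <- sub("^g", "", colnames(gm))
  fc <- gm - gm[, t0]
  data.frame(feature_id = feature_ids(x), batch = batch,
             F_statistic = res$F, p_value = res$p,
             max_abs_log2fc = apply(abs(fc), 1, max),
             n_groups = length(unique(m$timepoint_days)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: rejects
#' p-values outside \[0, 1\], preserves order, and guarantees q >= p.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stopf("'p' must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stopf("p-value(s) outside [0, 1]: %s",
                      paste(utils::head(p[bad], 3), collapse = ", "))
  stats::p.adjust(p, method = "BH")
}

#' Differential calling over all batches
#'
#' Runs [anova_per_feature()] per batch and adds BH q-values within each
#' batch, plus the modality-specific significance flag: metabolites need
#' q < `q_threshold`; genes additionally need
#' `max_abs_log2fc >= fc_threshold`.
#'
#' @param x a log-scale [omics_matrix()].
#' @param meta the study [sample_meta()].
#' @param q_threshold FDR cutoff (default 0.05).
#' @param fc_threshold gene log2 fold-change cutoff. The default reads the
#'   "1.5 x" rule as |log2FC| >= log2(1.5); pass `1.5` for the alternative
#'   |log2FC| >= 1.5 reading.
#' @return Data frame of per-(feature, batch) results with `q_value` and
#'   `significant`.
#' @export
differential_analysis <- function(x, meta, q_threshold = 0.05,
                                  fc_threshold = log2(1.5)) {
  meta <- sample_meta(meta)
  out <- do.call(rbind, lapply(unique(meta$batch), function(b) {
    res <- anova_per_feature(x, meta, b)
    res$q_value <- bh_fdr(res$p_value)
    res
  }))
  out$significant <- !is.na(out$q_value) & out$q_value < q_threshold &
    (if (x$modality == "gene") out$max_abs_log2fc >= fc_threshold else TRUE)
  out
}

#' Features differential in at least one batch
#'
#' The union-across-batches selection: a feature is kept when its
#' `significant` flag holds in any batch.
#'
#' @param results a [differential_analysis()] data frame.
#' @return Character vector of feature ids.
#' @export
select_differential <- function(results) {
  sort(unique(results$feature_id[results$significant]))
}

#' Remove the bottom 40 percent of genes by mean expression
#'
#' Genes are ranked by mean log expression over all samples;
#' `floor(fraction * n)` lowest are removed. Ties at the cut are resolved by
#' feature-id lexicographic order so the result is deterministic.
#'
#' @param x a log-scale gene [omics_matrix()].
#' @param fraction fraction to drop (default 0.4).
#' @return The filtered `omics_matrix`.
#' @export
low_expression_filter <- function(x, fraction = 0.4) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$modality != "gene") stopf("expression filter applies to gene matrices")
  if (x$scale != "log") stopf("low_expression_filter() expects log scale")
  n_drop <- floor(fraction * nrow(x$values))
  if (n_drop == 0) return(x)
  means <- rowMeans(x$values, na.rm = TRUE)
  ord <- order(means, feature_ids(x), method = "radix")
  keep <- sort(feature_ids(x)[ord[-seq_len(n_drop)]])
  subset_features(x, keep)
}

#' Collapse replicates to their median
#'
#' One column per (batch, timepoint); each entry is the median of that
#' feature's replicate measurements (mean-of-middle for even counts, the
#' usual `median()` convention). QC samples are excluded. The returned
#' matrix carries a `col_meta` element mapping columns to batch and
#' timepoint.
#'
#' @param x an [omics_matrix()].
#' @param meta the study [sample_meta()].
#' @return An `omics_matrix` whose columns are `batch@timepoint` medians,
#'   with a `col_meta` data frame element.
#' @export
collapse_replicates_median <- function(x, meta) {
  stopifnot(inherits(x, "omics_matrix"))
  meta <- sample_meta(meta)
  m <- meta[meta$role != "qc" & meta$sample_id %in% sample_ids(x), ]
  key <- paste0(m$batch, "@", m$timepoint_days)
  groups <- split(m$sample_id, key)
  info <- unique(data.frame(key = key, batch = m$batch,
                            timepoint_days = m$timepoint_days,
                            stringsAsFactors = FALSE))
  info <- info[order(info$batch, info$timepoint_days), ]
  med <- vapply(info$key, function(k)
    apply(x$values[, groups[[k]], drop = FALSE], 1, stats::median, na.rm = TRUE),
    numeric(nrow(x$values)))
  med <- matrix(med, nrow = nrow(x$values), ncol = length(info$key))
  med[is.nan(med)] <- NA
  colnames(med) <- info$key
  rownames(med) <- feature_ids(x)
  out <- omics_matrix(med, x$modality, x$scale)
  out$col_meta <- data.frame(sample_id = info$key, batch = info$batch,
                             timepoint_days = info$timepoint_days,
                             stringsAsFactors = FALSE)
  out
}

#' Metabolite-ratio fold changes between course start and end
#'
#' For each (numerator, denominator) metabolite pair and batch, computes the
#' fold change of the pair ratio at the end of the time course relative to
#' its start: `(A_end / B_end) / (A_start / B_start)`, where each term is
#' the replicate mean of the within-sample ratio `A/B` on raw intensities.
#' Per-replicate end ratios (each divided by the start mean ratio) feed a
#' two-sided one-sample t-test against 1. Because the ratio is formed
#' within each sample before averaging, any common per-sample
#' multiplicative factor cancels exactly.
#'
#' @param x a raw-scale metabolite [omics_matrix()].
#' @param meta the study [sample_meta()].
#' @param pairs data frame with columns `numerator` and `denominator`
#'   (feature ids).
#' @param batch batch id.
#' @param start_timepoint,end_timepoint reference timepoints; default the
#'   batch's first and last sampled day. A different proliferative reference
#'   can be supplied per call.
#' @return Data frame with `numerator`, `denominator`, `batch`,
#'   `fold_change`, `p_value`, `start_timepoint`, `end_timepoint`, `n_end`.
#' @export
sams_ratio_foldchange <- function(x, meta, pairs, batch,
                                  start_timepoint = NULL, end_timepoint = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$scale != "raw") stopf("ratio fold changes are defined on raw intensities")
  meta <- sample_meta(meta)
  m <- meta[meta$batch == batch & meta$role != "qc", ]
  if (nrow(m) == 0) stopf("no samples for batch '%s'", batch)
  t0 <- start_timepoint %||% min(m$timepoint_days)
  t1 <- end_timepoint %||% max(m$timepoint_days)
  s0 <- m$sample_id[m$timepoint_days == t0]
  s1 <- m$sample_id[m$timepoint_days == t1]
  if (length(s0) == 0 || length(s1) == 0)
    stopf("batch %s: no samples at requested start/end timepoints", batch)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- as.character(pairs$numerator[i]); b <- as.character(pairs$denominator[i])
    if (!all(c(a, b) %in% feature_ids(x)))
      stopf("unknown metabolite id in pair (%s, %s)", a, b)
    a0 <- x$values[a, s0]; a1 <- x$values[a, s1]
    b0 <- x$values[b, s0]; b1 <- x$values[b, s1]
    r0 <- a0 / b0; r1 <- a1 / b1
    r0_mean <- mean(r0, na.rm = TRUE); r1_mean <- mean(r1, na.rm = TRUE)
    if (any(b0 == 0, na.rm = TRUE) || any(b1 == 0, na.rm = TRUE) ||
        !is.finite(r0_mean) || !is.finite(r1_mean) || r0_mean <= 0)
      return(data.frame(numerator = a, denominator = b, batch = batch,
                        fold_change = NA_real_, p_value = NA_real_,
                        start_timepoint = t0, end_timepoint = t1,
                        n_end = length(s1), stringsAsFactors = FALSE))
    fc <- r1_mean / r0_mean
    rep_fc <- r1 / r0_mean
    p <- if (sum(!is.na(rep_fc)) >= 2 && stats::sd(rep_fc, na.rm = TRUE) > 0)
      stats::t.test(rep_fc, mu = 1)$p.value else NA_real_
    data.frame(numerator = a, denominator = b, batch = batch,
               fold_change = fc, p_value = p,
               start_timepoint = t0, end_timepoint = t1,
               n_end = length(s1), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
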