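#' Relative standard deviation across batches
#'
#' For each peak and each sample identity (the same (timepoint, replicate,
#' role) position measured once per batch), the ratio of the unbiased
#' standard deviation to the mean of the measurements over all batches.
#' Scale-invariant; groups with fewer than `min_group` measurements or with
#' zero mean are omitted.
#'
#' @param x an [omics_matrix()] (raw scale for the usual interpretation).
#' @param meta the study [sample_meta()].
#' @param min_group minimum measurements per identity (default 2).
#' @return Data frame with `feature_id`, `identity`, `n`, `rsd`.
#' @export
rsd <- function(x, meta, min_group = 2) {
  stopifnot(inherits(x, "omics_matrix"))
  meta <- sample_meta(meta)
  meta <- meta[meta$sample_id %in% sample_ids(x), ]
  identity <- paste0("D", meta$timepoint_days, "_R", meta$replicate, "_", meta$role)
  groups <- split(meta$sample_id, identity)
  groups <- groups[lengths(groups) >= min_group]
  if (length(groups) == 0) stopf("no sample identity occurs in >= %d batches", min_group)
  out <- lapply(names(groups), function(id) {
    v <- x$values[, groups[[id]], drop = FALSE]
    mu <- rowMeans(v, na.rm = TRUE)
    sd_ <- sqrt(row_vars(v, na.rm = TRUE))
    val <- ifelse(mu == 0 | is.na(mu), NA_real_, sd_ / mu)
    data.frame(feature_id = feature_ids(x), identity = id,
               n = length(groups[[id]]), rsd = val,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-peak repeatability across sample identities
#'
#' The fraction of variance lying between sample identities:
#' `sigma2_between / (sigma2_between + sigma2_within)`, where
#' `sigma2_between` is the variance of the per-identity means and
#' `sigma2_within` the mean of the per-identity variances (unbiased
#' estimators). High values mean identities are well separated with tightly
#' clustered repeated measurements; always in \[0, 1\].
#'
#' @param x an [omics_matrix()].
#' @param meta the study [sample_meta()].
#' @return Data frame with `feature_id` and `repeatability`.
#' @export
repeatability <- function(x, meta) {
  stopifnot(inherits(x, "omics_matrix"))
  meta <- sample_meta(meta)
  meta <- meta[meta$sample_id %in% sample_ids(x), ]
  identity <- paste0("D", meta$timepoint_days, "_R", meta$replicate, "_", meta$role)
  groups <- split(meta$sample_id, identity)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < 2)
    stopf("repeatability needs >= 2 identities with >= 2 measurements each")
  nf <- nrow(x$values)
  means <- matrix(vapply(groups, function(ids)
    rowMeans(x$values[, ids, drop = FALSE], na.rm = TRUE), numeric(nf)),
    nrow = nf)
  wvars <- matrix(vapply(groups, function(ids)
    row_vars(x$values[, ids, drop = FALSE], na.rm = TRUE), numeric(nf)),
    nrow = nf)
  s2_between <- row_vars(means)
  s2_within <- rowMeans(wvars, na.rm = TRUE)
  rep_ <- s2_between / (s2_between + s2_within)
  rep_[s2_between + s2_within == 0] <- NA_real_
  data.frame(feature_id = feature_ids(x), repeatability = rep_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bhattacharyya distance between two point clouds
#'
#' Covariance-aware separation of two sample clusters:
#' `DB = 1/8 (mu1-mu2)' S^-1 (mu1-mu2) + 1/2 ln( det S / sqrt(det S1 det S2) )`
#' with `S = (S1 + S2)/2` the pooled average covariance. Symmetric,
#' non-negative, and zero for identical clusters. A small ridge
#' (`ridge * trace/dim` on the diagonal) keeps the pooled covariance
#' invertible. `printed_form = TRUE` drops the square root in the
#' determinant term (a non-standard variant that is not guaranteed
#' non-negative; the standard form is the default).
#'
#' @param x1,x2 numeric matrices, one point per row (same column count).
#' @param ridge ridge multiplier (default 1e-6).
#' @param printed_form use the non-square-root determinant term.
#' @return Non-negative scalar distance (standard form).
#' @export
bhattacharyya_distance <- function(x1, x2, ridge = 1e-6, printed_form = FALSE) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (ncol(x1) != ncol(x2)) stopf("clusters live in different dimensions")
  if (nrow(x1) < 2 || nrow(x2) < 2) stopf("each cluster needs >= 2 points")
  bhattacharyya_moments(colMeans(x1), stats::cov(x1),
                        colMeans(x2), stats::cov(x2),
                        ridge = ridge, printed_form = printed_form)
}

#' @rdname bhattacharyya_distance
#' @param mu1,mu2 cluster means.
#' @param s1,s2 cluster covariance matrices.
#' @export
bhattacharyya_moments <- function(mu1, s1, mu2, s2, ridge = 1e-6,
                                  printed_form = FALSE) {
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  d <- length(mu1)
  pooled <- (s1 + s2) / 2
  # ridge only when needed, so exact supplied moments give exact distances
  lam <- 0
  inv <- tryCatch(solve(pooled), error = function(e) NULL)
  logdet <- function(m) {
    x <- determinant(m + diag(lam, d), logarithm = TRUE)
    as.numeric(x$modulus) * as.numeric(x$sign)
  }
  if (is.null(inv) || !all(is.finite(inv)) ||
      !all(is.finite(c(logdet(pooled), logdet(s1), logdet(s2))))) {
    lam <- ridge * sum(diag(pooled)) / d
    if (lam <= 0) lam <- ridge
    inv <- tryCatch(solve(pooled + diag(lam, d)), error = function(e)
      stopf("pooled covariance singular even after ridge; reduce dimensionality"))
  }
  dmu <- as.numeric(mu1 - mu2)
  term1 <- as.numeric(dmu %*% inv %*% dmu) / 8
  term2 <- if (printed_form)
    0.5 * (logdet(pooled) - logdet(s1) - logdet(s2))
  else
    0.5 * (logdet(pooled) - 0.5 * (logdet(s1) + logdet(s2)))
  as.numeric(term1 + term2)
}

#' Benchmark batch-correction methods
#'
#' Applies each requested method independently to the raw input and scores
#' the result (and the uncorrected input, always reported as method
#' `"none"`) with the three metrics: per-(peak, identity) r.s.d., per-peak
#' repeatability, and the mean pairwise Bhattacharyya distance between
#' batch clusters in a PCA-reduced coordinate space. All metrics are
#' computed on the raw intensity scale (log-domain methods are
#' back-transformed). A failing method is recorded and the others proceed.
#'
#' @param x a raw-scale [omics_matrix()].
#' @param meta the study [sample_meta()].
#' @param methods subset of `c("batch_mean", "baseline", "qc", "quantile", "eb")`.
#' @param npc dimensions used for the Bhattacharyya batch clusters.
#' @param eb_estimate_on estimation role for the EB method.
#' @return A list of class `benchmark_report`: `summary` (method x metric
#'   data frame), `rsd`, `repeatability` (per-method detail), `errors`.
#' @export
benchmark_methods <- function(x, meta,
                              methods = c("batch_mean", "baseline", "qc",
                                          "quantile", "eb"),
                              npc = 2, eb_estimate_on = "baseline") {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$scale != "raw") stopf("benchmark expects the raw input matrix")
  meta <- sample_meta(meta)
  meta <- meta[meta$sample_id %in% sample_ids(x), ]
  methods <- match.arg(methods, several.ok = TRUE)
  x <- impute_missing(x)
  corrected <- list(none = x)
  errors <- character()
  for (m in methods) {
    res <- tryCatch(switch(m,
      batch_mean = reference_scale_normalize(x, meta, reference_scheme("batch_mean")),
      baseline = reference_scale_normalize(x, meta, reference_scheme("baseline")),
      qc = reference_scale_normalize(x, meta, reference_scheme("qc")),
      quantile = quantile_normalize(x),
      eb = {
        adj <- eb_location_scale_adjust(log_transform(x), meta,
                                        estimate_on = eb_estimate_on)
        omics_matrix(2^adj$values, x$modality, "raw")
      }), error = function(e) e)
    if (inherits(res, "error")) errors[m] <- conditionMessage(res)
    else corrected[[m]] <- res
  }
  rsd_detail <- lapply(corrected, function(cm) rsd(cm, meta))
  rep_detail <- lapply(corrected, function(cm) repeatability(cm, meta))
  db_mean <- vapply(corrected, function(cm) {
    lv <- log2(pmax(cm$values, .Machine$double.eps))
    pcs <- tryCatch(stats::prcomp(t(lv), center = TRUE, scale. = FALSE)$x[, seq_len(npc), drop = FALSE],
                    error = function(e) NULL)
    if (is.null(pcs)) return(NA_real_)
    bs <- unique(meta$batch)
    pair_db <- utils::combn(bs, 2, function(p) {
      i1 <- meta$sample_id[meta$batch == p[1]]
      i2 <- meta$sample_id[meta$batch == p[2]]
      bhattacharyya_distance(pcs[i1, , drop = FALSE], pcs[i2, , drop = FALSE])
    })
    mean(pair_db)
  }, numeric(1))
  summary <- data.frame(
    method = names(corrected),
    median_rsd = vapply(rsd_detail, function(d) stats::median(d$rsd, na.rm = TRUE), numeric(1)),
    median_repeatability = vapply(rep_detail, function(d)
      stats::median(d$repeatability, na.rm = TRUE), numeric(1)),
    mean_batch_bhattacharyya = db_mean,
    row.names = NULL, stringsAsFactors = FALSE)
  summary$rank_rsd <- rank(summary$median_rsd, ties.method = "min")
  summary$rank_repeatability <- rank(-summary$median_repeatability, ties.method = "min")
  summary$rank_bhattacharyya <- rank(summary$mean_batch_bhattacharyya, ties.method = "min")
  structure(list(summary = summary, rsd = rsd_detail,
                 repeatability = rep_detail, errors = errors),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\n")
  print(x$summary, digits = 4)
  if (length(x$errors))
    cat("failed:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
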