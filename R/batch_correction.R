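#' Reference scheme for per-peak scaling normalization
#'
#' Chooses which samples define the per-batch correction factor: pooled QC
#' injections (`"qc"`), uninduced day-0 samples (`"baseline"`), or every
#' sample of the batch (`"batch_mean"`).
#'
#' @param kind `"qc"`, `"baseline"` or `"batch_mean"`.
#' @return An object of class `reference_scheme`.
#' @export
reference_scheme <- function(kind = c("batch_mean", "baseline", "qc")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "reference_scheme")
}

reference_samples <- function(scheme, meta, batch) {
  m <- meta[meta$batch == batch, ]
  switch(scheme$kind,
         qc = m$sample_id[m$role == "qc"],
         baseline = m$sample_id[m$role == "baseline"],
         batch_mean = m$sample_id)
}

#' Reference scaling normalization
#'
#' Per-peak rescaling of raw intensities: every entry of peak p in batch b is
#' multiplied by `R_p / C_p,b`, where `R_p` is the grand average of the peak
#' over all samples in all batches and `C_p,b` is the arithmetic mean of the
#' batch's reference samples (QC, uninduced, or all batch samples, per the
#' scheme). A purely multiplicative per-(peak, batch) distortion is removed
#' exactly by the `batch_mean` scheme; with a single batch the map is the
#' identity. Peaks whose reference mean is zero or all-missing in a batch
#' are flagged uncorrectable (left missing there) with a warning.
#'
#' @param x a raw-scale [omics_matrix()].
#' @param meta the study [sample_meta()].
#' @param scheme a [reference_scheme()].
#' @return The normalized `omics_matrix` (raw scale).
#' @export
reference_scale_normalize <- function(x, meta, scheme = reference_scheme()) {
  stopifnot(inherits(x, "omics_matrix"), inherits(scheme, "reference_scheme"))
  if (x$scale != "raw") stopf("reference scaling operates on raw intensities")
  meta <- sample_meta(meta)
  v <- x$values
  r_p <- rowMeans(v, na.rm = TRUE)
  out <- v
  for (b in unique(meta$batch)) {
    refs <- intersect(reference_samples(scheme, meta, b), colnames(v))
    if (length(refs) == 0)
      stopf("batch %s has no reference samples for scheme '%s'", b, scheme$kind)
    cols <- intersect(meta$sample_id[meta$batch == b], colnames(v))
    c_pb <- rowMeans(v[, refs, drop = FALSE], na.rm = TRUE)
    bad <- is.na(c_pb) | c_pb == 0
    if (any(bad))
      warnf("batch %s: %d peak(s) uncorrectable (reference mean 0 or missing)",
            b, sum(bad))
    scale_fac <- r_p / c_pb
    scale_fac[bad] <- NA
    out[, cols] <- v[, cols, drop = FALSE] * scale_fac
  }
  omics_matrix(out, x$modality, x$scale)
}

#' Quantile normalization across samples
#'
#' Forces every sample column to the identical sorted value distribution
#' (the mean of the order statistics), preserving within-column ranks.
#' Delegates to `limma::normalizeQuantiles()`. Input must be complete
#' (impute first).
#'
#' @param x an [omics_matrix()] without missing values.
#' @return The quantile-normalized `omics_matrix` (same scale tag).
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (anyNA(x$values)) stopf("quantile normalization needs a complete matrix; impute first")
  v <- limma::normalizeQuantiles(x$values)
  dimnames(v) <- dimnames(x$values)
  omics_matrix(v, x$modality, x$scale)
}

# parametric empirical-Bayes batch parameter solver (method-of-moments
# priors, iterative posterior update)
eb_solve <- function(z_est, gamma_hat, delta_hat, conv = 1e-4, max_iter = 200L) {
  n <- ncol(z_est)
  gamma_bar <- mean(gamma_hat)
  t2 <- stats::var(gamma_hat)
  m <- mean(delta_hat); s2 <- stats::var(delta_hat)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_new <- gamma_hat; d_new <- delta_hat
  if (!is.finite(t2) || t2 == 0 || !is.finite(s2) || s2 == 0)
    return(list(gamma = gamma_hat, delta = delta_hat))
  for (it in seq_len(max_iter)) {
    g_old <- g_new; d_old <- d_new
    g_new <- (t2 * n * gamma_hat + d_new * gamma_bar) / (t2 * n + d_new)
    ss <- rowSums((z_est - g_new)^2)
    d_new <- (0.5 * ss + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                  abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
    if (change < conv) break
  }
  list(gamma = g_new, delta = d_new)
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric empirical-Bayes adjustment of additive and multiplicative
#' per-(feature, batch) effects on log-scale data: features are standardized
#' against the grand mean and pooled variance, per-batch location
#' (`gamma`) and scale (`delta^2`) parameters are estimated on the
#' designated estimation samples, shrunk across features with
#' method-of-moments normal / inverse-gamma priors, then subtracted and
#' divided out of *all* samples of each batch. Estimating on
#' `estimate_on = "baseline"` mirrors using the initial, uninduced samples
#' of each batch to infer inter-batch effects; `"all"` estimates on every
#' sample.
#'
#' @param x a log-scale [omics_matrix()].
#' @param meta the study [sample_meta()].
#' @param estimate_on `"baseline"`, `"all"`, or any role name; every batch
#'   must contain estimation samples.
#' @return The adjusted `omics_matrix` (log scale).
#' @export
eb_location_scale_adjust <- function(x, meta, estimate_on = c("all", "baseline", "qc")) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$scale != "log") stopf("EB adjustment operates on log-scale data")
  estimate_on <- match.arg(estimate_on)
  meta <- sample_meta(meta)
  meta <- meta[meta$sample_id %in% sample_ids(x), ]
  batches <- unique(meta$batch)
  if (length(batches) < 2) return(x)
  est_ids <- lapply(batches, function(b) {
    m <- meta[meta$batch == b, ]
    ids <- if (estimate_on == "all") m$sample_id else m$sample_id[m$role == estimate_on]
    if (length(ids) == 0)
      stopf("batch %s has no '%s' samples to estimate on", b, estimate_on)
    ids
  })
  names(est_ids) <- batches
  v <- x$values
  if (anyNA(v)) stopf("EB adjustment needs a complete matrix; impute first")
  est_all <- unlist(est_ids, use.names = FALSE)
  n_b <- lengths(est_ids)
  batch_means <- vapply(batches, function(b)
    rowMeans(v[, est_ids[[b]], drop = FALSE]), numeric(nrow(v)))
  grand <- as.vector(batch_means %*% (n_b / sum(n_b)))
  resid <- v[, est_all, drop = FALSE] -
    batch_means[, rep(batches, n_b), drop = FALSE]
  var_pooled <- rowMeans(resid^2)
  var_pooled[var_pooled < 1e-12] <- 1e-12
  z <- (v - grand) / sqrt(var_pooled)
  out <- z
  for (b in batches) {
    ids <- est_ids[[b]]
    z_est <- z[, ids, drop = FALSE]
    gamma_hat <- rowMeans(z_est)
    delta_hat <- if (length(ids) > 1) row_vars(z_est) else rep(1, nrow(z))
    delta_hat[!is.finite(delta_hat) | delta_hat < 1e-12] <- 1e-12
    post <- eb_solve(z_est, gamma_hat, delta_hat)
    cols <- meta$sample_id[meta$batch == b]
    out[, cols] <- (z[, cols, drop = FALSE] - post$gamma) / sqrt(post$delta)
  }
  adj <- out * sqrt(var_pooled) + grand
  dimnames(adj) <- dimnames(v)
  omics_matrix(adj, x$modality, "log")
}
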