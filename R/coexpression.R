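#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power beta, builds the unsigned weighted adjacency
#' `a_ij = |cor(i, j)|^beta` over feature profiles and evaluates the
#' scale-free topology fit: connectivities `k_i = sum_j a_ij` are binned
#' into `n_bins` logarithmic bins and `log10 p(k)` is regressed on
#' `log10 k`. The chosen power is the lowest with fit R-squared at or above
#' `rsq_cut` (and non-positive slope); when no power qualifies, the elbow
#' of the R-squared curve (most negative second difference, the strongest
#' bend toward diminishing returns) is used instead.
#'
#' @param profiles numeric matrix, features x observations (median-collapsed
#'   profiles); at least 10 features.
#' @param powers candidate powers (default 1:20).
#' @param rsq_cut fit threshold (default 0.8).
#' @param n_bins connectivity bins for the fit (default 10).
#' @return A list of class `soft_threshold_scan`: `powers`, `rsq`, `slope`,
#'   `mean_k`, `power` (the choice), `rule` (`"threshold"` or `"elbow"`).
#' @export
pick_soft_threshold <- function(profiles, powers = 1:20, rsq_cut = 0.8,
                                n_bins = 10) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 10) stopf("soft-threshold fit needs >= 10 features")
  ac <- abs(stats::cor(t(profiles)))
  diag(ac) <- 0
  rsq <- slope <- mean_k <- rep(NA_real_, length(powers))
  for (i in seq_along(powers)) {
    k <- rowSums(ac^powers[i])
    mean_k[i] <- mean(k)
    fit <- scale_free_fit(k, n_bins)
    rsq[i] <- fit$rsq; slope[i] <- fit$slope
  }
  choice <- choose_soft_power(powers, rsq, slope, rsq_cut)
  structure(list(powers = powers, rsq = rsq, slope = slope, mean_k = mean_k,
                 power = choice$power, rule = choice$rule),
            class = "soft_threshold_scan")
}

# log k vs log p(k) regression over logarithmic connectivity bins
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins || stats::sd(k) == 0)
    return(list(rsq = NA_real_, slope = NA_real_))
  brk <- exp(seq(log(min(k)), log(max(k)), length.out = n_bins + 1))
  brk[1] <- brk[1] * (1 - 1e-8); brk[n_bins + 1] <- brk[n_bins + 1] * (1 + 1e-8)
  bin <- cut(k, brk, include.lowest = TRUE)
  freq <- tapply(rep(1, length(k)), bin, sum)
  centre <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(list(rsq = NA_real_, slope = NA_real_))
  lx <- log10(centre[keep]); ly <- log10(freq[keep] / length(k))
  fit <- stats::lm(ly ~ lx)
  list(rsq = summary(fit)$r.squared, slope = stats::coef(fit)[2])
}

choose_soft_power <- function(powers, rsq, slope, rsq_cut) {
  ok <- !is.na(rsq) & rsq >= rsq_cut & (is.na(slope) | slope <= 0)
  if (any(ok)) return(list(power = powers[which(ok)[1]], rule = "threshold"))
  usable <- which(!is.na(rsq))
  if (length(usable) < 3) {
    warnf("scale-free fit degenerate; falling back to median candidate power")
    return(list(power = powers[ceiling(length(powers) / 2)], rule = "fallback"))
  }
  r <- rsq[usable]
  d2 <- diff(diff(r))
  elbow <- usable[which.min(d2) + 1L]   # strongest downward bend of the curve
  list(power = powers[elbow], rule = "elbow")
}

#' Unsigned topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal, computed from a symmetric adjacency with entries in
#' \[0, 1\]. Neighbourhood sharing smooths the raw adjacency before
#' clustering.
#'
#' @param adjacency symmetric numeric matrix, entries in \[0, 1\].
#' @return Symmetric TOM matrix with entries in \[0, 1\] and unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-8)) stopf("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stopf("adjacency entries must lie in [0, 1]")
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Eigenprofile of a module
#'
#' The first principal-component score vector of the standardized member
#' profiles (one value per observation), sign-oriented to correlate
#' positively with the member mean profile. Carries an `explained`
#' attribute (fraction of variance on the first component).
#'
#' @param profiles numeric matrix, features x observations.
#' @param members feature ids (or indices) of the module.
#' @return Numeric vector over observations with attribute `explained`.
#' @export
module_eigenprofile <- function(profiles, members) {
  sub <- profiles[members, , drop = FALSE]
  if (nrow(sub) == 0) stopf("module has no members")
  z <- standardize_rows(sub)
  if (nrow(z) == 1) {
    out <- as.numeric(z)
    attr(out, "explained") <- 1
    return(out)
  }
  sv <- svd(z)
  e <- sv$v[, 1]
  expl <- sv$d[1]^2 / sum(sv$d^2)
  ref <- colMeans(z)
  if (stats::sd(ref) > 0 && stats::cor(e, ref) < 0) e <- -e
  out <- as.numeric(e)
  attr(out, "explained") <- expl
  out
}

#' Weighted-correlation module detection
#'
#' Reproduces the clustering procedure used for both modalities:
#' unsigned adjacency `|cor|^power` on (median-collapsed) profiles,
#' topological-overlap dissimilarity `1 - TOM`, average-linkage
#' hierarchical clustering, a simplified dynamic height cut whose
#' aggressiveness maps from `deep_split` (0..4 selects the cut height as a
#' decreasing fraction 0.99, 0.95, 0.85, 0.65, 0.55 of the tree height),
#' removal of clusters below `min_size` (label 0), and iterative merging of
#' modules whose eigenprofile dissimilarity `1 - cor` falls below
#' `merge_threshold` (i.e. correlation above `1 - merge_threshold`;
#' `merge_on = "correlation"` flips the reading so `merge_threshold` is the
#' correlation cutoff itself). Module labels are ordered by decreasing size.
#'
#' @param profiles numeric matrix, features x observations.
#' @param min_size minimum module size (smaller clusters become label 0).
#' @param deep_split integer 0..4, split aggressiveness.
#' @param merge_threshold merge cut (see Description; default 0.60).
#' @param power soft-threshold power; `NULL` runs [pick_soft_threshold()].
#' @param merge_on `"dissimilarity"` (default) or `"correlation"`.
#' @return A list of class `module_set`: `labels` (named integer vector,
#'   0 = unassigned), `eigenprofiles` (module x observation matrix),
#'   `merge_history`, `params`, `scan` (the soft-threshold scan, if run).
#' @export
cluster_modules <- function(profiles, min_size = 3, deep_split = 3,
                            merge_threshold = 0.60, power = NULL,
                            merge_on = c("dissimilarity", "correlation")) {
  profiles <- as.matrix(profiles)
  merge_on <- match.arg(merge_on)
  if (!deep_split %in% 0:4) stopf("deep_split must be an integer in 0..4")
  if (merge_threshold <= 0 || merge_threshold >= 1)
    stopf("merge_threshold must be in (0, 1)")
  if (!is_count(min_size)) stopf("min_size must be a count >= 1")
  ids <- rownames(profiles) %||% as.character(seq_len(nrow(profiles)))
  rownames(profiles) <- ids
  variable <- apply(profiles, 1, stats::sd) > 0
  labels <- stats::setNames(rep(0L, nrow(profiles)), ids)
  scan <- NULL
  if (sum(variable) >= 2) {
    pf <- profiles[variable, , drop = FALSE]
    if (is.null(power)) {
      scan <- tryCatch(pick_soft_threshold(pf), error = function(e) NULL)
      power <- if (!is.null(scan)) scan$power else 6
    }
    adj <- abs(stats::cor(t(pf)))^power
    tom <- tom_similarity(adj)
    diss <- 1 - tom
    tree <- stats::hclust(stats::as.dist(diss), method = "average")
    # average linkage is monotone; fix numerical-epsilon height inversions
    if (is.unsorted(tree$height)) tree$height <- sort(tree$height)
    cut_frac <- c(0.99, 0.95, 0.85, 0.65, 0.55)[deep_split + 1L]
    h <- cut_frac * max(tree$height)
    raw <- stats::cutree(tree, h = h)
    sizes <- table(raw)
    keep <- as.integer(names(sizes)[sizes >= min_size])
    lab <- ifelse(raw %in% keep, raw, 0L)
    # relabel by decreasing size, 1..K
    if (any(lab > 0)) {
      ord <- names(sort(table(lab[lab > 0]), decreasing = TRUE))
      remap <- stats::setNames(seq_along(ord), ord)
      lab[lab > 0] <- remap[as.character(lab[lab > 0])]
    }
    labels[rownames(pf)] <- lab
  }
  # iterative eigenprofile merging
  merge_history <- list()
  cor_cut <- if (merge_on == "dissimilarity") 1 - merge_threshold else merge_threshold
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    eig <- t(vapply(mods, function(m)
      module_eigenprofile(profiles, names(labels)[labels == m]),
      numeric(ncol(profiles))))
    rownames(eig) <- mods
    cc <- stats::cor(t(eig))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= cor_cut) break
    m1 <- mods[best[1]]; m2 <- mods[best[2]]
    merge_history[[length(merge_history) + 1L]] <-
      list(merged = c(m1, m2), correlation = max(cc))
    labels[labels == m2] <- m1
    # keep labels dense and size-ordered
    mods <- sort(unique(labels[labels > 0]))
    ord <- names(sort(table(labels[labels > 0]), decreasing = TRUE))
    remap <- stats::setNames(seq_along(ord), ord)
    new <- labels
    new[labels > 0] <- remap[as.character(labels[labels > 0])]
    labels <- new
  }
  mods <- sort(unique(labels[labels > 0]))
  eig <- if (length(mods)) {
    e <- t(vapply(mods, function(m)
      module_eigenprofile(profiles, names(labels)[labels == m]),
      numeric(ncol(profiles))))
    rownames(e) <- paste0("ME", mods)
    colnames(e) <- colnames(profiles)
    e
  } else matrix(numeric(0), 0, ncol(profiles))
  structure(list(labels = labels, eigenprofiles = eig,
                 merge_history = merge_history,
                 params = list(min_size = min_size, deep_split = deep_split,
                               merge_threshold = merge_threshold, power = power,
                               merge_on = merge_on),
                 scan = scan),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<module_set> %d features, %d modules (power %s)\n",
              length(x$labels), sum(names(tab) != "0"), x$params$power))
  print(tab)
  invisible(x)
}

#' Integrated trajectory PCA
#'
#' Centered (optionally unit-scaled) PCA of a batch-corrected,
#' feature-complete matrix, with the per-component percentage of variance,
#' per-batch temporal trajectories (ordered median-collapsed sample scores)
#' and correlation-circle coordinates (correlation of each feature with
#' each component score).
#'
#' @param x a feature-complete [omics_matrix()] (log scale recommended).
#' @param meta the study [sample_meta()].
#' @param scale. unit-scale features before PCA (default TRUE).
#' @param n_components components to report (default 2).
#' @return A list of class `trajectory_pca`: `scores`, `loadings`,
#'   `percent_variance`, `trajectories` (per batch, ordered by timepoint),
#'   `correlation_circle`.
#' @export
trajectory_pca <- function(x, meta, scale. = TRUE, n_components = 2) {
  stopifnot(inherits(x, "omics_matrix"))
  if (anyNA(x$values)) stopf("PCA needs a complete matrix; impute upstream")
  meta <- sample_meta(meta)
  meta <- meta[meta$sample_id %in% sample_ids(x), ]
  v <- x$values[apply(x$values, 1, stats::sd) > 0 | !scale., , drop = FALSE]
  pca <- stats::prcomp(t(v), center = TRUE, scale. = scale.)
  pv <- 100 * pca$sdev^2 / sum(pca$sdev^2)
  nc <- min(n_components, ncol(pca$x))
  scores <- pca$x
  cc <- stats::cor(t(v), scores[, seq_len(nc), drop = FALSE])
  traj <- lapply(split(meta, meta$batch), function(m) {
    m <- m[m$role != "qc", ]
    med <- vapply(split(m$sample_id, m$timepoint_days), function(ids)
      apply(scores[ids, seq_len(nc), drop = FALSE], 2, stats::median),
      numeric(nc))
    t(med[, order(as.numeric(colnames(med))), drop = FALSE])
  })
  structure(list(scores = scores, loadings = pca$rotation,
                 percent_variance = pv, trajectories = traj,
                 correlation_circle = cc),
            class = "trajectory_pca")
}
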