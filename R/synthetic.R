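#' Configuration for a synthetic multi-batch time-course study
#'
#' Describes a study emulating a multi-inducer senescence design: several
#' batches (one per stress inducer), each a time course sampled in
#' replicates, with a metabolome and a transcriptome measured on the same
#' samples. Latent temporal modules are planted in both modalities, plus
#' designated hub metabolites whose trajectories are shared with a block of
#' partner genes in every batch, so the cross-batch correlation network has a
#' known hub structure. Batch effects are multiplicative per (feature,
#' batch); replicate noise is log-normal.
#'
#' Defaults encode the reference study conditions used throughout the test
#' suite: 4 batches x 6 timepoints x 3 replicates, 60 metabolites, 500
#' genes, 5 modules, 2 hub metabolites with 30 gene partners each.
#'
#' @param n_batches number of batches (inducers).
#' @param timepoints numeric vector of sampling days (shared by all batches).
#' @param n_replicates replicates per (batch, timepoint).
#' @param n_metabolites,n_genes feature counts.
#' @param n_modules number of planted metabolite modules (non-hub).
#' @param n_gene_modules total planted gene modules, the first
#'   `length(hubs)` of which carry the hub trajectories.
#' @param hubs list of hub specifications, each a list with `metabolite`
#'   (index into the metabolome), `n_partners` (partner gene count) and
#'   `target_cor` (target absolute Spearman correlation per batch).
#' @param batch_sigma_loc,batch_sigma_scale log-normal batch-effect
#'   parameters: a batch-wide location shift drawn with sd
#'   `batch_sigma_loc` plus per-feature scatter with sd `batch_sigma_scale`
#'   (both on the natural-log scale).
#' @param noise_sd replicate-level measurement noise sd (natural-log scale).
#' @param qc_fraction fraction of each batch's sample count added as pooled
#'   QC samples (0 disables).
#' @param gene_noise_frac fraction of genes left unassigned (label 0):
#'   flat baseline profiles carrying replicate noise only.
#' @param shared_dynamics if `TRUE`, every batch re-measures the same latent
#'   trajectories (technical-batch benchmark setting); if `FALSE` (default),
#'   each batch has its own trajectory realization (inducer-specific
#'   kinetics, the study design proper).
#' @param seed integer seed; the single source of randomness.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_batches = 4,
                             timepoints = c(0, 2, 4, 7, 10, 14),
                             n_replicates = 3,
                             n_metabolites = 60,
                             n_genes = 500,
                             n_modules = 5,
                             n_gene_modules = 5,
                             hubs = list(
                               list(metabolite = 1, n_partners = 30, target_cor = 0.8),
                               list(metabolite = 2, n_partners = 30, target_cor = 0.8)),
                             batch_sigma_loc = 0.5,
                             batch_sigma_scale = 0.25,
                             noise_sd = 0.2,
                             qc_fraction = 0,
                             gene_noise_frac = 0.1,
                             shared_dynamics = FALSE,
                             seed = 42) {
  for (nm in c("n_batches", "n_replicates", "n_metabolites", "n_genes",
               "n_modules", "n_gene_modules"))
    if (!is_count(get(nm))) stopf("'%s' must be a count >= 1", nm)
  if (length(timepoints) < 2 || any(timepoints < 0) || anyDuplicated(timepoints))
    stopf("'timepoints' must be >= 2 distinct non-negative day values")
  if (noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (batch_sigma_loc < 0 || batch_sigma_scale < 0)
    stopf("batch-effect sigmas must be >= 0")
  if (qc_fraction < 0 || qc_fraction >= 1) stopf("'qc_fraction' must be in [0, 1)")
  if (length(hubs) > n_gene_modules)
    stopf("more hubs (%d) than gene modules (%d)", length(hubs), n_gene_modules)
  for (h in hubs) {
    if (!all(c("metabolite", "n_partners", "target_cor") %in% names(h)))
      stopf("each hub needs fields metabolite, n_partners, target_cor")
    if (h$metabolite < 1 || h$metabolite > n_metabolites)
      stopf("hub metabolite index %s out of range 1..%d", h$metabolite, n_metabolites)
    if (h$n_partners < 1 || h$n_partners > n_genes)
      stopf("hub partner count must be in 1..n_genes")
    if (h$target_cor <= 0 || h$target_cor > 1)
      stopf("hub target_cor must be in (0, 1]")
  }
  hub_idx <- vapply(hubs, function(h) as.integer(h$metabolite), integer(1))
  if (anyDuplicated(hub_idx)) stopf("hub metabolite indices must be distinct")
  if (sum(vapply(hubs, function(h) h$n_partners, numeric(1))) +
      round(gene_noise_frac * n_genes) > n_genes)
    stopf("hub partners plus noise genes exceed n_genes")
  structure(list(
    n_batches = as.integer(n_batches), timepoints = sort(as.numeric(timepoints)),
    n_replicates = as.integer(n_replicates),
    n_metabolites = as.integer(n_metabolites), n_genes = as.integer(n_genes),
    n_modules = as.integer(n_modules), n_gene_modules = as.integer(n_gene_modules),
    hubs = hubs, batch_sigma_loc = batch_sigma_loc,
    batch_sigma_scale = batch_sigma_scale, noise_sd = noise_sd,
    qc_fraction = qc_fraction, gene_noise_frac = gene_noise_frac,
    shared_dynamics = isTRUE(shared_dynamics), seed = as.integer(seed)),
    class = "synthetic_config")
}

# one standardized trajectory over scaled time t01 in [0,1]
make_shape <- function(t01, shape = c("linear", "logistic", "transient", "flat")) {
  shape <- match.arg(shape)
  v <- switch(shape,
    linear = t01,
    logistic = {
      k <- stats::runif(1, 6, 12); t0 <- stats::runif(1, 0.3, 0.7)
      1 / (1 + exp(-k * (t01 - t0)))
    },
    transient = {
      t0 <- stats::runif(1, 0.2, 0.8); w <- stats::runif(1, 0.15, 0.35)
      exp(-((t01 - t0) / w)^2)
    },
    flat = rep(0, length(t01)))
  s <- stats::sd(v)
  if (s == 0) return(v)
  v <- (v - mean(v)) / s
  # blend with the standardized rank vector: spreads near-tied values (e.g.
  # a transient's baseline points) so the rank order of the trajectory is
  # stable under replicate-level noise
  r <- rank(v, ties.method = "first")
  rs <- (r - mean(r)) / stats::sd(r)
  v <- 0.5 * v + 0.5 * rs
  sgn <- sample(c(-1, 1), 1)
  sgn * (v - mean(v)) / stats::sd(v)
}

draw_trajectory <- function(n_batches, t01, shared) {
  # transients dominate: monotone shapes are rank-degenerate with each other
  shapes <- c("linear", "logistic", "transient")
  w <- c(0.2, 0.3, 0.5)
  if (shared) {
    one <- make_shape(t01, sample(shapes, 1, prob = w))
    matrix(rep(one, n_batches), nrow = n_batches, byrow = TRUE)
  } else {
    t(vapply(seq_len(n_batches),
             function(b) make_shape(t01, sample(shapes, 1, prob = w)),
             numeric(length(t01))))
  }
}

# worst violation of per-pair concatenated-correlation caps against the
# already-accepted trajectories (<= 0 means all caps respected)
concat_cor_excess <- function(cand, others, caps) {
  if (length(others) == 0) return(-1)
  cv <- as.vector(t(cand))
  max(vapply(seq_along(others), function(i)
    abs(stats::cor(cv, as.vector(t(others[[i]])))) - caps[i], numeric(1)))
}

# TRUE when the pair is correlated (|Spearman| > thr) in *every* batch
all_batch_spearman <- function(a, b, thr) {
  all(vapply(seq_len(nrow(a)), function(i)
    abs(stats::cor(a[i, ], b[i, ], method = "spearman")) > thr, logical(1)))
}

#' Generate a synthetic multi-batch metabolome + transcriptome study
#'
#' Builds strictly positive raw-intensity matrices on the natural-exponential
#' scale: `intensity = exp(baseline + amplitude * module trajectory + noise)`.
#' Features in the same module share a latent trajectory per batch up to
#' feature amplitude and replicate noise; each hub metabolite's trajectory is
#' copied to its partner-gene module, so hub-partner correlations are planted
#' by construction in every batch. Latent trajectories are drawn under
#' rejection constraints that keep distinct modules decorrelated (so planted
#' structure is recoverable at zero noise) and prevent non-hub
#' metabolite/gene module pairs from correlating in all batches at once.
#' Batch-effect factors are drawn and stored in the ground truth but NOT
#' applied; see [inject_batch_effects()].
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_study` with elements `metabolome` and
#'   `transcriptome` ([omics_matrix()], raw scale), `meta` ([sample_meta()]),
#'   `truth` (planted structure: module labels, hub ids and partners,
#'   per-(feature, batch) multiplicative factors, clean latent profiles) and
#'   `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cfg <- config
  nb <- cfg$n_batches; tps <- cfg$timepoints; nt <- length(tps)
  nr <- cfg$n_replicates
  t01 <- (tps - min(tps)) / (max(tps) - min(tps))
  n_hubs <- length(cfg$hubs)
  n_reg_gene <- cfg$n_gene_modules - n_hubs

  # latent trajectories: hubs, metabolite modules, regular gene modules
  n_latent <- n_hubs + cfg$n_modules + n_reg_gene
  met_side <- seq_len(n_hubs + cfg$n_modules)
  gene_side <- c(seq_len(n_hubs),
                 n_hubs + cfg$n_modules + seq_len(n_reg_gene))
  # hubs must stand apart from every module trajectory (tight cap) while
  # module-module pairs only need moderate separation; additionally every
  # non-hub cross-side pair needs >= 1 batch with near-zero rank
  # correlation, so replicate noise cannot lift it over the network overlap
  # threshold in all batches at once
  # shared-dynamics studies only need non-duplicate trajectories: module and
  # hub recovery are properties of the batch-specific design
  hub_cap <- if (cfg$shared_dynamics) 0.95 else 0.25
  mod_cap <- if (cfg$shared_dynamics) 0.95 else 0.35
  screen_cut <- 0.2
  cap_of <- function(i) if (i <= n_hubs) hub_cap else mod_cap
  latents <- vector("list", n_latent)
  for (l in seq_len(n_latent)) {
    prev <- if (l %in% met_side) intersect(seq_len(l - 1L), met_side)
            else intersect(seq_len(l - 1L), gene_side)
    caps <- vapply(prev, function(j) min(cap_of(l), cap_of(j)), numeric(1))
    cross <- if (cfg$shared_dynamics) integer(0)
             else if (l %in% met_side) setdiff(intersect(seq_len(l - 1L), gene_side), l)
             else setdiff(intersect(seq_len(l - 1L), met_side), l)
    # total constraint violation: concatenated-correlation cap excess plus,
    # per cross pair, how far its best (lowest-|rho|) batch sits above the
    # screen cut
    violation <- function(cand) {
      v <- max(0, concat_cor_excess(cand, latents[prev], caps))
      for (j in cross) {
        rho <- vapply(seq_len(nb), function(b)
          abs(stats::cor(cand[b, ], latents[[j]][b, ], method = "spearman")),
          numeric(1))
        v <- v + max(0, min(rho) - screen_cut)
      }
      v
    }
    best <- draw_trajectory(nb, t01, cfg$shared_dynamics)
    best_v <- violation(best)
    for (try in seq_len(500L)) {
      if (best_v <= 0) break
      cand <- draw_trajectory(nb, t01, cfg$shared_dynamics)
      v <- violation(cand)
      if (v < best_v) { best <- cand; best_v <- v }
    }
    # local repair: redraw single batch rows while that reduces violation
    if (best_v > 0 && !cfg$shared_dynamics) {
      for (rep_ in seq_len(2000L)) {
        if (best_v <= 0) break
        cand <- best
        cand[sample(nb, 1), ] <- make_shape(t01, sample(c("linear", "logistic",
                                                          "transient"), 1,
                                                        prob = c(0.2, 0.3, 0.5)))
        v <- violation(cand)
        if (v < best_v) { best <- cand; best_v <- v }
      }
    }
    if (best_v > 0)
      warnf("trajectory %d accepted with residual constraint violation %.3f", l, best_v)
    latents[[l]] <- best
  }

  # feature -> latent assignment and truth labels
  hub_met_idx <- vapply(cfg$hubs, function(h) as.integer(h$metabolite), integer(1))
  met_latent <- integer(cfg$n_metabolites)
  met_module <- integer(cfg$n_metabolites)
  met_latent[hub_met_idx] <- seq_len(n_hubs)
  met_module[hub_met_idx] <- 0L          # hubs sit outside the planted modules
  non_hub <- setdiff(seq_len(cfg$n_metabolites), hub_met_idx)
  mods <- rep(seq_len(cfg$n_modules), length.out = length(non_hub))
  met_module[non_hub] <- mods
  met_latent[non_hub] <- n_hubs + mods

  n_noise_gene <- round(cfg$gene_noise_frac * cfg$n_genes)
  gene_module <- integer(cfg$n_genes)
  gene_latent <- integer(cfg$n_genes)    # 0 = flat baseline (noise only)
  nxt <- 1L
  for (k in seq_len(n_hubs)) {
    idx <- nxt:(nxt + cfg$hubs[[k]]$n_partners - 1L)
    gene_module[idx] <- k
    gene_latent[idx] <- k
    nxt <- nxt + cfg$hubs[[k]]$n_partners
  }
  noise_idx <- if (n_noise_gene > 0) nxt:(nxt + n_noise_gene - 1L) else integer(0)
  nxt <- nxt + n_noise_gene
  rest <- if (nxt <= cfg$n_genes) nxt:cfg$n_genes else integer(0)
  if (n_reg_gene > 0 && length(rest) > 0) {
    gm <- rep(seq_len(n_reg_gene), length.out = length(rest))
    gene_module[rest] <- n_hubs + gm
    gene_latent[rest] <- n_hubs + cfg$n_modules + gm
  }

  met_ids <- sprintf("M%03d", seq_len(cfg$n_metabolites))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  batches <- sprintf("B%d", seq_len(nb))

  met_base <- stats::rnorm(cfg$n_metabolites, 11, 1)
  met_amp <- stats::runif(cfg$n_metabolites, 0.8, 1.6)
  gene_base <- stats::rnorm(cfg$n_genes, 8, 1)
  gene_amp <- stats::runif(cfg$n_genes, 0.8, 1.6) *
    sample(c(-1, 1), cfg$n_genes, replace = TRUE)
  # clean latent (log-e) profile per feature over (batch, timepoint);
  # unassigned features (latent 0) are flat baseline, replicate noise only
  clean_profile <- function(base, amp, latent_of) {
    out <- matrix(NA_real_, length(base), nb * nt,
                  dimnames = list(NULL, paste0(rep(batches, each = nt), "@",
                                               rep(tps, nb))))
    for (f in seq_along(base)) {
      out[f, ] <- if (latent_of[f] > 0)
        base[f] + amp[f] * as.vector(t(latents[[latent_of[f]]]))
      else rep(base[f], nb * nt)
    }
    out
  }
  met_clean <- clean_profile(met_base, met_amp, met_latent)
  rownames(met_clean) <- met_ids
  gene_clean <- clean_profile(gene_base, gene_amp, gene_latent)
  rownames(gene_clean) <- gene_ids

  # sample layout and measured matrices
  n_qc <- if (cfg$qc_fraction > 0) ceiling(cfg$qc_fraction * nt * nr) else 0L
  meta_rows <- list(); met_cols <- list(); gene_cols <- list()
  for (b in seq_len(nb)) {
    for (ti in seq_len(nt)) for (r in seq_len(nr)) {
      sid <- sprintf("%s_D%s_R%d", batches[b], format(tps[ti], trim = TRUE), r)
      role <- if (tps[ti] == min(tps)) "baseline" else "treated"
      meta_rows[[length(meta_rows) + 1L]] <-
        data.frame(sample_id = sid, batch = batches[b], timepoint_days = tps[ti],
                   replicate = r, role = role, stringsAsFactors = FALSE)
      col <- (b - 1L) * nt + ti
      met_cols[[sid]] <- met_clean[, col] + stats::rnorm(cfg$n_metabolites, 0, cfg$noise_sd)
      gene_cols[[sid]] <- gene_clean[, col] + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
    }
    if (n_qc > 0) {
      cols_b <- (b - 1L) * nt + seq_len(nt)
      met_pool <- rowMeans(met_clean[, cols_b, drop = FALSE])
      gene_pool <- rowMeans(gene_clean[, cols_b, drop = FALSE])
      for (q in seq_len(n_qc)) {
        sid <- sprintf("%s_QC_R%d", batches[b], q)
        meta_rows[[length(meta_rows) + 1L]] <-
          data.frame(sample_id = sid, batch = batches[b], timepoint_days = NA_real_,
                     replicate = q, role = "qc", stringsAsFactors = FALSE)
        met_cols[[sid]] <- met_pool + stats::rnorm(cfg$n_metabolites, 0, cfg$noise_sd)
        gene_cols[[sid]] <- gene_pool + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
      }
    }
  }
  meta <- sample_meta(do.call(rbind, meta_rows))
  met_mat <- exp(do.call(cbind, met_cols)); rownames(met_mat) <- met_ids
  gene_mat <- exp(do.call(cbind, gene_cols)); rownames(gene_mat) <- gene_ids

  # planted multiplicative batch effects (stored, not applied)
  draw_factors <- function(nf, ids) {
    shift <- stats::rnorm(nb, 0, cfg$batch_sigma_loc)
    f <- exp(matrix(shift, nf, nb, byrow = TRUE) +
             matrix(stats::rnorm(nf * nb, 0, cfg$batch_sigma_scale), nf, nb))
    dimnames(f) <- list(ids, batches)
    f
  }
  truth <- list(
    metabolite_modules = stats::setNames(met_module, met_ids),
    gene_modules = stats::setNames(gene_module, gene_ids),
    hub_features = met_ids[hub_met_idx],
    hub_partners = stats::setNames(
      lapply(seq_len(n_hubs), function(k) gene_ids[gene_module == k]),
      met_ids[hub_met_idx]),
    hub_target_cor = vapply(cfg$hubs, function(h) h$target_cor, numeric(1)),
    batch_factors = list(metabolite = draw_factors(cfg$n_metabolites, met_ids),
                         gene = draw_factors(cfg$n_genes, gene_ids)),
    clean_profiles = list(metabolite = met_clean, gene = gene_clean),
    timepoints = tps, batches = batches)

  structure(list(
    metabolome = omics_matrix(met_mat, "metabolite", "raw"),
    transcriptome = omics_matrix(gene_mat, "gene", "raw"),
    meta = meta, truth = truth, config = cfg),
    class = "synthetic_study")
}

#' Apply planted multiplicative batch effects
#'
#' Multiplies every entry by its feature-by-batch factor from the ground
#' truth. QC samples receive their batch's factors too (they are measured in
#' the batch). Output stays strictly positive.
#'
#' @param matrix a raw-scale [omics_matrix()].
#' @param meta the study [sample_meta()] (maps samples to batches).
#' @param truth the `truth` element of a [generate_study()] result.
#' @return An `omics_matrix` with batch effects injected.
#' @export
inject_batch_effects <- function(matrix, meta, truth) {
  stopifnot(inherits(matrix, "omics_matrix"))
  fac <- truth$batch_factors[[matrix$modality]]
  if (is.null(fac)) stopf("no batch factors for modality '%s'", matrix$modality)
  meta <- sample_meta(meta)
  if (!all(feature_ids(matrix) %in% rownames(fac)))
    stopf("batch factor missing for feature(s): %s",
          paste(utils::head(setdiff(feature_ids(matrix), rownames(fac)), 3), collapse = ", "))
  if (!all(meta$batch %in% colnames(fac)))
    stopf("batch factor missing for batch(es): %s",
          paste(setdiff(unique(meta$batch), colnames(fac)), collapse = ", "))
  v <- matrix$values
  batch_of <- stats::setNames(meta$batch, meta$sample_id)[colnames(v)]
  if (anyNA(batch_of)) stopf("samples without metadata: %s",
                             paste(colnames(v)[is.na(batch_of)], collapse = ", "))
  v <- v * fac[rownames(v), batch_of]
  omics_matrix(v, matrix$modality, matrix$scale)
}

#' Write / read a synthetic study as plain text
#'
#' `metabolome.tsv`, `transcriptome.tsv` (feature id + sample columns),
#' `samples.tsv` (the metadata table) and `truth.json` (planted structure).
#' The round trip through [read_study()] restores numerically identical
#' matrices.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!nzchar(dir)) stopf("empty directory path")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(study$metabolome, file.path(dir, "metabolome.tsv"))
  write_matrix(study$transcriptome, file.path(dir, "transcriptome.tsv"))
  write_sample_meta(study$meta, file.path(dir, "samples.tsv"))
  tr <- study$truth
  json <- list(
    metabolite_modules = as.list(tr$metabolite_modules),
    gene_modules = as.list(tr$gene_modules),
    hub_features = tr$hub_features,
    hub_partners = tr$hub_partners,
    hub_target_cor = tr$hub_target_cor,
    batch_factors = lapply(tr$batch_factors, function(m)
      list(rows = rownames(m), cols = colnames(m), values = unname(apply(m, 1, c, simplify = FALSE)))),
    clean_profiles = lapply(tr$clean_profiles, function(m)
      list(rows = rownames(m), cols = colnames(m), values = unname(apply(m, 1, c, simplify = FALSE)))),
    timepoints = tr$timepoints, batches = tr$batches)
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  if (!dir.exists(dir)) stopf("directory not found: %s", dir)
  unpack <- function(x) {
    m <- do.call(rbind, lapply(x$values, unlist))
    dimnames(m) <- list(unlist(x$rows), unlist(x$cols))
    m
  }
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  truth <- list(
    metabolite_modules = unlist(tr$metabolite_modules),
    gene_modules = unlist(tr$gene_modules),
    hub_features = unlist(tr$hub_features),
    hub_partners = lapply(tr$hub_partners, unlist),
    hub_target_cor = unlist(tr$hub_target_cor),
    batch_factors = lapply(tr$batch_factors, unpack),
    clean_profiles = lapply(tr$clean_profiles, unpack),
    timepoints = unlist(tr$timepoints), batches = unlist(tr$batches))
  structure(list(
    metabolome = read_matrix(file.path(dir, "metabolome.tsv"), "metabolite", "raw"),
    transcriptome = read_matrix(file.path(dir, "transcriptome.tsv"), "gene", "raw"),
    meta = read_sample_meta(file.path(dir, "samples.tsv")),
    truth = truth, config = NULL),
    class = "synthetic_study")
}
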