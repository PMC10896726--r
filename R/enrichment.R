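#' Hypergeometric over-representation of a gene set
#'
#' Upper-tail test `P(X >= k)` for the overlap k between a query list and a
#' gene set inside a finite universe, via `stats::phyper`. When a
#' collection is supplied, p-values are BH-adjusted across its sets.
#'
#' @param query character vector of query gene ids (must lie in the
#'   universe).
#' @param sets a `gene_set_collection` (or plain named list of member
#'   vectors); each set is intersected with the universe.
#' @param universe character vector of all testable gene ids.
#' @return Data frame with `set_id`, `universe_size`, `set_size` (K),
#'   `query_size` (n), `overlap` (k), `p_value`, `q_value`.
#' @export
hypergeometric_ora <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside))
    stopf("query gene(s) outside the universe: %s",
          paste(utils::head(outside, 3), collapse = ", "))
  if (!is.list(sets)) sets <- list(set = sets)
  n <- length(query)
  big_n <- length(universe)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    k_cap <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, k_cap, big_n - k_cap, n, lower.tail = FALSE)
    data.frame(set_id = id, universe_size = big_n, set_size = k_cap,
               query_size = n, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out
}

#' Rank genes by end-versus-start log2 fold change
#'
#' Score per gene: mean log2 expression at the end of the time course minus
#' the mean at its start, in one dataset; genes ordered by decreasing score
#' with ties broken by id. The ordering is invariant to adding a constant
#' to every sample.
#'
#' @param x a log-scale gene [omics_matrix()].
#' @param meta the study [sample_meta()].
#' @param dataset batch id.
#' @param start_timepoint,end_timepoint reference days; default the
#'   dataset's first and last.
#' @return Named numeric vector of scores, sorted decreasing.
#' @export
rank_genes_by_foldchange <- function(x, meta, dataset,
                                     start_timepoint = NULL, end_timepoint = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$scale != "log") stopf("ranking expects a log-scale matrix")
  meta <- sample_meta(meta)
  m <- meta[meta$batch == dataset & meta$role != "qc", ]
  if (nrow(m) == 0) stopf("no samples for dataset '%s'", dataset)
  t0 <- start_timepoint %||% min(m$timepoint_days)
  t1 <- end_timepoint %||% max(m$timepoint_days)
  s0 <- m$sample_id[m$timepoint_days == t0]
  s1 <- m$sample_id[m$timepoint_days == t1]
  if (length(s0) == 0 || length(s1) == 0)
    stopf("dataset %s: missing start or end timepoint samples", dataset)
  score <- rowMeans(x$values[, s1, drop = FALSE], na.rm = TRUE) -
    rowMeans(x$values[, s0, drop = FALSE], na.rm = TRUE)
  score[order(-score, names(score), method = "radix")]
}

# weighted Kolmogorov-Smirnov running sum; scores must be sorted decreasing
gsea_running_es <- function(scores, hit, weight) {
  n <- length(scores)
  k <- sum(hit)
  w <- abs(scores)^weight
  w_hit <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (w_hit > 0) w[hit] / w_hit else 1 / k
  inc[!hit] <- -1 / (n - k)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Pre-ranked gene-set enrichment with a permutation null
#'
#' Subramanian-style running sum over a ranked gene list: set hits advance
#' the sum by `|score|^weight` (normalized by the total hit weight), misses
#' retreat by `1/(N - K)`; the enrichment score ES is the extreme deviation.
#' The null distribution permutes gene labels (`n_perm` draws),
#' NES = ES / mean(|null ES| of matching sign), and the permutation p is
#' one-sided within the matching-sign null pool with a +1 correction.
#'
#' @param scores named numeric vector of per-gene ranking scores (sorted
#'   internally, decreasing, ties by id).
#' @param gene_set character vector of member ids; must intersect the list.
#' @param weight score-weighting exponent (default 1; 0 gives the classic
#'   Kolmogorov-Smirnov statistic).
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed for reproducible permutation p-values.
#' @return A list of class `gsea_result`: `es`, `nes`, `p_value`,
#'   `n_perm`, `leading_edge` (member ids up to the ES extremum).
#' @export
preranked_gsea <- function(scores, gene_set, weight = 1, n_perm = 1000,
                           seed = NULL) {
  if (is.null(names(scores))) stopf("'scores' must be named by gene id")
  if (n_perm < 100) stopf("n_perm must be >= 100")
  scores <- scores[order(-scores, names(scores), method = "radix")]
  hit <- names(scores) %in% gene_set
  k <- sum(hit)
  if (k == 0) stopf("gene set is disjoint from the ranked list")
  if (k == length(scores)) stopf("gene set covers the whole list")
  if (!is.null(seed)) set.seed(seed)
  es <- gsea_running_es(scores, hit, weight)
  null_es <- vapply(seq_len(n_perm), function(i)
    gsea_running_es(scores, sample(hit), weight), numeric(1))
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  # one-sided p within the matching-sign null pool (the usual pre-ranked
  # convention; using the full pool would double the size of the test)
  pool <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  p <- if (es >= 0) (sum(pool >= es) + 1) / (length(pool) + 1)
       else (sum(pool <= es) + 1) / (length(pool) + 1)
  # leading edge: hits at or before the running-sum extremum
  n <- length(scores)
  w <- abs(scores)^weight
  w_hit <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (w_hit > 0) w[hit] / w_hit else 1 / k
  inc[!hit] <- -1 / (n - k)
  run <- cumsum(inc)
  peak <- which.max(abs(run))
  leading <- if (es >= 0) names(scores)[seq_len(peak)][hit[seq_len(peak)]]
             else names(scores)[peak:n][hit[peak:n]]
  structure(list(es = es, nes = nes, p_value = p, n_perm = n_perm,
                 leading_edge = leading),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES %.3f, NES %.3f, p %.4g (%d permutations), %d leading-edge genes\n",
              x$es, x$nes, x$p_value, x$n_perm, length(x$leading_edge)))
  invisible(x)
}
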