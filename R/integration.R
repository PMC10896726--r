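#' Spearman correlation of every gene-metabolite pair in one dataset
#'
#' Correlates temporal profiles: both matrices are median-collapsed to the
#' dataset's timepoints (replicate-level noise would otherwise leak into the
#' profile correlation) and every gene x metabolite pair gets a Spearman
#' rho with average-rank tie handling. Requires at least 4 shared
#' timepoints.
#'
#' @param genes,metabolites log-scale [omics_matrix()] objects on the same
#'   samples.
#' @param meta the study [sample_meta()].
#' @param dataset batch id defining the dataset.
#' @return Data frame with `gene_id`, `metabolite_id`, `dataset`,
#'   `spearman_rho`, `n_points`.
#' @export
spearman_pairs <- function(genes, metabolites, meta, dataset) {
  stopifnot(inherits(genes, "omics_matrix"), inherits(metabolites, "omics_matrix"))
  meta <- sample_meta(meta)
  gm <- collapse_replicates_median(genes, meta[meta$batch == dataset, ])
  mm <- collapse_replicates_median(metabolites, meta[meta$batch == dataset, ])
  shared <- intersect(sample_ids(gm), sample_ids(mm))
  if (length(shared) < 4)
    stopf("dataset %s has %d shared timepoints; >= 4 required", dataset, length(shared))
  rho <- stats::cor(t(gm$values[, shared, drop = FALSE]),
                    t(mm$values[, shared, drop = FALSE]),
                    method = "spearman")
  data.frame(gene_id = rep(rownames(rho), ncol(rho)),
             metabolite_id = rep(colnames(rho), each = nrow(rho)),
             dataset = dataset,
             spearman_rho = as.vector(rho),
             n_points = length(shared),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select pairs correlated in every dataset
#'
#' Keeps gene-metabolite pairs whose absolute Spearman correlation exceeds
#' the threshold in *all* datasets. Sign consistency is not required (the
#' threshold applies to the absolute value per dataset); pairs missing from
#' any dataset are excluded rather than imputed. Raising the threshold can
#' only shrink the selection.
#'
#' @param tables list of [spearman_pairs()] data frames, one per dataset.
#' @param threshold absolute-correlation cutoff (default 0.5).
#' @return Data frame with `gene_id`, `metabolite_id`, `min_abs_rho`,
#'   `mean_rho` and one `rho_<dataset>` column per dataset.
#' @export
overlap_select <- function(tables, threshold = 0.5) {
  if (length(tables) == 0) stopf("no correlation tables supplied")
  keyed <- lapply(tables, function(tb) {
    key <- paste(tb$gene_id, tb$metabolite_id, sep = "\r")
    stats::setNames(tb$spearman_rho, key)
  })
  datasets <- vapply(tables, function(tb) tb$dataset[1], character(1))
  keys <- Reduce(intersect, lapply(keyed, names))
  if (length(keys) == 0)
    return(data.frame(gene_id = character(0), metabolite_id = character(0)))
  rho <- vapply(keyed, function(kv) kv[keys], numeric(length(keys)))
  rho <- matrix(rho, nrow = length(keys),
                dimnames = list(NULL, paste0("rho_", datasets)))
  ok <- rowSums(is.na(rho)) == 0 & apply(abs(rho), 1, min) > threshold
  parts <- do.call(rbind, strsplit(keys[ok], "\r", fixed = TRUE))
  out <- data.frame(gene_id = parts[, 1], metabolite_id = parts[, 2],
                    min_abs_rho = apply(abs(rho[ok, , drop = FALSE]), 1, min),
                    mean_rho = rowMeans(rho[ok, , drop = FALSE]),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(rho[ok, , drop = FALSE]))
}

#' Assemble the bipartite gene-metabolite network
#'
#' Undirected, unweighted graph whose nodes are all genes and metabolites
#' appearing in at least one selected pair; each selected pair is one
#' gene-metabolite edge (never gene-gene or metabolite-metabolite).
#'
#' @param pairs a non-empty [overlap_select()] data frame (or any data frame
#'   with `gene_id` and `metabolite_id` columns).
#' @return A list of class `bipartite_graph`: `nodes` (id, type, degree),
#'   `edges` (gene_id, metabolite_id).
#' @export
build_network <- function(pairs) {
  if (nrow(pairs) == 0) stopf("empty pair set")
  edges <- unique(pairs[, c("gene_id", "metabolite_id")])
  genes <- sort(unique(edges$gene_id))
  mets <- sort(unique(edges$metabolite_id))
  if (length(intersect(genes, mets)))
    stopf("ids occur as both gene and metabolite: %s",
          paste(utils::head(intersect(genes, mets), 3), collapse = ", "))
  nodes <- data.frame(
    id = c(genes, mets),
    type = rep(c("gene", "metabolite"), c(length(genes), length(mets))),
    stringsAsFactors = FALSE)
  deg <- table(c(edges$gene_id, edges$metabolite_id))
  nodes$degree <- as.integer(deg[nodes$id])
  structure(list(nodes = nodes, edges = edges), class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("<bipartite_graph> %d genes + %d metabolites, %d edges\n",
              sum(x$nodes$type == "gene"), sum(x$nodes$type == "metabolite"),
              nrow(x$edges)))
  invisible(x)
}

# Brandes (2001) accumulation of pair dependencies on an unweighted graph;
# adj is a list of integer neighbour vectors
brandes_betweenness <- function(adj) {
  n <- length(adj)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    pred <- vector("list", n)
    order_visited <- integer(0)
    queue <- c(s)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in pred[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2   # undirected: every pair counted twice
}

#' Exact betweenness centrality
#'
#' Brandes-style exact betweenness on the undirected, unweighted graph,
#' with shortest-path multiplicities handled. Disconnected graphs are
#' allowed (contributions accrue within components). Reported raw and
#' normalized by `(n - 1)(n - 2) / 2`.
#'
#' @param graph a [build_network()] result.
#' @return The `nodes` data frame with `betweenness` and
#'   `betweenness_norm` columns added.
#' @export
betweenness_centrality <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  nodes <- graph$nodes
  n <- nrow(nodes)
  if (n < 3) stopf("betweenness needs >= 3 nodes")
  idx <- stats::setNames(seq_len(n), nodes$id)
  adj <- vector("list", n)
  for (e in seq_len(nrow(graph$edges))) {
    i <- idx[[graph$edges$gene_id[e]]]
    j <- idx[[graph$edges$metabolite_id[e]]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  bc <- brandes_betweenness(adj)
  nodes$betweenness <- bc
  nodes$betweenness_norm <- bc / ((n - 1) * (n - 2) / 2)
  nodes
}

#' Rank network hubs by betweenness
#'
#' Nodes sorted by descending betweenness, ties broken by degree (higher
#' first) then id; the type column allows metabolite-only rankings.
#'
#' @param graph a [build_network()] result.
#' @param top_k rows to return (default 20; larger than the node count
#'   returns the full ranking).
#' @param type optionally restrict to `"gene"` or `"metabolite"` nodes.
#' @return Ranked data frame with a `rank` column.
#' @export
rank_hubs <- function(graph, top_k = 20, type = NULL) {
  tab <- betweenness_centrality(graph)
  if (!is.null(type)) tab <- tab[tab$type %in% type, ]
  ord <- order(-tab$betweenness, -tab$degree, tab$id, method = "radix")
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  utils::head(tab, top_k)
}

#' Genes consistently correlated with one metabolite
#'
#' Genes whose correlation with the metabolite has the requested sign and
#' absolute value above the threshold in at least `min_datasets` of the
#' supplied datasets (e.g. 3 of 4 senescence inducers with quiescence
#' excluded).
#'
#' @param tables list of [spearman_pairs()] data frames.
#' @param metabolite metabolite id.
#' @param sign `"positive"` or `"negative"`.
#' @param threshold absolute-correlation cutoff (default 0.5).
#' @param min_datasets required number of qualifying datasets.
#' @return Character vector of gene ids.
#' @export
correlated_gene_sets <- function(tables, metabolite, sign = c("positive", "negative"),
                                 threshold = 0.5, min_datasets = length(tables)) {
  sign <- match.arg(sign)
  known <- unique(unlist(lapply(tables, function(tb) tb$metabolite_id)))
  if (!metabolite %in% known) stopf("unknown metabolite: %s", metabolite)
  counts <- list()
  for (tb in tables) {
    sub <- tb[tb$metabolite_id == metabolite, ]
    qual <- abs(sub$spearman_rho) > threshold &
      (if (sign == "positive") sub$spearman_rho > 0 else sub$spearman_rho < 0)
    for (g in sub$gene_id[qual]) counts[[g]] <- (counts[[g]] %||% 0L) + 1L
  }
  sort(names(counts)[vapply(counts, identity, integer(1)) >= min_datasets])
}
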