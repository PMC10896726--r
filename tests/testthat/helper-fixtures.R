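# shared fixture builders; everything is generated in code at test time

toy_matrix <- function(values, modality = "metabolite", scale = "raw",
                       features = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- features %||% sprintf("F%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  omics_matrix(m, modality, scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a regular design: n_batches x timepoints x replicates, role baseline at
# the first timepoint
toy_meta <- function(n_batches = 2, timepoints = c(0, 3, 7), replicates = 2) {
  grid <- expand.grid(replicate = seq_len(replicates),
                      timepoint_days = timepoints,
                      batch = sprintf("B%d", seq_len(n_batches)),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_D%g_R%d", grid$batch, grid$timepoint_days,
                            grid$replicate)
  grid$role <- ifelse(grid$timepoint_days == min(timepoints), "baseline", "treated")
  sample_meta(grid[, c("sample_id", "batch", "timepoint_days", "replicate", "role")])
}

# deterministic matrix matching toy_meta()'s sample ids
toy_study_matrix <- function(meta, n_features = 4, seed = 1, modality = "metabolite") {
  set.seed(seed)
  v <- matrix(exp(rnorm(n_features * nrow(meta), 8, 0.5)), n_features,
              dimnames = list(sprintf("F%02d", seq_len(n_features)), meta$sample_id))
  omics_matrix(v, modality, "raw")
}

# memoised default synthetic studies so the suite does not regenerate them
.study_cache <- new.env(parent = emptyenv())

cached_study <- function(key, cfg) {
  if (is.null(.study_cache[[key]])) .study_cache[[key]] <- generate_study(cfg)
  .study_cache[[key]]
}

default_study <- function() cached_study("default", synthetic_config())

zero_noise_study <- function() {
  cached_study("zero", synthetic_config(noise_sd = 0))
}

benchmark_study <- function() {
  cached_study("bench", synthetic_config(shared_dynamics = TRUE, qc_fraction = 0.1))
}

# independent betweenness oracle: explicit enumeration of all shortest
# paths per (s, t) pair via DFS over BFS-distance-decreasing edges
brute_betweenness <- function(adj_matrix) {
  n <- nrow(adj_matrix)
  bc <- numeric(n)
  nbrs <- lapply(seq_len(n), function(i) which(adj_matrix[i, ] > 0))
  bfs_dist <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in nbrs[[v]]) if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  for (s in seq_len(n - 1)) {
    d <- bfs_dist(s)
    for (t in seq(s + 1, n)) {
      if (!is.finite(d[t])) next
      paths <- list()
      walk <- function(v, acc) {
        if (v == s) { paths[[length(paths) + 1L]] <<- acc; return(invisible()) }
        for (u in nbrs[[v]]) if (d[u] == d[v] - 1) walk(u, c(u, acc))
      }
      walk(t, t)
      through <- table(unlist(lapply(paths, function(p) setdiff(p, c(s, t)))))
      if (length(through))
        bc[as.integer(names(through))] <- bc[as.integer(names(through))] +
          as.numeric(through) / length(paths)
    }
  }
  bc
}

# independent BH step-up oracle (textbook definition, sorted then cummin)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
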