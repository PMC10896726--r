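#' Per-sample study metadata
#'
#' One row per sample: which batch (senescence inducer / dataset) it belongs
#' to, the day of sampling, the replicate index and its role. Roles are
#' `"baseline"` (uninduced, day-0 reference), `"treated"` (on-course sample)
#' or `"qc"` (pooled quality-control injection; `timepoint_days` may be `NA`).
#'
#' @param df data frame with columns `sample_id`, `batch`, `timepoint_days`,
#'   `replicate`, `role`.
#' @return A validated `sample_meta` data frame.
#' @export
sample_meta <- function(df) {
  need <- c("sample_id", "batch", "timepoint_days", "replicate", "role")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("sample metadata missing column(s): %s", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$sample_id <- as.character(df$sample_id)
  df$batch <- as.character(df$batch)
  df$timepoint_days <- as.numeric(df$timepoint_days)
  df$replicate <- as.integer(df$replicate)
  df$role <- as.character(df$role)
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample ids in metadata: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad_role <- setdiff(unique(df$role), c("baseline", "treated", "qc"))
  if (length(bad_role))
    stopf("unknown role(s): %s", paste(bad_role, collapse = ", "))
  if (any(df$replicate < 1, na.rm = TRUE)) stopf("replicate indices must be >= 1")
  tp_bad <- !is.na(df$timepoint_days) & df$timepoint_days < 0
  if (any(tp_bad)) stopf("timepoint_days must be non-negative")
  if (any(is.na(df$timepoint_days) & df$role != "qc"))
    stopf("timepoint_days may be NA only for qc samples")
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' @rdname sample_meta
#' @param path tab-separated file with the metadata columns.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  sample_meta(df)
}

#' @rdname sample_meta
#' @param meta a `sample_meta` data frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validated study view: matrix plus metadata
#'
#' Checks that every matrix sample has exactly one metadata row, drops
#' metadata rows for absent samples (with a warning), and orders the samples
#' stably by (batch, timepoint, replicate, role). All downstream stages
#' consume this view rather than re-parsing files.
#'
#' @param matrix an [omics_matrix()].
#' @param meta a [sample_meta()] data frame covering all matrix samples.
#' @return A list of class `omics_study` with elements `matrix` and `meta`
#'   in aligned, stable order.
#' @export
align_study <- function(matrix, meta) {
  stopifnot(inherits(matrix, "omics_matrix"))
  meta <- sample_meta(meta)
  orphan <- setdiff(sample_ids(matrix), meta$sample_id)
  if (length(orphan))
    stopf("samples absent from metadata: %s", paste(orphan, collapse = ", "))
  extra <- setdiff(meta$sample_id, sample_ids(matrix))
  if (length(extra)) {
    warnf("dropping %d metadata rows without matrix columns", length(extra))
    meta <- meta[meta$sample_id %in% sample_ids(matrix), ]
  }
  ord <- order(meta$batch, meta$timepoint_days, meta$replicate, meta$role,
               meta$sample_id, method = "radix")
  meta <- meta[ord, ]
  rownames(meta) <- NULL
  structure(list(matrix = subset_samples(matrix, meta$sample_id), meta = meta),
            class = "omics_study")
}

#' Select sample ids from a study view
#'
#' @param study an [align_study()] result.
#' @param batch,timepoint,role optional filters; `NULL` means no restriction.
#' @return Character vector of sample ids, in study order.
#' @export
select_samples <- function(study, batch = NULL, timepoint = NULL, role = NULL) {
  stopifnot(inherits(study, "omics_study"))
  m <- study$meta
  keep <- rep(TRUE, nrow(m))
  if (!is.null(batch)) keep <- keep & m$batch %in% batch
  if (!is.null(timepoint)) keep <- keep & !is.na(m$timepoint_days) &
      m$timepoint_days %in% timepoint
  if (!is.null(role)) keep <- keep & m$role %in% role
  m$sample_id[keep]
}
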