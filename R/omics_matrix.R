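#' Feature-by-sample intensity matrix
#'
#' The core container shared by all analysis stages: a numeric matrix of
#' intensities with unique feature ids as row names and unique sample ids as
#' column names, tagged with its modality (`"metabolite"` or `"gene"`) and
#' scale (`"raw"` peak areas, strictly positive, or `"log"`, base-2).
#' Missing intensities are stored as `NA`, never as zero.
#'
#' @param values numeric matrix (features x samples) with row and column names.
#' @param modality `"metabolite"` or `"gene"`.
#' @param scale `"raw"` or `"log"`.
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `modality` and `scale`.
#' @export
omics_matrix <- function(values, modality = c("metabolite", "gene"),
                         scale = c("raw", "log")) {
  modality <- match.arg(modality)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stopf("'values' must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(fid))
    stopf("duplicate feature ids: %s",
          paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stopf("duplicate sample ids: %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (scale == "raw" && any(values <= 0, na.rm = TRUE))
    stopf("raw-scale matrix contains non-positive values; encode missing as NA")
  structure(list(values = values, modality = modality, scale = scale),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d %s features x %d samples [%s scale], %d missing\n",
              nrow(x$values), x$modality, ncol(x$values), x$scale,
              sum(is.na(x$values))))
  invisible(x)
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname omics_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

subset_samples <- function(x, ids) {
  missing <- setdiff(ids, sample_ids(x))
  if (length(missing))
    stopf("unknown sample ids: %s", paste(missing, collapse = ", "))
  omics_matrix(x$values[, ids, drop = FALSE], x$modality, x$scale)
}

subset_features <- function(x, ids) {
  missing <- setdiff(ids, feature_ids(x))
  if (length(missing))
    stopf("unknown feature ids: %s", paste(missing, collapse = ", "))
  omics_matrix(x$values[ids, , drop = FALSE], x$modality, x$scale)
}

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row of sample ids; the first column holds feature ids.
#' Empty cells and `NA` are recorded as missing, not zero. Duplicated ids and
#' non-numeric cells are format errors.
#'
#' @param path path to a tab-separated file.
#' @param modality `"metabolite"` or `"gene"`.
#' @param scale `"raw"` or `"log"` (what the file stores).
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, modality = c("metabolite", "gene"),
                        scale = c("raw", "log")) {
  modality <- match.arg(modality)
  scale <- match.arg(scale)
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample column in %s: %s", path,
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stopf("matrix file %s needs a feature-id column and >= 1 sample", path)
  fid <- raw[[1]]
  if (anyDuplicated(fid))
    stopf("duplicate feature id in %s: %s", path,
          paste(unique(fid[duplicated(fid)]), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells == ""] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("non-numeric cell in %s at row %d (feature %s), column %s: '%s'",
          path, bad[1, 1], fid[bad[1, 1]], sample_ids[bad[1, 2]],
          cells[bad[1, , drop = FALSE]])
  dimnames(num) <- list(fid, sample_ids)
  omics_matrix(num, modality, scale)
}

#' Write a feature-by-sample matrix to TSV
#'
#' Inverse of [read_matrix()]: first column `feature_id`, one column per
#' sample, `NA` for missing cells. Round trips are lossless for finite values.
#'
#' @param x an [omics_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  # %.17g guarantees an exact double round trip through text
  chr <- matrix(sprintf("%.17g", v), nrow = nrow(v))
  chr[is.na(v)] <- "NA"
  df <- data.frame(feature_id = feature_ids(x), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("feature_id", sample_ids(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Impute missing intensities by half the feature minimum
#'
#' Standard metabolomics practice ahead of a log transform: each missing cell
#' is replaced by half the smallest positive intensity observed for that
#' feature. Features with no observed value at all are left missing with a
#' warning.
#'
#' @param x a raw-scale [omics_matrix()].
#' @return An `omics_matrix` with missing cells filled in.
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$scale != "raw") stopf("impute_missing() expects a raw-scale matrix")
  v <- x$values
  miss_rows <- which(rowSums(is.na(v)) > 0)
  for (i in miss_rows) {
    obs <- v[i, !is.na(v[i, ])]
    if (length(obs) == 0) next
    v[i, is.na(v[i, ])] <- min(obs) / 2
  }
  if (any(rowSums(is.na(v)) == ncol(v)))
    warnf("features with no observed value left missing: %s",
          paste(feature_ids(x)[rowSums(is.na(v)) == ncol(v)], collapse = ", "))
  omics_matrix(v, x$modality, x$scale)
}
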