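#' Read a gene-set collection from GMT
#'
#' Standard MSigDB dialect: one set per line, tab-separated fields
#' `set_id <TAB> description <TAB> member1 <TAB> member2 ...`. Member order is
#' preserved; duplicated members within a set are dropped with a warning.
#'
#' @param path path to a `.gmt` file.
#' @return A named list of character vectors of class `gene_set_collection`,
#'   with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stopf("GMT line %d has %d field(s); need set id, description and >= 1 member",
            i, length(fields))
    id <- fields[1]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warnf("set '%s': duplicated member(s) deduplicated", id)
      members <- unique(members)
    }
    if (length(members) == 0)
      stopf("GMT line %d (set '%s') has no members", i, id)
    sets[[id]] <- members
    desc[id] <- fields[2]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets named list of member vectors (or a `gene_set_collection`).
#' @param descriptions optional named character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[id])) descriptions[id] else ""
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
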