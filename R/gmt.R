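#' Read and write signed GMT gene-set files
#'
#' Tab-delimited GMT: `term<TAB>description<TAB>gene...`.  Genes may carry
#' an optional direction suffix `GENE|+1` / `GENE|-1`; plain gene names
#' get direction 0 (unspecified).
#'
#' @param path File path.
#' @return `read_gmt`: named list of [marker_set()]s.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      abort_input("malformed GMT line (need term, description, >=1 gene)")
    genes <- f[-(1:2)]
    has_dir <- grepl("\\|[+-]?1$", genes)
    dir <- integer(length(genes))
    dir[has_dir] <- as.integer(sub("^.*\\|", "", genes[has_dir]))
    name <- sub("\\|[+-]?1$", "", genes)
    marker_set(f[1], setNames(dir, name))
  })
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' @param sets Named list of [marker_set()]s (or plain character vectors).
#' @param descriptions Optional character vector of descriptions.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "marker_set")) {
      genes <- ifelse(s$members == 0L, names(s$members),
                      sprintf("%s|%+d", names(s$members), s$members))
      nm <- s$name
    } else {
      genes <- s
      nm <- names(sets)[i]
    }
    desc <- if (is.null(descriptions)) "na" else descriptions[i]
    paste(c(nm, desc, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
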