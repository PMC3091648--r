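# Plain-text readers/writers for the pipeline's tabular formats.

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression dataset as TSV files
#'
#' @param data an `expression_dataset`.
#' @param values_file,design_file,present_file output paths; the present
#'   matrix is skipped when `present_file` is `NULL`.
#' @return invisibly, `data`.
#' @export
write_expression_dataset <- function(data, values_file, design_file,
                                     present_file = NULL) {
  utils::write.table(data$values, values_file, sep = "\t", quote = FALSE,
                     col.names = NA)
  write_tsv(data$design, design_file)
  if (!is.null(present_file)) {
    utils::write.table(data$present * 1L, present_file, sep = "\t",
                       quote = FALSE, col.names = NA)
  }
  invisible(data)
}

#' Read an expression dataset from TSV files
#'
#' @param values_file gene x sample matrix with row names in the first
#'   column; `design_file` a sample/experiment/group table;
#'   `present_file` optional 0/1 matrix of Present calls.
#' @return an `expression_dataset`.
#' @export
read_expression_dataset <- function(values_file, design_file,
                                    present_file = NULL) {
  values <- as.matrix(utils::read.table(values_file, sep = "\t",
                                        header = TRUE, row.names = 1,
                                        check.names = FALSE))
  design <- read_tsv(design_file)
  present <- NULL
  if (!is.null(present_file)) {
    present <- as.matrix(utils::read.table(present_file, sep = "\t",
                                           header = TRUE, row.names = 1,
                                           check.names = FALSE)) > 0
  }
  expression_dataset(values, design, present)
}

#' Write an annotation catalog in GMT format
#'
#' One line per term: term, description (the term again), then member genes.
#'
#' @param catalog an [annotation_catalog()].
#' @param file output path.
#' @return invisibly, `catalog`.
#' @export
write_gmt <- function(catalog, file) {
  lines <- vapply(names(catalog$terms), function(t) {
    paste(c(t, t, catalog$terms[[t]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(catalog)
}

#' Read a GMT file into an annotation catalog
#'
#' @param file GMT path (term, description, genes...).
#' @param n_terms optional size of the term universe; defaults to the
#'   number of terms in the file.
#' @return an [annotation_catalog()].
#' @export
read_gmt <- function(file, n_terms = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-c(1, 2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  annotation_catalog(sets, n_terms = n_terms)
}
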