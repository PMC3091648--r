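#' Pearson correlation matrix between TF and gene expression profiles
#'
#' Standard product-moment correlation of each TF profile with each gene
#' profile across all samples, yielding values in \[-1, 1\] (+1 perfect
#' positive, -1 perfect negative co-expression). An entry whose TF or gene
#' profile is constant is undefined and recorded as `NA`, not 0.
#'
#' @param tf_profiles,gene_profiles numeric matrices (rows = TFs / genes,
#'   columns = the same samples in the same order, >= 3 samples).
#' @return TF x gene numeric matrix of correlations.
#' @export
compute_correlation_matrix <- function(tf_profiles, gene_profiles) {
  stopifnot(is.matrix(tf_profiles), is.matrix(gene_profiles))
  if (!identical(colnames(tf_profiles), colnames(gene_profiles))) {
    stop("profiles must share an identical sample set", call. = FALSE)
  }
  if (ncol(tf_profiles) < 3L) {
    stop("need at least 3 samples for a correlation", call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(t(tf_profiles), t(gene_profiles)))
  R[!is.finite(R)] <- NA_real_
  R
}

#' Interaction-evidence score matrix
#'
#' Collapses curated interaction records into the four-level evidence
#' score per TF-gene pair: 0 no evidence; 1 a single computational or
#' high-throughput source, or low co-citation (<= 10); 2 evidence from
#' more than one resource together with co-citation >= 10; 3 direct
#' experimental evidence or a multi-source curated record. When a pair
#' satisfies several definitions the maximum applies (the higher the
#' score, the more certain the relationship).
#'
#' @param records data.frame with columns `tf`, `gene`, `source_class`
#'   (one of `"computational"`, `"high-throughput"`, `"multi-source"`,
#'   `"direct-experimental"`), `co_citations` (non-negative integer) and
#'   optionally `provenance` (the resource a record came from; used to
#'   count distinct resources, falling back to `source_class`).
#' @param tfs,genes identifiers forming the matrix axes; records naming
#'   unknown identifiers are skipped with a warning.
#' @return integer TF x gene matrix with entries in \{0, 1, 2, 3\}.
#' @export
score_interactions <- function(records, tfs, genes) {
  classes <- c("computational", "high-throughput", "multi-source",
               "direct-experimental")
  M <- matrix(0L, length(tfs), length(genes),
              dimnames = list(tfs, genes))
  if (nrow(records) == 0L) return(M)
  stopifnot(all(c("tf", "gene", "source_class", "co_citations") %in%
                  names(records)))
  if (!all(records$source_class %in% classes)) {
    stop("unknown source_class; expected one of: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  if (any(records$co_citations < 0) ||
      any(records$co_citations != floor(records$co_citations))) {
    stop("co_citations must be non-negative integers", call. = FALSE)
  }
  known <- records$tf %in% tfs & records$gene %in% genes
  if (any(!known)) {
    warning("skipping ", sum(!known),
            " record(s) with unknown TF or gene identifiers")
    records <- records[known, , drop = FALSE]
  }
  if (nrow(records) == 0L) return(M)
  resource <- if ("provenance" %in% names(records)) {
    records$provenance
  } else {
    records$source_class
  }
  key <- paste(records$tf, records$gene, sep = "\r")
  for (pair in unique(key)) {
    rows <- key == pair
    cls <- records$source_class[rows]
    score <- if (any(cls %in% c("direct-experimental", "multi-source"))) {
      3L
    } else if (length(unique(resource[rows])) >= 2L &&
               max(records$co_citations[rows]) >= 10L) {
      2L
    } else {
      1L
    }
    tf <- records$tf[rows][1L]
    g <- records$gene[rows][1L]
    M[tf, g] <- max(M[tf, g], score)
  }
  M
}
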