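#' Construct an annotation catalog
#'
#' A catalog maps functional terms to the genes annotated with them (the
#' shape of a GMT file). The term universe used for kappa agreement is by
#' default every term observed in the catalog.
#'
#' @param terms named list, term -> character vector of genes; empty term
#'   sets are dropped with a warning.
#' @param n_terms size of the term universe; defaults to the number of
#'   (non-empty) terms.
#' @return an object of class `annotation_catalog`: list with `terms`,
#'   `genes` (the annotated universe), `gene_terms` (gene -> term vector)
#'   and `n_terms`.
#' @export
annotation_catalog <- function(terms, n_terms = NULL) {
  stopifnot(is.list(terms))
  if (length(terms) > 0L && is.null(names(terms))) {
    stop("annotation_catalog: terms must be named", call. = FALSE)
  }
  sizes <- vapply(terms, length, 1L)
  if (any(sizes == 0L)) {
    warning("dropping ", sum(sizes == 0L), " empty term(s)")
    terms <- terms[sizes > 0L]
  }
  terms <- lapply(terms, unique)
  pairs <- data.frame(
    term = rep(names(terms), vapply(terms, length, 1L)),
    gene = unlist(terms, use.names = FALSE), stringsAsFactors = FALSE)
  gene_terms <- split(pairs$term, pairs$gene)
  if (is.null(n_terms)) n_terms <- length(terms)
  if (n_terms < length(terms)) {
    stop("annotation_catalog: n_terms smaller than the observed term count",
         call. = FALSE)
  }
  structure(list(terms = terms, genes = sort(unique(pairs$gene)),
                 gene_terms = gene_terms, n_terms = as.integer(n_terms)),
            class = "annotation_catalog")
}

#' Chance-corrected annotation agreement (Cohen's kappa)
#'
#' Treats the two genes' annotations as binary vectors over the term
#' universe and computes Cohen's kappa on the resulting 2x2
#' presence/absence table. Agreement no better than chance is clamped to
#' 0, so the statistic ranges from 0 (independent annotation) to 1
#' (identical annotation).
#'
#' @param a,b character vectors of annotation terms (both non-empty).
#' @param universe_size size of the term universe; must be at least
#'   `length(union(a, b))`.
#' @return kappa in \[0, 1\].
#' @export
compute_kappa <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("compute_kappa: both genes must be annotated", call. = FALSE)
  }
  n11 <- length(intersect(a, b))
  n10 <- length(a) - n11
  n01 <- length(b) - n11
  n00 <- universe_size - (n11 + n10 + n01)
  if (n00 < 0) {
    stop("compute_kappa: universe_size smaller than |union(a, b)|",
         call. = FALSE)
  }
  N <- universe_size
  po <- (n11 + n00) / N
  pe <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / N^2
  if (pe >= 1) return(if (n10 == 0L && n01 == 0L) 1 else 0)
  max(0, (po - pe) / (1 - pe))
}

#' Kappa similarity matrix between TFs and genes
#'
#' @param tfs,genes identifier vectors for the two axes (either may list
#'   any annotated entity; a gene x gene matrix is obtained by passing the
#'   same vector twice).
#' @param catalog an [annotation_catalog()].
#' @return TF x gene numeric matrix of kappa values; entries involving an
#'   unannotated identifier are `NA` (missing, not zero).
#' @export
compute_kappa_matrix <- function(tfs, genes, catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (length(catalog$terms) == 0L) {
    stop("compute_kappa_matrix: empty catalog", call. = FALSE)
  }
  K <- matrix(NA_real_, length(tfs), length(genes),
              dimnames = list(tfs, genes))
  ann <- catalog$gene_terms
  for (i in seq_along(tfs)) {
    a <- ann[[tfs[i]]]
    if (is.null(a)) next
    for (j in seq_along(genes)) {
      b <- ann[[genes[j]]]
      if (is.null(b)) next
      K[i, j] <- compute_kappa(a, b, catalog$n_terms)
    }
  }
  K
}

#' Over-represented functional terms in a gene cluster
#'
#' One-sided Fisher exact (hypergeometric tail) test of each term's
#' occurrence in the cluster against the rest of the annotated universe. A
#' term is reported when p < `alpha` and it covers more than
#' `min_fraction` of the cluster's genes.
#'
#' @param cluster character vector of cluster genes (a subset of the
#'   catalog's universe; genes outside it are dropped with a warning).
#' @param catalog an [annotation_catalog()].
#' @param alpha reporting p-value threshold (default 0.01).
#' @param min_fraction minimum fraction of cluster genes carrying the term
#'   (default 0.20, strict inequality).
#' @return data.frame sorted by p-value with columns `term`, `n_cluster`,
#'   `n_term`, `p_value`, `cluster_fraction`, `reported`.
#' @export
enrich_cluster_terms <- function(cluster, catalog, alpha = 0.01,
                                 min_fraction = 0.20) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  empty <- data.frame(term = character(), n_cluster = integer(),
                      n_term = integer(), p_value = numeric(),
                      cluster_fraction = numeric(), reported = logical(),
                      stringsAsFactors = FALSE)
  cluster <- unique(cluster)
  outside <- setdiff(cluster, catalog$genes)
  if (length(outside) > 0L) {
    warning(length(outside), " cluster gene(s) outside the annotated ",
            "universe dropped")
    cluster <- intersect(cluster, catalog$genes)
  }
  if (length(cluster) == 0L) return(empty)
  N <- length(catalog$genes)
  n <- length(cluster)
  res <- lapply(names(catalog$terms), function(t) {
    members <- catalog$terms[[t]]
    K <- length(members)
    k <- length(intersect(cluster, members))
    # upper tail P(X >= k) of the hypergeometric
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, n_cluster = k, n_term = K, p_value = p,
               cluster_fraction = k / n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$reported <- res$p_value < alpha & res$cluster_fraction > min_fraction
  res <- res[order(res$p_value, res$term), ]
  rownames(res) <- NULL
  res
}
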