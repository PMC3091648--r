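# End-to-end orchestration: differential filtering -> FLAME clustering ->
# per-cluster evidence matrices -> Score/Support/Confidence -> combined
# ranked edge table.

#' Infer a TF-target network from the four evidence sources
#'
#' Runs the complete integrative pipeline:
#' \enumerate{
#'   \item differential-expression filtering across perturbation
#'     experiments and candidate-gene selection;
#'   \item FLAME fuzzy clustering of candidate genes;
#'   \item per cluster: motif over-representation in conserved (ECR) and
#'     proximal promoter windows, motif importance, and the four TF x gene
#'     evidence matrices (TFBS, kappa, correlation, interaction) for the
#'     cluster's enriched motif families;
#'   \item scaling, integration into Score, hierarchical clustering of
#'     both axes, Support-gated cluster pairing and Confidence ranking.
#' }
#' Evidence for a motif family aggregates over its member TF genes (from
#' `family_map`) by the maximum, since any member's binding or interaction
#' supports the family-level edge.
#'
#' @param expression an [expression_dataset()] containing TF genes and
#'   candidate genes.
#' @param catalog an [annotation_catalog()].
#' @param hits a motif hit table (see [score_tfbs_matrix()]).
#' @param evidence interaction-evidence records (see
#'   [score_interactions()]).
#' @param family_map data.frame with columns `motif`, `tf` mapping motif
#'   families to member TF genes.
#' @param alpha,fc_min,present_min differential filters (defaults 0.05,
#'   1.5, 0.67).
#' @param min_experiments candidate-gene threshold on the number of
#'   flagged experiments. Default 1, suited to designs with a single
#'   perturbation per regulator; use 5 for large multi-perturbation
#'   compendia.
#' @param knn,membership_cutoff FLAME parameters (defaults 7 and 0.35).
#' @param min_cluster_size clusters smaller than this are skipped
#'   (default 5).
#' @param ecr_alpha,prom_alpha over-representation thresholds (defaults
#'   0.005 and 0.05).
#' @param support_threshold Support gate for cluster pairs (default 0.25).
#' @param tf_k,tg_k cluster counts for the TF and target axes within each
#'   expression cluster; `NULL` uses `cluster_axis()` defaults
#'   (`round(sqrt(n))`).
#' @param rectify_correlation clamp negative TF-TG correlations to 0
#'   before scaling (default `TRUE`).
#' @return an object of class `tf_network_fit`: list with `calls`,
#'   `candidates`, `flame`, `cluster_results` (per-cluster evidence,
#'   importance and confidence tables) and `edges` (the combined
#'   confidence table with a `cluster` column).
#' @export
infer_tf_network <- function(expression, catalog, hits, evidence,
                             family_map,
                             alpha = 0.05, fc_min = 1.5,
                             present_min = 0.67, min_experiments = 1L,
                             knn = 7L, membership_cutoff = 0.35,
                             min_cluster_size = 5L,
                             ecr_alpha = 0.005, prom_alpha = 0.05,
                             support_threshold = 0.25,
                             tf_k = NULL, tg_k = NULL,
                             rectify_correlation = TRUE) {
  stopifnot(inherits(expression, "expression_dataset"),
            all(c("motif", "tf") %in% names(family_map)))
  calls <- test_differential_expression(expression, alpha = alpha,
                                        fc_min = fc_min,
                                        present_min = present_min)
  candidates <- select_candidate_genes(calls, min_experiments)
  candidates <- setdiff(candidates, family_map$tf)
  fit <- list(calls = calls, candidates = candidates, flame = NULL,
              cluster_results = list(),
              edges = empty_edge_table())
  if (length(candidates) < knn + 1L) {
    warning("only ", length(candidates),
            " candidate genes; too few to cluster (need > knn)")
    class(fit) <- "tf_network_fit"
    return(fit)
  }
  fl <- flame_cluster(expression$values[candidates, , drop = FALSE],
                      k = knn, cutoff = membership_cutoff)
  fit$flame <- fl
  clusters <- Filter(function(g) length(g) >= min_cluster_size,
                     fl$clusters$clusters)
  all_hit_genes <- unique(hits$gene)
  motifs <- sort(unique(family_map$motif))
  for (cl_name in names(clusters)) {
    cl <- clusters[[cl_name]]
    res <- analyze_cluster(cl, expression, catalog, hits, evidence,
                           family_map, motifs, all_hit_genes,
                           ecr_alpha, prom_alpha, support_threshold,
                           tf_k, tg_k, rectify_correlation)
    if (is.null(res)) next
    fit$cluster_results[[cl_name]] <- res
    if (nrow(res$confidence) > 0L) {
      e <- res$confidence[, c("tf", "gene", "confidence")]
      e$cluster <- cl_name
      fit$edges <- rbind(fit$edges, e)
    }
  }
  rownames(fit$edges) <- NULL
  class(fit) <- "tf_network_fit"
  fit
}

empty_edge_table <- function() {
  data.frame(tf = character(), gene = character(), confidence = numeric(),
             cluster = character(), stringsAsFactors = FALSE)
}

# Evidence integration and confidence scoring within one expression
# cluster. Returns NULL when no motif family is enriched in the cluster.
analyze_cluster <- function(cl, expression, catalog, hits, evidence,
                            family_map, motifs, all_hit_genes,
                            ecr_alpha, prom_alpha, support_threshold,
                            tf_k, tg_k, rectify_correlation) {
  background <- setdiff(all_hit_genes, cl)
  if (length(background) == 0L) return(NULL)
  ecr <- test_overrepresentation(hits, cl, background, "ECR",
                                 alpha = ecr_alpha, motifs = motifs)
  prom <- test_overrepresentation(hits, cl, background, "proximal",
                                  alpha = prom_alpha, motifs = motifs)
  freq <- compute_frequency_rank(hits, cl,
                                 prom$motif[prom$enriched],
                                 motifs = motifs)
  imp <- tryCatch(
    suppressWarnings(rank_motif_importance(
      stats::setNames(ecr$rank, ecr$motif),
      stats::setNames(prom$rank, prom$motif),
      stats::setNames(freq$rank, freq$motif))),
    error = function(e) NULL)
  fams <- sort(union(ecr$motif[ecr$enriched], prom$motif[prom$enriched]))
  if (length(fams) == 0L) return(NULL)
  # evidence matrices span the whole motif vocabulary: the cluster's
  # enriched families are reported, but integration needs the contrast
  # against non-enriched families for a meaningful within-cluster
  # normalization
  fam_members <- split(family_map$tf, family_map$motif)[motifs]
  tf_genes <- intersect(unlist(fam_members), rownames(expression$values))

  tfbs_m <- score_tfbs_matrix(hits, cl, motifs = motifs)
  kappa_tf <- compute_kappa_matrix(unique(unlist(fam_members)), cl, catalog)
  kappa_m <- aggregate_family(kappa_tf, fam_members, cl)
  corr_m <- matrix(NA_real_, length(fams), length(cl),
                   dimnames = list(fams, cl))
  if (length(tf_genes) > 0L) {
    corr_tf <- compute_correlation_matrix(
      expression$values[tf_genes, , drop = FALSE],
      expression$values[cl, , drop = FALSE])
    corr_m <- aggregate_family(corr_tf, fam_members, cl)
  }
  inter_tf <- score_interactions(evidence, unique(unlist(fam_members)), cl)
  inter_m <- aggregate_family(inter_tf, fam_members, cl)

  layers <- list(
    tfbs = scale_evidence_matrix(tfbs_m, "tfbs"),
    kappa = scale_evidence_matrix(kappa_m, "kappa"),
    correlation = scale_evidence_matrix(corr_m, "correlation",
                                        rectify = rectify_correlation),
    interaction = scale_evidence_matrix(inter_m, "interaction"))
  integ <- integrate_matrices(layers)

  tf_clusters <- if (length(motifs) >= 2L) {
    cluster_axis(build_axis_features(layers, "TF"),
                 n_clusters = if (is.null(tf_k)) NULL else
                   min(tf_k, length(motifs)))
  } else {
    stats::setNames(1L, motifs)
  }
  tg_clusters <- if (length(cl) >= 2L) {
    cluster_axis(build_axis_features(layers, "TG"),
                 n_clusters = if (is.null(tg_k)) NULL else
                   min(tg_k, length(cl)))
  } else {
    stats::setNames(1L, cl)
  }
  pairs <- select_cluster_pairs(tf_clusters, tg_clusters, integ$score,
                                threshold = support_threshold)
  conf <- suppressWarnings(
    compute_confidence(integ$score, tf_clusters, tg_clusters, pairs,
                       importance = imp))
  list(genes = cl, ecr = ecr, promoter = prom, frequency = freq,
       importance = imp, families = fams, layers = layers,
       integrated = integ, tf_clusters = tf_clusters,
       tg_clusters = tg_clusters, pairs = pairs, confidence = conf)
}

# Collapse a member-TF x gene matrix to family level by the maximum over
# each family's member rows (all-NA columns stay NA).
aggregate_family <- function(m, fam_members, genes) {
  out <- matrix(NA_real_, length(fam_members), length(genes),
                dimnames = list(names(fam_members), genes))
  for (fam in names(fam_members)) {
    rows <- intersect(fam_members[[fam]], rownames(m))
    if (length(rows) == 0L) next
    block <- m[rows, genes, drop = FALSE]
    vals <- apply(block, 2, function(x) {
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
    })
    out[fam, ] <- vals
  }
  out
}

#' Map family-level predicted edges to TF-gene edges
#'
#' Expands each motif-family edge of a fitted network to one edge per
#' member TF gene, for comparison with a TF-level ground truth.
#'
#' @param edges data.frame with columns `tf` (motif family), `gene`,
#'   `confidence`.
#' @param family_map data.frame with columns `motif`, `tf`.
#' @return the expanded edge table with `tf` holding TF gene identifiers.
#' @export
expand_family_edges <- function(edges, family_map) {
  merged <- merge(edges, family_map, by.x = "tf", by.y = "motif")
  out <- merged[, setdiff(names(merged), "tf"), drop = FALSE]
  names(out)[names(out) == "tf.y"] <- "tf"
  out <- out[, c("tf", setdiff(names(out), "tf")), drop = FALSE]
  rownames(out) <- NULL
  out
}
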