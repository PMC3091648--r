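#' Score the TFBS matrix from a motif hit table
#'
#' The promoter-mining score between a motif family Ti and a gene Gj takes
#' three values: 0 when no conserved hit of Ti lies in Gj's promoter
#' windows, 1 for exactly one conserved hit, and 2 for multiple conserved
#' hits. Non-conserved hits never count.
#'
#' @param hits data.frame with columns `gene`, `motif`, `position`,
#'   `region_class`, `conserved`.
#' @param genes gene identifiers forming the matrix columns; hits for
#'   genes outside this set are skipped with a warning.
#' @param motifs motif families forming the rows; defaults to all motifs
#'   observed in `hits`.
#' @param region_class count conserved hits in `"any"` region (default),
#'   or restrict to `"ECR"` / `"proximal"` windows.
#' @return integer motif x gene matrix with entries in \{0, 1, 2\}.
#' @export
score_tfbs_matrix <- function(hits, genes, motifs = NULL,
                              region_class = c("any", "ECR", "proximal")) {
  region_class <- match.arg(region_class)
  stopifnot(all(c("gene", "motif", "conserved") %in% names(hits)))
  if (is.null(motifs)) motifs <- sort(unique(hits$motif))
  unknown <- setdiff(unique(hits$gene), genes)
  if (length(unknown) > 0L) {
    warning("skipping hits for ", length(unknown),
            " gene(s) not in the gene set")
  }
  keep <- hits$conserved & hits$gene %in% genes & hits$motif %in% motifs
  if (region_class != "any") keep <- keep & hits$region_class == region_class
  hits <- hits[keep, , drop = FALSE]
  M <- matrix(0L, length(motifs), length(genes),
              dimnames = list(motifs, genes))
  if (nrow(hits) > 0L) {
    counts <- table(factor(hits$motif, motifs), factor(hits$gene, genes))
    M[] <- pmin(as.integer(counts), 2L)
  }
  M
}

#' Motif over-representation in a gene cluster
#'
#' For each motif family, a one-sided hypergeometric test of whether the
#' fraction of conserved-hit-bearing genes in the cluster exceeds that in
#' the background set. The conserved-region (ECR) analysis conventionally
#' uses alpha = 0.005, the proximal-promoter analysis alpha = 0.05; these
#' defaults apply when `alpha` is `NULL`. Motifs are ranked by ascending
#' p-value with average (fractional) ranks on ties.
#'
#' @inheritParams score_tfbs_matrix
#' @param cluster character vector of cluster genes (non-empty).
#' @param background background gene set; defaults to all genes in the hit
#'   table minus the cluster. Must be non-empty and disjoint from the
#'   cluster (overlap is removed).
#' @param region_class which promoter window to test: `"ECR"`,
#'   `"proximal"` or `"any"`.
#' @param alpha enrichment threshold; `NULL` picks 0.005 for ECR and 0.05
#'   otherwise.
#' @return data.frame sorted by p-value with columns `motif`, `k_cluster`,
#'   `n_cluster`, `k_background`, `n_background`, `p_value`, `enriched`,
#'   `rank`.
#' @export
test_overrepresentation <- function(hits, cluster, background = NULL,
                                    region_class = c("ECR", "proximal",
                                                     "any"),
                                    alpha = NULL, motifs = NULL) {
  region_class <- match.arg(region_class)
  if (is.null(alpha)) alpha <- if (region_class == "ECR") 0.005 else 0.05
  cluster <- unique(cluster)
  if (length(cluster) == 0L) {
    stop("test_overrepresentation: empty cluster", call. = FALSE)
  }
  if (is.null(background)) background <- setdiff(unique(hits$gene), cluster)
  background <- setdiff(unique(background), cluster)
  if (length(background) == 0L) {
    stop("test_overrepresentation: empty background set", call. = FALSE)
  }
  if (is.null(motifs)) motifs <- sort(unique(hits$motif))
  keep <- hits$conserved
  if (region_class != "any") keep <- keep & hits$region_class == region_class
  hits <- hits[keep, , drop = FALSE]
  carriers <- split(hits$gene, factor(hits$motif, motifs))
  n <- length(cluster)
  nbg <- length(background)
  res <- lapply(motifs, function(m) {
    hit_genes <- unique(carriers[[m]])
    k <- length(intersect(cluster, hit_genes))
    kbg <- length(intersect(background, hit_genes))
    # draw n genes from cluster+background; white balls = hit carriers
    p <- stats::phyper(k - 1, k + kbg, (n - k) + (nbg - kbg), n,
                       lower.tail = FALSE)
    data.frame(motif = m, k_cluster = k, n_cluster = n,
               k_background = kbg, n_background = nbg, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$enriched <- res$p_value <= alpha
  res$rank <- rank(res$p_value)
  res <- res[order(res$p_value, res$motif), ]
  rownames(res) <- NULL
  res
}

#' Per-motif frequency in a cluster's promoters, with ND rule
#'
#' Frequency is the mean conserved-hit count per cluster gene. Motifs that
#' were not enriched in the cluster's proximal promoters are not determined
#' (ND, recorded as `NA`) and are excluded from the frequency ranking;
#' ranked motifs get rank 1 for the highest frequency, with average ranks
#' on ties.
#'
#' @inheritParams test_overrepresentation
#' @param promoter_enriched character vector of motifs that passed the
#'   proximal-promoter enrichment test.
#' @return data.frame with columns `motif`, `frequency`, `rank`
#'   (`NA` = ND).
#' @export
compute_frequency_rank <- function(hits, cluster, promoter_enriched,
                                   motifs = NULL) {
  cluster <- unique(cluster)
  if (is.null(motifs)) motifs <- sort(unique(hits$motif))
  hits <- hits[hits$conserved & hits$gene %in% cluster, , drop = FALSE]
  counts <- table(factor(hits$motif, motifs))
  freq <- as.numeric(counts) / max(1L, length(cluster))
  freq[!(motifs %in% promoter_enriched)] <- NA_real_
  rk <- rep(NA_real_, length(motifs))
  det <- !is.na(freq)
  rk[det] <- rank(-freq[det])
  data.frame(motif = motifs, frequency = freq, rank = rk,
             stringsAsFactors = FALSE)
}

#' Relative motif importance from the three analysis rankings
#'
#' A motif's relative importance is the average of its ranking orders in
#' the conserved-region (ECR), proximal-promoter and frequency analyses
#' (ND ranks are skipped in the average). Average ranks are mapped
#' linearly onto a heatmap score in \[-2.5, 2.5\] (best rank -> 2.5) and
#' onto the importance weight I in \[0.8, 1.2\] (best rank -> 1.2). With a
#' single motif, or when all average ranks tie, the map degenerates to the
#' midpoint (heatmap 0, weight 1).
#'
#' @param rank_ecr,rank_promoter,rank_frequency named numeric vectors of
#'   ranks per motif; `NA` marks a rank that was not determined. Motifs
#'   are aligned by name over the union of the three vectors.
#' @return an object of class `motif_importance`: data.frame with columns
#'   `motif`, `rank_ecr`, `rank_promoter`, `rank_frequency`,
#'   `average_rank`, `heatmap_score`, `weight`.
#' @export
rank_motif_importance <- function(rank_ecr, rank_promoter = NULL,
                                  rank_frequency = NULL) {
  motifs <- sort(unique(c(names(rank_ecr), names(rank_promoter),
                          names(rank_frequency))))
  if (length(motifs) == 0L) {
    stop("rank_motif_importance: no motifs supplied", call. = FALSE)
  }
  align <- function(x) {
    out <- rep(NA_real_, length(motifs))
    names(out) <- motifs
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  R <- cbind(rank_ecr = align(rank_ecr),
             rank_promoter = align(rank_promoter),
             rank_frequency = align(rank_frequency))
  all_nd <- rowSums(!is.na(R)) == 0L
  if (any(all_nd)) {
    warning("dropping ", sum(all_nd), " motif(s) with no determined rank")
    R <- R[!all_nd, , drop = FALSE]
    motifs <- motifs[!all_nd]
  }
  if (nrow(R) == 0L) {
    stop("rank_motif_importance: every motif had only ND ranks",
         call. = FALSE)
  }
  avg <- rowMeans(R, na.rm = TRUE)
  span <- max(avg) - min(avg)
  if (span == 0) {
    heat <- rep(0, length(avg))
    weight <- rep(1, length(avg))
  } else {
    rel <- (avg - min(avg)) / span    # 0 = best (lowest average rank)
    heat <- pmin(pmax(2.5 - 5 * rel, -2.5), 2.5)
    weight <- pmin(pmax(1.2 - 0.4 * rel, 0.8), 1.2)
  }
  out <- data.frame(motif = motifs, rank_ecr = R[, "rank_ecr"],
                    rank_promoter = R[, "rank_promoter"],
                    rank_frequency = R[, "rank_frequency"],
                    average_rank = avg, heatmap_score = heat,
                    weight = weight, stringsAsFactors = FALSE)
  out <- out[order(out$average_rank, out$motif), ]
  rownames(out) <- NULL
  class(out) <- c("motif_importance", "data.frame")
  out
}
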