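# Fusion of the four evidence layers into Score(Ti, Gj), cluster-pair
# Support and the per-pair Confidence ranking.

#' Scale one evidence matrix into \[0, 1\]
#'
#' Fixed maps per layer: TFBS \{0,1,2\} -> \{0, 0.5, 1\}; interaction
#' \{0..3\} -> \{0, 1/3, 2/3, 1\}; kappa is already in \[0, 1\] (clamped);
#' correlations are rectified at 0 by default, since only positive TF-TG
#' co-expression carries regulatory evidence (set `rectify = FALSE` to map
#' \[-1, 1\] affinely onto \[0, 1\] instead). The generic `"minmax"` kind
#' min-max scales an arbitrary matrix, with a constant matrix mapping to
#' all zeros. Missing entries are imputed as 0 and flagged in the
#' `"imputed"` attribute.
#'
#' @param m numeric matrix (finite where defined; `NA` = missing).
#' @param kind one of `"tfbs"`, `"interaction"`, `"kappa"`,
#'   `"correlation"`, `"minmax"`.
#' @param rectify for `kind = "correlation"`: clamp negative correlations
#'   to 0 (default `TRUE`).
#' @return matrix in \[0, 1\] with attribute `imputed` (logical matrix of
#'   originally missing entries).
#' @export
scale_evidence_matrix <- function(m, kind = c("tfbs", "interaction",
                                              "kappa", "correlation",
                                              "minmax"),
                                  rectify = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(m))
  imputed <- is.na(m)
  m[imputed] <- 0
  out <- switch(kind,
    tfbs = {
      if (!all(m %in% 0:2)) {
        stop("TFBS entries must lie in {0, 1, 2}", call. = FALSE)
      }
      m / 2
    },
    interaction = {
      if (!all(m %in% 0:3)) {
        stop("interaction entries must lie in {0, 1, 2, 3}", call. = FALSE)
      }
      m / 3
    },
    kappa = pmin(pmax(m, 0), 1),
    correlation = {
      if (any(m < -1 - 1e-9 | m > 1 + 1e-9)) {
        stop("correlations must lie in [-1, 1]", call. = FALSE)
      }
      if (rectify) pmax(m, 0) else (m + 1) / 2
    },
    minmax = {
      rng <- range(m)
      if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng)
    })
  attr(out, "imputed") <- imputed
  out
}

#' Integrate four scaled evidence layers into Score(Ti, Gj)
#'
#' The scaled matrices are summed entry-wise and the sum is min-max
#' rescaled over the whole matrix to \[0, 1\], giving the integrated
#' Score. In the degenerate all-equal case Score is 1 everywhere when the
#' common sum is positive and 0 otherwise.
#'
#' @param layers named list of numeric matrices in \[0, 1\] with identical
#'   dimnames (TFs x genes), typically the four scaled evidence layers.
#' @return an object of class `integrated_score_matrix`: list with `score`
#'   (the Score matrix), `sum` (pre-normalization sums) and `layers`.
#' @export
integrate_matrices <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  ref <- dimnames(layers[[1L]])
  for (l in layers) {
    if (!identical(dimnames(l), ref)) {
      stop("evidence matrices must be aligned on identical TF and gene ",
           "axes", call. = FALSE)
    }
  }
  S <- Reduce(`+`, layers)
  rng <- range(S)
  score <- if (diff(rng) == 0) {
    matrix(as.numeric(rng[1] > 0), nrow(S), ncol(S), dimnames = ref)
  } else {
    (S - rng[1]) / diff(rng)
  }
  structure(list(score = score, sum = S, layers = layers),
            class = "integrated_score_matrix")
}

#' Concatenated per-axis feature matrix across evidence layers
#'
#' For TF-axis clustering every row concatenates that TF's values across
#' the scaled layers; for the target-gene axis the transposed layers are
#' used.
#'
#' @param layers named list of aligned TF x gene matrices.
#' @param axis `"TF"` or `"TG"`.
#' @return numeric matrix, one row per axis item.
#' @export
build_axis_features <- function(layers, axis = c("TF", "TG")) {
  axis <- match.arg(axis)
  mats <- if (axis == "TF") layers else lapply(layers, t)
  out <- do.call(cbind, mats)
  colnames(out) <- unlist(lapply(names(mats), function(nm) {
    paste(nm, seq_len(ncol(mats[[nm]])), sep = "_")
  }))
  out
}

#' Hierarchical clustering of one matrix axis
#'
#' Deterministic agglomerative clustering (average linkage on Euclidean
#' distances by default) of the rows of a feature matrix, cut either into
#' `n_clusters` groups or at height `h`. With neither given, the cut
#' defaults to `round(sqrt(n))` groups.
#'
#' @param features numeric matrix, one row per item (>= 2 rows).
#' @param n_clusters number of clusters; must not exceed the item count.
#' @param h cut height (alternative to `n_clusters`).
#' @param method linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @return named integer vector of cluster labels.
#' @export
cluster_axis <- function(features, n_clusters = NULL, h = NULL,
                         method = "average") {
  stopifnot(is.matrix(features))
  n <- nrow(features)
  if (n < 2L) stop("cluster_axis: need at least 2 items", call. = FALSE)
  if (!is.null(n_clusters) && n_clusters > n) {
    stop("cluster_axis: fewer items than requested clusters",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(features), method = method)
  if (!is.null(h)) {
    stats::cutree(hc, h = h)
  } else {
    if (is.null(n_clusters)) n_clusters <- max(1L, round(sqrt(n)))
    stats::cutree(hc, k = n_clusters)
  }
}

#' Support between a TF cluster and a target-gene cluster
#'
#' The mean integrated Score over all pairs of the two clusters:
#' Support(Ct, Cg) = (1 / (m n)) * sum over Ti in Ct, Gj in Cg of
#' Score(Ti, Gj), with m = |Ct| and n = |Cg|. Lies in \[0, 1\].
#'
#' @param tf_cluster,tg_cluster non-empty identifier vectors indexing the
#'   score matrix rows/columns.
#' @param score the integrated Score matrix.
#' @return support value in \[0, 1\].
#' @export
compute_support <- function(tf_cluster, tg_cluster, score) {
  if (length(tf_cluster) == 0L || length(tg_cluster) == 0L) {
    stop("compute_support: empty cluster", call. = FALSE)
  }
  if (!all(tf_cluster %in% rownames(score)) ||
      !all(tg_cluster %in% colnames(score))) {
    stop("compute_support: cluster members missing from the score matrix",
         call. = FALSE)
  }
  mean(score[tf_cluster, tg_cluster, drop = FALSE])
}

#' Enumerate and select correlated cluster pairs by Support
#'
#' Every TF cluster is paired with every target-gene cluster; a pair is
#' selected when its Support reaches `threshold`.
#'
#' @param tf_clusters,tg_clusters named integer label vectors (e.g. from
#'   [cluster_axis()]) over the score matrix rows/columns.
#' @param score the integrated Score matrix.
#' @param threshold Support selection threshold (default 0.25).
#' @return data.frame with columns `tf_cluster`, `tg_cluster`, `m`, `n`,
#'   `support`, `selected`.
#' @export
select_cluster_pairs <- function(tf_clusters, tg_clusters, score,
                                 threshold = 0.25) {
  tfl <- split(names(tf_clusters), tf_clusters)
  tgl <- split(names(tg_clusters), tg_clusters)
  grid <- expand.grid(tf_cluster = names(tfl), tg_cluster = names(tgl),
                      stringsAsFactors = FALSE)
  grid$m <- vapply(tfl[grid$tf_cluster], length, 1L)
  grid$n <- vapply(tgl[grid$tg_cluster], length, 1L)
  grid$support <- mapply(function(ct, cg) {
    compute_support(tfl[[ct]], tgl[[cg]], score)
  }, grid$tf_cluster, grid$tg_cluster)
  grid$selected <- grid$support >= threshold
  rownames(grid) <- NULL
  grid
}

#' Confidence of each TF-TG pair within selected cluster pairs
#'
#' For a pair (Ti, Gj) with Ti in TF cluster Ct and Gj in gene cluster Cg
#' (the pair (Ct, Cg) having passed the Support threshold), five equally
#' weighted multiplicative factors are combined:
#' f1 the mean link strength between Ti and all genes of Cg,
#' f2 the mean link strength between Gj and all TFs of Ct,
#' f3 the pair's Support rescaled into \[0.5, 1\],
#' f4 the link strength L(Ti, Gj), and
#' f5 the relative TF importance I(Ti).
#' L(Ti, Gj) scales Score(Ti, Gj) into \[0.5, 1\]; I lies in
#' \[0.8, 1.2\]. The raw product is min-max normalized to \[0, 1\] over
#' all scored pairs (globally by default); if every raw value ties, all
#' pairs get confidence 1.
#'
#' @param score the integrated Score matrix.
#' @param tf_clusters,tg_clusters named cluster-label vectors.
#' @param pairs a [select_cluster_pairs()] table (only selected rows are
#'   scored).
#' @param importance a [rank_motif_importance()] table or a named numeric
#'   vector of I weights per TF; a TF without a weight defaults to 1 with
#'   a warning.
#' @param normalize `"global"` (over all scored pairs, default) or
#'   `"per_pair"` (within each cluster pair).
#' @return an object of class `confidence_table`: data.frame with columns
#'   `tf`, `gene`, `tf_cluster`, `tg_cluster`, `f1`..`f5`,
#'   `confidence_raw` and `confidence`.
#' @export
compute_confidence <- function(score, tf_clusters, tg_clusters, pairs,
                               importance = NULL,
                               normalize = c("global", "per_pair")) {
  normalize <- match.arg(normalize)
  I <- importance_weights(importance)
  L <- 0.5 + 0.5 * score
  tfl <- split(names(tf_clusters), tf_clusters)
  tgl <- split(names(tg_clusters), tg_clusters)
  sel <- pairs[pairs$selected, , drop = FALSE]
  rows <- vector("list", nrow(sel))
  missing_imp <- character()
  for (r in seq_len(nrow(sel))) {
    tfm <- tfl[[sel$tf_cluster[r]]]
    tgm <- tgl[[sel$tg_cluster[r]]]
    Lblk <- L[tfm, tgm, drop = FALSE]
    f1 <- rowMeans(Lblk)              # Ti vs all genes of Cg
    f2 <- colMeans(Lblk)              # Gj vs all TFs of Ct
    f3 <- 0.5 + 0.5 * sel$support[r]
    Iv <- stats::setNames(I[tfm], tfm)
    missing_imp <- c(missing_imp, tfm[is.na(Iv)])
    Iv[is.na(Iv)] <- 1
    grid <- expand.grid(tf = tfm, gene = tgm, stringsAsFactors = FALSE)
    grid$tf_cluster <- sel$tf_cluster[r]
    grid$tg_cluster <- sel$tg_cluster[r]
    grid$f1 <- f1[grid$tf]
    grid$f2 <- f2[grid$gene]
    grid$f3 <- f3
    grid$f4 <- Lblk[cbind(grid$tf, grid$gene)]
    grid$f5 <- Iv[grid$tf]
    rows[[r]] <- grid
  }
  if (length(missing_imp) > 0L) {
    warning("no importance weight for ",
            paste(sort(unique(missing_imp)), collapse = ", "),
            "; defaulting to 1.0")
  }
  empty <- data.frame(tf = character(), gene = character(),
                      tf_cluster = character(), tg_cluster = character(),
                      f1 = numeric(), f2 = numeric(), f3 = numeric(),
                      f4 = numeric(), f5 = numeric(),
                      confidence_raw = numeric(), confidence = numeric(),
                      stringsAsFactors = FALSE)
  if (length(rows) == 0L) {
    class(empty) <- c("confidence_table", "data.frame")
    return(empty)
  }
  out <- do.call(rbind, rows)
  out$confidence_raw <- out$f1 * out$f2 * out$f3 * out$f4 * out$f5
  minmax <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(1, length(x)) else (x - rng[1]) / diff(rng)
  }
  if (normalize == "global") {
    out$confidence <- minmax(out$confidence_raw)
  } else {
    key <- paste(out$tf_cluster, out$tg_cluster)
    out$confidence <- stats::ave(out$confidence_raw, key, FUN = minmax)
  }
  rownames(out) <- NULL
  class(out) <- c("confidence_table", "data.frame")
  out
}

importance_weights <- function(importance) {
  if (is.null(importance)) return(stats::setNames(numeric(), character()))
  if (inherits(importance, "motif_importance") ||
      (is.data.frame(importance) &&
         all(c("motif", "weight") %in% names(importance)))) {
    return(stats::setNames(importance$weight, importance$motif))
  }
  if (is.numeric(importance) && !is.null(names(importance))) {
    return(importance)
  }
  stop("importance must be a motif_importance table or a named numeric ",
       "vector", call. = FALSE)
}

#' Rank TF-TG predictions by confidence
#'
#' Descending by confidence with deterministic ties (TF then gene
#' identifier); pairs below `cutoff` are excluded.
#'
#' @param confidence a [compute_confidence()] table.
#' @param cutoff minimum confidence retained (default 0 keeps all pairs;
#'   0.5 is the conventional connectivity cutoff).
#' @return the filtered table, ordered, with a `rank` column.
#' @export
rank_predictions <- function(confidence, cutoff = 0) {
  out <- confidence[confidence$confidence >= cutoff, , drop = FALSE]
  out <- out[order(-out$confidence, out$tf, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
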