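# Fuzzy clustering by local approximation of membership (FLAME):
# kNN-density-seeded clustering in which each object's membership vector is
# iteratively replaced by the weighted average of its neighbors' vectors.
# Cluster-supporting objects (local density maxima) and outliers keep fixed
# indicator memberships; every other object converges to a convex
# combination, so genes can belong to more than one cluster.

#' Build a k-nearest-neighbor graph over expression profiles
#'
#' Distances default to 1 - Pearson correlation across all samples, so that
#' neighbors share expression *patterns* rather than absolute levels. Ties
#' are broken by gene identifier order, making the graph deterministic.
#'
#' @param profiles numeric gene x sample matrix with unique row names.
#' @param k number of neighbors (default 7).
#' @param metric `"correlation"` (1 - Pearson, default) or `"euclidean"`.
#' @return an object of class `knn_graph`: list with `neighbors` (gene x k
#'   index matrix), `dist` (matching distances), `weights` (positive, rows
#'   sum to 1), `genes`, `k`, `metric`.
#' @export
build_knn_graph <- function(profiles, k = 7L,
                            metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(profiles))
  n <- nrow(profiles)
  if (n < k + 1L) {
    stop("need at least k + 1 = ", k + 1L, " genes, got ", n,
         call. = FALSE)
  }
  if (any(!is.finite(profiles))) {
    stop("profiles must be finite", call. = FALSE)
  }
  genes <- rownames(profiles)
  if (is.null(genes)) genes <- as.character(seq_len(n))
  D <- if (metric == "correlation") {
    suppressWarnings(1 - stats::cor(t(profiles)))
  } else {
    as.matrix(stats::dist(profiles))
  }
  # constant profiles have undefined correlation; treat as maximally distant
  D[!is.finite(D)] <- 2
  ord_ids <- order(genes)
  nbr <- matrix(0L, n, k)
  nd <- matrix(0, n, k)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    o <- cand[order(D[i, cand], match(cand, ord_ids))]
    nbr[i, ] <- o[seq_len(k)]
    nd[i, ] <- D[i, nbr[i, ]]
  }
  w <- 1 / (nd + 1e-9)
  w <- w / rowSums(w)
  rownames(nbr) <- rownames(nd) <- rownames(w) <- genes
  structure(list(neighbors = nbr, dist = nd, weights = w, genes = genes,
                 k = k, metric = metric),
            class = "knn_graph")
}

#' Per-gene local density
#'
#' Density is the reciprocal of the mean distance to the k nearest
#' neighbors: tight neighborhoods score high, isolated points low.
#'
#' @param knn a [build_knn_graph()] result.
#' @return named positive numeric vector of densities.
#' @export
estimate_density <- function(knn) {
  stopifnot(inherits(knn, "knn_graph"))
  stats::setNames(1 / pmax(rowMeans(knn$dist), 1e-12), knn$genes)
}

#' Classify genes as cluster-supporting objects, outliers or rest
#'
#' A gene is a cluster-supporting object (CSO) when its density exceeds
#' that of every one of its k nearest neighbors; exact density ties are
#' resolved in favor of the lexicographically smaller identifier, so a flat
#' plateau still yields a deterministic single CSO. A gene is an outlier
#' when its density falls below all its neighbors' and below
#' mean - `outlier_factor` * SD of all densities. Everything else is
#' "rest". If no gene wins against all its neighbors, the global density
#' maximum is promoted to CSO so that at least one cluster seed exists.
#'
#' @param densities an [estimate_density()] vector.
#' @param knn the matching [build_knn_graph()].
#' @param outlier_factor SD multiplier of the outlier threshold (default 2).
#' @return named character vector over genes with values `"CSO"`,
#'   `"outlier"` or `"rest"`.
#' @export
classify_objects <- function(densities, knn, outlier_factor = 2) {
  stopifnot(inherits(knn, "knn_graph"))
  genes <- knn$genes
  d <- densities[genes]
  thr <- mean(d) - outlier_factor * stats::sd(d)
  if (is.na(thr)) thr <- -Inf
  cls <- rep("rest", length(genes))
  names(cls) <- genes
  for (i in seq_along(genes)) {
    nb <- knn$neighbors[i, ]
    beats <- d[i] > d[nb] | (d[i] == d[nb] & genes[i] < genes[nb])
    loses <- d[i] < d[nb] | (d[i] == d[nb] & genes[i] > genes[nb])
    if (all(beats)) {
      cls[i] <- "CSO"
    } else if (d[i] < thr && all(loses)) {
      cls[i] <- "outlier"
    }
  }
  if (!any(cls == "CSO")) {
    top <- genes[d == max(d)]
    cls[sort(top)[1L]] <- "CSO"
  }
  cls
}

#' Iterative local approximation of cluster memberships
#'
#' One membership column per CSO plus one outlier column. CSO and outlier
#' rows are fixed indicator vectors; each remaining row is repeatedly
#' replaced by the weighted average of its k nearest neighbors' rows, with
#' weights proportional to the neighbors' densities. Rows stay convex
#' combinations (non-negative, summing to 1) at every step; iteration stops
#' when the largest absolute entry change falls below `tol` or after
#' `max_iterations` approximation steps (non-convergence is reported in the
#' result, not fatal).
#'
#' @param object_class a [classify_objects()] vector.
#' @param knn the matching [build_knn_graph()].
#' @param densities optional densities used as propagation weights;
#'   defaults to [estimate_density()] of `knn`.
#' @param max_iterations maximum approximation steps (default 500).
#' @param tol convergence tolerance on the max row change (default 1e-6).
#' @return an object of class `membership_matrix`: list with `memberships`
#'   (gene x cluster matrix; last column `"outlier"`), `object_class`,
#'   `cso` (seed gene per cluster column), `params`, `converged`,
#'   `iterations`.
#' @export
propagate_memberships <- function(object_class, knn, densities = NULL,
                                  max_iterations = 500L, tol = 1e-6) {
  stopifnot(inherits(knn, "knn_graph"))
  if (is.null(densities)) densities <- estimate_density(knn)
  genes <- knn$genes
  cso <- genes[object_class[genes] == "CSO"]
  if (length(cso) == 0L) stop("no cluster-supporting object", call. = FALSE)
  cso <- sort(cso)
  cols <- c(paste0("C", seq_along(cso)), "outlier")
  M <- matrix(1 / length(cols), length(genes), length(cols),
              dimnames = list(genes, cols))
  for (j in seq_along(cso)) {
    M[cso[j], ] <- 0
    M[cso[j], j] <- 1
  }
  outl <- genes[object_class[genes] == "outlier"]
  M[outl, ] <- 0
  M[outl, "outlier"] <- 1
  rest <- which(!(genes %in% c(cso, outl)))
  W <- densities[genes][knn$neighbors]
  dim(W) <- dim(knn$neighbors)
  W <- W / rowSums(W)
  converged <- length(rest) == 0L
  iter <- 0L
  while (!converged && iter < max_iterations) {
    iter <- iter + 1L
    delta <- 0
    Mold <- M
    for (i in rest) {
      M[i, ] <- W[i, ] %*% Mold[knn$neighbors[i, ], , drop = FALSE]
    }
    delta <- max(abs(M - Mold))
    converged <- delta < tol
  }
  structure(list(memberships = M, object_class = object_class[genes],
                 cso = stats::setNames(cso, cols[seq_along(cso)]),
                 params = list(knn = knn$k, max_iterations = max_iterations,
                               tol = tol,
                               metric = knn$metric),
                 converged = converged, iterations = iter),
            class = "membership_matrix")
}

#' Threshold fuzzy memberships into (possibly overlapping) clusters
#'
#' A gene joins cluster c when its membership for c is at least `cutoff`;
#' since rows sum to 1, a 0.35 cutoff allows at most two cluster
#' assignments per gene. The outlier column is not reported as a cluster.
#'
#' @param membership a [propagate_memberships()] result.
#' @param cutoff membership cutoff (default 0.35).
#' @return an object of class `cluster_set`: list with `clusters` (named
#'   list of gene vectors), `outliers`, `cutoff`, `cso`.
#' @export
extract_clusters <- function(membership, cutoff = 0.35) {
  stopifnot(inherits(membership, "membership_matrix"))
  M <- membership$memberships
  cl_cols <- setdiff(colnames(M), "outlier")
  clusters <- lapply(cl_cols, function(cc) {
    sort(rownames(M)[M[, cc] >= cutoff])
  })
  names(clusters) <- cl_cols
  structure(list(clusters = clusters,
                 outliers = sort(rownames(M)[M[, "outlier"] >= cutoff]),
                 cutoff = cutoff, cso = membership$cso),
            class = "cluster_set")
}

#' Run the full FLAME stage
#'
#' Convenience wrapper: kNN graph, densities, object classification,
#' membership propagation and cluster extraction.
#'
#' @inheritParams build_knn_graph
#' @inheritParams classify_objects
#' @inheritParams propagate_memberships
#' @inheritParams extract_clusters
#' @return list with `knn`, `densities`, `object_class`, `membership`
#'   and `clusters`.
#' @export
flame_cluster <- function(profiles, k = 7L, metric = "correlation",
                          outlier_factor = 2, max_iterations = 500L,
                          tol = 1e-6, cutoff = 0.35) {
  knn <- build_knn_graph(profiles, k = k, metric = metric)
  densities <- estimate_density(knn)
  object_class <- classify_objects(densities, knn, outlier_factor)
  membership <- propagate_memberships(object_class, knn, densities,
                                      max_iterations, tol)
  list(knn = knn, densities = densities, object_class = object_class,
       membership = membership,
       clusters = extract_clusters(membership, cutoff))
}

#' Write cluster memberships and cluster sets
#'
#' @param membership a `membership_matrix`.
#' @param clusters a `cluster_set`.
#' @param membership_file,gmt_file output paths (either may be `NULL`).
#' @return invisibly `NULL`.
#' @export
write_clustering <- function(membership = NULL, clusters = NULL,
                             membership_file = NULL, gmt_file = NULL) {
  if (!is.null(membership) && !is.null(membership_file)) {
    utils::write.table(membership$memberships, membership_file,
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(clusters) && !is.null(gmt_file)) {
    lines <- vapply(names(clusters$clusters), function(cc) {
      paste(c(cc, cc, clusters$clusters[[cc]]), collapse = "\t")
    }, character(1))
    writeLines(lines, gmt_file)
  }
  invisible(NULL)
}
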