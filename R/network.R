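#' Per-TF connectivity at a confidence cutoff
#'
#' Connectivity is the number of distinct target genes a TF retains at or
#' above the confidence cutoff. Counts are reported per source cluster and
#' in total; a target predicted for the same TF in several clusters counts
#' once in the total but appears in each cluster column (so cluster
#' columns may sum to more than the total). TFs are sorted by descending
#' total, ties by identifier.
#'
#' @param edges data.frame with columns `tf`, `gene`, `confidence` and
#'   optionally `cluster` (defaults to a single cluster `"all"`).
#' @param cutoff confidence cutoff (default 0.5).
#' @return data.frame with one row per TF: `tf`, one column per cluster,
#'   and `total`.
#' @export
summarize_connectivity <- function(edges, cutoff = 0.5) {
  if (!"cluster" %in% names(edges)) edges$cluster <- "all"
  keep <- edges[edges$confidence >= cutoff,
                c("tf", "gene", "cluster"), drop = FALSE]
  tfs <- sort(unique(edges$tf))
  clusters <- sort(unique(edges$cluster))
  out <- data.frame(tf = tfs, stringsAsFactors = FALSE)
  for (cl in clusters) {
    sub <- unique(keep[keep$cluster == cl, c("tf", "gene")])
    counts <- table(factor(sub$tf, tfs))
    out[[cl]] <- as.integer(counts)
  }
  total <- table(factor(unique(keep[, c("tf", "gene")])$tf, tfs))
  out$total <- as.integer(total)
  out <- out[order(-out$total, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the regulatory network graph from ranked predictions
#'
#' Edges below the cutoff are dropped; optionally only the `top_k_tfs`
#' hub TFs (highest total connectivity at the same cutoff, ties broken by
#' identifier) are kept. Parallel per-cluster predictions of the same
#' TF-TG pair are merged into one edge carrying the maximum confidence,
#' the list of source clusters and the cross-cluster frequency (the count
#' of distinct clusters predicting it). Self-loops (a TF predicted as its
#' own target, i.e. autoregulation) are retained.
#'
#' @param edges data.frame with columns `tf`, `gene`, `confidence` and
#'   optionally `cluster`.
#' @param cutoff confidence cutoff (default 0.6).
#' @param top_k_tfs optional hub count; `0` yields an empty network.
#' @return a directed [igraph::igraph] with vertex attribute `type`
#'   (`"TF"` / `"target"`) and edge attributes `confidence`, `frequency`,
#'   `clusters`.
#' @export
build_network <- function(edges, cutoff = 0.6, top_k_tfs = NULL) {
  if (!"cluster" %in% names(edges)) edges$cluster <- "all"
  keep <- edges[edges$confidence >= cutoff, , drop = FALSE]
  if (!is.null(top_k_tfs)) {
    conn <- summarize_connectivity(edges, cutoff)
    hubs <- utils::head(conn$tf, top_k_tfs)
    keep <- keep[keep$tf %in% hubs, , drop = FALSE]
  }
  if (nrow(keep) == 0L) {
    return(igraph::make_empty_graph(directed = TRUE))
  }
  key <- paste(keep$tf, keep$gene, sep = "\r")
  agg <- lapply(split(keep, key), function(d) {
    data.frame(tf = d$tf[1L], gene = d$gene[1L],
               confidence = max(d$confidence),
               frequency = length(unique(d$cluster)),
               clusters = paste(sort(unique(d$cluster)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, agg)
  agg <- agg[order(agg$tf, agg$gene), , drop = FALSE]
  nodes <- data.frame(name = unique(c(agg$tf, agg$gene)),
                      stringsAsFactors = FALSE)
  nodes$type <- ifelse(nodes$name %in% agg$tf, "TF", "target")
  igraph::graph_from_data_frame(agg, directed = TRUE, vertices = nodes)
}

#' Export a regulatory network to SIF or GraphML
#'
#' SIF writes one `TF regulates gene` line per edge (Cytoscape's simple
#' interaction format, attributes dropped); GraphML carries all node and
#' edge attributes and round-trips through [read_network()].
#'
#' @param network an igraph network from [build_network()].
#' @param file output path.
#' @param format `"sif"` or `"graphml"`.
#' @return invisibly, `file`.
#' @export
export_network <- function(network, file, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    el <- igraph::as_edgelist(network)
    writeLines(if (nrow(el) == 0L) character() else
      paste(el[, 1L], "regulates", el[, 2L]), file)
  } else {
    igraph::write_graph(network, file, format = "graphml")
  }
  invisible(file)
}

#' Read a network back from SIF or GraphML
#'
#' @param file path written by [export_network()].
#' @param format `"sif"` or `"graphml"`.
#' @return a directed igraph.
#' @export
read_network <- function(file, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(file, format = "graphml"))
  }
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(igraph::make_empty_graph(directed = TRUE))
  parts <- do.call(rbind, strsplit(lines, "[ \t]+"))
  igraph::graph_from_data_frame(
    data.frame(tf = parts[, 1L], gene = parts[, 3L],
               stringsAsFactors = FALSE), directed = TRUE)
}
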