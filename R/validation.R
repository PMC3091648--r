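#' Binomial overlap test between predicted targets and responsive genes
#'
#' Tests whether the overlap between a predicted target set and a
#' perturbation-response gene list exceeds what the response list's
#' background rate in the analysis universe would produce by chance. The
#' background rate is |response| / |universe| and the p-value is the exact
#' upper binomial tail P(X >= overlap | n = |predicted|, p = rate).
#'
#' By convention, predictions with confidence above 0.55 form the positive
#' set and those below 0.45 the negative control in the deletion-array
#' validation.
#'
#' @param predicted,response character vectors, both subsets of
#'   `universe` (identifiers outside it are dropped with a warning).
#' @param universe the analysis universe (non-empty).
#' @return an object of class `overlap_test`: list with `n_predicted`,
#'   `n_overlap`, `background_rate`, `expected` and `p_value`.
#' @export
binomial_overlap_test <- function(predicted, response, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) {
    stop("binomial_overlap_test: empty universe", call. = FALSE)
  }
  clip <- function(x, what) {
    x <- unique(x)
    out <- setdiff(x, universe)
    if (length(out) > 0L) {
      warning(length(out), " ", what, " identifier(s) outside the ",
              "universe dropped")
    }
    intersect(x, universe)
  }
  predicted <- clip(predicted, "predicted")
  response <- clip(response, "response")
  n <- length(predicted)
  k <- length(intersect(predicted, response))
  rate <- length(response) / length(universe)
  p <- if (n == 0L || k == 0L) 1 else
    stats::pbinom(k - 1, n, rate, lower.tail = FALSE)
  structure(list(n_predicted = n, n_overlap = k, background_rate = rate,
                 expected = n * rate, p_value = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(paste0("Binomial overlap test: %d/%d predicted targets in ",
                     "the response set\n(expected %.2f at background ",
                     "rate %.4f), P(X >= %d) = %.4g\n"),
              x$n_overlap, x$n_predicted, x$expected, x$background_rate,
              x$n_overlap, x$p_value))
  invisible(x)
}

#' Deletion-response overlap validation of one TF's predictions
#'
#' Emulates the held-out deletion-array validation: the positive
#' prediction set is the TF family's targets with confidence above
#' `pos_cutoff` (0.55 by convention) and the negative control is the set
#' of genes whose best confidence across the whole prediction table falls
#' below `neg_cutoff` (0.45) — i.e. genes the integration scored but
#' ranked low for every regulator. Both sets are tested with
#' [binomial_overlap_test()] against the response list over the analysis
#' universe (the candidate genes the predictions were drawn from). A
#' well-calibrated ranking yields a smaller p-value for the positive set
#' than for the control.
#'
#' @param edges a prediction table (columns `tf`, `gene`, `confidence`),
#'   e.g. `infer_tf_network()$edges`.
#' @param family the motif family (or TF identifier) whose predictions
#'   are validated.
#' @param response responsive-gene list from the deletion experiment
#'   (clipped to the universe).
#' @param universe the analysis universe the predictions were drawn from
#'   (typically the candidate gene set).
#' @param pos_cutoff,neg_cutoff confidence thresholds for the positive
#'   set and negative control.
#' @return list with `positive` and `negative` (`overlap_test` objects or
#'   `NULL` when the respective set is empty), and the two gene sets.
#' @export
deletion_overlap_validation <- function(edges, family, response, universe,
                                        pos_cutoff = 0.55,
                                        neg_cutoff = 0.45) {
  response <- intersect(unique(response), universe)
  pos <- unique(edges$gene[edges$tf == family &
                             edges$confidence > pos_cutoff])
  best <- tapply(edges$confidence, edges$gene, max)
  neg <- names(best)[best < neg_cutoff]
  pos <- intersect(pos, universe)
  neg <- intersect(neg, universe)
  run <- function(set) {
    if (length(set) == 0L) return(NULL)
    binomial_overlap_test(set, response, universe)
  }
  list(positive = run(pos), negative = run(neg),
       positive_set = pos, negative_set = neg)
}

#' Rank percentiles of known TF-target pairs among predictions
#'
#' For each TF, reports where its known (e.g. literature-confirmed)
#' targets fall in the ranked prediction list: the percentile of a pair
#' ranked r among N predictions is 100 r / N, and the per-TF summary
#' records the worst (largest) percentile among its known targets found in
#' the list. Known pairs absent from the predictions are reported
#' separately.
#'
#' @param ranked a [rank_predictions()] table (columns `tf`, `gene`,
#'   `rank`).
#' @param known_pairs data.frame with columns `tf`, `gene`.
#' @return list with `summary` (per TF: `tf`, `n_known`, `n_found`,
#'   `worst_rank`, `worst_percentile`) and `missing` (pairs absent from
#'   the predictions).
#' @export
known_pair_rank_report <- function(ranked, known_pairs) {
  empty <- data.frame(tf = character(), n_known = integer(),
                      n_found = integer(), worst_rank = integer(),
                      worst_percentile = numeric(), stringsAsFactors = FALSE)
  if (nrow(known_pairs) == 0L) {
    return(list(summary = empty,
                missing = known_pairs[, c("tf", "gene"), drop = FALSE]))
  }
  if (!"rank" %in% names(ranked)) ranked <- rank_predictions(ranked)
  N <- nrow(ranked)
  key <- paste(ranked$tf, ranked$gene, sep = "\r")
  kkey <- paste(known_pairs$tf, known_pairs$gene, sep = "\r")
  idx <- match(kkey, key)
  found <- known_pairs[!is.na(idx), , drop = FALSE]
  found$rank <- ranked$rank[idx[!is.na(idx)]]
  found$percentile <- 100 * found$rank / N
  missing <- known_pairs[is.na(idx), c("tf", "gene"), drop = FALSE]
  rownames(missing) <- NULL
  summ <- lapply(split(seq_len(nrow(known_pairs)), known_pairs$tf),
                 function(ii) {
    tf <- known_pairs$tf[ii[1L]]
    ff <- found[found$tf == tf, , drop = FALSE]
    data.frame(tf = tf, n_known = length(ii), n_found = nrow(ff),
               worst_rank = if (nrow(ff)) max(ff$rank) else NA_integer_,
               worst_percentile = if (nrow(ff)) max(ff$percentile) else
                 NA_real_,
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  list(summary = summ, missing = missing, found = found)
}

#' Edge-recovery metrics against a planted ground truth
#'
#' Compares a confidence table with the planted edge set: precision and
#' recall of the predicted edge set at each cutoff of a grid, and the
#' rank-based area under the ROC curve (the Mann-Whitney probability that
#' a random true edge outranks a random non-edge) over all TF x gene
#' pairs of the prediction axes. Pairs absent from the table count as
#' confidence 0.
#'
#' @param confidence a [compute_confidence()] table (columns `tf`, `gene`,
#'   `confidence`). TF identifiers must match the truth's (map motif
#'   families to TF genes first if needed).
#' @param truth a `ground_truth` object, or a data.frame of true edges
#'   with columns `tf`, `gene`.
#' @param cutoffs cutoff grid (default 0, 0.1, ..., 1).
#' @param tfs,genes the prediction axes; default to the identifiers
#'   observed in `confidence`. Truth edges must lie within these axes.
#' @return list with `curve` (per cutoff: `cutoff`, `n_predicted`, `tp`,
#'   `precision`, `recall`), `auroc`, `n_true`, `n_pairs`.
#' @export
recovery_metrics <- function(confidence, truth,
                             cutoffs = seq(0, 1, by = 0.1),
                             tfs = NULL, genes = NULL) {
  edges <- if (inherits(truth, "ground_truth")) truth$edges else truth
  stopifnot(all(c("tf", "gene") %in% names(edges)))
  if (is.null(tfs)) tfs <- sort(unique(c(confidence$tf, edges$tf)))
  if (is.null(genes)) genes <- sort(unique(c(confidence$gene, edges$gene)))
  if (!all(edges$tf %in% tfs) || !all(edges$gene %in% genes)) {
    stop("recovery_metrics: truth references identifiers outside the ",
         "prediction axes", call. = FALSE)
  }
  if (!all(confidence$tf %in% tfs) || !all(confidence$gene %in% genes)) {
    stop("recovery_metrics: predictions reference identifiers outside ",
         "the declared axes", call. = FALSE)
  }
  all_pairs <- expand.grid(tf = tfs, gene = genes,
                           stringsAsFactors = FALSE)
  key <- paste(all_pairs$tf, all_pairs$gene, sep = "\r")
  score <- rep(0, nrow(all_pairs))
  ckey <- paste(confidence$tf, confidence$gene, sep = "\r")
  # a pair scored in several cluster contexts keeps its best confidence
  best <- tapply(confidence$confidence, ckey, max)
  score[match(names(best), key)] <- as.numeric(best)
  label <- key %in% paste(edges$tf, edges$gene, sep = "\r")
  npos <- sum(label); nneg <- sum(!label)
  auroc <- if (npos == 0L || nneg == 0L) NA_real_ else {
    r <- rank(score)
    (sum(r[label]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  curve <- do.call(rbind, lapply(cutoffs, function(ct) {
    # small slack absorbs floating-point error in seq-generated grids
    pred <- score >= ct - 1e-9 & score > 0
    tp <- sum(pred & label)
    data.frame(cutoff = ct, n_predicted = sum(pred), tp = tp,
               precision = if (sum(pred)) tp / sum(pred) else NA_real_,
               recall = if (npos) tp / npos else NA_real_)
  }))
  list(curve = curve, auroc = auroc, n_true = npos,
       n_pairs = nrow(all_pairs))
}
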