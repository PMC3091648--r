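#' Differential-expression calls across perturbation experiments
#'
#' Applies, per gene and experiment, an unpaired two-group Student's t-test
#' (mutant vs control) together with a fold-change filter on the linear
#' scale and a Present-call fraction filter. A gene is flagged in an
#' experiment when all three conditions hold: p-value <= `alpha`, absolute
#' linear fold change >= `fc_min` (i.e. max(ratio, 1/ratio) >= `fc_min`),
#' and Present fraction across the experiment's samples >= `present_min`.
#'
#' Values are assumed to be on the log2 scale; fold change is the ratio of
#' linear-scale group means (values exponentiated before averaging). When a
#' gene has zero variance in both groups the p-value is defined as 0 if the
#' group means differ and 1 if they coincide.
#'
#' @param data an [expression_dataset()].
#' @param alpha p-value threshold (default 0.05).
#' @param fc_min minimum absolute fold change (default 1.5).
#' @param present_min minimum Present-call fraction across the experiment's
#'   samples, both groups pooled (default 0.67).
#' @param var_equal use the pooled-variance form (default `TRUE`); `FALSE`
#'   switches to Welch's unequal-variance t-test.
#' @param log_base base of the log scale of `values` (default 2).
#' @return a data.frame with one row per (gene, experiment): `gene`,
#'   `experiment`, `p_value`, `fold_change` (linear mutant/control ratio),
#'   `present_fraction`, `flagged`.
#' @export
test_differential_expression <- function(data, alpha = 0.05, fc_min = 1.5,
                                         present_min = 0.67,
                                         var_equal = TRUE, log_base = 2) {
  stopifnot(inherits(data, "expression_dataset"))
  experiments <- unique(data$design$experiment)
  out <- vector("list", length(experiments))
  for (i in seq_along(experiments)) {
    e <- experiments[i]
    mut <- data$design$sample[data$design$experiment == e &
                                data$design$group == "mutant"]
    ctl <- data$design$sample[data$design$experiment == e &
                                data$design$group == "control"]
    if (length(mut) < 2L || length(ctl) < 2L) {
      stop("experiment '", e, "' has a group with fewer than 2 samples",
           call. = FALSE)
    }
    xm <- data$values[, mut, drop = FALSE]
    xc <- data$values[, ctl, drop = FALSE]
    n1 <- ncol(xm); n2 <- ncol(xc)
    m1 <- rowMeans(xm); m2 <- rowMeans(xc)
    v1 <- rowSums((xm - m1)^2) / (n1 - 1)
    v2 <- rowSums((xc - m2)^2) / (n2 - 1)
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- rep.int(n1 + n2 - 2, length(se))
    } else {
      se <- sqrt(v1 / n1 + v2 / n2)
      df <- (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    p <- 2 * stats::pt(-abs((m1 - m2) / se), df)
    degenerate <- se == 0 | !is.finite(p)
    p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
    fc <- rowMeans(log_base^xm) / rowMeans(log_base^xc)
    pf <- rowMeans(data$present[, c(mut, ctl), drop = FALSE])
    out[[i]] <- data.frame(
      gene = rownames(data$values), experiment = e,
      p_value = unname(p), fold_change = unname(fc),
      present_fraction = unname(pf),
      flagged = unname(p <= alpha & pmax(fc, 1 / fc) >= fc_min &
                         pf >= present_min),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls
}

#' Select candidate genes responsive across experiments
#'
#' Retains exactly the genes flagged as differentially expressed in at
#' least `min_experiments` distinct experiments, sorted by identifier.
#'
#' @param calls a [test_differential_expression()] call table.
#' @param min_experiments minimum number of distinct experiments in which a
#'   gene must be flagged (default 5, the study-scale setting; use 1 for
#'   designs where each gene responds to a single perturbation).
#' @return sorted character vector of gene identifiers.
#' @export
select_candidate_genes <- function(calls, min_experiments = 5L) {
  if (nrow(calls) == 0L) return(character())
  flagged <- calls[calls$flagged, c("gene", "experiment")]
  flagged <- unique(flagged)
  counts <- table(flagged$gene)
  sort(names(counts)[counts >= min_experiments])
}
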