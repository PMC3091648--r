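# Small in-code fixtures shared across the suite.

# Two-experiment, two-group dataset built from explicit per-group log2
# means; jitter keeps within-group variance positive.
toy_dataset <- function(mut_means, ctl_means, jitter = 1e-3, seed = 42,
                        n_rep = 3L, experiment = "E1") {
  set.seed(seed)
  genes <- names(mut_means)
  if (is.null(genes)) genes <- sprintf("g%d", seq_along(mut_means))
  design <- data.frame(
    sample = sprintf("%s_%s_%d", experiment,
                     rep(c("mut", "ctl"), each = n_rep),
                     rep(seq_len(n_rep), 2L)),
    experiment = experiment,
    group = rep(c("mutant", "control"), each = n_rep),
    stringsAsFactors = FALSE)
  values <- cbind(matrix(rep(mut_means, n_rep), ncol = n_rep),
                  matrix(rep(ctl_means, n_rep), ncol = n_rep))
  values <- values + matrix(rnorm(length(values), 0, jitter),
                            nrow = nrow(values))
  dimnames(values) <- list(genes, design$sample)
  expression_dataset(values, design)
}

# Hit-table row builder.
hit_rows <- function(gene, motif, n = 1L, region = "proximal",
                     conserved = TRUE, position = -100L) {
  data.frame(gene = rep(gene, n), motif = motif,
             position = rep(position, n), region_class = region,
             conserved = conserved, stringsAsFactors = FALSE)
}

# Deterministic random evidence-matrix quadruple on shared axes.
random_layers <- function(n_tf, n_gene, seed) {
  set.seed(seed)
  dn <- list(sprintf("T%d", seq_len(n_tf)), sprintf("g%d", seq_len(n_gene)))
  list(
    tfbs = matrix(sample(0:2, n_tf * n_gene, TRUE), n_tf, dimnames = dn),
    kappa = matrix(runif(n_tf * n_gene), n_tf, dimnames = dn),
    correlation = matrix(runif(n_tf * n_gene, -1, 1), n_tf,
                         dimnames = dn),
    interaction = matrix(sample(0:3, n_tf * n_gene, TRUE), n_tf,
                         dimnames = dn))
}

scale_layers <- function(layers) {
  list(tfbs = scale_evidence_matrix(layers$tfbs, "tfbs"),
       kappa = scale_evidence_matrix(layers$kappa, "kappa"),
       correlation = scale_evidence_matrix(layers$correlation,
                                           "correlation"),
       interaction = scale_evidence_matrix(layers$interaction,
                                           "interaction"))
}

# Brute-force hypergeometric upper tail P(X >= k) for small margins.
hyper_tail <- function(k, n_white, n_black, n_draw) {
  kk <- k:min(n_white, n_draw)
  sum(choose(n_white, kk) * choose(n_black, n_draw - kk)) /
    choose(n_white + n_black, n_draw)
}

# Brute-force binomial upper tail P(X >= k).
binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  kk <- k:n
  sum(choose(n, kk) * p^kk * (1 - p)^(n - kk))
}
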