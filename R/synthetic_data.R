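#' Configuration for the synthetic regulatory-study generator
#'
#' Bundles every tunable of the synthetic benchmark: a set of transcription
#' factors (TFs), disjoint regulatory modules of target genes, one two-group
#' perturbation experiment per TF, an annotation catalog in which co-module
#' genes share terms, a promoter motif-hit table enriched for each
#' regulator's motif among its targets, and curated-style interaction
#' evidence covering a subset of the true edges.
#'
#' Defaults describe the reference benchmark condition: 200 genes, 6 TFs,
#' one knockout experiment per TF with 3 mutant and 3 control arrays,
#' a perturbation effect of 1 log2 unit against within-group noise of 0.25
#' (a 4 standard-deviation effect), motif presence probability 0.8 for true
#' targets against a 0.1 background, and interaction-evidence coverage 0.3.
#'
#' @param n_genes number of (non-TF) genes.
#' @param n_tfs number of transcription factors; one regulatory module each.
#' @param n_experiments number of perturbation experiments; must be at least
#'   `n_tfs` (experiment i perturbs TF i; extras are null experiments).
#' @param replicates_per_group arrays per group (mutant / control); >= 2.
#' @param effect_size log2-fold shift applied to a perturbed TF and its
#'   targets in the mutant group.
#' @param noise_sd within-group standard deviation on the log2 scale.
#' @param term_universe number of annotation terms available (>= 10).
#' @param terms_per_module number of terms reserved for each module.
#' @param p_shared_term probability a module gene (or its TF) is annotated
#'   to each of its module's terms.
#' @param p_term_bg background probability of any other term per gene.
#' @param p_motif_true probability a true target's promoter carries at least
#'   one conserved hit of its regulator's motif.
#' @param p_motif_bg the same probability for a non-target.
#' @param p_nonconserved probability of an additional non-conserved decoy
#'   hit per gene/motif combination.
#' @param p_evidence probability a true edge has an interaction record.
#' @param p_second_record probability an evidenced edge carries a second
#'   record from another resource.
#' @param evidence_classes source classes records are drawn from.
#' @param cocitation_mean mean of the geometric co-citation count, chosen so
#'   that both the <=10 and >=10 branches of the interaction score occur.
#' @param module_size genes per regulatory module.
#' @param present_prob probability a measurement carries a Present call.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   expression (log2 scale).
#' @param seed integer seed; all five generators are deterministic in it.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_genes = 200L, n_tfs = 6L, n_experiments = 6L,
                             replicates_per_group = 3L,
                             effect_size = 1.0, noise_sd = 0.25,
                             term_universe = 100L, terms_per_module = 10L,
                             p_shared_term = 0.7, p_term_bg = 0.02,
                             p_motif_true = 0.8, p_motif_bg = 0.1,
                             p_nonconserved = 0.1,
                             p_evidence = 0.3, p_second_record = 0.3,
                             evidence_classes = c("computational",
                                                  "high-throughput",
                                                  "multi-source",
                                                  "direct-experimental"),
                             cocitation_mean = 8,
                             module_size = 15L, present_prob = 0.9,
                             baseline_mean = 8, baseline_sd = 1,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              n_experiments = as.integer(n_experiments),
              replicates_per_group = as.integer(replicates_per_group),
              effect_size = effect_size, noise_sd = noise_sd,
              term_universe = as.integer(term_universe),
              terms_per_module = as.integer(terms_per_module),
              p_shared_term = p_shared_term, p_term_bg = p_term_bg,
              p_motif_true = p_motif_true, p_motif_bg = p_motif_bg,
              p_nonconserved = p_nonconserved,
              p_evidence = p_evidence, p_second_record = p_second_record,
              evidence_classes = evidence_classes,
              cocitation_mean = cocitation_mean,
              module_size = as.integer(module_size),
              present_prob = present_prob,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  probs <- c("p_shared_term", "p_term_bg", "p_motif_true", "p_motif_bg",
             "p_nonconserved", "p_evidence", "p_second_record",
             "present_prob")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop("synthetic_config: `", p, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  counts <- c("n_genes", "n_tfs", "n_experiments", "replicates_per_group",
              "term_universe", "terms_per_module", "module_size")
  for (p in counts) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 1) {
      stop("synthetic_config: `", p, "` must be a positive count",
           call. = FALSE)
    }
  }
  if (cfg$p_motif_true < cfg$p_motif_bg) {
    stop("synthetic_config: p_motif_true must be >= p_motif_bg ",
         "for a recoverable network", call. = FALSE)
  }
  if (cfg$n_experiments < cfg$n_tfs) {
    stop("synthetic_config: need one experiment per TF ",
         "(n_experiments >= n_tfs)", call. = FALSE)
  }
  if (cfg$term_universe < 10L) {
    stop("synthetic_config: term_universe must be >= 10", call. = FALSE)
  }
  if (cfg$module_size * cfg$n_tfs > cfg$n_genes) {
    stop("synthetic_config: modules do not fit into n_genes", call. = FALSE)
  }
  if (cfg$noise_sd <= 0 || cfg$baseline_sd < 0) {
    stop("synthetic_config: noise_sd must be positive", call. = FALSE)
  }
  invisible(cfg)
}

# fixed per-generator seed offsets so each output is individually
# reproducible from config$seed
.seed_offsets <- c(truth = 0L, expression = 1L, catalog = 2L,
                   motifs = 3L, evidence = 4L)

#' Generate the planted ground-truth regulatory network
#'
#' Assigns each TF a motif family and a disjoint module of target genes;
#' the edge set is the union of TF x module memberships.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `ground_truth`: list with `tfs`, `genes`,
#'   `modules` (named list of gene sets), `module_tf` (module -> TF),
#'   `edges` (data.frame tf, gene) and `motif_of` (TF -> motif family).
#' @export
generate_ground_truth <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed + .seed_offsets[["truth"]])
  genes <- sprintf("g%03d", seq_len(config$n_genes))
  tfs <- sprintf("TF%d", seq_len(config$n_tfs))
  motif_of <- stats::setNames(sprintf("FAM%d", seq_len(config$n_tfs)), tfs)
  pool <- sample(genes, config$module_size * config$n_tfs)
  modules <- split(pool, rep(seq_len(config$n_tfs),
                             each = config$module_size))
  names(modules) <- sprintf("M%d", seq_len(config$n_tfs))
  modules <- lapply(modules, sort)
  module_tf <- stats::setNames(tfs, names(modules))
  edges <- do.call(rbind, lapply(names(modules), function(m) {
    data.frame(tf = module_tf[[m]], gene = modules[[m]],
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  structure(list(tfs = tfs, genes = genes, modules = modules,
                 module_tf = module_tf, edges = edges, motif_of = motif_of,
                 config = config),
            class = "ground_truth")
}

#' Simulate a perturbation-series expression dataset
#'
#' One two-group experiment per TF: in experiment i the mutant group loses
#' TF i, shifting the TF and all its module targets down by `effect_size`
#' log2 units; every other gene keeps an equal expectation in both groups.
#' Values are Gaussian around group means on the log2 scale and each
#' measurement carries an independent Present-call flag.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param config the matching [synthetic_config()].
#' @return an `expression_dataset`: list with `values` (gene x sample log2
#'   matrix; TF rows first), `design` (sample, experiment, group) and
#'   `present` (logical matrix).
#' @export
simulate_expression_dataset <- function(truth, config) {
  validate_synthetic_config(config)
  if (config$replicates_per_group < 2L) {
    stop("replicates_per_group must be >= 2 (a two-sample t-test needs ",
         "at least two arrays per group)", call. = FALSE)
  }
  set.seed(config$seed + .seed_offsets[["expression"]])
  ids <- c(truth$tfs, truth$genes)
  r <- config$replicates_per_group
  design <- do.call(rbind, lapply(seq_len(config$n_experiments), function(e) {
    data.frame(
      sample = sprintf("E%d_%s_%d", e, rep(c("mut", "ctl"), each = r),
                       rep(seq_len(r), 2L)),
      experiment = sprintf("E%d", e),
      group = rep(c("mutant", "control"), each = r),
      stringsAsFactors = FALSE)
  }))
  baseline <- stats::rnorm(length(ids), config$baseline_mean,
                           config$baseline_sd)
  values <- matrix(stats::rnorm(length(ids) * nrow(design),
                                mean = 0, sd = config$noise_sd),
                   nrow = length(ids),
                   dimnames = list(ids, design$sample))
  values <- values + baseline
  for (e in seq_len(min(config$n_tfs, config$n_experiments))) {
    tf <- truth$tfs[e]
    affected <- c(tf, truth$modules[[which(truth$module_tf == tf)]])
    mut <- design$sample[design$experiment == sprintf("E%d", e) &
                           design$group == "mutant"]
    values[affected, mut] <- values[affected, mut] - config$effect_size
  }
  present <- matrix(stats::runif(length(values)) < config$present_prob,
                    nrow = nrow(values), dimnames = dimnames(values))
  expression_dataset(values, design, present)
}

#' Construct (and validate) an expression dataset
#'
#' @param values numeric gene x sample matrix, log2 scale, finite.
#' @param design data.frame with columns `sample`, `experiment`, `group`
#'   (`"mutant"` / `"control"`), one row per column of `values`.
#' @param present logical matrix of Present calls, same shape as `values`;
#'   defaults to all-present.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, design, present = NULL) {
  if (is.null(present)) {
    present <- matrix(TRUE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  stopifnot(is.matrix(values), is.matrix(present),
            identical(dim(values), dim(present)))
  if (anyDuplicated(rownames(values))) {
    stop("expression_dataset: gene identifiers must be unique",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression_dataset: values must be finite", call. = FALSE)
  }
  if (!all(c("sample", "experiment", "group") %in% names(design))) {
    stop("expression_dataset: design needs sample/experiment/group columns",
         call. = FALSE)
  }
  if (!identical(colnames(values), design$sample)) {
    stop("expression_dataset: design rows must match value columns ",
         "in order", call. = FALSE)
  }
  if (!all(design$group %in% c("mutant", "control"))) {
    stop("expression_dataset: groups must be 'mutant' or 'control'",
         call. = FALSE)
  }
  structure(list(values = values, design = design, present = present),
            class = "expression_dataset")
}

#' Generate an annotation catalog with module-shared terms
#'
#' Each module (and its TF) draws from a reserved block of terms with
#' probability `p_shared_term`; every gene additionally picks up background
#' terms at rate `p_term_bg`, so within-module pairs share more terms in
#' expectation than cross-module pairs whenever `p_shared_term > p_term_bg`.
#'
#' @inheritParams simulate_expression_dataset
#' @return an [annotation_catalog()].
#' @export
generate_annotation_catalog <- function(truth, config) {
  validate_synthetic_config(config)
  set.seed(config$seed + .seed_offsets[["catalog"]])
  terms <- sprintf("T%03d", seq_len(config$term_universe))
  ids <- c(truth$tfs, truth$genes)
  if (length(ids) == 0L || length(truth$genes) == 0L) {
    return(annotation_catalog(stats::setNames(list(), character()),
                              n_terms = config$term_universe))
  }
  tpm <- min(config$terms_per_module,
             config$term_universe %/% max(1L, length(truth$modules)))
  tpm <- max(tpm, 1L)
  membership <- matrix(FALSE, length(ids), length(terms),
                       dimnames = list(ids, terms))
  for (m in seq_along(truth$modules)) {
    block <- terms[((m - 1L) * tpm + 1L):(m * tpm)]
    members <- c(truth$module_tf[[m]], truth$modules[[m]])
    draws <- matrix(stats::runif(length(members) * length(block)) <
                      config$p_shared_term,
                    nrow = length(members))
    membership[members, block] <- membership[members, block] | draws
  }
  bg <- matrix(stats::runif(length(membership)) < config$p_term_bg,
               nrow = nrow(membership))
  # background terms never overwrite the module blocks' guarantees
  membership <- membership | bg
  sets <- lapply(terms, function(t) ids[membership[, t]])
  names(sets) <- terms
  annotation_catalog(sets[vapply(sets, length, 1L) > 0L],
                     n_terms = config$term_universe)
}

#' Generate a promoter motif-hit table
#'
#' True targets carry at least one conserved hit of their regulator's motif
#' family with probability `p_motif_true`; non-targets with probability
#' `p_motif_bg`. Hit counts are drawn so that both single and multiple
#' conserved hits occur; positions span an upstream window of 3 kb plus
#' 200 bp downstream of the TSS, split into distal conserved regions (ECR)
#' and the proximal promoter. Non-conserved decoy hits are sprinkled in at
#' rate `p_nonconserved`.
#'
#' @inheritParams simulate_expression_dataset
#' @return a data.frame with columns gene, motif, position, region_class
#'   (`"ECR"` / `"proximal"`) and conserved.
#' @export
generate_motif_hits <- function(truth, config) {
  validate_synthetic_config(config)
  stopifnot(all(truth$tfs %in% names(truth$motif_of)))
  set.seed(config$seed + .seed_offsets[["motifs"]])
  fams <- unname(truth$motif_of)
  target_of <- lapply(truth$tfs, function(tf) {
    truth$edges$gene[truth$edges$tf == tf]
  })
  names(target_of) <- fams
  rows <- vector("list", length(fams) * 2L)
  i <- 0L
  one_gene_hits <- function(gene, motif, n, conserved) {
    pos <- sample(seq(-3000L, 199L), n)
    data.frame(gene = gene, motif = motif, position = pos,
               region_class = ifelse(pos < -1000L, "ECR", "proximal"),
               conserved = conserved, stringsAsFactors = FALSE)
  }
  for (fam in fams) {
    p_hit <- ifelse(truth$genes %in% target_of[[fam]],
                    config$p_motif_true, config$p_motif_bg)
    carriers <- truth$genes[stats::runif(length(truth$genes)) < p_hit]
    for (g in carriers) {
      n_hits <- 1L + stats::rbinom(1L, 2L, 0.35)
      i <- i + 1L
      rows[[i]] <- one_gene_hits(g, fam, n_hits, TRUE)
    }
    decoys <- truth$genes[stats::runif(length(truth$genes)) <
                            config$p_nonconserved]
    for (g in decoys) {
      i <- i + 1L
      rows[[i]] <- one_gene_hits(g, fam, 1L, FALSE)
    }
  }
  hits <- if (i > 0L) do.call(rbind, rows[seq_len(i)]) else
    data.frame(gene = character(), motif = character(),
               position = integer(), region_class = character(),
               conserved = logical(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  hits
}

#' Generate curated-style interaction-evidence records
#'
#' Each true edge receives a record with probability `p_evidence`; source
#' classes are drawn from `evidence_classes` and co-citation counts from a
#' geometric distribution with mean `cocitation_mean`, exercising both the
#' low and high co-citation branches of the interaction score. Some
#' evidenced edges carry a second record from a different resource.
#'
#' @inheritParams simulate_expression_dataset
#' @return a data.frame with columns tf, gene, source_class, co_citations
#'   and provenance.
#' @export
generate_interaction_evidence <- function(truth, config) {
  validate_synthetic_config(config)
  set.seed(config$seed + .seed_offsets[["evidence"]])
  empty <- data.frame(tf = character(), gene = character(),
                      source_class = character(), co_citations = integer(),
                      provenance = character(), stringsAsFactors = FALSE)
  if (nrow(truth$edges) == 0L || config$p_evidence == 0) return(empty)
  keep <- stats::runif(nrow(truth$edges)) < config$p_evidence
  if (!any(keep)) return(empty)
  covered <- truth$edges[keep, , drop = FALSE]
  draw <- function(edge_df, dbs) {
    n <- nrow(edge_df)
    data.frame(
      tf = edge_df$tf, gene = edge_df$gene,
      source_class = sample(config$evidence_classes, n, replace = TRUE),
      co_citations = stats::rgeom(n, 1 / (config$cocitation_mean + 1)),
      provenance = sample(dbs, n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  recs <- draw(covered, c("dbA", "dbB"))
  second <- stats::runif(nrow(covered)) < config$p_second_record
  if (any(second)) {
    recs <- rbind(recs, draw(covered[second, , drop = FALSE],
                             c("dbC", "dbD")))
  }
  rownames(recs) <- NULL
  recs
}

#' Simulate the complete synthetic study
#'
#' Runs all five generators for one configuration.
#'
#' @param config a [synthetic_config()].
#' @return list with `truth`, `expression`, `catalog`, `hits`, `evidence`
#'   and `family_map` (data.frame motif, tf).
#' @export
simulate_regulatory_study <- function(config = synthetic_config()) {
  truth <- generate_ground_truth(config)
  list(truth = truth,
       expression = simulate_expression_dataset(truth, config),
       catalog = generate_annotation_catalog(truth, config),
       hits = generate_motif_hits(truth, config),
       evidence = generate_interaction_evidence(truth, config),
       family_map = data.frame(motif = unname(truth$motif_of),
                               tf = names(truth$motif_of),
                               stringsAsFactors = FALSE),
       config = config)
}

#' Simulate an independent TF-deletion validation experiment
#'
#' Generates a fresh two-group experiment in which one TF is deleted, runs
#' the differential filters on it and returns the list of responsive genes
#' (decreased by default), emulating an in-vivo deletion array held out of
#' network construction.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param config the matching [synthetic_config()].
#' @param tf the TF to delete.
#' @param seed seed for this experiment (kept distinct from the training
#'   data's seed stream).
#' @param direction `"decreased"` (default) keeps genes whose mutant/control
#'   ratio is below 1; `"any"` keeps both directions.
#' @param alpha,fc_min significance and fold-change filters.
#' @return character vector of responsive gene identifiers.
#' @export
simulate_deletion_response <- function(truth, config, tf,
                                       seed = config$seed + 1000L,
                                       direction = c("decreased", "any"),
                                       alpha = 0.05, fc_min = 1.5) {
  direction <- match.arg(direction)
  stopifnot(tf %in% truth$tfs)
  cfg <- config
  cfg$seed <- as.integer(seed)
  cfg$n_experiments <- cfg$n_tfs
  set.seed(cfg$seed + 99L)
  ids <- c(truth$tfs, truth$genes)
  r <- cfg$replicates_per_group
  design <- data.frame(
    sample = sprintf("DEL_%s_%d", rep(c("mut", "ctl"), each = r),
                     rep(seq_len(r), 2L)),
    experiment = "DEL", group = rep(c("mutant", "control"), each = r),
    stringsAsFactors = FALSE)
  baseline <- stats::rnorm(length(ids), cfg$baseline_mean, cfg$baseline_sd)
  values <- baseline + matrix(stats::rnorm(length(ids) * nrow(design), 0,
                                           cfg$noise_sd),
                              nrow = length(ids),
                              dimnames = list(ids, design$sample))
  affected <- c(tf, truth$modules[[which(truth$module_tf == tf)]])
  mut <- design$sample[design$group == "mutant"]
  values[affected, mut] <- values[affected, mut] - cfg$effect_size
  ds <- expression_dataset(values, design)
  calls <- test_differential_expression(ds, alpha = alpha, fc_min = fc_min,
                                        present_min = 0)
  hit <- calls$flagged
  if (direction == "decreased") hit <- hit & calls$fold_change < 1
  sort(setdiff(calls$gene[hit], truth$tfs))
}

#' Write all synthetic inputs to plain-text files
#'
#' Emits the expression matrix and design as TSV, the annotation catalog as
#' GMT, the motif hits, evidence records and ground-truth edges as TSV, and
#' a JSON echo of the configuration.
#'
#' @param study a [simulate_regulatory_study()] result.
#' @param outdir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic_inputs <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(outdir, name)
  write_expression_dataset(study$expression, f("expression.tsv"),
                           f("design.tsv"), f("present.tsv"))
  write_gmt(study$catalog, f("annotations.gmt"))
  write_tsv(study$hits, f("motif_hits.tsv"))
  write_tsv(study$evidence, f("evidence.tsv"))
  write_tsv(study$truth$edges, f("truth_edges.tsv"))
  write_tsv(study$family_map, f("family_map.tsv"))
  cfg <- study$config
  cfg$evidence_classes <- paste(cfg$evidence_classes, collapse = ",")
  writeLines(paste0(names(cfg), "\t", unlist(cfg)), f("config.tsv"))
  invisible(file.path(outdir, list.files(outdir)))
}
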