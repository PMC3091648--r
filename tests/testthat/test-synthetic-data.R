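test_that("config validation rejects out-of-range settings", {
  expect_error(synthetic_config(p_motif_true = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(p_motif_true = 0.1, p_motif_bg = 0.5),
               "recoverable")
  expect_error(synthetic_config(n_genes = 0), "positive count")
  expect_error(synthetic_config(term_universe = 5), ">= 10")
  expect_error(synthetic_config(n_tfs = 4, n_experiments = 2),
               "experiment per TF")
})

test_that("all five generators are deterministic in the seed", {
  cfg <- synthetic_config(n_genes = 40, n_tfs = 2, n_experiments = 2,
                          module_size = 8, seed = 7)
  a <- simulate_regulatory_study(cfg)
  b <- simulate_regulatory_study(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$expression, b$expression)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$hits, b$hits)
  expect_identical(a$evidence, b$evidence)
})

test_that("ground-truth edge count equals the sum of module sizes", {
  cfg <- synthetic_config(n_genes = 30, n_tfs = 2, n_experiments = 2,
                          module_size = 5, seed = 3)
  truth <- generate_ground_truth(cfg)
  expect_equal(nrow(truth$edges), 10L)
  # every edge's gene belongs to the module assigned to that TF
  for (m in names(truth$modules)) {
    tf <- truth$module_tf[[m]]
    expect_setequal(truth$edges$gene[truth$edges$tf == tf],
                    truth$modules[[m]])
  }
  expect_false(anyDuplicated(truth$genes) > 0)
  expect_false(anyDuplicated(paste(truth$edges$tf, truth$edges$gene)) > 0)
})

test_that("unequal module sizes produce the enumerated edge count", {
  # three modules of sizes 4, 6 and 10 assigned to three TFs -> 20 edges;
  # emulated with equal-size API by direct enumeration over the pieces
  sizes <- c(4L, 6L, 10L)
  counts <- vapply(seq_along(sizes), function(i) {
    cfg <- synthetic_config(n_genes = 30, n_tfs = 1, n_experiments = 1,
                            module_size = sizes[i], seed = i)
    nrow(generate_ground_truth(cfg)$edges)
  }, integer(1))
  expect_identical(sum(counts), 20L)
})

test_that("expression nulls are calibrated and effects are recovered", {
  cfg <- synthetic_config(n_genes = 150, n_tfs = 2, n_experiments = 2,
                          module_size = 10, effect_size = 0, seed = 11)
  truth <- generate_ground_truth(cfg)
  ds <- simulate_expression_dataset(truth, cfg)
  calls <- test_differential_expression(ds, fc_min = 1, present_min = 0)
  # effect_size = 0: the p <= 0.05 rate matches the nominal type-I rate
  rate <- mean(calls$p_value <= 0.05)
  n <- nrow(calls)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.01)

  # a 4 SD effect flags targets and leaves non-targets at ~alpha;
  # Monte-Carlo over replicate simulations
  flagged_t <- flagged_n <- c()
  for (s in 1:8) {
    cfg2 <- synthetic_config(n_genes = 60, n_tfs = 2, n_experiments = 2,
                             module_size = 8, effect_size = 1,
                             noise_sd = 0.25, seed = s)
    tr <- generate_ground_truth(cfg2)
    d2 <- simulate_expression_dataset(tr, cfg2)
    cl <- test_differential_expression(d2, fc_min = 1, present_min = 0)
    for (e in unique(cl$experiment)) {
      tf <- tr$tfs[as.integer(sub("E", "", e))]
      tgt <- tr$edges$gene[tr$edges$tf == tf]
      sub <- cl[cl$experiment == e & cl$gene %in% tr$genes, ]
      flagged_t <- c(flagged_t, sub$flagged[sub$gene %in% tgt])
      flagged_n <- c(flagged_n, sub$flagged[!sub$gene %in% tgt])
    }
  }
  expect_gt(mean(flagged_t), 0.9)
  expect_lt(mean(flagged_n), 0.1)
})

test_that("simulated datasets satisfy their structural contract", {
  cfg <- synthetic_config(n_genes = 30, n_tfs = 2, n_experiments = 3,
                          module_size = 5, replicates_per_group = 2,
                          seed = 5)
  truth <- generate_ground_truth(cfg)
  ds <- simulate_expression_dataset(truth, cfg)
  expect_equal(nrow(ds$values), cfg$n_genes + cfg$n_tfs)
  expect_equal(ncol(ds$values), cfg$n_experiments * 2L * 2L)
  expect_identical(dim(ds$present), dim(ds$values))
  cfg_bad <- cfg
  cfg_bad$replicates_per_group <- 1L
  expect_error(simulate_expression_dataset(truth, cfg_bad), ">= 2")
})

test_that("annotation catalogs share terms within modules as configured", {
  cfg <- synthetic_config(n_genes = 20, n_tfs = 1, n_experiments = 1,
                          module_size = 20, p_shared_term = 1,
                          p_term_bg = 0, seed = 2)
  truth <- generate_ground_truth(cfg)
  cat1 <- generate_annotation_catalog(truth, cfg)
  # p_shared_term = 1, one module: all module genes annotated to the
  # module's full term block, so every pairwise kappa is 1
  g <- truth$modules[[1]][1:4]
  K <- compute_kappa_matrix(g, g, cat1)
  expect_true(all(K == 1))

  # p_shared_term = 0 with background only: within- and between-module
  # mean kappa agree (Monte-Carlo over seeds)
  wk <- bk <- c()
  for (s in 1:6) {
    cfg0 <- synthetic_config(n_genes = 40, n_tfs = 2, n_experiments = 2,
                             module_size = 10, p_shared_term = 0,
                             p_term_bg = 0.15, seed = s)
    tr <- generate_ground_truth(cfg0)
    ct <- generate_annotation_catalog(tr, cfg0)
    m1 <- tr$modules[[1]]; m2 <- tr$modules[[2]]
    Kw <- compute_kappa_matrix(m1, m1, ct)
    diag(Kw) <- NA
    Kb <- compute_kappa_matrix(m1, m2, ct)
    wk <- c(wk, mean(Kw, na.rm = TRUE))
    bk <- c(bk, mean(Kb, na.rm = TRUE))
  }
  expect_lt(abs(mean(wk) - mean(bk)), 0.05)

  # and with sharing on, within-module kappa strictly dominates
  cfgs <- synthetic_config(n_genes = 40, n_tfs = 2, n_experiments = 2,
                           module_size = 10, p_shared_term = 0.8,
                           seed = 9)
  trs <- generate_ground_truth(cfgs)
  cts <- generate_annotation_catalog(trs, cfgs)
  Kw <- compute_kappa_matrix(trs$modules[[1]], trs$modules[[1]], cts)
  diag(Kw) <- NA
  Kb <- compute_kappa_matrix(trs$modules[[1]], trs$modules[[2]], cts)
  expect_gt(mean(Kw, na.rm = TRUE), mean(Kb, na.rm = TRUE))
})

test_that("motif hits land on true edges at the configured rates", {
  cfg <- synthetic_config(n_genes = 30, n_tfs = 2, n_experiments = 2,
                          module_size = 6, p_motif_true = 1,
                          p_motif_bg = 0, p_nonconserved = 0, seed = 4)
  truth <- generate_ground_truth(cfg)
  hits <- generate_motif_hits(truth, cfg)
  M <- score_tfbs_matrix(hits, truth$genes)
  for (tf in truth$tfs) {
    fam <- truth$motif_of[[tf]]
    tgt <- truth$edges$gene[truth$edges$tf == tf]
    expect_true(all(M[fam, tgt] >= 1))
    expect_true(all(M[fam, setdiff(truth$genes, tgt)] == 0))
  }
  # binomial expectation on hit-bearing target counts (Monte-Carlo)
  n_hit <- c()
  for (s in 1:6) {
    cfg2 <- synthetic_config(n_genes = 100, n_tfs = 1, n_experiments = 1,
                             module_size = 50, p_motif_true = 0.9,
                             p_motif_bg = 0.1, seed = s)
    tr <- generate_ground_truth(cfg2)
    h <- generate_motif_hits(tr, cfg2)
    M2 <- score_tfbs_matrix(h, tr$genes)
    tgt <- tr$edges$gene
    n_hit <- c(n_hit, sum(M2[1, tgt] >= 1))
  }
  expect_lt(abs(mean(n_hit) - 45), 5)
})

test_that("interaction evidence covers true edges at rate p_evidence", {
  cfg0 <- synthetic_config(n_genes = 30, n_tfs = 2, n_experiments = 2,
                           module_size = 5, p_evidence = 0, seed = 1)
  truth0 <- generate_ground_truth(cfg0)
  expect_equal(nrow(generate_interaction_evidence(truth0, cfg0)), 0L)

  # p_evidence = 1 with only direct-experimental records: every true edge
  # scores 3 downstream
  cfg1 <- synthetic_config(n_genes = 30, n_tfs = 2, n_experiments = 2,
                           module_size = 5, p_evidence = 1,
                           evidence_classes = "direct-experimental",
                           seed = 1)
  truth1 <- generate_ground_truth(cfg1)
  recs <- generate_interaction_evidence(truth1, cfg1)
  M <- score_interactions(recs, truth1$tfs, truth1$genes)
  expect_true(all(M[cbind(truth1$edges$tf, truth1$edges$gene)] == 3L))

  # expected record coverage ~ p_evidence * |edges| (Monte-Carlo)
  cov <- c()
  for (s in 1:8) {
    cfg <- synthetic_config(n_genes = 120, n_tfs = 2, n_experiments = 2,
                            module_size = 50, p_evidence = 0.3, seed = s)
    tr <- generate_ground_truth(cfg)
    rc <- generate_interaction_evidence(tr, cfg)
    cov <- c(cov, length(unique(paste(rc$tf, rc$gene))))
  }
  expect_lt(abs(mean(cov) - 30), 5)
})

test_that("synthetic inputs round-trip through their text formats", {
  cfg <- synthetic_config(n_genes = 25, n_tfs = 2, n_experiments = 2,
                          module_size = 5, seed = 6)
  study <- simulate_regulatory_study(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_inputs(study, dir)
  ds <- read_expression_dataset(file.path(dir, "expression.tsv"),
                                file.path(dir, "design.tsv"),
                                file.path(dir, "present.tsv"))
  expect_equal(ds$values, study$expression$values, tolerance = 1e-12)
  expect_identical(ds$present, study$expression$present)
  ct <- read_gmt(file.path(dir, "annotations.gmt"),
                 n_terms = cfg$term_universe)
  expect_identical(ct$terms, study$catalog$terms)
})
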