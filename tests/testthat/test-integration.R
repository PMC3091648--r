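test_that("per-layer scaling applies the declared fixed maps", {
  dn <- list("T1", c("g1", "g2", "g3"))
  tfbs <- matrix(c(0L, 1L, 2L), 1, dimnames = dn)
  expect_equal(unname(scale_evidence_matrix(tfbs, "tfbs")[1, ]),
               c(0, 0.5, 1))
  inter <- matrix(c(0L, 2L, 3L), 1, dimnames = dn)
  expect_equal(unname(scale_evidence_matrix(inter, "interaction")[1, ]),
               c(0, 2 / 3, 1))
  corr <- matrix(c(-0.9, 0, 0.7), 1, dimnames = dn)
  expect_equal(unname(scale_evidence_matrix(corr, "correlation")[1, ]),
               c(0, 0, 0.7))      # negative correlations rectified
  expect_equal(unname(scale_evidence_matrix(corr, "correlation",
                                            rectify = FALSE)[1, ]),
               c(0.05, 0.5, 0.85))
  const <- matrix(5, 2, 2)
  expect_true(all(scale_evidence_matrix(const, "minmax") == 0))
  # missing entries are imputed as 0 and flagged
  km <- matrix(c(0.5, NA, 1), 1, dimnames = dn)
  sk <- scale_evidence_matrix(km, "kappa")
  expect_equal(unname(sk[1, ]), c(0.5, 0, 1))
  expect_true(attr(sk, "imputed")[1, 2])
  expect_error(scale_evidence_matrix(matrix(3L, 1, 1), "tfbs"), "0, 1, 2")
})

test_that("integration sums layers and min-max rescales to [0, 1]", {
  dn <- list(c("T1", "T2"), c("g1", "g2"))
  mk <- function(...) matrix(c(...), 2, dimnames = dn)
  layers <- list(a = mk(1, 0, 0.5, 0), b = mk(1, 0, 0.5, 0.2),
                 c = mk(1, 0, 0, 0.3), d = mk(1, 0, 0.5, 0.1))
  integ <- integrate_matrices(layers)
  # the all-maximal pair maps to 1, the all-zero pair to 0
  expect_equal(integ$score["T1", "g1"], 1)
  expect_equal(integ$score["T2", "g1"], 0)
  # interior entries follow the hand-computed sum + rescale
  expect_equal(integ$score["T1", "g2"], 1.5 / 4)
  expect_equal(integ$score["T2", "g2"], 0.6 / 4)
  misaligned <- layers
  rownames(misaligned$b) <- c("T2", "T1")
  expect_error(integrate_matrices(misaligned), "aligned")
  # degenerate all-equal positive sum -> all 1
  same <- list(x = mk(0.5, 0.5, 0.5, 0.5))
  expect_true(all(integrate_matrices(same)$score == 1))
})

test_that("axis clustering is deterministic and respects block structure", {
  f <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0),
             c = c(0, 0, 1, 1), d = c(0, 0, 1, 1.1))
  cl <- cluster_axis(f, n_clusters = 2)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_equal(cl[["c"]], cl[["d"]])
  expect_false(cl[["a"]] == cl[["c"]])
  # identical rows always co-cluster; as many clusters as rows -> singletons
  expect_equal(length(unique(cluster_axis(f, n_clusters = 4))), 4L)
  expect_error(cluster_axis(f, n_clusters = 5), "fewer items")
  expect_error(cluster_axis(f[1, , drop = FALSE]), "at least 2")
})

test_that("Support is the mean Score over the cluster pair", {
  dn <- list(c("T1", "T2"), c("g1", "g2", "g3"))
  sc <- matrix(c(1, 0.5, 0.5, 0.5, 0, 0.5), 2, dimnames = dn)
  expect_equal(compute_support(c("T1", "T2"), c("g1", "g2", "g3"), sc),
               0.5)
  ones <- matrix(1, 2, 3, dimnames = dn)
  expect_equal(compute_support(rownames(ones), colnames(ones), ones), 1)
  expect_equal(compute_support(rownames(ones), colnames(ones), ones * 0),
               0)
  expect_error(compute_support(character(), "g1", sc), "empty")
  # brute-force double sum over every enumerated sub-pair
  set.seed(2)
  big <- matrix(runif(25), 5,
                dimnames = list(sprintf("T%d", 1:5), sprintf("g%d", 1:5)))
  for (m in 1:3) for (n in 1:3) {
    ct <- sample(rownames(big), m); cg <- sample(colnames(big), n)
    brute <- 0
    for (ti in ct) for (gj in cg) brute <- brute + big[ti, gj]
    expect_equal(compute_support(ct, cg, big), brute / (m * n),
                 tolerance = 1e-12)
  }
})

test_that("cluster pairs are selected at the Support threshold
           inclusively", {
  dn <- list(c("T1", "T2"), c("g1", "g2"))
  sc <- matrix(c(0.25, 0.25, 0.24, 0.24), 2, dimnames = dn,
               byrow = FALSE)
  tf_cl <- c(T1 = 1L, T2 = 2L)
  tg_cl <- c(g1 = 1L, g2 = 2L)
  pairs <- select_cluster_pairs(tf_cl, tg_cl, sc, threshold = 0.25)
  sel <- pairs$selected
  names(sel) <- paste(pairs$tf_cluster, pairs$tg_cluster)
  expect_true(sel[["1 1"]])    # support 0.25 selected
  expect_false(sel[["1 2"]])   # support 0.24 not
  # nothing passing leaves the confidence table empty downstream
  none <- select_cluster_pairs(tf_cl, tg_cl, sc * 0, threshold = 0.25)
  conf <- compute_confidence(sc * 0, tf_cl, tg_cl, none)
  expect_equal(nrow(conf), 0L)
})

test_that("confidence combines the five factors multiplicatively", {
  dn <- list(c("T1", "T2"), c("g1", "g2"))
  sc <- matrix(c(1, 0.2, 0.6, 0), 2, dimnames = dn)
  tf_cl <- c(T1 = 1L, T2 = 1L)
  tg_cl <- c(g1 = 1L, g2 = 1L)
  pairs <- select_cluster_pairs(tf_cl, tg_cl, sc, threshold = 0.25)
  imp <- c(T1 = 1.2, T2 = 0.8)
  conf <- compute_confidence(sc, tf_cl, tg_cl, pairs, importance = imp)
  # hand computation for the 2x2 toy
  L <- 0.5 + 0.5 * sc
  s <- mean(sc)
  for (r in seq_len(nrow(conf))) {
    ti <- conf$tf[r]; gj <- conf$gene[r]
    raw <- mean(L[ti, ]) * mean(L[, gj]) * (0.5 + 0.5 * s) *
      L[ti, gj] * imp[[ti]]
    expect_equal(conf$confidence_raw[r], raw, tolerance = 1e-12)
  }
  # floors keep the raw product strictly positive even at Score = 0
  expect_true(all(conf$confidence_raw > 0))
  expect_true(all(conf$f4 >= 0.5 & conf$f4 <= 1))
  expect_true(all(conf$confidence >= 0 & conf$confidence <= 1))
  # the all-maximal pair with top importance normalizes to 1
  best <- conf[conf$tf == "T1" & conf$gene == "g1", ]
  expect_equal(best$confidence, 1)
  # a TF without an importance weight defaults to 1 with a warning
  expect_warning(
    compute_confidence(sc, tf_cl, tg_cl, pairs,
                       importance = c(T1 = 1.1)),
    "defaulting to 1")
})

test_that("raising any single evidence value never lowers raw
           confidence", {
  set.seed(17)
  for (rep in 1:10) {
    layers <- random_layers(3, 6, seed = rep)
    scaled <- scale_layers(layers)
    bump <- sample(names(layers), 1)
    i <- sample(3, 1); j <- sample(6, 1)
    layers2 <- layers
    top <- c(tfbs = 2, kappa = 1, correlation = 1, interaction = 3)
    layers2[[bump]][i, j] <- top[[bump]]
    scaled2 <- scale_layers(layers2)
    raw_conf <- function(sc_layers) {
      S <- Reduce(`+`, sc_layers)       # pre-normalization sums
      L <- 0.5 + 0.5 * S / 4
      mean(L[i, ]) * mean(L[, j]) *
        (0.5 + 0.5 * mean(S / 4)) * L[i, j]
    }
    expect_gte(raw_conf(scaled2), raw_conf(scaled) - 1e-12)
  }
})

test_that("prediction ranking is total, deterministic and cutoff-aware", {
  conf <- data.frame(
    tf = c("T2", "T1", "T1", "T2"), gene = c("g1", "g2", "g1", "g2"),
    tf_cluster = "1", tg_cluster = "1", f1 = 1, f2 = 1, f3 = 1, f4 = 1,
    f5 = 1, confidence_raw = c(0.5, 0.8, 0.8, 0.1),
    confidence = c(0.5, 0.8, 0.8, 0.1), stringsAsFactors = FALSE)
  ranked <- rank_predictions(conf)
  expect_identical(ranked$rank, 1:4)
  # ties resolved by (TF, gene) identifiers
  expect_identical(ranked$tf[1:2], c("T1", "T1"))
  expect_identical(ranked$gene[1:2], c("g1", "g2"))
  # permuting rows leaves the ranking unchanged
  ranked2 <- rank_predictions(conf[c(3, 1, 4, 2), ])
  expect_identical(ranked$tf, ranked2$tf)
  expect_identical(ranked$gene, ranked2$gene)
  expect_equal(nrow(rank_predictions(conf, cutoff = 0.5)), 3L)
  expect_equal(nrow(rank_predictions(conf, cutoff = 1.1)), 0L)
})

test_that("Score, Support and Confidence stay in their bounds on
           randomized inputs", {
  set.seed(99)
  for (rep in 1:40) {
    n_tf <- sample(2:5, 1); n_g <- sample(3:8, 1)
    scaled <- scale_layers(random_layers(n_tf, n_g, seed = rep + 1000))
    for (l in scaled) expect_true(all(l >= 0 & l <= 1))
    integ <- integrate_matrices(scaled)
    expect_true(all(integ$score >= 0 & integ$score <= 1))
    tf_cl <- stats::setNames(sample(1:2, n_tf, TRUE),
                             rownames(integ$score))
    tg_cl <- stats::setNames(sample(1:2, n_g, TRUE),
                             colnames(integ$score))
    pairs <- select_cluster_pairs(tf_cl, tg_cl, integ$score, 0)
    expect_true(all(pairs$support >= 0 & pairs$support <= 1))
    imp <- stats::setNames(runif(n_tf, 0.8, 1.2), rownames(integ$score))
    conf <- compute_confidence(integ$score, tf_cl, tg_cl, pairs, imp)
    expect_true(all(conf$f4 >= 0.5 & conf$f4 <= 1))
    expect_true(all(conf$f5 >= 0.8 & conf$f5 <= 1.2))
    expect_true(all(conf$confidence >= 0 & conf$confidence <= 1))
  }
})
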