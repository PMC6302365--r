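test_that("GMT parsing handles dedup, empty sets and malformed lines", {
  d <- withr::local_tempdir()
  f <- file.path(d, "sets.gmt")
  writeLines(c("setA\tdesc\tg1\tg2", "setB\tdesc\tg3\tg3\tg4",
               "setC\tdesc"), f)
  sets <- NULL
  expect_warning(sets <- read_gmt(f), "empty")
  expect_equal(sets$setA, c("g1", "g2"))
  expect_equal(sets$setB, c("g3", "g4"))  # duplicate collapsed
  expect_false("setC" %in% names(sets))
  writeLines(c("setA\tdesc\tg1", "lonely"), f)
  expect_error(read_gmt(f), "line 2")
  # round trip
  writeLines(c("setA\tdesc\tg1\tg2"), f)
  s1 <- read_gmt(f)
  write_gmt(s1, file.path(d, "out.gmt"))
  expect_equal(read_gmt(file.path(d, "out.gmt")), s1)
})

test_that("gene-set size filter is strict", {
  sets <- list(big = paste0("g", 1:50), ok = paste0("g", 1:49))
  out <- filter_gene_sets(sets, 50)
  expect_equal(names(out), "ok")
  expect_equal(filter_gene_sets(list(), 50), list())
})

test_that("gene sets are ranked by |t| of summarized expression and deduplicated", {
  set.seed(88)
  m <- matrix(rnorm(30 * 24), 30, 24)
  m[1:5, 1:12] <- m[1:5, 1:12] + 3   # planted shifted block
  rownames(m) <- sprintf("g%02d", 1:30); colnames(m) <- sprintf("s%02d", 1:24)
  z <- zscore_expression(make_es2(m))
  sets <- list(planted = sprintf("g%02d", 1:5),
               noise = sprintf("g%02d", 11:15),
               planted_copy = sprintf("g%02d", 1:5),
               outside = c("zz1", "zz2"))
  out <- NULL
  expect_warning(out <- rank_and_prune_gene_sets(sets, z), "no genes")
  expect_equal(names(out)[1], "planted")
  expect_false(all(c("planted", "planted_copy") %in% names(out)))
  expect_false("outside" %in% names(out))
})

test_that("top_k_individual_genes ranks by p and is deterministic", {
  set.seed(14)
  m <- matrix(rnorm(20 * 16), 20, 16)
  m[7, 1:8] <- m[7, 1:8] + 10
  rownames(m) <- sprintf("g%02d", 1:20); colnames(m) <- sprintf("s%02d", 1:16)
  z <- zscore_expression(make_es2(m))
  expect_equal(top_k_individual_genes(z, 1), "g07")
  expect_equal(sort(top_k_individual_genes(z, 20)), sort(rownames(m)))
  expect_equal(top_k_individual_genes(z, 5), top_k_individual_genes(z, 5))
  expect_error(top_k_individual_genes(z, 0), "positive")
  expect_error(top_k_individual_genes(z, 21), "exceeds")
})

test_that("feature tables are summarized expressions with provenance", {
  set.seed(19)
  m <- matrix(rnorm(6 * 10), 6, 10)
  rownames(m) <- paste0("g", 1:6); colnames(m) <- paste0("s", 1:10)
  z <- zscore_expression(make_es2(m))
  ft <- build_features(z, list(one = "g1", pair = c("g1", "g2"),
                               trio = c("g1", "g2", "g3")))
  expect_equal(unname(ft$values[, "one"]), unname(z$values["g1", ]))
  expect_equal(unname(ft$values[, "trio"]),
               unname(colMeans(z$values[paste0("g", 1:3), ])))
  expect_equal(ft$provenance$feature, c("one", "pair", "trio"))
  expect_warning(build_features(z, list(a = "g1", gone = "zz")), "absent")
})

test_that("roc_auc equals brute-force pair counting and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("P", "P", "N", "N"), "P")$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 8), rep(c("P", "N"), 4), "P")$auc, 0.5)
  set.seed(27)
  for (rep in 1:20) {
    n <- sample(6:15, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    truth <- sample(c("P", "N"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    expect_equal(roc_auc(scores, truth, "P")$auc,
                 oracle_auc(scores, truth, "P"), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(61)
  scores <- rnorm(30)
  truth <- sample(c("P", "N"), 30, replace = TRUE, prob = c(0.4, 0.6))
  a0 <- roc_auc(scores, truth, "P")$auc
  expect_equal(roc_auc(exp(scores), truth, "P")$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(scores * 100 - 3, truth, "P")$auc, a0, tolerance = 1e-12)
})

test_that("roc_auc agrees with pROC on a mixed ranking", {
  set.seed(73)
  scores <- rnorm(40)
  truth <- rep(c("P", "N"), 20)
  a <- roc_auc(scores, truth, "P")$auc
  pr <- pROC::roc(response = truth, predictor = scores, levels = c("N", "P"),
                  direction = "<", quiet = TRUE)
  expect_equal(a, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("F-score identities hold at the boundaries", {
  # precision = recall = 1 => F = 1
  expect_equal(netmark:::f_score(c("P", "P", "N"), c("P", "P", "N"), "P"), 1)
  # no true positives predicted => F = 0
  expect_equal(netmark:::f_score(c("N", "N", "N"), c("P", "P", "N"), "P"), 0)
  # hand-computed mixed case: precision 2/3, recall 2/4
  f <- netmark:::f_score(c("P", "P", "P", "N", "N", "N"),
                         c("P", "P", "N", "P", "P", "N"), "P")
  expect_equal(f, 2 * (2/3) * (1/2) / (2/3 + 1/2))
})

test_that("cross-validated SVM separates a separable feature and not pure noise", {
  set.seed(30)
  n <- 200
  lab <- rep(c("A", "B"), each = 100)
  sep <- matrix(c(rnorm(100, 5, 0.1), rnorm(100, -5, 0.1)), ncol = 1,
                dimnames = list(sprintf("s%03d", 1:n), "f1"))
  ftab <- structure(list(values = sep,
                         labels = factor(lab, levels = c("A", "B")),
                         provenance = data.frame(feature = "f1", genes = "f1",
                                                 strategy = "test")),
                    class = "feature_table")
  ev <- crossval_classify(ftab, folds = 5, repeats = 2, seed = 1)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$median_f, 1.0)

  noise <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(sprintf("s%03d", 1:n), paste0("f", 1:5)))
  ftab2 <- structure(list(values = noise,
                          labels = factor(lab, levels = c("A", "B")),
                          provenance = data.frame(feature = paste0("f", 1:5),
                                                  genes = paste0("f", 1:5),
                                                  strategy = "test")),
                     class = "feature_table")
  ev2 <- crossval_classify(ftab2, folds = 5, repeats = 2, seed = 1)
  expect_gt(ev2$auc, 0.35)
  expect_lt(ev2$auc, 0.65)
})

test_that("strategies share fold partitions and report per-size results", {
  inst <- toy_instance(seed = 44, n_background = 40, n_per_class = 15,
                       delta = 1.5)
  pruned <- prune_redundant(find_subnetworks(inst$net, inst$z, search_config()))
  expect_gt(length(pruned), 0)
  cmp <- compare_strategies(inst$z, pruned, sizes = c(2, 5), repeats = 2,
                            seed = 9)
  expect_true(all(c("subnetwork", "individual") %in% cmp$summary$strategy))
  expect_equal(sort(unique(cmp$summary$size_requested)), c(2, 5))
  # a strategy with fewer features than requested runs at its maximum
  expect_true(all(cmp$summary$size_used <= cmp$summary$size_requested))
  # identical seed => identical folds => reproducible results
  cmp2 <- compare_strategies(inst$z, pruned, sizes = c(2, 5), repeats = 2,
                             seed = 9)
  expect_equal(cmp$summary, cmp2$summary)
})

test_that("hypergeometric enrichment matches the closed form and BH", {
  bg <- paste0("g", 1:20)
  ann <- list(target = paste0("g", 1:5), other = paste0("g", 10:12))
  res <- enrich_gene_sets(paste0("g", 1:5), ann, bg)
  # closed form: query of 5 hits all 5 of the target set in a 20-gene universe
  p_hand <- dhyper(5, 5, 15, 5)
  expect_equal(res$p[res$set == "target"], p_hand, tolerance = 1e-12)
  expect_equal(res$p[res$set == "other"], 1)  # overlap 0 => P[X >= 0] = 1
  expect_equal(res$fdr, p.adjust(res$p, "BH")[order(res$p)])
  expect_error(enrich_gene_sets("g1", ann, character(0)), "empty")
  expect_error(enrich_gene_sets("zz", ann, bg), "subset")
  # BH on [0.01, 0.02, 0.03] -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})
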