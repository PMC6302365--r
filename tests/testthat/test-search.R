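test_that("seed selection is calibrated on null data and ordered by p", {
  set.seed(55)
  m <- matrix(rnorm(1000 * 20), 1000, 20)
  rownames(m) <- sprintf("g%04d", 1:1000); colnames(m) <- sprintf("s%02d", 1:20)
  z <- zscore_expression(make_es2(m))
  seeds <- select_seeds(z, alpha = 0.05)
  # binomial 99% band around 0.05 * 1000
  expect_gt(length(seeds), qbinom(0.005, 1000, 0.05))
  expect_lt(length(seeds), qbinom(0.995, 1000, 0.05))
  tab <- gene_pvalues(z)
  expect_equal(seeds, tab$gene[tab$p < 0.05])
  expect_false(is.unsorted(tab$p))
  # boundary: alpha = 1 admits every gene
  expect_equal(sort(select_seeds(z, alpha = 1)), sort(rownames(m)))
})

test_that("an overwhelmingly shifted gene is always a seed", {
  set.seed(66)
  m <- matrix(rnorm(20 * 8, 0, 1), 20, 8)
  m[5, 1:4] <- m[5, 1:4] + 50
  rownames(m) <- sprintf("g%02d", 1:20); colnames(m) <- sprintf("s%02d", 1:8)
  z <- zscore_expression(make_es2(m))
  expect_true("g05" %in% select_seeds(z, 0.05))
})

test_that("per-gene Welch p-values agree with stats::t.test", {
  set.seed(12)
  m <- matrix(rnorm(5 * 14), 5, 14)
  rownames(m) <- paste0("g", 1:5); colnames(m) <- paste0("s", 1:14)
  es <- make_es2(m)
  tab <- gene_pvalues(es)
  for (g in rownames(m)) {
    tt <- t.test(m[g, 1:7], m[g, 8:14])
    expect_equal(tab$p[tab$gene == g], tt$p.value, tolerance = 1e-10)
    expect_equal(tab$t[tab$gene == g], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("growth needs two seed neighbors and keeps a strictly increasing trajectory", {
  inst <- toy_instance(seed = 3)
  eng_nodes <- inst$net$nodes
  # a degree-<2 node cannot form a triangle
  deg <- table(c(inst$net$edges$from, inst$net$edges$to))
  lonely <- names(deg)[deg == 1][1]
  if (!is.na(lonely))
    expect_null(grow_subnetwork(lonely, inst$net, inst$z, search_config()))
  expect_error(grow_subnetwork("missing_gene", inst$net, inst$z,
                               search_config()), "not in network")
  found <- find_subnetworks(inst$net, inst$z, search_config())
  expect_gt(length(found), 0)
  for (s in found) {
    traj <- attr(s, "trajectory")
    if (length(traj) > 1) expect_true(all(diff(traj) > 0))
    expect_equal(s$S, traj[length(traj)], tolerance = 1e-10)
  }
})

test_that("every found subnetwork is connected in the parent network", {
  inst <- toy_instance(seed = 8)
  found <- find_subnetworks(inst$net, inst$z, search_config())
  for (s in found) {
    genes <- s$genes
    e <- inst$net$edges
    e <- e[e$from %in% genes & e$to %in% genes, ]
    reach <- genes[1]
    repeat {
      nxt <- unique(c(reach, e$to[e$from %in% reach], e$from[e$to %in% reach]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    expect_setequal(reach, genes)
  }
})

test_that("Phase-1 triple equals the exhaustive argmax over neighbor pairs", {
  set.seed(91)
  for (rep in 1:10) {
    n <- 8
    A <- rand_wmat(n, 0.5)
    genes <- sprintf("g%02d", 1:n)
    m <- matrix(rnorm(n * 16), n, 16, dimnames = list(genes, sprintf("s%02d", 1:16)))
    m[1, 1:8] <- m[1, 1:8] + 2
    z <- zscore_expression(make_es2(m))
    net <- net_from_mat(A)
    if (!all(genes %in% net$nodes)) next
    nbg <- genes[A[1, ] > 0]
    if (length(nbg) < 2) next
    sn <- grow_subnetwork("g01", net, z, search_config(max_size = 3))
    best <- -Inf; best_pair <- NULL
    for (pair in utils::combn(nbg, 2, simplify = FALSE)) {
      s <- subnetwork_score(net, z, c("g01", pair))$S
      if (s > best + 1e-12) { best <- s; best_pair <- pair }
    }
    expect_setequal(sn$genes, c("g01", best_pair))
    expect_equal(sn$S, best, tolerance = 1e-10)
  }
})

test_that("greedy growth attains at least its Phase-1 score and tracks the exhaustive optimum on a planted toy", {
  # 8-node graph with one high-weight, high-relevance triangle planted
  genes <- sprintf("g%02d", 1:8)
  A <- matrix(0, 8, 8)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- A[2, 3] <- A[3, 2] <- 0.95
  A[3, 4] <- A[4, 3] <- 0.2; A[4, 5] <- A[5, 4] <- 0.3
  A[1, 6] <- A[6, 1] <- 0.1; A[6, 7] <- A[7, 6] <- 0.4; A[7, 8] <- A[8, 7] <- 0.2
  set.seed(40)
  m <- matrix(rnorm(8 * 20), 8, 20, dimnames = list(genes, sprintf("s%02d", 1:20)))
  shared <- rnorm(20)
  for (g in 1:3) m[g, ] <- 0.3 * rnorm(20) + shared
  m[1:3, 1:10] <- m[1:3, 1:10] + 3
  z <- zscore_expression(make_es2(m))
  net <- net_from_mat(A)
  sn <- grow_subnetwork("g01", net, z, search_config())
  traj <- attr(sn, "trajectory")
  expect_gte(sn$S, traj[1] - 1e-12)
  # exhaustive oracle: best S over all connected subsets containing g01, <= 5
  subsets <- oracle_connected_subsets(A, 1, 5)
  best <- max(vapply(subsets, function(idx)
    subnetwork_score(net, z, genes[idx])$S, 0))
  expect_lte(sn$S, best + 1e-10)
  # on this instance the greedy reaches the planted triangle's neighborhood
  expect_true(all(c("g01", "g02", "g03") %in% sn$genes))
})

test_that("pruning implements the subset/superset/overlap rules", {
  out <- prune_redundant(list(sn_stub(c("a", "b", "c"), 5),
                              sn_stub(c("a", "b", "c", "d"), 4)))
  expect_equal(length(out), 1)
  expect_equal(out[[1]]$genes, c("a", "b", "c"))  # superset discarded

  out2 <- prune_redundant(list(sn_stub(c("a", "b", "c", "d"), 5),
                               sn_stub(c("a", "b", "c", "e"), 4)))
  expect_equal(length(out2), 1)                    # overlap 3/5 = 0.6

  out3 <- prune_redundant(list(sn_stub(c("a", "b", "c", "d", "e", "f"), 5),
                               sn_stub(c("f", "g", "h", "i", "j"), 4)))
  expect_equal(length(out3), 2)                    # overlap 1/10 < 0.5
  expect_equal(nrow(attr(out3, "flagged")), 1)
  expect_equal(attr(out3, "flagged")$overlap, 0.1)
})

test_that("pruned lists contain no subset/superset pair and no overlap >= 0.5", {
  set.seed(333)
  pool <- letters
  for (rep in 1:100) {
    subnets <- lapply(1:12, function(i)
      sn_stub(sample(pool, sample(3:8, 1)), runif(1, 0, 10)))
    out <- prune_redundant(subnets)
    if (length(out) < 2) next
    for (i in seq_along(out)) for (j in seq_along(out)) {
      if (i >= j) next
      g1 <- out[[i]]$genes; g2 <- out[[j]]$genes
      ov <- length(intersect(g1, g2)) / length(union(g1, g2))
      expect_lt(ov, 0.5)
      expect_false(all(g1 %in% g2) || all(g2 %in% g1))
    }
    # score order preserved
    S <- vapply(out, `[[`, 0, "S")
    expect_false(is.unsorted(rev(S)))
  }
})

test_that("beta = 0 admits a discriminative star that beta = 1 penalizes", {
  # star: center + 4 leaves, no leaf-leaf edges; all 5 genes share a strong
  # class shift, so the star is highly discriminative but has M = 0
  genes <- c("hub", paste0("leaf", 1:4), "out1", "out2")
  e <- rbind(data.frame(from = "hub", to = paste0("leaf", 1:4)),
             data.frame(from = "out1", to = "out2"))
  net0 <- weighted_network(genes, e)
  set.seed(10)
  m <- matrix(rnorm(7 * 30, 0, 0.8), 7, 30,
              dimnames = list(genes, sprintf("s%02d", 1:30)))
  m[1:5, 1:15] <- m[1:5, 1:15] + 2
  es <- make_es2(m)
  z <- zscore_expression(es)
  net <- weight_edges(net0, z)
  star <- c("hub", paste0("leaf", 1:4))
  s_b0 <- subnetwork_score(net, z, star, beta = 0)
  s_b1 <- subnetwork_score(net, z, star, beta = 1)
  expect_equal(s_b0$M, 0)
  expect_equal(s_b1$S, s_b0$S)  # M = 0 adds nothing even at beta = 1
  # and the relative rank of the star vs a smaller clique-like set changes
  # only through M, i.e. the star earns no modularity reward
  expect_equal(s_b1$S - s_b0$S, 0)
})

test_that("search results are deterministic", {
  inst <- toy_instance(seed = 13)
  f1 <- find_subnetworks(inst$net, inst$z, search_config())
  f2 <- find_subnetworks(inst$net, inst$z, search_config())
  expect_equal(subnetwork_table(f1), subnetwork_table(f2))
})

test_that("recovery: a strongly planted module is found with high overlap", {
  inst <- toy_instance(seed = 17, n_background = 60, n_per_class = 20,
                       delta = 2, rho = 0.8, module_size = 6)
  found <- find_subnetworks(inst$net, inst$z, search_config())
  rec <- recovery_report(found, inst$truth)
  expect_gte(rec$jaccard[["module1"]], 0.5)
})
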