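# Independent brute-force oracles, deliberately naive: explicit loops over the
# printed formulas, no code shared with the package internals.

# weighted clustering coefficient of node i by explicit double sum over
# ordered neighbor pairs (l, m)
oracle_clust <- function(A, i) {
  k <- nrow(A)
  num <- 0
  for (l in seq_len(k)) for (m in seq_len(k))
    if (l != i && m != i && m != l)
      num <- num + A[i, l] * A[l, m] * A[m, i]
  s1 <- 0; s2 <- 0
  for (l in seq_len(k)) if (l != i) { s1 <- s1 + A[i, l]; s2 <- s2 + A[i, l]^2 }
  den <- s1^2 - s2
  if (den <= 0) 0 else num / den
}

oracle_modularity <- function(A) {
  if (nrow(A) < 3) return(0)
  mean(vapply(seq_len(nrow(A)), function(i) oracle_clust(A, i), 0))
}

# random symmetric weight matrix with zero diagonal
rand_wmat <- function(n, p_edge = 0.6) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p_edge) A[i, j] <- A[j, i] <- stats::runif(1)
  A
}

# weighted_network from a symmetric weight matrix
net_from_mat <- function(A, genes = sprintf("g%02d", seq_len(nrow(A)))) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  weighted_network(genes, data.frame(from = genes[idx[, 1]],
                                     to = genes[idx[, 2]],
                                     weight = A[idx],
                                     stringsAsFactors = FALSE))
}

# two-class expression set: first half of columns class 1
make_es2 <- function(m, classes = c("caseA", "caseB")) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  half <- ncol(m) %/% 2
  expression_set(m, rep(classes, c(half, ncol(m) - half)))
}

# AUC by exhaustive pair counting, ties half-concordant
oracle_auc <- function(scores, truth, positive) {
  pos <- which(truth == positive); neg <- which(truth != positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# empirical CDF KS distance against a normal with estimated parameters
oracle_ks_stat <- function(x) {
  x <- sort(x); n <- length(x)
  F0 <- stats::pnorm(x, mean(x), stats::sd(x))
  max(pmax(abs(seq_len(n) / n - F0), abs((seq_len(n) - 1) / n - F0)))
}

# all connected subsets of a small graph containing `seed`, sizes 3..max_size
oracle_connected_subsets <- function(A, seed, max_size) {
  n <- nrow(A)
  others <- setdiff(seq_len(n), seed)
  out <- list()
  for (k in 2:(max_size - 1)) {
    for (comb in utils::combn(others, k, simplify = FALSE)) {
      genes <- c(seed, comb)
      sub <- A[genes, genes] > 0
      # connectivity by reachability
      reach <- c(1, rep(0, k))
      repeat {
        new <- reach
        for (i in which(reach == 1)) new[sub[i, ]] <- 1
        if (all(new == reach)) break
        reach <- new
      }
      if (all(reach == 1)) out[[length(out) + 1L]] <- genes
    }
  }
  out
}

# quick subnetwork stub for pruning tests
sn_stub <- function(genes, S) {
  structure(list(genes = sort(genes), n = length(genes), M = 0, R = S, S = S,
                 beta = 1, p = NA_real_, edges = NULL), class = "subnetwork")
}

# small planted-module instance shared across search/significance tests
toy_instance <- function(seed = 1, n_background = 60, n_per_class = 20,
                         delta = 2, rho = 0.7, n_modules = 1,
                         module_size = 5) {
  truth <- planted_truth(n_modules = n_modules, module_size = module_size,
                         n_background = n_background, delta = delta,
                         rho = rho, n_per_class = n_per_class)
  net <- generate_network(truth, seed = seed)
  extra <- setdiff(net$nodes, c(unlist(truth$modules), truth$background))
  expr <- generate_expression(truth, extra_genes = extra, seed = seed + 1000)
  z <- zscore_expression(expr)
  list(truth = truth, net = weight_edges(net, z), z = z)
}
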