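#' Search configuration
#'
#' Bundles the tunables of the greedy subnetwork search.
#'
#' @param seed_alpha per-gene differential-expression p-value cutoff used to
#'   pick seed genes, in (0, 1].
#' @param beta non-negative modularity weight in the score (default 1).
#' @param max_size optional cap on subnetwork size (>= 3 when finite); the
#'   default is unlimited — growth stops when the score stops improving.
#' @param var_equal pooled-variance t instead of Welch.
#' @return An object of class `search_config`.
#' @export
search_config <- function(seed_alpha = 0.05, beta = 1, max_size = Inf,
                          var_equal = FALSE) {
  stopifnot(seed_alpha > 0, seed_alpha <= 1, beta >= 0,
            is.infinite(max_size) || max_size >= 3)
  structure(list(seed_alpha = seed_alpha, beta = beta, max_size = max_size,
                 var_equal = var_equal), class = "search_config")
}

# vectorized per-gene Welch t and p for every row of a matrix
row_welch_p <- function(V, i1, i2, var_equal = FALSE) {
  n1 <- length(i1); n2 <- length(i2)
  V1 <- V[, i1, drop = FALSE]; V2 <- V[, i2, drop = FALSE]
  m1 <- rowMeans(V1); m2 <- rowMeans(V2)
  v1 <- rowSums((V1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((V2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    den2 <- sp * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    a <- v1 / n1; b <- v2 / n2
    den2 <- a + b
    df <- den2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (m1 - m2) / sqrt(den2)
  t[den2 == 0 & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[den2 == 0 & m1 == m2] <- 1
  p[is.infinite(t)] <- 0
  data.frame(t = t, p = p)
}

#' Per-gene differential expression table
#'
#' Welch t-test of every gene row between the two classes, the statistic the
#' seed selection and the individual-gene baseline both rank by.
#'
#' @param z an [expression_set()] (typically z-scored).
#' @param var_equal pooled-variance t instead of Welch.
#' @return data.frame with columns `gene`, `t`, `p`, ordered by ascending `p`
#'   (ties broken by gene id).
#' @export
gene_pvalues <- function(z, var_equal = FALSE) {
  stopifnot(inherits(z, "expr_set"))
  ci <- class_index(z)
  tp <- row_welch_p(z$values, ci[[1]], ci[[2]], var_equal = var_equal)
  out <- data.frame(gene = rownames(z$values), t = tp$t, p = tp$p,
                    stringsAsFactors = FALSE)
  out[order(out$p, out$gene), , drop = FALSE]
}

#' Select seed genes
#'
#' Individually differentially expressed genes (per-gene two-sample t-test
#' p-value < `alpha`) form the seeds from which subnetworks are grown,
#' ordered by ascending p-value.
#'
#' @inheritParams gene_pvalues
#' @param alpha p-value cutoff in (0, 1].
#' @return Character vector of seed gene ids (possibly empty, with a warning).
#' @export
select_seeds <- function(z, alpha = 0.05, var_equal = FALSE) {
  stopifnot(alpha > 0, alpha <= 1)
  tab <- gene_pvalues(z, var_equal = var_equal)
  seeds <- tab$gene[tab$p < alpha]
  if (!length(seeds)) warning("no differentially expressed seed genes found")
  seeds
}

# ---- greedy growth on the internal engine -----------------------------------
# Phase 1: among all unordered pairs {u, v} of network neighbors of the seed,
# take the triple maximizing S (the u-v edge need not exist; its absence just
# contributes weight 0 to M). Phase 2: repeatedly add the single adjacent node
# that most increases S, stopping when no strict improvement remains.
# Ties break to the lexicographically smallest gene (node indices follow
# sorted gene ids, and which.max takes the first maximum).
grow_engine <- function(eng, s, beta, max_size = Inf, var_equal = FALSE) {
  nb <- eng$nbr[[s]]
  if (length(nb) < 2) return(NULL)
  ns <- ncol(eng$z)
  pr <- utils::combn(nb, 2)  # columns in lexicographic (u, v) order
  u <- pr[1, ]; v <- pr[2, ]
  a <- eng$W[cbind(s, u)]; b <- eng$W[cbind(s, v)]; cc <- eng$W[cbind(u, v)]
  # closed-form modularity of the induced triple (verified against Eq. 2/3
  # kernels in the tests): each member's C is the opposite edge weight when
  # its own two incident weights are positive, else 0
  M3 <- (ifelse(a * b > 0, cc, 0) + ifelse(a * cc > 0, b, 0) +
           ifelse(b * cc > 0, a, 0)) / 3
  zs <- eng$z[s, ]
  V3 <- (matrix(zs, length(u), ns, byrow = TRUE) +
           eng$z[u, , drop = FALSE] + eng$z[v, , drop = FALSE]) / 3
  R3 <- row_welch_t(V3, eng$i1, eng$i2, var_equal = var_equal)
  S3 <- beta * M3 + abs(R3)
  best <- which.max(S3)
  cur <- c(s, u[best], v[best])
  Scur <- S3[best]
  traj <- Scur
  rsum <- colSums(eng$z[cur, , drop = FALSE])
  # incremental clustering-coefficient state on the induced subgraph:
  # A (k x k), per-node triangle numerator num_i = diag(A^3)_i, strength
  # s1_i = sum_l w_il and s2_i = sum_l w_il^2. Appending node w with incident
  # weight vector a updates num_i' = num_i + 2 a_i (A a)_i, s1' = s1 + a,
  # s2' = s2 + a^2, and num_w = a'Aa — no per-candidate cubic recomputation.
  A <- as.matrix(eng$W[cur, cur])
  num <- diag(A %*% A %*% A)
  s1 <- rowSums(A); s2 <- rowSums(A * A)
  repeat {
    if (length(cur) >= max_size) break
    cand <- setdiff(sort(unique(unlist(eng$nbr[cur]))), cur)
    if (!length(cand)) break
    k <- length(cur)
    Wc <- as.matrix(eng$W[cur, cand, drop = FALSE])     # k x C
    P <- A %*% Wc                                       # (A a) per candidate
    num2 <- num + 2 * Wc * P
    s1c <- s1 + Wc
    s2c <- s2 + Wc * Wc
    den2 <- s1c * s1c - s2c
    Cmat <- ifelse(den2 > 0, num2 / den2, 0)
    numw <- colSums(Wc * P)
    s1w <- colSums(Wc); s2w <- colSums(Wc * Wc)
    denw <- s1w * s1w - s2w
    Cw <- ifelse(denw > 0, numw / denw, 0)
    Mc <- (colSums(Cmat) + Cw) / (k + 1)
    Vc <- (matrix(rsum, length(cand), ns, byrow = TRUE) +
             eng$z[cand, , drop = FALSE]) / (k + 1)
    Rc <- row_welch_t(Vc, eng$i1, eng$i2, var_equal = var_equal)
    Sc <- beta * Mc + abs(Rc)
    j <- which.max(Sc)
    if (!(Sc[j] > Scur)) break
    w <- cand[j]
    aj <- Wc[, j]
    A <- rbind(cbind(A, aj, deparse.level = 0), c(aj, 0))
    num <- c(num2[, j], numw[j])
    s1 <- c(s1c[, j], s1w[j])
    s2 <- c(s2c[, j], s2w[j])
    cur <- c(cur, w)
    rsum <- rsum + eng$z[w, ]
    Scur <- Sc[j]
    traj <- c(traj, Scur)
  }
  list(members = cur, S = Scur, trajectory = traj)
}

#' Grow a subnetwork from a seed gene
#'
#' Two-phase greedy growth. Phase 1 enumerates all unordered pairs of the
#' seed's network neighbors and adds the pair whose triple scores highest,
#' forming an initial triangular subnetwork (the pair is added even when the
#' triple scores below the bare seed — improvement gating starts afterwards).
#' Phase 2 repeatedly evaluates every single node adjacent to the current
#' members and adds the best one only while it strictly increases S. Seeds
#' with fewer than two network neighbors cannot form a triangle and yield
#' `NULL`.
#'
#' @param seed gene id present in the network.
#' @param net a [weighted_network()] with co-expression weights.
#' @param z a z-scored [expression_set()].
#' @param cfg a [search_config()].
#' @return A `subnetwork` (see [subnetwork_score()]) with attribute
#'   `"trajectory"` (the S value after each accepted addition), or `NULL`.
#' @export
grow_subnetwork <- function(seed, net, z, cfg = search_config()) {
  stopifnot(inherits(net, "weighted_network"), inherits(z, "expr_set"),
            inherits(cfg, "search_config"))
  eng <- network_engine(net, z)
  if (!seed %in% eng$nodes) stop("seed '", seed, "' not in network")
  res <- grow_engine(eng, unname(eng$idx[seed]), cfg$beta, cfg$max_size,
                     cfg$var_equal)
  if (is.null(res)) return(NULL)
  sn <- subnetwork_score(net, z, eng$nodes[res$members], beta = cfg$beta,
                         var_equal = cfg$var_equal)
  attr(sn, "trajectory") <- res$trajectory
  sn
}

# deterministic ordering of a list of subnetworks: descending S, then genes
order_subnetworks <- function(subnets) {
  if (!length(subnets)) return(subnets)
  key <- vapply(subnets, function(s) paste(s$genes, collapse = ";"), "")
  S <- vapply(subnets, `[[`, 0, "S")
  subnets[order(-S, key)]
}

#' Find candidate subnetworks
#'
#' Runs [grow_subnetwork()] from every seed gene (ascending differential
#' expression p-value), drops seeds that cannot form a triangle, and returns
#' the candidates sorted by descending score. Overlapping results from seeds
#' inside the same module are expected; [prune_redundant()] resolves them.
#'
#' @inheritParams grow_subnetwork
#' @return List of `subnetwork` objects, sorted by descending S.
#' @export
find_subnetworks <- function(net, z, cfg = search_config()) {
  stopifnot(inherits(net, "weighted_network"), inherits(z, "expr_set"),
            inherits(cfg, "search_config"))
  eng <- network_engine(net, z)
  zi <- expression_set(eng$z, z$labels)
  seeds <- suppressWarnings(
    select_seeds(zi, alpha = cfg$seed_alpha, var_equal = cfg$var_equal))
  seeds <- seeds[seeds %in% eng$nodes]
  out <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    res <- grow_engine(eng, unname(eng$idx[seeds[k]]), cfg$beta,
                       cfg$max_size, cfg$var_equal)
    if (is.null(res)) next
    sn <- subnetwork_score(net, z, eng$nodes[res$members], beta = cfg$beta,
                           var_equal = cfg$var_equal)
    attr(sn, "trajectory") <- res$trajectory
    attr(sn, "seed") <- seeds[k]
    out[[k]] <- sn
  }
  order_subnetworks(Filter(Negate(is.null), out))
}

#' Remove redundant subnetworks
#'
#' Iterates over candidates in descending score order, keeping a retained set.
#' A candidate is discarded against any retained subnetwork when it is (a) a
#' subset of it, (b) a superset of it, or (c) overlaps it by at least
#' `overlap_threshold`, where overlap = |intersection| / |union| of the two
#' gene sets. Pairs with overlap strictly between 0 and the threshold are kept
#' but flagged for manual inspection.
#'
#' As printed, the superset rule discards "the super set"; under strict
#' descending-score iteration the superset encountered later is always the
#' lower-scoring item, so rules (a) and (b) coincide with "discard the
#' later-seen relative" — which is what this implementation does.
#'
#' @param subnets list of `subnetwork` objects.
#' @param overlap_threshold Jaccard overlap at or above which the
#'   lower-scoring subnetwork is discarded (default 0.5).
#' @return The retained list (descending score), with attribute `"flagged"`:
#'   a data.frame of kept-but-overlapping pairs (indices into the returned
#'   list, gene strings, and their overlap).
#' @export
prune_redundant <- function(subnets, overlap_threshold = 0.5) {
  subnets <- order_subnetworks(subnets)
  kept <- list()
  flagged <- list()
  for (cand in subnets) {
    drop <- FALSE
    for (ki in seq_along(kept)) {
      g1 <- kept[[ki]]$genes; g2 <- cand$genes
      inter <- length(intersect(g1, g2))
      if (inter == 0) next
      uni <- length(union(g1, g2))
      ov <- inter / uni
      if (all(g2 %in% g1) || all(g1 %in% g2) || ov >= overlap_threshold) {
        drop <- TRUE
        break
      }
      flagged[[length(flagged) + 1L]] <- data.frame(
        kept = ki, kept_genes = paste(g1, collapse = ";"),
        candidate_genes = paste(g2, collapse = ";"), overlap = ov,
        stringsAsFactors = FALSE)
    }
    if (!drop) kept[[length(kept) + 1L]] <- cand
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(kept = integer(0), kept_genes = character(0),
               candidate_genes = character(0), overlap = numeric(0))
  attr(kept, "flagged") <- flagged
  kept
}

#' Subnetwork list as a table
#'
#' @param subnets list of `subnetwork` objects.
#' @return data.frame with columns `subnetwork_id`, `genes` (semicolon-joined),
#'   `n`, `M`, `R_signed`, `S`, `p_empirical`.
#' @export
subnetwork_table <- function(subnets) {
  data.frame(
    subnetwork_id = seq_along(subnets),
    genes = vapply(subnets, function(s) paste(s$genes, collapse = ";"), ""),
    n = vapply(subnets, `[[`, 0L, "n"),
    M = vapply(subnets, `[[`, 0, "M"),
    R_signed = vapply(subnets, `[[`, 0, "R"),
    S = vapply(subnets, `[[`, 0, "S"),
    p_empirical = vapply(subnets, `[[`, 0, "p"),
    stringsAsFactors = FALSE
  )
}
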