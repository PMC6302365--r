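#' Subnetwork score components
#'
#' The score of a candidate gene set K on a co-expression-weighted interaction
#' network combines two ingredients:
#' \deqn{S = \beta M + |R|}
#' where M is the modularity of K — the mean weighted clustering coefficient of
#' its members on the subgraph induced by K — and R is the class relevance —
#' the two-sample t statistic comparing the per-sample mean z-score of K's
#' members (the summarized expression) between the two classes. \eqn{\beta}
#' trades connectivity against discriminative power; \eqn{\beta = 1} weighs
#' them equally and \eqn{\beta = 0} ignores topology entirely (the
#' "no-modularity" baseline, which tends to admit star-shaped sets).
#'
#' R enters the score by magnitude: a set strongly down-regulated in the first
#' class discriminates as well as one strongly up-regulated. The signed t value
#' is kept as metadata on the returned object.
#'
#' @name subnetwork-scoring
NULL

# ---- dense-matrix kernels ---------------------------------------------------
# A: induced symmetric weight matrix, zero diagonal, weights in [0,1].
# C_i = sum_{l!=i} sum_{m!=i,m!=l} w_il w_lm w_mi / ((sum_l w_il)^2 - sum_l w_il^2)
# The double sum over ordered (l, m) equals diag(A^3)_i exactly (the zero
# diagonal removes l = i, m = i and l = m terms). Denominator zero => C_i = 0.
clust_coef_mat <- function(A) {
  num <- diag(A %*% A %*% A)
  s1 <- rowSums(A)
  den <- s1 * s1 - rowSums(A * A)
  ifelse(den > 0, num / den, 0)
}

modularity_mat <- function(A) {
  if (nrow(A) < 3) return(0)
  mean(clust_coef_mat(A))
}

# Welch (or pooled) two-sample t on a single vector split by index sets
two_sample_t <- function(v, i1, i2, var_equal = FALSE) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- mean(v[i1]); m2 <- mean(v[i2])
  v1 <- stats::var(v[i1]); v2 <- stats::var(v[i2])
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    den <- sqrt(sp * (1 / n1 + 1 / n2))
  } else {
    den <- sqrt(v1 / n1 + v2 / n2)
  }
  if (den == 0) {
    if (m1 == m2) {
      warning("zero variance in both classes with equal means; t set to 0")
      return(0)
    }
    return(sign(m1 - m2) * Inf)
  }
  (m1 - m2) / den
}

# Row-wise Welch t for a matrix V (rows = candidates, cols = samples).
# Degenerate rows (zero within-class variance in both classes, equal means)
# get t = 0 without warning; unequal means give +/-Inf.
row_welch_t <- function(V, i1, i2, var_equal = FALSE) {
  n1 <- length(i1); n2 <- length(i2)
  V1 <- V[, i1, drop = FALSE]; V2 <- V[, i2, drop = FALSE]
  m1 <- rowMeans(V1); m2 <- rowMeans(V2)
  v1 <- rowSums((V1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((V2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    den <- sqrt(sp * (1 / n1 + 1 / n2))
  } else {
    den <- sqrt(v1 / n1 + v2 / n2)
  }
  t <- (m1 - m2) / den
  t[den == 0 & m1 == m2] <- 0
  unname(t)
}

# induced weight matrix over genes from a weighted_network (absent edges = 0)
induced_matrix <- function(net, genes) {
  genes <- as.character(genes)
  k <- length(genes)
  A <- matrix(0, k, k, dimnames = list(genes, genes))
  e <- net$edges
  keep <- e$from %in% genes & e$to %in% genes
  e <- e[keep, , drop = FALSE]
  if (nrow(e)) {
    A[cbind(e$from, e$to)] <- e$weight
    A[cbind(e$to, e$from)] <- e$weight
  }
  A
}

#' Weighted clustering coefficient of a node within a gene set
#'
#' Ratio of the weighted triangles through node `node` to the weighted
#' possible triangles extending off it, evaluated on the subgraph induced by
#' `genes` (pairs of `genes` without an edge contribute weight 0):
#' \deqn{C_i = \frac{\sum_{l \ne i}\sum_{m \ne i, m \ne l} w_{il} w_{lm} w_{mi}}
#'            {(\sum_{l \ne i} w_{il})^2 - \sum_{l \ne i} w_{il}^2}}
#' For weights in [0, 1], \eqn{C_i \in [0, 1]}, and \eqn{C_i = 1} iff every
#' pair of i's neighbors is connected with weight 1. A node with fewer than
#' two weighted neighbors in the set has a zero denominator and gets
#' \eqn{C_i = 0}.
#'
#' @param net a [weighted_network()].
#' @param node gene id, must be a member of `genes`.
#' @param genes character vector of gene ids defining the subnetwork.
#' @return The clustering coefficient, a number in [0, 1].
#' @export
clustering_coefficient <- function(net, node, genes) {
  stopifnot(inherits(net, "weighted_network"))
  genes <- as.character(genes)
  if (!node %in% genes) stop("node '", node, "' is not in the gene set")
  A <- induced_matrix(net, genes)
  unname(clust_coef_mat(A)[match(node, genes)])
}

#' Modularity of a gene set
#'
#' Mean clustering coefficient of the member genes, computed on the subgraph
#' induced by `genes`; defined as 0 for sets of fewer than 3 genes (no
#' triangle is possible).
#'
#' @inheritParams clustering_coefficient
#' @param full_network if `TRUE`, clustering coefficients are evaluated on
#'   each member's full-network neighborhood instead of the induced subgraph.
#'   The induced-subgraph default measures the internal cohesion the score is
#'   meant to reward.
#' @return Modularity M in [0, 1].
#' @export
modularity <- function(net, genes, full_network = FALSE) {
  stopifnot(inherits(net, "weighted_network"))
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene set")
  if (!all(genes %in% net$nodes))
    stop("gene(s) not in network: ",
         paste(setdiff(genes, net$nodes), collapse = ", "))
  if (length(genes) < 3) return(0)
  if (!full_network) return(modularity_mat(induced_matrix(net, genes)))
  mean(vapply(genes, function(g) {
    nb <- unique(c(g, net$edges$from[net$edges$to == g],
                   net$edges$to[net$edges$from == g]))
    clustering_coefficient(net, g, nb)
  }, 0))
}

#' Summarized expression of a gene set
#'
#' Per-sample unweighted mean of the member genes' z-scores,
#' \eqn{V_{Kj} = \sum_{i \in K} z_{ij} / n}. This is both the quantity the
#' class-relevance t-test compares and the classification feature value.
#'
#' @param z a z-scored [expression_set()] (see [zscore_expression()]).
#' @param genes character vector of member genes, all present in `z`.
#' @return Named numeric vector over samples.
#' @export
summarize_expression <- function(z, genes) {
  stopifnot(inherits(z, "expr_set"))
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(z$values))
  if (length(missing))
    stop("gene(s) missing from matrix: ", paste(missing, collapse = ", "))
  colMeans(z$values[genes, , drop = FALSE])
}

#' Class relevance of a gene set
#'
#' Two-sample t statistic (Welch by default) comparing the summarized
#' expression of `genes` between the two classes. The sign follows
#' first-class minus second-class means.
#'
#' @inheritParams summarize_expression
#' @param var_equal use the pooled-variance t instead of Welch.
#' @return The signed t statistic.
#' @export
class_relevance <- function(z, genes, var_equal = FALSE) {
  stopifnot(inherits(z, "expr_set"))
  ci <- class_index(z)
  if (any(lengths(ci) < 2)) stop("each class needs >= 2 samples")
  v <- summarize_expression(z, genes)
  two_sample_t(v, ci[[1]], ci[[2]], var_equal = var_equal)
}

#' Score a subnetwork
#'
#' Computes M, R and the combined score \eqn{S = \beta M + |R|} for a gene
#' set, returning a `subnetwork` object carrying the components, the signed
#' t value and the induced edges.
#'
#' @inheritParams modularity
#' @param z a z-scored [expression_set()].
#' @param beta non-negative modularity weight (default 1; 0 gives the
#'   no-modularity baseline).
#' @param var_equal passed to [class_relevance()].
#' @return An object of class `subnetwork`: list with `genes`, `n`, `M`,
#'   `R` (signed), `S`, `beta`, `p` (NA until [select_significant()]) and
#'   `edges` (induced edge data.frame).
#' @export
subnetwork_score <- function(net, z, genes, beta = 1, var_equal = FALSE) {
  stopifnot(beta >= 0)
  genes <- sort(as.character(genes))
  if (!length(genes)) stop("empty gene set")
  M <- modularity(net, genes)
  R <- class_relevance(z, genes, var_equal = var_equal)
  e <- net$edges
  e <- e[e$from %in% genes & e$to %in% genes, , drop = FALSE]
  structure(list(genes = genes, n = length(genes), M = M, R = R,
                 S = beta * M + abs(R), beta = beta, p = NA_real_,
                 edges = e),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("subnetwork of", x$n, "genes:",
      paste(utils::head(x$genes, 8), collapse = ", "),
      if (x$n > 8) "...\n" else "\n")
  cat(sprintf("M = %.4f, R = %.4f, S = %.4f (beta = %g)", x$M, x$R, x$S, x$beta))
  if (!is.na(x$p)) cat(sprintf(", p = %.4g", x$p))
  cat("\n")
  invisible(x)
}
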