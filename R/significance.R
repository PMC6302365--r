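#' Permute expression rows over gene identifiers
#'
#' Randomly reassigns whole expression vectors to gene identifiers: every gene
#' keeps some real expression row, but network neighbors end up with unrelated
#' vectors. This dissociates the interaction topology from the expression
#' signal while preserving each row's distribution and the sample labels — the
#' null the subnetwork scores are judged against. (Sample-label permutation,
#' which instead breaks the class signal, is available via
#' `unit = "labels"`.)
#'
#' @param z an [expression_set()].
#' @param unit `"genes"` (row reassignment, the default null) or `"labels"`.
#' @return A permuted [expression_set()]. Uses the current RNG state; seed
#'   with [set.seed()] for reproducibility.
#' @export
permute_expression <- function(z, unit = c("genes", "labels")) {
  stopifnot(inherits(z, "expr_set"))
  unit <- match.arg(unit)
  if (unit == "genes") {
    perm <- sample(nrow(z$values))
    v <- z$values[perm, , drop = FALSE]
    rownames(v) <- rownames(z$values)
    expression_set(v, z$labels)
  } else {
    perm <- sample(ncol(z$values))
    lab <- z$labels
    labp <- stats::setNames(lab[perm], names(lab))
    expression_set(z$values, labp)
  }
}

#' Build the permutation null distribution of subnetwork scores
#'
#' For each of `n_perm` permutations: reassign expression rows to genes,
#' recompute the co-expression edge weights from the permuted matrix, reselect
#' seeds and rerun the full subnetwork search with the same configuration; all
#' resulting scores are pooled into one reference distribution. Permutations
#' that yield no subnetwork contribute nothing (counted in `n_empty`).
#'
#' @param net a [weighted_network()] (its topology is reused; weights are
#'   recomputed per permutation unless `reweight = FALSE`).
#' @param z a z-scored [expression_set()].
#' @param cfg a [search_config()].
#' @param n_perm number of permutations (>= 1; the reference analysis used
#'   100).
#' @param seed integer RNG seed.
#' @param reweight recompute edge weights from the permuted matrix (default
#'   TRUE; weights derive from expression, which the permutation moves).
#' @param unit permutation unit, see [permute_expression()].
#' @return An object of class `null_distribution`: list with `scores`
#'   (pooled S values), `n_permutations`, `seed`, `n_empty`, `per_perm`
#'   (number of subnetworks per permutation).
#' @export
build_null <- function(net, z, cfg = search_config(), n_perm = 100,
                       seed = 1, reweight = TRUE,
                       unit = c("genes", "labels")) {
  stopifnot(inherits(net, "weighted_network"), inherits(z, "expr_set"))
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  unit <- match.arg(unit)
  scores <- numeric(0)
  per_perm <- integer(n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    zp <- permute_expression(z, unit = unit)
    netp <- if (reweight) weight_edges(net, zp) else net
    found <- find_subnetworks(netp, zp, cfg)
    per_perm[b] <- length(found)
    if (length(found))
      scores <- c(scores, vapply(found, `[[`, 0, "S"))
  }
  n_empty <- sum(per_perm == 0)
  if (n_empty) message(n_empty, " permutation(s) yielded no subnetworks")
  structure(list(scores = scores, n_permutations = n_perm, seed = seed,
                 n_empty = n_empty, per_perm = per_perm),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null_distribution:", length(x$scores), "pooled scores from",
      x$n_permutations, "permutation(s)\n")
  if (length(x$scores))
    cat("score quantiles:",
        paste(format(stats::quantile(x$scores, c(.5, .9, .95, .99)), digits = 4),
              collapse = " "), "(50/90/95/99%)\n")
  invisible(x)
}

#' Empirical p-value of a subnetwork score
#'
#' Fraction of the pooled null scores strictly greater than `s` — exactly the
#' plain fraction, with no +1 smoothing, so p = 0 is possible and means
#' "smaller than 1 / #null".
#'
#' @param s observed score (vectorized).
#' @param null a `null_distribution` from [build_null()], or a numeric vector
#'   of null scores.
#' @return p-value(s) in [0, 1].
#' @export
empirical_pvalue <- function(s, null) {
  scores <- if (inherits(null, "null_distribution")) null$scores else null
  if (!length(scores)) stop("empty null distribution")
  vapply(s, function(si) mean(scores > si), 0)
}

#' Select significant subnetworks
#'
#' Attaches the empirical p-value to every subnetwork and retains those with
#' p < `alpha`, preserving order.
#'
#' @param subnets list of `subnetwork` objects.
#' @param null a `null_distribution`.
#' @param alpha significance cutoff in [0, 1); 0 selects nothing.
#' @return List with `subnets` (all inputs, p attached) and `significant`
#'   (the retained subset).
#' @export
select_significant <- function(subnets, null, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha < 1)
  p <- empirical_pvalue(vapply(subnets, `[[`, 0, "S"), null)
  for (i in seq_along(subnets)) subnets[[i]]$p <- p[i]
  list(subnets = subnets, significant = subnets[p < alpha])
}
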