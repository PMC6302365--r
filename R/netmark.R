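#' Fit discriminative subnetwork markers
#'
#' End-to-end driver: per-gene Box-Cox normalization and z-scoring of the
#' expression matrix, co-expression weighting of the interaction network,
#' hub filtering, greedy seed-and-grow subnetwork search scored by
#' \eqn{S = \beta M + |R|}, redundancy pruning, and a permutation null giving
#' each retained subnetwork an empirical p-value.
#'
#' @param edges a [weighted_network()], a path to a TSV edge list, or a
#'   data.frame with `from`/`to` columns.
#' @param expr an [expression_set()] of raw values, or a path to an
#'   expression TSV (then `labels` must be the label-file path).
#' @param labels label-file path when `expr` is a path; ignored otherwise.
#' @param normalize apply per-gene Box-Cox before z-scoring (default TRUE;
#'   set FALSE when the matrix is already normalized).
#' @param hub_threshold nodes with degree above this are removed
#'   (default 200); `Inf` disables hub filtering.
#' @param seed_alpha per-gene p-value cutoff for seed genes (default 0.05).
#' @param beta modularity weight in the score (default 1).
#' @param n_perm permutations for the empirical null (default 100; 0 skips
#'   the null, leaving p-values NA).
#' @param alpha empirical p-value cutoff for the significant set
#'   (default 0.05).
#' @param overlap_threshold redundancy-pruning overlap cutoff (default 0.5).
#' @param max_size optional cap on subnetwork size.
#' @param var_equal pooled-variance t-tests instead of Welch.
#' @param seed RNG seed for the permutation null.
#' @return An object of class `netmark`: list with the weighted `network`,
#'   z-scored matrix `z`, all pruned `subnetworks` (p attached),
#'   `significant` subset, `null` distribution, `norm_report`,
#'   `removed_hubs`, `flagged` overlap pairs, and the `config` used.
#' @examples
#' truth <- planted_truth(n_modules = 1, module_size = 5, n_background = 30,
#'                        n_per_class = 10)
#' net <- generate_network(truth, seed = 1)
#' expr <- generate_expression(truth, extra_genes = setdiff(net$nodes,
#'   c(unlist(truth$modules), truth$background)), seed = 2)
#' fit <- netmark(net, expr, normalize = FALSE, n_perm = 3, seed = 1)
#' coef(fit)
#' @export
netmark <- function(edges, expr, labels = NULL, normalize = TRUE,
                    hub_threshold = 200, seed_alpha = 0.05, beta = 1,
                    n_perm = 100, alpha = 0.05, overlap_threshold = 0.5,
                    max_size = Inf, var_equal = FALSE, seed = 1) {
  cl <- match.call()
  if (is.character(edges)) edges <- read_edge_list(edges)
  if (is.data.frame(edges))
    edges <- weighted_network(unique(c(edges$from, edges$to)), edges)
  if (is.character(expr)) {
    if (is.null(labels)) stop("`labels` path required when `expr` is a path")
    expr <- read_expression(expr, labels)
  }
  stopifnot(inherits(edges, "weighted_network"), inherits(expr, "expr_set"))
  norm_report <- NULL
  if (normalize) {
    bc <- boxcox_transform(expr)
    expr <- bc$expr
    norm_report <- bc$report
  }
  z <- zscore_expression(expr)
  net <- weight_edges(edges, z)
  removed <- character(0)
  if (is.finite(hub_threshold)) {
    hb <- remove_hubs(net, hub_threshold)
    net <- hb$network
    removed <- hb$removed
  }
  cfg <- search_config(seed_alpha = seed_alpha, beta = beta,
                       max_size = max_size, var_equal = var_equal)
  found <- find_subnetworks(net, z, cfg)
  pruned <- prune_redundant(found, overlap_threshold)
  flagged <- attr(pruned, "flagged")
  null <- NULL
  significant <- list()
  if (n_perm > 0 && length(pruned)) {
    null <- build_null(net, z, cfg, n_perm = n_perm, seed = seed)
    sel <- select_significant(pruned, null, alpha)
    pruned <- sel$subnets
    significant <- sel$significant
  }
  structure(list(
    call = cl, network = net, z = z,
    subnetworks = pruned, significant = significant, null = null,
    norm_report = norm_report, removed_hubs = removed, flagged = flagged,
    config = list(seed_alpha = seed_alpha, beta = beta, n_perm = n_perm,
                  alpha = alpha, hub_threshold = hub_threshold,
                  overlap_threshold = overlap_threshold, seed = seed,
                  var_equal = var_equal)
  ), class = "netmark")
}

#' @export
print.netmark <- function(x, ...) {
  cat("netmark fit\n")
  cat("network: ", length(x$network$nodes), " nodes, ",
      nrow(x$network$edges), " edges",
      if (length(x$removed_hubs))
        paste0(" (", length(x$removed_hubs), " hub(s) removed)"), "\n",
      sep = "")
  cat("subnetworks after pruning:", length(x$subnetworks), "\n")
  if (!is.null(x$null))
    cat("significant at p < ", x$config$alpha, ": ",
        length(x$significant), "  (null: ", length(x$null$scores),
        " scores, ", x$null$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
summary.netmark <- function(object, ...) {
  print(object)
  tab <- coef(object)
  if (nrow(tab)) {
    cat("\ntop subnetworks:\n")
    print(utils::head(subnetwork_table(object$subnetworks), 5))
  }
  invisible(tab)
}

#' Score table of the fitted subnetworks
#'
#' @param object a `netmark` fit.
#' @param ... unused.
#' @return Numeric matrix with one row per pruned subnetwork and columns
#'   `n`, `M`, `R`, `S`, `p`.
#' @export
coef.netmark <- function(object, ...) {
  s <- object$subnetworks
  out <- cbind(n = vapply(s, `[[`, 0L, "n"),
               M = vapply(s, `[[`, 0, "M"),
               R = vapply(s, `[[`, 0, "R"),
               S = vapply(s, `[[`, 0, "S"),
               p = vapply(s, `[[`, 0, "p"))
  rownames(out) <- if (length(s)) paste0("subnet", seq_along(s)) else NULL
  out
}

#' Null-versus-observed score plot
#'
#' Histogram of the pooled permutation-null scores with the observed
#' subnetwork scores overlaid as a rug; significant scores are marked.
#'
#' @param x a `netmark` fit with a permutation null.
#' @param ... passed to [graphics::hist()].
#' @export
plot.netmark <- function(x, ...) {
  if (is.null(x$null) || !length(x$null$scores))
    stop("no permutation null to plot (fit with n_perm > 0)")
  S <- vapply(x$subnetworks, `[[`, 0, "S")
  graphics::hist(x$null$scores, breaks = 30, freq = FALSE, col = "grey85",
                 border = "white", main = "Subnetwork scores vs permutation null",
                 xlab = "score S", xlim = range(c(x$null$scores, S)), ...)
  graphics::rug(S, col = "grey40")
  sig <- vapply(x$significant, `[[`, 0, "S")
  if (length(sig)) {
    graphics::rug(sig, col = "red3", lwd = 2)
    graphics::legend("topright", legend = c("observed", "significant"),
                     col = c("grey40", "red3"), lwd = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Subnetwork features for new samples
#'
#' Encodes the fitted (significant, or all pruned) subnetworks as summarized
#' expression features on a new expression set, after z-scoring it with its
#' own per-gene statistics.
#'
#' @param object a `netmark` fit.
#' @param newdata an [expression_set()]; defaults to the training matrix.
#' @param which `"significant"` (default) or `"all"` pruned subnetworks.
#' @param normalize Box-Cox normalize `newdata` first (default matches the
#'   fit).
#' @param ... unused.
#' @return A [build_features()] `feature_table`.
#' @export
predict.netmark <- function(object, newdata = NULL,
                            which = c("significant", "all"),
                            normalize = FALSE, ...) {
  which <- match.arg(which)
  subnets <- if (which == "significant" && length(object$significant))
    object$significant else object$subnetworks
  if (!length(subnets)) stop("no subnetworks to encode")
  z <- if (is.null(newdata)) object$z else {
    if (normalize) newdata <- boxcox_transform(newdata)$expr
    zscore_expression(newdata)
  }
  build_features(z, lapply(subnets, `[[`, "genes"), strategy = "subnetwork")
}
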