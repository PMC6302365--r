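#' Weighted undirected gene network
#'
#' Simple undirected graph over gene identifiers with edge weights in [0, 1].
#' Edges are stored canonically (`from` < `to` lexicographically, sorted), so
#' two networks over the same edges compare identical.
#'
#' @param nodes character vector of gene identifiers.
#' @param edges data.frame with columns `from`, `to` and optionally `weight`
#'   (defaults to 1). Self-loops and duplicate pairs are rejected here; use
#'   [read_edge_list()] to clean raw input.
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(nodes, edges) {
  nodes <- unique(as.character(nodes))
  if (is.null(edges$weight)) edges$weight <- 1
  from <- as.character(edges$from); to <- as.character(edges$to)
  if (any(from == to)) stop("self-loops not allowed")
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges")
  if (!all(c(a, b) %in% nodes)) stop("edge endpoint not in node set")
  w <- as.numeric(edges$weight)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("edge weights must be finite and in [0, 1]")
  o <- order(a, b)
  structure(list(
    nodes = sort(nodes),
    edges = data.frame(from = a[o], to = b[o], weight = w[o],
                       stringsAsFactors = FALSE)
  ), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("weighted_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat("edge weights: [", format(min(x$edges$weight), digits = 4), ", ",
        format(max(x$edges$weight), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Read an interaction edge list
#'
#' Parses a tab-separated edge list (two or more columns; extra columns are
#' ignored) into an unweighted network: self-loops are dropped and duplicate
#' pairs collapsed, with counts reported via message. Weights are initialized
#' to 1 until [weight_edges()] overlays co-expression.
#'
#' @param path path to the TSV edge list.
#' @return A `weighted_network`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge list: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad))
    stop("malformed edge-list line ", bad[1], ": ", lines[bad[1]])
  from <- vapply(parts, `[`, "", 1L)
  to <- vapply(parts, `[`, "", 2L)
  loops <- from == to
  if (any(loops)) message("dropped ", sum(loops), " self-loop(s)")
  from <- from[!loops]; to <- to[!loops]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) message("collapsed ", sum(dup), " duplicate pair(s)")
  weighted_network(unique(c(a, b)),
                   data.frame(from = a[!dup], to = b[!dup], weight = 1,
                              stringsAsFactors = FALSE))
}

#' Read a weighted edge list
#'
#' Counterpart of [write_edge_list()]: three tab-separated columns
#' (gene_a, gene_b, weight), no header.
#'
#' @param path path to the TSV.
#' @return A `weighted_network`.
#' @export
read_weighted_edges <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("weighted edge list needs 3 columns")
  e <- data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
                  weight = as.numeric(df[[3]]), stringsAsFactors = FALSE)
  weighted_network(unique(c(e$from, e$to)), e)
}

#' Write a weighted network as TSV
#'
#' Three columns (gene_a, gene_b, weight to 6 decimals), no header.
#'
#' @param net a `weighted_network`.
#' @param path output path.
#' @return Invisibly, `net`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  df <- net$edges
  df$weight <- sprintf("%.6f", df$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(net)
}

#' Overlay co-expression weights on an interaction network
#'
#' Each edge whose two endpoint genes are present in the expression set gets
#' weight |Pearson r| between the two gene rows over all samples (both classes
#' pooled). Edges with an endpoint missing from the expression matrix, or
#' incident to a zero-variance gene row (correlation undefined), are removed
#' and counted in a message/warning. Isolated nodes left behind are dropped.
#'
#' @param net a `weighted_network` (typically from [read_edge_list()]).
#' @param es an [expression_set()] (raw or transformed; weights use whatever
#'   scale it carries).
#' @return A `weighted_network` with weights in [0, 1].
#' @export
weight_edges <- function(net, es) {
  stopifnot(inherits(net, "weighted_network"), inherits(es, "expr_set"))
  e <- net$edges
  present <- e$from %in% rownames(es$values) & e$to %in% rownames(es$values)
  if (any(!present))
    message("removed ", sum(!present), " edge(s) with endpoint absent from expression matrix")
  e <- e[present, , drop = FALSE]
  v <- es$values
  sds <- apply(v, 1, stats::sd)
  zero <- rownames(v)[sds == 0]
  if (length(zero)) {
    bad <- e$from %in% zero | e$to %in% zero
    if (any(bad))
      warning("removed ", sum(bad), " edge(s) incident to zero-variance gene(s)")
    e <- e[!bad, , drop = FALSE]
  }
  # standardize rows once; r = sum(za*zb)/(n-1)
  n <- ncol(v)
  zs <- (v - rowMeans(v)) / sds
  r <- rowSums(zs[e$from, , drop = FALSE] * zs[e$to, , drop = FALSE]) / (n - 1)
  e$weight <- pmin(abs(r), 1)  # guard rounding at |r| = 1
  nodes <- unique(c(e$from, e$to))
  weighted_network(nodes, e)
}

#' Remove hub nodes
#'
#' Deletes every node whose degree strictly exceeds `degree_threshold`,
#' together with its incident edges. Removal is a single pass on the original
#' degrees: two hubs are both removed even if deleting one would drop the
#' other below the threshold. Hubs mostly generate star-shaped neighborhoods
#' that the triangle-seeking search cannot use.
#'
#' @param net a `weighted_network`.
#' @param degree_threshold integer >= 1; nodes with degree > threshold go.
#' @return A list with `network` (filtered) and `removed` (character vector of
#'   removed hub ids).
#' @export
remove_hubs <- function(net, degree_threshold = 200) {
  stopifnot(inherits(net, "weighted_network"), degree_threshold >= 1)
  deg <- table(c(net$edges$from, net$edges$to))
  hubs <- names(deg)[deg > degree_threshold]
  if (!length(hubs)) return(list(network = net, removed = character(0)))
  e <- net$edges
  e <- e[!(e$from %in% hubs | e$to %in% hubs), , drop = FALSE]
  list(network = weighted_network(setdiff(net$nodes, hubs), e),
       removed = sort(hubs))
}

#' Network structure profile
#'
#' Degree, weighted-degree (sum of incident weights) and edge-weight
#' distributions, as used to profile the weighted interaction network.
#'
#' @param net a `weighted_network`.
#' @param breaks passed to [graphics::hist()]-style binning via
#'   [base::cut()]; default "Sturges" behaviour from [base::pretty()].
#' @return A list of class `network_summary` with `n_nodes`, `n_edges`,
#'   `degree`, `weighted_degree` (named numeric vectors per node) and
#'   `edge_weights`, plus histogram tables `degree_hist`,
#'   `weighted_degree_hist`, `edge_weight_hist`.
#' @export
summarize_network <- function(net, breaks = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  deg <- setNames(numeric(length(net$nodes)), net$nodes)
  wdeg <- deg
  if (nrow(net$edges)) {
    t1 <- table(c(net$edges$from, net$edges$to))
    deg[names(t1)] <- as.numeric(t1)
    ws <- tapply(c(net$edges$weight, net$edges$weight),
                 c(net$edges$from, net$edges$to), sum)
    wdeg[names(ws)] <- as.numeric(ws)
  }
  hist_of <- function(x) {
    if (!length(x)) return(table(factor(character(0))))
    table(cut(x, breaks = if (is.null(breaks)) pretty(x, 10) else breaks,
              include.lowest = TRUE))
  }
  structure(list(
    n_nodes = length(net$nodes), n_edges = nrow(net$edges),
    degree = deg, weighted_degree = wdeg, edge_weights = net$edges$weight,
    degree_hist = hist_of(deg),
    weighted_degree_hist = hist_of(wdeg),
    edge_weight_hist = hist_of(net$edges$weight)
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("network: ", x$n_nodes, " nodes, ", x$n_edges, " edges\n", sep = "")
  cat("degree: median ", stats::median(x$degree), ", max ", max(x$degree, 0), "\n", sep = "")
  if (length(x$edge_weights))
    cat("edge weight: median ", format(stats::median(x$edge_weights), digits = 3), "\n", sep = "")
  invisible(x)
}

# ---- internal adjacency engine ----------------------------------------------
# Index-based view of a weighted_network aligned to a z-scored matrix: sparse
# symmetric weight matrix W (nodes x nodes), neighbor index list, and gene-name
# lookup. Built once per search, reused across thousands of score evaluations.
network_engine <- function(net, z) {
  nodes <- intersect(net$nodes, rownames(z$values))
  idx <- seq_along(nodes); names(idx) <- nodes
  e <- net$edges
  e <- e[e$from %in% nodes & e$to %in% nodes, , drop = FALSE]
  i <- idx[e$from]; j <- idx[e$to]
  # dense base matrix avoids S4 dispatch in the hot growth loop; fall back to
  # a sparse matrix only when the node set is large
  if (length(nodes) <= 5000) {
    W <- matrix(0, length(nodes), length(nodes))
    W[cbind(c(i, j), c(j, i))] <- c(e$weight, e$weight)
  } else {
    W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = c(e$weight, e$weight),
                              dims = c(length(nodes), length(nodes)))
  }
  nbr <- vector("list", length(nodes))
  for (k in seq_len(length(nodes))) nbr[[k]] <- integer(0)
  if (nrow(e)) {
    spl <- split(c(j, i), c(i, j))
    for (nm in names(spl)) nbr[[as.integer(nm)]] <- sort(unique(spl[[nm]]))
  }
  zc <- class_index(z)
  list(nodes = nodes, idx = idx, W = W, nbr = nbr,
       z = z$values[nodes, , drop = FALSE],
       i1 = zc[[1]], i2 = zc[[2]])
}
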