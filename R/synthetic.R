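#' Planted-module study design
#'
#' Describes a synthetic two-class study: a sparse interaction network
#' containing planted dense modules whose genes are mutually co-expressed and
#' mean-shifted between the classes, against a background of independent noise
#' genes. The defaults emulate the reference study's simulation — per-gene
#' means and SDs drawn from realistic priors on a log2-like intensity scale,
#' 100 samples per class — extended with an explicit within-module
#' equicorrelation `rho` (setting `rho = 0` reproduces a fully
#' independent-gene scheme, which carries no co-expression for the modularity
#' term to reward).
#'
#' @param n_modules number of planted modules.
#' @param module_size genes per module (recycled to `n_modules`).
#' @param n_background number of background noise genes.
#' @param delta between-class mean shift of module genes, in units of each
#'   gene's SD.
#' @param rho within-module equicorrelation, in [0, 1).
#' @param n_per_class samples per class (>= 2).
#' @param mean_prior,sd_prior parameters of the per-gene priors: mean ~
#'   Normal(mean_prior[1], mean_prior[2]), SD ~ Uniform(sd_prior[1],
#'   sd_prior[2]).
#' @param classes two class labels; the first is the shifted (and positive)
#'   class.
#' @return An object of class `planted_truth` with the module gene sets and
#'   all parameters.
#' @export
planted_truth <- function(n_modules = 2, module_size = 6, n_background = 200,
                          delta = 1.0, rho = 0.7, n_per_class = 100,
                          mean_prior = c(7, 2), sd_prior = c(0.5, 1.5),
                          classes = c("classA", "classB")) {
  stopifnot(n_modules >= 0, n_background >= 0, rho >= 0, rho < 1,
            n_per_class >= 2, length(classes) == 2)
  module_size <- rep_len(module_size, n_modules)
  modules <- lapply(seq_len(n_modules), function(m)
    sprintf("mod%d_g%02d", m, seq_len(module_size[m])))
  names(modules) <- sprintf("module%d", seq_len(n_modules))
  background <- sprintf("bg%04d", seq_len(n_background))
  structure(list(modules = modules, background = background,
                 delta = delta, rho = rho, n_per_class = n_per_class,
                 mean_prior = mean_prior, sd_prior = sd_prior,
                 classes = classes),
            class = "planted_truth")
}

#' Generate a PPI-like topology with planted modules
#'
#' Each planted module is wired as a clique (a dense, fully cooperative
#' neighborhood). Background genes form a scale-free-style graph by
#' preferential attachment, mimicking the heavy-tailed degree distribution of
#' interaction databases. Module nodes attach to background nodes
#' independently with probability `attach_prob` per pair, so modules are
#' embedded rather than isolated. An optional hub of a given degree can be
#' planted for hub-filtering tests.
#'
#' @param truth a [planted_truth()].
#' @param attach_prob per (module node, background node) attachment
#'   probability.
#' @param pa_edges edges added per background node during preferential
#'   attachment (igraph `sample_pa` `m`).
#' @param hub_degree if non-NULL, adds one extra node `"hub1"` wired to
#'   `hub_degree` distinct nodes.
#' @param seed RNG seed; (truth, seed) fully determine the topology.
#' @return A [weighted_network()] with all weights 1 (topology only; use
#'   [weight_edges()] to overlay co-expression).
#' @export
generate_network <- function(truth, attach_prob = 0.005, pa_edges = 2,
                             hub_degree = NULL, seed = 1) {
  stopifnot(inherits(truth, "planted_truth"))
  if (anyDuplicated(unlist(truth$modules)))
    stop("planted modules must be disjoint")
  set.seed(seed)
  edges <- list()
  for (g in truth$modules) {
    if (length(g) >= 2) {
      pr <- utils::combn(g, 2)
      edges[[length(edges) + 1L]] <- data.frame(from = pr[1, ], to = pr[2, ],
                                                stringsAsFactors = FALSE)
    }
  }
  bg <- truth$background
  if (length(bg) >= 2) {
    gpa <- igraph::sample_pa(length(bg), m = min(pa_edges, length(bg) - 1),
                             directed = FALSE)
    el <- igraph::as_edgelist(gpa, names = FALSE)
    edges[[length(edges) + 1L]] <- data.frame(from = bg[el[, 1]],
                                              to = bg[el[, 2]],
                                              stringsAsFactors = FALSE)
  }
  mod_genes <- unlist(truth$modules)
  if (length(mod_genes) && length(bg) && attach_prob > 0) {
    hit <- which(matrix(stats::runif(length(mod_genes) * length(bg)),
                        length(mod_genes)) < attach_prob, arr.ind = TRUE)
    if (nrow(hit))
      edges[[length(edges) + 1L]] <- data.frame(from = mod_genes[hit[, 1]],
                                                to = bg[hit[, 2]],
                                                stringsAsFactors = FALSE)
  }
  nodes <- c(mod_genes, bg)
  if (!is.null(hub_degree)) {
    stopifnot(hub_degree <= length(nodes))
    targets <- sample(nodes, hub_degree)
    edges[[length(edges) + 1L]] <- data.frame(from = "hub1", to = targets,
                                              stringsAsFactors = FALSE)
    nodes <- c(nodes, "hub1")
  }
  e <- do.call(rbind, edges)
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  weighted_network(nodes, data.frame(from = a[!dup], to = b[!dup], weight = 1,
                                     stringsAsFactors = FALSE))
}

#' Generate a two-class expression matrix with planted signal
#'
#' Background genes are independent Gaussian noise, identical across classes,
#' with per-gene mean and SD drawn from the priors in `truth`. Module genes
#' share a per-module, per-sample latent factor giving pairwise correlation
#' `rho` (equicorrelation), and the first class's mean is shifted upward by
#' `delta` times the gene's SD.
#'
#' @param truth a [planted_truth()].
#' @param extra_genes additional gene ids (e.g. a planted hub) to fill with
#'   background-style noise.
#' @param seed RNG seed; (truth, seed) fully determine the matrix.
#' @return An [expression_set()] of raw (untransformed) values.
#' @export
generate_expression <- function(truth, extra_genes = character(0), seed = 1) {
  stopifnot(inherits(truth, "planted_truth"))
  set.seed(seed)
  npc <- truth$n_per_class
  ns <- 2L * npc
  genes <- c(unname(unlist(truth$modules)), truth$background, extra_genes)
  samples <- sprintf("s%03d", seq_len(ns))
  labels <- stats::setNames(rep(truth$classes, each = npc), samples)
  shifted <- labels == truth$classes[1]
  mu <- stats::rnorm(length(genes), truth$mean_prior[1], truth$mean_prior[2])
  sd_ <- stats::runif(length(genes), truth$sd_prior[1], truth$sd_prior[2])
  names(mu) <- names(sd_) <- genes
  m <- matrix(NA_real_, length(genes), ns, dimnames = list(genes, samples))
  rho <- truth$rho
  for (mod in truth$modules) {
    f <- stats::rnorm(ns)  # shared latent factor for this module
    for (g in mod) {
      eps <- stats::rnorm(ns)
      x <- sqrt(rho) * f + sqrt(1 - rho) * eps
      x <- mu[g] + sd_[g] * x
      x[shifted] <- x[shifted] + truth$delta * sd_[g]
      m[g, ] <- x
    }
  }
  for (g in c(truth$background, extra_genes))
    m[g, ] <- stats::rnorm(ns, mu[g], sd_[g])
  expression_set(m, labels)
}

#' Simulate a full study to disk
#'
#' Convenience wrapper writing `edges.tsv`, `expr.tsv`, `labels.tsv` and
#' `truth.json` under `out_dir`, the file layout the pipeline stages read.
#'
#' @param truth a [planted_truth()].
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed (topology uses `seed`, expression `seed + 1`).
#' @param ... passed to [generate_network()].
#' @return Invisibly, a list with `network`, `expr`, `truth`, and the paths.
#' @export
simulate_study <- function(truth, out_dir, seed = 1, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_network(truth, seed = seed, ...)
  extra <- setdiff(net$nodes, c(unlist(truth$modules), truth$background))
  expr <- generate_expression(truth, extra_genes = extra, seed = seed + 1)
  paths <- list(edges = file.path(out_dir, "edges.tsv"),
                expr = file.path(out_dir, "expr.tsv"),
                labels = file.path(out_dir, "labels.tsv"),
                truth = file.path(out_dir, "truth.json"))
  utils::write.table(net$edges[, c("from", "to")], paths$edges, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_expression(expr, paths$expr, paths$labels)
  jsonlite::write_json(
    list(modules = truth$modules, delta = truth$delta, rho = truth$rho,
         n_per_class = truth$n_per_class, seed = seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(network = net, expr = expr, truth = truth, paths = paths))
}

#' Planted-module recovery report
#'
#' How well a list of found subnetworks recovers the planted modules: per
#' module, the best Jaccard overlap with any found subnetwork, plus overall
#' precision and recall of planted genes over the union of found genes.
#'
#' @param found list of `subnetwork` objects (may be empty).
#' @param truth a [planted_truth()].
#' @return List with `jaccard` (named per module), `precision`, `recall`.
#' @export
recovery_report <- function(found, truth) {
  stopifnot(inherits(truth, "planted_truth"))
  found_sets <- lapply(found, `[[`, "genes")
  jac <- vapply(truth$modules, function(mod) {
    if (!length(found_sets)) return(0)
    max(vapply(found_sets, function(g)
      length(intersect(g, mod)) / length(union(g, mod)), 0))
  }, 0)
  planted <- unlist(truth$modules)
  found_union <- unique(unlist(found_sets))
  precision <- if (length(found_union))
    length(intersect(found_union, planted)) / length(found_union) else NA_real_
  recall <- if (length(planted))
    length(intersect(found_union, planted)) / length(planted) else NA_real_
  list(jaccard = jac, precision = precision, recall = recall)
}
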