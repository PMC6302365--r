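#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a line are collapsed; lines with no genes are
#' dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": ", lines[bad[1]])
  names(parts) <- vapply(parts, `[`, "", 1L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropped ", sum(empty), " empty gene set(s): ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of descriptions.
#' @return Invisibly, `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(sets)
}

#' Drop overly general gene sets
#'
#' Retains sets with strictly fewer than `max_size` genes; large sets (e.g.
#' broad GO terms) are too unspecific to act as discriminative features.
#'
#' @param sets named list of gene sets.
#' @param max_size strict upper bound on set size (default 50).
#' @return Filtered list.
#' @export
filter_gene_sets <- function(sets, max_size = 50) {
  stopifnot(max_size >= 1)
  sets[lengths(sets) < max_size]
}

#' Rank gene sets by discriminative power and drop redundant ones
#'
#' Each set is restricted to genes present in the expression matrix, scored by
#' |t| of its summarized expression between the two classes, sorted by
#' descending score, and pruned with the same subset/superset/overlap rules as
#' [prune_redundant()].
#'
#' @param sets named list of gene sets.
#' @param z a z-scored [expression_set()].
#' @param overlap_threshold see [prune_redundant()].
#' @param var_equal pooled-variance t instead of Welch.
#' @return Named list of retained sets, descending |t| order, with attribute
#'   `"score"` (the |t| values).
#' @export
rank_and_prune_gene_sets <- function(sets, z, overlap_threshold = 0.5,
                                     var_equal = FALSE) {
  stopifnot(inherits(z, "expr_set"))
  sets <- lapply(sets, intersect, rownames(z$values))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropped ", sum(empty), " set(s) with no genes in the matrix")
    sets <- sets[!empty]
  }
  if (!length(sets)) return(sets)
  score <- vapply(sets, function(g)
    abs(class_relevance(z, g, var_equal = var_equal)), 0)
  o <- order(-score, names(sets))
  sets <- sets[o]; score <- score[o]
  keep <- logical(length(sets))
  for (i in seq_along(sets)) {
    drop <- FALSE
    for (j in which(keep)) {
      g1 <- sets[[j]]; g2 <- sets[[i]]
      inter <- length(intersect(g1, g2))
      if (inter == 0) next
      ov <- inter / length(union(g1, g2))
      if (all(g2 %in% g1) || all(g1 %in% g2) || ov >= overlap_threshold) {
        drop <- TRUE; break
      }
    }
    keep[i] <- !drop
  }
  out <- sets[keep]
  attr(out, "score") <- score[keep]
  out
}

#' Top individually differentially expressed genes
#'
#' The k genes with the smallest per-gene t-test p-values (ties broken by gene
#' id); each becomes a singleton feature in the individual-gene baseline.
#'
#' @param z an [expression_set()].
#' @param k number of genes, 1 <= k <= number of genes.
#' @param var_equal pooled-variance t instead of Welch.
#' @return Character vector of k gene ids.
#' @export
top_k_individual_genes <- function(z, k, var_equal = FALSE) {
  if (!is.numeric(k) || k <= 0) stop("k must be positive")
  tab <- gene_pvalues(z, var_equal = var_equal)
  if (k > nrow(tab)) stop("k exceeds gene count")
  tab$gene[seq_len(k)]
}

#' Encode gene groups as per-sample features
#'
#' Feature value for (sample j, group K) is the summarized expression V_Kj —
#' the mean z-score of K's members in sample j. Groups with no genes in the
#' matrix are dropped with a warning.
#'
#' @param z a z-scored [expression_set()].
#' @param groups named list of gene sets (subnetworks, singletons, GO sets...).
#' @param strategy provenance tag stored with the table.
#' @return An object of class `feature_table`: list with `values` (samples x
#'   features matrix), `labels`, and `provenance` (data.frame of feature id,
#'   semicolon-joined genes, strategy).
#' @export
build_features <- function(z, groups, strategy = "subnetwork") {
  stopifnot(inherits(z, "expr_set"), length(groups) > 0)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0(strategy, "_", seq_along(groups))
  if (anyDuplicated(names(groups))) stop("duplicate feature ids")
  groups <- lapply(groups, intersect, rownames(z$values))
  empty <- lengths(groups) == 0
  if (any(empty)) {
    warning("dropped ", sum(empty), " group(s) absent from the matrix")
    groups <- groups[!empty]
  }
  vals <- vapply(groups, function(g) summarize_expression(z, g),
                 numeric(ncol(z$values)))
  structure(list(values = vals, labels = z$labels,
                 provenance = data.frame(
                   feature = names(groups),
                   genes = vapply(groups, paste, "", collapse = ";"),
                   strategy = strategy, stringsAsFactors = FALSE)),
            class = "feature_table")
}

# stratified fold assignment: named integer vector over samples
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("class '", cl, "' has fewer samples than folds")
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' ROC curve and AUC
#'
#' Full-threshold-sweep ROC with the rank-statistic AUC (concordance
#' probability; tied scores contribute half-concordance), which equals the
#' trapezoidal area under the tie-blocked ROC curve.
#'
#' @param scores numeric decision values, larger = more positive-class.
#' @param truth factor/character labels; `positive` defaults to the first
#'   level (or first value seen).
#' @param positive the positive-class label.
#' @return List with `roc` (data.frame of threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive = NULL) {
  truth <- as.character(truth)
  if (is.null(positive)) positive <- unique(truth)[1]
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[o]); fp <- cumsum(!pos[o])
  thr <- scores[o]
  last <- !duplicated(thr, fromLast = TRUE)  # one point per distinct threshold
  roc <- data.frame(threshold = c(Inf, thr[last]),
                    fpr = c(0, fp[last] / n0),
                    tpr = c(0, tp[last] / n1))
  list(roc = roc, auc = auc)
}

# F-score of predicted vs true labels for a given positive class
f_score <- function(pred, truth, positive) {
  pred <- as.character(pred); truth <- as.character(truth)
  tp <- sum(pred == positive & truth == positive)
  if (tp == 0) return(0)
  precision <- tp / sum(pred == positive)
  recall <- tp / sum(truth == positive)
  2 * precision * recall / (precision + recall)
}

#' Cross-validated SVM classification of a feature table
#'
#' Repeated stratified k-fold cross-validation of a linear-kernel SVM
#' (C = `cost`). Features are standardized with the training fold's means and
#' SDs only. Held-out decision values are pooled per repeat; the F-score (with
#' the first class positive) is computed per repeat from the pooled
#' predictions, and the ROC/AUC from decision values pooled over all repeats.
#'
#' @param features a [build_features()] table.
#' @param folds number of folds (default 5).
#' @param repeats number of cross-validation repeats (default 5).
#' @param seed RNG seed; identical seeds give identical fold partitions, so
#'   strategies evaluated with the same seed are compared on the same splits.
#' @param cost SVM regularization parameter.
#' @return An object of class `eval_result`: strategy tag, `n_features`,
#'   `auc`, `roc`, `f_scores` (one per repeat), `median_f`, `sd_f`, plus the
#'   pooled decision values and fold assignments.
#' @export
crossval_classify <- function(features, folds = 5, repeats = 5, seed = 1,
                              cost = 1) {
  stopifnot(inherits(features, "feature_table"), folds >= 2)
  X <- features$values
  y <- features$labels
  positive <- levels(y)[1]
  set.seed(seed)
  fold_sets <- replicate(repeats, stratified_folds(y, folds), simplify = FALSE)
  dv_all <- numeric(0); truth_all <- character(0)
  f_scores <- numeric(repeats)
  pred_rec <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- fold_sets[[r]]
    dv <- numeric(length(y)); pred <- character(length(y))
    for (k in seq_len(folds)) {
      tr <- fold != k; te <- fold == k
      mu <- colMeans(X[tr, , drop = FALSE])
      sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sd_, "/")
      fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = cost,
                        scale = FALSE)
      pr <- stats::predict(fit, Xte, decision.values = TRUE)
      d <- attr(pr, "decision.values")
      # orient decision values so larger = positive class
      lab1 <- strsplit(colnames(d)[1], "/", fixed = TRUE)[[1]][1]
      dv[te] <- if (lab1 == positive) d[, 1] else -d[, 1]
      pred[te] <- as.character(pr)
    }
    f_scores[r] <- f_score(pred, y, positive)
    pred_rec[[r]] <- pred
    dv_all <- c(dv_all, dv)
    truth_all <- c(truth_all, as.character(y))
  }
  ra <- roc_auc(dv_all, truth_all, positive = positive)
  structure(list(
    strategy = features$provenance$strategy[1],
    n_features = ncol(X),
    auc = ra$auc, roc = ra$roc,
    f_scores = f_scores, median_f = stats::median(f_scores),
    sd_f = stats::sd(f_scores),
    decision_values = dv_all, truth = truth_all,
    folds = folds, repeats = repeats, seed = seed,
    predictions = pred_rec
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result [%s, %d features]: AUC = %.3f, median F = %.3f (SD %.3f)\n",
              x$strategy, x$n_features, x$auc, x$median_f,
              if (is.na(x$sd_f)) 0 else x$sd_f))
  invisible(x)
}

#' Compare feature-encoding strategies by cross-validated classification
#'
#' Evaluates several gene-grouping strategies — subnetwork markers,
#' individual genes, and optional predefined gene-set collections — at a
#' series of feature-set sizes, all on identical fold partitions (same seed).
#' A strategy with fewer features than a requested size is evaluated at its
#' maximum and the size actually used is recorded.
#'
#' @param z a z-scored [expression_set()].
#' @param subnets list of `subnetwork` objects (descending S), used as the
#'   subnetwork strategy's ordered feature pool.
#' @param sets optional named list of gene-set collections (each a named list
#'   of character vectors), e.g. `list(GO = ..., pathway = ...)`; each is
#'   ranked and pruned with [rank_and_prune_gene_sets()].
#' @param extra_subnets optional named list of additional subnetwork lists
#'   (e.g. `list(beta0 = ...)` for the no-modularity baseline).
#' @param sizes feature-set sizes to evaluate (default 5, 10, 20, 30, 40, 50).
#' @param folds,repeats,seed,cost passed to [crossval_classify()].
#' @return List with `results` (list of `eval_result`) and `summary`
#'   (data.frame: strategy, size_requested, size_used, auc, median_f, sd_f).
#' @export
compare_strategies <- function(z, subnets, sets = NULL, extra_subnets = NULL,
                               sizes = c(5, 10, 20, 30, 40, 50),
                               folds = 5, repeats = 5, seed = 1, cost = 1) {
  stopifnot(inherits(z, "expr_set"))
  pools <- list()
  pools$subnetwork <- lapply(subnets, `[[`, "genes")
  if (!is.null(extra_subnets))
    for (nm in names(extra_subnets))
      pools[[nm]] <- lapply(extra_subnets[[nm]], `[[`, "genes")
  ngene <- nrow(z$values)
  pools$individual <- as.list(top_k_individual_genes(z, min(max(sizes), ngene)))
  if (!is.null(sets))
    for (nm in names(sets))
      pools[[nm]] <- rank_and_prune_gene_sets(sets[[nm]], z)
  results <- list()
  rows <- list()
  for (strategy in names(pools)) {
    pool <- pools[[strategy]]
    if (!length(pool)) {
      warning("strategy '", strategy, "' has no features; skipped")
      next
    }
    for (size in sizes) {
      used <- min(size, length(pool))
      ft <- build_features(z, pool[seq_len(used)], strategy = strategy)
      ev <- crossval_classify(ft, folds = folds, repeats = repeats,
                              seed = seed, cost = cost)
      ev$size_requested <- size
      key <- paste0(strategy, "_", size)
      results[[key]] <- ev
      rows[[key]] <- data.frame(
        strategy = strategy, size_requested = size, size_used = used,
        auc = ev$auc, median_f = ev$median_f, sd_f = ev$sd_f,
        stringsAsFactors = FALSE)
    }
  }
  list(results = results, summary = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Gene-set enrichment by the hypergeometric test
#'
#' For each annotation set (intersected with the background), the upper-tail
#' hypergeometric probability of observing at least the actual overlap with
#' the query genes, Benjamini-Hochberg adjusted across sets.
#'
#' @param genes query gene list (must be a subset of `background`).
#' @param annotation named list of gene sets.
#' @param background character vector: the gene universe.
#' @return data.frame sorted by ascending p: `set`, `set_size`, `overlap`,
#'   `p`, `fdr`.
#' @export
enrich_gene_sets <- function(genes, annotation, background) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  genes <- unique(genes)
  if (!all(genes %in% background))
    stop("query genes must be a subset of the background")
  N <- length(background)
  n <- length(genes)
  ann <- lapply(annotation, intersect, background)
  K <- lengths(ann)
  k <- vapply(ann, function(a) length(intersect(a, genes)), 0L)
  # P[X >= k] with X ~ Hypergeometric(N, K, n); k = 0 gives 1
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(ann), set_size = K, overlap = k, p = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$set), , drop = FALSE]
}
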