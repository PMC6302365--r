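#' Pipeline configuration
#'
#' Flat key-value configuration covering every stage parameter, serializable
#' to a `key = value` text file. A single global `seed` deterministically
#' derives per-stage seeds, so each stage is reproducible on its own.
#'
#' @param hub_threshold,seed_alpha,beta,n_perm,alpha,overlap_threshold,folds,repeats,seed
#'   stage parameters; see [netmark()] and [crossval_classify()].
#' @param sizes feature-set sizes for the evaluation stage.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(hub_threshold = 200, seed_alpha = 0.05, beta = 1,
                            n_perm = 100, alpha = 0.05,
                            overlap_threshold = 0.5, folds = 5, repeats = 5,
                            sizes = c(5, 10, 20, 30, 40, 50), seed = 1) {
  cfg <- list(hub_threshold = hub_threshold, seed_alpha = seed_alpha,
              beta = beta, n_perm = n_perm, alpha = alpha,
              overlap_threshold = overlap_threshold, folds = folds,
              repeats = repeats, sizes = sizes, seed = seed)
  stopifnot(cfg$seed_alpha > 0, cfg$seed_alpha <= 1, cfg$beta >= 0,
            cfg$n_perm >= 0, cfg$alpha > 0, cfg$alpha < 1, cfg$folds >= 2)
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline configuration
#'
#' Text format: one `key = value` per line; `sizes` is comma-separated.
#' `#` starts a comment.
#'
#' @param path config file path.
#' @return For `read_pipeline_config`, a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(x)
    as.numeric(strsplit(x[2], ",", fixed = TRUE)[[1]])),
    vapply(kv, `[`, "", 1))
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param cfg a [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    paste(k, "=", paste(cfg[[k]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(cfg)
}

# per-stage seeds derived deterministically from the global seed
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "preprocess", "network", "find",
                        "permute", "select", "evaluate"))
  as.integer((as.numeric(seed) * 131 + idx) %% 2147483647)
}

#' Run the full discovery pipeline
#'
#' Executes preprocess, build-network, find, permute, select and evaluate in
#' order, writing every intermediate artifact plus `manifest.json` (config,
#' seeds, stage timings) under `out_dir`. Any stage error aborts with the
#' stage name and cause.
#'
#' @param edges_path TSV edge list.
#' @param expr_path,labels_path expression matrix and labels TSVs.
#' @param out_dir output directory (created if needed).
#' @param cfg a [pipeline_config()].
#' @param gmt named character vector of GMT file paths for baseline gene-set
#'   strategies (optional).
#' @param normalize Box-Cox normalize before z-scoring.
#' @return Invisibly, the `netmark` fit.
#' @export
run_pipeline <- function(edges_path, expr_path, labels_path, out_dir,
                         cfg = pipeline_config(), gmt = NULL,
                         normalize = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  tick <- function(stage, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    stages[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }
  expr <- tick("preprocess", function() {
    es <- read_expression(expr_path, labels_path)
    if (normalize) es <- boxcox_transform(es)$expr
    es
  })
  z <- zscore_expression(expr)
  net <- tick("network", function() {
    n <- weight_edges(read_edge_list(edges_path), z)
    n <- remove_hubs(n, cfg$hub_threshold)$network
    write_edge_list(n, file.path(out_dir, "network.tsv"))
    n
  })
  scfg <- search_config(seed_alpha = cfg$seed_alpha, beta = cfg$beta)
  pruned <- tick("find", function() {
    found <- find_subnetworks(net, z, scfg)
    prune_redundant(found, cfg$overlap_threshold)
  })
  flagged <- attr(pruned, "flagged")
  utils::write.table(flagged, file.path(out_dir, "flagged_overlaps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  null <- NULL
  if (cfg$n_perm > 0 && length(pruned)) {
    null <- tick("permute", function()
      build_null(net, z, scfg, n_perm = cfg$n_perm,
                 seed = stage_seed(cfg$seed, "permute")))
    utils::write.table(data.frame(score = null$scores),
                       file.path(out_dir, "null_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sel <- tick("select", function() select_significant(pruned, null, cfg$alpha))
    pruned <- sel$subnets
    significant <- sel$significant
  } else significant <- list()
  utils::write.table(subnetwork_table(pruned),
                     file.path(out_dir, "subnetworks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  eval_summary <- NULL
  if (length(significant) || length(pruned)) {
    eval_summary <- tick("evaluate", function() {
      use <- if (length(significant)) significant else pruned
      sets <- if (!is.null(gmt)) lapply(gmt, read_gmt)
      cmp <- compare_strategies(z, use, sets = sets, sizes = cfg$sizes,
                                folds = cfg$folds, repeats = cfg$repeats,
                                seed = stage_seed(cfg$seed, "evaluate"))
      utils::write.table(cmp$summary, file.path(out_dir, "fscore_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (nm in names(cmp$results)) {
        r <- cmp$results[[nm]]
        utils::write.table(r$roc, file.path(out_dir, paste0("roc_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      cmp$summary
    })
  }
  manifest <- list(config = unclass(cfg), stages = stages,
                   n_subnetworks = length(pruned),
                   n_significant = length(significant),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("netmark")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fit <- structure(list(call = sys.call(), network = net, z = z,
                        subnetworks = pruned, significant = significant,
                        null = null, norm_report = NULL,
                        removed_hubs = character(0), flagged = flagged,
                        config = unclass(cfg), eval_summary = eval_summary),
                   class = "netmark")
  invisible(fit)
}
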