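#' Two-class expression set
#'
#' Container for a genes x samples expression matrix with a two-class sample
#' labelling. This is the object every stage of the pipeline consumes: rows are
#' genes, columns are samples, and `labels` maps each sample to one of exactly
#' two classes. The first class level (first to appear in the label vector or
#' label file) is treated downstream as the positive class for precision and
#' recall.
#'
#' @param values numeric matrix, genes in rows (rownames required), samples in
#'   columns (colnames required). All values must be finite.
#' @param labels factor or character vector of class labels, either named by
#'   sample id or in column order of `values`. Exactly two classes, each with
#'   at least two samples.
#' @return An object of class `expr_set`: a list with elements `values`
#'   (the matrix) and `labels` (a two-level factor named by sample id).
#' @examples
#' m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' es <- expression_set(m, c("A", "A", "A", "B", "B"))
#' @export
expression_set <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (!all(is.finite(values)))
    stop("all expression values must be finite")
  lab <- labels
  if (is.null(names(lab))) {
    if (length(lab) != ncol(values))
      stop("unnamed `labels` must have one entry per sample column")
    names(lab) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(lab))
  if (length(missing))
    stop("samples without a label: ", paste(missing, collapse = ", "))
  lab <- lab[colnames(values)]
  # preserve first-appearance order of classes: first class = positive class
  lev <- unique(as.character(lab))
  if (length(lev) != 2L)
    stop("exactly two classes required, got ", length(lev))
  lab <- factor(as.character(lab), levels = lev)
  names(lab) <- colnames(values)
  if (any(table(lab) < 2L))
    stop("both classes need >= 2 samples")
  structure(list(values = values, labels = lab), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  tab <- table(x$labels)
  cat("expr_set:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("classes: ", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "  [positive class: ", levels(x$labels)[1], "]\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Read an expression matrix from tab-separated text
#'
#' Expected layout: header row of sample ids, then one row per gene with the
#' gene id in the first column. Written and read files round-trip losslessly.
#'
#' @param expr_path path to the expression TSV.
#' @param labels_path path to a two-column TSV (sample_id, class), no header.
#' @return An [expression_set()].
#' @export
read_expression <- function(expr_path, labels_path) {
  if (!file.exists(expr_path)) stop("expression file not found: ", expr_path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)
  df <- utils::read.delim(expr_path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  lab <- utils::read.delim(labels_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stop("labels file must have two columns (sample_id, class)")
  labels <- lab[[2]]
  names(labels) <- as.character(lab[[1]])
  expression_set(m, labels)
}

#' Write an expression set to tab-separated text
#'
#' @param es an [expression_set()].
#' @param expr_path,labels_path output paths (see [read_expression()] layout).
#' @return Invisibly, `es`.
#' @export
write_expression <- function(es, expr_path, labels_path) {
  stopifnot(inherits(es, "expr_set"))
  df <- data.frame(gene = rownames(es$values), es$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(names(es$labels), as.character(es$labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(es)
}

# split sample indices by class; first element is the positive class
class_index <- function(es) split(seq_len(ncol(es$values)), es$labels)
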