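#' Per-gene Box-Cox normalization
#'
#' Raw microarray-style intensities are usually right-skewed, so each gene row
#' is transformed with its own maximum-likelihood Box-Cox exponent before any
#' correlation or t-statistic is computed. Rows containing non-positive values
#' are shifted by `1 - min(row)` first (the transform requires positive input);
#' the shift is recorded in the report. After transforming, each row is checked
#' for normality with a one-sample Kolmogorov-Smirnov test at `alpha`.
#'
#' Constant rows cannot be transformed: they are returned unchanged, flagged in
#' the report, and excluded from the KS pass set.
#'
#' @param raw an [expression_set()] of raw (untransformed) values.
#' @param alpha significance level of the per-gene KS normality check.
#' @return A list with `expr` (the transformed [expression_set()]) and `report`,
#'   a data.frame with one row per gene: `lambda`, `shift`, `ks_p`, `ks_pass`,
#'   and `constant`.
#' @seealso [ks_normality()], [zscore_expression()]
#' @export
boxcox_transform <- function(raw, alpha = 0.05) {
  stopifnot(inherits(raw, "expr_set"))
  v <- raw$values
  out <- v
  ng <- nrow(v)
  lambda <- rep(NA_real_, ng)
  shift <- numeric(ng)
  ks_p <- rep(NA_real_, ng)
  constant <- logical(ng)
  grid <- seq(-3, 3, by = 0.02)
  for (i in seq_len(ng)) {
    x <- v[i, ]
    if (stats::var(x) == 0) {
      constant[i] <- TRUE
      next
    }
    if (min(x) <= 0) {
      shift[i] <- 1 - min(x)
      x <- x + shift[i]
    }
    bc <- MASS::boxcox(x ~ 1, lambda = grid, plotit = FALSE)
    lam <- bc$x[which.max(bc$y)]
    lambda[i] <- lam
    out[i, ] <- if (abs(lam) < 1e-8) log(x) else (x^lam - 1) / lam
    ks_p[i] <- ks_normality(out[i, ], alpha)$p_value
  }
  report <- data.frame(
    gene = rownames(v),
    lambda = lambda,
    shift = shift,
    ks_p = ks_p,
    ks_pass = !constant & !is.na(ks_p) & ks_p >= alpha,
    constant = constant,
    stringsAsFactors = FALSE
  )
  list(expr = expression_set(out, raw$labels), report = report)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of `values` against a normal distribution whose mean and
#' SD are estimated from the same data. Estimating the parameters from the
#' data biases the plain KS p-value upward (the Lilliefors effect); no
#' correction is applied, so treat the pass flag as a screening device rather
#' than a calibrated test.
#'
#' @param values numeric vector, at least 8 observations.
#' @param alpha significance level in the open interval (0, 1).
#' @return A list with `p_value` and `pass` (`p_value >= alpha`).
#' @export
ks_normality <- function(values, alpha = 0.05) {
  if (length(values) < 8) stop("insufficient data: need >= 8 observations")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be in the open interval (0, 1)")
  p <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value)
  list(p_value = p, pass = p >= alpha)
}

#' Per-gene z-scores
#'
#' Centers and scales each gene row to mean 0 and (sample, n-1 denominator)
#' standard deviation 1 over all samples pooled across both classes. The
#' z-scored matrix feeds the summarized-expression statistic and the edge
#' weighting.
#'
#' @param es an [expression_set()].
#' @return An [expression_set()] of z-scores.
#' @export
zscore_expression <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  v <- es$values
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene row(s): ",
         paste(rownames(v)[sds == 0], collapse = ", "))
  z <- (v - rowMeans(v)) / sds
  # input is an already-validated expr_set; rebuild without revalidation
  structure(list(values = z, labels = es$labels), class = "expr_set")
}
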