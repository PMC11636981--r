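#' @title Count normalization and differential expression
#' @description CPM computation, low-expression filtering, TMM normalization
#'   factors, log2-CPM, voom-style precision weights and moderated-t
#'   differential expression with Benjamini-Hochberg FDR control.
#' @name expression-prep
NULL

#' Expression matrix container
#'
#' A light container for a gene x sample integer count matrix together with
#' its library sizes and TMM normalization factors (initialized to 1).
#'
#' @param counts Numeric matrix, genes in rows, samples in columns; counts
#'   must be non-negative and IDs unique.
#' @return Object of class `expr_matrix` with elements `counts`, `lib_size`,
#'   `norm_factors`.
#' @export
expression_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs")
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(list(
    counts = counts,
    lib_size = colSums(counts),
    norm_factors = stats::setNames(rep(1, ncol(counts)), colnames(counts))
  ), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("library sizes:", paste(signif(range(x$lib_size), 4), collapse = " - "),
      "\n")
  invisible(x)
}

as_expr_matrix <- function(x) {
  if (inherits(x, "expr_matrix")) x else expression_matrix(x)
}

#' Counts per million
#'
#' Library-size-scaled counts; each column sums to exactly 1e6.
#'
#' @param x An [expression_matrix()] or count matrix.
#' @return Matrix of CPM values.
#' @export
compute_cpm <- function(x) {
  x <- as_expr_matrix(x)
  zero <- x$lib_size == 0
  if (any(zero)) {
    stop("sample(s) with zero total count: ",
         paste(names(x$lib_size)[zero], collapse = ", "))
  }
  sweep(x$counts, 2, x$lib_size, "/") * 1e6
}

#' Filter genes with low expression
#'
#' Retains genes with CPM strictly greater than `min_cpm` in at least
#' `min_samples` samples (the "greater than one CPM in three or more
#' libraries" rule at the defaults).  Gene order is preserved; library sizes
#' are kept at their pre-filter values.
#'
#' @param x An [expression_matrix()] or count matrix.
#' @param min_cpm CPM threshold (strict >).
#' @param min_samples Minimum number of samples exceeding the threshold.
#' @return Filtered `expr_matrix`.
#' @export
filter_low_expression <- function(x, min_cpm = 1, min_samples = 3) {
  if (min_cpm <= 0 || min_samples <= 0) stop("thresholds must be > 0")
  x <- as_expr_matrix(x)
  keep <- rowSums(compute_cpm(x) > min_cpm) >= min_samples
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization: per-sample scaling
#' factors from the doubly-trimmed (30% on log-ratios, 5% on average
#' log-expression) precision-weighted mean of gene-wise log ratios against a
#' reference sample (the library whose upper quartile is closest to the mean
#' upper quartile).  Factors have geometric mean 1.
#'
#' @param x An [expression_matrix()] or count matrix.
#' @param trim_m Two-sided trim fraction on M-values.
#' @param trim_a Two-sided trim fraction on A-values.
#' @return Named per-sample factors.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  x <- as_expr_matrix(x)
  if (ncol(x$counts) < 2) stop("TMM needs at least 2 samples")
  f <- edgeR::calcNormFactors(x$counts, lib.size = x$lib_size,
                              method = "TMM", logratioTrim = trim_m,
                              sumTrim = trim_a)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("TMM failed: a sample shares no expressed genes with the reference")
  }
  stats::setNames(f, colnames(x$counts))
}

#' Attach normalization factors
#' @param x An `expr_matrix`.
#' @param factors Per-sample factors (geometric mean 1).
#' @export
set_norm_factors <- function(x, factors) {
  x <- as_expr_matrix(x)
  stopifnot(length(factors) == ncol(x$counts), all(factors > 0))
  x$norm_factors[] <- factors
  x
}

#' Log2-CPM with a prior count
#'
#' value = log2((count + prior) / (lib_size * factor + 2 * prior) * 1e6);
#' finite everywhere and invariant to a common scaling of counts and library
#' sizes up to the prior.
#'
#' @param x An [expression_matrix()] or count matrix.
#' @param factors Normalization factors; defaults to those stored in `x`.
#' @param prior_count Prior added to counts.
#' @return Log2-CPM matrix.
#' @export
log_expression <- function(x, factors = NULL, prior_count = 0.5) {
  x <- as_expr_matrix(x)
  if (is.null(factors)) factors <- x$norm_factors
  eff <- x$lib_size * factors
  log2(sweep(sweep(x$counts + prior_count, 2, eff + 2 * prior_count, "/"),
             2, 1e6, "*"))
}

#' Voom-style precision weights
#'
#' Observation-level weights from the fitted mean-variance trend of
#' log-counts (inverse predicted variance, lowess-smoothed), and per-sample
#' quality weights that down-weight noisy libraries so outlying samples need
#' not be discarded.  Sample weights are rescaled to mean 1.
#'
#' @param x An [expression_matrix()] with normalization factors set.
#' @param design Full-rank design matrix (samples x coefficients).
#' @param method Which weights to return: observation-level, sample-level or
#'   both combined (default).
#' @return List with `observation` (gene x sample matrix), `sample` (named
#'   vector), `combined` (their product) and `logexpr` (the log2-CPM matrix
#'   used by the fit).
#' @export
precision_weights <- function(x, design,
                              method = c("both", "observation", "sample")) {
  method <- match.arg(method)
  x <- as_expr_matrix(x)
  n <- ncol(x$counts)
  p <- ncol(design)
  if (nrow(design) != n) stop("design rows must match samples")
  if (qr(design)$rank < p) stop("design matrix is not full rank")
  if (n - p < 2) stop("fewer than 2 residual degrees of freedom")
  eff <- x$lib_size * x$norm_factors
  v <- limma::voom(x$counts, design, lib.size = eff)
  obs <- v$weights
  dimnames(obs) <- dimnames(x$counts)
  sw <- rep(1, n)
  if (method %in% c("both", "sample")) {
    sw <- limma::arrayWeights(v, design)
    sw <- sw / mean(sw)
  }
  names(sw) <- colnames(x$counts)
  if (method == "sample") obs[] <- 1
  combined <- sweep(obs, 2, sw, "*")
  list(observation = obs, sample = sw, combined = combined, logexpr = v$E)
}

#' Treatment design matrix
#'
#' Cell-means design (no intercept) with one column per treatment, suitable
#' for pairwise treatment contrasts.
#'
#' @param samples Sample table with a `treatment` column.
#' @export
treatment_design <- function(samples) {
  tr <- factor(samples$treatment)
  d <- stats::model.matrix(~ 0 + tr)
  colnames(d) <- levels(tr)
  rownames(d) <- samples$sample
  d
}

#' Fit linear models and moderate with empirical Bayes
#'
#' Per-gene weighted least squares on the design, linear contrasts between
#' treatments, empirical-Bayes shrinkage of the residual variances, and
#' per-contrast Benjamini-Hochberg adjustment.  A gene is flagged DE when
#' its adjusted p-value is <= `fdr` and |log2FC| >= `lfc`.
#'
#' @param logexpr Log2-expression matrix (genes x samples).
#' @param design Design matrix as from [treatment_design()].
#' @param contrasts Character vector of contrasts over design columns, e.g.
#'   `"T01-T02"`.
#' @param weights Optional observation-weight matrix (e.g.
#'   `precision_weights()$combined`).
#' @param fdr Adjusted-p threshold for the DE flag.
#' @param lfc Absolute log2-fold-change threshold for the DE flag.
#' @return Data frame (one row per gene per contrast): `gene`, `contrast`,
#'   `log2fc`, `t`, `p`, `padj`, `de`.
#' @export
fit_and_moderate <- function(logexpr, design, contrasts, weights = NULL,
                             fdr = 0.05, lfc = 1) {
  if (nrow(design) - ncol(design) < 1) {
    stop("zero residual degrees of freedom")
  }
  if (!length(contrasts)) stop("no contrasts given")
  fit <- limma::lmFit(logexpr, design, weights = weights)
  cm <- limma::makeContrasts(contrasts = contrasts, levels = colnames(design))
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm), robust = FALSE)
  out <- lapply(seq_along(contrasts), function(j) {
    p <- fit2$p.value[, j]
    padj <- stats::p.adjust(p, method = "BH")
    l2 <- fit2$coefficients[, j]
    data.frame(
      gene = rownames(logexpr),
      contrast = contrasts[j],
      log2fc = l2,
      t = fit2$t[, j],
      p = p,
      padj = padj,
      de = padj <= fdr & abs(l2) >= lfc,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, out)
}
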