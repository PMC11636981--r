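#' @title Signed-hybrid weighted co-expression network
#' @description Gene selection by variance, signed-hybrid adjacency,
#'   scale-free topology fit, topological overlap, static-cut module
#'   detection with eigengene merging, and module-trait / gene-significance /
#'   module-membership statistics.
#' @name coexpression
NULL

# ordered color palette for module labels; "grey" is reserved for
# unassigned genes
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "skyblue", "saddlebrown", "steelblue", "violet"
)

#' Select the most variable genes
#'
#' Ranks genes by variance of log-expression (ties broken lexicographically
#' by gene ID) and returns the top `n` rows.
#'
#' @param logexpr Log-expression matrix, genes in rows.
#' @param n Number of genes to keep (the network stage conventionally uses
#'   the 2,500 most variable).
#' @return Subset of `logexpr`, in rank order.
#' @export
select_top_variable <- function(logexpr, n = 2500) {
  if (n <= 0) stop("n must be > 0")
  if (n > nrow(logexpr)) {
    warning("n exceeds the number of genes; returning all")
    n <- nrow(logexpr)
  }
  v <- apply(logexpr, 1, stats::var)
  ord <- order(-v, rownames(logexpr))
  logexpr[ord[seq_len(n)], , drop = FALSE]
}

#' Signed-hybrid adjacency
#'
#' a_ij = max(cor(i, j), 0)^beta off the diagonal, a_ii = 1: positive
#' co-expression is raised to the soft-thresholding power, negative
#' correlations are zeroed.
#'
#' @param logexpr Log-expression matrix (genes x samples), >= 3 samples.
#' @param beta Soft-thresholding power, >= 1.
#' @return Symmetric adjacency matrix with entries in [0, 1].
#' @export
signed_hybrid_adjacency <- function(logexpr, beta = 8) {
  if (beta < 1) stop("beta must be >= 1")
  if (ncol(logexpr) < 3) stop("need at least 3 samples")
  sds <- apply(logexpr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(rownames(logexpr)[sds == 0], collapse = ", "))
  }
  a <- pmax(stats::cor(t(logexpr)), 0)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit
#'
#' Connectivity k_i (row sums of adjacency excluding self) is binned into 10
#' equal-width bins on the log10 scale; the log10 frequency per bin is
#' regressed on the log10 mean connectivity.  The signed R-squared is the
#' model R-squared times the sign of the negative slope, so networks whose
#' degree distribution decays like a power law score near +1.
#'
#' @param adjacency Adjacency matrix (diagonal ignored).
#' @param n_bins Number of connectivity bins.
#' @return List with `r2` (signed), `slope`, `mean_k`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  if (nrow(adjacency) < 20) stop("need at least 20 genes")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  k <- k[k > 0]
  if (length(k) < n_bins || stats::sd(k) == 0) {
    stop("degenerate connectivity distribution: binning impossible")
  }
  lk <- log10(k)
  breaks <- seq(min(lk), max(lk), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(lk, breaks = breaks)
  counts <- tabulate(bin, nbins = n_bins)
  keep <- counts > 0
  p_k <- counts[keep] / length(k)
  k_bar <- tapply(k, bin, mean)[keep]
  if (sum(keep) < 3) stop("degenerate connectivity distribution")
  fit <- stats::lm(log10(p_k) ~ log10(k_bar))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r2 = r2 * sign(-slope), slope = slope, mean_k = mean(k))
}

#' Choose the soft-thresholding power
#'
#' Computes the signed scale-free fit index for each candidate power and
#' returns the smallest power whose signed R-squared reaches `r2_cut`, or
#' the power with the maximal index if none does.
#'
#' @param logexpr Log-expression matrix of the network genes.
#' @param candidate_betas Powers to evaluate.
#' @param r2_cut Target signed R-squared.
#' @return List with `beta` and `fit_table` (beta, r2, slope, mean_k).
#' @export
pick_soft_threshold <- function(logexpr, candidate_betas = 1:20,
                                r2_cut = 0.8) {
  if (!length(candidate_betas)) stop("no candidate powers")
  cpos <- pmax(stats::cor(t(logexpr)), 0)
  rows <- lapply(candidate_betas, function(b) {
    a <- cpos^b
    diag(a) <- 1
    fit <- tryCatch(scale_free_fit(a),
                    error = function(e) list(r2 = NA_real_, slope = NA_real_,
                                             mean_k = NA_real_))
    data.frame(beta = b, r2 = fit$r2, slope = fit$slope, mean_k = fit$mean_k)
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$r2) & tab$r2 >= r2_cut)
  beta <- if (length(ok)) tab$beta[ok[1]] else tab$beta[which.max(tab$r2)]
  list(beta = beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) where
#' l_ij = sum_u a_iu a_uj over u != i, j and k is connectivity excluding
#' self; TOM_ii = 1.  Measures how much two genes share neighbors in
#' addition to their direct connection.
#'
#' @param adjacency Signed-hybrid adjacency (diagonal 1).
#' @return Symmetric TOM matrix, entries in [0, 1], diagonal 1.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  n <- nrow(a)
  kmin <- pmin(matrix(k, n, n), matrix(k, n, n, byrow = TRUE))
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity 1 - TOM
#' with a static branch cut; clusters smaller than `min_module_size` are
#' assigned to "grey" (unassigned).  Module labels are colors assigned in
#' decreasing size order from a fixed palette so reruns are comparable.
#'
#' @param tom TOM similarity matrix.
#' @param min_module_size Smallest retained module (>= 2).
#' @param cut_height Static cut height on the dissimilarity dendrogram.
#' @return Object of class `module_partition`: `labels` (named gene ->
#'   module), `sizes`, `tree` (the hclust object), `merge_history`.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  raw <- stats::cutree(tree, h = cut_height)
  genes <- rownames(tom)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  # deterministic label order: decreasing size, ties by first member gene
  first_gene <- sapply(big, function(cl) sort(genes[raw == as.integer(cl)])[1])
  ord <- big[order(-as.integer(sizes[big]), first_gene)]
  labels <- rep("grey", length(genes))
  names(labels) <- genes
  for (i in seq_along(ord)) {
    col <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i]
           else paste0("module", i)
    labels[raw == as.integer(ord[i])] <- col
  }
  structure(list(
    labels = labels,
    sizes = sort(table(labels), decreasing = TRUE),
    tree = tree,
    merge_history = data.frame(from = character(), to = character(),
                               stringsAsFactors = FALSE)
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", length(x$labels), "genes,",
      sum(names(x$sizes) != "grey"), "modules\n")
  print(x$sizes)
  invisible(x)
}

#' Module eigengenes
#'
#' The first principal component of each module's gene-standardized
#' expression submatrix: each member gene is z-scored across samples and the
#' leading right singular vector over samples is taken, sign-aligned so its
#' correlation with the module's mean expression profile is non-negative,
#' and unit-normalized.  Zero-variance genes are dropped from the SVD with a
#' warning.
#'
#' @param logexpr Log-expression matrix of the network genes.
#' @param partition A `module_partition`.
#' @return Matrix, modules (rows, named `ME<color>`) x samples; each row has
#'   unit norm.
#' @export
module_eigengenes <- function(logexpr, partition) {
  mods <- setdiff(names(partition$sizes), "grey")
  if (!length(mods)) stop("no modules to summarize")
  me <- matrix(0, length(mods), ncol(logexpr),
               dimnames = list(paste0("ME", mods), colnames(logexpr)))
  for (i in seq_along(mods)) {
    genes <- names(partition$labels)[partition$labels == mods[i]]
    sub <- logexpr[genes, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0)) {
      warning("module ", mods[i], ": dropped ", sum(sds == 0),
              " zero-variance gene(s) from the eigengene SVD")
      sub <- sub[sds > 0, , drop = FALSE]
    }
    if (nrow(sub) < 2) stop("module ", mods[i], " has fewer than 2 usable genes")
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (stats::cor(v, colMeans(sub)) < 0) v <- -v
    me[i, ] <- v
  }
  me
}

#' Merge modules with correlated eigengenes
#'
#' Single-linkage clustering on 1 - cor(ME); modules whose eigengene
#' correlation is >= 1 - `merge_height` end up merged (the chain behavior of
#' single linkage is intentional and documented).  Merged groups take the
#' label of the largest member; eigengenes are recomputed.
#'
#' @param partition A `module_partition`.
#' @param mes Eigengene matrix from [module_eigengenes()].
#' @param logexpr Log-expression matrix (for recomputing eigengenes).
#' @param merge_height Dissimilarity cut; default 0.25 merges modules with
#'   eigengene correlation >= 0.75.
#' @return List with updated `partition` and `mes`; the merge history is
#'   recorded on the partition.
#' @export
merge_modules <- function(partition, mes, logexpr, merge_height = 0.25) {
  mods <- sub("^ME", "", rownames(mes))
  if (length(mods) < 2) {
    return(list(partition = partition, mes = mes))
  }
  d <- stats::as.dist(1 - stats::cor(t(mes)))
  tree <- stats::hclust(d, method = "single")
  grp <- stats::cutree(tree, h = merge_height)
  labels <- partition$labels
  history <- partition$merge_history
  for (g in unique(grp)) {
    members <- mods[grp == g]
    if (length(members) < 2) next
    target <- members[which.max(partition$sizes[members])]
    for (m in setdiff(members, target)) {
      labels[labels == m] <- target
      history <- rbind(history,
                       data.frame(from = m, to = target,
                                  stringsAsFactors = FALSE))
    }
  }
  out <- partition
  out$labels <- labels
  out$sizes <- sort(table(labels), decreasing = TRUE)
  out$merge_history <- history
  new_mes <- module_eigengenes(logexpr, out)
  list(partition = out, mes = new_mes)
}

# correlation p-values via the Student-t transform, n observations
cor_pvalue <- function(r, n) {
  r2 <- pmin(r^2, 1 - 1e-15)
  t <- abs(r) * sqrt((n - 2) / (1 - r2))
  pmax(2 * stats::pt(t, df = n - 2, lower.tail = FALSE),
       .Machine$double.xmin)
}

#' Module-trait correlations
#'
#' Pearson correlation of each module eigengene with each (numeric, binary
#' coded) condition variable, with asymptotic Student-t p-values.
#'
#' @param mes Eigengene matrix (modules x samples).
#' @param conditions Numeric matrix or data frame, samples x condition
#'   variables.
#' @return List with `cor` and `p` (module x condition matrices).
#' @export
module_trait_correlation <- function(mes, conditions) {
  conditions <- as.matrix(conditions)
  if (any(apply(conditions, 2, stats::sd) == 0)) {
    stop("constant condition variable")
  }
  r <- stats::cor(t(mes), conditions)
  list(cor = r, p = cor_pvalue(r, ncol(mes)))
}

#' Gene significance for a condition
#'
#' GS is the Pearson correlation between each gene's expression profile and
#' the binary condition variable, with asymptotic p-values.
#'
#' @param logexpr Log-expression matrix of the network genes.
#' @param condition Numeric per-sample condition vector (e.g. from
#'   [encode_condition()]).
#' @return Data frame `gene`, `gs`, `p`.
#' @export
gene_significance <- function(logexpr, condition) {
  if (stats::sd(condition) == 0) stop("constant condition variable")
  r <- as.vector(stats::cor(t(logexpr), condition))
  data.frame(gene = rownames(logexpr), gs = r,
             p = cor_pvalue(r, ncol(logexpr)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Module membership
#'
#' MM is the Pearson correlation between each gene's profile and each module
#' eigengene.
#'
#' @param logexpr Log-expression matrix of the network genes.
#' @param mes Eigengene matrix (modules x samples).
#' @return Gene x module matrix of correlations.
#' @export
module_membership <- function(logexpr, mes) {
  stats::cor(t(logexpr), t(mes))
}
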