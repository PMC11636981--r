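#' @title Condition-associated candidate genes
#' @description Binary condition coding, ranking of modules by average gene
#'   significance, and the GS/MM/DE triple filter that selects genes most
#'   associated with sulfide or oxygen limitation.
#' @name condition-response
NULL

#' Encode a substrate condition as a binary vector
#'
#' Treatments replete in the substrate are coded 1; limiting or absent are
#' coded 0.
#'
#' @param samples Sample table with per-sample substrate state columns.
#' @param condition One of "sulfide", "oxygen", "nitrate", "hydrogen".
#' @return Named numeric vector (one value per sample).
#' @export
encode_condition <- function(samples, condition) {
  condition <- match.arg(condition, SUBSTRATES)
  states <- samples[[condition]]
  bad <- !states %in% c("replete", "limiting", "absent")
  if (any(bad)) {
    stop("unknown substrate state(s): ",
         paste(unique(states[bad]), collapse = ", "),
         " (allowed: replete, limiting, absent)")
  }
  v <- as.numeric(states == "replete")
  if (length(unique(v)) < 2) {
    stop("condition '", condition, "' is constant across samples")
  }
  stats::setNames(v, samples$sample)
}

#' Rank modules by average gene significance
#'
#' Modules ordered by the mean |GS| of their member genes for the given
#' condition; "grey" (unassigned) is excluded.  The top `k` (conventionally
#' two) are the condition's most significant modules.
#'
#' @param gs Data frame from [gene_significance()].
#' @param partition A `module_partition`.
#' @param k Number of top modules to return.
#' @return Data frame `module`, `mean_abs_gs`, in rank order.
#' @export
rank_modules_by_gs <- function(gs, partition, k = 2) {
  labels <- partition$labels[gs$gene]
  keep <- labels != "grey"
  means <- tapply(abs(gs$gs[keep]), labels[keep], mean)
  out <- data.frame(module = names(means), mean_abs_gs = as.vector(means),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_gs, out$module), , drop = FALSE]
  rownames(out) <- NULL
  if (k > nrow(out)) {
    warning("fewer than ", k, " modules available; returning all")
    k <- nrow(out)
  }
  out[seq_len(k), , drop = FALSE]
}

#' Select condition-associated candidate genes
#'
#' The triple filter: genes in the given modules whose |GS| is strictly
#' greater than `gs_min` with GS p-value <= `p_max`, whose own-module |MM|
#' is strictly greater than `mm_min`, and which are significantly DE
#' (adjusted p <= `fdr`) in at least one of the named pairwise comparisons.
#' The mean and SD of log2FC are taken over the comparisons that
#' individually reached significance.  Comparisons are coded
#' replete-minus-limiting, so a negative mean log2FC means expression
#' increases under limitation.
#'
#' @param gs Data frame from [gene_significance()] for the condition.
#' @param mm Gene x module MM matrix from [module_membership()].
#' @param de DE table from [fit_and_moderate()].
#' @param partition A `module_partition`.
#' @param modules Module labels to search (e.g. from
#'   [rank_modules_by_gs()]).
#' @param comparisons DE contrast names relevant to the condition.
#' @param gs_min,p_max,mm_min Thresholds (|GS| > 0.2, p <= 0.05, |MM| > 0.8
#'   by default; comparators strict as written).
#' @param fdr Adjusted-p threshold for a comparison to count as significant.
#' @return Data frame `gene`, `module`, `gs`, `gs_p`, `mm`,
#'   `mean_log2fc`, `sd_log2fc`, `n_significant`, `direction`.
#' @export
select_candidates <- function(gs, mm, de, partition, modules, comparisons,
                              gs_min = 0.2, p_max = 0.05, mm_min = 0.8,
                              fdr = 0.05) {
  if (!length(comparisons)) stop("comparisons must name at least one contrast")
  labels <- partition$labels
  cand <- gs$gene[labels[gs$gene] %in% modules]
  gs_row <- gs[match(cand, gs$gene), ]
  own_mm <- mm[cbind(match(cand, rownames(mm)),
                     match(paste0("ME", labels[cand]), colnames(mm)))]
  pass <- abs(gs_row$gs) > gs_min & gs_row$p <= p_max & abs(own_mm) > mm_min
  cand <- cand[pass]
  own_mm <- own_mm[pass]
  if (!length(cand)) {
    return(data.frame(gene = character(), module = character(),
                      gs = numeric(), gs_p = numeric(), mm = numeric(),
                      mean_log2fc = numeric(), sd_log2fc = numeric(),
                      n_significant = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  de_rel <- de[de$contrast %in% comparisons & de$gene %in% cand &
                 de$padj <= fdr, , drop = FALSE]
  rows <- lapply(cand, function(g) {
    dg <- de_rel[de_rel$gene == g, , drop = FALSE]
    if (nrow(dg) == 0) return(NULL)
    m <- mean(dg$log2fc)
    data.frame(
      gene = g,
      module = unname(labels[g]),
      gs = gs$gs[gs$gene == g],
      gs_p = gs$p[gs$gene == g],
      mm = own_mm[match(g, cand)],
      mean_log2fc = m,
      sd_log2fc = if (nrow(dg) > 1) stats::sd(dg$log2fc) else 0,
      n_significant = nrow(dg),
      direction = if (m < 0) "increase_under_limitation"
                  else "decrease_under_limitation",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), module = character(),
                      gs = numeric(), gs_p = numeric(), mm = numeric(),
                      mean_log2fc = numeric(), sd_log2fc = numeric(),
                      n_significant = integer(), direction = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
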