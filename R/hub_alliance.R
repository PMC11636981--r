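#' @title Hub scoring and first-neighbor alliances
#' @description Thresholds the weighted network into a simple graph, scores
#'   hubs by maximal clique centrality, extracts first-neighbor sets of the
#'   pathway seed gene sets, and computes their intersection (alliance)
#'   structure.
#' @name hub-alliance
NULL

#' Threshold the co-expression network into a graph
#'
#' Keeps edges whose weight (TOM by default) is strictly greater than
#' `min_weight`; optionally keeps only edges that are among either
#' endpoint's `top_k` strongest survivors; then iteratively removes nodes
#' with degree <= `min_degree` (strict ">", applied to a fixed point, so a
#' bare triangle is removed at the defaults).
#'
#' @param weights Square symmetric weight matrix (TOM or adjacency) with
#'   gene names.
#' @param min_weight Edge-weight filter (strict >).
#' @param min_degree Degree filter (nodes must have degree strictly greater).
#' @param top_k Optional per-node nearest-neighbor cap; `NULL` (default)
#'   disables the step.
#' @param weight_source Provenance label ("tom" or "adjacency").
#' @return An igraph graph with edge attribute `weight` and graph attributes
#'   recording the filters; empty graphs are returned with a warning.
#' @export
threshold_network <- function(weights, min_weight = 0.05, min_degree = 2,
                              top_k = NULL, weight_source = "tom") {
  stopifnot(nrow(weights) == ncol(weights))
  genes <- rownames(weights)
  w <- weights
  w[lower.tri(w, diag = TRUE)] <- 0
  idx <- which(w > min_weight, arr.ind = TRUE)
  edges <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                      weight = w[idx], stringsAsFactors = FALSE)
  if (!is.null(top_k) && nrow(edges) > 0) {
    long <- rbind(data.frame(node = edges$from, id = seq_len(nrow(edges)),
                             weight = edges$weight),
                  data.frame(node = edges$to, id = seq_len(nrow(edges)),
                             weight = edges$weight))
    keep_ids <- unlist(lapply(split(long, long$node), function(d) {
      d$id[order(-d$weight)][seq_len(min(top_k, nrow(d)))]
    }))
    edges <- edges[sort(unique(keep_ids)), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genes)
  # iterative strict degree filter to a fixed point
  repeat {
    drop <- igraph::V(g)[igraph::degree(g) <= min_degree]
    if (!length(drop)) break
    g <- igraph::delete_vertices(g, drop)
  }
  g$weight_source <- weight_source
  g$min_weight <- min_weight
  g$min_degree <- min_degree
  g$top_k <- if (is.null(top_k)) NA_integer_ else top_k
  if (igraph::vcount(g) == 0) {
    warning("thresholding left an empty graph")
  }
  g
}

#' Maximal clique centrality
#'
#' MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!, with
#' maximal cliques enumerated exactly (Bron-Kerbosch with pivoting).  A node
#' whose neighborhood contains no edges scores its degree (each incident
#' edge is a maximal 2-clique); an isolated node scores 0.
#'
#' @param graph Simple undirected igraph graph.
#' @return Named numeric vector of MCC scores.
#' @export
mcc_scores <- function(graph) {
  n <- igraph::vcount(graph)
  scores <- stats::setNames(numeric(n), igraph::V(graph)$name)
  if (n == 0) return(scores)
  cliques <- igraph::max_cliques(graph, min = 2)
  for (cl in cliques) {
    members <- igraph::V(graph)$name[as.integer(cl)]
    scores[members] <- scores[members] + factorial(length(cl) - 1)
  }
  scores
}

#' Rank hub genes
#'
#' Orders nodes by decreasing MCC, breaking ties by decreasing degree and
#' then lexicographically by gene ID.
#'
#' @param graph Thresholded graph.
#' @param top_n Number of hubs to return.
#' @param scores Precomputed MCC scores; computed if missing.
#' @return Data frame `gene`, `mcc`, `degree`, in rank order.
#' @export
rank_hubs <- function(graph, top_n = 10, scores = NULL) {
  if (is.null(scores)) scores <- mcc_scores(graph)
  deg <- igraph::degree(graph)[names(scores)]
  ord <- order(-scores, -deg, names(scores))
  if (top_n > length(ord)) {
    warning("top_n exceeds node count; returning all nodes")
    top_n <- length(ord)
  }
  sel <- ord[seq_len(top_n)]
  data.frame(gene = names(scores)[sel], mcc = unname(scores[sel]),
             degree = unname(deg[sel]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' First neighbors of a seed gene set
#'
#' Union of the direct neighbors of the seed genes in the thresholded graph,
#' excluding the seed-set members themselves.  Seeds absent from the graph
#' are skipped with a warning.
#'
#' @param graph Thresholded graph.
#' @param seed_set Character vector of seed gene IDs.
#' @return Character vector of neighbor genes (possibly empty).
#' @export
first_neighbors <- function(graph, seed_set) {
  present <- intersect(seed_set, igraph::V(graph)$name)
  if (length(present) < length(seed_set)) {
    warning(length(seed_set) - length(present),
            " seed gene(s) absent from the graph")
  }
  if (!length(present)) return(character())
  nb <- unique(unlist(lapply(
    igraph::adjacent_vertices(graph, present),
    function(v) igraph::V(graph)$name[as.integer(v)]
  )))
  sort(setdiff(nb, seed_set))
}

#' Alliance (set-intersection) structure of neighbor sets
#'
#' Builds the binary gene x set membership matrix over the named neighbor
#' sets, all exclusive intersection cardinalities (the UpSet decomposition),
#' pairwise shared counts and Jaccard indices, and, given a gene-category
#' map, per-category counts of neighbors shared with each set.
#'
#' @param neighbor_sets Named list of character vectors.
#' @param category_map Optional data frame `gene`, `category` (a gene may
#'   appear with several categories); genes unknown to the sets are ignored
#'   and counted.
#' @return Object of class `alliance_result`: `membership`, `intersections`
#'   (pattern + count), `shared` and `jaccard` (set x set matrices),
#'   `category_counts`, `n_unknown_category_genes`.
#' @export
alliance_matrix <- function(neighbor_sets, category_map = NULL) {
  stopifnot(is.list(neighbor_sets), !is.null(names(neighbor_sets)))
  sets <- names(neighbor_sets)
  universe <- sort(unique(unlist(neighbor_sets)))
  membership <- sapply(neighbor_sets, function(s) as.integer(universe %in% s))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, sets))

  pattern <- apply(membership, 1, paste, collapse = "")
  pat_counts <- table(pattern)
  inter <- data.frame(
    pattern = names(pat_counts),
    count = as.integer(pat_counts),
    stringsAsFactors = FALSE
  )
  inter$sets <- vapply(inter$pattern, function(p) {
    paste(sets[strsplit(p, "")[[1]] == "1"], collapse = "&")
  }, character(1))

  ns <- length(sets)
  shared <- matrix(0L, ns, ns, dimnames = list(sets, sets))
  jaccard <- matrix(0, ns, ns, dimnames = list(sets, sets))
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      a <- neighbor_sets[[i]]; b <- neighbor_sets[[j]]
      shared[i, j] <- length(intersect(a, b))
      u <- length(union(a, b))
      jaccard[i, j] <- if (u == 0) 0 else shared[i, j] / u
    }
  }

  cat_counts <- NULL
  n_unknown <- 0L
  if (!is.null(category_map)) {
    stopifnot(all(c("gene", "category") %in% names(category_map)))
    known <- category_map$gene %in% universe
    n_unknown <- sum(!known)
    cm <- category_map[known, , drop = FALSE]
    cats <- sort(unique(cm$category))
    cat_counts <- matrix(0L, length(cats), ns, dimnames = list(cats, sets))
    for (cc in cats) {
      g <- cm$gene[cm$category == cc]
      for (s in sets) {
        cat_counts[cc, s] <- length(intersect(g, neighbor_sets[[s]]))
      }
    }
  }

  structure(list(
    seed_sets = sets,
    membership = membership,
    intersections = inter[, c("sets", "pattern", "count")],
    shared = shared,
    jaccard = jaccard,
    category_counts = cat_counts,
    n_unknown_category_genes = n_unknown
  ), class = "alliance_result")
}

#' @export
print.alliance_result <- function(x, ...) {
  cat("alliance_result over sets:", paste(x$seed_sets, collapse = ", "), "\n")
  cat("genes in union:", nrow(x$membership), "\n")
  print(x$shared)
  invisible(x)
}
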