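#' Run the full analysis pipeline on synthetic data
#'
#' Chains every stage end to end: simulate the design and counts, filter and
#' TMM-normalize, compute precision weights and pairwise differential
#' expression, build the signed-hybrid network on the most variable genes,
#' detect and merge modules, compute eigengenes and GS/MM statistics,
#' threshold the network, score hubs, extract first neighbors of the two
#' pathway seed sets and their alliance structure, and select
#' condition-associated candidate genes for each configured condition.
#'
#' @param config A [simulation_config()]; its `rng_seed` drives all
#'   randomness.
#' @param beta Soft-thresholding power (8 by default); set to `NULL` to pick
#'   it from the scale-free fit.
#' @param n_top_variable Genes entering the network (capped at the number of
#'   filtered genes).
#' @param min_weight,min_degree Network thresholding filters.
#' @param min_module_size,cut_height,merge_height Module detection and
#'   merging parameters.
#' @return List with every intermediate product plus a `report`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         beta = 8,
                         n_top_variable = 2500,
                         min_weight = 0.05, min_degree = 2,
                         min_module_size = 30, cut_height = 0.99,
                         merge_height = 0.25) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  design <- simulate_design(config)
  sim <- simulate_module_counts(config, design)
  em <- sim$em
  truth <- sim$truth
  timings["simulate"] <- tic() - t0

  t1 <- tic()
  em_f <- filter_low_expression(em)
  em_f <- set_norm_factors(em_f, tmm_factors(em_f))
  dm <- treatment_design(design)
  pw <- precision_weights(em_f, dm)
  logexpr <- log_expression(em_f)
  contrasts <- unlist(config$comparisons, use.names = FALSE)
  de <- fit_and_moderate(logexpr, dm, contrasts, weights = pw$combined)
  timings["expression"] <- tic() - t1

  t2 <- tic()
  net_expr <- select_top_variable(logexpr,
                                  min(n_top_variable, nrow(logexpr)))
  if (is.null(beta)) {
    picked <- pick_soft_threshold(net_expr)
    beta <- picked$beta
  } else {
    picked <- NULL
  }
  adj <- signed_hybrid_adjacency(net_expr, beta)
  tom <- topological_overlap(adj)
  part <- detect_modules(tom, min_module_size, cut_height)
  mes <- module_eigengenes(net_expr, part)
  merged <- merge_modules(part, mes, net_expr, merge_height)
  part <- merged$partition
  mes <- merged$mes
  mm <- module_membership(net_expr, mes)
  timings["network"] <- tic() - t2

  t3 <- tic()
  graph <- threshold_network(tom, min_weight, min_degree)
  mcc <- mcc_scores(graph)
  hubs <- rank_hubs(graph, top_n = min(20, igraph::vcount(graph)),
                    scores = mcc)
  neighbors <- lapply(config$seed_gene_sets,
                      function(s) suppressWarnings(first_neighbors(graph, s)))
  alliance <- if (length(neighbors)) alliance_matrix(neighbors) else NULL
  timings["hubs"] <- tic() - t3

  t4 <- tic()
  conditions <- names(config$comparisons)
  gs <- list(); top_modules <- list(); candidates <- list()
  cond_mat <- sapply(conditions, function(cn) encode_condition(design, cn))
  trait <- module_trait_correlation(mes, cond_mat)
  for (cn in conditions) {
    gs[[cn]] <- gene_significance(net_expr, cond_mat[, cn])
    top_modules[[cn]] <- rank_modules_by_gs(gs[[cn]], part, k = 2)
    candidates[[cn]] <- select_candidates(
      gs[[cn]], mm, de, part, top_modules[[cn]]$module,
      config$comparisons[[cn]]
    )
  }
  timings["condition"] <- tic() - t4

  report <- run_report(
    config, config$rng_seed, timings = timings,
    notes = c("empirical-Bayes moderation uses standard moments estimation (robust variant not applied)",
              "network correlations computed on unweighted log-expression")
  )
  list(design = design, em = em, truth = truth, em_filtered = em_f,
       logexpr = logexpr, weights = pw, de = de, net_expr = net_expr,
       beta = beta, soft_threshold = picked, adjacency = adj, tom = tom,
       partition = part, eigengenes = mes, module_membership = mm,
       graph = graph, mcc = mcc, hubs = hubs, neighbors = neighbors,
       alliance = alliance, module_trait = trait, gene_significance = gs,
       top_modules = top_modules, candidates = candidates, report = report)
}
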