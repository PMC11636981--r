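named_mat <- function(m) {
  dimnames(m) <- list(sprintf("g%02d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  m
}

test_that("top-variable selection ranks by variance with lexicographic ties", {
  pattern <- seq(-1, 1, length.out = 10)
  m <- named_mat(outer(10:1, pattern))   # exactly known, descending variances
  expect_identical(rownames(select_top_variable(m, 10)), rownames(m))
  expect_identical(rownames(select_top_variable(m, 3)),
                   c("g01", "g02", "g03"))
  # exact variance tie between g05 and g06: lexicographic order breaks it
  m_tie <- m
  m_tie[6, ] <- -m[5, ]
  expect_identical(rownames(select_top_variable(m_tie, 6))[5:6],
                   c("g05", "g06"))
  # a constant gene is never selected before any varying gene
  m2 <- named_mat(rbind(matrix(rnorm(30), 3, 10), 0))
  expect_false("g04" %in% rownames(select_top_variable(m2, 3)))
  expect_error(select_top_variable(m, 0), "n must be")
  expect_warning(sel <- select_top_variable(m, 99), "exceeds")
  expect_equal(nrow(sel), 10)
})

test_that("signed-hybrid adjacency powers positive correlations and zeroes negatives", {
  s <- seq_len(10)
  m <- named_mat(rbind(s, s, rev(s), s + rnorm(10, 0, 3)))
  a <- signed_hybrid_adjacency(m, beta = 8)
  expect_equal(a["g01", "g02"], 1)          # cor 1
  expect_equal(a["g01", "g03"], 0)          # cor -1, zeroed
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(a, t(a))
  expect_equal(diag(a), setNames(rep(1, 4), rownames(m)))
  # cor 0.5 at beta 8 gives 0.5^8 exactly
  r <- 0.5
  expect_equal(max(pmax(r, 0)^8), 0.00390625)
  # zero-variance gene named in the error
  m2 <- named_mat(rbind(s, rep(1, 10)))
  expect_error(signed_hybrid_adjacency(m2, 8), "g02")
  # raising beta weakly decreases every off-diagonal entry
  a6 <- signed_hybrid_adjacency(m, beta = 6)
  expect_true(all(a - a6 <= 1e-12))
})

test_that("scale-free fit scores power-law degree sequences highly", {
  set.seed(31)
  ba <- igraph::sample_pa(800, m = 2, directed = FALSE)
  a <- as.matrix(igraph::as_adjacency_matrix(ba)); diag(a) <- 1
  fit_ba <- scale_free_fit(a)
  expect_gt(fit_ba$r2, 0.9)
  expect_lt(fit_ba$slope, 0)

  er <- igraph::sample_gnp(800, 0.05)
  a2 <- as.matrix(igraph::as_adjacency_matrix(er)); diag(a2) <- 1
  expect_lt(scale_free_fit(a2)$r2, fit_ba$r2)

  # equal-degree graph: degenerate binning is an error
  cg <- matrix(1, 30, 30)
  expect_error(scale_free_fit(cg), "degenerate")
})

test_that("soft-threshold choice is the smallest power meeting the fit cut", {
  res <- default_run()
  sub <- res$net_expr[1:150, ]
  pick <- pick_soft_threshold(sub, candidate_betas = c(2, 4, 6, 8, 10),
                              r2_cut = 0.8)
  tab <- pick$fit_table
  ok <- which(!is.na(tab$r2) & tab$r2 >= 0.8)
  if (length(ok)) {
    expect_equal(pick$beta, tab$beta[ok[1]])
  } else {
    expect_equal(pick$beta, tab$beta[which.max(tab$r2)])
  }
  # r2_cut of 0 returns the smallest candidate
  pick0 <- pick_soft_threshold(sub, candidate_betas = c(3, 5, 9), r2_cut = 0)
  expect_equal(pick0$beta, 3)
  # the per-beta rows agree with scale_free_fit called directly
  a6 <- signed_hybrid_adjacency(sub, 6)
  direct <- scale_free_fit(a6)
  row6 <- tab[tab$beta == 6, ]
  expect_equal(row6$r2, direct$r2, tolerance = 1e-12)
})

test_that("topological overlap matches the brute-force definition", {
  # isolated pair with a = 1: TOM exactly 1
  a <- diag(2); a[1, 2] <- a[2, 1] <- 1
  dimnames(a) <- list(c("x", "y"), c("x", "y"))
  expect_equal(topological_overlap(a)["x", "y"], 1)
  # no direct edge, no shared neighbors: TOM 0
  b <- diag(4)
  b[1, 2] <- b[2, 1] <- 1; b[3, 4] <- b[4, 3] <- 1
  dimnames(b) <- list(letters[1:4], letters[1:4])
  expect_equal(topological_overlap(b)["a", "c"], 0)
  # random instances vs the triple-loop oracle
  for (seed in 1:5) {
    adj <- random_adjacency(15, seed)
    expect_lt(max(abs(topological_overlap(adj) - tom_oracle(adj))), 1e-12)
  }
})

test_that("module detection separates planted blocks and labels small clusters grey", {
  # two perfect blocks
  tom <- matrix(0.01, 20, 20)
  tom[1:10, 1:10] <- 0.9
  tom[11:20, 11:20] <- 0.9
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:20), sprintf("g%02d", 1:20))
  part <- detect_modules(tom, min_module_size = 5, cut_height = 0.5)
  expect_equal(sum(names(part$sizes) != "grey"), 2)
  expect_equal(unname(part$sizes[names(part$sizes) != "grey"]),
               c(10, 10), ignore_attr = TRUE)
  expect_false("grey" %in% part$labels)
  # identical genes collapse to one module
  tom1 <- matrix(1, 12, 12)
  dimnames(tom1) <- list(sprintf("g%02d", 1:12), sprintf("g%02d", 1:12))
  part1 <- detect_modules(tom1, min_module_size = 5)
  expect_equal(length(unique(part1$labels)), 1)
  expect_error(detect_modules(tom1, min_module_size = 1), "min_module_size")
})

test_that("planted modules are recovered at high adjusted Rand index", {
  res <- default_run()
  truth <- res$truth$gene_module[rownames(res$net_expr)]
  expect_gte(adjusted_rand(truth, res$partition$labels), 0.9)
  # determinism: rerunning the network stage reproduces the partition
  part2 <- detect_modules(res$tom)
  merged2 <- merge_modules(part2, module_eigengenes(res$net_expr, part2),
                           res$net_expr)
  expect_identical(merged2$partition$labels, res$partition$labels)
})

test_that("eigengenes are unit-norm leading principal components", {
  res <- default_run()
  mes <- res$eigengenes
  expect_equal(apply(mes, 1, function(v) sqrt(sum(v^2))),
               setNames(rep(1, nrow(mes)), rownames(mes)), tolerance = 1e-12)
  # cross-check one module against prcomp
  mod <- sub("^ME", "", rownames(mes)[1])
  genes <- names(res$partition$labels)[res$partition$labels == mod]
  z <- t(scale(t(res$net_expr[genes, ])))
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)$x[, 1]
  pc <- pc / sqrt(sum(pc^2))
  agreement <- abs(cor(pc, mes[1, ]))
  expect_gt(agreement, 1 - 1e-10)
  # a module of identical genes yields the standardized common profile
  prof <- sin(seq_len(20))
  m <- named_mat(matrix(rep(prof, each = 4), 4, 20))
  part <- structure(list(labels = setNames(rep("turquoise", 4), rownames(m)),
                         sizes = table(rep("turquoise", 4))),
                    class = "module_partition")
  me1 <- module_eigengenes(m, part)
  zprof <- scale(prof)[, 1]; zprof <- zprof / sqrt(sum(zprof^2))
  expect_equal(abs(as.vector(me1)), abs(zprof), tolerance = 1e-10)
  expect_gte(cor(as.vector(me1), prof), 0)
  # flipping all gene signs leaves the mean-alignment convention consistent
  me2 <- module_eigengenes(-m, part)
  expect_gte(cor(as.vector(me2), colMeans(-m)), 0)
})

test_that("eigengene-correlated modules merge, with single-linkage chaining", {
  set.seed(21)
  n_s <- 30
  base <- rnorm(n_s)
  mk <- function(profile, n, noise) {
    t(sapply(seq_len(n), function(i) profile + rnorm(n_s, 0, noise)))
  }
  # modules A and B nearly identical; C independent
  m <- rbind(mk(base, 10, 0.1), mk(base, 10, 0.1), mk(rnorm(n_s), 10, 0.1))
  m <- named_mat(m)
  labels <- setNames(rep(c("blue", "brown", "turquoise"), each = 10),
                     rownames(m))
  part <- structure(list(labels = labels,
                         sizes = sort(table(labels), decreasing = TRUE),
                         merge_history = data.frame(from = character(),
                                                    to = character())),
                    class = "module_partition")
  mes <- module_eigengenes(m, part)
  merged <- merge_modules(part, mes, m, merge_height = 0.25)
  expect_equal(length(unique(merged$partition$labels)), 2)
  expect_equal(nrow(merged$partition$merge_history), 1)
  # orthogonal eigengenes never merge
  p2 <- structure(list(labels = labels[c(1:10, 21:30)],
                       sizes = sort(table(labels[c(1:10, 21:30)]),
                                    decreasing = TRUE),
                       merge_history = data.frame(from = character(),
                                                  to = character())),
                  class = "module_partition")
  m2 <- m[c(1:10, 21:30), ]
  mes2 <- module_eigengenes(m2, p2)
  merged2 <- merge_modules(p2, mes2, m2, merge_height = 0.25)
  expect_equal(length(unique(merged2$partition$labels)), 2)
})

test_that("module-trait correlation finds the planted driver module", {
  res <- default_run()
  cond <- sapply(c("sulfide", "oxygen"),
                 function(cn) encode_condition(res$design, cn))
  mt <- module_trait_correlation(res$eigengenes, cond)
  # the module holding the sulfide-driven genes has the max |cor| with sulfide
  truth <- res$truth$gene_module[rownames(res$net_expr)]
  m1_label <- names(which.max(table(res$partition$labels[truth == "m1"])))
  expect_equal(rownames(mt$cor)[which.max(abs(mt$cor[, "sulfide"]))],
               paste0("ME", m1_label))
  expect_true(all(mt$p > 0 & mt$p <= 1))
  # an eigengene equal to the condition correlates exactly 1
  fake <- rbind(res$eigengenes, MEfake = scale(cond[, "sulfide"])[, 1])
  mtf <- module_trait_correlation(fake, cond)
  expect_equal(mtf$cor["MEfake", "sulfide"], 1, tolerance = 1e-12)
  expect_error(module_trait_correlation(res$eigengenes,
                                        cbind(flat = rep(1, 30))),
               "constant")
  # permutation null: planted correlation exceeds the permuted 95th percentile
  set.seed(12)
  obs <- max(abs(mt$cor[, "sulfide"]))
  null_max <- replicate(99, {
    max(abs(cor(t(res$eigengenes), sample(cond[, "sulfide"]))))
  })
  expect_gt(obs, quantile(null_max, 0.95))
})

test_that("gene significance and module membership behave as correlations", {
  res <- default_run()
  cond <- encode_condition(res$design, "sulfide")
  gs <- gene_significance(res$net_expr, cond)
  expect_true(all(abs(gs$gs) <= 1) && all(gs$p > 0 & gs$p <= 1))
  # a gene equal to the condition vector has GS exactly 1
  m <- rbind(res$net_expr[1:3, ], probe = cond)
  gsp <- gene_significance(m, cond)
  expect_equal(gsp$gs[gsp$gene == "probe"], 1, tolerance = 1e-12)
  # planted sulfide-driver genes outrank non-members
  truth <- res$truth$gene_module[rownames(res$net_expr)]
  expect_gt(mean(abs(gs$gs[truth == "m1"])),
            mean(abs(gs$gs[truth %in% c("none", "m3", "m4")])))
  # independent noise genes stay below |GS| 0.6 at n = 30
  expect_lt(max(abs(gs$gs[truth == "none"])), 0.6)

  mm <- module_membership(res$net_expr, res$eigengenes)
  expect_true(all(abs(mm) <= 1 + 1e-12))
  # planted members correlate strongly with their own eigengene
  m1_label <- names(which.max(table(res$partition$labels[truth == "m1"])))
  own <- mm[truth == "m1", paste0("ME", m1_label)]
  expect_gt(mean(abs(own)), 0.8)
  # unrelated genes have weak membership in that module
  foreign <- mm[truth == "none", paste0("ME", m1_label)]
  expect_lt(mean(abs(foreign)), 0.5)
})
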