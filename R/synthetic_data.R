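#' @title Synthetic data with planted structure
#' @description Seeded generators for treatment designs, negative-binomial
#'   count matrices driven by planted co-expression modules, isotope tracer
#'   records with known true incorporation rates, and flow-through uptake
#'   series with known consumption — plus the ground-truth objects the tests
#'   compare against.
#' @name synthetic-data
NULL

SUBSTRATES <- c("sulfide", "oxygen", "nitrate", "hydrogen")

#' Default treatment layout
#'
#' Ten aquarium treatments encoded by the replete/limiting state of four
#' substrates, arranged so five treatment pairs differ only in sulfide and
#' two pairs differ only in oxygen.  Three worms per treatment.
#'
#' @param replicates Worms per treatment.
#' @return Data frame with `treatment`, the four substrate state columns and
#'   `replicates`.
#' @export
default_condition_layout <- function(replicates = 3) {
  state <- function(x) ifelse(x == 1, "replete", "limiting")
  lay <- rbind(
    T01 = c(1, 1, 1, 1), T02 = c(0, 1, 1, 1),
    T03 = c(1, 1, 1, 0), T04 = c(0, 1, 1, 0),
    T05 = c(1, 1, 0, 0), T06 = c(0, 1, 0, 0),
    T07 = c(1, 1, 0, 1), T08 = c(0, 1, 0, 1),
    T09 = c(1, 0, 1, 1), T10 = c(0, 0, 1, 1)
  )
  colnames(lay) <- SUBSTRATES
  out <- data.frame(treatment = rownames(lay),
                    apply(lay, 2, state),
                    replicates = replicates,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Default per-module condition effects (log scale)
#' @return Named list, one numeric vector of substrate coefficients per module.
#' @export
default_effect_sizes <- function() {
  list(
    m1 = c(sulfide = 2),
    m2 = c(oxygen = 2),
    m3 = c(nitrate = 2),
    m4 = c(hydrogen = 2),
    m5 = c(nitrate = 1, hydrogen = 1)
  )
}

#' Default pairwise treatment comparisons per condition
#'
#' Five sulfide and two oxygen replete-minus-limiting contrasts, each pair
#' differing only in the named substrate under the default layout.
#' @export
default_comparisons <- function() {
  list(
    sulfide = c("T01-T02", "T03-T04", "T05-T06", "T07-T08", "T09-T10"),
    oxygen = c("T01-T09", "T02-T10")
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator: the gene/module
#' layout, treatment design, module-on-condition effects, gene loadings,
#' negative-binomial dispersion, library sizes and the master seed.  The two
#' seed gene sets ("CBB"-like and "rTCA"-like, after the two carbon-fixation
#' pathways) are the highest-loading members of modules 1 and 2.
#'
#' @param n_genes Total genes; genes beyond the planted modules are
#'   independent noise.
#' @param module_sizes Genes per planted module (sum must be <= `n_genes`).
#' @param condition_layout Treatment table as from
#'   [default_condition_layout()].
#' @param effect_sizes Per-module named substrate coefficients (log scale).
#' @param loading_range Range of gene-on-eigengene loadings in [0, 1].
#' @param nb_dispersion Negative-binomial dispersion shared by all genes.
#' @param me_noise_sd SD of the Gaussian noise on each module's latent
#'   activity (eigengene) per sample.
#' @param baseline_logmean_range Range of per-gene baseline natural-log mean
#'   counts at a 1e6-read library.
#' @param libsize_range Range of per-sample library sizes (reads).
#' @param n_seed_genes Genes per pathway seed set.
#' @param comparisons Named list of treatment contrasts per condition.
#' @param rng_seed Master seed; all randomness flows from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 600,
                              module_sizes = rep(100L, 5),
                              condition_layout = default_condition_layout(),
                              effect_sizes = default_effect_sizes(),
                              loading_range = c(0.7, 1),
                              nb_dispersion = 0.1,
                              me_noise_sd = 1,
                              baseline_logmean_range = c(2, 6),
                              libsize_range = c(8e5, 1.2e6),
                              n_seed_genes = 10,
                              comparisons = default_comparisons(),
                              rng_seed = 1) {
  if (sum(module_sizes) > n_genes) {
    stop("module_sizes sum exceeds n_genes")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (any(libsize_range <= 0)) stop("library sizes must be > 0")
  if (any(loading_range < 0 | loading_range > 1)) {
    stop("loading_range must lie in [0, 1]")
  }
  n_modules <- length(module_sizes)
  if (length(effect_sizes) != n_modules) {
    stop("effect_sizes must name one entry per module")
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  gene_module <- rep("none", n_genes)
  idx <- 0L
  for (m in seq_len(n_modules)) {
    gene_module[idx + seq_len(module_sizes[m])] <- names(effect_sizes)[m]
    idx <- idx + module_sizes[m]
  }
  names(gene_module) <- gene_ids
  seed_sets <- list()
  if (n_modules >= 2 && n_seed_genes > 0) {
    m1 <- gene_ids[gene_module == names(effect_sizes)[1]]
    m2 <- gene_ids[gene_module == names(effect_sizes)[2]]
    if (n_seed_genes >= min(length(m1), length(m2))) {
      stop("n_seed_genes must be smaller than the seeded modules")
    }
    seed_sets <- list(CBB = m1[seq_len(n_seed_genes)],
                      rTCA = m2[seq_len(n_seed_genes)])
    stopifnot(length(intersect(seed_sets$CBB, seed_sets$rTCA)) == 0)
  }
  structure(list(
    n_genes = n_genes, n_modules = n_modules, module_sizes = module_sizes,
    condition_layout = condition_layout, effect_sizes = effect_sizes,
    loading_range = loading_range, nb_dispersion = nb_dispersion,
    me_noise_sd = me_noise_sd,
    baseline_logmean_range = baseline_logmean_range,
    libsize_range = libsize_range, n_seed_genes = n_seed_genes,
    seed_gene_sets = seed_sets, comparisons = comparisons,
    gene_ids = gene_ids, gene_module = gene_module, rng_seed = rng_seed
  ), class = "simulation_config")
}

#' Simulate the sample design table
#'
#' Expands the treatment layout into one row per worm, with sample and worm
#' IDs, a cruise-year covariate balanced across treatments, and the four
#' binary substrate state columns.
#'
#' @param config A [simulation_config()].
#' @return Data frame (`sample`, `treatment`, `worm`, `cruise`, substrate
#'   states).
#' @export
simulate_design <- function(config) {
  lay <- config$condition_layout
  cols <- c("treatment", SUBSTRATES, "replicates")
  miss <- setdiff(cols, names(lay))
  if (length(miss)) stop("condition_layout missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(lay) == 0) {
    return(data.frame(sample = character(), treatment = character(),
                      worm = character(), cruise = integer(),
                      sulfide = character(), oxygen = character(),
                      nitrate = character(), hydrogen = character(),
                      stringsAsFactors = FALSE))
  }
  dup <- duplicated(lay$treatment)
  if (any(dup)) {
    states <- lay[, SUBSTRATES, drop = FALSE]
    for (tr in unique(lay$treatment[dup])) {
      rows <- states[lay$treatment == tr, , drop = FALSE]
      if (nrow(unique(rows)) > 1) {
        stop("treatment ", tr,
             " listed with contradictory substrate states")
      }
    }
    lay <- lay[!dup, , drop = FALSE]
  }
  bad <- !unlist(lay[, SUBSTRATES]) %in% c("replete", "limiting", "absent")
  if (any(bad)) stop("substrate states must be replete/limiting/absent")
  reps <- rep(seq_len(nrow(lay)), lay$replicates)
  within <- stats::ave(reps, reps, FUN = seq_along)
  out <- data.frame(
    sample = sprintf("S%02d", seq_along(reps)),
    treatment = lay$treatment[reps],
    worm = sprintf("W%02d", seq_along(reps)),
    cruise = ifelse(within %% 2 == 1, 2014L, 2016L),
    lay[reps, SUBSTRATES, drop = FALSE],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Numeric condition matrix from a design table
#' @param design Design table from [simulate_design()].
#' @return Sample x substrate 0/1 matrix (1 = replete).
#' @keywords internal
condition_matrix <- function(design) {
  m <- sapply(SUBSTRATES, function(s) as.numeric(design[[s]] == "replete"))
  m <- matrix(m, nrow = nrow(design),
              dimnames = list(design$sample, SUBSTRATES))
  m
}

#' Simulate module-structured negative-binomial counts
#'
#' Each planted module m has a latent per-sample activity
#' ME_m(s) = sum_c effect_{m,c} * state_c(s) + N(0, me_noise_sd); member
#' genes have log mean baseline_g + loading_g * ME_m(s) plus a library-size
#' offset, and counts are drawn NB with shared dispersion.  Genes outside
#' modules are independent noise.  Seed-set genes carry the maximal loading
#' of their module.
#'
#' @param config A [simulation_config()].
#' @param design Design table from [simulate_design()].
#' @return List with `em` (an [expression_matrix()]) and `truth`
#'   (a `ground_truth` list: gene-module map, effects, loadings, latent
#'   module activities, expected log2 fold changes and true DE status per
#'   configured comparison, and the true first-neighbor sets of the two
#'   pathway seed sets).
#' @export
simulate_module_counts <- function(config, design) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(config$module_sizes > config$n_genes)) {
    stop("a module is larger than n_genes")
  }
  set.seed(config$rng_seed)
  n_g <- config$n_genes
  n_s <- nrow(design)
  genes <- config$gene_ids
  gmod <- config$gene_module

  loading <- stats::runif(n_g, config$loading_range[1], config$loading_range[2])
  loading[gmod == "none"] <- 0
  names(loading) <- genes
  for (ss in config$seed_gene_sets) loading[ss] <- max(config$loading_range)

  baseline <- stats::runif(n_g, config$baseline_logmean_range[1],
                           config$baseline_logmean_range[2])
  libsize <- round(stats::runif(n_s, config$libsize_range[1],
                                config$libsize_range[2]))
  cond <- condition_matrix(design)

  me <- matrix(0, nrow = length(config$effect_sizes), ncol = n_s,
               dimnames = list(names(config$effect_sizes), design$sample))
  for (m in names(config$effect_sizes)) {
    eff <- config$effect_sizes[[m]]
    drift <- if (length(eff)) cond[, names(eff), drop = FALSE] %*% eff
             else matrix(0, n_s, 1)
    me[m, ] <- drift + stats::rnorm(n_s, 0, config$me_noise_sd)
  }

  logmu <- matrix(baseline, n_g, n_s) +
    log(matrix(libsize, n_g, n_s, byrow = TRUE) / 1e6)
  in_mod <- gmod != "none"
  logmu[in_mod, ] <- logmu[in_mod, ] +
    loading[in_mod] * me[gmod[in_mod], , drop = FALSE]
  counts <- matrix(
    stats::rnbinom(n_g * n_s, mu = exp(logmu), size = 1 / config$nb_dispersion),
    n_g, n_s, dimnames = list(genes, design$sample)
  )

  # expected log2FC per configured comparison, from the noiseless model
  comps <- unlist(config$comparisons, use.names = FALSE)
  exp_l2fc <- matrix(0, n_g, length(comps), dimnames = list(genes, comps))
  treat_state <- cond[!duplicated(design$treatment), , drop = FALSE]
  rownames(treat_state) <- design$treatment[!duplicated(design$treatment)]
  for (cp in comps) {
    pair <- strsplit(cp, "-", fixed = TRUE)[[1]]
    dstate <- treat_state[pair[1], ] - treat_state[pair[2], ]
    for (m in names(config$effect_sizes)) {
      eff <- config$effect_sizes[[m]]
      dme <- sum(eff * dstate[names(eff)])
      sel <- gmod == m
      exp_l2fc[sel, cp] <- loading[sel] * dme / log(2)
    }
  }

  truth <- structure(list(
    gene_module = gmod,
    module_effects = config$effect_sizes,
    loadings = loading,
    module_activity = me,
    condition_layout = cond,
    expected_log2fc = exp_l2fc,
    de_status = exp_l2fc != 0,
    seed_gene_sets = config$seed_gene_sets,
    true_neighbors = true_neighbor_sets(config),
    true_rates = NULL
  ), class = "ground_truth")

  list(em = expression_matrix(counts), truth = truth)
}

true_neighbor_sets <- function(config) {
  ss <- config$seed_gene_sets
  if (!length(ss)) return(list())
  all_seeds <- unlist(ss, use.names = FALSE)
  lapply(ss, function(s) {
    mod <- unique(config$gene_module[s])
    setdiff(names(config$gene_module)[config$gene_module == mod], all_seeds)
  })
}

#' Write / read ground truth as JSON
#'
#' Lossless round trip of the `ground_truth` object produced by
#' [simulate_module_counts()].
#' @param truth A `ground_truth` object.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  enc <- list(
    gene_module = as.list(truth$gene_module),
    module_effects = lapply(truth$module_effects, as.list),
    loadings = as.list(truth$loadings),
    module_activity = mat_to_list(truth$module_activity),
    condition_layout = mat_to_list(truth$condition_layout),
    expected_log2fc = mat_to_list(truth$expected_log2fc),
    seed_gene_sets = truth$seed_gene_sets,
    true_neighbors = truth$true_neighbors,
    true_rates = truth$true_rates
  )
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  gm <- unlist(enc$gene_module)
  exp_l2fc <- list_to_mat(enc$expected_log2fc)
  structure(list(
    gene_module = gm,
    module_effects = lapply(enc$module_effects, unlist),
    loadings = unlist(enc$loadings),
    module_activity = list_to_mat(enc$module_activity),
    condition_layout = list_to_mat(enc$condition_layout),
    expected_log2fc = exp_l2fc,
    de_status = exp_l2fc != 0,
    seed_gene_sets = lapply(enc$seed_gene_sets, as.character),
    true_neighbors = lapply(enc$true_neighbors, as.character),
    true_rates = if (is.null(enc$true_rates)) NULL else unlist(enc$true_rates)
  ), class = "ground_truth")
}

mat_to_list <- function(m) {
  list(rows = rownames(m), cols = colnames(m), data = as.vector(m))
}

list_to_mat <- function(l) {
  matrix(unlist(l$data), nrow = length(l$rows),
         dimnames = list(unlist(l$rows), unlist(l$cols)))
}

#' Simulate isotope tracer records with known true rates
#'
#' Inverts the incorporation-rate equations: from a true wet-weight rate
#' (umol g-1 h-1), computes the labelled-tissue delta-13C a worm would show
#' after `hours` of incubation in water of the given label strength, then
#' adds per-mille measurement noise.  A noiseless pass through
#' [incorporation_rate()] recovers the true rates exactly.
#'
#' @param true_rates Per-worm true wet-weight incorporation rates (>= 0).
#' @param label_atom_pct_water Atom percent 13C of the water DIC (default
#'   2.64, the labelling strength used in the incubations).
#' @param hours Incubation duration.
#' @param dw_ww_ratio Tissue dry-to-wet weight ratio.
#' @param noise_sd_delta SD of Gaussian noise added to the measured
#'   delta-13C, per mille.
#' @param delta13c_nat Natural-abundance tissue delta-13C (per mille).
#' @param r_standard Reference standard ratio.
#' @param tissue Tissue label for the records.
#' @param seed RNG seed for dry weights and measurement noise.
#' @return Data frame of isotope records as consumed by
#'   [incorporation_rate()].
#' @export
simulate_isotope_records <- function(true_rates,
                                     label_atom_pct_water = 2.64,
                                     hours = 48,
                                     dw_ww_ratio = 0.25,
                                     noise_sd_delta = 0,
                                     delta13c_nat = -15,
                                     r_standard = VPDB_RATIO,
                                     tissue = "trophosome",
                                     seed = NULL) {
  if (any(true_rates < 0)) stop("true rates must be >= 0")
  a_nat <- atom_percent(ratio_from_delta(delta13c_nat, r_standard))
  if (label_atom_pct_water <= a_nat) {
    stop("label_atom_pct_water must exceed the natural-abundance atom percent")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_rates)
  dw <- stats::runif(n, 0.5, 2)
  dry_rate <- true_rates / dw_ww_ratio
  frac <- dry_rate * 13 * hours / 1000
  a_lab <- a_nat + frac * (label_atom_pct_water - a_nat)
  if (any(a_lab >= 100)) stop("true rate implies atom percent >= 100")
  delta_lab <- delta13c(ratio_from_atom_percent(a_lab), r_standard) +
    stats::rnorm(n, 0, noise_sd_delta)
  data.frame(
    worm_id = sprintf("W%03d", seq_len(n)),
    tissue = tissue,
    delta13c_lab = delta_lab,
    delta13c_nat = delta13c_nat,
    a_pct_water = label_atom_pct_water,
    dry_weight_g = dw,
    hours = hours,
    dw_ww_ratio = dw_ww_ratio,
    r_standard = r_standard,
    stringsAsFactors = FALSE
  )
}

#' Simulate a flow-through uptake series with known consumption
#'
#' Outlet concentration is c_in - consumption * biomass / flow, plus
#' measurement noise on both inlet and outlet; the noiseless series inverts
#' exactly through [uptake_rate()].
#'
#' @param c_in Inlet concentration (umol/l).
#' @param consumption True consumption rate (umol h-1 g-1).
#' @param biomass Total aquarium biomass (g).
#' @param flow Flow rate (l/h).
#' @param n_timepoints Number of timepoints.
#' @param noise_sd SD of measurement noise on concentrations.
#' @param substrate Substrate label.
#' @param seed RNG seed.
#' @return Data frame of uptake records for [uptake_rate()].
#' @export
simulate_uptake_series <- function(c_in, consumption, biomass, flow,
                                   n_timepoints = 10, noise_sd = 0,
                                   substrate = "H2S", seed = NULL) {
  if (flow <= 0) stop("flow must be > 0")
  if (biomass <= 0) stop("biomass must be > 0")
  c_out <- c_in - consumption * biomass / flow
  if (c_out < 0) {
    stop("consumption implies a negative outlet concentration")
  }
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    substrate = substrate,
    timepoint = seq_len(n_timepoints),
    c_in = c_in + stats::rnorm(n_timepoints, 0, noise_sd),
    c_out = c_out + stats::rnorm(n_timepoints, 0, noise_sd),
    flow_l_h = flow,
    biomass_g = biomass,
    stringsAsFactors = FALSE
  )
}
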