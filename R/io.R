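#' @title Readers, writers and run reports
#' @description Deterministic I/O for the exchanged formats: count matrices
#'   (TSV and MatrixMarket), sample metadata CSV, gene-annotation TSV, YAML
#'   configuration, network edge lists (TSV/SIF) and JSON run reports.
#' @name io
NULL

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 10), format = "g", digits = 10))
}

#' Read a count matrix
#'
#' TSV: genes in rows (first column), samples in the header.  MatrixMarket:
#' `<path>` plus companion `<path>.rows` / `<path>.cols` name files.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"mtx"`.
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    raw <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- raw[[1]]
    m <- as.matrix(raw[, -1, drop = FALSE])
    suppressWarnings(storage <- apply(raw[, -1, drop = FALSE], 2,
                                      function(col) as.numeric(col)))
    bad <- which(is.na(storage) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-numeric count at row ", bad[1, 1], " (gene ",
           genes[bad[1, 1]], "), column ", colnames(m)[bad[1, 2]])
    }
    m <- matrix(storage, nrow = length(genes),
                dimnames = list(genes, colnames(m)))
  } else {
    rows_file <- paste0(path, ".rows")
    cols_file <- paste0(path, ".cols")
    if (!file.exists(rows_file) || !file.exists(cols_file)) {
      stop("MatrixMarket input needs companion .rows and .cols name files")
    }
    mm <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rows_file)
    cn <- readLines(cols_file)
    if (length(rn) != nrow(mm) || length(cn) != ncol(mm)) {
      stop("dimension mismatch between MatrixMarket header and name files")
    }
    m <- matrix(as.numeric(mm), nrow = nrow(mm), dimnames = list(rn, cn))
  }
  expression_matrix(m)
}

#' Write a count matrix
#' @param x An [expression_matrix()] or count matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_counts <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  x <- as_expr_matrix(x)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(x$counts), x$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(rownames(x$counts), paste0(path, ".rows"))
    writeLines(colnames(x$counts), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with required columns `sample`, `treatment` and the four substrate
#' state columns; unknown columns are preserved.
#'
#' @param path CSV path.
#' @return Sample table data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "treatment", SUBSTRATES)
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing required column(s): ",
                         paste(miss, collapse = ", "))
  states <- unlist(df[, SUBSTRATES])
  bad <- !states %in% c("replete", "limiting", "absent")
  if (any(bad)) {
    stop("unknown substrate state(s): ",
         paste(unique(states[bad]), collapse = ", "),
         " (allowed: replete, limiting, absent)")
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in metadata")
  df
}

#' Read a gene annotation table
#'
#' TSV with required columns `gene` and `category`; a gene may carry several
#' categories on separate rows.
#'
#' @param path TSV path.
#' @return Data frame `gene`, `category` (plus any extra columns).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "category"), names(df))
  if (length(miss)) stop("annotation missing required column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Read / write a pipeline configuration (YAML)
#'
#' Unknown keys are rejected; omitted keys take the [simulation_config()]
#' defaults, so a round trip preserves the defaults exactly.
#'
#' @param path YAML path.
#' @return A validated `simulation_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(simulation_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(raw$condition_layout)) {
    raw$condition_layout <- as.data.frame(raw$condition_layout,
                                          stringsAsFactors = FALSE)
  }
  do.call(simulation_config, raw)
}

#' @rdname read_config
#' @param config A `simulation_config`.
#' @export
write_config <- function(config, path) {
  keep <- intersect(names(formals(simulation_config)), names(config))
  out <- config[keep]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a network edge list
#'
#' TSV (`source`, `target`, `weight`) or SIF (`source  co  target`) with
#' stable edge ordering and fixed float formatting so outputs are diffable.
#'
#' @param graph Thresholded igraph graph with a `weight` edge attribute.
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @export
write_edge_list <- function(graph, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  el <- igraph::as_data_frame(graph, what = "edges")
  el <- el[order(el$from, el$to), , drop = FALSE]
  if (format == "tsv") {
    lines <- c("source\ttarget\tweight",
               paste(el$from, el$to, fmt_num(el$weight), sep = "\t"))
  } else {
    lines <- paste(el$from, "co", el$to, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a numeric table with fixed formatting
#' @param df Data frame.
#' @param path Output TSV path.
#' @export
write_tsv_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble and write a run report
#'
#' JSON record of a pipeline run: the configuration snapshot, master seed,
#' stage timings, divergence notes (e.g. the robust empirical-Bayes variant
#' being replaced by standard moments estimation) and the output manifest.
#'
#' @param config `simulation_config` used.
#' @param seed Master seed.
#' @param timings Named numeric vector of stage timings (seconds).
#' @param outputs Character vector of output paths.
#' @param notes Character vector of divergence notes.
#' @param path Optional output path; if given, the JSON is written there.
#' @return The report list, invisibly if written.
#' @export
run_report <- function(config, seed, timings = NULL, outputs = character(),
                       notes = character(), path = NULL) {
  report <- list(
    package = "ventnet",
    config = config[setdiff(names(config),
                            c("gene_ids", "gene_module"))],
    rng_seed = seed,
    timings_s = as.list(timings),
    divergences = as.list(notes),
    outputs = as.list(outputs),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    return(invisible(report))
  }
  report
}
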