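#' Read gene sets in GMT format
#'
#' One set per line: name, description, then one or more tab-separated gene
#' identifiers. Duplicate genes within a set are removed (with a message);
#' CRLF line endings are accepted. Lines with fewer than three fields raise
#' an error naming the line number.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; set descriptions in
#'   `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty gene-set file: ", path)
    return(structure(list(), descriptions = character()))
  }
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i),
           call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      message(sprintf("set '%s': %d duplicate gene(s) removed",
                      fields[1], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
    desc[fields[1]] <- fields[2]
  }
  structure(sets, descriptions = desc)
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set descriptions (recycled).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a binary genes-by-samples mutation matrix from TSV
#'
#' Expects a header row of sample labels and a first column of gene labels;
#' `#`-prefixed comment lines are skipped. Values outside `{0, 1}` raise an
#' error naming the offending gene and sample.
#'
#' @param path Path to the TSV file.
#' @return A [mutation_matrix()].
#' @export
read_mutation_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene labels in ", path, call. = FALSE)
  if (anyDuplicated(colnames(df)[-1])) {
    stop("duplicate sample labels in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  mutation_matrix(m)
}

#' Write a mutation matrix as TSV with a provenance header
#'
#' @param x A [mutation_matrix()].
#' @param path Output path.
#' @param seed Optional seed recorded in the provenance header.
#' @export
write_mutation_matrix <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "mutation_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(list(rows = nrow(x), cols = ncol(x)), seed), con)
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  utils::write.table(unclass(x), con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Read an undirected edge list from TSV
#'
#' Two tab-separated node labels per line (extra columns ignored);
#' `#`-prefixed lines are comments; duplicate and reversed edges are
#' collapsed.
#'
#' @param path Path to the edge-list file.
#' @return A [frail_network()].
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", header = FALSE,
                          stringsAsFactors = FALSE)
  as_frail_network(df[, 1:2])
}

#' Write a network as an undirected edge list
#'
#' @param network A [frail_network()] or coercible.
#' @param path Output path.
#' @param seed Optional seed recorded in the provenance header.
#' @export
write_edge_list <- function(network, path, seed = NULL) {
  network <- as_frail_network(network)
  e <- igraph::as_edgelist(network$graph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(list(nodes = network$m, edges = nrow(e)), seed),
             con)
  writeLines(paste(e[, 1], e[, 2], sep = "\t"), con)
  invisible(path)
}

#' Read a labelled square adjacency matrix from TSV
#'
#' Header row and first column carry the node labels.
#'
#' @param path Path to the adjacency TSV.
#' @return A [frail_network()].
#' @export
read_adjacency <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- labels
  if (!identical(colnames(m), labels)) {
    stop("adjacency row and column labels disagree", call. = FALSE)
  }
  frail_network(m, labels = labels)
}

#' Write a network as a labelled adjacency TSV
#'
#' @param network A [frail_network()] or coercible.
#' @param path Output path.
#' @param seed Optional seed recorded in the provenance header.
#' @export
write_adjacency <- function(network, path, seed = NULL) {
  network <- as_frail_network(network)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(list(nodes = network$m), seed), con)
  writeLines(paste(c("node", network$labels), collapse = "\t"), con)
  utils::write.table(network$adjacency, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

# '#' comment lines recording package version, parameters and seed
provenance_header <- function(params = list(), seed = NULL) {
  stamp <- paste0(
    "# frailnet ",
    as.character(utils::packageVersion("frailnet"))
  )
  par_line <- paste0(
    "# params: ",
    paste(names(params), unlist(params), sep = "=", collapse = " "),
    if (!is.null(seed)) paste0(" seed=", seed) else "",
    " hash=", params_hash(c(params, seed = seed))
  )
  c(stamp, par_line)
}

params_hash <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(params), collapse = ""), f)
  substr(unname(tools::md5sum(f)), 1, 8)
}

#' Run configuration with the package defaults
#'
#' Collects the tunable parameters of the pipeline, optionally overridden
#' from a YAML file of `key: value` pairs and/or by named arguments.
#'
#' @param path Optional YAML configuration file.
#' @param ... Named overrides applied after the file.
#' @return Object of class `run_config` (a validated named list).
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    epsilon = 1.0,
    norm = "spectral",
    coupling = "per_query",
    variant = "consistent",
    scheme_tol = 1e-10,
    scheme_max_iter = 20000,
    divergence_bound = 1e6,
    kernel_tol = 1e-10,
    symmetry_tol = 1e-8,
    bisection_tol_rel = 1e-3,
    min_size = 10,
    max_size = 500,
    top_n = 10,
    min_patients = 20,
    marginal_degree = 1,
    exclude = NULL,
    seed = 1L
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(epsilon >= 0, scheme_tol > 0, kernel_tol > 0, symmetry_tol > 0,
              bisection_tol_rel > 0, min_size <= max_size, top_n >= 1,
              min_patients >= 1, marginal_degree >= 1)
  })
  if (!cfg$norm %in% c("spectral", "frobenius")) {
    stop("`norm` must be 'spectral' or 'frobenius'", call. = FALSE)
  }
  if (!cfg$coupling %in% c("per_query", "split")) {
    stop("`coupling` must be 'per_query' or 'split'", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}
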