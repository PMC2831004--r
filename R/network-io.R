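#' Construct a network object
#'
#' A `p2_network` is a simple graph over string node identifiers: no
#' self-loops, no duplicate edges, undirected edges stored canonically with
#' lexicographically ordered endpoints. Node order is the order of first
#' appearance and is stable, so draw matrices and summaries can be aligned
#' by position.
#'
#' @param nodes character vector of unique node IDs, in the order they
#'   should be kept.
#' @param edges two-column character matrix (or data frame) of endpoint
#'   pairs; may be empty.
#' @param directed logical; undirected by default.
#' @return An object of class `p2_network` with components `nodes`,
#'   `edges` (canonical two-column character matrix) and `directed`.
#' @export
p2_network <- function(nodes, edges, directed = FALSE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node IDs: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (any(!nzchar(nodes))) stop("empty node IDs are not allowed")
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have exactly two columns")
  storage.mode(edges) <- "character"
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- which(edges[, 1L] == edges[, 2L])[1L]
    stop("self-loop on node '", edges[bad, 1L], "' (edge ", bad, ")")
  }
  missing <- setdiff(c(edges), nodes)
  if (length(missing)) {
    stop("edge endpoints not in node list: ", paste(missing, collapse = ", "))
  }
  if (!directed) edges <- canonicalize_edges(edges)
  if (anyDuplicated(apply(edges, 1L, paste, collapse = "\r"))) {
    stop("duplicate edges after canonicalization")
  }
  structure(
    list(nodes = nodes, edges = edges, directed = isTRUE(directed)),
    class = "p2_network"
  )
}

canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  swap <- edges[, 1L] > edges[, 2L]
  tmp <- edges[swap, 1L]
  edges[swap, 1L] <- edges[swap, 2L]
  edges[swap, 2L] <- tmp
  dimnames(edges) <- NULL
  edges
}

#' @export
print.p2_network <- function(x, ...) {
  cat(sprintf("p2_network: %d nodes, %d %s edges\n",
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Number of nodes in a network
#' @param net a `p2_network`.
#' @return integer node count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' Number of edges in a network
#' @param net a `p2_network`.
#' @return integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' Read an edge list from a TSV file
#'
#' Reads a two-column whitespace/tab separated edge list. Lines starting
#' with `#` are treated as comments. For undirected networks edges are
#' stored canonically (lexicographically ordered endpoints), so `A B` and
#' `B A` describe the same edge; duplicates are removed with a warning
#' (or an error when `strict = TRUE`). The node universe is the set of
#' endpoint IDs in order of first appearance, optionally extended by an
#' explicit `nodes` vector so that isolated nodes can be represented.
#'
#' @param path path to the TSV edge list.
#' @param directed logical; default `FALSE`.
#' @param strict logical; if `TRUE`, duplicate edge lines are an error
#'   rather than a warning. Yeast two-hybrid edge lists commonly repeat
#'   pairs, so the default is lenient.
#' @param nodes optional character vector of node IDs to include even if
#'   they carry no edges (isolated nodes).
#' @return a [p2_network()].
#' @export
read_edge_list <- function(path, directed = FALSE, strict = FALSE,
                           nodes = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("edge list format error: line ", line_no[which(nf < 2L)[1L]],
         " has fewer than 2 columns")
  }
  from <- vapply(fields, `[`, character(1), 1L)
  to <- vapply(fields, `[`, character(1), 2L)
  loops <- from == to
  if (any(loops)) {
    stop("self-loop at line ", line_no[which(loops)[1L]],
         " ('", from[which(loops)[1L]], "')")
  }
  edges <- cbind(from, to)
  if (!directed) edges <- canonicalize_edges(edges)
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    msg <- sprintf("%d duplicate edge line(s) removed (e.g. line %d)",
                   sum(dup), line_no[which(dup)[1L]])
    if (strict) stop(msg)
    warning(msg)
  }
  edges <- edges[!dup, , drop = FALSE]
  ids <- unique(c(t(cbind(from, to))))
  if (!is.null(nodes)) ids <- unique(c(ids, as.character(nodes)))
  p2_network(ids, edges, directed = directed)
}

#' Write an edge list to a TSV file
#'
#' Writes the canonical edge set, one tab-separated pair per line. A
#' round trip through [read_edge_list()] reproduces the edge set exactly.
#'
#' @param net a `p2_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a node attribute table
#'
#' Reads a TSV with a header whose first column (`id`) holds node IDs;
#' remaining columns are numeric covariates. Duplicate IDs, non-numeric
#' covariate cells and missing values are errors: covariates feed directly
#' into the model likelihood, so silent coercion would corrupt a fit.
#'
#' @param path path to the TSV node table.
#' @return a `p2_covariates` data frame: row names are node IDs, columns
#'   are numeric covariates.
#' @export
read_node_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  if (ncol(raw) < 1L) stop("node table must have at least an id column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate node IDs in table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cov <- raw[, -1L, drop = FALSE]
  for (cn in names(cov)) {
    v <- suppressWarnings(as.numeric(cov[[cn]]))
    bad <- is.na(v) & !is.na(cov[[cn]]) & nzchar(cov[[cn]])
    if (any(bad)) {
      stop("non-numeric value in column '", cn, "' for node(s): ",
           paste(ids[bad], collapse = ", "))
    }
    if (anyNA(v) || any(!nzchar(cov[[cn]]))) {
      miss <- ids[is.na(v) | !nzchar(cov[[cn]])]
      stop("missing value in column '", cn, "' for node(s): ",
           paste(miss, collapse = ", "))
    }
    cov[[cn]] <- v
  }
  rownames(cov) <- ids
  class(cov) <- c("p2_covariates", "data.frame")
  cov
}

#' Align a covariate table with a network's node set
#'
#' Reorders the table rows to the network's node order. Any mismatch in
#' either direction (network node missing from the table, or table node
#' absent from the network) is an error naming the offending nodes;
#' isolated nodes must be declared explicitly when reading the network.
#'
#' @param net a `p2_network`.
#' @param covariates a `p2_covariates` table (or `NULL`, returned as a
#'   zero-column table aligned to the network).
#' @return the aligned `p2_covariates` table, one row per network node.
#' @export
align_covariates <- function(net, covariates) {
  if (is.null(covariates)) {
    out <- data.frame(row.names = net$nodes)
    class(out) <- c("p2_covariates", "data.frame")
    return(out)
  }
  absent <- setdiff(net$nodes, rownames(covariates))
  if (length(absent)) {
    stop("network node(s) absent from covariate table: ",
         paste(absent, collapse = ", "))
  }
  extra <- setdiff(rownames(covariates), net$nodes)
  if (length(extra)) {
    stop("covariate table node(s) not in the network: ",
         paste(extra, collapse = ", "))
  }
  out <- covariates[net$nodes, , drop = FALSE]
  class(out) <- c("p2_covariates", "data.frame")
  out
}

#' Binarize a continuous disorder-probability column
#'
#' Adds a binary column marking nodes whose disorder probability reaches
#' the threshold (inclusive: probability >= threshold maps to 1). With the
#' customary threshold of 0.7 on per-protein disorder probabilities this
#' reproduces the usual disordered/ordered split. The original column is
#' retained.
#'
#' @param table a `p2_covariates` table.
#' @param column name of the continuous column, values in \[0, 1\].
#' @param threshold cut point in \[0, 1\]; default 0.7.
#' @param name name for the new binary column; default `<column>_bin`.
#' @return the table with the binary column appended.
#' @export
binarize_disorder <- function(table, column, threshold = 0.7,
                              name = paste0(column, "_bin")) {
  if (!column %in% names(table)) stop("no column '", column, "' in table")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]")
  }
  v <- table[[column]]
  if (any(v < 0 | v > 1)) stop("column '", column, "' is not in [0, 1]")
  table[[name]] <- as.numeric(v >= threshold)
  class(table) <- c("p2_covariates", "data.frame")
  table
}

#' Degree sequence of a network
#'
#' @param net a `p2_network`.
#' @return named integer vector of degrees in node order; for an
#'   undirected network the degrees sum to twice the edge count.
#' @export
degree_sequence <- function(net) {
  deg <- integer(length(net$nodes))
  names(deg) <- net$nodes
  if (nrow(net$edges)) {
    tab <- table(factor(c(net$edges), levels = net$nodes))
    deg[] <- as.integer(tab)
  }
  deg
}

# 0/1 adjacency matrix in node order; used by the likelihood and sampler.
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  adj <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges[, 1L], net$nodes)
    j <- match(net$edges[, 2L], net$nodes)
    adj[cbind(i, j)] <- 1L
    if (!net$directed) adj[cbind(j, i)] <- 1L
  }
  adj
}
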