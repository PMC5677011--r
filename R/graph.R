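#' Weighted network as a tibble of links
#'
#' The universal input object of the toolkit: a tibble with columns `from`,
#' `to` and `weight` (one row per link; for undirected networks one row per
#' unordered pair, stored in a canonical orientation), carrying the node
#' order and directedness as attributes. All weights are strictly positive
#' and self-loops are rejected (dropped with a warning at construction).
#'
#' @param edges A data frame with columns `from` and `to` (coerced to
#'   character) and optionally `weight` (positive numeric; defaults to 1).
#' @param directed Logical; is the network directed?
#' @param nodes Optional character vector fixing the node order; nodes
#'   appearing in `edges` but not listed here are appended in first-appearance
#'   order.
#' @return A `link_tbl`: a tibble with columns `from`, `to`, `weight` and
#'   attributes `nodes` (ordered node identifiers) and `directed`.
#' @details Duplicate links (same pair, same orientation for directed
#'   networks, either orientation for undirected ones) collapse to the last
#'   weight seen. For undirected networks each pair is stored once, oriented
#'   from the earlier node in the node order; [as_adjacency()] installs both
#'   matrix entries.
#' @export
#' @examples
#' link_tbl(data.frame(from = c("a", "b"), to = c("b", "c")))
link_tbl <- function(edges, directed = FALSE, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    abort_mpd("`edges` must have columns `from` and `to`.")
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, nrow(edges))
  if (length(weight) == 0L) weight <- numeric(0)
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    abort_mpd("All link weights must be finite and strictly positive.",
              class = "mpdlink_weight_error")
  }
  loops <- from == to
  if (any(loops)) {
    rlang::warn(sprintf("Dropping %d self-loop link(s).", sum(loops)))
    from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
  }
  node_order <- unique(c(as.character(nodes), rbind(from, to)))
  if (!directed && length(from) > 0) {
    # canonical orientation: from = earlier node in the node order
    fi <- match(from, node_order); ti <- match(to, node_order)
    swap <- fi > ti
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  }
  # duplicate links: last occurrence wins
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key, fromLast = TRUE)
    rlang::warn(sprintf("Collapsing %d duplicate link(s); last weight wins.",
                        sum(!keep)))
    from <- from[keep]; to <- to[keep]; weight <- weight[keep]
  }
  out <- tibble::tibble(from = from, to = to, weight = weight)
  ord <- order(match(out$from, node_order), match(out$to, node_order))
  out <- out[ord, ]
  structure(out,
            nodes = node_order,
            directed = isTRUE(directed),
            class = c("link_tbl", class(tibble::tibble())))
}

#' @rdname link_tbl
#' @param g A `link_tbl`.
#' @export
network_nodes <- function(g) attr(g, "nodes")

#' @rdname link_tbl
#' @export
is_directed_network <- function(g) isTRUE(attr(g, "directed"))

#' @export
print.link_tbl <- function(x, ...) {
  cat(sprintf("# A %s network: %d nodes, %d links\n",
              if (is_directed_network(x)) "directed" else "undirected",
              length(network_nodes(x)), nrow(x)))
  NextMethod()
}

#' Read a network from a whitespace-separated edge list
#'
#' Each non-comment line has two or three whitespace-separated fields:
#' source, target and an optional positive weight (default 1). Lines
#' starting with `#` and blank lines are ignored. Self-loop lines are
#' skipped with a warning; duplicate lines collapse to the last weight seen.
#'
#' @param path Path to the edge-list file.
#' @param directed Logical; read as a directed network?
#' @param weighted Logical; if `FALSE` any third column is ignored and all
#'   weights are 1.
#' @return A [link_tbl()].
#' @export
read_edge_list <- function(path, directed = FALSE, weighted = TRUE) {
  if (!file.exists(path)) abort_mpd(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(toks)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad) > 0) {
    abort_mpd(sprintf("Malformed edge-list line %d in %s: expected 2 or 3 fields, got %d.",
                      keep[bad[1]], path, nf[bad[1]]),
              class = "mpdlink_parse_error")
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  weight <- rep(1, length(toks))
  if (weighted && any(nf == 3L)) {
    w3 <- vapply(toks, function(t) if (length(t) == 3L) t[[3L]] else "1", "")
    weight <- suppressWarnings(as.numeric(w3))
    if (anyNA(weight)) {
      i <- which(is.na(weight))[1]
      abort_mpd(sprintf("Malformed edge-list line %d in %s: non-numeric weight '%s'.",
                        keep[i], path, w3[i]),
                class = "mpdlink_parse_error")
    }
  }
  link_tbl(data.frame(from = from, to = to, weight = weight),
           directed = directed)
}

#' Write a network as a whitespace-separated edge list
#'
#' Inverse of [read_edge_list()]: links are written in the canonical node
#' order so that a read/write round trip reproduces the network exactly.
#'
#' @param g A [link_tbl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  lines <- sprintf("%s\t%s\t%.17g", g$from, g$to, g$weight)
  writeLines(c("# source\ttarget\tweight", lines), path)
  invisible(path)
}

#' Convert a network to its weighted adjacency matrix
#'
#' Uses the convention that entry `(i, j)` holds the weight of the link
#' from node `j` to node `i` (column = source, row = target). For
#' undirected networks both entries of each pair are installed, so the
#' matrix is exactly symmetric. Rows and columns follow the network's node
#' order and carry the node names as dimnames.
#'
#' @param g A [link_tbl()] with at least one node.
#' @return An n x n numeric matrix with zero diagonal.
#' @export
#' @examples
#' g <- link_tbl(data.frame(from = "a", to = "b", weight = 3), directed = TRUE)
#' as_adjacency(g) # entry ["b", "a"] is 3
as_adjacency <- function(g) {
  nodes <- network_nodes(g)
  if (length(nodes) == 0L) abort_mpd("Cannot build an adjacency matrix for an empty network.")
  n <- length(nodes)
  m <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(g) > 0) {
    fi <- match(g$from, nodes); ti <- match(g$to, nodes)
    m[cbind(ti, fi)] <- g$weight # row = target, column = source
    if (!is_directed_network(g)) m[cbind(fi, ti)] <- g$weight
  }
  m
}

#' Convert an adjacency matrix back to a network
#'
#' Inverse of [as_adjacency()] under the same column-source/row-target
#' convention. Entries must be nonnegative with a zero diagonal; for
#' `directed = FALSE` the matrix must be symmetric within `1e-12`.
#'
#' @param m A square numeric matrix; dimnames, if present, name the nodes.
#' @param directed Logical; interpret as a directed network?
#' @return A [link_tbl()].
#' @export
from_adjacency <- function(m, directed = FALSE) {
  assert_square(m)
  if (any(m < 0)) abort_mpd("Adjacency entries must be nonnegative.")
  if (any(diag(m) != 0)) abort_mpd("Adjacency diagonal must be zero (no self-loops).")
  nodes <- rownames(m)
  if (is.null(nodes)) nodes <- paste0("v", seq_len(nrow(m)))
  if (!directed && max(abs(m - t(m))) > 1e-12) {
    abort_mpd("Matrix is not symmetric; cannot interpret as an undirected network.")
  }
  idx <- which(m > 0, arr.ind = TRUE)
  if (!directed && nrow(idx) > 0) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  link_tbl(
    data.frame(from = nodes[idx[, 2]], to = nodes[idx[, 1]],
               weight = m[idx]),
    directed = directed, nodes = nodes
  )
}

#' Read and write dense adjacency matrices as CSV
#'
#' The CSV holds the full square matrix; an optional header row (and first
#' column, mirrored) carries node names. `header = NA` auto-detects by
#' checking whether the first row parses as numbers.
#'
#' @param path File path.
#' @param header `TRUE`, `FALSE`, or `NA` to auto-detect.
#' @return For the reader, a numeric matrix suitable for [from_adjacency()].
#' @export
read_adjacency_csv <- function(path, header = NA) {
  if (!file.exists(path)) abort_mpd(sprintf("File not found: %s", path))
  first <- utils::read.csv(path, header = FALSE, nrows = 1, colClasses = "character")
  if (is.na(header)) {
    header <- anyNA(suppressWarnings(as.numeric(unlist(first))))
  }
  df <- utils::read.csv(path, header = header, check.names = FALSE)
  m <- as.matrix(df)
  if (header) {
    nodes <- colnames(m)
    dimnames(m) <- list(nodes, nodes)
  } else {
    dimnames(m) <- NULL
  }
  storage.mode(m) <- "double"
  assert_square(m, "adjacency CSV")
  m
}

#' @rdname read_adjacency_csv
#' @param m A square numeric matrix.
#' @export
write_adjacency_csv <- function(m, path) {
  assert_square(m)
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = !is.null(colnames(m)))
  invisible(path)
}

#' Read and write sparse adjacency matrices in Matrix Market format
#'
#' Thin wrappers around [Matrix::readMM()] / [Matrix::writeMM()] returning
#' and accepting dense base matrices; Matrix Market carries no node names,
#' so nodes are labelled `v1..vn`.
#'
#' @param path File path.
#' @return For the reader, a dense numeric matrix.
#' @export
read_adjacency_mm <- function(path) {
  if (!file.exists(path)) abort_mpd(sprintf("File not found: %s", path))
  m <- as.matrix(Matrix::readMM(path))
  dimnames(m) <- list(paste0("v", seq_len(nrow(m))), paste0("v", seq_len(ncol(m))))
  m
}

#' @rdname read_adjacency_mm
#' @param m A square numeric matrix.
#' @export
write_adjacency_mm <- function(m, path) {
  assert_square(m)
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), path)
  invisible(path)
}

#' Convert a network to an igraph object
#'
#' Used internally for the topological descriptors; exported because it is
#' generally handy. By default returns the binary undirected view used by
#' the local similarity indices and the descriptors.
#'
#' @param g A [link_tbl()].
#' @param directed Keep direction? Defaults to the network's own flag.
#' @param weighted Attach weights as an edge attribute?
#' @return An igraph graph.
#' @export
as_igraph <- function(g, directed = is_directed_network(g), weighted = TRUE) {
  ig <- igraph::graph_from_data_frame(
    as.data.frame(g)[, c("from", "to", "weight")],
    directed = is_directed_network(g),
    vertices = data.frame(name = network_nodes(g))
  )
  if (!directed && igraph::is_directed(ig)) {
    ig <- igraph::as_undirected(ig, mode = "collapse",
                                edge.attr.comb = list(weight = "max"))
  }
  if (!weighted) ig <- igraph::delete_edge_attr(ig, "weight")
  ig
}

#' The Zachary karate club network
#'
#' Loads the canonical 34-node, 78-link social network of a university
#' karate club, shipped with the package as a plain-text edge list. It is
#' the classic worked example for the topological descriptors.
#'
#' @return An undirected, unweighted [link_tbl()] with 34 nodes and 78 links.
#' @export
#' @examples
#' compute_stats(karate_club())
karate_club <- function() {
  path <- system.file("extdata", "karate.tsv", package = "mpdlink")
  g <- read_edge_list(path, directed = FALSE, weighted = FALSE)
  # node order 1..34 as in the canonical labelling
  link_tbl(as.data.frame(g), directed = FALSE,
           nodes = as.character(seq_len(34)))
}
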