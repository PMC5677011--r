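#' Neighbour sets of the undirected, unweighted view of a network
#'
#' The three local similarity indices are defined through the neighbour
#' sets Gamma(x). Directed links are symmetrised (a neighbour is any node
#' connected in either direction) and weights are ignored, matching the
#' standard binary definitions of the indices.
#'
#' @param g A [link_tbl()].
#' @return An object of class `neighbor_sets`: a named list of character
#'   vectors, one per node, plus a `degree` attribute.
#' @export
neighbor_sets <- function(g) {
  nodes <- network_nodes(g)
  nb <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(nb)) nb[[i]] <- character(0)
  if (nrow(g) > 0) {
    ends <- unique(rbind(
      data.frame(a = g$from, b = g$to),
      data.frame(a = g$to, b = g$from)
    ))
    sp <- split(ends$b, factor(ends$a, levels = nodes))
    for (v in names(sp)) nb[[v]] <- unique(sp[[v]])
  }
  structure(nb, degree = lengths(nb), class = "neighbor_sets")
}

lookup_neighbors <- function(ns, x) {
  if (!x %in% names(ns)) {
    abort_mpd(sprintf("Unknown node '%s'.", x), class = "mpdlink_lookup_error")
  }
  ns[[x]]
}

common_neighbors <- function(ns, x, y) {
  if (identical(x, y)) abort_mpd("Similarity indices require two distinct nodes.")
  intersect(lookup_neighbors(ns, x), lookup_neighbors(ns, y))
}

#' Local similarity indices: common neighbours, Adamic-Adar, resource allocation
#'
#' The three classical comparator indices for a candidate pair (x, y):
#' `cn_score` counts the common neighbours `|Gamma(x) ∩ Gamma(y)|`;
#' `aa_score` down-weights each common neighbour z by `1/ln(degree(z))`;
#' `ra_score` by `1/degree(z)`. All use the binary undirected view of the
#' network and are symmetric in (x, y).
#'
#' @param ns A [neighbor_sets()] object.
#' @param x,y Distinct node identifiers.
#' @return A single nonnegative number.
#' @export
#' @examples
#' ns <- neighbor_sets(link_tbl(data.frame(from = c("a", "b"), to = c("b", "c"))))
#' cn_score(ns, "a", "c") # 1
#' aa_score(ns, "a", "c") # 1/log(2)
#' ra_score(ns, "a", "c") # 1/2
cn_score <- function(ns, x, y) {
  length(common_neighbors(ns, x, y))
}

#' @rdname cn_score
#' @export
aa_score <- function(ns, x, y) {
  z <- common_neighbors(ns, x, y)
  if (length(z) == 0) return(0)
  sum(1 / log(attr(ns, "degree")[z]))
}

#' @rdname cn_score
#' @export
ra_score <- function(ns, x, y) {
  z <- common_neighbors(ns, x, y)
  if (length(z) == 0) return(0)
  sum(1 / attr(ns, "degree")[z])
}

#' Score candidate pairs with a local similarity index
#'
#' Vectorised driver for the baseline predictors: scores every row of
#' `pairs` with the chosen index computed on the undirected view of the
#' training network.
#'
#' @param training A [link_tbl()] of observed links.
#' @param pairs A data frame with columns `from` and `to` (e.g. a score
#'   table from [scores_from_matrix()], whose scores are replaced).
#' @param method One of `"cn"`, `"aa"`, `"ra"`.
#' @return `pairs` as a tibble with a `score` column.
#' @export
similarity_scores <- function(training, pairs, method = c("cn", "aa", "ra")) {
  method <- match.arg(method)
  ns <- neighbor_sets(training)
  fn <- switch(method, cn = cn_score, aa = aa_score, ra = ra_score)
  out <- tibble::as_tibble(as.data.frame(pairs)[, c("from", "to")])
  out$score <- vapply(seq_len(nrow(out)), function(i) {
    as.numeric(fn(ns, out$from[i], out$to[i]))
  }, numeric(1))
  attr(out, "directed") <- attr(pairs, "directed")
  attr(out, "nodes") <- attr(pairs, "nodes")
  out
}
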