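#' Topological descriptors of a network
#'
#' Computes the standard descriptor set on the binary undirected view of
#' the network: the mean local clustering coefficient C (nodes of degree
#' < 2 count 0), the degree assortativity r (Pearson correlation of
#' end-point degrees over edges), the mean degree `<k> = 2|E|/|V|`, the
#' mean shortest-path length `<d>` over connected ordered pairs, and the
#' degree heterogeneity `H = <k^2>/<k>^2` (exactly 1 for regular graphs,
#' larger the broader the degree distribution).
#'
#' @param g A nonempty [link_tbl()].
#' @return A one-row tibble: `n_nodes`, `n_links`, `clustering`,
#'   `assortativity`, `mean_degree`, `mean_distance`, `heterogeneity`.
#' @details On a disconnected network the mean distance is computed over
#'   the largest connected component, with a warning. Graph-level
#'   computations (clustering, assortativity, shortest paths) are
#'   delegated to igraph.
#' @export
#' @examples
#' compute_stats(karate_club())
compute_stats <- function(g) {
  stopifnot(inherits(g, "link_tbl"))
  if (length(network_nodes(g)) == 0) abort_mpd("The network is empty.")
  ig <- as_igraph(g, directed = FALSE, weighted = FALSE)
  ig <- igraph::simplify(ig)
  k <- igraph::degree(ig)
  lc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  comps <- igraph::components(ig)
  if (comps$no > 1) {
    rlang::warn("Network is disconnected: mean distance computed on the largest component.")
    giant <- igraph::induced_subgraph(ig, which(comps$membership == which.max(comps$csize)))
  } else {
    giant <- ig
  }
  tibble::tibble(
    n_nodes = igraph::vcount(ig),
    n_links = igraph::ecount(ig),
    clustering = mean(lc),
    assortativity = igraph::assortativity_degree(ig),
    mean_degree = mean(k),
    mean_distance = igraph::mean_distance(giant, directed = FALSE),
    heterogeneity = mean(k^2) / mean(k)^2
  )
}
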