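# Small graph builders shared across the suite.

path_graph <- function(nodes = c("a", "b", "c")) {
  n <- length(nodes)
  link_tbl(data.frame(from = nodes[-n], to = nodes[-1]), directed = FALSE)
}

star_graph <- function(center = "hub", leaves = c("l1", "l2", "l3")) {
  link_tbl(data.frame(from = center, to = leaves), directed = FALSE)
}

# Erdos-Renyi graph on n nodes with link probability p (undirected).
random_graph <- function(n, p, seed) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- withr::with_seed(seed, stats::runif(nrow(idx)) < p)
  nodes <- paste0("n", seq_len(n))
  link_tbl(data.frame(from = nodes[idx[keep, 1]], to = nodes[idx[keep, 2]]),
           directed = FALSE, nodes = nodes)
}

# random nonnegative zero-diagonal adjacency matrix
random_adjacency <- function(n, seed, directed = TRUE, density = 0.4) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n), n, n) * (matrix(stats::runif(n * n), n, n) < density)
    if (!directed) m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    dimnames(m) <- list(paste0("v", 1:n), paste0("v", 1:n))
    m
  })
}
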