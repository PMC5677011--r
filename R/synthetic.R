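#' Planted low-rank plus sparse matrix
#'
#' Fixture factory for the robust-PCA stage: generates
#' `observed = L0 + S0` with `L0 = X Y'` (X, Y standard normal n x r, so
#' L0 has rank r almost surely) and S0 holding `+/- corruption_magnitude`
#' at a uniformly random `corruption_fraction` of the entries (chosen
#' without replacement, signs independent and equiprobable). Ground truth
#' is returned, so recovery can be measured exactly.
#'
#' @param n Matrix dimension.
#' @param rank Planted rank r, `0 <= r <= n`.
#' @param corruption_fraction Fraction of entries corrupted, in \[0, 1).
#' @param corruption_magnitude Absolute value of the corruptions.
#' @param seed Integer seed.
#' @return A list with `observed`, `low_rank` (L0), `sparse` (S0).
#' @export
#' @examples
#' p <- planted_low_rank_sparse(50, 2, 0.01, 5, seed = 3)
#' fit <- rpca(p$observed, lambda = 1 / sqrt(50))
#' norm(fit$backbone - p$low_rank, "F") / norm(p$low_rank, "F")
planted_low_rank_sparse <- function(n, rank, corruption_fraction = 0.01,
                                    corruption_magnitude = 1, seed = 1L) {
  if (rank < 0 || rank > n) abort_mpd("`rank` must be between 0 and n.")
  assert_scalar_in(corruption_fraction, 0, 1, "corruption_fraction", open = FALSE)
  if (corruption_fraction >= 1) abort_mpd("`corruption_fraction` must be < 1.")
  if (corruption_magnitude <= 0) abort_mpd("`corruption_magnitude` must be positive.")
  withr_seed(seed, {
    L0 <- if (rank == 0) {
      matrix(0, n, n)
    } else {
      X <- matrix(stats::rnorm(n * rank), n, rank)
      Y <- matrix(stats::rnorm(n * rank), n, rank)
      X %*% t(Y)
    }
    S0 <- matrix(0, n, n)
    n_corrupt <- round(corruption_fraction * n * n)
    if (n_corrupt > 0) {
      idx <- sample.int(n * n, n_corrupt)
      S0[idx] <- corruption_magnitude * sample(c(-1, 1), n_corrupt, replace = TRUE)
    }
    list(observed = L0 + S0, low_rank = L0, sparse = S0)
  })
}

#' Stochastic block model graph
#'
#' Generates a planted-partition network: each node belongs to a block,
#' and every (ordered, if directed) node pair is linked independently with
#' probability `p_within` inside a block and `p_between` across blocks.
#' Links have unit weight. The assortative two-block default regime is the
#' stand-in for a real network's community structure in the end-to-end
#' pipeline tests.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param p_within,p_between Link probabilities in \[0, 1\].
#' @param directed Generate a directed network?
#' @param seed Integer seed.
#' @return A [link_tbl()] on nodes `v1..vn` (all nodes kept, including
#'   isolated ones).
#' @export
#' @examples
#' g <- sbm_graph(c(50, 50), 0.3, 0.02, seed = 1)
#' glance(split_edges(g, 0.1, seed = 1))
sbm_graph <- function(block_sizes, p_within, p_between, directed = FALSE,
                      seed = 1L) {
  assert_scalar_in(p_within, 0, 1, "p_within", open = FALSE)
  assert_scalar_in(p_between, 0, 1, "p_between", open = FALSE)
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  nodes <- paste0("v", seq_len(n))
  pairs <- if (directed) {
    idx <- cbind(rep(seq_len(n), times = n), rep(seq_len(n), each = n))
    idx[idx[, 1] != idx[, 2], , drop = FALSE]
  } else {
    which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  }
  p <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], p_within, p_between)
  keep <- withr_seed(seed, stats::runif(nrow(pairs)) < p)
  link_tbl(
    data.frame(from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]],
               weight = rep(1, sum(keep))),
    directed = directed, nodes = nodes
  )
}
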