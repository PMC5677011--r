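#' Random train/probe split of a network's links
#'
#' Uniformly samples `round(probe_fraction * |E|)` links (never fewer than
#' one, never all of them) as the probe set, treated as missing; the
#' complement is the training set, treated as observed. For undirected
#' networks the sampling unit is the unordered pair. Rounding is
#' half-away-from-zero.
#'
#' @param g A [link_tbl()] with at least 2 links.
#' @param probe_fraction Fraction of links to hide, in (0, 1). The
#'   standard benchmark protocol keeps 90% for training (`0.1` here).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return An object of class `edge_split`: list with `training` and
#'   `probe` (both [link_tbl()]s on the full node set), plus `seed` and
#'   `probe_fraction`.
#' @export
#' @examples
#' g <- karate_club()
#' sp <- split_edges(g, 0.1, seed = 1)
#' glance(sp)
split_edges <- function(g, probe_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(g, "link_tbl"))
  assert_scalar_in(probe_fraction, 0, 1, "probe_fraction")
  m <- nrow(g)
  if (m < 2L) abort_mpd("Need at least 2 links to split.")
  size <- max(1L, as.integer(round_half_up(probe_fraction * m)))
  if (size >= m) size <- m - 1L
  idx <- withr_seed(seed, sample.int(m, size))
  nodes <- network_nodes(g)
  directed <- is_directed_network(g)
  probe <- link_tbl(as.data.frame(g[idx, ]), directed = directed, nodes = nodes)
  training <- link_tbl(as.data.frame(g[-idx, ]), directed = directed, nodes = nodes)
  structure(
    list(training = training, probe = probe,
         seed = seed, probe_fraction = probe_fraction),
    class = "edge_split"
  )
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf("Edge split (seed %d): %d training links, %d probe links\n",
              x$seed, nrow(x$training), nrow(x$probe)))
  invisible(x)
}

#' @method glance edge_split
#' @export
glance.edge_split <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(network_nodes(x$training)),
    n_training = nrow(x$training),
    n_probe = nrow(x$probe),
    probe_fraction = x$probe_fraction,
    seed = x$seed
  )
}

#' @method tidy edge_split
#' @export
tidy.edge_split <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(as.data.frame(x$training)), set = "training"),
    dplyr::mutate(tibble::as_tibble(as.data.frame(x$probe)), set = "probe")
  )
}

pair_key <- function(from, to, directed) {
  if (directed) {
    paste(from, to, sep = "\r")
  } else {
    paste(pmin(from, to), pmax(from, to), sep = "\r")
  }
}

#' Candidate scores read off a score matrix
#'
#' Builds the score table of a predictor from a full score matrix (e.g.
#' the robust-PCA backbone or the perturbed matrix itself): the candidates
#' are all non-self node pairs absent from the training link set, each
#' scored by its matrix entry under the column-source/row-target
#' convention. For undirected evaluation a candidate is an unordered pair
#' scored by the mean of its two entries.
#'
#' @param score_matrix An n x n numeric matrix aligned with the node order
#'   of the split's training network.
#' @param split An [split_edges()] result.
#' @param directed Evaluate ordered pairs? Defaults to the training
#'   network's directedness.
#' @return A tibble with columns `from`, `to`, `score` (class
#'   `score_table`), carrying `directed` and `nodes` attributes. Empty,
#'   with a warning, when the training graph is complete.
#' @export
scores_from_matrix <- function(score_matrix, split,
                               directed = is_directed_network(split$training)) {
  stopifnot(inherits(split, "edge_split"))
  nodes <- network_nodes(split$training)
  n <- length(nodes)
  assert_square(score_matrix, "score_matrix")
  if (nrow(score_matrix) != n) {
    abort_mpd("`score_matrix` dimension does not match the node count.")
  }
  # all non-self candidate pairs
  if (directed) {
    from <- rep(nodes, each = n); to <- rep(nodes, times = n)
    ok <- from != to
    from <- from[ok]; to <- to[ok]
    score <- score_matrix[cbind(match(to, nodes), match(from, nodes))]
  } else {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    from <- nodes[idx[, 1]]; to <- nodes[idx[, 2]]
    score <- (score_matrix[idx] + score_matrix[idx[, c(2, 1), drop = FALSE]]) / 2
  }
  train_keys <- pair_key(split$training$from, split$training$to, directed)
  keep <- !(pair_key(from, to, directed) %in% train_keys)
  out <- tibble::tibble(from = from[keep], to = to[keep], score = score[keep])
  if (nrow(out) == 0) {
    rlang::warn("Training graph is complete: no candidate pairs to score.")
  }
  attr(out, "directed") <- directed
  attr(out, "nodes") <- nodes
  class(out) <- c("score_table", class(tibble::tibble()))
  out
}

# probe membership indicator aligned with the score table rows
probe_indicator <- function(st, probe) {
  directed <- isTRUE(attr(st, "directed"))
  pk <- if (inherits(probe, "link_tbl") || is.data.frame(probe)) {
    pair_key(as.character(probe$from), as.character(probe$to), directed)
  } else {
    abort_mpd("`probe` must be a data frame of links.")
  }
  ck <- pair_key(st$from, st$to, directed)
  if (!all(pk %in% ck)) {
    abort_mpd("Some probe links are not candidates: the split and the score table disagree.",
              class = "mpdlink_consistency_error")
  }
  ck %in% pk
}

#' Precision of the top-L predicted links
#'
#' Ranks the candidates by score in descending order (ties broken by a
#' seeded random shuffle, avoiding any systematic insertion-order bias)
#' and reports the fraction of the top `L` that belong to the probe set.
#' The benchmark convention takes `L` equal to the probe size.
#'
#' @param st A score table from [scores_from_matrix()] or
#'   [similarity_scores()].
#' @param probe The probe links (a data frame with `from`, `to`).
#' @param L Number of predictions to take; defaults to `nrow(probe)`.
#' @param seed Seed for the tie-breaking shuffle.
#' @return Precision in \[0, 1\].
#' @export
precision_at_l <- function(st, probe, L = nrow(probe), seed = 1L) {
  if (L < 1 || L > nrow(st)) {
    abort_mpd("`L` must be between 1 and the number of candidates.")
  }
  hit <- probe_indicator(st, probe)
  shuffle <- withr_seed(seed, sample.int(nrow(st)))
  ord <- order(-st$score, shuffle)
  sum(hit[ord[seq_len(L)]]) / L
}

#' AUC of a score table against a probe set
#'
#' The probability that a randomly chosen missing (probe) link scores
#' higher than a randomly chosen nonexistent link, ties counted half:
#' `AUC = (n' + 0.5 n'') / n`. In exact mode the Mann-Whitney statistic is
#' computed over all probe x nonexistent pairs via midranks; in sampled
#' mode `n_comparisons` independent random comparisons are drawn.
#'
#' @inheritParams precision_at_l
#' @param n_comparisons `"exact"` (default for small problems) or a
#'   positive integer number of sampled comparisons.
#' @param seed Seed for sampled mode.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' # probe scores {3, 1} vs nonexistent {2, 0}: 3 of 4 comparisons win
#' st <- tibble::tibble(from = "a", to = c("b", "c", "d", "e"),
#'                      score = c(3, 1, 2, 0))
#' attr(st, "directed") <- TRUE
#' auc_score(st, data.frame(from = "a", to = c("b", "c"))) # 0.75
auc_score <- function(st, probe, n_comparisons = "exact", seed = 1L) {
  hit <- probe_indicator(st, probe)
  pos <- st$score[hit]
  neg <- st$score[!hit]
  if (length(pos) == 0) abort_mpd("The probe set is empty.")
  if (length(neg) == 0) {
    abort_mpd("No nonexistent candidate links: AUC is undefined.")
  }
  if (identical(n_comparisons, "exact")) {
    r <- rank(c(pos, neg)) # midranks give half credit to ties
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  } else {
    n <- as.integer(n_comparisons)
    if (is.na(n) || n < 1) abort_mpd("`n_comparisons` must be 'exact' or a positive integer.")
    withr_seed(seed, {
      p <- pos[sample.int(length(pos), n, replace = TRUE)]
      q <- neg[sample.int(length(neg), n, replace = TRUE)]
      (sum(p > q) + 0.5 * sum(p == q)) / n
    })
  }
}

#' Evaluate a score table on a split: precision@L and AUC together
#'
#' @inheritParams precision_at_l
#' @param split The [split_edges()] result whose probe set is the target.
#' @param auc_mode `"exact"`, `"auto"` (exact when the number of
#'   probe x nonexistent comparisons is at most 1e8, else sampled with
#'   672,400 draws), or an integer number of sampled comparisons.
#' @return A one-row tibble: `precision`, `auc`, `L`, `n_candidates`.
#' @export
evaluate_scores <- function(st, split, L = nrow(split$probe),
                            auc_mode = "auto", seed = 1L) {
  hit_n <- nrow(split$probe)
  neg_n <- nrow(st) - hit_n
  n_comp <- if (identical(auc_mode, "auto")) {
    if (as.numeric(hit_n) * neg_n <= 1e8) "exact" else 672400L
  } else if (identical(auc_mode, "exact")) "exact" else as.integer(auc_mode)
  tibble::tibble(
    precision = precision_at_l(st, split$probe, L = L, seed = seed),
    auc = auc_score(st, split$probe, n_comparisons = n_comp, seed = seed),
    L = as.integer(L),
    n_candidates = nrow(st)
  )
}
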