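#' Split a matrix into symmetric and antisymmetric parts
#'
#' Any square matrix A decomposes uniquely as A = A_S + A_AS with
#' A_S = (A + t(A))/2 symmetric and A_AS = (A - t(A))/2 antisymmetric.
#' For a weighted directed adjacency matrix, A_S is read as the average
#' linking tendency between a node pair and A_AS as the directional bias
#' of that tendency; the perturbation stage operates on A_S only and A_AS
#' is re-added afterwards.
#'
#' @param m A square numeric matrix.
#' @return A list of class `sym_split` with elements `symmetric` and
#'   `antisymmetric`; their sum reconstructs `m` to machine precision.
#' @export
#' @examples
#' symmetric_split(matrix(c(0, 0, 2, 0), 2, 2))
symmetric_split <- function(m) {
  assert_square(m)
  structure(list(symmetric = (m + t(m)) / 2, antisymmetric = (m - t(m)) / 2),
            class = "sym_split")
}

#' Full spectral decomposition of a symmetric matrix
#'
#' Wraps the symmetric eigensolver with a symmetry check and returns the
#' spectrum in descending eigenvalue order with orthonormal eigenvectors,
#' the basis the structural perturbation step keeps fixed.
#'
#' @param s A symmetric numeric matrix (checked within `1e-10`).
#' @return A list of class `eigen_system` with `values` (descending) and
#'   `vectors` (orthonormal columns aligned with `values`).
#' @export
eigen_decompose <- function(s) {
  assert_square(s, "s")
  if (max(abs(s - t(s))) > 1e-10) {
    abort_mpd("`s` must be symmetric (within 1e-10).")
  }
  es <- eigen((s + t(s)) / 2, symmetric = TRUE)
  structure(list(values = es$values, vectors = es$vectors),
            class = "eigen_system")
}

#' First-order eigenvalue shifts under a symmetric perturbation
#'
#' For a symmetric matrix with spectrum `es` perturbed by a symmetric
#' `delta`, the first-order change of each eigenvalue is the Rayleigh
#' quotient of `delta` in the unperturbed eigenvector:
#' `d_lambda_k = (x_k' delta x_k) / (x_k' x_k)`. Eigenvectors are held
#' fixed; the approximation error is second order in `||delta||`.
#'
#' @param es An [eigen_decompose()] result.
#' @param delta A symmetric matrix of the same dimension.
#' @return Numeric vector of shifts aligned with `es$values`.
#' @details The formula is applied verbatim to whatever orthonormal basis
#'   the eigensolver returned; when the spectrum has a near-degenerate pair
#'   (gap below `1e-8`) the per-mode shifts depend on that basis choice and
#'   a warning is issued.
#' @export
first_order_shifts <- function(es, delta) {
  stopifnot(inherits(es, "eigen_system"))
  assert_square(delta, "delta")
  if (nrow(delta) != nrow(es$vectors)) {
    abort_mpd("`delta` dimension does not match the decomposed matrix.")
  }
  if (max(abs(delta - t(delta))) > 1e-10) {
    abort_mpd("`delta` must be symmetric (within 1e-10).")
  }
  gaps <- abs(diff(es$values))
  if (length(gaps) > 0 && any(gaps < 1e-8)) {
    rlang::warn("Near-degenerate eigenvalues (gap < 1e-8): first-order shifts are basis-dependent.")
  }
  x <- es$vectors
  colSums(x * (delta %*% x)) / colSums(x * x)
}

# Build the adjacency of a set of perturbation links on the frame of the
# training matrix, validating that every link is a training link.
perturbation_adjacency <- function(training, links, undirected_pairs) {
  nodes <- rownames(training)
  fi <- match(as.character(links$from), nodes)
  ti <- match(as.character(links$to), nodes)
  if (anyNA(fi) || anyNA(ti)) {
    abort_mpd("Perturbation links mention nodes absent from the training matrix.")
  }
  d <- matrix(0, nrow(training), ncol(training), dimnames = dimnames(training))
  w <- training[cbind(ti, fi)] # row = target, column = source
  if (any(w == 0)) {
    abort_mpd("Perturbation links must be a subset of the training links.")
  }
  d[cbind(ti, fi)] <- w
  if (undirected_pairs) d[cbind(fi, ti)] <- training[cbind(fi, ti)]
  d
}

#' One structural perturbation of a training adjacency matrix
#'
#' Removes the given perturbation links (with their full weights) from the
#' training matrix, diagonalises the symmetric part of the remainder, and
#' rebuilds the matrix from the unperturbed eigenvectors with eigenvalues
#' corrected to first order for re-adding the removed links:
#' `sum_k (lambda_k + d_lambda_k) x_k x_k'`. The output extrapolates the
#' remainder's structural consistency to the full training matrix and is
#' exactly symmetric.
#'
#' @param training Square nonnegative adjacency matrix of the training
#'   links (row = target, column = source), with node dimnames.
#' @param perturbation_links Data frame with columns `from` and `to`
#'   naming a nonempty proper subset of the training links.
#' @param undirected_pairs Logical; if `TRUE` a link is an unordered pair
#'   and removing it clears both matrix entries.
#' @return A symmetric numeric matrix of the same dimension.
#' @export
spm_single <- function(training, perturbation_links,
                       undirected_pairs = FALSE) {
  assert_square(training, "training")
  if (is.null(rownames(training))) {
    dimnames(training) <- list(paste0("v", seq_len(nrow(training))),
                               paste0("v", seq_len(nrow(training))))
  }
  if (nrow(perturbation_links) == 0L) {
    abort_mpd("The perturbation set must be nonempty.")
  }
  dA <- perturbation_adjacency(training, perturbation_links, undirected_pairs)
  remainder <- training - dA
  if (all(remainder == 0)) {
    abort_mpd("The perturbation set must be a proper subset of the training links.")
  }
  delta <- symmetric_split(dA)$symmetric
  es <- eigen_decompose(symmetric_split(remainder)$symmetric)
  shifts <- first_order_shifts(es, delta)
  out <- es$vectors %*% (t(es$vectors) * (es$values + shifts))
  out <- (out + t(out)) / 2 # enforce exact symmetry
  dimnames(out) <- dimnames(training)
  out
}

#' Averaged structural perturbation estimate of a training network
#'
#' The perturbation stage of the predictor. Draws `n_selections`
#' independent uniform subsets of the training links (each a fraction
#' `fraction` of them, without replacement), applies [spm_single()] to
#' each, averages the symmetric estimates, and finally re-adds the
#' antisymmetric part of the full training matrix, which is assumed
#' unchanged by the perturbation. For undirected networks the sampling
#' unit is the unordered pair and the result is symmetric.
#'
#' @param training A training network as a [link_tbl()] (e.g. the
#'   `training` element of [split_edges()]).
#' @param fraction Fraction of training links per perturbation set,
#'   in (0, 1). Default 0.1.
#' @param n_selections Number of independent perturbation sets averaged.
#'   Default 10.
#' @param seed Integer seed making the subset draws reproducible.
#' @return An object of class `spm_estimate`: list with `values` (the
#'   perturbed matrix), `n_selections`, `fraction`, `directed`, `nodes`.
#' @export
#' @examples
#' g <- sbm_graph(c(10, 10), 0.8, 0.1, seed = 1)
#' est <- spm_estimate(g, seed = 7)
#' glance(est)
spm_estimate <- function(training, fraction = 0.1, n_selections = 10,
                         seed = 1L) {
  stopifnot(inherits(training, "link_tbl"))
  assert_scalar_in(fraction, 0, 1, "fraction")
  if (n_selections < 1) abort_mpd("`n_selections` must be >= 1.")
  m_links <- nrow(training)
  if (m_links < 2L) abort_mpd("The training network needs at least 2 links.")
  size <- max(1L, as.integer(round_half_up(fraction * m_links)))
  if (size >= m_links) size <- m_links - 1L
  A <- as_adjacency(training)
  undirected <- !is_directed_network(training)
  acc <- matrix(0, nrow(A), ncol(A))
  n_degenerate <- 0L
  withr_seed(seed, {
    for (s in seq_len(n_selections)) {
      idx <- sample.int(m_links, size)
      # collapse the per-selection degeneracy warnings into one summary
      withCallingHandlers(
        acc <- acc + spm_single(A, training[idx, , drop = FALSE],
                                undirected_pairs = undirected),
        warning = function(w) {
          if (grepl("Near-degenerate", conditionMessage(w))) {
            n_degenerate <<- n_degenerate + 1L
            invokeRestart("muffleWarning")
          }
        }
      )
    }
  })
  if (n_degenerate > 0) {
    rlang::warn(sprintf(
      "Near-degenerate eigenvalues in %d of %d perturbation selections; first-order shifts are basis-dependent there.",
      n_degenerate, n_selections
    ))
  }
  values <- acc / n_selections + symmetric_split(A)$antisymmetric
  dimnames(values) <- dimnames(A)
  structure(
    list(values = values, n_selections = n_selections, fraction = fraction,
         directed = !undirected, nodes = rownames(A)),
    class = "spm_estimate"
  )
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' @export
print.spm_estimate <- function(x, ...) {
  cat(sprintf(
    "Structural perturbation estimate: %d nodes, %d selections of %.0f%% of training links%s\n",
    length(x$nodes), x$n_selections, 100 * x$fraction,
    if (x$directed) " (directed)" else ""
  ))
  invisible(x)
}

#' @method glance spm_estimate
#' @export
glance.spm_estimate <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_selections = x$n_selections,
    perturbation_fraction = x$fraction,
    directed = x$directed,
    asymmetry = max(abs(x$values - t(x$values)))
  )
}

#' @method tidy spm_estimate
#' @export
tidy.spm_estimate <- function(x, ...) {
  nodes <- x$nodes
  n <- length(nodes)
  out <- tibble::tibble(
    from = rep(nodes, each = n),  # column = source
    to = rep(nodes, times = n),   # row = target
    score = as.vector(x$values)   # column-major walk of values[to, from]
  )
  out[out$from != out$to, ]
}

#' @method autoplot spm_estimate
#' @export
autoplot.spm_estimate <- function(object, ...) {
  df <- expand.grid(target = object$nodes, source = object$nodes,
                    stringsAsFactors = FALSE)
  df$value <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$source, object$nodes),
                                   y = factor(.data$target, rev(object$nodes)),
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "source", y = "target",
                  title = "Perturbed adjacency estimate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
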