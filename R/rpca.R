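#' Elementwise soft thresholding
#'
#' The proximal operator of the l1 norm: shrinks every entry towards zero
#' by `tau`, i.e. `sign(x) * max(|x| - tau, 0)`. One of the two alternating
#' steps of the robust-PCA solver.
#'
#' @param m A numeric matrix (or vector).
#' @param tau Nonnegative threshold.
#' @return A matrix of the same shape.
#' @export
#' @examples
#' soft_threshold(matrix(c(3, -1), 1), 1) # 2, 0
soft_threshold <- function(m, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    abort_mpd("`tau` must be a single nonnegative number.")
  }
  sign(m) * pmax(abs(m) - tau, 0)
}

#' Singular value thresholding
#'
#' The proximal operator of the nuclear norm: soft-thresholds the singular
#' values, `U shrink(S, tau) V'`, shrinking towards low rank. The other
#' alternating step of the robust-PCA solver.
#'
#' @param m A numeric matrix.
#' @param tau Nonnegative threshold applied to the singular values.
#' @return A matrix of the same shape with singular values reduced by
#'   `tau` (values below `tau` removed).
#' @export
singular_value_threshold <- function(m, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    abort_mpd("`tau` must be a single nonnegative number.")
  }
  sv <- svd(m)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Robust PCA: low-rank + sparse decomposition
#'
#' Splits a matrix into a low-rank backbone `B` and a sparse noise part
#' `N` by solving the convex program
#' `min ||B||_* + lambda ||N||_1  subject to  m = B + N`
#' (nuclear norm plus l1), the standard convex relaxation of the
#' rank-plus-cardinality objective. Solved with the inexact augmented
#' Lagrange multiplier method: alternating singular value thresholding on
#' `m - N + Y/mu` (threshold `1/mu`) and soft thresholding on
#' `m - B + Y/mu` (threshold `lambda/mu`), with dual update
#' `Y <- Y + mu (m - B - N)` and `mu <- rho mu`.
#'
#' In the link predictor the input is the perturbed adjacency estimate and
#' the recovered backbone is the score matrix; `lambda` balances rank
#' against sparsity, with larger values forcing the noise part to zero.
#'
#' @param m A finite numeric square (or rectangular) matrix.
#' @param lambda Positive balance parameter; the classic default for an
#'   n x n matrix is `1/sqrt(n)`.
#' @param tol Convergence tolerance on the relative constraint violation
#'   `||m - B - N||_F / ||m||_F`. Default 1e-7.
#' @param max_iter Iteration cap. Default 1000.
#' @param mu0,rho Initial penalty and its growth factor; defaults
#'   `1.25/||m||_2` and 1.5, the standard choices for this solver.
#' @return An object of class `rpca_result`: list with `backbone`,
#'   `noise`, `lambda`, `iterations`, `converged`, `residual`.
#' @export
#' @examples
#' p <- planted_low_rank_sparse(30, 2, 0.02, 3, seed = 1)
#' fit <- rpca(p$observed, lambda = 1 / sqrt(30))
#' glance(fit)
rpca <- function(m, lambda = 1 / sqrt(max(dim(m))), tol = 1e-7,
                 max_iter = 1000, mu0 = NULL, rho = 1.5) {
  if (!is.matrix(m) || !is.numeric(m)) abort_mpd("`m` must be a numeric matrix.")
  if (any(!is.finite(m))) abort_mpd("`m` must have finite entries.")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    abort_mpd("`lambda` must be a single positive number.")
  }
  norm_f <- sqrt(sum(m^2))
  if (norm_f == 0) {
    return(structure(
      list(backbone = m, noise = m, lambda = lambda, iterations = 1L,
           converged = TRUE, residual = 0),
      class = "rpca_result"
    ))
  }
  norm_2 <- svd(m, nu = 0, nv = 0)$d[1]
  norm_inf <- max(abs(m))
  if (is.null(mu0)) mu0 <- 1.25 / norm_2
  mu <- mu0
  Y <- m / max(norm_2, norm_inf / lambda)
  B <- matrix(0, nrow(m), ncol(m))
  N <- matrix(0, nrow(m), ncol(m))
  residual <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    B <- singular_value_threshold(m - N + Y / mu, 1 / mu)
    N <- soft_threshold(m - B + Y / mu, lambda / mu)
    R <- m - B - N
    Y <- Y + mu * R
    mu <- rho * mu
    residual <- sqrt(sum(R^2)) / norm_f
    if (residual < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    rlang::warn(sprintf(
      "Robust PCA did not converge in %d iterations (residual %.3g).",
      max_iter, residual
    ))
  }
  dimnames(B) <- dimnames(m)
  dimnames(N) <- dimnames(m)
  structure(
    list(backbone = B, noise = N, lambda = lambda, iterations = it,
         converged = converged, residual = residual),
    class = "rpca_result"
  )
}

#' @export
print.rpca_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Robust PCA decomposition (lambda = %.4g): backbone rank %d, noise density %.1f%%\n  %s in %d iterations (relative residual %.2e)\n",
    x$lambda, g$rank_backbone, 100 * g$noise_density,
    if (x$converged) "converged" else "NOT converged", x$iterations,
    x$residual
  ))
  invisible(x)
}

# numerical rank at a relative singular-value cutoff
numerical_rank <- function(m, rtol = 1e-6) {
  d <- svd(m, nu = 0, nv = 0)$d
  if (length(d) == 0 || d[1] == 0) return(0L)
  sum(d > rtol * d[1])
}

#' @method glance rpca_result
#' @export
glance.rpca_result <- function(x, ...) {
  d <- svd(x$backbone, nu = 0, nv = 0)$d
  tibble::tibble(
    lambda = x$lambda,
    iterations = x$iterations,
    converged = x$converged,
    residual = x$residual,
    rank_backbone = numerical_rank(x$backbone),
    noise_density = mean(x$noise != 0),
    nuclear_norm = sum(d),
    l1_norm = sum(abs(x$noise)),
    objective = sum(d) + x$lambda * sum(abs(x$noise))
  )
}

#' @method tidy rpca_result
#' @export
tidy.rpca_result <- function(x, ...) {
  tibble::tibble(
    component = seq_len(min(dim(x$backbone))),
    singular_value = svd(x$backbone, nu = 0, nv = 0)$d
  )
}

#' @method autoplot rpca_result
#' @export
autoplot.rpca_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$singular_value)) +
    ggplot2::geom_point() +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$component, yend = 0)) +
    ggplot2::labs(x = "component", y = "singular value",
                  title = sprintf("Backbone spectrum (lambda = %.3g)", object$lambda)) +
    ggplot2::theme_minimal()
}

#' Sweep the robust-PCA balance parameter over a grid
#'
#' Runs [rpca()] once per grid value, scores each decomposition with the
#' supplied evaluator, and returns the best value (ties broken towards the
#' smallest lambda) together with the full score table. The default grid,
#' 0.01 to 0.39 in steps of 0.01, spans the interval where the optimum
#' falls for most real networks.
#'
#' @param m Matrix to decompose.
#' @param grid Ordered vector of positive lambda values.
#' @param evaluator Function taking an `rpca_result` and returning a
#'   single numeric score (larger is better).
#' @param ... Passed on to [rpca()].
#' @return An object of class `lambda_sweep`: list with `best_lambda`,
#'   `best_score` and `scores` (a tibble of lambda, score).
#' @export
lambda_sweep <- function(m, grid = default_lambda_grid(), evaluator, ...) {
  if (length(grid) == 0) abort_mpd("`grid` must be nonempty.")
  if (any(grid <= 0)) abort_mpd("All `grid` values must be positive.")
  scores <- vapply(grid, function(l) {
    as.numeric(evaluator(rpca(m, lambda = l, ...)))
  }, numeric(1))
  best <- which.max(scores) # first maximum = smallest lambda on ties
  structure(
    list(best_lambda = grid[best], best_score = scores[best],
         scores = tibble::tibble(lambda = grid, score = scores)),
    class = "lambda_sweep"
  )
}

#' @rdname lambda_sweep
#' @export
default_lambda_grid <- function() seq(0.01, 0.39, by = 0.01)

#' @export
print.lambda_sweep <- function(x, ...) {
  cat(sprintf("Lambda sweep over %d values: best lambda = %.3g (score %.4g)\n",
              nrow(x$scores), x$best_lambda, x$best_score))
  invisible(x)
}

#' @method tidy lambda_sweep
#' @export
tidy.lambda_sweep <- function(x, ...) x$scores

#' @method autoplot lambda_sweep
#' @export
autoplot.lambda_sweep <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(.data$lambda, .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_lambda, linetype = 2) +
    ggplot2::labs(title = "Balance-parameter sweep",
                  x = expression(lambda), y = "score") +
    ggplot2::theme_minimal()
}
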