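test_that("symmetric/antisymmetric split is exact and idempotent on symmetric input", {
  m <- matrix(c(0, 0, 2, 0), 2, 2) # single entry m[1,2] = 2
  sp <- symmetric_split(m)
  expect_equal(sp$symmetric, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sp$antisymmetric, matrix(c(0, -1, 1, 0), 2, 2))

  s <- random_adjacency(5, 1, directed = FALSE)
  sp2 <- symmetric_split(s)
  expect_equal(sp2$symmetric, s)
  expect_equal(sp2$antisymmetric, matrix(0, 5, 5, dimnames = dimnames(s)))

  for (seed in 1:20) {
    m <- matrix(rnorm(25), 5, 5)
    sp <- symmetric_split(m)
    expect_identical(sp$symmetric, t(sp$symmetric))
    expect_identical(sp$antisymmetric, -t(sp$antisymmetric))
    expect_equal(sp$symmetric + sp$antisymmetric, m)
  }
  expect_error(symmetric_split(matrix(0, 2, 3)))
})

test_that("spectral decomposition returns a descending orthonormal system", {
  es <- eigen_decompose(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(es$values, c(1, -1))
  expect_equal(abs(es$vectors[, 1]), rep(1 / sqrt(2), 2))
  expect_equal(abs(crossprod(es$vectors)), diag(2))

  expect_equal(eigen_decompose(diag(3) * 2.5)$values, rep(2.5, 3))

  s <- crossprod(matrix(withr::with_seed(3, rnorm(64)), 8, 8))
  s <- (s + t(s)) / 2
  es <- eigen_decompose(s)
  recon <- es$vectors %*% (t(es$vectors) * es$values)
  expect_lt(norm(recon - s, "F") / norm(s, "F"), 1e-8)
  expect_false(is.unsorted(rev(es$values)))

  expect_error(eigen_decompose(matrix(c(0, 0, 1, 0), 2, 2)), "symmetric")
})

test_that("first-order shifts match closed forms for structured perturbations", {
  s <- random_adjacency(6, 2, directed = FALSE)
  es <- eigen_decompose(s)
  expect_equal(first_order_shifts(es, diag(6) * 1e-3), rep(1e-3, 6))
  expect_equal(first_order_shifts(es, 0.37 * s), 0.37 * es$values)
  expect_error(first_order_shifts(es, diag(5)), "dimension")
})

test_that("first-order shifts agree with exact re-diagonalisation to second order", {
  withr::with_seed(11, {
    s <- matrix(rnorm(36), 6, 6); s <- (s + t(s)) / 2
    d <- matrix(rnorm(36), 6, 6); d <- (d + t(d)) / 2
    d <- d / norm(d, "F") * 1e-3
  })
  es <- eigen_decompose(s)
  approx_vals <- sort(es$values + first_order_shifts(es, d), decreasing = TRUE)
  exact_vals <- eigen(s + d, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(approx_vals - exact_vals)), 1e-4)
})

test_that("a single structural perturbation reproduces the frozen path fixture", {
  # 4-node path a-b-c-d, unit weights; perturbation removes c-d, leaving a
  # path on {a,b,c} plus an isolated node. Expected output computed by the
  # explicit eigendecomposition formula, frozen below.
  g <- path_graph(c("a", "b", "c", "d"))
  A <- as_adjacency(g)
  out <- spm_single(A, data.frame(from = "c", to = "d"),
                    undirected_pairs = TRUE)
  frozen <- matrix(c(0, 1, 0, 0,
                     1, 0, 1, 0,
                     0, 1, 0, 0,
                     0, 0, 0, 0), 4, 4, byrow = TRUE,
                   dimnames = dimnames(A))
  expect_equal(out, frozen, tolerance = 1e-10)

  # independent oracle: the explicit formula, recomputed in place
  dA <- matrix(0, 4, 4, dimnames = dimnames(A)); dA[3, 4] <- dA[4, 3] <- 1
  es <- eigen(A - dA, symmetric = TRUE)
  sh <- vapply(1:4, function(k) {
    drop(es$vectors[, k] %*% dA %*% es$vectors[, k])
  }, numeric(1))
  oracle <- es$vectors %*% (t(es$vectors) * (es$values + sh))
  expect_equal(unname(out), unname((oracle + t(oracle)) / 2), tolerance = 1e-10)
})

test_that("single perturbations are symmetric and validate their link set", {
  A <- random_adjacency(8, 5, directed = TRUE)
  g <- from_adjacency(A, directed = TRUE)
  links <- as.data.frame(g)[1:3, ]
  out <- spm_single(A, links)
  expect_identical(out, t(out))

  expect_error(spm_single(A, links[0, ]), "nonempty")
  expect_error(spm_single(A, as.data.frame(g)), "proper subset")
  expect_error(spm_single(A, data.frame(from = "v1", to = "zz")), "absent")
  # a pair that is not a training link
  nonlink <- which(A == 0 & upper.tri(A), arr.ind = TRUE)[1, ]
  expect_error(
    spm_single(A, data.frame(from = colnames(A)[nonlink[2]],
                             to = rownames(A)[nonlink[1]])),
    "subset"
  )
})

test_that("the averaged perturbation estimate is reproducible and symmetric when undirected", {
  g <- sbm_graph(c(12, 12), 0.5, 0.1, seed = 4)
  e1 <- spm_estimate(g, fraction = 0.1, n_selections = 5, seed = 9)
  e2 <- spm_estimate(g, fraction = 0.1, n_selections = 5, seed = 9)
  expect_identical(e1$values, e2$values) # bitwise determinism
  expect_identical(e1$values, t(e1$values)) # undirected closure

  e3 <- spm_estimate(g, fraction = 0.1, n_selections = 5, seed = 10)
  expect_false(identical(e1$values, e3$values))

  expect_error(spm_estimate(g, fraction = 1.2), class = "mpdlink_error")
  expect_error(spm_estimate(g, fraction = 0), class = "mpdlink_error")
})

test_that("one selection equals a single perturbation plus the antisymmetric part", {
  A <- random_adjacency(9, 7, directed = TRUE)
  g <- from_adjacency(A, directed = TRUE)
  m <- nrow(g)
  size <- max(1L, round(0.2 * m))
  est <- spm_estimate(g, fraction = 0.2, n_selections = 1, seed = 33)
  idx <- mpdlink:::withr_seed(33, sample.int(m, size))
  manual <- spm_single(A, as.data.frame(g)[idx, ], undirected_pairs = FALSE) +
    symmetric_split(A)$antisymmetric
  expect_equal(est$values, manual)
})

test_that("only the symmetric part enters the perturbation stage", {
  # two directed matrices with identical symmetric parts but different
  # antisymmetric parts must give identical spm_single outputs
  A1 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A1["b", "a"] <- 2; A1["c", "b"] <- 2 # a->b->c
  A2 <- t(A1) # reversed cycle: same symmetric part
  links <- data.frame(from = "a", to = "b")
  out1 <- spm_single(A1, links)
  # the reversed link in A2 has the same symmetric perturbation part
  out2 <- spm_single(A2, data.frame(from = "b", to = "a"))
  expect_equal(unname(out1), unname(out2))
})
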