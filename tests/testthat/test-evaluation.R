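test_that("train/probe splits are exhaustive, disjoint and reproducible", {
  g <- karate_club() # 78 links
  sp <- split_edges(g, 0.1, seed = 3)
  expect_equal(nrow(sp$probe), 8) # round(7.8) half-away-from-zero
  expect_equal(nrow(sp$training), 70)
  tk <- paste(sp$training$from, sp$training$to)
  pk <- paste(sp$probe$from, sp$probe$to)
  expect_length(intersect(tk, pk), 0)
  expect_setequal(c(tk, pk), paste(g$from, g$to))

  sp2 <- split_edges(g, 0.1, seed = 3)
  expect_identical(tidy(sp), tidy(sp2))
  sp3 <- split_edges(g, 0.1, seed = 4)
  expect_false(identical(tidy(sp)$from, tidy(sp3)$from))

  # probe never rounds down to zero
  tiny <- split_edges(g, 0.001, seed = 1)
  expect_equal(nrow(tiny$probe), 1)

  expect_error(split_edges(g, 1.5), class = "mpdlink_error")
  # both split halves keep the full node set
  expect_identical(network_nodes(sp$training), network_nodes(g))
})

test_that("score tables are read off the matrix with the right convention", {
  g <- link_tbl(data.frame(from = c("a", "b"), to = c("b", "c")),
                directed = TRUE)
  sp <- list(training = g, probe = g[0, ], seed = 1L, probe_fraction = 0.1)
  class(sp) <- "edge_split"
  backbone <- matrix(c(0.0, 0.5, 0.9,
                       0.1, 0.0, 0.4,
                       0.8, 0.3, 0.0), 3, 3, byrow = TRUE,
                     dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  st <- scores_from_matrix(backbone, sp, directed = TRUE)
  expect_equal(nrow(st), 4) # 6 ordered pairs minus 2 training links
  look <- function(f, t) st$score[st$from == f & st$to == t]
  expect_equal(look("b", "a"), backbone["a", "b"]) # row = target
  expect_equal(look("c", "a"), backbone["a", "c"])
  expect_equal(look("a", "c"), backbone["c", "a"])
  expect_equal(look("c", "b"), backbone["b", "c"])

  # undirected: unordered-pair score is the mean of the two entries
  gu <- link_tbl(data.frame(from = "a", to = "b"), nodes = c("a", "b", "c"))
  spu <- list(training = gu, probe = gu[0, ], seed = 1L, probe_fraction = 0.1)
  class(spu) <- "edge_split"
  stu <- scores_from_matrix(backbone, spu, directed = FALSE)
  expect_equal(sort(stu$score),
               sort(c(mean(c(0.9, 0.8)), mean(c(0.4, 0.3)))))

  # complete training graph leaves nothing to score
  gc <- link_tbl(data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  spc <- list(training = gc, probe = gc[0, ], seed = 1L, probe_fraction = 0.1)
  class(spc) <- "edge_split"
  expect_warning(stc <- scores_from_matrix(backbone, spc), "complete")
  expect_equal(nrow(stc), 0)
})

make_score_table <- function(scores, probe_n = 0, directed = TRUE) {
  st <- tibble::tibble(from = "s", to = paste0("t", seq_along(scores)),
                       score = scores)
  attr(st, "directed") <- directed
  st
}

test_that("precision@L counts probe hits among the top-ranked candidates", {
  st <- make_score_table(c(5, 4, 3, 2, 1, 0))
  probe_hi <- data.frame(from = "s", to = c("t1", "t2"))
  expect_equal(precision_at_l(st, probe_hi, L = 2), 1.0)
  probe_lo <- data.frame(from = "s", to = c("t5", "t6"))
  expect_equal(precision_at_l(st, probe_lo, L = 2), 0.0)
  probe_mix <- data.frame(from = "s", to = c("t1", "t4")) # scores 5 and 2
  expect_equal(precision_at_l(st, probe_mix, L = 2), 0.5)

  expect_error(precision_at_l(st, probe_mix, L = 99), class = "mpdlink_error")
  expect_error(
    precision_at_l(st, data.frame(from = "s", to = "zz"), L = 2),
    class = "mpdlink_consistency_error"
  )
})

test_that("tied scores are ranked by a seeded shuffle, not insertion order", {
  st <- make_score_table(rep(1, 10))
  probe <- data.frame(from = "s", to = c("t9", "t10")) # last-inserted
  p <- vapply(1:50, function(s) precision_at_l(st, probe, L = 2, seed = s),
              numeric(1))
  # insertion-order ranking would give 0 always; a fair shuffle hits sometimes
  expect_gt(mean(p), 0)
  expect_lt(mean(p), 1)
  expect_equal(precision_at_l(st, probe, L = 2, seed = 7),
               precision_at_l(st, probe, L = 2, seed = 7))
})

test_that("exact AUC is the Mann-Whitney statistic with half-credit ties", {
  st <- make_score_table(c(3, 1, 2, 0))
  probe <- data.frame(from = "s", to = c("t1", "t2")) # scores 3 and 1
  expect_equal(auc_score(st, probe), 0.75) # 3 wins of 4 comparisons

  st_all_hi <- make_score_table(c(9, 8, 1, 0))
  expect_equal(auc_score(st_all_hi, probe), 1.0)

  st_tied <- make_score_table(rep(2, 6))
  expect_equal(auc_score(st_tied, probe), 0.5)

  expect_error(auc_score(make_score_table(1:2),
                         data.frame(from = "s", to = c("t1", "t2"))),
               "nonexistent")
})

test_that("sampled AUC converges to the exact value", {
  withr::with_seed(21, {
    scores <- c(rnorm(40, mean = 1), rnorm(160))
  })
  st <- make_score_table(scores)
  probe <- data.frame(from = "s", to = paste0("t", 1:40))
  exact <- auc_score(st, probe)
  sampled <- auc_score(st, probe, n_comparisons = 1e5, seed = 2)
  expect_lt(abs(sampled - exact), 0.01)
})

test_that("both metrics are invariant under strictly monotone score transforms", {
  withr::with_seed(5, {
    scores <- runif(30)
  })
  probe <- data.frame(from = "s", to = paste0("t", c(2, 9, 17)))
  st1 <- make_score_table(scores)
  st2 <- make_score_table(exp(5 * scores) + 3)
  expect_equal(auc_score(st1, probe), auc_score(st2, probe))
  expect_equal(precision_at_l(st1, probe, seed = 4),
               precision_at_l(st2, probe, seed = 4))
})

test_that("random scores give AUC near one half on average", {
  probe <- data.frame(from = "s", to = paste0("t", 1:20))
  aucs <- vapply(1:200, function(s) {
    st <- make_score_table(withr::with_seed(s, runif(100)))
    auc_score(st, probe)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
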