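test_that("group performance scores 1, 2/3, 1/3, 0 by groupmates in the top 3", {
  set.seed(31)
  bm <- block_matrix()
  gp <- group_performance(bm$S, bm$groups)
  # within-group similarity strictly above between-group: every item perfect
  expect_equal(gp$score, rep(1, 32))
  expect_equal(attr(gp, "mean_score"), 1)

  # engineer an item whose top-3 holds exactly two groupmates
  S <- bm$S
  S["i01", "i05"] <- S["i05", "i01"] <- 0.99  # an outsider enters the top 3
  S["i01", "i02"] <- S["i02", "i01"] <- 0.05  # a groupmate drops out
  gp2 <- group_performance(S, bm$groups)
  expect_equal(gp2$score[gp2$item == "i01"], 2 / 3)

  # exactly one groupmate, then none
  S["i01", "i06"] <- S["i06", "i01"] <- 0.98
  S["i01", "i03"] <- S["i03", "i01"] <- 0.05
  expect_equal(group_performance(S, bm$groups)$score[1], 1 / 3)
  S["i01", "i07"] <- S["i07", "i01"] <- 0.97
  S["i01", "i04"] <- S["i04", "i01"] <- 0.05
  expect_equal(group_performance(S, bm$groups)$score[1], 0)
})

test_that("group performance validates its inputs", {
  set.seed(32)
  bm <- block_matrix(n_groups = 2, group_size = 4)
  expect_error(group_performance(bm$S[1:3, 1:3], bm$groups), "at least 4")
  expect_error(group_performance(bm$S, bm$groups[-1, ]),
               "'i01' has no group")
  bad <- bm$groups
  bad$group[1] <- "lonely"
  expect_error(group_performance(bm$S, bad), "fewer than 4")
  dup <- rbind(bm$groups, bm$groups[1, ])
  expect_error(group_performance(bm$S, dup), "more than one group")
})

test_that("ties in the top 3 break by vocabulary order", {
  items <- sprintf("i%d", 1:8)
  groups <- tibble::tibble(item = items, group = rep(c("a", "b"), each = 4))
  S <- matrix(0.5, 8, 8, dimnames = list(items, items))
  diag(S) <- 1
  # all similarities tie: top-3 of i1 must be i2, i3, i4 (vocabulary order),
  # which are its groupmates
  gp <- group_performance(S, groups)
  expect_equal(gp$score[1], 1)
  # and for i5 the tie-broken top-3 is i1,i2,i3 - all in the other group
  expect_equal(gp$score[5], 0)
})

test_that("performance is invariant to relabeling and reordering", {
  set.seed(33)
  bm <- block_matrix(n_groups = 4, group_size = 4)
  S <- bm$S
  base <- attr(group_performance(S, bm$groups), "mean_score")

  relabeled <- bm$groups
  relabeled$group <- paste0("renamed_", relabeled$group)
  expect_equal(attr(group_performance(S, relabeled), "mean_score"), base)

  perm <- sample(nrow(S))
  expect_equal(
    attr(group_performance(S[perm, perm], bm$groups[perm, ]), "mean_score"),
    base
  )
})

test_that("matrix norms use the off-diagonal Frobenius form", {
  mk <- function(vals, tt) {
    structure(list(values = vals, vocabulary = rownames(vals), time = tt,
                   config = tss_config()), class = "tss_matrix")
  }
  items <- c("p", "q", "r")
  zero <- diag(3); dimnames(zero) <- list(items, items)
  const <- matrix(0.3, 3, 3, dimnames = list(items, items)); diag(const) <- 1
  ns <- matrix_norm_series(list(mk(zero, 1), mk(const, 2)))
  expect_equal(ns$norm[1], 0)                       # all-zero off-diagonal
  expect_equal(ns$norm[2], 0.3 * sqrt(3 * 2))       # c * sqrt(m(m-1))
  expect_equal(ns$time, c(1, 2))

  other <- matrix(0.3, 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  expect_error(matrix_norm_series(list(mk(zero, 1), mk(other, 2))),
               "same vocabulary")
})

test_that("subnetwork correlation behaves at its extremes and under the null", {
  tgrid <- 1:100
  set.seed(34)
  a <- tibble::tibble(time = tgrid, norm = cumsum(rnorm(100)))
  expect_equal(subnetwork_correlation(a, a)$estimate, 1)
  neg <- dplyr::mutate(a, norm = -norm)
  expect_equal(subnetwork_correlation(a, neg)$estimate, -1)

  b <- tibble::tibble(time = tgrid, norm = rnorm(100))
  c2 <- tibble::tibble(time = tgrid, norm = rnorm(100))
  expect_lt(abs(subnetwork_correlation(b, c2)$estimate), 0.2)

  expect_error(subnetwork_correlation(a[1:2, ], a[1:2, ]), "at least 3")
  # a window restricts the aligned grid
  res <- subnetwork_correlation(a, neg, window = c(10, 20))
  expect_equal(res$n, 11)
})

test_that("anchor drift reports zero similarity to a disconnected group", {
  t <- seq(0, 2000, 5)
  corpus <- make_corpus(t, rep_len(c("luz lamp", "luz candle"), length(t)))
  drift <- anchor_drift(corpus, "luz", c("lamp", "candle"),
                        c("riot", "protest"), times = c(500, 1000, 2000))
  expect_equal(drift$mean_g2, rep(0, 3))
  expect_true(all(drift$mean_g1 > 0))
})

test_that("anchor drift is exactly symmetric for mirrored anchor groups", {
  t <- seq(0, 3000, 5)
  text <- rep_len(c("luz one", "luz two"), length(t))
  corpus <- make_corpus(t, text)
  drift <- anchor_drift(corpus, "luz", "one", "two", times = c(1000, 3000))
  expect_equal(drift$mean_g1, drift$mean_g2)
})

test_that("anchor drift validates its groups", {
  corpus <- make_corpus(1:10, rep("x", 10))
  expect_error(anchor_drift(corpus, "luz", c("a", "b"), c("b", "c"), 10),
               "disjoint")
  expect_error(anchor_drift(corpus, "a", c("a", "b"), c("c"), 10),
               "concept")
  expect_error(anchor_drift(corpus, "luz", character(), "c", 10), "non-empty")
})

test_that("embedded drift adds a finite 2-D trajectory", {
  sc <- crisis_schedule(total = 1200, event_start = 500, event_end = 800)
  corpus <- simulate_stream(sc$schedule, seed = 55)
  drift <- anchor_drift(corpus, sc$concept, sc$g1, sc$g2,
                        times = c(400, 700, 1100), embed = TRUE)
  expect_true(all(c("x", "y") %in% names(drift)))
  expect_true(all(is.finite(drift$x)))
  expect_true(all(is.finite(drift$y)))
})
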