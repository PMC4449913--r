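test_that("rate estimation inverts the mean inter-arrival time", {
  expect_equal(estimate_rate(seq(0, 290, by = 10))$rate, 0.1)
  expect_equal(estimate_rate(c(0, 1, 3))$rate, 2 / 3)

  # undefined rates: short series or zero span
  expect_false(estimate_rate(numeric())$defined)
  expect_false(estimate_rate(5)$defined)
  expect_false(estimate_rate(c(3, 3, 3))$defined)
  expect_true(is.na(estimate_rate(c(3, 3))$rate))
})

test_that("the estimator telescopes: only first, last and count matter", {
  # independent oracle: the definition as the inverse mean of consecutive
  # differences, summed term by term
  oracle <- function(stamps) 1 / mean(diff(stamps))
  expect_equal(estimate_rate(c(0, 28, 29))$rate, oracle(c(0, 28, 29)))
  expect_equal(estimate_rate(c(0, 28, 29))$rate, estimate_rate(c(0, 1, 29))$rate)
  set.seed(11)
  for (i in 1:20) {
    stamps <- sort(runif(sample(2:40, 1), 0, 100))
    expect_equal(estimate_rate(stamps)$rate, oracle(stamps))
    shuffled_interior <- c(stamps[1],
                           sort(runif(length(stamps) - 2, stamps[1],
                                      stamps[length(stamps)])),
                           stamps[length(stamps)])
    expect_equal(estimate_rate(shuffled_interior)$rate,
                 estimate_rate(stamps)$rate)
  }
})

test_that("tss follows the ratio-power closed form", {
  corpus <- ratio_corpus()
  # engineered rates: joint 0.00625, max individual 0.1 -> 0.0625^(1/4)
  expect_equal(tss(corpus, "a", "b", 4640), 0.5)
  expect_equal(tss(corpus, "b", "a", 4640), 0.5)  # symmetric exactly
  # self-similarity is 1 whenever the rate is defined
  expect_equal(tss(corpus, "a", "a", 4640), 1)
  expect_equal(tss(corpus, "b", "b", 4640), 1)
})

test_that("tss is 0 whenever a needed rate is undefined", {
  corpus <- make_corpus(1:40, rep("filler words only", 40))
  expect_identical(tss(corpus, "ghost", "phantom", 40), 0)
  expect_identical(tss(corpus, "filler", "ghost", 40), 0)
  # both present but never co-occurring
  ab <- make_corpus(1:40, rep(c("a", "b"), 20))
  expect_identical(tss(ab, "a", "b", 40), 0)
  # a single co-occurrence is still an undefined joint rate (< 2 stamps)
  one <- make_corpus(1:41, c(rep(c("a", "b"), 20), "a b"))
  expect_identical(tss(one, "a", "b", 41), 0)
})

test_that("tss lies in [0,1] and is symmetric on simulated streams", {
  mod <- category_model()$model
  corpus <- simulate_stream(mod, seed = 401, duration = 400)
  vocab <- mod$vocabulary
  set.seed(402)
  for (i in 1:25) {
    pair <- sample(vocab, 2)
    tt <- runif(1, 50, 400)
    v12 <- tss(corpus, pair[1], pair[2], tt)
    v21 <- tss(corpus, pair[2], pair[1], tt)
    expect_identical(v12, v21)
    expect_gte(v12, 0)
    expect_lte(v12, 1)
  }
})

test_that("tss is decreasing in alpha for ratios strictly inside (0,1)", {
  corpus <- ratio_corpus()
  alphas <- c(0.1, 0.25, 0.5, 0.75, 1)
  vals <- vapply(alphas, function(a)
    tss(corpus, "a", "b", 4640, tss_config(alpha = a)), double(1))
  expect_true(all(diff(vals) < 0))
  # ratio = 1 is the fixed point: alpha has no effect
  ones <- vapply(alphas, function(a)
    tss(corpus, "a", "a", 4640, tss_config(alpha = a)), double(1))
  expect_equal(ones, rep(1, length(alphas)))
})

test_that("tss_matrix is symmetric with the documented diagonal", {
  single <- make_corpus(seq(0, 100, 5), rep("solo", 21))
  m1 <- tss_matrix(single, "solo", 100)
  expect_equal(unname(as.matrix(m1)), matrix(1))

  # three terms, none co-occurring: off-diagonal all zero
  t <- 1:60
  corpus <- make_corpus(t, rep(c("x", "y", "z"), 20))
  m3 <- as.matrix(tss_matrix(corpus, c("x", "y", "z"), 60))
  expect_equal(unname(m3), diag(3))

  # absent term: 0 on the diagonal, per the undefined-rate rule
  m2 <- as.matrix(tss_matrix(corpus, c("x", "ghost"), 60))
  expect_equal(unname(diag(m2)), c(1, 0))

  expect_error(tss_matrix(corpus, c("x", "x"), 60), "distinct")
  expect_error(tss_matrix(corpus, character(), 60), "non-empty")

  # entries agree with pairwise tss() calls
  mod <- category_model()$model
  sim <- simulate_stream(mod, seed = 77, duration = 300)
  vocab <- mod$vocabulary[c(1, 2, 5, 9)]
  mat <- as.matrix(tss_matrix(sim, vocab, 300))
  expect_equal(unname(mat), unname(t(mat)))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(mat[i, j], tss(sim, vocab[i], vocab[j], 300))
  }
})

test_that("tss_series matches per-time matrices and validates its grid", {
  mod <- category_model()$model
  corpus <- simulate_stream(mod, seed = 5, duration = 200)
  vocab <- mod$vocabulary[1:3]
  ser <- tss_series(corpus, vocab, 200)
  expect_length(ser, 1)
  expect_equal(as.matrix(ser[[1]]), as.matrix(tss_matrix(corpus, vocab, 200)))

  ser3 <- tss_series(corpus, vocab, c(100, 150, 200))
  expect_length(ser3, 3)
  # each matrix only sees its own past
  expect_equal(as.matrix(ser3[[1]]),
               as.matrix(tss_matrix(corpus[corpus$t <= 100, ], vocab, 100)))
  expect_error(tss_series(corpus, vocab, c(200, 100)), "ascending")

  long <- tidy(ser3)
  expect_equal(nrow(long), 3 * choose(3, 2))
  expect_true(all(long$tss >= 0 & long$tss <= 1))
})

test_that("joint frequency is the raw co-occurrence rate", {
  none <- make_corpus(1:40, rep(c("a", "b"), 20))
  expect_identical(joint_frequency(none, "a", "b", 40), 0)

  t <- seq(0, 400, 10)
  co <- make_corpus(t, rep("a b filler", length(t)))
  expect_equal(joint_frequency(co, "a", "b", 400), 0.1)

  # JF correlates with TSS across pairs of a structured stream
  mod <- category_model()$model
  sim <- simulate_stream(mod, seed = 19, duration = 500)
  pairs <- utils::combn(mod$vocabulary, 2)
  jf <- purrr::map2_dbl(pairs[1, ], pairs[2, ],
                        ~joint_frequency(sim, .x, .y, 500))
  ts <- purrr::map2_dbl(pairs[1, ], pairs[2, ], ~tss(sim, .x, .y, 500))
  expect_gt(cor(jf, ts, method = "spearman"), 0.5)
})

test_that("matrix serialization round-trips through wide and long CSV", {
  corpus <- ratio_corpus()
  mat <- tss_matrix(corpus, c("a", "b"), 4640)
  wide <- withr::local_tempfile(fileext = ".csv")
  write_tss_matrix(mat, wide, format = "wide")
  dfw <- readr::read_csv(wide, show_col_types = FALSE)
  expect_equal(dfw$term, c("a", "b"))
  expect_equal(dfw$b, c(0.5, 1))

  long <- withr::local_tempfile(fileext = ".csv")
  write_tss_matrix(mat, long, format = "long")
  dfl <- readr::read_csv(long, show_col_types = FALSE)
  expect_equal(names(dfl), c("term1", "term2", "time", "tss"))
  expect_equal(dfl$tss, 0.5)
})
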