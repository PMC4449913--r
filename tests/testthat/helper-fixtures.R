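# Shared fixtures: tiny corpora and generative models used across tests.

make_corpus <- function(t, text, id = NULL) {
  tibble::tibble(
    id = if (is.null(id)) sprintf("m%03d", seq_along(t)) else id,
    t = as.double(t), text = text
  )
}

# Corpus engineered so that rate(a) = 0.1/s, rate(b) = rate(a AND b) =
# 0.00625/s at reference time 4640 with n = 30: 'a' every 10 s, 'a b'
# every 160 s. Gives tss(a, b) = (0.0625)^alpha exactly.
ratio_corpus <- function() {
  t <- seq(0, 4640, by = 10)
  make_corpus(t, ifelse(t %% 160 == 0, "a b", "a"))
}

# Three well-separated categories: each topic strongly co-includes its own
# four words and barely touches the rest.
category_model <- function(lambda = 10, p_in = 0.5, p_out = 0.01) {
  words <- list(
    fruit = c("apple", "mango", "pear", "kiwi"),
    animal = c("dog", "horse", "owl", "shark"),
    color = c("red", "blue", "green", "pink")
  )
  vocab <- unlist(words, use.names = FALSE)
  topics <- lapply(words, function(w) {
    p <- setNames(rep(p_out, length(vocab)), vocab)
    p[w] <- p_in
    stream_topic(1 / 3, p)
  })
  list(model = stream_model(lambda, topics, vocab),
       labels = tibble::tibble(item = vocab,
                               label = rep(names(words), each = 4)))
}

# Draw-style schedule: 16 items in 4 groups of 4; i.i.d. co-occurrence
# before and after, group-aligned topics during [event_start, event_end).
draw_schedule <- function(lambda = 3, event_start = 900, event_end = 1200,
                          total = 2400) {
  items <- sprintf("c%02d", 1:16)
  groups <- tibble::tibble(item = items, group = rep(paste0("g", 1:4), each = 4))
  baseline <- stream_model(lambda, list(
    stream_topic(1, setNames(rep(0.15, 16), items))
  ))
  event_topics <- lapply(split(items, groups$group), function(w) {
    p <- setNames(rep(0.05, 16), items)
    p[w] <- 0.5
    stream_topic(0.25, p)
  })
  event <- stream_model(lambda, event_topics, items)
  sched <- event_schedule(list(
    list(start = 0, end = event_start, model = baseline),
    list(start = event_start, end = event_end, model = event),
    list(start = event_end, end = total, model = baseline)
  ))
  list(schedule = sched, groups = groups, items = items,
       event_start = event_start, event_end = event_end, total = total)
}

# Crisis-style schedule: a tracked concept whose co-inclusion moves from
# its habitual anchor group (g1) to an event group (g2) and back. The
# concept keeps a weak tie to the off-focus group throughout: the last-N
# windows only forget an event when fresh (slow) co-occurrences keep
# arriving to dilute them.
crisis_schedule <- function(lambda = 4, event_start = 900, event_end = 1200,
                            total = 2400) {
  g1 <- c("lamp", "candle", "spark", "bulb", "sun")
  g2 <- c("riot", "protest", "conflict", "outage", "anger")
  vocab <- c("luz", g1, g2)
  mix <- function(concept_with) {
    p1 <- setNames(rep(0, 11), vocab); p1[g1] <- 0.4
    p2 <- setNames(rep(0, 11), vocab); p2[g2] <- 0.4
    if (concept_with == "g1") {
      p1["luz"] <- 0.4; p2["luz"] <- 0.05
    } else {
      p1["luz"] <- 0.05; p2["luz"] <- 0.4
    }
    list(stream_topic(0.5, p1), stream_topic(0.5, p2))
  }
  before <- stream_model(lambda, mix("g1"), vocab)
  during <- stream_model(lambda, mix("g2"), vocab)
  sched <- event_schedule(list(
    list(start = 0, end = event_start, model = before),
    list(start = event_start, end = event_end, model = during),
    list(start = event_end, end = total, model = before)
  ))
  list(schedule = sched, g1 = g1, g2 = g2, concept = "luz",
       event_start = event_start, event_end = event_end, total = total)
}

# Block similarity matrix: within-group entries strictly above all
# between-group entries; diag 1. Deterministic given the RNG state.
block_matrix <- function(n_groups = 8, group_size = 4) {
  m <- n_groups * group_size
  items <- sprintf("i%02d", seq_len(m))
  grp <- rep(paste0("g", seq_len(n_groups)), each = group_size)
  S <- matrix(runif(m * m, 0, 0.4), m, m, dimnames = list(items, items))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    S[idx, idx] <- runif(group_size^2, 0.6, 1)
  }
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  diag(S) <- 1
  list(S = S, groups = tibble::tibble(item = items, group = grp))
}
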