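#' Topic for a stream model
#'
#' A topic is a mixture component of the generative stream model: a weight
#' (the probability a message is drawn from this topic) and a per-word
#' inclusion probability map. Within a message drawn from a topic, each
#' vocabulary word is included independently with its topic probability, so
#' the model has closed-form word and pairwise co-occurrence rates for any
#' pair — the analytic oracles [true_rate()] and [true_tss()].
#'
#' @param weight Non-negative topic weight; weights of a model's topics must
#'   sum to 1.
#' @param probs Named numeric vector of inclusion probabilities in [0, 1];
#'   names are vocabulary words. Words absent from a topic's map have
#'   probability 0 in that topic.
#' @return An object of class `"stream_topic"`.
#' @export
stream_topic <- function(weight, probs) {
  if (!is.numeric(weight) || length(weight) != 1 || weight < 0) {
    stop("weight must be a single non-negative number", call. = FALSE)
  }
  probs <- unlist(probs)
  if (length(probs) > 0 && (is.null(names(probs)) || any(!nzchar(names(probs))))) {
    stop("probs must be a named vector", call. = FALSE)
  }
  if (any(probs < 0 | probs > 1)) {
    stop("inclusion probabilities must be in [0, 1]", call. = FALSE)
  }
  structure(list(weight = as.double(weight), probs = probs),
            class = "stream_topic")
}

#' Generative model of a message stream
#'
#' Messages arrive as a homogeneous Poisson process at `message_rate` per
#' second. Each message independently draws one topic by weight, then
#' includes each vocabulary word independently with that topic's inclusion
#' probability; the message text is the space-joined list of included words
#' (in vocabulary order — matching is order-insensitive, so the order is
#' immaterial). The topic mixture induces controllable pairwise
#' co-inclusion: words sharing a topic co-occur, words in disjoint topics do
#' not, which naturally produces category clusters.
#'
#' @param message_rate Messages per second (> 0).
#' @param topics A list of [stream_topic()] objects; weights must sum to 1.
#' @param vocabulary Optional character vector of words; defaults to the
#'   union of the topics' prob names, in first-appearance order.
#' @return An object of class `"stream_model"`.
#' @export
stream_model <- function(message_rate, topics, vocabulary = NULL) {
  if (!is.numeric(message_rate) || length(message_rate) != 1 ||
      message_rate <= 0) {
    stop("message_rate must be a single positive number", call. = FALSE)
  }
  if (inherits(topics, "stream_topic")) topics <- list(topics)
  if (length(topics) == 0) stop("at least one topic is required", call. = FALSE)
  topics <- lapply(topics, function(tp) {
    if (!inherits(tp, "stream_topic")) tp <- stream_topic(tp$weight, tp$probs)
    tp
  })
  w <- vapply(topics, `[[`, double(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) {
    stop("topic weights must sum to 1 (got ", format(sum(w)), ")", call. = FALSE)
  }
  if (is.null(vocabulary)) {
    vocabulary <- unique(unlist(lapply(topics, function(tp) names(tp$probs))))
  }
  vocabulary <- as.character(vocabulary)
  if (length(vocabulary) == 0) stop("vocabulary must be non-empty", call. = FALSE)
  if (anyDuplicated(vocabulary)) stop("vocabulary terms must be distinct", call. = FALSE)
  # inclusion probability matrix: topics x words, 0 where unspecified
  P <- matrix(0, length(topics), length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (k in seq_along(topics)) {
    p <- topics[[k]]$probs
    known <- intersect(names(p), vocabulary)
    extra <- setdiff(names(p), vocabulary)
    if (length(extra) > 0) {
      stop("topic ", k, " assigns probabilities to words outside the ",
           "vocabulary: ", paste(extra, collapse = ", "), call. = FALSE)
    }
    P[k, known] <- p[known]
  }
  structure(
    list(message_rate = as.double(message_rate), weights = w,
         prob_matrix = P, vocabulary = vocabulary),
    class = "stream_model"
  )
}

#' @export
print.stream_model <- function(x, ...) {
  cat("<stream_model> ", length(x$weights), " topic(s), ",
      length(x$vocabulary), " words, ", x$message_rate,
      " messages/s\n", sep = "")
  invisible(x)
}

#' Piecewise-constant schedule of stream models
#'
#' A schedule is an ordered list of contiguous, non-overlapping half-open
#' segments `[start, end)`, each governed by its own [stream_model()].
#' Segments emulate scheduled events: a change-point is simply a boundary
#' where the model's rates or co-inclusion probabilities change.
#'
#' @param segments A list of segments, each a list with elements `start`,
#'   `end` and `model` (a [stream_model()]); or a single model via
#'   [stationary_schedule()].
#' @return An object of class `"event_schedule"`.
#' @export
event_schedule <- function(segments) {
  if (length(segments) == 0) stop("schedule needs at least one segment", call. = FALSE)
  segs <- lapply(segments, function(s) {
    stopifnot(is.list(s), !is.null(s$start), !is.null(s$end), !is.null(s$model))
    if (!inherits(s$model, "stream_model")) stop("segment model must be a stream_model", call. = FALSE)
    if (s$end <= s$start) stop("segment end must exceed start", call. = FALSE)
    list(start = as.double(s$start), end = as.double(s$end), model = s$model)
  })
  starts <- vapply(segs, `[[`, double(1), "start")
  ends <- vapply(segs, `[[`, double(1), "end")
  if (is.unsorted(starts, strictly = TRUE)) {
    stop("segment start times must be strictly ascending", call. = FALSE)
  }
  if (length(segs) > 1 && any(abs(starts[-1] - ends[-length(ends)]) > 1e-9)) {
    stop("segments must be contiguous: each start must equal the previous end",
         call. = FALSE)
  }
  structure(segs, class = "event_schedule")
}

#' @rdname event_schedule
#' @param model A [stream_model()].
#' @param duration Segment length in seconds.
#' @param start Segment start time (default 0).
#' @export
stationary_schedule <- function(model, duration, start = 0) {
  event_schedule(list(list(start = start, end = start + duration, model = model)))
}

#' Simulate a message stream
#'
#' Draws message arrival times as a Poisson process at each segment's rate,
#' assigns each message a topic by weight, includes vocabulary words
#' independently with the topic's probabilities, and joins included words
#' into the message text. The same seed always reproduces the same corpus
#' byte for byte. The caller's RNG state is left untouched when a seed is
#' given.
#'
#' @param schedule An [event_schedule()] (or a [stream_model()], in which
#'   case `duration` must be given).
#' @param seed Integer seed for reproducibility; `NULL` uses (and advances)
#'   the current RNG state.
#' @param duration Stream length in seconds when `schedule` is a bare model.
#' @return A message tibble (`id`, `t`, `text`) sorted by time. Messages
#'   that include no word have empty text.
#' @export
simulate_stream <- function(schedule, seed = NULL, duration = NULL) {
  if (inherits(schedule, "stream_model")) {
    if (is.null(duration)) {
      stop("duration is required when simulating a bare stream_model", call. = FALSE)
    }
    schedule <- stationary_schedule(schedule, duration)
  }
  if (!inherits(schedule, "event_schedule")) {
    stop("schedule must be an event_schedule or stream_model", call. = FALSE)
  }
  if (!is.null(seed)) {
    withr::local_preserve_seed()
    set.seed(as.integer(seed))
  }
  parts <- lapply(schedule, function(seg) {
    dur <- seg$end - seg$start
    m <- seg$model
    n_msg <- stats::rpois(1, m$message_rate * dur)
    if (n_msg == 0) {
      return(tibble::tibble(t = double(), text = character()))
    }
    t <- sort(stats::runif(n_msg, min = seg$start, max = seg$end))
    topic <- sample.int(length(m$weights), n_msg, replace = TRUE,
                        prob = m$weights)
    # inclusion: message x word Bernoulli with the drawn topic's probs
    P <- m$prob_matrix[topic, , drop = FALSE]
    inc <- matrix(stats::runif(length(P)) < P, nrow = n_msg)
    voc <- m$vocabulary
    text <- apply(inc, 1, function(row) paste(voc[row], collapse = " "))
    tibble::tibble(t = t, text = as.character(text))
  })
  out <- dplyr::bind_rows(parts)
  out <- tibble::add_column(out, id = sprintf("m%08d", seq_len(nrow(out))),
                            .before = 1)
  as_messages(out)
}

model_of <- function(x) {
  if (inherits(x, "stream_model")) x
  else stop("expected a stream_model", call. = FALSE)
}

word_prob_vector <- function(model, w) {
  w <- as.character(w)
  if (!w %in% model$vocabulary) {
    return(rep(0, length(model$weights)))
  }
  model$prob_matrix[, w]
}

#' Analytic occurrence rate of a word under a stream model
#'
#' The expected occurrence rate of `w` is the message rate times the
#' mixture-averaged inclusion probability: `Lambda * sum_k weight_k *
#' p_k(w)` (Poisson thinning). Words outside the vocabulary have rate 0.
#'
#' @param model A [stream_model()].
#' @param w A word.
#' @return Occurrences per second.
#' @export
true_rate <- function(model, w) {
  model <- model_of(model)
  model$message_rate * sum(model$weights * word_prob_vector(model, w))
}

#' Analytic co-occurrence rate of a word pair
#'
#' Within a topic words are included independently, so the co-occurrence
#' rate is `Lambda * sum_k weight_k * p_k(w1) * p_k(w2)`. For `w1 == w2`
#' the joint event is just the word's occurrence, so the joint rate equals
#' [true_rate()].
#'
#' @inheritParams true_rate
#' @param w1,w2 Words.
#' @return Occurrences per second.
#' @export
true_joint_rate <- function(model, w1, w2) {
  model <- model_of(model)
  if (identical(as.character(w1), as.character(w2))) {
    return(true_rate(model, w1))
  }
  model$message_rate * sum(model$weights * word_prob_vector(model, w1) *
                             word_prob_vector(model, w2))
}

#' Analytic similarity of a word pair under a stream model
#'
#' Plugs the model's closed-form rates into the similarity definition:
#' `(joint / max(rate1, rate2))^alpha`, 0 when any rate is 0. The ratio
#' never exceeds 1 analytically (co-inclusion cannot outpace inclusion).
#'
#' @inheritParams true_joint_rate
#' @param alpha Scaling exponent (default 0.25).
#' @return Similarity in [0, 1].
#' @export
true_tss <- function(model, w1, w2, alpha = 0.25) {
  model <- model_of(model)
  r1 <- true_rate(model, w1)
  r2 <- true_rate(model, w2)
  rj <- true_joint_rate(model, w1, w2)
  if (r1 <= 0 || r2 <= 0 || rj <= 0) return(0)
  min(rj / max(r1, r2), 1)^alpha
}

#' Ground-truth similarity table for a model or schedule
#'
#' @param x A [stream_model()] or [event_schedule()].
#' @param alpha Scaling exponent.
#' @return A tibble `term1, term2, segment, true_tss` over all unordered
#'   word pairs (segment = 1 for a bare model).
#' @export
true_tss_table <- function(x, alpha = 0.25) {
  segs <- if (inherits(x, "event_schedule")) x else
    list(list(start = NA_real_, end = NA_real_, model = model_of(x)))
  purrr::imap_dfr(segs, function(seg, k) {
    m <- seg$model
    v <- m$vocabulary
    if (length(v) < 2) return(NULL)
    pairs <- utils::combn(v, 2)
    tibble::tibble(
      term1 = pairs[1, ], term2 = pairs[2, ], segment = k,
      true_tss = purrr::map2_dbl(pairs[1, ], pairs[2, ],
                                 ~true_tss(m, .x, .y, alpha))
    )
  })
}

#' Read a stream model or schedule from YAML/JSON
#'
#' A configuration is either a single model — keys `message_rate` and
#' `topics` (each topic: `weight`, `probs` map) — or a schedule: a list
#' under `segments`, each with `start`, `end` and a nested `model`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [stream_model()] or [event_schedule()].
#' @export
read_stream_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  parse_model <- function(m) {
    topics <- lapply(m$topics, function(tp)
      stream_topic(tp$weight, unlist(tp$probs)))
    stream_model(m$message_rate, topics,
                 vocabulary = if (!is.null(m$vocabulary)) unlist(m$vocabulary))
  }
  if (!is.null(cfg$segments)) {
    event_schedule(lapply(cfg$segments, function(s)
      list(start = s$start, end = s$end, model = parse_model(s$model))))
  } else {
    parse_model(cfg)
  }
}
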