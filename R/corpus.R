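#' Read a time-stamped message corpus
#'
#' Reads a corpus of time-stamped messages from JSONL (one object per line
#' with keys `t`, `text` and optionally `id`) or CSV (header `t,text[,id]`,
#' RFC-4180 quoting). Messages are returned sorted ascending by timestamp;
#' ties keep file order.
#'
#' Timestamps are real-valued seconds (e.g. seconds since the epoch, UTC).
#' Integer-second corpora are valid; equal timestamps are allowed.
#'
#' @param path Path to the corpus file.
#' @param format One of `"auto"`, `"jsonl"`, `"csv"`. `"auto"` guesses from
#'   the file extension (`.jsonl`/`.ndjson` vs `.csv`), defaulting to JSONL.
#' @return A tibble with columns `id` (character), `t` (double, seconds) and
#'   `text` (character), sorted ascending by `t`.
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' writeLines(c('{"t": 5, "text": "c"}', '{"t": 1, "text": "a"}'), f)
#' read_messages(f)
#' @export
read_messages <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("corpus file does not exist: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else "jsonl"
  }
  msgs <- switch(format,
    jsonl = read_messages_jsonl(path),
    csv = read_messages_csv(path)
  )
  as_messages(msgs)
}

read_messages_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    return(tibble::tibble(id = character(), t = double(), text = character()))
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        stop("malformed JSONL record at line ", line_no[i], ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    if (is.null(rec$text)) {
      stop("record at line ", line_no[i], " is missing the 'text' field",
           call. = FALSE)
    }
    tval <- suppressWarnings(as.numeric(rec$t))
    if (length(tval) != 1 || is.na(tval) || !is.finite(tval)) {
      stop("record at line ", line_no[i],
           " has a missing or unparseable timestamp 't'", call. = FALSE)
    }
    recs[[i]] <- list(
      id = if (is.null(rec$id)) NA_character_ else as.character(rec$id),
      t = tval,
      text = as.character(rec$text)
    )
  }
  tibble::tibble(
    id = vapply(recs, `[[`, character(1), "id"),
    t = vapply(recs, `[[`, double(1), "t"),
    text = vapply(recs, `[[`, character(1), "text")
  )
}

read_messages_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0 && !all(c("t", "text") %in% names(df))) {
    return(tibble::tibble(id = character(), t = double(), text = character()))
  }
  if (!all(c("t", "text") %in% names(df))) {
    stop("CSV corpus must have columns 't' and 'text'", call. = FALSE)
  }
  tval <- suppressWarnings(as.numeric(df$t))
  bad <- which(is.na(tval) | !is.finite(tval))
  if (length(bad) > 0) {
    # +1 for the header row
    stop("unparseable timestamp at line ", bad[1] + 1L, call. = FALSE)
  }
  tibble::tibble(
    id = if ("id" %in% names(df)) as.character(df$id) else NA_character_,
    t = tval,
    text = ifelse(is.na(df$text), "", as.character(df$text))
  )
}

#' Coerce a data frame to a message corpus
#'
#' Validates and normalises a data frame of messages: requires a numeric,
#' finite `t` column and a character `text` column, adds an `id` column when
#' absent, and sorts ascending by timestamp with stable order for ties.
#'
#' @param x A data frame with columns `t` and `text` (and optionally `id`).
#' @return A tibble with columns `id`, `t`, `text`, sorted by `t`.
#' @export
as_messages <- function(x) {
  stopifnot(is.data.frame(x))
  if (!all(c("t", "text") %in% names(x))) {
    stop("messages need columns 't' and 'text'", call. = FALSE)
  }
  t <- as.double(x$t)
  if (any(!is.finite(t))) stop("all timestamps must be finite", call. = FALSE)
  out <- tibble::tibble(
    id = if ("id" %in% names(x)) as.character(x$id) else NA_character_,
    t = t,
    text = as.character(x$text)
  )
  # radix order is stable: equal timestamps keep input (file) order
  out[order(out$t, method = "radix"), , drop = FALSE]
}

#' Write a message corpus
#'
#' Serialises a corpus in the same JSONL or CSV dialect that
#' [read_messages()] reads, so a load/write/load round trip is the identity
#' on timestamps, text and order.
#'
#' @param messages A message tibble (see [as_messages()]).
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_messages <- function(messages, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  messages <- as_messages(messages)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(messages)), function(i) {
      rec <- list(t = messages$t[i], text = messages$text[i])
      if (!is.na(messages$id[i])) rec$id <- messages$id[i]
      # 17 significant digits: doubles survive the round trip exactly
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- messages[, c("t", "text", "id")]
    if (all(is.na(df$id))) df$id <- NULL
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

# --- term matching -----------------------------------------------------------

# Tokenise text: lower-case, tokens are maximal runs of letters/digits,
# optionally prefixed by '#' (hashtags are distinct tokens from bare words).
tokenize <- function(x) {
  x <- tolower(x)
  m <- gregexpr("#?[\\p{L}\\p{N}]+", x, perl = TRUE)
  regmatches(x, m)
}

term_token_seq <- function(term) {
  term <- trimws(as.character(term))
  if (length(term) != 1 || is.na(term) || !nzchar(term)) {
    stop("term must be a single non-empty string", call. = FALSE)
  }
  tok <- tokenize(term)[[1]]
  if (length(tok) == 0) stop("term '", term, "' contains no tokens", call. = FALSE)
  tok
}

phrase_in_tokens <- function(msg_tok, term_tok) {
  k <- length(term_tok)
  nm <- length(msg_tok)
  if (nm < k) return(FALSE)
  if (k == 1L) return(any(msg_tok == term_tok))
  starts <- which(msg_tok == term_tok[1L])
  starts <- starts[starts + k - 1L <= nm]
  for (s in starts) {
    if (all(msg_tok[s:(s + k - 1L)] == term_tok)) return(TRUE)
  }
  FALSE
}

#' Does a term occur in each message?
#'
#' Matching is case-insensitive and token-based: messages are split into
#' tokens on non-alphanumeric boundaries (a leading `#` is kept, so hashtags
#' are distinct tokens from bare words), and a multi-word term matches only
#' as a contiguous, ordered token run. Any number of occurrences in a message
#' counts once.
#'
#' @param term A single term: a word, a contiguous multi-word phrase, or a
#'   hashtag.
#' @param text Character vector of message texts.
#' @return Logical vector, one element per message.
#' @examples
#' term_matches("apple", "I love Apple pie")          # TRUE
#' term_matches("passion fruit", "fruit of passion")  # FALSE: order matters
#' term_matches("#worldcup", "go #WorldCup!!")        # TRUE
#' @export
term_matches <- function(term, text) {
  term_tok <- term_token_seq(term)
  toks <- tokenize(text)
  if (length(term_tok) == 1L) {
    vapply(toks, function(tk) any(tk == term_tok), logical(1))
  } else {
    vapply(toks, phrase_in_tokens, logical(1), term_tok = term_tok)
  }
}

# Match a precomputed token list against a term token sequence.
match_token_list <- function(toks, term_tok) {
  if (length(term_tok) == 1L) {
    vapply(toks, function(tk) any(tk == term_tok), logical(1))
  } else {
    vapply(toks, phrase_in_tokens, logical(1), term_tok = term_tok)
  }
}

# Sorted occurrence timestamps of a term (or the conjunction of several
# terms) in a sorted message corpus.
occurrence_stamps <- function(messages, terms, toks = NULL) {
  if (is.null(toks)) toks <- tokenize(messages$text)
  hit <- rep(TRUE, nrow(messages))
  for (term in terms) {
    hit <- hit & match_token_list(toks, term_token_seq(term))
    if (!any(hit)) break
  }
  messages$t[hit]
}

#' Timestamps of the last N matching messages
#'
#' Returns the timestamps of the up-to-`n` most recent messages with
#' timestamp at or before `reference_time` that contain all the given terms
#' (one term, or a two-term conjunction meaning both terms occur in the same
#' message, in any order). Fewer than `n` stamps are returned when fewer
#' matching messages exist; an empty series is a valid result. Windows are
#' closed on the right: no stamp exceeds `reference_time`, and no look-ahead
#' ever occurs.
#'
#' @param messages A message tibble (see [read_messages()]).
#' @param terms Character vector of one or two terms; with two, only
#'   messages containing both count.
#' @param reference_time The query time (seconds).
#' @param n Maximum number of stamps to return (the paper-default window is
#'   30); must be at least 2.
#' @return An object of class `"timestamp_series"`: a list with elements
#'   `stamps` (ascending numeric), `terms`, `reference_time`, `requested_n`.
#' @export
last_n_timestamps <- function(messages, terms, reference_time, n = 30) {
  stopifnot(length(terms) %in% c(1L, 2L))
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  messages <- as_messages(messages)
  occ <- occurrence_stamps(messages, terms)
  occ <- occ[occ <= reference_time]
  m <- length(occ)
  stamps <- if (m > n) occ[(m - n + 1L):m] else occ
  structure(
    list(stamps = as.double(stamps), terms = as.character(terms),
         reference_time = as.double(reference_time),
         requested_n = as.integer(n)),
    class = "timestamp_series"
  )
}

#' @export
print.timestamp_series <- function(x, ...) {
  cat("<timestamp_series> ", paste(shQuote(x$terms), collapse = " AND "),
      ": ", length(x$stamps), "/", x$requested_n,
      " stamps at t = ", format(x$reference_time), "\n", sep = "")
  invisible(x)
}

#' Read a term list
#'
#' One term per line, UTF-8; leading/trailing whitespace trimmed, empty
#' lines dropped. A `#` at line start is a literal hashtag — term files have
#' no comment syntax.
#'
#' @param path Path to the term list.
#' @return Character vector of terms.
#' @export
read_terms <- function(path) {
  if (!file.exists(path)) stop("term file does not exist: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  x[nzchar(x)]
}

#' Packaged semantic category word lists
#'
#' Returns the packaged everyday-category word lists (fruits, animals,
#' colors) used by the evaluation examples and vignette.
#'
#' @param category One of `"fruits"`, `"animals"`, `"colors"`, or `"all"`.
#' @return A character vector of terms, or for `"all"` a tibble with columns
#'   `term` and `category`.
#' @export
category_words <- function(category = c("all", "fruits", "animals", "colors")) {
  category <- match.arg(category)
  dir <- system.file("extdata", "categories", package = "tsstream")
  cats <- c("fruits", "animals", "colors")
  if (category != "all") {
    return(read_terms(file.path(dir, paste0(category, ".txt"))))
  }
  purrr::map_dfr(cats, function(cc) {
    tibble::tibble(term = read_terms(file.path(dir, paste0(cc, ".txt"))),
                   category = cc)
  })
}
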