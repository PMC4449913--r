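#' Query configuration for rate and similarity estimation
#'
#' Bundles the two tunable parameters of the similarity measure: the window
#' size `n` — rates are estimated from the inter-arrival times of the last
#' `n` matching messages — and the scaling exponent `alpha` applied to the
#' rate ratio. The defaults (`n = 30`, `alpha = 1/4`) are the values used
#' throughout the analyses this package reproduces.
#'
#' @param n Window size, an integer >= 2. Default 30.
#' @param alpha Scaling exponent in (0, 1]. Default 0.25.
#' @return An object of class `"tss_config"`.
#' @export
tss_config <- function(n = 30, alpha = 0.25) {
  n <- as.integer(n)
  if (length(n) != 1 || is.na(n) || n < 2) {
    stop("n must be a single integer >= 2", call. = FALSE)
  }
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  structure(list(n = n, alpha = as.double(alpha)), class = "tss_config")
}

#' @export
print.tss_config <- function(x, ...) {
  cat("<tss_config> n =", x$n, ", alpha =", x$alpha, "\n")
  invisible(x)
}

as_tss_config <- function(config) {
  if (inherits(config, "tss_config")) return(config)
  if (is.list(config)) return(do.call(tss_config, config))
  stop("config must be a tss_config", call. = FALSE)
}

# Scalar rate from a stamp vector: (M-1)/span for M >= 2 stamps with
# positive span, NA otherwise ("undefined"). The sum of consecutive
# inter-arrival times telescopes, so the estimate depends on the stamps
# only through (first, last, count).
rate_scalar <- function(stamps) {
  m <- length(stamps)
  if (m < 2) return(NA_real_)
  span <- stamps[m] - stamps[1]
  if (span <= 0) return(NA_real_)
  (m - 1) / span
}

# Vectorised over reference times: rate of the last up-to-n stamps <= each
# time. `stamps` must be sorted ascending. Returns NA where undefined.
rates_at <- function(stamps, times, n) {
  res <- rep(NA_real_, length(times))
  if (length(stamps) < 2) return(res)
  idx <- findInterval(times, stamps)
  ok <- which(idx >= 2)
  if (length(ok) == 0) return(res)
  m <- pmin(idx[ok], n)
  last <- stamps[idx[ok]]
  first <- stamps[idx[ok] - m + 1L]
  span <- last - first
  def <- span > 0
  res[ok[def]] <- (m[def] - 1) / span[def]
  res
}

#' Estimate an occurrence rate from a timestamp series
#'
#' The occurrence rate (velocity of production) of a term is estimated as
#' the inverse of the mean inter-arrival time of its timestamp series: with
#' stamps tau_1 <= ... <= tau_M, the rate is (M - 1) / (tau_M - tau_1),
#' since the sum of consecutive differences telescopes. The rate is
#' *undefined* when fewer than 2 stamps are available or the span is zero;
#' undefined is a value, not an error, and any similarity that needs an
#' undefined rate is 0.
#'
#' @param series A `"timestamp_series"` from [last_n_timestamps()], or a
#'   sorted numeric vector of timestamps.
#' @return A one-row tibble with columns `rate` (occurrences per second;
#'   `NA` when undefined), `n_used` (number of stamps) and `defined`.
#' @examples
#' estimate_rate(seq(0, 290, by = 10))  # mean interval 10 s -> 0.1 per s
#' @export
estimate_rate <- function(series) {
  stamps <- if (inherits(series, "timestamp_series")) series$stamps else as.double(series)
  if (is.unsorted(stamps)) stop("timestamps must be ascending", call. = FALSE)
  r <- rate_scalar(stamps)
  tibble::tibble(rate = r, n_used = length(stamps), defined = !is.na(r))
}

# Shared corpus preparation: tokens + per-term occurrence stamp vectors.
corpus_index <- function(messages, vocabulary) {
  messages <- as_messages(messages)
  toks <- tokenize(messages$text)
  hits <- lapply(vocabulary, function(w) match_token_list(toks, term_token_seq(w)))
  names(hits) <- vocabulary
  list(t = messages$t, hits = hits)
}

# TSS values for one pair at many times, from occurrence stamp vectors.
tss_values <- function(occ1, occ2, occ_joint, times, config) {
  r1 <- rates_at(occ1, times, config$n)
  r2 <- rates_at(occ2, times, config$n)
  rj <- rates_at(occ_joint, times, config$n)
  denom <- pmax(r1, r2)
  out <- rep(0, length(times))
  def <- !is.na(r1) & !is.na(r2) & !is.na(rj)
  ratio <- pmin(rj[def] / denom[def], 1)  # finite windows can push the ratio past 1
  out[def] <- ratio^config$alpha
  out
}

#' Time-resolved semantic similarity between two terms
#'
#' The similarity of `w1` and `w2` at `reference_time` is
#' `(rate(w1 AND w2) / max(rate(w1), rate(w2)))^alpha`, where each rate is
#' estimated from the last `n` matching messages at or before the reference
#' time (see [estimate_rate()]); "w1 AND w2" counts messages containing both
#' terms, in any order, once per message. The value is 0 whenever any needed
#' rate is undefined — in particular for terms absent from the corpus — and
#' the rate ratio is clipped at 1 so the result always lies in [0, 1]. The
#' measure is symmetric in its term arguments.
#'
#' @param messages A message tibble (see [read_messages()]).
#' @param w1,w2 Terms (words, contiguous phrases, or hashtags).
#' @param reference_time Query time in seconds.
#' @param config A [tss_config()].
#' @return A single similarity value in [0, 1].
#' @export
tss <- function(messages, w1, w2, reference_time, config = tss_config()) {
  config <- as_tss_config(config)
  messages <- as_messages(messages)
  toks <- tokenize(messages$text)
  h1 <- match_token_list(toks, term_token_seq(w1))
  h2 <- match_token_list(toks, term_token_seq(w2))
  t <- messages$t
  tss_values(t[h1], t[h2], t[h1 & h2], reference_time, config)[1]
}

#' Joint co-occurrence rate baseline
#'
#' The raw co-occurrence rate of two terms: the estimated rate of messages
#' containing both, 0 when undefined. This is the "joint frequency"
#' baseline against which the normalised similarity is compared; unlike
#' [tss()] it is not normalised by the individual term rates.
#'
#' @inheritParams tss
#' @return Co-occurrence rate in occurrences per second (0 when undefined).
#' @export
joint_frequency <- function(messages, w1, w2, reference_time,
                            config = tss_config()) {
  config <- as_tss_config(config)
  messages <- as_messages(messages)
  toks <- tokenize(messages$text)
  h <- match_token_list(toks, term_token_seq(w1)) &
    match_token_list(toks, term_token_seq(w2))
  r <- rates_at(messages$t[h], reference_time, config$n)[1]
  if (is.na(r)) 0 else r
}

# Build the symmetric similarity matrix at one time from a corpus index.
tss_matrix_at <- function(index, vocabulary, time, config) {
  V <- length(vocabulary)
  t <- index$t
  vals <- matrix(0, V, V, dimnames = list(vocabulary, vocabulary))
  rates <- vapply(vocabulary, function(w)
    rates_at(t[index$hits[[w]]], time, config$n), double(1))
  diag(vals) <- ifelse(is.na(rates), 0, 1)
  if (V >= 2) {
    for (i in seq_len(V - 1)) {
      if (is.na(rates[i])) next
      hi <- index$hits[[i]]
      for (j in (i + 1):V) {
        if (is.na(rates[j])) next
        rj <- rates_at(t[hi & index$hits[[j]]], time, config$n)[1]
        if (is.na(rj)) next
        vals[i, j] <- vals[j, i] <- min(rj / max(rates[i], rates[j]), 1)^config$alpha
      }
    }
  }
  structure(
    list(values = vals, vocabulary = vocabulary, time = as.double(time),
         config = config),
    class = "tss_matrix"
  )
}

#' Pairwise similarity matrix at one time point
#'
#' Computes the symmetric term-by-term similarity matrix over a vocabulary
#' at a reference time; each unordered pair is computed once. Diagonal
#' entries are 1 for terms whose rate is defined at that time and 0
#' otherwise.
#'
#' @param messages A message tibble.
#' @param vocabulary Character vector of distinct terms.
#' @param reference_time Query time in seconds.
#' @param config A [tss_config()].
#' @return An object of class `"tss_matrix"`: a list with `values` (named
#'   symmetric matrix in [0,1]), `vocabulary`, `time`, `config`. Use
#'   [tidy.tss_matrix()] for a long tibble, `as.matrix()` for the raw
#'   matrix.
#' @export
tss_matrix <- function(messages, vocabulary, reference_time,
                       config = tss_config()) {
  config <- as_tss_config(config)
  vocabulary <- as.character(vocabulary)
  if (length(vocabulary) == 0) stop("vocabulary must be non-empty", call. = FALSE)
  if (anyDuplicated(vocabulary)) {
    stop("vocabulary terms must be distinct", call. = FALSE)
  }
  index <- corpus_index(messages, vocabulary)
  tss_matrix_at(index, vocabulary, reference_time, config)
}

#' Similarity matrices along a time grid
#'
#' One similarity matrix per time point. Matrices are independent: each
#' uses only messages with timestamps at or before its own time.
#'
#' @inheritParams tss_matrix
#' @param times Ascending numeric vector of reference times.
#' @return An object of class `"tss_series"`: a list of `"tss_matrix"`
#'   objects, one per time.
#' @export
tss_series <- function(messages, vocabulary, times, config = tss_config()) {
  config <- as_tss_config(config)
  vocabulary <- as.character(vocabulary)
  if (length(vocabulary) == 0) stop("vocabulary must be non-empty", call. = FALSE)
  if (anyDuplicated(vocabulary)) {
    stop("vocabulary terms must be distinct", call. = FALSE)
  }
  if (is.unsorted(times, strictly = FALSE)) {
    stop("times must be ascending", call. = FALSE)
  }
  index <- corpus_index(messages, vocabulary)
  out <- lapply(times, function(tt) tss_matrix_at(index, vocabulary, tt, config))
  structure(out, class = "tss_series")
}

#' @export
as.matrix.tss_matrix <- function(x, ...) x$values

#' @export
print.tss_matrix <- function(x, digits = 3, ...) {
  cat("<tss_matrix> ", length(x$vocabulary), " terms at t = ",
      format(x$time), " (n = ", x$config$n, ", alpha = ", x$config$alpha,
      ")\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

#' @export
print.tss_series <- function(x, ...) {
  cat("<tss_series> ", length(x), " time points, ",
      length(x[[1]]$vocabulary), " terms\n", sep = "")
  invisible(x)
}

#' Tidy a similarity matrix into long format
#'
#' @param x A `"tss_matrix"`.
#' @param upper Keep only unordered pairs (upper triangle, excluding the
#'   diagonal)? Default `TRUE`.
#' @param ... Unused.
#' @return A tibble with columns `term1`, `term2`, `time`, `tss`.
#' @method tidy tss_matrix
#' @export
tidy.tss_matrix <- function(x, upper = TRUE, ...) {
  v <- x$vocabulary
  df <- tidyr::expand_grid(term1 = v, term2 = v)
  df$tss <- as.vector(t(x$values))
  df$time <- x$time
  if (upper) {
    i <- match(df$term1, v)
    j <- match(df$term2, v)
    df <- df[i < j, , drop = FALSE]
  }
  df[, c("term1", "term2", "time", "tss")]
}

#' @rdname tidy.tss_matrix
#' @method tidy tss_series
#' @export
tidy.tss_series <- function(x, upper = TRUE, ...) {
  purrr::map_dfr(x, tidy.tss_matrix, upper = upper)
}

#' One-line summary of a similarity matrix
#'
#' @param x A `"tss_matrix"`.
#' @param ... Unused.
#' @return A one-row tibble with the number of terms, the time, the window
#'   size and exponent, and the mean off-diagonal similarity.
#' @method glance tss_matrix
#' @export
glance.tss_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  tibble::tibble(
    n_terms = length(x$vocabulary), time = x$time,
    n = x$config$n, alpha = x$config$alpha,
    mean_tss = if (length(off)) mean(off) else NA_real_
  )
}

#' Heatmap of a similarity matrix
#'
#' @param object A `"tss_matrix"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tss_matrix
#' @export
autoplot.tss_matrix <- function(object, ...) {
  df <- tidy.tss_matrix(object, upper = FALSE)
  df$term1 <- factor(df$term1, levels = object$vocabulary)
  df$term2 <- factor(df$term2, levels = rev(object$vocabulary))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term1, y = .data$term2,
                                   fill = .data$tss)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "TSS",
                  title = paste0("TSS at t = ", format(object$time))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Write a similarity matrix to CSV
#'
#' `"wide"` writes the matrix with a header row and a leading `term`
#' column; `"long"` writes `term1,term2,time,tss` rows (unordered pairs).
#'
#' @param x A `"tss_matrix"`.
#' @param path Output path.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_tss_matrix <- function(x, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- tibble::as_tibble(x$values, .name_repair = "minimal")
    df <- tibble::add_column(df, term = x$vocabulary, .before = 1)
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_csv(tidy.tss_matrix(x), path, progress = FALSE)
  }
  invisible(path)
}
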