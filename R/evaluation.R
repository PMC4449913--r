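#' Normalised rank position of a designated synonym
#'
#' Given per-candidate similarity scores for a probe word, sorts ascending
#' and returns the designated synonym's normalised position
#' `(rank - 1) / (M - 1)` for `M` candidates: 1 when the synonym is the
#' most similar candidate, 0 when it is the least, 0.5 in expectation for
#' exchangeable scores. Ties receive the mean rank. The position depends on
#' the scores only through their order, so it is invariant under any
#' strictly increasing transform.
#'
#' @param scores Numeric vector of similarity scores, one per candidate.
#' @param synonym Index of the designated synonym in `scores`.
#' @return The normalised position in [0, 1].
#' @export
synonym_rank <- function(scores, synonym) {
  m <- length(scores)
  if (m < 2) stop("need at least 2 candidates", call. = FALSE)
  synonym <- as.integer(synonym)
  if (length(synonym) != 1 || is.na(synonym) || synonym < 1 || synonym > m) {
    stop("synonym index out of range", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")[synonym]
  (r - 1) / (m - 1)
}

#' Synonym test over a probe/candidate table
#'
#' For each probe, computes the similarity to every candidate at the
#' reference time and the normalised rank position of the designated
#' synonym ([synonym_rank()]). A well-behaved similarity measure places
#' synonyms near position 1; chance is 0.5.
#'
#' @param messages A message tibble.
#' @param pairs A data frame `probe, candidate, is_synonym` (logical or
#'   0/1); each probe must have exactly one synonym and at least 2
#'   candidates.
#' @param reference_time Query time.
#' @param config A [tss_config()].
#' @return A tibble `probe, n_candidates, position`.
#' @export
synonym_test <- function(messages, pairs, reference_time,
                         config = tss_config()) {
  if (!all(c("probe", "candidate", "is_synonym") %in% names(pairs))) {
    stop("pairs needs columns probe, candidate, is_synonym", call. = FALSE)
  }
  config <- as_tss_config(config)
  messages <- as_messages(messages)
  toks <- tokenize(messages$text)
  t <- messages$t
  purrr::map_dfr(split(pairs, pairs$probe), function(df) {
    syn <- which(as_flag(df$is_synonym))
    if (length(syn) != 1) {
      stop("probe '", df$probe[1], "' must have exactly one synonym",
           call. = FALSE)
    }
    hp <- match_token_list(toks, term_token_seq(df$probe[1]))
    scores <- vapply(df$candidate, function(w) {
      hw <- match_token_list(toks, term_token_seq(w))
      tss_values(t[hp], t[hw], t[hp & hw], reference_time, config)
    }, double(1))
    tibble::tibble(probe = df$probe[1], n_candidates = nrow(df),
                   position = synonym_rank(scores, syn))
  })
}

#' Cross-validated classification of similarity rows
#'
#' Estimates how well a similarity matrix separates labelled categories:
#' items are split into `k` folds (stratified by label when every class has
#' at least `k` members, otherwise plain random folds), each item is
#' represented by its similarity row restricted to the training items of
#' its fold split, and a classifier predicts the held-out labels. Feature
#' columns are always the training items, so a held-out item's own
#' similarity column is never among its features: its prediction rests
#' solely on how similar it is to the training items.
#'
#' Shipped classifiers are Gaussian Naive Bayes and k-nearest-neighbours;
#' they stand in for the instance-based entropic-distance classifier used
#' in the original analyses, whose internals are not reproduced here.
#'
#' @param x A `"tss_matrix"` or named symmetric similarity matrix.
#' @param labels A data frame `item, label` or named vector mapping item to
#'   class label; every matrix item must be labelled, with >= 2 classes.
#' @param k Number of folds (>= 2, <= number of items).
#' @param classifier `"knn"` or `"gaussian_nb"`.
#' @param seed Integer seed for the fold draw (reproducible); `NULL` uses
#'   the current RNG state.
#' @param k_neighbors Neighbourhood size for the knn classifier.
#' @return An object of class `"tss_cv"`: per-fold accuracies plus the
#'   mean. Use `tidy()` for the fold table, `glance()` for the one-row
#'   summary.
#' @export
crossval_classify <- function(x, labels, k = 10,
                              classifier = c("knn", "gaussian_nb"),
                              seed = NULL, k_neighbors = 1) {
  classifier <- match.arg(classifier)
  S <- similarity_values(x)
  items <- rownames(S)
  m <- length(items)
  if (k > m) stop("k exceeds the number of items", call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  lab <- as_label_vector(labels, items)
  if (length(unique(lab)) < 2) stop("need at least 2 classes", call. = FALSE)
  if (!is.null(seed)) {
    withr::local_preserve_seed()
    set.seed(as.integer(seed))
  }
  fold <- assign_folds(lab, k)
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    test <- which(fold == f)
    train <- which(fold != f)
    Xtr <- S[train, train, drop = FALSE]
    Xte <- S[test, train, drop = FALSE]
    pred <- switch(classifier,
      knn = as.character(class::knn(Xtr, Xte, cl = factor(lab[train]),
                                    k = k_neighbors)),
      gaussian_nb = {
        fit <- e1071::naiveBayes(as.data.frame(Xtr), factor(lab[train]))
        as.character(stats::predict(fit, as.data.frame(Xte)))
      }
    )
    tibble::tibble(fold = f, n_test = length(test),
                   accuracy = mean(pred == lab[test]))
  })
  structure(
    list(folds = folds, accuracy = mean(folds$accuracy),
         classifier = classifier, k = k, n_items = m),
    class = "tss_cv"
  )
}

# Lenient truth flags: logical, 0/1 numeric, or "1"/"true"/"yes" strings
# (CSV columns often arrive as character).
as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(trimws(as.character(x))) %in% c("1", "true", "t", "yes")
}

as_label_vector <- function(labels, items) {
  if (is.data.frame(labels)) {
    if (!all(c("item", "label") %in% names(labels))) {
      stop("labels need columns 'item' and 'label'", call. = FALSE)
    }
    lv <- stats::setNames(as.character(labels$label),
                          as.character(labels$item))
  } else if (!is.null(names(labels))) {
    lv <- stats::setNames(as.character(labels), names(labels))
  } else if (length(labels) == length(items)) {
    lv <- stats::setNames(as.character(labels), items)
  } else {
    stop("labels must be named or aligned with the matrix items", call. = FALSE)
  }
  missing <- setdiff(items, names(lv))
  if (length(missing) > 0) {
    stop("item '", missing[1], "' has no label", call. = FALSE)
  }
  unname(lv[items])
}

# Stratified folds when every class has >= k members; otherwise plain
# random folds (graceful degradation for small classes).
assign_folds <- function(lab, k) {
  m <- length(lab)
  fold <- integer(m)
  if (all(table(lab) >= k)) {
    for (cl in unique(lab)) {
      idx <- sample(which(lab == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(m)] <- rep_len(seq_len(k), m)
  }
  fold
}

#' @export
print.tss_cv <- function(x, ...) {
  cat("<tss_cv> ", x$k, "-fold ", x$classifier, " on ", x$n_items,
      " items: mean accuracy ", format(round(x$accuracy, 4)), "\n", sep = "")
  invisible(x)
}

#' Tidy / summarise a cross-validation result
#'
#' @param x A `"tss_cv"` from [crossval_classify()].
#' @param ... Unused.
#' @return `tidy()`: the per-fold accuracy tibble. `glance()`: a one-row
#'   tibble `accuracy, k, classifier, n_items`.
#' @method tidy tss_cv
#' @export
tidy.tss_cv <- function(x, ...) x$folds

#' @rdname tidy.tss_cv
#' @method glance tss_cv
#' @export
glance.tss_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, k = x$k,
                 classifier = x$classifier, n_items = x$n_items)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a square symmetric dissimilarity matrix in `dims` dimensions by
#' double-centering and the top eigenvectors (via [stats::cmdscale()]),
#' with a deterministic sign convention: in each output axis the first
#' coordinate of non-negligible magnitude is made positive, so repeated
#' runs give identical coordinates. Dissimilarities realisable by a point
#' configuration in `dims` dimensions are reproduced exactly up to
#' numerical tolerance.
#'
#' @param d A square symmetric non-negative matrix with zero diagonal
#'   (e.g. from [tss_to_dissimilarity()]), or a [stats::dist] object.
#' @param dims Embedding dimension (default 2).
#' @return A tibble with columns `item` and the coordinates (`x`, `y` for
#'   the first two axes, `dim3`, ... beyond).
#' @export
classical_mds <- function(d, dims = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("d must be a square matrix", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) stop("d must be symmetric", call. = FALSE)
  if (any(d < 0)) stop("dissimilarities must be non-negative", call. = FALSE)
  if (max(abs(diag(d))) > 1e-8) {
    stop("d must have a zero diagonal", call. = FALSE)
  }
  m <- nrow(d)
  if (dims >= m) stop("dims must be smaller than the number of items", call. = FALSE)
  coords <- stats::cmdscale(d, k = dims)
  if (ncol(coords) < dims) {  # degenerate spectra yield fewer axes; pad
    coords <- cbind(coords, matrix(0, m, dims - ncol(coords)))
  }
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-10)
    if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  nm <- if (!is.null(rownames(d))) rownames(d) else paste0("item", seq_len(m))
  cn <- c("x", "y", paste0("dim", seq_len(max(dims - 2, 0)) + 2))[seq_len(dims)]
  out <- tibble::as_tibble(coords, .name_repair = ~cn)
  tibble::add_column(out, item = nm, .before = 1)
}

#' Similarity-to-dissimilarity transform
#'
#' `d = 1 - TSS`, with the diagonal forced to zero, ready for
#' [classical_mds()].
#'
#' @param x A `"tss_matrix"` or numeric matrix with entries in [0, 1].
#' @return A numeric matrix of dissimilarities.
#' @export
tss_to_dissimilarity <- function(x) {
  v <- if (inherits(x, "tss_matrix")) x$values else as.matrix(x)
  if (any(v < 0 | v > 1)) stop("similarities must be in [0, 1]", call. = FALSE)
  d <- 1 - v
  diag(d) <- 0
  d
}

#' Scatter plot of an MDS embedding
#'
#' @param coords A tibble from [classical_mds()].
#' @param labels Optional named vector or `item, label` data frame of
#'   category labels used to colour points.
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, labels = NULL) {
  df <- coords
  if (!is.null(labels)) {
    df$label <- as_label_vector(labels, df$item)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$label))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  }
  p + ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$item), vjust = -0.7,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", colour = NULL) +
    ggplot2::theme_minimal()
}
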