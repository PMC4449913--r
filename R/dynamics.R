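as_group_table <- function(groups, items = NULL) {
  if (is.data.frame(groups)) {
    if (!all(c("item", "group") %in% names(groups))) {
      stop("group table needs columns 'item' and 'group'", call. = FALSE)
    }
    out <- tibble::tibble(item = as.character(groups$item),
                          group = as.character(groups$group))
  } else if (!is.null(names(groups))) {
    out <- tibble::tibble(item = names(groups), group = as.character(groups))
  } else {
    stop("groups must be a data frame (item, group) or a named vector",
         call. = FALSE)
  }
  if (anyDuplicated(out$item)) {
    dup <- out$item[duplicated(out$item)][1]
    stop("item '", dup, "' is assigned to more than one group", call. = FALSE)
  }
  if (!is.null(items)) {
    missing <- setdiff(items, out$item)
    if (length(missing) > 0) {
      stop("item '", missing[1], "' has no group assignment", call. = FALSE)
    }
    out <- out[match(items, out$item), , drop = FALSE]
  }
  out
}

similarity_values <- function(x) {
  if (inherits(x, "tss_matrix")) return(x$values)
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("similarity matrix must be square", call. = FALSE)
    if (is.null(rownames(x))) {
      dimnames(x) <- list(paste0("item", seq_len(nrow(x))),
                          paste0("item", seq_len(nrow(x))))
    }
    return(x)
  }
  stop("expected a tss_matrix or a named square matrix", call. = FALSE)
}

#' Group-organisation performance of a similarity matrix
#'
#' For each item, takes the three most similar other items (largest
#' off-diagonal entries of its row; ties broken by vocabulary order) and
#' scores how many belong to the item's own group: 1 if all three are
#' groupmates, 2/3 if two, 1/3 if one, 0 if none. The mean score over items
#' summarises how strongly the similarity structure reflects the grouping;
#' for an i.i.d. random matrix with groups of four the expected mean is
#' 3/(m-1) for m items (3/31 for 32 items in 8 groups of 4).
#'
#' @param x A `"tss_matrix"` or a named symmetric similarity matrix.
#' @param groups A data frame with columns `item`, `group`, or a named
#'   vector mapping item to group label. Every matrix item must be
#'   assigned; every group must have at least 4 members so a perfect score
#'   is attainable.
#' @return A tibble with columns `item`, `group`, `n_groupmates` (how many
#'   of the top three share the item's group) and `score`; the mean score
#'   is attached as attribute `"mean_score"` and is `mean(out$score)`.
#' @export
group_performance <- function(x, groups) {
  S <- similarity_values(x)
  items <- rownames(S)
  m <- length(items)
  if (m < 4) stop("need at least 4 items: each item requires 3 others", call. = FALSE)
  gt <- as_group_table(groups, items)
  size <- table(gt$group)
  small <- names(size)[size < 4]
  if (length(small) > 0) {
    stop("group '", small[1], "' has fewer than 4 members", call. = FALSE)
  }
  grp <- gt$group
  hits <- integer(m)
  for (i in seq_len(m)) {
    sims <- S[i, -i]
    other_grp <- grp[-i]
    # order() is stable, so equal similarities fall back to vocabulary order
    top3 <- order(sims, decreasing = TRUE)[1:3]
    hits[i] <- sum(other_grp[top3] == grp[i])
  }
  out <- tibble::tibble(item = items, group = grp,
                        n_groupmates = hits, score = hits / 3)
  attr(out, "mean_score") <- mean(out$score)
  out
}

#' Mean group performance along a matrix series
#'
#' Applies [group_performance()] to each matrix of a [tss_series()] and
#' returns the mean-score curve.
#'
#' @param series A `"tss_series"` (or list of `"tss_matrix"`).
#' @param groups As in [group_performance()].
#' @return A tibble `time, mean_score`.
#' @export
performance_series <- function(series, groups) {
  purrr::map_dfr(series, function(mat) {
    gp <- group_performance(mat, groups)
    tibble::tibble(time = mat$time, mean_score = attr(gp, "mean_score"))
  })
}

#' Concept drift relative to two anchor groups
#'
#' Tracks the semantic drift of a concept by its mean similarity to two
#' fixed, disjoint anchor word groups over a time grid: at each time, the
#' mean of `tss(concept, x)` over the words of each group. A concept
#' drifting from its habitual neighbourhood (group 1) towards an
#' event-driven one (group 2) shows the group-2 mean rising while the
#' group-1 mean falls.
#'
#' With `embed = TRUE` a 2-D trajectory is added: the anchor words are
#' embedded once by classical MDS of the time-averaged dissimilarity
#' (1 - mean similarity), and the concept is placed at each time by
#' least-squares matching of its embedded distances to its
#' (1 - similarity) dissimilarities to the anchors.
#'
#' @param messages A message tibble.
#' @param concept The tracked term; must not belong to either group.
#' @param g1,g2 Character vectors of anchor terms; disjoint, non-empty.
#' @param times Ascending reference times.
#' @param config A [tss_config()].
#' @param embed Add a 2-D embedded position per time point?
#' @return A tibble `time, mean_g1, mean_g2` (plus `x, y` when embedded).
#' @export
anchor_drift <- function(messages, concept, g1, g2, times,
                         config = tss_config(), embed = FALSE) {
  config <- as_tss_config(config)
  g1 <- as.character(g1); g2 <- as.character(g2)
  if (length(g1) == 0 || length(g2) == 0) {
    stop("anchor groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(g1, g2)) > 0) {
    stop("anchor groups must be disjoint (overlap: ",
         paste(intersect(g1, g2), collapse = ", "), ")", call. = FALSE)
  }
  if (concept %in% c(g1, g2)) {
    stop("concept must not belong to an anchor group", call. = FALSE)
  }
  if (is.unsorted(times)) stop("times must be ascending", call. = FALSE)
  messages <- as_messages(messages)
  toks <- tokenize(messages$text)
  t <- messages$t
  hc <- match_token_list(toks, term_token_seq(concept))
  anchors <- c(g1, g2)
  vals <- sapply(anchors, function(w) {
    hw <- match_token_list(toks, term_token_seq(w))
    tss_values(t[hc], t[hw], t[hc & hw], times, config)
  })
  vals <- matrix(vals, nrow = length(times),
                 dimnames = list(NULL, anchors))
  out <- tibble::tibble(
    time = as.double(times),
    mean_g1 = rowMeans(vals[, g1, drop = FALSE]),
    mean_g2 = rowMeans(vals[, g2, drop = FALSE])
  )
  if (embed) {
    pos <- drift_embedding(messages, concept, anchors, times, config, vals)
    out$x <- pos[, 1]
    out$y <- pos[, 2]
  }
  out
}

# D11-style trajectory: embed anchors from the time-averaged similarity
# matrix, then place the concept per time by least squares against its
# (1 - TSS) dissimilarities to the anchors.
drift_embedding <- function(messages, concept, anchors, times, config,
                            concept_vals) {
  series <- tss_series(messages, anchors, times, config)
  avg <- Reduce(`+`, lapply(series, as.matrix)) / length(series)
  d <- 1 - avg
  diag(d) <- 0
  coords <- classical_mds(d, dims = 2)
  A <- as.matrix(coords[, c("x", "y")])
  t(vapply(seq_along(times), function(i) {
    target <- 1 - concept_vals[i, ]
    obj <- function(p) {
      dd <- sqrt(rowSums((A - matrix(p, nrow(A), 2, byrow = TRUE))^2))
      sum((dd - target)^2)
    }
    start <- colSums(A * (1 - target)) / max(sum(1 - target), 1e-12)
    stats::optim(start, obj, method = "Nelder-Mead")$par
  }, double(2)))
}

#' Frobenius norm series of similarity matrices
#'
#' The Frobenius norm of each matrix with the diagonal excluded (self
#' similarity is constant and carries no reorganisation signal). A rise in
#' the norm means the network's off-diagonal similarity mass is growing —
#' the signature of an event pulling terms together.
#'
#' @param series A `"tss_series"` or list of `"tss_matrix"` sharing one
#'   vocabulary.
#' @return A tibble `time, norm`.
#' @export
matrix_norm_series <- function(series) {
  if (inherits(series, "tss_matrix")) series <- list(series)
  vocabs <- lapply(series, function(m) m$vocabulary)
  if (length(unique(vocabs)) != 1) {
    stop("all matrices must share the same vocabulary", call. = FALSE)
  }
  purrr::map_dfr(series, function(m) {
    v <- as.matrix(m)
    diag(v) <- 0
    tibble::tibble(time = m$time, norm = sqrt(sum(v^2)))
  })
}

#' Correlation between two norm series
#'
#' Pearson correlation of two matrix-norm series on their shared time grid,
#' optionally restricted to a window; used to quantify whether two
#' subnetworks reorganise in concert during an event.
#'
#' @param norms_a,norms_b Tibbles `time, norm` as returned by
#'   [matrix_norm_series()].
#' @param window Optional numeric `c(lo, hi)`: keep only times in
#'   `[lo, hi]`.
#' @return A one-row tibble `estimate, p_value, n`.
#' @export
subnetwork_correlation <- function(norms_a, norms_b, window = NULL) {
  joined <- dplyr::inner_join(
    dplyr::rename(norms_a, norm_a = "norm"),
    dplyr::rename(norms_b, norm_b = "norm"),
    by = "time"
  )
  if (!is.null(window)) {
    joined <- dplyr::filter(joined, .data$time >= window[1],
                            .data$time <= window[2])
  }
  if (nrow(joined) < 3) {
    stop("need at least 3 aligned time points", call. = FALSE)
  }
  ct <- stats::cor.test(joined$norm_a, joined$norm_b, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(joined))
}

#' Line plot of a drift record
#'
#' @param drift A tibble from [anchor_drift()].
#' @return A ggplot object: the two group means over time.
#' @export
plot_drift <- function(drift) {
  df <- tidyr::pivot_longer(drift[, c("time", "mean_g1", "mean_g2")],
                            cols = c("mean_g1", "mean_g2"),
                            names_to = "group", values_to = "mean_tss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean_tss,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean TSS", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Line plot of a performance curve
#'
#' @param perf A tibble from [performance_series()].
#' @param chance Optional chance level to draw as a dashed reference line.
#' @return A ggplot object.
#' @export
plot_performance <- function(perf, chance = NULL) {
  p <- ggplot2::ggplot(perf, ggplot2::aes(x = .data$time,
                                          y = .data$mean_score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean group performance") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(chance)) {
    p <- p + ggplot2::geom_hline(yintercept = chance, linetype = "dashed")
  }
  p
}
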