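#' Clusterings of a word sequence
#'
#' A clustering is an ordered partition of a produced word sequence into
#' contiguous clusters. It is stored as a tibble of class `vf_clustering`
#' with one row per cluster: `cluster` (1-based index), `start` and `end`
#' (1-based inclusive token positions), `n_words`, and `size`
#' (`n_words - 1`, the field convention: a singleton has size 0).
#' Attributes carry the clustering `method` and `n_tokens`. All three
#' clustering methods in the package reduce to a logical *join* vector
#' over adjacent word pairs; maximal joined runs become clusters and every
#' remaining word is a singleton cluster.
#'
#' @param join Logical vector of length `n_tokens - 1`; `join[i]` states
#'   whether tokens `i` and `i + 1` belong to one cluster.
#' @param method Method tag, e.g. `"list_based"`, `"rule_based"`,
#'   `"relatedness"`.
#' @param n_tokens Number of tokens in the sequence.
#' @return A `vf_clustering` tibble.
#' @examples
#' clusters_from_joins(c(TRUE, FALSE, TRUE), method = "list_based")
#' @export
clusters_from_joins <- function(join, method = "custom", n_tokens = length(join) + 1L) {
  join <- as.logical(join)
  if (n_tokens == 0) {
    return(new_clustering(integer(), integer(), method, 0L))
  }
  if (length(join) != n_tokens - 1L) {
    abort("`join` must have length n_tokens - 1.")
  }
  join[is.na(join)] <- FALSE
  # cluster id increments after every non-joined boundary
  ids <- cumsum(c(1L, as.integer(!join)))
  start <- which(!duplicated(ids))
  end <- c(start[-1] - 1L, n_tokens)
  new_clustering(start, end, method, n_tokens)
}

new_clustering <- function(start, end, method, n_tokens) {
  out <- tibble(
    cluster = seq_along(start),
    start = as.integer(start), end = as.integer(end),
    n_words = as.integer(end - start + 1L),
    size = as.integer(end - start)
  )
  attr(out, "method") <- method
  attr(out, "n_tokens") <- as.integer(n_tokens)
  class(out) <- c("vf_clustering", class(tibble()))
  out
}

#' @export
print.vf_clustering <- function(x, ...) {
  cat(sprintf("<vf_clustering: %s, %d tokens, %d clusters, %d switches>\n",
              attr(x, "method"), attr(x, "n_tokens"), nrow(x),
              max(nrow(x) - 1L, 0L)))
  NextMethod()
}

#' Per-token cluster assignments
#'
#' @param clustering A `vf_clustering`.
#' @return Integer vector of length `n_tokens` giving each token's
#'   cluster index.
#' @export
cluster_assignments <- function(clustering) {
  rep(clustering$cluster, clustering$n_words)
}

#' Rand index between two clusterings of the same sequence
#'
#' The Rand index is the fraction of token pairs on which two clusterings
#' agree (both place the pair together or both apart); 1 means identical
#' partitions. Used to score recovery of planted cluster structure.
#'
#' @param a,b `vf_clustering` objects or integer assignment vectors over
#'   the same number of tokens.
#' @return The Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (inherits(a, "vf_clustering")) a <- cluster_assignments(a)
  if (inherits(b, "vf_clustering")) b <- cluster_assignments(b)
  n <- length(a)
  if (length(b) != n) abort("Assignments must cover the same tokens.")
  if (n < 2) return(1)
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  agree_together <- sum_comb(tab)
  total <- choose(n, 2)
  a_pairs <- sum_comb(rowSums(tab))
  b_pairs <- sum_comb(colSums(tab))
  # pairs apart in both = total - a_pairs - b_pairs + together
  (agree_together + (total - a_pairs - b_pairs + agree_together)) / total
}

#' Plot a clustering along the production sequence
#'
#' Draws each produced word at its sequence position, colour-banded by
#' cluster, so runs and switches are visible at a glance.
#'
#' @param object A `vf_clustering`.
#' @param words Optional character vector of the clustered words, used as
#'   labels.
#' @param ... Ignored.
#' @return A `ggplot` object.
#' @method autoplot vf_clustering
#' @export
autoplot.vf_clustering <- function(object, words = NULL, ...) {
  asg <- cluster_assignments(object)
  df <- tibble(
    position = seq_along(asg),
    cluster = factor(asg),
    word = if (is.null(words)) as.character(seq_along(asg)) else words
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = 1, fill = .data$cluster)) +
    ggplot2::geom_tile(height = 0.6, colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$word), angle = 90, size = 3) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = "production order", y = NULL, fill = "cluster",
      title = sprintf("%s clustering: %d clusters, %d switches",
                      attr(object, "method"), nrow(object),
                      max(nrow(object) - 1L, 0L))
    ) +
    ggplot2::theme_minimal()
}
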