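#' Cluster characteristics of one transcript
#'
#' Computes the standard fluency cluster characteristics under the
#' field's inclusion conventions: the *total word count* is the number of
#' words after removing rule violations, while *mean cluster size* and
#' *switches* are computed over the full produced sequence (violations
#' are not excluded from clustering). Cluster size is the number of
#' words in the cluster minus 1 and singletons count as clusters, so
#' `switches = clusters - 1` and the closed form
#' `mean_cluster_size = n_tokens / (switches + 1) - 1` holds exactly.
#' The mean sequential relatedness is the mean over the defined
#' (non-OOV) adjacent-pair scores when a score table is supplied.
#'
#' @param tokens A single-transcript `vf_tokens` tibble (flags already
#'   marked).
#' @param clustering A `vf_clustering` covering exactly those tokens.
#' @param scores Optional sequential-relatedness tibble from
#'   [sequential_relatedness()] (or the `scores` attribute of
#'   [cluster_relatedness()]); must have `n_tokens - 1` rows.
#' @return One-row tibble: `transcript_id`, `task`, `method`,
#'   `n_tokens`, `total_word_count`, `n_clusters`, `mean_cluster_size`,
#'   `switches`, `mean_sequential_relatedness`, `n_oov_pairs`.
#' @examples
#' tr <- mark_violations(vf_tokens(c("hund", "katze", "hund")))
#' cl <- clusters_from_joins(c(TRUE, TRUE), method = "list_based")
#' cluster_metrics(tr, cl)
#' @export
cluster_metrics <- function(tokens, clustering, scores = NULL) {
  if (length(unique(tokens$transcript_id)) > 1) {
    abort("`tokens` must hold a single transcript; see metrics_table().")
  }
  n <- nrow(tokens)
  if (attr(clustering, "n_tokens") != n) {
    abort(sprintf("Clustering covers %d tokens but transcript has %d.",
                  attr(clustering, "n_tokens"), n))
  }
  k <- nrow(clustering)
  msr <- NA_real_
  n_oov <- NA_integer_
  if (is.null(scores)) scores <- attr(clustering, "scores")
  if (!is.null(scores)) {
    if (nrow(scores) != max(n - 1L, 0L)) {
      abort("`scores` must have n_tokens - 1 rows.")
    }
    defined <- scores$score[!scores$oov]
    n_oov <- sum(scores$oov)
    msr <- if (length(defined) > 0) mean(defined) else NA_real_
  }
  tibble(
    transcript_id = if (n > 0) tokens$transcript_id[1] else NA_character_,
    task = if (n > 0) tokens$task[1] else NA_character_,
    method = attr(clustering, "method"),
    n_tokens = n,
    total_word_count = sum(!has_violation(tokens$flags)),
    n_clusters = k,
    mean_cluster_size = if (k > 0) sum(clustering$size) / k else NA_real_,
    switches = if (k > 0) k - 1L else NA_integer_,
    mean_sequential_relatedness = msr,
    n_oov_pairs = n_oov
  )
}

#' Cluster characteristics for a corpus of transcripts
#'
#' Applies [cluster_metrics()] across transcripts and stacks the rows
#' into one table, ready for summaries and association statistics.
#'
#' @param tokens A `vf_tokens` tibble holding one or more transcripts.
#' @param clusterings Named list of `vf_clustering` objects keyed by
#'   `transcript_id` (or an unnamed list parallel to the transcript
#'   order).
#' @param scores Optional named list of sequential-relatedness tibbles,
#'   keyed like `clusterings`.
#' @return Tibble with one row per transcript (empty, with the metric
#'   columns, for empty input).
#' @export
metrics_table <- function(tokens, clusterings, scores = NULL) {
  ids <- unique(tokens$transcript_id)
  if (length(ids) == 0) {
    return(cluster_metrics(
      vf_tokens(character()),
      clusters_from_joins(logical(0), n_tokens = 0L)
    )[0, ])
  }
  if (is.null(names(clusterings))) names(clusterings) <- ids
  rows <- lapply(ids, function(id) {
    sc <- if (!is.null(scores)) scores[[id]] else NULL
    cluster_metrics(tokens[tokens$transcript_id == id, ],
                    clusterings[[id]], sc)
  })
  dplyr::bind_rows(rows)
}

#' Summary of a metrics table
#'
#' Column means and sample standard deviations (n - 1 denominator) of
#' the numeric cluster characteristics, by method, in the shape used for
#' group-characteristics tables.
#'
#' @param metrics A tibble from [metrics_table()].
#' @return Tibble with one row per method and per statistic
#'   (`mean`, `sd`).
#' @export
summarize_metrics <- function(metrics) {
  num_cols <- c("n_tokens", "total_word_count", "mean_cluster_size",
                "switches", "mean_sequential_relatedness")
  num_cols <- intersect(num_cols, names(metrics))
  long <- tidyr::pivot_longer(
    dplyr::select(metrics, "method", dplyr::all_of(num_cols)),
    -"method", names_to = "characteristic", values_to = "value"
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$method, .data$characteristic),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    .groups = "drop"
  )
}
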