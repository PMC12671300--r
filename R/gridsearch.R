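#' Default hyperparameter lattice for the embedding grid search
#'
#' Dimensions 200/500/1000, window 4/10, CBOW and skip-gram: 12
#' combinations, each swept over 101 relatedness thresholds.
#'
#' @return Tibble with columns `dimensions`, `window`, `algorithm`
#'   (12 rows).
#' @export
vf_default_grid <- function() {
  tidyr::expand_grid(
    dimensions = c(200L, 500L, 1000L),
    window = c(4L, 10L),
    algorithm = c("cbow", "skipgram")
  )
}

#' The 101-point threshold lattice (0 to 1 in steps of 0.01)
#' @return Numeric vector of thresholds.
#' @export
vf_theta_grid <- function() seq(0, 1, by = 0.01)

classification_score <- function(pred, truth, metric) {
  if (metric == "accuracy") return(mean(pred == truth))
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (metric == "balanced_accuracy") {
    tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    return(mean(c(tpr, tnr), na.rm = TRUE))
  }
  if (metric == "f1") {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    return(if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
  abort(sprintf("Unknown metric '%s'.", metric))
}

#' Sweep the relatedness threshold over labelled pair scores
#'
#' For each threshold theta in the lattice, classifies a pair as
#' same-list when its relatedness score is strictly greater than theta
#' and scores the classification against the supervision labels.
#'
#' @param scores Numeric relatedness scores, one per pair (NA = OOV pair,
#'   dropped).
#' @param labels Logical same-list labels, parallel to `scores`.
#' @param metric `"balanced_accuracy"` (default), `"accuracy"`, or
#'   `"f1"`.
#' @param thetas Threshold lattice (default [vf_theta_grid()]).
#' @return Tibble with columns `theta`, `score`.
#' @export
sweep_threshold <- function(scores, labels,
                            metric = c("balanced_accuracy", "accuracy", "f1"),
                            thetas = vf_theta_grid()) {
  metric <- match.arg(metric)
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(scores) == 0) abort("All pairs are out of vocabulary.")
  out <- vapply(thetas, function(th) {
    classification_score(scores > th, labels, metric)
  }, numeric(1))
  tibble(theta = thetas, score = out)
}

# plateau-midpoint tie-break: among equal-best thetas take the central
# one, maximizing the margin to both plateau edges
best_theta <- function(sweep) {
  top <- which(sweep$score == max(sweep$score))
  sweep[top[ceiling(length(top) / 2)], ]
}

#' Hyperparameter grid search supervised by a category lexicon
#'
#' For every combination in the hyperparameter lattice, trains an
#' embedding model on the corpus, scores random supervision pairs drawn
#' from the lexicon, and sweeps the relatedness threshold over
#' 0, 0.01, ..., 1.00, classifying a pair as same-list when its score
#' exceeds theta. The hyperparameters are tuned against the category
#' lists, not against any participant word sequence, which guards
#' against overfitting the transcripts. The default selection metric is
#' balanced accuracy (robust to unbalanced class counts from random
#' sampling); pairs containing out-of-vocabulary words are dropped and
#' counted.
#'
#' @param corpus Sentence corpus (character vector or file path).
#' @param lexicon A `vf_lexicon` supplying supervision pairs.
#' @param grid Hyperparameter lattice tibble with columns `dimensions`,
#'   `window`, `algorithm` (default [vf_default_grid()]).
#' @param n_pairs Number of supervision pairs to draw.
#' @param seed Integer seed driving pair sampling and training.
#' @param metric Classification metric (see [sweep_threshold()]).
#' @param min_count,epochs Training settings shared across combinations.
#' @param balanced Balanced pair sampling (see
#'   [sample_supervision_pairs()]).
#' @return A `vf_grid_search` object: `best` (one-row tibble with the
#'   winning combination, theta, and score), `table` (all combinations x
#'   101 thetas), `pairs`, `n_oov_pairs`, `metric`, `seed`.
#' @export
grid_search <- function(corpus, lexicon, grid = vf_default_grid(),
                        n_pairs = 100, seed = 1L,
                        metric = c("balanced_accuracy", "accuracy", "f1"),
                        min_count = 1, epochs = 5, balanced = FALSE) {
  metric <- match.arg(metric)
  pairs <- sample_supervision_pairs(lexicon, n_pairs, seed = seed,
                                    balanced = balanced)
  rows <- vector("list", nrow(grid))
  n_oov <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- embedding_config(
      dimensions = grid$dimensions[g], window = grid$window[g],
      algorithm = grid$algorithm[g], min_count = min_count,
      epochs = epochs, seed = seed + g
    )
    model <- train_embeddings(corpus, cfg)
    sc <- relatedness(model, pairs$w1, pairs$w2)
    n_oov[g] <- sum(sc$oov)
    if (all(sc$oov)) abort("All supervision pairs are out of vocabulary.")
    sw <- sweep_threshold(sc$score, pairs$same_list, metric)
    rows[[g]] <- dplyr::mutate(sw,
      dimensions = grid$dimensions[g], window = grid$window[g],
      algorithm = grid$algorithm[g], .before = 1
    )
  }
  tab <- dplyr::bind_rows(rows)
  per_combo <- dplyr::bind_rows(lapply(rows, best_theta))
  per_combo <- dplyr::bind_cols(grid, per_combo[, c("theta", "score")])
  best <- per_combo[which.max(per_combo$score), ]
  structure(
    list(best = best, table = tab, per_combo = per_combo, pairs = pairs,
         n_pairs = n_pairs, n_oov_pairs = n_oov, metric = metric,
         seed = seed),
    class = "vf_grid_search"
  )
}

#' @export
print.vf_grid_search <- function(x, ...) {
  cat(sprintf("<vf_grid_search: %d combinations x %d thresholds, metric %s>\n",
              nrow(x$per_combo), length(unique(x$table$theta)), x$metric))
  cat("best: ")
  print(x$best)
  invisible(x)
}

#' @describeIn grid_search Full combination-by-threshold score table.
#' @param x A `vf_grid_search`.
#' @param ... Ignored.
#' @method tidy vf_grid_search
#' @export
tidy.vf_grid_search <- function(x, ...) x$table

#' @describeIn grid_search One-row summary: the winning combination.
#' @method glance vf_grid_search
#' @export
glance.vf_grid_search <- function(x, ...) {
  dplyr::mutate(x$best, metric = x$metric, n_pairs = x$n_pairs,
                seed = x$seed)
}

#' @describeIn grid_search Threshold-sweep curves, one panel per
#'   combination.
#' @param object A `vf_grid_search`.
#' @method autoplot vf_grid_search
#' @export
autoplot.vf_grid_search <- function(object, ...) {
  df <- dplyr::mutate(object$table,
    combo = paste0("d", .data$dimensions, " w", .data$window, " ",
                   .data$algorithm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best$theta, linetype = 2,
                        colour = "red") +
    ggplot2::facet_wrap(~combo) +
    ggplot2::labs(x = "relatedness threshold", y = object$metric) +
    ggplot2::theme_minimal()
}
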