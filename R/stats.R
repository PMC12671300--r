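#' Association statistics between cluster characteristics and
#' neuropsychological scores
#'
#' Thin, uniformly-shaped wrappers around the classical tests used to
#' validate cluster characteristics against paper-based
#' neuropsychological instruments: Pearson product-moment correlation
#' (the default for metric-score associations), Spearman rank
#' correlation (used for ordinal items such as a dysarthria rating), and
#' the Mann-Whitney U test for two-group comparisons of non-normal
#' scores. Missing values are handled by pairwise-complete deletion;
#' two-sided p-values throughout (Pearson/Spearman via the t
#' transformation with n - 2 degrees of freedom; Mann-Whitney exact when
#' both groups have at most 8 tie-free observations, normal
#' approximation with tie correction otherwise).
#'
#' @param x,y Numeric vectors of equal length (pairwise-complete cases
#'   are used).
#' @param x_name,y_name Variable names recorded in the result.
#' @return One-row tibble: `x`, `y`, `method`, `estimate` (r, rho, or U),
#'   `statistic`, `p_value`, `n`.
#' @examples
#' vf_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @name association
NULL

complete_xy <- function(x, y, min_n = 3L) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_n) {
    abort(sprintf("Need at least %d pairwise-complete observations.", min_n))
  }
  list(x = x, y = y, n = length(x))
}

#' @rdname association
#' @export
vf_pearson <- function(x, y, x_name = "x", y_name = "y") {
  d <- complete_xy(x, y)
  if (sd(d$x) == 0 || sd(d$y) == 0) {
    abort("Correlation undefined: zero variance in one variable.")
  }
  ct <- stats::cor.test(d$x, d$y, method = "pearson")
  tibble(x = x_name, y = y_name, method = "pearson",
         estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p_value = ct$p.value, n = d$n)
}

#' @rdname association
#' @export
vf_spearman <- function(x, y, x_name = "x", y_name = "y") {
  d <- complete_xy(x, y)
  if (sd(rank(d$x)) == 0 || sd(rank(d$y)) == 0) {
    abort("Correlation undefined: zero variance in one variable's ranks.")
  }
  ct <- stats::cor.test(d$x, d$y, method = "spearman", exact = FALSE)
  tibble(x = x_name, y = y_name, method = "spearman",
         estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p_value = ct$p.value, n = d$n)
}

#' @rdname association
#' @param a,b Numeric vectors: the two groups to compare.
#' @export
vf_mann_whitney <- function(a, b, x_name = "a", y_name = "b") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort("Both groups must be non-empty.")
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !has_ties
  wt <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  tibble(x = x_name, y = y_name, method = "mannwhitney",
         estimate = unname(wt$statistic), statistic = unname(wt$statistic),
         p_value = wt$p.value, n = length(a) + length(b))
}

#' Correlation network between cluster characteristics and test scores
#'
#' Correlates every cluster characteristic with every neuropsychological
#' score (and characteristics with each other) across participants, then
#' keeps the edges a fluency validation network displays: variable pairs
#' with `p < alpha`, excluding test-test edges and tests with no
#' significant link to any cluster characteristic.
#' Characteristic-characteristic edges are retained but marked
#' unlabelled. Edge weight is `|r|`.
#'
#' @param metrics Wide tibble: one row per participant, a
#'   `participant_id` column, and numeric cluster-characteristic columns.
#' @param scores Wide tibble: one row per participant, a
#'   `participant_id` column, and numeric test-score columns.
#' @param alpha Significance level for edge inclusion (default 0.05,
#'   unadjusted; set `adjust = "BH"` for Benjamini-Hochberg).
#' @param adjust `"none"` (default, matching unadjusted reporting) or
#'   `"BH"`.
#' @return Tibble of edges: `from`, `to`, `from_type`, `to_type`
#'   (`"metric"`/`"test"`), `r`, `p_value`, `n`, `weight`, `labeled`.
#' @export
correlation_network <- function(metrics, scores, alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!"participant_id" %in% names(metrics) ||
      !"participant_id" %in% names(scores)) {
    abort("Both tables need a `participant_id` column.")
  }
  merged <- dplyr::inner_join(metrics, scores, by = "participant_id")
  if (nrow(merged) == 0) abort("No shared participant ids between tables.")
  metric_vars <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))],
                         "participant_id")
  test_vars <- setdiff(names(scores)[vapply(scores, is.numeric, logical(1))],
                       "participant_id")
  vars <- c(metric_vars, test_vars)
  types <- stats::setNames(
    c(rep("metric", length(metric_vars)), rep("test", length(test_vars))), vars
  )
  combos <- utils::combn(vars, 2)
  edges <- lapply(seq_len(ncol(combos)), function(k) {
    v1 <- combos[1, k]; v2 <- combos[2, k]
    res <- tryCatch(
      vf_pearson(merged[[v1]], merged[[v2]], v1, v2),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    tibble(from = v1, to = v2, from_type = types[[v1]], to_type = types[[v2]],
           r = res$estimate, p_value = res$p_value, n = res$n)
  })
  edges <- dplyr::bind_rows(edges)
  if (nrow(edges) == 0) return(empty_edges())
  if (adjust == "BH") edges$p_value <- stats::p.adjust(edges$p_value, "BH")
  edges <- edges[edges$p_value < alpha, ]
  # display rules: no test-test edges; dropping them also removes tests
  # with no metric link (a test node survives only through a metric edge)
  edges <- edges[!(edges$from_type == "test" & edges$to_type == "test"), ]
  if (nrow(edges) == 0) return(empty_edges())
  edges$weight <- abs(edges$r)
  edges$labeled <- !(edges$from_type == "metric" & edges$to_type == "metric")
  edges
}

empty_edges <- function() {
  tibble(from = character(), to = character(), from_type = character(),
         to_type = character(), r = numeric(), p_value = numeric(),
         n = integer(), weight = numeric(), labeled = logical())
}

#' Export a correlation network edge list
#'
#' Writes the edge list from [correlation_network()] as JSON or
#' Graphviz DOT, renderable by any graph tool.
#'
#' @param edges Edge tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(edges, path) {
  jsonlite::write_json(edges, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
write_network_dot <- function(edges, path) {
  lines <- c("graph vft {")
  nodes <- unique(c(edges$from, edges$to))
  ntype <- stats::setNames(
    c(edges$from_type, edges$to_type)[match(nodes, c(edges$from, edges$to))],
    nodes
  )
  for (nd in nodes) {
    shape <- if (ntype[[nd]] == "metric") "box" else "ellipse"
    lines <- c(lines, sprintf("  \"%s\" [shape=%s];", nd, shape))
  }
  for (i in seq_len(nrow(edges))) {
    lab <- if (edges$labeled[i]) sprintf(" [label=\"%.2f\"]", edges$r[i]) else ""
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\"%s;",
                              edges$from[i], edges$to[i], lab))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
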