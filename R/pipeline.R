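#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: the task, the clustering
#' methods to apply, their resources, and reproducibility settings.
#' Method requirements are validated up front (before any computation):
#' list-based clustering needs a lexicon, relatedness clustering needs a
#' model and threshold. Default thresholds are 0.40 for the semantic and
#' 0.30 for the phonematic task.
#'
#' @param task `"semantic"` or `"phonematic"`.
#' @param methods Subset of `c("list", "rule", "relatedness")`.
#' @param lexicon A `vf_lexicon` (required for `"list"`).
#' @param model A `vf_embedding` or a path to a word2vec text file
#'   (required for `"relatedness"`).
#' @param theta Relatedness threshold; task default when `NULL`.
#' @param rules A [vf_rules()] configuration for `"rule"`.
#' @param first10_rule Apply the 10-second QC rule.
#' @param check_cue Mark non-cue-initial words as violations in
#'   phonematic transcripts.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `vf_run_config`.
#' @export
vf_run_config <- function(task = c("semantic", "phonematic"),
                          methods = c("list", "rule", "relatedness"),
                          lexicon = NULL, model = NULL, theta = NULL,
                          rules = vf_rules(), first10_rule = TRUE,
                          check_cue = TRUE, out_dir = tempfile("vft_run_"),
                          seed = 1L) {
  task <- match.arg(task)
  methods <- match.arg(methods, several.ok = TRUE)
  if ("list" %in% methods && is.null(lexicon)) {
    abort("Configuration error: method 'list' requires a `lexicon`.")
  }
  if ("relatedness" %in% methods && is.null(model)) {
    abort("Configuration error: method 'relatedness' requires a `model`.")
  }
  theta <- default_theta(task, theta)
  structure(
    list(task = task, methods = methods, lexicon = lexicon, model = model,
         theta = theta, rules = rules, first10_rule = first10_rule,
         check_cue = check_cue, out_dir = out_dir, seed = as.integer(seed)),
    class = "vf_run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Wires quality control, clustering, and cluster characteristics into
#' one reproducible run: marks violations, writes a QC report, emits
#' per-transcript cluster annotations for *all* transcripts (excluded
#' ones flagged, so exclusions can be audited), computes metrics for the
#' retained transcripts only — mirroring the exclusion flow of a
#' clinical analysis — and records a manifest with the configuration,
#' seed, package version, and model checksum. The run is deterministic:
#' identical configuration and seed yield byte-identical output files.
#'
#' @param tokens A `vf_tokens` tibble (one or many transcripts).
#' @param config A [vf_run_config()].
#' @param stems,proper_names Optional violation-detection resources
#'   passed to [mark_violations()].
#' @return Invisibly, a list with tibbles `qc`, `clusters`, `metrics`
#'   and the output `paths`.
#' @export
run_pipeline <- function(tokens, config, stems = NULL, proper_names = NULL) {
  stopifnot(inherits(config, "vf_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- config$model
  model_checksum <- NA_character_
  if ("relatedness" %in% config$methods) {
    if (is.character(model)) {
      model_checksum <- unname(tools::md5sum(model))
      model <- read_word2vec(model)
    } else {
      model_checksum <- rlang::hash(model$vectors)
    }
  }

  tokens <- mark_violations(tokens, stems = stems,
                            proper_names = proper_names,
                            check_cue = config$check_cue)
  qc <- qc_transcripts(tokens, first10_rule = config$first10_rule,
                       quiet = TRUE)

  ids <- unique(tokens$transcript_id)
  cluster_rows <- list()
  metric_rows <- list()
  for (id in ids) {
    tr <- tokens[tokens$transcript_id == id, ]
    excluded <- qc$excluded[qc$transcript_id == id]
    for (m in config$methods) {
      cl <- switch(m,
        list = cluster_list_based(tr, config$lexicon),
        rule = cluster_rule_based(tr, config$rules),
        relatedness = cluster_relatedness(tr, model, theta = config$theta,
                                          task = config$task)
      )
      ann <- dplyr::mutate(as_tibble(cl), transcript_id = id, method = m,
                           excluded = excluded, .before = 1)
      cluster_rows[[length(cluster_rows) + 1L]] <- ann
      if (!excluded) {
        metric_rows[[length(metric_rows) + 1L]] <- cluster_metrics(tr, cl)
      }
    }
  }
  clusters <- dplyr::bind_rows(cluster_rows)
  metrics <- dplyr::bind_rows(metric_rows)

  paths <- list(
    qc = file.path(config$out_dir, "qc_report.csv"),
    clusters = file.path(config$out_dir, "clusters.csv"),
    metrics = file.path(config$out_dir, "metrics.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  readr::write_csv(qc, paths$qc)
  readr::write_csv(clusters, paths$clusters)
  readr::write_csv(metrics, paths$metrics)
  manifest <- list(
    package = "fluencer",
    version = as.character(utils::packageVersion("fluencer")),
    task = config$task, methods = config$methods, theta = config$theta,
    rules = config$rules$enabled, first10_rule = config$first10_rule,
    check_cue = config$check_cue, seed = config$seed,
    model_checksum = model_checksum,
    n_transcripts = length(ids), n_excluded = sum(qc$excluded)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(qc = qc, clusters = clusters, metrics = metrics,
                 paths = paths))
}
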