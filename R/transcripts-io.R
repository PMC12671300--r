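#' Read and write transcript files
#'
#' Two plain-text encodings are supported and round-trip losslessly.
#' JSON-lines holds one object per transcript:
#' `{"transcript_id","task","cue","duration_s","source","tokens":[{"surface","onset_s","flags":[...]}]}`.
#' The CSV long format holds one row per token with columns
#' `transcript_id, task, cue, duration_s, source, position, surface,
#' onset_s, flags` (flags semicolon-joined). Malformed rows raise an
#' error naming the offending line and field.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; by default inferred from the file
#'   extension.
#' @return `read_transcripts()` returns a `vf_tokens` tibble covering all
#'   transcripts in the file; `write_transcripts()` returns `path`
#'   invisibly.
#' @examples
#' tr <- vf_tokens(c("hund", "katze"), transcript_id = "p1")
#' f <- tempfile(fileext = ".jsonl")
#' write_transcripts(tr, f)
#' identical_tokens <- read_transcripts(f)
#' @export
read_transcripts <- function(path, format = NULL) {
  format <- format %||% infer_format(path, c("jsonl", "csv"))
  if (format == "jsonl") read_transcripts_jsonl(path) else read_transcripts_csv(path)
}

#' @rdname read_transcripts
#' @param tokens A `vf_tokens` tibble.
#' @export
write_transcripts <- function(tokens, path, format = NULL) {
  format <- format %||% infer_format(path, c("jsonl", "csv"))
  if (format == "jsonl") {
    lines <- vapply(unique(tokens$transcript_id), function(id) {
      df <- tokens[tokens$transcript_id == id, ]
      obj <- list(
        transcript_id = id, task = df$task[1], cue = df$cue[1],
        duration_s = df$duration_s[1], source = df$source[1],
        tokens = lapply(seq_len(nrow(df)), function(i) {
          tk <- list(surface = df$surface[i])
          if (!is.na(df$onset_s[i])) tk$onset_s <- df$onset_s[i]
          tk$flags <- as.list(df$flags[[i]])
          tk
        })
      )
      jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    flat <- tokens
    flat$flags <- vapply(flat$flags, paste, character(1), collapse = ";")
    flat$normalized <- NULL
    readr::write_csv(flat, path, na = "")
  }
  invisible(path)
}

infer_format <- function(path, choices) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% choices) return(ext)
  if (ext %in% c("json", "ndjson") && "jsonl" %in% choices) return("jsonl")
  abort(sprintf("Cannot infer format from '%s'; pass `format` explicitly.", path))
}

read_transcripts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(seq_along(lines), function(ln) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
      error = function(e) abort(sprintf("Line %d: invalid JSON (%s).", ln, conditionMessage(e)))
    )
    for (field in c("transcript_id", "task", "cue", "tokens")) {
      if (is.null(obj[[field]])) abort(sprintf("Line %d: missing field '%s'.", ln, field))
    }
    surf <- vapply(obj$tokens, function(t) {
      if (is.null(t$surface)) abort(sprintf("Line %d: token missing field 'surface'.", ln))
      as.character(t$surface)
    }, character(1))
    onset <- vapply(obj$tokens, function(t) {
      if (is.null(t$onset_s)) return(NA_real_)
      o <- as.numeric(t$onset_s)
      if (!is.na(o) && o < 0) abort(sprintf("Line %d: field 'onset_s' is negative.", ln))
      o
    }, numeric(1))
    flg <- lapply(obj$tokens, function(t) {
      as.character(unlist(t$flags %||% character()))
    })
    tryCatch(
      vf_tokens(surf,
        transcript_id = obj$transcript_id, task = obj$task, cue = obj$cue,
        duration_s = obj$duration_s %||% 60, source = obj$source %||% "manual",
        onset_s = onset, flags = flg
      ),
      error = function(e) abort(sprintf("Line %d: %s", ln, conditionMessage(e)))
    )
  })
  preserve_tokens_class(dplyr::bind_rows(out))
}

read_transcripts_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           transcript_id = readr::col_character(),
                           task = readr::col_character(),
                           cue = readr::col_character(),
                           duration_s = readr::col_double(),
                           source = readr::col_character(),
                           position = readr::col_integer(),
                           surface = readr::col_character(),
                           onset_s = readr::col_double(),
                           flags = readr::col_character()
                         ))
  needed <- c("transcript_id", "task", "cue", "position", "surface")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(sprintf("CSV is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (any(!is.na(raw$onset_s) & raw$onset_s < 0)) {
    bad <- which(!is.na(raw$onset_s) & raw$onset_s < 0)[1]
    abort(sprintf("Line %d: field 'onset_s' is negative.", bad + 1L))
  }
  out <- lapply(unique(raw$transcript_id), function(id) {
    df <- raw[raw$transcript_id == id, ]
    df <- df[order(df$position), ]
    flg <- strsplit(ifelse(is.na(df$flags) | df$flags == "", "", df$flags), ";", fixed = TRUE)
    dur <- if ("duration_s" %in% names(df) && !is.na(df$duration_s[1])) df$duration_s[1] else 60
    src <- if ("source" %in% names(df) && !is.na(df$source[1])) df$source[1] else "manual"
    vf_tokens(df$surface,
      transcript_id = id, task = df$task[1], cue = df$cue[1],
      duration_s = dur, source = src,
      onset_s = df$onset_s, flags = flg
    )
  })
  preserve_tokens_class(dplyr::bind_rows(out))
}
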