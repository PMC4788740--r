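#' Read a message corpus from delimited text or JSON lines
#'
#' Messages need an `id` and a `text` field; `timestamp` and `author`
#' are kept when present. Records missing `id` or `text` (or unparseable
#' JSON lines) are dropped with a warning and counted in the
#' `n_malformed` attribute; if more than half the records are malformed
#' the read aborts.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or
#'   `"jsonl"` (one JSON object per line).
#' @return A tibble of messages with attribute `n_malformed`.
#' @export
read_corpus <- function(path, format = c("auto", "csv", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tsv = "tsv", jsonl = "jsonl", ndjson = "jsonl",
      abort(paste0("Cannot infer corpus format from extension: ", path))
    )
  }
  n_malformed <- 0L
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      warn("Empty corpus file.")
      return(structure(
        tibble(id = character(), text = character()), n_malformed = 0L
      ))
    }
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    bad_json <- vapply(recs, is.null, logical(1))
    n_malformed <- sum(bad_json)
    out <- dplyr::bind_rows(lapply(recs[!bad_json], function(r) {
      as_tibble(r[lengths(r) == 1L])
    }))
  } else {
    out <- if (format == "csv") {
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    } else {
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    }
  }
  if (nrow(out) == 0L) {
    warn("Empty corpus file.")
    return(structure(
      tibble(id = character(), text = character()),
      n_malformed = n_malformed
    ))
  }
  if (!all(c("id", "text") %in% names(out))) {
    abort("Corpus must carry `id` and `text` fields.")
  }
  out$id <- as.character(out$id)
  ok <- !is.na(out$id) & nzchar(out$id) & !is.na(out$text) & nzchar(out$text)
  n_malformed <- n_malformed + sum(!ok)
  if (n_malformed > 0L) {
    warn(sprintf("Dropped %d malformed record(s).", n_malformed))
    out <- out[ok, , drop = FALSE]
  }
  if (n_malformed > nrow(out)) {
    abort(sprintf(
      "More than half of the records are malformed (%d bad vs %d good); refusing to continue.",
      n_malformed, nrow(out)
    ))
  }
  if ("timestamp" %in% names(out) && !inherits(out$timestamp, "POSIXct")) {
    out$timestamp <- readr::parse_datetime(as.character(out$timestamp))
  }
  structure(as_tibble(out), n_malformed = n_malformed)
}

#' Write a message corpus
#'
#' Round-trips with [read_corpus()]: all fields are preserved.
#'
#' @param corpus A message tibble.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path,
                         format = c("auto", "csv", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      csv = "csv", tsv = "tsv", jsonl = "jsonl", ndjson = "jsonl",
      abort(paste0("Cannot infer corpus format from extension: ", path))
    )
  }
  corpus <- as_tibble(corpus)
  if ("timestamp" %in% names(corpus) &&
      inherits(corpus$timestamp, "POSIXct")) {
    corpus$timestamp <- format(corpus$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC")
  }
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      jsonlite::toJSON(as.list(corpus[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path)
  } else if (format == "csv") {
    readr::write_csv(corpus, path, progress = FALSE)
  } else {
    readr::write_tsv(corpus, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a search-filter definition from YAML
#'
#' Expected structure:
#' ```yaml
#' keywords:
#'   - {term: vape, category: device, mode: word}
#'   - {term: "@blucigs", category: brand, mode: handle}
#' rule: 'vape OR e-cig'        # optional
#' exclusions:                  # optional
#'   - [atomizer, perfume]
#' ```
#'
#' @param path Path to the YAML definition.
#' @return A [search_filter()].
#' @export
read_filter <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$keywords) || length(cfg$keywords) == 0L) {
    abort("Filter definition needs a non-empty `keywords` block.")
  }
  kw <- dplyr::bind_rows(lapply(cfg$keywords, function(k) {
    tibble(
      term = k$term %||% abort("Each keyword needs a `term`."),
      category = k$category %||% "general",
      mode = k$mode %||% "word"
    )
  }))
  search_filter(
    filter_keywords(kw$term, kw$category, kw$mode),
    rule = cfg$rule,
    exclusions = cfg$exclusions
  )
}

#' Read beta priors from a configuration list or YAML file
#'
#' Each named entry is either explicit shapes
#' `{alpha: 4, beta: 2}` or an elicitation target
#' `{mean: 0.667, interval: [0.34, 0.954], kind: equal_tail}` resolved
#' via [elicit_beta()]. The resolved shapes are what every report
#' echoes.
#'
#' @param x A named list, or a path to a YAML file whose top level (or
#'   `priors:` block) is one.
#' @return Named list of [beta_prior()] objects.
#' @export
read_priors <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(paste0("No such file: ", x))
    x <- yaml::read_yaml(x)
    if (!is.null(x$priors)) x <- x$priors
  }
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("`x` must be a named list of prior specifications.")
  }
  lapply(x, function(spec) {
    if (!is.null(spec$alpha)) {
      beta_prior(spec$alpha, spec$beta)
    } else if (!is.null(spec$mean)) {
      elicit_beta(
        spec$mean, unlist(spec$interval),
        interval_kind = spec$kind %||% "equal_tail"
      )
    } else {
      abort("Each prior needs either {alpha, beta} or {mean, interval}.")
    }
  })
}
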