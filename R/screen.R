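#' Screen candidate keywords by frequency and precision
#'
#' During filter development each candidate keyword is kept or discarded
#' by two rules: discard when it matches fewer than `freq_threshold`
#' messages per calendar month (too rare to matter), or when the coded
#' precision among its matches falls below `precision_threshold` (it
#' mostly returns irrelevant content; the customary cut discards
#' keywords whose matches are irrelevant more than 70% of the time).
#' Without coded labels the precision rule cannot fire and precision is
#' reported as `NA`.
#'
#' @param corpus A data frame with `id`, `text` and, for monthly
#'   frequencies, a `timestamp` column (POSIXct or parseable character);
#'   without timestamps the corpus is treated as spanning one month.
#' @param keywords A keyword tibble from [filter_keywords()], or a
#'   [search_filter()] whose keywords are screened.
#' @param coded_labels Optional per-message relevance: a data frame with
#'   `id` and logical `relevant`.
#' @param freq_threshold Minimum matches per month, default 10.
#' @param precision_threshold Minimum coded precision, default 0.30.
#' @return A tibble with one row per keyword: `term`, `category`,
#'   `n_matches`, `months`, `freq_per_month`, `n_coded`, `precision`,
#'   `keep`, `reason`.
#' @export
screen_keywords <- function(corpus, keywords, coded_labels = NULL,
                            freq_threshold = 10,
                            precision_threshold = 0.30) {
  if (inherits(keywords, "search_filter")) keywords <- keywords$keywords
  if (!is.data.frame(keywords) || !all(c("term", "mode") %in% names(keywords))) {
    abort("`keywords` must come from `filter_keywords()` or a search_filter.")
  }
  if (!is.data.frame(corpus) || !all(c("id", "text") %in% names(corpus))) {
    abort("`corpus` must be a data frame with `id` and `text` columns.")
  }
  corpus <- as_tibble(corpus)

  months <- 1
  if ("timestamp" %in% names(corpus)) {
    ts <- corpus$timestamp
    if (!inherits(ts, "POSIXct")) {
      ts <- readr::parse_datetime(as.character(ts))
    }
    ts <- ts[!is.na(ts)]
    if (length(ts) > 0L) {
      months <- length(unique(format(ts, "%Y-%m")))
    }
  }

  relevant <- NULL
  if (!is.null(coded_labels)) {
    if (!is.data.frame(coded_labels) ||
        !all(c("id", "relevant") %in% names(coded_labels))) {
      abort("`coded_labels` must be a data frame with `id` and `relevant`.")
    }
    relevant <- setNames(as.logical(coded_labels$relevant),
                         as.character(coded_labels$id))
  }

  text_lc <- tolower(corpus$text)
  purrr::map_dfr(seq_len(nrow(keywords)), function(i) {
    rex <- keyword_regex(keywords$term[[i]], keywords$mode[[i]])
    hit <- grepl(rex, text_lc, perl = TRUE)
    n_matches <- sum(hit)
    freq <- n_matches / months
    prec <- NA_real_
    n_coded <- 0L
    if (!is.null(relevant)) {
      coded <- relevant[as.character(corpus$id[hit])]
      coded <- coded[!is.na(coded)]
      n_coded <- length(coded)
      if (n_coded > 0L) prec <- mean(coded)
    }
    low_freq <- freq < freq_threshold
    low_prec <- !is.na(prec) && prec < precision_threshold
    tibble(
      term = keywords$term[[i]],
      category = if ("category" %in% names(keywords))
        keywords$category[[i]] else NA_character_,
      n_matches = n_matches,
      months = months,
      freq_per_month = freq,
      n_coded = n_coded,
      precision = prec,
      keep = !(low_freq || low_prec),
      reason = dplyr::case_when(
        low_freq && low_prec ~ "frequency+precision",
        low_freq ~ "frequency",
        low_prec ~ "precision",
        .default = ""
      )
    )
  })
}
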