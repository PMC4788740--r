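#' Assemble an assessment report following the reporting checklist
#'
#' Collects everything a methods section needs to describe a
#' social-media data collection: the data source, how the search filter
#' was developed, the assumptions made about human coding, the sampling
#' frame and per-stratum sample sizes, and the precision/recall
#' estimates with their intervals. Bayesian assessments must carry the
#' resolved priors (echoed as beta shapes) so a reader can reproduce the
#' run; omitting them is a validation error.
#'
#' @param estimates A tibble of estimates: from [assess_classical()], or
#'   [summarize_posterior()] / [tidy()] on a Gibbs fit.
#' @param mode `"classical"`, `"unarchived"`, or `"latent_class"`.
#' @param data_source Named list: `site`, `time_frame`, `access`,
#'   `suitability` (free text).
#' @param filter_development Named list: `keyword_generation`,
#'   `keyword_refinement`, `keywords` (a [search_filter()] or
#'   descriptive text).
#' @param coding_assumptions Free-text description of what is assumed
#'   about human coding (gold, silver, or imperfect classifier).
#' @param sampling Optional [stratified_design()] describing the coding
#'   sample.
#' @param priors Named list of [beta_prior()] objects; required for the
#'   Bayesian modes.
#' @param seed Seed used for any randomness in the assessment.
#' @return An object of class `assessment_report`.
#' @export
assessment_report <- function(estimates, mode = c("classical", "unarchived",
                                                  "latent_class"),
                              data_source = list(),
                              filter_development = list(),
                              coding_assumptions = "",
                              sampling = NULL, priors = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.data.frame(estimates) || nrow(estimates) == 0L) {
    abort("`estimates` must be a non-empty data frame.")
  }
  if (mode != "classical") {
    if (is.null(priors) || length(priors) == 0L) {
      abort("Bayesian assessment reports must include the resolved priors.")
    }
    check_priors(priors, names(priors))
  }
  if (!is.null(sampling) && !inherits(sampling, "stratified_design")) {
    abort("`sampling` must be a `stratified_design`.")
  }
  report <- list(
    mode = mode,
    data_source = data_source,
    filter_development = filter_development,
    coding_assumptions = coding_assumptions,
    sampling = sampling,
    priors = priors,
    estimates = as_tibble(estimates),
    seed = seed
  )
  report$config_hash <- rlang::hash(report[setdiff(names(report),
                                                   "config_hash")])
  structure(report, class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("<assessment_report> mode: %s  hash: %s\n", x$mode,
              substr(x$config_hash, 1, 12)))
  print(x$estimates)
  invisible(x)
}

format_estimates_md <- function(est) {
  cols <- intersect(
    c("term", "metric", "prior_mean", "prior_low", "prior_high",
      "estimate", "conf.low", "conf.high", "level", "method"),
    names(est)
  )
  est <- est[, cols, drop = FALSE]
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "-", sprintf("%.4f", v))
    else ifelse(is.na(v), "-", as.character(v))
  }
  body <- do.call(cbind, lapply(est, fmt))
  header <- paste0("| ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|")
  rows <- apply(body, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Write an assessment report to machine- and human-readable files
#'
#' Emits `<stem>.json` (the full report, machine-readable) and/or
#' `<stem>.md` (a markdown document with every checklist section: data
#' source, search-filter development, coding assumptions, sampling frame
#' and sizes, and the estimates table). Content is deterministic given
#' the report, so identical configurations and seeds produce
#' byte-identical files.
#'
#' @param report An [assessment_report()].
#' @param stem Output path without extension.
#' @param formats Any of `"json"`, `"md"`.
#' @return Character vector of files written, invisibly.
#' @export
emit_report <- function(report, stem, formats = c("json", "md")) {
  if (!inherits(report, "assessment_report")) {
    abort("`report` must come from `assessment_report()`.")
  }
  formats <- match.arg(formats, several.ok = TRUE)
  dir <- dirname(stem)
  if (!dir.exists(dir)) {
    abort(paste0("Output directory does not exist: ", dir))
  }
  written <- character()

  if ("json" %in% formats) {
    path <- paste0(stem, ".json")
    payload <- list(
      mode = report$mode,
      config_hash = report$config_hash,
      seed = report$seed,
      data_source = report$data_source,
      filter_development = lapply(report$filter_development, function(x) {
        if (inherits(x, "search_filter")) {
          list(keywords = as.data.frame(x$keywords), rule = x$rule,
               exclusions = x$exclusions)
        } else x
      }),
      coding_assumptions = report$coding_assumptions,
      sampling = if (!is.null(report$sampling)) {
        unclass(report$sampling)
      },
      priors = if (!is.null(report$priors)) {
        lapply(report$priors, function(p) list(alpha = p$alpha, beta = p$beta))
      },
      estimates = as.data.frame(report$estimates)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    written <- c(written, path)
  }

  if ("md" %in% formats) {
    path <- paste0(stem, ".md")
    ds <- report$data_source
    fd <- report$filter_development
    kw_lines <- if (inherits(fd$keywords, "search_filter")) {
      f <- fd$keywords
      c(
        paste0("Keywords (", nrow(f$keywords), "): ",
               paste(sprintf("%s [%s/%s]", f$keywords$term,
                             f$keywords$category, f$keywords$mode),
                     collapse = ", ")),
        if (!is.null(f$rule)) paste0("Rule: `", f$rule, "`"),
        if (!is.null(f$exclusions)) paste0(
          "Exclusions: ",
          paste(vapply(f$exclusions, paste, character(1),
                       collapse = " AND "), collapse = "; ")
        )
      )
    } else {
      as.character(fd$keywords %||% "not specified")
    }
    lines <- c(
      "# Search-filter assessment report",
      "",
      paste0("Mode: ", report$mode,
             " | seed: ", report$seed %||% "none",
             " | config hash: ", report$config_hash),
      "",
      "## 1. Data source",
      paste0("- Site: ", ds$site %||% "not specified"),
      paste0("- Time frame: ", ds$time_frame %||% "not specified"),
      paste0("- Access method: ", ds$access %||% "not specified"),
      paste0("- Suitability and limitations: ",
             ds$suitability %||% "not specified"),
      "",
      "## 2. Development of search filter",
      paste0("- Candidate keyword generation: ",
             fd$keyword_generation %||% "not specified"),
      paste0("- Keyword refinement: ",
             fd$keyword_refinement %||% "not specified"),
      paste0("- ", kw_lines),
      "",
      "## 3. Assessment of search filter",
      paste0("- Assumptions about human coding: ",
             if (nzchar(report$coding_assumptions))
               report$coding_assumptions else "not specified"),
      if (!is.null(report$sampling)) {
        s <- report$sampling
        sprintf(
          "- Sampling frame and sizes: stratified by retrieval status; retrieved %d coded of %d, unretrieved %d coded of %d.",
          s$retrieved_sampled, s$retrieved_population,
          s$unretrieved_sampled, s$unretrieved_population
        )
      } else {
        "- Sampling frame and sizes: not specified"
      },
      if (!is.null(report$priors)) {
        c("- Resolved priors:",
          vapply(names(report$priors), function(nm) {
            p <- report$priors[[nm]]
            sprintf("    - %s: Beta(%.4g, %.4g)", nm, p$alpha, p$beta)
          }, character(1)))
      },
      "- Retrieval precision and recall estimates:",
      "",
      format_estimates_md(report$estimates),
      ""
    )
    writeLines(unlist(lines), path)
    written <- c(written, path)
  }
  invisible(written)
}
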