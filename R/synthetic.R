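#' Built-in vocabulary for synthetic corpora
#'
#' A deliberately simple vocabulary for generating test corpora:
#' `relevant` terms that mark topic-relevant messages (vaping-flavoured,
#' mirroring the e-cigarette case study), `decoys` that contain
#' look-alike strings in irrelevant senses (the "smoking hot" problem
#' that gives naive term filters false positives), and neutral
#' `background` words.
#'
#' @return A named list with character vectors `relevant`, `decoys`,
#'   `background`.
#' @export
default_vocabulary <- function() {
  list(
    relevant = c("vape", "vaping", "e-cig", "ecig", "e-juice", "atomizer",
                 "cartomizer", "vape pen", "mod kit", "nicotine juice"),
    decoys = c("smoking hot", "smoking ribs", "smoked brisket",
               "chain smoking jokes", "atomizer perfume"),
    background = c("coffee", "monday", "weather", "traffic", "lunch",
                   "movie", "music", "game", "work", "weekend", "news",
                   "friends", "morning", "sleep", "rain")
  )
}

#' Generate a labeled synthetic message corpus
#'
#' Builds a corpus with known ground truth for end-to-end testing of
#' filters and estimators. Each message is relevant with probability
#' `prevalence`; relevant texts embed one or two `relevant` vocabulary
#' terms among background words, and a fraction `decoy_fraction` of
#' irrelevant texts embed a decoy phrase so that term filters exhibit
#' realistic false positives. Text generation is bag-of-terms on
#' purpose: the statistical structure (prevalence, plantable error
#' rates), not linguistic realism, is the contract.
#'
#' @param n_messages Number of messages.
#' @param prevalence Probability a message is topic-relevant.
#' @param vocabulary List with `relevant`, `decoys`, `background`
#'   character vectors; see [default_vocabulary()].
#' @param decoy_fraction Fraction of irrelevant messages carrying a
#'   decoy phrase.
#' @param start_time Corpus start, POSIXct; messages get timestamps
#'   uniform over `span_days` days from here.
#' @param span_days Corpus time span in days.
#' @param seed Optional integer seed; the corpus is deterministic given
#'   the seed.
#' @return A tibble with `id`, `timestamp`, `text`, `author`, and the
#'   ground-truth logical `relevant`.
#' @examples
#' corpus <- generate_labeled_corpus(100, prevalence = 0.2, seed = 1)
#' mean(corpus$relevant)
#' @export
generate_labeled_corpus <- function(n_messages, prevalence,
                                    vocabulary = default_vocabulary(),
                                    decoy_fraction = 0.05,
                                    start_time = as.POSIXct(
                                      "2015-01-01", tz = "UTC"),
                                    span_days = 31, seed = NULL) {
  if (!is_count(n_messages) || n_messages <= 0) {
    abort("`n_messages` must be a positive count.")
  }
  check_proportion(prevalence, "prevalence")
  check_proportion(decoy_fraction, "decoy_fraction")
  for (part in c("relevant", "decoys", "background")) {
    if (length(vocabulary[[part]]) == 0L) {
      abort(paste0("`vocabulary$", part, "` must be non-empty."))
    }
  }

  with_seed(seed, {
    relevant <- runif(n_messages) < prevalence
    n_rel <- sum(relevant)
    n_irr <- n_messages - n_rel
    bg <- function(n, k = 3L) {
      if (n == 0L) return(character())
      words <- matrix(
        sample(vocabulary$background, n * k, replace = TRUE), nrow = n
      )
      do.call(paste, as.data.frame(words))
    }
    text <- character(n_messages)
    if (n_rel > 0L) {
      terms <- sample(vocabulary$relevant, n_rel, replace = TRUE)
      text[relevant] <- paste(bg(n_rel, 2L), terms, bg(n_rel, 1L))
    }
    if (n_irr > 0L) {
      irr_text <- bg(n_irr, 4L)
      decoy <- runif(n_irr) < decoy_fraction
      if (any(decoy)) {
        irr_text[decoy] <- paste(
          bg(sum(decoy), 2L),
          sample(vocabulary$decoys, sum(decoy), replace = TRUE)
        )
      }
      text[!relevant] <- irr_text
    }
    tibble(
      id = sprintf("msg%07d", seq_len(n_messages)),
      timestamp = start_time +
        runif(n_messages, 0, span_days * 86400),
      text = text,
      author = sprintf("user%05d", sample.int(
        max(10L, round(n_messages / 5)), n_messages, replace = TRUE)),
      relevant = relevant
    )
  })
}

#' Simulate filter and coder outcomes with planted error rates
#'
#' Given ground-truth relevance labels, draws a filter flag and a human
#' coder label for each message from conditionally independent Bernoulli
#' mechanisms: relevant messages are flagged with probability
#' `filter_recall` and coded relevant with probability `coder_recall`;
#' irrelevant messages are flagged with probability
#' `1 - filter_specificity` and coded relevant with probability
#' `1 - coder_specificity`. This bypasses the text deliberately so
#' estimator tests control the error rates exactly; route the corpus
#' through [apply_filter()] instead for integration tests.
#'
#' @param truth A logical vector of ground-truth relevance, or a corpus
#'   tibble with a `relevant` column (e.g. from
#'   [generate_labeled_corpus()]).
#' @param filter_recall,filter_specificity Filter error mechanism (S1,
#'   C1).
#' @param coder_recall,coder_specificity Coder error mechanism (S2, C2).
#' @param seed Optional integer seed.
#' @return If `truth` is a data frame, the tibble with added logical
#'   columns `filter_flag` and `coder_label`; otherwise a tibble with
#'   `relevant`, `filter_flag`, `coder_label`.
#' @seealso [outcome_table()] to cross-tabulate the result.
#' @export
simulate_outcomes <- function(truth, filter_recall, filter_specificity,
                              coder_recall, coder_specificity,
                              seed = NULL) {
  corpus <- NULL
  if (is.data.frame(truth)) {
    if (!"relevant" %in% names(truth)) {
      abort("`truth` data frame needs a logical `relevant` column.")
    }
    corpus <- as_tibble(truth)
    truth <- corpus$relevant
  }
  truth <- as.logical(truth)
  if (length(truth) == 0L || anyNA(truth)) {
    abort("`truth` must be non-empty with no missing values.")
  }
  check_proportion(filter_recall, "filter_recall")
  check_proportion(filter_specificity, "filter_specificity")
  check_proportion(coder_recall, "coder_recall")
  check_proportion(coder_specificity, "coder_specificity")

  n <- length(truth)
  res <- with_seed(seed, {
    p_flag <- ifelse(truth, filter_recall, 1 - filter_specificity)
    p_code <- ifelse(truth, coder_recall, 1 - coder_specificity)
    list(
      filter_flag = runif(n) < p_flag,
      coder_label = runif(n) < p_code
    )
  })
  if (!is.null(corpus)) {
    return(dplyr::mutate(corpus, filter_flag = res$filter_flag,
                         coder_label = res$coder_label))
  }
  tibble(relevant = truth, filter_flag = res$filter_flag,
         coder_label = res$coder_label)
}

#' Cross-tabulate simulated or observed outcomes into a confusion table
#'
#' Builds the observed filter-by-coding table: `a` flagged and coded
#' relevant, `b` flagged and coded irrelevant, `c` unflagged and coded
#' relevant, `d` unflagged and coded irrelevant.
#'
#' @param outcomes A data frame with logical `filter_flag` (or
#'   `retrieved`) and `coder_label` columns.
#' @return A [confusion_table()].
#' @export
outcome_table <- function(outcomes) {
  if (!is.data.frame(outcomes)) abort("`outcomes` must be a data frame.")
  flag_col <- intersect(c("filter_flag", "retrieved"), names(outcomes))[1]
  if (is.na(flag_col) || !"coder_label" %in% names(outcomes)) {
    abort("`outcomes` needs `filter_flag` (or `retrieved`) and `coder_label`.")
  }
  flag <- as.logical(outcomes[[flag_col]])
  code <- as.logical(outcomes$coder_label)
  confusion_table(
    a = sum(flag & code), b = sum(flag & !code),
    c = sum(!flag & code), d = sum(!flag & !code)
  )
}
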