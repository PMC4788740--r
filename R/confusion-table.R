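#' Cross-tabulation of a search filter against coded relevance
#'
#' A `confusion_table` holds the four counts of the filter-by-coding
#' cross-tabulation used throughout filter assessment: `a` retrieved and
#' coded relevant (true positives), `b` retrieved and coded irrelevant
#' (false positives), `c` unretrieved and coded relevant (false
#' negatives), and `d` unretrieved and coded irrelevant (true negatives).
#' Margins `n1 = a + b` (retrieved), `n2 = c + d` (unretrieved) and
#' `n = n1 + n2` are derived.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return An object of class `confusion_table`.
#' @examples
#' ct <- confusion_table(a = 128, b = 6, c = 20, d = 6285)
#' precision(ct)
#' recall_direct(ct)
#' @export
confusion_table <- function(a, b, c, d) {
  for (nm in c("a", "b", "c", "d")) {
    v <- get(nm)
    if (!is_count(v)) {
      abort(paste0("`", nm, "` must be a single non-negative integer count."))
    }
  }
  counts <- c(a = round(a), b = round(b), c = round(c), d = round(d))
  # an all-zero table is allowed (the no-data limit of the Bayesian
  # models); every classical metric on it raises an undefined-metric error
  structure(
    list(
      a = counts[["a"]], b = counts[["b"]],
      c = counts[["c"]], d = counts[["d"]]
    ),
    class = "confusion_table"
  )
}

#' Coerce counts to a confusion table
#'
#' Accepts a `confusion_table`, a data frame whose first row carries
#' columns `a`, `b`, `c`, `d`, or a named vector/list with those names.
#'
#' @param x Object to coerce.
#' @return A `confusion_table`.
#' @export
as_confusion_table <- function(x) {
  if (inherits(x, "confusion_table")) {
    return(x)
  }
  if (is.data.frame(x)) {
    if (!all(c("a", "b", "c", "d") %in% names(x)) || nrow(x) < 1L) {
      abort("Data frame input needs columns `a`, `b`, `c`, `d` and one row.")
    }
    return(confusion_table(x$a[1L], x$b[1L], x$c[1L], x$d[1L]))
  }
  x <- as.list(x)
  if (!all(c("a", "b", "c", "d") %in% names(x))) {
    abort("Input must carry named counts `a`, `b`, `c`, `d`.")
  }
  confusion_table(x$a, x$b, x$c, x$d)
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(
    c(x$a, x$b, x$a + x$b, x$c, x$d, x$c + x$d,
      x$a + x$c, x$b + x$d, x$a + x$b + x$c + x$d),
    nrow = 3, byrow = TRUE,
    dimnames = list(
      c("retrieved", "unretrieved", "total"),
      c("coded relevant", "coded irrelevant", "total")
    )
  )
  cat("<confusion_table>\n")
  print(m)
  invisible(x)
}

#' @export
#' @method as_tibble confusion_table
as_tibble.confusion_table <- function(x, ...) {
  tibble(a = x$a, b = x$b, c = x$c, d = x$d,
         n1 = x$a + x$b, n2 = x$c + x$d, n = x$a + x$b + x$c + x$d)
}

undefined_metric <- function(metric, denom) {
  abort(
    paste0("`", metric, "` is undefined: denominator ", denom, " is zero."),
    class = "retrievalqc_undefined_metric"
  )
}

#' Retrieval precision, recall, specificity, and NPV
#'
#' Exact (non-Bayesian) retrieval-quality statistics from a coded
#' cross-tabulation. Precision is the proportion of retrieved messages
#' coded relevant, `a / (a + b)` (the positive predictive value of the
#' filter). Recall is the proportion of relevant messages retrieved,
#' `a / (a + c)` (filter sensitivity). Specificity is the proportion of
#' irrelevant messages discarded, `d / (b + d)`, and NPV the proportion
#' of unretrieved messages coded irrelevant, `d / (c + d)`. Note
#' `1 - npv()` is the proportion of unretrieved messages that are
#' relevant, the `p_rel_unretr` input of [recall_bayes()].
#'
#' @param x A [confusion_table()] or anything [as_confusion_table()]
#'   accepts.
#' @return A single proportion in `[0, 1]`.
#' @seealso [recall_bayes()] for the Bayes-theorem recall that does not
#'   need the full table, [f_score()] to combine precision and recall.
#' @export
precision <- function(x) {
  x <- as_confusion_table(x)
  if (x$a + x$b == 0) undefined_metric("precision", "a + b")
  x$a / (x$a + x$b)
}

#' @rdname precision
#' @export
recall_direct <- function(x) {
  x <- as_confusion_table(x)
  if (x$a + x$c == 0) undefined_metric("recall", "a + c")
  x$a / (x$a + x$c)
}

#' @rdname precision
#' @export
specificity <- function(x) {
  x <- as_confusion_table(x)
  if (x$b + x$d == 0) undefined_metric("specificity", "b + d")
  x$d / (x$b + x$d)
}

#' @rdname precision
#' @export
npv <- function(x) {
  x <- as_confusion_table(x)
  if (x$c + x$d == 0) undefined_metric("npv", "c + d")
  x$d / (x$c + x$d)
}

#' F-score combining precision and recall
#'
#' `F = (1 + beta^2) P R / (beta^2 P + R)`. `beta = 1` gives the F1
#' score; `beta > 1` weights recall more heavily. When both precision
#' and recall are zero the limit value 0 is returned.
#'
#' @param precision,recall Proportions in `[0, 1]`.
#' @param beta Positive weight on recall relative to precision.
#' @return The F-score, a proportion.
#' @examples
#' f_score(0.955, 0.8637) # F1
#' @export
f_score <- function(precision, recall, beta = 1) {
  check_proportion(precision, "precision")
  check_proportion(recall, "recall")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    abort("`beta` must be a single non-negative number.")
  }
  den <- beta^2 * precision + recall
  if (den == 0) {
    return(0)
  }
  (1 + beta^2) * precision * recall / den
}

#' Retrieval recall via Bayes' theorem
#'
#' Computes recall without the full cross-tabulation, from the retrieval
#' precision, the proportion of the archive retrieved `P(retr)`, and the
#' proportion of unretrieved messages found relevant
#' `P(relevant | unretr)`:
#' `recall = P * P(retr) / [P * P(retr) + P(relevant|unretr) * (1 - P(retr))]`.
#' On an internally consistent table this reduces algebraically to
#' `a / (a + c)`.
#'
#' @param precision Retrieval precision of the retrieved stratum.
#' @param p_retr Proportion of the archive retrieved by the filter.
#' @param p_rel_unretr Proportion of unretrieved messages that are
#'   relevant (`1 - npv`).
#' @return Recall as a proportion.
#' @examples
#' recall_bayes(0.955, 0.0208, 0.0032)
#' @export
recall_bayes <- function(precision, p_retr, p_rel_unretr) {
  check_proportion(precision, "precision")
  check_proportion(p_retr, "p_retr")
  check_proportion(p_rel_unretr, "p_rel_unretr")
  num <- precision * p_retr
  den <- num + p_rel_unretr * (1 - p_retr)
  if (den == 0) undefined_metric("recall", "precision*P(retr) + P(rel|unretr)*(1-P(retr))")
  num / den
}

#' Stratified coding-sample design
#'
#' Records how many messages were sampled for coding from each retrieval
#' stratum and how large the strata are in the archive. Used to adjust
#' coded counts for disproportionate sampling and to propagate sampling
#' variance into recall intervals.
#'
#' @param retrieved_sampled,unretrieved_sampled Messages coded per stratum.
#' @param retrieved_population,unretrieved_population Stratum sizes in the
#'   archive.
#' @return An object of class `stratified_design`.
#' @export
stratified_design <- function(retrieved_sampled, unretrieved_sampled,
                              retrieved_population, unretrieved_population) {
  vals <- list(
    retrieved_sampled = retrieved_sampled,
    unretrieved_sampled = unretrieved_sampled,
    retrieved_population = retrieved_population,
    unretrieved_population = unretrieved_population
  )
  for (nm in names(vals)) {
    if (!is_count(vals[[nm]])) {
      abort(paste0("`", nm, "` must be a single non-negative integer count."))
    }
  }
  if (retrieved_sampled > retrieved_population ||
      unretrieved_sampled > unretrieved_population) {
    abort("Sampled counts cannot exceed the stratum population.")
  }
  if (retrieved_sampled <= 0 || unretrieved_sampled <= 0) {
    abort("Both strata need a positive coded sample.")
  }
  structure(lapply(vals, round), class = "stratified_design")
}

#' @export
print.stratified_design <- function(x, ...) {
  cat(
    "<stratified_design>\n",
    sprintf("  retrieved:   %d coded of %d (fraction %.5f)\n",
            x$retrieved_sampled, x$retrieved_population,
            x$retrieved_sampled / x$retrieved_population),
    sprintf("  unretrieved: %d coded of %d (fraction %.5f)\n",
            x$unretrieved_sampled, x$unretrieved_population,
            x$unretrieved_sampled / x$unretrieved_population),
    sep = ""
  )
  invisible(x)
}

#' Adjust coded counts for disproportionate stratified sampling
#'
#' With retrieval-status strata sampled at different fractions, the raw
#' coded counts overstate the retrieved stratum. This rescales the
#' retrieved-stratum counts by the ratio of the unretrieved to the
#' retrieved sampling fraction (round-half-to-even per cell), leaves the
#' unretrieved stratum untouched, and recomputes margins from the cells,
#' so that recall read directly off the adjusted table agrees with the
#' Bayes-theorem computation.
#'
#' @param retrieved Length-2 vector `c(a, b)`: coded-relevant and
#'   coded-irrelevant counts in the retrieved coded sample.
#' @param unretrieved Length-2 vector `c(c, d)` for the unretrieved coded
#'   sample.
#' @param design A [stratified_design()].
#' @return A [confusion_table()] on the unretrieved-stratum sampling scale.
#' @examples
#' design <- stratified_design(4373, 6305, 82205, 3872370)
#' adjust_for_sampling(c(4176, 197), c(20, 6285), design)
#' @export
adjust_for_sampling <- function(retrieved, unretrieved, design) {
  if (!inherits(design, "stratified_design")) {
    abort("`design` must be a `stratified_design`.")
  }
  if (length(retrieved) != 2L || length(unretrieved) != 2L) {
    abort("`retrieved` and `unretrieved` must each hold two counts.")
  }
  f_retr <- design$retrieved_sampled / design$retrieved_population
  f_unretr <- design$unretrieved_sampled / design$unretrieved_population
  if (f_retr <= 0 || f_unretr <= 0) {
    abort("Sampling fractions must be positive.")
  }
  ratio <- f_unretr / f_retr
  confusion_table(
    a = round(retrieved[[1L]] * ratio),
    b = round(retrieved[[2L]] * ratio),
    c = unretrieved[[1L]],
    d = unretrieved[[2L]]
  )
}

#' Precision corrected for a silver-standard coder
#'
#' When human coding has perfect specificity but imperfect recall `S2`
#' (a "silver standard" that misses some relevant messages but never
#' invents them), the naive precision `a / (a + b)` underestimates the
#' filter's precision. The bias-corrected value is `a / (S2 * (a + b))`.
#' Inconsistent inputs can push the corrected value above 1; it is then
#' clamped to 1 with a warning.
#'
#' @inheritParams precision
#' @param coder_recall Recall of the human coding, in `(0, 1]`.
#' @return Corrected precision in `[0, 1]`.
#' @export
corrected_precision <- function(x, coder_recall) {
  x <- as_confusion_table(x)
  if (!is.numeric(coder_recall) || length(coder_recall) != 1L ||
      is.na(coder_recall) || coder_recall <= 0 || coder_recall > 1) {
    abort("`coder_recall` must be a single value in (0, 1].")
  }
  if (x$a + x$b == 0) undefined_metric("precision", "a + b")
  value <- x$a / (coder_recall * (x$a + x$b))
  if (value > 1) {
    warn(sprintf(
      "Corrected precision %.4f exceeds 1 (inconsistent coder_recall for this table); clamping to 1.",
      value
    ))
    value <- 1
  }
  value
}
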