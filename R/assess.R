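#' Classical assessment of a search filter from coded samples
#'
#' The full gold-standard workflow on one table: adjusts the coded counts
#' for disproportionate stratified sampling when a design is supplied,
#' then reports precision, recall (direct on the adjusted table and via
#' Bayes' theorem), specificity, NPV, `P(relevant | unretr)` and the
#' F-score, each with a confidence interval where one is defined.
#'
#' @param x Coded counts: a data frame with columns `a`, `b`, `c`, `d`
#'   (sampling scale), or a [confusion_table()].
#' @param design Optional [stratified_design()]. When supplied, counts
#'   are assumed to be raw coded counts and are adjusted with
#'   [adjust_for_sampling()]; `P(retr)` is taken from the design
#'   populations. Without a design the table is treated as a simple
#'   random sample (`P(retr) = n1 / n`).
#' @param level Confidence level for intervals.
#' @param beta F-score weight, default 1 (F1).
#' @param ci_method Interval method for simple proportions, see
#'   [proportion_ci()].
#' @param n_boot,seed Bootstrap settings passed to [recall_bayes_ci()].
#' @return A tibble with one row per metric: `metric`, `estimate`,
#'   `conf.low`, `conf.high` (NA where no interval is defined), `level`,
#'   `method`.
#' @examples
#' design <- stratified_design(4373, 6305, 82205, 3872370)
#' counts <- data.frame(a = 4176, b = 197, c = 20, d = 6285)
#' assess_classical(counts, design, seed = 1)
#' @export
assess_classical <- function(x, design = NULL, level = 0.95, beta = 1,
                             ci_method = "wald", n_boot = 2000,
                             seed = NULL) {
  raw <- as_confusion_table(x)
  if (!is.null(design)) {
    adjusted <- adjust_for_sampling(
      c(raw$a, raw$b), c(raw$c, raw$d), design
    )
    p_retr <- design$retrieved_population /
      (design$retrieved_population + design$unretrieved_population)
  } else {
    adjusted <- raw
    p_retr <- (raw$a + raw$b) / (raw$a + raw$b + raw$c + raw$d)
  }

  prec <- proportion_ci(raw$a, raw$a + raw$b, level, ci_method)
  pru <- proportion_ci(raw$c, raw$c + raw$d, level, ci_method)
  spec <- specificity(adjusted)
  npv_val <- npv(adjusted)
  rec_direct <- recall_direct(adjusted)
  rec_bayes <- recall_bayes(prec$estimate, p_retr, pru$estimate)
  rec_ci <- if (!is.null(design)) {
    recall_bayes_ci(raw, design, level = level, n_boot = n_boot, seed = seed)
  } else {
    tibble(conf.low = NA_real_, conf.high = NA_real_, method = NA_character_)
  }
  f <- f_score(prec$estimate, rec_bayes, beta = beta)

  tibble(
    metric = c("precision", "recall_direct", "recall_bayes", "specificity",
               "npv", "p_rel_unretr", "f_score"),
    estimate = c(prec$estimate, rec_direct, rec_bayes, spec, npv_val,
                 pru$estimate, f),
    conf.low = c(prec$conf.low, NA, rec_ci$conf.low, NA, NA, pru$conf.low, NA),
    conf.high = c(prec$conf.high, NA, rec_ci$conf.high, NA, NA,
                  pru$conf.high, NA),
    level = level,
    method = c(prec$method, NA, rec_ci$method, NA, NA, pru$method, NA)
  )
}
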