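#' Confidence interval for a binomial proportion
#'
#' Two-sided interval for `successes / trials`. The default Wald interval
#' (normal approximation) is what the published assessments print for
#' retrieval precision; Wilson score and exact Clopper-Pearson intervals
#' are available. At boundary counts (0 or all successes) the Wald
#' interval degenerates, so the exact interval is substituted with a
#' warning.
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials > 0`.
#' @param level Confidence level, default 0.95.
#' @param method One of `"wald"`, `"wilson"`, `"exact"`.
#' @return A one-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `level`, `method`.
#' @examples
#' proportion_ci(4176, 4373)
#' @export
proportion_ci <- function(successes, trials, level = 0.95,
                          method = c("wald", "wilson", "exact")) {
  method <- match.arg(method)
  if (!is_count(successes) || !is_count(trials) || trials <= 0 ||
      successes > trials) {
    abort("Need integer counts with 0 <= successes <= trials and trials > 0.")
  }
  check_proportion(level, "level")
  p <- successes / trials
  if (method == "wald" && (successes == 0 || successes == trials)) {
    warn("Wald interval degenerates at boundary counts; using the exact (Clopper-Pearson) interval instead.")
    method <- "exact"
  }
  z <- qnorm(1 - (1 - level) / 2)
  ci <- switch(method,
    wald = {
      half <- z * sqrt(p * (1 - p) / trials)
      c(max(0, p - half), min(1, p + half))
    },
    wilson = {
      centre <- (p + z^2 / (2 * trials)) / (1 + z^2 / trials)
      half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) /
        (1 + z^2 / trials)
      c(max(0, centre - half), min(1, centre + half))
    },
    exact = {
      alpha <- 1 - level
      lo <- if (successes == 0) 0 else
        qbeta(alpha / 2, successes, trials - successes + 1)
      hi <- if (successes == trials) 1 else
        qbeta(1 - alpha / 2, successes + 1, trials - successes)
      c(lo, hi)
    }
  )
  tibble(
    estimate = p, conf.low = ci[[1L]], conf.high = ci[[2L]],
    level = level, method = method
  )
}

#' Interval for Bayes-theorem recall with propagated sampling variance
#'
#' The recall of [recall_bayes()] depends on two estimated proportions:
#' the precision of the retrieved coded sample and the relevant fraction
#' of the unretrieved coded sample. This propagates both sampling
#' variances by a seeded parametric bootstrap: the coded-relevant counts
#' of each stratum are resampled binomially at their observed rates, the
#' Bayes-theorem recall recomputed, and equal-tailed quantiles taken. A
#' first-order delta-method interval is available as a cross-check.
#' `P(retr)` is taken from the archive-level stratum sizes in `design`
#' and treated as known (the filter is run on the full archive, so it
#' carries no coding-sampling variance). When both strata were coded in
#' full there is no sampling variance and a zero-width interval at the
#' direct recall is returned.
#'
#' @param x A [confusion_table()] of coded counts (sampling scale, i.e.
#'   unadjusted), or anything [as_confusion_table()] accepts.
#' @param design A [stratified_design()] matching the coded sample.
#' @param level Confidence level.
#' @param n_boot Bootstrap replicates.
#' @param seed Optional integer seed for the bootstrap.
#' @param method `"bootstrap"` (default) or `"delta"`.
#' @return One-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `level`, `method`, `n_boot`.
#' @examples
#' ct <- confusion_table(4176, 197, 20, 6285)
#' design <- stratified_design(4373, 6305, 82205, 3872370)
#' recall_bayes_ci(ct, design, seed = 1)
#' @export
recall_bayes_ci <- function(x, design, level = 0.95, n_boot = 2000,
                            seed = NULL,
                            method = c("bootstrap", "delta")) {
  method <- match.arg(method)
  x <- as_confusion_table(x)
  if (!inherits(design, "stratified_design")) {
    abort("`design` must be a `stratified_design`.")
  }
  n1s <- x$a + x$b
  n2s <- x$c + x$d
  if (n1s != design$retrieved_sampled || n2s != design$unretrieved_sampled) {
    abort("Coded counts do not match the design's per-stratum sample sizes.")
  }
  check_proportion(level, "level")
  p_retr <- design$retrieved_population /
    (design$retrieved_population + design$unretrieved_population)
  prec_hat <- x$a / n1s
  pru_hat <- x$c / n2s
  est <- recall_bayes(prec_hat, p_retr, pru_hat)

  census <- design$retrieved_sampled == design$retrieved_population &&
    design$unretrieved_sampled == design$unretrieved_population
  if (census) {
    return(tibble(
      estimate = est, conf.low = est, conf.high = est,
      level = level, method = "census", n_boot = 0L
    ))
  }

  if (method == "delta") {
    # recall = f(P, u) with u = P(rel|unretr); first-order propagation
    r <- est
    g_p <- r * (1 - r) / prec_hat
    g_u <- if (pru_hat > 0) -r * (1 - r) / pru_hat else
      -r^2 * (1 - p_retr) / (prec_hat * p_retr) # limit form at u = 0
    v <- g_p^2 * prec_hat * (1 - prec_hat) / n1s +
      g_u^2 * pru_hat * (1 - pru_hat) / n2s
    z <- qnorm(1 - (1 - level) / 2)
    return(tibble(
      estimate = est,
      conf.low = max(0, est - z * sqrt(v)),
      conf.high = min(1, est + z * sqrt(v)),
      level = level, method = "delta", n_boot = 0L
    ))
  }

  if (!is_count(n_boot) || n_boot < 2) {
    abort("`n_boot` must be an integer >= 2.")
  }
  draws <- with_seed(seed, {
    a_star <- rbinom(n_boot, n1s, prec_hat)
    c_star <- rbinom(n_boot, n2s, pru_hat)
    p_star <- a_star / n1s
    u_star <- c_star / n2s
    num <- p_star * p_retr
    num / (num + u_star * (1 - p_retr))
  })
  qs <- quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, na.rm = TRUE)
  tibble(
    estimate = est, conf.low = qs[[1L]], conf.high = qs[[2L]],
    level = level, method = "bootstrap", n_boot = as.integer(n_boot)
  )
}
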