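#' Scenario for planning stratified coding samples
#'
#' Describes an assumed archive and filter for sample-size planning:
#' archive size `N`, assumed retrieval precision, recall and retrieved
#' proportion, a fixed coded-sample size for the retrieved stratum, and
#' a grid of candidate unretrieved coded-sample sizes `k`. Prevalence is
#' derived from (precision, recall, p_retr) so the scenario is always
#' internally consistent:
#' `pi = precision * p_retr / recall`, and the relevant fraction of the
#' unretrieved stratum follows as `(pi - precision * p_retr) / (1 - p_retr)`.
#'
#' @param population_total Archive size `N`.
#' @param precision,recall,p_retr Assumed filter characteristics.
#' @param retrieved_sample_size Coded sample fixed for the retrieved
#'   stratum.
#' @param unretrieved_sample_sizes Increasing grid of candidate `k`.
#' @param replicates Simulation replicates per grid point.
#' @param n_boot Bootstrap replicates inside each simulated interval.
#' @param seed Optional integer seed.
#' @return An object of class `design_scenario`.
#' @examples
#' design_scenario(4e6, precision = 0.95, recall = 0.84)
#' @export
design_scenario <- function(population_total = 4e6, precision = 0.95,
                            recall = 0.84, p_retr = 0.0208,
                            retrieved_sample_size = 3000,
                            unretrieved_sample_sizes =
                              c(1000, 2000, 4000, 6000, 10000, 20000),
                            replicates = 200, n_boot = 200, seed = NULL) {
  check_proportion(precision, "precision")
  check_proportion(recall, "recall")
  check_proportion(p_retr, "p_retr")
  if (!is_count(population_total) || population_total <= 0) {
    abort("`population_total` must be a positive count.")
  }
  if (!is_count(retrieved_sample_size) || retrieved_sample_size <= 0) {
    abort("`retrieved_sample_size` must be a positive count.")
  }
  if (recall <= 0) abort("`recall` must be positive to imply a prevalence.")
  ks <- sort(unique(round(unretrieved_sample_sizes)))
  if (length(ks) < 1L || any(ks <= 0)) {
    abort("`unretrieved_sample_sizes` must be positive counts.")
  }

  prevalence <- precision * p_retr / recall
  p_rel_unretr <- (prevalence - precision * p_retr) / (1 - p_retr)
  cells <- c(
    a = precision * p_retr,
    b = (1 - precision) * p_retr,
    c = p_rel_unretr * (1 - p_retr),
    d = (1 - p_rel_unretr) * (1 - p_retr)
  )
  if (any(cells < 0) || any(cells > 1) || prevalence > 1) {
    bad <- names(cells)[which(cells < 0 | cells > 1)][1L]
    abort(sprintf(
      "Infeasible scenario: implied population cell `%s` falls outside [0, 1].",
      bad %||% "prevalence"
    ))
  }
  n_unretr_pop <- round(population_total * (1 - p_retr))
  if (any(ks > n_unretr_pop)) {
    abort("Unretrieved sample sizes exceed the implied unretrieved population.")
  }
  if (retrieved_sample_size > round(population_total * p_retr)) {
    abort("`retrieved_sample_size` exceeds the implied retrieved population.")
  }

  structure(
    list(
      population_total = population_total,
      precision = precision, recall = recall, p_retr = p_retr,
      prevalence = prevalence, p_rel_unretr = p_rel_unretr,
      retrieved_sample_size = retrieved_sample_size,
      unretrieved_sample_sizes = ks,
      replicates = replicates, n_boot = n_boot, seed = seed
    ),
    class = "design_scenario"
  )
}

#' @export
print.design_scenario <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<design_scenario> N = %s, precision %.3f, recall %.3f, P(retr) %.4f\n",
      "  implied prevalence %.5f, P(relevant|unretr) %.5f\n",
      "  retrieved sample %d; k grid: %s; %d replicates\n"
    ),
    format(x$population_total, big.mark = ","), x$precision, x$recall,
    x$p_retr, x$prevalence, x$p_rel_unretr, x$retrieved_sample_size,
    paste(x$unretrieved_sample_sizes, collapse = ", "), x$replicates
  ))
  invisible(x)
}

# draw a stratum's relevant count: binomial for effectively infinite
# strata, hypergeometric once the sample is a nontrivial share
draw_relevant <- function(n_rep, sample_size, rate, population) {
  if (sample_size / population > 0.02) {
    successes <- round(population * rate)
    rhyper(n_rep, successes, population - successes, sample_size)
  } else {
    rbinom(n_rep, sample_size, rate)
  }
}

#' Simulate recall confidence-interval width against coding budget
#'
#' For each candidate unretrieved sample size `k`, repeatedly draws
#' stratified coded samples from the scenario's implied population,
#' estimates recall via [recall_bayes()] with a parametric-bootstrap
#' interval (the same machinery as [recall_bayes_ci()]), and averages
#' the interval limits. The mean interval length shrinks as `k` grows,
#' with diminishing gains: the plot of this table is the standard aid
#' for choosing a coding budget.
#'
#' @param scenario A [design_scenario()].
#' @return A tibble with one row per `k`: `k`, `mean_lower`,
#'   `mean_upper`, `mean_length`, `replicates`. Classed
#'   `recall_ci_sim` for [autoplot()].
#' @examples
#' sc <- design_scenario(1e5, replicates = 20, n_boot = 50, seed = 1,
#'                       unretrieved_sample_sizes = c(500, 1000, 2000))
#' simulate_recall_ci(sc)
#' @export
simulate_recall_ci <- function(scenario) {
  if (!inherits(scenario, "design_scenario")) {
    abort("`scenario` must be a design_scenario.")
  }
  m <- scenario$retrieved_sample_size
  n_retr_pop <- round(scenario$population_total * scenario$p_retr)
  n_unretr_pop <- scenario$population_total - n_retr_pop
  p_retr <- scenario$p_retr
  reps <- scenario$replicates
  n_boot <- scenario$n_boot
  alpha <- 0.05

  res <- with_seed(scenario$seed, {
    purrr::map_dfr(scenario$unretrieved_sample_sizes, function(k) {
      a_s <- draw_relevant(reps, m, scenario$precision, n_retr_pop)
      c_s <- draw_relevant(reps, k, scenario$p_rel_unretr, n_unretr_pop)
      census <- k >= n_unretr_pop && m >= n_retr_pop
      lims <- vapply(seq_len(reps), function(r) {
        prec_hat <- a_s[[r]] / m
        pru_hat <- c_s[[r]] / k
        if (census) {
          est <- recall_bayes(prec_hat, p_retr, pru_hat)
          return(c(est, est))
        }
        p_star <- rbinom(n_boot, m, prec_hat) / m
        u_star <- rbinom(n_boot, k, pru_hat) / k
        num <- p_star * p_retr
        quantile(num / (num + u_star * (1 - p_retr)),
                 c(alpha / 2, 1 - alpha / 2), names = FALSE, na.rm = TRUE)
      }, numeric(2))
      tibble(
        k = k,
        mean_lower = mean(lims[1L, ]),
        mean_upper = mean(lims[2L, ]),
        mean_length = mean(lims[2L, ] - lims[1L, ]),
        replicates = reps
      )
    })
  })
  class(res) <- c("recall_ci_sim", class(res))
  attr(res, "scenario") <- scenario
  res
}

#' @export
autoplot.recall_ci_sim <- function(object, ...) {
  ggplot(object, aes(x = .data$k)) +
    geom_ribbon(aes(ymin = .data$mean_lower, ymax = .data$mean_upper),
                alpha = 0.25) +
    geom_line(aes(y = .data$mean_lower)) +
    geom_line(aes(y = .data$mean_upper)) +
    geom_point(aes(y = .data$mean_lower)) +
    geom_point(aes(y = .data$mean_upper)) +
    labs(
      x = "unretrieved coded sample size (k)",
      y = "average 95% CI limits for recall"
    )
}

#' Recommend per-stratum coding sample sizes
#'
#' Evaluates the scenario's grid (optionally also a grid of retrieved
#' sample sizes) and returns the smallest sizes whose simulated mean
#' recall-interval length meets the target. Deterministic given the
#' scenario seed.
#'
#' @param scenario A [design_scenario()].
#' @param target_ci_length Required mean 95% interval length for recall.
#' @param retrieved_sizes Optional increasing grid of retrieved coded
#'   sample sizes to search; defaults to the scenario's single value.
#' @return A one-row tibble: `retrieved_n`, `unretrieved_k`,
#'   `mean_length`, `feasible`. When no grid point meets the target,
#'   `feasible` is `FALSE` and the sizes are `NA` with the best
#'   achievable length reported.
#' @export
recommend_sample_sizes <- function(scenario, target_ci_length,
                                   retrieved_sizes = NULL) {
  if (!inherits(scenario, "design_scenario")) {
    abort("`scenario` must be a design_scenario.")
  }
  if (!is.numeric(target_ci_length) || length(target_ci_length) != 1L ||
      is.na(target_ci_length) || target_ci_length <= 0) {
    abort("`target_ci_length` must be a single positive number.")
  }
  retrieved_sizes <- sort(unique(round(
    retrieved_sizes %||% scenario$retrieved_sample_size
  )))
  best_len <- Inf
  for (m in retrieved_sizes) {
    sc <- scenario
    sc$retrieved_sample_size <- m
    sim <- simulate_recall_ci(sc)
    hit <- which(sim$mean_length <= target_ci_length)
    if (length(hit) > 0L) {
      i <- hit[[1L]]
      return(tibble(
        retrieved_n = m, unretrieved_k = sim$k[[i]],
        mean_length = sim$mean_length[[i]], feasible = TRUE
      ))
    }
    best_len <- min(best_len, min(sim$mean_length))
  }
  tibble(
    retrieved_n = NA_integer_, unretrieved_k = NA_integer_,
    mean_length = best_len, feasible = FALSE
  )
}
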