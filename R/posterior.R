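#' Highest posterior density interval from MCMC draws
#'
#' The shortest contiguous interval containing at least `mass` of the
#' draws, found by sliding a window of `ceiling(mass * n)` order
#' statistics over the sorted sample. For skewed posteriors this is
#' narrower than the equal-tailed interval.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param mass Probability mass, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rbeta(10000, 2, 8))
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 100L) {
    abort("`hpd_interval()` needs at least 100 draws.")
  }
  if (!is_proportion(mass) || mass <= 0 || mass >= 1) {
    abort("`mass` must lie strictly inside (0, 1).")
  }
  sorted <- sort(draws)
  n <- length(sorted)
  m <- ceiling(mass * n)
  if (m >= n) {
    return(c(lower = sorted[[1L]], upper = sorted[[n]]))
  }
  widths <- sorted[(m + 1L):n] - sorted[1L:(n - m)]
  i <- which.min(widths)
  c(lower = sorted[[i]], upper = sorted[[i + m]])
}

# container for Gibbs output -------------------------------------------------

new_posterior_draws <- function(draws, model, priors, data,
                                n_cycles, burn_in, seed) {
  structure(
    list(
      draws = draws, # tibble, one column per monitored quantity
      model = model,
      priors = priors,
      data = data,
      n_cycles = n_cycles,
      burn_in = burn_in,
      seed = seed
    ),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "<posterior_draws: %s>  %d retained cycles (%d total, %d burn-in)%s\n",
    x$model, nrow(x$draws), x$n_cycles, x$burn_in,
    if (is.null(x$seed)) "" else sprintf(", seed %d", as.integer(x$seed))
  ))
  print(summarize_posterior(x))
  invisible(x)
}

#' Summarize posterior draws in the prior/posterior table layout
#'
#' One row per monitored quantity: the prior mean and central interval
#' (where a prior was specified; derived quantities such as precision or
#' the F-score have no explicit prior), the posterior mean, and the
#' highest posterior density interval.
#'
#' @param x A `posterior_draws` object from [gibbs_unarchived()] or
#'   [gibbs_two_classifier()].
#' @param mass Credible mass for the HPD intervals.
#' @return A tibble with columns `term`, `prior_mean`, `prior_low`,
#'   `prior_high`, `estimate`, `conf.low`, `conf.high`.
#' @export
summarize_posterior <- function(x, mass = 0.95) {
  if (!inherits(x, "posterior_draws")) {
    abort("`x` must be a posterior_draws object.")
  }
  if (nrow(x$draws) == 0L) abort("No retained draws to summarise.")
  purrr::map_dfr(names(x$draws), function(nm) {
    d <- x$draws[[nm]]
    hpd <- if (length(d) >= 100L) hpd_interval(d, mass) else
      c(lower = min(d), upper = max(d))
    pr <- x$priors[[nm]]
    prow <- if (!is.null(pr)) prior_row(pr, mass) else
      c(mean = NA_real_, lower = NA_real_, upper = NA_real_)
    tibble(
      term = nm,
      prior_mean = prow[["mean"]],
      prior_low = prow[["lower"]],
      prior_high = prow[["upper"]],
      estimate = mean(d),
      conf.low = hpd[["lower"]],
      conf.high = hpd[["upper"]]
    )
  })
}

#' @rdname summarize_posterior
#' @param ... Passed on to `summarize_posterior()`.
#' @export
tidy.posterior_draws <- function(x, mass = 0.95, ...) {
  summarize_posterior(x, mass = mass)
}

#' @export
glance.posterior_draws <- function(x, ...) {
  tibble(
    model = x$model,
    n_cycles = x$n_cycles,
    burn_in = x$burn_in,
    n_retained = nrow(x$draws),
    n_parameters = ncol(x$draws),
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' Plot posterior densities or traces of a Gibbs run
#'
#' @param object A `posterior_draws` object.
#' @param type `"density"` or `"trace"`.
#' @param ... Ignored.
#' @return A ggplot object, facetted by monitored quantity.
#' @export
autoplot.posterior_draws <- function(object, type = c("density", "trace"),
                                     ...) {
  type <- match.arg(type)
  long <- tidyr::pivot_longer(
    dplyr::mutate(object$draws, .cycle = dplyr::row_number()),
    -".cycle", names_to = "term", values_to = "value"
  )
  if (type == "density") {
    ggplot(long, aes(x = .data$value)) +
      ggplot2::geom_density() +
      facet_wrap(~term, scales = "free") +
      labs(x = NULL, y = "posterior density")
  } else {
    ggplot(long, aes(x = .data$.cycle, y = .data$value)) +
      geom_line(linewidth = 0.2) +
      facet_wrap(~term, scales = "free_y") +
      labs(x = "retained cycle", y = NULL)
  }
}
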