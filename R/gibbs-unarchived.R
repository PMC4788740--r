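#' Gibbs sampler for filter quality when unretrieved messages were not archived
#'
#' Many collections keep only the messages a filter retrieved, so the
#' unretrieved cells of the cross-tabulation (`c` relevant and `d`
#' irrelevant messages among the `n2` unretrieved) are never observed.
#' Following the single-classifier latent-class model of Joseph et al.
#' adapted to retrieval assessment, prevalence `pi`, filter recall `S`
#' and filter specificity `C` get beta priors, and the missing
#' false-negative count `c` is treated as latent. Each cycle:
#'
#' 1. precision is drawn uniformly on `precision_interval` (its coded
#'    sample is summarised by a confidence interval), giving
#'    `a = round(precision * n1)` and `b = n1 - a`;
#' 2. `c ~ Binomial(n2, q)` with
#'    `q = (1 - S) pi / [(1 - S) pi + C (1 - pi)]`, the conditional
#'    probability that an unretrieved message is relevant, and
#'    `d = n2 - c`;
#' 3. conjugate updates
#'    `pi ~ Beta(a + c + alpha_pi, n - a - c + beta_pi)`,
#'    `S ~ Beta(a + alpha_S, c + beta_S)`,
#'    `C ~ Beta(d + alpha_C, b + beta_C)`;
#' 4. the cycle's precision and recall give the F1 score, and NPV is
#'    recorded as `C (1 - pi) / [C (1 - pi) + (1 - S) pi]`.
#'
#' Redrawing precision every cycle (the default) propagates its sampling
#' uncertainty into all posteriors; `precision_redraw = FALSE` draws it
#' once at initialisation instead. A degenerate `precision_interval`
#' with equal endpoints fixes precision exactly.
#'
#' @param n1 Number of retrieved messages (archive scale).
#' @param n2 Number of unretrieved messages (may be approximate).
#' @param precision_interval Length-2 vector, the 95% confidence limits
#'   of the coded-sample precision of the retrieved stratum.
#' @param priors Named list of [beta_prior()] objects: `prevalence`,
#'   `recall`, `specificity`. See [ecig_priors()].
#' @param n_cycles,burn_in Gibbs cycles to run and discard.
#' @param seed Optional integer seed (chains are bit-reproducible given
#'   the seed).
#' @param precision_redraw Draw precision each cycle (default) or once.
#' @return A `posterior_draws` object monitoring `prevalence`, `recall`,
#'   `specificity`, `precision`, `npv`, `f1`.
#' @examples
#' fit <- gibbs_unarchived(
#'   n1 = 1000, n2 = 50000, precision_interval = c(0.9, 0.96),
#'   priors = ecig_priors("unarchived"), n_cycles = 2000, burn_in = 500,
#'   seed = 1
#' )
#' tidy(fit)
#' @export
gibbs_unarchived <- function(n1, n2, precision_interval, priors,
                             n_cycles = 100000, burn_in = 10000,
                             seed = NULL, precision_redraw = TRUE) {
  if (!is_count(n1) || !is_count(n2)) {
    abort("`n1` and `n2` must be non-negative integer counts.")
  }
  if (length(precision_interval) != 2L || any(is.na(precision_interval)) ||
      any(precision_interval < 0) || any(precision_interval > 1) ||
      precision_interval[[1L]] > precision_interval[[2L]]) {
    abort("`precision_interval` must be an ordered pair inside [0, 1].")
  }
  check_priors(priors, c("prevalence", "recall", "specificity"))
  if (!is_count(n_cycles) || !is_count(burn_in) || n_cycles <= burn_in) {
    abort("`n_cycles` must exceed `burn_in`.")
  }

  a_pi <- priors$prevalence$alpha; b_pi <- priors$prevalence$beta
  a_S <- priors$recall$alpha; b_S <- priors$recall$beta
  a_C <- priors$specificity$alpha; b_C <- priors$specificity$beta
  n <- n1 + n2
  keep <- n_cycles - burn_in

  draws <- with_seed(seed, {
    pi_v <- a_pi / (a_pi + b_pi)
    S_v <- a_S / (a_S + b_S)
    C_v <- a_C / (a_C + b_C)
    prec_fixed <- runif(1, precision_interval[[1L]], precision_interval[[2L]])
    out <- matrix(NA_real_, keep, 6L)
    for (i in seq_len(n_cycles)) {
      prec <- if (precision_redraw) {
        runif(1, precision_interval[[1L]], precision_interval[[2L]])
      } else {
        prec_fixed
      }
      a <- round(prec * n1)
      b <- n1 - a
      q <- safe_odds((1 - S_v) * pi_v, C_v * (1 - pi_v))
      cc <- rbinom(1, n2, q)
      d <- n2 - cc
      pi_v <- rbeta(1, a + cc + a_pi, n - a - cc + b_pi)
      S_v <- rbeta(1, a + a_S, cc + b_S)
      C_v <- rbeta(1, d + a_C, b + b_C)
      if (i > burn_in) {
        npv_v <- safe_odds(C_v * (1 - pi_v), (1 - S_v) * pi_v)
        out[i - burn_in, ] <- c(
          pi_v, S_v, C_v, prec, npv_v, f_score(prec, S_v)
        )
      }
    }
    out
  })
  colnames(draws) <- c("prevalence", "recall", "specificity",
                       "precision", "npv", "f1")
  new_posterior_draws(
    draws = as_tibble(draws),
    model = "unarchived",
    priors = priors,
    data = list(n1 = n1, n2 = n2, precision_interval = precision_interval,
                precision_redraw = precision_redraw),
    n_cycles = n_cycles, burn_in = burn_in, seed = seed
  )
}
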