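#' Latent-class Gibbs sampler for two imperfect classifiers
#'
#' When neither the search filter nor human coding is a gold standard,
#' the observed filter-by-coding cross-tabulation `(a, b, c, d)` mixes
#' truly relevant and irrelevant messages in every cell. Under the
#' latent-class model of Joseph et al. extended to two classifiers, each
#' cell count splits into a latent number of truly relevant messages
#' `y1..y4`, and prevalence `pi`, filter recall/specificity `S1`/`C1`,
#' and coder recall/specificity `S2`/`C2` carry beta priors. Assuming
#' the two classifiers err independently given true relevance (the
#' standard identifiability assumption of this model family), every full
#' conditional is binomial or beta. Each cycle draws:
#'
#' * `y1 ~ Binomial(a, pi S1 S2 / [pi S1 S2 + (1-pi)(1-C1)(1-C2)])` and
#'   the analogous splits for `y2`, `y3`, `y4`;
#' * `pi ~ Beta(sum(y) + alpha_pi, n - sum(y) + beta_pi)`;
#' * `S1 ~ Beta(y1 + y2 + alpha_S1, y3 + y4 + beta_S1)`,
#'   `C1 ~ Beta(c + d - y3 - y4 + alpha_C1, a + b - y1 - y2 + beta_C1)`;
#' * by the symmetry of the two classifiers,
#'   `S2 ~ Beta(y1 + y3 + alpha_S2, y2 + y4 + beta_S2)`,
#'   `C2 ~ Beta(b + d - y2 - y4 + alpha_C2, a + c - y1 - y3 + beta_C2)`.
#'
#' Per cycle the derived quantities
#' `precision_j = S_j pi / [S_j pi + (1 - C_j)(1 - pi)]`,
#' `npv_j = C_j (1 - pi) / [C_j (1 - pi) + (1 - S_j) pi]` and the F1
#' score of each classifier are recorded.
#'
#' @param x A [confusion_table()] of observed (sampling-adjusted) counts,
#'   or anything [as_confusion_table()] accepts.
#' @param priors Named list of [beta_prior()] objects: `prevalence`,
#'   `recall_filter`, `specificity_filter`, `recall_coder`,
#'   `specificity_coder`. See [ecig_priors("latent_class")][ecig_priors].
#' @inheritParams gibbs_unarchived
#' @return A `posterior_draws` object monitoring the five model
#'   parameters plus `precision_filter`, `npv_filter`, `f1_filter`,
#'   `precision_coder`, `npv_coder`, `f1_coder`.
#' @examples
#' fit <- gibbs_two_classifier(
#'   confusion_table(128, 6, 20, 6285),
#'   priors = ecig_priors("latent_class"),
#'   n_cycles = 2000, burn_in = 500, seed = 1
#' )
#' tidy(fit)
#' @export
gibbs_two_classifier <- function(x, priors, n_cycles = 100000,
                                 burn_in = 10000, seed = NULL) {
  x <- as_confusion_table(x)
  check_priors(priors, c("prevalence", "recall_filter", "specificity_filter",
                         "recall_coder", "specificity_coder"))
  if (!is_count(n_cycles) || !is_count(burn_in) || n_cycles <= burn_in) {
    abort("`n_cycles` must exceed `burn_in`.")
  }
  a <- x$a; b <- x$b; cc <- x$c; d <- x$d
  n <- a + b + cc + d
  a_pi <- priors$prevalence$alpha; b_pi <- priors$prevalence$beta
  a_S1 <- priors$recall_filter$alpha; b_S1 <- priors$recall_filter$beta
  a_C1 <- priors$specificity_filter$alpha; b_C1 <- priors$specificity_filter$beta
  a_S2 <- priors$recall_coder$alpha; b_S2 <- priors$recall_coder$beta
  a_C2 <- priors$specificity_coder$alpha; b_C2 <- priors$specificity_coder$beta
  keep <- n_cycles - burn_in

  draws <- with_seed(seed, {
    pi_v <- a_pi / (a_pi + b_pi)
    S1 <- a_S1 / (a_S1 + b_S1); C1 <- a_C1 / (a_C1 + b_C1)
    S2 <- a_S2 / (a_S2 + b_S2); C2 <- a_C2 / (a_C2 + b_C2)
    out <- matrix(NA_real_, keep, 11L)
    for (i in seq_len(n_cycles)) {
      q1 <- safe_odds(pi_v * S1 * S2, (1 - pi_v) * (1 - C1) * (1 - C2))
      q2 <- safe_odds(pi_v * S1 * (1 - S2), (1 - pi_v) * (1 - C1) * C2)
      q3 <- safe_odds(pi_v * (1 - S1) * S2, (1 - pi_v) * C1 * (1 - C2))
      q4 <- safe_odds(pi_v * (1 - S1) * (1 - S2), (1 - pi_v) * C1 * C2)
      y1 <- rbinom(1, a, q1)
      y2 <- rbinom(1, b, q2)
      y3 <- rbinom(1, cc, q3)
      y4 <- rbinom(1, d, q4)
      sy <- y1 + y2 + y3 + y4
      pi_v <- rbeta(1, sy + a_pi, n - sy + b_pi)
      S1 <- rbeta(1, y1 + y2 + a_S1, y3 + y4 + b_S1)
      C1 <- rbeta(1, cc + d - y3 - y4 + a_C1, a + b - y1 - y2 + b_C1)
      S2 <- rbeta(1, y1 + y3 + a_S2, y2 + y4 + b_S2)
      C2 <- rbeta(1, b + d - y2 - y4 + a_C2, a + cc - y1 - y3 + b_C2)
      if (i > burn_in) {
        prec1 <- safe_odds(S1 * pi_v, (1 - C1) * (1 - pi_v))
        npv1 <- safe_odds(C1 * (1 - pi_v), (1 - S1) * pi_v)
        prec2 <- safe_odds(S2 * pi_v, (1 - C2) * (1 - pi_v))
        npv2 <- safe_odds(C2 * (1 - pi_v), (1 - S2) * pi_v)
        out[i - burn_in, ] <- c(
          pi_v, S1, C1, S2, C2,
          prec1, npv1, f_score(prec1, S1),
          prec2, npv2, f_score(prec2, S2)
        )
      }
    }
    out
  })
  colnames(draws) <- c(
    "prevalence", "recall_filter", "specificity_filter",
    "recall_coder", "specificity_coder",
    "precision_filter", "npv_filter", "f1_filter",
    "precision_coder", "npv_coder", "f1_coder"
  )
  new_posterior_draws(
    draws = as_tibble(draws),
    model = "latent_class",
    priors = priors,
    data = list(table = x),
    n_cycles = n_cycles, burn_in = burn_in, seed = seed
  )
}
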