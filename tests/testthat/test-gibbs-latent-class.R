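latent_priors <- list(
  prevalence = beta_prior(2, 30),
  recall_filter = beta_prior(4, 2),
  specificity_filter = beta_prior(6, 2),
  recall_coder = beta_prior(6, 2),
  specificity_coder = beta_prior(8, 2)
)

test_that("with an all-zero table every posterior equals its prior", {
  fit <- gibbs_two_classifier(confusion_table(0, 0, 0, 0), latent_priors,
                              n_cycles = 6000, burn_in = 1000, seed = 2)
  td <- tidy(fit)
  for (nm in names(latent_priors)) {
    row <- td[td$term == nm, ]
    expect_lt(abs(row$estimate - row$prior_mean), 0.02)
  }
})

test_that("tiny-table posterior means match the full enumeration oracle", {
  fit <- gibbs_two_classifier(confusion_table(8, 2, 1, 9), latent_priors,
                              n_cycles = 80000, burn_in = 8000, seed = 12)
  want <- oracle_latent_exact(8, 2, 1, 9, latent_priors)
  td <- tidy(fit)
  for (nm in names(want)) {
    expect_equal(td$estimate[td$term == nm], want[[nm]], tolerance = 0.02)
  }
})

test_that("a forced-perfect coder reduces to the gold-standard conjugate posterior", {
  # near point-mass priors for S2, C2 at 1 make the table effectively
  # fully observed: S1 | data ~ Beta(a + alpha, c + beta) in closed form
  perfect <- modifyList(latent_priors, list(
    recall_coder = beta_prior(1e6, 1),
    specificity_coder = beta_prior(1e6, 1)
  ))
  a <- 60; b <- 5; cc <- 12; d <- 923
  fit <- gibbs_two_classifier(confusion_table(a, b, cc, d), perfect,
                              n_cycles = 20000, burn_in = 4000, seed = 17)
  aS <- latent_priors$recall_filter$alpha
  bS <- latent_priors$recall_filter$beta
  closed_form <- (a + aS) / (a + cc + aS + bS)
  expect_equal(mean(fit$draws$recall_filter), closed_form, tolerance = 0.01)
  aC <- latent_priors$specificity_filter$alpha
  bC <- latent_priors$specificity_filter$beta
  expect_equal(mean(fit$draws$specificity_filter),
               (d + aC) / (d + b + aC + bC), tolerance = 0.01)
})

test_that("derived precision and NPV draws satisfy their defining identities", {
  fit <- gibbs_two_classifier(confusion_table(50, 10, 8, 500), latent_priors,
                              n_cycles = 3000, burn_in = 500, seed = 3)
  d <- fit$draws
  expect_equal(
    d$precision_filter,
    d$recall_filter * d$prevalence /
      (d$recall_filter * d$prevalence +
         (1 - d$specificity_filter) * (1 - d$prevalence)),
    tolerance = 1e-12
  )
  expect_equal(
    d$npv_coder,
    d$specificity_coder * (1 - d$prevalence) /
      (d$specificity_coder * (1 - d$prevalence) +
         (1 - d$recall_coder) * d$prevalence),
    tolerance = 1e-12
  )
  expect_true(all(as.matrix(d) >= 0 & as.matrix(d) <= 1))
})

test_that("posterior means recover generating parameters from synthetic tables", {
  truth <- c(pi = 0.02, S1 = 0.93, C1 = 0.999, S2 = 0.96, C2 = 0.998)
  for (rep in 1:3) {
    out <- simulate_outcomes(
      truth = c(rep(TRUE, round(5e5 * truth["pi"])),
                rep(FALSE, 5e5 - round(5e5 * truth["pi"]))),
      filter_recall = truth[["S1"]], filter_specificity = truth[["C1"]],
      coder_recall = truth[["S2"]], coder_specificity = truth[["C2"]],
      seed = 400 + rep
    )
    fit <- gibbs_two_classifier(outcome_table(out), latent_priors,
                                n_cycles = 8000, burn_in = 2000,
                                seed = 500 + rep)
    d <- fit$draws
    for (pair in list(c("prevalence", truth[["pi"]]),
                      c("recall_filter", truth[["S1"]]),
                      c("specificity_filter", truth[["C1"]]),
                      c("recall_coder", truth[["S2"]]),
                      c("specificity_coder", truth[["C2"]]))) {
      est <- mean(d[[pair[1]]])
      sd_post <- stats::sd(d[[pair[1]]])
      expect_lt(abs(est - as.numeric(pair[2])), 3 * sd_post + 0.01)
    }
  }
})

test_that("independent seeds agree on posterior means (initialisation robustness)", {
  ct <- confusion_table(128, 6, 20, 6285)
  f1 <- gibbs_two_classifier(ct, latent_priors, n_cycles = 15000,
                             burn_in = 3000, seed = 1)
  f2 <- gibbs_two_classifier(ct, latent_priors, n_cycles = 15000,
                             burn_in = 3000, seed = 2)
  expect_equal(mean(f1$draws$recall_filter), mean(f2$draws$recall_filter),
               tolerance = 0.02)
  expect_equal(mean(f1$draws$prevalence), mean(f2$draws$prevalence),
               tolerance = 0.005)
})
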