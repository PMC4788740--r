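unarch_priors <- list(
  prevalence = beta_prior(1.5, 40),
  recall = beta_prior(4, 2),
  specificity = beta_prior(6, 2)
)

test_that("with no data every posterior equals its prior", {
  fit <- gibbs_unarchived(0, 0, c(0.4, 0.6), unarch_priors,
                          n_cycles = 6000, burn_in = 1000, seed = 3)
  td <- tidy(fit)
  for (nm in c("prevalence", "recall", "specificity")) {
    row <- td[td$term == nm, ]
    expect_lt(abs(row$estimate - row$prior_mean), 0.02)
  }
  # precision is uniform on its interval
  expect_lt(abs(td$estimate[td$term == "precision"] - 0.5), 0.01)
})

test_that("small-instance posterior means match the exact enumeration oracle", {
  # n1 = 10, n2 = 50, precision fixed at 0.8 so a = 8 every cycle
  fit <- gibbs_unarchived(10, 50, c(0.8, 0.8), unarch_priors,
                          n_cycles = 120000, burn_in = 10000, seed = 5)
  want <- oracle_unarchived_exact(8, 10, 50, unarch_priors)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "prevalence"], want$prevalence,
               tolerance = 0.01)
  expect_equal(td$estimate[td$term == "recall"], want$recall,
               tolerance = 0.02)
  expect_equal(td$estimate[td$term == "specificity"], want$specificity,
               tolerance = 0.02)
})

test_that("near point-mass priors pin the posterior at the prior point", {
  sharp <- list(
    prevalence = beta_prior(3000, 97000),   # 0.03
    recall = beta_prior(80000, 20000),      # 0.80
    specificity = beta_prior(99500, 500)    # 0.995
  )
  fit <- gibbs_unarchived(5000, 150000, c(0.84, 0.86), sharp,
                          n_cycles = 8000, burn_in = 2000, seed = 8)
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "prevalence"] - 0.03), 0.005)
  expect_lt(abs(td$estimate[td$term == "recall"] - 0.80), 0.01)
  expect_lt(abs(td$estimate[td$term == "specificity"] - 0.995), 0.003)
})

test_that("posterior recall recovers the generating parameters", {
  # population built from known (pi, S, C); evidence as the model sees it
  pi0 <- 0.03; S0 <- 0.8; C0 <- 0.995
  n <- 2e5
  set.seed(21)
  for (rep in 1:3) {
    n_rel <- rbinom(1, n, pi0)
    a <- rbinom(1, n_rel, S0)
    b <- rbinom(1, n - n_rel, 1 - C0)
    n1 <- a + b
    # precision interval from a coded subsample of the retrieved stratum
    m <- min(n1, 2000L)
    a_coded <- rbinom(1, m, a / n1)
    pci <- suppressWarnings(proportion_ci(a_coded, m))
    fit <- gibbs_unarchived(n1, n - n1, c(pci$conf.low, pci$conf.high),
                            unarch_priors, n_cycles = 30000,
                            burn_in = 5000, seed = 100 + rep)
    dr <- fit$draws
    for (pair in list(c("prevalence", pi0), c("recall", S0),
                      c("specificity", C0))) {
      est <- mean(dr[[pair[1]]])
      sd_post <- stats::sd(dr[[pair[1]]])
      expect_lt(abs(est - as.numeric(pair[2])), 3 * sd_post + 0.02)
    }
  }
})

test_that("raising the recall prior mean does not lower the recall posterior", {
  lo <- modifyList(unarch_priors, list(recall = beta_prior(2, 4)))
  hi <- modifyList(unarch_priors, list(recall = beta_prior(8, 2)))
  f_lo <- gibbs_unarchived(200, 5000, c(0.85, 0.95), lo,
                           n_cycles = 20000, burn_in = 4000, seed = 6)
  f_hi <- gibbs_unarchived(200, 5000, c(0.85, 0.95), hi,
                           n_cycles = 20000, burn_in = 4000, seed = 6)
  expect_gte(mean(f_hi$draws$recall), mean(f_lo$draws$recall) - 0.01)
})

test_that("chains are bit-reproducible given a seed and stay in [0, 1]", {
  f1 <- gibbs_unarchived(100, 3000, c(0.8, 0.9), unarch_priors,
                         n_cycles = 2000, burn_in = 200, seed = 99)
  f2 <- gibbs_unarchived(100, 3000, c(0.8, 0.9), unarch_priors,
                         n_cycles = 2000, burn_in = 200, seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(as.matrix(f1$draws) >= 0 & as.matrix(f1$draws) <= 1))
  g <- glance(f1)
  expect_equal(g$n_retained, 1800)
  expect_equal(g$model, "unarchived")
})

test_that("sampler inputs are validated", {
  expect_error(
    gibbs_unarchived(100, 100, c(0.9, 0.8), unarch_priors),
    "ordered pair"
  )
  expect_error(
    gibbs_unarchived(100, 100, c(0.8, 0.9), unarch_priors,
                     n_cycles = 100, burn_in = 100),
    "exceed"
  )
  expect_error(
    gibbs_unarchived(100, 100, c(0.8, 0.9), list(prevalence = beta_prior(1, 1))),
    "priors"
  )
})
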