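# Independent oracles used to validate the samplers and intervals.
# These never call the implementation paths they check.

# Exact posterior means for the unarchived model at a fixed true-positive
# count `a`: the parameter integrals are analytic (beta-function ratios),
# so the posterior reduces to a weighted sum over the latent count c.
oracle_unarchived_exact <- function(a, n1, n2, priors) {
  ap <- priors$prevalence$alpha; bp <- priors$prevalence$beta
  aS <- priors$recall$alpha; bS <- priors$recall$beta
  aC <- priors$specificity$alpha; bC <- priors$specificity$beta
  b <- n1 - a
  cs <- 0:n2
  lw <- lchoose(n2, cs) +
    lbeta(a + cs + ap, n1 + n2 - a - cs + bp) +
    lbeta(a + aS, cs + bS) +
    lbeta(n2 - cs + aC, b + bC)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  list(
    prevalence = sum(w * (a + cs + ap) / (n1 + n2 + ap + bp)),
    recall = sum(w * (a + aS) / (a + cs + aS + bS)),
    specificity = sum(w * (n2 - cs + aC) / (n2 - cs + b + aC + bC)),
    p_c = w
  )
}

# Exact posterior means for the two-classifier latent-class model by full
# enumeration of the latent splits (y1, y2, y3, y4); feasible for tiny
# tables only.
oracle_latent_exact <- function(a, b, cc, d, priors) {
  ap <- priors$prevalence$alpha; bp <- priors$prevalence$beta
  aS1 <- priors$recall_filter$alpha; bS1 <- priors$recall_filter$beta
  aC1 <- priors$specificity_filter$alpha; bC1 <- priors$specificity_filter$beta
  aS2 <- priors$recall_coder$alpha; bS2 <- priors$recall_coder$beta
  aC2 <- priors$specificity_coder$alpha; bC2 <- priors$specificity_coder$beta
  n <- a + b + cc + d
  g <- expand.grid(y1 = 0:a, y2 = 0:b, y3 = 0:cc, y4 = 0:d)
  sy <- g$y1 + g$y2 + g$y3 + g$y4
  lw <- lchoose(a, g$y1) + lchoose(b, g$y2) +
    lchoose(cc, g$y3) + lchoose(d, g$y4) +
    lbeta(sy + ap, n - sy + bp) +
    lbeta(g$y1 + g$y2 + aS1, g$y3 + g$y4 + bS1) +
    lbeta(cc + d - g$y3 - g$y4 + aC1, a + b - g$y1 - g$y2 + bC1) +
    lbeta(g$y1 + g$y3 + aS2, g$y2 + g$y4 + bS2) +
    lbeta(b + d - g$y2 - g$y4 + aC2, a + cc - g$y1 - g$y3 + bC2)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  list(
    prevalence = sum(w * (sy + ap) / (n + ap + bp)),
    recall_filter = sum(w * (g$y1 + g$y2 + aS1) / (sy + aS1 + bS1)),
    specificity_filter = sum(
      w * (cc + d - g$y3 - g$y4 + aC1) / (n - sy + aC1 + bC1)
    ),
    recall_coder = sum(w * (g$y1 + g$y3 + aS2) / (sy + aS2 + bS2)),
    specificity_coder = sum(
      w * (b + d - g$y2 - g$y4 + aC2) / (n - sy + aC2 + bC2)
    )
  )
}

# HPD interval of a Beta(a, b) density by density-threshold grid search:
# lower the threshold until the region {f > t} holds the requested mass.
oracle_beta_hpd_grid <- function(alpha, beta, mass = 0.95,
                                 n_grid = 200001L) {
  x <- seq(0, 1, length.out = n_grid)
  fx <- dbeta(x, alpha, beta)
  ord <- order(fx, decreasing = TRUE)
  cum <- cumsum(fx[ord]) / sum(fx)
  inside <- ord[seq_len(which(cum >= mass)[1L])]
  c(min(x[inside]), max(x[inside]))
}

# random internally consistent confusion tables for identity properties
random_tables <- function(n, seed, max_cell = 5000L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      tb <- list(
        a = sample.int(max_cell, 1L),
        b = sample.int(max_cell, 1L) - 1L,
        c = sample.int(max_cell, 1L) - 1L,
        d = sample.int(max_cell, 1L)
      )
      if (tb$a + tb$c > 0 && tb$a + tb$b > 0) return(tb)
    }
  })
}
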