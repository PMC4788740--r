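test_that("precision, recall, specificity, NPV match hand-computed values", {
  expect_equal(precision(ecig_coded_sample()), 4176 / 4373, tolerance = 1e-12)
  expect_equal(round(precision(ecig_coded_sample()), 3), 0.955)
  expect_equal(precision(confusion_table(5, 0, 1, 1)), 1)
  expect_equal(round(precision(ecig_adjusted_table()), 4), 0.9552)

  expect_equal(round(recall_direct(ecig_adjusted_table()), 4), 0.8649)
  expect_equal(recall_direct(confusion_table(7, 3, 0, 10)), 1)
  expect_equal(recall_direct(confusion_table(0, 3, 5, 10)), 0)

  expect_equal(round(specificity(ecig_adjusted_table()), 4), 0.9990)
  expect_equal(round(npv(ecig_adjusted_table()), 4), 0.9968)
  expect_equal(round(1 - npv(ecig_adjusted_table()), 4), 0.0032)
  expect_equal(specificity(confusion_table(1, 1, 1, 0)), 0)
})

test_that("metrics raise undefined-metric errors on empty denominators", {
  expect_error(precision(confusion_table(0, 0, 5, 5)),
               class = "retrievalqc_undefined_metric")
  expect_error(recall_direct(confusion_table(0, 5, 0, 5)),
               class = "retrievalqc_undefined_metric")
  expect_error(specificity(confusion_table(5, 0, 5, 0)),
               class = "retrievalqc_undefined_metric")
  expect_error(npv(confusion_table(5, 5, 0, 0)),
               class = "retrievalqc_undefined_metric")
})

test_that("confusion_table validates and coerces inputs", {
  expect_error(confusion_table(-1, 0, 0, 1), "non-negative")
  expect_error(confusion_table(1.5, 0, 0, 1), "non-negative integer")
  ct <- as_confusion_table(data.frame(a = 1, b = 2, c = 3, d = 4))
  expect_s3_class(ct, "confusion_table")
  tb <- tibble::as_tibble(ct)
  expect_equal(tb$n1, 3)
  expect_equal(tb$n2, 7)
  expect_equal(tb$n, 10)
})

test_that("F-score matches the combining formula and its limits", {
  expect_equal(round(f_score(0.955, 0.8637), 3), 0.907)
  expect_equal(f_score(0.4, 0.4, 3), 0.4) # P = R = x for any beta
  expect_equal(f_score(0.5, 1.0, 2), 5 / 6, tolerance = 1e-12)
  expect_equal(f_score(0, 0), 0)
  expect_error(f_score(0.5, 0.5, beta = -1), "non-negative")
})

test_that("F1 is bounded by precision and recall and monotone in each", {
  set.seed(71)
  for (i in 1:200) {
    p <- runif(1); r <- runif(1)
    f <- f_score(p, r)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_gte(f + 1e-12, min(p, r))
    expect_lte(f - 1e-12, max(p, r))
    eps <- 1e-4
    if (p + eps <= 1) expect_gte(f_score(p + eps, r), f)
    if (r + eps <= 1) expect_gte(f_score(p, r + eps), f)
  }
})

test_that("Bayes-theorem recall reproduces the published value and limits", {
  expect_equal(round(recall_bayes(0.955, 0.0208, 0.0032), 4), 0.8637)
  expect_equal(recall_bayes(0.9, 0.1, 0), 1)
  expect_error(recall_bayes(0, 0.5, 0), class = "retrievalqc_undefined_metric")
})

test_that("Bayes-theorem recall on consistent summaries equals direct recall", {
  ct <- ecig_adjusted_table()
  n <- 128 + 6 + 20 + 6285
  got <- recall_bayes(
    precision = 128 / 134, p_retr = 134 / n, p_rel_unretr = 20 / 6305
  )
  expect_equal(got, 128 / 148, tolerance = 1e-12)
  expect_equal(round(got, 4), 0.8649)

  for (tb in random_tables(250, seed = 11)) {
    n <- tb$a + tb$b + tb$c + tb$d
    expect_equal(
      recall_bayes(tb$a / (tb$a + tb$b), (tb$a + tb$b) / n,
                   if (tb$c + tb$d > 0) tb$c / (tb$c + tb$d) else 0),
      tb$a / (tb$a + tb$c),
      tolerance = 1e-10
    )
  }
})

test_that("sampling-fraction adjustment reproduces the published table", {
  adj <- adjust_for_sampling(c(4176, 197), c(20, 6285), ecig_design())
  expect_equal(adj$a, 128)
  expect_equal(adj$b, 6)
  expect_equal(adj$c, 20)
  expect_equal(adj$d, 6285)
  expect_equal(adj$a + adj$b, 134)
})

test_that("adjustment is identity under equal fractions and preserves strata", {
  eq <- stratified_design(100, 200, 1000, 2000)
  adj <- adjust_for_sampling(c(60, 40), c(30, 170), eq)
  expect_equal(c(adj$a, adj$b, adj$c, adj$d), c(60, 40, 30, 170))

  # 10-message toy: retrieved 4 of 8 (f = 1/2), unretrieved 2 of 16
  # (f = 1/8); ratio 1/4 rescales (4, 0) -> (1, 0)
  toy <- stratified_design(4, 2, 8, 16)
  adj <- adjust_for_sampling(c(4, 0), c(1, 1), toy)
  expect_equal(c(adj$a, adj$b, adj$c, adj$d), c(1, 0, 1, 1))

  # unretrieved stratum verbatim; retrieved proportions kept up to rounding
  set.seed(5)
  for (i in 1:50) {
    rp <- sample(1000:100000, 1); up <- sample(10000:1000000, 1)
    rs <- sample(100:min(rp, 5000), 1); us <- sample(100:min(up, 5000), 1)
    des <- stratified_design(rs, us, rp, up)
    av <- sample.int(rs, 1) - 1L
    cv <- sample.int(us, 1) - 1L
    adj <- adjust_for_sampling(c(av, rs - av), c(cv, us - cv), des)
    expect_equal(adj$c, cv)
    expect_equal(adj$d, us - cv)
    # retrieved cells equal the rescaled counts up to half a unit
    ratio <- (us / up) / (rs / rp)
    expect_lte(abs(adj$a - av * ratio), 0.5)
    expect_lte(abs(adj$b - (rs - av) * ratio), 0.5)
  }
})

test_that("silver-standard precision correction behaves per the bias formula", {
  ct <- confusion_table(90, 10, 5, 95)
  expect_equal(corrected_precision(ct, 1), precision(ct))
  expect_equal(round(corrected_precision(ct, 0.95), 4), 0.9474)
  expect_warning(
    val <- corrected_precision(ecig_adjusted_table(), 0.90),
    "exceeds 1"
  )
  expect_equal(val, 1)
  # anti-monotone in coder recall (before the clamp)
  s2 <- seq(0.96, 1, by = 0.01)
  vals <- vapply(s2, function(s) corrected_precision(ct, s), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(corrected_precision(ct, 0), "in \\(0, 1\\]")
})
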