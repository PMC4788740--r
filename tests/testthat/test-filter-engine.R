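test_that("the ten-message fixture partitions exactly as hand-computed", {
  part <- apply_filter(fixture_corpus(), fixture_filter())
  expect_equal(part$id[part$retrieved], fixture_expected_retrieved)
  expect_equal(nrow(part), 10)
  # veto provenance on the perfume bottle message
  expect_equal(part$provenance[part$id == "m04"], "excluded")
  expect_equal(part$provenance[part$id == "m07"], "handle")
  expect_false(part$retrieved[part$id == "m04"])
})

test_that("an empty keyword set retrieves nothing", {
  f <- search_filter(filter_keywords(character()))
  part <- apply_filter(fixture_corpus(), f)
  expect_false(any(part$retrieved))
  expect_true(all(part$provenance == ""))
})

test_that("co-occurrence vetoes drop joint matches but keep single matches", {
  f <- search_filter(
    filter_keywords(c("atomizer", "perfume")),
    exclusions = list(c("atomizer", "perfume"))
  )
  corpus <- tibble::tibble(
    id = c("x1", "x2", "x3"),
    text = c("new atomizer arrived", "atomizer perfume spray bottle",
             "perfume counter at the mall")
  )
  part <- apply_filter(corpus, f)
  expect_equal(part$retrieved, c(TRUE, FALSE, TRUE))
})

test_that("handle keywords retrieve by author or mention regardless of vetoes", {
  f <- search_filter(
    filter_keywords(c("vape", "@blucigs"), mode = c("word", "handle"))
  )
  corpus <- tibble::tibble(
    id = c("h1", "h2", "h3"),
    text = c("morning all", "have you seen @blucigs today", "no topic here"),
    author = c("blucigs", "someone", "other")
  )
  part <- apply_filter(corpus, f)
  expect_equal(part$retrieved, c(TRUE, TRUE, FALSE))
  expect_equal(part$provenance[1:2], c("handle", "handle"))
})

test_that("boolean rules parse and evaluate with AND, OR, NOT and phrases", {
  kw <- filter_keywords(c("vape", "e-cig", "cigar", "vape pen"),
                        mode = c("word", "word", "word", "phrase"))
  f <- search_filter(kw, rule = '(vape OR "e-cig") AND NOT cigar')
  corpus <- tibble::tibble(
    id = as.character(1:4),
    text = c("my vape arrived", "vape and a cigar", "cigar lounge",
             "an e-cig on my desk")
  )
  part <- apply_filter(corpus, f)
  expect_equal(part$retrieved, c(TRUE, FALSE, FALSE, TRUE))

  expect_error(search_filter(kw, rule = "vape AND hookah"), "undeclared")
  expect_error(search_filter(kw, rule = "vape AND (e-cig"), "parse error")
  expect_error(search_filter(kw, rule = "AND vape"), "parse error")
})

test_that("match modes respect word boundaries, hashtags and phrases", {
  kw <- filter_keywords(c("ecig", "#vapelife", "mod kit"),
                        mode = c("word", "hashtag", "phrase"))
  f <- search_filter(kw)
  corpus <- tibble::tibble(
    id = as.character(1:6),
    text = c("my ecig broke", "theecigstore discount", "#vapelife forever",
             "living that vapelife now", "bought a mod kit", "modkit v2")
  )
  part <- apply_filter(corpus, f)
  expect_equal(part$retrieved, c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("partition is exhaustive, disjoint and deterministic", {
  part1 <- apply_filter(fixture_corpus(), fixture_filter())
  part2 <- apply_filter(fixture_corpus(), fixture_filter())
  expect_identical(part1, part2)
  expect_equal(sum(part1$retrieved) + sum(!part1$retrieved), nrow(part1))
})

test_that("malformed records are skipped and counted, never silently dropped", {
  corpus <- fixture_corpus()
  corpus$text[3] <- NA
  corpus$id[6] <- NA
  expect_warning(part <- apply_filter(corpus, fixture_filter()), "2 malformed")
  expect_equal(nrow(part), 8)
  expect_equal(attr(part, "n_malformed"), 2)
})

test_that("planted match rates are recovered within binomial bounds", {
  set.seed(77)
  n <- 100000
  hit <- runif(n) < 0.02
  corpus <- tibble::tibble(
    id = as.character(seq_len(n)),
    text = ifelse(hit, "going to vape later", "nothing to see here")
  )
  part <- apply_filter(corpus, search_filter(filter_keywords("vape")))
  p_hat <- mean(part$retrieved)
  bound <- qnorm(0.995) * sqrt(0.02 * 0.98 / n)
  expect_lt(abs(p_hat - mean(hit)), 1e-12) # filter finds exactly the plants
  expect_lt(abs(p_hat - 0.02), bound + 1e-3)
})

test_that("adding an include keyword never shrinks the retrieved set", {
  corpus <- generate_labeled_corpus(400, 0.3, seed = 15)
  base_terms <- c("vape", "e-cig")
  f0 <- search_filter(filter_keywords(base_terms))
  r0 <- apply_filter(corpus, f0)$retrieved
  for (extra in c("atomizer", "vaping", "coffee")) {
    f1 <- search_filter(filter_keywords(c(base_terms, extra)))
    r1 <- apply_filter(corpus, f1)$retrieved
    expect_true(all(r1[r0]))
  }
})
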