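# Ordinal core: Bandt-Pompe patterns, ranking, entropy, missing patterns.

test_that("single-window patterns follow the ascending-index convention", {
  expect_identical(ordinal_pattern(c(3, 6, 8)), c(1L, 2L, 3L))
  expect_identical(ordinal_pattern(c(8, 9, 5)), c(3L, 1L, 2L))
  expect_identical(ordinal_pattern(c(9, 5, 10)), c(2L, 1L, 3L))
  # ties resolve to the earlier index (stable)
  expect_identical(ordinal_pattern(c(5, 5, 7)), c(1L, 2L, 3L))
  expect_error(ordinal_pattern(c(1, NA, 2)), "NA")
})

test_that("lexicographic ranking is bijective with ascending first", {
  expect_identical(pattern_rank(1:3), 1L)
  expect_identical(pattern_rank(3:1), 6L)
  expect_identical(pattern_rank(c(3, 1, 2)), 5L)
  expect_error(pattern_rank(c(1, 1, 2)), "permutation")
  for (m in 2:7) {
    expect_identical(pattern_rank(seq_len(m)), 1L)
    expect_identical(pattern_rank(rev(seq_len(m))), as.integer(factorial(m)))
  }
  # rank_of . unrank is the identity (full for small m, sampled for m = 7)
  for (m in 2:5)
    expect_identical(vapply(seq_len(factorial(m)),
                            function(r) pattern_rank(unrank_pattern(r, m)),
                            integer(1)),
                     seq_len(as.integer(factorial(m))))
  set.seed(11)
  for (r in sample.int(factorial(7), 50))
    expect_identical(pattern_rank(unrank_pattern(r, 7)), as.integer(r))
})

test_that("ranking agrees with explicit lexicographic enumeration", {
  for (m in 2:5) {
    P <- perms_lex(m)
    expect_identical(vapply(seq_len(nrow(P)),
                            function(i) pattern_rank(P[i, ]), integer(1)),
                     seq_len(nrow(P)))
  }
})

test_that("the seven-sample worked series symbolizes as documented", {
  x <- c(3, 6, 8, 9, 5, 10, 2)
  s <- symbolize(x, m = 3, tau = 1)
  expect_length(s, 5L)  # T - (m-1)*tau = 5 embedded vectors
  expect_identical(s, c(1L, 1L, 5L, 3L, 5L))
  d <- pattern_distribution(s, m = 3)
  expect_identical(d$counts, c(2L, 0L, 1L, 0L, 2L, 0L))
  expect_equal(d$probs[c(1, 3, 5)], c(0.4, 0.2, 0.4))
  expect_equal(sum(d$probs), 1)
  # three of the six patterns (132, 231, 321) never occur
  mp <- missing_patterns(d)
  expect_identical(mp$count, 3L)
  expect_equal(mp$normalized, 0.5)
  expect_equal(permutation_entropy(d),
               -(2 * 0.4 * log(0.4) + 0.2 * log(0.2)) / log(6))
})

test_that("monotone series yield a single pattern and zero entropy", {
  up <- symbolize(seq_len(50), m = 4)
  expect_true(all(up == 1L))
  expect_equal(permutation_entropy(pattern_distribution(up, 4)), 0)
  down <- symbolize(seq(50, 1), m = 4)
  expect_true(all(down == factorial(4)))
})

test_that("uniform coverage gives maximal entropy and no missing patterns", {
  d <- pattern_distribution(sample.int(720), m = 6)
  expect_equal(permutation_entropy(d), 1)
  expect_identical(missing_patterns(d)$count, 0L)
  one <- pattern_distribution(rep(1L, 10), m = 3)
  expect_equal(permutation_entropy(one), 0)
  expect_identical(missing_patterns(one)$count, 5L)
})

test_that("entropy of long i.i.d. noise approaches 1 and stays in [0,1]", {
  set.seed(4)
  d <- pattern_distribution(symbolize(runif(2e4), m = 3), m = 3)
  expect_gt(permutation_entropy(d), 0.99)
  for (i in 1:20) {
    x <- cumsum(rnorm(60))
    di <- pattern_distribution(symbolize(x, m = 3), m = 3)
    h <- permutation_entropy(di)
    expect_gte(h, 0)
    expect_lte(h, 1)
  }
})

test_that("PE and NMP are invariant under relabelling of patterns", {
  set.seed(9)
  ranks <- symbolize(rnorm(500), m = 3)
  d <- pattern_distribution(ranks, m = 3)
  relab <- sample.int(6)  # arbitrary bijection on pattern labels
  d2 <- pattern_distribution(relab[ranks], m = 3)
  expect_equal(permutation_entropy(d2), permutation_entropy(d))
  expect_identical(missing_patterns(d2)$count, missing_patterns(d)$count)
})

test_that("the missing-pattern count never grows as a series is extended", {
  set.seed(21)
  x <- rnorm(400)
  nmp <- vapply(seq(10, 400, by = 10), function(n) {
    missing_patterns(pattern_distribution(symbolize(x[1:n], m = 3), 3))$count
  }, integer(1))
  expect_true(all(diff(nmp) <= 0L))
})

test_that("symbolization agrees with the brute-force enumerator", {
  set.seed(33)
  for (m in 2:3) for (i in 1:25) {
    x <- sample.int(4, size = sample(m:10, 1), replace = TRUE)
    expect_identical(symbolize(x, m = m), brute_symbolize(x, m = m))
  }
  # delays > 1 as well
  x <- rnorm(40)
  expect_identical(symbolize(x, m = 3, tau = 4), brute_symbolize(x, 3, 4L))
})

test_that("invalid embeddings and short series are rejected", {
  expect_error(symbolize(1:10, m = 1), "m")
  expect_error(symbolize(1:10, m = 11), "capped")
  expect_error(symbolize(1:10, m = 3, tau = 0), "tau")
  expect_error(symbolize(1:3, m = 4), "too short")
  expect_warning(out <- symbolize(1:3, m = 4, strict = FALSE), "too short")
  expect_identical(out, integer(0))
  expect_error(pattern_distribution(integer(0), m = 3), "empty")
  expect_error(pattern_distribution(c(1L, 7L), m = 3), "1..m!")
})
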