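test_that("collector curves accumulate distinct taxa per specimen", {
  cc <- collector_curve(c("a", "a", "b", "c", "c", "a"))
  expect_equal(cc$n, 1:6)
  expect_equal(cc$S, c(1, 1, 2, 3, 3, 3))

  all_new <- collector_curve(c("x", "y", "z"))
  expect_equal(all_new$S, 1:3)

  expect_equal(nrow(collector_curve(character())), 0)

  # structural invariants on a simulated session
  s <- simulate_session(uneven_assemblage(), 500, threshold = 0.05,
                        rare_tracks = 5, specimens_per_track = 100, seed = 3)
  cc2 <- collector_curve(s)
  expect_equal(cc2$S[[1]], 1)
  expect_true(all(cc2$S <= cc2$n))
  expect_true(all(diff(cc2$S) >= 0))
  expect_equal(cc2$n, seq_len(nrow(cc2)))
})

test_that("closed-form rarefaction matches exhaustive enumeration", {
  expect_equal(expected_richness(c(3, 4, 5), 1)$expected_S, 1)
  expect_equal(expected_richness(c(5, 5), 10)$expected_S, 2)

  # oracle: enumerate all C(10, 2) = 45 two-specimen subsamples of (9, 1)
  pool <- rep(c("a", "b"), c(9, 1))
  pairs <- utils::combn(10, 2)
  enum <- mean(apply(pairs, 2, function(ix) length(unique(pool[ix]))))
  expect_equal(enum, 1.2)  # frozen enumeration value
  expect_equal(expected_richness(c(9, 1), 2)$expected_S, enum,
               tolerance = 1e-12)

  # a larger enumeration: counts (4, 3, 2, 1), n = 3
  pool2 <- rep(letters[1:4], c(4, 3, 2, 1))
  trips <- utils::combn(10, 3)
  enum2 <- mean(apply(trips, 2, function(ix) length(unique(pool2[ix]))))
  expect_equal(expected_richness(c(4, 3, 2, 1), 3)$expected_S, enum2,
               tolerance = 1e-12)

  expect_equal(expected_richness(c(9, 1), 0)$expected_S, 0)
  expect_error(expected_richness(c(9, 1), 11), "exceeds")
  # log-space evaluation stays finite at large N
  big <- expected_richness(c(9e4, 5e3, rep(10, 50)), 2e4)$expected_S
  expect_true(is.finite(big) && big > 2 && big <= 52)
})

test_that("Monte-Carlo rarefaction agrees with the closed form", {
  mc <- rarefy_mc(c(9, 1), 2, replicates = 10000, seed = 5)
  expect_lt(abs(mc$expected_S - 1.2), 3 * mc$sd / sqrt(10000))

  expect_identical(rarefy_mc(c(9, 1), 2, 100, seed = 8),
                   rarefy_mc(c(9, 1), 2, 100, seed = 8))
  expect_equal(rarefy_mc(c(2, 3, 4), 9, replicates = 1, seed = 1)$expected_S, 3)

  # property over random count vectors (<= 20 taxa, N <= 200)
  agree <- withr::with_seed(11, {
    vapply(1:50, function(i) {
      counts <- sample(1:20, sample(2:20, 1), replace = TRUE)
      counts <- counts[cumsum(counts) <= 200]
      if (length(counts) < 2) counts <- c(5, 5)
      n <- sample.int(sum(counts), 1)
      cf <- expected_richness(counts, n)$expected_S
      mc <- rarefy_mc(counts, n, replicates = 400, seed = i)
      # zero-variance draws (every subsample holds all taxa) agree up to
      # the closed form's sub-1e-3 hypergeometric remainder
      tol <- max(3 * mc$sd / sqrt(400), 1e-3)
      abs(mc$expected_S - cf) <= tol
    }, logical(1))
  })
  expect_gte(mean(agree), 0.95)
})

test_that("hyperbolic fits recover known parameters", {
  n <- c(100, 250, 500, 1000, 2000, 5000)
  curve <- tibble::tibble(n = n, S = 200 * n / (n + 500))
  fit <- fit_decaprariis(curve)
  expect_true(fit$converged)
  expect_equal(fit$S_max, 200, tolerance = 1e-3)
  expect_equal(fit$b, 500, tolerance = 1e-3)
  expect_equal(tidy(fit)$term, c("S_max", "b"))
  expect_equal(glance(fit)$S_observed, max(curve$S))

  # constant curve: asymptote is the constant, b = 0
  const <- fit_decaprariis(tibble::tibble(n = c(10, 20, 30), S = 7))
  expect_true(const$converged)
  expect_equal(const$S_max, 7)
  expect_equal(const$b, 0)

  # strictly linear (all singletons): asymptote unidentifiable
  lin <- fit_decaprariis(tibble::tibble(n = 1:50, S = 1:50))
  expect_false(lin$converged)

  expect_error(fit_decaprariis(tibble::tibble(n = 1:2, S = 1:2)), "3")

  # 5% multiplicative noise: S_max within 10% (median over 100 seeds)
  rel_err <- withr::with_seed(21, vapply(1:100, function(i) {
    noisy <- tibble::tibble(n = n, S = 200 * n / (n + 500) *
                              (1 + rnorm(length(n), 0, 0.05)))
    f <- fit_decaprariis(noisy)
    abs(f$S_max - 200) / 200
  }, numeric(1)))
  expect_lt(median(rel_err), 0.10)
})

test_that("improvement percent is zero without a rare phase and positive with one", {
  s1 <- count_session(demo_taxa())
  for (id in c("A", "B", "B")) s1 <- record_count(s1, id)
  expect_equal(improvement_percent(s1, seed = 1)$improvement_pct, 0)

  # rare mode entered but empty exclusion set: identical counting regimes
  s2 <- enter_rare_mode(s1)
  s2 <- increment_track(s2)
  expect_equal(improvement_percent(s2, seed = 1)$improvement_pct, 0)

  s <- simulate_session(uneven_assemblage(), 1000, threshold = 0.05,
                        rare_tracks = 20, specimens_per_track = 100, seed = 2)
  imp <- improvement_percent(s, replicates = 300, seed = 4)
  expect_gt(imp$improvement_pct, 0)
  expect_equal(imp$n_actual, nrow(session_events(s)))
  expect_identical(improvement_percent(s, replicates = 100, seed = 9),
                   improvement_percent(s, replicates = 100, seed = 9))
})

test_that("diversity history files round-trip", {
  cc <- collector_curve(c("a", "b", "a", "c"))
  path <- tempfile(fileext = ".tsv")
  write_diversity_history(cc, path)
  back <- read_diversity_history(path)
  expect_equal(back$n, cc$n)
  expect_equal(back$S, cc$S)
  expect_equal(back$n, seq_len(nrow(back)))

  header <- readLines(path, n = 1)
  expect_equal(header, "specimens\tcumulative_taxa")

  empty <- collector_curve(character())
  p2 <- tempfile(fileext = ".tsv")
  write_diversity_history(empty, p2)
  expect_equal(length(readLines(p2)), 1)   # header only
  expect_equal(nrow(read_diversity_history(p2)), 0)
})
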