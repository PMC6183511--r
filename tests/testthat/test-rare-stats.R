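test_that("exclusion suggestions rank by descending count and flag by share", {
  tal <- tibble::tibble(taxon_id = c("D", "B", "A", "C"),
                        n_full = c(40L, 300L, 500L, 60L))
  sug <- suggest_exclusions(tal, threshold = 0.05)
  expect_equal(sug$taxon_id, c("A", "B", "C", "D"))
  expect_equal(sug$share, c(500, 300, 60, 40) / 900)
  expect_equal(sug$excluded, c(TRUE, TRUE, TRUE, FALSE))

  expect_false(any(suggest_exclusions(tal, 1)$excluded))
  expect_equal(suggest_exclusions(tal, 0.5)$excluded,
               c(TRUE, FALSE, FALSE, FALSE))

  # ties broken by taxon_id for a stable ordering
  tie <- tibble::tibble(taxon_id = c("z", "a"), n_full = c(5L, 5L))
  expect_equal(suggest_exclusions(tie, 0.5)$taxon_id, c("a", "z"))

  expect_error(suggest_exclusions(tal, 0), "threshold")
  expect_error(suggest_exclusions(tibble::tibble(taxon_id = "A",
                                                 n_full = 0L), 0.5),
               "No full-phase")
})

test_that("combined estimates scale excluded taxa by relative rare effort", {
  s <- demo_session()  # full: A=3,B=2,C=1, T_full=2; rare: B=1,C=2, T_rare=1
  est <- combined_estimates(s)
  # A excluded: 3 * (1 + 1/2) = 4.5; B: 2+1 = 3; C: 1+2 = 3; D: 0
  expect_equal(est$estimated_count[match(c("A", "B", "C", "D"),
                                         est$taxon_id)],
               c(4.5, 3, 3, 0))
  expect_equal(est$basis[est$taxon_id == "A"], "effort_scaled")
  expect_equal(est$basis[est$taxon_id == "B"], "observed")
  expect_equal(sum(est$proportion), 1, tolerance = 1e-12)
  expect_equal(est$proportion[est$taxon_id == "A"], 4.5 / 10.5)

  # no rare phase: estimates are the raw counts (identity)
  s1 <- count_session(demo_taxa())
  for (id in c("A", "A", "B")) s1 <- record_count(s1, id)
  est1 <- combined_estimates(s1)
  expect_equal(est1$estimated_count[match(c("A", "B"), est1$taxon_id)],
               c(2, 1))
  expect_true(all(est1$basis == "observed"))

  # rare phase without full-phase effort is undefined
  s2 <- count_session(demo_taxa())
  s2 <- record_count(s2, "A")
  s2 <- enter_rare_mode(s2, "A")
  s2 <- increment_track(s2)
  expect_error(combined_estimates(s2), "effort|track")
})

test_that("epsilon follows the binomial relative standard error", {
  # p = 0.5, N = 100: sqrt(0.25/100)/0.5 = 0.10 exactly
  expect_equal(relative_error(0.5, 100)$epsilon, 0.1)

  # the cut-off rule of thumb: 5% at N = 2000 -> just under 10%
  eps <- relative_error(0.05, 2000)$epsilon
  expect_lt(eps, 0.10)
  expect_equal(eps, 0.0975, tolerance = 1e-3)

  # Monte-Carlo oracle at p = 0.05, N = 1000: sd of the estimated share,
  # relative to p, over binomial replicates
  mc <- withr::with_seed(99, {
    phat <- rbinom(2e5, 1000, 0.05) / 1000
    sd(phat) / 0.05
  })
  analytic <- relative_error(0.05, 1000)$epsilon
  expect_equal(analytic, 0.1378, tolerance = 1e-3)
  expect_equal(analytic, mc, tolerance = 0.01)

  expect_error(relative_error(0, 100), "p")
  expect_error(relative_error(1, 100), "p")
  expect_error(relative_error(0.5, 0), "N")
})

test_that("the error landscape is monotone and scales as expected", {
  land <- error_landscape(c(0.05, 0.1, 0.5), c(100, 400, 1600))
  expect_equal(nrow(land), 9)

  # single cell equals the scalar case
  expect_equal(error_landscape(0.3, 250)$epsilon,
               relative_error(0.3, 250)$epsilon)

  # 1/sqrt(N): quadrupling N halves epsilon at fixed p
  at <- function(p, N) land$epsilon[land$p == p & land$N == N]
  expect_equal(at(0.5, 400), at(0.5, 100) / 2)
  expect_equal(at(0.5, 1600), at(0.5, 100) / 4)
  # decreasing in N for every p
  for (p in unique(land$p)) {
    sub <- land[land$p == p, ]
    expect_true(all(diff(sub$epsilon[order(sub$N)]) < 0))
  }
  # linear in z
  land2 <- error_landscape(c(0.05, 0.1, 0.5), c(100, 400, 1600), z = 2)
  expect_equal(land2$epsilon, 2 * land$epsilon)
})

test_that("eliminated fraction is the excluded share of full-phase specimens", {
  tal <- tibble::tibble(taxon_id = c("A", "B", "C", "D"),
                        n_full = c(500L, 300L, 60L, 40L))
  expect_equal(eliminated_fraction(tal, character()), 0)
  expect_equal(eliminated_fraction(tal, tal$taxon_id), 1)
  expect_equal(eliminated_fraction(tal, c("A", "B", "C")), 860 / 900)
})

test_that("threshold summaries match exhaustive enumeration on known tables", {
  # two hand-constructed 3-species samples
  dataset <- tibble::tibble(
    sample = rep(c("s1", "s2"), each = 3),
    taxon_id = rep(c("x", "y", "z"), 2),
    proportion = c(0.7, 0.2, 0.1,
                   0.4, 0.35, 0.25)
  )
  out <- threshold_summary(dataset, p_grid = c(0, 0.3, 0.5, 0.8))

  # p = 0: every species in every sample is above threshold
  expect_equal(out$frac_samples[out$p == 0], 1)
  expect_equal(out$frac_species[out$p == 0], 1)
  expect_equal(out$cum_mean[out$p == 0], 1)

  # p = 0.3: s1 has x (0.7); s2 has x (0.4), y (0.35) -> both samples;
  # species above in >= 1 sample: x, y -> 2/3; cumulative: 0.7 and 0.75
  expect_equal(out$frac_samples[out$p == 0.3], 1)
  expect_equal(out$frac_species[out$p == 0.3], 2 / 3)
  expect_equal(out$cum_mean[out$p == 0.3], (0.7 + 0.75) / 2)
  expect_equal(out$cum_min[out$p == 0.3], 0.7)
  expect_equal(out$cum_max[out$p == 0.3], 0.75)

  # p = 0.5: only s1's x qualifies
  expect_equal(out$frac_samples[out$p == 0.5], 0.5)
  expect_equal(out$frac_species[out$p == 0.5], 1 / 3)
  expect_equal(out$cum_mean[out$p == 0.5], 0.35)

  # p = 0.8: nothing qualifies
  expect_equal(out$frac_samples[out$p == 0.8], 0)
  expect_equal(out$cum_max[out$p == 0.8], 0)

  # all three curves are non-increasing in p
  expect_true(all(diff(out$frac_samples) <= 0))
  expect_true(all(diff(out$frac_species) <= 0))
  expect_true(all(diff(out$cum_mean) <= 0))

  # degenerate single sample / single species: everything 1 below p = 1
  single <- tibble::tibble(sample = "s", taxon_id = "t", proportion = 1)
  one <- threshold_summary(single, c(0, 0.5, 0.99))
  expect_true(all(one$frac_samples == 1))
  expect_true(all(one$frac_species == 1))

  expect_error(threshold_summary(dplyr::mutate(dataset,
                                               proportion = proportion * 2),
                                 0.1),
               "sum to 1")
})
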