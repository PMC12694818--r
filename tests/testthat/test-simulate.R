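test_that("pedigree simulator: determinism, schema, neutral drift moments", {
  a <- simulate_pedigree(n_mothers = 8, pups_per_mother = 6, seed = 10)
  b <- simulate_pedigree(n_mothers = 8, pups_per_mother = 6, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, simulate_pedigree(n_mothers = 8,
                                              pups_per_mother = 6, seed = 11)))
  expect_equal(nrow(a), 48)
  expect_true(all(c("mother_id", "pup_id", "generation", "mother_h", "pup_h",
                    "maternal_age_months", "litter_id", "litter_size")
                  %in% names(a)))
  expect_true(all(a$pup_h >= 0 & a$pup_h <= 1))
  expect_true(all(a$litter_size >= 1))

  # neutral drift is unbiased on the frequency scale
  big <- simulate_pedigree(n_mothers = 50, pups_per_mother = 200,
                           bottleneck_n = 200,
                           generations_per_transmission = 15,
                           selection_s = 0, seed = 21)
  dev <- big$pup_h - big$mother_h
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(nrow(big)))

  # drift variance matches p(1-p)(1 - (1-1/N)^t) within 5%
  b_theory <- (1 - 1 / 200)^15
  per_mother <- split(big, big$mother_id)
  ratio <- vapply(per_mother, function(g) {
    var(g$pup_h) / (g$mother_h[1] * (1 - g$mother_h[1]) * (1 - b_theory))
  }, numeric(1))
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("selection drives the transmission slope down monotonically", {
  slopes <- vapply(c(0, -0.02, -0.05, -0.10), function(s) {
    p <- simulate_pedigree(n_mothers = 40, pups_per_mother = 25,
                           selection_s = s, seed = 33)
    fit_transmission_regression(p)$slope
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
  expect_gt(slopes[1], 0.9)  # neutral is near the unbiased line
})

test_that("follicle simulator: identity, elimination, expansion tempo", {
  ed <- simulate_follicle_timecourse(n_oocytes = 25, seed = 3)
  expect_identical(ed, simulate_follicle_timecourse(n_oocytes = 25, seed = 3))
  # total = wt + mut at every day for every oocyte, h consistent
  expect_equal(ed$h, ed$mut_copies / (ed$wt_copies + ed$mut_copies))

  # full elimination: no mutant copies from day 1 onward
  kill <- simulate_follicle_timecourse(n_oocytes = 10,
                                       elimination_rate_delta = 1, seed = 4)
  expect_true(all(kill$mut_copies[kill$day >= 1] == 0))
  expect_true(all(kill$h[kill$day >= 1] == 0))

  # unedited: h stays 0 and totals reach >= 90% of target by day 3
  un <- simulate_follicle_timecourse(n_oocytes = 25, initial_h = 0,
                                     elimination_rate_delta = 0,
                                     group = "unedited", seed = 5)
  expect_true(all(un$h == 0))
  d3 <- un[un$day == 3, ]
  expect_gte(mean(d3$wt_copies + d3$mut_copies), 0.9 * 1e5)

  # mean heteroplasmy strictly decreasing across days (mutant elimination)
  daymeans <- tapply(ed$h, ed$day, mean)
  expect_true(all(diff(daymeans) < 0))
})

test_that("generators share the master-seed stream-splitting scheme", {
  s1 <- simulate_site_counts(20, depth = 500, seed = 8)
  expect_identical(s1, simulate_site_counts(20, depth = 500, seed = 8))
  expect_false(identical(s1, simulate_site_counts(20, depth = 500, seed = 9)))
  expect_equal(s1$a_count + s1$c_count + s1$g_count + s1$t_count,
               rep(500L, 20))
  # caller RNG state is untouched
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_pedigree(n_mothers = 3, pups_per_mother = 2, seed = 1))
  expect_identical(runif(1), before)
})
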