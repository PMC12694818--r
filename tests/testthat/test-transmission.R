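test_that("regression recovers perfect transmission and rejects degenerate input", {
  h0 <- seq(0.05, 0.5, length.out = 20)
  # lm warns about the essentially perfect fit on exact data; that is fine
  fit <- suppressWarnings(fit_transmission_regression(make_pairs(h0, h0)))
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  fo <- suppressWarnings(
    fit_transmission_regression(make_pairs(h0, h0), through_origin = TRUE))
  expect_true(fo$through_origin)
  expect_true(is.na(fo$intercept))
  expect_equal(fo$slope, 1)

  expect_error(fit_transmission_regression(make_pairs(0.3, rep(0.2, 5))),
               "singular")
  expect_error(fit_transmission_regression(make_pairs(0.3, 0.2)), "at least 3")
})

test_that("regression recovers a known slope with nominal CI coverage (scaled)", {
  cover <- 0
  for (r in 1:30) {
    set.seed(700 + r)
    h0 <- runif(200, 0.05, 0.6)
    pup <- pmin(pmax(0.8 * h0 + rnorm(200, 0, 0.03), 0), 1)
    fit <- fit_transmission_regression(make_pairs(h0, pup))
    cover <- cover + (fit$slope_ci95[1] <= 0.8 && 0.8 <= fit$slope_ci95[2])
  }
  expect_gte(cover, 26)
})

test_that("mean_shift_test gates on normality and flags degenerate data", {
  d <- make_pairs(0.3, rep(0.3, 10))
  res <- mean_shift_test(d)
  expect_equal(res$mean_log_shift, 0)
  expect_match(res$test_used, "zero variance")

  set.seed(12)
  L <- rnorm(200, -0.4, 0.5)
  d2 <- make_pairs(0.3, plogis(qlogis(0.3) + L))
  res2 <- mean_shift_test(d2)
  expect_equal(res2$test_used, "one-sample t-test")
  expect_lt(res2$p_value, 0.01)
  expect_lt(res2$mean_log_shift, 0)
  expect_equal(res2$mean_log_shift, mean(L), tolerance = 1e-10)

  # heavy-tailed shifts fail the gate -> Wilcoxon
  L3 <- rt(300, df = 1) * 0.5
  d3 <- make_pairs(0.3, plogis(qlogis(0.3) + L3))
  expect_equal(mean_shift_test(d3)$test_used, "Wilcoxon signed-rank")

  expect_error(mean_shift_test(make_pairs(0.3, c(0, 1, 0, 1))),
               "insufficient")
})

test_that("mean_shift_test detects purifying selection and keeps type-I error (scaled)", {
  hits <- 0
  for (r in 1:15) {
    p <- simulate_pedigree(n_mothers = 10, pups_per_mother = 20,
                           selection_s = -0.05, seed = 800 + r)
    res <- mean_shift_test(p)
    hits <- hits + (res$mean_log_shift < 0 && res$p_value <= 0.05)
  }
  expect_gte(hits, 13)

  rej <- 0
  for (r in 1:40) {
    p <- simulate_pedigree(n_mothers = 10, pups_per_mother = 20,
                           selection_s = 0, seed = 900 + r)
    rej <- rej + (mean_shift_test(p)$p_value <= 0.05)
  }
  # nominal 0.05; scaled-down band (40 runs) around the [0.01, 0.10] target
  expect_lte(rej, 6)
})

test_that("stage summary: trivial identity, ordering, invariances", {
  stages <- c("primary", "early_secondary", "late_secondary")
  rec <- data.frame(mouse_id = "m", mother_h = 0.3,
                    stage = rep(stages, each = 6), h = 0.3)
  res <- stage_shift_summary(rec, seed = 4)
  expect_equal(res$summary$mean_shift, rep(1, 3))
  expect_true(all(res$pairwise$p_value == 1))
  expect_equal(res$summary$stage, stages)  # canonical stage order

  set.seed(31)
  rec2 <- data.frame(mouse_id = "m", mother_h = 0.3,
                     stage = sample(rep(stages, each = 20)),
                     h = runif(60, 0.1, 0.5))
  a <- stage_shift_summary(rec2, seed = 4)
  b <- stage_shift_summary(rec2[sample(nrow(rec2)), ], seed = 4)
  expect_equal(a$summary$mean_shift, b$summary$mean_shift)
  # duplicating the data keeps means, shrinks bootstrap CIs
  dup <- stage_shift_summary(rbind(rec2, rec2), seed = 4)
  expect_equal(dup$summary$mean_shift, a$summary$mean_shift)
  expect_true(all(dup$summary$ci95_upper - dup$summary$ci95_lower <
                    a$summary$ci95_upper - a$summary$ci95_lower))
  # Holm adjustment never decreases a p-value
  expect_true(all(a$pairwise$p_holm >= a$pairwise$p_value))
  expect_error(stage_shift_summary(transform(rec, stage = "blastocyst")),
               "unknown stage")
})

test_that("age_effect finds injected trends and not null ones", {
  sim_age <- function(slope, seed) {
    simulate_pedigree(n_mothers = 25, pups_per_mother = 12,
                      age_slope = slope, seed = seed)
  }
  null_small <- 0
  for (r in 1:10) {
    res <- age_effect(sim_age(0, 1000 + r))
    null_small <- null_small + (abs(res$pearson_r) < 0.25)
  }
  expect_gte(null_small, 8)

  trend_hits <- 0
  for (r in 1:10) {
    res <- age_effect(sim_age(-0.06, 1100 + r))
    trend_hits <- trend_hits + (res$pearson_r < 0 && res$p_value <= 0.05)
  }
  expect_gte(trend_hits, 8)

  one <- make_pairs(0.3, c(0.2, 0.25, 0.3))
  one$maternal_age_months <- 3
  one$litter_id <- c("L1", "L2", "L3")
  expect_error(age_effect(one), "single distinct maternal age")
})

test_that("litter_size_association: null behaviour, first-litter filter, degenerate", {
  p <- simulate_pedigree(n_mothers = 44, pups_per_mother = 18, seed = 77)
  res <- litter_size_association(p)
  expect_true(abs(res$correlation) < 0.5)
  expect_equal(res$n_deliveries, length(unique(p$litter_id)))

  first <- litter_size_association(p, first_litter_only = TRUE)
  expect_equal(first$n_deliveries, 44)

  d <- make_pairs(0.3, runif(12, 0.1, 0.5))
  d$litter_id <- rep(c("a", "b", "c"), each = 4)
  d$litter_size <- 8
  expect_error(litter_size_association(d), "constant litter size")
})

test_that("tissue_cv matches hand arithmetic and is scale invariant", {
  m <- data.frame(mouse_id = "m1", tissue = c("tail", "liver"),
                  h = c(0.10, 0.12))
  res <- tissue_cv(m)
  expect_equal(res$grand_mean_cv, 100 * sd(c(0.10, 0.12)) / 0.11,
               tolerance = 1e-12)  # ~12.86%

  same <- data.frame(mouse_id = "m2", tissue = letters[1:5], h = 0.2)
  expect_equal(tissue_cv(same)$grand_mean_cv, 0)

  set.seed(5)
  two <- data.frame(mouse_id = rep(c("a", "b"), each = 6),
                    tissue = rep(letters[1:6], 2),
                    h = runif(12, 0.05, 0.3))
  base_cv <- tissue_cv(two)$per_mouse_cv$cv_percent
  two$h[two$mouse_id == "a"] <- two$h[two$mouse_id == "a"] * 3
  expect_equal(tissue_cv(two)$per_mouse_cv$cv_percent, base_cv)

  # grand mean is the arithmetic mean of per-mouse CVs
  res2 <- tissue_cv(two)
  expect_equal(res2$grand_mean_cv, mean(res2$per_mouse_cv$cv_percent))
  expect_warning(tissue_cv(rbind(two, data.frame(mouse_id = "c",
                                                 tissue = "tail", h = 0.2))),
                 "< 2 tissues")
})

test_that("copy_dynamics_summary: flat series, group comparison, skip warning", {
  rec <- data.frame(day = rep(c(0, 3, 7), each = 4),
                    group = "edited", h = 0.2,
                    wt_copies = 8000, mut_copies = 2000)
  expect_warning(res <- copy_dynamics_summary(rec), "skipped")
  expect_true(all(res$per_day$total_mean == 10000))
  expect_true(all(res$per_day$wt_sem == 0))
  expect_null(res$comparison)

  ed <- simulate_follicle_timecourse(n_oocytes = 20, seed = 1)
  un <- simulate_follicle_timecourse(n_oocytes = 20, initial_h = 0,
                                     elimination_rate_delta = 0,
                                     group = "unedited", seed = 2)
  res2 <- copy_dynamics_summary(rbind(ed, un))
  expect_false(is.null(res2$comparison))
  expect_true(res2$comparison$p_value >= 0 && res2$comparison$p_value <= 1)
  expect_true(res2$comparison$test_used %in%
                c("two-sample t-test", "Mann-Whitney U"))
  # mutant decline and wild-type compensation are visible in the day means
  edsum <- res2$per_day[res2$per_day$group == "edited", ]
  expect_true(all(diff(edsum$mut_mean) < 0))
  expect_gt(edsum$wt_mean[nrow(edsum)], edsum$wt_mean[1])
  expect_error(copy_dynamics_summary(rec[rec$day == 0, ]), "2 distinct days")
})
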