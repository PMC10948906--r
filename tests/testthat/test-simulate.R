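info1 <- example_roi_info("functional", n_roi = 1)

test_that("visit-count proportions converge to the configured mix", {
  cfg <- cohort_config(n_subjects = 5000, seed = 42)
  rec <- simulate_cohort(cfg, example_roi_models(info1, config = cfg))
  per_subj <- table(table(rec$subject_id))
  props <- as.numeric(per_subj) / 5000
  expect_true(all(abs(props - c(0.562, 0.380, 0.058)) < 0.015))
})

test_that("same config and seed gives identical cohorts", {
  cfg <- cohort_config(n_subjects = 300, seed = 9)
  models <- example_roi_models(info1, config = cfg)
  expect_identical(simulate_cohort(cfg, models),
                   simulate_cohort(cfg, models))
})

test_that("with no slope and Gaussian residuals measures are normal", {
  # oracle: residuals collapse to standard normal; aggregate the test
  # over independent seeds by pooling
  z <- unlist(lapply(1:3, function(sd_) {
    cfg <- cohort_config(n_subjects = 1400, seed = 100 + sd_)
    m <- roi_model(info1, intercept = 0, slope = 0, scale = 1,
                   epsilon = 0, delta = 1,
                   cells = batch_cell_keys(cfg))
    simulate_cohort(cfg, list(m))$func01
  }))
  expect_gt(length(z), 3 * 2000)
  expect_gt(suppressWarnings(ks.test(z, "pnorm"))$p.value, 0.01)
})

test_that("Gaussian-reduction residual moments are standard normal", {
  cfg <- cohort_config(n_subjects = 7e4, seed = 500)
  m <- roi_model(info1, intercept = 0, slope = 0, scale = 1,
                 epsilon = 0, delta = 1, cells = batch_cell_keys(cfg))
  x <- simulate_cohort(cfg, list(m))$func01
  expect_gt(length(x), 1e5 - 2e4)
  sk <- mean((x - mean(x))^3) / sd(x)^3
  ku <- mean((x - mean(x))^4) / sd(x)^4 - 3
  expect_lt(abs(sk), 0.1)
  expect_lt(abs(ku), 0.2)
})

test_that("cohort structure: scanner-wave confound and age bounds", {
  cfg <- cohort_config(n_subjects = 1000, seed = 77)
  rec <- simulate_cohort(cfg, example_roi_models(info1, config = cfg))
  expect_true(all(rec$scanner == cfg$scanner_map[rec$wave]))
  for (w in 1:3) {
    a <- rec$age[rec$wave == w]
    expect_true(all(a >= cfg$wave_age_ranges[w, 1] &
                    a <= cfg$wave_age_ranges[w, 2]))
  }
  # visits are contiguous wave patterns
  pats <- tapply(rec$wave, rec$subject_id,
                 function(w) paste(sort(w), collapse = ""))
  expect_true(all(pats %in% c("1", "2", "3", "12", "23", "123")))
  # roughly half female
  p_f <- mean(tapply(rec$sex, rec$subject_id, `[`, 1) == "female")
  expect_lt(abs(p_f - 0.506), 0.05)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohort_config(visit_count_probs = c(0.5, 0.4, 0.2)),
               "visit_count_probs")
  expect_error(cohort_config(wave_age_means = c(10, 9, 14)),
               "wave_age_means")
  expect_error(roi_model(info1, scale = -1), "scale")
  expect_error(roi_model(info1, delta = 0), "delta")
})

test_that("inject_gradient sets an arithmetic slope progression", {
  info <- example_roi_info("functional", n_roi = 10)
  models <- example_roi_models(info)
  m0 <- inject_gradient(models, base_slope = 0.2, increment = 0)
  expect_true(all(vapply(m0, function(m) all(m$slope == 0.2),
                         logical(1))))
  m1 <- inject_gradient(models, base_slope = 0.1, increment = 0.01)
  slopes <- vapply(m1, function(m) unname(m$slope[1]), numeric(1))
  expect_equal(slopes, 0.1 + 0.01 * (1:10), tolerance = 1e-12)
  dup <- models[c(1, 1)]
  expect_error(inject_gradient(dup, 0.1, 0.01), "distinct")
})

test_that("high-trait tagging flags the expected count and shifts", {
  cfg <- cohort_config(n_subjects = 2210, seed = 13)
  m <- roi_model(info1, intercept = 0, slope = 0, scale = 1,
                 epsilon = 0, delta = 1, cells = batch_cell_keys(cfg))
  rec <- simulate_cohort(cfg, list(m))
  tagged <- tag_high_trait_subgroup(rec, list(m), fraction = 0.09,
                                    volume_shift = -1, seed = 4)
  n_flag <- sum(tapply(tagged$high_trait, tagged$subject_id, `[`, 1))
  expect_lte(abs(n_flag - round(0.09 * 2210)), 2)

  # oracle: with a -1 SD shift the mass below -1.96 is
  # pnorm(-0.96) ~ 0.169, far above the null 2.5%
  z_true <- tagged$func01  # true model has mu 0, scale 1
  flag_rate <- mean(z_true[tagged$high_trait] < -1.96)
  n_fl <- sum(tagged$high_trait)
  expect_gte(n_fl, 150)
  expect_lt(binom.test(sum(z_true[tagged$high_trait] < -1.96), n_fl,
                       0.025, alternative = "greater")$p.value, 0.05)
  expect_lt(abs(flag_rate - pnorm(-0.96)), 0.06)

  # null case: zero shift leaves the flagged group indistinguishable
  null_t <- tag_high_trait_subgroup(rec, list(m), fraction = 0.09,
                                    volume_shift = 0, seed = 4)
  r_f <- mean(null_t$func01[null_t$high_trait] < -1.96)
  r_u <- mean(null_t$func01[!null_t$high_trait] < -1.96)
  expect_lt(abs(r_f - r_u), 0.02)
  expect_error(tag_high_trait_subgroup(rec, list(m), 1.2, 0), "fraction")
})
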