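info1 <- example_roi_info("functional", n_roi = 1)

test_that("log-posterior gradient matches finite differences", {
  set.seed(21)
  n <- 40; K <- 2; B <- 4
  X <- cbind(1, rnorm(n))
  cell <- sample(0:(B - 1), n, replace = TRUE)
  y <- rnorm(n)
  for (centered in c(FALSE, TRUE)) {
    dim <- 2 * K + 2 + B * K + B + 2
    theta <- rnorm(dim, 0, 0.4)
    r <- cerebnorm:::.hbr_logpost_grad(theta, y, X, cell, B, centered)
    fd <- vapply(seq_len(dim), function(j) {
      h <- 1e-6
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (cerebnorm:::.hbr_logpost_grad(tp, y, X, cell, B, centered)$logpost -
       cerebnorm:::.hbr_logpost_grad(tm, y, X, cell, B, centered)$logpost) /
        (2 * h)
    }, numeric(1))
    expect_equal(r$grad, fd, tolerance = 1e-5)
  }
})

test_that("posterior slope agrees with the OLS oracle on Gaussian data", {
  cfg <- cohort_config(n_subjects = 300, seed = 31)
  m <- roi_model(info1, intercept = 5, slope = 0.5, scale = 1,
                 epsilon = 0, delta = 1, cells = batch_cell_keys(cfg))
  rec <- simulate_cohort(cfg, list(m))
  fit <- fit_normative(rec, "func01", fast_hbr(seed = 31))
  # pooled hyper-mean slope vs closed-form OLS on the same
  # standardized data (homogeneous truth across cells)
  as_ <- (rec$age - mean(rec$age)) / sd(rec$age)
  ys <- (rec$func01 - mean(rec$func01)) / sd(rec$func01)
  ols <- ols_oracle(as_, ys)
  d <- cerebnorm:::.pooled_draws(fit)
  expect_lt(abs(mean(d[, "mu_beta_age_std"]) - ols$slope),
            3 * sd(d[, "mu_beta_age_std"]))
  # posterior epsilon/delta hover near the Gaussian reduction
  expect_lt(abs(mean(d[, "epsilon"])), 0.3)
  expect_lt(abs(mean(d[, "delta"]) - 1), 0.35)
})

test_that("known batch offsets are recovered within credible intervals", {
  cfg <- cohort_config(n_subjects = 500, seed = 37)
  cells <- batch_cell_keys(cfg)
  icpt <- setNames(c(9.5, 10.1, 10.3, 10.6), cells)
  m <- roi_model(info1, intercept = icpt, slope = 0.25, scale = 1,
                 epsilon = 0, delta = 1, cells = cells)
  rec <- simulate_cohort(cfg, list(m))
  fit <- fit_normative(rec, "func01", fast_hbr(seed = 37))
  d <- cerebnorm:::.pooled_draws(fit)
  sc <- fit$scaler
  covered <- vapply(cells, function(cl) {
    dr <- d[, paste0("alpha[", cl, "]")] * sc$scale + sc$center
    ci <- quantile(dr, c(0.025, 0.975))
    icpt[cl] >= ci[1] && icpt[cl] <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 3L)  # allow one near-miss at this n
  expect_equal(nrow(d), 2 * 450)
  expect_true(all(d[, grep("^sigma", colnames(d))] > 0))
})

test_that("fit validates inputs and warns on sparse cells", {
  cfg <- cohort_config(n_subjects = 60, seed = 3)
  rec <- simulate_cohort(cfg, example_roi_models(info1, config = cfg))
  expect_error(fit_normative(rec, "nope", fast_hbr()), "nope")
  one_cell <- rec[rec$sex == "female" & rec$scanner == "MR750w", ]
  expect_error(fit_normative(one_cell, "func01", fast_hbr()),
               "2 batch cells")
  sparse <- rbind(rec[rec$sex == "female", ],
                  head(rec[rec$sex == "male", ], 2))
  expect_warning(fit_normative(sparse, "func01",
                               hbr_config(n_chains = 2, n_samples = 60,
                                          n_tune = 30, seed = 1,
                                          keep_loglik = FALSE)),
                 "pooled")
  expect_error(hbr_config(n_chains = 1), "n_chains")
  expect_error(hbr_config(n_samples = 100, n_tune = 100), "n_tune")
})

test_that("split R-hat: identical streams pass, separated chains fail", {
  set.seed(8)
  stream <- rnorm(1000)
  expect_lt(split_rhat(cbind(stream, stream)), 1.01)
  sep <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(split_rhat(sep), 1.5)
  # direct-formula oracle agrees on well-behaved draws
  x <- matrix(rnorm(4000), 1000, 4)
  expect_equal(split_rhat(x), split_rhat_oracle(x), tolerance = 0.01)
  expect_error(split_rhat(matrix(1:10, ncol = 1)), "2 chains")
})

test_that("summarize_slope reports means of draws and sex contrasts", {
  cfg <- cohort_config(n_subjects = 400, seed = 41)
  cells <- batch_cell_keys(cfg)
  sex <- sub(":.*", "", cells)
  # females grow faster by 0.5 in residual-SD units
  slp <- setNames(ifelse(sex == "female", 0.75, 0.25), cells)
  m <- roi_model(info1, intercept = 10, slope = slp, scale = 1,
                 epsilon = 0, delta = 1, cells = cells)
  rec <- simulate_cohort(cfg, list(m))
  fit <- fit_normative(rec, "func01", fast_hbr(seed = 41))
  sl <- summarize_slope(fit)
  expect_gt(sl$by_sex$female$mean, sl$by_sex$male$mean)
  expect_gt(sl$contrast$ci95[1], 0)  # interval excludes 0
  expect_equal(sl$by_sex$female$mean, mean(sl$by_sex$female$draws),
               tolerance = 1e-12)

  # null contrast: equal true slopes cover zero
  m2 <- roi_model(info1, intercept = 10, slope = 0.15, scale = 1,
                  epsilon = 0, delta = 1, cells = cells)
  cfg2 <- cohort_config(n_subjects = 300, seed = 43)
  rec2 <- simulate_cohort(cfg2, list(m2))
  fit2 <- fit_normative(rec2, "func01", fast_hbr(seed = 43))
  ci <- summarize_slope(fit2)$contrast$ci95
  expect_true(ci[1] < 0 && ci[2] > 0)
  # spline fits have no single slope
  cfgb <- fast_hbr(seed = 1, basis = basis_spec("bspline3"))
  cfgb$keep_loglik <- FALSE
  fitb <- fit_normative(rec2, "func01", cfgb)
  expect_error(summarize_slope(fitb), "linear basis")
})

test_that("LOO: identical fits tie exactly; misfit prefers the spline", {
  cfg <- cohort_config(n_subjects = 250, seed = 51)
  m <- roi_model(info1, intercept = 10, slope = 0.3, scale = 1,
                 cells = batch_cell_keys(cfg))
  rec <- simulate_cohort(cfg, list(m))
  fit <- fit_normative(rec, "func01", fast_hbr(seed = 51))
  same <- compare_loo(fit, fit)
  expect_identical(same$elpd_diff, 0)
  expect_true(same$equal)

  # linear truth: linear and spline perform equally well
  cfgb <- fast_hbr(seed = 51, basis = basis_spec("bspline3"))
  fitb <- fit_normative(rec, "func01", cfgb)
  cmp <- compare_loo(fit, fitb)
  expect_true(abs(cmp$elpd_diff) < 2 * cmp$se_diff)

  # strongly sigmoidal truth: the spline wins decisively
  cfg2 <- cohort_config(n_subjects = 400, seed = 53)
  rec2 <- simulate_cohort(cfg2, list(m))
  a_std <- (rec2$age - mean(rec2$age)) / sd(rec2$age)
  set.seed(53)
  rec2$func01 <- 10 + 3 * plogis(6 * a_std) + rnorm(nrow(rec2), 0, 0.3)
  fl <- fit_normative(rec2, "func01", fast_hbr(seed = 53))
  fs <- fit_normative(rec2, "func01",
                      fast_hbr(seed = 53, basis = basis_spec("bspline3")))
  cmp2 <- compare_loo(fs, fl)
  expect_gt(cmp2$elpd_diff, 2 * cmp2$se_diff)
  # mismatched scan sets are rejected
  expect_error(compare_loo(fit, fs), "same scans")
})
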