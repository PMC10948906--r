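test_that("families: hemispheric averaging, counts, collinearity", {
  info <- example_roi_info("anatomical")
  # one lobule with asymmetric hemispheres
  slopes <- data.frame(roi = info$roi, sex = "female",
                       slope = 0.1, stringsAsFactors = FALSE)
  slopes$slope[slopes$roi == "left_V"] <- 0.10
  slopes$slope[slopes$roi == "right_V"] <- 0.20
  fam <- prepare_families(slopes, info)
  hemi <- fam[fam$family == "volume_hemispheres", ]
  expect_equal(hemi$value[hemi$rank == 3], 0.15)  # V has rank 3
  expect_equal(nrow(fam[fam$family == "volume_vermis", ]), 10)

  infoF <- example_roi_info("functional", n_roi = 10)
  sl <- data.frame(roi = infoF$roi, sex = "male",
                   slope = 0.1 + 0.01 * infoF$ap_rank)
  famF <- prepare_families(sl, infoF)
  expect_equal(nrow(famF), 10)
  expect_equal(unique(famF$family), "volume_func")
  # collinear by construction
  ft <- fit_ap_trend(famF)
  expect_equal(ft$slope, 0.01, tolerance = 1e-12)
  expect_lt(ft$p, 1e-12)

  # missing hemisphere partner is reported by lobule
  broken <- slopes[slopes$roi != "right_V", ]
  expect_error(prepare_families(broken, info[info$roi != "right_V", ]),
               "lobule 'V'")
})

test_that("AP trend: null series, OLS oracle, prediction interval", {
  flat <- data.frame(rank = 1:8, value = rep(0.2, 8))
  ft <- fit_ap_trend(flat)
  expect_equal(ft$slope, 0, tolerance = 1e-12)
  expect_equal(ft$p, 1, tolerance = 1e-9)

  set.seed(81)
  for (i in 1:10) {
    ser <- data.frame(rank = 1:8, value = rnorm(8, 0.1, 0.05))
    ft <- fit_ap_trend(ser)
    o <- ols_oracle(ser$rank, ser$value)
    expect_equal(ft$slope, o$slope, tolerance = 1e-10)
    expect_equal(ft$p, o$p, tolerance = 1e-10)
    expect_equal(ft$se, o$se, tolerance = 1e-10)
  }
  pi <- predict_ap_trend(fit_ap_trend(
    data.frame(rank = 1:10, value = 0.1 * (1:10) + rnorm(10, 0, 0.01))),
    rank = 1:10)
  expect_true(all(pi$lower < pi$fit & pi$fit < pi$upper))
  expect_error(fit_ap_trend(flat[1:2, ]), "3 points")
  expect_error(fit_ap_trend(data.frame(rank = rep(1, 5), value = 1:5)),
               "constant")
})

test_that("BH adjustment matches the published AP-gradient family", {
  # the ten AP trend p-values (five families x two sexes); the
  # below-detection male GMD value is entered as 0.0002
  p <- c(volM = 0.019, gmdM = 0.0002, wmdM = 0.003, hemM = 0.060,
         verM = 0.569, volF = 0.036, gmdF = 0.005, wmdF = 0.003,
         hemF = 0.004, verF = 0.544)
  adj <- round(adjust_fdr(p), 3)
  expect_equal(unname(adj["volM"]), 0.032)
  expect_equal(unname(adj["volF"]), 0.051)
  expect_equal(unname(adj["hemM"]), 0.075)
  expect_equal(unname(adj["gmdM"]), 0.002)
  expect_equal(unname(adj[c("wmdM", "gmdF", "wmdF", "hemF")]),
               rep(0.010, 4))
  expect_equal(unname(adj[c("verM", "verF")]), rep(0.569, 2))
})

test_that("BH properties: single p, ties, monotonicity, order, oracle", {
  expect_equal(adjust_fdr(0.07), 0.07)
  expect_equal(adjust_fdr(rep(0.2, 6)), rep(0.2, 6))
  set.seed(83)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- adjust_fdr(p)
    expect_equal(adj, p.adjust(p, "BH"))  # library oracle
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    perm <- sample(seq_along(p))
    expect_equal(adjust_fdr(p[perm]), adj[perm])
  }
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("gradient recovery: estimated AP coefficient matches truth", {
  # end-to-end on an injected gradient, against the closed-form OLS of
  # the true standardized slopes (single scaled-down replicate; the
  # full fits run in the acceptance suite)
  info <- example_roi_info("functional", n_roi = 6)
  cfg <- cohort_config(n_subjects = 350, seed = 91)
  models <- inject_gradient(example_roi_models(info, config = cfg),
                            base_slope = 0.1, increment = 0.05)
  rec <- simulate_cohort(cfg, models)
  sp <- split_cohort(rec, 0.5, seed = 91)
  slopes <- do.call(rbind, lapply(info$roi, function(r) {
    fit <- fit_normative(sp$train, r,
                         fast_hbr(seed = 91, keep_loglik = FALSE))
    sl <- summarize_slope(fit)
    data.frame(roi = r, sex = c("female", "male"),
               slope = c(sl$by_sex$female$mean, sl$by_sex$male$mean))
  }))
  res <- ap_gradient_analysis(slopes, info)
  # oracle: true standardized slope per ROI is slope_r / sd(y_r)
  truth <- vapply(models, function(m)
    unname(m$slope[1]) / sd(sp$train[[m$roi]]), numeric(1))
  tr_fit <- ols_oracle(info$ap_rank, truth)
  for (sx in c("female", "male")) {
    row <- res[res$family == "volume_func" & res$sex == sx, ]
    expect_lt(abs(row$ap_coefficient - tr_fit$slope), 2 * row$se)
  }
  expect_true(all(res$p_fdr >= res$p))
})
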