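# direct construction of deviation tables keeps these tests analytic
make_dev_table <- function(z, subject_id = sprintf("s%05d",
                                                   seq_along(z)),
                           age = rep(10, length(z)), roi = "roi1",
                           threshold = 1.96) {
  out <- data.frame(subject_id = subject_id, wave = 1L, age = age,
                    sex = "female", scanner = "A", roi = roi, y = z,
                    z = z, extreme_neg = z < -threshold,
                    extreme_pos = z > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("deviation_table", "data.frame")
  out
}

test_that("binomial tail: trivial cases and brute-force oracle", {
  expect_equal(binomial_tail(0, 50, 0.025), 1)
  expect_equal(binomial_tail(10, 10, 0.5), 2^-10)
  set.seed(17)
  for (i in 1:25) {
    n <- sample(500, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.005, 0.5)
    expect_equal(binomial_tail(k, n, p0), binom_tail_oracle(k, n, p0),
                 tolerance = 1e-12)
  }
  expect_error(binomial_tail(11, 10, 0.1), "\\[0, n\\]")
})

test_that("critical counts bracket the published thresholds", {
  # n = 2012: the tail first drops below 0.05 at k = 63
  expect_lt(binomial_tail(63, 2012, 0.025), 0.05)
  expect_gte(binomial_tail(62, 2012, 0.025), 0.05)
  expect_equal(critical_percent(2012, 0.025, 0.05)$percent, 3.13)
  expect_equal(critical_percent(198, 0.025, 0.05)$percent, 5.05)
  # exact enumeration oracle at n = 40, p0 = 0.5
  cp <- critical_percent(40, 0.5, 0.05)
  expect_equal(cp$k, 26L)
  expect_equal(cp$percent, 65.00)
  tails <- vapply(0:40, binom_tail_oracle, numeric(1), n = 40, p0 = 0.5)
  expect_equal(cp$k, which(tails < 0.05)[1] - 1L)
  # large-n consistency: critical percent approaches 100 * p0
  expect_lt(abs(critical_percent(1e6, 0.025, 0.05)$percent - 2.5), 0.05)
  # monotone decreasing in n
  ns <- c(100, 500, 2012, 10000)
  cps <- vapply(ns, function(n) critical_percent(n)$percent, numeric(1))
  expect_true(all(diff(cps) < 0))
  expect_error(critical_percent(3, 0.025, 1e-10), "significance")
})

test_that("group comparison: null rates, shifted subgroup, edge cases", {
  set.seed(19)
  # null cohort of 2000 typical subjects
  z <- rnorm(2000)
  dev <- make_dev_table(z)
  flags <- setNames(rep(FALSE, 2000), dev$subject_id)
  res <- compare_groups(dev, flags)
  expect_setequal(res$group, "typical")
  expect_true(all(res$percent >= 1.5 & res$percent <= 3.5))
  expect_equal(res$critical_percent,
               rep(critical_percent(2000)$percent, 2))

  # -1 SD shifted subgroup of 200: negative tail significant in >= 90%
  # of seeds (oracle: extreme rate pnorm(-0.96) ~ 0.169)
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    zz <- c(rnorm(1800), rnorm(200, -1))
    dv <- make_dev_table(zz)
    fl <- setNames(c(rep(FALSE, 1800), rep(TRUE, 200)), dv$subject_id)
    r <- compare_groups(dv, fl)
    r$p[r$group == "high" & r$tail == "neg"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # permuted flags: no excess significance on null data
  set.seed(23)
  fp <- vapply(1:40, function(s) {
    zz <- rnorm(400)
    dv <- make_dev_table(zz)
    fl <- setNames(sample(c(rep(TRUE, 40), rep(FALSE, 360))),
                   dv$subject_id)
    r <- compare_groups(dv, fl)
    any(r$p[r$group == "high"] < 0.05)
  }, logical(1))
  expect_lte(mean(fp), 0.25)

  expect_error(compare_groups(dev[0, ], flags), "empty")
  expect_error(compare_groups(dev, flags[-1]), "missing")
})

test_that("multi-scan subjects enter once, by the latest scan", {
  dev <- make_dev_table(c(3, 0, 0, 3),
                        subject_id = c("a", "a", "b", "b"),
                        age = c(8, 12, 8, 12))
  flags <- c(a = FALSE, b = FALSE)
  res <- compare_groups(dev, flags)
  # latest: a contributes z=0, b contributes z=3 -> one positive
  expect_equal(res$k[res$tail == "pos"], 1L)
  res_e <- compare_groups(dev, flags, scan_rule = "earliest")
  expect_equal(res_e$k[res_e$tail == "pos"], 1L)  # now a's z=3 counts
  expect_equal(res$n, rep(2L, 2))
})

test_that("deviation-on-score regression: recovery and calibration", {
  set.seed(29)
  n <- 400
  score <- setNames(rnorm(n, 50, 10), sprintf("s%05d", 1:n))
  z <- 0.05 * (score - 50) + rnorm(n, 0, 0.7)
  dev <- make_dev_table(unname(z))
  res <- regress_deviation_on_score(dev, score)
  expect_lt(abs(res$slope - 0.05), 2 * res$se)
  expect_true(all(res$p_fdr >= res$p))

  # type-I calibration across many null ROIs
  devs <- do.call(rbind, lapply(1:40, function(i)
    make_dev_table(rnorm(n), roi = sprintf("roi%02d", i))))
  attr(devs, "threshold") <- 1.96
  class(devs) <- c("deviation_table", "data.frame")
  res0 <- regress_deviation_on_score(devs, score)
  expect_lte(mean(res0$p < 0.05), 0.2)

  expect_error(regress_deviation_on_score(dev, score * 0 + 1),
               "constant")
  expect_error(regress_deviation_on_score(dev[1:5, ], score),
               "10 subjects")
})
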