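# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# textbook de Boor recursion for B-spline basis functions on a full
# (clamped) knot vector
deboor_basis <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1L
  sapply(seq_len(n_basis), function(i)
    vapply(x, function(xx) .deboor_one(xx, i, degree, knots), numeric(1)))
}

.deboor_one <- function(x, i, p, t) {
  if (p == 0L) {
    # right-closed at the final interval so the boundary is covered
    hi <- t[i + 1L]
    is_last <- abs(hi - t[length(t)]) < 1e-14
    return(as.numeric(x >= t[i] && (x < hi || (is_last && x <= hi))))
  }
  d1 <- t[i + p] - t[i]
  d2 <- t[i + p + 1L] - t[i + 1L]
  a <- if (d1 > 0) (x - t[i]) / d1 * .deboor_one(x, i, p - 1L, t) else 0
  b <- if (d2 > 0) (t[i + p + 1L] - x) / d2 *
      .deboor_one(x, i + 1L, p - 1L, t) else 0
  a + b
}

# closed-form simple OLS with the exact t-test, via normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- b / se
  list(slope = b, intercept = a, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), n - 2))
}

# brute-force binomial upper tail by direct probability-mass summation
binom_tail_oracle <- function(k, n, p0) {
  if (k > n) stop("k > n")
  if (k <= 0) return(1)
  kk <- k:n
  sum(exp(lchoose(n, kk) + kk * log(p0) + (n - kk) * log1p(-p0)))
}

# classic (non rank-normalized) split R-hat from the direct formula
split_rhat_oracle <- function(x) {
  half <- floor(nrow(x) / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[seq.int(half + 1, 2 * half), , drop = FALSE])
  W <- mean(apply(sp, 2, var))
  B <- half * var(colMeans(sp))
  sqrt(((half - 1) / half * W + B / half) / W)
}

# a hand-built posterior object with constant draws: exact control over
# the plug-in parameters used by deviation scoring and growth bands
make_fake_posterior <- function(alpha, beta, sigma, epsilon = 0,
                                delta = 1, cells = c("female:A",
                                                     "male:A"),
                                age_mean = 10, age_sd = 2,
                                age_range = c(6, 17), center = 0,
                                scale = 1, n_keep = 50L) {
  B <- length(cells)
  alpha <- rep_len(alpha, B); beta <- rep_len(beta, B)
  sigma <- rep_len(sigma, B)
  pars <- c("mu_alpha", "mu_beta_age_std", "tau_alpha",
            "tau_beta_age_std", "mu_s", "tau_s",
            as.vector(t(outer(cells, c("alpha", "beta_age_std"),
                              function(b, k) paste0(k, "[", b, "]")))),
            paste0("sigma[", cells, "]"), "epsilon", "delta")
  tr <- array(0, c(n_keep, 2L, length(pars)),
              dimnames = list(NULL, NULL, pars))
  for (b in seq_len(B)) {
    tr[, , paste0("alpha[", cells[b], "]")] <- alpha[b]
    tr[, , paste0("beta_age_std[", cells[b], "]")] <- beta[b]
    tr[, , paste0("sigma[", cells[b], "]")] <- sigma[b]
  }
  tr[, , "epsilon"] <- epsilon
  tr[, , "delta"] <- delta
  basis <- basis_spec("linear", age_range = age_range)
  basis$age_mean <- age_mean; basis$age_sd <- age_sd
  basis$locked <- TRUE
  cfg <- hbr_config(n_chains = 2L, n_samples = n_keep + 1L, n_tune = 1L,
                    basis = basis)
  structure(
    list(roi = "roi1", draws = tr,
         rhat = stats::setNames(rep(1, length(pars)), pars),
         cells = cells, cell_counts = rep(10L, B),
         cell_info = cerebnorm:::.cell_table(cells, c("sex", "scanner")),
         basis = basis, scaler = list(center = center, scale = scale),
         config = cfg, n_chains = 2L, n_keep = n_keep, n_train = 20L,
         accept_rate = c(1, 1), divergences = c(0L, 0L), div_frac = 0,
         divergent_flag = FALSE, loglik = NULL),
    class = "normative_posterior")
}

# quick records table for a fake posterior: scans in given cells
make_fake_records <- function(n, cells = c("female:A", "male:A"),
                              ages = NULL, seed = 1) {
  set.seed(seed)
  cell <- sample(cells, n, replace = TRUE)
  parts <- strsplit(cell, ":", fixed = TRUE)
  data.frame(subject_id = sprintf("s%04d", seq_len(n)), wave = 1L,
             age = if (is.null(ages)) runif(n, 6, 17) else ages,
             sex = vapply(parts, `[`, "", 1L),
             scanner = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# small, fast sampler settings for unit tests (not the study protocol)
fast_hbr <- function(seed = 1, ...) {
  hbr_config(n_chains = 2L, n_samples = 700L, n_tune = 250L,
             seed = seed, ...)
}
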