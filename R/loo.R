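#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density (ELPD) from a
#' pointwise log-likelihood matrix.  Leave-one-out importance ratios
#' (the reciprocal pointwise likelihoods) have their upper tail
#' stabilized by replacing the largest raw weights with expected order
#' statistics of a generalized Pareto distribution fitted to the tail
#' (Zhang-Stephens estimator), truncated at the raw maximum.
#'
#' @param loglik matrix of pointwise log-likelihood values, draws x
#'   observations.
#' @return list with `elpd`, `elpd_i` (pointwise), `se`, and the Pareto
#'   shape diagnostics `khat` per observation.
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  n <- ncol(loglik)
  elpd_i <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    sm <- .psis_smooth(lw)
    lw <- sm$lw
    khat[i] <- sm$khat
    # elpd_i = log( sum w * lik ) - log( sum w )
    elpd_i[i] <- .logsumexp(lw + ll) - .logsumexp(lw)
  }
  list(elpd = sum(elpd_i), elpd_i = elpd_i,
       se = sqrt(n * stats::var(elpd_i)), khat = khat)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# smooth the upper tail of normalized log-weights; returns khat
.psis_smooth <- function(lw) {
  S <- length(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5L || length(unique(lw)) < 5L)
    return(list(lw = lw, khat = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[seq.int(S - M + 1L, S)]
  cutoff <- exp(lw[ord[S - M]])
  exceed <- exp(lw[tail_ids]) - cutoff
  fit <- .gpdfit(exceed)
  if (!is.finite(fit$k)) return(list(lw = lw, khat = NA_real_))
  p <- (seq_len(M) - 0.5) / M
  smoothed <- .qgpd(p, fit$k, fit$sigma) + cutoff
  smoothed <- pmin(smoothed, exp(max(lw)))  # truncate at raw maximum
  lw[tail_ids[order(exceed)]] <- log(smoothed)
  list(lw = lw, khat = fit$k)
}

# Zhang & Stephens (2009) profile-posterior generalized Pareto fit
.gpdfit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[floor(n / 4 + 0.5)]
  bs <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / prior_bs / xstar
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  ls <- n * (log(bs / ks) + ks - 1)
  w <- exp(ls - .logsumexp(ls))
  b <- sum(bs * w)
  k <- -mean(log1p(-b * x))
  list(k = k, sigma = k / b)
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma * expm1(-k * log1p(-p)) / k
}

#' Compare two normative model fits by PSIS-LOO
#'
#' ELPD difference (first minus second) with its standard error from the
#' pointwise differences.  Models are declared to perform "equally well"
#' when the absolute difference is below twice its standard error.
#'
#' @param posterior_a,posterior_b two [fit_normative()] results carrying
#'   pointwise log-likelihoods on the same training scans.
#' @return list with `elpd_a`, `elpd_b`, `elpd_diff`, `se_diff`,
#'   `equal`, and the per-model `khat` diagnostics.
#' @export
compare_loo <- function(posterior_a, posterior_b) {
  lla <- posterior_a$loglik
  llb <- posterior_b$loglik
  if (is.null(lla) || is.null(llb))
    stop("both fits must carry pointwise log-likelihoods ",
         "(keep_loglik = TRUE)", call. = FALSE)
  if (ncol(lla) != ncol(llb))
    stop("the two fits were not computed on the same scans",
         call. = FALSE)
  la <- psis_loo(lla)
  lb <- psis_loo(llb)
  di <- la$elpd_i - lb$elpd_i
  se_diff <- sqrt(length(di) * stats::var(di))
  diff <- sum(di)
  list(elpd_a = la$elpd, elpd_b = lb$elpd, elpd_diff = diff,
       se_diff = se_diff, equal = abs(diff) <= 2 * se_diff,
       khat_a = la$khat, khat_b = lb$khat)
}
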