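#' MCMC configuration for the normative model
#'
#' Defaults follow the original analysis protocol: 4 chains of 2000
#' samples each, of which the first 500 are tuning (warmup) samples and
#' are discarded, leaving 4 x 1500 = 6000 retained draws.
#'
#' @param n_chains number of chains (>= 2, required for split R-hat).
#' @param n_samples samples per chain, including tuning.
#' @param n_tune leading samples per chain used for adaptation and
#'   discarded.
#' @param seed RNG seed for the sampler.
#' @param basis a [basis_spec()] for the age effect.
#' @param batch_vars record columns treated as batch effects; their
#'   crossed cells each receive their own intercept, slope(s) and scale
#'   under shared hyperpriors.
#' @param parameterization `"noncentered"` (default; no divergences on
#'   these models) or `"centered"`.
#' @param target_accept dual-averaging acceptance target.
#' @param traj_len nominal integration length of a Hamiltonian
#'   trajectory (mass-standardized units).
#' @param max_steps leapfrog step cap per trajectory.
#' @param init_jitter SD of the random initial point.
#' @param keep_loglik store the pointwise log-likelihood matrix needed
#'   for LOO comparison.
#' @return an object of class `hbr_config`.
#' @export
hbr_config <- function(n_chains = 4L, n_samples = 2000L, n_tune = 500L,
                       seed = 1L, basis = basis_spec("linear"),
                       batch_vars = c("sex", "scanner"),
                       parameterization = c("noncentered", "centered"),
                       target_accept = 0.9, traj_len = 3,
                       max_steps = 100L, init_jitter = 0.2,
                       keep_loglik = TRUE) {
  parameterization <- match.arg(parameterization)
  n_chains <- as.integer(n_chains)
  n_samples <- as.integer(n_samples)
  n_tune <- as.integer(n_tune)
  if (n_chains < 2L)
    stop("'n_chains' must be >= 2 (split R-hat needs multiple chains)",
         call. = FALSE)
  if (n_tune >= n_samples)
    stop("'n_tune' must be smaller than 'n_samples'", call. = FALSE)
  stopifnot(inherits(basis, "basis_spec"))
  structure(
    list(n_chains = n_chains, n_samples = n_samples, n_tune = n_tune,
         seed = as.integer(seed), basis = basis,
         batch_vars = batch_vars, parameterization = parameterization,
         target_accept = target_accept, traj_len = traj_len,
         max_steps = as.integer(max_steps), init_jitter = init_jitter,
         keep_loglik = isTRUE(keep_loglik)),
    class = "hbr_config")
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Fit the hierarchical Bayesian normative model for one ROI
#'
#' Model: standardized measure `y_i ~ SHASHb(mu_i, sigma_b(i), epsilon,
#' delta)` with `mu_i = alpha_b + sum_k beta_{b,k} basis_k(age_i)` and
#' `sigma_b = softplus(s_b)`; the per-batch-cell intercepts, slopes and
#' scale parameters are drawn from shared Normal hyperpriors (partial
#' pooling over the crossed sex-by-scanner cells), the skew and tail
#' parameters are global per ROI.  Inference is adaptive Hamiltonian
#' Monte Carlo (dual-averaged step size, diagonal mass adaptation,
#' jittered trajectory lengths) on the non-centered parameterization.
#'
#' Responses are standardized on the training data; basis and
#' standardization statistics are stored in the result so that held-out
#' scans are scored on exactly the training scale.
#'
#' @param records training scans: a long-format cohort `data.frame`
#'   with `age`, the batch-variable columns, and one column per ROI.
#' @param roi name of the measure column to model.
#' @param config an [hbr_config()].
#' @return an object of class `normative_posterior`: transformed draws
#'   (`iterations x chains x parameters`), split R-hat per parameter,
#'   pointwise log-likelihoods, basis/scaler metadata, and sampler
#'   diagnostics.
#' @export
fit_normative <- function(records, roi, config = hbr_config()) {
  stopifnot(inherits(config, "hbr_config"))
  if (!roi %in% names(records))
    stop(sprintf("ROI column '%s' not found in records", roi),
         call. = FALSE)
  miss <- setdiff(config$batch_vars, names(records))
  if (length(miss))
    stop("missing batch variable column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  cell_df <- records[config$batch_vars]
  cell_key <- do.call(paste, c(cell_df, sep = ":"))
  cells <- sort(unique(cell_key))
  B <- length(cells)
  if (B < 2L)
    stop("at least 2 batch cells are required for partial pooling",
         call. = FALSE)
  counts <- table(factor(cell_key, levels = cells))
  sparse <- names(counts)[counts < 3L]
  if (length(sparse))
    warning("batch cell(s) with < 3 scans fall back on the pooled ",
            "prior: ", paste(sparse, collapse = ", "), call. = FALSE)
  y_raw <- records[[roi]]
  if (any(!is.finite(y_raw)))
    stop(sprintf("non-finite measures in ROI '%s'", roi), call. = FALSE)

  scaler <- response_scaler(y_raw)
  y <- scaler$transform(y_raw)
  basis <- lock_basis(config$basis, records$age)
  X <- build_basis(records$age, basis)
  K <- ncol(X)
  cell0 <- match(cell_key, cells) - 1L

  set.seed(config$seed)
  raw <- .hbr_sample(y, X, cell0, B, config$n_chains, config$n_samples,
                     config$n_tune, config$target_accept,
                     config$parameterization == "centered",
                     config$traj_len, config$max_steps,
                     config$init_jitter)
  n_keep <- config$n_samples - config$n_tune
  dim_raw <- 2L * K + 2L + B * K + B + 2L
  theta <- array(raw$draws, c(n_keep, dim_raw, config$n_chains))

  tr <- .transform_draws(theta, K, B, cells, colnames(X),
                         config$parameterization == "centered")
  P <- dim(tr)[3]
  rhat <- apply(tr, 3, function(m) split_rhat(m))
  names(rhat) <- dimnames(tr)[[3]]

  div_frac <- sum(raw$divergences) / (n_keep * config$n_chains)
  if (div_frac > 0.05)
    warning(sprintf("%.1f%% divergent transitions; estimates may be %s",
                    100 * div_frac, "unreliable"), call. = FALSE)

  post <- structure(
    list(roi = roi, draws = tr, rhat = rhat, cells = cells,
         cell_counts = as.integer(counts),
         cell_info = .cell_table(cells, config$batch_vars),
         basis = basis, scaler = list(center = scaler$center,
                                      scale = scaler$scale),
         config = config, n_chains = config$n_chains,
         n_keep = n_keep, n_train = nrow(records),
         accept_rate = raw$accept_rate,
         divergences = raw$divergences, div_frac = div_frac,
         divergent_flag = div_frac > 0.05, loglik = NULL),
    class = "normative_posterior")
  if (config$keep_loglik)
    post$loglik <- .pointwise_loglik(post, y, X, cell0 + 1L)
  post
}

# split "sex:scanner" keys back into a per-cell metadata table
.cell_table <- function(cells, batch_vars) {
  parts <- strsplit(cells, ":", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- batch_vars
  out$cell <- cells
  out
}

# raw unconstrained draws -> named interpretable parameters
.transform_draws <- function(theta, K, B, cells, basis_cols, centered) {
  n_keep <- dim(theta)[1]
  n_chains <- dim(theta)[3]
  d0 <- log(exp(1) - 1)
  coef_lab <- c("alpha", if (K > 1L) paste0("beta_", basis_cols[-1L]))
  i_mu <- seq_len(K)
  i_lt <- K + seq_len(K)
  i_ms <- 2L * K + 1L
  i_lts <- 2L * K + 2L
  i_zc <- 2L * K + 2L + seq_len(B * K)
  i_zs <- 2L * K + 2L + B * K + seq_len(B)
  i_eps <- 2L * K + 2L + B * K + B + 1L
  i_dr <- i_eps + 1L

  par_names <- c(paste0("mu_", coef_lab), paste0("tau_", coef_lab),
                 "mu_s", "tau_s",
                 as.vector(t(outer(cells, coef_lab,
                                   function(b, k) paste0(k, "[", b, "]")))),
                 paste0("sigma[", cells, "]"), "epsilon", "delta")
  P <- length(par_names)
  out <- array(NA_real_, c(n_keep, n_chains, P),
               dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(n_chains)) {
    th <- theta[, , ch, drop = FALSE]
    dim(th) <- dim(theta)[1:2]
    tau <- exp(th[, i_lt, drop = FALSE])
    tau_s <- exp(th[, i_lts])
    out[, ch, seq_len(K)] <- th[, i_mu]
    out[, ch, K + seq_len(K)] <- tau
    out[, ch, 2L * K + 1L] <- th[, i_ms]
    out[, ch, 2L * K + 2L] <- tau_s
    idx <- 2L * K + 2L
    for (b in seq_len(B)) {
      for (k in seq_len(K)) {
        z <- th[, i_zc[(b - 1L) * K + k]]
        out[, ch, idx + (b - 1L) * K + k] <-
          if (centered) z else th[, i_mu[k]] + tau[, k] * z
      }
    }
    idx <- idx + B * K
    for (b in seq_len(B)) {
      zs <- th[, i_zs[b]]
      s_b <- if (centered) zs else th[, i_ms] + tau_s * zs
      out[, ch, idx + b] <- .softplus(s_b)
    }
    out[, ch, P - 1L] <- th[, i_eps]
    out[, ch, P] <- .softplus(d0 + th[, i_dr])
  }
  out
}

# pooled draws x observations log-likelihood on the standardized scale
.pointwise_loglik <- function(post, y, X, cell1) {
  d <- .pooled_draws(post)
  K <- ncol(X)
  B <- length(post$cells)
  coef_lab <- c("alpha",
                if (K > 1L) paste0("beta_", colnames(X)[-1L]))
  S <- nrow(d)
  n <- length(y)
  ll <- matrix(NA_real_, S, n)
  coef_cols <- outer(post$cells, coef_lab,
                     function(b, k) paste0(k, "[", b, "]"))
  sig_cols <- paste0("sigma[", post$cells, "]")
  for (s in seq_len(S)) {
    coef <- matrix(d[s, coef_cols], B, K)
    mu_all <- X %*% t(coef)
    mu <- mu_all[cbind(seq_len(n), cell1)]
    sig <- d[s, sig_cols][cell1]
    ll[s, ] <- dshashb(y, mu, sig, d[s, "epsilon"], d[s, "delta"],
                       log = TRUE)
  }
  ll
}

# draws pooled over chains: matrix (n_keep*n_chains) x parameters
.pooled_draws <- function(post) {
  tr <- post$draws
  m <- matrix(tr, dim(tr)[1] * dim(tr)[2], dim(tr)[3])
  colnames(m) <- dimnames(tr)[[3]]
  m
}

#' Posterior-mean parameters of a fitted normative model
#'
#' Plug-in estimates used for deviation scoring and growth bands:
#' per-cell intercepts/slopes/scales plus the global skew and tail
#' parameters, all on the standardized response scale.
#'
#' @param posterior a [fit_normative()] result.
#' @return list with `coef` (cells x basis columns), `sigma` (per
#'   cell), `epsilon`, `delta`.
#' @export
posterior_means <- function(posterior) {
  stopifnot(inherits(posterior, "normative_posterior"))
  d <- .pooled_draws(posterior)
  mn <- colMeans(d)
  K <- length(grep("^mu_", names(mn))) - 1L  # mu_s is not a coefficient
  coef_lab <- sub("^mu_", "", grep("^mu_(alpha|beta)", names(mn),
                                   value = TRUE))
  B <- length(posterior$cells)
  coef <- sapply(coef_lab, function(k)
    mn[paste0(k, "[", posterior$cells, "]")])
  coef <- matrix(coef, B, length(coef_lab),
                 dimnames = list(posterior$cells, coef_lab))
  list(coef = coef,
       sigma = stats::setNames(mn[paste0("sigma[", posterior$cells, "]")],
                               posterior$cells),
       epsilon = unname(mn["epsilon"]), delta = unname(mn["delta"]))
}

#' Summarize the standardized age slope per sex
#'
#' Slope draws are averaged over scanner cells within each sex,
#' weighted by the training scan counts of the cells, yielding the
#' per-sex standardized age beta; the sex contrast (female minus male)
#' is reported with a 95% credible interval.
#'
#' @param posterior a [fit_normative()] result with a linear basis.
#' @param sex_var which batch variable holds sex (default `"sex"`).
#' @return list with per-sex `mean`, `sd`, `draws`, and the `contrast`
#'   (draws, mean, 95% interval).
#' @export
summarize_slope <- function(posterior, sex_var = "sex") {
  stopifnot(inherits(posterior, "normative_posterior"))
  if (posterior$basis$kind != "linear")
    stop("a single slope is only defined for the linear basis; ",
         "summarize spline fits through growth_bands()", call. = FALSE)
  if (!sex_var %in% names(posterior$cell_info))
    stop(sprintf("'%s' is not a batch variable of this fit", sex_var),
         call. = FALSE)
  d <- .pooled_draws(posterior)
  info <- posterior$cell_info
  info$n <- posterior$cell_counts
  sexes <- sort(unique(info[[sex_var]]))
  per_sex <- lapply(sexes, function(sx) {
    rows <- info[info[[sex_var]] == sx, ]
    w <- rows$n / sum(rows$n)
    cols <- paste0("beta_age_std[", rows$cell, "]")
    draws <- as.vector(d[, cols, drop = FALSE] %*% w)
    list(mean = mean(draws), sd = stats::sd(draws), draws = draws)
  })
  names(per_sex) <- sexes
  out <- list(by_sex = per_sex)
  if (all(c("female", "male") %in% sexes)) {
    cd <- per_sex[["female"]]$draws - per_sex[["male"]]$draws
    out$contrast <- list(draws = cd, mean = mean(cd),
                         ci95 = unname(stats::quantile(cd,
                                                       c(0.025, 0.975))))
  }
  out
}

#' @export
print.normative_posterior <- function(x, ...) {
  cat(sprintf("Normative SHASHb model for ROI '%s'\n", x$roi))
  cat(sprintf("  %d training scans, %d batch cells (%s)\n", x$n_train,
              length(x$cells), paste(x$cells, collapse = ", ")))
  cat(sprintf("  %d chains x %d retained draws; basis: %s\n",
              x$n_chains, x$n_keep, x$basis$kind))
  cat(sprintf("  max split R-hat %.3f; %.1f%% divergent transitions\n",
              max(x$rhat, na.rm = TRUE), 100 * x$div_frac))
  invisible(x)
}
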