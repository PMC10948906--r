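#' Batch-free deviation z-scores for held-out scans
#'
#' Each scan's measure is pushed through the SHASHb predictive CDF of
#' its own batch cell (at plug-in posterior-mean parameters) and mapped
#' to a standard-normal quantile:
#' `z = qnorm( SHASHb-CDF(y; mu_i, sigma_b, epsilon, delta) )`.
#' Under the model, z is exactly standard normal regardless of which
#' batch cell produced the scan — the z-scores are free of batch
#' effects by construction — and reduces to `(y - mu_i)/sigma_b` in the
#' Gaussian case.  The CDF route (rather than the raw standardized
#' residual) is what keeps the "2.5% beyond +/-1.96" interpretation
#' valid under skewed likelihoods.
#'
#' @param posterior a [fit_normative()] result.
#' @param records held-out scans; batch levels must have been seen in
#'   training.
#' @param threshold extreme-deviation cutoff (default 1.96, the
#'   two-sided 95% normal bound).
#' @param method `"plugin"` (posterior-mean parameters, default) or
#'   `"draws"` (z averaged over a thinned set of posterior draws).
#' @param n_draws number of draws used when `method = "draws"`.
#' @return a `deviation_table` data.frame: one row per scan with `z`,
#'   `extreme_neg` (z < -threshold) and `extreme_pos` (z > threshold).
#' @export
score_deviations <- function(posterior, records, threshold = 1.96,
                             method = c("plugin", "draws"),
                             n_draws = 200L) {
  stopifnot(inherits(posterior, "normative_posterior"))
  method <- match.arg(method)
  roi <- posterior$roi
  if (!roi %in% names(records))
    stop(sprintf("ROI column '%s' not found in records", roi),
         call. = FALSE)
  bv <- posterior$config$batch_vars
  cell_key <- do.call(paste, c(records[bv], sep = ":"))
  unseen <- setdiff(unique(cell_key), posterior$cells)
  if (length(unseen))
    stop("batch level(s) not seen in training: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  cell1 <- match(cell_key, posterior$cells)
  y <- (records[[roi]] - posterior$scaler$center) / posterior$scaler$scale
  X <- build_basis(records$age, posterior$basis)

  if (method == "plugin") {
    pm <- posterior_means(posterior)
    mu <- (X %*% t(pm$coef))[cbind(seq_along(y), cell1)]
    p <- pshashb(y, mu, pm$sigma[cell1], pm$epsilon, pm$delta)
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    z <- stats::qnorm(p)
  } else {
    d <- .pooled_draws(posterior)
    keep <- round(seq(1L, nrow(d), length.out = min(n_draws, nrow(d))))
    coef_lab <- colnames(posterior_means(posterior)$coef)
    coef_cols <- outer(posterior$cells, coef_lab,
                       function(b, k) paste0(k, "[", b, "]"))
    sig_cols <- paste0("sigma[", posterior$cells, "]")
    zs <- matrix(0, length(y), length(keep))
    for (j in seq_along(keep)) {
      s <- keep[j]
      coef <- matrix(d[s, coef_cols], length(posterior$cells))
      mu <- (X %*% t(coef))[cbind(seq_along(y), cell1)]
      p <- pshashb(y, mu, d[s, sig_cols][cell1], d[s, "epsilon"],
                   d[s, "delta"])
      zs[, j] <- stats::qnorm(pmin(pmax(p, 1e-15), 1 - 1e-15))
    }
    z <- rowMeans(zs)
  }

  keep_cols <- intersect(c("subject_id", "wave", "age", "sex",
                           "scanner", "high_trait"), names(records))
  out <- cbind(records[keep_cols],
               data.frame(roi = roi, y = records[[roi]], z = z,
                          extreme_neg = z < -threshold,
                          extreme_pos = z > threshold,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("deviation_table", "data.frame")
  out
}

#' Normative growth bands for one batch cell
#'
#' Mean trajectory `mu(age)` and the band `mu +/- 2 sd` of the SHASHb
#' predictive at plug-in posterior-mean parameters, on the raw measure
#' scale; in the Gaussian case the band contains ~95.45% of the
#' population.  Optional centile curves are computed through the SHASHb
#' quantile function, so they remain correct under skew.
#'
#' @param posterior a [fit_normative()] result.
#' @param sex,scanner batch levels identifying the cell.
#' @param age_grid ages (years) at which to evaluate; values outside the
#'   training range are boundary-clamped.
#' @param centiles optional vector of probabilities for centile curves.
#' @return data.frame with `age`, `mean`, `lower`, `upper` (and one
#'   column per requested centile).
#' @export
growth_bands <- function(posterior, sex, scanner, age_grid,
                         centiles = NULL) {
  stopifnot(inherits(posterior, "normative_posterior"))
  if (length(age_grid) == 0L)
    stop("empty age grid", call. = FALSE)
  cell <- paste(sex, scanner, sep = ":")
  if (!cell %in% posterior$cells)
    stop(sprintf("batch cell '%s' not seen in training", cell),
         call. = FALSE)
  pm <- posterior_means(posterior)
  X <- build_basis(age_grid, posterior$basis)
  mu <- as.vector(X %*% pm$coef[cell, ])
  sig <- pm$sigma[[cell]]
  ctr <- posterior$scaler$center
  scl <- posterior$scaler$scale
  out <- data.frame(age = age_grid,
                    mean = mu * scl + ctr,
                    lower = (mu - 2 * sig) * scl + ctr,
                    upper = (mu + 2 * sig) * scl + ctr)
  for (p in centiles) {
    q <- qshashb(p, mu, sig, pm$epsilon, pm$delta)
    out[[sprintf("c%g", 100 * p)]] <- q * scl + ctr
  }
  out
}
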