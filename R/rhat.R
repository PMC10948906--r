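#' Split rank-normalized R-hat
#'
#' Convergence diagnostic computed per parameter from an
#' iterations-by-chains matrix: chains are split in half, all draws are
#' jointly rank-normalized through the normal quantile function, and the
#' classic between/within variance ratio is computed; the folded
#' version (on absolute deviations from the median) is computed the same
#' way and the maximum of the two is returned.  Values near 1 indicate
#' convergence; > 1.1 is the conventional alarm threshold for these
#' models.
#'
#' @param x numeric matrix, iterations x chains (>= 2 chains).
#' @return scalar R-hat (NA if draws are degenerate but constant draws
#'   give 1, since there is nothing left to mix).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    stop("split R-hat requires at least 2 chains", call. = FALSE)
  if (stats::var(as.vector(x)) == 0) return(1)
  bulk <- .rhat_basic(.rank_normalize(.split_chains(x)))
  folded <- .rhat_basic(.rank_normalize(.split_chains(
    abs(x - stats::median(x)))))
  max(bulk, folded)
}

.split_chains <- function(x) {
  half <- floor(nrow(x) / 2)
  cbind(x[seq_len(half), , drop = FALSE],
        x[seq.int(half + 1L, 2L * half), , drop = FALSE])
}

.rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x))
}

.rhat_basic <- function(x) {
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence summary of a fitted normative model
#'
#' Fraction of model parameters with split rank-normalized R-hat below
#' the threshold, plus the offending parameters.
#'
#' @param posterior a [fit_normative()] result.
#' @param threshold R-hat alarm level (default 1.1).
#' @return list with `fraction`, per-parameter `rhat`, and `offenders`.
#' @export
check_convergence <- function(posterior, threshold = 1.1) {
  stopifnot(inherits(posterior, "normative_posterior"))
  if (posterior$n_chains < 2L)
    stop("convergence diagnostics require at least 2 chains",
         call. = FALSE)
  rh <- posterior$rhat
  list(fraction = mean(rh < threshold, na.rm = TRUE), rhat = rh,
       offenders = names(rh)[!is.na(rh) & rh >= threshold])
}
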