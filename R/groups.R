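#' Exact one-sided binomial upper tail
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, the exact (no normal
#' approximation) one-sided p-value used to compare an observed
#' extreme-deviation count against the 2.5% expected under a calibrated
#' normative model.
#'
#' @param k observed count (0 <= k <= n).
#' @param n group size.
#' @param p0 null probability (default 0.025).
#' @return upper-tail probability.
#' @export
binomial_tail <- function(k, n, p0 = 0.025) {
  if (any(k < 0) || any(k > n))
    stop("'k' must lie in [0, n]", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("'p0' must lie in (0, 1)", call. = FALSE)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Critical extreme-deviation percentage
#'
#' The smallest count `k*` whose exact upper-tail probability under
#' `Binomial(n, p0)` is strictly below `alpha`, reported as the
#' percentage `100 k*/n` (two decimals): the smallest percentage of a
#' group of size `n` that is significant at level `alpha`.  The strict
#' inequality is what reproduces the published thresholds (63/2012 =
#' 3.13%, 10/198 = 5.05%).
#'
#' @param n group size (>= 1).
#' @param p0 null probability (default 0.025).
#' @param alpha significance level (default 0.05).
#' @return list with `k`, `percent` (rounded to two decimals), and the
#'   attained tail probability `p`.
#' @export
critical_percent <- function(n, p0 = 0.025, alpha = 0.05) {
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  # tail is decreasing in k; bracket the crossing around the quantile
  k0 <- stats::qbinom(1 - alpha, n, p0)
  cand <- max(0L, k0 - 2L):min(n, k0 + 5L)
  tails <- binomial_tail(cand, n, p0)
  hit <- which(tails < alpha)
  if (!length(hit)) {
    if (binomial_tail(n, n, p0) >= alpha)
      stop(sprintf("no count in 0..%d reaches significance at alpha=%g",
                   n, alpha), call. = FALSE)
    hit <- length(cand)
  }
  k <- cand[hit[1L]]
  list(k = k, percent = round(100 * k / n, 2), p = tails[hit[1L]])
}

# collapse a deviation table to one scan per subject and ROI
.one_per_subject <- function(dev, scan_rule) {
  sp <- split(seq_len(nrow(dev)), dev$subject_id)
  idx <- vapply(sp, function(ii) {
    switch(scan_rule,
           latest = ii[which.max(dev$age[ii])],
           earliest = ii[which.min(dev$age[ii])],
           ii[1L])
  }, integer(1))
  if (scan_rule == "mean_z") {
    z <- vapply(sp, function(ii) mean(dev$z[ii]), numeric(1))
    out <- dev[idx, , drop = FALSE]
    out$z <- z
    thr <- attr(dev, "threshold")
    out$extreme_neg <- out$z < -thr
    out$extreme_pos <- out$z > thr
    out
  } else {
    dev[idx, , drop = FALSE]
  }
}

#' Extreme-deviation comparison between a flagged subgroup and the rest
#'
#' For each ROI and each tail (z below -threshold / above +threshold),
#' counts extreme individuals in the flagged ("high") group and the
#' remainder ("typical") and tests the observed count against the
#' expected `p0` with the exact one-sided binomial tail.  Individuals,
#' not scans, are counted: subjects with several scans contribute one
#' observation per ROI (latest scan by default).
#'
#' @param deviation_table a [score_deviations()] result (may hold
#'   several ROIs row-bound together).
#' @param group_flags logical vector named by `subject_id` (TRUE =
#'   member of the flagged subgroup); if `NULL`, a `high_trait` column
#'   of the table is used.
#' @param p0 null extreme probability (default 0.025).
#' @param alpha significance level (default 0.05).
#' @param scan_rule which scan represents a multi-scan subject:
#'   `"latest"` (default), `"earliest"`, or `"mean_z"`.
#' @return data.frame with one row per ROI, group and tail: `n`, `k`,
#'   `percent`, `p`, `critical_percent`, `significant`.
#' @export
compare_groups <- function(deviation_table, group_flags = NULL,
                           p0 = 0.025, alpha = 0.05,
                           scan_rule = c("latest", "earliest",
                                         "mean_z")) {
  scan_rule <- match.arg(scan_rule)
  dev <- deviation_table
  if (nrow(dev) == 0L) stop("empty deviation table", call. = FALSE)
  if (is.null(group_flags)) {
    if (!"high_trait" %in% names(dev))
      stop("no 'group_flags' given and no 'high_trait' column present",
           call. = FALSE)
    group_flags <- tapply(dev$high_trait, dev$subject_id, any)
  }
  miss <- setdiff(unique(dev$subject_id), names(group_flags))
  if (length(miss))
    stop("flags missing for subject(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  out <- list()
  for (roi in unique(dev$roi)) {
    dr <- dev[dev$roi == roi, , drop = FALSE]
    attr(dr, "threshold") <- attr(deviation_table, "threshold")
    one <- .one_per_subject(dr, scan_rule)
    grp <- ifelse(group_flags[one$subject_id], "high", "typical")
    for (g in intersect(c("typical", "high"), unique(grp))) {
      sub <- one[grp == g, ]
      n <- nrow(sub)
      cp <- critical_percent(n, p0, alpha)$percent
      for (tail in c("neg", "pos")) {
        k <- sum(sub[[paste0("extreme_", tail)]])
        out[[length(out) + 1L]] <- data.frame(
          roi = roi, group = g, tail = tail, n = n, k = k,
          percent = round(100 * k / n, 2),
          p = binomial_tail(k, n, p0), critical_percent = cp,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res$significant <- res$p < alpha
  res
}

#' Regress deviation scores on a continuous trait score
#'
#' Per-ROI ordinary least squares of the individual deviation z-scores
#' on a continuous score (e.g. a behavioral questionnaire total), with
#' Benjamini-Hochberg adjustment across ROIs.
#'
#' @param deviation_table a [score_deviations()] result.
#' @param score numeric vector named by `subject_id`.
#' @param scan_rule subject-collapsing rule, as in [compare_groups()].
#' @return data.frame with per-ROI `slope`, `se`, `p`, `p_fdr`, `n`.
#' @export
regress_deviation_on_score <- function(deviation_table, score,
                                       scan_rule = c("latest",
                                                     "earliest",
                                                     "mean_z")) {
  scan_rule <- match.arg(scan_rule)
  dev <- deviation_table
  subs <- unique(dev$subject_id)
  if (length(subs) < 10L)
    stop("at least 10 subjects are required", call. = FALSE)
  miss <- setdiff(subs, names(score))
  if (length(miss))
    stop("score missing for subject(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  if (any(!is.finite(score[subs])))
    stop("scores must be finite", call. = FALSE)
  if (stats::var(score[subs]) == 0)
    stop("constant score; regression undefined", call. = FALSE)
  rows <- lapply(unique(dev$roi), function(roi) {
    dr <- dev[dev$roi == roi, , drop = FALSE]
    attr(dr, "threshold") <- attr(deviation_table, "threshold")
    one <- .one_per_subject(dr, scan_rule)
    fit <- stats::lm(one$z ~ score[one$subject_id])
    co <- summary(fit)$coefficients
    data.frame(roi = roi, slope = co[2, 1], se = co[2, 2], p = co[2, 4],
               n = nrow(one), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- adjust_fdr(out$p)
  out
}
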