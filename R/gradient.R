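#' Assemble anterior-posterior analysis families
#'
#' Groups per-ROI standardized age slopes into the test families of the
#' growth-gradient analysis: the anatomical volumes split into a vermal
#' family and a hemispheric family (mean of the left/right standardized
#' betas per lobule), and the functional parcellation split by modality
#' (`volume_func`, `GMD`, `WMD`).  Families are emitted per sex.
#'
#' @param slopes data.frame with columns `roi`, `sex`, `slope`
#'   (standardized age beta per ROI and sex).
#' @param info the matching [roi_info()] metadata.
#' @return data.frame with columns `family`, `sex`, `rank`, `value`.
#' @export
prepare_families <- function(slopes, info) {
  req <- c("roi", "sex", "slope")
  if (!all(req %in% names(slopes)))
    stop("'slopes' needs columns roi, sex, slope", call. = FALSE)
  unknown <- setdiff(slopes$roi, info$roi)
  if (length(unknown))
    stop("ROI(s) missing from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  m <- merge(slopes, info, by = "roi")
  out <- list()
  for (sx in unique(m$sex)) {
    ms <- m[m$sex == sx, ]
    an <- ms[ms$parcellation == "anatomical", ]
    if (nrow(an)) {
      ver <- an[an$class == "vermal", ]
      if (nrow(ver))
        out[[length(out) + 1L]] <- data.frame(
          family = "volume_vermis", sex = sx, rank = ver$ap_rank,
          value = ver$slope, stringsAsFactors = FALSE)
      hem <- an[an$class %in% c("hemispheric_left", "hemispheric_right"), ]
      if (nrow(hem)) {
        for (lb in unique(hem$lobule)) {
          sides <- hem[hem$lobule == lb, ]
          if (!all(c("hemispheric_left", "hemispheric_right") %in%
                   sides$class))
            stop(sprintf("missing hemisphere partner for lobule '%s'",
                         lb), call. = FALSE)
        }
        agg <- stats::aggregate(cbind(value = slope) ~ lobule + ap_rank,
                                data = hem, FUN = mean)
        out[[length(out) + 1L]] <- data.frame(
          family = "volume_hemispheres", sex = sx, rank = agg$ap_rank,
          value = agg$value, stringsAsFactors = FALSE)
      }
    }
    fn <- ms[ms$parcellation == "functional", ]
    if (nrow(fn)) {
      for (mod in unique(fn$modality)) {
        sub <- fn[fn$modality == mod, ]
        fam <- if (mod == "volume") "volume_func" else mod
        out[[length(out) + 1L]] <- data.frame(
          family = fam, sex = sx, rank = sub$ap_rank, value = sub$slope,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  for (key in unique(paste(res$family, res$sex))) {
    r <- res$rank[paste(res$family, res$sex) == key]
    if (anyDuplicated(r))
      stop("duplicate AP ranks within family ", key, call. = FALSE)
  }
  res[order(res$family, res$sex, res$rank), ]
}

#' Fit the anterior-posterior linear trend
#'
#' Ordinary least squares of the standardized age slopes on integer AP
#' rank; the fitted coefficient is the AP growth coefficient, tested
#' two-sided against zero with the exact t distribution.  Enough
#' sufficient statistics are stored to reconstruct the 95% prediction
#' interval of the fit line at any rank.
#'
#' @param series data.frame with columns `rank`, `value` (>= 3 rows).
#' @return an object of class `ap_gradient_fit` with fields `slope`
#'   (AP growth coefficient), `intercept`, `se`, `t`, `df`, `p`,
#'   `sigma`, `mean_rank`, `sxx`, `n`.
#' @export
fit_ap_trend <- function(series) {
  if (nrow(series) < 3L)
    stop("at least 3 points are needed for the AP trend",
         call. = FALSE)
  x <- as.numeric(series$rank)
  y <- as.numeric(series$value)
  if (stats::var(x) == 0)
    stop("constant AP ranks; trend undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)["x"])
  icpt <- unname(stats::coef(fit)["(Intercept)"])
  df <- fit$df.residual
  sxx <- sum((x - mean(x))^2)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / df)
  se <- sigma / sqrt(sxx)
  # degenerate (perfect or constant) fits: t = 0 -> p = 1, else p -> 0
  if (se < 1e-14 * max(abs(y), 1)) {
    tval <- if (abs(slope) < 1e-12) 0 else sign(slope) * Inf
  } else {
    tval <- slope / se
  }
  structure(
    list(slope = slope, intercept = icpt, se = se, t = tval, df = df,
         p = 2 * stats::pt(-abs(tval), df), sigma = sigma,
         mean_rank = mean(x), sxx = sxx, n = length(x)),
    class = "ap_gradient_fit")
}

#' 95% prediction interval of an AP trend line
#'
#' @param fit an [fit_ap_trend()] result.
#' @param rank ranks at which to evaluate.
#' @param level interval level (default 0.95).
#' @return data.frame with `rank`, `fit`, `lower`, `upper`.
#' @export
predict_ap_trend <- function(fit, rank, level = 0.95) {
  stopifnot(inherits(fit, "ap_gradient_fit"))
  mu <- fit$intercept + fit$slope * rank
  se_pred <- fit$sigma *
    sqrt(1 + 1 / fit$n + (rank - fit$mean_rank)^2 / fit$sxx)
  tq <- stats::qt(1 - (1 - level) / 2, fit$df)
  data.frame(rank = rank, fit = mu, lower = mu - tq * se_pred,
             upper = mu + tq * se_pred)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `adjusted_(i) = min_{j >= i} min(1, p_(j) * m / j)` on the sorted
#' p-values; order-preserving and never below the raw p-value.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
adjust_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 1L) return(stats::setNames(p, names(pvalues)))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  stats::setNames(pmin(1, cummin(m / seq(m, 1) * p[o]))[ro],
                  names(pvalues))
}

#' Full anterior-posterior gradient analysis
#'
#' Builds the per-sex families, fits each AP trend, and adjusts the
#' whole set of p-values jointly by Benjamini-Hochberg (the FDR family
#' is all family-by-sex tests together).
#'
#' @param slopes data.frame with `roi`, `sex`, `slope`.
#' @param info the [roi_info()] metadata.
#' @return data.frame with one row per family and sex: `family`, `sex`,
#'   `n_roi`, `ap_coefficient`, `intercept`, `se`, `p`, `p_fdr`.
#' @export
ap_gradient_analysis <- function(slopes, info) {
  fam <- prepare_families(slopes, info)
  keys <- unique(fam[c("family", "sex")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- fam[fam$family == keys$family[i] & fam$sex == keys$sex[i], ]
    ft <- fit_ap_trend(sub)
    data.frame(family = keys$family[i], sex = keys$sex[i],
               n_roi = ft$n, ap_coefficient = ft$slope,
               intercept = ft$intercept, se = ft$se, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- adjust_fdr(out$p)
  out
}
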