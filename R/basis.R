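#' Age design-basis specification
#'
#' Describes how age enters the normative regression: either a linear
#' basis (intercept plus standardized age) or a cubic B-spline basis over
#' evenly spaced knots.  The specification is completed ("locked") on the
#' training ages by [lock_basis()], which records the training age range
#' and standardization statistics so that test-time design matrices are
#' bit-compatible with training.
#'
#' @param kind `"linear"` or `"bspline3"`.
#' @param n_knots number of evenly spaced knots (default 5).  By default
#'   the count includes the two boundary knots (`boundary_in_count =
#'   TRUE`), i.e. 5 knots place 3 interior knots; set it to `FALSE` to
#'   read the count as interior knots only.
#' @param age_range optional `(lo, hi)` in years; when `NULL` it is taken
#'   from the training ages at lock time.
#' @param standardize center/scale age by the training mean/sd for the
#'   linear basis.
#' @param boundary_in_count see `n_knots`.
#' @return an object of class `basis_spec`.
#' @export
basis_spec <- function(kind = c("linear", "bspline3"), n_knots = 5L,
                       age_range = NULL, standardize = TRUE,
                       boundary_in_count = TRUE) {
  kind <- match.arg(kind)
  n_knots <- as.integer(n_knots)
  if (kind == "bspline3" && n_knots < 2L)
    stop("'n_knots' must be >= 2 for a cubic B-spline basis", call. = FALSE)
  if (!is.null(age_range)) {
    if (length(age_range) != 2L || !all(is.finite(age_range)) ||
        age_range[1] >= age_range[2])
      stop("'age_range' must be (lo, hi) with lo < hi", call. = FALSE)
  }
  structure(
    list(kind = kind, n_knots = n_knots, age_range = age_range,
         standardize = isTRUE(standardize),
         boundary_in_count = isTRUE(boundary_in_count),
         age_mean = NULL, age_sd = NULL, locked = FALSE),
    class = "basis_spec")
}

#' Lock a basis specification on training ages
#'
#' Records the training age mean/sd and (if not supplied) the age range,
#' after which [build_basis()] evaluates identically for any input ages.
#'
#' @param spec a [basis_spec()].
#' @param train_ages numeric vector of training ages (years).
#' @return the locked `basis_spec`.
#' @export
lock_basis <- function(spec, train_ages) {
  stopifnot(inherits(spec, "basis_spec"))
  if (length(train_ages) == 0L || any(!is.finite(train_ages)))
    stop("training ages must be a non-empty finite vector", call. = FALSE)
  spec$age_mean <- mean(train_ages)
  spec$age_sd <- stats::sd(train_ages)
  if (is.null(spec$age_sd) || is.na(spec$age_sd) || spec$age_sd == 0)
    stop("training ages have zero variance", call. = FALSE)
  if (is.null(spec$age_range))
    spec$age_range <- range(train_ages)
  spec$locked <- TRUE
  spec
}

# knot sequence: evenly spaced over the locked range
.basis_knots <- function(spec) {
  lo <- spec$age_range[1]; hi <- spec$age_range[2]
  if (spec$boundary_in_count) {
    all_knots <- seq(lo, hi, length.out = spec$n_knots)
    list(interior = all_knots[-c(1, length(all_knots))],
         boundary = c(lo, hi))
  } else {
    list(interior = seq(lo, hi, length.out = spec$n_knots + 2L)[
      seq(2L, spec$n_knots + 1L)],
      boundary = c(lo, hi))
  }
}

#' Build the age design matrix
#'
#' Linear basis: columns `(Intercept)`, `age_std`.  Cubic B-spline basis:
#' an intercept column plus degree-3 B-spline columns over evenly spaced
#' knots spanning the locked age range.  Ages outside the range are
#' clamped to the boundary (boundary-basis evaluation); the returned
#' matrix carries a `clamped` attribute flagging such rows.
#'
#' @param ages numeric vector of ages in years.
#' @param spec a locked [basis_spec()].
#' @return numeric matrix, one row per age.
#' @export
build_basis <- function(ages, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (!isTRUE(spec$locked))
    stop("basis spec must be locked on training ages first; see lock_basis()",
         call. = FALSE)
  if (length(ages) == 0L) stop("empty age vector", call. = FALSE)
  if (any(!is.finite(ages))) stop("ages must be finite", call. = FALSE)
  lo <- spec$age_range[1]; hi <- spec$age_range[2]
  clamped <- ages < lo | ages > hi
  a <- pmin(pmax(ages, lo), hi)
  if (spec$kind == "linear") {
    x <- if (spec$standardize) (a - spec$age_mean) / spec$age_sd else a
    X <- cbind(`(Intercept)` = 1, age_std = x)
  } else {
    kn <- .basis_knots(spec)
    S <- splines::bs(a, knots = kn$interior, degree = 3L,
                     intercept = TRUE, Boundary.knots = kn$boundary)
    X <- cbind(`(Intercept)` = 1, unclass(S))
    colnames(X) <- c("(Intercept)", paste0("bs", seq_len(ncol(X) - 1L)))
  }
  attr(X, "clamped") <- clamped
  X
}

#' Response standardization
#'
#' Create an invertible standardizer from training responses; slope
#' coefficients reported on the standardized age and response scales are
#' the "standardized betas" used throughout the growth-gradient
#' analyses.
#'
#' @param y_train numeric vector of training responses.
#' @return list with `center`, `scale`, and functions `transform(y)` /
#'   `inverse(y_std)`.
#' @export
response_scaler <- function(y_train) {
  if (any(!is.finite(y_train))) stop("training responses must be finite",
                                     call. = FALSE)
  ctr <- mean(y_train)
  scl <- stats::sd(y_train)
  if (is.na(scl) || scl <= 0)
    stop("training responses have zero variance", call. = FALSE)
  list(center = ctr, scale = scl,
       transform = function(y) (y - ctr) / scl,
       inverse = function(y_std) y_std * scl + ctr)
}

#' @describeIn response_scaler standardize `y` by training statistics in
#'   one call; returns `y_std` with attributes `center` and `scale`.
#' @param y responses to standardize (defaults to `y_train`).
#' @export
standardize_response <- function(y_train, y = y_train) {
  sc <- response_scaler(y_train)
  structure(sc$transform(y), center = sc$center, scale = sc$scale)
}
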