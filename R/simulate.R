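#' Configuration of the synthetic longitudinal cohort
#'
#' Captures the design of the emulated study: three measurement waves
#' with mean ages 7.9 / 10.1 / 14.0 years (hard age ranges 6.1-10.7,
#' 8.6-12.0, 12.6-17.1), subjects measured once/twice/three times in
#' proportions 56.2% / 38.0% / 5.8%, roughly half female, and scanner
#' confounded with wave (wave 1 on one scanner, waves 2-3 on its
#' successor).
#'
#' @param n_subjects number of subjects.
#' @param wave_age_means mean age per wave, strictly increasing (years).
#' @param wave_age_sds within-wave age spread (years).
#' @param wave_age_ranges 3x2 matrix of hard age bounds per wave;
#'   within-wave ages are truncated-normal draws.
#' @param visit_count_probs probabilities of 1/2/3 visits; must sum to 1.
#' @param p_female probability that a subject is female.
#' @param scanner_map character vector mapping wave 1..3 to a scanner
#'   label.
#' @param single_visit_wave_probs wave allocation for once-measured
#'   subjects (chosen to match the printed per-wave scan counts).
#' @param two_visit_late_prob probability that a twice-measured subject
#'   attends waves 2+3 (otherwise waves 1+2).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1000L,
                          wave_age_means = c(7.9, 10.1, 14.0),
                          wave_age_sds = c(1.0, 0.6, 0.8),
                          wave_age_ranges = rbind(c(6.1, 10.7),
                                                  c(8.6, 12.0),
                                                  c(12.6, 17.1)),
                          visit_count_probs = c(0.562, 0.380, 0.058),
                          p_female = 0.506,
                          scanner_map = c("MR750", "MR750w", "MR750w"),
                          single_visit_wave_probs = c(0.12, 0.60, 0.28),
                          two_visit_late_prob = 0.8,
                          seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("'n_subjects' must be a positive integer", call. = FALSE)
  if (abs(sum(visit_count_probs) - 1) > 1e-12)
    stop("'visit_count_probs' must sum to 1", call. = FALSE)
  if (any(visit_count_probs < 0))
    stop("'visit_count_probs' must be non-negative", call. = FALSE)
  if (any(diff(wave_age_means) <= 0))
    stop("'wave_age_means' must be strictly increasing", call. = FALSE)
  if (any(wave_age_sds <= 0))
    stop("'wave_age_sds' must be positive", call. = FALSE)
  if (p_female < 0 || p_female > 1)
    stop("'p_female' must lie in [0, 1]", call. = FALSE)
  if (abs(sum(single_visit_wave_probs) - 1) > 1e-12)
    stop("'single_visit_wave_probs' must sum to 1", call. = FALSE)
  if (length(scanner_map) != 3L)
    stop("'scanner_map' must map each of the 3 waves to a scanner",
         call. = FALSE)
  structure(
    list(n_subjects = n_subjects, wave_age_means = wave_age_means,
         wave_age_sds = wave_age_sds, wave_age_ranges = wave_age_ranges,
         visit_count_probs = visit_count_probs, p_female = p_female,
         scanner_map = as.character(scanner_map),
         single_visit_wave_probs = single_visit_wave_probs,
         two_visit_late_prob = two_visit_late_prob,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' ROI metadata table
#'
#' One row per measure column of the cohort: ROI name, parcellation
#' (anatomical or functional), modality (volume, GMD, WMD),
#' anterior-posterior rank, structural class, and the lobule label used
#' to pair left/right hemispheric ROIs.
#'
#' @param roi,parcellation,modality,ap_rank,class,lobule vectors of equal
#'   length (lobule defaults to the ROI name).
#' @return a `data.frame` with class `roi_info`.
#' @export
roi_info <- function(roi, parcellation, modality, ap_rank, class,
                     lobule = roi) {
  parcellation <- match.arg(parcellation, c("anatomical", "functional"),
                            several.ok = TRUE)
  modality <- match.arg(modality, c("volume", "GMD", "WMD"),
                        several.ok = TRUE)
  class <- match.arg(class, c("vermal", "hemispheric_left",
                              "hemispheric_right", "functional"),
                     several.ok = TRUE)
  out <- data.frame(roi = as.character(roi), parcellation = parcellation,
                    modality = modality, ap_rank = as.integer(ap_rank),
                    class = class, lobule = as.character(lobule),
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_info", "data.frame")
  out
}

#' Example ROI metadata
#'
#' A ready-made metadata table: either the ten functional parcels (ranks
#' 1..10, one modality) or ten anatomical lobules with a vermal and two
#' hemispheric (left/right) ROIs each.
#'
#' @param parcellation `"functional"` or `"anatomical"`.
#' @param modality measure type for functional parcels.
#' @param n_roi number of functional parcels (default 10).
#' @return a [roi_info()] table.
#' @export
example_roi_info <- function(parcellation = c("functional", "anatomical"),
                             modality = "volume", n_roi = 10L) {
  parcellation <- match.arg(parcellation)
  if (parcellation == "functional") {
    roi_info(roi = sprintf("func%02d", seq_len(n_roi)),
             parcellation = "functional", modality = modality,
             ap_rank = seq_len(n_roi), class = "functional")
  } else {
    lob <- c("III", "IV", "V", "VI", "CrusI", "CrusII", "VIIB",
             "VIIIA", "VIIIB", "IX")
    n <- length(lob)
    roi_info(
      roi = c(paste0("vermis_", lob), paste0("left_", lob),
              paste0("right_", lob)),
      parcellation = "anatomical", modality = "volume",
      ap_rank = rep(seq_len(n), 3L),
      class = rep(c("vermal", "hemispheric_left", "hemispheric_right"),
                  each = n),
      lobule = rep(lob, 3L))
  }
}

#' Batch-cell keys of a cohort configuration
#'
#' The crossed sex-by-scanner cell labels (`"sex:scanner"`) implied by
#' a [cohort_config()]'s scanner map; the naming scheme used by
#' [roi_model()] parameter vectors and by the fitted posteriors.
#'
#' @param config a [cohort_config()].
#' @return character vector of cell keys.
#' @export
batch_cell_keys <- function(config) {
  scanners <- unique(config$scanner_map)
  as.vector(outer(c("female", "male"), scanners, paste, sep = ":"))
}

# recycle a scalar or validate a named per-cell vector
.per_cell <- function(x, cells, field) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(as.numeric(x), length(cells)), cells))
  if (is.null(names(x)) || !all(cells %in% names(x)))
    stop(sprintf("'%s' must be a scalar or a vector named by batch cells (%s)",
                 field, paste(cells, collapse = ", ")), call. = FALSE)
  stats::setNames(as.numeric(x[cells]), cells)
}

#' True generative model for one ROI
#'
#' The data-generating law of a single measure column:
#' `measure = intercept_b + slope_b * age_std + scale_b * S` with `S` a
#' zero-mean unit-variance SHASHb residual and `b` the scan's batch cell
#' (sex by scanner).  Intercept, slope and scale may be scalars
#' (shared) or vectors named by batch cell (`"sex:scanner"`).
#'
#' @param info one row of a [roi_info()] table.
#' @param intercept,slope,scale per-cell generative parameters (measure
#'   units; slope per standardized-age unit); `scale` must be > 0.
#' @param epsilon,delta residual skew and tail weight (`delta` > 0).
#' @param cells batch-cell keys; defaults to the cells of the default
#'   [cohort_config()].
#' @return an object of class `true_roi_model`.
#' @export
roi_model <- function(info, intercept = 10, slope = 0.25, scale = 1.2,
                      epsilon = 0, delta = 1,
                      cells = batch_cell_keys(cohort_config())) {
  stopifnot(nrow(info) == 1L)
  sc <- .per_cell(scale, cells, "scale")
  if (any(sc <= 0)) stop("'scale' must be positive", call. = FALSE)
  if (delta <= 0) stop("'delta' must be positive", call. = FALSE)
  structure(
    list(roi = info$roi, info = info,
         intercept = .per_cell(intercept, cells, "intercept"),
         slope = .per_cell(slope, cells, "slope"),
         scale = sc, epsilon = epsilon, delta = delta, cells = cells),
    class = "true_roi_model")
}

#' Default ROI models for an ROI metadata table
#'
#' Builds one [roi_model()] per metadata row with realistic batch
#' structure: males slightly larger, a small offset on the later
#' scanner, standardized-age slopes around 0.25 measure units, and a
#' mildly skewed SHASHb residual.
#'
#' @param info a [roi_info()] table.
#' @param base_intercept,sex_effect,scanner_effect,base_slope,scale,epsilon,delta
#'   generative parameters shared across ROIs.
#' @param config the [cohort_config()] supplying scanner labels.
#' @return list of `true_roi_model`, one per ROI.
#' @export
example_roi_models <- function(info, base_intercept = 10,
                               sex_effect = 0.5, scanner_effect = 0.3,
                               base_slope = 0.25, scale = 1.2,
                               epsilon = 0.1, delta = 1.05,
                               config = cohort_config()) {
  cells <- batch_cell_keys(config)
  sex <- sub(":.*$", "", cells)
  scn <- sub("^.*:", "", cells)
  icpt <- base_intercept + ifelse(sex == "male", sex_effect, 0) +
    ifelse(scn == config$scanner_map[1], 0, scanner_effect)
  names(icpt) <- cells
  lapply(seq_len(nrow(info)), function(i)
    roi_model(info[i, , drop = FALSE], intercept = icpt,
              slope = base_slope, scale = scale, epsilon = epsilon,
              delta = delta, cells = cells))
}

# truncated-normal draws via inverse-CDF
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate a longitudinal cohort
#'
#' Draws per-subject visit counts and contiguous wave patterns, ages
#' (truncated normal within each wave's hard range), sex, and the
#' wave-determined scanner, then generates every ROI measure from its
#' [roi_model()].  Age is standardized with the generated cohort's own
#' mean/sd (recorded as attributes), mirroring how standardized
#' coefficients are reported.
#'
#' @param config a [cohort_config()].
#' @param models list of [roi_model()] objects (at least one).
#' @return long-format `data.frame`, one row per scan, with columns
#'   `subject_id`, `wave`, `age`, `sex`, `scanner` and one column per
#'   ROI; attributes `age_mean`, `age_sd`, `seed`.
#' @export
simulate_cohort <- function(config, models) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(models) < 1L)
    stop("at least one ROI model is required", call. = FALSE)
  if (inherits(models, "true_roi_model")) models <- list(models)
  set.seed(config$seed)
  n <- config$n_subjects
  nv <- sample.int(3L, n, replace = TRUE, prob = config$visit_count_probs)
  waves <- lapply(seq_len(n), function(i) {
    switch(nv[i],
           sample.int(3L, 1L, prob = config$single_visit_wave_probs),
           if (stats::runif(1) < config$two_visit_late_prob) c(2L, 3L)
           else c(1L, 2L),
           1:3)
  })
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  subj <- rep(seq_len(n), lengths(waves))
  wave <- unlist(waves)
  age <- numeric(length(wave))
  for (w in 1:3) {
    idx <- which(wave == w)
    age[idx] <- .rtruncnorm(length(idx), config$wave_age_means[w],
                            config$wave_age_sds[w],
                            config$wave_age_ranges[w, 1],
                            config$wave_age_ranges[w, 2])
  }
  rec <- data.frame(subject_id = sprintf("sub%05d", subj),
                    wave = wave, age = age, sex = sex[subj],
                    scanner = config$scanner_map[wave],
                    stringsAsFactors = FALSE)
  age_mean <- mean(rec$age)
  age_sd <- stats::sd(rec$age)
  age_std <- (rec$age - age_mean) / age_sd
  cell <- paste(rec$sex, rec$scanner, sep = ":")
  for (m in models) {
    if (!all(cell %in% m$cells))
      stop(sprintf("ROI model '%s' lacks batch cells: %s", m$roi,
                   paste(setdiff(unique(cell), m$cells), collapse = ", ")),
           call. = FALSE)
    resid <- rshashb(nrow(rec), 0, 1, m$epsilon, m$delta)
    rec[[m$roi]] <- m$intercept[cell] + m$slope[cell] * age_std +
      m$scale[cell] * resid
  }
  attr(rec, "age_mean") <- age_mean
  attr(rec, "age_sd") <- age_sd
  attr(rec, "seed") <- config$seed
  rec
}

#' Inject an anterior-posterior slope gradient
#'
#' Sets the growth slope of the ROI with AP rank `r` to
#' `base_slope + increment * r` in every batch cell, producing a cohort
#' whose true standardized-age effects increase (or decrease) linearly
#' from anterior to posterior.
#'
#' @param models list of [roi_model()]; AP ranks must be distinct.
#' @param base_slope slope at rank 0 (measure units per standardized
#'   age).
#' @param increment slope change per rank unit.
#' @return the model list with modified slopes.
#' @export
inject_gradient <- function(models, base_slope, increment) {
  ranks <- vapply(models, function(m) m$info$ap_rank, integer(1))
  if (anyDuplicated(ranks))
    stop("AP ranks must be distinct across models", call. = FALSE)
  lapply(models, function(m) {
    m$slope[] <- base_slope + increment * m$info$ap_rank
    m
  })
}

#' Flag a high-trait subgroup and shift its measures
#'
#' Randomly flags a fraction of subjects (sampling without replacement)
#' and shifts all their scans' measures on the selected ROIs by
#' `volume_shift` times the generative residual scale of the scan's
#' batch cell, emulating a subgroup with systematically smaller (or
#' larger) morphometrics.
#'
#' @param records cohort from [simulate_cohort()].
#' @param models the generating [roi_model()] list (provides per-cell
#'   scales).
#' @param fraction fraction of subjects to flag, in \[0, 1\].
#' @param volume_shift shift in residual-SD units (negative = smaller).
#' @param rois ROI names to shift (default: all modelled ROIs).
#' @param seed RNG seed for the subject draw.
#' @return `records` with an added logical column `high_trait`.
#' @export
tag_high_trait_subgroup <- function(records, models, fraction,
                                    volume_shift, rois = NULL,
                                    seed = 1L) {
  if (fraction < 0 || fraction > 1)
    stop("'fraction' must lie in [0, 1]", call. = FALSE)
  if (inherits(models, "true_roi_model")) models <- list(models)
  if (is.null(rois)) rois <- vapply(models, `[[`, "", "roi")
  subjects <- unique(records$subject_id)
  set.seed(seed)
  n_flag <- round(fraction * length(subjects))
  flagged <- sample(subjects, n_flag)
  records$high_trait <- records$subject_id %in% flagged
  cell <- paste(records$sex, records$scanner, sep = ":")
  for (m in models) {
    if (!m$roi %in% rois) next
    idx <- records$high_trait
    records[[m$roi]][idx] <- records[[m$roi]][idx] +
      volume_shift * m$scale[cell[idx]]
  }
  records
}
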