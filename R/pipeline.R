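#' Run the full normative-modelling pipeline
#'
#' Orchestrates the analysis end to end: split the cohort at the
#' subject level, fit the hierarchical SHASHb normative model per ROI
#' on the training half, write a convergence report, score batch-free
#' deviations on the test half, run the anterior-posterior gradient
#' analysis on the per-sex standardized slopes, and (when a
#' `high_trait` flag is present) compare extreme-deviation rates
#' between the flagged subgroup and the remainder.  Every artifact is
#' written as TSV into `out_dir` together with a JSON snapshot of the
#' configuration and seed.
#'
#' @param cohort cohort data.frame or path to a cohort TSV.
#' @param info [roi_info()] table or path to a metadata TSV.
#' @param out_dir output directory (created if needed).
#' @param hbr an [hbr_config()]; its seed is re-derived per ROI from
#'   `seed` so every stage is reproducible from the one global seed.
#' @param rois ROI columns to model (default: all metadata ROIs present
#'   in the cohort).
#' @param split_prop training proportion of the subject-level split.
#' @param do_gradient,do_groups,do_loo stage toggles; LOO refits each
#'   ROI with a cubic B-spline basis and compares by PSIS-LOO.
#' @param seed global pipeline seed.
#' @return (invisibly) a list with the in-memory results: `fits`,
#'   `convergence`, `deviations`, `slopes`, `gradient`, `groups`,
#'   `loo`.
#' @export
run_pipeline <- function(cohort, info, out_dir, hbr = hbr_config(),
                         rois = NULL, split_prop = 0.5,
                         do_gradient = TRUE, do_groups = TRUE,
                         do_loo = FALSE, seed = 1L) {
  t_start <- Sys.time()
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(info)) info <- read_roi_info(info)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, roi, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed%s: %s", name,
                   if (is.null(roi)) "" else sprintf(" for ROI '%s'", roi),
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.null(rois)) rois <- intersect(info$roi, names(cohort))
  if (!length(rois)) stop("no metadata ROI found in the cohort",
                          call. = FALSE)
  logf("pipeline start: %d scans, %d ROIs, seed %d", nrow(cohort),
       length(rois), seed)

  sp <- stage("split", NULL, split_cohort(cohort, split_prop, seed))
  logf("split: %d train / %d test scans", nrow(sp$train), nrow(sp$test))

  fits <- list()
  loo_rows <- list()
  slope_rows <- list()
  conv_rows <- list()
  dev_list <- list()
  for (i in seq_along(rois)) {
    roi <- rois[i]
    cfg <- hbr
    cfg$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    t0 <- Sys.time()
    fit <- stage("fit", roi, fit_normative(sp$train, roi, cfg))
    fits[[roi]] <- fit
    cv <- check_convergence(fit)
    conv_rows[[roi]] <- data.frame(
      roi = roi, frac_rhat_ok = cv$fraction,
      max_rhat = max(cv$rhat, na.rm = TRUE),
      divergences = sum(fit$divergences),
      stringsAsFactors = FALSE)
    dev_list[[roi]] <- stage("deviate", roi,
                             score_deviations(fit, sp$test))
    if (fit$basis$kind == "linear") {
      sl <- stage("slopes", roi, summarize_slope(fit))
      for (sx in names(sl$by_sex))
        slope_rows[[paste(roi, sx)]] <- data.frame(
          roi = roi, sex = sx, slope = sl$by_sex[[sx]]$mean,
          slope_sd = sl$by_sex[[sx]]$sd, stringsAsFactors = FALSE)
    }
    if (do_loo) {
      cfg_bs <- cfg
      cfg_bs$basis <- basis_spec("bspline3")
      fit_bs <- stage("fit-spline", roi,
                      fit_normative(sp$train, roi, cfg_bs))
      cmp <- stage("loo", roi, compare_loo(fit, fit_bs))
      loo_rows[[roi]] <- data.frame(
        roi = roi, elpd_linear = cmp$elpd_a, elpd_spline = cmp$elpd_b,
        elpd_diff = cmp$elpd_diff, se_diff = cmp$se_diff,
        equal = cmp$equal, stringsAsFactors = FALSE)
    }
    logf("ROI %s done in %.1fs (max R-hat %.3f)", roi,
         as.numeric(difftime(Sys.time(), t0, units = "secs")),
         max(cv$rhat, na.rm = TRUE))
  }
  convergence <- do.call(rbind, conv_rows)
  utils::write.table(convergence, file.path(out_dir, "convergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  deviations <- do.call(rbind, dev_list)
  rownames(deviations) <- NULL
  utils::write.table(deviations, file.path(out_dir, "deviations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  slopes <- if (length(slope_rows)) do.call(rbind, slope_rows) else NULL
  if (!is.null(slopes)) {
    rownames(slopes) <- NULL
    utils::write.table(slopes, file.path(out_dir, "slopes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  gradient <- NULL
  if (do_gradient && !is.null(slopes)) {
    gradient <- stage("gradient", NULL,
                      ap_gradient_analysis(slopes, info))
    utils::write.table(gradient, file.path(out_dir, "gradient.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("gradient: %d family tests", nrow(gradient))
  }

  groups <- NULL
  if (do_groups && "high_trait" %in% names(cohort)) {
    thr <- attr(dev_list[[1L]], "threshold")
    dev_all <- deviations
    attr(dev_all, "threshold") <- thr
    groups <- stage("compare", NULL, compare_groups(dev_all))
    utils::write.table(groups, file.path(out_dir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("groups: %d comparisons", nrow(groups))
  }

  loo <- if (length(loo_rows)) do.call(rbind, loo_rows) else NULL
  if (!is.null(loo))
    utils::write.table(loo, file.path(out_dir, "loo.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  snapshot <- list(seed = seed, split_prop = split_prop, rois = rois,
                   do_gradient = do_gradient, do_groups = do_groups,
                   do_loo = do_loo,
                   hbr = list(n_chains = hbr$n_chains,
                              n_samples = hbr$n_samples,
                              n_tune = hbr$n_tune,
                              basis = hbr$basis$kind,
                              batch_vars = hbr$batch_vars,
                              parameterization = hbr$parameterization))
  jsonlite::write_json(snapshot, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("pipeline finished in %.1fs",
       as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  invisible(list(fits = fits, convergence = convergence,
                 deviations = deviations, slopes = slopes,
                 gradient = gradient, groups = groups, loo = loo))
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands used by the
#' `inst/scripts/cerebnorm-cli.R` wrapper: `simulate` (write a synthetic
#' cohort and its ROI metadata), `run-all` (full pipeline on a cohort
#' file), `gradient` (AP analysis from a slopes TSV), `compare`
#' (group comparison from a deviations TSV) and `report` (summarize an
#' output directory).  All subcommands accept `--seed`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: cerebnorm <simulate|run-all|gradient|compare|report>",
        "[options]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- .parse_cli(args[-1L])
  seed <- as.integer(.opt(opt, "seed", 1))
  switch(cmd,
    simulate = {
      n <- as.integer(.opt(opt, "n-subjects", 500))
      out <- .opt(opt, "out", "cohort.tsv")
      out_roi <- .opt(opt, "out-roi", "roi_info.tsv")
      info <- example_roi_info("functional")
      cfg <- cohort_config(n_subjects = n, seed = seed)
      models <- inject_gradient(example_roi_models(info, config = cfg),
                                base_slope = 0.1, increment = 0.02)
      rec <- simulate_cohort(cfg, models)
      write_cohort(rec, out)
      write_roi_info(info, out_roi)
      cat(sprintf("wrote %s (%d scans) and %s\n", out, nrow(rec),
                  out_roi))
    },
    `run-all` = {
      hbr <- hbr_config(
        n_chains = as.integer(.opt(opt, "chains", 4)),
        n_samples = as.integer(.opt(opt, "samples", 2000)),
        n_tune = as.integer(.opt(opt, "tune", 500)))
      run_pipeline(.opt(opt, "cohort", "cohort.tsv"),
                   .opt(opt, "roi-info", "roi_info.tsv"),
                   .opt(opt, "out", "cerebnorm_out"), hbr = hbr,
                   do_loo = isTRUE(as.logical(.opt(opt, "loo", FALSE))),
                   seed = seed)
      cat(sprintf("pipeline output in %s\n",
                  .opt(opt, "out", "cerebnorm_out")))
    },
    gradient = {
      slopes <- utils::read.table(.opt(opt, "slopes", "slopes.tsv"),
                                  header = TRUE, sep = "\t")
      info <- read_roi_info(.opt(opt, "roi-info", "roi_info.tsv"))
      res <- ap_gradient_analysis(slopes, info)
      utils::write.table(res, .opt(opt, "out", "gradient.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      print(res)
    },
    compare = {
      dev <- utils::read.table(.opt(opt, "deviations", "deviations.tsv"),
                               header = TRUE, sep = "\t")
      attr(dev, "threshold") <- as.numeric(.opt(opt, "threshold", 1.96))
      res <- compare_groups(dev)
      utils::write.table(res, .opt(opt, "out", "groups.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      print(res)
    },
    report = {
      dir <- .opt(opt, "dir", "cerebnorm_out")
      for (f in c("convergence.tsv", "gradient.tsv", "groups.tsv")) {
        p <- file.path(dir, f)
        if (file.exists(p)) {
          cat("==", f, "==\n")
          print(utils::read.table(p, header = TRUE, sep = "\t"))
        }
      }
    },
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE))
  invisible(0L)
}

.parse_cli <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opt[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opt[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  opt
}

.opt <- function(opt, key, default) {
  if (!is.null(opt[[key]])) opt[[key]] else default
}
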