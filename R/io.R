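#' Read and write long-format cohort tables
#'
#' The cohort file is a tab-separated table with one row per scan,
#' columns `subject_id`, `wave`, `age`, `sex`, `scanner`, optionally
#' `high_trait`, and one numeric column per ROI measure.  A leading
#' `#`-comment line records the generator seed and the cohort age
#' standardization statistics.  Comma-separated files are accepted on
#' read (the separator is sniffed from the header line).
#'
#' @param records cohort data.frame (from [simulate_cohort()] or
#'   equivalent).
#' @param path file path.
#' @return `read_cohort` returns the typed cohort data.frame with
#'   `age_mean` / `age_sd` / `seed` attributes when present in the
#'   header comment.
#' @export
write_cohort <- function(records, path) {
  hdr <- sprintf("# cerebnorm cohort seed=%s age_mean=%s age_sd=%s",
                 .attr_or(records, "seed", "NA"),
                 .attr_or(records, "age_mean", "NA"),
                 .attr_or(records, "age_sd", "NA"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.attr_or <- function(x, name, default) {
  v <- attr(x, name)
  if (is.null(v)) default else format(v, digits = 17)
}

.sniff_sep <- function(line) if (grepl("\t", line)) "\t" else ","

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, n = 50L)
  n_comment <- 0L
  while (n_comment < length(lines) &&
         startsWith(lines[n_comment + 1L], "#")) n_comment <- n_comment + 1L
  sep <- .sniff_sep(lines[n_comment + 1L])
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("subject_id", "age", "sex", "scanner", "wave")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  special <- c(required, "high_trait")
  for (cn in setdiff(names(df), special)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (any(is.na(v) & !is.na(df[[cn]])))
      stop(sprintf("non-numeric measure in column '%s', row %d", cn,
                   which(is.na(v) & !is.na(df[[cn]]))[1L]),
           call. = FALSE)
    df[[cn]] <- v
  }
  if ("high_trait" %in% names(df))
    df$high_trait <- as.logical(df$high_trait)
  if (n_comment > 0L) {
    hdr <- lines[1L]
    for (key in c("seed", "age_mean", "age_sd")) {
      m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1L]]
      if (length(m) == 2L && m[2] != "NA")
        attr(df, key) <- as.numeric(m[2])
    }
  }
  df
}

#' Read and write ROI metadata tables
#'
#' Tab-separated with columns `roi`, `parcellation`, `modality`,
#' `ap_rank`, `class` and optionally `lobule` (defaults to `roi`).
#'
#' @param info a [roi_info()] table.
#' @param path file path.
#' @export
write_roi_info <- function(info, path) {
  utils::write.table(info, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_info
#' @export
read_roi_info <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.table(path, header = TRUE, sep = .sniff_sep(first),
                          comment.char = "#", stringsAsFactors = FALSE)
  required <- c("roi", "parcellation", "modality", "ap_rank", "class")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("ROI metadata file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"lobule" %in% names(df)) df$lobule <- df$roi
  roi_info(df$roi, df$parcellation, df$modality, df$ap_rank, df$class,
           df$lobule)
}

#' Persist and reload a fitted normative model
#'
#' The model is written as a directory of plain-text files: the
#' configuration and metadata as JSON (basis spec, response scaler,
#' batch cells, diagnostics) and the posterior draws as a columnar TSV
#' (`chain`, `iter`, one column per named parameter), so that a reloaded
#' model scores deviations bit-identically.  Pointwise log-likelihoods
#' are not persisted.
#'
#' @param posterior a [fit_normative()] result.
#' @param dir target directory (created if needed).
#' @return `load_normative` returns the restored `normative_posterior`.
#' @export
save_normative <- function(posterior, dir) {
  stopifnot(inherits(posterior, "normative_posterior"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    roi = posterior$roi, cells = posterior$cells,
    cell_counts = posterior$cell_counts,
    batch_vars = posterior$config$batch_vars,
    scaler = posterior$scaler,
    basis = unclass(posterior$basis),
    n_chains = posterior$n_chains, n_keep = posterior$n_keep,
    n_train = posterior$n_train,
    accept_rate = posterior$accept_rate,
    divergences = posterior$divergences,
    config = list(n_chains = posterior$config$n_chains,
                  n_samples = posterior$config$n_samples,
                  n_tune = posterior$config$n_tune,
                  seed = posterior$config$seed,
                  batch_vars = posterior$config$batch_vars,
                  parameterization = posterior$config$parameterization))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  d <- .pooled_draws(posterior)
  tab <- data.frame(chain = rep(seq_len(posterior$n_chains),
                                each = posterior$n_keep),
                    iter = rep(seq_len(posterior$n_keep),
                               posterior$n_chains))
  tab <- cbind(tab, as.data.frame(d, check.names = FALSE))
  utils::write.table(tab, file.path(dir, "draws.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  conv <- data.frame(parameter = names(posterior$rhat),
                     rhat = unname(posterior$rhat))
  utils::write.table(conv, file.path(dir, "convergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_normative
#' @export
load_normative <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  tab <- utils::read.table(file.path(dir, "draws.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  pars <- setdiff(names(tab), c("chain", "iter"))
  n_keep <- meta$n_keep
  n_chains <- meta$n_chains
  tr <- array(NA_real_, c(n_keep, n_chains, length(pars)),
              dimnames = list(NULL, NULL, pars))
  for (ch in seq_len(n_chains))
    tr[, ch, ] <- as.matrix(tab[tab$chain == ch, pars])
  basis <- structure(meta$basis, class = "basis_spec")
  basis$age_range <- as.numeric(basis$age_range)
  cfg <- hbr_config(n_chains = meta$config$n_chains,
                    n_samples = meta$config$n_samples,
                    n_tune = meta$config$n_tune,
                    seed = meta$config$seed, basis = basis,
                    batch_vars = meta$config$batch_vars,
                    parameterization = meta$config$parameterization)
  rhat <- apply(tr, 3, split_rhat)
  names(rhat) <- pars
  structure(
    list(roi = meta$roi, draws = tr, rhat = rhat, cells = meta$cells,
         cell_counts = meta$cell_counts,
         cell_info = .cell_table(meta$cells, meta$batch_vars),
         basis = basis,
         scaler = list(center = meta$scaler$center,
                       scale = meta$scaler$scale),
         config = cfg, n_chains = n_chains, n_keep = n_keep,
         n_train = meta$n_train, accept_rate = meta$accept_rate,
         divergences = meta$divergences,
         div_frac = sum(meta$divergences) / (n_keep * n_chains),
         divergent_flag = sum(meta$divergences) /
           (n_keep * n_chains) > 0.05,
         loglik = NULL),
    class = "normative_posterior")
}

#' Subject-level stratified train/test split
#'
#' Splits the cohort at the subject level (all scans of a subject stay
#' together, preventing longitudinal leakage), stratified on sex
#' crossed with the subject's set of scanners so both halves carry all
#' batch cells in near-equal proportion.
#'
#' @param records cohort data.frame.
#' @param prop training proportion (default 0.5).
#' @param seed RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_cohort <- function(records, prop = 0.5, seed = 1L) {
  if (prop <= 0 || prop >= 1)
    stop("'prop' must lie strictly within (0, 1)", call. = FALSE)
  subj <- unique(records$subject_id)
  strat <- vapply(split(records, records$subject_id), function(df)
    paste(df$sex[1L],
          paste(sort(unique(df$scanner)), collapse = "+"), sep = ":"),
    character(1))
  strat <- strat[subj]
  set.seed(seed)
  train_ids <- unlist(lapply(split(subj, strat), function(ids) {
    n_tr <- round(prop * length(ids))
    sample(ids, n_tr)
  }), use.names = FALSE)
  in_train <- records$subject_id %in% train_ids
  out <- list(train = records[in_train, , drop = FALSE],
              test = records[!in_train, , drop = FALSE])
  for (nm in c("age_mean", "age_sd", "seed")) {
    attr(out$train, nm) <- attr(records, nm)
    attr(out$test, nm) <- attr(records, nm)
  }
  out
}
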