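#' Pipeline configuration
#'
#' Collects every tunable of the subject-level pipeline in one place.
#' The defaults are the constants of the published analysis: a 200-
#' breath pre-peak window, an AR(6) filter with removal threshold 0.8,
#' and two-level (95%/99%) white-noise screening of the IMFs.
#'
#' @param k pre-peak window length in breaths.
#' @param ar_order AR model order.
#' @param ar_threshold removal threshold on observed/predicted VE.
#' @param sd_stop EMD sifting stop tolerance.
#' @param max_imfs cap on extracted IMFs.
#' @param max_sift cap on sifting iterations per IMF.
#' @param prominence_frac peak-count prominence threshold (fraction of
#'   RMS).
#' @param levels significance confidence levels.
#' @param n_null Monte-Carlo realisations for the white-noise null.
#' @param seed root RNG seed; all pipeline randomness derives from it.
#' @param variant t-test variant for the cohort comparison.
#' @param allow_short allow windows shorter than `k` breaths.
#' @return Object of class `pipeline_config` (validated list).
#' @export
pipeline_config <- function(k = 200L, ar_order = 6L, ar_threshold = 0.8,
                            sd_stop = 0.2, max_imfs = 10L,
                            max_sift = 50L, prominence_frac = 0.5,
                            levels = c(0.95, 0.99), n_null = 1000L,
                            seed = 1L, variant = "pooled",
                            allow_short = FALSE) {
  cfg <- list(k = as.integer(k), ar_order = as.integer(ar_order),
              ar_threshold = ar_threshold, sd_stop = sd_stop,
              max_imfs = as.integer(max_imfs),
              max_sift = as.integer(max_sift),
              prominence_frac = prominence_frac, levels = levels,
              n_null = as.integer(n_null), seed = as.integer(seed),
              variant = variant, allow_short = isTRUE(allow_short))
  for (f in c("k", "ar_order", "n_null", "max_imfs", "max_sift"))
    if (cfg[[f]] <= 0L)
      stop(sprintf("config field '%s' must be positive", f),
           call. = FALSE)
  for (f in c("sd_stop", "prominence_frac"))
    if (cfg[[f]] <= 0)
      stop(sprintf("config field '%s' must be positive", f),
           call. = FALSE)
  if (cfg$ar_threshold <= 0 || cfg$ar_threshold >= 1)
    stop("config field 'ar_threshold' must lie in (0, 1)",
         call. = FALSE)
  if (!cfg$variant %in% c("pooled", "welch"))
    stop("config field 'variant' must be 'pooled' or 'welch'",
         call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration file
#'
#' A minimal `key: value` format (one pair per line, `#` comments);
#' vector values are comma-separated.  Round-trips losslessly through
#' [write_config()] / [read_config()].
#'
#' @param path file path.
#' @return [read_config()]: a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")),
                 character(1))
  defaults <- pipeline_config()
  args <- list()
  for (i in seq_along(keys)) {
    key <- keys[i]
    if (!key %in% names(unclass(defaults)))
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    args[[key]] <- if (key == "variant") v
                   else if (key == "allow_short") as.logical(v)
                   else as.numeric(v)
  }
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  fmt <- function(v) paste(vapply(v, function(x)
    format(x, scientific = FALSE, trim = TRUE), character(1)),
    collapse = ",")
  lines <- vapply(names(unclass(config)), function(k)
    sprintf("%s: %s", k, fmt(config[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis for one subject
#'
#' Applies the stages in order: pre-peak window + AR gasp filter
#' ([filter_mee()]), EMD ([emd()]), white-noise screening
#' ([test_imfs()]), and peak-count features
#' ([features_for_subject()]).  When `outdir` is given every
#' intermediate is persisted as CSV.
#'
#' @param series a [breath_series()].
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for intermediates.
#' @param null optional precomputed [null_ensemble()] (reused across
#'   subjects of a cohort when window lengths match).
#' @param with_significance if `FALSE`, skip the Monte-Carlo white-noise
#'   screening (the feature path does not depend on it).
#' @param verbose log stage progress to stderr.
#' @return List with elements `meeve` (`meeve_result`), `imfs`
#'   (`imf_set`), `significance` (`significance_result`, or `NULL`
#'   when skipped), `features` (`feature_vector`).
#' @export
run_subject <- function(series, config = pipeline_config(),
                        outdir = NULL, null = NULL,
                        with_significance = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  sid <- series$subject_id
  log_msg <- function(...) if (verbose)
    message(sprintf("[%s] ", sid), sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("subject %s failed at stage '%s': %s", sid, name,
                   conditionMessage(e)), call. = FALSE))
  }
  log_msg("filter: n=%d, k=%d, AR(%d), threshold=%.2f",
          length(series$ve), config$k, config$ar_order,
          config$ar_threshold)
  mee <- stage("filter",
               filter_mee(series, k = config$k, p = config$ar_order,
                          threshold = config$ar_threshold,
                          allow_short = config$allow_short))
  log_msg("decompose: %d kept breaths", length(mee$kept))
  imfs <- stage("decompose",
                emd(mee$kept, max_imfs = config$max_imfs,
                    sd_stop = config$sd_stop,
                    max_sift = config$max_sift))
  sig <- NULL
  if (with_significance) {
    log_msg("significance: %d IMFs, n_null=%d", imfs$n, config$n_null)
    sig <- stage("significance",
                 test_imfs(imfs, levels = config$levels,
                           n_null = config$n_null, seed = config$seed,
                           null = null))
  }
  feat <- stage("features",
                features_for_subject(imfs, subject_id = sid,
                                     label = series$label,
                                     prominence_frac =
                                       config$prominence_frac))
  log_msg("features: %s", paste(feat$deltas, collapse = " "))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_meeve_csv(mee, file.path(outdir,
                                   paste0(sid, "_meeve.csv")))
    write_imf_csv(imfs, file.path(outdir, paste0(sid, "_imfs.csv")))
    if (!is.null(sig))
      write_significance_csv(sig, file.path(outdir,
                                            paste0(sid, "_significance.csv")))
    utils::write.csv(data.frame(feature = names(feat$deltas),
                                value = as.integer(feat$deltas)),
                     file.path(outdir, paste0(sid, "_features.csv")),
                     row.names = FALSE)
  }
  list(meeve = mee, imfs = imfs, significance = sig, features = feat)
}

#' Run the analysis for a whole cohort and compare groups
#'
#' Runs [run_subject()] for every manifest entry and compares the PB
#' and non-PB peak-count features with [compare_cohorts()].  Subjects
#' that fail a stage are excluded with a warning rather than aborting
#' the cohort; the run errors only if no subject survives.  One
#' white-noise null is computed per distinct MEE-Ve length and reused.
#'
#' @param manifest a `cohort_manifest` from [read_manifest()], or a
#'   list of [breath_series()] objects.
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param with_significance if `FALSE`, skip the white-noise screening
#'   for every subject (much faster; the group comparison is
#'   unaffected).
#' @param verbose log progress to stderr.
#' @return List with `comparison` (`group_comparison`), `features`
#'   (list of `feature_vector`), `results` (per-subject pipeline
#'   outputs), `excluded` (data.frame of failed subjects and reasons).
#' @export
run_cohort <- function(manifest, config = pipeline_config(),
                       outdir = NULL, with_significance = TRUE,
                       verbose = FALSE) {
  if (inherits(manifest, "cohort_manifest")) {
    if (nrow(manifest) == 0L)
      stop("empty manifest", call. = FALSE)
    loaders <- lapply(seq_len(nrow(manifest)), function(i)
      function() read_series(manifest$path[i],
                             subject_id = manifest$subject_id[i],
                             label = manifest$label[i]))
  } else if (is.list(manifest) && length(manifest) &&
             all(vapply(manifest, inherits, logical(1),
                        "breath_series"))) {
    loaders <- lapply(manifest, function(s) function() s)
  } else stop("empty manifest", call. = FALSE)

  nulls <- list()       # cache of null_curves keyed by series length
  results <- list()
  excluded <- data.frame(subject_id = character(0),
                         reason = character(0))
  for (i in seq_along(loaders)) {
    res <- tryCatch({
      series <- loaders[[i]]()
      null <- NULL
      if (with_significance) {
        mee_len <- length(filter_mee(series, k = config$k,
                                     p = config$ar_order,
                                     threshold = config$ar_threshold,
                                     allow_short = config$allow_short)$kept)
        key <- as.character(mee_len)
        if (is.null(nulls[[key]]))
          nulls[[key]] <- null_ensemble(mee_len,
                                        n_null = config$n_null,
                                        seed = config$seed,
                                        levels = config$levels)
        null <- nulls[[key]]
      }
      run_subject(series, config, outdir = outdir, null = null,
                  with_significance = with_significance,
                  verbose = verbose)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("excluding subject %d: %s", i,
                      conditionMessage(res)), call. = FALSE)
      excluded <- rbind(excluded,
                        data.frame(subject_id = as.character(i),
                                   reason = conditionMessage(res)))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (!length(results))
    stop("all subjects failed; nothing to compare", call. = FALSE)
  features <- lapply(results, `[[`, "features")
  comparison <- compare_cohorts(features, variant = config$variant)
  if (!is.null(outdir))
    utils::write.csv(as.data.frame(comparison),
                     file.path(outdir, "comparison.csv"),
                     row.names = FALSE)
  list(comparison = comparison, features = features,
       results = results, excluded = excluded)
}

# --- CSV writers for intermediates -----------------------------------

write_meeve_csv <- function(mee, path) {
  n <- length(mee$kept)
  lines <- c("breath_index,time_s,ve_l_min",
             if (n > 0)
               sprintf("%d,%.6f,%.6f", 0:(n - 1L), as.numeric(0:(n - 1L)),
                       mee$kept))
  writeLines(lines, path)
  # companion removal report
  rpt <- sub("\\.csv$", "_removed.csv", path)
  p <- mee$model$p
  rem <- mee$removed_indices
  df <- data.frame(window_index = rem - 1L,
                   y = mee$window_ve[rem],
                   yhat = if (length(rem)) mee$predictions[rem - p]
                          else numeric(0))
  utils::write.csv(df, rpt, row.names = FALSE)
  invisible(path)
}

write_imf_csv <- function(imfs, path) {
  df <- as.data.frame(imfs$imfs)
  df$residue <- imfs$residue
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_imf_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot("residue" %in% names(df))
  icols <- grep("^imf", names(df), value = TRUE)
  m <- as.matrix(df[icols])
  structure(list(imfs = m, residue = df$residue, n = length(icols)),
            class = "imf_set")
}

write_significance_csv <- function(sig, path) {
  df <- sig$summaries
  for (l in seq_along(sig$levels))
    df[[paste0("flag", sub("^0\\.", "", sprintf("%g", sig$levels[l])))]] <-
      sig$flags[, l]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
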