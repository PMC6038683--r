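#' Read a breath-by-breath ventilation series from CSV
#'
#' The dialect is fixed: header exactly
#' `breath_index,time_s,ve_l_min`, with `breath_index` contiguous from
#' 0, `time_s` strictly increasing and `ve_l_min` strictly positive.
#' Readers never silently drop rows: any violation raises a diagnostic
#' naming the offending row.
#'
#' @param path CSV file path.
#' @param subject_id identifier for the returned series; defaults to the
#'   file name without extension.
#' @param label group label to attach (`"PB"`, `"nPB"`, `"unknown"`).
#' @return A [breath_series()].
#' @export
read_series <- function(path, subject_id = NULL, label = "unknown") {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "breath_index,time_s,ve_l_min"))
    stop(sprintf("malformed header in %s: expected 'breath_index,time_s,ve_l_min', got '%s'",
                 path, header), call. = FALSE)
  df <- utils::read.csv(path, colClasses = c("integer", "numeric",
                                             "numeric"))
  n <- nrow(df)
  if (n > 0L && !identical(df$breath_index, 0:(n - 1L)))
    stop(sprintf("breath_index must be contiguous 0..%d in %s",
                 n - 1L, path), call. = FALSE)
  bad_ve <- which(!is.finite(df$ve_l_min) | df$ve_l_min <= 0)
  if (length(bad_ve))
    stop(sprintf("non-positive ve_l_min at row %d of %s",
                 bad_ve[1], path), call. = FALSE)
  if (n > 1L) {
    bad_t <- which(diff(df$time_s) <= 0)
    if (length(bad_t))
      stop(sprintf("time_s not strictly increasing at row %d of %s",
                   bad_t[1] + 1L, path), call. = FALSE)
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  breath_series(df$time_s, df$ve_l_min, subject_id = subject_id,
                label = label)
}

#' Write a breath series to CSV
#'
#' Inverse of [read_series()]: writes the fixed header and one row per
#' breath with VE printed to 6 decimal places, so write-then-read is the
#' identity to that precision.
#'
#' @param series a [breath_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "breath_series"))
  n <- length(series$ve)
  lines <- c("breath_index,time_s,ve_l_min",
             if (n > 0L)
               sprintf("%d,%.6f,%.6f", 0:(n - 1L), series$times,
                       series$ve))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest maps subjects to group labels and series files.  Header:
#' `subject_id,label,path`.  Labels are matched case-insensitively and
#' normalized to `PB` / `nPB`; relative paths are resolved against the
#' manifest's own directory.
#'
#' @param path manifest CSV path.
#' @return An object of class `cohort_manifest`: a data.frame with
#'   columns `subject_id`, `label`, `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "subject_id,label,path"))
    stop(sprintf("malformed manifest header in %s: expected 'subject_id,label,path'",
                 path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop(sprintf("duplicate subject_id in manifest: %s", dup[1]),
         call. = FALSE)
  norm <- c(pb = "PB", npb = "nPB", "non-pb" = "nPB", nonpb = "nPB")
  key <- tolower(trimws(df$label))
  unknown <- setdiff(unique(key), names(norm))
  if (length(unknown))
    stop(sprintf("unknown label '%s' in manifest (expected PB or nPB)",
                 unknown[1]), call. = FALSE)
  df$label <- unname(norm[key])
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(base, df$path[rel])
  structure(df, class = c("cohort_manifest", "data.frame"))
}

#' Write a cohort manifest
#'
#' @param entries data.frame with columns `subject_id`, `label`, `path`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  stopifnot(all(c("subject_id", "label", "path") %in% names(entries)))
  utils::write.csv(entries[c("subject_id", "label", "path")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
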