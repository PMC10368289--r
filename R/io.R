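# Serialization: abundance tables and configurations travel as two-column
# CSV (variant_id, count); diversity profiles and training sets as wide
# CSV with one column per q value; scalar results and manifests as JSON.

#' Read a sample configuration from CSV
#'
#' Expects columns `variant_id` and `count`; counts must be positive
#' integers and variant ids unique.  Errors name the offending line.
#'
#' @param path CSV file path.
#' @return A [sample_configuration()].
#' @export
read_sample_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "count") %in% names(df))) {
    stop(sprintf("%s: expected columns variant_id, count", path),
         call. = FALSE)
  }
  counts <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(counts) | counts < 1 | counts != round(counts))
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d: count must be a positive integer (got %s)",
                 path, bad[1] + 1L, df$count[bad[1]]), call. = FALSE)
  }
  dup <- which(duplicated(df$variant_id))
  if (length(dup) > 0L) {
    stop(sprintf("%s: line %d: duplicate variant_id %s", path,
                 dup[1] + 1L, df$variant_id[dup[1]]), call. = FALSE)
  }
  sample_configuration(as.integer(counts))
}

#' Write an abundance table or configuration to CSV
#'
#' @param x A `"variant_pool"`, `"sample_configuration"` or
#'   `"steady_state"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_csv <- function(x, path) {
  if (inherits(x, "steady_state")) x <- x$table
  if (inherits(x, "variant_pool")) {
    df <- data.frame(variant_id = x$labels, count = x$counts)
  } else {
    x <- sample_configuration(x)
    df <- data.frame(variant_id = seq_len(config_k(x)) - 1L,
                     count = as.integer(x))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read diversity-profile and training-set CSV
#'
#' Wide format: 13 feature columns `q0, q0.25, ..., q3` plus any further
#' columns present (`label`, `sample_size`, parameters ...).
#'
#' @param df Data frame containing at least the feature columns.
#' @param path CSV path.
#' @return `path` (write) or the validated data frame (read).
#' @export
write_profile_csv <- function(df, path) {
  stopifnot(all(feature_names() %in% names(df)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(feature_names(), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing feature columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a run manifest
#'
#' Every CLI run writes a JSON manifest (full configuration, package
#' version, seed) alongside its outputs so any artifact can be reproduced.
#'
#' @param config Named list of run settings.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  config$package_version <-
    as.character(utils::packageVersion("agedrift"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an experiment grid from JSON
#'
#' The grid file is a JSON array of objects with fields `b`, `p_death`,
#' `c_thresh` (mirroring the constellations of the rejection-probability
#' figures).
#'
#' @param path JSON path.
#' @return A data frame suitable for [rejection_experiment()].
#' @export
read_grid <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (!all(c("b", "p_death", "c_thresh") %in% names(df))) {
    stop(sprintf("%s: grid entries need b, p_death, c_thresh", path),
         call. = FALSE)
  }
  df
}
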