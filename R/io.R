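#' Read a trial table from delimited text
#'
#' Reads a CSV of behavioral trials and validates it against the expected
#' schema. Foreign column names (e.g. from a deposited dataset) can be
#' mapped with `column_map`.
#'
#' Required columns after mapping: `participant`, `trial_index`,
#' `has_load`, `load_level`, `theta`, `reported`, `rt`. Optional: `block`,
#' `memory_correct` (missing values on no-load trials are treated as
#' not applicable), `is_lapse`.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping expected
#'   column names to the names used in the file, e.g.
#'   `c(theta = "stim_ori", reported = "resp_ori")`.
#' @return A validated trial-table data.frame.
#' @export
read_trials <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df)) {
        stop("column-map source column not found in file: ", src,
             call. = FALSE)
      }
      names(df)[names(df) == src] <- std
    }
  }
  validate_trials(df)
}

validate_trials <- function(df) {
  required <- c("participant", "trial_index", "has_load", "load_level",
                "theta", "reported", "rt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$has_load <- as.logical(df$has_load)
  bad <- which(!is.finite(df$theta) | df$theta < 1 | df$theta > 180)
  if (length(bad)) {
    stop("stimulus orientation outside [1, 180] in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  bad_rt <- which(!is.finite(df$rt) | df$rt <= 0)
  if (length(bad_rt)) {
    stop("non-positive response time in row(s): ",
         paste(utils::head(bad_rt, 10), collapse = ", "), call. = FALSE)
  }
  bad_lvl <- which(!df$load_level %in% c("none", "low", "high"))
  if (length(bad_lvl)) {
    stop("unknown load_level in row(s): ",
         paste(utils::head(bad_lvl, 10), collapse = ", "), call. = FALSE)
  }
  bad_mix <- which(!df$has_load & df$load_level != "none")
  if (length(bad_mix)) {
    stop("no-load trial with a load level in row(s): ",
         paste(utils::head(bad_mix, 10), collapse = ", "), call. = FALSE)
  }
  if (!"memory_correct" %in% names(df)) {
    df$memory_correct <- NA
  }
  df$memory_correct <- as.logical(df$memory_correct)
  df$memory_correct[!df$has_load] <- NA   # not applicable without a task
  df$reported <- df$reported %% 180       # reports interpreted modulo 180
  df
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trials()]; the pair round-trips a generated dataset
#' losslessly.
#'
#' @param trials Trial-table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      # full-precision decimal text so the reader restores identical doubles
      out[[nm]] <- sprintf("%.17g", out[[nm]])
      out[[nm]][out[[nm]] %in% c("NA", "nan")] <- NA
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
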