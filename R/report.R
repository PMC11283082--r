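#' Folded serial-dependence curve for display
#'
#' Multiplies trial-wise errors by the sign of the trial-wise delta
#' (folded errors) and computes a circular running mean and standard
#' deviation over `|delta|`, the display convention for serial-dependence
#' curves. Folding is display-only; model fitting always uses the raw
#' signed variables. Trials at delta exactly 0 contribute a folded error
#' of 0.
#'
#' @param deltas,errors Trial-wise values; pairs with missing values are
#'   dropped.
#' @param smooth_window Running-window half-width in degrees of delta.
#'   Default 10.
#' @param grid_step Spacing of the `|delta|` evaluation grid. Default 1.
#' @return A data.frame `delta_abs`, `mean_folded`, `sd_folded`, `n`.
#' @export
fold_and_smooth <- function(deltas, errors, smooth_window = 10,
                            grid_step = 1) {
  stopifnot(length(deltas) == length(errors))
  if (!is.numeric(smooth_window) || smooth_window <= 0) {
    stop("`smooth_window` must be positive", call. = FALSE)
  }
  keep <- is.finite(deltas) & is.finite(errors)
  d <- deltas[keep]
  folded <- errors[keep] * sign(d)
  ad <- abs(d)
  grid <- seq(0, 90, by = grid_step)
  rows <- lapply(grid, function(g) {
    # distance on the folded half-circle: a trial is near g if |delta| is
    # within the window of g directly or through either reflection point
    near <- abs(wrap_orientation(ad - g)) <= smooth_window |
      abs(wrap_orientation(ad + g)) <= smooth_window
    x <- folded[near]
    data.frame(delta_abs = g,
               mean_folded = if (length(x)) mean(x) else NA_real_,
               sd_folded = if (length(x) > 1) stats::sd(x) else NA_real_,
               n = length(x))
  })
  do.call(rbind, rows)
}

#' Configuration for a full pipeline run
#'
#' Bundles every setting of the end-to-end analysis so a run is fully
#' described by one object: the input (a trial-table path, a
#' [sim_config()], or an in-memory table), the cleaning thresholds, the
#' fit constant, the resampling sizes, all seeds, and the display windows.
#'
#' @param input A path to a trial CSV, a `sim_config`, or a data.frame of
#'   trials.
#' @param lapse_cutoff,iqr_k,rt_cutoff Cleaning parameters, see
#'   [preprocess()].
#' @param n_perm Permutation count for every shuffle test. Default 10000.
#' @param n_boot Bootstrap resamples (0 disables bootstrap intervals).
#'   Default 0.
#' @param seed Base seed for all resampling streams.
#' @param scatter_window Residualization half-width for the scatter
#'   analysis, degrees. Default 10.
#' @param smooth_window Folded-curve display half-width, degrees.
#'   Default 10.
#' @param column_map Optional column mapping for [read_trials()].
#' @param out_dir Optional directory; when given the run report (JSON) and
#'   the cleaned series / scatter tables (CSV) are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, lapse_cutoff = 45, iqr_k = 1.5,
                       rt_cutoff = 10, n_perm = 10000L, n_boot = 0L,
                       seed = 1L, scatter_window = 10, smooth_window = 10,
                       column_map = NULL, out_dir = NULL) {
  structure(list(
    input = input, lapse_cutoff = lapse_cutoff, iqr_k = iqr_k,
    rt_cutoff = rt_cutoff, n_perm = as.integer(n_perm),
    n_boot = as.integer(n_boot), seed = as.integer(seed),
    scatter_window = scatter_window, smooth_window = smooth_window,
    column_map = column_map, out_dir = out_dir
  ), class = "run_config")
}

#' Run the full serial-dependence analysis pipeline
#'
#' Executes simulate-or-load, preprocessing, condition splitting,
#' condition-wise DoG fits with sign-shuffle significance, condition
#' contrasts by label shuffling (previous-trial low vs high, current-trial
#' low vs high, load vs no-load), the residualized error-scatter analysis
#' with paired comparisons, memory-task accuracy comparison, and folded
#' display curves. Returns a structured, self-describing report.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`: nested list with elements
#'   `fits`, `sign_tests`, `contrasts`, `scatter`, `memory`, `folded`,
#'   `exclusions` and `config_echo`. If `config$out_dir` is set, the
#'   report (JSON) and tables (CSV) are also written there.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  trials <- if (inherits(config$input, "sim_config")) {
    generate_dataset(config$input)
  } else if (is.character(config$input)) {
    read_trials(config$input, config$column_map)
  } else if (is.data.frame(config$input)) {
    validate_trials(config$input)
  } else {
    stop("`input` must be a path, a sim_config, or a data.frame",
         call. = FALSE)
  }

  series <- preprocess(trials, lapse_cutoff = config$lapse_cutoff,
                       iqr_k = config$iqr_k, rt_cutoff = config$rt_cutoff)
  split <- split_conditions(series)

  cond_names <- c("prev_low", "prev_high", "curr_low", "curr_high",
                  "no_load", "load")
  sign_tests <- list()
  fits <- list()
  for (i in seq_along(cond_names)) {
    cn <- cond_names[i]
    sub <- split[[cn]]
    st <- sign_shuffle_test(sub$delta, sub$error_clean,
                            n_perm = config$n_perm,
                            seed = child_seed(config$seed, i))
    sign_tests[[cn]] <- st
    fits[[cn]] <- st$observed
  }

  contrasts <- list(
    prev_low_vs_high = label_shuffle_difference(
      split$prev_low$delta, split$prev_low$error_clean,
      split$prev_high$delta, split$prev_high$error_clean,
      n_perm = config$n_perm, seed = child_seed(config$seed, 101L)),
    curr_low_vs_high = label_shuffle_difference(
      split$curr_low$delta, split$curr_low$error_clean,
      split$curr_high$delta, split$curr_high$error_clean,
      n_perm = config$n_perm, seed = child_seed(config$seed, 102L)),
    no_load_vs_load = label_shuffle_difference(
      split$no_load$delta, split$no_load$error_clean,
      split$load$delta, split$load$error_clean,
      n_perm = config$n_perm, seed = child_seed(config$seed, 103L))
  )

  boot <- NULL
  if (config$n_boot >= 100L) {
    boot <- lapply(seq_along(cond_names), function(i) {
      sub <- split[[cond_names[i]]]
      bootstrap_params(sub$delta, sub$error_clean, n_boot = config$n_boot,
                       seed = child_seed(config$seed, 200L + i))
    })
    names(boot) <- cond_names
  }

  scat <- error_scatter(series, window = config$scatter_window)
  wide <- function(cnd) {
    s <- scat[scat$condition == cnd, ]
    s$scatter[order(s$participant)]
  }
  scatter_tests <- list(
    no_load_vs_load = paired_comparison(wide("no_load"), wide("load")),
    low_vs_high = paired_comparison(wide("low"), wide("high"))
  )

  memory <- NULL
  if (any(!is.na(trials$memory_correct))) {
    lt <- trials[trials$has_load & !is.na(trials$memory_correct), ]
    pc <- stats::aggregate(memory_correct ~ participant + load_level,
                           data = lt, FUN = mean)
    pc_wide <- function(lvl) {
      s <- pc[pc$load_level == lvl, ]
      s$memory_correct[order(s$participant)]
    }
    pcl <- pc_wide("low"); pch <- pc_wide("high")
    memory <- list(
      pc = pc,
      pc_low = mean(pcl), pc_high = mean(pch),
      low_vs_high = if (length(pcl) == length(pch) && length(pcl) >= 3)
        paired_comparison(pcl, pch) else NULL
    )
  }

  folded <- lapply(split[cond_names], function(sub) {
    fold_and_smooth(sub$delta, sub$error_clean,
                    smooth_window = config$smooth_window)
  })

  report <- structure(list(
    fits = fits,
    sign_tests = sign_tests,
    contrasts = contrasts,
    bootstrap = boot,
    scatter = scat,
    scatter_tests = scatter_tests,
    memory = memory,
    folded = folded,
    exclusions = list(
      fraction = attr(series, "exclusion_fraction"),
      by_reason = table(series$exclusion_reason)
    ),
    counts = attr(split, "counts"),
    series = series,
    config_echo = config[setdiff(names(config), "input")]
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Serial-dependence run report\n")
  cat(sprintf("  trials excluded by cleaning: %.1f%%\n",
              100 * x$exclusions$fraction))
  for (cn in names(x$fits)) {
    f <- x$fits[[cn]]
    cat(sprintf("  %-10s alpha = %6.3f deg (p = %.4g), w = %.4f, n = %d\n",
                cn, f$alpha, x$sign_tests[[cn]]$p_alpha, f$w, f$n_trials))
  }
  for (cn in names(x$contrasts)) {
    ct <- x$contrasts[[cn]]
    cat(sprintf("  %-18s alpha diff = %6.3f (p = %.4g), w diff = %7.4f (p = %.4g)\n",
                cn, ct$observed_alpha_diff, ct$p_alpha,
                ct$observed_w_diff, ct$p_w))
  }
  invisible(x)
}

#' Serialize a run report to disk
#'
#' Writes `report.json` (parameters, p-values, counts, seeds) plus
#' `cleaned_series.csv`, `scatter.csv` and per-condition `folded_*.csv`
#' tables.
#'
#' @param report A `run_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- list(
    exclusion_fraction = report$exclusions$fraction,
    counts = as.list(report$counts),
    fits = lapply(report$fits, function(f) {
      list(alpha = f$alpha, w = f$w, c = f$c, sse = f$sse, n = f$n_trials,
           converged = f$converged)
    }),
    p_alpha = lapply(report$sign_tests, function(s) s$p_alpha),
    p_w = lapply(report$sign_tests, function(s) s$p_w),
    contrasts = lapply(report$contrasts, function(ct) {
      list(alpha_diff = ct$observed_alpha_diff, p_alpha = ct$p_alpha,
           w_diff = ct$observed_w_diff, p_w = ct$p_w)
    }),
    scatter_summary = attr(report$scatter, "summary"),
    scatter_tests = lapply(report$scatter_tests, unclass),
    memory = if (!is.null(report$memory)) list(
      pc_low = report$memory$pc_low, pc_high = report$memory$pc_high,
      low_vs_high = if (!is.null(report$memory$low_vs_high))
        unclass(report$memory$low_vs_high) else NULL
    ) else NULL,
    config = report$config_echo
  )
  jsonlite::write_json(flat, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  utils::write.csv(as.data.frame(report$series),
                   file.path(dir, "cleaned_series.csv"), row.names = FALSE)
  utils::write.csv(report$scatter, file.path(dir, "scatter.csv"),
                   row.names = FALSE)
  for (cn in names(report$folded)) {
    utils::write.csv(report$folded[[cn]],
                     file.path(dir, paste0("folded_", cn, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Run the pipeline on a locally downloaded deposited dataset
#'
#' Convenience entry point for reanalysing a deposited trial-level dataset:
#' reads one CSV (or every CSV in a directory, concatenated) with an
#' optional column mapping onto this package's schema, then runs
#' [run_full_analysis()].
#'
#' @param path CSV file or directory of CSVs.
#' @param column_map Named character vector mapping this package's column
#'   names to the deposit's, see [read_trials()].
#' @param ... Passed to [run_config()].
#' @return A `run_report`.
#' @export
reproduce_zenodo <- function(path, column_map = NULL, ...) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else path
  if (!length(files)) stop("no CSV files found under ", path, call. = FALSE)
  tables <- lapply(files, read_trials, column_map = column_map)
  trials <- do.call(rbind, tables)
  run_full_analysis(run_config(trials, ...))
}

#' Plot a folded serial-dependence curve
#'
#' Base-graphics display of a [fold_and_smooth()] table with a +/- 1 SD
#' band and, optionally, the folded fitted DoG curve.
#'
#' @param folded Output of [fold_and_smooth()].
#' @param fit Optional `dog_fit` whose folded curve is overlaid.
#' @param ... Passed to [plot()].
#' @return Invisibly, `folded`.
#' @export
plot_folded <- function(folded, fit = NULL, ...) {
  graphics::plot(folded$delta_abs, folded$mean_folded, type = "l",
                 xlab = expression(paste("|", Delta, "| (deg)")),
                 ylab = "folded error (deg)", ...)
  graphics::polygon(c(folded$delta_abs, rev(folded$delta_abs)),
                    c(folded$mean_folded + folded$sd_folded,
                      rev(folded$mean_folded - folded$sd_folded)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.4))
  graphics::lines(folded$delta_abs, folded$mean_folded, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(fit)) {
    graphics::curve(dog_curve(x, fit$alpha, fit$w, fit$c), from = 0,
                    to = 90, add = TRUE, col = "red", lwd = 2)
  }
  invisible(folded)
}
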