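## Sweep drivers: grids of noise strength, Gamma, steepness or
## secondary-field parameters across seeds, with pooled defect summaries,
## onset detection and the correction-factor statistic.

#' Specification of a parameter sweep
#'
#' @param varied_parameter One of `"noise_strength_threshold"`,
#'   `"noise_strength_size"` (both in percent of the mean),
#'   `"gamma"`, `"steepness"`, `"d1_rel"` (`d1/d0`), `"tau_rel"`
#'   (`tau` in units of the mean plastochron) or `"delta_a_rel"`
#'   (class-iii age shift in mean plastochrons).
#' @param grid Strictly monotone vector of parameter values.
#' @param seeds Distinct integer seeds; each grid value is run once per
#'   seed.
#' @param events_per_run Initiations recorded per run.
#' @param base_config The fixed [simulation_config()]; the varied parameter
#'   and seed are overridden per run.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(varied_parameter, grid, seeds, events_per_run,
                       base_config = simulation_config()) {
  varied_parameter <- match.arg(varied_parameter,
                                c("noise_strength_threshold",
                                  "noise_strength_size", "gamma",
                                  "steepness", "d1_rel", "tau_rel",
                                  "delta_a_rel"))
  if (any(diff(grid) <= 0) && any(diff(grid) >= 0) && length(grid) > 1L)
    if (!(all(diff(grid) > 0) || all(diff(grid) < 0)))
      stop("`grid` must be strictly monotone")
  if (anyDuplicated(seeds)) stop("`seeds` must be distinct")
  stopifnot(inherits(base_config, "phyllo_config"))
  structure(list(varied_parameter = varied_parameter, grid = grid,
                 seeds = as.integer(seeds),
                 events_per_run = as.integer(events_per_run),
                 base_config = base_config),
            class = "sweep_spec")
}

## apply one sweep point to the base configuration
apply_sweep_value <- function(cfg, param, value, mean_plastochron = NULL) {
  switch(param,
    noise_strength_threshold = {
      cfg$noise_mode <- "threshold"
      cfg$noise_sd_threshold <- value / 100 * cfg$threshold_mean
    },
    noise_strength_size = {
      cfg$noise_mode <- "size"
      cfg$noise_sd_radius <- value / 100 * cfg$R0_mean
    },
    gamma = cfg$field$range_d0 <- value * cfg$R0_mean,
    steepness = cfg$field$steepness_s <- value,
    d1_rel = cfg$secondary$range_d1 <- value * cfg$field$range_d0,
    tau_rel = {
      pl <- mean_plastochron %||%
        attr(make_equilibrium_state(cfg), "mean_plastochron")
      cfg$secondary$delay_tau <- value * pl
    },
    delta_a_rel = {
      pl <- mean_plastochron %||%
        attr(make_equilibrium_state(cfg), "mean_plastochron")
      cfg$secondary$age_shift_delta <- value * pl
    })
  cfg
}

run_file_key <- function(param, value, seed, n_events) {
  sprintf("run_%s_%s_seed%d_n%d", param,
          gsub("[^0-9A-Za-z.-]", "_", format(value, digits = 10)),
          seed, n_events)
}

#' Execute a parameter sweep
#'
#' Runs the full grid-by-seeds design, pools runs per grid value with
#' [defect_summary()], and optionally persists per-run event CSVs (plus
#' JSON metadata) under `out_dir`.  A sweep with an `out_dir` is resumable:
#' runs whose event file already exists and whose recorded configuration
#' matches are loaded instead of recomputed.  Failures of individual runs
#' are collected and reported at the end; completed runs are kept.
#'
#' @param spec A [sweep_spec()].
#' @param out_dir Optional output directory for per-run CSVs and the
#'   summary CSV.
#' @param progress Print one line per run.
#' @param ... Passed to [defect_summary()] (detector tolerances).
#' @return The summary data frame (one row per grid value), invisibly
#'   carrying the run list as attribute `runs`.  Errors if any run failed.
#' @export
run_sweep <- function(spec, out_dir = NULL, progress = FALSE, ...) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  ## resolve the mean plastochron once (tau_rel / delta_a_rel conversions)
  pl <- attr(make_equilibrium_state(spec$base_config), "mean_plastochron")
  runs <- list()
  conds <- numeric(0)
  failures <- character(0)
  for (v in spec$grid) {
    for (sd_i in spec$seeds) {
      cfg <- apply_sweep_value(spec$base_config, spec$varied_parameter, v, pl)
      cfg$seed <- sd_i
      cfg$n_events <- spec$events_per_run
      key <- run_file_key(spec$varied_parameter, v, sd_i,
                          spec$events_per_run)
      csv <- if (!is.null(out_dir)) file.path(out_dir, paste0(key, ".csv"))
      res <- NULL
      from_cache <- FALSE
      if (!is.null(out_dir) && file.exists(csv)) {
        cached <- tryCatch(read_event_csv(csv), error = function(e) NULL)
        if (!is.null(cached) && !is.null(cached$config) &&
            identical(write_config(cached$config), write_config(cfg))) {
          res <- cached
          from_cache <- TRUE
          if (progress) message("cache hit: ", key)
        }
      }
      if (is.null(res))
        res <- tryCatch(run_simulation(cfg), error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s: %s", key, conditionMessage(res)))
        next
      }
      if (!is.null(out_dir) && !from_cache) {
        write_event_csv(res, csv)
        write_run_metadata(res, file.path(out_dir, paste0(key, ".json")))
      }
      runs[[length(runs) + 1L]] <- res
      conds <- c(conds, v)
      if (progress)
        message(sprintf("%s = %g, seed %d: %d events", spec$varied_parameter,
                        v, sd_i, nrow(res$events)))
    }
  }
  summary <- defect_summary(runs, conds, ...)
  if (!is.null(out_dir))
    write.csv(summary, file.path(out_dir, "sweep_summary.csv"),
              row.names = FALSE)
  if (length(failures))
    stop("sweep finished with failed runs:\n  ",
         paste(failures, collapse = "\n  "))
  attr(summary, "runs") <- runs
  attr(summary, "conditions") <- conds
  invisible(summary)
}

#' Detect the onset noise strength of a defect class
#'
#' The operational reading of a defect "appearing": the smallest grid value
#' whose pooled proportion exceeds `floor` (default 1% of events).
#'
#' @param summary A [defect_summary()] / [run_sweep()] table.
#' @param defect One of `"concomitant"`, `"m_shape"`, `"distichous"`,
#'   `"reversal"`.
#' @param floor Proportion floor.
#' @return The smallest qualifying condition value, or `NA` (printed as
#'   `"none"`) if the floor is never exceeded.
#' @export
onset_detect <- function(summary, defect = c("concomitant", "m_shape",
                                             "distichous", "reversal"),
                         floor = 0.01) {
  defect <- match.arg(defect)
  col <- paste0("prop_", defect)
  stopifnot(col %in% names(summary))
  ord <- order(summary$condition)
  hit <- which(summary[[col]][ord] > floor)
  if (length(hit) == 0L) return(NA_real_)
  summary$condition[ord][hit[1L]]
}

#' M-shape correction factor of a secondary field
#'
#' The per-event M-shape count of the control (no secondary field) divided
#' by that of the treated (secondary field on) condition; a factor greater
#' than 1 means the secondary field reduced defects.  A zero treated count
#' returns `Inf` with the raw counts attached as attributes.
#'
#' @param control_summary,treated_summary One-row [defect_summary()]
#'   tables with matched noise settings.
#' @return The fold reduction (numeric scalar).
#' @export
correction_factor <- function(control_summary, treated_summary) {
  stopifnot("m_per_event" %in% names(control_summary),
            "m_per_event" %in% names(treated_summary))
  ctrl <- control_summary$m_per_event[1L]
  trt <- treated_summary$m_per_event[1L]
  if (trt == 0) {
    out <- Inf
    attr(out, "control_m_per_event") <- ctrl
    attr(out, "treated_m_per_event") <- trt
    return(out)
  }
  ctrl / trt
}
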