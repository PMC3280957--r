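## Tabular input/output: event CSV, run-metadata JSON, external angle
## tables, annotation and histogram exports.

#' Write an event sequence to CSV
#'
#' One row per event with header `rank, time, azimuth_rad, radius_used,
#' threshold_used, concomitance_group, age_shift` (RFC-4180 quoting, `.`
#' decimal separator).
#'
#' @param seq An `event_sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(seq, path) {
  stopifnot(inherits(seq, "event_sequence"))
  write.csv(seq$events, path, row.names = FALSE)
  invisible(path)
}

#' Read an event sequence from CSV
#'
#' @param path A CSV written by [write_event_csv()].
#' @param time_precision Concomitance time precision to attach; when `NULL`
#'   and a metadata sidecar (same path with extension `.json`) exists, it
#'   is read from there.
#' @return An `event_sequence` (with `config = NULL` unless recoverable
#'   from the sidecar).
#' @export
read_event_csv <- function(path, time_precision = NULL) {
  ev <- read.csv(path)
  need <- c("rank", "time", "azimuth_rad", "radius_used", "threshold_used",
            "concomitance_group", "age_shift")
  if (!all(need %in% names(ev)))
    stop("missing required event columns: ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  meta_path <- paste0(tools::file_path_sans_ext(path), ".json")
  cfg <- NULL
  mean_pl <- NA_real_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (is.null(time_precision)) time_precision <- meta$time_precision
    mean_pl <- meta$mean_plastochron %||% NA_real_
    if (!is.null(meta$config_yaml)) cfg <- read_config(meta$config_yaml)
  }
  structure(list(events = ev[order(ev$rank), , drop = FALSE], config = cfg,
                 time_precision = time_precision,
                 mean_plastochron = mean_pl,
                 eq_divergence_deg = NA_real_, final_state = NULL),
            class = "event_sequence")
}

#' Write the JSON metadata sidecar of a run
#'
#' Records the full configuration (as embedded YAML), the seed, the package
#' version, the solver time precision, and the equilibrium fixture
#' statistics, so a run can be replayed or audited.
#'
#' @param seq An `event_sequence`.
#' @param path Output file (conventionally the event CSV path with a
#'   `.json` extension).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(seq, path) {
  stopifnot(inherits(seq, "event_sequence"))
  meta <- list(
    package_version = as.character(utils::packageVersion("phyllonoise")),
    seed = seq$config$seed,
    time_precision = seq$time_precision,
    mean_plastochron = seq$mean_plastochron,
    eq_divergence_deg = seq$eq_divergence_deg,
    n_events = nrow(seq$events),
    config_yaml = write_config(seq$config))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an external divergence-angle table
#'
#' Bare two-column plain text (`rank`, `divergence_angle_deg`), whitespace
#' or comma separated, optional header.
#'
#' @param path File path.
#' @return An `angle_sequence`.
#' @export
read_angle_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  tab <- read.table(path, sep = sep, header = header)
  if (ncol(tab) < 2L) stop("expected two columns: rank, divergence_angle_deg")
  angle_sequence(tab[[2L]], source_ranks = tab[[1L]])
}

#' Write per-angle defect annotations to CSV
#'
#' Columns `index`, `angle_deg`, `label`.
#'
#' @param ann A `defect_annotation` from [annotate_defects()].
#' @param angles The matching `angle_sequence` (or anything coercible).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_csv <- function(ann, angles, path) {
  stopifnot(inherits(ann, "defect_annotation"))
  a <- as_angles(angles)
  stopifnot(length(a) == length(ann$labels))
  write.csv(data.frame(index = seq_along(a), angle_deg = a,
                       label = ann$labels),
            path, row.names = FALSE)
  invisible(path)
}

#' Histogram of divergence angles as JSON
#'
#' Fixed-width binning of signed angles over `(-180, 180]`; the JSON object
#' carries `bin_edges` and `counts`.
#'
#' @param angles An `angle_sequence` or numeric vector of degrees.
#' @param path Output file; `NULL` returns the list instead.
#' @param bin_width Bin width in degrees (default 5).
#' @return The histogram list, invisibly if written.
#' @export
write_angle_histogram <- function(angles, path = NULL, bin_width = 5) {
  a <- as_angles(angles)
  edges <- seq(-180, 180, by = bin_width)
  counts <- as.integer(table(cut(a, breaks = edges, include.lowest = TRUE)))
  h <- list(bin_edges = edges, counts = counts)
  if (is.null(path)) return(h)
  jsonlite::write_json(h, path, auto_unbox = TRUE, digits = NA)
  invisible(h)
}
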