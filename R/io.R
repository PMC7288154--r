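#' Write / read experiment curves as delimited text
#'
#' Curves are stored as plain CSV with a JSON sidecar (`<path>.json`)
#' carrying the metadata, the time step and the segment boundaries, so a
#' round trip preserves everything a fit needs.
#'
#' @param curve an `experiment_curve`.
#' @param path CSV file path.
#' @export
write_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  side <- list(metadata = attr(curve, "metadata"),
               dt = attr(curve, "dt"),
               boundaries = attr(curve, "boundaries"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  side_path <- paste0(path, ".json")
  out <- structure(df, class = c("experiment_curve", "data.frame"))
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(out, "metadata") <- as.list(side$metadata)
    attr(out, "dt") <- side$dt
    attr(out, "boundaries") <- as.integer(side$boundaries)
  }
  out
}

#' Serialize a GENERIC model to JSON
#'
#' All per-window matrices, the time step, scheme, window boundaries and
#' channel scaling are stored; [read_model()] restores a working
#' `generic_model`.
#'
#' @param model a `generic_model`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  payload <- list(
    d = model$d, dt = model$dt, theta = model$theta,
    boundaries = model$boundaries, n_total = model$n_total,
    channels = model$channels, scales = model$scales,
    windows = lapply(model$windows, function(w)
      lapply(w[c("L", "M", "A", "B")], unclass)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- p$d[[1]]
  as_square <- function(m) matrix(unlist(m), d, d, byrow = TRUE)
  windows <- lapply(p$windows, function(w)
    lapply(w[c("L", "M", "A", "B")], as_square))
  sc <- unlist(p$scales)
  generic_model(windows = windows, boundaries = as.integer(unlist(p$boundaries)),
                n_total = unlist(p$n_total), dt = unlist(p$dt),
                theta = unlist(p$theta),
                channels = unlist(p$channels), scales = sc, check = FALSE)
}

#' Write a run report to a directory
#'
#' Emits `report.json` (full report), `errors.csv` (the per-variant error
#' table) and, when a persistence diagram is present, `persistence.csv`.
#'
#' @param report a `run_report` from [run_pseudo_experiment()] or
#'   [run_carotid_experiment()].
#' @param dir output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_payload(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write.csv(report$errors, file.path(dir, "errors.csv"), row.names = FALSE)
  if (!is.null(report$diagram))
    write.csv(as.data.frame(report$diagram),
              file.path(dir, "persistence.csv"), row.names = FALSE)
  invisible(dir)
}

report_payload <- function(report) {
  list(experiment = report$experiment,
       errors = report$errors,
       r_star = report$r_star,
       neighbors = report$neighbors,
       weights = report$weights,
       audits = report$audits,
       seeds = report$seeds,
       settings = report$settings,
       failures = report$failures)
}
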