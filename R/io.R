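#' Write / read a trajectory ensemble as CSV plus JSON sidecar
#'
#' The on-disk format is a tidy CSV whose first column is `time_s` followed by
#' one column per trial (`trial_001`, ...), written at full double precision
#' (`%.17g`, lossless round trip), plus a `<prefix>.json` sidecar holding the
#' units and metadata (task, architecture, seed, parameter snapshot).
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param prefix output path prefix; `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return `write_ensemble`: the CSV path, invisibly. `read_ensemble`: a
#'   [trajectory_ensemble()].
#' @export
write_ensemble <- function(ensemble, prefix) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  n <- nrow(ensemble$positions)
  header <- c("time_s", sprintf("trial_%03d", seq_len(n)))
  m <- cbind(ensemble$time, t(ensemble$positions))
  lines <- c(paste(header, collapse = ","),
             apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")))
  csv <- paste0(prefix, ".csv")
  writeLines(lines, csv)
  jsonlite::write_json(list(units = ensemble$units, meta = ensemble$meta),
                       paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(csv)
}

#' @param path a CSV path (or prefix without extension); any tidy CSV with a
#'   time column first and one column per trial is accepted. A matching
#'   `.json` sidecar is read when present.
#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("ensemble CSV needs a time column plus at least one trial column")
  sidecar <- sub("\\.csv$", ".json", path)
  units <- "units"; meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$units)) units <- side$units
    if (!is.null(side$meta)) meta <- side$meta
  }
  trajectory_ensemble(df[[1]], t(as.matrix(df[, -1, drop = FALSE])),
                      units = units, meta = meta, align = FALSE)
}

#' Read a model/task configuration file
#'
#' YAML (or JSON) files mirror the constructor field names: top-level blocks
#' `plant`, `controller` (with optional nested `intermittent`) and `task`.
#' Bundled examples encoding the default arm and stance parameter sets ship in
#' `inst/extdata/` (`arm_default.yaml`, `stance_default.yaml`).
#'
#' @param path configuration file path.
#' @return A list with `plant` ([plant_params()]), `controller`
#'   ([controller_spec()]) and `task` ([task_spec()]).
#' @examples
#' cfg <- read_config(system.file("extdata", "arm_default.yaml",
#'                                package = "brownmotor"))
#' cfg$plant
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  plant <- do.call(plant_params, raw$plant)
  ctl <- raw$controller
  if (!is.null(ctl$intermittent))
    ctl$intermittent <- do.call(intermittent_spec, ctl$intermittent)
  controller <- do.call(controller_spec, ctl)
  task <- do.call(task_spec, raw$task)
  list(plant = plant, controller = controller, task = task)
}
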