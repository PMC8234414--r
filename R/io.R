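# CSV dialects and structured (YAML) reports.
#
# All files are plain UTF-8 CSV with headers and '.' decimals, mirroring the
# instrument's native displacement log. Traces: time_s, displacement_um
# (+ sample_id, condition); calibration: deflection_um, force_uN; plates:
# well, analyte, condition, od450; blot lanes: condition, pmlc, total_mlc,
# actin.

#' Read / write a calibration CSV
#'
#' Columns `deflection_um`, `force_uN`.
#'
#' @param path CSV file path.
#' @return `read_calibration_csv` returns a [calibration_series()].
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("deflection_um", "force_uN") %in% names(df)))
    cf_stop("calibration CSV needs columns deflection_um, force_uN",
            "clotforce_invalid_calibration")
  calibration_series(df$deflection_um, df$force_uN)
}

#' @rdname read_calibration_csv
#' @param cal A [calibration_series()].
#' @export
write_calibration_csv <- function(cal, path) {
  utils::write.csv(as.data.frame(cal), path, row.names = FALSE)
  invisible(path)
}

#' Read / write displacement traces as CSV
#'
#' One file can hold several traces, distinguished by `sample_id` and
#' `condition`; columns `time_s`, `displacement_um` are required.
#'
#' @param path CSV file path.
#' @param max_duration Maximum trace span in seconds (default 3600).
#' @return `read_trace_csv` returns a list of [displacement_trace()] objects
#'   (class `condition_dataset`).
#' @export
read_trace_csv <- function(path, max_duration = 3600) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "displacement_um") %in% names(df)))
    cf_stop("trace CSV needs columns time_s, displacement_um",
            "clotforce_invalid_trace")
  if (!"sample_id" %in% names(df)) df$sample_id <- "S1"
  if (!"condition" %in% names(df)) df$condition <- "control"
  key <- interaction(df$condition, df$sample_id, drop = TRUE)
  traces <- lapply(split(df, key), function(g)
    displacement_trace(g$time_s, g$displacement_um,
                       sample_id = g$sample_id[1L],
                       condition = g$condition[1L],
                       max_duration = max_duration))
  structure(unname(traces), class = "condition_dataset")
}

#' @rdname read_trace_csv
#' @param traces A list of [displacement_trace()] objects.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "displacement_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_s = tr$times, displacement_um = tr$deflections,
               sample_id = tr$sample_id, condition = tr$condition,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a force trace as CSV
#'
#' Columns `time_s`, `force_uN`, `sample_id`, `condition`.
#'
#' @param ftrace A [to_force_trace()] result.
#' @param path CSV file path.
#' @export
write_force_csv <- function(ftrace, path) {
  stopifnot(inherits(ftrace, "force_trace"))
  utils::write.csv(data.frame(time_s = ftrace$times,
                              force_uN = ftrace$forces,
                              sample_id = ftrace$sample_id,
                              condition = ftrace$condition,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write an ELISA plate CSV
#'
#' Columns `well`, `analyte`, `condition`, `od450`.
#'
#' @param path CSV file path.
#' @return `read_plate_csv` returns an [elisa_plate()].
#' @export
read_plate_csv <- function(path) {
  elisa_plate(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_plate_csv
#' @param plate An [elisa_plate()].
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(as.data.frame(plate), path, row.names = FALSE)
  invisible(path)
}

#' Read blot lanes from CSV
#'
#' Columns `condition`, `pmlc`, `total_mlc`, `actin`.
#'
#' @param path CSV file path.
#' @return Named list of [blot_lane()] objects.
#' @export
read_lane_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("condition", "pmlc", "total_mlc", "actin")
  if (!all(req %in% names(df)))
    cf_stop("lane CSV needs columns condition, pmlc, total_mlc, actin",
            "clotforce_invalid_lane")
  lanes <- lapply(seq_len(nrow(df)), function(i)
    blot_lane(df$condition[i], df$pmlc[i], df$total_mlc[i], df$actin[i]))
  stats::setNames(lanes, df$condition)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a deterministic run bit-for-bit:
#' the seed, the full configuration echo, input/output paths and the package
#' version, in YAML.
#'
#' @param path Output YAML path.
#' @param seed Seed used (or `NULL`).
#' @param config Named list echoing the run configuration.
#' @param inputs,outputs Character vectors of file paths.
#' @export
write_manifest <- function(path, seed = NULL, config = list(),
                           inputs = character(), outputs = character()) {
  yaml::write_yaml(list(
    package = "clotforce",
    version = as.character(utils::packageVersion("clotforce")),
    seed = seed,
    config = config,
    inputs = as.list(inputs),
    outputs = as.list(outputs)), path)
  invisible(path)
}
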