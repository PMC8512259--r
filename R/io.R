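# Plain-text interchange: session CSV + JSON sidecar, annotation JSON,
# feature tables as CSV, configuration snippets as YAML.

#' Write / read a recording as CSV with a JSON sidecar header
#'
#' The CSV has columns `t,ax,ay,az`; the sidecar `<path>.json` records
#' `sensor_id`, `unit` and `nominal_rate_hz`.
#'
#' @param recording a [sensor_recording].
#' @param path CSV file path (sidecar written next to it).
#' @param nominal_rate_hz rate recorded in the sidecar.
#' @return `path`, invisibly (writer); a [sensor_recording] (reader).
#' @rdname session_io
#' @export
write_recording_csv <- function(recording, path, nominal_rate_hz = 32) {
  stopifnot(inherits(recording, "sensor_recording"))
  df <- data.frame(t = recording$timestamps, recording$acc)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(sensor_id = recording$sensor_id,
                            unit = recording$unit,
                            nominal_rate_hz = nominal_rate_hz),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  sensor_recording(hdr$sensor_id, df$t, as.matrix(df[, c("ax", "ay", "az")]),
                   unit = hdr$unit)
}

#' Write / read an annotation track as JSON
#'
#' A JSON array of `{label, start_s, end_s}` objects.
#'
#' @param annotations an [annotation_track].
#' @param path JSON file path.
#' @rdname annotation_io
#' @export
write_annotations_json <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_track"))
  jsonlite::write_json(as.data.frame(annotations), path, digits = NA)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_annotations_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  annotation_track(df$label, df$start_s, df$end_s)
}

#' Write / read a domain's feature table as CSV
#'
#' One row per window; feature columns use the `axis_band_stat` naming of
#' [extract_features], preceded by a `label` column when labels exist.
#'
#' @param domain a [domain_dataset].
#' @param path CSV file path.
#' @rdname feature_io
#' @export
write_features_csv <- function(domain, path) {
  stopifnot(inherits(domain, "domain_dataset"))
  df <- as.data.frame(domain$X)
  if (!is.null(domain$labels)) df <- cbind(label = domain$labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname feature_io
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.character(df$label)
    df$label <- NULL
  }
  domain_dataset(as.matrix(df), labels = labels)
}

#' Serialize a scenario specification to / from YAML
#'
#' @param scenario a `scenario_spec`.
#' @param path YAML file path.
#' @rdname scenario_io
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_spec"))
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname scenario_io
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$kind, "separate")) {
    scenario_separate(tasks = x$tasks, block_s = x$block_s)
  } else if (identical(x$kind, "mixed")) {
    scenario_mixed(tasks = x$tasks, circuits = x$circuits, total_s = x$total_s)
  } else {
    stop("unknown scenario kind in YAML", call. = FALSE)
  }
}
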