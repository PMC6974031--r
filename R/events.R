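#' Read a BIDS-style events table
#'
#' Events are tab-separated with at least `onset`, `duration` and `cue_role`
#' columns; the pipeline additionally uses `phase`, `run`, `cue_set`,
#' `position_in_pair`, `outcome`, `response`, `press_side` and
#' `response_time` where the phase defines them. Missing values are encoded
#' as `n/a` (BIDS convention). Extra columns are preserved.
#'
#' Validation enforces: onsets strictly increasing within the file (one file
#' per run), positive durations, numeric onset/duration/response_time,
#' `cue_set` absent (`n/a`) for control (`E`) cues, and conditioning rows
#' restricted to cue roles B and D.
#'
#' @param path TSV file.
#' @return a `data.table` with class `event_table`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort_validation("events file not found: %s", path)
  ev <- data.table::fread(path, sep = "\t", na.strings = c("n/a", "NA", ""),
                          colClasses = NULL, data.table = TRUE)
  validate_events(ev, where = path)
}

#' @rdname read_events
#' @param events a data.frame of events.
#' @param where label used in error messages.
#' @export
validate_events <- function(events, where = "events") {
  ev <- data.table::as.data.table(events)
  required <- c("onset", "duration", "cue_role")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    abort_validation("%s: missing required column(s): %s", where,
                     paste(missing, collapse = ", "))
  for (col in intersect(c("onset", "duration", "response_time"), names(ev))) {
    if (!is.numeric(ev[[col]]))
      abort_validation("%s: column '%s' is not numeric", where, col)
  }
  if (anyNA(ev$onset) || anyNA(ev$duration))
    abort_validation("%s: onset/duration contain missing values", where)
  if (any(diff(ev$onset) <= 0))
    abort_validation("%s: onsets must be strictly increasing within a run", where)
  if (any(ev$duration <= 0))
    abort_validation("%s: durations must be positive", where)
  if (!all(ev$cue_role %in% c("A", "B", "C", "D", "E")))
    abort_validation("%s: cue_role must be one of A,B,C,D,E", where)
  if ("cue_set" %in% names(ev)) {
    if (any(ev$cue_role == "E" & !is.na(ev$cue_set)))
      abort_validation("%s: control (E) cues must not carry a cue_set", where)
    ok <- is.na(ev$cue_set) | (ev$cue_set >= 1 & ev$cue_set <= 8)
    if (!all(ok)) abort_validation("%s: cue_set out of range 1-8", where)
  }
  if ("phase" %in% names(ev) &&
      any(ev$phase == "conditioning" & !(ev$cue_role %in% c("B", "D"))))
    abort_validation("%s: conditioning rows must have cue_role B or D", where)
  data.table::setattr(ev, "class", unique(c("event_table", class(ev))))
  ev
}

#' Write an events table as BIDS-style TSV
#'
#' Missing values become `n/a`; missing response times are written as `n/a`,
#' never 0.
#' @param events event table.
#' @param path output TSV path.
#' @export
write_events <- function(events, path) {
  ev <- data.table::as.data.table(events)
  out <- data.table::copy(ev)
  for (col in names(out)) {
    v <- out[[col]]
    if (is.numeric(v)) v <- formatC(v, format = "g", digits = 15)
    v[is.na(out[[col]])] <- "n/a"
    data.table::set(out, j = col, value = v)
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a results table with a JSON provenance sidecar
#'
#' The table is written as TSV with a stable column order (as given) and a
#' `.json` sidecar records the configuration, seed and package version, so
#' any result file can be traced to the run that produced it.
#'
#' @param table a data.frame of results.
#' @param path output TSV path.
#' @param config optional list recorded in the sidecar.
#' @param seed optional seed recorded in the sidecar.
#' @export
write_results <- function(table, path, config = NULL, seed = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tb <- data.table::as.data.table(table)
  data.table::fwrite(tb, path, sep = "\t", quote = FALSE, na = "n/a")
  sidecar <- list(
    file = basename(path),
    package = "preconmvpa",
    version = as.character(utils::packageVersion("preconmvpa")),
    seed = seed,
    config = config
  )
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "n/a")
}
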