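#' @include AllClasses.R
NULL

# On-disk session layout:
#   <dir>/session.json   cell_id, clamp_mode, sampling_rate_hz, primary_units,
#                        command_units, holding, drug_condition, epochs[]
#   <dir>/sweep_NNN.csv  header time_s,primary,command,light (NNN from 000)
# Floats are written with 12 significant digits so read(write(x)) == x within
# numerical tolerance.

.eventCols <- c("cell_id", "condition", "event_time_s", "amplitude_pA",
                "rise_ms", "decay_ms", "correlation", "included",
                "exclusion_reason")

fmtNum <- function(x) sprintf("%.12g", x)

#' Write a sweep bundle to a session directory
#'
#' Serialises a [SweepBundle-class] to the neutral on-disk format:
#' `session.json` with the metadata and protocol epochs, and one
#' `sweep_NNN.csv` per sweep with columns `time_s,primary,command,light`
#' (time is `t0` plus sweep-local time).
#'
#' @param bundle A validated [SweepBundle-class].
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
writeBundle <- function(bundle, path) {
  methods::validObject(bundle)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stopf("cannot create directory '%s'", path)
  fs <- samplingRate(bundle)
  meta <- list(cell_id = cellId(bundle), clamp_mode = clampMode(bundle),
               sampling_rate_hz = fs, primary_units = bundle@primaryUnits,
               command_units = bundle@commandUnits, holding = bundle@holding,
               drug_condition = drugCondition(bundle),
               epochs = epochs(bundle))
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  for (i in seq_along(sweeps(bundle))) {
    s <- sweeps(bundle)[[i]]
    tt <- s$t0 + (seq_along(s$primary) - 1) / fs
    con <- file(file.path(path, sprintf("sweep_%03d.csv", i - 1)), "w")
    writeLines("time_s,primary,command,light", con)
    writeLines(paste(fmtNum(tt), fmtNum(s$primary), fmtNum(s$command),
                     as.integer(s$light), sep = ","), con)
    close(con)
  }
  invisible(path)
}

#' Read a sweep bundle from a session directory
#'
#' Inverse of [writeBundle()]. Validates the metadata/sample consistency and
#' the monotone time column.
#'
#' @param path Session directory containing `session.json` and at least one
#'   `sweep_NNN.csv`.
#' @return A validated [SweepBundle-class].
#' @export
readBundle <- function(path) {
  sj <- file.path(path, "session.json")
  if (!file.exists(sj)) stopf("not a session directory: missing %s", sj)
  meta <- jsonlite::read_json(sj, simplifyVector = TRUE)
  files <- sort(list.files(path, pattern = "^sweep_\\d{3}\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stopf("no sweep_NNN.csv files in '%s'", path)
  fs <- meta$sampling_rate_hz
  sw <- lapply(files, function(f) {
    d <- utils::read.csv(f, colClasses = "numeric")
    if (!identical(names(d), c("time_s", "primary", "command", "light")))
      stopf("unexpected sweep header in '%s'", f)
    if (nrow(d) > 1 && any(diff(d$time_s) <= 0))
      stopf("non-monotone time column in '%s'", f)
    list(t0 = d$time_s[1], primary = d$primary, command = d$command,
         light = as.integer(d$light))
  })
  ep <- meta$epochs
  if (is.null(ep) || length(ep) == 0 || NROW(ep) == 0) {
    ep <- emptyEpochs()
  } else {
    ep <- as.data.frame(ep, stringsAsFactors = FALSE)
    for (col in .epochCols) if (is.null(ep[[col]])) ep[[col]] <- NA
    ep <- ep[, .epochCols]
    ep$sweep <- as.integer(ep$sweep)
    ep$train_n <- as.integer(ep$train_n)
    for (col in setdiff(.epochCols, c("sweep", "kind", "train_n")))
      ep[[col]] <- as.numeric(ep[[col]])
  }
  SweepBundle(cellId = meta$cell_id, clampMode = meta$clamp_mode,
              samplingRate = fs, sweeps = sw, epochs = ep,
              holding = if (is.null(meta$holding)) NA_real_
                        else as.numeric(meta$holding),
              drugCondition = meta$drug_condition,
              primaryUnits = meta$primary_units,
              commandUnits = meta$command_units)
}

#' Create an empty event table
#'
#' @return Zero-row `data.frame` with the canonical event columns
#'   (`cell_id, condition, event_time_s, amplitude_pA, rise_ms, decay_ms,
#'   correlation, included, exclusion_reason`).
#' @export
emptyEventTable <- function() {
  data.frame(cell_id = character(0), condition = character(0),
             event_time_s = numeric(0), amplitude_pA = numeric(0),
             rise_ms = numeric(0), decay_ms = numeric(0),
             correlation = numeric(0), included = logical(0),
             exclusion_reason = character(0), stringsAsFactors = FALSE)
}

validateEventTable <- function(events) {
  if (!all(.eventCols %in% names(events)))
    stopf("event table must have columns: %s", paste(.eventCols,
                                                     collapse = ", "))
  extra <- setdiff(names(events), .eventCols)
  if (length(extra)) stopf("unknown event-table column(s): %s",
                           paste(extra, collapse = ", "))
  bad <- !is.na(events$included) & !events$included &
    (is.na(events$exclusion_reason) | events$exclusion_reason == "")
  if (any(bad)) stopf("excluded events must carry an exclusion_reason")
  sp <- split(events$event_time_s,
              paste(events$cell_id, events$condition, sep = "\r"))
  for (v in sp) if (length(v) > 1 && any(diff(v) <= 0))
    stopf("event_time_s must be strictly increasing within cell/condition")
  invisible(events)
}

#' Write / read an event table
#'
#' Columnar text (CSV) with the exact canonical header; lossless round trip.
#'
#' @param events Event `data.frame` (see [emptyEventTable()]).
#' @param path CSV file path.
#' @return `writeEventTable`: `path` invisibly; `readEventTable`: the table.
#' @export
writeEventTable <- function(events, path) {
  validateEventTable(events)
  con <- file(path, "w")
  writeLines(paste(.eventCols, collapse = ","), con)
  if (nrow(events))
    writeLines(paste(events$cell_id, events$condition,
                     fmtNum(events$event_time_s), fmtNum(events$amplitude_pA),
                     fmtNum(events$rise_ms), fmtNum(events$decay_ms),
                     fmtNum(events$correlation),
                     ifelse(events$included, "TRUE", "FALSE"),
                     events$exclusion_reason, sep = ","), con)
  close(con)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(cell_id = "character",
                                      condition = "character",
                                      exclusion_reason = "character"))
  if (!identical(names(d), .eventCols))
    stopf("unexpected event-table header in '%s'", path)
  d$included <- as.logical(d$included)
  d$exclusion_reason[is.na(d$exclusion_reason)] <- ""
  for (col in c("event_time_s", "amplitude_pA", "rise_ms", "decay_ms",
                "correlation"))
    d[[col]] <- as.numeric(d[[col]])
  validateEventTable(d)
  d
}

#' Write / read simulator ground truth
#'
#' Ground truth (planted events, model parameters, per-trial latencies, spike
#' times) is serialised as JSON alongside the session directory.
#'
#' @param gt Ground-truth list as returned by the simulators.
#' @param path JSON file path.
#' @return `writeGroundTruth`: `path` invisibly; `readGroundTruth`: the list.
#' @export
writeGroundTruth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
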