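#' @include utils.R
NULL

# Epoch kinds understood by the protocol table.
.epochKinds <- c("step", "ramp", "test_pulse", "light_pulse", "light_train",
                 "none")

.epochCols <- c("sweep", "kind", "start", "duration", "amplitude",
                "ramp_end_amplitude", "train_n", "train_pulse_ms",
                "train_interval_ms", "wavelength_nm")

#' Build a protocol-epoch table
#'
#' Epochs describe command waveforms and light stimulation in sweep-local
#' time (seconds from sweep start). `sweep` is the 1-based index of the sweep
#' an epoch belongs to.
#'
#' @param sweep Integer sweep index.
#' @param kind One of `"step"`, `"ramp"`, `"test_pulse"`, `"light_pulse"`,
#'   `"light_train"`, `"none"`.
#' @param start,duration Epoch start and duration in seconds.
#' @param amplitude Step/pulse amplitude (pA in current clamp, mV in voltage
#'   clamp); for ramps the ramp-end amplitude is given separately.
#' @param ramp_end_amplitude Final amplitude of a ramp.
#' @param train_n,train_pulse_ms,train_interval_ms Light-train shape
#'   (required iff `kind = "light_train"`).
#' @param wavelength_nm Light wavelength (460 blue, 595 red control).
#' @return One-row `data.frame` with the canonical epoch columns; rows can be
#'   concatenated with `rbind()`.
#' @export
protocolEpoch <- function(sweep, kind, start, duration, amplitude = NA_real_,
                          ramp_end_amplitude = NA_real_, train_n = NA_integer_,
                          train_pulse_ms = NA_real_,
                          train_interval_ms = NA_real_,
                          wavelength_nm = NA_real_) {
  kind <- match.arg(kind, .epochKinds)
  if (!is.numeric(duration) || duration <= 0)
    stopf("epoch duration must be > 0")
  if (kind == "light_train" &&
      (is.na(train_n) || is.na(train_pulse_ms) || is.na(train_interval_ms)))
    stopf("light_train epochs need train_n, train_pulse_ms, train_interval_ms")
  if (kind != "light_train" && !is.na(train_n))
    stopf("train fields are only valid for light_train epochs")
  data.frame(sweep = as.integer(sweep), kind = kind, start = start,
             duration = duration, amplitude = amplitude,
             ramp_end_amplitude = ramp_end_amplitude,
             train_n = as.integer(train_n),
             train_pulse_ms = train_pulse_ms,
             train_interval_ms = train_interval_ms,
             wavelength_nm = wavelength_nm,
             stringsAsFactors = FALSE)
}

emptyEpochs <- function() {
  protocolEpoch(1L, "none", 0, 1)[0, ]
}

#' SweepBundle: one cell's recording session
#'
#' Container for an ordered set of equally sampled sweeps from a single cell
#' under a single drug condition, together with the protocol epochs and clamp
#' metadata. In voltage clamp the primary signal is membrane current (pA) and
#' the command is voltage (mV); in current clamp the roles are reversed.
#' Each sweep is a list with fields `t0` (session time of the first sample,
#' seconds), `primary`, `command` and `light` (binary, 1 = light on), all
#' sample vectors of equal length.
#'
#' @slot cellId Cell identifier.
#' @slot clampMode `"voltage"` or `"current"`.
#' @slot samplingRate Sampling rate in Hz.
#' @slot primaryUnits `"pA"` (voltage clamp) or `"mV"` (current clamp).
#' @slot commandUnits `"mV"` or `"pA"`.
#' @slot holding Holding level in command units.
#' @slot drugCondition Free-text condition label (e.g. `"baseline"`,
#'   `"PTX"`, `"TTX"`).
#' @slot sweeps List of sweeps (see above).
#' @slot epochs Protocol table built from [protocolEpoch()] rows.
#' @export
setClass("SweepBundle",
  representation(cellId = "character", clampMode = "character",
                 samplingRate = "numeric", primaryUnits = "character",
                 commandUnits = "character", holding = "numeric",
                 drugCondition = "character", sweeps = "list",
                 epochs = "data.frame"))

setValidity("SweepBundle", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (!object@clampMode %in% c("voltage", "current"))
    msg <- c(msg, "clampMode must be 'voltage' or 'current'")
  want <- if (identical(object@clampMode, "voltage")) c("pA", "mV")
          else c("mV", "pA")
  if (!identical(object@primaryUnits, want[1]) ||
      !identical(object@commandUnits, want[2]))
    msg <- c(msg, sprintf(
      "%s clamp requires primary '%s' and command '%s' units",
      object@clampMode, want[1], want[2]))
  if (length(object@sweeps) == 0)
    msg <- c(msg, "bundle must contain at least one sweep")
  lens <- vapply(object@sweeps, function(s) length(s$primary), integer(1))
  for (s in object@sweeps) {
    if (!all(c("t0", "primary", "command", "light") %in% names(s))) {
      msg <- c(msg, "each sweep needs t0, primary, command, light"); break
    }
    if (length(s$command) != length(s$primary) ||
        length(s$light) != length(s$primary)) {
      msg <- c(msg, "sweep arrays must have equal length"); break
    }
    if (!all(s$light %in% c(0, 1))) {
      msg <- c(msg, "light channel must be binary 0/1"); break
    }
  }
  if (length(unique(lens)) > 1)
    msg <- c(msg, "all sweeps must have the same length")
  if (!all(.epochCols %in% names(object@epochs)))
    msg <- c(msg, "epochs must carry the canonical epoch columns")
  if (length(msg)) msg else TRUE
})

#' Construct a SweepBundle
#'
#' @param cellId,clampMode,samplingRate,holding,drugCondition,sweeps,epochs
#'   See the class documentation.
#' @param primaryUnits,commandUnits Signal units; defaulted from `clampMode`.
#' @return A validated [SweepBundle-class] object.
#' @export
SweepBundle <- function(cellId, clampMode, samplingRate, sweeps,
                        epochs = emptyEpochs(), holding = NA_real_,
                        drugCondition = "baseline",
                        primaryUnits = NULL, commandUnits = NULL) {
  if (is.null(primaryUnits))
    primaryUnits <- if (clampMode == "voltage") "pA" else "mV"
  if (is.null(commandUnits))
    commandUnits <- if (clampMode == "voltage") "mV" else "pA"
  methods::new("SweepBundle", cellId = cellId, clampMode = clampMode,
               samplingRate = samplingRate, primaryUnits = primaryUnits,
               commandUnits = commandUnits, holding = holding,
               drugCondition = drugCondition, sweeps = sweeps,
               epochs = epochs)
}

#' @describeIn SweepBundle Cell identifier.
#' @param object,x A `SweepBundle`.
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))
#' @rdname SweepBundle-class
#' @export
setMethod("cellId", "SweepBundle", function(object) object@cellId)

#' @rdname SweepBundle-class
#' @export
setGeneric("clampMode", function(object) standardGeneric("clampMode"))
#' @rdname SweepBundle-class
#' @export
setMethod("clampMode", "SweepBundle", function(object) object@clampMode)

#' @rdname SweepBundle-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname SweepBundle-class
#' @export
setMethod("samplingRate", "SweepBundle", function(object) object@samplingRate)

#' @rdname SweepBundle-class
#' @export
setGeneric("sweeps", function(object) standardGeneric("sweeps"))
#' @rdname SweepBundle-class
#' @export
setMethod("sweeps", "SweepBundle", function(object) object@sweeps)

#' @rdname SweepBundle-class
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))
#' @rdname SweepBundle-class
#' @export
setMethod("epochs", "SweepBundle", function(object) object@epochs)

#' @rdname SweepBundle-class
#' @export
setGeneric("drugCondition", function(object) standardGeneric("drugCondition"))
#' @rdname SweepBundle-class
#' @export
setMethod("drugCondition", "SweepBundle",
          function(object) object@drugCondition)

#' @rdname SweepBundle-class
#' @export
setGeneric("nSweeps", function(object) standardGeneric("nSweeps"))
#' @rdname SweepBundle-class
#' @export
setMethod("nSweeps", "SweepBundle", function(object) length(object@sweeps))

#' Total recorded duration of a bundle in seconds
#' @param bundle A [SweepBundle-class].
#' @return Numeric scalar, seconds.
#' @export
bundleDuration <- function(bundle) {
  sum(vapply(sweeps(bundle),
             function(s) length(s$primary), integer(1))) /
    samplingRate(bundle)
}

setMethod("show", "SweepBundle", function(object) {
  n <- length(object@sweeps)
  len <- if (n) length(object@sweeps[[1]]$primary) else 0L
  cat(sprintf(
    "SweepBundle '%s' [%s clamp, %s]\n  %d sweep(s) x %d samples @ %g Hz, holding %g %s\n  %d epoch(s)\n",
    object@cellId, object@clampMode, object@drugCondition, n, len,
    object@samplingRate, object@holding, object@commandUnits,
    nrow(object@epochs)))
})

#' PSCTemplate: detection template for postsynaptic currents
#'
#' A unit-peak waveform used for sliding-window correlation detection. The
#' waveform carries the event polarity in the sign of its peak (inward
#' events: peak = -1). `prePeakMs` is the length of the flat pre-event
#' segment preceding the kernel onset, used as the baseline window during
#' amplitude measurement.
#'
#' @slot waveform Numeric vector, peak magnitude 1.
#' @slot samplingRate Hz.
#' @slot prePeakMs Pre-event baseline span, ms.
#' @slot source `"parametric"` or `"averaged"`.
#' @export
setClass("PSCTemplate",
  representation(waveform = "numeric", samplingRate = "numeric",
                 prePeakMs = "numeric", source = "character"))

setValidity("PSCTemplate", function(object) {
  msg <- character(0)
  if (length(object@waveform) < 2) msg <- c(msg, "waveform too short")
  if (abs(max(abs(object@waveform)) - 1) > 1e-8)
    msg <- c(msg, "waveform peak magnitude must be 1")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (object@prePeakMs < 0) msg <- c(msg, "prePeakMs must be >= 0")
  if (!object@source %in% c("parametric", "averaged"))
    msg <- c(msg, "source must be 'parametric' or 'averaged'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PSCTemplate", function(object) {
  cat(sprintf(
    "PSCTemplate (%s): %d samples @ %g Hz, pre-peak %g ms, polarity %s\n",
    object@source, length(object@waveform), object@samplingRate,
    object@prePeakMs,
    if (min(object@waveform) < -0.5) "inward" else "outward"))
})

#' Template polarity sign
#' @param template A [PSCTemplate-class].
#' @return `-1` for inward (negative-going) templates, `+1` for outward.
#' @export
templatePolarity <- function(template) {
  if (abs(min(template@waveform)) > abs(max(template@waveform))) -1 else 1
}
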