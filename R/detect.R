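#' @include AllClasses.R kernel.R ephys_io.R
NULL

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase, DC gain
#' 1). Voltage-clamp traces are filtered at 400 Hz before event detection
#' and measurement.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate, Hz; must exceed twice the cutoff.
#' @param cutoffHz Cutoff frequency, Hz.
#' @return Filtered trace of the same length.
#' @export
lowpassTrace <- function(x, fs, cutoffHz = 400) {
  if (fs <= 2 * cutoffHz)
    stopf("sampling rate (%g Hz) must exceed twice the cutoff (%g Hz)",
          fs, cutoffHz)
  bf <- signal::butter(4, cutoffHz / (fs / 2), type = "low")
  n <- length(x)
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (which otherwise assumes zeros outside the trace)
  p <- min(n - 1, max(50L, round(10 * fs / cutoffHz)))
  if (p > 0) {
    head <- 2 * x[1] - x[(p + 1):2]
    tail <- 2 * x[n] - x[(n - 1):(n - p)]
    y <- as.numeric(signal::filtfilt(bf, c(head, x, tail)))
    y[(p + 1):(p + n)]
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

# Sliding-window Pearson correlation of `w` against `x`, hop 1 sample.
# Returns r for every full window start (length n - L + 1). Uses running
# sums for the window mean/variance and an FFT cross-correlation for the
# inner products.
slidingCorrelation <- function(x, w) {
  n <- length(x); L <- length(w)
  if (n < L) return(numeric(0))
  s1 <- cumsum(x); s2 <- cumsum(x^2)
  winSum <- s1[L:n] - c(0, s1[seq_len(n - L)])
  winSum2 <- s2[L:n] - c(0, s2[seq_len(n - L)])
  m <- stats::nextn(n + L - 1, 2)
  X <- stats::fft(c(x, numeric(m - n)))
  W <- stats::fft(c(rev(w), numeric(m - L)))
  xw <- Re(stats::fft(X * W, inverse = TRUE))[L:n] / m
  mw <- mean(w); sw <- sum((w - mw)^2)
  denom2 <- pmax(winSum2 - winSum^2 / L, 0) * sw
  r <- (xw - winSum * mw) / sqrt(denom2)
  r[denom2 <= 0] <- 0
  r
}

#' Build a postsynaptic-current detection template
#'
#' Either parametric -- a flat pre-event baseline followed by the
#' bi-exponential [pscKernel()], signed by its polarity -- or averaged from
#' at least five seed event waveforms, which are peak-aligned, averaged and
#' renormalised to unit peak magnitude.
#'
#' @param source A [pscKernelParams()] list, or a list of >= 5 numeric event
#'   windows (each containing one extremum).
#' @param fs Sampling rate, Hz.
#' @param prePeakMs Flat baseline span before the event onset (parametric)
#'   or before the aligned peak (averaged), ms.
#' @param lengthMs Total template length, ms; parametric default
#'   `prePeakMs + 3 * tauDecayMs`.
#' @return A [PSCTemplate-class].
#' @export
buildTemplate <- function(source, fs, prePeakMs = 5, lengthMs = NULL) {
  preN <- round(prePeakMs / 1000 * fs)
  if (inherits(source, "pscKernelParams")) {
    if (is.null(lengthMs)) lengthMs <- prePeakMs + 3 * source$tauDecayMs
    if (lengthMs < prePeakMs + 3 * source$tauDecayMs)
      stopf("parametric template length must cover prePeakMs + 3 tau_decay")
    tk <- seq(0, (lengthMs - prePeakMs) / 1000, by = 1 / fs)
    sgn <- if (source$polarity == "inward") -1 else 1
    w <- c(numeric(preN), sgn * pscKernel(source, tk))
    return(methods::new("PSCTemplate", waveform = w / max(abs(w)),
                        samplingRate = fs, prePeakMs = prePeakMs,
                        source = "parametric"))
  }
  if (!is.list(source) || !all(vapply(source, is.numeric, logical(1))))
    stopf("'source' must be pscKernelParams or a list of numeric windows")
  if (length(source) < 5)
    stopf("averaged templates need at least 5 seed events (got %d)",
          length(source))
  peaks <- vapply(source, function(v) which.max(abs(v - stats::median(v))),
                  integer(1))
  postN <- min(vapply(source, length, integer(1)) - peaks)
  if (min(peaks) <= preN)
    stopf("seed windows too short for a %g ms pre-peak span", prePeakMs)
  acc <- rowMeans(vapply(seq_along(source), function(i) {
    v <- source[[i]] - stats::median(source[[i]][seq_len(preN)])
    v[(peaks[i] - preN):(peaks[i] + postN)]
  }, numeric(preN + postN + 1)))
  methods::new("PSCTemplate", waveform = acc / max(abs(acc)),
               samplingRate = fs, prePeakMs = prePeakMs,
               source = "averaged")
}

#' 20-80% rise span of a template
#'
#' Interpolated interval between the 20% and 80% crossings on the rising
#' limb of the template; used as the minimum separation between accepted
#' event peaks.
#'
#' @param template A [PSCTemplate-class].
#' @return Rise span in ms.
#' @export
templateRiseSpanMs <- function(template) {
  w <- template@waveform * templatePolarity(template)  # positive-going
  pk <- which.max(w)
  seg <- w[seq_len(pk)] / w[pk]
  b20 <- which(seg[seq_len(pk - 1)] < 0.2)
  b20 <- b20[length(b20)]
  t20 <- b20 + (0.2 - seg[b20]) / (seg[b20 + 1] - seg[b20])
  a80 <- which(seg >= 0.8)[1]
  t80 <- (a80 - 1) + (0.8 - seg[a80 - 1]) / (seg[a80] - seg[a80 - 1])
  (t80 - t20) / template@samplingRate * 1000
}

#' Measure amplitude and 20-80% kinetics of one event window
#'
#' The amplitude is the absolute difference between the window extremum and
#' the supplied baseline. Rise time is the interval between the last 20% and
#' first 80% crossing of the normalised deviation before the peak; decay
#' time between the first 80% and the following 20% crossing after it, all
#' crossings linearly interpolated between samples. Windows whose crossings
#' are cut off (event truncated by the window edge or overlapped) are
#' flagged.
#'
#' @param window Numeric trace segment containing a single event extremum.
#' @param baseline Baseline level (same units as `window`).
#' @param fs Sampling rate, Hz.
#' @return `list(amplitude, rise_ms, decay_ms, truncated, peak_index)`;
#'   unmeasurable components are `NA` with `truncated = TRUE`.
#' @export
measureKinetics <- function(window, baseline, fs) {
  dev <- window - baseline
  pk <- which.max(abs(dev))
  amp <- abs(dev[pk])
  out <- list(amplitude = amp, rise_ms = NA_real_, decay_ms = NA_real_,
              truncated = TRUE, peak_index = pk)
  if (amp == 0) return(out)
  d <- abs(dev) / amp
  d[sign(dev) != sign(dev[pk])] <- 0       # opposite-polarity excursions
  # rising limb
  if (pk < 2) return(out)
  seg <- d[seq_len(pk)]
  b20 <- which(seg[seq_len(pk - 1)] < 0.2)
  if (length(b20) == 0) return(out)
  b20 <- b20[length(b20)]
  t20r <- b20 + (0.2 - seg[b20]) / (seg[b20 + 1] - seg[b20])
  a80 <- which(seg >= 0.8)[1]
  if (is.na(a80) || a80 <= b20) return(out)
  t80r <- (a80 - 1) + (0.8 - seg[a80 - 1]) / (seg[a80] - seg[a80 - 1])
  out$rise_ms <- (t80r - t20r) / fs * 1000
  # decaying limb
  segd <- d[pk:length(d)]
  if (length(segd) < 2) return(out)
  u80 <- which(segd[-1] < 0.8)[1] + 1
  if (is.na(u80) || u80 < 2) return(out)
  t80d <- (u80 - 2) + (segd[u80 - 1] - 0.8) / (segd[u80 - 1] - segd[u80])
  u20 <- which(segd < 0.2)
  u20 <- u20[u20 > u80][1]
  if (is.na(u20)) return(out)
  t20d <- (u20 - 2) + (segd[u20 - 1] - 0.2) / (segd[u20 - 1] - segd[u20])
  out$decay_ms <- (t20d - t80d) / fs * 1000
  out$truncated <- FALSE
  out
}

#' Detect postsynaptic currents by template correlation
#'
#' Low-pass filters each sweep at `cutoffHz`, slides the template along the
#' trace (hop one sample) computing the Pearson correlation of each window
#' with the template, and emits one event per contiguous supra-threshold
#' (`r >= rMin`) region at the local correlation maximum. Event amplitude is
#' the absolute difference between the window extremum and the median of the
#' pre-peak baseline window; kinetics come from [measureKinetics()].
#' Accepted peaks closer than the template's 20-80% rise span are pruned,
#' keeping the higher correlation.
#'
#' Events whose kinetics cannot be measured (truncated by the sweep edge or
#' by overlap) are emitted with `included = FALSE` and reason
#' `"truncated"`; all other events are emitted pre-filter with
#' `included = TRUE` and should be passed through [applyExclusions()].
#'
#' @param bundle Voltage-clamp [SweepBundle-class].
#' @param template [PSCTemplate-class] at the bundle's sampling rate.
#' @param rMin Correlation threshold for inclusion (default 0.6).
#' @param cutoffHz Low-pass cutoff, Hz.
#' @return Event table (see [emptyEventTable()]); times are session seconds
#'   (sweep `t0` + sweep-local peak time).
#' @export
detectEvents <- function(bundle, template, rMin = 0.6, cutoffHz = 400) {
  stopifnot(methods::is(bundle, "SweepBundle"),
            methods::is(template, "PSCTemplate"))
  if (clampMode(bundle) != "voltage")
    stopf("event detection requires a voltage-clamp bundle")
  fs <- samplingRate(bundle)
  if (abs(template@samplingRate - fs) > 1e-9)
    stopf("template sampling rate (%g) does not match the bundle (%g)",
          template@samplingRate, fs)
  w <- template@waveform
  L <- length(w)
  preN <- max(1L, round(template@prePeakMs / 1000 * fs))
  minSep <- max(1L, round(templateRiseSpanMs(template) / 1000 * fs))
  pol <- templatePolarity(template)
  rows <- list()
  for (si in seq_along(sweeps(bundle))) {
    s <- sweeps(bundle)[[si]]
    x <- lowpassTrace(s$primary, fs, cutoffHz)
    n <- length(x)
    r <- slidingCorrelation(x, w)
    above <- r >= rMin
    if (!any(above)) next
    rl <- rle(above)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    regStart <- starts[rl$values]; regEnd <- ends[rl$values]
    cand <- lapply(seq_along(regStart), function(k) {
      i0 <- regStart[k] - 1 + which.max(r[regStart[k]:regEnd[k]])
      win <- x[i0:min(n, i0 + L - 1)]
      pk <- i0 - 1 + if (pol < 0) which.min(win) else which.max(win)
      list(start = i0, peak = pk, r = max(r[regStart[k]:regEnd[k]]))
    })
    # minimum peak separation: greedy by descending correlation
    ord <- order(vapply(cand, `[[`, numeric(1), "r"), decreasing = TRUE)
    keptPeaks <- integer(0); keep <- logical(length(cand))
    for (k in ord) {
      pk <- cand[[k]]$peak
      if (!any(abs(keptPeaks - pk) < minSep)) {
        keep[k] <- TRUE
        keptPeaks <- c(keptPeaks, pk)
      }
    }
    for (cd in cand[keep]) {
      baseEnd <- max(1, cd$start + preN - 1)
      base <- stats::median(x[cd$start:min(baseEnd, cd$peak - 1)])
      win <- x[cd$start:min(n, cd$start + L - 1)]
      kin <- measureKinetics(win, base, fs)
      pkIdx <- cd$start - 1 + kin$peak_index
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = cellId(bundle), condition = drugCondition(bundle),
        event_time_s = s$t0 + (pkIdx - 1) / fs,
        amplitude_pA = kin$amplitude, rise_ms = kin$rise_ms,
        decay_ms = kin$decay_ms, correlation = cd$r,
        included = !kin$truncated,
        exclusion_reason = if (kin$truncated) "truncated" else "",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(emptyEventTable())
  out <- do.call(rbind, rows)
  out <- out[order(out$event_time_s), , drop = FALSE]
  out <- out[!duplicated(out$event_time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the four event exclusion criteria
#'
#' Events are excluded when (1) amplitude < `minAmplitudePa`, (2) rise time
#' > `maxRiseMs`, (3) decay time > `maxDecayMs`, or (4) decay time <
#' `minDecayRiseRatio` times the rise time. Rules are evaluated in that
#' order and the first failure is recorded; boundary values (exactly 5 pA,
#' 3 ms, 20 ms, decay exactly 1.5 x rise) pass. Events already excluded as
#' `"truncated"` are left untouched.
#'
#' @param events Event table from [detectEvents()].
#' @param minAmplitudePa,maxRiseMs,maxDecayMs,minDecayRiseRatio Thresholds;
#'   defaults 5 pA, 3 ms, 20 ms, 1.5.
#' @return The event table with `included` / `exclusion_reason` set.
#' @export
applyExclusions <- function(events, minAmplitudePa = 5, maxRiseMs = 3,
                            maxDecayMs = 20, minDecayRiseRatio = 1.5) {
  if (nrow(events) == 0) return(events)
  open <- events$exclusion_reason != "truncated"
  reason <- rep("", nrow(events))
  reason[open & events$amplitude_pA < minAmplitudePa] <- "amplitude"
  hit <- function(cond) open & reason == "" & !is.na(cond) & cond
  reason[hit(events$rise_ms > maxRiseMs)] <- "rise_time"
  reason[hit(events$decay_ms > maxDecayMs)] <- "decay_time"
  reason[hit(events$decay_ms < minDecayRiseRatio * events$rise_ms)] <-
    "decay_rise_ratio"
  events$included[open] <- reason[open] == ""
  events$exclusion_reason[open] <- reason[open]
  events
}

#' Equal-representation subsampling of events
#'
#' Draws the same number of included events per cell and condition,
#' uniformly without replacement, so that no neuron dominates pooled
#' statistics. Deterministic given `seed`.
#'
#' @param events Event table (post-exclusion).
#' @param n Events per cell/condition; default the minimum group size.
#' @param seed Seed.
#' @return Subsampled event table (included events only), time-sorted within
#'   groups.
#' @export
subsampleEqual <- function(events, n = NULL, seed = NULL) {
  inc <- events[!is.na(events$included) & events$included, , drop = FALSE]
  grp <- paste(inc$cell_id, inc$condition, sep = " / ")
  sizes <- table(grp)
  if (length(sizes) == 0) stopf("no included events to subsample")
  if (is.null(n)) n <- min(sizes)
  deficit <- sizes[sizes < n]
  if (length(deficit))
    stopf("cells with fewer than %d included events: %s", n,
          paste(sprintf("%s (%d)", names(deficit), deficit),
                collapse = ", "))
  withSeed(seed, {
    idx <- unlist(lapply(split(seq_len(nrow(inc)), grp),
                         function(ii) ii[sort(sample.int(length(ii), n))]))
  })
  out <- inc[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inter-event intervals of included events
#'
#' Intervals between consecutive included events within each cell and
#' condition, in ms.
#'
#' @param events Event table.
#' @return Numeric vector of intervals (ms), pooled across groups.
#' @export
eventIEIs <- function(events) {
  inc <- events[!is.na(events$included) & events$included, , drop = FALSE]
  unlist(lapply(split(inc$event_time_s,
                      paste(inc$cell_id, inc$condition, sep = " / ")),
                function(tt) if (length(tt) > 1) diff(sort(tt)) * 1000
                             else numeric(0)),
         use.names = FALSE)
}

#' Per-cell event summary
#'
#' Frequency is defined as included events per analysed duration, and the
#' mean inter-event interval over consecutive included events; the two are
#' deliberately computed independently (they are not reciprocal for
#' non-stationary trains).
#'
#' @param events Event table for one cell and condition.
#' @param analyzedDurationS Analysed recording duration, s (> 0).
#' @return One-row `data.frame(cell_id, condition, n_events,
#'   mean_amplitude_pA, mean_iei_ms, frequency_hz, analyzed_duration_s)`;
#'   `mean_iei_ms` is `NA` with fewer than two events.
#' @export
summarizeCell <- function(events, analyzedDurationS) {
  if (!is.numeric(analyzedDurationS) || analyzedDurationS <= 0)
    stopf("analyzedDurationS must be > 0")
  inc <- events[!is.na(events$included) & events$included, , drop = FALSE]
  if (nrow(inc) > 0 &&
      (length(unique(inc$cell_id)) > 1 ||
       length(unique(inc$condition)) > 1))
    stopf("summarizeCell expects events from a single cell and condition")
  iei <- if (nrow(inc) > 1) diff(sort(inc$event_time_s)) * 1000 else NA_real_
  data.frame(
    cell_id = if (nrow(events)) events$cell_id[1] else NA_character_,
    condition = if (nrow(events)) events$condition[1] else NA_character_,
    n_events = nrow(inc),
    mean_amplitude_pA = if (nrow(inc)) mean(inc$amplitude_pA) else NA_real_,
    mean_iei_ms = mean(iei),
    frequency_hz = nrow(inc) / analyzedDurationS,
    analyzed_duration_s = analyzedDurationS,
    stringsAsFactors = FALSE)
}

#' Average per-cell frequency change between paired conditions
#'
#' Per cell, the percent change `100 (f_base - f_drug) / f_base`, averaged
#' across cells.
#'
#' @param fBaseHz,fDrugHz Per-cell frequencies under baseline and drug
#'   (same order and length).
#' @return `list(per_cell_pct, mean_pct, sem_pct)`.
#' @export
frequencyChangePct <- function(fBaseHz, fDrugHz) {
  stopifnot(length(fBaseHz) == length(fDrugHz))
  pc <- 100 * (fBaseHz - fDrugHz) / fBaseHz
  list(per_cell_pct = pc, mean_pct = mean(pc),
       sem_pct = stats::sd(pc) / sqrt(length(pc)))
}
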