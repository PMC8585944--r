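#' @include AllClasses.R detect.R
NULL

#' Resting membrane potential
#'
#' Mean voltage over the first `windowS` seconds of the zero-current epoch
#' (a sweep whose command is identically zero), with +/- 5 ms around any
#' spike masked before averaging.
#'
#' @param bundle Current-clamp [SweepBundle-class] containing a zero-current
#'   sweep.
#' @param windowS Averaging window, s.
#' @return RMP in mV.
#' @export
measureRMP <- function(bundle, windowS = 1) {
  stopifnot(methods::is(bundle, "SweepBundle"))
  if (clampMode(bundle) != "current")
    stopf("RMP is measured in current clamp")
  fs <- samplingRate(bundle)
  zi <- which(vapply(sweeps(bundle), function(s) all(s$command == 0),
                     logical(1)))[1]
  if (is.na(zi)) stopf("no zero-current epoch in this bundle")
  v <- sweeps(bundle)[[zi]]$primary
  n <- min(length(v), round(windowS * fs))
  v <- v[seq_len(n)]
  sp <- detectAPs(v, fs)
  mask <- rep(TRUE, n)
  if (nrow(sp)) {
    half <- round(0.005 * fs)
    for (pk in round(sp$time_s * fs) + 1)
      mask[max(1, pk - half):min(n, pk + half)] <- FALSE
  }
  mean(v[mask])
}

#' Series and input resistance from a test pulse
#'
#' From a small voltage pulse of amplitude dV: `Rs = dV / I_peak` (peak of
#' the capacitive transient), `R_total = dV / I_steady` (mean of the last
#' 25% of the pulse, baseline-subtracted) and `Ri = R_total - Rs`.
#'
#' @param bundle Voltage-clamp [SweepBundle-class] with a `test_pulse`
#'   epoch.
#' @return `list(r_series_mohm, r_input_mohm, rs_resolved)`;
#'   `rs_resolved = FALSE` (with `r_series_mohm = NA`) when the transient
#'   peak does not exceed 3 x the baseline noise sd.
#' @export
measureResistances <- function(bundle) {
  stopifnot(methods::is(bundle, "SweepBundle"))
  ep <- epochs(bundle)
  ep <- ep[ep$kind == "test_pulse", , drop = FALSE]
  if (nrow(ep) == 0) stopf("no test_pulse epoch in this bundle")
  ep <- ep[1, ]
  if (is.na(ep$amplitude) || ep$amplitude == 0)
    stopf("test pulse amplitude must be nonzero")
  fs <- samplingRate(bundle)
  s <- sweeps(bundle)[[ep$sweep]]
  i0 <- round(ep$start * fs) + 1
  i1 <- min(length(s$primary), i0 + round(ep$duration * fs) - 1)
  base <- mean(s$primary[seq_len(max(1, i0 - 1))])
  noiseSd <- stats::sd(s$primary[seq_len(max(2, i0 - 1))])
  pulse <- s$primary[i0:i1] - base
  pk <- max(abs(pulse))
  steadyIdx <- seq(floor(length(pulse) * 0.75) + 1, length(pulse))
  steady <- mean(pulse[steadyIdx])
  dV <- ep$amplitude
  rTotal <- 1000 * dV / steady               # mV / pA -> MOhm via 1000x
  resolved <- pk > 3 * noiseSd
  rs <- if (resolved) abs(1000 * dV / (sign(dV) * pk)) else NA_real_
  list(r_series_mohm = rs,
       r_input_mohm = if (resolved) rTotal - rs else rTotal,
       rs_resolved = resolved)
}

#' Detect action potentials and their features
#'
#' Spikes are upward crossings of `dV/dt >= dvdtThreshMvMs` followed by a
#' voltage peak of at least `minPeakMv` within 5 ms. Threshold is the
#' voltage at the last such crossing before the peak; amplitude is peak
#' minus threshold; duration is the width of the spike at the threshold
#' voltage; AHP is threshold minus the deepest voltage between the peak and
#' the next spike (or trace end).
#'
#' @param v Current-clamp voltage trace, mV.
#' @param fs Sampling rate, Hz.
#' @param dvdtThreshMvMs Rate-of-rise criterion, mV/ms.
#' @param minPeakMv Minimum spike apex, mV.
#' @return `data.frame(time_s, threshold_mv, peak_mv, amplitude_mv,
#'   duration_ms, ahp_mv)`; zero rows when no spikes.
#' @export
detectAPs <- function(v, fs, dvdtThreshMvMs = 10, minPeakMv = -10) {
  n <- length(v)
  empty <- data.frame(time_s = numeric(0), threshold_mv = numeric(0),
                      peak_mv = numeric(0), amplitude_mv = numeric(0),
                      duration_ms = numeric(0), ahp_mv = numeric(0))
  if (n < 3) return(empty)
  dvdt <- diff(v) * fs / 1000                 # mV/ms
  up <- which(dvdt[-1] >= dvdtThreshMvMs & dvdt[-length(dvdt)] <
                dvdtThreshMvMs) + 1
  if (length(up) == 0) return(empty)
  win <- round(0.005 * fs)
  peaks <- integer(0)
  for (i in up) {
    j <- i:min(n, i + win)
    pk <- j[which.max(v[j])]
    if (v[pk] >= minPeakMv) peaks <- c(peaks, pk)
  }
  peaks <- sort(unique(peaks))
  if (length(peaks) == 0) return(empty)
  # merge apex candidates within a 2 ms refractory span (keep the highest)
  refr <- round(0.002 * fs)
  merged <- integer(0)
  grp <- peaks[1]
  for (pk in peaks[-1]) {
    if (pk - grp[length(grp)] <= refr) grp <- c(grp, pk)
    else {
      merged <- c(merged, grp[which.max(v[grp])])
      grp <- pk
    }
  }
  peaks <- c(merged, grp[which.max(v[grp])])
  rows <- lapply(seq_along(peaks), function(k) {
    pk <- peaks[k]
    cr <- up[up <= pk & up > pk - win]
    cr <- cr[length(cr)]
    if (length(cr) == 0) return(NULL)
    thr <- v[cr]
    # width at threshold: crossings flanking the peak
    iDown <- pk + which(v[(pk + 1):min(n, pk + 20 * win)] <= thr)[1]
    dur <- if (is.na(iDown)) NA_real_ else (iDown - cr) / fs * 1000
    nxt <- if (k < length(peaks)) peaks[k + 1] else n
    ahp <- if (nxt > pk + 1) thr - min(v[(pk + 1):nxt]) else NA_real_
    data.frame(time_s = (pk - 1) / fs, threshold_mv = thr, peak_mv = v[pk],
               amplitude_mv = v[pk] - thr, duration_ms = dur, ahp_mv = ahp)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Maximum spike count over a square-step series
#'
#' Counts action potentials within each step epoch and reports the maximum
#' over the series together with the corresponding sustained rate
#' (max count / step duration).
#'
#' @param bundle Current-clamp [SweepBundle-class] with `step` epochs.
#' @param ... Passed to [detectAPs()].
#' @return `list(per_step = data.frame(step_pa, n_spikes), max_count,
#'   sustained_rate_hz)`.
#' @export
maxAPCount <- function(bundle, ...) {
  stopifnot(methods::is(bundle, "SweepBundle"))
  ep <- epochs(bundle)
  ep <- ep[ep$kind == "step", , drop = FALSE]
  if (nrow(ep) == 0) stopf("no step epochs in this bundle")
  fs <- samplingRate(bundle)
  counts <- vapply(seq_len(nrow(ep)), function(i) {
    s <- sweeps(bundle)[[ep$sweep[i]]]
    sp <- detectAPs(s$primary, fs, ...)
    sum(sp$time_s >= ep$start[i] & sp$time_s < ep$start[i] + ep$duration[i])
  }, numeric(1))
  dur <- ep$duration[1]
  list(per_step = data.frame(step_pa = ep$amplitude, n_spikes = counts),
       max_count = max(counts),
       sustained_rate_hz = max(counts) / dur)
}

#' Extract Na/K current-voltage curves from a voltage-step series
#'
#' Leak and capacitive currents are removed by scaled subtraction of the
#' most hyperpolarised (-90 mV) step, whose trace contains no voltage-gated
#' current; the scale factor is the ratio of command excursions. Per step,
#' the transient inward Na peak is the minimum within `naWindowMs` of step
#' onset, and the sustained K current is the mean of the last `kWindowMs`
#' of the step. When a drug bundle is supplied with the same step set, the
#' drug-sensitive component (control minus drug) is returned as its own
#' curve.
#'
#' @param bundle Voltage-clamp step-series [SweepBundle-class].
#' @param drugBundle Optional matching bundle recorded under a channel
#'   blocker.
#' @param naWindowMs Na peak search window from step onset, ms.
#' @param kWindowMs Sustained-current window at the end of the step, ms.
#' @return `list(curve, noise_sd_pa)` where `curve` is
#'   `data.frame(step_mv, na_peak_pA, k_sustained_pA)` with attribute
#'   `condition`; plus `sensitive` (control - drug) when `drugBundle` is
#'   given.
#' @export
extractIV <- function(bundle, drugBundle = NULL, naWindowMs = 10,
                      kWindowMs = 20) {
  one <- function(b) {
    ep <- epochs(b)
    ep <- ep[ep$kind == "step", , drop = FALSE]
    if (nrow(ep) == 0) stopf("no step epochs in this bundle")
    fs <- samplingRate(b)
    ref <- which.min(ep$amplitude)
    refSweep <- sweeps(b)[[ep$sweep[ref]]]
    hold <- refSweep$command[1]
    refI0 <- round(ep$start[ref] * fs) + 1
    refDV <- ep$amplitude[ref] - hold
    rows <- lapply(seq_len(nrow(ep)), function(i) {
      s <- sweeps(b)[[ep$sweep[i]]]
      i0 <- round(ep$start[i] * fs) + 1
      i1 <- i0 + round(ep$duration[i] * fs) - 1
      scale <- (ep$amplitude[i] - hold) / refDV
      sub <- s$primary[i0:i1] - scale * refSweep$primary[refI0:(refI0 +
                                                                  i1 - i0)]
      naIdx <- seq_len(round(naWindowMs / 1000 * fs))
      kIdx <- (length(sub) - round(kWindowMs / 1000 * fs) + 1):length(sub)
      data.frame(step_mv = ep$amplitude[i], na_peak_pA = min(sub[naIdx]),
                 k_sustained_pA = mean(sub[kIdx]))
    })
    curve <- do.call(rbind, rows)
    curve <- curve[order(curve$step_mv), ]
    rownames(curve) <- NULL
    attr(curve, "condition") <- drugCondition(b)
    # residual noise of the subtracted reference step (self-subtraction is
    # exact, so this is sqrt(2) x the trace noise at unit scale)
    noiseSd <- stats::sd(refSweep$primary[seq_len(max(2, refI0 - 1))])
    list(curve = curve, noise_sd_pa = noiseSd)
  }
  a <- one(bundle)
  if (is.null(drugBundle)) return(a)
  b <- one(drugBundle)
  if (!isTRUE(all.equal(a$curve$step_mv, b$curve$step_mv)))
    stopf("control and drug bundles use different step sets")
  sens <- data.frame(step_mv = a$curve$step_mv,
                     na_peak_pA = a$curve$na_peak_pA - b$curve$na_peak_pA,
                     k_sustained_pA = a$curve$k_sustained_pA -
                       b$curve$k_sustained_pA)
  attr(sens, "condition") <- sprintf("%s - %s",
                                     attr(a$curve, "condition"),
                                     attr(b$curve, "condition"))
  list(curve = a$curve, drug_curve = b$curve, sensitive = sens,
       noise_sd_pa = a$noise_sd_pa)
}
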