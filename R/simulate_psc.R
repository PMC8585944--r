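#' @include kernel.R ephys_io.R
NULL

#' Event-train parameters
#'
#' Homogeneous Poisson arrival of synaptic events. The default rate is the
#' baseline spontaneous-event frequency observed in mature cultures
#' (about 1 Hz).
#'
#' @param rateHz Poisson rate (Hz), >= 0.
#' @param durationS Total recorded duration (s), > 0.
#' @param seed Integer seed or `NULL`.
#' @return Parameter list of class `"eventTrainParams"`.
#' @export
eventTrainParams <- function(rateHz = 1.01, durationS = 120, seed = NULL) {
  checkScalar(rateHz, "rateHz", 0)
  checkScalar(durationS, "durationS", 0, strict_lower = TRUE)
  structure(list(rateHz = rateHz, durationS = durationS, seed = seed),
            class = "eventTrainParams")
}

#' Recording-noise parameters
#'
#' Additive Gaussian baseline noise. The default standard deviation is a
#' quarter of the target peak-to-peak noise floor, so that ~95% of the
#' peak-to-peak excursion (the 2.5-97.5 percentile span, 3.92 sd) stays
#' within the floor. The 4 pA default floor matches a typical patch-clamp
#' amplifier's intrinsic noise.
#'
#' @param gaussianSdPa Noise standard deviation (pA), > 0. Defaults to
#'   `targetP2pFloorPa / 4`.
#' @param targetP2pFloorPa Target peak-to-peak noise floor (pA).
#' @return Parameter list of class `"noiseParams"`.
#' @export
noiseParams <- function(gaussianSdPa = targetP2pFloorPa / 4,
                        targetP2pFloorPa = 4) {
  checkScalar(gaussianSdPa, "gaussianSdPa", 0, strict_lower = TRUE)
  structure(list(gaussianSdPa = gaussianSdPa,
                 targetP2pFloorPa = targetP2pFloorPa),
            class = "noiseParams")
}

# Draw Poisson event times and log-normal amplitudes; shared by the PSC and
# opto simulators. Returns data.frame(time_s, amplitude_pA).
drawEventTrain <- function(rateHz, durationS, kernel) {
  if (rateHz * durationS > 1e6)
    stopf("event train too large (rate * duration > 1e6 events)")
  n <- stats::rpois(1, rateHz * durationS)
  if (n == 0)
    return(data.frame(time_s = numeric(0), amplitude_pA = numeric(0)))
  times <- sort(stats::runif(n, 0, durationS))
  if (kernel$amplitudeCv > 0) {
    sdlog <- sqrt(log(1 + kernel$amplitudeCv^2))
    meanlog <- log(kernel$amplitudeMeanPa) - sdlog^2 / 2
    amps <- stats::rlnorm(n, meanlog, sdlog)
  } else {
    amps <- rep(kernel$amplitudeMeanPa, n)
  }
  data.frame(time_s = times, amplitude_pA = amps)
}

# Add signed kernels at the given sweep-local times into a trace vector.
addEventsToTrace <- function(x, times, amps, kernel, fs) {
  if (length(times) == 0) return(x)
  tk <- seq(0, 5 * kernel$tauDecayMs / 1000, by = 1 / fs)
  kshape <- pscKernel(kernel, tk)
  sign <- if (kernel$polarity == "inward") -1 else 1
  n <- length(x)
  for (j in seq_along(times)) {
    i0 <- round(times[j] * fs) + 1
    if (i0 > n) next
    idx <- i0:min(n, i0 + length(kshape) - 1)
    x[idx] <- x[idx] + sign * amps[j] * kshape[seq_along(idx)]
  }
  x
}

#' Simulate a spontaneous-PSC voltage-clamp session
#'
#' Generates a voltage-clamp bundle held at -70 mV containing bi-exponential
#' postsynaptic currents arriving as a Poisson process on a Gaussian noise
#' floor, together with the ground truth of every planted event.
#'
#' @param kernel [pscKernelParams()] event shape/amplitude model.
#' @param train [eventTrainParams()] arrival process; `train$durationS` is
#'   split into `nSweeps` sweeps of `sweepLenS` when those are given.
#' @param noise [noiseParams()].
#' @param nSweeps Number of sweeps (default 1).
#' @param sweepLenS Sweep length in seconds (default `train$durationS /
#'   nSweeps`).
#' @param fs Sampling rate, Hz.
#' @param cellId Cell label.
#' @param condition Drug-condition label stored in the bundle.
#' @param seed Integer seed (overrides `train$seed`).
#' @return `list(bundle = SweepBundle, groundTruth = list(...))`; the ground
#'   truth records every planted event time (session seconds, event onset),
#'   its peak time, amplitude and the generator parameters.
#' @export
simulatePSCSession <- function(kernel = pscKernelParams(),
                               train = eventTrainParams(),
                               noise = noiseParams(), nSweeps = 1,
                               sweepLenS = train$durationS / nSweeps,
                               fs = 1e4, cellId = "cell01",
                               condition = "baseline", seed = train$seed) {
  stopifnot(inherits(kernel, "pscKernelParams"),
            inherits(train, "eventTrainParams"),
            inherits(noise, "noiseParams"))
  withSeed(seed, {
    total <- nSweeps * sweepLenS
    ev <- drawEventTrain(train$rateHz, total, kernel)
    nsamp <- round(sweepLenS * fs)
    sw <- vector("list", nSweeps)
    for (i in seq_len(nSweeps)) {
      t0 <- (i - 1) * sweepLenS
      x <- stats::rnorm(nsamp, 0, noise$gaussianSdPa)
      sel <- ev$time_s >= t0 & ev$time_s < t0 + sweepLenS
      x <- addEventsToTrace(x, ev$time_s[sel] - t0, ev$amplitude_pA[sel],
                            kernel, fs)
      sw[[i]] <- list(t0 = t0, primary = x, command = rep(-70, nsamp),
                      light = integer(nsamp) + 0)
    }
    gt <- list(kind = "psc_session",
               events = data.frame(
                 onset_time_s = ev$time_s,
                 peak_time_s = ev$time_s + kernelPeakTime(kernel),
                 amplitude_pA = ev$amplitude_pA),
               rate_hz = train$rateHz, duration_s = total,
               kernel = unclass(kernel), noise = unclass(noise),
               seed = seed)
    list(bundle = SweepBundle(cellId = cellId, clampMode = "voltage",
                              samplingRate = fs, sweeps = sw,
                              holding = -70, drugCondition = condition),
         groundTruth = gt)
  })
}
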