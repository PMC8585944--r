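#' @include simulate_psc.R simulate_neuron.R
NULL

#' Channelrhodopsin photocurrent parameters
#'
#' Single-exponential activation toward a desensitising plateau during the
#' light pulse and exponential deactivation after light-off:
#' `g(t) = gMax a(t) d(t)` with `a` rising with `tauOn` and `d` decaying from
#' 1 to `1 - desensFraction` with `tauDesens`. The photocurrent at holding
#' potential V is `g (V - eRev)`, inward (negative) at -70 mV.
#'
#' @param gMaxNs Peak light-gated conductance, nS (0 disables the
#'   photocurrent).
#' @param eRevMv Reversal potential, mV.
#' @param tauOnMs,tauOffMs Activation/deactivation time constants, ms.
#' @param desensFraction Fraction of the peak conductance lost to
#'   desensitisation at steady state, in \[0, 1\].
#' @param tauDesensMs Desensitisation time constant, ms.
#' @return Parameter list of class `"chr2Params"`.
#' @export
chr2Params <- function(gMaxNs = 2, eRevMv = 0, tauOnMs = 2, tauOffMs = 10,
                       desensFraction = 0.3, tauDesensMs = 50) {
  checkScalar(gMaxNs, "gMaxNs", 0)
  checkScalar(desensFraction, "desensFraction", 0, 1)
  checkScalar(tauOnMs, "tauOnMs", 0, strict_lower = TRUE)
  checkScalar(tauOffMs, "tauOffMs", 0, strict_lower = TRUE)
  checkScalar(tauDesensMs, "tauDesensMs", 0, strict_lower = TRUE)
  structure(list(gMaxNs = gMaxNs, eRevMv = eRevMv, tauOnMs = tauOnMs,
                 tauOffMs = tauOffMs, desensFraction = desensFraction,
                 tauDesensMs = tauDesensMs), class = "chr2Params")
}

#' Optogenetic circuit parameters for a downstream (synaptically driven) cell
#'
#' A cell that receives light-evoked synaptic input from channelrhodopsin-
#' expressing presynaptic partners responds at a per-cell characteristic
#' latency after light onset with small trial-to-trial jitter, on top of its
#' spontaneous background activity.
#'
#' @param nTrials Number of light trials (sweeps).
#' @param latencyMeanMs Cell-characteristic response latency, ms (>= 0).
#' @param latencyJitterSdMs Across-trial jitter sd, ms.
#' @param synapseClass `"gaba"` or `"glut"` (label only; determines which
#'   blocker abolishes the response).
#' @param direct If `TRUE` the cell is treated as directly light-gated and
#'   the latency is 0.
#' @param baselineRateHz Spontaneous background event rate, Hz.
#' @return Parameter list of class `"optoCircuitParams"`.
#' @export
optoCircuitParams <- function(nTrials = 20, latencyMeanMs = 15,
                              latencyJitterSdMs = 1,
                              synapseClass = c("gaba", "glut"),
                              direct = FALSE, baselineRateHz = 0.5) {
  synapseClass <- match.arg(synapseClass)
  checkScalar(latencyMeanMs, "latencyMeanMs", 0)
  checkScalar(latencyJitterSdMs, "latencyJitterSdMs", 0)
  checkScalar(baselineRateHz, "baselineRateHz", 0)
  if (nTrials < 1) stopf("nTrials must be >= 1")
  if (direct) latencyMeanMs <- 0
  structure(list(nTrials = as.integer(nTrials),
                 latencyMeanMs = latencyMeanMs,
                 latencyJitterSdMs = latencyJitterSdMs,
                 synapseClass = synapseClass, direct = direct,
                 baselineRateHz = baselineRateHz),
            class = "optoCircuitParams")
}

# Light channel for one sweep: 500 ms pulse or 5 x 3 ms train @ 97 ms gaps.
lightChannel <- function(nSamp, fs, onsetS, protocol, pulseS = 0.5,
                         trainN = 5, trainPulseMs = 3, trainIntervalMs = 97) {
  light <- integer(nSamp)
  on <- round(onsetS * fs) + 1
  if (protocol == "pulse") {
    light[on:min(nSamp, on + round(pulseS * fs) - 1)] <- 1L
    starts <- onsetS
  } else {
    period <- (trainPulseMs + trainIntervalMs) / 1000
    starts <- onsetS + (seq_len(trainN) - 1) * period
    for (s in starts) {
      i0 <- round(s * fs) + 1
      light[i0:min(nSamp, i0 + round(trainPulseMs / 1000 * fs) - 1)] <- 1L
    }
  }
  list(light = light, pulseStarts = starts)
}

chr2Conductance <- function(nSamp, fs, light, p) {
  g <- numeric(nSamp)
  tms <- 1000 / fs
  a <- 0; d <- 1
  for (i in seq_len(nSamp)) {
    if (light[i] > 0) {
      a <- a + tms * (1 - a) / p$tauOnMs
      d <- d + tms * ((1 - p$desensFraction) - d) / p$tauDesensMs
    } else {
      a <- a - tms * a / p$tauOffMs
    }
    g[i] <- p$gMaxNs * a * d
  }
  g
}

#' Simulate an optogenetic stimulation session
#'
#' Generates voltage-clamp sweeps with a populated light channel. Exactly one
#' of `chr2` (a directly light-gated, channelrhodopsin-expressing cell) or
#' `circuit` (a downstream cell receiving light-evoked synaptic input at a
#' fixed per-cell latency) must be supplied. Downstream cells additionally
#' show spontaneous background events at `circuit$baselineRateHz`. With
#' `redControl = TRUE`, an equal number of control sweeps with 595 nm light
#' (to which channelrhodopsin is insensitive) is appended; they contain no
#' light-locked response.
#'
#' @param chr2 [chr2Params()] or `NULL`.
#' @param circuit [optoCircuitParams()] or `NULL`.
#' @param kernel [pscKernelParams()] shape of the evoked/background events.
#' @param noise [noiseParams()].
#' @param protocol `"pulse"` (500 ms) or `"train"` (5 x 3 ms, 97 ms
#'   intervals).
#' @param sweepDurS Sweep duration, s.
#' @param lightOnsetS Light onset within the sweep, s.
#' @param redControl Append 595 nm control sweeps.
#' @param holdingMv Holding potential, mV.
#' @param fs Sampling rate, Hz.
#' @param cellId Cell label.
#' @param seed Seed.
#' @return `list(bundle, groundTruth)`; ground truth records the per-trial
#'   planted latencies (ms) and all background event times.
#' @export
simulateOptoSession <- function(chr2 = NULL, circuit = NULL,
                                kernel = pscKernelParams(),
                                noise = noiseParams(),
                                protocol = c("pulse", "train"),
                                sweepDurS = 1, lightOnsetS = 0.2,
                                redControl = FALSE, holdingMv = -70,
                                fs = 1e4, cellId = "cell01", seed = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(chr2) == is.null(circuit))
    stopf("supply exactly one of 'chr2' or 'circuit'")
  nTrials <- if (is.null(circuit)) 20L else circuit$nTrials
  nSamp <- round(sweepDurS * fs)
  lc <- lightChannel(nSamp, fs, lightOnsetS, protocol)
  withSeed(seed, {
    sw <- list(); ep <- list()
    latencies <- rep(NA_real_, nTrials)
    bgTimes <- list()
    mkEpoch <- function(i, wl) {
      if (protocol == "pulse")
        protocolEpoch(i, "light_pulse", lightOnsetS, 0.5,
                      wavelength_nm = wl)
      else
        protocolEpoch(i, "light_train", lightOnsetS,
                      5 * 0.003 + 4 * 0.097, train_n = 5L,
                      train_pulse_ms = 3, train_interval_ms = 97,
                      wavelength_nm = wl)
    }
    for (i in seq_len(nTrials)) {
      x <- stats::rnorm(nSamp, 0, noise$gaussianSdPa)
      if (!is.null(chr2)) {
        g <- chr2Conductance(nSamp, fs, lc$light, chr2)
        x <- x + g * (holdingMv - chr2$eRevMv)
      } else {
        bg <- drawEventTrain(circuit$baselineRateHz, sweepDurS, kernel)
        x <- addEventsToTrace(x, bg$time_s, bg$amplitude_pA, kernel, fs)
        bgTimes[[i]] <- bg$time_s
        lat <- max(0, stats::rnorm(1, circuit$latencyMeanMs,
                                   circuit$latencyJitterSdMs))
        latencies[i] <- lat
        evT <- lc$pulseStarts + lat / 1000
        amps <- rep(kernel$amplitudeMeanPa, length(evT))
        x <- addEventsToTrace(x, evT, amps, kernel, fs)
      }
      sw[[i]] <- list(t0 = (i - 1) * sweepDurS, primary = x,
                      command = rep(holdingMv, nSamp), light = lc$light)
      ep[[i]] <- mkEpoch(i, 460)
    }
    if (redControl) {
      for (j in seq_len(nTrials)) {
        i <- nTrials + j
        x <- stats::rnorm(nSamp, 0, noise$gaussianSdPa)
        if (is.null(chr2)) {
          bg <- drawEventTrain(circuit$baselineRateHz, sweepDurS, kernel)
          x <- addEventsToTrace(x, bg$time_s, bg$amplitude_pA, kernel, fs)
        }
        sw[[i]] <- list(t0 = (i - 1) * sweepDurS, primary = x,
                        command = rep(holdingMv, nSamp), light = lc$light)
        ep[[i]] <- mkEpoch(i, 595)
      }
    }
    gt <- list(kind = "opto_session",
               direct = !is.null(chr2),
               trial_latency_ms = latencies,
               background_times_s = bgTimes,
               chr2 = if (!is.null(chr2)) unclass(chr2),
               circuit = if (!is.null(circuit)) unclass(circuit),
               protocol = protocol, light_onset_s = lightOnsetS,
               seed = seed)
    list(bundle = SweepBundle(cellId = cellId, clampMode = "voltage",
                              samplingRate = fs, sweeps = sw,
                              epochs = do.call(rbind, ep),
                              holding = holdingMv,
                              drugCondition = "baseline"),
         groundTruth = gt)
  })
}
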