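#' @include ephys_io.R
NULL

#' Neuron model parameters for the synthetic cell
#'
#' Two complementary single-cell models share this parameter set:
#'
#' * Current clamp: an adaptive exponential integrate-and-fire (AdEx)
#'   membrane (`cPf, gLnS, elMv, vtMv, deltaTMv, aNs, bPa, tauWMs,
#'   vResetMv, vPeakMv`). `elMv` is the resting potential; spikes are emitted
#'   when V crosses `vPeakMv` and reset to `vResetMv` with adaptation
#'   increment `bPa`. The defaults describe a mature interneuron-like cell:
#'   regular spiking with strong adaptation, maximum sustained rate about
#'   42 Hz over the full -40..200 pA step series (below the 62 Hz ceiling
#'   seen in such cultures).
#' * Voltage clamp: Boltzmann-gated transient Na (m^3 h) and sustained K
#'   (single gate) conductances plus leak and a series-resistance capacitive
#'   transient. Gates relax exponentially with fixed time constants toward
#'   voltage-dependent steady states
#'   `x_inf(V) = 1 / (1 + exp(-(V - vHalf)/k))` (inactivation has negative
#'   slope).
#'
#' @param cPf Membrane capacitance, pF.
#' @param gLnS Leak conductance, nS.
#' @param elMv Leak reversal = resting potential, mV.
#' @param vtMv,deltaTMv AdEx exponential threshold and slope, mV.
#' @param aNs,bPa,tauWMs Subthreshold/spike-triggered adaptation and its
#'   time constant.
#' @param vResetMv,vPeakMv Reset and spike-cut potentials, mV.
#' @param gNaMaxNs,eNaMv,naActVHalfMv,naActKMv Na conductance, reversal and
#'   activation Boltzmann.
#' @param naInactVHalfMv,naInactKMv Na inactivation Boltzmann (`k` > 0; the
#'   gate closes with depolarisation).
#' @param tauMMs,tauHMs,tauNMs Gate time constants, ms.
#' @param gKMaxNs,eKMv,kActVHalfMv,kActKMv K conductance, reversal and
#'   activation Boltzmann.
#' @param rMMohm,rSMohm,cMPf Passive membrane/series resistance (MOhm) and
#'   capacitance (pF) for the voltage-clamp equivalent circuit;
#'   `rSMohm < rMMohm`.
#' @param rmpMv Resting membrane potential reported as ground truth
#'   (defaults to `elMv`).
#' @param vNoiseSdMv,iNoiseSdPa Additive observation noise for
#'   current-clamp (mV) and voltage-clamp (pA) traces.
#' @return Parameter list of class `"neuronModelParams"`.
#' @export
neuronModelParams <- function(cPf = 60, gLnS = 2, elMv = -47.2, vtMv = -38,
                              deltaTMv = 2, aNs = 2, bPa = 20, tauWMs = 150,
                              vResetMv = -48, vPeakMv = 30,
                              gNaMaxNs = 40, eNaMv = 60,
                              naActVHalfMv = -30, naActKMv = 6,
                              naInactVHalfMv = -55, naInactKMv = 7,
                              tauMMs = 0.2, tauHMs = 1.5, tauNMs = 8,
                              gKMaxNs = 15, eKMv = -90,
                              kActVHalfMv = -10, kActKMv = 10,
                              rMMohm = 500, rSMohm = 10, cMPf = 60,
                              rmpMv = elMv, vNoiseSdMv = 0.5,
                              iNoiseSdPa = 2) {
  for (nm in c("cPf", "gLnS", "tauWMs", "gNaMaxNs", "gKMaxNs", "tauMMs",
               "tauHMs", "tauNMs", "cMPf"))
    checkScalar(get(nm), nm, 0)
  if (naActKMv == 0 || naInactKMv == 0 || kActKMv == 0)
    stopf("Boltzmann slope factors must be nonzero")
  if (rSMohm >= rMMohm)
    stopf("series resistance must be smaller than membrane resistance")
  as.list(environment())[c(
    "cPf", "gLnS", "elMv", "vtMv", "deltaTMv", "aNs", "bPa", "tauWMs",
    "vResetMv", "vPeakMv", "gNaMaxNs", "eNaMv", "naActVHalfMv", "naActKMv",
    "naInactVHalfMv", "naInactKMv", "tauMMs", "tauHMs", "tauNMs",
    "gKMaxNs", "eKMv", "kActVHalfMv", "kActKMv", "rMMohm", "rSMohm",
    "cMPf", "rmpMv", "vNoiseSdMv", "iNoiseSdPa")] -> p
  structure(p, class = "neuronModelParams")
}

# Forward-Euler AdEx integration at the sampling step. I in pA, dt in ms.
# Returns V (mV, spike samples set to vPeakMv) and spike sample indices.
adexIntegrate <- function(I, dtMs, p, v0 = p$elMv, w0 = NULL) {
  n <- length(I)
  if (is.null(w0)) w0 <- p$aNs * (v0 - p$elMv)
  V <- numeric(n)
  v <- v0; w <- w0
  spikes <- integer(0)
  for (i in seq_len(n)) {
    dv <- (-p$gLnS * (v - p$elMv) +
             p$gLnS * p$deltaTMv * exp((v - p$vtMv) / p$deltaTMv) -
             w + I[i]) / p$cPf
    w <- w + dtMs * (p$aNs * (v - p$elMv) - w) / p$tauWMs
    v <- v + dtMs * dv
    if (!is.finite(v) || (v > 200 && FALSE))
      stopf("current-clamp simulation blew up at sample %d", i)
    if (v >= p$vPeakMv) {
      V[i] <- p$vPeakMv
      spikes <- c(spikes, i)
      v <- p$vResetMv
      w <- w + p$bPa
    } else {
      if (abs(v) > 200)
        stopf("current-clamp simulation blew up at sample %d", i)
      V[i] <- v
    }
  }
  list(V = V, spikes = spikes)
}

#' Simulate a current-clamp session (RMP, step and ramp protocols)
#'
#' Integrates the AdEx membrane model through the requested protocols:
#' `"rmp"` (a zero-current sweep), `"steps"` (500 ms square steps, -40 to
#' 200 pA in 10 pA increments, from a -70 mV holding potential maintained by
#' a bias current) and `"ramps"` (1 s depolarising ramps, 0 to
#' 25...300 pA). Ground truth records the true resting potential and the
#' spike times of every sweep.
#'
#' @param model [neuronModelParams()].
#' @param protocol Character vector, subset of `c("rmp", "steps", "ramps")`;
#'   sweeps are concatenated in that order.
#' @param stepsPa Step amplitudes, pA.
#' @param rampPeaksPa Ramp end amplitudes, pA.
#' @param rmpDurS Zero-current sweep duration, s.
#' @param holdingMv Membrane potential maintained (via bias current) during
#'   step/ramp sweeps.
#' @param fs Sampling rate, Hz.
#' @param cellId Cell label.
#' @param seed Seed for the observation noise.
#' @return `list(bundle, groundTruth)`; ground truth carries `rmp_mv` and
#'   per-sweep spike times (s, sweep-local).
#' @export
simulateCurrentClampSession <- function(model = neuronModelParams(),
                                        protocol = c("rmp", "steps"),
                                        stepsPa = seq(-40, 200, by = 10),
                                        rampPeaksPa = seq(25, 300, by = 25),
                                        rmpDurS = 1.5, holdingMv = -70,
                                        fs = 1e4, cellId = "cell01",
                                        seed = NULL) {
  stopifnot(inherits(model, "neuronModelParams"))
  protocol <- match.arg(protocol, c("rmp", "steps", "ramps"),
                        several.ok = TRUE)
  dtMs <- 1000 / fs
  # bias current holding the cell at holdingMv against leak AND the
  # steady-state subthreshold adaptation a (V - EL)
  bias <- (model$gLnS + model$aNs) * (holdingMv - model$elMv)
  cmds <- list(); eps <- list()
  addCmd <- function(I, epoch) {
    i <- length(cmds) + 1
    epoch$sweep <- i
    cmds[[i]] <<- I
    eps[[i]] <<- epoch
  }
  if ("rmp" %in% protocol)
    addCmd(rep(0, round(rmpDurS * fs)),
           protocolEpoch(1L, "none", 0, rmpDurS, 0))
  if ("steps" %in% protocol) {
    pre <- round(0.2 * fs); dur <- round(0.5 * fs); post <- round(0.3 * fs)
    for (s in stepsPa)
      addCmd(c(rep(bias, pre), rep(bias + s, dur), rep(bias, post)),
             protocolEpoch(1L, "step", pre / fs, dur / fs, s))
  }
  if ("ramps" %in% protocol) {
    pre <- round(0.2 * fs); dur <- round(1 * fs); post <- round(0.1 * fs)
    for (pk in rampPeaksPa)
      addCmd(c(rep(bias, pre), bias + seq(0, pk, length.out = dur),
               rep(bias, post)),
             protocolEpoch(1L, "ramp", pre / fs, dur / fs, 0,
                           ramp_end_amplitude = pk))
  }
  # harmonise sweep lengths (bundle invariant) by extending the final
  # holding segment of the shorter protocols
  nMax <- max(vapply(cmds, length, integer(1)))
  cmds <- lapply(cmds, function(I) c(I, rep(I[length(I)], nMax -
                                              length(I))))
  withSeed(seed, {
    sw <- list(); spikeTimes <- list()
    for (i in seq_along(cmds)) {
      I <- cmds[[i]]
      r <- adexIntegrate(I, dtMs, model,
                         v0 = if (eps[[i]]$kind %in% c("step", "ramp"))
                                holdingMv else model$elMv)
      v <- r$V + stats::rnorm(length(I), 0, model$vNoiseSdMv)
      v[r$spikes] <- model$vPeakMv  # keep the spike apex above the noise
      sw[[i]] <- list(t0 = (i - 1) * nMax / fs, primary = v, command = I,
                      light = integer(length(I)) + 0)
      spikeTimes[[i]] <- (r$spikes - 1) / fs
    }
    ep <- eps
    gt <- list(kind = "current_clamp", rmp_mv = model$rmpMv,
               spike_times_s = spikeTimes,
               model = unclass(model), protocol = protocol, seed = seed)
    list(bundle = SweepBundle(cellId = cellId, clampMode = "current",
                              samplingRate = fs, sweeps = sw,
                              epochs = do.call(rbind, ep),
                              holding = 0, drugCondition = "baseline"),
         groundTruth = gt)
  })
}

boltz <- function(v, vHalf, k) 1 / (1 + exp(-(v - vHalf) / k))

# Na/K/leak/capacitive current at a fixed command potential, evaluated on an
# arbitrary time grid (s) from the step onset. Gates start from their steady
# state at vFrom. Used both for the sampled traces and the dense-grid ground
# truth.
clampStepCurrent <- function(t, vTo, vFrom, p, gNa = p$gNaMaxNs,
                             gK = p$gKMaxNs, leakRefMv = vFrom) {
  m0 <- boltz(vFrom, p$naActVHalfMv, p$naActKMv)
  h0 <- boltz(vFrom, p$naInactVHalfMv, -p$naInactKMv)
  n0 <- boltz(vFrom, p$kActVHalfMv, p$kActKMv)
  mI <- boltz(vTo, p$naActVHalfMv, p$naActKMv)
  hI <- boltz(vTo, p$naInactVHalfMv, -p$naInactKMv)
  nI <- boltz(vTo, p$kActVHalfMv, p$kActKMv)
  m <- mI + (m0 - mI) * exp(-t * 1000 / p$tauMMs)
  h <- hI + (h0 - hI) * exp(-t * 1000 / p$tauHMs)
  nn <- nI + (n0 - nI) * exp(-t * 1000 / p$tauNMs)
  iNa <- gNa * m^3 * h * (vTo - p$eNaMv)          # nS * mV = pA
  iK <- gK * nn * (vTo - p$eKMv)
  iLeak <- 1000 * (vTo - leakRefMv) / p$rMMohm    # mV / MOhm = nA -> pA
  tauC <- p$rSMohm * p$cMPf / 1000                # ms
  iCap <- 1000 * (vTo - vFrom) / p$rSMohm * exp(-t * 1000 / tauC)
  iNa + iK + iLeak + iCap
}

#' Simulate a voltage-step I-V session
#'
#' 14 voltage-clamp sweeps stepping from the -70 mV holding potential to
#' -90..+40 mV (10 mV increments, 100 ms steps) over Boltzmann-gated Na/K
#' conductances with leak and a series-resistance capacitive transient.
#' `drug = "TTX"` zeroes the Na conductance; `"TTX+TEA"` additionally zeroes
#' K. Ground truth stores, per step, the dense-grid (2 us) minimum of the
#' leak-subtracted voltage-gated current within 10 ms of onset (the
#' quantity ideal leak subtraction recovers as the transient inward peak),
#' the Na-only component of that peak, and the steady K current.
#'
#' @param model [neuronModelParams()].
#' @param drug `"none"`, `"TTX"` or `"TTX+TEA"`.
#' @param stepMv Step potentials, mV.
#' @param holdingMv Holding potential, mV.
#' @param stepDurS,preS,postS Step timing, s.
#' @param fs Sampling rate, Hz.
#' @param cellId Cell label.
#' @param seed Seed for the current noise.
#' @return `list(bundle, groundTruth)`.
#' @export
simulateVoltageClampIV <- function(model = neuronModelParams(),
                                   drug = c("none", "TTX", "TTX+TEA"),
                                   stepMv = seq(-90, 40, by = 10),
                                   holdingMv = -70, stepDurS = 0.1,
                                   preS = 0.05, postS = 0.05, fs = 1e4,
                                   cellId = "cell01", seed = NULL) {
  stopifnot(inherits(model, "neuronModelParams"))
  drug <- match.arg(drug)
  gNa <- if (drug %in% c("TTX", "TTX+TEA")) 0 else model$gNaMaxNs
  gK <- if (drug == "TTX+TEA") 0 else model$gKMaxNs
  nPre <- round(preS * fs); nStep <- round(stepDurS * fs)
  nPost <- round(postS * fs)
  tStep <- (seq_len(nStep) - 1) / fs
  tDense <- seq(0, min(0.01, stepDurS), by = 2e-6)
  withSeed(seed, {
    sw <- list(); ep <- list()
    gtNa <- numeric(length(stepMv)); gtK <- numeric(length(stepMv))
    gtNaOnly <- numeric(length(stepMv))
    for (i in seq_along(stepMv)) {
      v <- stepMv[i]
      iStep <- clampStepCurrent(tStep, v, holdingMv, model, gNa, gK,
                                leakRefMv = holdingMv)
      # post segment: relaxation back at holding (capacitive + tail)
      iPost <- clampStepCurrent((seq_len(nPost) - 1) / fs, holdingMv, v,
                                model, gNa, gK, leakRefMv = holdingMv)
      x <- c(rep(0, nPre), iStep, iPost) +
        stats::rnorm(nPre + nStep + nPost, 0, model$iNoiseSdPa)
      cmd <- c(rep(holdingMv, nPre), rep(v, nStep), rep(holdingMv, nPost))
      sw[[i]] <- list(t0 = (i - 1) * length(x) / fs, primary = x,
                      command = cmd, light = integer(length(x)) + 0)
      ep[[i]] <- protocolEpoch(i, "step", nPre / fs, stepDurS, v)
      # dense-grid oracle of what ideal leak/capacitive subtraction leaves:
      # the total voltage-gated (Na + K) current; the Na-only component is
      # kept alongside (it differs by the small early K contamination)
      denseTot <- clampStepCurrent(tDense, v, holdingMv, model, gNa, gK,
                                   leakRefMv = holdingMv) -
        clampStepCurrent(tDense, v, holdingMv, model, 0, 0,
                         leakRefMv = holdingMv)
      denseNa <- clampStepCurrent(tDense, v, holdingMv, model, gNa, 0,
                                  leakRefMv = holdingMv) -
        clampStepCurrent(tDense, v, holdingMv, model, 0, 0,
                         leakRefMv = holdingMv)
      gtNa[i] <- min(denseTot)
      gtNaOnly[i] <- min(denseNa)
      gtK[i] <- gK * boltz(v, model$kActVHalfMv, model$kActKMv) *
        (v - model$eKMv)
    }
    gt <- list(kind = "voltage_clamp_iv", step_mv = stepMv,
               na_peak_pA = gtNa, na_only_peak_pA = gtNaOnly,
               k_steady_pA = gtK, drug = drug,
               model = unclass(model), seed = seed)
    list(bundle = SweepBundle(cellId = cellId, clampMode = "voltage",
                              samplingRate = fs, sweeps = sw,
                              epochs = do.call(rbind, ep),
                              holding = holdingMv, drugCondition = drug),
         groundTruth = gt)
  })
}

#' Simulate a series-resistance test pulse
#'
#' Voltage-clamp RC response to a small command step through the pipette:
#' `I(t) = dV/Rs exp(-t/tau) + dV/(Rs+Rm) (1 - exp(-t/tau))` with
#' `tau = Cm Rs Rm / (Rs + Rm)`. Used to validate series/input-resistance
#' estimation.
#'
#' @param rSMohm,rMMohm,cMPf RC-circuit parameters.
#' @param dVmV Test-pulse amplitude, mV (must be nonzero).
#' @param pulseDurS,preS,postS Timing, s.
#' @param noiseSdPa Current noise sd, pA.
#' @param fs Sampling rate, Hz.
#' @param cellId Cell label.
#' @param seed Seed.
#' @return `list(bundle, groundTruth)`.
#' @export
simulateTestPulse <- function(rSMohm = 10, rMMohm = 500, cMPf = 60,
                              dVmV = 5, pulseDurS = 0.1, preS = 0.05,
                              postS = 0.05, noiseSdPa = 1, fs = 1e4,
                              cellId = "cell01", seed = NULL) {
  if (dVmV == 0) stopf("test-pulse amplitude must be nonzero")
  if (rSMohm >= rMMohm) stopf("rSMohm must be smaller than rMMohm")
  nPre <- round(preS * fs); nP <- round(pulseDurS * fs)
  nPost <- round(postS * fs)
  tau <- cMPf * rSMohm * rMMohm / (rSMohm + rMMohm) / 1000     # ms
  tms <- (seq_len(nP) - 1) / fs * 1000
  iPulse <- 1000 * dVmV / rSMohm * exp(-tms / tau) +
    1000 * dVmV / (rSMohm + rMMohm) * (1 - exp(-tms / tau))
  iPost <- -(1000 * dVmV / rSMohm - 1000 * dVmV / (rSMohm + rMMohm)) *
    exp(-(seq_len(nPost) - 1) / fs * 1000 / tau)
  withSeed(seed, {
    x <- c(rep(0, nPre), iPulse, iPost) +
      stats::rnorm(nPre + nP + nPost, 0, noiseSdPa)
    cmd <- c(rep(-70, nPre), rep(-70 + dVmV, nP), rep(-70, nPost))
    bundle <- SweepBundle(cellId = cellId, clampMode = "voltage",
                          samplingRate = fs,
                          sweeps = list(list(t0 = 0, primary = x,
                                             command = cmd,
                                             light = integer(length(x)) + 0)),
                          epochs = protocolEpoch(1L, "test_pulse", nPre / fs,
                                                 pulseDurS, dVmV),
                          holding = -70, drugCondition = "baseline")
    list(bundle = bundle,
         groundTruth = list(kind = "test_pulse", r_s_mohm = rSMohm,
                            r_m_mohm = rMMohm, c_m_pf = cMPf, dV_mV = dVmV,
                            seed = seed))
  })
}
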