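#' @include AllClasses.R
NULL

#' Postsynaptic-current kernel parameters
#'
#' Bi-exponential event shape `k(t) = A (exp(-t/tau_decay) -
#' exp(-t/tau_rise))`, normalised to unit peak. The defaults (rise 0.5 ms,
#' decay 5 ms) describe a fast GABAergic synaptic current whose 20-80%
#' rise/decay times sit well inside the analysis exclusion window (rise <= 3
#' ms, decay <= 20 ms) even after 400 Hz low-pass filtering. Amplitudes are
#' drawn log-normal with the stated arithmetic mean and coefficient of
#' variation; inward currents are negative in the traces while amplitude
#' parameters are magnitudes.
#'
#' @param tauRiseMs,tauDecayMs Rise/decay time constants (ms);
#'   `tauDecayMs > tauRiseMs > 0`.
#' @param amplitudeMeanPa Mean event amplitude magnitude (pA), > 0.
#' @param amplitudeCv Coefficient of variation of amplitudes, >= 0.
#' @param polarity `"inward"` (negative-going, the voltage-clamp convention
#'   at -70 mV) or `"outward"`.
#' @return Parameter list of class `"pscKernelParams"`.
#' @export
pscKernelParams <- function(tauRiseMs = 0.5, tauDecayMs = 5,
                            amplitudeMeanPa = 30, amplitudeCv = 0.3,
                            polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  checkScalar(tauRiseMs, "tauRiseMs", 0, strict_lower = TRUE)
  if (tauDecayMs <= tauRiseMs)
    stopf("tauDecayMs must be greater than tauRiseMs")
  checkScalar(amplitudeMeanPa, "amplitudeMeanPa", 0, strict_lower = TRUE)
  checkScalar(amplitudeCv, "amplitudeCv", 0)
  structure(list(tauRiseMs = tauRiseMs, tauDecayMs = tauDecayMs,
                 amplitudeMeanPa = amplitudeMeanPa, amplitudeCv = amplitudeCv,
                 polarity = polarity),
            class = "pscKernelParams")
}

#' Time of the kernel peak
#'
#' Closed form `t* = ln(tau_d/tau_r) * tau_d tau_r / (tau_d - tau_r)`.
#'
#' @param params A [pscKernelParams()] list.
#' @return Peak time in seconds.
#' @export
kernelPeakTime <- function(params) {
  tr <- params$tauRiseMs / 1000
  td <- params$tauDecayMs / 1000
  log(td / tr) * td * tr / (td - tr)
}

#' Evaluate the unit-peak PSC kernel
#'
#' @param params A [pscKernelParams()] list.
#' @param t Time points in seconds, `t >= 0` (values < 0 evaluate to 0).
#' @return Unsigned kernel values with maximum exactly 1 (the polarity sign
#'   is applied by the simulators / [buildTemplate()]).
#' @export
pscKernel <- function(params, t) {
  stopifnot(inherits(params, "pscKernelParams"))
  tr <- params$tauRiseMs / 1000
  td <- params$tauDecayMs / 1000
  tstar <- kernelPeakTime(params)
  peak <- exp(-tstar / td) - exp(-tstar / tr)
  k <- ifelse(t < 0, 0, exp(-t / td) - exp(-t / tr))
  k / peak
}
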