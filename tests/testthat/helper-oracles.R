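# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Exhaustive two-sided Mann-Whitney p-value by enumerating all group
# assignments (tie-free data), mirroring the doubling rule used for exact
# rank tests.
mwEnumP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  uObs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  uAll <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  if (uObs > n1 * n2 / 2) {
    min(2 * mean(uAll >= uObs - 1e-9), 1)
  } else {
    min(2 * mean(uAll <= uObs + 1e-9), 1)
  }
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
fisherEnumP <- function(k1, n1, k2, n2) {
  K <- k1 + k2; N <- n1 + n2
  support <- max(0, K - n2):min(n1, K)
  probs <- stats::dhyper(support, K, N - K, n1)
  pObs <- stats::dhyper(k1, K, N - K, n1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Grubbs critical value at level alpha for n values.
grubbsCrit <- function(n, alpha = 0.05) {
  t <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

# Dense-grid 20-80% rise/decay (ms) of the bi-exponential kernel, by direct
# evaluation at 0.1 us resolution.
denseKinetics <- function(tauRiseMs, tauDecayMs) {
  tr <- tauRiseMs / 1000; td <- tauDecayMs / 1000
  tt <- seq(0, 8 * td, by = 1e-7)
  k <- exp(-tt / td) - exp(-tt / tr)
  k <- k / max(k)
  pk <- which.max(k)
  i20r <- max(which(k[seq_len(pk)] < 0.2))
  i80r <- min(which(k[seq_len(pk)] >= 0.8))
  post <- k[pk:length(k)]
  i80d <- min(which(post < 0.8))
  i20d <- min(which(post < 0.2))
  list(rise_ms = (i80r - i20r) * 1e-4, decay_ms = (i20d - i80d) * 1e-4,
       peak_s = (pk - 1) * 1e-7)
}

# Random valid bundle for round-trip property tests.
randomBundle <- function(seed) {
  set.seed(seed)
  fs <- sample(c(5000, 10000, 20000), 1)
  nSweep <- sample(1:3, 1)
  n <- sample(50:200, 1)
  mode <- sample(c("voltage", "current"), 1)
  sw <- lapply(seq_len(nSweep), function(i)
    list(t0 = (i - 1) * n / fs, primary = round(rnorm(n, 0, 20), 6),
         command = round(rnorm(n, -70, 5), 6),
         light = sample(0:1, n, replace = TRUE)))
  ep <- rbind(protocolEpoch(1L, "step", 0.001, 0.002, 10),
              protocolEpoch(1L, "light_train", 0.001, 0.4, train_n = 5L,
                            train_pulse_ms = 3, train_interval_ms = 97,
                            wavelength_nm = 460))
  SweepBundle(cellId = sprintf("rand%02d", seed), clampMode = mode,
              samplingRate = fs, sweeps = sw, epochs = ep,
              holding = if (mode == "voltage") -70 else 0,
              drugCondition = sample(c("baseline", "PTX", "NBQX+AP5"), 1))
}

# Random event table for round-trip tests.
randomEventTable <- function(seed) {
  set.seed(seed)
  n <- sample(1:20, 1)
  reasons <- c("", "amplitude", "rise_time", "decay_time",
               "decay_rise_ratio", "truncated")
  df <- data.frame(
    cell_id = sample(sprintf("cell%02d", 1:3), n, replace = TRUE),
    condition = sample(c("baseline", "PTX"), n, replace = TRUE),
    event_time_s = NA_real_,
    amplitude_pA = round(runif(n, 1, 80), 4),
    rise_ms = round(runif(n, 0.2, 4), 4),
    decay_ms = round(runif(n, 1, 25), 4),
    correlation = round(runif(n, 0.6, 1), 4),
    included = NA, exclusion_reason = "", stringsAsFactors = FALSE)
  # strictly increasing times within cell/condition
  grp <- paste(df$cell_id, df$condition)
  for (g in unique(grp))
    df$event_time_s[grp == g] <- sort(runif(sum(grp == g), 0, 100))
  df$exclusion_reason <- sample(reasons, n, replace = TRUE)
  df$included <- df$exclusion_reason == ""
  df
}

# Planted single-event sweep used by detection tests.
plantKernelTrace <- function(ampPa, tauRiseMs = 0.5, tauDecayMs = 5,
                             noiseSd = 1, durS = 2, atS = 1, fs = 1e4,
                             seed = 1) {
  set.seed(seed)
  x <- rnorm(durS * fs, 0, noiseSd)
  kp <- pscKernelParams(tauRiseMs, tauDecayMs, amplitudeMeanPa = ampPa,
                        amplitudeCv = 0)
  tk <- seq(0, 5 * tauDecayMs / 1000, by = 1 / fs)
  i0 <- round(atS * fs) + 1
  idx <- i0:min(length(x), i0 + length(tk) - 1)
  x[idx] <- x[idx] - ampPa * pscKernel(kp, tk)[seq_along(idx)]
  x
}

# Wrap a bare trace in a voltage-clamp bundle.
traceBundle <- function(x, fs = 1e4, condition = "baseline",
                        cellId = "cellT") {
  SweepBundle(cellId = cellId, clampMode = "voltage", samplingRate = fs,
              sweeps = list(list(t0 = 0, primary = x,
                                 command = rep(-70, length(x)),
                                 light = integer(length(x)) + 0)),
              holding = -70, drugCondition = condition)
}
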