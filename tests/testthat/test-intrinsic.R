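test_that("RMP measurement recovers the true resting potential", {
  flat <- SweepBundle(cellId = "c", clampMode = "current",
                      samplingRate = 1e4,
                      sweeps = list(list(t0 = 0, primary = rep(-70, 1e4),
                                         command = rep(0, 1e4),
                                         light = rep(0, 1e4))))
  expect_equal(measureRMP(flat), -70)
  sim <- simulateCurrentClampSession(
    neuronModelParams(elMv = -47.2, vNoiseSdMv = 0.5),
    protocol = "rmp", seed = 51)
  expect_equal(measureRMP(sim$bundle), -47.2, tolerance = 0.1)
  # spiking cell: spikes are masked before averaging
  spiky <- neuronModelParams(elMv = -36, vNoiseSdMv = 0.5)
  sim2 <- simulateCurrentClampSession(spiky, protocol = "rmp", seed = 52)
  nSpk <- length(sim2$groundTruth$spike_times_s[[1]])
  rmp <- measureRMP(sim2$bundle)
  expect_lt(rmp, -30)   # unmasked spikes at +30 mV would drag this up
  # no zero-current sweep: protocol error
  noz <- simulateCurrentClampSession(protocol = "steps", stepsPa = c(0, 10),
                                     seed = 53)
  expect_error(measureRMP(noz$bundle), "zero-current")
})

test_that("test-pulse resistances match the RC-circuit ground truth", {
  sim <- simulateTestPulse(rSMohm = 10, rMMohm = 500, cMPf = 60, seed = 54)
  r <- measureResistances(sim$bundle)
  expect_true(r$rs_resolved)
  expect_equal(r$r_series_mohm, 10, tolerance = 0.5)
  expect_equal(r$r_input_mohm, 500, tolerance = 25)
  expect_error(simulateTestPulse(dVmV = 0), "nonzero")
  # pure Ohm check: steady 10 pA at 5 mV with tiny Rs -> Ri ~ 500 MOhm
  sim2 <- simulateTestPulse(rSMohm = 0.5, rMMohm = 499.5, cMPf = 60,
                            noiseSdPa = 0.01, seed = 55)
  r2 <- measureResistances(sim2$bundle)
  expect_equal(r2$r_input_mohm + r2$r_series_mohm, 500, tolerance = 5)
})

test_that("AP detection: amplitude identity and exact spike counts", {
  sim <- simulateCurrentClampSession(protocol = "steps", seed = 56)
  ep <- epochs(sim$bundle)
  fs <- samplingRate(sim$bundle)
  totalDetected <- 0; totalTrue <- 0
  for (i in seq_len(nrow(ep))) {
    sp <- detectAPs(sweeps(sim$bundle)[[i]]$primary, fs)
    if (nrow(sp)) {
      expect_equal(sp$amplitude_mv, sp$peak_mv - sp$threshold_mv)
      expect_true(all(sp$amplitude_mv > 0))
      expect_true(all(sp$duration_ms > 0, na.rm = TRUE))
    }
    totalDetected <- totalDetected + nrow(sp)
    totalTrue <- totalTrue + length(sim$groundTruth$spike_times_s[[i]])
  }
  expect_equal(totalDetected, totalTrue)
  # subthreshold trace: no spikes
  expect_equal(nrow(detectAPs(rep(-70, 1000) + rnorm(1000, 0, 0.5), fs)),
               0)
})

test_that("step-series firing stays under the 62 Hz ceiling, monotone", {
  sim <- simulateCurrentClampSession(protocol = "steps", seed = 57)
  fire <- maxAPCount(sim$bundle)
  expect_lte(fire$sustained_rate_hz, 62)
  expect_true(all(diff(fire$per_step$n_spikes) >= 0))
  expect_equal(fire$max_count, max(fire$per_step$n_spikes))
  # no suprathreshold steps
  quiet <- simulateCurrentClampSession(protocol = "steps",
                                       stepsPa = c(-40, -20, 0), seed = 58)
  expect_equal(maxAPCount(quiet$bundle)$max_count, 0)
})

test_that("I-V extraction matches the dense-grid conductance oracle", {
  sim <- simulateVoltageClampIV(seed = 59)
  res <- extractIV(sim$bundle)
  gt <- sim$groundTruth
  expect_equal(res$curve$step_mv, gt$step_mv)
  big <- abs(gt$na_peak_pA) > 200
  expect_equal(res$curve$na_peak_pA[big], gt$na_peak_pA[big],
               tolerance = 0.05)
  bigK <- gt$step_mv >= 0
  expect_equal(res$curve$k_sustained_pA[bigK], gt$k_steady_pA[bigK],
               tolerance = 0.05)
  # sign conventions above activation
  act <- gt$step_mv >= -20
  expect_true(all(res$curve$na_peak_pA[act] <= 0))
  expect_true(all(res$curve$k_sustained_pA[act] >= 0))
  # the -90 reference step self-subtracts to ~0
  expect_equal(res$curve$na_peak_pA[1], 0)
  expect_equal(res$curve$k_sustained_pA[1], 0)
})

test_that("TTX abolishes the transient inward current", {
  ttx <- simulateVoltageClampIV(drug = "TTX", seed = 60)
  res <- extractIV(ttx$bundle)
  # residual minima are consistent with subtraction noise alone
  scaleMax <- (40 + 70) / 20
  bound <- 3 * res$noise_sd_pa * sqrt(1 + scaleMax^2)
  expect_true(all(abs(res$curve$na_peak_pA) < bound))
  # drug-pair interface: TTX-sensitive component recovers the Na peak
  ctl <- simulateVoltageClampIV(seed = 60)
  pair <- extractIV(ctl$bundle, ttx$bundle)
  gt <- ctl$groundTruth
  big <- abs(gt$na_peak_pA) > 500
  expect_equal(pair$sensitive$na_peak_pA[big], gt$na_peak_pA[big],
               tolerance = 0.1)
  # mismatched step sets are rejected
  short <- simulateVoltageClampIV(stepMv = seq(-90, 0, by = 10), seed = 61)
  expect_error(extractIV(ctl$bundle, short$bundle), "different step sets")
})
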