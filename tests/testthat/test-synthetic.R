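test_that("planted event counts follow the Poisson law", {
  sim <- simulatePSCSession(train = eventTrainParams(1.01, 120), seed = 21)
  expected <- 1.01 * 120
  expect_lt(abs(nrow(sim$groundTruth$events) - expected),
            3 * sqrt(expected))
  # rate 0: pure noise, empty ground truth
  sim0 <- simulatePSCSession(train = eventTrainParams(0, 5), seed = 22)
  expect_equal(nrow(sim0$groundTruth$events), 0)
  expect_lt(max(abs(sweeps(sim0$bundle)[[1]]$primary)), 10)
})

test_that("noise floor: 2.5-97.5 percentile span of event-free trace is ~4 pA", {
  sim <- simulatePSCSession(train = eventTrainParams(0, 10),
                            noise = noiseParams(gaussianSdPa = 1),
                            seed = 23)
  x <- sweeps(sim$bundle)[[1]]$primary
  span <- diff(stats::quantile(x, c(0.025, 0.975)))
  expect_equal(unname(span), 4, tolerance = 0.1)
})

test_that("same seed gives bit-identical sessions; overflow guarded", {
  a <- simulatePSCSession(train = eventTrainParams(2, 10), seed = 24)
  b <- simulatePSCSession(train = eventTrainParams(2, 10), seed = 24)
  expect_identical(sweeps(a$bundle)[[1]]$primary,
                   sweeps(b$bundle)[[1]]$primary)
  expect_identical(a$groundTruth$events, b$groundTruth$events)
  expect_error(simulatePSCSession(train = eventTrainParams(1e5, 100)),
               "too large")
})

test_that("current-clamp generator reproduces its resting state", {
  # no-noise, zero-amplitude protocol: V stays at EL
  m <- neuronModelParams(vNoiseSdMv = 1e-12)
  sim <- simulateCurrentClampSession(m, protocol = "steps", stepsPa = 0,
                                     seed = 25)
  v <- sweeps(sim$bundle)[[1]]$primary
  # sweep is held at -70 via bias; relaxes toward nothing else
  expect_lt(max(abs(v + 70)), 0.5)
  simR <- simulateCurrentClampSession(neuronModelParams(vNoiseSdMv = 1e-12),
                                      protocol = "rmp", seed = 26)
  expect_equal(mean(sweeps(simR$bundle)[[1]]$primary),
               simR$groundTruth$rmp_mv, tolerance = 0.01)
})

test_that("step-series spike counts rise with amplitude up to the ceiling", {
  sim <- simulateCurrentClampSession(protocol = "steps", seed = 27)
  counts <- vapply(sim$groundTruth$spike_times_s, length, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_lte(max(counts) / 0.5, 62)
})

test_that("voltage-step generator honours the drug conditions", {
  m <- neuronModelParams(iNoiseSdPa = 1e-9)
  tt <- simulateVoltageClampIV(m, drug = "TTX+TEA", seed = 28)
  # TTX+TEA: leak + capacitive only; the late step current is pure leak,
  # flat and proportional to the step excursion
  ep <- epochs(tt$bundle)
  fsHz <- samplingRate(tt$bundle)
  for (i in seq_len(nrow(ep))) {
    s <- sweeps(tt$bundle)[[ep$sweep[i]]]
    iEnd <- round((ep$start[i] + ep$duration[i]) * fsHz)
    late <- s$primary[(iEnd - 199):iEnd]
    expect_lt(stats::sd(late), 0.1)
    leak <- 1000 * (ep$amplitude[i] + 70) / 500   # dV / Rm
    expect_equal(mean(late), leak, tolerance = 0.05)
  }
  expect_true(all(tt$groundTruth$na_peak_pA == 0))
  # step to -90 from -70: below Na activation, no inward transient
  ctl <- simulateVoltageClampIV(m, seed = 29)
  expect_gt(min(ctl$groundTruth$na_only_peak_pA[1]), -0.5)
})

test_that("opto generator plants photocurrents and latencies as configured", {
  # gMax 0: no light-locked current
  quiet <- simulateOptoSession(chr2 = chr2Params(gMaxNs = 0),
                               noise = noiseParams(gaussianSdPa = 1),
                               seed = 30)
  x <- sweeps(quiet$bundle)[[1]]$primary
  expect_lt(max(abs(x)), 6)
  # direct cell: current rises immediately at light onset
  direct <- simulateOptoSession(chr2 = chr2Params(gMaxNs = 2),
                                noise = noiseParams(gaussianSdPa = 0.01),
                                seed = 31)
  s <- sweeps(direct$bundle)[[1]]
  on <- which(s$light == 1)[1]
  expect_lt(s$primary[on + 20], -20)     # inward within 2 ms
  expect_gt(min(abs(s$primary[seq_len(on - 1)])), -1)
  # downstream cell: empirical mean latency near the configured mean
  ds <- simulateOptoSession(circuit = optoCircuitParams(
    nTrials = 20, latencyMeanMs = 15, latencyJitterSdMs = 1), seed = 32)
  expect_equal(mean(ds$groundTruth$trial_latency_ms), 15, tolerance = 1)
})

test_that("count-field generator matches its binomial law", {
  all1 <- simulateCountFields(c(m = 1), seed = 33)
  expect_true(all(all1$n_marker == all1$n_map2))
  big <- simulateCountFields(c(m = 0.5), cellsPerField = 2000, nFields = 5,
                             timepoints = 35, seed = 34)
  frac <- sum(big$n_marker) / sum(big$n_map2)
  expect_equal(frac, 0.5, tolerance = 0.015)
  # default design: field sizes near the reference 52 cells/area
  def <- simulateCountFields(c(m = 0.5), seed = 35)
  expect_equal(mean(def$n_map2), 52, tolerance = 5)
})

test_that("Ct generator encodes expression levels and NA propagates", {
  noisefree <- simulateCtTable(c(g1 = 1), triplicateSd = 1e-12, seed = 36)
  expect_equal(mean(noisefree$ct[noisefree$gene == "g1"]), 20,
               tolerance = 1e-6)
  tbl <- simulateCtTable(c(g2 = 2^-5, gone = NA), seed = 37)
  res <- deltaCt(tbl)
  expect_equal(res$delta_ct[res$gene == "g2"], 5, tolerance = 0.3)
  expect_false(res$detected[res$gene == "gone"])
})
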