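tmplOpto <- buildTemplate(pscKernelParams(), 1e4)

test_that("photocurrent measurement separates responders from silent cells", {
  silent <- simulateOptoSession(chr2 = chr2Params(gMaxNs = 0), seed = 71)
  ph0 <- measurePhotocurrent(silent$bundle)
  expect_false(ph0$response)
  lit <- simulateOptoSession(chr2 = chr2Params(gMaxNs = 2, tauOnMs = 2),
                             noise = noiseParams(gaussianSdPa = 1),
                             seed = 72)
  ph <- measurePhotocurrent(lit$bundle)
  expect_true(ph$response)
  expect_lt(ph$onset_latency_ms, 2)
  expect_gt(ph$peak_pA, 50)
  expect_gt(ph$steady_pA, 0.5 * ph$peak_pA)   # sustained plateau
  # red-light control sweeps show no response
  ctl <- simulateOptoSession(chr2 = chr2Params(gMaxNs = 2),
                             redControl = TRUE, seed = 73)
  phc <- measurePhotocurrent(ctl$bundle)
  expect_true(phc$response)
  expect_false(phc$red_response)
})

test_that("latency histograms take one first event per trial", {
  h0 <- latencyHistogram(list(numeric(0), numeric(0), numeric(0),
                              numeric(0), numeric(0)), onsetS = 0.2)
  expect_equal(sum(h0$counts), 0)
  trials <- list(c(0.215, 0.4), c(0.212), c(0.31, 0.35), numeric(0),
                 c(0.1))  # pre-onset event does not count
  h <- latencyHistogram(trials, onsetS = 0.2, windowMs = 600, binMs = 10)
  expect_equal(length(h$trial_latencies_ms), 3)
  expect_lte(sum(h$counts), h$n_trials)
  expect_equal(h$counts[2], 2L)   # 15 ms and 12 ms fall in [10, 20)
})

test_that("evoked latencies recover the planted circuit latency", {
  ds <- simulateOptoSession(circuit = optoCircuitParams(
    nTrials = 20, latencyMeanMs = 15, latencyJitterSdMs = 1), seed = 74)
  h <- extractEvokedLatencies(ds$bundle, tmplOpto)
  expect_gte(length(h$trial_latencies_ms), 15)
  expect_equal(mean(h$trial_latencies_ms), 15,
               tolerance = 2 * 1 / sqrt(20) + 1)
  modal <- which.max(h$counts)
  expect_equal(h$breaks_ms[modal], 10)   # modal bin [10, 20)
})

test_that("Poisson bin test matches direct pmf summation and is monotone", {
  h <- latencyHistogram(list(c(0.215), c(0.217), c(0.212), c(0.214),
                             c(0.216)), onsetS = 0.2)
  h$baseline_window_s <- 5 * 0.2
  res <- poissonBinTest(h, baselineRateHz = 0.5)
  lambda <- 0.5 * 0.01 * 5
  expect_equal(res$observed, 5)
  expect_equal(res$expected, lambda)
  # oracle: direct pmf summation of the upper tail
  expect_equal(res$p_value, sum(dpois(5:200, lambda)), tolerance = 1e-12)
  # k = 0 -> p = 1
  h0 <- latencyHistogram(list(numeric(0), numeric(0), numeric(0),
                              numeric(0), numeric(0)), onsetS = 0.2)
  h0$baseline_window_s <- 1
  expect_equal(poissonBinTest(h0, baselineRateHz = 0.5)$p_value, 1)
  # p decreases with the observed count at fixed lambda
  ps <- vapply(1:8, function(k) {
    hh <- h
    hh$counts[2] <- k
    poissonBinTest(hh, baselineRateHz = 0.5)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # lambda = 0.5, k = 5 worked example against ppois
  expect_equal(1 - ppois(4, 0.5),
               poissonBinTest({
                 hh <- h; hh$counts[2] <- 5L; hh$n_trials <- 100L;
                 hh
               }, baselineRateHz = 0.5)$p_value, tolerance = 1e-12)
})

test_that("response classification follows construction", {
  lit <- simulateOptoSession(chr2 = chr2Params(gMaxNs = 2), seed = 75)
  ph <- measurePhotocurrent(lit$bundle)
  expect_equal(classifyResponse(photo = ph)$class, "direct")
  ds <- simulateOptoSession(circuit = optoCircuitParams(nTrials = 20),
                            seed = 76)
  h <- extractEvokedLatencies(ds$bundle, tmplOpto)
  pt <- poissonBinTest(h)
  cls <- classifyResponse(hist = h, poisson = pt,
                          drugFlags = list(abolished_ptx = TRUE,
                                           abolished_nbqx_ap5 = FALSE))
  expect_equal(cls$class, "synaptic")
  expect_equal(cls$transmitter, "gaba")
  expect_equal(classifyResponse()$class, "none")
  expect_warning(
    amb <- classifyResponse(photo = ph,
                            drugFlags = list(abolished_ptx = TRUE,
                                             abolished_nbqx_ap5 = FALSE)),
    "ambiguous")
  expect_equal(amb$class, "ambiguous")
})

test_that("classification matches the simulator label across seeded sessions", {
  labels <- rep(c("direct", "synaptic", "none"), length.out = 24)
  correct <- 0
  for (i in seq_along(labels)) {
    seed <- 200 + i
    if (labels[i] == "direct") {
      sim <- simulateOptoSession(chr2 = chr2Params(gMaxNs = 2),
                                 seed = seed)
      got <- classifyResponse(photo = measurePhotocurrent(sim$bundle))$class
    } else if (labels[i] == "synaptic") {
      sim <- simulateOptoSession(circuit = optoCircuitParams(nTrials = 12),
                                 seed = seed)
      h <- extractEvokedLatencies(sim$bundle, tmplOpto)
      got <- classifyResponse(hist = h, poisson = poissonBinTest(h))$class
    } else {
      # a cell with no light-gated conductance and no light-coupled input
      sim <- simulateOptoSession(chr2 = chr2Params(gMaxNs = 0),
                                 seed = seed)
      h <- extractEvokedLatencies(sim$bundle, tmplOpto)
      got <- classifyResponse(photo = measurePhotocurrent(sim$bundle),
                              hist = h, poisson = poissonBinTest(h))$class
    }
    correct <- correct + (got == labels[i])
  }
  expect_gte(correct / length(labels), 0.95)
})
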