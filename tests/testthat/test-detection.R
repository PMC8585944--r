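fs <- 1e4

test_that("low-pass filter: DC gain 1, passband flat, stopband attenuated", {
  expect_equal(lowpassTrace(rep(3.5, 1000), fs), rep(3.5, 1000),
               tolerance = 1e-6)
  tt <- seq(0, 1, by = 1 / fs)
  slow <- sin(2 * pi * 10 * tt)
  fast <- sin(2 * pi * 1000 * tt)
  mid <- 2000:8000   # avoid edge transients
  expect_equal(max(abs(lowpassTrace(slow, fs)[mid])), 1, tolerance = 0.01)
  expect_lt(max(abs(lowpassTrace(fast, fs)[mid])), 0.05)
  expect_error(lowpassTrace(slow, 700), "twice the cutoff")
})

test_that("parametric template peaks at the kernel's closed-form time", {
  kp <- pscKernelParams(tauRiseMs = 0.5, tauDecayMs = 5)
  tmpl <- buildTemplate(kp, fs)
  expect_s4_class(tmpl, "PSCTemplate")
  expect_equal(max(abs(tmpl@waveform)), 1)
  expect_equal(templatePolarity(tmpl), -1)
  pk <- which.min(tmpl@waveform)
  pkTime <- (pk - 1) / fs - tmpl@prePeakMs / 1000
  expect_lte(abs(pkTime - kernelPeakTime(kp)), 1 / fs)
})

test_that("averaged template reproduces and interpolates its seeds", {
  kp <- pscKernelParams(tauRiseMs = 0.5, tauDecayMs = 5)
  tk <- seq(0, 0.02, by = 1 / fs)
  w <- c(rep(0, 80), -30 * pscKernel(kp, tk))
  same <- buildTemplate(replicate(6, w, simplify = FALSE), fs)
  ref <- buildTemplate(kp, fs)
  # peak-aligned overlap: averaging identical copies reproduces the kernel
  pkS <- which.min(same@waveform); pkR <- which.min(ref@waveform)
  off <- -30:120
  expect_equal(same@waveform[pkS + off], ref@waveform[pkR + off],
               tolerance = 1e-6)
  expect_error(buildTemplate(list(w, w, w), fs), "at least 5")
  # mixed kinetics: rise span of the average equals the span of the
  # peak-aligned mean waveform computed independently on a dense grid
  kpSlow <- pscKernelParams(tauRiseMs = 1.5, tauDecayMs = 10)
  wSlow <- c(rep(0, 80), -30 * pscKernel(kpSlow, tk))
  mix <- buildTemplate(c(replicate(3, w, simplify = FALSE),
                         replicate(3, wSlow, simplify = FALSE)), fs)
  tD <- seq(0, 0.04, by = 1e-6)
  kF <- pscKernel(kp, tD); kS <- pscKernel(kpSlow, tD)
  align <- function(k) {
    pk <- which.max(k)
    k[pmax(1, pk + seq(-20000, 20000))]
  }
  avg <- align(kF) + align(kS)
  avg <- avg / max(avg)
  pkA <- which.max(avg)
  seg <- avg[seq_len(pkA)]
  i20 <- max(which(seg < 0.2)); i80 <- min(which(seg >= 0.8))
  oracleRise <- (i80 - i20) * 1e-3   # ms
  expect_equal(templateRiseSpanMs(mix), oracleRise, tolerance = 0.15)
  expect_gt(templateRiseSpanMs(mix), templateRiseSpanMs(ref))
})

test_that("kinetics measurement matches the dense-grid oracle", {
  kp <- pscKernelParams(tauRiseMs = 0.5, tauDecayMs = 5)
  tk <- seq(0, 0.025, by = 1 / fs)
  win <- c(rep(0, 50), -30 * pscKernel(kp, tk))
  m <- measureKinetics(win, baseline = 0, fs = fs)
  oracle <- denseKinetics(0.5, 5)
  expect_false(m$truncated)
  expect_equal(m$amplitude, 30, tolerance = 0.01)
  expect_equal(m$rise_ms, oracle$rise_ms, tolerance = 0.1)
  expect_equal(m$decay_ms, oracle$decay_ms, tolerance = 0.1)
})

test_that("kinetics: symmetric pulse has equal rise and decay; truncation flagged", {
  tri <- c(seq(0, 10, length.out = 101), seq(10, 0, length.out = 101)[-1])
  m <- measureKinetics(tri, baseline = 0, fs = fs)
  expect_equal(m$rise_ms, m$decay_ms, tolerance = 1e-9)
  # window clipped before the decay recovers to 20%
  kp <- pscKernelParams(tauRiseMs = 0.5, tauDecayMs = 5)
  tk <- seq(0, 0.004, by = 1 / fs)
  clipped <- c(rep(0, 20), -30 * pscKernel(kp, tk))
  mc <- measureKinetics(clipped, baseline = 0, fs = fs)
  expect_true(mc$truncated)
  expect_true(is.na(mc$decay_ms))
})

test_that("a planted event is recovered once with accurate amplitude", {
  x <- plantKernelTrace(30, seed = 41)
  tmpl <- buildTemplate(pscKernelParams(), fs)
  ev <- applyExclusions(detectEvents(traceBundle(x), tmpl))
  inc <- ev[ev$included, ]
  expect_equal(nrow(inc), 1)
  expect_equal(inc$amplitude_pA, 30, tolerance = 3)
  expect_equal(inc$event_time_s, 1 + kernelPeakTime(pscKernelParams()),
               tolerance = 0.002)
  # flat trace: nothing detected
  expect_equal(nrow(detectEvents(traceBundle(rep(0, 2e4)), tmpl)), 0)
})

test_that("pure noise yields under 0.05 included events per second", {
  set.seed(42)
  x <- rnorm(60 * fs, 0, 1)
  tmpl <- buildTemplate(pscKernelParams(), fs)
  ev <- applyExclusions(detectEvents(traceBundle(x), tmpl))
  expect_lte(sum(ev$included) / 60, 0.05)
})

test_that("detection is invariant to polarity flip", {
  x <- plantKernelTrace(30, seed = 43)
  inTmpl <- buildTemplate(pscKernelParams(polarity = "inward"), fs)
  outTmpl <- buildTemplate(pscKernelParams(polarity = "outward"), fs)
  a <- applyExclusions(detectEvents(traceBundle(x), inTmpl))
  b <- applyExclusions(detectEvents(traceBundle(-x), outTmpl))
  expect_equal(sum(a$included), sum(b$included))
  expect_equal(a$amplitude_pA[a$included], b$amplitude_pA[b$included],
               tolerance = 1e-6)
})

test_that("recall and precision reach 0.9 on 15 pA events at 1 pA noise", {
  tmpl <- buildTemplate(pscKernelParams(), fs)
  tp <- 0; nTrue <- 0; nDet <- 0
  for (seed in 1:2) {
    sim <- simulatePSCSession(
      kernel = pscKernelParams(amplitudeMeanPa = 15, amplitudeCv = 0),
      train = eventTrainParams(1, 60),
      noise = noiseParams(gaussianSdPa = 1), seed = 100 + seed)
    ev <- applyExclusions(detectEvents(sim$bundle, tmpl))
    inc <- ev[ev$included, ]
    truth <- sim$groundTruth$events$peak_time_s
    nTrue <- nTrue + length(truth)
    nDet <- nDet + nrow(inc)
    tp <- tp + sum(vapply(truth, function(tt)
      any(abs(inc$event_time_s - tt) < 0.002), logical(1)))
  }
  expect_gte(tp / nTrue, 0.9)
  expect_gte(tp / nDet, 0.9)
})

test_that("exclusion flags equal the brute-force four-criteria oracle", {
  set.seed(44)
  n <- 400
  ev <- data.frame(
    cell_id = "c", condition = "b",
    event_time_s = sort(runif(n, 0, 1000)),
    amplitude_pA = runif(n, 0, 40),
    rise_ms = runif(n, 0.1, 6), decay_ms = runif(n, 0.5, 30),
    correlation = runif(n, 0.6, 1), included = TRUE,
    exclusion_reason = "", stringsAsFactors = FALSE)
  # plant exact boundary cases: they must all pass
  ev$amplitude_pA[1:3] <- 5; ev$rise_ms[1] <- 3; ev$decay_ms[1] <- 20
  ev$decay_ms[2] <- 1.5 * ev$rise_ms[2]
  ev$decay_ms[3] <- pmax(ev$rise_ms[3] * 1.5, 4)
  out <- applyExclusions(ev)
  oracle <- !(ev$amplitude_pA < 5 | ev$rise_ms > 3 | ev$decay_ms > 20 |
                ev$decay_ms < 1.5 * ev$rise_ms)
  expect_identical(out$included, oracle)
  expect_true(all(out$included[1:3]))
  # first-failing-rule reason order
  one <- ev[4, ]
  one$amplitude_pA <- 4.9; one$rise_ms <- 5
  expect_equal(applyExclusions(one)$exclusion_reason, "amplitude")
  two <- ev[4, ]; two$rise_ms <- 2; two$decay_ms <- 2.9
  expect_equal(applyExclusions(two)$exclusion_reason, "decay_rise_ratio")
})

test_that("equal-representation subsampling is deterministic and guarded", {
  ev <- rbind(randomEventTable(5), randomEventTable(6))
  ev <- ev[order(ev$cell_id, ev$condition, ev$event_time_s), ]
  ev$included <- TRUE; ev$exclusion_reason <- ""
  sizes <- table(paste(ev$cell_id, ev$condition))
  n <- min(sizes)
  a <- subsampleEqual(ev, n, seed = 7)
  b <- subsampleEqual(ev, n, seed = 7)
  expect_identical(a, b)
  expect_true(all(table(paste(a$cell_id, a$condition)) == n))
  expect_error(subsampleEqual(ev, max(sizes) + 1, seed = 7), "fewer than")
  # n equal to every group size: identity
  full <- subsampleEqual(ev, NULL, seed = 8)
  expect_true(all(table(paste(full$cell_id, full$condition)) == n))
})

test_that("cell summaries implement the frequency and change conventions", {
  ev <- data.frame(cell_id = "c1", condition = "baseline",
                   event_time_s = seq(0.5, 119.5, length.out = 120),
                   amplitude_pA = rep(20, 120), rise_ms = 1, decay_ms = 5,
                   correlation = 0.9, included = TRUE,
                   exclusion_reason = "", stringsAsFactors = FALSE)
  s <- summarizeCell(ev, 120)
  expect_equal(s$frequency_hz, 1)
  expect_equal(s$n_events, 120)
  empty <- summarizeCell(emptyEventTable(), 10)
  expect_equal(empty$frequency_hz, 0)
  expect_true(is.na(empty$mean_iei_ms))
  expect_error(summarizeCell(ev, 0), "> 0")
  fc <- frequencyChangePct(c(1, 1), c(0.5, 0.21))
  expect_equal(fc$mean_pct, mean(c(50, 79)))
  expect_equal(fc$mean_pct, 64.5)
})
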