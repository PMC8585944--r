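#' @include detect.R intrinsic.R opto.R stats.R simulate_psc.R
NULL

#' Default pipeline configuration
#'
#' All analysis thresholds default to the standard values used throughout
#' the package: 400 Hz low-pass, template correlation 0.6, exclusion limits
#' 5 pA / 3 ms / 20 ms / 1.5x, significance 0.05 (0.01 for KS).
#'
#' @param seed Master seed for the run.
#' @param outDir Output directory.
#' @param nCells Cells per condition in the demo experiment.
#' @param durationS Recording duration per cell, s.
#' @param nSubsample Events per cell for pooled statistics.
#' @return Config list of class `"runConfig"`.
#' @export
defaultRunConfig <- function(seed = 1, outDir = tempfile("hdinephys_run"),
                             nCells = 4, durationS = 60, nSubsample = 10) {
  structure(list(
    seed = seed, out_dir = outDir, n_cells = nCells,
    duration_s = durationS, n_subsample = nSubsample,
    lowpass_hz = 400, r_min = 0.6,
    min_amplitude_pa = 5, max_rise_ms = 3, max_decay_ms = 20,
    min_decay_rise_ratio = 1.5,
    alpha = 0.05, alpha_ks = 0.01,
    baseline_rate_hz = 1.01, drug_rate_hz = 0.37,
    baseline_amp_pa = 29.61, drug_amp_pa = 15.97,
    opto_latency_ms = 15, opto_jitter_ms = 1, opto_trials = 20),
    class = "runConfig")
}

validateRunConfig <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  if (config$r_min < -1 || config$r_min > 1)
    stopf("r_min must be a correlation in [-1, 1]")
  if (config$lowpass_hz <= 0) stopf("lowpass_hz must be > 0")
  for (nm in c("min_amplitude_pa", "max_rise_ms", "max_decay_ms",
               "min_decay_rise_ratio"))
    checkScalar(config[[nm]], nm, 0)
  for (nm in c("alpha", "alpha_ks")) checkScalar(config[[nm]], nm, 0, 1)
  invisible(config)
}

# Simulate + detect + summarise one group of cells at a given event rate
# and amplitude; returns events and per-cell summaries.
runPscGroup <- function(config, condition, rateHz, ampPa, seedOffset) {
  kern <- pscKernelParams(amplitudeMeanPa = ampPa)
  tmpl <- buildTemplate(kern, fs = 1e4)
  ev <- list(); summ <- list()
  for (i in seq_len(config$n_cells)) {
    sim <- simulatePSCSession(
      kernel = kern,
      train = eventTrainParams(rateHz, config$duration_s),
      cellId = sprintf("cell%02d", i), condition = condition,
      seed = config$seed + seedOffset + i)
    d <- applyExclusions(
      detectEvents(sim$bundle, tmpl, rMin = config$r_min,
                   cutoffHz = config$lowpass_hz),
      config$min_amplitude_pa, config$max_rise_ms, config$max_decay_ms,
      config$min_decay_rise_ratio)
    ev[[i]] <- d
    summ[[i]] <- summarizeCell(d, config$duration_s)
  }
  list(events = do.call(rbind, ev), summaries = do.call(rbind, summ))
}

#' Run the end-to-end demonstration pipeline
#'
#' Deterministically (given `config$seed`) simulates and analyses a small
#' replica of the package's three core experiments: a baseline-versus-
#' picrotoxin spontaneous-current comparison (detection, exclusion,
#' equal-representation subsampling, KS/Mann-Whitney statistics), an
#' intrinsic-property session (RMP, test-pulse resistances, step-series
#' spike counts) and a light-evoked synaptic-latency session with the
#' Poisson bin test. Writes `events.csv`, `stats.json`, `profile.json`,
#' `opto.json` and a `provenance.json` run log into `config$out_dir`.
#'
#' @param config A [defaultRunConfig()] list.
#' @return Invisibly, the output directory; the parsed result objects are
#'   attached as the attribute `"results"`.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  validateRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ## spontaneous currents: baseline vs picrotoxin
  base <- runPscGroup(config, "baseline", config$baseline_rate_hz,
                      config$baseline_amp_pa, seedOffset = 1000)
  drug <- runPscGroup(config, "PTX", config$drug_rate_hz,
                      config$drug_amp_pa, seedOffset = 2000)
  events <- rbind(base$events, drug$events)
  writeEventTable(events, file.path(config$out_dir, "events.csv"))
  nSub <- min(config$n_subsample,
              min(base$summaries$n_events), min(drug$summaries$n_events))
  subB <- subsampleEqual(base$events, nSub, seed = config$seed + 1)
  subD <- subsampleEqual(drug$events, nSub, seed = config$seed + 2)
  ieiB <- sampleIEIs(base$events, nSub, seed = config$seed + 3)
  ieiD <- sampleIEIs(drug$events, nSub, seed = config$seed + 4)
  statsOut <- list(
    amplitude = compareDistributions(subB$amplitude_pA, subD$amplitude_pA,
                                     alphaKs = config$alpha_ks,
                                     alphaRank = config$alpha),
    iei = compareDistributions(ieiB, ieiD, alphaKs = config$alpha_ks,
                               alphaRank = config$alpha),
    frequency_change = frequencyChangePct(base$summaries$frequency_hz,
                                          drug$summaries$frequency_hz),
    per_cell = list(baseline = base$summaries, drug = drug$summaries))
  jsonlite::write_json(statsOut, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  ## intrinsic properties
  cc <- simulateCurrentClampSession(seed = config$seed + 10)
  tp <- simulateTestPulse(seed = config$seed + 11)
  profile <- list(rmp_mv = measureRMP(cc$bundle),
                  resistances = measureResistances(tp$bundle),
                  firing = maxAPCount(cc$bundle)[c("max_count",
                                                   "sustained_rate_hz")])
  jsonlite::write_json(profile, file.path(config$out_dir, "profile.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  ## optogenetics: downstream cell
  opto <- simulateOptoSession(
    circuit = optoCircuitParams(nTrials = config$opto_trials,
                                latencyMeanMs = config$opto_latency_ms,
                                latencyJitterSdMs = config$opto_jitter_ms),
    seed = config$seed + 20)
  tmpl <- buildTemplate(pscKernelParams(), fs = 1e4)
  h <- extractEvokedLatencies(opto$bundle, tmpl)
  pt <- poissonBinTest(h, alpha = config$alpha)
  cls <- classifyResponse(hist = h, poisson = pt,
                          drugFlags = list(abolished_ptx = TRUE,
                                           abolished_nbqx_ap5 = FALSE))
  optoOut <- list(latency_histogram = unclass(h), poisson = pt,
                  classification = cls)
  jsonlite::write_json(optoOut, file.path(config$out_dir, "opto.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  ## provenance
  prov <- list(package_version =
                 as.character(utils::packageVersion("hdinephys")),
               config = unclass(config),
               counts = list(events_total = nrow(events),
                             events_included = sum(events$included),
                             cells = 2 * config$n_cells,
                             opto_trials = h$n_trials))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  res <- list(stats = statsOut, profile = profile, opto = optoOut,
              provenance = prov)
  out <- config$out_dir
  attr(out, "results") <- res
  invisible(out)
}

#' Subsample per-cell inter-event intervals
#'
#' Intervals are computed over consecutive included events first, then `n`
#' intervals per cell/condition are drawn without replacement, keeping the
#' rate contrast between conditions intact (subsampling event times to a
#' fixed count per fixed duration would equalise apparent rates).
#'
#' @param events Event table (post-exclusion).
#' @param n Intervals per cell.
#' @param seed Seed.
#' @return Numeric vector of intervals (ms), pooled across cells.
#' @export
sampleIEIs <- function(events, n, seed = NULL) {
  inc <- events[!is.na(events$included) & events$included, , drop = FALSE]
  grp <- split(inc$event_time_s,
               paste(inc$cell_id, inc$condition, sep = " / "))
  withSeed(seed, {
    unlist(lapply(grp, function(tt) {
      iei <- diff(sort(tt)) * 1000
      if (length(iei) <= n) iei
      else iei[sample.int(length(iei), n)]
    }), use.names = FALSE)
  })
}
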