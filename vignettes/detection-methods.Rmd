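---
title: "Detection, intrinsic-property and optogenetic analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detection, intrinsic-property and optogenetic analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdinephys)
```

## Scope

`hdinephys` analyses whole-cell patch-clamp recordings from cultured human
stem cell-derived GABAergic interneurons (hdINs) and the host neurons they
innervate: spontaneous postsynaptic current (PSC) detection and kinetics,
passive and active intrinsic properties, Na/K current-voltage curves,
light-evoked (channelrhodopsin-2) response analysis, nonparametric
pharmacology statistics, and the cell-composition / delta-Ct arithmetic
used alongside such experiments. Because raw recordings from these
preparations are rarely published, the package pairs every analysis stage
with a ground-truthed simulator, so the whole chain can be validated by
parameter recovery rather than by reference traces.

## PSC detection by template correlation

Voltage-clamp traces (10 kHz sampling, holding -70 mV) are first low-pass
filtered with a 4th-order Butterworth at 400 Hz, applied forward and
backward so the filter is zero-phase with unit DC gain. The forward-
backward pass assumes zeros outside the trace, which distorts the edges;
`lowpassTrace()` therefore pads by odd reflection (about the end values)
before filtering and strips the pads afterwards.

Detection slides a unit-peak template along the filtered trace with a hop
of one sample and computes the Pearson correlation between the template
and each window. Pearson correlation on mean-subtracted windows is
scale-free, so small and large events match equally well; this is the
simplest reading of a "correlation coefficient to the template" criterion,
and the alternative (normalised cross-covariance) differs only in
windowing details. Contiguous regions with `r >= 0.6` yield one candidate
event each, at the local correlation maximum. Two accepted peaks may not
lie closer than the template's 20-80% rise span (about 0.9 ms for the
default template): overlapping candidates are pruned greedily by
descending correlation. This prevents double counting while still
resolving bursts a few milliseconds apart; truly overlapping events within
one rise span are counted once, a known limitation shared by all
single-template detectors.

The default parametric template is a bi-exponential kernel

$$k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r},\qquad
\tau_r = 0.5\ \mathrm{ms},\ \tau_d = 5\ \mathrm{ms},$$

normalised to unit peak (the analytic peak time is
$t^* = \ln(\tau_d/\tau_r)\,\tau_d\tau_r/(\tau_d-\tau_r)$), preceded by a
5 ms flat baseline segment. `buildTemplate()` can instead average at least
five peak-aligned seed events, renormalised to unit peak, which is how a
recording-derived template is built in practice. Note that peak-aligned
averaging of heterogeneous kinetics slightly flattens the apex, so the
averaged template's 20-80% rise can exceed the rise of its slowest
component; the tests pin this behaviour against a dense-grid averaging
oracle rather than assuming an interpolation property that does not hold.

### Amplitude, kinetics and exclusions

Event amplitude is the absolute difference between the window extremum and
the median of the pre-peak baseline window (the median is robust to a
neighbouring event intruding into the baseline span). Rise time is the
interpolated interval between the last 20% and first 80% crossing before
the peak; decay time between the first 80% and the following 20% crossing
after it. Events whose crossings are cut off by the sweep edge are flagged
`"truncated"` and excluded.

Four exclusion rules are then applied in order, recording the first
failure: amplitude < 5 pA (the working amplifier noise floor is ~4 pA
peak-to-peak), rise > 3 ms, decay > 20 ms, and decay < 1.5 x rise.
The inequalities are strict, so boundary values (exactly 5 pA, 3 ms,
20 ms, 1.5x) pass. The included set is tested to be exactly the set the
four criteria select when evaluated independently.

For pooled statistics, `subsampleEqual()` draws the same number of
included events per cell and condition (10 by convention) so that no
neuron dominates. Inter-event intervals (IEIs) are computed over
consecutive included events *before* any subsampling, and the
equal-representation sample for IEI comparisons is drawn from those
interval values (`sampleIEIs()`): subsampling event *times* to a fixed
count over a fixed duration would force both conditions to the same
apparent rate and erase the very contrast being tested. Frequency is
defined as included events / analysed duration, deliberately independent
of the mean IEI (the two are not reciprocal for non-stationary or
subsampled trains).

## What the simulator emulates

`simulatePSCSession()` plants bi-exponential PSCs as a homogeneous Poisson
process with log-normal amplitudes (mean and CV configurable) on Gaussian
noise with sd = floor/4, so the 2.5-97.5 percentile span of the baseline
equals the 4 pA peak-to-peak floor. The kernel defaults sit inside the
exclusion window even after 400 Hz filtering: the filtered 20-80% rise is
~0.9 ms and the filtered peak is transmitted at 1.03 (the zero-phase
filter slightly overshoots), numbers established by a design-time filter
response computation. The simulator does not model 1/f or line noise,
series-resistance filtering of the synaptic current, overlapping-event
interactions beyond summation, or rundown; recovery results on synthetic
data therefore bound performance from above on real traces.

The current-clamp cell is an adaptive exponential integrate-and-fire
(AdEx) membrane integrated with forward Euler at the sampling step. The
default mature-cell parameters (C = 60 pF, gL = 2 nS, EL = -47.2 mV,
VT = -38 mV, DeltaT = 2 mV, a = 2 nS, b = 20 pA, tau_w = 150 ms,
Vreset = -48 mV, spike apex +30 mV) produce regular adapting spiking,
monotone step counts and a maximum sustained rate of ~30-42 Hz over the
-40..200 pA / 500 ms step series, below the 62 Hz ceiling such cultures
show; the holding bias current compensates both leak and the steady-state
subthreshold adaptation $a(V-E_L)$. AdEx resets instantaneously, so the
measured AP "duration at threshold" reflects mainly the upstroke --
adequate for recovery testing, not a biophysical width model. The AHP is
measured to the deepest post-spike voltage before the next spike (a fixed
post-spike window would be an equally defensible choice; the deepest point
is parameter-free).

The voltage-clamp cell uses Boltzmann-gated conductances: transient Na
($m^3 h$, instantaneous-ish activation with $\tau_m = 0.2$ ms,
inactivation $\tau_h = 1.5$ ms) and a sustained single-gate K
($\tau_n = 8$ ms, activation V1/2 = -10 mV), plus leak and a
series-resistance capacitive transient. TTX zeroes gNa; TTX+TEA also
zeroes gK. Ground truth stores the dense-grid (2 microsecond) minimum of
the leak-subtracted voltage-gated current in the first 10 ms -- the
quantity ideal leak subtraction recovers -- alongside the Na-only
component; the two differ by the small early K contamination that every
peak-inward measurement inherits.

Light-evoked responses: a direct (ChR2-expressing) cell shows a
photocurrent with single-exponential activation to a desensitising
plateau; a downstream cell shows PSCs at a per-cell latency (Gaussian
jitter, truncated at zero) after each light onset, on top of Poisson
background activity. Red-light (595 nm) control sweeps carry the light
channel but no response.

## Intrinsic-property conventions

* RMP: mean of the first second of the zero-current sweep, with +/- 5 ms
  around detected spikes masked.
* Rs/Ri from a 5 mV test pulse: Rs = dV / transient peak,
  R_total = dV / steady current (last 25% of the pulse), Ri = R_total -
  Rs. The transient must exceed 3 x baseline noise sd, otherwise Rs is
  flagged unresolved.
* Spikes: upward crossings of dV/dt >= 10 mV/ms followed by an apex above
  -10 mV within 5 ms -- a standard, noise-robust criterion at 10 kHz
  (voltage noise of 0.5 mV at 10 kHz produces dV/dt excursions near this
  threshold, which the apex requirement rejects). Apex candidates within
  2 ms are merged.
* I-V extraction: leak/capacitive removal by scaled subtraction of the
  -90 mV step (both components are linear in the command excursion, so a
  single scaled reference removes them without hardware-compensation
  metadata); Na peak = minimum within 10 ms of onset, K = mean of the
  last 20 ms. Windows are arguments.

## Optogenetic latency analysis and the Poisson bin test

Only the first included event per trial within the response window
(default: pulse duration + 100 ms) contributes a latency; the histogram
uses 10 ms bins. Both choices are configurable; 10 ms resolves the 1-2 ms
jitter of a monosynaptic connection while keeping per-bin counts
interpretable at 10-20 trials. The spontaneous rate is estimated from the
pooled pre-light windows of the same sweeps (a within-cell control; at
least 1 s of pooled baseline is required).

For the fullest bin with count $k$ and expectation
$\lambda = r_{\mathrm{base}} \cdot \Delta t_{\mathrm{bin}} \cdot
n_{\mathrm{trials}}$, the single-bin upper tail
$P(X \ge k \mid \lambda)$ is the conventional quantity quoted for "the
highest frequency distribution time". Selecting the maximal of
$n_{\mathrm{bins}}$ bins makes that single-bin tail anticonservative
under the null (with ~60 bins its false-positive rate approaches 50% in
realistic settings), so `poissonBinTest()` also reports
$p_{\mathrm{adj}} = 1 - P(X < k)^{n_{\mathrm{bins}}}$, the probability
that the maximum of $n_{\mathrm{bins}}$ independent Poisson counts
reaches $k$. The `significant` flag and `classifyResponse()` use
$p_{\mathrm{adj}}$; first-event depletion makes the independence
assumption conservative, and the calibration is verified on 500 null
sessions in the test suite. A genuinely coupled cell concentrates most
trials in one bin, where both p-values are astronomically small, so the
adjustment costs essentially no power.

Classification: *direct* if the photocurrent onset is within 2 ms of
light onset and survives both synaptic blockers; *synaptic* if the median
latency exceeds 2 ms, the across-trial latency sd is at most 20 ms and
the Poisson test is significant; GABAergic if abolished by picrotoxin but
not by NBQX+AP5. Conflicting evidence yields `"ambiguous"` with a
warning.

## Statistics and composition arithmetic

Distribution comparisons use the two-sample KS test (significance 0.01 by
convention for cumulative event measures); central-tendency comparisons
use Mann-Whitney (unpaired) or Wilcoxon signed-rank (paired) at 0.05,
with the exact small-sample null when the data are tie-free -- required
for agreement with exhaustive enumeration, which the suite checks for all
group sizes up to 8. Proportions use Fisher's exact test. The outlier
screen is a single-pass Grubbs test (one flagged value at most); Grubbs
is the simplest defensible choice where the original screening procedure
is unspecified, and the flag is advisory -- values are reported, not
silently dropped. One-way ANOVA with Tukey contrasts, where needed, is
plain `stats::aov` + `TukeyHSD` and deliberately not wrapped.

Composition summaries express each marker as a percentage of MAP2+
neurons per field, average fields within a time point (mean +/- SEM), and
combine time points as the unweighted mean of the time-point means
(`averageAcrossTimepoints()`); fewer than 600 counted cells per marker
and time point raises a flag, not an error. `inferTotalFraction()`
divides an observed reporter-labelled percentage by the labelling
efficiency to recover the total population fraction (e.g. 2.01% labelled
at 74.1% efficiency implies 2.71% total, 0.70% unlabelled). Relative
expression uses triplicate-mean Cts and
$\Delta C_t = C_t^{\mathrm{gene}} - \tfrac12(C_t^{ACTB} +
C_t^{GAPDH})$, reporting both $\Delta C_t$ and $2^{-\Delta C_t}$; any
missing triplicate set marks the gene not detected, and a missing
housekeeping gene is fatal for that sample.

## Problem sizes and determinism

The validation suite uses desk-scale problem sizes chosen to keep each
property statistically decisive: 14-cell cohorts of 120 s sessions for
rate/amplitude recovery (binomial/Poisson error of the cohort mean ~2-3%,
comfortably inside the 10% acceptance band), 3 x 60 s sessions for
recall/precision, 100 s of pure noise for the false-positive bound,
500 event-level null sessions for the Poisson-test calibration and 100
event-level replicates for the pharmacology KS power check. All
simulators take explicit seeds and restore the caller's RNG state; a
fixed seed reproduces sessions bit-identically.

## Known limitations

* Single-template detection cannot decompose overlapping events closer
  than the template rise span, and amplitudes are measured on the 400 Hz
  filtered trace (3% transmission bias for the default kernel).
* The AdEx reset makes spike width and afterdepolarisation shapes
  schematic.
* The Poisson bin adjustment assumes independent bins; true first-event
  sampling is slightly conservative under the null.
* Composition and delta-Ct stages consume counts/Ct tables; imaging and
  qPCR preprocessing are out of scope.
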