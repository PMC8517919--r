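---
title: "Transient bursts and burst-coincidence connectomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient bursts and burst-coincidence connectomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Band-limited "oscillatory" power in electrophysiological recordings —
beta-band (13–30 Hz) power in particular — is to a large degree not a
sustained rhythm but the time-average of transient, high-amplitude,
pan-spectral *burst* events.  Two consequences follow.  First, classical
amplitude metrics conflate how strong bursts are with how often they
occur; burst-resolved metrics (amplitude, occupancy, duration, rate)
disentangle them.  Second, functional connectivity between regions can
be re-expressed as the *temporal coincidence* of bursting: two regions
are coupled to the degree that their bursts co-occur.

`burstconn` implements this analysis chain for regional ("virtual
sensor") time series: signal conditioning, per-region burst detection
with a time-delay-embedded hidden Markov model (TDE-HMM),
burst-coincidence (Jaccard) connectomics, movement-locked burst
dynamics, non-parametric group statistics, and classification of
connectomes.  Because no public dataset accompanies this problem
setting, the package includes a first-class synthetic-data generator
that plants known burst structure, so every downstream stage is
testable against ground truth.

## Signal conditioning

The conditioning sequence is fixed: band-pass filter →
symmetric orthogonalisation → resample → standardise
(`condition_recording()`).

* **Band-pass** (`bandpass()`): zero-phase (forward–backward)
  Butterworth filtering, applied per region.  Zero-phase application is
  deliberate: burst *timing* is the quantity of interest downstream,
  and a causal filter would lag-shift it.  The band-pass is realised as
  a cascade of a high-pass and a low-pass stage because a direct
  band-pass design with a lower edge at ~1/300 of Nyquist (1 Hz at
  600 Hz sampling) is numerically fragile; the cascade has the same
  pass band and is stable.
* **Leakage correction** (`symmetric_orthogonalize()`): source
  reconstruction mixes signal between nearby regions at zero lag, which
  inflates any coincidence metric.  The correction replaces the
  regional time courses by the closest set of mutually orthogonal ones:
  stage one takes the polar factor (closest orthonormal frame, via
  SVD); stage two alternates between re-fitting the frame and
  re-fitting per-region lengths, which monotonically decreases the
  Frobenius distance to the input.  Convergence is declared when the
  relative change in total vector length falls below `1e-9` (or at 200
  iterations); the distance trace is returned for inspection.  Regions
  are mean-centred first, so the output has exactly zero pairwise
  correlation, not just zero dot products.  Orthogonalisation is run on
  the concatenated recording, not per epoch: the mixing it removes is
  an anatomical/geometrical property of the reconstruction and does not
  change between epochs, and a single decomposition uses all available
  samples.
* **Resampling** (`resample_recording()`): an 8th-order zero-phase
  Butterworth low-pass at 90% of the target Nyquist removes content
  that would alias, then samples are taken on the target grid (exact
  sample-picking for integer ratios such as 600 Hz → 100 Hz).  Epoch
  boundaries are treated as half-open positions and events as sample
  marks; both are rescaled and rounded to the nearest output sample.
* **Standardisation** (`standardize()`): per-region mean 0, variance 1.
  The HMM observation model assumes zero-mean data, and unit variance
  puts regions and subjects on a common amplitude scale.

Simulated data are generated directly in "source space" with
independent backgrounds, so the default pipeline configuration skips
orthogonalisation (`orthogonalize = FALSE` in `run_config()`); it is
exercised explicitly in the conditioning tests.

## Burst detection: the TDE-HMM

Each region is processed independently (`fit_tdehmm()`).  The series is
lag-embedded over a 230 ms window (`tde_embed()`; 23 lags at 100 Hz),
and a K-state HMM (default K = 3) is fitted in the embedded space.
Each state is a **zero-mean Gaussian with full covariance over the
lags**: a state is therefore characterised by an autocovariance
pattern, i.e. by its spectral content over the window, which is what
lets one state capture the transient high-power burst regime.  Means
are fixed at zero because the data are standardised and bursts are
amplitude-symmetric.

Inference is maximum-likelihood EM with numerically scaled
forward–backward recursions (`forward_backward()`), safe for
T′ ≈ 24,000 columns.  A variational treatment would require prior
hyperparameters that have no principled values at this data scale; EM
keeps the model free of invented constants while preserving every
property the pipeline relies on: a monotone objective, exact smoothing
(validated against brute-force path enumeration on small instances),
and recovery of planted spectral regimes.  Initialisation is k-means on
the embedded vectors; the best of `n_restarts` (default 3) seeded
restarts by final log-likelihood is kept.  If a state's covariance
collapses it is ridge-regularised and the event is logged in
`collapse_log`.  Epochs are independent observation segments — the
chain restarts at each epoch boundary — sharing one parameter set, so
no spurious transition spans a boundary.  Posterior columns are mapped
back to original sample indices; the (L−1)/2 edge samples of each epoch
are flagged `NA` and treated as non-burst downstream.

The **burst state** is identified post hoc (`select_burst_state()`): it
is the state whose probability course correlates highest with the
beta-band amplitude envelope.  The envelope (`beta_envelope()`) is a
Morlet-style analytic filter bank — frequency-domain Gaussians with
spectral SD f/7 (seven cycles), stepped at 1 Hz through 13–30 Hz, with
the modulus averaged across frequencies.  Binarisation
(`binarize_posterior()`) marks a sample as burst iff the state
probability **strictly exceeds 2/3**; a probability of exactly 2/3 is
non-burst.  Visits are maximal runs of burst samples within an epoch.
No minimum duration is imposed.

Per-region metrics (`burst_summary()`): burst amplitude = mean over
visits of the per-visit envelope maximum; non-burst amplitude = mean
envelope over non-burst samples (per-gap maxima are ill-defined for
arbitrary-length gaps, so the mean is used); total burst time; mean
visit duration; visit rate.  `global_collapse()` averages these across
regions, excluding (and counting) regions with no visits from the
amplitude mean.

## Burst-coincidence connectomics

Connectivity between regions i and j is the Jaccard index of their
binary burst trains: the number of samples where both burst divided by
the number where either bursts (`jaccard()`, `burst_connectome()`).
Values lie in [0, 1]; 1 is perfect coincidence.  A pair whose union is
empty is assigned 0 and masked (rather than NaN) so group averaging
stays defined.  The diagonal is fixed at 0; for 78 regions there are
3003 unique connections.  Under independence, two trains of occupancy
p have expected J ≈ p/(2−p), which the tests use as a closed-form
check.  Edge selection (`top_fraction()`) keeps the ⌊f·n⌋ largest
edges, breaking ties lexicographically so results are deterministic.
The Jaccard index is computed over the concatenated recording rather
than per epoch: the statistic is a ratio of counts, and concatenation
weights every sample equally while avoiding 10 s-epoch small-sample
noise.

## Movement-locked dynamics

For task data, binary trains and envelopes are cut into ±3 s trials
around each button press (`epoch_trials()`; trials overlapping the
record edge are dropped).  The burst-probability course
(`burst_probability_course()`) is the across-trial mean at each
trial time; it dips during movement (the movement-related beta
decrease) and overshoots after movement offset (the post-movement
rebound).  Window statistics (`window_burst_stats()`) use the rebound
window 0.45–0.85 s.  The suppression window is not numerically defined
by convention, so the package defaults to (−0.3, 0.1) s — bracketing
the button press — and exposes it in `window_spec()`.  Rebound-window
burst amplitude includes every visit that intersects the window
(equivalently: falls within, begins, or ends during it).  The
time-resolved coincidence course (`coincidence_course()`) computes the
Jaccard index *across trials* at each trial time.

## Group statistics

`run_group_battery()` executes the study design's families:
patient-vs-control Wilcoxon rank-sum tests on the three global resting
metrics (Benjamini–Hochberg across the three), the 12-test movement
battery (2 cortices × 2 press sides × 3 metrics, BH across twelve), a
single test on global connectivity, and Spearman correlations with
symptom severity run separately within patients and across the
combined group — combined-group results are annotated as likely driven
by the group difference and only support the group comparisons.  Tests
are two-sided throughout; the rank-sum p-value is exact for pooled
n ≤ 20 without ties and a tie- and continuity-corrected normal
approximation otherwise.  These operations delegate to the standard R
implementations behind the module surface and are validated against
enumeration oracles in the test suite.

## Connectome classification

`svm_cv()` runs stratified 10-fold cross-validation over subjects with
all 3003 (or R(R−1)/2) connection values as features.  Inside each
training fold only: recursive random-forest feature selection
(`rrf_select()`), feature standardisation, and a linear-kernel SVM; the
held-out fold is scored by decision value and summarised as ROC-AUC.
The selection recursion fits a permutation-importance forest (500
trees), drops features below the mean importance, and refits until the
set stabilises or reaches a floor of 5 features; this is repeated over
10 stratified bootstrap resamples, and the consensus keeps features
selected in ≥ 50% of resamples.  These constants are not fixed by the
problem and are exposed in `classifier_config()`.  The linear kernel is
deliberate: selected edges stay interpretable as connections.
Significance uses label permutation of the full pipeline
(`permutation_test()`), p = (1 + #{null ≥ observed})/(1 + n_perm), so
p can never fall below 1/(n_perm + 1).  `selected_edge_report()`
summarises the consensus edges: per-subject mean connectivity, group
contrast, symptom correlations, and the fraction of interhemispheric
edges (parsed from `_L`/`_R` label suffixes).

## The synthetic-data generator

`simulate_resting()` / `simulate_task()` emulate the regional data this
pipeline consumes; `sim_config()` collects the knobs.

* **Background**: 1/f^α Gaussian noise per region (default α = 1),
  spectrally shaped in the frequency domain and standardised.
* **Bursts**: a Poisson stream of events per region (default
  1.2 visits/s), log-normal durations (mean 0.3 s, CV 0.5 — positive
  and right-skewed, as empirical burst durations are).  Each visit is a
  Tukey-windowed sinusoid at a carrier drawn uniformly from 13–30 Hz
  plus a small broadband transient (30% white noise inside the window),
  i.e. a beta-dominant but pan-spectral packet, scaled by
  `burst_amplitude` (default 3 × background SD).  Overlapping events
  merge into one visit, so planted occupancy tracks
  1 − exp(−rate × duration) ≈ 30% at the defaults, and no visit
  crosses a 10 s epoch boundary.  With no stated quantitative burst
  statistics for this kind of cohort, these defaults are conventions
  chosen once: rate and duration give the ~30% burst occupancy typical
  of resting beta, and amplitude 3 gives clearly super-threshold but
  not artefact-like events.
* **Coincidence**: pairwise co-occurrence is planted by shared event
  pools: a pair with co-occurrence c receives a shared Poisson stream
  at rate c × rate whose events appear in both regions with a common
  start and duration; each region's independent stream makes up the
  remainder of its total rate (hence row sums of the off-diagonal
  co-occurrence must stay ≤ 1).  This gives direct control of the
  Jaccard ground truth.  Two stock structures: homologous left–right
  pairs only (`homologous_coincidence()`, the default, mirroring the
  empirically dominant interhemispheric coupling) and a dense variant
  with a baseline on every pair (`all_pairs_coincidence()`), used when
  a *global* connectivity effect must be planted — with the sparse
  structure a global-mean metric is mostly unplanted chance coincidence
  and carries almost no group signal.
* **Group effects** (patients): burst amplitude × 0.8, co-occurrence
  × 0.7, movement-locked modulation depth × 0.6; occupancy untouched.
  Between-subject variability is log-normal (SD 0.15 on the log scale)
  on each subject's amplitude and coincidence scales; the coincidence
  scale doubles as the planted severity covariate for
  `sample_symptom_scores()` (score = baseline − slope × covariate +
  noise, truncated at 0).
* **Task modulation**: candidate events are drawn at an inflated rate
  and thinned by the profile value at the candidate's midpoint lag
  relative to the nearest press (suppression ×0.2 in (−0.3, 0.1) s,
  elevation ×2 in (0.45, 0.85) s by default).  Midpoint thinning keeps
  the planted occupancy profile centred on the windows instead of
  smeared rightward, as start-rate modulation would.  Thinning is
  decided per shared event, so coincidence survives modulation.

What the generator does **not** emulate: sensor arrays and forward
fields, head motion, physiological artefacts, spatially correlated
leakage (beyond what `symmetric_orthogonalize()` is tested on
directly), non-stationary background spectra, or the real cohort's
effect sizes.  Passing tests therefore demonstrate that the pipeline
recovers the structure this model plants — not that real recordings
meet the model's assumptions.

## Numerical choices and degenerate inputs

* Binarisation is strictly `>` at 2/3; exactly 2/3 is non-burst.
* Burst-state correlation ties resolve to the lower state index, as do
  Viterbi ties; both are logged.
* Rank-deficient input to orthogonalisation errors with the offending
  region labels; zero-variance regions error in `standardize()`.
* Empty burst trains flag amplitude/duration as undefined; empty
  unions yield J = 0 with a mask; empty consensus feature sets fall
  back to the top-voted features, with a message.
* `ranger` reports `NA` importance for features never used in any
  tree; these are treated as zero importance.
* Subject containers are delimited text (`%.17g`) plus a JSON sidecar
  and round-trip float64 payloads bitwise.

## Problem sizes used in the shipped checks

The validation suite runs on scaled-down cohorts chosen to exercise
every stage at interactive cost: planted-effect recovery uses 6-region,
60 s recordings at n = 20/group over 40 simulation seeds (resting) and
2-region, 40-trial task cohorts over 20 seeds; null calibration of the
classifier uses 200 seeds of 20 × 20 feature tables and 60 permutation
runs of 19 permutations each; the exact-inference oracle enumerates all
paths for K ≤ 3, T ≤ 12.  The acceptance script
(`scripts/acceptance.R`) uses the same machinery at the study's cohort
sizes (23 patients vs 20 controls) with a 6-region full-HMM cohort and
a 20-region classification cohort.  These sizes are the package's
validation choices; all thresholds are stated in the tests themselves.

## Known limitations

* The HMM is univariate per region; a coincident burst in two regions
  is evidence of coordination, not proof of interaction, and a
  noise-dominated region still receives a (meaningless) burst state —
  the selection correlations are returned so such regions can be
  screened.
* EM finds local optima; restarts mitigate but do not eliminate this.
* The Jaccard index depends on occupancy as well as coordination;
  group comparisons are interpretable here because planted occupancy
  is held fixed across groups, and empirical occupancy should be
  checked alongside connectivity in any real application.
* The generator's bursts are stationary in rate and spectrum within a
  recording; real data are not.
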