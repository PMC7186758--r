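---
title: "Models and methods: social states and spike-rate analysis in beesocial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: social states and spike-rate analysis in beesocial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beesocial)
```

## The problem

A honeybee carrying a chronic extracellular electrode walks freely in an
observation hive (a 55 cm x 55 cm wax floor tilted 17 degrees from the
horizontal) among untethered nest mates, while one mushroom-body extrinsic
neuron is recorded. The question is how the unit's spike rate relates to the
bee's *self-initiated* behavior: its walking, its body orientation relative
to gravity, its distance to the nearest other bee, and the social contacts
it experiences or initiates. `beesocial` implements that analysis chain —
from tracker CSV and sorted spike times to state-resolved statistics — plus
a synthetic colony generator with planted, recoverable effects, so that
every stage can be validated by parameter recovery rather than by eye.

All analyses live on a common 100 ms clock: video frames arrive at 10 Hz
and spikes are counted in half-open 100 ms bins aligned to the frame grid
(`bin_spikes()`); a partial trailing bin is dropped.

## Social states

Five kinds of 4 s windows are defined from two covariates only — nearest-bee
distance and the focal bee's own movement — each synchronized at its 2 s
mark (`classify_all()`):

* **alone** — no other bee closer than 10 cm (strictly) for the whole
  window. Maximal alone runs are tiled greedily from their start into
  non-overlapping 4 s windows.
* **walking onset** — the focal bee moves less than 1 mm (total path) for
  2 s and then walks continuously for at least 2 s; the sync mark is the
  onset frame. Overlapping candidates are resolved by keeping the earliest
  and skipping 4 s.
* **passive contact** — the focal bee is alone at the window start, exactly
  one bee comes closer than 1 cm at the sync mark, and the focal bee either
  does not move for the entire window or moves for the entire window.
* **active contact** — same geometry, but the focal bee was still early in
  the window and started walking within the last second before the contact
  moment (and keeps walking).
* **random** — control windows drawn uniformly over the recording, one per
  passive contact, so baseline comparisons are count-matched.

Two operational parameters are not fixed by the rule set and are explicit
configuration with defaults chosen here: a frame counts as *moving* at
walking speed >= 0.5 cm/s (about half a body length per second, above
tracker jitter), and a span counts as continuous walking when >= 90% of its
frames are moving (one or two dropped frames in 2 s do not break a bout).
Both live in `analysis_config()` alongside every threshold above, so the
whole rule set is one inspectable object. Other conventions: "alone
beforehand" is evaluated at the window start frame; windows of the same
state never overlap while cross-state overlaps are permitted and counted;
random windows may overlap real states (they are a baseline draw, not an
exclusion); contacts whose movement pattern matches neither the passive nor
the active template are dropped and counted, as are events whose window
would poke outside the recording.

## Event-aligned rate analyses

**Perievent time histogram.** For each event with a full +/-8 s context,
the 160 surrounding rate bins are extracted and divided by that event's own
mean rate over the context (`peth()`); events with zero spikes in context
are dropped. Averaging these per-event relative profiles makes the mean
over lags exactly 1, so "1" is always the null line. The alternative
normalization by the grand mean rate is available by flag.

**Pre-event peak latency.** The mean relative profile is smoothed with a
0.3 s boxcar and the maximum within [-4 s, 0] is reported as positive
seconds-before-event (`peak_pre_event_latency()`). A histogram whose
smoothed maximum is within 5% of the overall mean is reported as having no
phasic peak rather than a spurious latency.

**Window variance.** Each 4 s window is reduced to the population variance
(denominator n = 40) of its 40 bin rates, in Hz^2 (`window_variance()`) —
a single "rate instability" parameter independent of the mean level and of
the direction of rate excursions. Pairwise state comparisons use the
rank-sum test with a Bonferroni family of the 6 pairs among the four
non-alone states; an alpha/6 correction determines the star levels 0.05/6,
0.01/6 and 0.005/6 (0.0083, 0.0017, 0.00083). The 6-pair family is an
interpretive choice — with five states there are ten pairs, and alpha/6 can
only refer to the four non-alone states — and a 10-pair variant is
available (`family = "all"`).

**Distance deciles.** Frames with a defined nearest-bee distance are
sorted by spike rate into 10 equal-count groups and each group's distance
distribution is summarized; group 10 (highest rates) is compared with
group 1 by rank-sum (`decile_distance_analysis()`). With 100 ms count bins
most frames tie (0 or 1 spike), and breaking ties by time order would put
the tied members of each group at one end of the recording; because
positions are strongly autocorrelated, that alone rejects the null far
above nominal (we measured ~72% at the 5% level). Ties are therefore broken
by a deterministic multiplicative hash of the frame index — reproducible
but uncorrelated with time — which restores the nominal level (3–5% in the
type-I simulations).

**5 cm split.** The same frame set is split at 5 cm (exactly 5 counts as
near) into near/far rate distributions per contiguous data quarter
(`distance_split_profiles()`), for judging the stability of the distance
effect over the session; `quarter_split()` sends remainder frames to the
fourth quarter so the quarters always concatenate to the original series.

**Orientation profiles.** Body-axis angles are resolved in 10 degree bins
(`angular_rate_profile()`), both relative to gravity (up-slope is +y;
pointing down-slope is 180 degrees) and relative to the nearest bee's body
axis, with the approach bearing as the alternative covariate. Circular
uniformity of spike mass over angle is tested with a Rayleigh test whose
observations are weighted by per-frame spike counts;
\(\bar R = |\sum w e^{i\theta}|/\sum w\), \(Z = (\sum w)\bar R^2\),
\(p = e^{-Z}[1+(2Z-Z^2)/(4\sum w)]\). Treating each spike as an independent
angle observation is accurate when bins rarely hold more than one spike
(the regime of these recordings); with strongly multi-spike bins the test
becomes anticonservative, which the binned-rate weighting variant avoids.

## The statistics

The rank-sum test (`rank_sum_test()`) uses midranks, a tie-corrected
normal approximation with continuity correction, and the exact Mann-Whitney
null distribution for n_x + n_y <= 20 without ties; two-sided p-values
double the smaller tail. Exactness is verified against brute-force
enumeration of all rank assignments up to n_x + n_y = 10, and the normal
branch tracks the exact tail within 0.01 at 10 + 10. Both the rank-sum and
Rayleigh tests hold a 5% type-I level within [0.04, 0.06] in
2000-replicate null simulations.

## The synthetic colony

The generator (`simulate_colony()`) is the package's test bed. Its
defaults mirror the recording setup — 55 cm x 55 cm arena, 17 degree tilt,
10 frames/s — and the rest is a deliberately simple generative model:

* **Locomotion** is a per-bee stop/go Markov chain (per-frame transition
  probabilities 0.05, i.e., 2 s mean bouts), log-normal walking speed
  (mean 2 cm/s, about one body length per second), and wrapped-normal
  heading persistence (20 degrees/frame). Arena walls reflect the walk.
  The body axis equals the realized direction of motion; stationary bees
  keep their last heading.
* **Home ranges.** The focal bee and the other bees walk in disjoint
  ranges separated by more than the alone radius plus the largest scripted
  excursion. Every sub-1 cm encounter is therefore *scripted*, and the
  ground truth for contacts and alone windows is complete — the price is
  that spontaneous unscripted contacts, which real colonies have, are not
  modeled. (A per-frame repulsion scheme was tried and rejected: projecting
  intruders off a moving exclusion disk distorts companion speed
  distributions, which must stay exchangeable with the focal bee's for the
  walking-speed control comparison.)
* **Scripted approaches** are placed as a Poisson stream per type with a
  12 s minimum separation. In a passive episode the partner closes from
  16 cm to 0.8 cm (crossing 1 cm exactly at the sync frame) while the focal
  bee stays still; in an active episode the focal bee starts walking toward
  the partner 0.5 s before the contact moment and continues past it. The
  partner's transit in and out of the encounter is interpolated in polar
  coordinates around the focal bee, so its distance never dips below the
  alone radius off-script.
* **Ground truth without circularity.** Walking-onset truth is derived
  from the *latent* locomotion program (the chain states plus script
  overrides), alone-window truth from the generator's own scripted
  distances; the detectors see only the realized tracks. Both sides apply
  the same run-length rules, which is exactly the property under test: on
  noise-free planted fixtures, detector precision and recall are 1.0.
* **Firing rate.** \(\lambda(t) = [\beta_0 + \beta_d e^{-d(t)/d_0} +
  \alpha\,g(t)]\,m(t)\), clipped at zero, with baseline 5 Hz (within the
  0.6–23 Hz span such units cover), d the nearest-bee distance with a 3 cm
  kernel scale, and g a raised-cosine bump of width 1 s whose *peak* sits
  `lead_s` before each planted active contact — "a phasic increase X s
  before contact" means the peak, not the onset, so peak-latency recovery
  targets `lead_s` itself. m(t) is a per-window, per-0.5 s-segment
  log-normal multiplier with state-dependent log-sd (meanlog 0, so the
  multiplier is median-preserving and larger sigma strictly increases
  within-window rate dispersion); a constant per-window multiplier would
  change only the window's mean, which the variance parameter is designed
  to ignore. Spikes are drawn by thinning a homogeneous Poisson stream at
  max lambda; for constant rate the inter-spike intervals pass a KS test
  against the exponential law.

## Numerical conventions and degenerate inputs

Half-open bins with left-edge timestamps and 0-based frames throughout; a
spike exactly on an edge belongs to the right-hand bin. Coordinates are
emitted and serialized at micrometer precision, so fixtures round-trip
bit-exactly and re-runs are byte-identical under a fixed seed. Nearest-bee
ties break by lexicographic bee id; bees missing from a frame are skipped
by the nearest-bee search (real tracker output is gappy; the rule set is
silent on dropouts, so this is this package's documented choice). Distances
are centroid-to-centroid — worth remembering when interpreting the 1 cm
contact radius, which is commensurate with body size. Degenerate inputs
fail loudly and specifically: unsorted spike files are an error rather than
silently reordered, empty samples and all-zero Rayleigh weights are
errors, all-equal rank-sum samples return p = 1, recordings with no
contacts mark the contact-dependent analyses "not applicable" instead of
failing the pipeline.

## What the recovery suite shows (sizes used)

The packaged checks run, per study condition: detector fidelity on a 600 s
colony with 3 companions; latency recovery with leads of 0.5/1.0/1.2/2.0 s
from >= 60 active contacts in 45 min of recording (alpha = 15 Hz over a
5 Hz baseline), recovered within one bin of the truth; variance-effect
detection with sigma(active) = 1 versus sigma(random) = 0 at 50 windows per
state over 100 seeded runs, and family-wise error control over 500
equal-sigma runs; the distance effect with beta_d = 12 Hz on 10^4 frames
plus a 200-run null; and flatness of control perievent histograms from 100
random windows of a homogeneous 10 Hz recording within the
\(4/\sqrt{n\bar\nu}\) sampling band. These sizes were chosen a priori by
design-stage power analysis (see the multiplier discussion above) and then
frozen.

Passing them shows the chain recovers *planted* effects of realistic size
under this generator's assumptions. It does not certify behavior on real
tracker output — occlusions, identity swaps, unscripted contact geometry
and non-Poisson spiking are all outside the generative model — and the
place-preference question is deliberately left at a plotting utility
(`plot_trajectory_rate()`), as no quantitative place statistic is defined
here.
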