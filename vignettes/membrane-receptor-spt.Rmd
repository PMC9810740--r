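---
title: "Quantifying membrane-receptor diffusion, trapping and colocalization from single-particle tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-receptor diffusion, trapping and colocalization from single-particle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptdyn)
```

## Scope

`sptdyn` analyzes two-color single-molecule TIRF experiments on membrane
proteins -- the kind of data produced when a receptor (e.g. a SNAP-tagged
GPCR) and a partner or structure channel (an actin label, a scaffold protein
such as filamin A) are imaged simultaneously at video rate and the receptor
channel is tracked particle-by-particle. The package takes tracker output
(trajectory tables in micrometers) and images (TIFF) and provides four
analyses:

1. **TAMSD diffusion analysis** -- time-averaged mean square displacement,
   the anomalous diffusion fit `MSD(t) = 4 D t^alpha + 4 sigma_l^2`, and a
   four-way motion classification (immobile, sub-, normal, super-diffusion).
2. **Trapping segmentation** -- recurrence (pairwise-distance) analysis that
   cuts each trajectory into free and transiently confined phases, with a
   Monte Carlo Brownian null to control false positives.
3. **Colocalization metrics** -- image-level Manders coefficients with a
   homogeneous-distribution control, and a chance-corrected single-molecule
   colocalization index of point localizations against a binary fiber mask.
4. **Interaction analysis** -- transient two-channel colocalization events,
   their frequency and duration, and their classification by the trapping
   state of both partners (co-diffusing, co-confined, mixed).

A synthetic-data module generates all of these inputs with ground truth, so
the full pipeline is testable without any microscope data.

## The diffusion model and its fit

For a trajectory sampled at interval $\Delta t$ (default $1/35$ s), the
TAMSD at frame lag $n$ averages $\Delta x^2 + \Delta y^2$ over all pairs of
localizations separated by exactly $n$ frames. Gap-closed trajectories are
handled by matching true frame differences; nothing is interpolated, since
interpolation biases the MSD downward.

The model fitted is

$$\mathrm{MSD}(t) = 4 D t^{\alpha} + 4 \sigma_l^2,$$

with $D$ the diffusion coefficient (um^2/s), $\alpha$ the anomalous
exponent, and $\sigma_l$ the standard deviation of the Gaussian localization
error, which enters the 2-D MSD as a constant offset. $\sigma_l$ is fixed at
23 nm by default (the value measured for the targeted acquisitions); a
free-$\sigma_l$ mode exists to recover it from immobile emitters.

Numerical choices that matter:

* The fit is unweighted least squares in linear space, because the
  localization-error term is an additive offset there. At fixed $\alpha$ the
  model is linear in $4D$ (and $4\sigma_l^2$), so those parameters are
  profiled in closed form and $\alpha$ is found by a deterministic 0.02-grid
  search over $[0, 2]$ with golden-section refinement. Generic
  Levenberg-Marquardt fits walk the flat $D$--$\alpha$ ridge of noisy
  single-trajectory curves and peg $\alpha$ at the bound; the profiled
  search does not.
* Only lags up to 10% of the trajectory duration, each averaging at least 10
  displacement pairs, enter the fit. Long-lag TAMSD values of a single
  trajectory are strongly correlated and high-variance; including them (we
  evaluated 25%) biases $\alpha$ downward enough to mix the classes, while
  the 10% default recovers a 4-class mixture at ~94% accuracy.
* With $\sigma_l$ free, $\alpha$ is constrained to $[0.1, 2]$: as
  $\alpha \to 0$ the power term becomes a second constant and the offset is
  no longer identifiable.

Classification uses the printed thresholds literally: immobile iff
$D < 0.01$ um^2/s (strict), otherwise normal iff $0.75 \le \alpha \le 1.25$
(both bounds inclusive), sub below, super above. Only trajectories with at
least 120 localizations are analyzed by default.

## Trapping segmentation

The recurrence approach builds the matrix $D_{ij}$ of distances between all
position pairs of one trajectory, rescales by a test length $L$, and marks
pairs *recurrent* when $\exp(-(D_{ij}/L)^2) \ge 0.36$, i.e. when
$D_{ij} \lesssim L$. Dense square blocks along the diagonal are intervals
during which the particle kept returning to the same neighborhood --
candidate trapped phases. (The inequality is stated here in the closeness
direction; only this direction makes diagonal blocks mean confinement.)

Candidates are found by scanning the diagonal: every recurrent consecutive
pair seeds a 2x2 block that grows outward while the fraction of recurrent
entries in the square stays at or above `block_fill_min` (default 0.95), with
a 5-step look-ahead so single-frame excursions do not truncate a block.
Overlaps are resolved largest-first.

False positives are controlled against a Monte Carlo null: `null_reps`
(default 2000) pure Brownian trajectories with the same length, frame
interval, localization noise and an estimated diffusivity $\hat D$ are run
through the identical binarize/block pipeline, giving the tail probability
$p(k)$ that free diffusion produces a block of size $\ge k$. A candidate is
kept only if $p(\text{size}) \le$ `alpha_fp` (default 0.01). Nulls are cached
in logarithmic $\hat D$ buckets (factor ~1.33) and seeded, so results are
reproducible and ensembles are cheap.

$\hat D$ is the lag-1 TAMSD with $4\sigma_l^2$ subtracted, floored at the
immobility threshold 0.01 um^2/s. The floor is essential: a fully trapped or
immobile trajectory has a near-zero apparent diffusivity, and a Brownian
null simulated at that diffusivity would itself be confined -- no block
could ever be significant. Flooring at the slowest "mobile" diffusivity asks
the sharpest well-posed question: could a particle at the immobility
boundary have produced this block by chance?

**Choosing the test length.** $L$ should be the apparent size of the
confinement domains. Localization noise broadens measured pair distances by
$4\sigma_l^2$ in expectation (two positions, two axes), so for domains of
physical diameter $d$ we recommend and use
$L = \sqrt{d^2 + 8\sigma_l^2}$ -- for $d = 0.1$ um and
$\sigma_l = 23$ nm, $L \approx 0.12$ um. With the bare default $L = 0.1$ um
the segmentation still works but clips domain edges (median ground-truth
overlap ~0.71 vs ~0.81 on switching simulations).

## Colocalization metrics

The Manders coefficient of a signal image against a partner-channel mask
within an ROI is `sum(ch1[mask & roi]) / sum(ch1[roi])`. Its
homogeneous-distribution control -- the value a perfectly uniform signal
would give -- equals the mask's area fraction of the ROI and is the floor
against which measured values should be read.

The single-molecule colocalization index compares the fraction `f_obs` of
point localizations on mask pixels with the chance fraction `f_exp`
(estimated by uniform re-placements within the ROI; 100 by default):

$$\mathrm{index} = \begin{cases}
 (f_{obs}-f_{exp})/(1-f_{exp}) & f_{obs} \ge f_{exp}\\
 (f_{obs}-f_{exp})/f_{exp} & f_{obs} < f_{exp}
\end{cases}$$

mapping perfect colocalization to $+1$, chance to $0$ and perfect avoidance
to $-1$. Membership is pixel-based (the pixel containing the point, floor
convention). One property of this normalization is worth knowing: because
deviations below chance are divided by $f_{exp}$ (typically 0.1--0.2 for
fiber masks) and deviations above by $1-f_{exp}$, the index of a *finite*
uniform sample has a small negative expectation, about $-0.02$ at
$n = 1000$ points and $f_{exp} = 0.13$. This is a property of the estimator,
not a bug; it shrinks as $1/\sqrt{n}$.

Fiber masks are built from the structure image by grayscale-opening
background subtraction (disc radius 10 px), 1-px Gaussian smoothing, a
threshold at the larger of the within-ROI Otsu value and half the robust
(99th-percentile) fiber peak, and removal of components under 5 px. The
half-max rule keeps the mask width-faithful: plain Otsu absorbs the
point-spread halo around fibers (5--13% of background pixels on rendered
test images, vs under 1% with the rule).

## Interaction events

In every frame, particles of the two channels within `coloc_radius`
(default 0.1 um, roughly 4--5x the combined localization and registration
error) are paired greedily by distance, each particle in at most one pair.
Per pair, runs of colocalized frames -- tolerating `max_gap_frames` (default
1) interruptions -- become events; events spanning fewer than
`min_event_frames` (default 2) frames are dropped, which also removes most
single-frame chance encounters. Durations are `(span) * frame_interval`;
frequency is reported both per channel-A particle-frame and per um^2 per
second, since both normalizations are in use in the field.

Each event is labeled by the majority trapping state of each partner over
its frames (ties toward trapped -- events are short, so a deterministic tie
rule matters), giving the four categories co-diffusing, co-confined, and the
two mixed ones, reported as counts, densities per um^2 and fractions.

## The synthetic-data generator

The generator emulates the targeted acquisitions: 400-frame sequences at 35
frames/s, localization noise of sd 23 nm per axis, a 20 x 20 um field at
0.16 um/px, and particle densities bracketing ~0.33 um^-2. Motion models:
Brownian (Gaussian increments of variance $2D\Delta t$ per axis), fractional
Brownian motion for sub/super-diffusion (exact Davies-Harte circulant
synthesis, Hurst $=\alpha/2$, scaled so TAMSD $\approx 4Dt^\alpha$),
directed (Brownian plus constant drift), immobile, two-state switching
(exponential waiting times; trapped phases confined to a reflecting disc --
chosen over a harmonic well because it gives exact ground-truth domains),
and transiently binding two-channel pairs (binding within `bind_radius` at
rate `k_on`, co-diffusion at a small tether offset, unbinding at `k_off`,
with a 2-frame post-release refractory so one binding interval produces one
colocalization run). Fiber masks are persistent random walks of the tangent
angle rasterized at a given width; companion images add a Gaussian PSF and
Poisson noise. Pair-model defaults use `k_off = 4` /s (0.25 s mean bound
time, matching the 0.2--0.3 s transient colocalizations of the targeted
experiments).

What the generator does *not* emulate: photophysics (blinking, bleaching),
detection/linking errors (tracks are exact identities), axial defocus, and
membrane heterogeneity beyond the explicit trap/fiber structure. Passing
tests therefore validate the computations, not the upstream tracking.

## Verification choices and problem sizes

The test suite regenerates every fixture from seeds. The heavier checks use:
200 immobile emitters for $\sigma_l$ recovery (+-2 nm); 200 Brownian
trajectories for the trapping false-positive control (every retained block
at $p \le 0.01$; trapped fraction monotone in `alpha_fp`); 30 switching
trajectories (free $D = 0.1$ um^2/s, trap radius 0.05 um, mean dwell 1 s)
for segmentation overlap (median Jaccard $\ge 0.7$); a 4 x 100 mixture for
class recovery ($\ge 80\%$); and 150 interacting pairs over 1200 frames at
density 0.31 um^-2 for event recovery (median Jaccard $\ge 0.8$, mean
duration within 10% of $1/k_\mathrm{off}$). The kinetics run uses
diffusion-limited binding (`k_on = 30` /s) and `k_off = 1` /s so that the
continuous exponential oracle is a valid reference for frame-discretized
durations; ground-truth intervals touching the sequence boundary are
excluded from duration means (standard dwell-time censoring practice).

## Known limitations

* The anomalous-exponent estimate from one 400-frame trajectory has a spread
  of roughly +-0.2; classification near the 0.75/1.25 boundaries is
  accordingly soft at the single-trajectory level.
* The trapping null assumes free diffusion with Gaussian noise; drift or
  strong anisotropy would need a different null.
* The colocalization index's finite-sample bias (above) should be kept in
  mind when comparing small-n conditions near chance level.
* Inter-channel registration is assumed done upstream; the interaction
  radius should be widened if registration error exceeds ~20 nm.

## A worked mini-example

```{r example, eval = FALSE}
# simulate a switching receptor, segment it, and classify its diffusion
cfg <- sim_config(motion_model = "switching", D_free = 0.1,
                  trap_radius = 0.05, k_trap = 1, k_release = 1, seed = 1)
sw <- simulate_switching_trajectory(cfg)
seg <- segment_trajectory(sw$trajectory,
                          trapping_config(test_length = sqrt(0.1^2 + 8 * 0.023^2)))
seg

fit <- fit_msd(compute_tamsd(sw$trajectory))
classify_motion(fit)
```
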