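---
title: "Models and methods behind lipomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lipomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipomech)
```

`lipomech` links the fatty-acyl composition of membrane phospholipids to the
mechanical resilience of muscle cells. This vignette documents the models
each module implements, the tunable parameters with their defaults and
units, how the synthetic-data layer is calibrated, and the numerical and
design choices a maintainer should know about. It states no empirical result
beyond what the package's tests and acceptance script themselves compute.

## 1. Lipidomics profiling

A PC species `PC x:y` denotes a diacyl phosphatidylcholine with `x` total
acyl-chain carbons and `y` total C=C double bonds across both chains. Its
elemental composition is C(x+8) H(2x+16−2y) N O8 P, so the monoisotopic
mass is an exact elemental sum; each double bond removes one H2
(2.0156500638 Da) and each added carbon pair adds C2H4 (28.0313001 Da).
Peak annotation assigns each peak to the candidate whose adduct m/z
([M+H]+ = M + 1.007276 Da in positive mode; [M−H]− symmetric) is nearest in
ppm within a tolerance (default 5 ppm, typical for a high-resolution ToF).
Ties in ppm leave the peak unassigned with a warning, a deliberately
conservative rule since the reference workflow's tie behavior is unknown.
Two documented simplifications:

* **Isotopologue overlap is ignored.** The M+2 isotopologue of a `y+1`
  species falls 2 × 1.00336 Da above its monoisotopic peak, close to
  (but ~9 mDa away from) the M peak of the `y` species; at 5 ppm this does
  not cross-assign, but intensity bleed into an unresolved peak is not
  corrected.
* **Only PC masses are computed.** PE/PS/PI tables are accepted
  pre-annotated; the quantitative conclusions the package supports rest on
  PC.

Relative abundance is intensity divided by the summed intensity *within the
same lipid class*, times 100 — radar-style per-class distributions — and
tables are validated to sum to 100 ± 1e-6 per class. The double-bond (DB)
index bins those percentages by `y` ∈ {0}, {1}, {2}, {>2}; the DHA/AA ratio
is Σ%(PC 36:6, 38:6, 40:6) / Σ%(PC 36:4, 38:4, 40:4), reported as 0 with no
DHA species and as `Inf` (with a warning) when the AA denominator is empty.
The cross-sample PCA is mean-centered and unscaled — the four DB columns
share units (percent), so scaling would only inflate low-variance bins —
and component signs follow a deterministic convention (largest-magnitude
loading positive). Identical rows produce a warning and `NA` explained
variances rather than an error.

## 2. VLD trace analysis

Traces are per-ROI mean fluorescence sampled every 5 s (300 frames by
default) with the osmotic-shock onset marked; at least three pre-shock
samples are required. The baseline F0 is the pre-shock mean and the working
signal is the relative fluorescence (F − F0)/F0. (An F/F0 mode exists
because "relative intensity" is used both ways in the literature; the
difference form is the default, and the breakage threshold of 10 refers to
it.)

Kinetics extraction on one normalized trace:

* **Onset `t0`** — first post-shock time where the Savitzky–Golay-smoothed
  trace exceeds `baseline_noise_k` (default 3) times the pre-shock sd for
  `run_length` (default 3) consecutive samples. The experimental definition
  of "time to fluorescence appearance" was manual; this is a standard
  noise-gated threshold.
* **`Vmax` and `tVmax`** — maximum (and argmax time) of the smoothed first
  derivative over the *rising phase*, from `t0` to the first attainment of
  95% of the plateau. Restricting the search window matters: on ensembles
  of noisy logistic traces at the package's default noise (sd 0.05 relative
  units), searching the entire post-`t0` trace lets plateau-region noise
  maxima inflate `Vmax` by ~+0.002 s⁻¹ and drag `tVmax` ~+12 s late, while
  the restricted search is unbiased within two SEM.
* **Smoothing window** — Savitzky–Golay, order 2, default **7 samples**
  (35 s). Window 5 leaves too much derivative noise (the `Vmax` bias
  above); window 9+ oversmooths steep traces (>5% underestimate of the
  analytic inflection slope). Window 7 keeps the noiseless-logistic
  recovery within 5% of A·k/4 while removing the ensemble bias; both facts
  are asserted in the test suite.
* **Plateau** — mean of the final 10% of samples (nonparametric default),
  with an optional logistic-fit asymptote mode.

Breakage is called on the 543-nm channel when the relative intensity
reaches the threshold (default 10); the crossing time is interpolated
linearly between samples. The call is monotone in the threshold by
construction. Per-cell VLD counts are binned into {0, 1–5, 6–10, >10}.

Surface metrics treat an adhered myoblast as a hemisphere, so percent
changes of the cross-section area equal percent changes of the hemisphere
surface. The initial surface is the pre-shock mean area; the maximum of a
lightly smoothed post-shock series (moving mean over 5 samples — single
noisy frames should not set the maximum) gives the percent increase and its
time. The percent is scale-free by construction.

Spot detection operates on the final frame of a 515-nm stack (0.13 µm/px
default): outside-mask pixels are first filled with the in-mask median so
the cell boundary produces no band-pass edge, then a difference-of-Gaussians
(σ = d_min/4 px and d_max/2 px for expected spot diameters 1–3 µm) is
thresholded at median + 6 lower-tail-MAD-equivalents (the lower tail is
used because spots only push the distribution upward), local maxima are
kept with a minimum separation of one expected diameter, and each candidate
must stay elevated over the trailing 3 frames. All parameters are exposed;
detection is deterministic given them.

## 3. MD membrane post-processing

Extension levels scale both in-plane box lengths by (1 + e/100), the area
by its square; the default ladder is 0–25% in 5% steps, matching the range
over which a bilayer patch survives before persistent rupture and covering
the measured cellular surface expansion. The acyl-chain tilt angle is the
angle between the chain's first-to-last bead vector and the +z membrane
normal: 0° is perpendicular to the membrane plane (upper leaflet), 90°
in-plane, 180° perpendicular in the lower leaflet. Distributions are
reported as per-bin probability mass (default bin width 2.5°, summing
to 1) over all selected chains × frames, unfolded to [0°, 180°] by default
so a leaflet-symmetric membrane shows its two symmetric lobes; a fold
option maps α → min(α, 180° − α). The joint angle × distance histogram
shares its binning with the 1D distributions, so its marginals match them
exactly. Chains are assumed imaged together (no periodic-boundary
unwrapping); a chain vector longer than half the box triggers a warning.
Distances are in nm throughout — reported sub-nanometre "Å" chain-extension
figures in the source literature are physically implausible for a six-bead
chain and are read as nm here.

Surface tension uses the Kirkwood–Irving diagonal-pressure form, per frame:
γ = (Lz/2) · (Pzz − (Pxx+Pyy)/2), i.e. 0.05 · Lz[nm] · ΔP[bar] in mN/m.
The factor 1/2 attributes the tension to each of the bilayer's two
interfaces and is echoed in the output metadata, since conventions differ.
A stretched membrane (normal pressure exceeding lateral) yields γ > 0. The
reported value is the time average over the (concatenated) series; the
error is a block-averaged standard error with 5 blocks by default — the
pressure components of a few-thousand-lipid patch fluctuate by hundreds of
bar, so single-frame values are meaningless and correlated-sample naive
errors would be optimistic. Results are reported in mN/m with a
configurable unit label (nN/m labels appear in the literature for the same
numbers).

## 4. The synthetic-data layer

Every generator is a pure function of (parameters, seed): the same seed
gives bit-identical output, and ground truth accompanies every dataset so
each estimator can be validated by parameter recovery.

**Species tables** draw from fixed per-preset weight profiles
(muscle/heart: PC 38:6–40:6 dominated; brain: PC 34:1; lung: PC 32:0;
pancreas/liver: DB = 2 with an AA component; untreated myoblasts: DB = 1/2
with ~2% polyunsaturated; AA- and DHA-supplemented myoblasts gain
PC 36:4/38:4 and PC 38:6 respectively) with multiplicative lognormal jitter
(default sd 0.1) and per-class renormalization.

**Cell cohorts.** Four experimental conditions are packaged (NT untreated,
its VLD-forming and cracked sub-populations, AA- and DHA-supplemented),
each with the published mean ± SEM at its published n. Where only mean and
SEM are printed, the generator SD is SEM × √n. Positive quantities are
drawn lognormal with matched mean and SD, which preserves both moments
exactly while staying positive even when SEM × √n is large relative to the
mean.

Per-cell VLD counts follow a zero-inflated negative binomial. Its three
free parameters (structural zero fraction π, conditional mean μ,
dispersion) are solved once per condition — against closed-form NB
probabilities, frozen in the package, and re-verified by a test — for the
three published constraints: the overall mean, the overall SD (SEM × √n),
and one distribution feature (34% of untreated cells form no VLD; 48% of
AA cells form 1–5; half of DHA cells form more than 10). The implied
unprinted quantities (e.g. ~21% total zero-count AA cells, ~14% for DHA)
follow from those constraints rather than from any direct observation.

Each VLD's 515-nm trace is a logistic A/(1 + exp(−k(t − tm))) plus Gaussian
noise (default sd 0.05 relative units — ROI-mean confocal traces are
considerably cleaner than single pixels), with tm the drawn `tVmax`, A the
drawn plateau (mean 2.0 ± 0.5, chosen so VLD traces sit well below the
breakage threshold, as observed for VLD-forming cells), and k = 4·Vmax/A so
the drawn `Vmax` is the true inflection slope. Onset `t0` is emergent (via
the detector), not drawn: calibrating a drawn `t0` against the detector
would only be possible by simulation and no printed `t0` value constrains
it. Broken cells' 543-nm traces step to the breakage threshold at the drawn
breakage time and relax exponentially (τ = 20 s) to a final fill level
(mean 15), making the interpolated crossing essentially unbiased. Area
series rise from the resting area as a Gaussian bump in time peaking at
the drawn `t_surface_max` with the drawn percent increase (width
0.4 · t_surface_max), plus 0.5% area noise; the locally symmetric peak
keeps the smoothed-argmax estimator unbiased.

Unprinted condition parameters are package choices: surface increases for
DHA (17%) and NT-VLD (17.5%) sit inside the published 12.6–19.5% bracket
with a realistic 5-point SD (the SEM × √n rule applies to the printed AA
and NT-cracked values); `t_surface_max` for AA (180 s) and NT-cracked
(240 s) follow the published event ordering (DHA fastest, untreated
slowest); breakage probabilities (NT 0.25, AA 0.10, DHA 0.05, NT-cracked 1,
NT-VLD 0) reflect the qualitative protection ranking; NT breakage times
center on 400 s, after the supplemented conditions' formation onsets.
The default imaging geometry is 300 frames at 5 s and 0.13 µm/px with the
shock at 60 s (12 baseline frames).

**Trajectories** place two mirrored leaflets and sample each chain's
first-to-last vector from an imposed angle law (delta, uniform, normal, or
a custom function; the lower leaflet is mirrored through the membrane
plane) and an imposed distance law (including a two-mode mixture for
compact-vs-expanded chain conformations); intermediate beads sit on the
chain line. **Pressure series** choose the mean anisotropy so the expected
per-interface tension equals the target and add independent Gaussian
fluctuations (default sd 100 bar) to each diagonal component.

What a green recovery test establishes — and what it does not: the
generators emulate the published condition-level statistics and qualitative
trace shapes, not microscope optics, spatial correlations within cells,
parameter covariances (all per-cell draws are independent), or real MD
dynamics. Passing recovery therefore validates the estimation chain against
the stated statistical world, and nothing more.

## 5. Numerical choices and degenerate inputs

* Savitzky–Golay edges are `NA` (no extrapolated samples enter any
  argmax); traces shorter than the window error out.
* A flat or never-above-threshold trace returns `event_detected = FALSE`
  with `NA` kinetics rather than fabricated values.
* A constant area series reports 0% increase and flags itself degenerate.
* Annotation ties at < 1e-6 ppm are treated as exact ties (no real
  instrument distinguishes them) and left unassigned.
* PCA on identical rows warns and returns `NA` variances; a zero AA
  denominator yields `Inf` with a warning, zero DHA yields 0.
* All derived child seeds stay below 2³¹ − 1; generators save and restore
  the caller's RNG state.

## 6. Known limitations

* Isotopologue intensity bleed is uncorrected (see Section 1); MS/MS-level
  structural assignment is out of scope.
* The hemisphere assumption makes surface metrics insensitive to cell
  shapes that flatten rather than expand isotropically.
* Spot detection assumes approximately circular, non-merging VLDs; heavily
  overlapping dilations would be undercounted.
* The trajectory generator imposes chain geometry directly; it is an
  oracle for the post-processing code, not a physical membrane model, and
  published per-bin probabilities from full-scale coarse-grained runs are
  not reproduction targets.
* Statistical hypothesis testing across conditions (ANOVA-style) is
  deliberately not included; the summaries expose mean, SEM and n.
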