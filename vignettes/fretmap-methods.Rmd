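---
title: "Methods: acceptor-photobleaching FRET analysis and coat mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acceptor-photobleaching FRET analysis and coat mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretmap)
```

# What this package computes

`fretmap` implements a complete analysis chain for mapping the architecture
of a multiprotein assembly — the clathrin-mediated endocytic coat of budding
yeast is the motivating system — from three kinds of wide-field fluorescence
measurements:

1. **Acceptor-photobleaching FRET.** A donor fluorophore (GFP-class) on one
   protein terminus is quenched by energy transfer to an acceptor
   (mCherry-class) on a second terminus whenever the two sit within ~10 nm.
   Destroying the acceptor with an intense laser pulse de-quenches the
   donor; the fractional rise in donor fluorescence measures the transfer
   efficiency.
2. **Stage-resolved per-patch FRET.** Individual endocytic patches are
   classified by the presence of a third-channel marker (Abp1, which
   arrives with actin-driven membrane invagination), and per-patch
   efficiencies are compared between stages.
3. **FRAP.** A single patch is bleached and the fluorescence recovery is
   followed to estimate the mobile fraction and exchange time of the tagged
   protein at the endocytic site.

Classified pairwise proximities are then assembled into a terminus-level
proximity graph, decomposed into proximity networks, and embedded on the
axis perpendicular to the plasma membrane under anchor and molecular-ruler
constraints.

Because real image data are not required anywhere, the package ships a
synthetic two-channel microscopy simulator with exact ground truth; every
estimator is validated against it.

# The forward model and its noise

A simulated cell (`cell_scene()`) is an ellipse of uniform cytoplasmic
intensity on a dark background, carrying 5–15 diffraction-limited membrane
patches rendered as pixel-integrated 2-D Gaussians (sigma 1.1 px ≈ 250 nm
FWHM at the 178 nm pixel size of the motivating instrument; the physical
patches of 50–80 nm are unresolved, so a PSF-sized spot is the correct
rendering). Acquisition (`acquisition_config()`) follows the
acceptor-photobleaching protocol: two acceptor and three to five donor
frames, a 3–5 s bleach pulse, then the same counts again.

The donor signal of patches and cytoplasm is scaled by `1 - E` before the
bleach and `1 - E(1 - beta)` after it, where `E` is the ground-truth
transfer efficiency and `beta` the bleached acceptor fraction; every donor
acquisition additionally costs a factor `1 - delta` (structural
photobleaching). The acceptor is scaled by `1 - beta` after the pulse.
Ground truth uses the de-quenching convention `E = 1 - D_pre/D_post` at
complete bleach.

Camera noise is a scaled-Poisson approximation of an EM register: pixel
values are drawn as `g * Poisson(mean/g)` with `g` the squared excess-noise
factor (default `sqrt(2)`, the asymptotic EMCCD value), plus Gaussian read
noise, so the per-pixel variance is `F^2 * mean + sigma_read^2`. A full
gain-register cascade is deliberately not modelled; at the simulated photon
counts the Gaussian excess-noise approximation is indistinguishable.

**Default photon budget.** The source instrument's photon budgets are not
published. Defaults (patch amplitude 4000 expected photons/frame, cytoplasm
300/px, background 20/px, read noise 10, 8 patches/cell) were chosen once so
that the per-cell efficiency SD is ~0.7–1.0 percentage points, which makes
95 % CI half-widths of ~0.3–0.6 points at 10–40 cells — the magnitude of the
published per-pair intervals. The default bleach completeness is
`beta_bleach = 1`: the saturating multi-second pulse justifies it, and the
quantification (like the original workflow) applies no partial-bleach
correction, so incomplete bleach is a QC condition (`beta_hat < 0.5` flags a
cell), not a calibration.

# Quantification

Quantification (`quantify_apb()`) mirrors the manual workflow it
replaces: subtract the general background (median of an extracellular
region, or a constant), average the frames of each phase, estimate the
per-cell intensity threshold as the mean cytoplasmic donor level of the
averaged pre-bleach image, then over ROI pixels above the threshold in
**both** averaged images compute the per-pixel de-quenching and average it.
Two conventions are reported side by side:

* `increase_over_pre`: `e = 100 (post - pre)/pre` — the percentage increase
  in donor fluorescence, the published definition;
* `dequench_over_post`: `e = 100 (post - pre)/post` — the classical
  transfer efficiency, the quantity the cited ImageJ plugin computes.

On noise-free data they are algebraically linked by
`e_pre = e_post / (1 - e_post/100)`; at 10 % efficiency they differ by about
10 % relative, and it is not resolvable from the published text which one
the printed values used. All tables carry both. Whether the threshold was
applied to the pre-bleach image only or to both is equally unstated; both
images is the default (matching the plugin), pre-only is a switch
(`threshold_on = "pre"`).

Donor-only cells measured with identical settings give slightly negative
apparent FRET (structural photobleaching lowers the post-bleach donor);
their batch mean is subtracted from every measurement
(`apply_donor_only_correction()`), matched by acquisition batch. This
correction also cancels the small shared biases of the estimator itself
(threshold selection on noisy skirts, ratio nonlinearity), which is why
simulated recovery is accurate to < 0.3 percentage points across
efficiencies of 0–15 %.

Two caveats the simulations make explicit:

* Selecting pixels by a threshold applied to noisy images biases the ratio
  estimator; with patch ROIs (small ovals or a polygon over the patches)
  the effect is at the 0.1-point level and is removed by the donor-only
  correction, but quantifying a whole cell against a cytoplasm-level
  threshold lets noise-selected cytoplasm pixels dominate and is not a
  supported design.
* Background subtraction clips at zero by default, which biases
  near-zero extracellular residuals upward; this is irrelevant inside the
  cell but `clip = FALSE` is available for diagnostics.

# Screen statistics

Per-pair aggregation uses the published rules exactly: the mean efficiency
over 10–40 cells with a Student-t 95 % CI (the paper states only "95 %
confidence intervals"; t-based is the declared choice, a bootstrap is
available), and the positivity rule — a pair is FRET-positive iff its mean
and both CI bounds are positive. No multiple-testing correction is applied,
matching the per-pair rule (a Benjamini–Hochberg helper exists in the usual
`stats::p.adjust` if wanted; it is off by default by design). Group
comparisons use two-tailed Welch tests. Box-plot summaries pin the quartile
convention (linear interpolation, `stats::quantile` type 7), whiskers at the
most extreme points within 1.5 IQR, and median notches of
`1.58 IQR / sqrt(n)` — the conventional formula; the source figure legend
gives none.

Under the simulator's default conditions the rule's operating
characteristics are: false-positive rate ≈ 2.5 % for null pairs at
n = 20 cells (the one-sided tail of the CI bound), and essentially complete
detection of 2 % efficiency pairs — consistent with a screen that reported
positives down to 1 %.

# Stage-resolved analysis

Patches are detected by Laplacian-of-Gaussian filtering at the PSF scale
with greedy minimum-separation selection and sub-pixel centroid refinement.
Step edges (the cell outline) also excite the LoG; candidates whose
smoothed-image Hessian has `trace^2/det > 5` are rejected — isotropic spots
score 4, edges much higher. Marker presence uses a k-sigma rule: a patch is
marker-positive when its mean marker intensity exceeds the cytoplasmic
level by 3 SDs of the cytoplasmic distribution (the original assignment was
visual; this is our formalisation, and the threshold is a parameter).
Per-patch efficiencies use 2 px oval ROIs (≈ 360 nm, covering the
PSF-blurred spot; ROI size is not stated in the source) and require at
least 3 supra-threshold pixels.

One property worth stating: a per-patch efficiency measured through a
PSF-sized ROI is diluted by the cytoplasmic pedestal under the patch, so
group **differences** are attenuated relative to the per-patch ground
truth. The two-group comparison is still correctly calibrated (uniform
p-values when the groups share one efficiency) and easily powered at the
published design size (~70 patches per group), which is what the design
validates.

# FRAP

Traces are extracted as background-subtracted means of a spot ROI and an
unbleached in-cell reference, double-normalised
(`(spot/ref) / mean_pre(spot/ref)`) so the pre-bleach level is exactly 1
and acquisition photobleaching cancels. The reference is replaced by its
fitted geometric decay (log-linear in time) before division: per-frame
bleaching is multiplicative, so this is the correct model, and it keeps the
reference region's shot noise out of every time point. The recovery model
is the minimal single exponential
`F(t) = F0 + M (1 - F0)(1 - exp(-(t - t0)/tau))` with `M` in `[0, 1.2]`;
the prior work this protocol descends from does not print its normalisation
or model, so these are declared package choices, and the reported `tau` is
an effective exchange time (no diffusion-vs-binding decomposition).

Fitting is profiled least squares: for fixed `tau` the model is linear in
`(F0, B)`, so an 80-point log grid of `tau` is scanned and solved exactly,
then polished by bounded Levenberg–Marquardt. The profile makes flat traces
(immobile pools) well-behaved — descent-only fitting stalls there because
`tau` is unidentifiable — and `tau` is capped at five times the observed
span, beyond which the exponential is indistinguishable from a line and
`(M, tau)` drift along a ridge. The bleach frame is taken from phase tags
when present, else auto-detected as the largest fractional single-frame
drop.

The FRAP simulator design uses a bright spot (60 000 expected photons/frame
against a 100/px cytoplasm, 0.5 s frames for 60 s): endocytic-patch FRAP
sums dozens of fluorophores, and at this budget the fitted `tau` has a
~5 % CV, which matches recovery curves smooth enough to publish with
n = 9–17 cells. With that design the full simulate–extract–normalise–fit
round trip recovers `M` and `tau` within 10 % in ≥ 90 % of replicates over
`M ∈ {0.3, 0.7, 1} × tau ∈ {2, 5, 15}` s, and pins `M ≤ 0.05` for immobile
pools.

# Proximity mapping

The classified screen becomes an undirected graph on protein termini with
an edge per FRET-positive pair. Connected components of ≥ 3 termini are
proximity networks; 2-node components are isolated pairs. Terminus
orientation relative to a reference uses the Welch test on per-cell values
(`p < 0.05` to call the higher-FRET terminus closer, otherwise
"unresolved"; means-only comparisons are flagged low-confidence).

The axial (membrane-normal) embedding minimises, by deterministic
multi-start L-BFGS-B under a fixed seed (the random starts are preceded by
one informed start that trilaterates each node from the two anchors along
graph geodesics with edge length `d_max - weight` — 1-D embeddings fold
easily from random initialisations, and this start is near the unfolded
configuration whenever FRET magnitude decreases with distance):

* for each positive edge, `max(0, |xi - xj| - d_max)^2` with
  `d_max = 10 nm` (the physical FRET radius);
* for each tested-but-negative pair, a **soft, low-weight** repulsion
  `0.1 * max(0, d_max + 2 - |xi - xj|)^2` — absence of FRET is weak
  evidence, since fluorophore orientation and stoichiometry also suppress
  transfer;
* quadratic hinge penalties for interval anchors, molecular-ruler bounds
  (`apply_ruler_evidence()`: a full-length terminus negative to a marker
  whose shortened construct is positive must lie > d_max from it, the
  shortened one within), and ordered marker pairs (the clathrin heavy
  chain's C-terminus membrane-proximal to the light chain's, separation
  constrained to a configurable 5–15 nm — the source gives the ordering,
  not a distance);
* a tiny magnitude-weighted attraction (`1e-3 * weight * (d/d_max)^2`) so
  that FRET magnitude breaks ties among otherwise equivalent zero-penalty
  placements. Efficiencies are never converted to distances through a
  Förster-law calibration — orientation factors and copy numbers are
  unknown, and the underlying reasoning is ordinal, not metric.

Hard anchors (the two experimentally placed Sla2 termini at 1.5 and 33 nm)
fix coordinates exactly; nodes unreachable from any anchor are reported
unplaced rather than positioned arbitrarily. Layer labels come from
configurable nm intervals (membrane-binding, adaptor, lattice,
actin-regulatory). Lateral (membrane-parallel) structure is explicitly not
modelled; the screen does not constrain it.

On planted 1-D geometries (random positions, edges wherever the distance is
below `d_max`, magnitudes decreasing with distance) the optimizer recovers
the true ordering with mean Kendall tau ≥ 0.9 on 12-node instances and
matches exhaustive 1-nm grid search on 5-node instances.

# The curated published records

The complete per-pair screen table is distributed as the study's
supplementary dataset and is not redistributed here. The package instead
ships a **curated reconstruction** (`published_screen()`,
`inst/extdata/endocytic_screen_curated.csv`) assembled from the printed
records: every pair whose mean and CI appear in the text or tables carries
those numbers; pairs only stated to be FRET-positive are encoded with
`value_printed = FALSE`. The `group` column mirrors the published map
grouping. Two curation decisions are worth flagging: the published text
lists both End3 termini among both networks because the printed
cross-proximities bridge them, so the literal positive-edge graph is one
component — the two-network decomposition holds for the within-network edge
sets, with End3-N assigned to the first network and End3-C to the second,
exactly as the published orientation argument places them; and only one of
the three isolated pairs is named explicitly, so the other two are encoded
from the stated actin-regulator proximities (their identity does not affect
any computed quantity, only the count).

# Problem sizes and numerical choices

Validation simulations use 40–48 px scenes with 6–10 patches, 200 cells per
efficiency condition for estimator recovery, 400 replicates of 20-cell
pairs for classification calibration, 60 replicates of 14-cell fields
(~70 patches/group) for stage-sorting power, and 100 replicates per
`(M, tau)` grid point for FRAP — sizes at which every Monte-Carlo tolerance
in the test suite has comfortable binomial margin. Degenerate inputs are
rejected loudly (zero-area ROIs, empty phases, non-positive reference
traces, infeasible hard anchors must be points), ties in patch selection
are broken by response strength, and all simulator randomness flows from a
single integer seed per experiment, making every stack bit-reproducible.

# Known limitations

* The simulator has no 3-D optics, no membrane-invagination geometry, no
  spectral bleed-through or direct acceptor excitation (acceptor
  photobleaching needs none of those corrections), and uniform in-cell
  background — real cells have vacuoles and nuclei that the cytoplasm ROI
  must avoid by hand.
* Passing recovery tests on synthetic data shows the estimators are
  faithful to the declared forward model, not that the model captures every
  property of real acquisitions (e.g. focus drift, fixation artefacts,
  camera nonlinearity).
* Per-patch efficiencies are pedestal-diluted (above), so stage-resolved
  magnitudes are comparative, not absolute.
* The axial map treats every positive edge identically; bystander crowding
  and direct proximity cannot be distinguished, and FRET magnitudes serve
  only as tie-breakers.
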