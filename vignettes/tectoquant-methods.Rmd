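---
title: "Quantifying tectal neuron structure and function: methods and design notes"
author: "tectoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tectal neuron structure and function: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tectoquant)
```

tectoquant packages, as tested and reusable code, the quantification
pipelines commonly assembled ad hoc for studies of dendritic refinement in
the *Xenopus* optic tectum: static arbor morphometry, short-interval
time-lapse dynamics of terminal dendritic processes, two-channel synaptic
puncta counting, and calcium-imaging retinotopic mapping with a
receptive-field sharpness statistic. Every pipeline can be exercised on
synthetic data with known ground truth, so its correctness is testable
without access to microscope data. This vignette explains the models and
conventions behind each pipeline, the parameters that matter, and the design
choices that were genuinely open.

## Arbor morphometry

A neuron is a rooted tree of 3-D nodes in micrometres (`neuron_arbor`), read
and written as 7-column SWC. Total dendritic length is the sum of Euclidean
segment lengths, soma-to-child segments included; branch tips are childless
non-soma nodes.

The **Sholl profile** counts crossings of concentric spheres centred on the
soma. Along a straight segment the squared distance to the soma is a
quadratic in the path parameter, so crossings of a sphere of radius $r$ are
the simple roots of that quadratic inside the segment — computed exactly,
not by sampling. Three conventions are fixed deliberately:

* a segment that dips inside a shell and exits again counts **twice**
  (crossing semantics, not segment-intersects-shell semantics);
* a tangent touch (double root) counts zero — a measure-zero case that needs
  a deterministic rule;
* each root is attributed to the half-open interval $(0, 1]$ of its segment
  so a crossing exactly at a shared node is counted once.

The test suite checks these exact counts against an independent oracle that
densely samples every segment at 0.01 µm steps and counts sign changes, on
100 randomly generated arbors, and checks invariance of all morphometric
outputs under rigid motion. Default shell radii are 10, 20, …, 200 µm,
spanning typical tectal arbor extents; distances are 3-D by default with a
`projected` option because published Sholl analyses do not always state
which was used.

**Maturity** splits arbors at 500 µm total length, the conventional boundary
between immature and mature tectal cells; the boundary itself belongs to the
mature class (`>= 500` µm).

## Terminal-process dynamics

The unit of time-lapse analysis is the **terminal process**: the path from a
leaf back to the nearest branch point (or the soma). Processes shorter than
10 µm are filopodia; 10 µm and above are branches — the boundary belongs to
branches. Correspondence across timepoints comes from persistent identities
attached by the reconstruction (or the generator); no image-based tracking
is implemented.

For a series of timepoints 10 min apart, `summarize_dynamics()` reports per
class: additions, losses, total elongation (sum of positive length changes),
total retraction (sum of absolute negative changes), motility per interval
(sum of absolute changes), and mean density (processes per µm of arbor,
averaged over timepoints). Attribution when a process crosses the 10 µm
boundary is deterministic: a length change belongs to the class the process
had at the *earlier* timepoint; an added process is classified by its first
observed length, a lost one by its last. Because of this attribution rule,
reversing a series swaps additions with losses and elongation with
retraction exactly in the class-combined totals, while per-class totals may
differ when processes cross the boundary mid-series; the suite tests the
combined symmetry. Elongation totals sum per-interval positive changes; an
end-minus-start variant can be assembled from `diff_arbors()` on the first
and last timepoints if needed.

## Synaptic puncta

Two pipelines mirror the two common experimental designs.

**Anatomical synapses** (immunostained sections): each channel is
background-subtracted with a 10 px rolling ball, median filtered with a 2 px
disk, and binarised with the moment-preserving threshold; the pixelwise AND
of the two masks marks pre/post colocalisation; 8-connected components with
area in the closed interval 0.1–5.0 µm² are counted. Both a per-µm² density
and a per-20×20 µm-field count are reported, since either denominator is in
use.

**Dendritic puncta** (live two-channel z-stacks): the cytosolic cell-fill
channel is thresholded with the maximum-entropy criterion and the punctum
channel with the moment-preserving criterion; a supplied exclusion mask
(somata, axons) is removed from the dendritic mask; puncta are detected per
slice inside the dendritic mask and detections whose pixel footprints
overlap between adjacent slices are merged and counted once; density is the
merged count divided by the dendritic mask volume. Two conventions are worth
noting: thresholds are computed from the whole-stack histogram (one per
channel) rather than per slice, because slices without labelled structure
are near-constant and have no defined threshold; and 3-D handling by
per-slice detection plus overlap merging was chosen over projection because
projection conflates puncta at different depths (pure per-slice counting is
available via `merge_slices = FALSE`).

### Auto-thresholding

Both criteria are implemented from first principles on histograms and are
the package's own code, since they are the load-bearing step of the puncta
pipelines.

* **Moment-preserving (Tsai).** Every candidate threshold splits the
  histogram into two classes with fractions $q_0, q_1$. The two class levels
  that preserve the first two gray-level moments exactly are
  $\mu \mp \sqrt{v\,q_{1}/q_{0}}$ and $\mu + \sqrt{v\,q_{0}/q_{1}}$ (with
  $\mu$ the mean and $v$ the variance); the selected threshold minimises the
  resulting third-moment error. This is the direct form of the
  moment-preservation criterion and is checked, candidate by candidate,
  against an exhaustive scalar-loop oracle.
* **Maximum-entropy (Kapur).** The threshold maximises the sum of Shannon
  entropies of the normalised foreground and background histograms.

Ties in either objective are broken at the *median* tied candidate, so a
perfectly bimodal histogram thresholds strictly between its modes rather
than at the lower mode. Foreground is strictly above the threshold.
Integer-valued images are binned at unit width, which makes the threshold
shift by exactly $c$ when $c$ is added to every pixel (tested); other images
use 256 equal bins over their range.

### Rolling ball and median filter

The rolling-ball background is the grayscale opening by a *non-flat
spherical* structuring element (heights $\sqrt{r^2 - d^2}$); the paraboloid
dialect used by some tools is available via `shape`. The spherical element
was chosen because its semantics are exact and oracle-checkable
(erode-then-dilate with the explicit ball). One consequence worth knowing:
an isolated 1 px impulse is preserved only up to the spherical-cap sag
$r - \sqrt{r^2 - 1}$ (≈ 0.05 intensity units at $r = 10$), whereas a flat
disk would preserve it exactly; the tests assert the analytic bound. The
median filter uses a true disk neighbourhood (13 pixels at radius 2) with
mirrored edges and is checked against a per-pixel sort oracle.

## Retinotopic mapping

$\Delta F/F_0$ is computed per pixel with $F_0$ the mean over designated
pre-stimulus baseline frames (the convention differs across labs; the
protocol object makes the choice explicit). Responses are averaged per ROI
over each presentation's response window — stimulus onset to offset plus a
1 s decay allowance for the slow indicator — and then across presentations
of the same bar position.

The **optimal stimulus position** is the response-weighted mean of the
position indices after rectifying negative responses to zero (weighting is
undefined for negative weights; rectification is the conservative choice,
and a cell with no positive response has no estimate). **Receptive-field
sharpness** is the mean response at the two positions closest to the optimal
position divided by the mean response at the remaining positions, with
distance ties broken toward the lower index — another measure-zero case
fixed deterministically. Sharpness is undefined (and the cell excluded with
a logged reason) when the peripheral mean is not positive, rather than
clipped. Both statistics are invariant to positive scaling of the
responses, which the tests verify.

Cells are evaluated only if the maximal response exceeds 2 $\Delta F/F_0$
units, the optimal position falls within the three central bar positions
(read as the closed interval $[2, 4]$ of 5), and the ROI is at least 30
pixels; animals with fewer than 30 surviving cells are dropped entirely.
Each exclusion carries a machine-readable reason. Cohorts are compared by
the two-sample Kolmogorov–Smirnov statistic on pooled sharpness values
(`ks_two_sample()`, a thin wrapper over `stats::ks.test` with the asymptotic
p-value; its $D$ statistic is verified against a pooled-ECDF oracle).

## The synthetic-data generators

The generators define the conditions under which the pipelines are tested;
they are first-class, tested code, not fixtures.

* **Arbors** grow a stem plus random branch events with gamma segment
  lengths (defaults: 10 branch events, 15 µm mean segment), yielding
  immature-range arbors of a few hundred µm. Ground truth (total length,
  tip count) is exact by construction.
* **Dynamics series** evolve the terminal processes of a base arbor over
  six 10-min intervals: per-interval loss probability 0.05 per process, one
  candidate addition per interval with probability 0.4, Gaussian length
  steps of SD 1.5 µm, new processes 1–5 µm long (filopodia by the 10 µm
  rule). The addition and loss rates are balanced so process density stays
  roughly stationary over the hour, as in short-interval imaging of tectal
  arbors; unbalanced rates (including certain loss) remain available and
  tested. Timepoints are laid out as a soma-centred star — one straight
  edge per process — because under random loss on an arbitrary tree,
  removing a leaf chain can merge a sibling's process with upstream
  segments, silently changing its length with no logged event; the star
  keeps leaf-to-branch-point extraction exact for any surviving process
  count, and the dynamics metrics depend only on identities and lengths.
  Every event is logged, and `summarize_dynamics()` must reproduce the log
  exactly over 50 seeded series.
* **Puncta fields** place Gaussian spots (SD 0.5 µm, roughly the confocal
  scale of synaptic puncta) at 0.496 µm/px over a constant background, with
  a controllable colocalised fraction and additive Gaussian noise. Spot
  centres are kept at least 3.5 µm apart so each spot is individually
  resolvable by the particle counter (closer pairs fuse into one
  above-threshold component and can exceed the 5 µm² criterion). Noiseless
  fields must be recovered exactly; noisy fields are only required to
  rank-order the generated colocalised counts.
* **Dendrite stacks** render a tube-shaped dendrite (radius 1 µm) plus a
  bright soma sphere in one channel and inside/outside puncta in the other,
  with the soma region returned as the exclusion mask. An axial punctum SD
  larger than the lateral one emulates the microscope's axial elongation
  and exercises the cross-slice merge rule.
* **Calcium movies** give each cell a square ROI and a Gaussian receptive
  field over the bar-position axis (positions 22° apart, matching five bars
  across ~110° of azimuth). Each presentation evokes a transient with
  instantaneous rise and single-exponential decay (τ = 1.5 s, a GCaMP6s-like
  stand-in), truncated at the next presentation's onset so that responses
  remain exactly proportional to the programmed amplitudes — this is what
  makes the noiseless on-grid recovery test exact rather than approximate.
  Amplitudes are log-normal around 6 peak ΔF/F₀ so that window-averaged
  responses clear the >2 inclusion threshold for most, but not all, cells.

What the generators deliberately do **not** emulate: photon-counting noise,
bleaching, motion artefacts, optical point-spread blur in x/y, overlapping
ROIs, or carry-over between stimulus presentations. Passing tests therefore
demonstrate correctness of the *quantification* under known conditions, not
robustness to every imaging pathology; the preprocessing steps address
smooth background and impulse noise only. The Gaussian-over-position
receptive-field model is an assumption of the generator, not a claim about
tectal biology; the spatial receptive-field shape of tectal cells is not
modelled.

## Problem sizes and determinism

All generators are deterministic in their integer seed. The shipped test
suite exercises: 100 random histograms per thresholding criterion against
exhaustive oracles; 100 random arbors against the dense Sholl oracle; 50
dynamics series against their event logs; ~70 synthetic puncta fields
(6 noiseless + 60 noisy + stacks); and, for the receptive-field module,
exact on-grid recovery, sharpness monotonicity over widths {5°, 15°, 40°}
across 10 seeds, and ten replicate pairs of 60-cell cohorts (widths 10°
vs 30°) compared by KS — sizes chosen to give the properties real coverage
while keeping the whole suite comfortably fast on one CPU.

## Known limitations

* Sholl tangency and exact-node crossings rely on deterministic
  conventions; other tools may count such degenerate cases differently.
* The rolling-ball implementation is an exact morphological opening; tools
  that approximate the ball (e.g. with shrunken images at large radii) will
  differ slightly.
* The moments threshold uses the direct enumeration form of the
  moment-preservation criterion; implementations using the closed-form
  percentile lookup can differ by a gray level when the preserved fraction
  falls between attainable cumulative counts.
* Per-animal inclusion interacts strongly with cohort size: a single weak
  cell in a 30-cell animal removes the whole animal, so realistic use needs
  animals comfortably above the 30-cell minimum.
* The dynamics module analyses terminal processes only; internal shaft
  elongation and branch-order statistics are out of scope, as are group
  statistics beyond the KS comparison (repeated-measures models belong in a
  general statistics package).
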