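---
title: "Methods: detection, identity tracking and activity extraction of head-ganglion neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, identity tracking and activity extraction of head-ganglion neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, every tunable that matters, the numerical
choices behind the code, and what the synthetic experiments do and do not
demonstrate.

## The problem

Whole-brain imaging of a freely behaving *C. elegans* yields a 4D recording:
at each time point a Z-stack (nominally 1024 × 1024 × 18 voxels; our
synthetic default 256 × 256 × 12) of two fluorescence channels, a red
activity-independent nuclear reference and a green calcium-dependent signal.
The head ganglion contains on the order of 100–160 labelled nuclei that
translate, rotate and bend with the animal, and that look nearly identical
to one another. The pipeline must (1) find every 2D neuronal cross-section
per frame, (2) assemble cross-sections into 3D neurons, (3) give each neuron
a *digital ID* that is stable across the whole recording of one animal, and
(4) read out the activity ratio per neuron per volume. A digital ID is an
arbitrary integer kept consistent within one animal; it carries no
anatomical meaning, and assigning biological cell-type identities is
explicitly out of scope.

Two structural assumptions run through everything. The *exclusion principle*
— a neuron appears at most once per frame — and the *continuum principle* —
a neuron occupies one frame or a set of consecutive frames. Both follow
from imaging geometry (nuclei are compact and the Z-step is finer than a
nucleus) and reduce 3D assembly from general graph matching to a chain of
bipartite problems. A third assumption, specific to recognition, is that a
neuron's *position relative to its neighbours*, expressed in a
body-intrinsic coordinate system, is far more stable across volumes than
its appearance; this is what makes few-shot identity learning possible, and
it is also the assumption that breaks during extreme head deformation.

## Stage 1: head segmentation and the worm coordinate system

The maximum intensity projection of the red stack is median-blurred
(5 × 5), thresholded (Otsu by default; a fixed threshold can be supplied),
and the binary foreground is closed with a dilation disc of radius 5
followed by an erosion disc of radius 4, then hole-filled. Closing after
thresholding — rather than grayscale closing before it — is what actually
fuses separated nuclei into one component at realistic contrast: the
intensity in the gaps between nuclei is statistically indistinguishable
from background, so no global threshold can keep grayscale-closed bridges
alive. The deliberately asymmetric disc pair (dilation > erosion) leaves a
small safety margin around the head. The largest connected component is the
head; all others are body regions, available for inspection and rejected
from further processing.

The coordinate system follows the intensity-moment construction: points of
interest (POI) are head pixels at least one standard deviation above the
head mean (the threshold is capped at the in-mask maximum so a uniform head
still yields POIs); the origin `O` is their intensity-weighted centroid;
the anterior–posterior (A–P) axis is the longest chord through `O`, found
by scanning directions at 1° resolution (ties broken toward the smaller
angle index); the ventral–dorsal (V–D) axis is the perpendicular chord. The
chord search marches along the ray through the binary mask in 0.5 px steps
rather than intersecting the traced contour polygon: contour chains from
connected-component tracing contain spurs and double-back segments that
make exact segment-intersection counting unreliable, while mask marching is
robust and equally deterministic. Orientation is decided by POI counts: the
side of the V–D axis with more POIs is anterior, the side of the A–P axis
with more POIs is ventral. An exact tie is broken toward the side
containing the contour point farthest from `O`, with a warning. Degenerate
inputs (constant image, empty mask, centre of mass outside the mask, failed
chord search) raise errors rather than guessing. Heads that touch the body
or twist onto themselves merge into one component and are not recovered;
the construction simply fails or degrades there, which matches the known
hard cases of this approach.

Worm coordinates of a point are `x_ap` (anterior positive), `y_vd` (ventral
positive) and `z` (frames × `z_scale`; the physical Z-step is 1.5 µm per
frame in the nominal setup, `z_scale = 1` keeps frame units). The azimuth
is measured from the ventral axis, `phi = atan2(x_ap, y_vd)` remapped to
`[-π/2, 3π/2)`, so the ventral half is exactly `phi ∈ [−π/2, π/2]` — the
convention the density territories below are written in.

## Stage 2: anchor-box detection

Local maxima of each frame inside the head mask (5 × 5 neighbourhood,
intensity floor = in-mask mean + 2 sd) seed anchor boxes of 9 × 9 px, the
empirical nucleus scale; sizes {7, 11} are available as a configuration.
For each anchor, five concentric fields are cropped: the anchor itself and
15², 31², 41², 81² contexts. The canonical network input pads fields
smaller than 41² with zeros and bilinearly resizes the 81² field down to
41², with pixel values scaled to [0, 1] by the frame maximum.

The regression targets and their inverse are the standard box
parameterisation

```
Δx = (x_G − x_A)/w_A   Δy = (y_G − y_A)/h_A   ω = w_G/w_A   η = h_G/h_A
x  = Δx̂·w_A + x_A      y  = Δŷ·h_A + y_A      w = ω̂·w_A    h = η̂·h_A
```

which are exact inverses of each other; the test suite holds this to 1e−9
over a thousand random pairs. Box convention throughout the package:
0-based pixel coordinates, (x, y) = (column, row), half-open
`[x, x+w) × [y, y+h)`; widths and heights are rounded to integers ≥ 1 only
at final output.

The scoring/correction network is a fully connected residual network: each
field is bilinearly pooled to 13 × 13 (845 inputs), standardised, passed
through a width-256 trunk with two residual blocks, and read by two heads —
a sigmoid region score and a linear 4-vector whose two scale components go
through `exp()` so predicted ratios are always positive. A convolutional
trunk would be conventional here; a pooled fully connected one reaches the
same operating point on nucleus-scale blobs at a small fraction of the
training cost in a pure-R implementation, and the pooled resolution
(≈ 3 px/cell on the widest field, ≈ 1 px/cell on the 15² field) is finer
than the ~2 px corrections being regressed.

Training anchors are labelled by their best ground-truth IoU: positive at
≥ 0.3 (matching the evaluation criterion), negative below 0.1, ignored in
between. The loss is binary cross-entropy on the score over all anchors
plus an L2 penalty on (Δx̂, Δŷ, ω̂, η̂) over positives (weight `lambda = 1`).
Optimisation is momentum SGD (0.9) with cosine-annealed warm restarts
(maximum rate 0.01, floor 1e−4, first cycle 10 epochs, cycle doubling),
batch 256, 20 epochs, gradients clipped to global norm 5; negatives are
subsampled to at most twice the positives and the training set capped at
9000 patches, both with the training seed. All of these are arguments with
the stated defaults. Two runs with the same seed are bit-identical;
inference is deterministic.

At inference, scored and corrected anchors pass per-frame non-maximum
suppression: drop scores < 0.4, then greedily keep the best-scoring region
and suppress anything overlapping a kept region with IoU > 0.20, ties
broken by (score desc, x, y). Detection quality is measured by greedy
one-to-one matching at IoU > 0.3: precision = TP/predictions,
recall = TP/ground truth, F1 their harmonic mean.

## Stage 3: merging regions into neurons

The total-weight objective over a volume decomposes into independent
adjacent-frame problems, because edges only connect consecutive frames and
may not share vertices. Each pair is solved as a linear sum assignment on
the IoU matrix with weights below τ = 0.05 zeroed (the solver is
`clue::solve_LSAP`; the tests verify it against exhaustive permutation
enumeration on every instance size up to 5 × 5, and chain linking against
the exhaustive chain optimum on 3-frame instances). Zero-weight assignments
are discarded; selected edges are chased into chains; every unmatched
region becomes a single-frame object. Output objects are renumbered by
(z_start, cx, cy) for determinism.

Neighbouring neurons stacked along Z can fuse into one chain. The split
rule uses the member regions' mean pixel intensity profile I(z): every
*strict* interior local minimum is a cut, and the region at the minimum
joins the later (higher-z) part — a convention that keeps both parts
non-empty even when the minimum sits at the second frame. Plateaus are not
minima. A 3-point moving-average smoothing of the profile is available but
off by default: the split signature of two fused somata at this Z-sampling
is a single sharp dip, which smoothing can erase. Optional bounds on object
length re-split over-long objects at their weakest internal IoU link
(off by default). Splitting never merges, and the outputs always partition
the input region multiset.

Because no published criterion defines a 3D true positive for merging, the
package's merging evaluation is its own (documented, configurable) choice:
a predicted object matches a ground-truth object if their shared frames
overlap at mean IoU ≥ 0.3 and the spans agree on at least half their
union, with greedy one-to-one matching by descending mean IoU.

## Stage 4: features and identity recognition

For neuron *i*, all context positions are translated so *i*'s centroid is
the origin and expressed in worm cylindrical coordinates. The density
feature counts context points between nested cylinders: cylinder *t*
(t = 1..q) has radius `t·Δl` and half-height `t·Δz/2`, and bin *t* counts
points inside cylinder *t* but not cylinder *t−1* — a set difference, so an
L-shaped shell — split into 4 territories: ventral (`phi ∈ [−π/2, π/2]`)
vs dorsal, crossed with `z ≥ 0` vs `z < 0`. The nested-difference form is
what makes the conservation law hold exactly (the bins sum to the count of
points inside the outermost cylinder), and the tests check every bin
against a direct membership oracle. Context is the 2D region centres
outside the neuron (`source_mode = "regions"`, the default when region data
exist) or the other objects' centroids (`source_mode = "objects"`, for
centroid-only data). Defaults: q = 8 shells, Δl = head semi-major
length / q (so the outermost shell reaches the head boundary), Δz = volume
depth / q (the outermost band covers the full depth). The KNN feature is
the cylindrical triple (ρ, phi, z) of the K = 25 nearest context objects by
3D Euclidean distance, ascending, ties broken by context index; a deficit
is padded with (0, 0, 0) and the pad count recorded, so trained models stay
portable across volumes with different neuron counts. The concatenated
feature has length q·4 + 3K (107 at defaults). Features depend only on
relative positions in the worm frame and are therefore invariant to rigid
motion of the volume; the tests verify this directly.

The recognition model standardises features (stored mean/sd — a fixed
input normalisation in place of batch normalisation, which adds running
state without benefit at these data sizes), embeds them with a
256–128–d fully connected ReLU network (d = 128), and L2-normalises both
the embedding `c` and every column of the class-weight matrix `W`
(one column per digital ID, plus one extra class reserved for neurons
outside the tracked set; the extra class is excluded from matching at
inference). With θ_j the angle between `c` and `w_j`, the training loss
for a neuron with label ξ is the softmax cross-entropy of margin-penalised
logits: the target logit is `s·(cos(m₁·θ_ξ + m₂) − m₃)`, all others
`s·cos θ_j`. Hyperparameters: hypersphere radius s = 30, multiplicative
angular margin m₁ = 1.05, additive angular margin m₂ = 0, additive cosine
margin m₃ = 0.05. With m₁ = 1, m₂ = m₃ = 0 the loss reduces exactly to
normalised, s-scaled softmax cross-entropy (held to 1e−8 in the tests),
and it is monotone in m₂ and m₃ — both properties are tested. Angles come
from `acos` of cosines clipped to [−1+ε, 1−ε]; the gradient uses the
composite form with the sine term floored away from zero, avoiding the
arccos endpoint singularity. Training is full-batch Adam (rate 2e−3,
200 epochs), deterministic per seed.

Inference within an animal embeds one volume's neurons, forms the cosine
distance matrix `D_ij = 1 − cos(c_i, w_j)` against the trained class
columns, and minimises the assignment trace by the Hungarian method;
rectangular problems are padded at cost 2 (the cosine-distance maximum) and
padded assignments are reported unassigned. Across animals, `W` is replaced
by the embeddings of a chosen template volume, so the network only supplies
the representation. Top-1 accuracy is averaged per volume, then over
volumes (the per-volume/global distinction is unspecified in the source
method; per-volume weighting is the package's choice).

## Activity extraction

F_RFP is the mean red intensity over a neuron's member-region pixels;
green pixels are sampled at affine-mapped coordinates (nearest pixel;
identity map by default, least-squares fitting from landmark pairs
provided); R = F_GCaMP/F_RFP. By default each channel's mean is reduced by
the median of a 5-px annulus around the region before the ratio — diffuse
neuropil autofluorescence under the neuron otherwise compresses R toward 1.
Whether to average over the box or a segmented mask inside it is an open
choice; box-mean is implemented. Regions mapping outside the green frame
are flagged, never zeroed.

## The synthetic generator

The generator is the package's study design, not a fixture. One *animal* is
a canonical layout: blob centres placed by dart throwing inside an
ellipsoidal head (default semi-axes 75 × 40 px in a 256 × 256 × 12 volume)
with a minimum in-plane separation (6 px; placement fails loudly if the
requested density is infeasible after bounded retries). The layout mimics
head-ganglion anatomy: ~40 % of nuclei form a bright, dense
anterior-ventral cluster (nerve-ring analogue), ~20 % a dimmer
posterior-ventral band (ventral-cord analogue), the rest diffuse. These
asymmetries are load-bearing: the coordinate-system builder orients its
axes by point-of-interest counts, and a layout with no anterior/ventral
structure has no recoverable orientation. Radii (2–4 px) set both the
lateral Gaussian width (sd = r/2) and the axial span — 1 to 4 consecutive
frames, larger nuclei spanning more — with an axial intensity taper peaked
at the span centre, so a single nucleus never exhibits the interior
intensity minimum that the split rule treats as evidence of fusion.

Per volume, the layout is bent (anterior and posterior halves rotated
relative to each other by up to ±30°, smooth transition over the central
20 % of the head) and rigidly rotated (±20°) and shifted (±12 px). During
the Z-scan the whole layout drifts by a cumulative in-plane random walk of
at most 2 px per frame, emulating motion during acquisition; ground-truth
boxes follow the drift. Rendering adds a head-shaped autofluorescence glow
(peak 45 grey levels; it is what makes the head one connected region at
threshold, as in real tissue), a dim body-shaped smear outside the head (so
segmentation has something to reject), and Gaussian background
(level 10, sd 6). Intensities are clamped and rounded so volumes round-trip
bit-identically through 16-bit TIFF. A green channel multiplies each blob
by a smoothly varying activity factor (log-sinusoid per neuron), recorded
as ground truth. Every stage of randomness derives from the layout seed
plus the volume index, so identical (spec, seed) give bit-identical
datasets. The `"hard"` preset scales to 512 × 512 × 18, 150 neurons,
±45° bends and 4 px drift.

What the generator does *not* emulate: optics (PSF, spectral
bleed-through), occlusion and brightness changes from pose, Z-dependent
aberrations, annotation error, gut autofluorescence, or animals whose heads
touch their bodies. Passing the synthetic study therefore shows the
algorithms are implemented correctly and behave as designed under
deformation, drift and noise — not that the trained models transfer to any
particular microscope's data, which requires annotating volumes from that
system.

## Study sizes and numerical conventions

The end-to-end study used by the tests and by `scripts/acceptance.R` is 40
volumes of one easy-regime animal — 30 for training both models, 10 held
out — plus a 6-volume second animal for across-animal inference; the
recognition learning curve retrains at 5/10/20/30 volumes. These sizes keep
the full study in the minutes range on one CPU while leaving ~600 held-out
regions and ~580 held-out neurons to measure on. Key numeric conventions
collected in one place: exact-inverse tolerance 1e−9; loss-reduction
tolerance 1e−8; IoU thresholds 0.3 (detection TP), 0.20 (NMS), 0.05 (τ,
linking); score floor 0.4; assignment padding cost 2.0; acos clipping
ε = 1e−7; all tie-breaks deterministic (row-major peaks, smaller angle
index, score-then-position in NMS, lower column index in assignment,
context index in KNN).

## Known limitations

* Orientation of the V–D axis rests on a count asymmetry around the
  intensity-weighted centre of mass. Under strong bends a few percent of
  synthetic volumes still flip the ventral label; in those volumes the
  azimuthal features mirror and recognition degrades for that volume —
  the same worst-case behaviour deep head bends cause on real data. The
  per-volume cosine-distance column of the assignment output is the
  practical flag for such volumes.
* Across-animal accuracy on synthetic animals is optimistic relative to
  real recordings: deformation between synthetic volumes leaves worm-frame
  features nearly invariant, so template matching is easier than between
  genuinely different animals. The within- vs across-animal *ordering* is
  the meaningful synthetic observable, not the absolute gap.
* The detector's fully connected trunk is tuned to nucleus-scale blobs;
  images at very different scales need the anchor size and field sizes
  reconfigured, not just retraining.
* Head–body contact and self-twisting heads are detected only as
  segmentation failures (no single dominant component); no recovery is
  attempted.
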