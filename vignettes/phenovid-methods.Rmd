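---
title: "Measuring 3D phenotypes of leafy vegetables from video-derived point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D phenotypes of leafy vegetables from video-derived point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenovid)
```

## The measurement problem

Breeding and crop-management programmes need per-plant structural traits --
plant height, leaf number, leaf length, leaf angle -- for rosette-forming
leafy vegetables such as leaf beet, measured in the field without destroying
the plant. A smartphone video circling a single plant, together with two
reference cubes of known edge length placed beside it, contains everything
needed: sharp frames can be fed to structure-from-motion (SfM) photogrammetry
to reconstruct a dense 3D point cloud, and the cubes anchor the
reconstruction's arbitrary "virtual" unit to millimetres.

`phenovid` implements every stage of that pipeline except the SfM/MVS
reconstruction itself, which remains an external tool behind a one-function
adapter contract (`reconstruction_adapter()`): any program that turns an
ordered key-frame directory into a PLY file can be used. The stages are:

1. **Key-frame selection** (`select_keyframes()`): pick `m` sharp,
   crop-containing frames from the video.
2. **Cloud preprocessing** (`fit_ground_plane()`, `align_to_ground()`,
   `remove_ground()`, `select_plant_component()`, `simplify_cloud()`,
   `radius_outlier_filter()`): turn the raw scene cloud into a clean,
   ground-aligned plant cloud.
3. **Skeletonisation** (`extract_skeleton()`): slice the plant along Z,
   cluster each slice, link clusters across slices into branches, prune
   artefacts, smooth with cubic B-splines, and segment the cloud by
   skeleton seeds.
4. **Trait extraction** (`measure_traits()`): calibrated height, leaf
   count, per-leaf length and angle.
5. **Evaluation** (`rmse()`, `mape()`, `accuracy_from_mape()`,
   `evaluate_traits()`).

A seeded synthetic generator (`make_plant_scene()`, `make_video()`) supplies
ground-truth fixtures for every stage.

## Key-frame selection

A hand-held recording yields hundreds of frames, many motion-blurred.
Frame sharpness is scored by the response of the discrete Laplacian: for
luminance image $f$ with Laplacian response $G(x,y)$,

$$D(f) = \sum_y \sum_x |G(x, y)|.$$

Two score modes exist because two formulations of this metric circulate: the
absolute-sum above (`sum_abs`, the default, divided by the pixel count so
scores are resolution-independent) and the variance of $G$ (`variance`).
Both are exposed; they rank frames almost identically. The Laplacian stencil
is the minimal 4-neighbour `[[0,1,0],[1,-4,1],[0,1,0]]`, with
replicate-padded borders; luminance uses Rec.601 weights. The rejection
threshold is `blur_fraction` (default 0.75) times the mean score of sharp
reference frames -- by default the 10 highest-scoring frames of the video,
standing in for a manually chosen set of visibly sharp images.

Crop saliency uses visible-band vegetation indices computed on chromaticity
$r = R/(R{+}G{+}B)$ etc.: NDI, ExG, ExR, ExGR and VEG are available, with
ExGR $= \mathrm{ExG} - \mathrm{ExR} = 3g - 2.48r - b$ the default since it
separates green crop from brown soil most cleanly. Negative (soil) values
are clipped and the map rescaled to 0--255. Black pixels and
division-by-zero pixels map to 0 rather than NaN.

Selection partitions the video into `m` equal contiguous sets (default
`m = 40`, inside the 30--45-image band that balances reconstruction quality
against computation). The first surviving frame of set 1 seeds the chain;
in each later set the member whose saliency map has the most feature
matches against the previous key frame's map wins (ties: earliest frame).
A set whose frames are all blurred contributes its least-blurred member
with a warning. Matching uses a compact scale/rotation-invariant detector
written for this package: single-octave difference-of-Gaussians extrema
(6 scales, $\sigma = 1.4 \cdot 2^{k/3}$), dominant-orientation assignment
from a 36-bin gradient histogram, classic 4x4x8 gradient descriptors
sampled on a rotated grid, and nearest-neighbour matching under Lowe's
ratio test (0.75) plus a mutual-nearest-neighbour cross-check. Matching
operates on the saliency maps themselves, so soil texture cannot
contribute matches.

## Cloud preprocessing

The ground is found by RANSAC over 3-point samples (default 1000
iterations, seeded; inlier threshold defaults to 0.005 x the bounding-box
diagonal), refined by a least-squares fit to the inliers, and oriented so
the plant side is positive. The scene is rigidly rotated so the ground
normal becomes the +Z axis and the plane sits at z = 0; pairwise distances
are preserved to machine precision. Points with $z \le$ margin (default:
the inlier threshold) are removed.

Two automated steps replace interactive scene cleanup: the margin above,
and `select_plant_component()`, which keeps the largest 26-connected
component of occupied voxels (voxel = 2% of the bounding-box diagonal) --
necessary because the reference cubes also stand above the ground plane and
would otherwise be skeletonised as spurious "leaves". An explicit
exclusion-index list is honoured for anything the heuristics miss.

Dense reconstructions carry hundreds of thousands of points; skeleton
extraction is accurate and cheap at 10,000--30,000, so
`simplify_cloud()` voxel-downsamples (one centroid per occupied voxel) with
the voxel edge bisected until the output lands in that range. Isolated
reconstruction noise is removed by `radius_outlier_filter()`: a point
survives if it has at least `min_neighbors` (default 5) neighbours within
`radius` (default 4 x the median nearest-neighbour distance). Counting is
exact (grid cell lists for large N, verified against brute force).

`principal_axis_tilt()` gives the angle between the first principal
component of the plant cloud and the ground, for correcting the height of a
leaning plant ($H = |z_{max} - z_{min}| / \sin\theta$). This is meaningful
for elongated, single-stemmed plants; for a spreading rosette the first
principal component follows the leaf spread, not the growth axis, so tilt
correction is **off** by default (`tilt = "off"`, $\theta = 90^\circ$) and
must be enabled deliberately.

## Skeleton by slice clustering

The plant cloud is cut into horizontal slices of height `dh` (half-open
intervals $[j\,dh, (j{+}1)\,dh)$). Default `dh` is 1/50 of the plant height,
clamped so a slice averages at least 20 points, and padded by a relative
1e-9 so the topmost point falls strictly inside the last slice instead of
exactly on its boundary (where floating-point rounding is unstable and
broke exact scale invariance). Each slice is clustered by single-linkage
Euclidean connected components at distance `eps`; each cluster's centroid
becomes a skeleton node that remembers its member points.

Two defaults here deviate from the obvious first choices, for reasons found
empirically on ground-truth scenes:

* `eps = max(3 x median NN distance, 1.5 dh)`. The nearest-neighbour term
  alone under-connects: a slice through a wide blade is a long thin strip
  of points, and with sparse or noise-free sampling, random gaps wider than
  a few NN spacings split the strip, spawning parallel artefact chains.
  The `dh` floor ties connectivity to the slicing resolution.
* `link_dist = 3 dh` (nearest-centroid linking between adjacent layers). A
  chain climbing at elevation $e$ advances $dh/\tan e$ horizontally per
  layer; at drooping blade tips ($e \approx 35^\circ$) this is $1.4\,dh$
  and centroid jitter pushed genuine leaves past a $2\,dh$ limit, cutting
  one leaf into two branches.

A cluster that receives two or more children is a junction: the child most
collinear with the incoming direction continues the branch, the others
start new branches there. Branches with fewer than `min_nodes` nodes are
pruned and their points unassigned; the pipeline default adapts to the
resolution, `max(3, 0.12 x layer count)` (about 6 at the default 50
slices), because artefact chains persist for a handful of layers while true
leaves span tens. `prune_branches()` itself always takes an explicit
threshold.

Surviving branches are smoothed by least-squares cubic B-splines
(chord-length parameterised, `df = max(4, min(n-1, n/3 + 2))`, so roughly
one basis function per three nodes: enough flexibility for a drooping
midrib, enough stiffness to average centroid jitter). Collinear nodes
reproduce their line exactly. For segmentation the splines are resampled at
`dh/2` and every cloud point takes the branch label of its nearest
resampled skeleton point; labels therefore partition the cloud.

## Traits and calibration

The scale factor is $k = L_{real} / L_{virtual}$ in mm per virtual unit
(reference cubes are 56 mm; with two cubes the two factors are averaged).
`cube_edge_from_cloud()` implements the operator-free alternative:
sequential RANSAC planes on the cube cloud, a tightening refit so strips of
perpendicular faces cannot tilt each plane, then the distance between the
two largest near-parallel faces as the difference of median point
projections along the mean normal. At reconstruction noise of ~0.4% of the
cube edge this recovers the edge to ~0.1%; at 5% noise its error (~3%)
dominates the trait budgets, so scenes that noisy should be calibrated from
an operator measurement of the cube instead (`cube_l_virtual`).

* **Height**: $H = k\,|z_{max} - z_{min}| / \sin\theta$, reported in cm.
* **Leaf number**: the branch count -- rosette leaf beets have no clear
  stem/leaf boundary, so one pruned skeleton branch is one leaf.
* **Leaf length**: $L_b = \sum_i |v_i v_{i+1}|$ along the branch, by
  default on the densely resampled spline (raw nodes via
  `use_spline = FALSE`).
* **Leaf angle**: $\theta = \arccos\big(\frac{\alpha\cdot\gamma}
  {|\alpha||\gamma|}\big)$ with $\alpha$ the ground normal ($(0,0,1)$ after
  alignment) and $\gamma$ the tip-ward basal tangent of the branch. Three
  non-identical conventions for "leaf angle" circulate (from the ground
  normal, from the ground plane, from the stem); the report stores the
  normal-referenced angle as primary and $90^\circ - \theta$ (angle with
  the ground) alongside, and merges none of them silently. $\gamma$ is
  evaluated as the chord over the basal 15% of the spline: node-to-node
  differences carry +-6 degrees of centroid jitter, while the chord
  averages it out at a curvature bias of about 1 degree.

Evaluation uses $\mathrm{RMSE} = \sqrt{\tfrac1n\sum (x_{s i}-x_{m i})^2}$,
$\mathrm{MAPE} = \tfrac{100}{n}\sum |x_{s i}-x_{m i}|/x_{m i}$, and
accuracy $= 100 - \mathrm{MAPE}$ rounded to one decimal.

## What the synthetic scenes emulate -- and what they do not

`make_plant_scene()` builds a leaf-beet-like rosette with exact truth:
a 28 cm plant with 6 leaves radiating at equal azimuths from a basal crown
of radius 2.5 cm (leaves attach around a short stem, not at a point --
a degenerate shared base fuses the basal centimetres of every leaf into one
cluster), basal elevations 50--75 degrees paired with midrib arc lengths
0.70--0.95 x height, each midrib a quadratic Bezier drooping 15 degrees
from base to tip, carrying a uniform point tube (radius 2 mm) and a blade
patch (half-width 0.08 x leaf length over the outer 40% of the midrib).
Around it: a rough brown ground disc, one or two 56 mm cube surfaces, and
isotropic Gaussian coordinate noise, default 0.28 cm = 1% of plant size.
The noise-free plant is rescaled once so the canopy top sits exactly at the
requested height; all per-leaf truth rescales with it. Everything is
deterministic per seed. `make_video()` renders a textured green rosette
polygon rotating over brown textured ground, with chromaticity (not just
intensity) structure so vegetation-index saliency has features to match,
and Gaussian-blurs a designated subset of frames.

These fixtures establish that the algorithms recover known geometry through
the full pipeline (at the study sizes below: leaf count exact, height MAPE
< 3%, leaf-length MAPE < 6%, basal-angle MAE < 3 degrees). They do **not**
contain SfM reconstruction artefacts (holes, ghost surfaces, non-uniform
density), wind deformation between frames, occlusion by neighbouring
plants, or heavily overlapping leaves. Overlap is the known failure mode of
slice clustering -- merged slices lose skeleton nodes and undercount leaves
-- and the generator exposes `overlap = TRUE` to reproduce it rather than a
remedy for it. Passing tests on synthetic scenes bound algorithmic error,
not field error.

## Numerical choices and degenerate inputs

* All stochastic steps (RANSAC, simulators) draw from seeded streams; one
  top-level pipeline seed derives per-stage sub-seeds. RNG state of the
  caller is restored.
* Black pixels get zero chromaticity; NDI/VEG division-by-zero pixels are 0.
* Collinear RANSAC samples are discarded and resampled; an all-planar cloud
  fits with every point an inlier and a +Z-ward normal.
* Ties in key-frame match counts resolve to the earliest frame; clustering
  and linking are deterministic, so reruns are byte-identical.
* A branch with fewer than 4 nodes keeps its polyline instead of a spline;
  single-node branches cannot yield a length and raise an error.
* Voxel keys are packed with strides far beyond any realistic grid size;
  simplification returns the input unchanged when it is already below the
  upper target.
* Degenerate traits fail loudly: empty skeletons, zero tangents, theta = 0,
  MAPE with a zero manual value.

## Study sizes

The shipped tests and the acceptance script use desk-scale problem sizes
chosen to exercise every code path at full fidelity: 300-frame videos at
128 x 96 (the selection logic is resolution-independent; scores are
per-pixel), scene clouds of ~23,000 points (6 leaves x 2,500 points plus
ground, cubes), and 10-plant recovery studies. A field reconstruction at
hundreds of thousands of points passes through the same operations after
`simplify_cloud()` brings it into the 10,000--30,000 band.

## Known limitations

* Leaf surface area and volume are out of scope: no validated procedure for
  them is implemented.
* Automatic cube calibration degrades at high noise (see above).
* PCA tilt correction is unreliable for rosettes; it is opt-in.
* Heavily overlapping leaves undercount; the generator can reproduce the
  failure but the method does not fix it.
* Video container decoding is not included: the keyframes stage consumes
  ordered PNG frame directories or in-memory frame lists.
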