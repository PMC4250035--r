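---
title: "Models, methods and design choices in ConnectomeView"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, methods and design choices in ConnectomeView}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConnectomeView)
```

ConnectomeView visualizes and quantifies brain networks that have already
been estimated elsewhere. This vignette explains the data model, the exact
formulas and algorithms behind each statistic, the rendering semantics, the
synthetic data the package tests itself against, and the design decisions
taken where the problem left genuine freedom.

## 1. The data model

A network is an `AdjacencyNetwork`: a square, symmetric, zero-diagonal
weight matrix bound to an `Ordering` — a plain list of ROI names in which
line $k$ labels row and column $k$ of the matrix. Keeping the ordering as a
separate plain-text artifact (rather than an opaque bundled format) means
any tool that can write a matrix can feed the package.

Only undirected, single-edged, static networks are supported. Asymmetric
input is either rejected (reporting the largest $|A - A^\top|$ entry) or,
on request, coerced to $(A + A^\top)/2$ with a warning: averaging preserves
total weight and is deterministic, which matters for reproducible figures.
The diagonal is always zeroed — self-loops have no meaning in any of the
three views. Node indices are 1-based throughout, matching R and the
line-numbering of ordering files.

The spatial side is a `Parcellation`: per node a name, a 3D center in mm
(RAS convention), a hemisphere, an anatomical group, and a group color.
It can be built three ways:

1. **Surface parcels** — a triangulated cortical surface (FreeSurfer binary
   or GIFTI) plus a per-vertex annotation (`.annot` or GIFTI label file).
   A parcel's center is the *arithmetic mean of its member vertices*. The
   mean is not guaranteed to lie on the surface; for deep, curved parcels
   the alternative `nearestVertex = TRUE` snaps the center to the member
   vertex closest to the mean. The mean is the default because it is
   smooth, exactly permutation-stable, and always inside the parcel's
   bounding box.
2. **Segmentation volume** — a labeled 3D volume (NIFTI or MGZ) whose
   integer voxel values follow the FreeSurfer aseg convention. A shipped
   lookup covers thalamus, caudate, putamen, pallidum, hippocampus,
   amygdala, accumbens (left/right) and brainstem; it is a configurable
   table, not a hard-coded limit. Structure centers are affine-transformed
   voxel-index centroids under the **voxel-center convention**: index
   $(i,j,k)$, 0-based, maps through the affine with no half-voxel shift.
   This matches the NIFTI sform; it is stated explicitly because FreeSurfer
   conventions differ and a silent half-voxel disagreement is a classic
   registration bug.
3. **Coordinate table** — name plus three mm coordinates per line (EEG
   electrodes, MNI centroids, ...). Hemisphere is inferred from the name
   when a marker is present.

An optional 4×4 homogeneous `AffineRegistration` (volume space → surface
space) is validated as invertible with bottom row $(0,0,0,1)$.

Ordering names and parcellation names rarely agree byte-for-byte, so
matching first tries exact equality, then a canonical key: lower-cased,
with hemisphere markers normalized (`lh_X`, `X-lh`, `lh.X`, `Left-X` all
collapse to `lh:x`). Unmatched or ambiguous names are reported all at once,
by name, rather than one failure at a time.

## 2. Thresholding

Drawing every connection of a dense connectome produces an unreadable
hairball, so display passes through a threshold. The default keeps the
strongest **500** connections, counted as *undirected* edges. Three modes
exist: `count` (top $k$, default 500), `proportion` (top $\lceil pE \rceil$
of the $E$ nonzero edges), and `value` (weight $\ge v$).

Two decisions here were genuinely open:

* **Signed weights.** Correlation-based networks carry meaningful negative
  weights. The default ranks by raw signed weight — the "strongest"
  connections are the most positive, consistent with the positive-weight
  colormaps of the views — with `rankBy = "absolute"` available when
  magnitude is what matters.
* **Ties.** Equal weights are ordered by ascending $(i, j)$. Any rule would
  do statistically; a deterministic one makes renders byte-reproducible.

## 3. Network statistics

Formulas are the standard ones from the complex-networks literature (the
same forms used by the Brain Connectivity Toolbox family of tools):

* **Strength** $s_i = \sum_j W_{ij}$ (weighted degree).
* **Clustering.** Binary: Watts–Strogatz
  $C_i = 2t_i / (k_i(k_i-1))$ with $t_i$ the triangle count through $i$ on
  the graph binarized at $w > 0$; weighted: Onnela's geometric-mean form,
  each triangle contributing $(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$
  with weights normalized by the network maximum. Nodes of degree < 2
  get 0.
* **Efficiency.** Global efficiency is the mean over ordered node pairs of
  $1/d_{ij}$, with $1/\infty = 0$ for disconnected pairs; weighted path
  lengths are $1/w$ (strong connections are short), shortest paths by
  Dijkstra (weighted) or BFS (binary). Local efficiency of node $i$ is the
  global efficiency of the subgraph induced on $i$'s neighbors.
* **Betweenness** is unnormalized Brandes pair-dependency betweenness with
  endpoints excluded; tied geodesics share credit fractionally. Weighted
  distances compare with an absolute tolerance of $10^{-12}$ when deciding
  whether two paths tie.
* **Eigenvector centrality** is the principal eigenvector of $W$, by power
  iteration to $10^{-10}$, normalized to unit maximum. The iteration runs
  on $W + cI$ with $c$ the maximum strength: the shift leaves eigenvectors
  unchanged but strictly separates the dominant eigenvalue, so the
  iteration also converges on bipartite graphs (a plain power iteration
  oscillates on a star). On a disconnected network the centrality is
  computed on the largest component — ties broken by lowest node index —
  with zeros elsewhere and a warning, since the principal eigenvector of a
  disconnected matrix is not meaningfully comparable across components.
* **Modularity** $Q = \frac{1}{2m}\sum_{ij}(W_{ij} - s_i s_j/2m)\,
  \delta(c_i, c_j)$ with $2m = \sum_{ij} W_{ij}$. The all-in-one-module
  partition has $Q = 0$ identically, which doubles as a free correctness
  check.

Distance-based statistics and modularity **reject negative weights** with
an instructive error (threshold or take absolute values first): lengths
$1/w$ and the configuration null model are undefined for signed weights,
and silently proceeding would produce numbers with no interpretation.

### Module detection

`detectModules` implements spectral modularity maximization: recursive
bisection along the leading eigenvector of the modularity matrix
$B_{ij} = W_{ij} - s_i s_j / 2m$, using the generalized
$B^{(g)}_{ij} = B_{ij} - \delta_{ij}\sum_{k \in g} B_{ik}$ for subdivisions
of an existing group. After each bisection a fine-tuning pass repeatedly
moves the *single* node whose switch most increases $Q$ — deterministic
ascending-index scan, stopping when no move improves $Q$ by more than
$10^{-12}$ — and the recursion stops when a split's $Q$ contribution is at
most $10^{-10}$ or the leading eigenvalue is non-positive (the group is
indivisible). Because splits are only accepted when they increase $Q$, the
result never falls below the trivial partition's $Q = 0$.

The algorithm is deterministic. The `seed` argument matters only when the
leading eigenvalue is degenerate (e.g. perfectly symmetric graphs): the
bisection vector is then drawn from the degenerate eigenspace with a seeded
RNG, so runs remain reproducible.

## 4. The three views

All rendering flows through a `Scene` — parcellation (aligned to the
ordering), network, active `EdgeSet`, per-node radii and colors, optional
partition and surface, and a `ViewStyle`. The interactive gestures of a GUI
(click a node to isolate its connections; pick a module to isolate edges
with *both* endpoints inside it) are explicit functions (`isolateNode`,
`applyModuleDisplay`) that transform the scene; because every renderer
reads the same scene, the three views can never disagree — the draw logs
emitted alongside each image record the connection count and are asserted
identical in the test suite.

Rendering is an orthographic painter's-algorithm software rasterizer
writing PNG via `png::writePNG`. This was a deliberate design choice over
an R graphics device: no font stack, no anti-aliasing policy, no device
version can perturb the output, so a fixed scene + style + camera is
byte-identical across machines — which also makes image regression testing
trivial. The cost is plain aesthetics (no text labels, 1-px lines).

Semantics worth recording:

* **Edge color** interpolates the edge colormap (default yellow→red weak→
  strong; blue→orange selectable) over *rank-normalized* weights — robust
  to the heavy-tailed weight distributions of fiber-count networks; linear
  mapping is available by flag.
* **Scalar mapping**: node radius maps the size scalar's min–max range
  linearly onto `scalarSizeRange`; node color passes the min–max-normalized
  color scalar through the scalar colormap (light green → dark green).
  Size and color may carry two unrelated variables. A constant scalar maps
  to the range midpoint (no information → median emphasis).
* **Circle layout**: node $k$ of $n$ sits at $90° - 360°(k-1)/n$, i.e.
  node 1 at the top proceeding clockwise on screen, left hemisphere first
  under the conventional ordering. Each connection is a cubic Bézier whose
  two interior control points lie on the endpoints' radii at
  $r_c = r\,(1 - g/180°)$, clamped to $[0.05r, 0.95r]$, where $g$ is the
  angular separation: adjacent nodes get shallow arcs, antipodal nodes pass
  near the center. This visually separates short- and long-range
  connections without a full hierarchical edge-bundling algorithm (out of
  scope).
* **Module colors** come from a seeded random permutation of equally
  spaced hues: the same seed always yields the same colors and distinct
  modules always get distinct colors. Under module isolation, in-module
  nodes are purple, others blue.
* **3D cameras** are the six anatomical presets (left/right lateral,
  dorsal, ventral, anterior, posterior) or an explicit azimuth/elevation;
  the translucent surface (opacity 0.15 by default) is drawn as
  depth-sorted alpha-blended triangles behind depth-sorted edges and node
  spheres.
* `exportViews` scales pixel dimensions linearly with `dpi` (reference 96),
  so doubling dpi exactly doubles image size.

## 5. Synthetic data: what it emulates and what it does not

The fixture generator stands in for real surface/annotation/segmentation
data and for modality-specific network signatures:

* `makeToyBrain` builds two *exactly mirrored* ellipsoid-shell hemispheres
  (so left/right symmetry can be asserted to machine precision), assigns
  vertices to parcels by nearest anchor along a sweep that starts in medial
  frontal cortex, wraps over parietal and occipital cortex and ends at the
  temporal pole — the principled anatomical ordering that makes matrix and
  circle views legible — with four angular "lobe" groups per hemisphere,
  and places two subcortical structures per side (thalamus, hippocampus)
  in a small labeled volume using real aseg codes. The default scale is 33
  nodes per hemisphere (66 cortical), mirroring the coarsest common
  parcellation resolution.
* `makeModularNetwork` draws a planted-partition graph: contiguous blocks,
  within-module edge probability `pIn = 0.9`, between-module `pOut = 0.05`,
  i.i.d. uniform$(0,1]$ weights by default (lognormal available for
  heavy-tailed fiber-count-like weights). These defaults give community
  structure that is strong but not trivial — the regime where a correct
  spectral implementation should recover the planted labels essentially
  always at $n = 40$, which the tests assert at a 95% recovery floor over
  100 seeds.
* `makeLateralNetwork` reproduces the qualitative signature of resting
  fMRI connectomes — dominant lateral connections between homologous
  (lh_X, rh_X) region pairs — as an additive boost over a distance-decay
  background, for view-oriented tests.

Fixtures are written to disk in the genuine external formats (GIFTI,
FreeSurfer binary, `.annot`, NIFTI, MGZ, `.npy`, `.mat`, text), so the
readers are exercised end-to-end rather than in memory only.

What passing these tests does *not* show: real annotations with exotic
color tables, GIFTI files using Base64/GZip encodings (the reader supports
ASCII encoding and says so), compressed MATLAB v7 files (rejected with a
pointer to `-v6` export), scanner-specific affine quirks, or parcellations
whose naming conventions fall outside the canonicalization table. Real
networks are also weighted more heterogeneously than the uniform-weight
fixtures; the rank-based edge coloring exists precisely for that case.

## 6. Numerical choices and degenerate inputs

* Symmetry tolerance $10^{-8}$ on construction; registration bottom row
  checked at $10^{-6}$; writer/reader round-trips hold to $10^{-12}$ or
  exactly (labels, voxels, text at 17 significant digits).
* Shortest-path tie tolerance $10^{-12}$ (absolute); power iteration
  tolerance $10^{-10}$; fine-tuning improvement threshold $10^{-12}$;
  split-acceptance threshold $10^{-10}$.
* Empty edge sets are valid everywhere: views render nodes only and log
  zero connections. Edgeless networks give strength 0 and efficiency 0;
  modularity and module detection raise a computation error, which
  `computeAllStats` records per metric instead of failing the whole
  report.
* A node with fewer than two neighbors has clustering and local efficiency
  0 by convention (the formulas' denominators vanish).

## 7. Problem sizes used in the tests

The suite runs entirely on synthetic data: oracle-equivalence checks use
200 random graphs with up to 8 nodes against brute-force enumerations
(Floyd–Warshall, triple loops, exhaustive bipartition search) and igraph as
an independent implementation; planted-partition recovery uses 100 draws at
40 nodes; threshold checks use a dense 90-node network (4005 distinct
weights); view-consistency checks render 50 random scenes at 80×80 px.
These sizes make the full suite and the acceptance script run in well under
a minute while still exercising every code path; all statistics scale
comfortably to the hundreds-of-nodes parcellations typical of connectome
work, where exact brute-force verification is no longer possible.

## 8. Known limitations

* No directed networks, multigraphs, or dynamic networks — undirected
  single-edged static graphs only.
* No connectivity estimation, no surface reconstruction or segmentation:
  upstream tools own those steps by design.
* No GUI or movie export; the scriptable API and CLI are the interface.
* The rasterizer favors determinism over beauty: no anti-aliasing, no
  labels, no hierarchical edge bundling.
* Signed-network statistics are rejected rather than given ad-hoc
  definitions.
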