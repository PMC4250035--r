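# ConnectomeView

Visualization and graph analysis of human brain networks in R.

Connectomics represents the brain as a network: a *parcellation* divides the
cortex (and optionally subcortex) into named regions of interest that serve
as nodes, and an *adjacency matrix* — from diffusion tractography fiber
counts, resting-state fMRI correlations, MEG synchronization, or any other
modality — carries the connection weights. ConnectomeView is for researchers
who already have such a network (it deliberately does **not** estimate
connectivity) and want to inspect, quantify and publish it. It loads the
standard interchange formats, computes the common graph-theoretic statistics,
finds modular structure, and renders three complementary, *linked* views of
the same network state:

* **3D brain** — node spheres at their anatomical millimeter centers with
  straight connection segments, inside a translucent cortical surface;
* **matrix** — the n×n heatmap in ordering order, with anatomical-group
  color bands along both axes;
* **circle** — a circular connectogram with nodes on the circumference and
  connections drawn as interior Bézier arcs.

All three renderers draw from one `Scene` object, so node isolation, scalar
mapping and module coloring appear consistently everywhere. Rendering is a
pure-software rasterizer: a fixed scene always produces byte-identical PNGs,
and each view emits a machine-readable draw log.

## The model in brief

* **Networks are undirected.** A weight matrix `W` is bound to an ordering
  file (one ROI name per line; line *k* labels row/column *k*). The diagonal
  is ignored; asymmetric input must be explicitly symmetrized as
  `(A + Aᵀ)/2`.
* **Thresholding.** Dense connectomes are unreadable drawn in full, so by
  default all but the strongest **500** connections are cut before display
  (count, proportion and value cutoffs, and signed vs absolute ranking, stay
  under user control). Ties break by ascending `(i, j)` so output is
  reproducible.
* **Statistics** use the standard forms: node strength `sᵢ = Σⱼ Wᵢⱼ`;
  Watts–Strogatz clustering `Cᵢ = 2tᵢ/(kᵢ(kᵢ−1))` (Onnela geometric-mean
  form for weights); Latora–Marchiori efficiency
  `E = ⟨1/dᵢⱼ⟩` with edge lengths `1/w`; Brandes betweenness; Bonacich
  eigenvector centrality; Newman–Girvan modularity
  `Q = (1/2m) Σᵢⱼ (Wᵢⱼ − sᵢsⱼ/2m) δ(cᵢ, cⱼ)`.
* **Module detection** is Newman's spectral method: recursive bisection by
  the leading eigenvector of the (generalized) modularity matrix
  `Bᵢⱼ = Wᵢⱼ − sᵢsⱼ/2m`, each split refined by a Kernighan–Lin-style
  fine-tuning pass that repeatedly moves the single node whose switch most
  increases Q.
* **Parcellations** may be supplied three ways: surface parcels (FreeSurfer
  binary or GIFTI surface + `.annot`/GIFTI label annotation; node center =
  mean of parcel vertices), a labeled segmentation volume (NIFTI or MGZ,
  FreeSurfer aseg codes for the subcortical lookup), or a plain coordinate
  table (e.g. EEG electrodes). An optional 4×4 registration maps volume
  coordinates into surface space.

A synthetic fixture generator (`makeToyBrain`, `makeModularNetwork`,
`makeLateralNetwork`) builds complete toy datasets — mirrored ellipsoid
hemispheres, annotations, a small labeled volume, planted-module networks —
so the entire pipeline runs and is tested without downloading any
neuroimaging data.

## Worked example

```r
library(ConnectomeView)

toy <- makeToyBrain(fixtureSpec(nNodesPerHemisphere = 8L, seed = 4L))
net <- makeModularNetwork(fixtureSpec(nNodesPerHemisphere = 8L,
                                      nModules = 2L, seed = 4L),
                          toy$ordering)$network
net
#> AdjacencyNetwork: 20 nodes, 82 nonzero undirected edges

detectModules(net)
#> ModulePartition: 2 modules over 20 nodes, Q = 0.4278

computeAllStats(net)
#> StatsReport over 20 nodes
#>   nodal: strength, clustering_binary, clustering_weighted, local_efficiency,
#>          betweenness, eigenvector, module
#>   global: global_efficiency_binary=0.6825, global_efficiency_weighted=0.4059,
#>           mean_clustering=0.7458, Q=0.4278

es <- thresholdEdges(net, thresholdSpec(k = 40))   # keep the strongest 40
sc <- makeScene(net, toy$parcellation, edges = es, surface = toy$surface)
sc <- applyScalarMapping(sc, nodeStrength(net))    # size+color by strength
res <- exportViews(sc, "demo", camera = "left-lateral")
vapply(res$logs, function(l) l$edges, 0L)
#>     3d matrix circle
#>     40     40     40
```

The detected partition splits the 20 nodes into the two planted modules
(Q = 0.43); the three exported PNGs draw exactly the same 40 thresholded
connections, with node spheres sized and colored light-to-dark green by
strength.

The same pipeline is available from the shell:

```sh
Rscript inst/cli/connectomeview.R fixtures generate --out toydata --seed 1
Rscript inst/cli/connectomeview.R render --matrix toydata/network.txt \
    --ordering toydata/ordering.txt --coords toydata/coords.txt \
    --isolate-node lh_frontal_1 --out figures
Rscript inst/cli/connectomeview.R stats --matrix toydata/network.txt \
    --ordering toydata/ordering.txt --modules --out stats
```

Every run writes a JSON manifest (inputs, merged config, config hash, seed,
edge count) sufficient to reproduce it bit-exactly. Exit codes: 0 success,
2 input/validation error, 3 computation error.

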