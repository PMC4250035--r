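#' @import methods
NULL

SYMMETRY_TOL <- 1e-8

#' Ordering: the ROI name sequence defining matrix row/column identity
#'
#' An ordering is a plain sequence of region-of-interest (ROI) names.  Row and
#' column \code{i} of an adjacency matrix refer to the region on line \code{i}
#' of the ordering file.  Order is significant; duplicates are forbidden.
#'
#' @slot names character vector of ROI names, in file order.
#' @seealso [readOrdering()], [Ordering()]
#' @export
setClass("Ordering", representation(names = "character"))

setValidity("Ordering", function(object) {
    nm <- object@names
    if (length(nm) < 1L) return("ordering must contain at least one name")
    if (any(!nzchar(trimws(nm)))) return("ordering names must be non-empty")
    dup <- nm[duplicated(nm)]
    if (length(dup) > 0L)
        return(sprintf("duplicate ROI name(s) in ordering: %s",
                       paste(unique(dup), collapse = ", ")))
    TRUE
})

#' AdjacencyNetwork: an undirected weighted brain network
#'
#' A square, symmetric, zero-diagonal weight matrix bound to an [Ordering]
#' giving each row/column a region name.  All networks are undirected;
#' asymmetric input must be symmetrized explicitly (see [bindMatrix()]).
#'
#' @slot weights numeric n x n matrix, symmetric, zero diagonal.
#' @slot ordering the [Ordering] naming the n nodes.
#' @seealso [bindMatrix()], [thresholdEdges()]
#' @export
setClass("AdjacencyNetwork",
         representation(weights = "matrix", ordering = "Ordering"))

setValidity("AdjacencyNetwork", function(object) {
    w <- object@weights
    if (!is.numeric(w)) return("weights must be numeric")
    if (nrow(w) != ncol(w)) return("weight matrix must be square")
    if (nrow(w) != length(object@ordering@names))
        return(sprintf("matrix dimension (%d) does not match ordering length (%d)",
                       nrow(w), length(object@ordering@names)))
    if (any(!is.finite(w))) return("weights must be finite")
    asym <- max(abs(w - t(w)))
    if (asym > SYMMETRY_TOL)
        return(sprintf("weight matrix asymmetric: max |W - t(W)| = %g", asym))
    if (any(diag(w) != 0)) return("diagonal must be zero")
    TRUE
})

#' ThresholdSpec: how to cut a dense network down to drawable edges
#'
#' Dense connectomes are unreadable when every connection is drawn, so by
#' default all but the strongest 500 connections are cut off before
#' rendering.  Three modes are available: keep the top \code{k} edges
#' (\code{count}), the top fraction \code{p} of nonzero edges
#' (\code{proportion}), or all edges with weight at least \code{v}
#' (\code{value}).  Ranking uses raw weight (\code{signed}) or magnitude
#' (\code{absolute}).
#'
#' @slot mode one of "count", "proportion", "value".
#' @slot k positive integer, count mode (default 500).
#' @slot p fraction in (0, 1], proportion mode.
#' @slot v numeric cutoff, value mode.
#' @slot rankBy "signed" (descending weight) or "absolute" (descending |weight|).
#' @seealso [thresholdSpec()], [thresholdEdges()]
#' @export
setClass("ThresholdSpec",
         representation(mode = "character", k = "integer",
                        p = "numeric", v = "numeric", rankBy = "character"))

setValidity("ThresholdSpec", function(object) {
    if (!object@mode %in% c("count", "proportion", "value"))
        return("mode must be one of count, proportion, value")
    if (!object@rankBy %in% c("signed", "absolute"))
        return("rankBy must be 'signed' or 'absolute'")
    if (object@mode == "count" && (length(object@k) != 1L || object@k < 1L))
        return("count mode requires a positive integer k")
    if (object@mode == "proportion" &&
        (length(object@p) != 1L || object@p <= 0 || object@p > 1))
        return("proportion mode requires p in (0, 1]")
    if (object@mode == "value" && length(object@v) != 1L)
        return("value mode requires a single cutoff v")
    TRUE
})

#' EdgeSet: the undirected edges a view actually draws
#'
#' Materialized list of weighted undirected edges surviving a threshold or
#' isolation filter.  Node indices are 1-based with \code{i < j}.
#'
#' @slot edges data.frame with integer columns \code{i}, \code{j} and numeric
#'   \code{w}; each (i, j) pair appears at most once, 1 <= i < j <= sourceN.
#' @slot sourceN node count of the originating network.
#' @export
setClass("EdgeSet", representation(edges = "data.frame", sourceN = "integer"))

setValidity("EdgeSet", function(object) {
    e <- object@edges
    if (!all(c("i", "j", "w") %in% names(e)))
        return("edges must have columns i, j, w")
    if (nrow(e) == 0L) return(TRUE)
    if (any(e$i >= e$j)) return("edges must satisfy i < j")
    if (any(e$i < 1L) || any(e$j > object@sourceN))
        return("edge indices out of range 1..sourceN")
    if (anyDuplicated(e[, c("i", "j")]) > 0L)
        return("duplicate (i, j) pairs in EdgeSet")
    TRUE
})

#' AffineRegistration: 4x4 homogeneous transform into anatomical space
#'
#' Maps parcellation-volume mm coordinates into anatomical surface space.
#'
#' @slot matrix 4x4 numeric matrix, bottom row (0,0,0,1), invertible.
#' @seealso [affineRegistration()], [applyRegistration()]
#' @export
setClass("AffineRegistration", representation(matrix = "matrix"))

setValidity("AffineRegistration", function(object) {
    m <- object@matrix
    if (!identical(dim(m), c(4L, 4L))) return("registration must be 4x4")
    if (any(abs(m[4, ] - c(0, 0, 0, 1)) > 1e-6))
        return("bottom row of registration matrix must be (0, 0, 0, 1)")
    d <- det(m)
    if (!is.finite(d) || abs(d) < 1e-12)
        return("registration matrix must be invertible")
    TRUE
})

#' NodeScalar: a per-node scalar metric aligned to an ordering
#'
#' One real value per node, e.g. node strength, mapped to sphere size and/or
#' color in the 3D view.  Externally computed scalars can be imported and
#' displayed just like native statistics.
#'
#' @slot values numeric vector, finite, one entry per node.
#' @slot name label used in file names and legends.
#' @export
setClass("NodeScalar", representation(values = "numeric", name = "character"))

setValidity("NodeScalar", function(object) {
    if (any(!is.finite(object@values))) return("scalar values must be finite")
    if (length(object@name) != 1L) return("name must be a single string")
    TRUE
})

#' Parcellation: named nodes with anatomical positions and groupings
#'
#' The spatial embedding of the network: each node has a name, a 3D center
#' (mm, RAS), a hemisphere, an anatomical group (used for the color bands in
#' the matrix and circle views), and a group color.
#'
#' @slot nodes data.frame with columns \code{name}, \code{x}, \code{y},
#'   \code{z}, \code{hemisphere} (one of lh/rh/subcortical/unknown),
#'   \code{group}, \code{groupColor} (hex RGB).
#' @export
setClass("Parcellation", representation(nodes = "data.frame"))

setValidity("Parcellation", function(object) {
    nd <- object@nodes
    need <- c("name", "x", "y", "z", "hemisphere", "group", "groupColor")
    if (!all(need %in% names(nd)))
        return(paste("parcellation nodes need columns:",
                     paste(need, collapse = ", ")))
    if (nrow(nd) == 0L) return("parcellation must have at least one node")
    if (any(!is.finite(as.matrix(nd[, c("x", "y", "z")]))))
        return("node centers must be finite")
    key <- canonicalNodeKey(nd$name)
    if (anyDuplicated(key) > 0L)
        return(sprintf("duplicate canonical node name(s): %s",
                       paste(unique(nd$name[duplicated(key)]), collapse = ", ")))
    if (!all(nd$hemisphere %in% c("lh", "rh", "subcortical", "unknown")))
        return("hemisphere must be lh, rh, subcortical, or unknown")
    TRUE
})

#' SurfaceGeometry: triangulated cortical surface mesh
#'
#' @slot vertices V x 3 numeric matrix of mm coordinates.
#' @slot faces F x 3 integer matrix of 1-based vertex indices.
#' @seealso [readSurface()], [writeSurface()]
#' @export
setClass("SurfaceGeometry",
         representation(vertices = "matrix", faces = "matrix"))

setValidity("SurfaceGeometry", function(object) {
    v <- object@vertices; f <- object@faces
    if (ncol(v) != 3L) return("vertices must be V x 3")
    if (any(!is.finite(v))) return("vertices must be finite")
    if (nrow(f) > 0L) {
        if (ncol(f) != 3L) return("faces must be F x 3")
        if (min(f) < 1L || max(f) > nrow(v))
            return("face indices must lie in 1..V")
    }
    TRUE
})

#' SurfaceAnnotation: per-vertex parcel labels with a color table
#'
#' @slot vertexLabels integer label id per vertex (0 = unknown/background).
#' @slot labelTable data.frame with columns \code{id}, \code{name},
#'   \code{color} (hex RGB); every nonzero vertex label appears here.
#' @seealso [readAnnotation()], [writeAnnotation()], [parcelCenters()]
#' @export
setClass("SurfaceAnnotation",
         representation(vertexLabels = "integer", labelTable = "data.frame"))

setValidity("SurfaceAnnotation", function(object) {
    lt <- object@labelTable
    if (!all(c("id", "name", "color") %in% names(lt)))
        return("labelTable needs columns id, name, color")
    used <- setdiff(unique(object@vertexLabels), 0L)
    if (!all(used %in% lt$id))
        return("every nonzero vertex label must appear in the label table")
    TRUE
})

#' SegmentationVolume: labeled MRI volume locating subcortical structures
#'
#' A 3D integer array whose voxel values are hard-coded structure labels
#' (FreeSurfer aseg convention), an affine taking 0-based voxel indices to mm
#' coordinates (voxel-center convention, no half-voxel shift), and a lookup
#' from label value to structure name.
#'
#' @slot voxels 3D integer array of structure labels.
#' @slot affine 4x4 voxel-index-to-mm transform.
#' @slot lookup data.frame with columns \code{label} (positive integer) and
#'   \code{name}.
#' @seealso [segmentationCenters()], [readSegmentation()]
#' @export
setClass("SegmentationVolume",
         representation(voxels = "array", affine = "matrix",
                        lookup = "data.frame"))

setValidity("SegmentationVolume", function(object) {
    if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
    if (!identical(dim(object@affine), c(4L, 4L)))
        return("affine must be 4x4")
    d <- det(object@affine)
    if (!is.finite(d) || abs(d) < 1e-12) return("affine must be invertible")
    lk <- object@lookup
    if (!all(c("label", "name") %in% names(lk)))
        return("lookup needs columns label, name")
    if (nrow(lk) > 0L && any(lk$label < 1L))
        return("lookup labels must be positive integers")
    TRUE
})

#' ModulePartition: a node-to-module assignment with its modularity
#'
#' Output of spectral community detection: module ids 1..M (every id used at
#' least once) and the Newman-Girvan modularity Q of the assignment.
#'
#' @slot assignment integer module id per node, ids 1..M each occurring.
#' @slot Q modularity of the assignment, in [-1, 1].
#' @seealso [detectModules()], [modularityQ()]
#' @export
setClass("ModulePartition",
         representation(assignment = "integer", Q = "numeric"))

setValidity("ModulePartition", function(object) {
    a <- object@assignment
    if (length(a) < 1L) return("assignment must cover at least one node")
    M <- max(a)
    if (!setequal(unique(a), seq_len(M)))
        return("module ids must be 1..M with every id occurring")
    if (length(object@Q) != 1L || object@Q < -1 - 1e-9 || object@Q > 1 + 1e-9)
        return("Q must be a single value in [-1, 1]")
    TRUE
})

#' StatsReport: all native network statistics for one network
#'
#' Bundles the nodal metrics (as [NodeScalar]s) and global scalars computed by
#' [computeAllStats()], aligned to one ordering.  Metrics whose preconditions
#' fail (e.g. modularity of an edgeless network) are recorded as missing with
#' the error message retained.
#'
#' @slot nodal named list of [NodeScalar].
#' @slot global named list of single numeric values.
#' @slot ordering the shared [Ordering].
#' @slot errors named character vector of per-metric failure messages.
#' @export
setClass("StatsReport",
         representation(nodal = "list", global = "list",
                        ordering = "Ordering", errors = "character"))

setValidity("StatsReport", function(object) {
    n <- length(object@ordering@names)
    for (nm in names(object@nodal)) {
        v <- object@nodal[[nm]]
        if (!is(v, "NodeScalar")) return("nodal entries must be NodeScalar")
        if (length(v@values) != n)
            return(sprintf("nodal metric '%s' not aligned to ordering", nm))
    }
    TRUE
})

#' ViewStyle: colors, sizes and output geometry shared by the three views
#'
#' @slot edgeColormap name of the edge colormap ("yellow-red" default,
#'   "blue-orange" alternative).
#' @slot nodeDefaultColor hex RGB for nodes with no scalar/module coloring.
#' @slot scalarColormap name of the node-scalar colormap ("green" default:
#'   light green = low, dark green = high).
#' @slot scalarSizeRange numeric (minRadius, maxRadius) in render units (px).
#' @slot background hex RGB.
#' @slot imageSize integer (width, height) pixels at reference dpi 96.
#' @slot surfaceOpacity translucent-surface opacity in [0, 1] (default 0.15).
#' @slot edgeColorMode "rank" (rank-normalized weights, robust) or "linear".
#' @seealso [viewStyle()]
#' @export
setClass("ViewStyle",
         representation(edgeColormap = "character",
                        nodeDefaultColor = "character",
                        scalarColormap = "character",
                        scalarSizeRange = "numeric",
                        background = "character",
                        imageSize = "integer",
                        surfaceOpacity = "numeric",
                        edgeColorMode = "character"))

setValidity("ViewStyle", function(object) {
    if (any(object@imageSize < 1L)) return("image dimensions must be positive")
    if (object@surfaceOpacity < 0 || object@surfaceOpacity > 1)
        return("surfaceOpacity must be in [0, 1]")
    if (length(object@scalarSizeRange) != 2L ||
        object@scalarSizeRange[1] > object@scalarSizeRange[2])
        return("scalarSizeRange must be (min, max) with min <= max")
    if (!object@edgeColorMode %in% c("rank", "linear"))
        return("edgeColorMode must be 'rank' or 'linear'")
    TRUE
})

#' Scene: one consistent state feeding all three renderers
#'
#' The three views are linked: they all draw from a single Scene, so any
#' isolation, scalar mapping or module display applied to the scene appears
#' consistently in the 3D brain, matrix and circle renderings.
#'
#' @slot parcellation [Parcellation] aligned (row k = ordering name k).
#' @slot network the [AdjacencyNetwork].
#' @slot edges active [EdgeSet] (already thresholded/isolated).
#' @slot nodeRadii numeric per-node sphere radii (render units).
#' @slot nodeColors character per-node hex colors.
#' @slot partition [ModulePartition] or NULL.
#' @slot surface [SurfaceGeometry] or NULL (translucent backdrop in 3D).
#' @slot style the [ViewStyle].
#' @seealso [makeScene()], [render3d()], [renderMatrix()], [renderCircle()]
#' @export
setClass("Scene",
         representation(parcellation = "Parcellation",
                        network = "AdjacencyNetwork",
                        edges = "EdgeSet",
                        nodeRadii = "numeric",
                        nodeColors = "character",
                        partition = "ANY",
                        surface = "ANY",
                        style = "ViewStyle"))

setValidity("Scene", function(object) {
    n <- length(object@network@ordering@names)
    if (nrow(object@parcellation@nodes) != n)
        return("parcellation not aligned to network ordering")
    if (object@edges@sourceN != n)
        return("edge set not aligned to network")
    if (length(object@nodeRadii) != n || length(object@nodeColors) != n)
        return("node radii/colors must have one entry per node")
    if (!is.null(object@partition) &&
        length(object@partition@assignment) != n)
        return("partition not aligned to network")
    TRUE
})

#' FixtureSpec: parameters of the synthetic toy-brain and network generator
#'
#' @slot nNodesPerHemisphere cortical nodes per hemisphere (default 33, i.e.
#'   66 cortical nodes total, the coarsest common parcellation scale).
#' @slot nModules number of planted modules for [makeModularNetwork()].
#' @slot pIn,pOut within/between-module edge probabilities.
#' @slot weightDistribution "uniform" (weights in (0,1]) or "lognormal".
#' @slot logMu,logSigma lognormal parameters (used when lognormal).
#' @slot seed integer RNG seed.
#' @seealso [fixtureSpec()], [makeToyBrain()], [makeModularNetwork()]
#' @export
setClass("FixtureSpec",
         representation(nNodesPerHemisphere = "integer",
                        nModules = "integer",
                        pIn = "numeric", pOut = "numeric",
                        weightDistribution = "character",
                        logMu = "numeric", logSigma = "numeric",
                        seed = "integer"))

setValidity("FixtureSpec", function(object) {
    if (object@nNodesPerHemisphere < 1L)
        return("need at least one node per hemisphere")
    if (2L * object@nNodesPerHemisphere < 2L) return("need at least 2 nodes")
    if (object@pOut < 0 || object@pIn > 1 || object@pOut > object@pIn)
        return("need 0 <= pOut <= pIn <= 1")
    if (!object@weightDistribution %in% c("uniform", "lognormal"))
        return("weightDistribution must be 'uniform' or 'lognormal'")
    if (object@nModules < 1L) return("nModules must be >= 1")
    TRUE
})
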