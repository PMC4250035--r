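# Synthetic fixture generator: a complete toy dataset (surface, annotation,
# segmentation, parcellation, ordering, networks) with known structure, so
# every reader, statistic and renderer is testable end-to-end without any
# neuroimaging download.  The toy brain is two mirrored ellipsoid shells
# with four angular "lobe" groups per hemisphere and a small labeled volume
# providing two subcortical structures per side.

LOBE_COLORS <- c(frontal = "#E41A1C", parietal = "#377EB8",
                 occipital = "#4DAF4A", temporal = "#FF7F00",
                 subcortical = "#984EA3")

#' Construct a fixture specification
#'
#' Defaults emulate the coarsest common parcellation scale: 33 cortical
#' nodes per hemisphere (66 total), 4 planted modules, strong within-module
#' connectivity (pIn = 0.9) against a sparse background (pOut = 0.05), and
#' uniform(0, 1] weights.
#'
#' @param nNodesPerHemisphere cortical nodes per hemisphere.
#' @param nModules planted module count for [makeModularNetwork()].
#' @param pIn,pOut within/between-module edge probabilities.
#' @param weightDistribution "uniform" or "lognormal".
#' @param logMu,logSigma lognormal parameters.
#' @param seed RNG seed.
#' @return a [FixtureSpec].
#' @export
fixtureSpec <- function(nNodesPerHemisphere = 33L, nModules = 4L,
                        pIn = 0.9, pOut = 0.05,
                        weightDistribution = "uniform",
                        logMu = 0, logSigma = 0.5, seed = 1L) {
    new("FixtureSpec", nNodesPerHemisphere = as.integer(nNodesPerHemisphere),
        nModules = as.integer(nModules), pIn = pIn, pOut = pOut,
        weightDistribution = weightDistribution, logMu = logMu,
        logSigma = logSigma, seed = as.integer(seed))
}

# anchor positions for n nodes sweeping one hemisphere shell: the sweep
# starts in medial frontal cortex, wraps over parietal and occipital cortex
# and ends at the temporal pole (the principled anatomical ordering)
hemisphereAnchors <- function(n, side = c("lh", "rh")) {
    side <- match.arg(side)
    t <- (seq_len(n) - 0.5) / n
    psi <- 0.25 + t * (2 * pi - 0.9)
    y <- 80 * cos(psi) - 8
    z <- 52 * sin(psi) + 12
    x <- (42 + 6 * cos(2 * psi)) * if (side == "lh") -1 else 1
    lobe <- as.character(cut(t, c(0, 0.25, 0.5, 0.75, 1),
                             labels = c("frontal", "parietal", "occipital",
                                        "temporal")))
    within <- stats::ave(seq_len(n), lobe, FUN = seq_along)
    data.frame(name = sprintf("%s_%s_%d", side, lobe, within),
               x = x, y = y, z = z, lobe = lobe)
}

# mirrored ellipsoid shell mesh for one hemisphere (quad grid of triangles)
hemisphereMesh <- function(side = c("lh", "rh"), nu = 12L, nv = 22L) {
    side <- match.arg(side)
    u <- seq(0.12 * pi, 0.95 * pi, length.out = nu)  # polar, top to bottom
    v <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
    g <- expand.grid(u = u, v = v)
    sx <- if (side == "lh") -1 else 1
    verts <- cbind(sx * (28 * sin(g$u) * abs(cos(g$v)) + 20),
                   85 * sin(g$u) * sin(g$v) - 8,
                   58 * cos(g$u) + 12)
    idx <- function(iu, iv) (iv - 1L) * nu + iu
    faces <- NULL
    for (iv in seq_len(nv)) {
        iv2 <- if (iv == nv) 1L else iv + 1L
        for (iu in seq_len(nu - 1L)) {
            faces <- rbind(faces,
                           c(idx(iu, iv), idx(iu + 1L, iv), idx(iu, iv2)),
                           c(idx(iu + 1L, iv), idx(iu + 1L, iv2), idx(iu, iv2)))
        }
    }
    list(vertices = verts, faces = faces)
}

distinctColor <- function(k) {
    # injective index -> RGB, never black; parcels must have distinct colors
    grDevices::rgb(k %% 256, (k %/% 256) %% 256, 60 + (k * 37) %% 180,
                   maxColorValue = 255)
}

#' Generate the synthetic toy brain
#'
#' Produces mutually consistent fixtures: two mirrored ellipsoid-shell
#' hemispheres (surface + annotation whose parcels are the nodes), a small
#' labeled segmentation volume placing two subcortical structures per
#' hemisphere (thalamus, hippocampus), the assembled [Parcellation], and the
#' principled ordering (per hemisphere: medial frontal, around parietal and
#' occipital cortex, to the temporal pole, then the subcortical nodes; left
#' hemisphere first).  Left and right cortical centers mirror exactly in x.
#'
#' @param spec a [FixtureSpec].
#' @return list with elements \code{parcellation}, \code{surface},
#'   \code{annotation}, \code{segmentation}, \code{ordering}.
#' @export
makeToyBrain <- function(spec = fixtureSpec()) {
    n <- spec@nNodesPerHemisphere
    anchors <- rbind(hemisphereAnchors(n, "lh"), hemisphereAnchors(n, "rh"))
    lh <- hemisphereMesh("lh")
    rhv <- lh$vertices; rhv[, 1] <- -rhv[, 1]       # exact mirror
    V <- nrow(lh$vertices)
    surface <- new("SurfaceGeometry",
                   vertices = rbind(lh$vertices, rhv),
                   faces = rbind(lh$faces, lh$faces + V))
    # assign each vertex to the nearest same-hemisphere anchor
    labels <- integer(2L * V)
    for (h in 1:2) {
        vidx <- seq_len(V) + (h - 1L) * V
        aidx <- seq_len(n) + (h - 1L) * n
        am <- as.matrix(anchors[aidx, c("x", "y", "z")])
        vm <- surface@vertices[vidx, ]
        d2 <- outer(rowSums(vm^2), rep(1, n)) + outer(rep(1, V), rowSums(am^2)) -
            2 * vm %*% t(am)
        labels[vidx] <- aidx[max.col(-d2, ties.method = "first")]
    }
    annot <- new("SurfaceAnnotation", vertexLabels = labels,
                 labelTable = data.frame(id = seq_len(2L * n),
                                         name = anchors$name,
                                         color = distinctColor(seq_len(2L * n))))
    # small labeled volume: thalamus + hippocampus per side, mirrored
    dims <- c(20L, 20L, 20L)
    vox <- array(0L, dims)
    affine <- diag(c(4, 4, 4, 1)); affine[1:3, 4] <- -38
    stamp <- function(mm, label) {
        ijk <- round((mm + 38) / 4)
        vox[ijk[1] + 0:1 + 1L, ijk[2] + 0:1 + 1L, ijk[3] + 0:1 + 1L] <<- label
    }
    stamp(c(-10, -8, 2), 10L);   stamp(c(6, -8, 2), 49L)    # thalami
    stamp(c(-22, -20, -10), 17L); stamp(c(18, -20, -10), 53L) # hippocampi
    seg <- segmentationVolume(vox, affine)
    groups <- data.frame(name = anchors$name, group = anchors$lobe,
                         color = LOBE_COLORS[anchors$lobe])
    parc <- suppressWarnings(
        buildParcellation(surface, annot, segmentation = seg, groups = groups))
    sc <- parc@nodes$hemisphere == "subcortical"
    parc@nodes$groupColor[sc] <- LOBE_COLORS[["subcortical"]]
    scNames <- parc@nodes$name[sc]
    ordering <- Ordering(c(anchors$name[seq_len(n)],
                           sort(scNames[startsWith(scNames, "Left")]),
                           anchors$name[n + seq_len(n)],
                           sort(scNames[startsWith(scNames, "Right")])))
    list(parcellation = parc, surface = surface, annotation = annot,
         segmentation = seg, ordering = ordering)
}

drawWeights <- function(spec, n) {
    switch(spec@weightDistribution,
           uniform = 1 - stats::runif(n),          # in (0, 1]
           lognormal = stats::rlnorm(n, spec@logMu, spec@logSigma))
}

#' Generate a planted-partition modular network
#'
#' Nodes are split into \code{spec@nModules} contiguous blocks; each within-
#' module node pair receives an edge with probability \code{pIn}, each
#' between-module pair with probability \code{pOut}, and edge weights are
#' drawn i.i.d. from the configured weight distribution.  The matrix is
#' symmetric with zero diagonal; the planted labels are returned alongside
#' for recovery tests.
#'
#' @param spec a [FixtureSpec] (seed, module count, probabilities, weights).
#' @param parcellation a [Parcellation] supplying node names (or an
#'   [Ordering]).
#' @return list(network = [AdjacencyNetwork], labels = integer vector).
#' @export
makeModularNetwork <- function(spec, parcellation) {
    nm <- orderingNames(parcellation)
    n <- length(nm)
    labels <- sort(rep_len(seq_len(spec@nModules), n))
    set.seed(spec@seed)
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w), arr.ind = TRUE)
    pvec <- ifelse(labels[ut[, 1]] == labels[ut[, 2]], spec@pIn, spec@pOut)
    present <- stats::rbinom(nrow(ut), 1L, pvec) == 1L
    vals <- numeric(nrow(ut))
    vals[present] <- drawWeights(spec, sum(present))
    w[ut] <- vals
    w <- w + t(w)
    list(network = bindMatrix(w, Ordering(nm)), labels = labels)
}

#' Generate a network dominated by lateral homologous connections
#'
#' Reproduces the qualitative signature of resting-state fMRI connectomes:
#' homologous (lh_X, rh_X) region pairs receive weights boosted by
#' \code{lateralBoost} above a distance-decay background.
#'
#' @param parcellation a [Parcellation] with mirrored hemispheres.
#' @param lateralBoost additive weight boost for homologous pairs.
#' @param seed RNG seed for the background.
#' @param decayScale distance-decay length constant in mm.
#' @return an [AdjacencyNetwork] over the parcellation's nodes.
#' @export
makeLateralNetwork <- function(parcellation, lateralBoost = 5, seed = 1L,
                               decayScale = 30) {
    nd <- parcellation@nodes
    n <- nrow(nd)
    key <- sub("^(lh|rh):", "", canonicalNodeKey(nd$name))
    hemi <- nodeHemisphere(nd$name)
    homol <- outer(key, key, "==") & outer(hemi, hemi, "!=") &
        outer(hemi != "unknown", hemi != "unknown", "&")
    if (!any(homol))
        cvStop("cvInputError",
               "parcellation has no homologous (lh, rh) node pairs")
    ctr <- as.matrix(nd[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(ctr))
    set.seed(seed)
    noise <- matrix(stats::runif(n * n, 0.5, 1), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    w <- exp(-d / decayScale) * noise
    w[homol] <- w[homol] + lateralBoost
    diag(w) <- 0
    bindMatrix(w, Ordering(nd$name))
}

#' Write a complete toy dataset to disk in real external formats
#'
#' Emits the fixtures in the external formats the readers consume, so I/O is
#' exercised end-to-end: ordering file, connectivity matrix (text, .npy,
#' .mat), surface (GIFTI + FreeSurfer binary), annotation (.annot + GIFTI
#' labels), segmentation (NIFTI + MGZ) and a coordinate table.
#'
#' @param dir output directory (created).
#' @param spec a [FixtureSpec].
#' @return invisibly, named character vector of the files written.
#' @export
writeFixtureDataset <- function(dir, spec = fixtureSpec()) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    toy <- makeToyBrain(spec)
    net <- makeModularNetwork(spec, toy$ordering)$network
    p <- function(f) file.path(dir, f)
    writeLines(toy$ordering@names, p("ordering.txt"))
    writeMatrixFile(networkWeights(net), p("network.txt"))
    writeNpy(net@weights, p("network.npy"))
    writeMat5(net@weights, p("network.mat"))
    writeSurface(toy$surface, p("surface.gii"))
    writeSurface(toy$surface, p("surface.fsbin"))
    writeAnnotation(toy$annotation, p("parcels.annot"))
    writeAnnotation(toy$annotation, p("parcels.label.gii"))
    writeSegmentation(toy$segmentation, p("seg.nii.gz"))
    writeSegmentation(toy$segmentation, p("seg.mgz"))
    nd <- toy$parcellation@nodes
    writeLines(sprintf("%s %s %s %s", nd$name, formatNum(nd$x),
                       formatNum(nd$y), formatNum(nd$z)), p("coords.txt"))
    files <- c(ordering = p("ordering.txt"), matrix = p("network.txt"),
               npy = p("network.npy"), mat = p("network.mat"),
               surface_gii = p("surface.gii"), surface_fs = p("surface.fsbin"),
               annot = p("parcels.annot"), labels_gii = p("parcels.label.gii"),
               seg_nii = p("seg.nii.gz"), seg_mgz = p("seg.mgz"),
               coords = p("coords.txt"))
    invisible(files)
}
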