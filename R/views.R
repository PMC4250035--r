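# The three linked views.  All renderers draw from one Scene, so isolation,
# scalar mapping and module display applied to the scene appear consistently
# in the 3D brain, the connectivity matrix and the circular connectogram.
# Each renderer also emits a machine-readable draw log recording exactly how
# many connection primitives it drew — the contract is that this count is
# identical across the three views and equals the size of the active EdgeSet.

EDGE_COLORMAPS <- list(
    "yellow-red"  = c("#FFFF00", "#FF0000"),   # weak yellow -> strong red
    "blue-orange" = c("#3B6FD4", "#FF8C00"))   # weak blue -> strong orange

SCALAR_COLORMAPS <- list(
    "green" = c("#BFEFBF", "#004D00"))         # low light green -> high dark

#' Construct a view style
#'
#' Defaults follow the conventional connectome display: edges colored
#' yellow (weak) to red (strong) by rank-normalized weight, royal-blue
#' nodes, light-to-dark-green scalar colormap, black background, and a
#' translucent cortical surface at opacity 0.15.
#'
#' @param edgeColormap "yellow-red" or "blue-orange".
#' @param nodeDefaultColor hex color for unstyled nodes.
#' @param scalarColormap "green".
#' @param scalarSizeRange (min, max) node radius in pixels.
#' @param background hex background color.
#' @param imageSize (width, height) in pixels at the reference dpi of 96.
#' @param surfaceOpacity surface translucency in [0, 1].
#' @param edgeColorMode "rank" (robust to outlier weights) or "linear".
#' @return a [ViewStyle].
#' @export
viewStyle <- function(edgeColormap = "yellow-red",
                      nodeDefaultColor = "#4169E1",
                      scalarColormap = "green",
                      scalarSizeRange = c(2, 8),
                      background = "#000000",
                      imageSize = c(400L, 400L),
                      surfaceOpacity = 0.15,
                      edgeColorMode = "rank") {
    if (!edgeColormap %in% names(EDGE_COLORMAPS))
        cvStop("cvInputError", "unknown edge colormap '%s'; available: %s",
               edgeColormap, paste(names(EDGE_COLORMAPS), collapse = ", "))
    if (!scalarColormap %in% names(SCALAR_COLORMAPS))
        cvStop("cvInputError", "unknown scalar colormap '%s'; available: %s",
               scalarColormap, paste(names(SCALAR_COLORMAPS), collapse = ", "))
    new("ViewStyle", edgeColormap = edgeColormap,
        nodeDefaultColor = nodeDefaultColor, scalarColormap = scalarColormap,
        scalarSizeRange = as.numeric(scalarSizeRange), background = background,
        imageSize = as.integer(imageSize),
        surfaceOpacity = as.numeric(surfaceOpacity),
        edgeColorMode = edgeColorMode)
}

# edge weight -> color via rank normalization (default) or linear scaling
edgeColors <- function(w, style) {
    anchors <- EDGE_COLORMAPS[[style@edgeColormap]]
    if (length(w) == 0L) return(character(0))
    if (length(w) == 1L) return(lerpColor(anchors[1], anchors[2], 1))
    t <- if (style@edgeColorMode == "rank") {
        (rank(w, ties.method = "average") - 1) / (length(w) - 1)
    } else {
        rng <- range(w)
        if (diff(rng) == 0) rep(1, length(w)) else (w - rng[1]) / diff(rng)
    }
    lerpColor(anchors[1], anchors[2], t)
}

#' Assemble a renderable scene
#'
#' Aligns the parcellation to the network's ordering (via [matchNodes()]),
#' applies the default threshold if no EdgeSet is given, and seeds default
#' node radii and colors.  The Scene is the single state object feeding all
#' three renderers, realizing the linked-views behavior.
#'
#' @param network an [AdjacencyNetwork].
#' @param parcellation a [Parcellation] covering all ordering names.
#' @param edges active [EdgeSet]; default \code{thresholdEdges(network)}.
#' @param style a [ViewStyle].
#' @param surface optional [SurfaceGeometry] drawn translucently in 3D.
#' @return a [Scene].
#' @export
makeScene <- function(network, parcellation, edges = NULL,
                      style = viewStyle(), surface = NULL) {
    idx <- matchNodes(network@ordering, parcellation)
    nodes <- parcellation@nodes[idx, , drop = FALSE]
    rownames(nodes) <- NULL
    aligned <- new("Parcellation", nodes = nodes)
    if (is.null(edges)) edges <- thresholdEdges(network)
    n <- nNodes(network)
    new("Scene", parcellation = aligned, network = network, edges = edges,
        nodeRadii = rep(mean(style@scalarSizeRange), n),
        nodeColors = rep(style@nodeDefaultColor, n),
        partition = NULL, surface = surface, style = style)
}

#' Map scalars to node size and color
#'
#' Node radius is a linear map of the size scalar's min-max range onto the
#' style's \code{scalarSizeRange}; node color maps the min-max-normalized
#' color scalar through the scalar colormap.  A constant scalar maps to the
#' midpoint of the range.  Size and color may represent two unrelated
#' variables.
#'
#' @param scene a [Scene].
#' @param sizeScalar a [NodeScalar] (or NULL to leave sizes).
#' @param colorScalar a [NodeScalar] (or NULL to leave colors; defaults to
#'   \code{sizeScalar} so one scalar drives both, as with node strength).
#' @return the updated [Scene].
#' @export
applyScalarMapping <- function(scene, sizeScalar, colorScalar = sizeScalar) {
    n <- nNodes(scene@network)
    norm01 <- function(v) {
        if (length(v) != n)
            cvStop("cvValidationError",
                   "scalar has %d values; network has %d nodes", length(v), n)
        if (any(!is.finite(v)))
            cvStop("cvValidationError", "scalar values must be finite")
        rng <- range(v)
        if (diff(rng) == 0) rep(0.5, n) else (v - rng[1]) / diff(rng)
    }
    if (!is.null(sizeScalar)) {
        t <- norm01(sizeScalar@values)
        sr <- scene@style@scalarSizeRange
        scene@nodeRadii <- sr[1] + t * (sr[2] - sr[1])
    }
    if (!is.null(colorScalar)) {
        t <- norm01(colorScalar@values)
        anchors <- SCALAR_COLORMAPS[[scene@style@scalarColormap]]
        scene@nodeColors <- lerpColor(anchors[1], anchors[2], t)
    }
    scene
}

#' Color modules and optionally isolate one
#'
#' Each module receives a color drawn from a seeded random palette (the same
#' seed always yields the same colors; distinct modules get distinct
#' colors).  When \code{isolate} names a module, the active EdgeSet is
#' reduced to connections with BOTH ends inside that module, in-module nodes
#' are restyled purple and all other nodes blue.
#'
#' @param scene a [Scene].
#' @param partition a [ModulePartition] aligned to the scene's ordering.
#' @param seed palette seed.
#' @param isolate optional module id (1..M) to isolate.
#' @return the updated [Scene].
#' @export
applyModuleDisplay <- function(scene, partition, seed = 1L, isolate = NULL) {
    n <- nNodes(scene@network)
    if (length(partition@assignment) != n)
        cvStop("cvValidationError",
               "partition covers %d nodes; network has %d",
               length(partition@assignment), n)
    M <- max(partition@assignment)
    set.seed(seed)
    hues <- ((sample.int(M) - 1L) / M + stats::runif(1) / M) %% 1
    palette <- grDevices::hsv(hues, s = 0.75, v = 0.95)
    scene@partition <- partition
    if (is.null(isolate)) {
        scene@nodeColors <- palette[partition@assignment]
        return(scene)
    }
    if (!isolate %in% seq_len(M))
        cvStop("cvInputError", "unknown module id %s; valid ids: %s",
               as.character(isolate),
               paste(seq_len(M), collapse = ", "))
    inside <- partition@assignment == isolate
    e <- scene@edges@edges
    keep <- inside[e$i] & inside[e$j]
    scene@edges <- EdgeSet(e[keep, , drop = FALSE], scene@edges@sourceN)
    scene@nodeColors <- ifelse(inside, "#A020F0", "#4169E1")
    scene
}

# ---- cameras and projection ------------------------------------------------

CAMERA_PRESETS <- list(
    "right-lateral" = c(az = 0,   el = 0),
    "left-lateral"  = c(az = 180, el = 0),
    "anterior"      = c(az = 90,  el = 0),
    "posterior"     = c(az = 270, el = 0),
    "dorsal"        = c(az = 270, el = 90),
    "ventral"       = c(az = 90,  el = -90))

# orthographic projection of m x 3 RAS mm coordinates for a given camera;
# returns screen x (right), screen y (up, pre-flip) and depth (toward camera)
projectCamera <- function(coords, camera) {
    if (is.character(camera)) {
        if (!camera %in% names(CAMERA_PRESETS))
            cvStop("cvInputError", "unknown camera preset '%s'; presets: %s",
                   camera, paste(names(CAMERA_PRESETS), collapse = ", "))
        camera <- CAMERA_PRESETS[[camera]]
    }
    a <- camera[["az"]] * pi / 180; e <- camera[["el"]] * pi / 180
    d <- c(cos(e) * cos(a), cos(e) * sin(a), sin(e))
    r <- c(-sin(a), cos(a), 0)
    u <- c(-sin(e) * cos(a), -sin(e) * sin(a), cos(e))
    cbind(x = coords %*% r, y = coords %*% u, depth = coords %*% d)
}

# map projected coordinates into pixel space (margin fraction of the image)
pixelMapper <- function(proj, width, height, margin = 0.08) {
    rx <- range(proj[, 1]); ry <- range(proj[, 2])
    if (diff(rx) == 0) rx <- rx + c(-1, 1)
    if (diff(ry) == 0) ry <- ry + c(-1, 1)
    s <- min((1 - 2 * margin) * width / diff(rx),
             (1 - 2 * margin) * height / diff(ry))
    cx <- mean(rx); cy <- mean(ry)
    function(p) cbind(x = width / 2 + (p[, 1] - cx) * s,
                      y = height / 2 - (p[, 2] - cy) * s)
}

# ---- renderers -------------------------------------------------------------

finishRender <- function(cv, log, path) {
    out <- list(image = canvasArray(cv), log = log)
    if (!is.null(path)) {
        writeCanvas(cv, path)
        out$path <- path
    }
    invisible(out)
}

#' Render the 3D brain node-link view
#'
#' Orthographic projection of node spheres at their anatomical mm centers
#' with straight connection segments, behind an optional translucent
#' cortical surface.  Primitives are depth-sorted (painter's algorithm) and
#' drawn into a raster, so a fixed scene + camera + style always produces
#' byte-identical output.
#'
#' @param scene a [Scene] (parcellation centers required).
#' @param camera preset name (left-lateral, right-lateral, dorsal, ventral,
#'   anterior, posterior) or c(az = degrees, el = degrees).
#' @param path optional PNG output path.
#' @return invisibly, list(image, log[, path]); the draw log records the
#'   number of node and connection primitives drawn.
#' @export
render3d <- function(scene, camera = "left-lateral", path = NULL) {
    nodes <- scene@parcellation@nodes
    if (nrow(nodes) == 0L)
        cvStop("cvInputError",
               "no node centers available; supply a parcellation (surface+annot, segmentation, or coordinate table)")
    centers <- as.matrix(nodes[, c("x", "y", "z")])
    style <- scene@style
    cv <- newCanvas(style@imageSize[1], style@imageSize[2], style@background)
    allpts <- if (!is.null(scene@surface))
        rbind(centers, scene@surface@vertices) else centers
    proj_all <- projectCamera(allpts, camera)
    mapper <- pixelMapper(proj_all, cv$w, cv$h)
    pnode <- proj_all[seq_len(nrow(centers)), , drop = FALSE]
    pix <- mapper(pnode)
    if (!is.null(scene@surface) && style@surfaceOpacity > 0) {
        sv <- proj_all[-seq_len(nrow(centers)), , drop = FALSE]
        spix <- mapper(sv)
        f <- scene@surface@faces
        fdepth <- (sv[f[, 1], 3] + sv[f[, 2], 3] + sv[f[, 3], 3]) / 3
        for (k in order(fdepth)) {
            tri <- f[k, ]
            canvasFillTriangle(cv, spix[tri, 1], spix[tri, 2], "#B8B8C8",
                               style@surfaceOpacity)
        }
    }
    e <- scene@edges@edges
    if (nrow(e) > 0L) {
        cols <- edgeColors(e$w, style)
        edepth <- (pnode[e$i, 3] + pnode[e$j, 3]) / 2
        for (k in order(edepth))
            canvasLine(cv, pix[e$i[k], 1], pix[e$i[k], 2],
                       pix[e$j[k], 1], pix[e$j[k], 2], cols[k])
    }
    for (k in order(pnode[, 3]))
        canvasFillCircle(cv, pix[k, 1], pix[k, 2], scene@nodeRadii[k],
                         scene@nodeColors[k])
    log <- list(view = "3d", camera = if (is.character(camera)) camera else "custom",
                nodes = nrow(nodes), edges = nrow(e),
                edge_list = unname(as.matrix(e[, c("i", "j")])))
    finishRender(cv, log, path)
}

#' Render the connectivity-matrix view
#'
#' An n x n heatmap in ordering order: cell (i, j) is colored by the weight
#' of the active edge between nodes i and j (cells outside the active
#' EdgeSet stay background, the diagonal is ignored).  Per-group color bands
#' run along both axes, identifying each node's anatomical grouping.
#'
#' @param scene a [Scene].
#' @param path optional PNG output path.
#' @return invisibly, list(image, log[, path]).
#' @export
renderMatrix <- function(scene, path = NULL) {
    style <- scene@style
    n <- nNodes(scene@network)
    cv <- newCanvas(style@imageSize[1], style@imageSize[2], style@background)
    band <- max(3L, round(min(cv$w, cv$h) * 0.025))
    gap <- 2L
    x0 <- band + 2L * gap; y0 <- band + 2L * gap
    cell <- max(1, min((cv$w - x0 - gap) / n, (cv$h - y0 - gap) / n))
    cellX <- function(k) x0 + (k - 1) * cell
    cellY <- function(k) y0 + (k - 1) * cell
    e <- scene@edges@edges
    if (nrow(e) > 0L) {
        cols <- edgeColors(e$w, style)
        for (k in seq_len(nrow(e))) {
            for (rc in list(c(e$i[k], e$j[k]), c(e$j[k], e$i[k])))
                canvasFillRect(cv, cellX(rc[2]), cellY(rc[1]),
                               cellX(rc[2]) + cell - 1, cellY(rc[1]) + cell - 1,
                               cols[k])
        }
    }
    groupCols <- scene@parcellation@nodes$groupColor
    for (k in seq_len(n)) {
        canvasFillRect(cv, cellX(k), gap, cellX(k) + cell - 1, gap + band - 1,
                       groupCols[k])                      # top band
        canvasFillRect(cv, gap, cellY(k), gap + band - 1, cellY(k) + cell - 1,
                       groupCols[k])                      # left band
    }
    log <- list(view = "matrix", nodes = n, edges = nrow(e),
                edge_list = unname(as.matrix(e[, c("i", "j")])))
    finishRender(cv, log, path)
}

#' Node angles of the circular layout
#'
#' Node k (1-based) sits at \code{startAngle - 360 * (k - 1) / n} degrees
#' (mod 360), i.e. equally spaced starting at the top and proceeding
#' clockwise in screen coordinates.  Orderings are conventionally written
#' left hemisphere first.
#'
#' @param n node count.
#' @param startAngle angle of node 1 in degrees (default 90, the top).
#' @return numeric vector of angles in degrees.
#' @export
circleLayout <- function(n, startAngle = 90) {
    (startAngle - 360 * (seq_len(n) - 1) / n) %% 360
}

#' Render the circular connectogram view
#'
#' Nodes are spaced equally on a circle in ordering order; each connection
#' is a cubic Bezier arc whose interior control points are pulled toward the
#' center in proportion to the angular separation of its endpoints
#' (adjacent nodes get a shallow arc, antipodal nodes pass near the
#' center).  Circumference segments are colored by anatomical group; arc
#' color encodes weight.
#'
#' @param scene a [Scene].
#' @param startAngle angle of node 1 in degrees (default 90).
#' @param path optional PNG output path.
#' @return invisibly, list(image, log[, path]).
#' @export
renderCircle <- function(scene, startAngle = 90, path = NULL) {
    style <- scene@style
    n <- nNodes(scene@network)
    cv <- newCanvas(style@imageSize[1], style@imageSize[2], style@background)
    cx <- cv$w / 2; cy <- cv$h / 2
    r <- 0.40 * min(cv$w, cv$h)
    ang <- circleLayout(n, startAngle) * pi / 180
    px <- cx + r * cos(ang); py <- cy - r * sin(ang)
    # group band on the circumference
    groupCols <- scene@parcellation@nodes$groupColor
    half <- pi / n
    for (k in seq_len(n)) {
        seg <- seq(ang[k] - half, ang[k] + half, length.out = 12L)
        canvasPolyline(cv, cx + 1.07 * r * cos(seg), cy - 1.07 * r * sin(seg),
                       groupCols[k], lwd = max(2, r * 0.035))
    }
    e <- scene@edges@edges
    if (nrow(e) > 0L) {
        cols <- edgeColors(e$w, style)
        for (k in seq_len(nrow(e))) {
            a1 <- ang[e$i[k]]; a2 <- ang[e$j[k]]
            gdeg <- abs(e$i[k] - e$j[k]) / n * 360
            gdeg <- min(gdeg, 360 - gdeg)
            rc <- r * min(0.95, max(0.05, 1 - gdeg / 180))
            ctrl <- rbind(c(px[e$i[k]], py[e$i[k]]),
                          c(cx + rc * cos(a1), cy - rc * sin(a1)),
                          c(cx + rc * cos(a2), cy - rc * sin(a2)),
                          c(px[e$j[k]], py[e$j[k]]))
            bp <- bezierPoints(ctrl)
            canvasPolyline(cv, bp[, 1], bp[, 2], cols[k])
        }
    }
    for (k in seq_len(n))
        canvasFillCircle(cv, px[k], py[k], min(scene@nodeRadii[k], half * r),
                         scene@nodeColors[k])
    log <- list(view = "circle", nodes = n, edges = nrow(e),
                startAngle = startAngle,
                edge_list = unname(as.matrix(e[, c("i", "j")])))
    finishRender(cv, log, path)
}

#' Export all three views of one scene
#'
#' Renders the SAME scene through the 3D, matrix and circle renderers so any
#' isolation, scalar or module state appears consistently in all three
#' images.  Pixel dimensions scale linearly with \code{dpi} (reference 96).
#'
#' @param scene a [Scene].
#' @param outDir output directory (created if needed).
#' @param dpi output resolution; doubling dpi doubles pixel dimensions.
#' @param camera camera for the 3D view.
#' @param drawLog if TRUE (default) a JSON draw log is written next to each
#'   image.
#' @param prefix file-name prefix.
#' @return invisibly, a named list with image paths and the three draw logs.
#' @export
exportViews <- function(scene, outDir, dpi = 96, camera = "left-lateral",
                        drawLog = TRUE, prefix = "view") {
    ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir))
        cvStop("cvInputError", "cannot create output directory '%s'", outDir)
    scale <- dpi / 96
    style <- scene@style
    style@imageSize <- as.integer(round(style@imageSize * scale))
    style@scalarSizeRange <- style@scalarSizeRange * scale
    scene@style <- style
    scene@nodeRadii <- scene@nodeRadii * scale
    paths <- list()
    logs <- list()
    renders <- list(
        `3d` = function(p) render3d(scene, camera, p),
        matrix = function(p) renderMatrix(scene, p),
        circle = function(p) renderCircle(scene, startAngle = 90, p))
    for (nm in names(renders)) {
        p <- file.path(outDir, sprintf("%s_%s.png", prefix, nm))
        res <- tryCatch(renders[[nm]](p), error = function(e) e)
        if (inherits(res, "error")) stop(res)
        paths[[nm]] <- p
        logs[[nm]] <- res$log
        if (drawLog) {
            lp <- file.path(outDir, sprintf("%s_%s_drawlog.json", prefix, nm))
            jsonlite::write_json(res$log, lp, auto_unbox = TRUE, digits = NA)
            paths[[paste0(nm, "_log")]] <- lp
        }
    }
    invisible(list(paths = paths, logs = logs))
}
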