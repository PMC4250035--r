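test_that("scalar mapping sends min/max to the radius range endpoints", {
    sc <- smallScene()
    n <- nNodes(sc@network)
    v <- seq_len(n)
    sc2 <- applyScalarMapping(sc, nodeScalar(v, "v"))
    sr <- sc@style@scalarSizeRange
    expect_equal(sc2@nodeRadii[which.min(v)], sr[1])
    expect_equal(sc2@nodeRadii[which.max(v)], sr[2])
    # monotone: radius ordering matches scalar ordering
    expect_equal(order(sc2@nodeRadii), order(v))
    # constant scalar -> midpoint radius everywhere
    sc3 <- applyScalarMapping(sc, nodeScalar(rep(2.5, n), "const"))
    expect_equal(sc3@nodeRadii, rep(mean(sr), n))
    # size and color can carry two unrelated variables
    sc4 <- applyScalarMapping(sc, nodeScalar(v, "a"), nodeScalar(rev(v), "b"))
    expect_equal(order(sc4@nodeRadii), order(v))
    expect_equal(sc4@nodeColors, rev(sc2@nodeColors))
    expect_error(applyScalarMapping(sc, nodeScalar(1:3, "short")),
                 class = "cvValidationError")
})

test_that("module display colors are seeded, distinct, and reproducible", {
    sc <- smallScene()
    part <- detectModules(sc@network, seed = 1L)
    a <- applyModuleDisplay(sc, part, seed = 7L)
    b <- applyModuleDisplay(sc, part, seed = 7L)
    expect_identical(a@nodeColors, b@nodeColors)
    expect_equal(length(unique(a@nodeColors)), max(part@assignment))
    c2 <- applyModuleDisplay(sc, part, seed = 8L)
    expect_false(identical(a@nodeColors, c2@nodeColors))
})

test_that("module isolation keeps only edges with both ends inside", {
    tc <- twinCliques(5L)
    parc <- coordinateParcellation(Ordering(orderingNames(tc)),
                                   matrix(rnorm(30), 10, 3))
    sc <- makeScene(tc, parc, style = viewStyle(imageSize = c(100L, 100L)))
    part <- detectModules(tc)
    iso <- applyModuleDisplay(sc, part, isolate = 1L)
    e <- edgeTable(iso@edges)
    # set-filter oracle over the full thresholded edge set
    full <- edgeTable(sc@edges)
    inside <- part@assignment == 1L
    oracle <- full[inside[full$i] & inside[full$j], ]
    expect_equal(e, oracle, ignore_attr = TRUE)
    expect_equal(nEdges(iso@edges), 10L)   # C(5,2) within the clique
    # cross-module edge excluded under isolation of either module
    w <- tc@weights; w[1, 6] <- 0.5; w[6, 1] <- 0.5
    net2 <- networkFromWeights(w)
    sc2 <- makeScene(net2, parc, style = viewStyle(imageSize = c(100L, 100L)))
    for (m in 1:2) {
        iso2 <- applyModuleDisplay(sc2, part, isolate = m)
        e2 <- edgeTable(iso2@edges)
        expect_false(any(e2$i == 1L & e2$j == 6L))
    }
    # in-module nodes purple, others blue
    expect_equal(unique(iso@nodeColors[inside]), "#A020F0")
    expect_equal(unique(iso@nodeColors[!inside]), "#4169E1")
    err <- expect_error(applyModuleDisplay(sc, part, isolate = 9L),
                        class = "cvInputError")
    expect_match(conditionMessage(err), "1, 2")
})

test_that("circle layout spaces nodes by exactly 360/n from the start angle", {
    for (n in c(3L, 4L, 7L, 12L)) {
        ang <- circleLayout(n)
        expect_equal(ang[1], 90)
        gaps <- (ang[-n] - ang[-1]) %% 360
        expect_equal(gaps, rep(360 / n, n - 1))
        expect_equal(ang, (90 - 360 * (seq_len(n) - 1) / n) %% 360)
    }
    # 4 equally spaced nodes: adjacent nodes subtend a 90 degree chord
    ang4 <- circleLayout(4L)
    expect_equal((ang4[1] - ang4[2]) %% 360, 90)
})

test_that("draw logs record exactly the active connections in every view", {
    sc <- smallScene()
    e3 <- EdgeSet(edgeTable(sc@edges)[1:3, ], sc@edges@sourceN)
    sc3 <- sc; sc3@edges <- e3
    empty <- sc; empty@edges <- EdgeSet(edgeTable(sc@edges)[0, ], sc@edges@sourceN)
    for (scn in list(sc3, empty)) {
        want <- nEdges(scn@edges)
        expect_equal(render3d(scn, "dorsal")$log$edges, want)
        expect_equal(renderMatrix(scn)$log$edges, want)
        expect_equal(renderCircle(scn)$log$edges, want)
    }
})

test_that("rendering is deterministic: same scene, byte-identical files", {
    sc <- smallScene()
    sc <- applyScalarMapping(sc, nodeStrength(sc@network))
    d <- withr::local_tempdir()
    for (pass in 1:2) {
        render3d(sc, "left-lateral", file.path(d, sprintf("a%d.png", pass)))
        renderMatrix(sc, file.path(d, sprintf("m%d.png", pass)))
        renderCircle(sc, 90, file.path(d, sprintf("c%d.png", pass)))
    }
    for (v in c("a", "m", "c"))
        expect_identical(readBin(file.path(d, paste0(v, "1.png")), "raw", 1e7),
                         readBin(file.path(d, paste0(v, "2.png")), "raw", 1e7))
})

test_that("permuting the ordering permutes matrix/circle positions, not the 3D view", {
    toy <- smallToy()
    net <- makeModularNetwork(smallSpec(), toy$ordering)$network
    n <- nNodes(net)
    set.seed(4); perm <- sample(n)
    netp <- bindMatrix(net@weights[perm, perm],
                       Ordering(orderingNames(net)[perm]))
    style <- viewStyle(imageSize = c(120L, 120L))
    sc <- makeScene(net, toy$parcellation, style = style)
    scp <- makeScene(netp, toy$parcellation, style = style)
    # same undirected edges survive the default threshold, relabeled by perm
    inv <- order(perm)   # node k of the original sits at position inv[k]
    eo <- edgeTable(sc@edges); ep <- edgeTable(scp@edges)
    keyp <- apply(cbind(inv[eo$i], inv[eo$j]), 1,
                  function(r) paste(sort(r), collapse = "-"))
    expect_setequal(paste(ep$i, ep$j, sep = "-"), keyp)
    # 3D view depends only on anatomy: same node pixel positions drawn
    r1 <- render3d(sc, "dorsal"); r2 <- render3d(scp, "dorsal")
    expect_equal(r2$log$edges, r1$log$edges)
    # the circular slot set is mirror-symmetric: reflecting every angle
    # across the vertical axis maps the layout onto itself, so a reversed
    # ordering yields the mirror-image arrangement
    ang <- circleLayout(n)
    expect_setequal(round((180 - ang) %% 360, 9), round(ang %% 360, 9))
})

test_that("matrix view draws group bands for each anatomical group", {
    sc <- smallScene(n = 6L, imageSize = 160L)
    img <- renderMatrix(sc)$image
    # band row at the top margin contains one pixel run per group color
    groupCols <- unique(sc@parcellation@nodes$groupColor)
    bandRow <- img[4, , ]
    hex <- grDevices::rgb(bandRow[, 1], bandRow[, 2], bandRow[, 3])
    expect_true(all(toupper(groupCols) %in% toupper(hex)))
})

test_that("exportViews writes three linked images with consistent state", {
    sc <- smallScene(n = 6L, imageSize = 120L)
    d <- withr::local_tempdir()
    res <- exportViews(sc, d, dpi = 96)
    for (nm in c("3d", "matrix", "circle"))
        expect_true(file.exists(res$paths[[nm]]))
    counts <- vapply(res$logs, function(l) l$edges, 0L)
    expect_true(all(counts == nEdges(sc@edges)))
    img <- png::readPNG(res$paths[["matrix"]])
    expect_equal(dim(img)[1:2], c(120L, 120L))
    # doubling dpi doubles pixel dimensions
    res2 <- exportViews(sc, file.path(d, "hi"), dpi = 192)
    img2 <- png::readPNG(res2$paths[["matrix"]])
    expect_equal(dim(img2)[1:2], c(240L, 240L))
    # isolation state appears consistently in all three draw logs
    iso <- sc
    iso@edges <- isolateNode(sc@network, sc@edges, 1L)
    res3 <- exportViews(iso, file.path(d, "iso"))
    counts3 <- vapply(res3$logs, function(l) l$edges, 0L)
    expect_true(all(counts3 == nEdges(iso@edges)))
    # draw logs are written as JSON next to the images
    lg <- jsonlite::read_json(res3$paths[["3d_log"]])
    expect_equal(lg$edges, nEdges(iso@edges))
})
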