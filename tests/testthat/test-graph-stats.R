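test_that("strength is the row sum of weights", {
    expect_equal(scalarValues(nodeStrength(networkFromWeights(matrix(0, 4, 4)))),
                 rep(0, 4))
    tri <- completeNetwork(3L)
    expect_equal(scalarValues(nodeStrength(tri)), rep(2, 3))
    w <- matrix(0, 3, 3); w[1, 2] <- 3; w[1, 3] <- 2; w <- w + t(w)
    expect_equal(scalarValues(nodeStrength(networkFromWeights(w)))[1], 5)
})

test_that("clustering coefficient matches the closed cases and the triple-loop oracle", {
    expect_equal(scalarValues(clusteringCoefficient(completeNetwork(4L))), rep(1, 4))
    expect_equal(scalarValues(clusteringCoefficient(starNetwork(4L))), rep(0, 5))
    # 5-node kite: clique of 4 plus a tail
    w <- matrix(0, 5, 5)
    w[1:4, 1:4] <- 1; diag(w) <- 0; w[4, 5] <- 1; w[5, 4] <- 1
    kite <- networkFromWeights(w)
    for (variant in c("binary", "weighted"))
        expect_equal(scalarValues(clusteringCoefficient(kite, variant)),
                     oracleClustering(w, variant))
})

test_that("global efficiency matches analytic values and Floyd-Warshall oracle", {
    expect_equal(globalEfficiency(completeNetwork(5L)), 1)
    expect_equal(globalEfficiency(networkFromWeights(matrix(0, 4, 4))), 0)
    expect_equal(globalEfficiency(pathNetwork(3L), "binary"), 5 / 6)
    for (seed in 1:10) {
        net <- randomWeightedNetwork(sample(3:12, 1), p = 0.4, seed = seed)
        for (variant in c("binary", "weighted"))
            expect_equal(globalEfficiency(net, variant),
                         oracleEfficiency(net@weights, variant))
    }
})

test_that("local efficiency is the neighbor-subgraph efficiency", {
    expect_equal(scalarValues(localEfficiency(completeNetwork(4L))), rep(1, 4))
    expect_equal(scalarValues(localEfficiency(starNetwork(4L))), rep(0, 5))
    net <- randomWeightedNetwork(8L, p = 0.5, seed = 11L)
    w <- net@weights
    for (variant in c("binary", "weighted")) {
        expected <- vapply(seq_len(8L), function(i) {
            nb <- which(w[i, ] > 0)
            if (length(nb) < 2) return(0)
            oracleEfficiency(w[nb, nb, drop = FALSE], variant)
        }, 0)
        expect_equal(scalarValues(localEfficiency(net, variant)), expected)
    }
})

test_that("betweenness matches hand counts and igraph on weighted graphs", {
    expect_equal(scalarValues(betweennessCentrality(pathNetwork(3L))), c(0, 1, 0))
    expect_equal(scalarValues(betweennessCentrality(starNetwork(4L))),
                 c(6, 0, 0, 0, 0))
    expect_equal(scalarValues(betweennessCentrality(completeNetwork(5L))), rep(0, 5))
    for (seed in 1:15) {
        net <- randomWeightedNetwork(sample(4:12, 1), p = 0.5, seed = seed)
        g <- igraphFromNetwork(net)
        expect_equal(scalarValues(betweennessCentrality(net, "weighted")),
                     unname(igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)),
                     tolerance = 1e-10)
        expect_equal(scalarValues(betweennessCentrality(net, "binary")),
                     unname(igraph::betweenness(g, weights = rep(1, igraph::ecount(g)))),
                     tolerance = 1e-10)
    }
})

test_that("eigenvector centrality has max 1, matches dense eigensolver, handles bipartite stars", {
    cyc <- pathNetwork(6L)@weights; cyc[1, 6] <- 1; cyc[6, 1] <- 1
    expect_equal(scalarValues(eigenvectorCentrality(networkFromWeights(cyc))),
                 rep(1, 6))
    star <- starNetwork(4L)
    vs <- scalarValues(eigenvectorCentrality(star))
    expect_equal(which.max(vs), 1L)
    expect_true(all(vs[2:5] < vs[1]))
    for (seed in 1:10) {
        net <- randomWeightedNetwork(sample(4:12, 1), p = 0.7, seed = seed + 100)
        comp <- table(ConnectomeView:::graphComponents(net@weights))
        ev <- eigen(net@weights, symmetric = TRUE)
        ref <- abs(ev$vectors[, which.max(ev$values)])
        got <- suppressWarnings(scalarValues(eigenvectorCentrality(net)))
        if (length(comp) == 1L)
            expect_equal(got, ref / max(ref), tolerance = 1e-6)
    }
})

test_that("disconnected networks get centrality on the largest component only", {
    net <- twinCliques(3L)  # two equal components: first kept by index
    expect_warning(vs <- scalarValues(eigenvectorCentrality(net)), "disconnected")
    expect_equal(vs, c(1, 1, 1, 0, 0, 0))
})

test_that("modularity matches identities and the double-sum oracle", {
    for (seed in 1:10) {
        net <- randomWeightedNetwork(sample(3:12, 1), p = 0.6, seed = seed)
        if (sum(net@weights) == 0) next
        n <- nNodes(net)
        expect_equal(modularityQ(net, rep(1L, n)), 0, tolerance = 1e-14)
        set.seed(seed)
        assign <- sample(1:3, n, replace = TRUE)
        expect_equal(modularityQ(net, assign), oracleQ(net@weights, assign))
    }
    # two disconnected triangles split by component: Q = 1/2
    tt <- twinCliques(3L)
    expect_equal(modularityQ(tt, rep(1:2, each = 3)), 0.5)
    expect_error(modularityQ(networkFromWeights(matrix(0, 3, 3)), rep(1L, 3)),
                 class = "cvComputationError")
    neg <- matrix(0, 2, 2); neg[1, 2] <- -1; neg <- neg + t(neg)
    expect_error(modularityQ(networkFromWeights(neg), c(1L, 1L)),
                 class = "cvComputationError")
})

test_that("spectral module detection recovers exact community structure", {
    # twin 5-cliques: must return exactly the two cliques, matching the
    # exhaustive bipartition search
    tc <- twinCliques(5L)
    part <- detectModules(tc)
    expect_equal(max(part@assignment), 2L)
    expect_equal(part@assignment, rep(1:2, each = 5))
    best <- oracleBestBipartition(tc@weights)
    expect_equal(part@Q, best$Q)
    # complete graph: indivisible
    partK <- detectModules(completeNetwork(6L))
    expect_equal(max(partK@assignment), 1L)
    expect_equal(partK@Q, 0)
    expect_error(detectModules(networkFromWeights(matrix(0, 3, 3))),
                 class = "cvComputationError")
})

test_that("detected modularity is never below the trivial partition", {
    for (seed in 1:25) {
        net <- randomWeightedNetwork(sample(4:20, 1), p = 0.3, seed = seed + 40)
        if (sum(net@weights) == 0) next
        part <- detectModules(net, seed = seed)
        expect_gte(part@Q, 0)
        expect_equal(part@Q, modularityQ(net, part@assignment))
    }
})

test_that("nodal metrics are permutation equivariant; globals invariant", {
    net <- randomWeightedNetwork(10L, p = 0.5, seed = 5L)
    set.seed(6); perm <- sample(10L)
    wp <- net@weights[perm, perm]
    netp <- bindMatrix(wp, Ordering(orderingNames(net)[perm]))
    for (f in list(nodeStrength,
                   function(x) clusteringCoefficient(x, "weighted"),
                   function(x) localEfficiency(x, "weighted"),
                   function(x) betweennessCentrality(x, "weighted")))
        expect_equal(scalarValues(f(netp)), scalarValues(f(net))[perm])
    expect_equal(globalEfficiency(netp), globalEfficiency(net))
    assign <- rep(1:2, each = 5)
    expect_equal(modularityQ(netp, assign[perm]), modularityQ(net, assign))
})

test_that("weighted metrics reduce to binary ones on unit weights", {
    net <- randomWeightedNetwork(9L, p = 0.5, seed = 13L, weights = "unit")
    expect_equal(scalarValues(clusteringCoefficient(net, "weighted")),
                 scalarValues(clusteringCoefficient(net, "binary")))
    expect_equal(globalEfficiency(net, "weighted"),
                 globalEfficiency(net, "binary"))
    expect_equal(scalarValues(betweennessCentrality(net, "weighted")),
                 scalarValues(betweennessCentrality(net, "binary")))
})

test_that("computeAllStats bundles consistent metrics and records failures", {
    tri <- completeNetwork(3L)
    rep1 <- computeAllStats(tri)
    expect_equal(scalarValues(rep1@nodal$strength), rep(2, 3))
    expect_equal(scalarValues(rep1@nodal$clustering_binary), rep(1, 3))
    expect_equal(rep1@global$Q, 0)
    net <- smallScene(6L)@network
    rep2 <- computeAllStats(net, seed = 2L)
    expect_equal(scalarValues(rep2@nodal$strength),
                 scalarValues(nodeStrength(net)))
    expect_equal(rep2@global$global_efficiency_weighted,
                 globalEfficiency(net, "weighted"))
    expect_equal(rep2@global$Q, detectModules(net, seed = 2L)@Q)
    # edgeless network: strengths still produced, modularity recorded missing
    empty <- networkFromWeights(matrix(0, 4, 4))
    rep3 <- computeAllStats(empty)
    expect_equal(scalarValues(rep3@nodal$strength), rep(0, 4))
    expect_equal(rep3@global$global_efficiency_binary, 0)
    expect_true("modularity" %in% names(rep3@errors))
    expect_false("Q" %in% names(rep3@global))
})

test_that("stats reports serialize to per-metric files plus a JSON summary", {
    net <- randomWeightedNetwork(7L, p = 0.6, seed = 21L)
    rep <- computeAllStats(net)
    d <- withr::local_tempdir()
    paths <- writeStatsReport(rep, d)
    expect_true(file.exists(file.path(d, "strength.txt")))
    back <- readScalars(file.path(d, "strength.txt"), n = 7L)
    expect_equal(scalarValues(back), scalarValues(rep@nodal$strength),
                 tolerance = 1e-12)
    summ <- jsonlite::read_json(file.path(d, "global_summary.json"))
    expect_equal(summ$global$Q, rep@global$Q, tolerance = 1e-12)
})
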