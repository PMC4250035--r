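test_that("ordering files read names in order, skipping blanks and comments", {
    f <- withr::local_tempfile(lines = c("lh_precentral", "rh_precentral",
                                         "", "# comment", "Left-Hippocampus",
                                         ""))
    o <- readOrdering(f)
    expect_identical(orderingNames(o),
                     c("lh_precentral", "rh_precentral", "Left-Hippocampus"))

    f2 <- withr::local_tempfile(lines = c("  a  ", "b", ""))
    expect_identical(orderingNames(readOrdering(f2)), c("a", "b"))
})

test_that("empty and duplicate ordering files are rejected with clear errors", {
    f <- withr::local_tempfile(lines = c("", "  "))
    expect_error(readOrdering(f), class = "cvFormatError")
    f2 <- withr::local_tempfile(lines = c("a", "b", "a"))
    err <- expect_error(readOrdering(f2), class = "cvValidationError")
    expect_match(conditionMessage(err), "a")
    expect_error(readOrdering(tempfile()), class = "cvInputError")
})

test_that("bindMatrix attaches ordering, zeroes diagonal, checks dimensions", {
    w <- matrix(c(0, 1, 2, 1, 5, 3, 2, 3, 0), 3, 3)
    net <- bindMatrix(w, Ordering(c("a", "b", "c")))
    expect_equal(diag(net@weights), rep(0, 3))
    expect_equal(net@weights[1, 2], 1)
    err <- expect_error(bindMatrix(matrix(0, 3, 3), Ordering(letters[1:4])),
                        class = "cvValidationError")
    expect_match(conditionMessage(err), "3")
    expect_match(conditionMessage(err), "4")
    expect_error(bindMatrix(matrix(0, 2, 3), Ordering(c("a", "b"))),
                 class = "cvValidationError")
})

test_that("asymmetric input symmetrizes to (A + t(A))/2 only when allowed", {
    a <- matrix(c(0, 0, 2, 0), 2, 2)   # w(1,2) = 2 one-way
    expect_warning(net <- bindMatrix(a, Ordering(c("a", "b")),
                                     symmetrize = TRUE), "symmetrized")
    expect_equal(net@weights, matrix(c(0, 1, 1, 0), 2, 2))
    err <- expect_error(bindMatrix(a, Ordering(c("a", "b"))),
                        class = "cvValidationError")
    expect_match(conditionMessage(err), "2")  # reports max |A - t(A)|
})

test_that("count threshold keeps the strongest edges with deterministic ties", {
    w <- matrix(0, 4, 4)
    w[1, 2] <- 3; w[1, 3] <- 2; w[2, 3] <- 1; w[3, 4] <- 0.5
    w <- w + t(w)
    es <- thresholdEdges(networkFromWeights(w), thresholdSpec(k = 2))
    expect_equal(edgeTable(es),
                 data.frame(i = c(1L, 1L), j = c(2L, 3L), w = c(3, 2)))
    # more requested than available
    expect_equal(nEdges(thresholdEdges(networkFromWeights(w),
                                       thresholdSpec(k = 500))), 4L)
    # ties broken by ascending (i, j)
    wt <- matrix(0, 3, 3); wt[1, 2] <- 1; wt[1, 3] <- 1; wt[2, 3] <- 1
    wt <- wt + t(wt)
    es2 <- thresholdEdges(networkFromWeights(wt), thresholdSpec(k = 2))
    expect_equal(edgeTable(es2)[, c("i", "j")],
                 data.frame(i = c(1L, 1L), j = c(2L, 3L)))
})

test_that("threshold agrees with the full-sort oracle and is idempotent", {
    for (seed in 1:20) {
        n <- sample(4:30, 1)
        net <- randomWeightedNetwork(n, p = 0.4, seed = seed)
        k <- sample(1:40, 1)
        es <- thresholdEdges(net, thresholdSpec(k = k))
        oracle <- oracleTopEdges(net@weights, k)
        expect_equal(unname(as.matrix(edgeTable(es))), unname(oracle))
        # idempotence: rebuild a network holding exactly these edges
        w2 <- matrix(0, n, n)
        e <- edgeTable(es)
        for (r in seq_len(nrow(e))) {
            w2[e$i[r], e$j[r]] <- e$w[r]; w2[e$j[r], e$i[r]] <- e$w[r]
        }
        es2 <- thresholdEdges(networkFromWeights(w2),
                              thresholdSpec(k = nEdges(es)))
        expect_equal(edgeTable(es2), e)
    }
})

test_that("proportion, value and absolute-rank threshold modes behave", {
    w <- matrix(0, 4, 4)
    w[1, 2] <- -3; w[1, 3] <- 2; w[2, 3] <- 1; w[3, 4] <- 0.5
    w <- w + t(w)
    net <- networkFromWeights(w)
    # proportion: ceiling(p * E) of E = 4 nonzero edges
    expect_equal(nEdges(thresholdEdges(net, thresholdSpec("proportion", p = 0.5))), 2L)
    expect_equal(nEdges(thresholdEdges(net, thresholdSpec("proportion", p = 0.3))), 2L)
    # value: weight >= v
    ev <- thresholdEdges(net, thresholdSpec("value", v = 1))
    expect_setequal(edgeTable(ev)$w, c(2, 1))
    # signed ranking puts -3 last; absolute ranking first
    es <- thresholdEdges(net, thresholdSpec(k = 1))
    expect_equal(edgeTable(es)$w, 2)
    ea <- thresholdEdges(net, thresholdSpec(k = 1, rankBy = "absolute"))
    expect_equal(edgeTable(ea)$w, -3)
    # empty result is valid
    expect_equal(nEdges(thresholdEdges(networkFromWeights(matrix(0, 3, 3)))), 0L)
})

test_that("isolateNode returns exactly the incident edges", {
    star <- starNetwork(4L)
    es <- thresholdEdges(star)
    expect_equal(nEdges(isolateNode(star, es, 1L)), 4L)
    leaf <- isolateNode(star, es, "n3")
    expect_equal(nEdges(leaf), 1L)
    expect_true(all(c(leaf@edges$i, leaf@edges$j) %in% c(1L, 3L)))
    # isolated node: network with a node of degree 0
    w <- matrix(0, 3, 3); w[1, 2] <- 1; w <- w + t(w)
    net <- networkFromWeights(w)
    expect_equal(nEdges(isolateNode(net, thresholdEdges(net), 3L)), 0L)
    # unknown name errors with nearest matches
    err <- expect_error(isolateNode(star, es, "n99"), class = "cvInputError")
    expect_match(conditionMessage(err), "nearest matches")
})

test_that("isolation partitions the edge set: union over nodes covers each edge twice", {
    net <- randomWeightedNetwork(12L, p = 0.4, seed = 7L)
    es <- thresholdEdges(net, thresholdSpec(k = 20))
    counts <- integer(nEdges(es))
    key <- paste(es@edges$i, es@edges$j)
    for (v in seq_len(nNodes(net))) {
        sub <- isolateNode(net, es, v)
        expect_true(all(sub@edges$i == v | sub@edges$j == v))
        counts <- counts + key %in% paste(sub@edges$i, sub@edges$j)
    }
    expect_true(all(counts == 2L))
})

test_that("affine registration maps homogeneous coordinates correctly", {
    expect_equal(applyRegistration(matrix(1:9, 3, 3), affineRegistration(diag(4))),
                 matrix(1:9, 3, 3))
    tr <- diag(4); tr[1:3, 4] <- c(1, 2, 3)
    expect_equal(as.vector(applyRegistration(c(0, 0, 0), affineRegistration(tr))),
                 c(1, 2, 3))
    sc <- diag(c(2, 2, 2, 1))
    expect_equal(as.vector(applyRegistration(c(1, 1, 1), affineRegistration(sc))),
                 c(2, 2, 2))
})

test_that("registration round-trips through its inverse and rejects bad matrices", {
    set.seed(3)
    m <- diag(4)
    m[1:3, 1:3] <- matrix(rnorm(9), 3) + diag(3) * 2
    m[1:3, 4] <- rnorm(3)
    reg <- affineRegistration(m)
    pts <- matrix(rnorm(30), 10, 3)
    back <- applyRegistration(applyRegistration(pts, reg), invertRegistration(reg))
    expect_lt(max(abs(back - pts)), 1e-9)
    sing <- diag(4); sing[1, 1] <- 0
    expect_error(affineRegistration(sing), "invertible")
    bad <- diag(4); bad[4, 1] <- 1
    expect_error(affineRegistration(bad), "bottom row")
})

test_that("node matching canonicalizes case and hemisphere conventions", {
    parc <- coordinateParcellation(Ordering(c("LH_A", "rh_a", "lh_b")),
                                   matrix(0, 3, 3) + 1:3)
    expect_equal(matchNodes(Ordering(c("lh_a", "b-lh", "a-rh")), parc),
                 c(1L, 3L, 2L))
    expect_equal(matchNodes(Ordering("lh.a"), parc), 1L)
    err <- expect_error(matchNodes(Ordering(c("lh_a", "lh_zzz")), parc),
                        class = "cvValidationError")
    expect_match(conditionMessage(err), "lh_zzz")
})

test_that("constructed networks are symmetric within tolerance", {
    for (seed in 1:10) {
        net <- randomWeightedNetwork(sample(3:20, 1), seed = seed)
        expect_lte(max(abs(net@weights - t(net@weights))), 1e-8)
    }
})
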