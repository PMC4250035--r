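# Independent brute-force oracles used to check the package's statistics.
# These deliberately use the most direct (slow) formulation of each
# quantity; they share no code with the implementation under test.

randomWeightedNetwork <- function(n, p = 0.5, seed = 1L, weights = "runif") {
    set.seed(seed)
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w), arr.ind = TRUE)
    on <- stats::runif(nrow(ut)) < p
    w[ut[on, , drop = FALSE]] <- if (weights == "unit") 1 else
        stats::runif(sum(on), 0.1, 2)
    w <- w + t(w)
    bindMatrix(w, Ordering(paste0("n", seq_len(n))))
}

# all-pairs shortest distances by Floyd-Warshall over lengths 1/w (or 1)
oracleDistances <- function(w, variant = "weighted") {
    n <- nrow(w)
    d <- matrix(Inf, n, n)
    pos <- w > 0
    d[pos] <- if (variant == "binary") 1 else 1 / w[pos]
    diag(d) <- 0
    for (k in seq_len(n))
        for (i in seq_len(n))
            for (j in seq_len(n))
                if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    d
}

oracleEfficiency <- function(w, variant = "weighted") {
    d <- oracleDistances(w, variant)
    n <- nrow(d)
    if (n < 2) return(0)
    inv <- 1 / d
    diag(inv) <- 0
    sum(inv[is.finite(inv)]) / (n * (n - 1))
}

# clustering by exhaustive loop over vertex triples
oracleClustering <- function(w, variant = "binary") {
    n <- nrow(w)
    a <- (w != 0) * 1
    wh <- if (variant == "binary") a else (abs(w) / max(abs(w)))^(1 / 3)
    k <- rowSums(a)
    out <- numeric(n)
    for (i in seq_len(n)) {
        if (k[i] < 2) next
        t_i <- 0
        for (j in seq_len(n)) for (h in seq_len(n)) {
            if (j == i || h == i || j >= h) next
            t_i <- t_i + wh[i, j] * wh[i, h] * wh[j, h]
        }
        out[i] <- 2 * t_i / (k[i] * (k[i] - 1))
    }
    out
}

# Newman-Girvan Q by the direct O(n^2) double sum
oracleQ <- function(w, assign) {
    m2 <- sum(w)
    s <- rowSums(w)
    q <- 0
    n <- nrow(w)
    for (i in seq_len(n)) for (j in seq_len(n))
        if (assign[i] == assign[j])
            q <- q + w[i, j] - s[i] * s[j] / m2
    q / m2
}

# full descending edge sort over all n(n-1)/2 pairs
oracleTopEdges <- function(w, k, rankBy = "signed") {
    n <- nrow(w)
    rows <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        if (w[i, j] != 0) rows <- rbind(rows, c(i, j, w[i, j]))
    if (is.null(rows)) return(rows)
    key <- if (rankBy == "absolute") abs(rows[, 3]) else rows[, 3]
    rows <- rows[order(-key, rows[, 1], rows[, 2]), , drop = FALSE]
    rows[seq_len(min(k, nrow(rows))), , drop = FALSE]
}

# exhaustive search over all bipartitions maximizing Q
oracleBestBipartition <- function(w) {
    n <- nrow(w)
    best <- list(Q = -Inf, assign = rep(1L, n))
    for (code in 0:(2^(n - 1) - 1)) {
        assign <- c(1L, 1L + as.integer(intToBits(code))[seq_len(n - 1)])
        q <- oracleQ(w, assign)
        if (q > best$Q) best <- list(Q = q, assign = assign)
    }
    best
}

igraphFromNetwork <- function(network) {
    igraph::graph_from_adjacency_matrix(networkWeights(network),
                                        mode = "undirected", weighted = TRUE,
                                        diag = FALSE)
}
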