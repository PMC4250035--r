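# Nodal and global network statistics, and the spectral modular
# decomposition.  Formulas are the standard forms from the complex-networks
# literature: Watts-Strogatz clustering (Onnela geometric-mean form for
# weighted graphs), Latora-Marchiori efficiency with edge lengths 1/w,
# Brandes betweenness accumulation, Bonacich eigenvector centrality by power
# iteration, Newman-Girvan modularity, and Newman's leading-eigenvector
# bisection with a Kernighan-Lin-style single-node fine-tuning pass.
#
# Negative weights are rejected by the distance-based and modularity
# operations: path lengths 1/w and the null model are undefined for signed
# weights.  Threshold or take absolute values first.

requireNonNegative <- function(w, what) {
    if (any(w < 0))
        cvStop("cvComputationError",
               "%s is undefined for negative weights; threshold the network or take absolute values first",
               what)
}

#' Node strength (weighted degree)
#'
#' The sum of each node's connection weights (diagonal excluded).  For a
#' binary network this is the degree.
#'
#' @param network an [AdjacencyNetwork].
#' @return a [NodeScalar] named "strength".
#' @export
nodeStrength <- function(network)
    nodeScalar(rowSums(network@weights), "strength")

binarize <- function(w) (w != 0) * 1

#' Clustering coefficient
#'
#' Binary variant: Watts-Strogatz \eqn{C_i = 2 t_i / (k_i (k_i - 1))} with
#' \eqn{t_i} the number of triangles through node i, on the graph binarized
#' at weight > 0.  Weighted variant: Onnela's geometric-mean form, where each
#' triangle contributes the cube root of the product of its three weights
#' normalized by the maximum weight.  Nodes with degree < 2 get 0.
#'
#' @param network an [AdjacencyNetwork].
#' @param variant "binary" or "weighted".
#' @return a [NodeScalar].
#' @export
clusteringCoefficient <- function(network, variant = c("binary", "weighted")) {
    variant <- match.arg(variant)
    w <- abs(network@weights)
    a <- binarize(w)
    k <- rowSums(a)
    wh <- if (variant == "binary") a else (w / max(w, 1e-300))^(1 / 3)
    t3 <- diag(wh %*% wh %*% wh) / 2   # triangle intensity through each node
    denom <- k * (k - 1)
    c_i <- ifelse(denom > 0, 2 * t3 / denom, 0)
    nodeScalar(c_i, paste0("clustering_", variant))
}

# All-pairs shortest-path distances.  Edge lengths are 1 (binary) or 1/w
# (weighted, positive weights).  Dijkstra per source; n is small enough that
# the O(n^2) extraction is fine.
shortestDistances <- function(w, variant) {
    n <- nrow(w)
    len <- matrix(Inf, n, n)
    pos <- w > 0
    len[pos] <- if (variant == "binary") 1 else 1 / w[pos]
    d <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        dist <- rep(Inf, n); dist[s] <- 0
        done <- rep(FALSE, n)
        for (it in seq_len(n)) {
            cand <- ifelse(done, Inf, dist)
            u <- which.min(cand)
            if (!is.finite(cand[u])) break
            done[u] <- TRUE
            relax <- dist[u] + len[u, ]
            better <- !done & relax < dist
            dist[better] <- relax[better]
        }
        d[s, ] <- dist
    }
    diag(d) <- 0
    d
}

efficiencyFromDistances <- function(d) {
    n <- nrow(d)
    if (n < 2L) return(0)
    inv <- 1 / d
    diag(inv) <- 0
    sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean over node pairs of the inverse shortest-path distance, with
#' \eqn{1/\infty = 0} for disconnected pairs.  Weighted edge lengths are
#' 1/w; shortest paths by Dijkstra (weighted) or BFS (binary).
#'
#' @param network an [AdjacencyNetwork].
#' @param variant "binary" or "weighted".
#' @return a single numeric value in [0, 1] for binary graphs.
#' @export
globalEfficiency <- function(network, variant = c("binary", "weighted")) {
    variant <- match.arg(variant)
    requireNonNegative(network@weights, "efficiency")
    efficiencyFromDistances(shortestDistances(network@weights, variant))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbors; nodes with fewer than 2 neighbors get 0.
#'
#' @param network an [AdjacencyNetwork].
#' @param variant "binary" or "weighted".
#' @return a [NodeScalar].
#' @export
localEfficiency <- function(network, variant = c("binary", "weighted")) {
    variant <- match.arg(variant)
    w <- network@weights
    requireNonNegative(w, "efficiency")
    n <- nrow(w)
    out <- numeric(n)
    for (i in seq_len(n)) {
        nb <- which(w[i, ] > 0)
        if (length(nb) < 2L) next
        out[i] <- efficiencyFromDistances(
            shortestDistances(w[nb, nb, drop = FALSE], variant))
    }
    nodeScalar(out, paste0("local_efficiency_", variant))
}

#' Betweenness centrality (Brandes accumulation)
#'
#' Unnormalized pair-dependency betweenness: the number of shortest paths
#' between other node pairs passing through each node, counted fractionally
#' when geodesics tie.  Endpoints are excluded.  Weighted paths use edge
#' lengths 1/w.
#'
#' @param network an [AdjacencyNetwork].
#' @param variant "binary" or "weighted".
#' @return a [NodeScalar].
#' @export
betweennessCentrality <- function(network, variant = c("binary", "weighted")) {
    variant <- match.arg(variant)
    w <- network@weights
    requireNonNegative(w, "betweenness")
    n <- nrow(w)
    len <- matrix(Inf, n, n)
    pos <- w > 0
    len[pos] <- if (variant == "binary") 1 else 1 / w[pos]
    bc <- numeric(n)
    tol <- 1e-12
    for (s in seq_len(n)) {
        dist <- rep(Inf, n); dist[s] <- 0
        sigma <- numeric(n); sigma[s] <- 1
        done <- rep(FALSE, n)
        order_popped <- integer(0)
        preds <- vector("list", n)
        for (it in seq_len(n)) {
            cand <- ifelse(done, Inf, dist)
            u <- which.min(cand)
            if (!is.finite(cand[u])) break
            done[u] <- TRUE
            order_popped <- c(order_popped, u)
            for (v in which(is.finite(len[u, ]))) {
                if (done[v]) next
                alt <- dist[u] + len[u, v]
                if (alt < dist[v] - tol) {
                    dist[v] <- alt
                    sigma[v] <- sigma[u]
                    preds[[v]] <- u
                } else if (abs(alt - dist[v]) <= tol) {
                    sigma[v] <- sigma[v] + sigma[u]
                    preds[[v]] <- c(preds[[v]], u)
                }
            }
        }
        delta <- numeric(n)
        for (v in rev(order_popped)) {
            for (u in preds[[v]])
                delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
            if (v != s) bc[v] <- bc[v] + delta[v]
        }
    }
    nodeScalar(bc / 2, "betweenness")  # each unordered pair counted once
}

# connected components of the positive-weight graph
graphComponents <- function(w) {
    n <- nrow(w)
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (comp[s] != 0L) next
        cur <- cur + 1L
        queue <- s; comp[s] <- cur
        while (length(queue) > 0L) {
            u <- queue[1L]; queue <- queue[-1L]
            nb <- which(w[u, ] != 0 & comp == 0L)
            comp[nb] <- cur
            queue <- c(queue, nb)
        }
    }
    comp
}

#' Eigenvector centrality (Bonacich)
#'
#' The principal eigenvector of the weight matrix, computed by power
#' iteration to tolerance 1e-10 and normalized to unit maximum.  On a
#' disconnected network the centrality is computed on the largest component
#' (ties broken by lowest node index) with zeros elsewhere and a warning.
#'
#' @param network an [AdjacencyNetwork].
#' @return a [NodeScalar], non-negative with maximum 1.
#' @export
eigenvectorCentrality <- function(network) {
    w <- network@weights
    requireNonNegative(w, "eigenvector centrality")
    n <- nrow(w)
    comp <- graphComponents(w)
    sizes <- tabulate(comp)
    keep <- which(comp == which.max(sizes))
    if (length(keep) < n)
        cvWarn("network is disconnected; eigenvector centrality computed on the largest component (%d of %d nodes), zeros elsewhere",
               length(keep), n)
    out <- numeric(n)
    ws <- w[keep, keep, drop = FALSE]
    if (length(keep) == 1L || sum(ws) == 0) {
        out[keep] <- 1
        return(nodeScalar(out, "eigenvector"))
    }
    # shifted iteration (W + cI): same eigenvectors, but the dominant
    # eigenvalue is strictly separated even on bipartite graphs
    shift <- max(rowSums(ws))
    x <- rep(1, length(keep))
    for (it in seq_len(100000L)) {
        xn <- as.vector(ws %*% x) + shift * x
        xn <- xn / max(xn)
        if (max(abs(xn - x)) < 1e-10) { x <- xn; break }
        x <- xn
    }
    out[keep] <- x
    nodeScalar(out, "eigenvector")
}

#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(W_{ij} - \frac{s_i s_j}{2m}\right)
#'   \delta(c_i, c_j)}
#' where \eqn{s} is node strength and \eqn{2m = \sum_{ij} W_{ij}}.  The
#' all-in-one-module partition has Q = 0 exactly.
#'
#' @param network an [AdjacencyNetwork] with positive total weight.
#' @param partition a [ModulePartition] or an integer membership vector.
#' @return a single numeric Q.
#' @export
modularityQ <- function(network, partition) {
    w <- network@weights
    requireNonNegative(w, "modularity")
    assign <- if (is(partition, "ModulePartition")) partition@assignment
              else as.integer(partition)
    if (length(assign) != nrow(w))
        cvStop("cvValidationError", "partition covers %d nodes, network has %d",
               length(assign), nrow(w))
    m2 <- sum(w)
    if (m2 <= 0)
        cvStop("cvComputationError",
               "modularity undefined for a network with zero total weight")
    s <- rowSums(w)
    q <- 0
    for (g in unique(assign)) {
        idx <- assign == g
        q <- q + sum(w[idx, idx]) - sum(s[idx])^2 / m2
    }
    q / m2
}

# modularity matrix restricted to a group, with the generalized diagonal
# correction B(g)_ij = B_ij - delta_ij * sum_{k in g} B_ik
generalizedB <- function(B, g) {
    Bg <- B[g, g, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    Bg
}

# greedy single-node fine-tuning of a bisection sign vector: repeatedly flip
# the node whose switch most increases the split's Q contribution, until no
# flip improves it by more than 1e-12.  Scan order and tie-break are the
# ascending node index, so the pass is deterministic.
fineTuneBisection <- function(Bg, s) {
    repeat {
        gain <- -2 * s * as.vector(Bg %*% s) + 2 * diag(Bg)
        best <- which.max(gain)
        if (gain[best] <= 1e-12) break
        s[best] <- -s[best]
    }
    s
}

#' Detect modules by spectral modularity maximization with fine-tuning
#'
#' Recursive leading-eigenvector bisection of the modularity matrix
#' \eqn{B_{ij} = W_{ij} - s_i s_j / 2m} (generalized \eqn{B(g)} for
#' subdivisions): each group is split by the sign of the leading eigenvector
#' of its generalized modularity matrix, a Kernighan-Lin-style fine-tuning
#' pass then repeatedly moves the single node whose switch most increases Q
#' until no move helps, and recursion stops when a split's Q contribution is
#' at most 1e-10 or the group is indivisible.  The resulting Q is never below
#' the single-module partition's Q of 0.
#'
#' The algorithm is deterministic; \code{seed} only breaks ties when the
#' leading eigenvalue is degenerate (the eigenvector is then drawn from the
#' degenerate subspace with a seeded RNG).
#'
#' @param network an [AdjacencyNetwork] with positive total weight.
#' @param seed integer seed for degenerate-eigenvalue tie-breaking.
#' @return a [ModulePartition].
#' @export
detectModules <- function(network, seed = 1L) {
    w <- network@weights
    requireNonNegative(w, "module detection")
    m2 <- sum(w)
    if (m2 <= 0)
        cvStop("cvComputationError",
               "module detection undefined for a network with zero total weight")
    n <- nrow(w)
    s <- rowSums(w)
    B <- w - outer(s, s) / m2
    final <- list()
    stack <- list(seq_len(n))
    while (length(stack) > 0L) {
        g <- stack[[1L]]; stack <- stack[-1L]
        if (length(g) < 2L) { final <- c(final, list(g)); next }
        Bg <- generalizedB(B, g)
        eg <- eigen(Bg, symmetric = TRUE)
        lead <- eg$values[1L]
        if (lead <= 1e-10) { final <- c(final, list(g)); next }
        v <- eg$vectors[, 1L]
        degenerate <- sum(eg$values > lead - 1e-10) > 1L
        if (degenerate) {
            sub <- eg$vectors[, eg$values > lead - 1e-10, drop = FALSE]
            set.seed(seed)
            mix <- stats::rnorm(ncol(sub))
            v <- as.vector(sub %*% (mix / sqrt(sum(mix^2))))
        }
        sv <- ifelse(v >= 0, 1, -1)
        sv <- fineTuneBisection(Bg, sv)
        if (all(sv == sv[1L])) { final <- c(final, list(g)); next }
        dQ <- as.vector(sv %*% Bg %*% sv) / (2 * m2)
        if (dQ <= 1e-10) { final <- c(final, list(g)); next }
        stack <- c(list(g[sv > 0], g[sv < 0]), stack)
    }
    # number modules by their first node index
    firsts <- vapply(final, min, 0L)
    final <- final[order(firsts)]
    assign <- integer(n)
    for (k in seq_along(final)) assign[final[[k]]] <- k
    new("ModulePartition", assignment = assign,
        Q = modularityQ(network, assign))
}

#' Compute every native statistic for a network
#'
#' Runs each metric once and bundles the results into a [StatsReport]
#' aligned to the network's ordering.  Metrics whose preconditions fail
#' (e.g. modularity on an edgeless network) are recorded as missing, with
#' the error message kept under the metric's name.
#'
#' @param network an [AdjacencyNetwork].
#' @param seed seed forwarded to [detectModules()].
#' @return a [StatsReport].
#' @export
computeAllStats <- function(network, seed = 1L) {
    nodal <- list(); global <- list(); errors <- character(0)
    put <- function(name, expr) {
        r <- tryCatch(expr, error = function(e) e)
        if (inherits(r, "error")) {
            errors[[name]] <<- conditionMessage(r)
            return(NULL)
        }
        r
    }
    nodal$strength <- put("strength", nodeStrength(network))
    nodal$clustering_binary <-
        put("clustering_binary", clusteringCoefficient(network, "binary"))
    nodal$clustering_weighted <-
        put("clustering_weighted", clusteringCoefficient(network, "weighted"))
    nodal$local_efficiency <-
        put("local_efficiency", localEfficiency(network, "weighted"))
    nodal$betweenness <-
        put("betweenness", betweennessCentrality(network, "weighted"))
    nodal$eigenvector <- put("eigenvector",
                             suppressWarnings(eigenvectorCentrality(network)))
    global$global_efficiency_binary <-
        put("global_efficiency_binary", globalEfficiency(network, "binary"))
    global$global_efficiency_weighted <-
        put("global_efficiency_weighted", globalEfficiency(network, "weighted"))
    cb <- nodal$clustering_binary
    if (!is.null(cb)) global$mean_clustering <- mean(cb@values)
    part <- put("modularity", detectModules(network, seed = seed))
    if (!is.null(part)) {
        global$Q <- part@Q
        nodal$module <- nodeScalar(as.numeric(part@assignment), "module")
    }
    nodal <- Filter(Negate(is.null), nodal)
    global <- Filter(Negate(is.null), global)
    new("StatsReport", nodal = nodal, global = global,
        ordering = network@ordering, errors = unlist(errors) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a StatsReport to disk
#'
#' One matrix file per nodal metric (via [writeScalars()]) plus a JSON
#' summary of the global scalars (and any per-metric errors).
#'
#' @param report a [StatsReport].
#' @param dir output directory (created if needed).
#' @param format scalar file format ("text", "mat" or "npy").
#' @return invisibly, the paths written.
#' @export
writeStatsReport <- function(report, dir, format = "text") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ext <- switch(format, text = "txt", mat = "mat", npy = "npy")
    paths <- character(0)
    for (nm in names(report@nodal)) {
        p <- file.path(dir, paste0(nm, ".", ext))
        writeScalars(report@nodal[[nm]], p, format)
        paths <- c(paths, p)
    }
    summary <- list(global = report@global,
                    errors = as.list(report@errors))
    sp <- file.path(dir, "global_summary.json")
    jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA)
    invisible(c(paths, sp))
}

setMethod("show", "StatsReport", function(object) {
    cat(sprintf("StatsReport over %d nodes\n  nodal: %s\n  global: %s\n",
                length(object@ordering@names),
                paste(names(object@nodal), collapse = ", "),
                paste(sprintf("%s=%.4f", names(object@global),
                              unlist(object@global)), collapse = ", ")))
    if (length(object@errors) > 0L)
        cat(sprintf("  failed: %s\n", paste(names(object@errors), collapse = ", ")))
})
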