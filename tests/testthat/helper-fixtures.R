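# Small shared fixtures built in code at test time.

smallSpec <- function(n = 6L, ...) fixtureSpec(nNodesPerHemisphere = n, ...)

# cached toy brain (generation is deterministic, so sharing is safe)
.toyCache <- new.env(parent = emptyenv())
smallToy <- function(n = 6L) {
    key <- as.character(n)
    if (is.null(.toyCache[[key]]))
        .toyCache[[key]] <- makeToyBrain(smallSpec(n))
    .toyCache[[key]]
}

networkFromWeights <- function(w) {
    bindMatrix(w, Ordering(paste0("n", seq_len(nrow(w)))))
}

completeNetwork <- function(n) {
    w <- matrix(1, n, n); diag(w) <- 0
    networkFromWeights(w)
}

starNetwork <- function(leaves) {
    n <- leaves + 1L
    w <- matrix(0, n, n)
    w[1, 2:n] <- 1; w[2:n, 1] <- 1
    networkFromWeights(w)
}

pathNetwork <- function(n) {
    w <- matrix(0, n, n)
    for (i in seq_len(n - 1)) { w[i, i + 1] <- 1; w[i + 1, i] <- 1 }
    networkFromWeights(w)
}

# two disconnected cliques of size k each
twinCliques <- function(k) {
    n <- 2L * k
    w <- matrix(0, n, n)
    w[seq_len(k), seq_len(k)] <- 1
    w[k + seq_len(k), k + seq_len(k)] <- 1
    diag(w) <- 0
    networkFromWeights(w)
}

smallScene <- function(n = 6L, imageSize = 140L, ...) {
    toy <- smallToy(n)
    net <- makeModularNetwork(smallSpec(n, nModules = 2L), toy$ordering)$network
    makeScene(net, toy$parcellation,
              style = viewStyle(imageSize = c(imageSize, imageSize)), ...)
}
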