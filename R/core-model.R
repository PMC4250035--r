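#' Construct an Ordering from names
#' @param names character vector of ROI names.
#' @return an [Ordering].
#' @export
Ordering <- function(names) new("Ordering", names = as.character(names))

#' Read an ordering file
#'
#' Ordering files are UTF-8 plain text with one ROI name per line; the region
#' on line 1 labels row/column 1 of the adjacency matrix, and so on.  Blank
#' lines and lines starting with \code{#} are skipped; surrounding whitespace
#' is stripped.
#'
#' @param path path to the ordering file.
#' @return an [Ordering].
#' @export
readOrdering <- function(path) {
    if (!file.exists(path))
        cvStop("cvInputError", "ordering file does not exist: %s", path)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L)
        cvStop("cvFormatError",
               "ordering file '%s' contains no ROI names (empty file?)", path)
    dup <- unique(lines[duplicated(lines)])
    if (length(dup) > 0L)
        cvStop("cvValidationError",
               "duplicate ROI name(s) in ordering file '%s': %s",
               path, paste(dup, collapse = ", "))
    Ordering(lines)
}

#' Names of an ordering (accessor)
#' @param x an [Ordering], [AdjacencyNetwork] or [Parcellation].
#' @return character vector of node names.
#' @export
orderingNames <- function(x) {
    if (is(x, "Ordering")) return(x@names)
    if (is(x, "AdjacencyNetwork")) return(x@ordering@names)
    if (is(x, "Parcellation")) return(x@nodes$name)
    stop("no ordering names for this object")
}

#' Number of nodes
#' @param x an [AdjacencyNetwork], [Ordering] or [Parcellation].
#' @return integer node count.
#' @export
nNodes <- function(x) length(orderingNames(x))

#' Weight matrix of a network (accessor)
#' @param x an [AdjacencyNetwork].
#' @return numeric matrix with node names as dimnames.
#' @export
networkWeights <- function(x) {
    w <- x@weights
    dimnames(w) <- list(x@ordering@names, x@ordering@names)
    w
}

#' Bind a weight matrix to an ordering, producing a network
#'
#' The first row and column of the matrix correspond to the region listed on
#' line 1 of the ordering, and so on.  The diagonal is always zeroed
#' (self-loops are undefined for these views).  Asymmetric input is either
#' rejected, or symmetrized as \code{(A + t(A))/2} with a warning when
#' \code{symmetrize = TRUE} — this preserves total weight and is
#' deterministic.
#'
#' @param weights square numeric matrix.
#' @param ordering an [Ordering] with \code{nrow(weights)} names.
#' @param symmetrize coerce asymmetric input by averaging with its transpose.
#' @return an [AdjacencyNetwork].
#' @export
bindMatrix <- function(weights, ordering, symmetrize = FALSE) {
    weights <- as.matrix(weights)
    if (nrow(weights) != ncol(weights))
        cvStop("cvValidationError", "matrix is not square: %d x %d",
               nrow(weights), ncol(weights))
    n <- length(ordering@names)
    if (nrow(weights) != n)
        cvStop("cvValidationError",
               "matrix dimension (%d) does not match ordering length (%d)",
               nrow(weights), n)
    asym <- max(abs(weights - t(weights)))
    if (asym > SYMMETRY_TOL) {
        if (!symmetrize) {
            idx <- which(abs(weights - t(weights)) == asym, arr.ind = TRUE)[1, ]
            cvStop("cvValidationError",
                   paste0("matrix is asymmetric (max |A - t(A)| = %g at row %d, ",
                          "col %d); pass symmetrize = TRUE to average with the ",
                          "transpose"), asym, idx[1], idx[2])
        }
        cvWarn("asymmetric matrix symmetrized as (A + t(A))/2 (max |A - t(A)| = %g)",
               asym)
        weights <- (weights + t(weights)) / 2
    }
    diag(weights) <- 0
    dimnames(weights) <- NULL
    new("AdjacencyNetwork", weights = weights, ordering = ordering)
}

#' Construct a threshold specification
#'
#' Default is the standard cutoff: keep the strongest 500 connections.
#'
#' @param mode "count", "proportion" or "value".
#' @param k edge count for count mode (default 500).
#' @param p fraction in (0, 1] for proportion mode.
#' @param v weight cutoff for value mode.
#' @param rankBy "signed" ranks by raw weight; "absolute" by magnitude.
#' @return a [ThresholdSpec].
#' @export
thresholdSpec <- function(mode = c("count", "proportion", "value"),
                          k = 500L, p = NA_real_, v = NA_real_,
                          rankBy = c("signed", "absolute")) {
    mode <- match.arg(mode)
    new("ThresholdSpec", mode = mode, k = as.integer(k), p = as.numeric(p),
        v = as.numeric(v), rankBy = match.arg(rankBy))
}

# all nonzero undirected edges (i < j) of a network, as a data.frame
allEdges <- function(network) {
    w <- network@weights
    n <- nrow(w)
    idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L)
        return(data.frame(i = integer(0), j = integer(0), w = numeric(0)))
    data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
               w = w[idx])
}

#' Construct an EdgeSet directly
#' @param edges data.frame with columns i, j, w (1-based, i < j).
#' @param sourceN node count of the originating network.
#' @return an [EdgeSet].
#' @export
EdgeSet <- function(edges, sourceN) {
    rownames(edges) <- NULL
    new("EdgeSet", edges = edges, sourceN = as.integer(sourceN))
}

#' Edge table of an EdgeSet (accessor)
#' @param x an [EdgeSet].
#' @return data.frame with columns i, j, w.
#' @export
edgeTable <- function(x) x@edges

#' Number of edges in an EdgeSet
#' @param x an [EdgeSet].
#' @return integer edge count.
#' @export
nEdges <- function(x) nrow(x@edges)

#' Threshold a network's connections for display
#'
#' Dense connectomes are not interpretable with every connection drawn, so by
#' default all but the strongest 500 connections are cut off; count,
#' proportion and absolute-value cutoffs remain under user control.  Ranking
#' is by descending weight (\code{rankBy = "signed"}) or descending magnitude
#' (\code{"absolute"}); ties are broken by ascending (i, j) lexicographic
#' order so the result — and any image rendered from it — is deterministic.
#'
#' @param network an [AdjacencyNetwork].
#' @param spec a [ThresholdSpec]; default keeps the top 500 edges.
#' @return an [EdgeSet].  Count mode returns exactly
#'   \code{min(k, E)} edges where E is the number of nonzero undirected
#'   edges; proportion mode the top \code{ceiling(p * E)}; value mode all
#'   edges with weight >= v.
#' @export
thresholdEdges <- function(network, spec = thresholdSpec()) {
    validObject(spec)
    e <- allEdges(network)
    if (nrow(e) == 0L) return(EdgeSet(e, nrow(network@weights)))
    key <- if (spec@rankBy == "absolute") abs(e$w) else e$w
    ord <- order(-key, e$i, e$j)
    e <- e[ord, , drop = FALSE]
    keep <- switch(spec@mode,
        count      = seq_len(min(spec@k, nrow(e))),
        proportion = seq_len(min(nrow(e), ceiling(spec@p * nrow(e)))),
        value      = which(e$w >= spec@v))
    EdgeSet(e[keep, , drop = FALSE], nrow(network@weights))
}

#' Resolve a node given by index or name against a network's ordering
#' @param network an [AdjacencyNetwork].
#' @param node integer index or character name.
#' @return integer node index.
#' @export
resolveNode <- function(network, node) {
    nm <- network@ordering@names
    if (is.numeric(node)) {
        node <- as.integer(node)
        if (node < 1L || node > length(nm))
            cvStop("cvInputError", "node index %d out of range 1..%d",
                   node, length(nm))
        return(node)
    }
    hit <- which(nm == node)
    if (length(hit) == 0L) {
        key <- canonicalNodeKey(node)
        hit <- which(canonicalNodeKey(nm) == key)
    }
    if (length(hit) == 1L) return(hit)
    if (length(hit) > 1L)
        cvStop("cvInputError", "node name '%s' is ambiguous: matches %s",
               node, paste(nm[hit], collapse = ", "))
    d <- utils::adist(tolower(node), tolower(nm))
    near <- nm[order(d)][seq_len(min(3L, length(nm)))]
    cvStop("cvInputError", "unknown node name '%s'; nearest matches: %s",
           node, paste(near, collapse = ", "))
}

#' Isolate the connections of a single node
#'
#' Mirrors the interactive click-to-isolate gesture: returns only the edges
#' of the active set that are incident to the given node.  The input EdgeSet
#' is not modified.
#'
#' @param network an [AdjacencyNetwork] (provides name resolution).
#' @param edges an [EdgeSet] over the same network.
#' @param node node index or name.
#' @return the incident subset, as an [EdgeSet].
#' @export
isolateNode <- function(network, edges, node) {
    v <- resolveNode(network, node)
    e <- edges@edges
    EdgeSet(e[e$i == v | e$j == v, , drop = FALSE], edges@sourceN)
}

#' Construct an affine registration from a 4x4 matrix
#' @param matrix 4x4 homogeneous transform (volume space to anatomical mm).
#' @return an [AffineRegistration].
#' @export
affineRegistration <- function(matrix) {
    matrix <- as.matrix(matrix)
    new("AffineRegistration", matrix = matrix)
}

#' Apply a 4x4 registration to mm coordinates
#'
#' Each coordinate row x is mapped to the first three components of
#' \code{R \%*\% c(x, 1)}.
#'
#' @param coords m x 3 numeric matrix of coordinates (or a length-3 vector).
#' @param reg an [AffineRegistration].
#' @return m x 3 matrix of transformed coordinates.
#' @export
applyRegistration <- function(coords, reg) {
    if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
    stopifnot(ncol(coords) == 3)
    if (any(!is.finite(coords))) cvStop("cvInputError", "coordinates must be finite")
    h <- cbind(coords, 1) %*% t(reg@matrix)
    h[, 1:3, drop = FALSE]
}

#' Invert an affine registration
#' @param reg an [AffineRegistration].
#' @return the inverse [AffineRegistration].
#' @export
invertRegistration <- function(reg) affineRegistration(solve(reg@matrix))

#' Match ordering names to parcellation nodes
#'
#' Exact name match is attempted first; remaining names are matched
#' case-insensitively after hemisphere-prefix/suffix canonicalization
#' ("lh_X", "X-lh", "lh.X" and "Left-X" all collapse to the same key, see
#' [canonicalNodeKey()]).  Every ordering name must resolve to exactly one
#' parcellation node.
#'
#' @param ordering an [Ordering].
#' @param parcellation a [Parcellation].
#' @return integer vector: for each ordering name, the matching row of
#'   \code{parcellation@nodes}.
#' @export
matchNodes <- function(ordering, parcellation) {
    onames <- ordering@names
    pnames <- parcellation@nodes$name
    out <- match(onames, pnames)
    todo <- which(is.na(out))
    if (length(todo) > 0L) {
        okey <- canonicalNodeKey(onames[todo])
        pkey <- canonicalNodeKey(pnames)
        amb <- okey[okey %in% pkey[duplicated(pkey)]]
        if (length(amb) > 0L)
            cvStop("cvValidationError",
                   "ambiguous match for ordering name(s) %s: candidates %s",
                   paste(onames[todo][okey %in% amb], collapse = ", "),
                   paste(pnames[pkey %in% amb], collapse = ", "))
        out[todo] <- match(okey, pkey)
    }
    if (anyNA(out))
        cvStop("cvValidationError",
               "ordering name(s) not found in parcellation: %s",
               paste(onames[is.na(out)], collapse = ", "))
    if (anyDuplicated(out) > 0L)
        cvStop("cvValidationError",
               "multiple ordering names map to the same parcellation node: %s",
               paste(onames[duplicated(out) | duplicated(out, fromLast = TRUE)],
                     collapse = ", "))
    out
}

#' Construct a per-node scalar
#' @param values numeric vector, one value per node.
#' @param name label for the scalar.
#' @return a [NodeScalar].
#' @export
nodeScalar <- function(values, name = "scalar")
    new("NodeScalar", values = as.numeric(values), name = name)

#' Values of a NodeScalar (accessor)
#' @param x a [NodeScalar].
#' @return numeric vector.
#' @export
scalarValues <- function(x) x@values

setMethod("show", "Ordering", function(object) {
    cat(sprintf("Ordering of %d ROI(s): %s%s\n", length(object@names),
                paste(utils::head(object@names, 4), collapse = ", "),
                if (length(object@names) > 4) ", ..." else ""))
})

setMethod("show", "AdjacencyNetwork", function(object) {
    e <- allEdges(object)
    cat(sprintf("AdjacencyNetwork: %d nodes, %d nonzero undirected edges\n",
                nrow(object@weights), nrow(e)))
})

setMethod("show", "EdgeSet", function(object) {
    cat(sprintf("EdgeSet: %d edge(s) over %d nodes\n",
                nrow(object@edges), object@sourceN))
})

setMethod("show", "ModulePartition", function(object) {
    cat(sprintf("ModulePartition: %d modules over %d nodes, Q = %.4f\n",
                max(object@assignment), length(object@assignment), object@Q))
})

setMethod("show", "Parcellation", function(object) {
    tb <- table(object@nodes$hemisphere)
    cat(sprintf("Parcellation: %d nodes (%s)\n", nrow(object@nodes),
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
})
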