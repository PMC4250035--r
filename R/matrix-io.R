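# Matrix-format I/O: delimited text, NumPy .npy (2-D arrays), and the
# uncompressed MATLAB .mat v5 double-matrix subset.  These are the common
# interchange formats for connectivity matrices; readers reject anything
# outside the supported subset with an explicit format error rather than
# guessing.

#' Read a matrix from text, .mat or .npy
#'
#' Format is chosen by extension: \code{.npy} NumPy, \code{.mat} MATLAB v5,
#' anything else whitespace- or comma-delimited text.
#'
#' @param path input file.
#' @param matVariable for .mat files with several variables, the variable
#'   name to load (default: the single 2-D numeric variable present).
#' @return numeric matrix.
#' @export
readMatrixFile <- function(path, matVariable = NULL) {
    if (!file.exists(path))
        cvStop("cvInputError", "matrix file does not exist: %s", path)
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           npy = readNpy(path),
           mat = readMat5(path, variable = matVariable),
           readTextMatrix(path))
}

#' Write a matrix to text, .mat or .npy (chosen by extension)
#' @param m numeric matrix.
#' @param path output file; extension selects the format.
#' @return invisibly, \code{path}.
#' @export
writeMatrixFile <- function(m, path) {
    m <- as.matrix(m)
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           npy = writeNpy(m, path),
           mat = writeMat5(m, path),
           writeTextMatrix(m, path))
    invisible(path)
}

readTextMatrix <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L)
        cvStop("cvFormatError", "no data rows in matrix file '%s'", path)
    sep <- if (grepl(",", lines[1], fixed = TRUE)) "," else "[[:space:]]+"
    rows <- lapply(lines, function(l) {
        fields <- strsplit(l, sep)[[1]]
        fields <- fields[nzchar(fields)]
        v <- suppressWarnings(as.numeric(fields))
        if (anyNA(v))
            cvStop("cvFormatError",
                   "non-numeric field in matrix file '%s': %s", path,
                   paste(fields[is.na(v)], collapse = ", "))
        v
    })
    ncols <- lengths(rows)
    if (length(unique(ncols)) != 1L)
        cvStop("cvFormatError",
               "ragged rows in matrix file '%s' (widths %s)", path,
               paste(unique(ncols), collapse = ", "))
    do.call(rbind, rows)
}

writeTextMatrix <- function(m, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(apply(m, 1, function(r) paste(formatNum(r), collapse = " ")), con)
}

# ---- NumPy .npy (format version 1.0, C or Fortran order, common dtypes) ----

npyDtypes <- list("<f8" = list(what = "double",  size = 8L),
                  "<f4" = list(what = "double",  size = 4L),
                  "<i8" = list(what = "integer", size = 8L),
                  "<i4" = list(what = "integer", size = 4L),
                  "<i2" = list(what = "integer", size = 2L),
                  "|u1" = list(what = "integer", size = 1L))

#' Read a 2-D NumPy .npy array
#' @param path input .npy file.
#' @return numeric matrix.
#' @export
readNpy <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 6L)
    if (length(magic) < 6L || !identical(magic, as.raw(c(0x93, utf8ToInt("NUMPY")))))
        cvStop("cvFormatError", "'%s' is not a NumPy .npy file", path)
    ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
    hlen <- if (ver[1] >= 2L)
        readBin(con, "integer", 1L, size = 4L, endian = "little")
    else
        readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
    header <- rawToChar(readBin(con, "raw", hlen))
    descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
    fortran <- grepl("'fortran_order':\\s*True", header)
    shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
    shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
    if (length(shape) == 1L) shape <- c(shape, 1L)
    if (length(shape) != 2L)
        cvStop("cvFormatError", "only 2-D .npy arrays supported; shape (%s)",
               shape_s)
    dt <- npyDtypes[[descr]]
    if (is.null(dt))
        cvStop("cvFormatError", ".npy dtype '%s' not supported (use %s)",
               descr, paste(names(npyDtypes), collapse = ", "))
    n <- prod(shape)
    signed <- if (dt$size <= 2L && dt$what == "integer") descr != "|u1" else TRUE
    vals <- readBin(con, dt$what, n, size = dt$size, signed = signed,
                    endian = "little")
    if (length(vals) < n)
        cvStop("cvFormatError", "truncated .npy file '%s'", path)
    m <- if (fortran) matrix(vals, shape[1], shape[2])
         else t(matrix(vals, shape[2], shape[1]))
    storage.mode(m) <- "double"
    m
}

#' Write a matrix as NumPy .npy (float64, C order)
#' @param m numeric matrix.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNpy <- function(m, path) {
    m <- as.matrix(m)
    dict <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
    # total header (magic 6 + version 2 + len 2 + dict) padded to multiple of 64
    total <- 10L + nchar(dict) + 1L
    pad <- (64L - total %% 64L) %% 64L
    dict <- paste0(dict, strrep(" ", pad), "\n")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
    writeBin(nchar(dict), con, size = 2L, endian = "little")
    writeBin(charToRaw(dict), con)
    writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
    invisible(path)
}

# ---- MATLAB .mat v5 (uncompressed, numeric 2-D matrices) -------------------

mat5Types <- c("1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
               "7" = 4L, "9" = 8L, "12" = 8L, "13" = 8L)  # type id -> bytes

readMat5Element <- function(con, endian) {
    tag <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (length(tag) == 0L) return(NULL)
    if (bitwAnd(tag, -65536L) != 0L) {
        # small data element: type in low 16 bits, size in high 16 bits
        type <- bitwAnd(tag, 65535L)
        nbytes <- bitwShiftR(bitwAnd(tag, -65536L), 16L)
        data <- readBin(con, "raw", 4L)
        list(type = type, nbytes = nbytes, data = data[seq_len(nbytes)])
    } else {
        nbytes <- readBin(con, "integer", 1L, size = 4L, endian = endian)
        data <- readBin(con, "raw", nbytes)
        pad <- (8L - nbytes %% 8L) %% 8L
        if (pad > 0L) readBin(con, "raw", pad)
        list(type = tag, nbytes = nbytes, data = data)
    }
}

mat5Numeric <- function(el, endian) {
    sz <- mat5Types[as.character(el$type)]
    if (is.na(sz))
        cvStop("cvFormatError", ".mat data type %d not supported", el$type)
    what <- if (el$type %in% c(7L, 9L)) "double" else "integer"
    signed <- !el$type %in% c(2L, 4L, 6L, 13L)
    v <- readBin(el$data, what, el$nbytes %/% sz, size = sz,
                 signed = if (sz <= 2L) signed else TRUE, endian = endian)
    as.numeric(v)
}

#' Read a matrix from an uncompressed MATLAB .mat (v5) file
#' @param path input file.
#' @param variable optional variable name; default is the single 2-D numeric
#'   variable in the file.
#' @return numeric matrix.
#' @export
readMat5 <- function(path, variable = NULL) {
    con <- file(path, "rb")
    on.exit(close(con))
    header <- readBin(con, "raw", 128L)
    if (length(header) < 128L)
        cvStop("cvFormatError", "'%s' is not a MATLAB v5 .mat file (truncated header)", path)
    ei <- rawToChar(header[127:128])
    endian <- if (ei == "IM") "little" else if (ei == "MI") "big" else
        cvStop("cvFormatError", "'%s' is not a MATLAB v5 .mat file", path)
    found <- list()
    repeat {
        el <- readMat5Element(con, endian)
        if (is.null(el)) break
        if (el$type == 15L)
            cvStop("cvFormatError",
                   "compressed .mat element in '%s'; only uncompressed v5 .mat supported (save with -v6/-nocompression)",
                   path)
        if (el$type != 14L) next  # skip non-matrix elements
        sub <- rawConnection(el$data)
        flags <- readMat5Element(sub, endian)
        cls <- as.integer(flags$data[1])
        dimsEl <- readMat5Element(sub, endian)
        dims <- mat5Numeric(dimsEl, endian)
        nameEl <- readMat5Element(sub, endian)
        vname <- rawToChar(nameEl$data[nameEl$data != as.raw(0)])
        ok <- cls %in% 6:15 && length(dims) == 2L
        if (ok) {
            dataEl <- readMat5Element(sub, endian)
            vals <- mat5Numeric(dataEl, endian)
            found[[vname]] <- matrix(vals, dims[1], dims[2])
        }
        close(sub)
    }
    if (length(found) == 0L)
        cvStop("cvFormatError", "no 2-D numeric variable found in '%s'", path)
    if (!is.null(variable)) {
        if (is.null(found[[variable]]))
            cvStop("cvInputError", "variable '%s' not in '%s' (has: %s)",
                   variable, path, paste(names(found), collapse = ", "))
        return(found[[variable]])
    }
    if (length(found) > 1L)
        cvStop("cvInputError",
               "multiple variables in '%s' (%s); specify one with matVariable",
               path, paste(names(found), collapse = ", "))
    found[[1L]]
}

writeMat5Tag <- function(con, type, nbytes) {
    writeBin(as.integer(type), con, size = 4L, endian = "little")
    writeBin(as.integer(nbytes), con, size = 4L, endian = "little")
}

padTo8 <- function(con, nbytes) {
    pad <- (8L - nbytes %% 8L) %% 8L
    if (pad > 0L) writeBin(raw(pad), con)
}

#' Write a matrix as uncompressed MATLAB .mat (v5)
#' @param m numeric matrix.
#' @param path output file.
#' @param name MATLAB variable name (default "cv").
#' @return invisibly, \code{path}.
#' @export
writeMat5 <- function(m, path, name = "cv") {
    m <- as.matrix(m); storage.mode(m) <- "double"
    con <- file(path, "wb")
    on.exit(close(con))
    desc <- sprintf("MATLAB 5.0 MAT-file, written by ConnectomeView")
    header <- raw(128L)
    header[seq_len(nchar(desc))] <- charToRaw(desc)
    header[(nchar(desc) + 1L):116L] <- as.raw(32L)
    header[125:126] <- as.raw(c(0x00, 0x01))   # version 0x0100, little-endian
    header[127:128] <- charToRaw("IM")
    writeBin(header, con)
    nameRaw <- charToRaw(name)
    namePad <- (8L - length(nameRaw) %% 8L) %% 8L
    dataBytes <- 8L * length(m)
    total <- 16L + 16L + (8L + length(nameRaw) + namePad) + (8L + dataBytes) +
        (8L - dataBytes %% 8L) %% 8L
    writeMat5Tag(con, 14L, total)              # miMATRIX
    writeMat5Tag(con, 6L, 8L)                  # array flags (miUINT32)
    writeBin(c(6L, 0L), con, size = 4L, endian = "little")  # mxDOUBLE_CLASS
    writeMat5Tag(con, 5L, 8L)                  # dimensions (miINT32)
    writeBin(dim(m), con, size = 4L, endian = "little")
    writeMat5Tag(con, 1L, length(nameRaw))     # name (miINT8)
    writeBin(nameRaw, con); padTo8(con, length(nameRaw))
    writeMat5Tag(con, 9L, dataBytes)           # real part (miDOUBLE)
    writeBin(as.vector(m), con, size = 8L, endian = "little")
    padTo8(con, dataBytes)
    invisible(path)
}

# ---- scalar and coordinate-table I/O ---------------------------------------

#' Write a per-node scalar to disk as a matrix file
#'
#' Writes the n values as an n x 1 matrix in the format selected by the
#' path's extension (text, .mat or .npy), so statistics can be consumed by
#' any matrix-reading tool.  Round-trips through [readScalars()] exactly.
#'
#' @param scalars a [NodeScalar].
#' @param path output path.
#' @param format optional explicit format ("text", "mat", "npy"); default
#'   inferred from the extension.
#' @return invisibly, \code{path}.
#' @export
writeScalars <- function(scalars, path, format = NULL) {
    validObject(scalars)
    fmt <- if (is.null(format)) {
        e <- tolower(tools::file_ext(path))
        if (e %in% c("mat", "npy")) e else "text"
    } else format
    if (!fmt %in% c("text", "mat", "npy"))
        cvStop("cvInputError",
               "unsupported scalar format '%s'; supported: text, mat, npy", fmt)
    m <- matrix(scalars@values, ncol = 1)
    switch(fmt, text = writeTextMatrix(m, path), mat = writeMat5(m, path),
           npy = writeNpy(m, path))
    invisible(path)
}

#' Read a per-node scalar from a matrix file
#' @param path input path (text, .mat or .npy; an n x 1 or 1 x n matrix).
#' @param n expected node count; a mismatch is an error.
#' @param name label for the resulting scalar (default: file base name).
#' @return a [NodeScalar].
#' @export
readScalars <- function(path, n = NULL, name = NULL) {
    m <- readMatrixFile(path)
    if (min(dim(m)) != 1L)
        cvStop("cvFormatError", "scalar file '%s' is %d x %d, expected a vector",
               path, nrow(m), ncol(m))
    v <- as.numeric(m)
    if (!is.null(n) && length(v) != n)
        cvStop("cvValidationError",
               "scalar file '%s' has %d values but the network has %d nodes",
               path, length(v), n)
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
    nodeScalar(v, name)
}

#' Read a parcellation from a plain coordinate table
#'
#' Each row is a node: a name followed by 3 numeric mm coordinates
#' (whitespace- or comma-delimited).  This is the simplest way to supply a
#' parcellation, e.g. EEG electrode positions.  Hemisphere is inferred from
#' the name where possible; group defaults to the hemisphere.
#'
#' @param path input table.
#' @return a [Parcellation].
#' @export
readCoordinateTable <- function(path) {
    if (!file.exists(path))
        cvStop("cvInputError", "coordinate table does not exist: %s", path)
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
    if (length(keep) == 0L)
        cvStop("cvFormatError", "no rows in coordinate table '%s'", path)
    rows <- lapply(keep, function(k) {
        f <- strsplit(trimws(lines[k]), "[,[:space:]]+")[[1]]
        if (length(f) != 4L)
            cvStop("cvFormatError",
                   "line %d of '%s': expected name + 3 coordinates, got %d field(s)",
                   k, path, length(f))
        xyz <- suppressWarnings(as.numeric(f[2:4]))
        if (anyNA(xyz))
            cvStop("cvFormatError",
                   "line %d of '%s': non-numeric coordinate '%s'",
                   k, path, paste(f[2:4][is.na(xyz)], collapse = ", "))
        data.frame(name = f[1], x = xyz[1], y = xyz[2], z = xyz[3])
    })
    df <- do.call(rbind, rows)
    coordinateParcellation(Ordering(df$name), as.matrix(df[, c("x", "y", "z")]))
}

#' Build a parcellation from an ordering plus an n x 3 coordinate matrix
#' @param ordering an [Ordering] of n names.
#' @param coords n x 3 numeric matrix of mm centers (row k = name k).
#' @param group optional group label per node; defaults to hemisphere.
#' @param groupColor optional hex color per node.
#' @return a [Parcellation].
#' @export
coordinateParcellation <- function(ordering, coords, group = NULL,
                                   groupColor = NULL) {
    coords <- as.matrix(coords)
    if (nrow(coords) != length(ordering@names) || ncol(coords) != 3L)
        cvStop("cvValidationError",
               "coordinates must be %d x 3 (got %d x %d)",
               length(ordering@names), nrow(coords), ncol(coords))
    hemi <- nodeHemisphere(ordering@names)
    if (is.null(group)) group <- hemi
    if (is.null(groupColor)) groupColor <- groupPalette(group)
    new("Parcellation", nodes = data.frame(
        name = ordering@names, x = coords[, 1], y = coords[, 2],
        z = coords[, 3], hemisphere = hemi, group = group,
        groupColor = groupColor))
}

# stable color per distinct group label
groupPalette <- function(group) {
    levs <- unique(group)
    pal <- grDevices::hcl.colors(max(3L, length(levs)), "Dark 3")
    pal[match(group, levs)]
}
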