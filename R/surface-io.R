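# Surface and annotation I/O.  Two formats each: the native FreeSurfer
# binary formats (triangle surface, .annot) and GIFTI (surface and label
# files, ASCII-encoded DataArrays).  Readers validate magic numbers and
# reject unrecognized input with an error naming the accepted formats.

FS_TRIANGLE_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))

#' Read a cortical surface (FreeSurfer binary or GIFTI)
#'
#' Format is detected from the file: \code{.gii} files are parsed as GIFTI
#' surfaces (ASCII-encoded DataArrays), anything else must carry the
#' FreeSurfer triangle-file magic.  Vertices are returned in the file's
#' native mm coordinate frame.
#'
#' @param path surface file.
#' @return a [SurfaceGeometry].
#' @export
readSurface <- function(path) {
    if (!file.exists(path))
        cvStop("cvInputError", "surface file does not exist: %s", path)
    if (grepl("\\.gii$", path, ignore.case = TRUE))
        return(readGiftiSurface(path))
    readFsSurface(path)
}

readFsSurface <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 3L)
    if (!identical(magic, FS_TRIANGLE_MAGIC))
        cvStop("cvFormatError",
               paste0("'%s' is not a recognized surface file; accepted formats: ",
                      "FreeSurfer binary surface, GIFTI (.gii)"), path)
    # comment line terminated by "\n\n"
    prev <- as.raw(0)
    repeat {
        b <- readBin(con, "raw", 1L)
        if (length(b) == 0L)
            cvStop("cvFormatError", "truncated FreeSurfer surface '%s'", path)
        if (b == as.raw(10) && prev == as.raw(10)) break
        prev <- b
    }
    counts <- readBin(con, "integer", 2L, size = 4L, endian = "big")
    if (length(counts) < 2L || any(counts < 0L))
        cvStop("cvFormatError", "truncated FreeSurfer surface '%s'", path)
    v <- readBin(con, "double", counts[1] * 3L, size = 4L, endian = "big")
    f <- readBin(con, "integer", counts[2] * 3L, size = 4L, endian = "big")
    if (length(v) < counts[1] * 3L || length(f) < counts[2] * 3L)
        cvStop("cvFormatError", "truncated FreeSurfer surface '%s'", path)
    new("SurfaceGeometry",
        vertices = matrix(v, ncol = 3, byrow = TRUE),
        faces = matrix(f, ncol = 3, byrow = TRUE) + 1L)
}

#' Write a cortical surface (FreeSurfer binary or GIFTI, by extension)
#' @param surface a [SurfaceGeometry].
#' @param path output file; \code{.gii} selects GIFTI.
#' @return invisibly, \code{path}.
#' @export
writeSurface <- function(surface, path) {
    validObject(surface)
    if (grepl("\\.gii$", path, ignore.case = TRUE))
        return(writeGiftiSurface(surface, path))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(FS_TRIANGLE_MAGIC, con)
    writeBin(charToRaw("created by ConnectomeView\n\n"), con)
    writeBin(c(nrow(surface@vertices), nrow(surface@faces)), con,
             size = 4L, endian = "big")
    writeBin(as.vector(t(surface@vertices)), con, size = 4L, endian = "big")
    writeBin(as.vector(t(surface@faces)) - 1L, con, size = 4L, endian = "big")
    invisible(path)
}

# ---- GIFTI (ASCII encoding) ------------------------------------------------

giftiDataArray <- function(root, intent, datatype, mat) {
    da <- xml2::xml_add_child(root, "DataArray",
        Intent = intent, DataType = datatype,
        ArrayIndexingOrder = "RowMajorOrder",
        Dimensionality = "2", Dim0 = as.character(nrow(mat)),
        Dim1 = as.character(ncol(mat)),
        Encoding = "ASCII", Endian = "LittleEndian")
    txt <- paste(apply(mat, 1, paste, collapse = " "), collapse = "\n")
    xml2::xml_add_child(da, "Data", txt)
    da
}

writeGiftiSurface <- function(surface, path) {
    doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                              NumberOfDataArrays = "2")
    giftiDataArray(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                   matrix(formatNum(surface@vertices),
                          nrow(surface@vertices), 3))
    giftiDataArray(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                   surface@faces - 1L)
    xml2::write_xml(doc, path)
    invisible(path)
}

giftiArrays <- function(path) {
    doc <- tryCatch(xml2::read_xml(path), error = function(e)
        cvStop("cvFormatError",
               paste0("'%s' is not readable GIFTI XML; accepted formats: ",
                      "FreeSurfer binary, GIFTI (.gii)"), path))
    das <- xml2::xml_find_all(doc, ".//DataArray")
    if (length(das) == 0L)
        cvStop("cvFormatError", "no DataArray elements in GIFTI file '%s'", path)
    lapply(das, function(da) {
        enc <- xml2::xml_attr(da, "Encoding")
        if (!identical(enc, "ASCII"))
            cvStop("cvFormatError",
                   "GIFTI encoding '%s' in '%s' not supported (ASCII only)",
                   enc, path)
        dim0 <- as.integer(xml2::xml_attr(da, "Dim0"))
        dim1 <- as.integer(xml2::xml_attr(da, "Dim1"))
        if (is.na(dim1)) dim1 <- 1L
        vals <- scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
                     what = numeric(), quiet = TRUE)
        if (length(vals) != dim0 * dim1)
            cvStop("cvFormatError", "GIFTI DataArray in '%s' has %d values, expected %d",
                   path, length(vals), dim0 * dim1)
        list(intent = xml2::xml_attr(da, "Intent"),
             data = matrix(vals, dim0, dim1, byrow = TRUE),
             node = da)
    })
}

readGiftiSurface <- function(path) {
    arrays <- giftiArrays(path)
    intents <- vapply(arrays, `[[`, "", "intent")
    vi <- which(intents == "NIFTI_INTENT_POINTSET")
    fi <- which(intents == "NIFTI_INTENT_TRIANGLE")
    if (length(vi) != 1L || length(fi) != 1L)
        cvStop("cvFormatError",
               "GIFTI surface '%s' must contain one POINTSET and one TRIANGLE array",
               path)
    f <- arrays[[fi]]$data
    storage.mode(f) <- "integer"
    new("SurfaceGeometry", vertices = arrays[[vi]]$data, faces = f + 1L)
}

# ---- annotations -----------------------------------------------------------

packAnnotColor <- function(hex) {
    m <- grDevices::col2rgb(hex)
    as.integer(m[1, ] + 256L * m[2, ] + 65536L * m[3, ])
}

#' Read a surface parcellation annotation (.annot or GIFTI label file)
#'
#' Parcels are renumbered 1..K in label-table order; label 0 means
#' unknown/background.  Parcel display colors are preserved.
#'
#' @param path annotation file (FreeSurfer .annot or .gii label file).
#' @return a [SurfaceAnnotation].
#' @export
readAnnotation <- function(path) {
    if (!file.exists(path))
        cvStop("cvInputError", "annotation file does not exist: %s", path)
    if (grepl("\\.gii$", path, ignore.case = TRUE))
        return(readGiftiLabels(path))
    readFsAnnotation(path)
}

readFsAnnotation <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    vtxct <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    if (length(vtxct) == 0L || is.na(vtxct) || vtxct < 0L)
        cvStop("cvFormatError",
               paste0("'%s' is not a recognized annotation; accepted formats: ",
                      "FreeSurfer .annot, GIFTI label (.gii)"), path)
    pairs <- readBin(con, "integer", 2L * vtxct, size = 4L, endian = "big")
    if (length(pairs) < 2L * vtxct)
        cvStop("cvFormatError", "truncated .annot file '%s'", path)
    vno <- pairs[seq(1L, by = 2L, length.out = vtxct)]
    packed <- pairs[seq(2L, by = 2L, length.out = vtxct)]
    tag <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    if (length(tag) == 0L || tag != 1L)
        cvStop("cvFormatError", "missing color table in .annot file '%s'", path)
    ver <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    if (ver >= 0L)
        cvStop("cvFormatError", "old-style .annot color table in '%s' not supported", path)
    readBin(con, "integer", 1L, size = 4L, endian = "big")  # max entries
    flen <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    readBin(con, "raw", flen)                               # orig ctab filename
    nentries <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    ids <- integer(0); names <- character(0); colors <- character(0)
    packedTab <- integer(0)
    for (k in seq_len(nentries)) {
        readBin(con, "integer", 1L, size = 4L, endian = "big")  # structure idx
        nlen <- readBin(con, "integer", 1L, size = 4L, endian = "big")
        nmr <- readBin(con, "raw", nlen)
        nm <- rawToChar(nmr[nmr != as.raw(0)])
        rgba <- readBin(con, "integer", 4L, size = 4L, endian = "big")
        p <- rgba[1] + 256L * rgba[2] + 65536L * rgba[3]
        if (p == 0L || tolower(nm) %in% c("unknown", "none")) next
        ids <- c(ids, length(ids) + 1L)
        names <- c(names, nm)
        colors <- c(colors, grDevices::rgb(rgba[1], rgba[2], rgba[3],
                                           maxColorValue = 255))
        packedTab <- c(packedTab, p)
    }
    labels <- integer(vtxct)
    labels[vno + 1L] <- c(0L, ids)[match(packed, c(0L, packedTab),
                                         nomatch = 1L)]
    ann <- new("SurfaceAnnotation", vertexLabels = labels,
               labelTable = data.frame(id = ids, name = names, color = colors))
    if (length(ids) == 0L) cvWarn("annotation '%s' contains no parcels", path)
    ann
}

#' Write a surface annotation (.annot or GIFTI label file, by extension)
#'
#' Parcel colors must be distinct (FreeSurfer annotations identify parcels by
#' packed RGB value).
#'
#' @param annot a [SurfaceAnnotation].
#' @param path output file; \code{.gii} selects GIFTI.
#' @return invisibly, \code{path}.
#' @export
writeAnnotation <- function(annot, path) {
    validObject(annot)
    if (grepl("\\.gii$", path, ignore.case = TRUE))
        return(writeGiftiLabels(annot, path))
    lt <- annot@labelTable
    packed <- packAnnotColor(lt$color)
    if (anyDuplicated(packed) > 0L || any(packed == 0L))
        cvStop("cvValidationError",
               "parcel colors must be distinct and non-black to write .annot")
    con <- file(path, "wb")
    on.exit(close(con))
    V <- length(annot@vertexLabels)
    writeBin(V, con, size = 4L, endian = "big")
    vpacked <- c(0L, packed)[match(annot@vertexLabels, c(0L, lt$id))]
    inter <- integer(2L * V)
    inter[seq(1L, by = 2L, length.out = V)] <- seq_len(V) - 1L
    inter[seq(2L, by = 2L, length.out = V)] <- vpacked
    writeBin(inter, con, size = 4L, endian = "big")
    writeBin(c(1L, -2L, nrow(lt) + 1L), con, size = 4L, endian = "big")
    fname <- charToRaw("ConnectomeView.ctab")
    writeBin(length(fname), con, size = 4L, endian = "big")
    writeBin(fname, con)
    writeBin(nrow(lt) + 1L, con, size = 4L, endian = "big")
    writeCtabEntry <- function(idx, nm, rgb) {
        writeBin(idx, con, size = 4L, endian = "big")
        nmr <- charToRaw(nm)
        writeBin(length(nmr), con, size = 4L, endian = "big")
        writeBin(nmr, con)
        writeBin(as.integer(c(rgb, 0L)), con, size = 4L, endian = "big")
    }
    writeCtabEntry(0L, "unknown", c(0L, 0L, 0L))
    for (k in seq_len(nrow(lt)))
        writeCtabEntry(k, lt$name[k], as.integer(grDevices::col2rgb(lt$color[k])))
    invisible(path)
}

writeGiftiLabels <- function(annot, path) {
    doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                              NumberOfDataArrays = "1")
    ltab <- xml2::xml_add_child(doc, "LabelTable")
    lt <- annot@labelTable
    xml2::xml_add_child(ltab, "Label", "unknown", Key = "0",
                        Red = "0", Green = "0", Blue = "0", Alpha = "0")
    for (k in seq_len(nrow(lt))) {
        rgb <- grDevices::col2rgb(lt$color[k]) / 255
        xml2::xml_add_child(ltab, "Label", lt$name[k],
                            Key = as.character(lt$id[k]),
                            Red = formatNum(rgb[1]), Green = formatNum(rgb[2]),
                            Blue = formatNum(rgb[3]), Alpha = "1")
    }
    giftiDataArray(doc, "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32",
                   matrix(annot@vertexLabels, ncol = 1))
    xml2::write_xml(doc, path)
    invisible(path)
}

readGiftiLabels <- function(path) {
    arrays <- giftiArrays(path)
    li <- which(vapply(arrays, `[[`, "", "intent") == "NIFTI_INTENT_LABEL")
    if (length(li) != 1L)
        cvStop("cvFormatError", "GIFTI label file '%s' must contain one LABEL array",
               path)
    doc <- xml2::read_xml(path)
    labs <- xml2::xml_find_all(doc, ".//LabelTable/Label")
    key <- as.integer(xml2::xml_attr(labs, "Key"))
    nm <- xml2::xml_text(labs)
    col <- grDevices::rgb(as.numeric(xml2::xml_attr(labs, "Red")),
                          as.numeric(xml2::xml_attr(labs, "Green")),
                          as.numeric(xml2::xml_attr(labs, "Blue")))
    keep <- key != 0L & !tolower(nm) %in% c("unknown", "none", "???")
    labels <- as.integer(arrays[[li]]$data[, 1])
    ann <- new("SurfaceAnnotation", vertexLabels = labels,
               labelTable = data.frame(id = key[keep], name = nm[keep],
                                       color = col[keep]))
    if (!any(keep)) cvWarn("annotation '%s' contains no parcels", path)
    ann
}

#' Pair an annotation with a surface and compute parcel centers
#'
#' The center of each parcel is the arithmetic mean of its member vertex
#' coordinates (see the vignette for the nearest-vertex alternative for deep
#' sulci).  Background/unknown labels are excluded; empty parcels are dropped
#' with a warning.
#'
#' @param surface a [SurfaceGeometry].
#' @param annot a [SurfaceAnnotation] over the same vertices.
#' @param nearestVertex if TRUE, return the member vertex nearest the mean
#'   instead of the mean itself (keeps centers on the surface).
#' @return numeric matrix (parcels x 3) with parcel names as rownames.
#' @export
parcelCenters <- function(surface, annot, nearestVertex = FALSE) {
    V <- nrow(surface@vertices)
    if (length(annot@vertexLabels) != V)
        cvStop("cvValidationError",
               "annotation covers %d vertices but surface has %d",
               length(annot@vertexLabels), V)
    lt <- annot@labelTable
    out <- matrix(NA_real_, 0L, 3L)
    nms <- character(0)
    for (k in seq_len(nrow(lt))) {
        member <- which(annot@vertexLabels == lt$id[k])
        if (length(member) == 0L) {
            cvWarn("parcel '%s' has no vertices; excluded", lt$name[k])
            next
        }
        pts <- surface@vertices[member, , drop = FALSE]
        ctr <- colMeans(pts)
        if (nearestVertex) {
            d2 <- rowSums((pts - rep(ctr, each = nrow(pts)))^2)
            ctr <- pts[which.min(d2), ]
        }
        out <- rbind(out, ctr)
        nms <- c(nms, lt$name[k])
    }
    rownames(out) <- nms
    out
}
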