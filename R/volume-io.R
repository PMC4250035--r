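# Segmentation-volume I/O and subcortical center extraction.
#
# Coordinate convention: the affine maps 0-based voxel *indices* to mm
# (voxel-center convention, no half-voxel shift).  This matches the NIFTI
# sform; it is stated explicitly because FreeSurfer conventions differ.

#' Standard subcortical structure lookup (FreeSurfer aseg codes)
#'
#' The shipped table covers the predefined set of subcortical structures
#' resolved against the segmentation volume rather than the surface
#' annotation: thalamus, caudate, putamen, pallidum, hippocampus, amygdala,
#' accumbens (left/right) and the brainstem.  Extend or replace it via the
#' \code{lookup} argument of [readSegmentation()].
#'
#' @return data.frame with columns \code{label}, \code{name}.
#' @export
asegLookup <- function() {
    data.frame(
        label = c(10L, 11L, 12L, 13L, 17L, 18L, 26L,
                  49L, 50L, 51L, 52L, 53L, 54L, 58L, 16L),
        name = c("Left-Thalamus", "Left-Caudate", "Left-Putamen",
                 "Left-Pallidum", "Left-Hippocampus", "Left-Amygdala",
                 "Left-Accumbens-area",
                 "Right-Thalamus", "Right-Caudate", "Right-Putamen",
                 "Right-Pallidum", "Right-Hippocampus", "Right-Amygdala",
                 "Right-Accumbens-area", "Brain-Stem"))
}

#' Construct a segmentation volume
#' @param voxels 3D integer array of structure labels.
#' @param affine 4x4 voxel-index (0-based) to mm transform.
#' @param lookup label-to-name table; default [asegLookup()].
#' @return a [SegmentationVolume].
#' @export
segmentationVolume <- function(voxels, affine = diag(4), lookup = asegLookup()) {
    storage.mode(voxels) <- "integer"
    new("SegmentationVolume", voxels = voxels, affine = as.matrix(affine),
        lookup = lookup)
}

#' Read a labeled segmentation volume (NIFTI or MGZ/MGH)
#'
#' @param path \code{.nii}/\code{.nii.gz} (read with RNifti) or
#'   \code{.mgz}/\code{.mgh} (native FreeSurfer volume).
#' @param lookup label value to structure name table; default the standard
#'   aseg codes from [asegLookup()].
#' @return a [SegmentationVolume].
#' @export
readSegmentation <- function(path, lookup = asegLookup()) {
    if (!file.exists(path))
        cvStop("cvInputError", "segmentation file does not exist: %s", path)
    if (grepl("\\.(mgz|mgh)$", path, ignore.case = TRUE)) {
        v <- readMgh(path)
        return(segmentationVolume(v$voxels, v$affine, lookup))
    }
    img <- tryCatch(RNifti::readNifti(path), error = function(e)
        cvStop("cvFormatError",
               "'%s' is not a readable volume; accepted formats: NIFTI (.nii/.nii.gz), MGZ/MGH",
               path))
    arr <- array(as.numeric(img), dim(img))
    if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
        arr <- arr[, , , 1L, drop = TRUE]
    if (length(dim(arr)) != 3L)
        cvStop("cvFormatError", "segmentation volume '%s' must be 3-D", path)
    aff <- structure(RNifti::xform(img), class = NULL)
    segmentationVolume(round(arr), matrix(as.numeric(aff), 4, 4), lookup)
}

#' Write a segmentation volume (NIFTI or MGZ/MGH, by extension)
#' @param seg a [SegmentationVolume].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSegmentation <- function(seg, path) {
    validObject(seg)
    if (grepl("\\.(mgz|mgh)$", path, ignore.case = TRUE))
        return(writeMgh(seg@voxels, seg@affine, path))
    img <- RNifti::asNifti(seg@voxels)
    img <- RNifti::`sform<-`(img, structure(seg@affine, code = 2L))
    RNifti::writeNifti(img, path)
    invisible(path)
}

# ---- FreeSurfer MGH/MGZ volumes (big-endian; MGZ is gzipped MGH) -----------

readMgh <- function(path) {
    con <- if (grepl("\\.mgz$", path, ignore.case = TRUE))
        gzfile(path, "rb") else file(path, "rb")
    on.exit(close(con))
    ver <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    if (length(ver) == 0L || ver != 1L)
        cvStop("cvFormatError", "'%s' is not an MGH/MGZ volume", path)
    dims <- readBin(con, "integer", 4L, size = 4L, endian = "big")
    type <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    readBin(con, "integer", 1L, size = 4L, endian = "big")  # dof
    good <- readBin(con, "integer", 1L, size = 2L, endian = "big")
    affine <- diag(4)
    hdrRead <- 2L
    if (good > 0L) {
        spacing <- readBin(con, "double", 3L, size = 4L, endian = "big")
        mdc <- matrix(readBin(con, "double", 9L, size = 4L, endian = "big"), 3, 3)
        cras <- readBin(con, "double", 3L, size = 4L, endian = "big")
        M <- mdc %*% diag(spacing)
        affine[1:3, 1:3] <- M
        affine[1:3, 4] <- cras - M %*% (dims[1:3] / 2)
        hdrRead <- hdrRead + 60L
    }
    readBin(con, "raw", 284L - 28L - hdrRead)  # pad to data offset 284
    n <- prod(dims[1:3]) * max(1L, dims[4])
    vals <- switch(as.character(type),
        "0" = readBin(con, "integer", n, size = 1L, signed = FALSE),
        "1" = readBin(con, "integer", n, size = 4L, endian = "big"),
        "3" = readBin(con, "double", n, size = 4L, endian = "big"),
        "4" = readBin(con, "integer", n, size = 2L, endian = "big"),
        cvStop("cvFormatError", "MGH data type %d in '%s' not supported", type, path))
    if (length(vals) < n)
        cvStop("cvFormatError", "truncated MGH/MGZ volume '%s'", path)
    list(voxels = array(as.integer(round(vals[seq_len(prod(dims[1:3]))])),
                        dim = dims[1:3]),
         affine = affine)
}

writeMgh <- function(voxels, affine, path) {
    con <- if (grepl("\\.mgz$", path, ignore.case = TRUE))
        gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    dims <- dim(voxels)
    writeBin(1L, con, size = 4L, endian = "big")
    writeBin(as.integer(c(dims, 1L)), con, size = 4L, endian = "big")
    writeBin(c(1L, 0L), con, size = 4L, endian = "big")  # type MRI_INT, dof
    writeBin(1L, con, size = 2L, endian = "big")         # goodRASflag
    M <- affine[1:3, 1:3]
    spacing <- sqrt(colSums(M^2))
    mdc <- sweep(M, 2, spacing, "/")
    cras <- affine[1:3, 4] + M %*% (dims / 2)
    writeBin(spacing, con, size = 4L, endian = "big")
    writeBin(as.vector(mdc), con, size = 4L, endian = "big")
    writeBin(as.vector(cras), con, size = 4L, endian = "big")
    writeBin(raw(284L - 90L), con)
    writeBin(as.integer(voxels), con, size = 4L, endian = "big")
    invisible(path)
}

#' Subcortical structure centers from a segmentation volume
#'
#' For each wanted structure, the center is the affine-transformed centroid
#' of the 0-based voxel indices carrying the structure's label
#' (voxel-center convention).  Structures absent from the volume are omitted
#' with a warning.
#'
#' @param seg a [SegmentationVolume].
#' @param wanted character vector of structure names (must be in the lookup).
#' @return numeric matrix (structures x 3) with names as rownames.
#' @export
segmentationCenters <- function(seg, wanted = seg@lookup$name) {
    lk <- seg@lookup
    unknown <- setdiff(wanted, lk$name)
    if (length(unknown) > 0L)
        cvStop("cvInputError",
               "structure name(s) not in the segmentation lookup: %s",
               paste(unknown, collapse = ", "))
    out <- matrix(NA_real_, 0L, 3L); nms <- character(0)
    for (nm in wanted) {
        lab <- lk$label[lk$name == nm]
        idx <- which(seg@voxels == lab, arr.ind = TRUE)
        if (nrow(idx) == 0L) {
            cvWarn("structure '%s' (label %d) absent from segmentation volume",
                   nm, lab)
            next
        }
        centroid <- colMeans(idx) - 1  # 0-based voxel indices
        out <- rbind(out, as.vector(applyRegistration(
            matrix(centroid, 1, 3), affineRegistration(seg@affine))))
        nms <- c(nms, nm)
    }
    rownames(out) <- nms
    out
}

#' Assemble a full parcellation from surface, annotation and segmentation
#'
#' Cortical node centers come from [parcelCenters()] on the surface parcels;
#' subcortical nodes from [segmentationCenters()] on the labeled volume.  An
#' optional 4x4 registration maps segmentation-space centers into the
#' anatomical surface space.  Anatomical groups come from a name-to-group
#' mapping (data.frame with columns \code{name}, \code{group}, optional
#' \code{color}); without one, groups default to hemisphere, with
#' subcortical structures grouped as "subcortical".
#'
#' @param surface a [SurfaceGeometry].
#' @param annot a [SurfaceAnnotation] over the same vertices.
#' @param segmentation optional [SegmentationVolume] for subcortical nodes.
#' @param subcortical names of subcortical structures to include (default:
#'   all lookup structures present in the volume).
#' @param registration optional [AffineRegistration] (volume to surface mm).
#' @param groups optional name-to-group mapping data.frame.
#' @return a [Parcellation].
#' @export
buildParcellation <- function(surface, annot, segmentation = NULL,
                              subcortical = NULL, registration = NULL,
                              groups = NULL) {
    ctr <- parcelCenters(surface, annot)
    nm <- rownames(ctr)
    hemi <- nodeHemisphere(nm)
    df <- data.frame(name = nm, x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                     hemisphere = hemi)
    if (!is.null(segmentation)) {
        wanted <- if (is.null(subcortical)) {
            present <- segmentation@lookup$label %in% unique(as.vector(segmentation@voxels))
            segmentation@lookup$name[present]
        } else subcortical
        if (length(wanted) > 0L) {
            sc <- suppressWarnings(segmentationCenters(segmentation, wanted))
            if (!is.null(registration) && nrow(sc) > 0L)
                sc[] <- applyRegistration(sc, registration)
            if (nrow(sc) > 0L)
                df <- rbind(df, data.frame(name = rownames(sc), x = sc[, 1],
                                           y = sc[, 2], z = sc[, 3],
                                           hemisphere = "subcortical"))
        }
    }
    if (!is.null(groups)) {
        g <- groups$group[match(canonicalNodeKey(df$name),
                                canonicalNodeKey(groups$name))]
        g[is.na(g)] <- df$hemisphere[is.na(g)]
    } else {
        g <- df$hemisphere
    }
    col <- if (!is.null(groups) && !is.null(groups$color)) {
        cc <- groups$color[match(g, groups$group)]
        cc[is.na(cc)] <- groupPalette(g)[is.na(cc)]
        cc
    } else groupPalette(g)
    rownames(df) <- NULL
    new("Parcellation", nodes = cbind(df, group = g, groupColor = col))
}
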