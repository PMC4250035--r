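# Name canonicalization for matching ordering names against parcellation
# nodes.  The same region may be written "lh_precentral", "precentral-lh",
# "LH.precentral" or "Left-Precentral" depending on the tool that produced
# the file; all collapse to the canonical key "lh:precentral".  Exact
# (case-sensitive) match is always attempted before canonical matching.

#' Canonical node key for case/hemisphere-insensitive matching
#'
#' Lower-cases the name and normalizes hemisphere markers: prefixes
#' \code{lh_}/\code{lh.}/\code{lh-}, suffixes \code{_lh}/\code{.lh}/\code{-lh}
#' (likewise \code{rh}) and the FreeSurfer \code{Left-}/\code{Right-}
#' conventions all map to an explicit \code{lh:}/\code{rh:} prefix.  Names
#' with no hemisphere marker keep the prefix \code{x:}.
#'
#' @param x character vector of node names.
#' @return character vector of canonical keys.
#' @export
canonicalNodeKey <- function(x) {
    y <- tolower(trimws(x))
    hemi <- rep("x", length(y))
    core <- y
    pat_pre <- "^(lh|rh|left|right)[._-]"
    pre <- regmatches(core, regexpr(pat_pre, core))
    has_pre <- grepl(pat_pre, core)
    hemi[has_pre] <- substr(sub("[._-]$", "", pre), 1L, 1L)
    core[has_pre] <- sub(pat_pre, "", core[has_pre])
    pat_suf <- "[._-](lh|rh|left|right)$"
    has_suf <- !has_pre & grepl(pat_suf, core)
    if (any(has_suf)) {
        suf <- sub(paste0(".*", pat_suf), "\\1", core[has_suf])
        hemi[has_suf] <- substr(suf, 1L, 1L)
        core[has_suf] <- sub(pat_suf, "", core[has_suf])
    }
    hemi[hemi == "l"] <- "l"; hemi[hemi == "r"] <- "r"
    hemi <- c(l = "lh", r = "rh", x = "x")[hemi]
    paste0(hemi, ":", core)
}

#' Hemisphere implied by a node name
#' @param x character vector of node names.
#' @return character vector: "lh", "rh" or "unknown".
#' @export
nodeHemisphere <- function(x) {
    key <- canonicalNodeKey(x)
    h <- sub(":.*$", "", key)
    ifelse(h == "x", "unknown", h)
}

# interpolate between two hex colors; t in [0,1]
lerpColor <- function(colLow, colHigh, t) {
    lo <- grDevices::col2rgb(colLow) / 255
    hi <- grDevices::col2rgb(colHigh) / 255
    t <- pmin(1, pmax(0, t))
    m <- lo %*% t(1 - t) + hi %*% t(t)
    grDevices::rgb(m[1, ], m[2, ], m[3, ])
}

cvStop <- function(class, fmt, ...) {
    msg <- sprintf(fmt, ...)
    stop(structure(class = c(class, "cvError", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
}

cvWarn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic formatting of numbers for text matrix output
formatNum <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
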