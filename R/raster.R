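# Minimal deterministic software rasterizer.  The views render to plain
# pixel arrays written with png::writePNG, so a fixed scene always produces
# byte-identical files — no graphics device, font stack or GPU is involved.
# Coordinates: x grows right (1..width), y grows down (1..height).

newCanvas <- function(width, height, bg = "#000000") {
    rgb <- grDevices::col2rgb(bg) / 255
    cv <- new.env(parent = emptyenv())
    cv$w <- as.integer(width); cv$h <- as.integer(height)
    cv$r <- matrix(rgb[1], cv$h, cv$w)
    cv$g <- matrix(rgb[2], cv$h, cv$w)
    cv$b <- matrix(rgb[3], cv$h, cv$w)
    cv
}

canvasArray <- function(cv) {
    a <- array(0, c(cv$h, cv$w, 3))
    a[, , 1] <- cv$r; a[, , 2] <- cv$g; a[, , 3] <- cv$b
    a
}

writeCanvas <- function(cv, path) {
    png::writePNG(canvasArray(cv), path)
    invisible(path)
}

# set pixels (vectors xs, ys) to col, optionally alpha-blended
canvasSet <- function(cv, xs, ys, col, alpha = 1) {
    xs <- round(xs); ys <- round(ys)
    ok <- xs >= 1 & xs <= cv$w & ys >= 1 & ys <= cv$h
    if (!any(ok)) return(invisible())
    idx <- cbind(ys[ok], xs[ok])
    rgb <- grDevices::col2rgb(col) / 255
    if (alpha >= 1) {
        cv$r[idx] <- rgb[1]; cv$g[idx] <- rgb[2]; cv$b[idx] <- rgb[3]
    } else {
        cv$r[idx] <- (1 - alpha) * cv$r[idx] + alpha * rgb[1]
        cv$g[idx] <- (1 - alpha) * cv$g[idx] + alpha * rgb[2]
        cv$b[idx] <- (1 - alpha) * cv$b[idx] + alpha * rgb[3]
    }
    invisible()
}

canvasFillRect <- function(cv, x0, y0, x1, y1, col, alpha = 1) {
    xs <- max(1, round(min(x0, x1))):min(cv$w, round(max(x0, x1)))
    ys <- max(1, round(min(y0, y1))):min(cv$h, round(max(y0, y1)))
    if (length(xs) == 0L || length(ys) == 0L) return(invisible())
    grid <- expand.grid(y = ys, x = xs)
    canvasSet(cv, grid$x, grid$y, col, alpha)
}

canvasFillCircle <- function(cv, cx, cy, radius, col, alpha = 1) {
    radius <- max(radius, 0.5)
    xs <- floor(cx - radius):ceiling(cx + radius)
    ys <- floor(cy - radius):ceiling(cy + radius)
    grid <- expand.grid(y = ys, x = xs)
    inside <- (grid$x - cx)^2 + (grid$y - cy)^2 <= radius^2
    canvasSet(cv, grid$x[inside], grid$y[inside], col, alpha)
}

canvasLine <- function(cv, x0, y0, x1, y1, col, lwd = 1, alpha = 1) {
    n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) * 2L)
    xs <- seq(x0, x1, length.out = n)
    ys <- seq(y0, y1, length.out = n)
    if (lwd <= 1) return(canvasSet(cv, xs, ys, col, alpha))
    r <- lwd / 2
    off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
    off <- off[off$dx^2 + off$dy^2 <= r^2, ]
    for (k in seq_len(nrow(off)))
        canvasSet(cv, xs + off$dx[k], ys + off$dy[k], col, alpha)
    invisible()
}

canvasPolyline <- function(cv, xs, ys, col, lwd = 1, alpha = 1) {
    for (k in seq_len(length(xs) - 1L))
        canvasLine(cv, xs[k], ys[k], xs[k + 1L], ys[k + 1L], col, lwd, alpha)
    invisible()
}

canvasFillTriangle <- function(cv, px, py, col, alpha = 1) {
    xs <- max(1, floor(min(px))):min(cv$w, ceiling(max(px)))
    ys <- max(1, floor(min(py))):min(cv$h, ceiling(max(py)))
    if (length(xs) == 0L || length(ys) == 0L) return(invisible())
    grid <- expand.grid(y = ys, x = xs)
    d <- (py[2] - py[3]) * (px[1] - px[3]) + (px[3] - px[2]) * (py[1] - py[3])
    if (abs(d) < 1e-12) return(invisible())
    l1 <- ((py[2] - py[3]) * (grid$x - px[3]) +
           (px[3] - px[2]) * (grid$y - py[3])) / d
    l2 <- ((py[3] - py[1]) * (grid$x - px[3]) +
           (px[1] - px[3]) * (grid$y - py[3])) / d
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    canvasSet(cv, grid$x[inside], grid$y[inside], col, alpha)
}

# sampled cubic Bezier curve through control points (4 x 2 matrix)
bezierPoints <- function(ctrl, n = 48L) {
    t <- seq(0, 1, length.out = n)
    b <- cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
    b %*% ctrl
}
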