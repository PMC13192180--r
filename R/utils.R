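# Internal helpers: local RNG scoping, rasterization, small numerics.

# Evaluate expr under a given seed without touching the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Set pixels of a filled disk into matrix `m` (value = max(existing, value)).
# cx, cy in pixel coordinates (row, col), r in pixels.
drawDisk <- function(m, cx, cy, r, value) {
  nr <- nrow(m); nc <- ncol(m)
  i0 <- max(1L, floor(cx - r)); i1 <- min(nr, ceiling(cx + r))
  j0 <- max(1L, floor(cy - r)); j1 <- min(nc, ceiling(cy + r))
  if (i0 > i1 || j0 > j1) return(m)
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - cx)^2, (jj - cy)^2, "+")
  sub <- m[ii, jj, drop = FALSE]
  hit <- d2 <= r^2
  sub[hit] <- pmax(sub[hit], value)
  m[ii, jj] <- sub
  m
}

# Rasterize a thick line segment (pixel coords) into m, max semantics.
drawSegment <- function(m, x0, y0, x1, y1, width, value) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len == 0) return(drawDisk(m, x0, y0, width / 2, value))
  nstep <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = nstep)
  xs <- x0 + t * (x1 - x0); ys <- y0 + t * (y1 - y0)
  r <- max(width / 2, 0.5)
  nr <- nrow(m); nc <- ncol(m)
  # stamp small disks along the segment; cheap and exact enough at r >= 0.5
  for (k in seq_len(nstep)) {
    i0 <- max(1L, floor(xs[k] - r)); i1 <- min(nr, ceiling(xs[k] + r))
    j0 <- max(1L, floor(ys[k] - r)); j1 <- min(nc, ceiling(ys[k] + r))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - xs[k])^2, (jj - ys[k])^2, "+")
    sub <- m[ii, jj, drop = FALSE]
    hit <- d2 <= r^2
    sub[hit] <- pmax(sub[hit], value)
    m[ii, jj] <- sub
  }
  m
}

# Linear interpolation crossing time: first time v crosses `level` upward
# between samples, searching from index i0. Returns time in samples (1-based,
# fractional) or NA.
upCrossing <- function(v, level, i0 = 1L) {
  n <- length(v)
  idx <- which(v[i0:(n - 1)] < level & v[(i0 + 1):n] >= level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1] + i0 - 1L
  i + (level - v[i]) / (v[i + 1] - v[i])
}

# Simple polynomial rolling hash of a character string, hex output
# (provenance tags only, not cryptographic).
fnvHash <- function(s) {
  bytes <- utf8ToInt(paste(s, collapse = "\r"))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Strip EBImage's Image class down to a plain 2-D matrix.
ebMat <- function(img) {
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2) m <- m[, , 1]
  m
}
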