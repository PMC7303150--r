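# Internal helpers shared across modules: seed scoping, small 3-D image
# primitives (connected components, dilation, distance to background).
# These operate on logical/numeric 3-D arrays indexed (z, y, x), 0-based
# physical coordinates at voxel centers (i - 0.5) * pitch.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr under a fixed RNG seed without disturbing the caller's stream.
# seed = NULL means "use the current stream".
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# 26-connected (or 6-connected) component labelling of a logical 3-D array.
# Returns an integer array of the same shape, 0 = background.
label_components_3d <- function(vol, connectivity = 26) {
  stopifnot(length(dim(vol)) == 3)
  d <- dim(vol)
  lab <- array(0L, d)
  idx <- which(vol)
  if (length(idx) == 0L) return(lab)
  offs <- neighbor_offsets(connectivity)
  # map linear index -> (z,y,x)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  cur <- 0L
  inset <- logical(prod(d))
  inset[idx] <- TRUE
  visited <- logical(prod(d))
  for (start in idx) {
    if (visited[start]) next
    cur <- cur + 1L
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      lab[v] <- cur
      zi <- (v - 1L) %% nz + 1L
      yi <- ((v - 1L) %/% nz) %% ny + 1L
      xi <- (v - 1L) %/% (nz * ny) + 1L
      nzs <- zi + offs[, 1]; nys <- yi + offs[, 2]; nxs <- xi + offs[, 3]
      ok <- nzs >= 1L & nzs <= nz & nys >= 1L & nys <= ny & nxs >= 1L & nxs <= nx
      nb <- (nxs[ok] - 1L) * nz * ny + (nys[ok] - 1L) * nz + nzs[ok]
      nb <- nb[inset[nb] & !visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

neighbor_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

# Spherical binary dilation of a logical 3-D array, radius in voxels.
dilate_3d <- function(vol, radius) {
  if (radius <= 0) return(vol)
  d <- dim(vol)
  r <- ceiling(radius)
  se <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  se <- se[rowSums(se^2) <= radius^2, , drop = FALSE]
  idx <- which(vol, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(vol)
  out <- array(FALSE, d)
  for (k in seq_len(nrow(se))) {
    z <- idx[, 1] + se[k, 1]; y <- idx[, 2] + se[k, 2]; x <- idx[, 3] + se[k, 3]
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    out[cbind(z[ok], y[ok], x[ok])] <- TRUE
  }
  out
}

# Distance (in voxels) from each query voxel to the nearest background voxel
# of a logical foreground volume. Brute force over background shells; meant
# for small fixtures only.
dist_to_background <- function(vol, voxels) {
  d <- dim(vol)
  bg <- which(!vol, arr.ind = TRUE)
  apply(voxels, 1, function(p) {
    if (nrow(bg) == 0L) return(Inf)
    # voxels outside the array count as background at the face distance
    dmin <- min(sqrt(colSums((t(bg) - p)^2)))
    edge <- min(p[1] - 0, d[1] + 1 - p[1], p[2] - 0, d[2] + 1 - p[2],
                p[3] - 0, d[3] + 1 - p[3])
    min(dmin, edge)
  })
}

# Arc length (in voxel units) of an ordered voxel path given as an n x 3 matrix.
path_arc_length <- function(path) {
  if (nrow(path) < 2L) return(0)
  steps <- diff(path)
  sum(sqrt(rowSums(steps^2)))
}

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
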