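#' Render a vascular network into a multi-channel time-lapse image stack
#'
#' Rasterizes the vessels of a \linkS4class{VesselGraph} into a calibrated
#' \linkS4class{TimeStack} emulating in vivo two-photon plasma-labelled
#' imaging: the plasma channel is bright inside the vessel lumen, and blood
#' cells appear as dark ellipsoidal patches (negative contrast). Patches in
#' flowing vessels advance along the centerline by speed x frame interval
#' between frames (wrapping within the segment); patches in stalled vessels
#' are static. Leukocyte-caused stalls co-label the rhodamine and hoechst
#' channels at the patch, platelet-caused stalls label rhodamine only, and
#' red-blood-cell-only stalls carry no cell label.
#'
#' @param graph a \linkS4class{VesselGraph}.
#' @param fov micrometer (z, y, x) extents of the rendered field of view;
#'   NULL renders the graph bounding box plus a margin.
#' @param origin micrometer (z, y, x) position of the stack corner in graph
#'   coordinates; NULL places it at the bounding-box corner.
#' @param dz,dxy voxel pitch, micrometers (defaults 1, matching 1-um spaced
#'   planes).
#' @param nFrames number of frames (default 5, i.e. a ~5 s observation
#'   window at 1 frame/s).
#' @param frameIntervalS seconds between frames (default 1).
#' @param noiseSd Gaussian noise SD added to every channel.
#' @param background baseline intensity outside vessels.
#' @param lumenIntensity plasma intensity inside the lumen.
#' @param darkIntensity plasma intensity inside a blood-cell patch.
#' @param cellIntensity added rhodamine/hoechst intensity at labelled cells.
#' @param patchLengthUm blood-cell patch length along the centerline.
#' @param maxPatches flowing vessels carry 1..maxPatches patches.
#' @param seed RNG seed (patch placement and noise), or NULL.
#' @return a \linkS4class{TimeStack}.
#' @export
renderStack <- function(graph, fov = NULL, origin = NULL, dz = 1, dxy = 1,
                        nFrames = 5, frameIntervalS = 1, noiseSd = 4,
                        background = 10, lumenIntensity = 200,
                        darkIntensity = 40, cellIntensity = 150,
                        patchLengthUm = 6, maxPatches = 3, seed = NULL) {
  stopifnot(methods::is(graph, "VesselGraph"))
  nd <- nodeTable(graph)
  ed <- edgeTable(graph)
  pos <- cbind(z = nd$z, y = nd$y, x = nd$x)
  rownames(pos) <- nd$name
  rmax <- max(ed$radius_um)
  bb_lo <- apply(pos, 2, min) - rmax - 2
  bb_hi <- apply(pos, 2, max) + rmax + 2
  if (is.null(origin)) origin <- bb_lo
  if (is.null(fov)) fov <- bb_hi - origin
  hi <- origin + fov
  # edges with at least one endpoint inside the fov box (padded by radius)
  inside <- function(p, pad) all(p >= origin - pad) && all(p <= hi + pad)
  keep <- vapply(seq_len(nrow(ed)), function(i) {
    pad <- ed$radius_um[i]
    inside(pos[ed$from[i], ], pad) || inside(pos[ed$to[i], ], pad)
  }, logical(1))
  if (!any(keep))
    stop2("empty field: the requested fov lies outside the graph ",
          "bounding box (no vessel intersects it)")
  ed <- ed[keep, , drop = FALSE]

  dimzyx <- c(max(1L, ceiling(fov[1] / dz)),
              max(1L, ceiling(fov[2] / dxy)),
              max(1L, ceiling(fov[3] / dxy)))
  arr <- array(0, c(nFrames, dimzyx, 3L))

  with_seed_or_not(seed, {
    for (i in seq_len(nrow(ed))) {
      p0 <- pos[ed$from[i], ] - origin
      p1 <- pos[ed$to[i], ] - origin
      arr <- rasterize_vessel(
        arr, p0, p1, ed$radius_um[i], ed$is_stalled[i], ed$stall_cause[i],
        ed$speed_um_s[i], dz, dxy, nFrames, frameIntervalS, lumenIntensity,
        darkIntensity, cellIntensity, patchLengthUm, maxPatches)
    }
    arr <- arr + background
    if (noiseSd > 0)
      arr <- arr + stats::rnorm(length(arr), sd = noiseSd)
  })
  arr[arr < 0] <- 0

  methods::new("TimeStack", data = arr, dz = dz, dxy = dxy,
               frameInterval = frameIntervalS,
               channels = c("plasma", "rhodamine", "hoechst"),
               origin = as.numeric(origin))
}

# Draw one vessel (lumen + per-frame blood-cell patches) into arr.
# p0, p1 in stack-relative micrometers (z, y, x). Consumes RNG (patch
# placement) and therefore must run inside the caller's seed scope.
rasterize_vessel <- function(arr, p0, p1, radius, stalled, cause, speed,
                             dz, dxy, nFrames, frameIntervalS,
                             lumenI, darkI, cellI, patchLen, maxPatches) {
  dims <- dim(arr)[2:4]
  axis <- p1 - p0
  L <- sqrt(sum(axis^2))
  if (L <= 0) return(arr)
  u <- axis / L
  pad <- radius + 1
  pitch <- c(dz, dxy, dxy)
  lo <- pmax(1L, as.integer(floor((pmin(p0, p1) - pad) / pitch)))
  hi <- pmin(dims, as.integer(ceiling((pmax(p0, p1) + pad) / pitch)))
  if (any(hi < lo)) return(arr)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  cz <- (iz - 0.5) * dz; cy <- (iy - 0.5) * dxy; cx <- (ix - 0.5) * dxy
  grid <- expand.grid(z = cz, y = cy, x = cx)
  rel <- cbind(grid$z - p0[1], grid$y - p0[2], grid$x - p0[3])
  ax <- rel %*% u                       # axial coordinate, um
  axc <- pmin(pmax(ax, 0), L)
  perp2 <- rowSums(rel^2) - 2 * ax * axc + axc^2
  perp2 <- pmax(perp2, 0)
  lumen <- as.vector(perp2 <= radius^2 & ax >= -radius & ax <= L + radius)
  if (!any(lumen)) return(arr)
  gidx <- as.matrix(expand.grid(z = iz, y = iy, x = ix))

  # patch layout
  halfLen <- patchLen / 2
  if (stalled) {
    s0 <- L / 2
    nP <- 1L
  } else {
    nP <- sample.int(maxPatches, 1L)
    s0 <- (stats::runif(1) + (seq_len(nP) - 1) / nP) %% 1 * L
  }
  prad <- 0.9 * radius
  dperp <- sqrt(as.vector(perp2))
  axv <- as.vector(ax)

  # cells transit the whole segment between frames at fast flow, so the
  # patches in successive frames are different cells at random phases;
  # slow flow advances the same patch deterministically
  refresh <- !stalled && speed * frameIntervalS > 2 * patchLen
  for (f in seq_len(nFrames)) {
    tsec <- (f - 1) * frameIntervalS
    s <- if (stalled) s0
    else if (refresh) stats::runif(nP) * L
    else (s0 + speed * tsec) %% L
    li <- cbind(f, gidx[lumen, , drop = FALSE], 1L)
    arr[li] <- pmax(arr[li], lumenI)
    for (k in seq_len(nP)) {
      inside <- ((axv - s[k]) / halfLen)^2 + (dperp / prad)^2 <= 1
      inside <- inside & lumen
      if (!any(inside)) next
      pi_ <- cbind(f, gidx[inside, , drop = FALSE])
      arr[cbind(pi_, 1L)] <- darkI
      if (stalled && cause == "leukocyte") {
        arr[cbind(pi_, 2L)] <- arr[cbind(pi_, 2L)] + cellI
        arr[cbind(pi_, 3L)] <- arr[cbind(pi_, 3L)] + cellI
      } else if (stalled && cause == "platelet") {
        arr[cbind(pi_, 2L)] <- arr[cbind(pi_, 2L)] + cellI
      }
    }
  }
  arr
}

#' Render a small crop around one capillary segment of a network
#'
#' Renders only the field of view covering one edge (plus a margin), the
#' way annotation crops are served: returns the stack together with the
#' segment descriptor (stack-relative endpoints and radius) needed by the
#' measurement functions.
#'
#' @param graph a \linkS4class{VesselGraph}.
#' @param edgeId edge index to crop around.
#' @param marginUm margin around the segment bounding box, um.
#' @param ... passed to \code{\link{renderStack}}.
#' @return list(stack, segment, edge_id).
#' @export
renderSegmentCrop <- function(graph, edgeId, marginUm = 4, ...) {
  nd <- nodeTable(graph)
  ed <- edgeTable(graph)[edgeId, ]
  pos <- cbind(z = nd$z, y = nd$y, x = nd$x)
  rownames(pos) <- nd$name
  p0 <- pos[ed$from, ]; p1 <- pos[ed$to, ]
  pad <- ed$radius_um + marginUm
  origin <- pmin(p0, p1) - pad
  fov <- abs(p1 - p0) + 2 * pad
  sub <- subgraph_single_edge(graph, edgeId)
  stack <- renderStack(sub, fov = fov, origin = origin, ...)
  list(stack = stack,
       segment = list(p0 = p0 - origin, p1 = p1 - origin,
                      radius = ed$radius_um),
       edge_id = edgeId)
}

# One-edge VesselGraph preserving the edge's geometry and state.
subgraph_single_edge <- function(graph, edgeId) {
  nd <- nodeTable(graph)
  ed <- edgeTable(graph)[edgeId, , drop = FALSE]
  keep <- nd$name %in% c(ed$from, ed$to)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = nd[keep, , drop = FALSE])
  methods::new("VesselGraph", graph = g)
}

#' Render a line-scan space-time image for a known centerline speed
#'
#' Emulates repeated scanning along a vessel centerline: rows are scan lines
#' (time), columns are positions along the centerline. Unlabelled red blood
#' cells produce dark streaks whose slope in (time, distance) coordinates is
#' the reciprocal of the flow speed; a stationary cell (speed 0) produces a
#' vertical streak. Zero-mean Gaussian noise is added.
#'
#' @param speed true centerline speed, um/s (>= 0).
#' @param radius vessel radius, um (recorded as an attribute).
#' @param scanRate lines per second.
#' @param duration scan duration, seconds.
#' @param pixelPitch um per pixel along the scan.
#' @param scanLengthUm scanned centerline length, um.
#' @param noiseSd Gaussian noise SD.
#' @param cellLengthUm dark-streak (cell) length, um.
#' @param cellSpacingUm mean spacing between cells, um.
#' @param seed RNG seed or NULL.
#' @return numeric matrix (lines x pixels) with attributes
#'   \code{pixel_pitch_um}, \code{line_rate_hz}, \code{radius_um},
#'   \code{true_speed_um_s}.
#' @export
renderLinescan <- function(speed, radius = 10, scanRate = 1000,
                           duration = 0.5, pixelPitch = 0.5,
                           scanLengthUm = 64, noiseSd = 0,
                           cellLengthUm = 6, cellSpacingUm = 15,
                           seed = NULL) {
  if (speed < 0) stop2("speed must be >= 0")
  if (duration <= 0) stop2("duration must be > 0")
  nLines <- max(1L, round(duration * scanRate))
  nPix <- max(2L, round(scanLengthUm / pixelPitch))
  if (speed / scanRate > scanLengthUm)
    warn2("aliasing: the streak crosses the full scan in less than one ",
          "line; speed is above the resolvable range at this line rate")
  Ld <- scanLengthUm + cellLengthUm  # wrap domain, keeps a continuous stream
  nCells <- max(1L, round(Ld / cellSpacingUm))
  img <- matrix(200, nrow = nLines, ncol = nPix)
  with_seed_or_not(seed, {
    x0 <- stats::runif(nCells, 0, Ld)
    tt <- (seq_len(nLines) - 1) / scanRate
    half <- cellLengthUm / 2
    for (k in seq_len(nCells)) {
      xc <- (x0[k] + speed * tt) %% Ld - half  # left edge can be < 0
      jlo <- pmax(1L, as.integer(ceiling((xc - half) / pixelPitch + 0.5)))
      jhi <- pmin(nPix, as.integer(floor((xc + half) / pixelPitch + 0.5)))
      for (i in which(jlo <= jhi)) img[i, jlo[i]:jhi[i]] <- 40
    }
    if (noiseSd > 0)
      img <- img + stats::rnorm(length(img), sd = noiseSd)
  })
  img[img < 0] <- 0
  structure(img, pixel_pitch_um = pixelPitch, line_rate_hz = scanRate,
            radius_um = radius, true_speed_um_s = speed)
}
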