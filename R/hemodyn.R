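#' Volumetric blood flow from centerline speed and vessel radius
#'
#' Computes F = pi * v * r^2 / 2, the volumetric flux implied by a
#' centerline red blood cell speed \code{v} and vessel radius \code{r},
#' with the factor 1/2 accounting for the difference between centerline and
#' mean speed in a parabolic-like profile.
#'
#' @param v centerline speed, um/s (>= 0). Vectorized.
#' @param r vessel radius, um (> 0). Vectorized.
#' @return volumetric flow, um^3/s.
#' @examples
#' volumetricFlow(2000, 2)  # 4000 * pi
#' @export
volumetricFlow <- function(v, r) {
  if (any(r <= 0)) stop2("radius must be positive")
  if (any(v < 0)) stop2("speed must be >= 0")
  pi * v * r^2 / 2
}

#' Build a per-vessel flow measurement table
#'
#' @param id vessel identifiers.
#' @param radius radii, um.
#' @param speed centerline speeds, um/s.
#' @param quality optional quality flags.
#' @return data.frame with columns vessel_id, radius_um, speed_um_s,
#'   flow_um3_s (= pi v r^2 / 2 exactly), quality.
#' @export
flowMeasurement <- function(id, radius, speed, quality = "ok") {
  data.frame(vessel_id = id, radius_um = radius, speed_um_s = speed,
             flow_um3_s = volumetricFlow(speed, radius),
             quality = quality, stringsAsFactors = FALSE)
}

#' Stall-detectability speed bound
#'
#' The smallest motion resolvable over the observation window sets an upper
#' bound on the flow speed of a vessel scored as stalled: a displacement
#' resolution of 1 um over five 1-s frames implies a speed below 0.2 um/s.
#'
#' @param resolutionUm displacement resolution, um.
#' @param nFrames frames observed.
#' @param frameIntervalS seconds per frame.
#' @return implied speed bound, um/s.
#' @export
stallSpeedBound <- function(resolutionUm = 1, nFrames = 5,
                            frameIntervalS = 1) {
  resolutionUm / (nFrames * frameIntervalS)
}

#' Estimate red blood cell speed from a line-scan space-time image
#'
#' Radon-style angle estimation: the image (rows = scan lines/time, columns
#' = distance along the centerline) is projected along candidate streak
#' slopes by shearing each line by s pixels/line and summing columns; the
#' projection variance is maximal when the shear matches the true streak
#' slope. Speed = s * pixel pitch * line rate (equivalently pitch * rate /
#' tan(theta) for the Radon angle theta from the time axis). Estimates are
#' computed in overlapping windows and averaged, weighted by a peak-
#' sharpness confidence; when no dominant angle exists the estimate is
#' flagged and the speed is not reported.
#'
#' @param linescan matrix from \code{\link{renderLinescan}} or equivalent
#'   (rows = time).
#' @param pixelPitch um/pixel; defaults to the matrix attribute.
#' @param lineRate lines/s; defaults to the matrix attribute.
#' @param windowLines window length (lines); windows overlap 50\%.
#' @param confidenceFloor minimum peak sharpness (peak variance over the
#'   median variance across candidate angles) to report a speed.
#' @return list with \code{speed_um_s} (NA when flagged),
#'   \code{confidence}, \code{low_confidence}, \code{windows} (per-window
#'   estimates).
#' @export
estimateSpeed <- function(linescan, pixelPitch = NULL, lineRate = NULL,
                          windowLines = 128, confidenceFloor = 6) {
  pixelPitch <- pixelPitch %||% attr(linescan, "pixel_pitch_um")
  lineRate <- lineRate %||% attr(linescan, "line_rate_hz")
  if (is.null(pixelPitch) || is.null(lineRate))
    stop2("pixelPitch and lineRate are required (attributes or arguments)")
  n <- nrow(linescan)
  if (n < 64) stop2("line-scan image must have at least 64 lines")
  windowLines <- min(windowLines, n)
  step <- max(1L, windowLines %/% 2L)
  starts <- unique(c(seq(1L, n - windowLines + 1L, by = step)))
  ests <- lapply(starts, function(s0)
    shear_peak(linescan[s0:(s0 + windowLines - 1L), , drop = FALSE]))
  conf <- vapply(ests, `[[`, numeric(1), "confidence")
  shift <- vapply(ests, `[[`, numeric(1), "shift")
  ok <- conf >= confidenceFloor
  overall_conf <- mean(conf)
  if (!any(ok)) {
    return(list(speed_um_s = NA_real_, confidence = overall_conf,
                low_confidence = TRUE,
                windows = data.frame(shift_px_per_line = shift,
                                     confidence = conf)))
  }
  # consensus around the most confident window: windows that disagree with
  # it by more than 20% are treated as locked onto a harmonic and dropped
  best <- abs(shift[ok][which.max(conf[ok])])
  keep <- ok & abs(abs(shift) - best) <= 0.2 * max(best, 0.5)
  s_hat <- sum(abs(shift[keep]) * conf[keep]) / sum(conf[keep])
  list(speed_um_s = s_hat * pixelPitch * lineRate,
       confidence = overall_conf, low_confidence = FALSE,
       windows = data.frame(shift_px_per_line = shift, confidence = conf))
}

# Find the shear (pixels/line) maximizing projection variance for one
# window. Coarse symmetric grid, then local golden-section refinement.
shear_peak <- function(win) {
  win <- win - mean(win)
  nr <- nrow(win); nc <- ncol(win)
  smax <- nc / 4
  grid <- seq(-smax, smax, length.out = 129)
  v <- vapply(grid, function(s) shear_variance(win, s), numeric(1))
  i <- which.max(v)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(s) shear_variance(win, s),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-4)
  valid <- v > 0  # shears outside the window's usable range report 0
  med <- if (sum(valid) >= 16) stats::median(v[valid]) else 0
  confidence <- if (med > 0) opt$objective / med else 0
  # a maximum at the edge of the searched range is not a streak peak
  smax_valid <- if (any(valid)) max(abs(grid[valid])) else 0
  if (abs(opt$maximum) > 0.97 * smax_valid) confidence <- 0
  list(shift = opt$maximum, confidence = confidence)
}

# Variance across columns of the shear-projected image: row i is displaced
# by -s*i pixels (linear interpolation) and columns are averaged.
shear_variance <- function(win, s) {
  nr <- nrow(win); nc <- ncol(win)
  acc <- numeric(nc)
  cnt <- numeric(nc)
  for (i in seq_len(nr)) {
    f <- -s * (i - 1)
    i0 <- floor(f); w <- f - i0
    j <- seq_len(nc) + i0
    ok <- j >= 1 & j <= nc
    if (any(ok)) {
      acc[j[ok]] <- acc[j[ok]] + (1 - w) * win[i, ok]
      cnt[j[ok]] <- cnt[j[ok]] + (1 - w)
    }
    j2 <- j + 1
    ok2 <- j2 >= 1 & j2 <= nc
    if (w > 0 && any(ok2)) {
      acc[j2[ok2]] <- acc[j2[ok2]] + w * win[i, ok2]
      cnt[j2[ok2]] <- cnt[j2[ok2]] + w
    }
  }
  # without real multi-row averaging the projection degenerates to raw
  # rows, whose variance rivals the aligned-streak peak; such shears are
  # outside the usable range of this window
  if (max(cnt) < 8) return(0)
  full <- cnt >= 0.5 * max(cnt)
  if (sum(full) < 4) return(0)
  stats::var(acc[full] / cnt[full])
}

# Segment descriptor in stack-relative micrometer coordinates for one edge
# of the generating graph: list(p0, p1, radius) with (z, y, x) triples.
segment_descriptor <- function(stack, graph, edgeId = 1L) {
  nd <- nodeTable(graph)
  ed <- edgeTable(graph)[edgeId, ]
  pos <- cbind(z = nd$z, y = nd$y, x = nd$x)
  rownames(pos) <- nd$name
  list(p0 = pos[ed$from, ] - stack@origin,
       p1 = pos[ed$to, ] - stack@origin,
       radius = ed$radius_um)
}

# Lumen voxel indices (n x 3, (z,y,x)) of a segment descriptor in a stack.
lumen_voxels <- function(stack, segment) {
  d <- dim(stack@data)[2:4]
  pitch <- c(stack@dz, stack@dxy, stack@dxy)
  p0 <- segment$p0; p1 <- segment$p1; r <- segment$radius
  lo <- pmax(1L, as.integer(floor((pmin(p0, p1) - r - 1) / pitch)))
  hi <- pmin(d, as.integer(ceiling((pmax(p0, p1) + r + 1) / pitch)))
  if (any(hi < lo)) return(matrix(integer(), 0, 3))
  gidx <- as.matrix(expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2],
                                x = lo[3]:hi[3]))
  cent <- sweep(gidx - 0.5, 2, pitch, `*`)
  axis <- p1 - p0
  L <- sqrt(sum(axis^2)); u <- axis / L
  rel <- sweep(cent, 2, p0)
  ax <- as.vector(rel %*% u)
  axc <- pmin(pmax(ax, 0), L)
  perp2 <- pmax(rowSums(rel^2) - 2 * ax * axc + axc^2, 0)
  gidx[perp2 <= r^2 & ax >= 0 & ax <= L, , drop = FALSE]
}

# Dark (blood cell) connected components inside the segment lumen for one
# frame. Returns a list of components with voxel index matrices and
# micrometer centroids, plus the plasma reference level used.
lumen_dark_components <- function(stack, segment, frame,
                                  darkFraction = 0.5, minVoxels = 3,
                                  plasmaLevel = NULL) {
  lum <- lumen_voxels(stack, segment)
  if (nrow(lum) == 0L) return(NULL)
  ch <- match("plasma", stack@channels)
  vals <- stack@data[cbind(frame, lum, ch)]
  if (is.null(plasmaLevel))
    plasmaLevel <- stats::quantile(vals, 0.75, names = FALSE)
  dark <- vals < darkFraction * plasmaLevel
  if (!any(dark)) {
    return(list(components = list(), plasma_level = plasmaLevel, lumen = lum))
  }
  # label within the lumen bounding box
  lo <- apply(lum, 2, min); hi <- apply(lum, 2, max)
  sub <- array(FALSE, hi - lo + 1L)
  sub[sweep(lum[dark, , drop = FALSE], 2, lo - 1L)] <- TRUE
  lab <- label_components_3d(sub)
  pitch <- c(stack@dz, stack@dxy, stack@dxy)
  comps <- list()
  for (k in seq_len(max(lab))) {
    vox <- which(lab == k, arr.ind = TRUE)
    if (nrow(vox) < minVoxels) next
    vox <- sweep(vox, 2, lo - 1L, `+`)
    centroid <- colMeans(sweep(vox - 0.5, 2, pitch, `*`))
    comps[[length(comps) + 1L]] <- list(voxels = vox, centroid = centroid)
  }
  list(components = comps, plasma_level = plasmaLevel, lumen = lum)
}

#' Ground-truth stall detection by dark-patch tracking
#'
#' Implements the operational stall definition: a capillary is stalled if a
#' dark (blood cell) patch in its lumen does not move over the observation
#' window. Dark patches are connected components of voxels below a fraction
#' of the local plasma intensity; their centroids are tracked across frames
#' (nearest neighbor against the first frame), and the segment is called
#' stalled iff every patch's maximum displacement stays below the
#' displacement resolution. The implied speed bound is
#' resolution / (frames x frame interval).
#'
#' @param stack a \linkS4class{TimeStack}.
#' @param segment a segment descriptor: list(p0, p1, radius) in
#'   stack-relative micrometers (see \code{singleVesselGraph} +
#'   \code{renderStack} for the usual source), or a
#'   \linkS4class{VesselGraph} together with \code{edgeId}.
#' @param edgeId edge index when \code{segment} is a VesselGraph.
#' @param resolutionUm displacement resolution, um (default 1).
#' @param minFrames minimum observed frames required (default 5).
#' @param darkFraction dark threshold as a fraction of plasma level.
#' @return list with \code{call} ("stalled"/"flowing"),
#'   \code{max_displacement_um}, \code{n_frames},
#'   \code{implied_speed_bound_um_s}, \code{n_patches}.
#' @export
detectStallGroundTruth <- function(stack, segment, edgeId = 1L,
                                   resolutionUm = 1, minFrames = 5,
                                   darkFraction = 0.5) {
  stopifnot(methods::is(stack, "TimeStack"))
  if (methods::is(segment, "VesselGraph"))
    segment <- segment_descriptor(stack, segment, edgeId)
  nF <- dim(stack@data)[1]
  if (nF < minFrames)
    stop2("segment observed for ", nF, " frames; at least ", minFrames,
          " are required")
  f1 <- lumen_dark_components(stack, segment, 1, darkFraction)
  if (is.null(f1) || nrow(f1$lumen) == 0L)
    stop2("segment never visible: no lumen voxels inside the stack")
  bound <- resolutionUm / (nF * stack@frameInterval)
  if (length(f1$components) == 0L) {
    return(list(call = "flowing", max_displacement_um = NA_real_,
                n_frames = nF, implied_speed_bound_um_s = bound,
                n_patches = 0L))
  }
  ref <- t(vapply(f1$components, `[[`, numeric(3), "centroid"))
  maxDisp <- 0
  for (f in 2:nF) {
    ff <- lumen_dark_components(stack, segment, f, darkFraction,
                                plasmaLevel = f1$plasma_level)
    if (length(ff$components) == 0L) { maxDisp <- Inf; break }
    cent <- t(vapply(ff$components, `[[`, numeric(3), "centroid"))
    for (k in seq_len(nrow(ref))) {
      dists <- sqrt(rowSums(sweep(cent, 2, ref[k, ])^2))
      maxDisp <- max(maxDisp, min(dists))
    }
  }
  call <- if (maxDisp < resolutionUm) "stalled" else "flowing"
  list(call = call, max_displacement_um = maxDisp, n_frames = nF,
       implied_speed_bound_um_s = bound, n_patches = nrow(ref))
}

#' Measure vessel diameter from a rendered stack by FWHM profiling
#'
#' Extracts intensity profiles perpendicular to the vessel centerline at
#' several axial positions (trilinear interpolation of the plasma channel)
#' and returns the mean full width at half maximum.
#'
#' @param stack a \linkS4class{TimeStack}.
#' @param segment segment descriptor (list(p0, p1, radius)) or a
#'   \linkS4class{VesselGraph} with \code{edgeId}.
#' @param edgeId edge index when segment is a VesselGraph.
#' @param nPositions number of axial sampling positions (>= 3).
#' @param frame frame to measure, or "max" (default) for the elementwise
#'   maximum over frames, which fills in the transient dark blood cells so
#'   the lumen profile reflects the plasma-filled caliber.
#' @return diameter, um.
#' @export
measureDiameter <- function(stack, segment, edgeId = 1L, nPositions = 5,
                            frame = "max") {
  stopifnot(methods::is(stack, "TimeStack"))
  if (methods::is(segment, "VesselGraph"))
    segment <- segment_descriptor(stack, segment, edgeId)
  nPositions <- max(3L, nPositions)
  p0 <- segment$p0; p1 <- segment$p1
  axis <- p1 - p0
  L <- sqrt(sum(axis^2)); u <- axis / L
  # perpendicular direction: least-aligned cardinal axis, orthogonalized
  cand <- diag(3)[, which.min(abs(u))]
  e1 <- cand - sum(cand * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  rmax <- segment$radius * 3 + 2
  offs <- seq(-rmax, rmax, by = 0.25)
  ts <- seq(0.3, 0.7, length.out = nPositions) * L
  use_stack <- stack
  if (identical(frame, "max")) {
    arr <- stack@data
    mx <- array(apply(arr, 2:5, max), c(1, dim(arr)[2:5]))
    use_stack <- methods::initialize(stack, data = mx)
    frame <- 1
  }
  widths <- numeric(0)
  for (tpos in ts) {
    center <- p0 + tpos * u
    pts <- t(vapply(offs, function(o) center + o * e1, numeric(3)))
    prof <- interp_stack(use_stack, pts, frame = frame, channel = "plasma")
    if (all(is.na(prof))) next
    w <- fwhm(offs, prof)
    if (!is.na(w)) widths <- c(widths, w)
  }
  if (length(widths) == 0L)
    stop2("no intensity peak found across the section; ",
          "does the vessel cross it?")
  mean(widths)
}

# Full width at half maximum of profile y(x); NA when there is no peak.
fwhm <- function(x, y) {
  ok <- !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 5) return(NA_real_)
  ymax <- max(y); ymin <- min(y)
  if (ymax - ymin < 1e-6 * max(1, ymax)) return(NA_real_)
  half <- (ymax + ymin) / 2
  ipk <- which.max(y)
  above <- y >= half
  if (!above[ipk]) return(NA_real_)
  il <- ipk
  while (il > 1 && above[il - 1]) il <- il - 1
  ir <- ipk
  while (ir < length(y) && above[ir + 1]) ir <- ir + 1
  xl <- if (il == 1) x[1] else {
    stats::approx(y[c(il - 1, il)], x[c(il - 1, il)], xout = half)$y
  }
  xr <- if (ir == length(y)) x[length(x)] else {
    stats::approx(y[c(ir, ir + 1)], x[c(ir, ir + 1)], xout = half)$y
  }
  xr - xl
}

# Trilinear interpolation of one frame/channel at micrometer (z,y,x) points.
interp_stack <- function(stack, pts, frame = 1, channel = "plasma") {
  ch <- if (is.character(channel)) match(channel, stack@channels) else channel
  d <- dim(stack@data)[2:4]
  pitch <- c(stack@dz, stack@dxy, stack@dxy)
  # continuous voxel coordinates (voxel center i at (i - 0.5) * pitch)
  vc <- sweep(pts, 2, pitch, `/`) + 0.5
  out <- rep(NA_real_, nrow(pts))
  i0 <- floor(vc)
  fr <- vc - i0
  for (n in seq_len(nrow(pts))) {
    acc <- 0; wsum <- 0; bad <- FALSE
    for (dz_ in 0:1) for (dy_ in 0:1) for (dx_ in 0:1) {
      idx <- i0[n, ] + c(dz_, dy_, dx_)
      w <- prod(ifelse(c(dz_, dy_, dx_) == 1, fr[n, ], 1 - fr[n, ]))
      if (w == 0) next
      if (any(idx < 1) || any(idx > d)) { bad <- TRUE; next }
      acc <- acc + w * stack@data[frame, idx[1], idx[2], idx[3], ch]
      wsum <- wsum + w
    }
    if (!bad && wsum > 0) out[n] <- acc / wsum
    else if (wsum > 0.5) out[n] <- acc / wsum
  }
  out
}

#' Percent change between two groups of flow measurements
#'
#' 100 * (median(after) - median(before)) / median(before), computed on
#' centerline speeds or volumetric flows. Medians (not means) summarize the
#' groups.
#'
#' @param before,after numeric vectors, or data.frames from
#'   \code{\link{flowMeasurement}}.
#' @param measure "speed" or "flow" (for data.frame input).
#' @return percent change.
#' @export
percentChange <- function(before, after, measure = c("speed", "flow")) {
  measure <- match.arg(measure)
  col <- if (measure == "speed") "speed_um_s" else "flow_um3_s"
  if (is.data.frame(before)) before <- before[[col]]
  if (is.data.frame(after)) after <- after[[col]]
  if (length(before) == 0 || length(after) == 0)
    stop2("both groups must be nonempty")
  mb <- stats::median(before)
  if (mb == 0) stop2("zero baseline median; percent change undefined")
  100 * (stats::median(after) - mb) / mb
}
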