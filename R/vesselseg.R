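# Vessel mask -> centerline skeleton -> capillary segments -> crop tasks.
# Volumes are logical/0-1 3-D arrays indexed (z, y, x); coordinates are
# 0-based voxel indices in (z, y, x) order, crop boxes half-open.

#' Mask out surface vessels / poor-SNR regions from a stack
#'
#' Voxels where the mask is zero are set to zero in every frame and
#' channel; masks are user-supplied (e.g. excluding the large surface
#' vessels and low-signal regions). Provenance is recorded as an attribute.
#'
#' @param stack a \linkS4class{TimeStack} (or plain 3-D array).
#' @param mask logical/0-1 3-D array matching the spatial shape.
#' @return the masked stack, attribute \code{masked_fraction}.
#' @export
maskSurfaceVessels <- function(stack, mask) {
  arr <- if (methods::is(stack, "TimeStack")) stack@data else stack
  sp <- if (length(dim(arr)) == 5) dim(arr)[2:4] else dim(arr)
  if (!identical(as.integer(dim(mask)), as.integer(sp)))
    stop2("mask shape (", paste(dim(mask), collapse = "x"),
          ") does not match stack spatial shape (",
          paste(sp, collapse = "x"), ")")
  keep <- mask > 0
  if (length(dim(arr)) == 5) {
    for (f in seq_len(dim(arr)[1])) for (ch in seq_len(dim(arr)[5])) {
      sl <- arr[f, , , , ch]
      sl[!keep] <- 0
      arr[f, , , , ch] <- sl
    }
  } else {
    arr[!keep] <- 0
  }
  out <- if (methods::is(stack, "TimeStack")) {
    methods::initialize(stack, data = arr)
  } else arr
  attr(out, "masked_fraction") <- mean(!keep)
  out
}

#' Extract 1-voxel-wide vessel centerlines by homotopic thinning
#'
#' Iteratively deletes simple border voxels (Malandain-Bertrand
#' characterization: exactly one 26-connected foreground component and one
#' 6-connected background component in the neighborhood) that are not curve
#' endpoints, sweeping the six face directions in turn and, within a sweep,
#' removing voxels in order of their distance to the background so the
#' skeleton stays medial. Deleting only simple points preserves homotopy:
#' connected components and loops are unchanged.
#'
#' @param binary logical/0-1 3-D array (z, y, x).
#' @return logical 3-D skeleton array of the same shape.
#' @export
extractCenterlines <- function(binary) {
  if (!(is.logical(binary) || all(binary %in% c(0, 1))))
    stop2("input volume must be binary")
  vol <- binary > 0
  if (length(dim(vol)) != 3) stop2("input must be a 3-D array")
  dirs <- neighbor_offsets(6)
  repeat {
    removed <- 0L
    for (d in seq_len(nrow(dirs))) {
      cand <- border_voxels(vol, dirs[d, ])
      if (nrow(cand) == 0L) next
      # peel outside-in: lowest distance-to-background first
      dist <- dist_to_background(vol, cand)
      cand <- cand[order(dist), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, ]
        if (!vol[p[1], p[2], p[3]]) next
        if (n_fg_neighbors(vol, p) <= 1L) next  # curve endpoint
        if (is_simple_point(vol, p)) {
          vol[p[1], p[2], p[3]] <- FALSE
          removed <- removed + 1L
        }
      }
    }
    if (removed == 0L) break
  }
  vol
}

# Out-of-volume voxels count as foreground: vessels clipped by the field
# of view continue outside it, so their ends must not erode inward.
border_voxels <- function(vol, dir) {
  d <- dim(vol)
  idx <- which(vol, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(idx)
  nb <- sweep(idx, 2, dir, `+`)
  outside <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
    nb[, 3] < 1 | nb[, 3] > d[3]
  isbg <- rep(FALSE, nrow(idx))
  inb <- nb[!outside, , drop = FALSE]
  isbg[!outside] <- !vol[inb]
  idx[isbg, , drop = FALSE]
}

n_fg_neighbors <- function(vol, p) {
  d <- dim(vol)
  offs <- neighbor_offsets(26)
  nb <- sweep(offs, 2, as.integer(p), `+`)
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  sum(vol[nb[ok, , drop = FALSE]])
}

# Simple-point test on the 3x3x3 neighborhood: the point can be deleted
# without changing topology iff (a) the foreground 26-neighbors form
# exactly one 26-connected component and (b) the background 6-neighbors
# belong to exactly one 6-connected background component within the
# 18-neighborhood.
is_simple_point <- function(vol, p) {
  d <- dim(vol)
  local <- array(FALSE, c(3, 3, 3))
  for (dz_ in -1:1) for (dy_ in -1:1) for (dx_ in -1:1) {
    q <- p + c(dz_, dy_, dx_)
    inside <- all(q >= 1) && q[1] <= d[1] && q[2] <= d[2] && q[3] <= d[3]
    # out-of-volume counts as foreground (clipped vessels continue)
    local[dz_ + 2, dy_ + 2, dx_ + 2] <- !inside || vol[q[1], q[2], q[3]]
  }
  fg <- local
  fg[2, 2, 2] <- FALSE
  nfg <- sum(fg)
  if (nfg == 0L) return(FALSE)
  if (max(label_components_3d(fg, 26)) != 1L) return(FALSE)
  # background condition: 6-components of background within the
  # 18-neighborhood containing a 6-neighbor of p
  bg <- !local
  # restrict to the 18-neighborhood (Chebyshev 1 positions with <=2 offsets)
  off <- abs(slice.index(bg, 1) - 2) + abs(slice.index(bg, 2) - 2) +
    abs(slice.index(bg, 3) - 2)
  cheb <- pmax(abs(slice.index(bg, 1) - 2),
               pmax(abs(slice.index(bg, 2) - 2),
                    abs(slice.index(bg, 3) - 2)))
  in18 <- cheb == 1 & off <= 2
  bg18 <- bg & in18
  if (!any(bg18 & off == 1)) return(FALSE)  # no background 6-neighbor
  lab <- label_components_3d(bg18, 6)
  touch <- unique(lab[bg18 & off == 1])
  length(setdiff(touch, 0L)) == 1L
}

#' Identify capillary segments between bifurcations in a skeleton
#'
#' Builds the skeleton voxel adjacency (26-connectivity with redundant
#' diagonal shortcuts removed), flags junction voxels (>= 3 neighbors) and
#' clusters junctions within 2 voxels into nodes, prunes terminal spurs
#' shorter than \code{spurThresholdUm} (re-enumerating until stable, so
#' branches separated only by a pruned spur merge), and walks the
#' degree-2 chains between nodes/endpoints into segments. Every skeleton
#' voxel belongs to exactly one segment or one node cluster.
#'
#' @param skeleton logical 3-D array from \code{\link{extractCenterlines}}.
#' @param spurThresholdUm minimum terminal branch length, um (default 5).
#' @param voxelSizeUm isotropic voxel pitch, um.
#' @param volume optional original binary volume; when given, per-segment
#'   mean radius is estimated from the distance to the background.
#' @return list of segments; each is a list with \code{id}, \code{path}
#'   (n x 3 voxel matrix, (z, y, x), 1-based), \code{endpoints} (node
#'   cluster ids, NA for a terminal end), \code{length_um},
#'   \code{radius_um} (NA without \code{volume}), plus attributes
#'   \code{nodes} (cluster list) and \code{skeleton} (the pruned skeleton).
#' @export
identifySegments <- function(skeleton, spurThresholdUm = 5,
                             voxelSizeUm = 1, volume = NULL) {
  vol <- skeleton > 0
  repeat {
    res <- enumerate_segments(vol)
    if (length(res$segments) == 0L) break
    spur <- vapply(res$segments, function(s)
      is.null(s$cycle) && xor(is.na(s$endpoints[1]), is.na(s$endpoints[2])) &&
        s$length_um(voxelSizeUm) < spurThresholdUm, logical(1))
    if (!any(spur)) break
    for (s in res$segments[spur]) {
      keep_mask <- rep(TRUE, nrow(s$path))
      # keep voxels shared with a node cluster
      vol[s$path[keep_mask, , drop = FALSE]] <- FALSE
    }
    # restore node-cluster voxels (they may be shared with other branches)
    for (ncl in res$nodes) vol[ncl$voxels] <- TRUE
  }
  res <- enumerate_segments(vol)
  segs <- lapply(seq_along(res$segments), function(i) {
    s <- res$segments[[i]]
    radius <- NA_real_
    if (!is.null(volume))
      radius <- mean(dist_to_background(volume > 0, s$path)) * voxelSizeUm
    list(id = i, path = s$path, endpoints = s$endpoints,
         length_um = s$length_um(voxelSizeUm), radius_um = radius,
         n_voxels = nrow(s$path), cycle = isTRUE(s$cycle))
  })
  attr(segs, "nodes") <- res$nodes
  attr(segs, "skeleton") <- vol
  segs
}

# Core enumeration: adjacency, junction clustering, chain walking.
enumerate_segments <- function(vol) {
  idx <- which(vol, arr.ind = TRUE)
  nV <- nrow(idx)
  if (nV == 0L) return(list(segments = list(), nodes = list()))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  id_of <- stats::setNames(seq_len(nV), key(idx))
  offs <- neighbor_offsets(26)
  ord <- rowSums(abs(offs))            # 1 = face, 2 = edge, 3 = corner
  d <- dim(vol)
  adj <- vector("list", nV)
  for (v in seq_len(nV)) {
    nb <- sweep(offs, 2, idx[v, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    hit <- ok
    hit[ok] <- vol[nb[ok, , drop = FALSE]]
    adj[[v]] <- list(ids = unname(id_of[key(nb[hit, , drop = FALSE])]),
                     ord = ord[hit])
  }
  # prune redundant diagonal shortcuts: drop a link u-v of order o if a
  # common neighbor w links to both with strictly lower order
  for (v in seq_len(nV)) {
    ids <- adj[[v]]$ids; oo <- adj[[v]]$ord
    drop <- logical(length(ids))
    for (k in seq_along(ids)) {
      if (oo[k] == 1L) next
      u <- ids[k]
      common <- intersect(ids, adj[[u]]$ids)
      for (w in common) {
        o1 <- adj[[v]]$ord[match(w, adj[[v]]$ids)]
        o2 <- adj[[u]]$ord[match(w, adj[[u]]$ids)]
        if (o1 < oo[k] && o2 < oo[k]) { drop[k] <- TRUE; break }
      }
    }
    adj[[v]]$ids <- ids[!drop]; adj[[v]]$ord <- oo[!drop]
  }
  # symmetrize (pruning decisions agree by construction, but be safe)
  deg <- vapply(adj, function(a) length(a$ids), integer(1))
  junction <- deg >= 3L
  # cluster junction voxels within Chebyshev distance 2
  nodes <- list()
  node_of <- integer(nV)
  if (any(junction)) {
    jids <- which(junction)
    visited <- logical(length(jids))
    for (s in seq_along(jids)) {
      if (visited[s]) next
      comp <- jids[s]; visited[s] <- TRUE
      queue <- jids[s]
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        cheb <- pmax(abs(idx[jids, 1] - idx[v, 1]),
                     pmax(abs(idx[jids, 2] - idx[v, 2]),
                          abs(idx[jids, 3] - idx[v, 3])))
        near <- which(!visited & cheb <= 2)
        if (length(near)) {
          visited[near] <- TRUE
          comp <- c(comp, jids[near])
          queue <- c(queue, jids[near])
        }
      }
      nodes[[length(nodes) + 1L]] <-
        list(id = length(nodes) + 1L,
             voxels = idx[comp, , drop = FALSE],
             centroid = colMeans(idx[comp, , drop = FALSE]))
      node_of[comp] <- length(nodes)
    }
  }
  # walk chains
  used <- node_of > 0L
  segments <- list()
  connector_pairs <- character(0)
  arc <- function(path) {
    force(path)
    function(pitch) path_arc_length(path) * pitch
  }
  walk <- function(start, from_node) {
    path <- integer(0)
    prev <- NA_integer_
    v <- start
    repeat {
      path <- c(path, v)
      used[v] <<- TRUE
      nxt <- setdiff(adj[[v]]$ids, c(prev))
      nxt <- nxt[node_of[nxt] == 0L & !used[nxt] |
                   (node_of[nxt] > 0L & node_of[nxt] != from_node)]
      # prefer continuing along unvisited chain voxels
      chain <- nxt[node_of[nxt] == 0L]
      if (length(chain)) {
        prev <- v; v <- chain[1]
        next
      }
      nodehit <- nxt[node_of[nxt] > 0L]
      if (length(nodehit))
        return(list(path = path, end_node = node_of[nodehit[1]]))
      return(list(path = path, end_node = NA_integer_))
    }
  }
  for (ncl in nodes) {
    members <- which(node_of == ncl$id)
    for (v in members) {
      for (u in adj[[v]]$ids) {
        if (node_of[u] == ncl$id) next
        if (node_of[u] > 0L) {
          # two node clusters directly adjacent: zero-length connector
          pair <- paste(ncl$id, node_of[u])
          if (node_of[u] > ncl$id && !pair %in% connector_pairs) {
            connector_pairs <- c(connector_pairs, pair)
            segments[[length(segments) + 1L]] <- list(
              path = idx[integer(0), , drop = FALSE],
              endpoints = c(ncl$id, node_of[u]),
              length_um = arc(idx[integer(0), , drop = FALSE]))
          }
          next
        }
        if (used[u]) next
        w <- walk(u, ncl$id)
        segments[[length(segments) + 1L]] <- list(
          path = idx[w$path, , drop = FALSE],
          endpoints = c(ncl$id, w$end_node),
          length_um = arc(idx[w$path, , drop = FALSE]))
      }
    }
  }
  # open chains starting at endpoints (degree <= 1) not yet used
  for (v in which(deg <= 1L & !used)) {
    if (used[v]) next
    w <- walk(v, 0L)
    segments[[length(segments) + 1L]] <- list(
      path = idx[w$path, , drop = FALSE],
      endpoints = c(NA_integer_, w$end_node),
      length_um = arc(idx[w$path, , drop = FALSE]))
  }
  # pure cycles: every remaining voxel has degree 2
  for (v in which(!used)) {
    if (used[v]) next
    w <- walk(v, 0L)
    segments[[length(segments) + 1L]] <- list(
      path = idx[w$path, , drop = FALSE],
      endpoints = c(NA_integer_, NA_integer_),
      length_um = arc(idx[w$path, , drop = FALSE]),
      cycle = TRUE)
  }
  list(segments = segments, nodes = nodes)
}

#' Build normalized, outlined crop tasks for annotation
#'
#' For each segment, crops a sub-stack centered on the segment (bounding
#' box plus margin), rescales intensities to span the full unit range
#' (a constant crop maps to midscale 0.5), and draws a per-plane outline as
#' the dilated centerline. Segments extending outside the stack are skipped
#' with a warning.
#'
#' @param segments list from \code{\link{identifySegments}}.
#' @param stack a \linkS4class{TimeStack} (plasma channel is cropped).
#' @param marginUm crop margin around the segment bounding box, um.
#' @param dilationRadius outline dilation radius, voxels (0 = the
#'   centerline trace itself).
#' @param kind "research" or "calibration".
#' @param calibrationTruth logical truth, required when kind =
#'   "calibration".
#' @return list of CropTask lists: \code{segment_id}, \code{bbox}
#'   (0-based, half-open, (z, y, x)), \code{substack} (t, z, y, x array in
#'   [0, 1]), \code{outline} (logical (z, y, x) array), \code{kind},
#'   \code{calibration_truth}.
#' @export
makeCropTasks <- function(segments, stack, marginUm = 5,
                          dilationRadius = 3, kind = "research",
                          calibrationTruth = NULL) {
  stopifnot(methods::is(stack, "TimeStack"))
  if (kind == "calibration" && is.null(calibrationTruth))
    stop2("calibration tasks must carry truth")
  arr <- stack@data
  d <- dim(arr)[2:4]
  pitch <- c(stack@dz, stack@dxy, stack@dxy)
  margin <- ceiling(marginUm / pitch)
  ch <- match("plasma", stack@channels)
  out <- list()
  for (s in segments) {
    if (nrow(s$path) == 0L) next
    lo <- apply(s$path, 2, min) - margin
    hi <- apply(s$path, 2, max) + margin
    if (any(s$path < 1) || any(sweep(s$path, 2, d, `>`))) {
      warn2("segment ", s$id, " lies outside the stack; skipped")
      next
    }
    lo <- pmax(1L, as.integer(lo)); hi <- pmin(d, as.integer(hi))
    sub <- arr[, lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], ch, drop = FALSE]
    sub <- array(sub, dim(sub)[1:4])
    rng <- range(sub)
    sub <- if (diff(rng) < 1e-12) array(0.5, dim(sub))
    else (sub - rng[1]) / diff(rng)
    cl <- array(FALSE, hi - lo + 1L)
    cl[sweep(s$path, 2, lo - 1L)] <- TRUE
    outline <- dilate_3d(cl, dilationRadius)
    out[[length(out) + 1L]] <- list(
      segment_id = s$id,
      bbox = list(lo = lo - 1L, hi = hi),  # 0-based half-open
      substack = sub, outline = outline, kind = kind,
      calibration_truth = if (kind == "calibration") calibrationTruth
      else NA)
  }
  out
}
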