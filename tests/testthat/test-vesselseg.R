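test_that("masking: identity, annihilation, and shape checking", {
  r <- render_single(FALSE, seed = 1)
  sp <- dim(stackArray(r$stack))[2:4]
  ones <- array(1, sp)
  m1 <- maskSurfaceVessels(r$stack, ones)
  expect_equal(stackArray(m1), stackArray(r$stack))
  zeros <- array(0, sp)
  m0 <- maskSurfaceVessels(r$stack, zeros)
  expect_true(all(stackArray(m0) == 0))
  plasma <- stackArray(m0)[1, , , , 1]
  expect_equal(length(identifySegments(extractCenterlines(plasma > 100))), 0)
  bad <- array(1, sp + c(1, 0, 0))
  expect_error(maskSurfaceVessels(r$stack, bad), "does not match")
})

test_that("masking the top planes removes the surface vessel's segments", {
  # two parallel tubes: one in the top 5 planes, one deeper
  vol <- array(FALSE, c(16, 9, 20))
  vol[2:4, 4:6, ] <- TRUE    # surface vessel
  vol[10:12, 4:6, ] <- TRUE  # deep capillary
  n_before <- length(identifySegments(extractCenterlines(vol)))
  mask <- array(1, dim(vol))
  mask[1:5, , ] <- 0
  masked <- maskSurfaceVessels(vol, mask)
  n_after <- length(identifySegments(extractCenterlines(masked > 0)))
  expect_equal(n_before, 2)
  expect_equal(n_after, 1)
})

test_that("thinning a thick tube leaves a 1-voxel line of the same extent", {
  vol <- fixture_tube(thick = 5, len = 20)
  sk <- extractCenterlines(vol)
  vox <- which(sk, arr.ind = TRUE)
  expect_lte(abs((max(vox[, 3]) - min(vox[, 3]) + 1) - 20), 2)
  # single voxel per x position = 1-voxel-wide line
  expect_true(all(table(vox[, 3]) == 1))
  expect_equal(length(identifySegments(sk)), 1)
})

test_that("non-binary input to thinning is rejected", {
  expect_error(extractCenterlines(array(runif(27), c(3, 3, 3))), "binary")
})

test_that("a Y junction yields one bifurcation node and three segments", {
  segs <- identifySegments(fixture_y(), spurThreshold = 0)
  expect_equal(length(segs), 3)
  expect_equal(length(attr(segs, "nodes")), 1)
  # all three share that node
  eps <- vapply(segs, function(s) s$endpoints[1], numeric(1))
  expect_true(all(eps == 1))
  # brute-force oracle: components after removing the junction voxel
  expect_equal(oracle_segment_count(fixture_y()), 3)
})

test_that("a loop thins to a skeleton that retains exactly one cycle", {
  sk <- extractCenterlines(fixture_torus())
  segs <- identifySegments(sk, spurThreshold = 0)
  nodes <- attr(segs, "nodes")
  closed <- vapply(segs, function(s)
    isTRUE(s$cycle) ||
      (!anyNA(s$endpoints) && s$endpoints[1] == s$endpoints[2]),
    logical(1))
  # cycle rank of the segment-level graph is 1
  n_nodes <- max(1, length(nodes))
  expect_equal(length(segs) - n_nodes + 1, 1)
  expect_true(any(closed) || length(nodes) > 0)
})

test_that("short terminal spurs are pruned and residual branches merge", {
  vol <- array(FALSE, c(3, 15, 15))
  vol[2, 8, 1:8] <- TRUE    # stem
  vol[2, 9:14, 8] <- TRUE   # long arm
  vol[2, 8, 9:10] <- TRUE   # 2-voxel spur at the junction
  with_spur <- identifySegments(vol, spurThreshold = 0)
  expect_equal(length(with_spur), 3)
  pruned <- identifySegments(vol, spurThreshold = 5)
  expect_equal(length(pruned), 1)
  expect_equal(pruned[[1]]$n_voxels, 14)  # junction dissolves into the chain
})

test_that("an empty skeleton gives an empty segment list, not an error", {
  expect_equal(length(identifySegments(array(FALSE, c(4, 4, 4)))), 0)
})

test_that("segment enumeration is idempotent and conserves skeleton voxels", {
  vol <- fixture_y()
  segs1 <- identifySegments(vol, spurThreshold = 2)
  sk1 <- attr(segs1, "skeleton")
  segs2 <- identifySegments(sk1, spurThreshold = 2)
  expect_equal(length(segs1), length(segs2))
  expect_equal(lapply(segs1, `[[`, "path"), lapply(segs2, `[[`, "path"))
  owned <- sum(vapply(segs1, function(s) s$n_voxels, integer(1))) +
    sum(vapply(attr(segs1, "nodes"), function(n) nrow(n$voxels), integer(1)))
  expect_equal(owned, sum(sk1))
})

test_that("segment radius estimates follow the vessel caliber", {
  vol <- fixture_tube(thick = 5, len = 20)
  sk <- extractCenterlines(vol)
  segs <- identifySegments(sk, volume = vol)
  expect_equal(length(segs), 1)
  expect_gt(segs[[1]]$radius_um, 1.5)
  expect_lt(segs[[1]]$radius_um, 4)
})

test_that("crop tasks are normalized, centered, and contain the centerline", {
  r <- render_single(FALSE, seed = 2, noiseSd = 2)
  plasma <- stackArray(r$stack)[1, , , , 1]
  segs <- identifySegments(extractCenterlines(plasma > 100))
  tasks <- makeCropTasks(segs, r$stack, marginUm = 3, dilationRadius = 3)
  expect_equal(length(tasks), length(segs))
  for (tk in tasks) {
    expect_equal(min(tk$substack), 0)
    expect_equal(max(tk$substack), 1)
    seg <- segs[[tk$segment_id]]
    inbox <- sweep(seg$path, 2, tk$bbox$lo) >= 1 &
      sweep(seg$path, 2, tk$bbox$hi, `<=`)
    expect_true(all(inbox))
    # outline encloses every centerline voxel
    rel <- sweep(seg$path, 2, tk$bbox$lo)
    expect_true(all(tk$outline[rel]))
  }
})

test_that("degenerate constant crops map to midscale, and zero dilation is the trace", {
  const <- methods::new("TimeStack",
                        data = array(7, c(2, 6, 6, 6, 1)), dz = 1, dxy = 1,
                        frameInterval = 1, channels = "plasma",
                        origin = c(0, 0, 0))
  seg <- list(id = 1L,
              path = cbind(z = rep(3L, 4), y = rep(3L, 4), x = 2:5),
              endpoints = c(NA, NA), length_um = 3, radius_um = 1,
              n_voxels = 4L)
  tasks <- makeCropTasks(list(seg), const, marginUm = 1, dilationRadius = 0)
  expect_true(all(tasks[[1]]$substack == 0.5))
  expect_equal(sum(tasks[[1]]$outline), 4)  # exactly the centerline voxels
})

test_that("segments outside the stack are skipped with a warning", {
  r <- render_single(FALSE, seed = 3)
  seg <- list(id = 9L, path = cbind(z = 999L, y = 2L, x = 2L),
              endpoints = c(NA, NA), length_um = 0, radius_um = 1,
              n_voxels = 1L)
  expect_warning(tk <- makeCropTasks(list(seg), r$stack), "outside")
  expect_equal(length(tk), 0)
})

test_that("calibration tasks must carry truth", {
  r <- render_single(FALSE, seed = 4)
  seg <- list(id = 1L, path = cbind(z = 5L, y = 5L, x = 5L),
              endpoints = c(NA, NA), length_um = 0, radius_um = 1,
              n_voxels = 1L)
  expect_error(makeCropTasks(list(seg), r$stack, kind = "calibration"),
               "truth")
})
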