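test_that("zero stall rate yields a graph with no stalled edges", {
  vg <- generateNetwork(3, 50, stallRate = 0, seed = 1)
  ed <- edgeTable(vg)
  expect_equal(sum(ed$is_stalled), 0)
  expect_true(all(ed$stall_cause == "none"))
})

test_that("an invalid composition simplex is rejected naming the fields", {
  expect_error(
    generateNetwork(2, 20, composition = c(leukocyte = 0.9, platelet = 0.2,
                                           rbc_only = 0.1), seed = 1),
    "invalid simplex.*leukocyte")
  expect_error(
    generateNetwork(2, 20, composition = c(wrong = 1, platelet = 0,
                                           rbc_only = 0), seed = 1),
    "named over")
})

test_that("stalled edges match an independent re-draw of the documented stream", {
  vg <- generateNetwork(10, 50, stallRate = 0.02, seed = 42)
  ed <- edgeTable(vg)
  cap <- ed$branch_order >= 1
  set.seed(43)  # stall uniforms use seed + 1, one per capillary edge
  u <- runif(sum(cap))
  expect_identical(which(ed$is_stalled[cap]), which(u < 0.02))
})

test_that("stall-cause fractions recover the configured mix over many stalls", {
  vg <- generateNetwork(6, 18000, stallRate = 0.1,
                        composition = c(leukocyte = 0.86, platelet = 0.05,
                                        rbc_only = 0.09),
                        loopFraction = 0, seed = 7)
  ed <- edgeTable(vg)
  causes <- ed$stall_cause[ed$is_stalled]
  expect_gt(length(causes), 10000)
  frac <- 100 * table(factor(causes, c("leukocyte", "platelet",
                                       "rbc_only"))) / length(causes)
  expect_lt(abs(frac[["leukocyte"]] - 86), 2)
  expect_lt(abs(frac[["platelet"]] - 5), 2)
  expect_lt(abs(frac[["rbc_only"]] - 9), 2)
  # composition conservation: counts partition the stalled set exactly
  expect_equal(sum(table(causes)), sum(ed$is_stalled))
})

test_that("network invariants hold: connectivity, radii, speeds, branch order", {
  vg <- generateNetwork(4, 120, stallRate = 0.05, seed = 11)
  expect_true(igraph::is_connected(vg@graph))
  ed <- edgeTable(vg)
  cap <- ed$branch_order >= 1
  expect_true(all(ed$radius_um[cap] >= 1.5 & ed$radius_um[cap] <= 4))
  expect_true(all(ed$speed_um_s[ed$is_stalled] == 0))
  # stall_cause is "none" exactly on the flowing edges
  expect_true(all(xor(ed$is_stalled, ed$stall_cause == "none")))
  # branch order = 1 + min branch order of adjacent upstream edges
  g <- vg@graph
  for (i in which(cap)) {
    ends <- igraph::ends(g, i)
    inc <- setdiff(unlist(igraph::incident_edges(
      g, igraph::V(g)[ends])), i)
    expect_equal(ed$branch_order[i],
                 1L + min(ed$branch_order[as.integer(inc)]))
  }
})

test_that("identical seeds give identical graphs, pools, and logs", {
  a <- edgeTable(generateNetwork(3, 80, stallRate = 0.03, seed = 5))
  b <- edgeTable(generateNetwork(3, 80, stallRate = 0.03, seed = 5))
  expect_identical(a, b)
  p1 <- playerTable(generatePlayers(20, seed = 5))
  p2 <- playerTable(generatePlayers(20, seed = 5))
  expect_identical(p1, p2)
  l1 <- generateBehavior(5, seed = 5)
  l2 <- generateBehavior(5, seed = 5)
  expect_identical(l1, l2)
  s1 <- stackArray(render_single(TRUE, seed = 5)$stack)
  s2 <- stackArray(render_single(TRUE, seed = 5)$stack)
  expect_identical(s1, s2)
})

test_that("a rendered leukocyte stall is static and co-labelled", {
  r <- render_single(TRUE, "leukocyte", seed = 2)
  det <- detectStallGroundTruth(r$stack, r$seg)
  expect_equal(det$call, "stalled")
  expect_lt(det$max_displacement_um, 1)
  expect_equal(classifyStallCause(r$stack, r$seg), "leukocyte")
})

test_that("a flowing patch advances by speed x frame interval between frames", {
  r <- render_single(FALSE, speed = 2, len = 40, maxPatches = 1,
                     noiseSd = 0, seed = 1)
  cents <- lapply(1:5, function(f)
    stallflow:::lumen_dark_components(r$stack, r$seg, f)$components[[1]]$centroid)
  steps <- vapply(1:4, function(f)
    sqrt(sum((cents[[f + 1]] - cents[[f]])^2)), numeric(1))
  expect_true(all(abs(steps - 2) < 0.5))
})

test_that("an all-flowing graph produces zero ground-truth stall calls", {
  vg <- generateNetwork(2, 6, stallRate = 0, seed = 8)
  ed <- edgeTable(vg)
  calls <- vapply(which(ed$branch_order >= 1), function(i) {
    r <- renderSegmentCrop(vg, i, seed = i)
    detectStallGroundTruth(r$stack, r$segment)$call
  }, character(1))
  expect_true(all(calls == "flowing"))
})

test_that("a fov outside the graph bounding box is an empty-field error", {
  vg <- singleVesselGraph(c(5, 5, 0), c(5, 5, 20))
  expect_error(renderStack(vg, fov = c(10, 10, 10), origin = c(500, 500, 500)),
               "empty field")
})

test_that("line scans: stationary cells give vertical streaks", {
  ls <- renderLinescan(0, scanRate = 1000, duration = 0.1, seed = 1)
  # every row identical: dark columns do not move
  expect_true(all(apply(ls, 2, function(col) length(unique(col)) == 1)))
})

test_that("line-scan velocimetry round-trips a known speed within 2%", {
  ls <- renderLinescan(1000, scanRate = 2000, duration = 0.2, seed = 4)
  est <- estimateSpeed(ls)
  expect_false(est$low_confidence)
  expect_lt(abs(est$speed_um_s / 1000 - 1), 0.02)
})

test_that("very noisy line scans are flagged instead of silently estimated", {
  set.seed(9)
  noise <- matrix(rnorm(128 * 64, 100, 50), 128, 64)
  est <- estimateSpeed(noise, pixelPitch = 0.5, lineRate = 1000)
  expect_true(est$low_confidence)
  expect_true(is.na(est$speed_um_s))
})

test_that("aliasing-range speeds trigger a warning at render time", {
  expect_warning(renderLinescan(1e6, scanRate = 1000, duration = 0.1,
                                seed = 1), "aliasing")
})

test_that("player pools: size, fixed skill, and Beta mean", {
  expect_error(generatePlayers(0), "at least one")
  p <- playerTable(generatePlayers(3, fixed = 1.0, seed = 1))
  expect_true(all(p$sensitivity == 1 & p$specificity == 1))
  pp <- playerTable(generatePlayers(100, 8, 2, seed = 2))
  expect_lt(abs(mean(pp$sensitivity) - 0.8), 0.04)
  expect_true(all(pp$sensitivity >= 0 & pp$sensitivity <= 1))
})

test_that("behavior generator hits configured preference and alternation", {
  logs50 <- generateBehavior(1000, orPreference = 0.5, seed = 1)
  or50 <- vapply(logs50, function(l)
    orPreference(l$exploration[["novel"]], l$exploration[["familiar"]]),
    numeric(1))
  expect_lt(abs(mean(or50) - 50), 2)
  logs60 <- generateBehavior(1000, orPreference = 0.6, seed = 2)
  or60 <- vapply(logs60, function(l)
    orPreference(l$exploration[["novel"]], l$exploration[["familiar"]]),
    numeric(1))
  expect_lt(abs(mean(or60) - 60), 2)
  perfect <- generateBehavior(50, alternationAvoid = 1, seed = 3)
  alt <- vapply(perfect, function(l) alternationScore(l$arm_entries),
                numeric(1))
  expect_true(all(alt == 100))
  expect_error(generateBehavior(2, orPreference = 1.5), "\\[0, 1\\]")
})
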