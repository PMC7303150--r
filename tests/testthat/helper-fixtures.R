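# Fixtures built in code: small binary volumes with known topology, and
# convenience wrappers for rendered single-vessel stacks.

# Thick straight tube along x.
fixture_tube <- function(thick = 5, len = 20) {
  pad <- 2
  d <- thick + 2 * pad
  vol <- array(FALSE, c(d, d, len))
  vol[pad + seq_len(thick), pad + seq_len(thick), ] <- TRUE
  vol
}

# Thin Y: an x stem, a +y arm, a diagonal arm, meeting at (2, 8, 8).
fixture_y <- function() {
  vol <- array(FALSE, c(3, 15, 15))
  vol[2, 8, 1:8] <- TRUE
  vol[2, 9:14, 8] <- TRUE
  for (k in 1:6) vol[2, 8 - k, 8 + k] <- TRUE
  vol
}

# Thick square annulus (torus-like loop).
fixture_torus <- function() {
  vol <- array(FALSE, c(5, 12, 12))
  vol[2:4, 3:9, 3:9] <- TRUE
  vol[2:4, 5:7, 5:7] <- FALSE
  vol
}

# Rendered stack around one capillary along x; returns list(stack, seg).
render_single <- function(stalled, cause = "leukocyte", speed = 800,
                          radius = 2.5, len = 28, seed = 1, ...) {
  vg <- singleVesselGraph(c(8, 6, 2), c(8, 6, 2 + len), radius = radius,
                          stalled = stalled, cause = cause, speed = speed)
  st <- renderStack(vg, seed = seed, ...)
  list(stack = st, seg = stallflow:::segment_descriptor(st, vg),
       graph = vg)
}

# Independent brute-force segment counter: connected components of the
# skeleton after deleting junction voxels (>= 3 neighbors under pruned
# 26-adjacency is approximated here by plain 26-adjacency on thin
# axis-aligned fixtures).
oracle_segment_count <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(0L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    adj[i, j] <- max(abs(idx[i, ] - idx[j, ])) == 1
  }
  deg <- rowSums(adj)
  keep <- deg <= 2
  if (!any(keep)) return(0L)
  sub <- adj[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  igraph::components(g)$no
}
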