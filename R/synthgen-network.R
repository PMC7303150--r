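#' Generate a synthetic cortical microvascular network with known stalls
#'
#' Builds a layered random geometric network: a chain of surface arterioles
#' feeding penetrating arterioles (PAs), each of which supplies a
#' binary-branching capillary bed. Every capillary edge carries a
#' ground-truth flow state: a per-edge uniform draw below \code{stallRate}
#' marks it stalled (speed 0) with a cause drawn from \code{composition};
#' flowing capillaries get log-normal centerline speeds.
#'
#' RNG streams are documented and reproducible: geometry uses
#' \code{seed}, the per-edge stall uniforms use \code{seed + 1} (one
#' \code{runif} per capillary edge, in increasing edge-id order), causes use
#' \code{seed + 2} (one categorical draw per stalled edge, in stalled-edge
#' id order) and flowing speeds use \code{seed + 3}.
#'
#' @param nPenetrating number of penetrating arterioles.
#' @param capillariesPerPA number of capillary segments in each PA's bed.
#' @param stallRate per-capillary stall probability, in [0, 0.1].
#' @param composition named 3-simplex over stall causes
#'   \code{c(leukocyte=, platelet=, rbc_only=)}; must sum to 1 (1e-9).
#' @param speedMedianUm median flowing-capillary centerline speed, um/s.
#' @param speedSdlog log-SD of the flowing speed distribution.
#' @param lengthMedianUm median capillary segment length, um.
#' @param loopFraction anastomotic cross-links added per PA bed as a
#'   fraction of its tree edges (capillary beds are meshes, not pure
#'   trees; loops provide the redundancy that lets flow reroute around an
#'   occlusion).
#' @param seed integer RNG seed, or NULL to use the current stream.
#' @return a \linkS4class{VesselGraph}.
#' @examples
#' vg <- generateNetwork(nPenetrating = 2, capillariesPerPA = 30,
#'                       stallRate = 0.02, seed = 1)
#' vg
#' @export
generateNetwork <- function(nPenetrating,
                            capillariesPerPA,
                            stallRate = 0.01,
                            composition = c(leukocyte = 0.86,
                                            platelet = 0.05,
                                            rbc_only = 0.09),
                            speedMedianUm = 800,
                            speedSdlog = 0.35,
                            lengthMedianUm = 55,
                            loopFraction = 0.3,
                            seed = NULL) {
  if (nPenetrating < 1 || capillariesPerPA < 1)
    stop2("need at least one penetrating arteriole and one capillary")
  if (stallRate < 0 || stallRate > 0.1)
    stop2("stallRate must lie in [0, 0.1]")
  causes <- c("leukocyte", "platelet", "rbc_only")
  if (is.null(names(composition)))
    names(composition) <- causes
  if (!setequal(names(composition), causes))
    stop2("composition must be named over {leukocyte, platelet, rbc_only}; ",
          "got fields: ", paste(names(composition), collapse = ", "))
  if (abs(sum(composition) - 1) > 1e-9)
    stop2("invalid simplex: composition (",
          paste(sprintf("%s=%g", names(composition), composition),
                collapse = ", "),
          ") sums to ", format(sum(composition), digits = 12), ", not 1")
  composition <- composition[causes]

  seed <- if (is.null(seed)) NULL else as.integer(seed)

  geom <- with_seed_or_not(seed, build_network_geometry(
    nPenetrating, capillariesPerPA, lengthMedianUm, loopFraction))
  edges <- geom$edges
  nodes <- geom$nodes

  cap <- which(edges$branch_order >= 1)  # capillary edges, id order
  nCap <- length(cap)

  u <- with_seed_or_not(if (is.null(seed)) NULL else seed + 1L,
                        stats::runif(nCap))
  stalled <- u < stallRate

  edges$is_stalled <- FALSE
  edges$is_stalled[cap] <- stalled
  edges$stall_cause <- "none"
  nStalled <- sum(stalled)
  if (nStalled > 0) {
    drawn <- with_seed_or_not(if (is.null(seed)) NULL else seed + 2L,
                              sample(causes, nStalled, replace = TRUE,
                                     prob = composition))
    edges$stall_cause[cap[stalled]] <- drawn
  }

  speeds <- with_seed_or_not(if (is.null(seed)) NULL else seed + 3L,
                             stats::rlnorm(nCap, meanlog = log(speedMedianUm),
                                           sdlog = speedSdlog))
  edges$speed_um_s <- 0
  # surface and PA edges: fast arteriolar flow (fixed nominal values)
  edges$speed_um_s[edges$kind == "surface"] <- 8000
  edges$speed_um_s[edges$kind == "pa"] <- 6000
  edges$speed_um_s[cap] <- ifelse(stalled, 0, speeds)
  edges$kind <- NULL

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  methods::new("VesselGraph", graph = g)
}

# Deterministic-given-RNG-state geometry builder. Node ids are strings.
build_network_geometry <- function(nPA, capPerPA, lengthMedianUm,
                                   loopFraction = 0.3) {
  nodes <- data.frame(name = character(), kind = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = character(), to = character(),
                      radius_um = numeric(), length_um = numeric(),
                      branch_order = integer(), kind = character(),
                      stringsAsFactors = FALSE)
  spacing <- 250  # um between PA territories on the surface
  # surface arteriole chain at z = 0
  sn <- paste0("S", seq_len(nPA))
  nodes <- rbind(nodes, data.frame(
    name = sn, kind = "surface-arteriole",
    x = (seq_len(nPA) - 1) * spacing, y = 0, z = 0))
  if (nPA > 1) {
    edges <- rbind(edges, data.frame(
      from = sn[-nPA], to = sn[-1], radius_um = 12,
      length_um = spacing, branch_order = 0L, kind = "surface"))
  }
  for (p in seq_len(nPA)) {
    base <- paste0("P", p)
    bx <- (p - 1) * spacing
    nodes <- rbind(nodes, data.frame(
      name = base, kind = "penetrating-arteriole", x = bx, y = 0, z = 120))
    edges <- rbind(edges, data.frame(
      from = sn[p], to = base, radius_um = 6, length_um = 120,
      branch_order = 0L, kind = "pa"))
    tree <- build_capillary_tree(base, capPerPA, c(120, 0, bx),
                                 lengthMedianUm, prefix = paste0("C", p, "_"),
                                 loopFraction = loopFraction)
    nodes <- rbind(nodes, tree$nodes)
    edges <- rbind(edges, tree$edges)
  }
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

# Binary-branching capillary tree below one PA using heap indexing:
# capillary edge i (1..m) joins node floor(i/2) to node i (node 0 = PA base);
# its branch order is floor(log2(i)) + 1. Radii taper with branch order
# (pre-capillary branches near the PA are wider than deep true
# capillaries), and anastomotic cross-links between same-depth nodes close
# loops. Cross-link branch order is 1 + min(upstream branch orders).
build_capillary_tree <- function(baseName, m, basePos, lengthMedianUm,
                                 prefix, loopFraction = 0.3) {
  ids <- seq_len(m)
  parent <- ids %/% 2L
  order <- as.integer(floor(log2(ids)) + 1)
  len <- stats::rlnorm(m, meanlog = log(lengthMedianUm), sdlog = 0.25)
  radius <- pmin(4, pmax(1.5, 4 * 0.85^(order - 1) *
                           stats::rlnorm(m, 0, 0.08)))
  # random outward directions, biased downward into the cortex
  theta <- stats::runif(m, 0, 2 * pi)
  dzc <- stats::runif(m, 0.2, 0.9)
  horiz <- sqrt(pmax(0, 1 - dzc^2))
  dir <- cbind(z = dzc, y = horiz * sin(theta), x = horiz * cos(theta))
  pos <- matrix(NA_real_, nrow = m + 1, ncol = 3)  # row i+1 = node i, (z,y,x)
  pos[1, ] <- basePos
  for (i in ids) pos[i + 1, ] <- pos[parent[i] + 1, ] + dir[i, ] * len[i]
  nodeName <- function(i) ifelse(i == 0L, baseName, paste0(prefix, i))
  nodes <- data.frame(
    name = paste0(prefix, ids), kind = "capillary-junction",
    x = pos[ids + 1, 3], y = pos[ids + 1, 2], z = pos[ids + 1, 1])
  edges <- data.frame(
    from = nodeName(parent), to = paste0(prefix, ids),
    radius_um = radius, length_um = len, branch_order = order,
    kind = "capillary")
  nLoop <- round(loopFraction * m)
  if (nLoop > 0 && m >= 4) {
    depth <- order  # node i sits below edge i: depth(node i) = order(i)
    la <- sample(ids, nLoop, replace = TRUE)
    lb <- vapply(la, function(a) {
      cand <- ids[depth == depth[a] & ids != a]
      if (length(cand) == 0) NA_integer_ else cand[sample.int(length(cand), 1)]
    }, integer(1))
    ok <- !is.na(lb) & la != lb
    la <- la[ok]; lb <- lb[ok]
    if (length(la)) {
      dup <- duplicated(paste(pmin(la, lb), pmax(la, lb)))
      la <- la[!dup]; lb <- lb[!dup]
    }
    if (length(la)) {
      llen <- sqrt(rowSums((pos[la + 1, , drop = FALSE] -
                              pos[lb + 1, , drop = FALSE])^2))
      keep <- llen > 1
      la <- la[keep]; lb <- lb[keep]; llen <- llen[keep]
      if (length(la)) {
        lord <- as.integer(pmin(depth[la], depth[lb]) + 1L)
        lrad <- pmin(4, pmax(1.5, 4 * 0.85^(lord - 1) *
                               stats::rlnorm(length(la), 0, 0.08)))
        edges <- rbind(edges, data.frame(
          from = paste0(prefix, la), to = paste0(prefix, lb),
          radius_um = lrad, length_um = llen, branch_order = lord,
          kind = "capillary"))
      }
    }
  }
  list(nodes = nodes, edges = edges)
}

#' Build a minimal single-vessel graph (one capillary between two junctions)
#'
#' Convenience constructor used for rendering and measurement tests: a
#' single capillary segment with explicit endpoints (micrometer (z, y, x)
#' triples), radius, flow state and cause.
#'
#' @param p0,p1 numeric(3) micrometer (z, y, x) endpoints.
#' @param radius capillary radius, um.
#' @param stalled logical; is the segment stalled?
#' @param cause stall cause when stalled.
#' @param speed centerline speed um/s (forced to 0 when stalled).
#' @return a \linkS4class{VesselGraph} with one edge.
#' @export
singleVesselGraph <- function(p0, p1, radius = 2.5, stalled = FALSE,
                              cause = c("leukocyte", "platelet", "rbc_only"),
                              speed = 800) {
  cause <- match.arg(cause)
  nodes <- data.frame(name = c("a", "b"), kind = "capillary-junction",
                      x = c(p0[3], p1[3]), y = c(p0[2], p1[2]),
                      z = c(p0[1], p1[1]))
  edges <- data.frame(
    from = "a", to = "b", radius_um = radius,
    length_um = sqrt(sum((p1 - p0)^2)), branch_order = 1L,
    is_stalled = stalled, stall_cause = if (stalled) cause else "none",
    speed_um_s = if (stalled) 0 else speed)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  methods::new("VesselGraph", graph = g)
}
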