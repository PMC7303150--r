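#' Classify the cellular cause of a stalled capillary from channel logic
#'
#' Leukocytes are labelled by both rhodamine (mitochondria) and hoechst
#' (DNA), platelets by rhodamine only, and red blood cells by neither
#' (dark patch only). The static dark patch is located in the first frame;
#' a channel is positive when its mean intensity over the patch exceeds
#' \code{k} times the background (median channel intensity over lumen
#' voxels outside the patch).
#'
#' @param stack a \linkS4class{TimeStack} containing the stalled segment.
#' @param segment segment descriptor (list(p0, p1, radius), stack-relative
#'   micrometers) or a \linkS4class{VesselGraph} with \code{edgeId}.
#' @param edgeId edge index when segment is a VesselGraph.
#' @param k positivity factor over background (default 2).
#' @return "leukocyte", "platelet", "rbc_only", or "ambiguous" (hoechst
#'   without rhodamine; logged via warning).
#' @export
classifyStallCause <- function(stack, segment, edgeId = 1L, k = 2) {
  stopifnot(methods::is(stack, "TimeStack"))
  if (methods::is(segment, "VesselGraph"))
    segment <- segment_descriptor(stack, segment, edgeId)
  f1 <- lumen_dark_components(stack, segment, 1)
  if (is.null(f1) || length(f1$components) == 0L)
    stop2("no dark patch found in the segment lumen; ",
          "cause classification requires a stalled segment")
  # the (static) patch = largest dark component
  sizes <- vapply(f1$components, function(cc) nrow(cc$voxels), integer(1))
  patch <- f1$components[[which.max(sizes)]]$voxels
  lum <- f1$lumen
  inpatch <- paste(lum[, 1], lum[, 2], lum[, 3]) %in%
    paste(patch[, 1], patch[, 2], patch[, 3])
  chmean <- function(chname, vox)
    mean(stack@data[cbind(1, vox, match(chname, stack@channels))])
  bg_vox <- lum[!inpatch, , drop = FALSE]
  if (nrow(bg_vox) == 0L) bg_vox <- lum
  rho_bg <- stats::median(
    stack@data[cbind(1, bg_vox, match("rhodamine", stack@channels))])
  hoe_bg <- stats::median(
    stack@data[cbind(1, bg_vox, match("hoechst", stack@channels))])
  rho_pos <- chmean("rhodamine", patch) > k * max(rho_bg, 1e-6)
  hoe_pos <- chmean("hoechst", patch) > k * max(hoe_bg, 1e-6)
  if (rho_pos && hoe_pos) "leukocyte"
  else if (rho_pos) "platelet"
  else if (hoe_pos) {
    warn2("hoechst-positive but rhodamine-negative patch: ambiguous")
    "ambiguous"
  } else "rbc_only"
}

#' Stall prevalence and composition summaries per stack and group
#'
#' The reported stall fraction of an image stack is the number of
#' expert-confirmed stalled segments divided by the total number of
#' capillary segments in that stack, exactly. Group rows carry the mean and
#' SD of the per-stack fractions.
#'
#' @param tables list of finalized \linkS4class{StallCallTable}s (one per
#'   stack, after \code{\link{expertTriage}}).
#' @param groups character vector of group labels, one per stack.
#' @param causes optional list of per-stack character vectors with the
#'   classified cause of each confirmed stall.
#' @return list with \code{per_stack} (stack_id, group, n_segments,
#'   n_stalled, stall_fraction, composition counts) and \code{per_group}
#'   (group, mean_fraction, sd_fraction).
#' @export
stallSummary <- function(tables, groups = NULL, causes = NULL) {
  if (methods::is(tables, "StallCallTable")) tables <- list(tables)
  n <- length(tables)
  groups <- groups %||% rep("all", n)
  per <- do.call(rbind, lapply(seq_len(n), function(i) {
    calls <- callTable(tables[[i]])
    if (nrow(calls) == 0) stop2("stack ", i, " has zero segments")
    ns <- sum(calls$expert_verdict == "stalled")
    cc <- c(leukocyte = 0L, platelet = 0L, rbc_only = 0L)
    if (!is.null(causes)) {
      tb <- table(factor(causes[[i]], levels = names(cc)))
      cc[names(tb)] <- as.integer(tb)
    }
    data.frame(stack_id = i, group = groups[i], n_segments = nrow(calls),
               n_stalled = ns, stall_fraction = ns / nrow(calls),
               leukocyte = cc[["leukocyte"]], platelet = cc[["platelet"]],
               rbc_only = cc[["rbc_only"]])
  }))
  grp <- do.call(rbind, lapply(split(per, per$group), function(d)
    data.frame(group = d$group[1], n_stacks = nrow(d),
               mean_fraction = mean(d$stall_fraction),
               sd_fraction = stats::sd(d$stall_fraction))))
  rownames(grp) <- NULL
  list(per_stack = per, per_group = grp)
}

#' Tiered arithmetic model of the CBF deficit from capillary stalls
#'
#' With a fraction p of capillaries occluded (0\% of baseline flow), the
#' vessels 1, 2, and 3-4 branches downstream of each occlusion are reduced
#' to fixed fractions of baseline flow. Tier affected fractions double per
#' branch (2p, 4p, 8p with tiers 3-4 pooled) and the default multipliers
#' are 0.10, 0.25 and 0.50 of baseline. The predicted CBF decrease is
#' 100 [ p + sum_k n_k (1 - m_k) ]: at p = 0.02 this is
#' 2 + 3.6 + 6 + 8 = 19.6\%.
#'
#' Downstream sets of distinct stalls are assumed not to interact; the
#' model is linear in p.
#'
#' @param p occluded capillary fraction.
#' @param multipliers per-tier flow multipliers m_k in [0, 1].
#' @param affectedPerOcclusion per-tier affected fraction per unit p
#'   (default c(2, 4, 8): doubling per branch order, tiers 3-4 pooled).
#' @return percent CBF decrease.
#' @examples
#' arithmeticDeficit(0.02)  # 19.6
#' @export
arithmeticDeficit <- function(p,
                              multipliers = c(0.10, 0.25, 0.50),
                              affectedPerOcclusion = c(2, 4, 8)) {
  if (p < 0 || p > 1) stop2("p must lie in [0, 1]")
  if (length(multipliers) != length(affectedPerOcclusion))
    stop2("multipliers and affectedPerOcclusion must align")
  if (any(multipliers < 0 | multipliers > 1))
    stop2("flow multipliers must lie in [0, 1]")
  n <- p * affectedPerOcclusion
  if (p + sum(n) > 1 + 1e-9)
    stop2("affected fractions plus p exceed 1; model assumptions violated")
  100 * (p + sum(n * (1 - multipliers)))
}

#' Linear network model of the CBF deficit from a stalled edge set
#'
#' A simplified Poiseuille solver (not a full computational fluid dynamics
#' model): each edge has conductance proportional to radius^4 / length,
#' flow is conserved at interior nodes, inlet nodes are held at unit
#' pressure and outlets at zero. The deficit is the percent decrease of
#' total inlet flow when the stalled edges' conductances are set to zero.
#'
#' @param graph a \linkS4class{VesselGraph}.
#' @param stalledEdges integer edge indices to occlude; default: the edges
#'   marked stalled in the graph.
#' @param inlets,outlets vertex names; defaults: surface-arteriole nodes as
#'   inlets and terminal (degree-1) capillary junctions as outlets.
#' @return percent CBF decrease; attributes \code{flow_baseline},
#'   \code{flow_stalled}, \code{residual} (max interior node flow imbalance
#'   relative to inlet flow).
#' @export
networkDeficit <- function(graph, stalledEdges = NULL, inlets = NULL,
                           outlets = NULL) {
  stopifnot(methods::is(graph, "VesselGraph"))
  g <- graph@graph
  ed <- edgeTable(graph)
  nd <- nodeTable(graph)
  if (is.null(stalledEdges)) stalledEdges <- which(ed$is_stalled)
  deg <- igraph::degree(g)
  if (is.null(inlets)) {
    inlets <- nd$name[nd$kind == "surface-arteriole"]
    if (length(inlets) == 0) inlets <- nd$name[deg == 1][1]
  }
  if (is.null(outlets)) {
    outlets <- setdiff(nd$name[nd$kind == "capillary-junction" & deg == 1],
                       inlets)
    if (length(outlets) == 0) outlets <- setdiff(nd$name[deg == 1], inlets)
  }
  if (length(inlets) == 0 || length(outlets) == 0)
    stop2("need at least one inlet and one outlet")
  gcond <- ed$radius_um^4 / ed$length_um
  f0 <- solve_network_flow(g, nd$name, gcond, inlets, outlets)
  gs <- gcond
  gs[stalledEdges] <- 0
  f1 <- solve_network_flow(g, nd$name, gs, inlets, outlets)
  if (f0$inflow <= 0) stop2("no baseline flow from inlets to outlets")
  if (f1$disconnected)
    warn2("stalling disconnects part of the network from the outlets; ",
          "the isolated component contributes a 100% local deficit")
  deficit <- 100 * (1 - f1$inflow / f0$inflow)
  structure(deficit, flow_baseline = f0$inflow, flow_stalled = f1$inflow,
            residual = max(f0$residual, f1$residual))
}

# Solve node pressures with Dirichlet conditions (inlets at 1, outlets at
# 0) and return total inlet flow plus the flow-conservation residual.
solve_network_flow <- function(g, vnames, cond, inlets, outlets) {
  n <- length(vnames)
  el <- igraph::as_edgelist(g, names = FALSE)
  keep <- cond > 0
  el <- el[keep, , drop = FALSE]
  cw <- cond[keep]
  iIn <- match(inlets, vnames)
  iOut <- match(outlets, vnames)
  fixed <- c(iIn, iOut)
  pfix <- c(rep(1, length(iIn)), rep(0, length(iOut)))
  # weighted graph Laplacian
  L <- Matrix::sparseMatrix(
    i = c(el[, 1], el[, 2]), j = c(el[, 2], el[, 1]),
    x = c(-cw, -cw), dims = c(n, n))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  free <- setdiff(seq_len(n), fixed)
  P <- numeric(n)
  P[fixed] <- pfix
  # an inlet sharing no component with any outlet feeds nothing (100%
  # local deficit)
  gall <- igraph::make_graph(as.vector(t(el)), n = n, directed = FALSE)
  compall <- igraph::components(gall)$membership
  disconnected <- !all(compall[iIn] %in% compall[iOut])
  if (length(free) > 0) {
    # nodes isolated from all Dirichlet nodes make A singular; solve the
    # connected part and leave isolated nodes at zero flow
    gk <- igraph::make_graph(as.vector(t(el)), n = n, directed = FALSE)
    comp <- igraph::components(gk)
    anchored <- unique(comp$membership[fixed])
    live <- free[comp$membership[free] %in% anchored]
    if (length(live) < length(free)) disconnected <- TRUE
    if (length(live) > 0) {
      Al <- L[live, live, drop = FALSE]
      bl <- -L[live, fixed, drop = FALSE] %*% pfix
      P[live] <- as.numeric(Matrix::solve(Al, bl))
    }
  }
  # edge flows and node balance
  fl <- cw * (P[el[, 1]] - P[el[, 2]])
  net <- numeric(n)
  for (k in seq_along(fl)) {
    net[el[k, 1]] <- net[el[k, 1]] - fl[k]
    net[el[k, 2]] <- net[el[k, 2]] + fl[k]
  }
  inflow <- -sum(net[iIn])
  interior <- setdiff(seq_len(n), fixed)
  residual <- if (length(interior) && inflow > 0)
    max(abs(net[interior])) / inflow else 0
  list(inflow = inflow, residual = residual, disconnected = disconnected)
}
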