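#' @import methods
NULL

#' VesselGraph: a cortical microvascular network with ground-truth flow state
#'
#' An S4 container wrapping an \pkg{igraph} graph whose vertices are vessel
#' junctions (surface arterioles, penetrating arterioles, capillary
#' junctions) and whose edges are vessel segments carrying geometry
#' (radius and length in micrometers), topology (branch order downstream of
#' a penetrating arteriole) and ground-truth hemodynamic state (stalled or
#' flowing, stall cause, centerline red blood cell speed).
#'
#' Vertex attributes: \code{name}, \code{kind} (one of
#' \code{"surface-arteriole"}, \code{"penetrating-arteriole"},
#' \code{"capillary-junction"}), \code{x}, \code{y}, \code{z} (micrometers,
#' z increasing with cortical depth). Edge attributes: \code{radius_um},
#' \code{length_um}, \code{branch_order}, \code{is_stalled},
#' \code{stall_cause} (\code{"leukocyte"}, \code{"platelet"},
#' \code{"rbc_only"} or \code{"none"}), \code{speed_um_s}.
#'
#' @slot graph an \code{igraph} object with the attributes above.
#' @export
setClass("VesselGraph", representation(graph = "ANY"))

setValidity("VesselGraph", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("slot 'graph' must be an igraph object")
  msgs <- character()
  need_v <- c("kind", "x", "y", "z")
  miss <- setdiff(need_v, igraph::vertex_attr_names(g))
  if (length(miss)) msgs <- c(msgs, paste("missing vertex attributes:",
                                          paste(miss, collapse = ", ")))
  need_e <- c("radius_um", "length_um", "branch_order", "is_stalled",
              "stall_cause", "speed_um_s")
  miss <- setdiff(need_e, igraph::edge_attr_names(g))
  if (length(miss)) msgs <- c(msgs, paste("missing edge attributes:",
                                          paste(miss, collapse = ", ")))
  if (length(msgs)) return(msgs)
  if (igraph::vcount(g) > 0 && !igraph::is_connected(g))
    msgs <- c(msgs, "graph must be connected")
  e <- igraph::as_data_frame(g, what = "edges")
  cap <- e$branch_order >= 1
  if (any(cap) && (any(e$radius_um[cap] < 1.5 - 1e-9) ||
                   any(e$radius_um[cap] > 4 + 1e-9)))
    msgs <- c(msgs, "capillary radii must lie in [1.5, 4] um")
  if (any(e$is_stalled & e$speed_um_s != 0))
    msgs <- c(msgs, "stalled edges must have centerline speed 0")
  if (any(xor(e$is_stalled, e$stall_cause != "none")))
    msgs <- c(msgs, "stall_cause must be 'none' iff the edge is flowing")
  if (length(msgs)) msgs else TRUE
})

#' TimeStack: a calibrated multi-channel time-lapse image stack
#'
#' A 5-D intensity array with dimensions (frame, z, y, x, channel) plus the
#' physical calibration needed to interpret it: axial plane spacing
#' \code{dz} (micrometers), in-plane pixel pitch \code{dxy} (micrometers),
#' frame interval (seconds), channel names, and the physical origin of the
#' first voxel corner in the coordinate frame of the generating
#' \linkS4class{VesselGraph}, so segment coordinates map into the stack.
#'
#' @slot data numeric 5-D array, dim = (t, z, y, x, channel).
#' @slot dz numeric(1), micrometers per z plane (default 1).
#' @slot dxy numeric(1), micrometers per in-plane pixel (default 1).
#' @slot frameInterval numeric(1), seconds between frames (default 1).
#' @slot channels character vector naming the channel dimension
#'   (plasma, rhodamine, hoechst).
#' @slot origin numeric(3), micrometer (z, y, x) position of the stack corner.
#' @export
setClass("TimeStack", representation(
  data = "array", dz = "numeric", dxy = "numeric",
  frameInterval = "numeric", channels = "character", origin = "numeric"))

setValidity("TimeStack", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 5)
    msgs <- c(msgs, "data must be a 5-D array (t, z, y, x, channel)")
  else if (dim(object@data)[5] != length(object@channels))
    msgs <- c(msgs, "channel dimension must match length(channels)")
  if (object@dz <= 0 || object@dxy <= 0 || object@frameInterval <= 0)
    msgs <- c(msgs, "dz, dxy and frameInterval must be positive")
  if (length(object@origin) != 3)
    msgs <- c(msgs, "origin must be a (z, y, x) micrometer triple")
  if (length(msgs)) msgs else TRUE
})

#' PlayerPool: a simulated pool of citizen-scientist annotators
#'
#' Each player has a true (latent) sensitivity -- the probability of
#' answering "stalled" on a truly stalled item -- and a true specificity --
#' the probability of answering "flowing" on a truly flowing item. Responses
#' are Bernoulli draws with these probabilities. The crowd engine never sees
#' the true values; it estimates sensitivity from calibration items.
#'
#' @slot players data.frame with columns \code{player_id},
#'   \code{sensitivity}, \code{specificity}, all in [0, 1].
#' @export
setClass("PlayerPool", representation(players = "data.frame"))

setValidity("PlayerPool", function(object) {
  p <- object@players
  need <- c("player_id", "sensitivity", "specificity")
  if (!all(need %in% names(p)))
    return(paste("players must have columns", paste(need, collapse = ", ")))
  if (nrow(p) < 1) return("pool must contain at least one player")
  if (any(p$sensitivity < 0 | p$sensitivity > 1 |
          p$specificity < 0 | p$specificity > 1))
    return("sensitivities and specificities must lie in [0, 1]")
  TRUE
})

#' StallCallTable: per-segment crowd scoring state and final verdicts
#'
#' One row per research segment: the accuracy-weighted crowd confidence of
#' being stalled, the accumulated sum of answering players' sensitivities
#' (the stopping-rule currency), the open/closed status, the expert verdict
#' (assigned only to items with confidence >= 0.5 during triage), and --
#' in simulations -- the ground truth.
#'
#' @slot calls data.frame with columns \code{segment_id}, \code{confidence},
#'   \code{sum_sensitivity}, \code{n_answers}, \code{status}
#'   ("open"/"closed"), \code{expert_verdict} ("stalled"/"flowing"/
#'   "unreviewed"), \code{truth} (logical, NA when unknown).
#' @slot threshold numeric(1), the sensitivity-sum stopping threshold used.
#' @export
setClass("StallCallTable",
         representation(calls = "data.frame", threshold = "numeric"))

setValidity("StallCallTable", function(object) {
  cl <- object@calls
  need <- c("segment_id", "confidence", "sum_sensitivity", "n_answers",
            "status", "expert_verdict", "truth")
  if (!all(need %in% names(cl)))
    return(paste("calls must have columns", paste(need, collapse = ", ")))
  ok_conf <- is.na(cl$confidence) | (cl$confidence >= 0 & cl$confidence <= 1)
  if (!all(ok_conf)) return("confidence must lie in [0, 1]")
  if (!all(cl$status %in% c("open", "closed")))
    return("status must be 'open' or 'closed'")
  if (!all(cl$expert_verdict %in% c("stalled", "flowing", "unreviewed")))
    return("invalid expert_verdict value")
  rev <- cl$expert_verdict != "unreviewed"
  if (any(rev & (is.na(cl$confidence) | cl$confidence < 0.5)))
    return("expert verdicts are only assigned to items with confidence >= 0.5")
  TRUE
})
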