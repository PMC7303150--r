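#' @include AllClasses.R
NULL

#' Accessors for stallflow S4 containers
#'
#' \code{edgeTable}/\code{nodeTable} return the edge and vertex tables of a
#' \linkS4class{VesselGraph} as data.frames; \code{stackArray} the raw 5-D
#' intensity array of a \linkS4class{TimeStack}; \code{playerTable} the
#' annotator table of a \linkS4class{PlayerPool}; \code{callTable} the call
#' table of a \linkS4class{StallCallTable}.
#'
#' @param x the object.
#' @return a data.frame (tables) or array (\code{stackArray}).
#' @name accessors
#' @aliases edgeTable nodeTable stackArray playerTable callTable
NULL

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))
#' @rdname accessors
#' @export
setGeneric("stackArray", function(x) standardGeneric("stackArray"))
#' @rdname accessors
#' @export
setGeneric("playerTable", function(x) standardGeneric("playerTable"))
#' @rdname accessors
#' @export
setGeneric("callTable", function(x) standardGeneric("callTable"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
setMethod("edgeTable", "VesselGraph", function(x)
  igraph::as_data_frame(x@graph, what = "edges"))
#' @rdname accessors
setMethod("nodeTable", "VesselGraph", function(x)
  igraph::as_data_frame(x@graph, what = "vertices"))
#' @rdname accessors
setMethod("stackArray", "TimeStack", function(x) x@data)
#' @rdname accessors
setMethod("playerTable", "PlayerPool", function(x) x@players)
#' @rdname accessors
setMethod("callTable", "StallCallTable", function(x) x@calls)
#' @rdname accessors
setMethod("frameInterval", "TimeStack", function(x) x@frameInterval)
#' @rdname accessors
setMethod("voxelSize", "TimeStack", function(x)
  c(z = x@dz, y = x@dxy, x = x@dxy))
#' @rdname accessors
setMethod("channelNames", "TimeStack", function(x) x@channels)

setMethod("show", "VesselGraph", function(object) {
  e <- edgeTable(object)
  cap <- e$branch_order >= 1
  cat("VesselGraph:", igraph::vcount(object@graph), "nodes,",
      nrow(e), "edges (", sum(cap), "capillary )\n")
  if (any(cap)) {
    ns <- sum(e$is_stalled[cap])
    cat(sprintf("  stalled capillaries: %d (%.2f%%)\n",
                ns, 100 * ns / sum(cap)))
  }
})

setMethod("show", "TimeStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "TimeStack: %d frames x %d z x %d y x %d x, %d channel(s) [%s]\n",
    d[1], d[2], d[3], d[4], d[5], paste(object@channels, collapse = ", ")))
  cat(sprintf("  dz = %g um, dxy = %g um, frame interval = %g s\n",
              object@dz, object@dxy, object@frameInterval))
})

setMethod("show", "PlayerPool", function(object) {
  p <- object@players
  cat(sprintf(
    "PlayerPool: %d players, mean sensitivity %.3f, mean specificity %.3f\n",
    nrow(p), mean(p$sensitivity), mean(p$specificity)))
})

setMethod("show", "StallCallTable", function(object) {
  cl <- object@calls
  cat(sprintf("StallCallTable: %d segments (%d closed), threshold %.2f\n",
              nrow(cl), sum(cl$status == "closed"), object@threshold))
  conf <- sum(cl$expert_verdict == "stalled")
  cat(sprintf("  expert-confirmed stalls: %d\n", conf))
})
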