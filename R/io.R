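# File interchange: GraphML for vessel networks, multi-page TIFF (+ JSON
# sidecar) for time stacks, CSV for player pools and behavior scores, YAML
# for scenario configs.

#' Read/write a VesselGraph as GraphML
#'
#' Edge attributes radius_um, length_um, branch_order, is_stalled,
#' stall_cause, speed_um_s and vertex attributes kind/x/y/z round-trip.
#'
#' @param graph a \linkS4class{VesselGraph}.
#' @param path file path (.graphml).
#' @return \code{readVesselGraph} returns a \linkS4class{VesselGraph};
#'   \code{writeVesselGraph} returns \code{path} invisibly.
#' @export
writeVesselGraph <- function(graph, path) {
  stopifnot(methods::is(graph, "VesselGraph"))
  g <- graph@graph
  # GraphML has no logical type in igraph's writer; encode as 0/1
  igraph::E(g)$is_stalled <- as.integer(igraph::E(g)$is_stalled)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname writeVesselGraph
#' @export
readVesselGraph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  igraph::E(g)$is_stalled <- as.logical(igraph::E(g)$is_stalled)
  if ("id" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "id")
  methods::new("VesselGraph", graph = g)
}

#' Read/write a TimeStack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered (t, z, channel), channel fastest; intensities are
#' stored as 32-bit floats scaled into [0, 1] by the recorded
#' \code{scale}. The sidecar (same path + ".json") holds dimensions,
#' calibration, channel names and the scale.
#'
#' @param stack a \linkS4class{TimeStack}.
#' @param path file path (.tif).
#' @return \code{readTimeStack} returns a \linkS4class{TimeStack};
#'   \code{writeTimeStack} returns \code{path} invisibly.
#' @export
writeTimeStack <- function(stack, path) {
  stopifnot(methods::is(stack, "TimeStack"))
  d <- dim(stack@data)
  scale <- max(stack@data, 1e-12)
  pages <- list()
  for (f in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[5]))
    pages[[length(pages) + 1L]] <- stack@data[f, z, , , ch] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(dim = d, dz = stack@dz, dxy = stack@dxy,
               frame_interval_s = stack@frameInterval,
               channels = stack@channels, origin = stack@origin,
               scale = scale, page_order = "t,z,channel (channel fastest)")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTimeStack
#' @export
readTimeStack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  arr <- array(0, d)
  i <- 0L
  for (f in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[5])) {
    i <- i + 1L
    arr[f, z, , , ch] <- pages[[i]] * meta$scale
  }
  methods::new("TimeStack", data = arr, dz = meta$dz, dxy = meta$dxy,
               frameInterval = meta$frame_interval_s,
               channels = meta$channels, origin = meta$origin)
}

#' Read/write a PlayerPool as CSV
#'
#' @param pool a \linkS4class{PlayerPool}.
#' @param path file path (.csv).
#' @return \code{readPlayerPool} returns a \linkS4class{PlayerPool}.
#' @export
writePlayerPool <- function(pool, path) {
  utils::write.csv(playerTable(pool), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePlayerPool
#' @export
readPlayerPool <- function(path) {
  methods::new("PlayerPool",
               players = utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a scenario configuration (YAML)
#'
#' A scenario names the cohort structure for an end-to-end synthetic run:
#' per-group stall rates, compositions, cohort sizes, annotator pool
#' parameters and behavioral effect sizes. See
#' \code{\link{runScenario}}.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readScenario <- function(path) yaml::read_yaml(path)

#' Run an end-to-end synthetic cohort scenario
#'
#' Chains the pipeline on synthetic data: per group, generate vascular
#' networks at the configured stall rate and composition, simulate the
#' crowd-scoring engine (calibrated stopping threshold, accuracy-weighted
#' aggregation, expert triage), and summarize stall fractions; optionally
#' generate and score behavioral logs.
#'
#' @param config list as returned by \code{\link{readScenario}}: elements
#'   \code{groups} (named list with \code{stall_rate}, optional
#'   \code{composition}, \code{n_stacks}, \code{segments_per_stack}),
#'   \code{players} (n, shape1, shape2), \code{crowd} (q, base_rate,
#'   threshold or "calibrate"), \code{seed}.
#' @return list with per-group \code{\link{stallSummary}} results and the
#'   thresholds used.
#' @export
runScenario <- function(config) {
  seed <- config$seed %||% 1L
  pl <- config$players %||% list()
  pool <- generatePlayers(pl$n %||% 100, pl$shape1 %||% 8,
                          pl$shape2 %||% 2, seed = seed)
  cw <- config$crowd %||% list()
  q <- cw$q %||% 0.25
  base <- cw$base_rate %||% 0.01
  thr <- cw$threshold %||% "calibrate"
  out <- list()
  gi <- 0L
  for (gname in names(config$groups)) {
    gi <- gi + 1L
    gc_ <- config$groups[[gname]]
    rate <- gc_$stall_rate
    comp <- gc_$composition %||% c(leukocyte = 0.86, platelet = 0.05,
                                   rbc_only = 0.09)
    comp <- stats::setNames(as.numeric(comp),
                            names(comp) %||%
                              c("leukocyte", "platelet", "rbc_only"))
    nStacks <- gc_$n_stacks %||% 3
    perStack <- gc_$segments_per_stack %||% 2000
    if (identical(thr, "calibrate")) {
      test_truth <- rep(c(TRUE, FALSE), c(20, 380))
      T_use <- calibrateThreshold(test_truth, pool, q = q, baseRate = base,
                                  seed = seed + 17L * gi)
    } else T_use <- thr
    tables <- list()
    for (s in seq_len(nStacks)) {
      vg <- generateNetwork(
        nPenetrating = max(1L, perStack %/% 1000L + 1L),
        capillariesPerPA = ceiling(perStack /
                                     max(1L, perStack %/% 1000L + 1L)),
        stallRate = rate, composition = comp,
        seed = seed + 1000L * gi + 10L * s)
      truth <- edgeTable(vg)$is_stalled[edgeTable(vg)$branch_order >= 1]
      tab <- simulateCrowd(truth, pool, threshold = as.numeric(T_use),
                           q = q, baseRate = base,
                           seed = seed + 1000L * gi + 10L * s + 1L)
      tables[[s]] <- expertTriage(tab)
    }
    out[[gname]] <- list(
      threshold = as.numeric(T_use),
      summary = stallSummary(tables, groups = rep(gname, nStacks)))
  }
  out
}
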