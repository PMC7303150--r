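#' Generate a pool of simulated annotators with heterogeneous skill
#'
#' True sensitivities are Beta(shape1, shape2) draws (default Beta(8, 2),
#' mean 0.8); by default each player's specificity equals their sensitivity
#' draw. A fixed value can be requested instead of a distribution, and the
#' pool can be truncated below (rejection sampling) to emulate a vetted,
#' uniformly competent crowd.
#'
#' @param n number of players (>= 1).
#' @param shape1,shape2 Beta parameters for sensitivity.
#' @param fixed if non-NULL, every player's sensitivity (and specificity)
#'   is this value and no draws are made.
#' @param minSensitivity lower truncation for both rates (0 = none).
#' @param specificity NULL (same value as the sensitivity draw), a fixed
#'   number, or "independent" for an independent Beta draw.
#' @param seed RNG seed or NULL.
#' @return a \linkS4class{PlayerPool}.
#' @export
generatePlayers <- function(n, shape1 = 8, shape2 = 2, fixed = NULL,
                            minSensitivity = 0, specificity = NULL,
                            seed = NULL) {
  if (n < 1) stop2("need at least one player")
  with_seed_or_not(seed, {
    if (!is.null(fixed)) {
      sens <- rep(fixed, n)
    } else {
      sens <- rbeta_truncated(n, shape1, shape2, minSensitivity)
    }
    spec <- if (is.null(specificity)) sens
    else if (identical(specificity, "independent"))
      rbeta_truncated(n, shape1, shape2, minSensitivity)
    else rep(specificity, n)
    methods::new("PlayerPool", players = data.frame(
      player_id = paste0("player", seq_len(n)),
      sensitivity = sens, specificity = spec,
      stringsAsFactors = FALSE))
  })
}

rbeta_truncated <- function(n, a, b, lo) {
  x <- stats::rbeta(n, a, b)
  while (any(bad <- x < lo)) x[bad] <- stats::rbeta(sum(bad), a, b)
  x
}
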