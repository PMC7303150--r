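#' Generate synthetic behavioral event logs with known effect sizes
#'
#' Produces one log per mouse emulating the four assays scored by the
#' package:
#' \itemize{
#'   \item Y-maze arm entries: a Markov chain on three arms where, with the
#'     configured avoid-last-two probability, the next entry is the arm not
#'     visited in the previous two entries (perfect alternation at
#'     probability 1), and otherwise a uniform choice between the two arms
#'     other than the current one.
#'   \item Object replacement (trial 2) exploration: the moved-object share
#'     of total exploration time is Beta-distributed with mean equal to the
#'     configured preference, so the expected preference score is
#'     preference x 100.
#'   \item Three-chamber sociability: chamber and direct-contact times with
#'     the configured stranger-side preference.
#'   \item Balance beam: three trials of (crossing time, hindpaw slips);
#'     the first trial is a slow habituation trial; times cap at 60 s.
#' }
#'
#' @param nMice number of mice.
#' @param group group label attached to each log.
#' @param alternationAvoid probability of avoiding the last two arms.
#' @param orPreference expected moved-object exploration share in [0, 1].
#' @param orKappa Beta concentration of the per-mouse share.
#' @param sociabilityPreference expected stranger-side share in [0, 1].
#' @param beamTimeMean,beamTimeSd crossing-time distribution (s) for trials
#'   after habituation.
#' @param beamSlipMean mean hindpaw slips per trial (Poisson).
#' @param meanEntries mean number of Y-maze arm entries.
#' @param seed RNG seed or NULL.
#' @return list of behavior logs; each log is a list with elements
#'   \code{mouse_id}, \code{group}, \code{arm_entries} (character vector
#'   over A/B/C), \code{exploration} (named seconds: novel, familiar),
#'   \code{sociability} (list of session 1 and 2 chamber/contact seconds),
#'   \code{beam} (data.frame time_s, slips).
#' @export
generateBehavior <- function(nMice, group = "WT-NC",
                             alternationAvoid = 0.6,
                             orPreference = 0.6, orKappa = 50,
                             sociabilityPreference = 0.65,
                             beamTimeMean = 10, beamTimeSd = 2,
                             beamSlipMean = 1, meanEntries = 25,
                             seed = NULL) {
  if (orPreference < 0 || orPreference > 1 ||
      alternationAvoid < 0 || alternationAvoid > 1 ||
      sociabilityPreference < 0 || sociabilityPreference > 1)
    stop2("propensities and preferences must lie in [0, 1]")
  with_seed_or_not(seed, {
    lapply(seq_len(nMice), function(m) {
      entries <- markov_arm_entries(
        max(3L, stats::rpois(1, meanEntries)), alternationAvoid)
      total <- stats::rlnorm(1, log(50), 0.2)
      share <- if (orKappa <= 0) orPreference
      else stats::rbeta(1, orKappa * orPreference,
                        orKappa * (1 - orPreference))
      soc <- sociability_log(sociabilityPreference)
      beam <- data.frame(
        time_s = pmin(60, c(stats::runif(1, 25, 60),
                            stats::rnorm(2, beamTimeMean, beamTimeSd))),
        slips = c(stats::rpois(1, beamSlipMean + 2),
                  stats::rpois(2, beamSlipMean)))
      beam$time_s <- pmax(beam$time_s, 2)
      list(mouse_id = paste0("m", m), group = group,
           arm_entries = entries,
           exploration = c(novel = total * share,
                           familiar = total * (1 - share)),
           sociability = soc, beam = beam)
    })
  })
}

markov_arm_entries <- function(n, avoid) {
  arms <- c("A", "B", "C")
  out <- character(n)
  out[1] <- sample(arms, 1)
  if (n >= 2) out[2] <- sample(setdiff(arms, out[1]), 1)
  for (i in seq_len(n)[-(1:2)]) {
    others <- setdiff(arms, out[i - 1])
    third <- setdiff(arms, c(out[i - 1], out[i - 2]))
    if (length(third) == 1 && stats::runif(1) < avoid) {
      out[i] <- third
    } else {
      out[i] <- sample(others, 1)
    }
  }
  out
}

sociability_log <- function(pref, session_s = 600) {
  # session 1: stranger chamber vs center vs empty chamber
  s1_str <- session_s * pref * stats::rbeta(1, 40, 10) / 0.8
  s1_str <- min(s1_str, 0.9 * session_s)
  rest <- session_s - s1_str
  s1 <- c(stranger = s1_str, center = rest * 0.4, empty = rest * 0.6)
  # session 2: novel stranger vs familiar stranger
  s2_nov <- session_s * pref * stats::rbeta(1, 40, 10) / 0.8
  s2_nov <- min(s2_nov, 0.9 * session_s)
  rest2 <- session_s - s2_nov
  s2 <- c(novel = s2_nov, center = rest2 * 0.4, familiar = rest2 * 0.6)
  list(
    session1 = list(chamber_s = s1,
                    contact_s = c(stranger = 0.6 * s1_str)),
    session2 = list(chamber_s = s2,
                    contact_s = c(novel = 0.6 * s2_nov,
                                  familiar = 0.4 * rest2 * 0.6)),
    session_s = session_s)
}
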