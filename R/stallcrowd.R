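#' Create empty player profiles for a pool of annotators
#'
#' A profile tracks the running sensitivity estimate used both to weight a
#' player's answers and to decide how many research (unscored) versus
#' calibration (gold standard) items the player is served. A new player
#' starts at the smoothed symmetric prior s-hat = 0.5 (Laplace smoothing
#' with alpha = 1 and no calibration items seen).
#'
#' @param ids player identifiers (character or integer).
#' @return data.frame with columns \code{player_id}, \code{shat},
#'   \code{stalled_seen}, \code{stalled_correct}, \code{flowing_seen},
#'   \code{flowing_correct}, \code{serve_ratio}.
#' @export
newPlayerProfiles <- function(ids) {
  data.frame(player_id = ids, shat = 0.5,
             stalled_seen = 0L, stalled_correct = 0L,
             flowing_seen = 0L, flowing_correct = 0L,
             serve_ratio = servingRatio(0.5),
             stringsAsFactors = FALSE)
}

#' Update a player's sensitivity estimate from a calibration answer
#'
#' Sensitivity is operationalized as the smoothed true-positive rate on
#' truly stalled calibration items:
#' s-hat = (correct on stalled + alpha) / (stalled seen + 2 alpha), with
#' alpha = 1. Answers on flowing calibration items update the (tracked but
#' unweighted) specificity counts.
#'
#' @param profile one-row data.frame from \code{\link{newPlayerProfiles}}.
#' @param answer "stalled" or "flowing".
#' @param truth logical: was the calibration item truly stalled? Must not
#'   be NA (calibration items carry truth).
#' @param alpha smoothing pseudo-count (default 1).
#' @return the updated one-row profile.
#' @export
updateSensitivity <- function(profile, answer, truth, alpha = 1) {
  if (is.na(truth))
    stop2("calibration items must carry ground truth")
  answer <- match.arg(answer, c("stalled", "flowing"))
  correct <- (answer == "stalled") == truth
  if (truth) {
    profile$stalled_seen <- profile$stalled_seen + 1L
    profile$stalled_correct <- profile$stalled_correct + as.integer(correct)
  } else {
    profile$flowing_seen <- profile$flowing_seen + 1L
    profile$flowing_correct <- profile$flowing_correct + as.integer(correct)
  }
  profile$shat <- (profile$stalled_correct + alpha) /
    (profile$stalled_seen + 2 * alpha)
  profile$serve_ratio <- servingRatio(profile$shat)
  profile
}

#' Research-to-calibration serving ratio as a function of skill
#'
#' A documented nondecreasing step schedule: more skilled players (higher
#' running sensitivity) are served proportionally more research vessels,
#' from 1:1 at s-hat <= 0.6 up to 9:1 at s-hat >= 0.95.
#'
#' @param shat running sensitivity estimate(s) in [0, 1].
#' @return research items per calibration item (vectorized).
#' @export
servingRatio <- function(shat) {
  breaks <- c(-Inf, 0.6, 0.7, 0.8, 0.9, 0.95, Inf)
  ratios <- c(1, 2, 3, 5, 7, 9)
  ratios[findInterval(shat, breaks, left.open = TRUE)]
}

#' Calibration stalled fraction keeping the shown base rate constant
#'
#' Research vessels stall at a low base rate (< 1\%), so the stalled
#' fraction among shown items is controlled through the calibration mix.
#' With r research items per calibration item and research base rate b,
#' the calibration stalled fraction f solving
#' (r b + f) / (r + 1) = q is f = q (r + 1) - r b. Values outside [0, 1]
#' are infeasible: they are clamped and flagged.
#'
#' @param q target overall shown-stalled fraction.
#' @param ratio research:calibration serving ratio r.
#' @param baseRate research stall base rate b.
#' @return the calibration stalled fraction, with attribute
#'   \code{feasible} (logical).
#' @export
calibrationStallMix <- function(q, ratio, baseRate) {
  f <- q * (ratio + 1) - baseRate * ratio
  feasible <- f >= 0 & f <= 1
  f <- pmin(1, pmax(0, f))
  structure(f, feasible = feasible)
}

#' Serve the next annotation task to a player
#'
#' Draws research vs calibration with probability ratio r:1 given the
#' player's current serving ratio, and -- for calibration items -- draws a
#' stalled vs flowing gold item so the expected overall stalled fraction
#' shown equals \code{q}. When the required calibration mix is infeasible,
#' the closest achievable mix is served and a deviation is logged (warning).
#'
#' @param profile one-row player profile.
#' @param queues list with elements \code{research} (ids),
#'   \code{calibration_stalled} (ids), \code{calibration_flowing} (ids);
#'   all nonempty where needed.
#' @param q target shown-stalled fraction (default 0.25).
#' @param baseRate estimated research stall base rate (default 0.01).
#' @param warnInfeasible warn when the mix is clamped.
#' @return list(kind = "research"|"calibration", item, truth (NA for
#'   research), profile).
#' @export
serveNext <- function(profile, queues, q = 0.25, baseRate = 0.01,
                      warnInfeasible = TRUE) {
  if (length(queues$research) == 0 &&
      length(queues$calibration_stalled) == 0 &&
      length(queues$calibration_flowing) == 0)
    stop2("all queues are empty")
  r <- profile$serve_ratio
  pick_research <- length(queues$research) > 0 &&
    stats::runif(1) < r / (r + 1)
  if (pick_research) {
    item <- queues$research[[1]]
    return(list(kind = "research", item = item, truth = NA, profile = profile))
  }
  f <- calibrationStallMix(q, r, baseRate)
  if (warnInfeasible && !attr(f, "feasible"))
    warn2(sprintf(
      "target shown-stall rate %.2f infeasible at ratio %d:1 and base rate %.3f; serving best-effort mix %.2f",
      q, r, baseRate, as.numeric(f)))
  stalled <- stats::runif(1) < f
  if (stalled && length(queues$calibration_stalled) > 0) {
    list(kind = "calibration", item = queues$calibration_stalled[[1]],
         truth = TRUE, profile = profile)
  } else if (length(queues$calibration_flowing) > 0) {
    list(kind = "calibration", item = queues$calibration_flowing[[1]],
         truth = FALSE, profile = profile)
  } else {
    list(kind = "calibration", item = queues$calibration_stalled[[1]],
         truth = TRUE, profile = profile)
  }
}

#' Accuracy-weighted crowd confidence for one vessel
#'
#' c = sum(w_i 1[answer_i = stalled]) / sum(w_i), where w_i is the player's
#' sensitivity estimate frozen at the time of the answer. Confidence near 1
#' implies a high probability of being stalled.
#'
#' @param answers data.frame with columns \code{answer} ("stalled"/
#'   "flowing") and \code{weight}.
#' @return list(confidence, status = "ok" | "insufficient signal").
#' @export
crowdConfidence <- function(answers) {
  if (nrow(answers) < 1) stop2("at least one answer is required")
  w <- answers$weight
  if (any(w < 0 | w > 1)) stop2("weights must lie in [0, 1]")
  sw <- sum(w)
  if (sw == 0)
    return(list(confidence = NA_real_, status = "insufficient signal"))
  list(confidence = sum(w * (answers$answer == "stalled")) / sw,
       status = "ok")
}

#' Sensitivity-sum stopping rule
#'
#' A vessel's scoring is closed once the sum of the sensitivities of all
#' players that answered reaches the threshold T.
#'
#' @param answers data.frame with a \code{weight} column (sensitivities at
#'   answer time).
#' @param threshold T > 0 (T = 0 closes everything immediately; warned).
#' @return "open" or "closed".
#' @export
stoppingRule <- function(answers, threshold) {
  if (threshold < 0) stop2("threshold must be >= 0")
  if (threshold == 0)
    warn2("threshold 0: every item closes immediately (degenerate)")
  if (sum(answers$weight) >= threshold) "closed" else "open"
}

#' Simulate the full crowd-scoring engine over a set of research segments
#'
#' A round-based driver over the engine's primitives: in each round every
#' open segment receives one answer from a randomly drawn player (Bernoulli
#' response with the player's true sensitivity on stalled items and true
#' specificity on flowing items, weighted by the player's current
#' sensitivity estimate), each player then sees calibration items in
#' proportion to their serving ratio, with the calibration stalled/flowing
#' mix chosen to hold the shown-stalled fraction at \code{q}, and profiles
#' are updated from the calibration answers. Segments close when their
#' accumulated answer sensitivity reaches \code{threshold} and they have at
#' least \code{minAnswers} answers.
#'
#' @param truth logical vector: ground-truth stalled state per research
#'   segment.
#' @param pool a \linkS4class{PlayerPool}.
#' @param threshold sensitivity-sum stopping threshold T.
#' @param q target shown-stalled fraction.
#' @param baseRate research base-rate estimate used for the mix.
#' @param minAnswers minimum answers per segment before closing.
#' @param maxRounds safety cap on rounds.
#' @param seed RNG seed or NULL.
#' @return a \linkS4class{StallCallTable}; attribute \code{served} holds the
#'   serving log (counts of research/calibration items shown by truth), and
#'   \code{profiles} the final player profiles.
#' @export
simulateCrowd <- function(truth, pool, threshold, q = 0.25,
                          baseRate = 0.01, minAnswers = 1L,
                          maxRounds = 200L, seed = NULL) {
  stopifnot(methods::is(pool, "PlayerPool"))
  pl <- playerTable(pool)
  nP <- nrow(pl)
  nS <- length(truth)
  with_seed_or_not(seed, {
    prof <- newPlayerProfiles(pl$player_id)
    sumw <- numeric(nS)
    sumw_stalled <- numeric(nS)
    nans <- integer(nS)
    served <- c(research_stalled = 0, research_flowing = 0,
                calib_stalled = 0, calib_flowing = 0)
    for (round in seq_len(maxRounds)) {
      open <- which(sumw < threshold | nans < minAnswers)
      if (length(open) == 0L) break
      who <- sample.int(nP, length(open), replace = TRUE)
      p_stalled <- ifelse(truth[open], pl$sensitivity[who],
                          1 - pl$specificity[who])
      ans <- stats::runif(length(open)) < p_stalled
      w <- prof$shat[who]
      sumw[open] <- sumw[open] + w
      sumw_stalled[open] <- sumw_stalled[open] + w * ans
      nans[open] <- nans[open] + 1L
      served["research_stalled"] <- served["research_stalled"] +
        sum(truth[open])
      served["research_flowing"] <- served["research_flowing"] +
        sum(!truth[open])
      # calibration serving per player, proportional to research served
      kres <- tabulate(who, nbins = nP)
      active <- which(kres > 0)
      ncal <- stats::rbinom(length(active), kres[active],
                            1 / prof$serve_ratio[active])
      for (j in seq_along(active)) {
        pj <- active[j]
        if (ncal[j] == 0L) next
        f <- calibrationStallMix(q, prof$serve_ratio[pj], baseRate)
        ctruth <- stats::runif(ncal[j]) < as.numeric(f)
        p_corr <- ifelse(ctruth, pl$sensitivity[pj], pl$specificity[pj])
        corr <- stats::runif(ncal[j]) < p_corr
        prof$stalled_seen[pj] <- prof$stalled_seen[pj] + sum(ctruth)
        prof$stalled_correct[pj] <- prof$stalled_correct[pj] +
          sum(corr & ctruth)
        prof$flowing_seen[pj] <- prof$flowing_seen[pj] + sum(!ctruth)
        prof$flowing_correct[pj] <- prof$flowing_correct[pj] +
          sum(corr & !ctruth)
        served["calib_stalled"] <- served["calib_stalled"] + sum(ctruth)
        served["calib_flowing"] <- served["calib_flowing"] + sum(!ctruth)
      }
      prof$shat <- (prof$stalled_correct + 1) / (prof$stalled_seen + 2)
      prof$serve_ratio <- servingRatio(prof$shat)
    }
    calls <- data.frame(
      segment_id = seq_len(nS),
      confidence = ifelse(sumw > 0, sumw_stalled / sumw, NA_real_),
      sum_sensitivity = sumw,
      n_answers = nans,
      status = ifelse(sumw >= threshold & nans >= minAnswers,
                      "closed", "open"),
      expert_verdict = "unreviewed",
      truth = truth,
      stringsAsFactors = FALSE)
    out <- methods::new("StallCallTable", calls = calls,
                        threshold = threshold)
    attr(out, "served") <- served
    attr(out, "profiles") <- prof
    out
  })
}

#' Expert triage of high-confidence crowd calls
#'
#' Items with crowd confidence >= 0.5 (ties at exactly 0.5 included) are
#' reviewed by the expert oracle in order of descending confidence; final
#' stall calls are the expert-confirmed items. In simulation the oracle is
#' the ground truth; for real data supply a function(segment_id) ->
#' "stalled"/"flowing".
#'
#' @param table a \linkS4class{StallCallTable} with all items closed.
#' @param oracle NULL (use stored ground truth) or a function.
#' @param bins confidence bin edges for the precision report.
#' @return the finalized table; attribute \code{report} holds the
#'   per-confidence-bin counts and precision.
#' @export
expertTriage <- function(table, oracle = NULL,
                         bins = seq(0.5, 1, by = 0.1)) {
  stopifnot(methods::is(table, "StallCallTable"))
  calls <- callTable(table)
  if (any(calls$status != "closed"))
    stop2("triage requires all items closed")
  review <- which(!is.na(calls$confidence) & calls$confidence >= 0.5)
  review <- review[order(-calls$confidence[review])]
  for (i in review) {
    verdict <- if (is.null(oracle)) {
      if (isTRUE(calls$truth[i])) "stalled" else "flowing"
    } else oracle(calls$segment_id[i])
    calls$expert_verdict[i] <- verdict
  }
  # precision-by-confidence report over reviewed bins
  report <- data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1])
  report$n <- 0L
  report$n_stalled <- 0L
  for (b in seq_len(nrow(report))) {
    inb <- calls$confidence > report$bin_lo[b] &
      calls$confidence <= report$bin_hi[b] &
      calls$expert_verdict != "unreviewed"
    report$n[b] <- sum(inb, na.rm = TRUE)
    report$n_stalled[b] <- sum(inb & calls$expert_verdict == "stalled",
                               na.rm = TRUE)
  }
  report$precision <- ifelse(report$n > 0, report$n_stalled / report$n, NA)
  out <- methods::new("StallCallTable", calls = calls,
                      threshold = table@threshold)
  attr(out, "report") <- report
  attr(out, "served") <- attr(table, "served")
  attr(out, "profiles") <- attr(table, "profiles")
  out
}

#' Calibrate the stopping threshold on a test set with known stalls
#'
#' Returns the smallest candidate threshold such that, in a full simulated
#' run over the test set, every known stalled item's crowd confidence
#' exceeds the 95th percentile of the flowing items' confidences -- i.e.
#' known stalls sit at the top of the rank-ordered confidence list. If no
#' candidate satisfies the criterion the largest is returned with a
#' diagnostic.
#'
#' @param truth logical vector for the test set (>= 1 known stall).
#' @param pool a \linkS4class{PlayerPool}.
#' @param grid candidate thresholds, ascending.
#' @param q,baseRate,minAnswers passed to \code{\link{simulateCrowd}}.
#' @param seed RNG seed (same seed per candidate, so candidates differ only
#'   in the threshold).
#' @return selected threshold; attribute \code{satisfied} (logical).
#' @export
calibrateThreshold <- function(truth, pool, grid = seq(2, 8, by = 0.5),
                               q = 0.25, baseRate = 0.01, minAnswers = 1L,
                               seed = NULL) {
  if (!any(truth)) stop2("test set must contain at least one known stall")
  grid <- sort(grid)
  for (T in grid) {
    tab <- simulateCrowd(truth, pool, threshold = T, q = q,
                         baseRate = baseRate, minAnswers = minAnswers,
                         seed = seed)
    conf <- callTable(tab)$confidence
    cut <- stats::quantile(conf[!truth], 0.95, names = FALSE, na.rm = TRUE)
    if (all(conf[truth] > cut, na.rm = FALSE) && !anyNA(conf[truth]))
      return(structure(T, satisfied = TRUE))
  }
  warn2("no candidate threshold ranked all known stalls above the 95th ",
        "percentile of flowing confidences; returning the largest")
  structure(grid[length(grid)], satisfied = FALSE)
}

#' Empirical confidence calibration across bins
#'
#' Over a simulated table with ground truth, the fraction of truly stalled
#' items per confidence bin; used to verify that P(stalled | bin) is
#' nondecreasing across bins.
#'
#' @param table a \linkS4class{StallCallTable} with truth.
#' @param bins bin edges over [0, 1].
#' @return data.frame(bin_lo, bin_hi, n, frac_stalled).
#' @export
confidenceCalibration <- function(table, bins = seq(0, 1, by = 0.25)) {
  calls <- callTable(table)
  out <- data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1])
  out$n <- 0L
  out$frac_stalled <- NA_real_
  for (b in seq_len(nrow(out))) {
    inb <- !is.na(calls$confidence) &
      calls$confidence > out$bin_lo[b] & calls$confidence <= out$bin_hi[b]
    if (b == 1)
      inb <- inb | (!is.na(calls$confidence) & calls$confidence == 0)
    out$n[b] <- sum(inb)
    if (out$n[b] > 0) out$frac_stalled[b] <- mean(calls$truth[inb])
  }
  out
}
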