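#' Y-maze spontaneous alternation score
#'
#' A triad is three consecutive arm entries that are all distinct; the
#' score is (number of alternating triads) / (total arm entries - 2) x 100.
#'
#' @param entries ordered character vector of arm labels (3-arm set).
#' @return percent in [0, 100]; NA with a warning when fewer than 3
#'   entries.
#' @examples
#' alternationScore(c("A", "B", "C", "A", "B", "C"))  # 100
#' @export
alternationScore <- function(entries) {
  n <- length(entries)
  if (n < 3) {
    warn2("fewer than 3 arm entries; alternation score undefined")
    return(NA_real_)
  }
  triads <- vapply(seq_len(n - 2), function(i)
    length(unique(entries[i:(i + 2)])) == 3L, logical(1))
  100 * sum(triads) / (n - 2)
}

#' Object replacement preference score
#'
#' (exploration time of the novel/moved object) / (exploration time of
#' both objects) x 100, from trial 2.
#'
#' @param novel seconds exploring the moved object.
#' @param familiar seconds exploring the unmoved object.
#' @return percent; NA with a warning when total exploration is zero.
#' @examples
#' orPreference(36, 24)  # 60
#' @export
orPreference <- function(novel, familiar) {
  total <- novel + familiar
  if (any(c(novel, familiar) < 0)) stop2("exploration times must be >= 0")
  if (total == 0) {
    warn2("zero total exploration; preference undefined")
    return(NA_real_)
  }
  100 * novel / total
}

#' Three-chamber sociability scores
#'
#' Session 1 quantifies sociability (stranger vs empty chamber), session 2
#' preference for social novelty (novel vs familiar stranger). Chamber
#' fraction = time in the stranger-containing chamber / session time;
#' contact fraction = direct-contact time / session time.
#'
#' @param log one behavior log from \code{\link{generateBehavior}} (or any
#'   list with the same \code{sociability} structure).
#' @return data.frame with one row per session: chamber_fraction,
#'   contact_fraction.
#' @export
sociabilityScores <- function(log) {
  soc <- log$sociability
  if (is.null(soc$session1$chamber_s) || is.null(soc$session2$chamber_s))
    stop2("missing chamber record in sociability log")
  tot <- soc$session_s
  s1 <- soc$session1
  s2 <- soc$session2
  data.frame(
    session = c(1L, 2L),
    chamber_fraction = c(s1$chamber_s[["stranger"]] / tot,
                         s2$chamber_s[["novel"]] / tot),
    contact_fraction = c(sum(s1$contact_s) / tot,
                         s2$contact_s[["novel"]] / tot))
}

#' Balance beam metrics from trial lists
#'
#' Mice habituate on the first trial, so metrics are the means of the last
#' two trials only; crossing times are capped at 60 s upstream and the cap
#' is retained.
#'
#' @param trials data.frame with columns \code{time_s} and \code{slips},
#'   one row per trial in order.
#' @return list(mean_time_s, mean_slips).
#' @export
beamMetrics <- function(trials) {
  n <- nrow(trials)
  if (n < 3) {
    warn2("fewer than 3 trials; using the available last trials without ",
          "dropping a habituation trial")
    use <- trials
  } else {
    use <- trials[(n - 1):n, , drop = FALSE]
  }
  list(mean_time_s = mean(use$time_s), mean_slips = mean(use$slips))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness and kurtosis into
#' K^2 = Z(b1)^2 + Z(b2)^2, chi-squared with 2 df under normality, using
#' the standard transformations (D'Agostino's skewness Z and the
#' Anscombe-Glynn kurtosis Z). Requires n >= 8.
#'
#' @param x numeric vector.
#' @return list(statistic, p.value, n).
#' @export
dagostinoPearsonTest <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop2("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness: D'Agostino (1970)
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zb1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Zb2 <- ((1 - 2 / (9 * A)) -
            ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1/3)) /
    sqrt(2 / (9 * A))
  K2 <- Zb1^2 + Zb2^2
  list(statistic = K2, p.value = stats::pchisq(K2, 2, lower.tail = FALSE),
       n = n)
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak: order raw p ascending; adjusted p_i = max_{j <= i}
#' [1 - (1 - p_(j))^(m - j + 1)], clamped to 1.
#'
#' @param p raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holmSidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Dunn's post-hoc pairwise test after Kruskal-Wallis
#'
#' Rank-based z tests on all group pairs with tie correction:
#' z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)), with
#' T = sum(t^3 - t) / (12 (N - 1)) over tie groups; two-sided p-values with
#' Holm adjustment.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return data.frame(group1, group2, z, p, p.adj).
#' @export
dunnTest <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  Tadj <- sum(ties^3 - ties) / (12 * (N - 1))
  rb <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  gl <- levels(groups)
  pairs <- utils::combn(gl, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - Tadj) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[k] <- (rb[[a]] - rb[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p.adj = stats::p.adjust(p, "holm"))
}

#' Normality-gated group comparison with the study's reporting conventions
#'
#' Per group, normality is assessed with the D'Agostino-Pearson omnibus
#' test. When every group is consistent with normality (and large enough to
#' test), groups are compared by one-way ANOVA with Holm-Sidak-adjusted
#' pairwise Welch t tests; otherwise by Kruskal-Wallis with Holm-adjusted
#' Dunn pairwise tests. Adjusted p < 0.05 is significant; p in [0.05, 0.1)
#' is reported as a trend. Significance markers are a pure function of the
#' comparison design: * genotype, # treatment, \eqn{\dagger} diet,
#' \eqn{\lambda} age.
#'
#' @param values numeric vector of the measure.
#' @param groups group labels.
#' @param design one of "genotype", "treatment", "diet", "age" (sets the
#'   marker symbol).
#' @param alpha significance level.
#' @return object of class \code{GroupComparison} (list): \code{test}
#'   ("ANOVA+Holm-Sidak" or "Kruskal-Wallis+Dunn"), \code{normality_p},
#'   \code{omnibus_p}, \code{pairwise} (data.frame with p, p.adj,
#'   category in {significant, trend, ns}, marker), \code{excluded}.
#' @export
compareGroups <- function(values, groups, design = "genotype",
                          alpha = 0.05) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  cnt <- table(groups)
  small <- names(cnt)[cnt < 3]
  if (length(small)) {
    warn2("excluding group(s) with fewer than 3 values: ",
          paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
    cnt <- table(groups)
  }
  if (length(cnt) < 2) stop2("need at least two groups with >= 3 values")
  gf <- factor(groups)
  norm_p <- vapply(levels(gf), function(g) {
    x <- values[gf == g]
    if (length(x) < 8 || stats::sd(x) == 0) return(NA_real_)
    dagostinoPearsonTest(x)$p.value
  }, numeric(1))
  all_normal <- all(!is.na(norm_p)) && all(norm_p >= alpha)
  marker <- c(genotype = "*", treatment = "#", diet = "†",
              age = "λ")[[design]]
  if (all_normal) {
    fit <- stats::aov(values ~ gf)
    omni <- summary(fit)[[1]][["Pr(>F)"]][1]
    pairs <- utils::combn(levels(gf), 2)
    praw <- vapply(seq_len(ncol(pairs)), function(k)
      stats::t.test(values[gf == pairs[1, k]],
                    values[gf == pairs[2, k]])$p.value, numeric(1))
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     p = praw, p.adj = holmSidak(praw))
    test <- "ANOVA+Holm-Sidak"
  } else {
    kw <- stats::kruskal.test(values, gf)
    omni <- kw$p.value
    dn <- dunnTest(values, gf)
    pw <- dn[, c("group1", "group2", "p", "p.adj")]
    test <- "Kruskal-Wallis+Dunn"
  }
  pw$category <- ifelse(pw$p.adj < alpha, "significant",
                        ifelse(pw$p.adj < 0.1, "trend", "ns"))
  pw$marker <- ifelse(pw$category == "significant", marker, "")
  structure(list(test = test, normality_p = norm_p, omnibus_p = omni,
                 pairwise = pw, excluded = small, design = design),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("Group comparison (", x$test, "), omnibus p = ",
      format.pval(x$omnibus_p, digits = 3), "\n", sep = "")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
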