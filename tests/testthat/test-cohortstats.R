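test_that("alternation scoring counts distinct triads over entries - 2", {
  expect_equal(alternationScore(c("A", "B", "C", "A", "B", "C")), 100)
  expect_equal(alternationScore(c("A", "B", "A", "B", "A")), 0)
  expect_equal(alternationScore(c("A", "B", "C", "C", "A", "B")), 50)
  expect_warning(s <- alternationScore(c("A", "B")), "fewer than 3")
  expect_true(is.na(s))
})

test_that("alternation matches brute-force recomputation on random logs", {
  brute <- function(e) {
    n <- length(e)
    hits <- 0
    for (i in 1:(n - 2))
      if (e[i] != e[i + 1] && e[i] != e[i + 2] && e[i + 1] != e[i + 2])
        hits <- hits + 1
    100 * hits / (n - 2)
  }
  withr::with_seed(14, {
    for (rep in 1:25) {
      e <- sample(c("A", "B", "C"), sample(3:40, 1), replace = TRUE)
      expect_equal(alternationScore(e), brute(e))
    }
  })
})

test_that("object replacement preference follows the printed formula", {
  expect_equal(orPreference(30, 30), 50)
  expect_equal(orPreference(36, 24), 60)
  expect_equal(orPreference(5, 0), 100)
  expect_warning(s <- orPreference(0, 0), "zero total")
  expect_true(is.na(s))
  expect_error(orPreference(-1, 2), ">= 0")
})

test_that("sociability fractions cover the degenerate layouts", {
  all_in <- list(sociability = list(
    session1 = list(chamber_s = c(stranger = 600, center = 0, empty = 0),
                    contact_s = c(stranger = 300)),
    session2 = list(chamber_s = c(novel = 200, center = 200,
                                  familiar = 200),
                    contact_s = c(novel = 100, familiar = 50)),
    session_s = 600))
  sc <- sociabilityScores(all_in)
  expect_equal(sc$chamber_fraction[1], 1)
  expect_equal(sc$chamber_fraction[2], 1 / 3)
  expect_error(sociabilityScores(list(sociability = list(
    session1 = list(), session2 = list(), session_s = 600))),
    "missing chamber")
})

test_that("generated sociability logs recover the configured preference", {
  logs <- generateBehavior(1000, sociabilityPreference = 0.6, seed = 4)
  fr <- vapply(logs, function(l) sociabilityScores(l)$chamber_fraction[1],
               numeric(1))
  expect_lt(abs(mean(fr) - 0.6), 0.02)
})

test_that("beam metrics use the mean of the last two trials", {
  trials <- data.frame(time_s = c(60, 10, 12), slips = c(5, 1, 3))
  m <- beamMetrics(trials)
  expect_equal(m$mean_time_s, 11)
  expect_equal(m$mean_slips, 2)
  same <- data.frame(time_s = c(9, 9, 9), slips = c(2, 2, 2))
  expect_equal(beamMetrics(same)$mean_time_s, 9)
  expect_warning(m2 <- beamMetrics(trials[1:2, ]), "fewer than 3")
  expect_equal(m2$mean_time_s, 35)
  # a trial capped at 60 s stays in the average
  capped <- data.frame(time_s = c(30, 60, 20), slips = c(0, 0, 0))
  expect_equal(beamMetrics(capped)$mean_time_s, 40)
})

test_that("the omnibus normality test matches an independent implementation", {
  # frozen from scipy.stats.normaltest on the same vectors
  x <- c(2.1, 3.4, 1.9, 4.2, 2.8, 3.1, 2.5, 3.9, 2.2, 3.6)
  r <- dagostinoPearsonTest(x)
  expect_equal(r$statistic, 1.482877765269126, tolerance = 1e-10)
  expect_equal(r$p.value, 0.476427898260804, tolerance = 1e-10)
  y <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.30218,
         0.12784, -0.316243, -0.016801, -0.853044, 0.879398, 0.777792,
         0.066031, 1.127241, 0.467509)
  r2 <- dagostinoPearsonTest(y)
  expect_equal(r2$statistic, 1.8870521380318772, tolerance = 1e-10)
  expect_equal(r2$p.value, 0.38925288016953197, tolerance = 1e-10)
  expect_error(dagostinoPearsonTest(rnorm(5)), "n >= 8")
})

test_that("Holm-Sidak step-down matches hand arithmetic", {
  p <- c(0.3, 0.01, 0.04)
  adj <- holmSidak(p)
  expect_equal(adj[2], 1 - (1 - 0.01)^3)
  expect_equal(adj[3], max(1 - (1 - 0.01)^3, 1 - (1 - 0.04)^2))
  expect_equal(adj[1], max(1 - (1 - 0.01)^3, 1 - (1 - 0.04)^2, 0.3))
  expect_true(all(adj >= p))
})

test_that("Dunn's test matches hand-computed rank arithmetic", {
  v <- 1:9
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunnTest(v, g)
  se <- sqrt((9 * 10 / 12) * (2 / 3))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], (2 - 5) / se)
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], (2 - 8) / se)
  expect_equal(d$p, 2 * pnorm(-abs(d$z)))
  expect_true(all(d$p.adj >= d$p))
})

test_that("identical groups yield no significant pairs", {
  withr::with_seed(3, v <- rnorm(30))
  g <- rep(c("g1", "g2", "g3"), each = 10)
  cmp <- compareGroups(v, g)
  expect_true(all(cmp$pairwise$category != "significant"))
})

test_that("well-separated normal groups take the ANOVA branch and detect", {
  withr::with_seed(15, {
    v <- c(rnorm(10), rnorm(10, 3))
  })
  g <- rep(c("WT", "APP"), each = 10)
  cmp <- compareGroups(v, g)
  expect_equal(cmp$test, "ANOVA+Holm-Sidak")
  expect_true(all(cmp$pairwise$category == "significant"))
  expect_equal(cmp$pairwise$marker, "*")
})

test_that("heavy-tailed data routes to the nonparametric branch", {
  withr::with_seed(5, {
    taken <- replicate(50, {
      v <- c(rnorm(50), rcauchy(50))
      g <- rep(c("a", "b"), each = 50)
      compareGroups(v, g)$test
    })
  })
  expect_gte(mean(taken == "Kruskal-Wallis+Dunn"), 0.8)
})

test_that("type-I error of the gated pipeline is controlled under the null", {
  withr::with_seed(6, {
    rej <- replicate(500, {
      v <- rnorm(24)
      g <- rep(c("a", "b"), each = 12)
      any(compareGroups(v, g)$pairwise$p.adj < 0.05)
    })
  })
  expect_lte(mean(rej), 0.07)
})

test_that("small groups are excluded with a warning and markers map designs", {
  v <- c(rnorm(10), rnorm(10), rnorm(2))
  g <- rep(c("a", "b", "c"), c(10, 10, 2))
  expect_warning(cmp <- compareGroups(v, g), "fewer than 3")
  expect_false("c" %in% c(cmp$pairwise$group1, cmp$pairwise$group2))
  for (des in c(genotype = "*", treatment = "#", diet = "†", age = "λ")) {
    # marker is a pure function of the design label
  }
  withr::with_seed(7, v2 <- c(rnorm(10), rnorm(10, 5)))
  g2 <- rep(c("x", "y"), each = 10)
  expect_equal(compareGroups(v2, g2, design = "diet")$pairwise$marker, "†")
  expect_equal(compareGroups(v2, g2, design = "age")$pairwise$marker, "λ")
})

test_that("trend band [0.05, 0.1) is reported as its own category", {
  # construct a two-group case with a p-value in the trend band
  withr::with_seed(11, {
    found <- FALSE
    for (i in 1:200) {
      v <- c(rnorm(10), rnorm(10, 0.9))
      g <- rep(c("a", "b"), each = 10)
      cmp <- compareGroups(v, g)
      pa <- cmp$pairwise$p.adj[1]
      if (pa >= 0.05 && pa < 0.1) {
        expect_equal(cmp$pairwise$category[1], "trend")
        expect_equal(cmp$pairwise$marker[1], "")
        found <- TRUE
        break
      }
    }
    expect_true(found)
  })
})
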