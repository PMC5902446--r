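test_that("pathway classification follows the deterministic rules", {
  cls <- classifyTrajectories(list(
    mkPath(c(US = 20, PS = 20, FS = 50), id = "a"),
    mkPath(c(US = 20, PS = 5, US = 8, PS = 4, FS = 30), id = "b"),
    mkPath(c(US = 20, PS = 5, US = 8, PS = 9), id = "c"),
    mkPath(c(US = 60), id = "d"),
    mkPath(c(US = 20, FS = 40), id = "e")))
  expect_equal(cls$class, c("single_scrunch_with_pause", "cycling_then_FS",
                            "cycling_only", "inactive",
                            "single_scrunch_no_pause"))
  expect_equal(cls$n_attempts, c(0L, 1L, 1L, 0L, 0L))
  expect_equal(cls$first_outcome,
               c("success", "failure", "failure", "none", "success"))
})

test_that("classification partitions every analyzable trace", {
  sc <- buildDefaultScheme(ntp = 10)
  paths <- gillespieSimulate(sc, 300, 60, seed = 41, injectionTime = 20)
  cls <- classifyTrajectories(lapply(paths, truthLabeledPath))
  expect_equal(nrow(cls), 60L)
  expect_true(all(cls$class %in% c("single_scrunch_with_pause",
                                   "single_scrunch_no_pause",
                                   "cycling_then_FS", "cycling_only",
                                   "inactive", "withheld")))
  expect_false(any(is.na(cls$class)))
})

test_that("first-attempt probability uses the Wilson interval", {
  mk <- function(n, success) {
    lapply(seq_len(n), function(i) {
      if (i <= success) mkPath(c(US = 10, PS = 10, FS = 30),
                               id = sprintf("s%d", i))
      else mkPath(c(US = 10, PS = 10, US = 10, PS = 10), id = sprintf("c%d", i))
    })
  }
  cls <- classifyTrajectories(mk(100, 80))
  fa <- firstAttemptProbability(cls)
  expect_equal(fa$p, 0.8)
  expect_equal(fa$ci, c(0.712, 0.867), tolerance = 0.005)
  allCyc <- classifyTrajectories(mk(40, 0))
  expect_equal(firstAttemptProbability(allCyc)$p, 0)
  # invariant to ordering and duplication
  clsRev <- cls[rev(seq_len(nrow(cls))), ]
  expect_equal(firstAttemptProbability(clsRev)$p, 0.8)
  expect_equal(firstAttemptProbability(rbind(cls, cls))$p, 0.8)
})

test_that("simulated saturating NTP gives a first-attempt fraction near P_max", {
  sc <- buildDefaultScheme(ntp = 1e6)  # p -> P_max = 0.79
  paths <- gillespieSimulate(sc, 500, 200, seed = 42, injectionTime = 20)
  cls <- classifyTrajectories(lapply(paths, truthLabeledPath))
  fa <- firstAttemptProbability(cls)
  expect_true(fa$ci[1] <= 0.79 && 0.79 <= fa$ci[2])
})

test_that("the escape isotherm is recovered exactly from noiseless points", {
  pts <- data.frame(ntp = c(1, 5, 10, 30, 80, 500))
  pts$p <- 0.79 * pts$ntp / (pts$ntp + 28)
  fit <- fitIsotherm(pts)
  expect_equal(fit@Kntp, 28, tolerance = 1e-6)
  expect_equal(fit@Pmax, 0.79, tolerance = 1e-6)
  expect_true(all(abs(fit@residuals$residual) < 1e-8))
})

test_that("non-identifiable isotherm inputs are rejected", {
  sat <- data.frame(ntp = c(100, 500), p = c(0.78, 0.79))
  expect_error(fitIsotherm(sat), "4 distinct")
  sat6 <- data.frame(ntp = c(100, 200, 300, 400, 500, 600),
                     p = c(0.78, 0.785, 0.79, 0.788, 0.789, 0.79))
  expect_error(fitIsotherm(sat6), "saturated")
})

test_that("isotherm residuals at truth beat perturbed parameters", {
  set.seed(8)
  pts <- data.frame(ntp = c(1, 5, 10, 30, 80, 500))
  pts$p <- 0.79 * pts$ntp / (pts$ntp + 28) +
    rnorm(6, sd = 0.01)
  rss <- function(K, Pm) sum((pts$p - Pm * pts$ntp / (pts$ntp + K))^2)
  fit <- fitIsotherm(pts, weighted = FALSE)
  expect_lt(rss(fit@Kntp, fit@Pmax), rss(fit@Kntp * 1.3, fit@Pmax))
  expect_lt(rss(fit@Kntp, fit@Pmax), rss(fit@Kntp, min(1, fit@Pmax * 1.1)))
})

test_that("transition counting tallies ordered consecutive pairs", {
  tc <- transitionHistogram(list(mkPath(c(US = 5, FS = 3, US = 4, FS = 6))))
  expect_equal(tc@counts["US", "FS"], 2L)
  expect_equal(tc@counts["FS", "US"], 1L)
  expect_equal(sum(tc@counts), 3L)
  expect_true(all(diag(tc@counts) == 0))
  empty <- transitionHistogram(list())
  expect_true(all(empty@counts == 0))
})

test_that("withdrawal cyclers favor US<->FS about 4-fold over US<->PS", {
  sc <- buildWithdrawalScheme(frac_usps = 0)  # US/PS/FS subpopulation only
  paths <- gillespieSimulate(sc, 500, 80, seed = 44)
  tc <- transitionHistogram(lapply(paths, truthLabeledPath))
  usfs <- tc@counts["US", "FS"] + tc@counts["FS", "US"]
  usps <- tc@counts["US", "PS"] + tc@counts["PS", "US"]
  psfs <- tc@counts["PS", "FS"] + tc@counts["FS", "PS"]
  expect_equal(usfs / usps, 4, tolerance = 0.3)
  expect_lt(psfs, usps)
})

test_that("memory-less dwells show no rank correlation; alternation does", {
  sc <- buildWithdrawalScheme(frac_usps = 1)
  paths <- gillespieSimulate(sc, 2000, 40, seed = 45)
  mt <- dwellMemoryTest(lapply(paths, truthLabeledPath), "US", seed = 1)
  expect_lt(abs(mt$rho), 0.1)
  expect_gt(mt$p_value, 0.05)

  # adversarial generator: deterministic slow/fast alternation
  set.seed(9)
  alt <- lapply(1:10, function(i) {
    durs <- rep(c(10, 1), 12) * exp(rnorm(24, sd = 0.05))
    lab <- rep(c("US", "PS"), 24)[1:48]
    spec <- as.numeric(rbind(durs, rep(2, 24)))
    names(spec) <- lab
    mkPath(spec, id = sprintf("a%d", i))
  })
  mtAlt <- dwellMemoryTest(alt, "US", seed = 1)
  expect_lt(mtAlt$rho, -0.5)
  expect_lt(mtAlt$p_value, 0.01)

  const <- lapply(1:30, function(i)
    mkPath(stats::setNames(rep(5, 10), rep(c("US", "PS"), 5)),
           id = sprintf("k%d", i)))
  mtC <- dwellMemoryTest(const, "US", seed = 1, min_pairs = 10)
  expect_true(is.na(mtC$rho))
  expect_match(mtC$reason, "degenerate")
  expect_error(dwellMemoryTest(alt[1], "US"), "pairs")
})

test_that("withdrawal subpopulations split by visited levels with kinetics", {
  sc <- buildWithdrawalScheme(frac_usps = 0.5)
  paths <- gillespieSimulate(sc, 600, 160, seed = 101)
  lps <- lapply(paths, truthLabeledPath)
  out <- withdrawalSubpopulations(lps, restarts = 8)
  fr <- out$fractions
  expect_equal(sum(fr$n), 160L)
  i <- which(fr$subpopulation == "US/PS")
  expect_true(fr$ci_lo[i] <= 0.5 && 0.5 <= fr$ci_hi[i])
  # US/PS/FS subpopulation is about 6x faster in k1
  k1a <- rates(out$fits[["US/PS"]][["US"]])[1]
  k1b <- rates(out$fits[["US/PS/FS"]][["US"]])[1]
  expect_equal(k1b / k1a, 0.96 / 0.16, tolerance = 0.25)
  # a trace visiting a single level is assigned to no subpopulation
  solo <- classifyTrajectories(list(mkPath(c(US = 50, US2 = 1)[1],
                                           id = "solo")))
  expect_equal(solo$subpopulation, "none")
})
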