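test_that("escape isotherm has the right midpoint and saturation limit", {
  expect_equal(escapeProbability(28, K_ntp = 28, P_max = 0.79), 0.79 / 2)
  expect_equal(escapeProbability(1e9, K_ntp = 28, P_max = 0.79), 0.79,
               tolerance = 1e-6)
  expect_equal(escapeProbability(0, K_ntp = 28, P_max = 0.79), 0)
})

test_that("default scheme with published rates passes all invariants", {
  sc <- buildDefaultScheme(k_itc6 = 0.11, K_ntp = 28, P_max = 0.79,
                           k1 = 0.15, k2 = 0.02, P_k1 = 0.6, ntp = 80)
  expect_true(validObject(sc))
  st <- sc@states
  # each observable maps to exactly one FRET level
  for (obs in unique(st$observable))
    expect_length(unique(st$fret[st$observable == obs]), 1L)
  # pause exits at k_itc6 in total
  tr <- sc@transitions
  expect_equal(sum(tr$rate[tr$from == "PSpause"]), 0.11)
  # productive branch carries p(ntp) of the pause exit flux
  p <- escapeProbability(80, 28, 0.79)
  expect_equal(tr$rate[tr$from == "PSpause" & tr$to == "FS"], 0.11 * p)
})

test_that("invalid scheme parameters raise errors naming the field", {
  expect_error(buildDefaultScheme(k_itc6 = -1), "k_itc6")
  expect_error(buildDefaultScheme(P_max = 1.2), "P_max")
  expect_error(buildDefaultScheme(P_k1 = -0.1), "P_k1")
  expect_error(buildDefaultScheme(k1 = 0.01, k2 = 0.02), "k1")
  expect_error(buildDefaultScheme(K_ntp = 0), "K_ntp")
})

test_that("withdrawal scheme is valid and splits subpopulations", {
  sc <- buildWithdrawalScheme(frac_usps = 0.48)
  expect_true(validObject(sc))
  expect_equal(sum(sc@initProb), 1)
  expect_equal(sum(sc@initProb[c("a.US_f", "a.US_s")]), 0.48)
})

test_that("single-state dwell times are exponential with mean 1/k", {
  # two-state cycle at rate 0.5 each: every dwell is Exp(0.5)
  sc <- new("KineticScheme",
            states = data.frame(label = c("A", "B"),
                                observable = c("US", "PS"),
                                fret = c(0.49, 0.37),
                                absorbing = FALSE),
            transitions = data.frame(from = c("A", "B"), to = c("B", "A"),
                                     rate = 0.5),
            initProb = c(A = 1), ntpBranching = list())
  paths <- gillespieSimulate(sc, duration = 2100, n_traces = 10, seed = 4)
  dw <- unlist(lapply(paths, function(p) {
    sg <- p@segments
    sg$duration_s[-c(1L, nrow(sg))]  # complete dwells only
  }))
  expect_gt(length(dw), 9000)
  se <- sd(dw) / sqrt(length(dw))
  expect_lt(abs(mean(dw) - 2), 3 * se)
})

test_that("two-substate cycling produces the closed-form mixture dwell law", {
  sc <- buildWithdrawalScheme(frac_usps = 1,
                              slow = c(k1 = 0.15, k2 = 0.02, P_k1 = 0.6))
  paths <- gillespieSimulate(sc, duration = 25000, n_traces = 20, seed = 9)
  dw <- unlist(lapply(paths, function(p) {
    os <- observedSegments(p)
    keep <- os$observable == "US"
    keep[c(1L, nrow(os))] <- FALSE
    os$duration_s[keep]
  }))
  expect_gt(length(dw), 1e4)
  # mean matches p/k1 + (1-p)/k2 within 3 SE
  mth <- 0.6 / 0.15 + 0.4 / 0.02
  expect_lt(abs(mean(dw) - mth) / (sd(dw) / sqrt(length(dw))), 3)
  # Kolmogorov-Smirnov against the closed-form mixture CDF at alpha = 0.01
  cdf <- function(q) 1 - (0.6 * exp(-0.15 * q) + 0.4 * exp(-0.02 * q))
  ks <- suppressWarnings(ks.test(dw, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulation is reproducible and conserves total time", {
  sc <- buildDefaultScheme(ntp = 30)
  a <- gillespieSimulate(sc, duration = 300, n_traces = 5, seed = 11)
  b <- gillespieSimulate(sc, duration = 300, n_traces = 5, seed = 11)
  expect_identical(lapply(a, segments), lapply(b, segments))
  for (p in a) expect_equal(sum(p@segments$duration_s), 300)
})

test_that("absorbing-only schemes are rejected", {
  sc <- new("KineticScheme",
            states = data.frame(label = "X", observable = "FS", fret = 0.8,
                                absorbing = TRUE),
            transitions = data.frame(from = character(0), to = character(0),
                                     rate = numeric(0)),
            initProb = c(X = 1), ntpBranching = list())
  expect_error(gillespieSimulate(sc, 10, 1, seed = 1), "no dynamics")
})

test_that("two-state occupancies match the analytic stationary law", {
  # A <-> B with rates 0.3 (A->B) and 0.1 (B->A): pi_A = 0.1/0.4
  sc <- new("KineticScheme",
            states = data.frame(label = c("A", "B"),
                                observable = c("US", "PS"),
                                fret = c(0.49, 0.37), absorbing = FALSE),
            transitions = data.frame(from = c("A", "B"), to = c("B", "A"),
                                     rate = c(0.3, 0.1)),
            initProb = c(A = 0.25, B = 0.75), ntpBranching = list())
  paths <- gillespieSimulate(sc, duration = 20000, n_traces = 10, seed = 5)
  tA <- sum(unlist(lapply(paths, function(p)
    p@segments$duration_s[p@segments$state == "A"])))
  occ <- tA / (20000 * 10)
  expect_equal(occ, 0.1 / 0.4, tolerance = 0.02)
})

test_that("rendering is exact without noise and reflects bleaching", {
  sc <- buildDefaultScheme(ntp = 80)
  path <- new("StatePath", traceId = "x",
              segments = data.frame(state = "US0", observable = "US",
                                    fret = 0.49, start_s = 0,
                                    duration_s = 100),
              truncation = "end-of-record")
  em0 <- emissionParams(noiseSd = 0, donorBleachRate = 0,
                        acceptorBleachRate = 0)
  tr <- renderTrace(path, em0, seed = 1)
  E <- tr@IDA / (tr@IDA + tr@IDD)
  expect_equal(E, rep(0.49, 500))
  expect_equal(tr@IAA, rep(1000, 500))

  # acceptor bleaching kills I_AA at the bleach frame
  em1 <- emissionParams(noiseSd = 0, donorBleachRate = 0,
                        acceptorBleachRate = 0.05)
  tr1 <- renderTrace(path, em1, seed = 3)
  bl <- tr1@meta$acceptorBleach_s
  f <- which(tr1@IAA == 0)[1L]
  expect_equal(f, floor(bl / 0.2) + 1, tolerance = 1)
  expect_true(all(tr1@IAA[f:length(tr1@IAA)] == 0))
  expect_true(all(tr1@IDD[f:length(tr1@IDD)] == 1000))
})

test_that("per-frame FRET noise matches the error-propagation target", {
  # sigma_E ~ noiseSd * sqrt(E^2 + (1-E)^2) / total; defaults aim at ~0.05
  path <- new("StatePath", traceId = "x",
              segments = data.frame(state = "US0", observable = "US",
                                    fret = 0.49, start_s = 0,
                                    duration_s = 2000),
              truncation = "end-of-record")
  em <- emissionParams(donorBleachRate = 0, acceptorBleachRate = 0)
  tr <- renderTrace(path, em, seed = 8)
  E <- tr@IDA / (tr@IDA + tr@IDD)
  target <- em@noiseSd * sqrt(0.49^2 + 0.51^2) / em@totalIntensity
  expect_equal(sd(E), target, tolerance = 0.1)
  expect_equal(sd(E), 0.05, tolerance = 0.1)
})

test_that("frame discretization hides sub-half-frame events", {
  segs <- data.frame(state = c("A", "B", "A"),
                     observable = c("US", "PS", "US"),
                     fret = c(0.49, 0.37, 0.49),
                     start_s = c(0, 1.00, 1.06),
                     duration_s = c(1.00, 0.06, 8.94))
  path <- new("StatePath", traceId = "x", segments = segs,
              truncation = "end-of-record")
  em0 <- emissionParams(noiseSd = 0, donorBleachRate = 0,
                        acceptorBleachRate = 0)
  tr <- renderTrace(path, em0, seed = 1)
  E <- tr@IDA / (tr@IDA + tr@IDD)
  expect_equal(unique(E), 0.49)  # 60 ms event < half a 200 ms frame
})
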