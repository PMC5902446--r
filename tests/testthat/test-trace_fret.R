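test_that("FRET efficiency follows the two-channel ratio", {
  tr <- mkTrace(IDD = c(80, 100, 51), IDA = c(80, 0, 49))
  ft <- computeFret(tr)
  expect_equal(ft@E, c(0.5, 0, 0.49))
  expect_true(all(ft@mask))
})

test_that("non-positive summed intensity frames are masked", {
  tr <- mkTrace(IDD = c(80, -40, 80), IDA = c(80, 40, 80))
  ft <- computeFret(tr)
  expect_equal(ft@mask, c(TRUE, FALSE, TRUE))
  tr2 <- mkTrace(IDD = c(-1, -1), IDA = c(0, 0))
  expect_error(computeFret(tr2), "no usable frames")
})

test_that("FRET is scale invariant and monotone in the acceptor channel", {
  idd <- runif(50, 100, 900); ida <- runif(50, 100, 900)
  e1 <- computeFret(mkTrace(idd, ida))@E
  e2 <- computeFret(mkTrace(idd * 7.3, ida * 7.3))@E
  expect_equal(e1, e2, tolerance = 1e-12)
  ida_grid <- seq(10, 1000, by = 10)
  e <- computeFret(mkTrace(rep(500, length(ida_grid)), ida_grid))@E
  expect_true(all(diff(e) > 0))
})

test_that("selection keeps single-bleach traces and windows them", {
  set.seed(2)
  n <- 300
  # acceptor bleaches at frame 200: I_AA drops, I_DA off, I_DD full
  iaa <- c(rnorm(200, 1000, 20), rnorm(100, 0, 20))
  idd <- c(rnorm(200, 500, 20), rnorm(100, 1000, 20))
  ida <- c(rnorm(200, 500, 20), rnorm(100, 0, 20))
  sel <- selectTraces(list(mkTrace(idd, ida, iaa, id = "ok")))
  expect_true(sel$report$kept)
  expect_equal(sel$report$window_end_frame, 200, tolerance = 2)
  expect_lt(abs(sel$kept[[1]]@meta$windowFrames - 200), 3)
})

test_that("multistep photobleaching in the donor channels is rejected", {
  set.seed(3)
  # two donor dyes: summed donor-excitation signal steps 2000 -> 1000 -> 0
  idd <- c(rnorm(100, 2000, 20), rnorm(100, 1000, 20), rnorm(100, 0, 20))
  ida <- rnorm(300, 0, 20)
  iaa <- rnorm(300, 1000, 20)
  sel <- selectTraces(list(mkTrace(idd, ida, iaa, id = "two")))
  expect_false(sel$report$kept)
  expect_match(sel$report$reason, "multistep")
})

test_that("selection is idempotent", {
  set.seed(4)
  traces <- lapply(1:5, function(i) {
    iaa <- c(rnorm(150, 1000, 30), rnorm(50, 0, 30))
    idd <- c(rnorm(150, 500, 30), rnorm(50, 1000, 30))
    ida <- c(rnorm(150, 500, 30), rnorm(50, 0, 30))
    mkTrace(idd, ida, iaa, id = sprintf("t%d", i))
  })
  s1 <- selectTraces(traces)
  s2 <- selectTraces(s1$kept)
  expect_equal(length(s2$kept), length(s1$kept))
  expect_equal(vapply(s2$kept, function(t) t@meta$windowFrames, numeric(1)),
               vapply(s1$kept, function(t) t@meta$windowFrames, numeric(1)))
})

test_that("doped double-dye traces are overwhelmingly rejected", {
  em <- emissionParams()
  sc <- buildDefaultScheme(ntp = 80)
  paths <- gillespieSimulate(sc, duration = 120, n_traces = 500, seed = 14,
                             injectionTime = 10)
  traces <- lapply(seq_along(paths), function(i)
    renderTrace(paths[[i]], em, seed = 4000 + i))
  doped <- seq_len(50)
  extra <- gillespieSimulate(sc, duration = 120, n_traces = 50, seed = 15,
                             injectionTime = 10)
  for (j in doped) {
    tr2 <- renderTrace(extra[[j]], em, seed = 9000 + j)
    n <- min(length(traces[[j]]@IDD), length(tr2@IDD))
    traces[[j]]@IDD <- traces[[j]]@IDD[1:n] + tr2@IDD[1:n]
    traces[[j]]@IDA <- traces[[j]]@IDA[1:n] + tr2@IDA[1:n]
    traces[[j]]@IAA <- traces[[j]]@IAA[1:n] + tr2@IAA[1:n]
  }
  sel <- selectTraces(traces)
  rejectedDoped <- sum(!sel$report$kept[doped])
  expect_gte(rejectedDoped / length(doped), 0.95)
})

test_that("active fraction is 0 for flat and 1 for stepping traces", {
  flat <- new("SegmentedTrace", traceId = "f", frameTime = 0.2,
              segments = data.frame(level = 0.49, start_frame = 0L,
                                    n_frames = 100L, confidence = 1))
  step <- new("SegmentedTrace", traceId = "s", frameTime = 0.2,
              segments = data.frame(level = c(0.49, 0.37),
                                    start_frame = c(0L, 60L),
                                    n_frames = c(60L, 40L),
                                    confidence = 1))
  expect_equal(detectActive(list(flat, flat), injection_frame = 10)$fraction, 0)
  out <- detectActive(list(step, step), injection_frame = 10)
  expect_equal(out$fraction, 1)
  expect_true(out$ci[1] >= 0 && out$ci[2] <= 1)
  expect_error(detectActive(list(), 0), "no traces")
})

test_that("a partly inactive population is recovered within its CI", {
  # 30% of molecules never leave US
  em <- emissionParams(donorBleachRate = 0, acceptorBleachRate = 0)
  sc <- buildDefaultScheme(ntp = 80)
  set.seed(6)
  paths <- gillespieSimulate(sc, 200, 140, seed = 16, injectionTime = 20)
  lp <- lapply(paths, truthLabeledPath)
  inert <- sample(length(lp), 42)
  for (i in inert) {
    lp[[i]]@segments <- data.frame(label = "US", start_s = 0,
                                   duration_s = 200, is_first = TRUE,
                                   is_last = TRUE, stringsAsFactors = FALSE)
  }
  out <- detectActive(lp, injection_frame = 100)
  expect_true(out$ci[1] <= 0.70 && 0.70 <= out$ci[2])
})

test_that("Gaussian level calibration recovers noiseless and noisy peaks", {
  set.seed(7)
  mk <- function(sd, seed) mkThreeLevelSet(30, n_frames = 300, minDwell = 8,
                                           sd = sd, seed = seed)
  # noiseless: centers are exact cluster means
  s0 <- mk(0, 1)
  segs0 <- lapply(s0$fret, function(f) {
    r <- rle(f@E)
    new("SegmentedTrace", traceId = f@traceId, frameTime = 0.2,
        segments = data.frame(level = r$values,
                              start_frame = cumsum(c(0L, r$lengths[-length(r$lengths)])),
                              n_frames = r$lengths, confidence = 1))
  })
  lev0 <- fitFretLevels(segs0)
  expect_equal(lev0@table$center, c(0.37, 0.49, 0.80), tolerance = 1e-8)
  expect_equal(lev0@table$label, c("PS", "US", "FS"))

  # noisy: centers within 0.01 of truth, peak SD near the frame noise
  s1 <- mk(0.05, 2)
  segs1 <- segmentHmm(s1$fret, max_states = 3)
  lev1 <- fitFretLevels(segs1, fret = s1$fret)
  expect_equal(lev1@table$center, c(0.37, 0.49, 0.80), tolerance = 0.011)
  expect_true(all(abs(lev1@table$sd - 0.05) < 0.02))
})
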