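test_that("Allan deviation matches its closed forms", {
  expect_equal(allanDeviation(rep(0.5, 100), block = 5), 0)
  # alternating block means 0,1,0,1,... give sqrt(0.5)
  expect_equal(allanDeviation(rep(c(0, 1), each = 5, times = 20), block = 5),
               sqrt(0.5))
  # white noise of SD sigma: sigma_A -> sigma / sqrt(block)
  set.seed(1)
  x <- rnorm(1e5, sd = 0.05)
  expect_equal(allanDeviation(x, block = 5), 0.05 / sqrt(5), tolerance = 0.05)
  expect_error(allanDeviation(rnorm(8), block = 5), "too short")
})

test_that("noiseless square waves are segmented exactly", {
  E <- rep(c(0.4, 0.8), each = 25, times = 8)
  segs <- segmentHmm(list(mkFret(E)), max_states = 3)
  sg <- segs[[1]]@segments
  expect_equal(nrow(sg), 16L)
  expect_equal(sg$n_frames, rep(25L, 16))
  expect_equal(unique(sg$level), c(0.4, 0.8))
  expect_equal(sg$start_frame, seq(0L, 375L, by = 25L))
})

test_that("segmentation is deterministic across repeated runs", {
  s <- mkThreeLevelSet(8, n_frames = 300, sd = 0.05, seed = 3)
  a <- segmentHmm(s$fret, max_states = 3)
  b <- segmentHmm(s$fret, max_states = 3)
  expect_identical(lapply(a, segments), lapply(b, segments))
})

test_that("three-level traces reach 95% frame accuracy at E SD 0.05", {
  s <- mkThreeLevelSet(40, n_frames = 400, minDwell = 5, sd = 0.05, seed = 4)
  segs <- segmentHmm(s$fret, max_states = 3)
  par <- attr(segs, "hmm")
  ord <- order(par$mu)
  acc <- vapply(seq_along(segs), function(i) {
    sg <- segs[[i]]@segments
    # assign each frame its segment's nearest true level index
    lvl <- rep(sg$level, times = sg$n_frames)
    pred <- vapply(lvl, function(v)
      which.min(abs(v - c(0.37, 0.49, 0.80))), integer(1))
    mean(pred == s$truth[[i]])
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("accuracy degrades monotonically with emission noise", {
  accAt <- function(sd) {
    s <- mkThreeLevelSet(12, n_frames = 300, minDwell = 6, sd = sd, seed = 5)
    segs <- segmentHmm(s$fret, max_states = 3)
    mean(vapply(seq_along(segs), function(i) {
      sg <- segs[[i]]@segments
      lvl <- rep(sg$level, times = sg$n_frames)
      pred <- vapply(lvl, function(v)
        which.min(abs(v - c(0.37, 0.49, 0.80))), integer(1))
      mean(pred == s$truth[[i]])
    }, numeric(1)))
  }
  accs <- vapply(c(0.02, 0.05, 0.09), accAt, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("step filter removes blips and respects the Allan threshold", {
  mkSeg <- function(levels, lens) {
    new("SegmentedTrace", traceId = "s", frameTime = 0.2,
        segments = data.frame(level = levels,
                              start_frame = cumsum(c(0L, lens[-length(lens)])),
                              n_frames = lens,
                              confidence = rep(1, length(lens))))
  }
  # a single 1-frame blip between identical levels collapses to one segment
  blip <- mkSeg(c(0.5, 0.8, 0.5), c(30L, 1L, 30L))
  out <- filterSteps(blip, sigma_A = 0.02)
  expect_equal(nrow(out@segments), 1L)
  expect_equal(out@segments$n_frames, 61L)

  # separation 1.9 sigma_A merges, 2.1 sigma_A survives
  sA <- 0.05
  close_ <- mkSeg(c(0.50, 0.50 + 1.9 * sA), c(20L, 20L))
  apart <- mkSeg(c(0.50, 0.50 + 2.1 * sA), c(20L, 20L))
  expect_equal(nrow(filterSteps(close_, sA)@segments), 1L)
  expect_equal(nrow(filterSteps(apart, sA)@segments), 2L)
})

test_that("step filter is idempotent and conserves total duration", {
  set.seed(6)
  s <- mkThreeLevelSet(6, n_frames = 300, minDwell = 3, sd = 0.06, seed = 6)
  segs <- segmentHmm(s$fret, max_states = 3)
  for (i in seq_along(segs)) {
    f1 <- filterSteps(segs[[i]], sigma_A = 0.025)
    f2 <- filterSteps(f1, sigma_A = 0.025)
    expect_identical(f1@segments, f2@segments)
    expect_equal(sum(f1@segments$n_frames), sum(segs[[i]]@segments$n_frames))
  }
})

test_that("filtering reduces spurious transitions relative to raw Viterbi", {
  s <- mkThreeLevelSet(50, n_frames = 300, minDwell = 5, sd = 0.06, seed = 7)
  segs <- segmentHmm(s$fret, max_states = 3)
  nTrue <- sum(vapply(s$truth, function(tr) sum(diff(tr) != 0), numeric(1)))
  nRaw <- sum(vapply(segs, function(x) nrow(x@segments) - 1L, numeric(1)))
  filt <- lapply(seq_along(segs), function(i) {
    x <- s$fret[[i]]@E
    filterSteps(segs[[i]], sigma_A = 0.06 / sqrt(5))
  })
  nFilt <- sum(vapply(filt, function(x) nrow(x@segments) - 1L, numeric(1)))
  expect_gt(nRaw, nTrue)      # raw Viterbi over-segments at this noise
  expect_lt(nFilt, nRaw)      # the filter strictly reduces transitions
})

test_that("state mapping labels by nearest center with a lower-level tie rule", {
  lev <- mkLevelTable()
  mkSeg <- function(levels, lens) {
    new("SegmentedTrace", traceId = "s", frameTime = 0.2,
        segments = data.frame(level = levels,
                              start_frame = cumsum(c(0L, lens[-length(lens)])),
                              n_frames = lens,
                              confidence = rep(1, length(lens))))
  }
  lp <- mapStates(mkSeg(c(0.50, 0.585, 0.37), c(10L, 10L, 10L)), lev)
  # 0.585 maps to US like its neighbor; the two segments collapse
  expect_equal(lp@segments$label, c("US", "PS"))
  expect_equal(lp@segments$duration_s, c(4, 2))
  # exactly equidistant between PS (0.37) and US (0.49): lower level wins
  lp2 <- mapStates(mkSeg(c(0.43, 0.80), c(10L, 10L)), lev)
  expect_equal(lp2@segments$label[1], "PS")
  expect_true(lp2@segments$tie[1])
  # far from every center: unassigned, trace flagged when dominant
  lp3 <- mapStates(mkSeg(c(0.49, 1.6), c(5L, 50L)), mkLevelTable(sd = 0.01))
  expect_equal(lp3@segments$label, c("US", "unassigned"))
  expect_true(lp3@flagged)
  # durations in seconds, total conserved
  expect_equal(sum(lp@segments$duration_s), 6)
})

test_that("mapped labels are at least 98% correct at E SD 0.05", {
  s <- mkThreeLevelSet(40, n_frames = 400, minDwell = 8, sd = 0.05, seed = 8)
  segs <- segmentHmm(s$fret, max_states = 3)
  lev <- fitFretLevels(segs, fret = s$fret)
  labs <- c("PS", "US", "FS")
  ok <- 0; tot <- 0
  for (i in seq_along(segs)) {
    filt <- filterSteps(segs[[i]], sigma_A = 0.05 / sqrt(5))
    lp <- mapStates(filt, lev)
    pred <- rep(lp@segments$label, times = round(lp@segments$duration_s / 0.2))
    truth <- labs[s$truth[[i]]]
    n <- min(length(pred), length(truth))
    ok <- ok + sum(pred[1:n] == truth[1:n]); tot <- tot + n
  }
  expect_gte(ok / tot, 0.98)
})
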