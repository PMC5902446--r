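# shared builders for synthetic objects used across the test files

mkTrace <- function(IDD, IDA, IAA = rep(1000, length(IDD)), id = "t",
                    frameTime = 0.2, meta = list()) {
  new("IntensityTrace", traceId = id, frameTime = frameTime,
      IDD = IDD, IDA = IDA, IAA = IAA, meta = meta)
}

mkFret <- function(E, id = "t", frameTime = 0.2) {
  new("FretTrace", traceId = id, frameTime = frameTime, E = E,
      mask = rep(TRUE, length(E)))
}

mkDwells <- function(tau, state = "PS") {
  new("DwellSet", state = state, tau = tau,
      censored = rep(FALSE, length(tau)),
      traceId = rep("t", length(tau)))
}

# labeled path from a label/duration spec, e.g. mkPath(c(US = 5, PS = 3))
mkPath <- function(durations, id = "p", frameTime = 0.2,
                   truncation = "bleach") {
  lab <- names(durations)
  n <- length(durations)
  start <- cumsum(c(0, unname(durations)[-n]))
  new("LabeledPath", traceId = id, frameTime = frameTime,
      segments = data.frame(label = lab, start_s = start,
                            duration_s = unname(durations),
                            is_first = seq_len(n) == 1L,
                            is_last = seq_len(n) == n,
                            stringsAsFactors = FALSE),
      truncation = truncation, flagged = FALSE)
}

# FretTrace with known piecewise levels: dwell lengths in frames, with
# Gaussian noise; returns the trace and the true per-frame level index
mkLevelTrace <- function(dwellFrames, levelIdx, levels, sd, id = "t",
                         seed = 1) {
  set.seed(seed)
  truth <- rep(levels[levelIdx], times = dwellFrames)
  E <- truth + rnorm(length(truth), sd = sd)
  list(fret = mkFret(E, id = id),
       truthLevel = rep(levelIdx, times = dwellFrames))
}

# a batch of 3-level traces with exponential-ish dwells bounded below
mkThreeLevelSet <- function(n_traces, n_frames = 400, minDwell = 5,
                            meanDwell = 20, sd = 0.05,
                            levels = c(0.37, 0.49, 0.80), seed = 1) {
  set.seed(seed)
  out <- vector("list", n_traces)
  truths <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    frames <- 0L
    dw <- integer(0); li <- integer(0)
    cur <- sample(3L, 1L)
    while (frames < n_frames) {
      d <- minDwell + rgeom(1L, 1 / (meanDwell - minDwell))
      d <- min(d, n_frames - frames)
      if (d < 1L) break
      dw <- c(dw, d); li <- c(li, cur)
      frames <- frames + d
      cur <- sample(setdiff(1:3, cur), 1L)
    }
    truth <- rep(levels[li], times = dw)
    E <- truth + rnorm(length(truth), sd = sd)
    out[[i]] <- mkFret(E, id = sprintf("t%03d", i))
    truths[[i]] <- rep(li, times = dw)
  }
  list(fret = out, truth = truths)
}

mkLevelTable <- function(centers = c(0.37, 0.49, 0.80), sd = 0.05) {
  new("LevelTable",
      table = data.frame(label = c("PS", "US", "FS"), center = centers,
                         sd = rep(sd, 3), se_center = rep(1e-3, 3),
                         stringsAsFactors = FALSE),
      merged = FALSE)
}
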