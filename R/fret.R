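#' @include AllClasses.R
NULL

#' Compute the FRET efficiency trajectory of a trace
#'
#' Applies E = I_DA / (I_DA + I_DD) per frame.  Frames whose summed
#' donor-excitation intensity is non-positive are masked out, as are frames
#' beyond the trace's analysis window when [selectTraces()] has set one
#' (`meta$windowFrames`).  E is deliberately not clipped to \[0, 1\]: noise
#' can push it outside and clipping would bias the Gaussian level fits.
#'
#' @param trace an [IntensityTrace-class].
#' @return a [FretTrace-class].
#' @examples
#' tr <- new("IntensityTrace", traceId = "t", frameTime = 0.2,
#'           IDD = c(80, 51), IDA = c(80, 49), IAA = c(100, 100), meta = list())
#' computeFret(tr)@E
#' @export
computeFret <- function(trace) {
  stopifnot(is(trace, "IntensityTrace"))
  validObject(trace)
  s <- trace@IDA + trace@IDD
  mask <- is.finite(s) & s > 0
  if (!is.null(trace@meta$windowFrames)) {
    w <- trace@meta$windowFrames
    mask <- mask & (seq_along(s) <= w)
  }
  if (!any(mask)) stop("no usable frames")
  E <- rep(NA_real_, length(s))
  E[mask] <- trace@IDA[mask] / s[mask]
  new("FretTrace", traceId = trace@traceId, frameTime = trace@frameTime,
      E = E, mask = mask)
}

#' Selection policy for single-pair traces
#'
#' Thresholds for the automated surrogate of manual trace sorting: traces
#' must show a single acceptor (I_AA high until at most one terminal drop),
#' at most a single-step donor bleach, and a bounded number of blinking
#' events.
#'
#' @param maxBlinks maximum tolerated blink (off-then-on) events per channel.
#' @param stepSigma significance of a mean shift, in units of the estimated
#'   frame noise SD, for the change-point step detector.
#' @param minStepFrac a downward step must remove at least this fraction of
#'   the preceding level to count as a bleaching step.
#' @param minSegFrames minimum segment length for change-point detection.
#' @param maxBrightness traces whose initial intensity exceeds this multiple
#'   of the cohort median (in either the acceptor-excitation channel or the
#'   summed donor-excitation channels) are rejected as multi-dye spots;
#'   with bleach-limited records a second dye need not show its own
#'   bleaching step inside the record, so brightness is the trace-level
#'   surrogate for spot-based multi-emitter filters.
#' @return a list with class `"SelectionPolicy"`.
#' @export
selectionPolicy <- function(maxBlinks = 1L, stepSigma = 5, minStepFrac = 0.35,
                            minSegFrames = 3L, maxBrightness = 1.5) {
  structure(list(maxBlinks = as.integer(maxBlinks), stepSigma = stepSigma,
                 minStepFrac = minStepFrac,
                 minSegFrames = as.integer(minSegFrames),
                 maxBrightness = maxBrightness),
            class = "SelectionPolicy")
}

# recursive binary segmentation for mean shifts; returns change points
# (index of last frame of the left part) accepted at |delta| >= minJump
.changePoints <- function(x, minJump, minSeg) {
  n <- length(x)
  if (n < 2L * minSeg) return(integer(0))
  cs <- cumsum(x)
  idx <- minSeg:(n - minSeg)
  lm <- cs[idx] / idx
  rm_ <- (cs[n] - cs[idx]) / (n - idx)
  # gain of the two-segment mean-shift model ~ weighted squared mean difference
  gain <- (idx * (n - idx) / n) * (lm - rm_)^2
  b <- idx[which.max(gain)]
  delta <- mean(x[(b + 1L):n]) - mean(x[1:b])
  if (abs(delta) < minJump) return(integer(0))
  sort(c(.changePoints(x[1:b], minJump, minSeg), b,
         b + .changePoints(x[(b + 1L):n], minJump, minSeg)))
}

# piecewise means between change points
.stepLevels <- function(x, cps) {
  bounds <- c(0L, cps, length(x))
  vapply(seq_len(length(bounds) - 1L), function(i)
    mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
}

# robust per-frame noise SD from first differences
.frameNoiseSd <- function(x) {
  d <- diff(x)
  s <- stats::mad(d) / sqrt(2)
  if (!is.finite(s) || s == 0) s <- stats::sd(d) / sqrt(2)
  if (!is.finite(s) || s == 0) s <- 1e-12
  s
}

# analyze one channel: classify piecewise segments on/off, count blinks and
# bleaching (downward) steps, report first terminal off
.channelSteps <- function(x, policy) {
  sdN <- .frameNoiseSd(x)
  minJump <- max(policy$stepSigma * sdN,
                 policy$minStepFrac * max(abs(stats::median(x[seq_len(min(10, length(x)))])), 4 * sdN))
  cps <- .changePoints(x, minJump, policy$minSegFrames)
  lev <- .stepLevels(x, cps)
  top <- max(lev)
  on <- lev > 0.5 * top
  bounds <- c(0L, cps, length(x))
  # blink: off segment with an on segment after it
  isBlink <- vapply(seq_along(on), function(i)
    !on[i] && any(on[seq_along(on) > i]), logical(1))
  blinks <- sum(isBlink)
  # bleaching steps: downward jumps that are not the entry into a blink
  downSteps <- 0L
  if (length(lev) > 1L) {
    for (j in 2:length(lev)) {
      if (lev[j - 1L] - lev[j] >= minJump && !isBlink[j])
        downSteps <- downSteps + 1L
    }
  }
  firstOff <- if (any(!on)) bounds[which(!on)[1]] else length(x)
  list(levels = lev, on = on, blinks = blinks, downSteps = downSteps,
       firstOff = firstOff, bounds = bounds)
}

#' Select analyzable single-pair traces
#'
#' Automated replacement for manual trace sorting: rejects traces whose
#' acceptor-excitation channel shows no initial acceptor, more than one
#' bleaching step, or excessive blinking, and traces whose total
#' donor-excitation intensity shows multistep photobleaching.  Kept traces
#' get `meta$windowFrames` set to the analysis window (recording start to
#' first bleach event).
#'
#' @param traces list of [IntensityTrace-class] objects.
#' @param policy a [selectionPolicy()].
#' @return list with elements `kept` (traces, windowed) and `report`
#'   (data.frame: trace_id, kept, reason, window_end_frame).
#' @export
selectTraces <- function(traces, policy = selectionPolicy()) {
  if (!length(traces)) stop("at least one trace is required")
  kept <- list()
  rows <- vector("list", length(traces))
  initInt <- function(x) stats::median(x[seq_len(min(20L, length(x)))])
  brightAA <- vapply(traces, function(t) initInt(t@IAA), numeric(1))
  brightD <- vapply(traces, function(t) initInt(t@IDD + t@IDA), numeric(1))
  medAA <- stats::median(brightAA)
  medD <- stats::median(brightD)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    w <- tr@meta$windowFrames
    n <- length(tr@IAA)
    use <- seq_len(if (is.null(w)) n else min(w, n))
    aa <- .channelSteps(tr@IAA[use], policy)
    dsum <- .channelSteps((tr@IDD + tr@IDA)[use], policy)
    reason <- NA_character_
    if (!aa$on[1L]) {
      reason <- "no initial acceptor"
    } else if (brightAA[i] > policy$maxBrightness * medAA ||
               brightD[i] > policy$maxBrightness * medD) {
      reason <- "multiple dyes (excess brightness)"
    } else if (aa$downSteps > 1L) {
      reason <- "acceptor multistep photobleaching"
    } else if (dsum$downSteps > 1L) {
      reason <- "donor multistep photobleaching"
    } else if (aa$blinks + dsum$blinks > policy$maxBlinks) {
      reason <- "extensive blinking"
    }
    windowEnd <- min(aa$firstOff, dsum$firstOff)
    if (windowEnd < policy$minSegFrames * 2L && is.na(reason))
      reason <- "bleached immediately"
    ok <- is.na(reason)
    rows[[i]] <- data.frame(trace_id = tr@traceId, kept = ok,
                            reason = ifelse(ok, "", reason),
                            window_end_frame = windowEnd,
                            stringsAsFactors = FALSE)
    if (ok) {
      tr@meta$windowFrames <- windowEnd
      kept[[length(kept) + 1L]] <- tr
    }
  }
  list(kept = kept, report = do.call(rbind, rows))
}

#' Fraction of transcriptionally active molecules
#'
#' A molecule is active when at least one accepted level change occurs after
#' the NTP injection frame.  Returns the active fraction with a Wilson 95%
#' confidence interval.
#'
#' @param paths list of [SegmentedTrace-class] or [LabeledPath-class]
#'   objects (post step-filter).
#' @param injection_frame frame index (0-based) of NTP addition.
#' @return list with `fraction`, `ci` (length 2), `n_active`, `n_total`.
#' @export
detectActive <- function(paths, injection_frame) {
  if (!length(paths)) stop("no traces supplied")
  isActive <- vapply(paths, function(p) {
    sg <- p@segments
    if (nrow(sg) < 2L) return(FALSE)
    if (is(p, "SegmentedTrace")) {
      bounds <- sg$start_frame[-1L]
      any(bounds > injection_frame)
    } else {
      bounds <- sg$start_s[-1L]
      any(bounds > injection_frame * p@frameTime)
    }
  }, logical(1))
  n <- length(isActive)
  k <- sum(isActive)
  list(fraction = k / n, ci = wilsonCI(k, n), n_active = k, n_total = n)
}

#' Wilson score confidence interval
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric length-2 vector (lower, upper).
#' @export
wilsonCI <- function(k, n, conf = 0.95) {
  if (n <= 0) stop("n must be > 0")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Calibrate FRET levels by Gaussian peak fitting
#'
#' Pools the fitted level of every segment (weighted by its length in
#' frames), histograms them, and fits a sum of `n_levels` Gaussians by least
#' squares, mirroring the peak-position extraction used for FRET sensor
#' calibration.  Levels are labeled PS < US < FS by increasing center.
#'
#' @param segs list of [SegmentedTrace-class] objects.
#' @param n_levels number of peaks (3 for the scrunching sensor).
#' @param binwidth histogram bin width in E units.
#' @param overlap_sd peaks closer than `overlap_sd` times the sum of their
#'   SDs are reported merged (with a warning).
#' @param fret optional list of the [FretTrace-class] objects the segments
#'   came from; when supplied, each peak's Gaussian is fit to the histogram
#'   of the *per-frame* E values of its segments, so the peak SD reflects the
#'   frame noise (the width used by [mapStates()] to reject outlying
#'   segments).  Without it the histogram of segment means is used and the
#'   peak SD underestimates the frame noise.
#' @param centers0 optional numeric vector of `n_levels` seed centers (e.g.
#'   the grouped HMM state means): segments are assigned to the nearest seed
#'   instead of k-means-clustered.  Protects the calibration when one
#'   physical level is represented by several HMM states whose segments
#'   would otherwise dominate the clustering.
#' @return a [LevelTable-class].
#' @export
fitFretLevels <- function(segs, n_levels = 3L, binwidth = 0.01,
                          overlap_sd = 1, fret = NULL, centers0 = NULL) {
  vals <- unlist(lapply(segs, function(s) s@segments$level))
  wts <- unlist(lapply(segs, function(s) s@segments$n_frames))
  frames <- NULL
  if (!is.null(fret)) {
    ids <- vapply(fret, traceId, character(1))
    frames <- unlist(lapply(segs, function(s) {
      f <- fret[[match(s@traceId, ids)]]
      x <- f@E[f@mask]
      wm <- which(f@mask) - 1L
      sg <- s@segments
      lapply(seq_len(nrow(sg)), function(i) {
        pos <- match(sg$start_frame[i], wm)
        x[pos:(pos + sg$n_frames[i] - 1L)]
      })
    }), recursive = FALSE)
  }
  if (sum(wts) < 50L * n_levels)
    stop(sprintf("need >= %d pooled level samples, got %d",
                 50L * n_levels, sum(wts)))
  if (!is.null(centers0)) {
    stopifnot(length(centers0) == n_levels)
    cl <- apply(abs(outer(vals, sort(centers0), "-")), 1L, which.min)
    km <- list(cluster = cl, centers = sort(centers0))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(1L)  # k-means initialization only; result is effectively exact
    km <- stats::kmeans(vals, centers = min(n_levels, length(unique(vals))),
                        nstart = 10)
  }
  if (length(unique(km$cluster)) < n_levels)
    stop("fewer distinct levels than requested peaks")
  ord <- order(km$centers)

  centers <- numeric(n_levels); sds <- numeric(n_levels)
  seC <- numeric(n_levels)
  for (r in seq_len(n_levels)) {
    j <- ord[r]
    if (is.null(frames)) {
      v <- vals[km$cluster == j]
      w <- wts[km$cluster == j]
    } else {
      # per-frame E values of this peak's segments
      v <- unlist(frames[km$cluster == j])
      w <- rep(1, length(v))
    }
    if (sum(w) < 50L)
      warning(sprintf("peak %d has only %d pooled samples", r, sum(w)))
    mu0 <- sum(v * w) / sum(w)
    sd0 <- sqrt(max(sum(w * (v - mu0)^2) / sum(w), (binwidth / 2)^2))
    # least-squares Gaussian on the frame-weighted histogram of this peak
    br <- seq(min(v) - binwidth, max(v) + binwidth, by = binwidth)
    fitted <- NULL
    if (length(br) >= 5L) {
      h <- .weightedHist(v, w, br)
      a0 <- sum(w) * binwidth / (sd0 * sqrt(2 * pi))
      fitted <- tryCatch(
        minpack.lm::nlsLM(cnt ~ a * exp(-(mids - c0)^2 / (2 * s0^2)),
                          data = data.frame(mids = h$mids, cnt = h$counts),
                          start = list(a = a0, c0 = mu0, s0 = sd0),
                          lower = c(0, -0.2, binwidth / 4),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    }
    if (!is.null(fitted) &&
        abs(stats::coef(fitted)[["c0"]] - mu0) < 0.1) {
      cf <- stats::coef(fitted)
      centers[r] <- cf[["c0"]]
      sds[r] <- abs(cf[["s0"]])
      seC[r] <- tryCatch(sqrt(diag(stats::vcov(fitted)))[["c0"]],
                         error = function(e) NA_real_)
    } else {
      # moments of the pooled samples when the histogram is degenerate
      centers[r] <- mu0
      sds[r] <- sd0
      seC[r] <- sd0 / sqrt(length(v))
    }
  }

  merged <- FALSE
  if (n_levels > 1L) {
    gaps <- diff(centers)
    lim <- overlap_sd * (sds[-length(sds)] + sds[-1L])
    if (any(gaps < lim)) {
      warning("unresolvable peaks: adjacent centers closer than the overlap threshold; merged-level flag set")
      merged <- TRUE
    }
  }
  labs <- if (n_levels == 3L) c("PS", "US", "FS") else
    paste0("L", seq_len(n_levels))
  tb <- data.frame(label = labs,
                   center = pmin(pmax(as.numeric(centers), 0), 1),
                   sd = as.numeric(sds), se_center = as.numeric(seC),
                   stringsAsFactors = FALSE)
  new("LevelTable", table = tb, merged = merged)
}

.weightedHist <- function(x, w, breaks) {
  bin <- findInterval(x, breaks, all.inside = TRUE)
  counts <- vapply(seq_len(length(breaks) - 1L),
                   function(b) sum(w[bin == b]), numeric(1))
  list(mids = (breaks[-1L] + breaks[-length(breaks)]) / 2, counts = counts)
}
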