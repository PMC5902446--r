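#' @include AllClasses.R
NULL

#' Allan deviation of a FRET time series
#'
#' Two-sample deviation of consecutive non-overlapping block means:
#' sigma_A = sqrt(0.5 * mean((ybar_{i+1} - ybar_i)^2)), the noise floor used
#' by [filterSteps()] to accept level steps.  For white noise of SD sigma the
#' Allan deviation at block length m converges to sigma / sqrt(m).
#'
#' @param series numeric vector of per-frame E values.
#' @param block block length in frames (default 5).
#' @return the Allan deviation (scalar).
#' @examples
#' allanDeviation(rep(c(0, 1), each = 5, times = 10), block = 5)  # sqrt(0.5)
#' @export
allanDeviation <- function(series, block = 5L) {
  series <- series[is.finite(series)]
  n <- length(series)
  if (n < 2L * block)
    stop(sprintf("series too short: need >= %d frames, got %d", 2L * block, n))
  nb <- n %/% block
  ybar <- colMeans(matrix(series[seq_len(nb * block)], nrow = block))
  sqrt(0.5 * mean(diff(ybar)^2))
}

#' Filter segmentation steps by length and Allan-deviation separation
#'
#' Post-processes an HMM segmentation the way dwell assembly requires: only
#' steps longer than `min_len` frames and separated from their neighbor by
#' more than twice the Allan deviation are conserved.  Short segments are
#' absorbed into the neighbor nearer in level; adjacent segments whose levels
#' differ by at most `2 * sigma_A` are merged into one segment with the
#' duration-weighted mean level.  Merging is applied iteratively, shortest
#' segment first (ties to the earliest), until a fixed point; the result is
#' idempotent and conserves total duration exactly.
#'
#' @param seg a [SegmentedTrace-class].
#' @param sigma_A Allan deviation (E units), >= 0; typically
#'   [allanDeviation()] of the trace at five frames.
#' @param min_len segments of this many frames or fewer are absorbed
#'   (default 2).
#' @return the filtered [SegmentedTrace-class].
#' @export
filterSteps <- function(seg, sigma_A, min_len = 2L) {
  stopifnot(is(seg, "SegmentedTrace"))
  if (sigma_A < 0) stop("'sigma_A' must be >= 0")
  sg <- seg@segments
  lev <- sg$level
  nfr <- sg$n_frames
  conf <- if ("confidence" %in% names(sg)) sg$confidence else rep(1, nrow(sg))
  start0 <- if (nrow(sg)) sg$start_frame[1L] else 0L
  repeat {
    len <- length(lev)
    if (len < 2L) break
    # 1. absorb a too-short segment into the nearer-in-level neighbor
    short <- which(nfr <= min_len)
    if (length(short)) {
      i <- short[order(nfr[short], short)][1L]
      nb <- c(if (i > 1L) i - 1L, if (i < len) i + 1L)
      j <- nb[which.min(abs(lev[nb] - lev[i]))]
      nfr[j] <- nfr[j] + nfr[i]
      lev <- lev[-i]; nfr <- nfr[-i]; conf <- conf[-i]
      next
    }
    # 2. merge the adjacent pair whose levels are within 2 sigma_A
    # (includes equal-level adjacencies created by an absorption)
    close_ <- which(abs(diff(lev)) <= 2 * sigma_A)
    if (!length(close_)) break
    pairLen <- pmin(nfr[close_], nfr[close_ + 1L])
    i <- close_[order(pairLen, close_)][1L]
    w <- nfr[i:(i + 1L)]
    lev[i] <- sum(lev[i:(i + 1L)] * w) / sum(w)
    conf[i] <- sum(conf[i:(i + 1L)] * w) / sum(w)
    nfr[i] <- sum(w)
    lev <- lev[-(i + 1L)]; nfr <- nfr[-(i + 1L)]; conf <- conf[-(i + 1L)]
  }
  out <- data.frame(level = lev,
                    start_frame = start0 + cumsum(c(0L, nfr[-length(nfr)])),
                    n_frames = nfr, confidence = conf)
  new("SegmentedTrace", traceId = seg@traceId, frameTime = seg@frameTime,
      segments = out)
}

#' Map fitted levels to scrunching-state labels
#'
#' Labels every segment by the nearest calibrated FRET level.  Segments
#' farther than `tol_sd` peak SDs from every center are labeled
#' `"unassigned"` and excluded from dwell pooling; exact ties break
#' deterministically to the lower level.  Durations are converted to seconds
#' and the first/last dwell of the trace are flagged for removal by
#' [extractDwells()].
#'
#' @param seg a [SegmentedTrace-class] (after [filterSteps()]).
#' @param levels a [LevelTable-class] with three levels.
#' @param tol_sd assignment tolerance in peak-SD multiples (default 3).
#' @param truncation truncation cause recorded on the path.
#' @return a [LabeledPath-class]; `flagged` is TRUE when more than half of
#'   the frames are unassigned.
#' @export
mapStates <- function(seg, levels, tol_sd = 3, truncation = "bleach") {
  stopifnot(is(seg, "SegmentedTrace"), is(levels, "LevelTable"))
  tb <- levels@table
  if (nrow(tb) != 3L) stop("LevelTable must contain exactly 3 levels")
  sg <- seg@segments
  n <- nrow(sg)
  lab <- character(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    d <- abs(sg$level[i] - tb$center)
    jmin <- which(d == min(d))
    if (length(jmin) > 1L) {  # equidistant: lower level wins, flagged
      jmin <- jmin[which.min(tb$center[jmin])]
      tie[i] <- TRUE
    }
    lab[i] <- if (d[jmin] > tol_sd * tb$sd[jmin]) "unassigned" else tb$label[jmin]
  }
  out <- data.frame(label = lab,
                    start_s = sg$start_frame * seg@frameTime,
                    duration_s = sg$n_frames * seg@frameTime,
                    tie = tie, stringsAsFactors = FALSE)
  # collapse adjacency created when two fitted levels map to one label
  if (nrow(out) > 1L) {
    grp <- cumsum(c(1L, as.integer(out$label[-1L] != out$label[-nrow(out)])))
    out <- do.call(rbind, lapply(split(out, grp), function(g) data.frame(
      label = g$label[1L], start_s = g$start_s[1L],
      duration_s = sum(g$duration_s), tie = any(g$tie),
      stringsAsFactors = FALSE)))
    rownames(out) <- NULL
  }
  m <- nrow(out)
  out$is_first <- seq_len(m) == 1L
  out$is_last <- seq_len(m) == m
  unassignedFrac <- sum(out$duration_s[out$label == "unassigned"]) /
    sum(out$duration_s)
  new("LabeledPath", traceId = seg@traceId, frameTime = seg@frameTime,
      segments = out, truncation = truncation,
      flagged = unassignedFrac > 0.5)
}
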