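#' @include AllClasses.R
NULL

#' Simulate state paths from a kinetic scheme
#'
#' Continuous-time Markov-chain (Gillespie) simulation: the dwell in each
#' hidden state is exponential with the state's total exit rate and the next
#' state is drawn proportionally to the outgoing rates.  Paths are truncated
#' at `duration` (cause `"end-of-record"`); a path that reaches an absorbing
#' state keeps that state's observable until the end of the record and is
#' marked `"escape"`.
#'
#' @param scheme a [KineticScheme-class].
#' @param duration record length in seconds, > 0.
#' @param n_traces number of molecules to simulate, >= 1.
#' @param seed integer seed; simulations are reproducible for a fixed seed.
#' @param injectionTime seconds added to the first dwell, emulating the
#'   pre-NTP baseline during which the scheme is frozen in its initial state.
#' @param idPrefix prefix for trace identifiers.
#' @return list of [StatePath-class] objects.
#' @examples
#' sc <- buildDefaultScheme(ntp = 80)
#' paths <- gillespieSimulate(sc, duration = 300, n_traces = 3, seed = 1)
#' paths[[1]]
#' @export
gillespieSimulate <- function(scheme, duration, n_traces, seed,
                              injectionTime = 0, idPrefix = "trace") {
  stopifnot(is(scheme, "KineticScheme"))
  validObject(scheme)
  if (duration <= 0) stop("'duration' must be > 0")
  if (n_traces < 1) stop("'n_traces' must be >= 1")
  st <- scheme@states
  tr <- scheme@transitions
  if (all(st$absorbing[match(names(scheme@initProb), st$label)]) ||
      nrow(tr) == 0L)
    stop("no dynamics: scheme has no reachable transitions")

  labels <- st$label
  exitRate <- vapply(labels, function(s) sum(tr$rate[tr$from == s]), numeric(1))
  dest <- lapply(labels, function(s) tr$to[tr$from == s])
  destP <- lapply(labels, function(s) {
    r <- tr$rate[tr$from == s]
    if (length(r)) r / sum(r) else numeric(0)
  })
  names(dest) <- names(destP) <- labels
  obs <- st$observable; names(obs) <- labels
  frt <- st$fret; names(frt) <- labels
  absb <- st$absorbing; names(absb) <- labels

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  initLabels <- names(scheme@initProb)
  out <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    cur <- if (length(initLabels) == 1L) initLabels else
      sample(initLabels, 1L, prob = scheme@initProb)
    t0 <- 0
    segState <- character(0); segStart <- numeric(0); segDur <- numeric(0)
    truncation <- "end-of-record"
    first <- TRUE
    while (t0 < duration) {
      if (absb[[cur]]) {
        segState <- c(segState, cur)
        segStart <- c(segStart, t0)
        segDur <- c(segDur, duration - t0)
        truncation <- "escape"
        t0 <- duration
        break
      }
      tau <- stats::rexp(1L, rate = exitRate[[cur]])
      if (first) {
        tau <- tau + injectionTime
        first <- FALSE
      }
      dt <- min(tau, duration - t0)
      segState <- c(segState, cur)
      segStart <- c(segStart, t0)
      segDur <- c(segDur, dt)
      t0 <- t0 + dt
      if (tau >= duration - segStart[length(segStart)]) break
      nxt <- dest[[cur]]
      cur <- if (length(nxt) == 1L) nxt else sample(nxt, 1L, prob = destP[[cur]])
    }
    sg <- data.frame(state = segState, observable = unname(obs[segState]),
                     fret = unname(frt[segState]), start_s = segStart,
                     duration_s = segDur, stringsAsFactors = FALSE)
    out[[i]] <- new("StatePath", traceId = sprintf("%s%04d", idPrefix, i),
                    segments = sg, truncation = truncation)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Collapse hidden substates into observable segments
#'
#' Merges adjacent segments of a [StatePath-class] that share the same
#' observable label, yielding the dwell sequence a FRET measurement could in
#' principle resolve.
#'
#' @param path a [StatePath-class].
#' @return data.frame with columns \code{observable}, \code{fret},
#'   \code{start_s}, \code{duration_s}.
#' @export
observedSegments <- function(path) {
  sg <- path@segments
  if (!nrow(sg))
    return(data.frame(observable = character(0), fret = numeric(0),
                      start_s = numeric(0), duration_s = numeric(0)))
  grp <- cumsum(c(1L, as.integer(sg$observable[-1L] != sg$observable[-nrow(sg)])))
  data.frame(
    observable = sg$observable[!duplicated(grp)],
    fret = sg$fret[!duplicated(grp)],
    start_s = sg$start_s[!duplicated(grp)],
    duration_s = as.numeric(tapply(sg$duration_s, grp, sum)),
    stringsAsFactors = FALSE)
}

#' Ground-truth labeled path from a simulated state path
#'
#' Converts a simulated [StatePath-class] into a [LabeledPath-class] of
#' observable dwells, optionally truncated at `window_s` (e.g. the bleach
#' time of the rendered trace), for scoring inferred paths against truth.
#'
#' @param path a [StatePath-class].
#' @param frame_time frame duration (s) recorded on the result.
#' @param window_s optional truncation time (s).
#' @return a [LabeledPath-class].
#' @export
truthLabeledPath <- function(path, frame_time = 0.2, window_s = Inf) {
  sg <- observedSegments(path)
  trunc <- path@truncation
  if (is.finite(window_s) && nrow(sg)) {
    keep <- sg$start_s < window_s
    sg <- sg[keep, , drop = FALSE]
    if (nrow(sg)) {
      last <- nrow(sg)
      sg$duration_s[last] <- min(sg$duration_s[last], window_s - sg$start_s[last])
      trunc <- "bleach"
    }
  }
  n <- nrow(sg)
  seg <- data.frame(label = sg$observable, start_s = sg$start_s,
                    duration_s = sg$duration_s,
                    is_first = seq_len(n) == 1L, is_last = seq_len(n) == n,
                    stringsAsFactors = FALSE)
  new("LabeledPath", traceId = path@traceId, frameTime = frame_time,
      segments = seg, truncation = trunc, flagged = FALSE)
}
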