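#' @include AllClasses.R
NULL

#' Read and write intensity traces
#'
#' Traces travel as plain CSV with columns `trace_id`, `frame`, `I_DD`,
#' `I_DA`, `I_AA` plus optional metadata columns (`ntp`, `substrate`,
#' `promoter`) that are constant within a trace.
#'
#' @param traces list of [IntensityTrace-class] objects.
#' @param file path to a CSV file.
#' @param frame_time frame duration (s) to stamp on traces read back.
#' @return `readTraces()` returns a list of [IntensityTrace-class];
#'   `writeTraces()` returns `file` invisibly.
#' @export
writeTraces <- function(traces, file) {
  rows <- lapply(traces, function(tr) {
    n <- length(tr@IDD)
    df <- data.frame(trace_id = tr@traceId, frame = seq_len(n) - 1L,
                     I_DD = tr@IDD, I_DA = tr@IDA, I_AA = tr@IAA)
    for (f in c("ntp", "substrate", "promoter"))
      if (!is.null(tr@meta[[f]])) df[[f]] <- tr@meta[[f]]
    df
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTraces
#' @export
readTraces <- function(file, frame_time = 0.2) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("trace_id", "frame", "I_DD", "I_DA", "I_AA")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$frame), ]
    meta <- list()
    for (f in c("ntp", "substrate", "promoter"))
      if (f %in% names(d)) meta[[f]] <- d[[f]][1L]
    new("IntensityTrace", traceId = as.character(d$trace_id[1L]),
        frameTime = frame_time, IDD = d$I_DD, IDA = d$I_DA, IAA = d$I_AA,
        meta = meta)
  })
}

#' Read and write state paths
#'
#' Ground-truth paths are stored as CSV with columns `trace_id`, `state`,
#' `observable`, `fret`, `start_s`, `duration_s`, `truncation`.
#'
#' @param paths list of [StatePath-class] objects.
#' @param file path to a CSV file.
#' @return `readPaths()` returns a list of [StatePath-class].
#' @export
writePaths <- function(paths, file) {
  out <- do.call(rbind, lapply(paths, function(p) {
    cbind(data.frame(trace_id = p@traceId, stringsAsFactors = FALSE),
          p@segments, truncation = p@truncation)
  }))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writePaths
#' @export
readPaths <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$start_s), ]
    new("StatePath", traceId = as.character(d$trace_id[1L]),
        segments = data.frame(state = d$state, observable = d$observable,
                              fret = d$fret, start_s = d$start_s,
                              duration_s = d$duration_s,
                              stringsAsFactors = FALSE),
        truncation = d$truncation[1L])
  })
}

#' Read and write kinetic schemes as JSON
#'
#' @param scheme a [KineticScheme-class].
#' @param file path to a JSON file.
#' @return `readScheme()` returns a [KineticScheme-class].
#' @export
writeScheme <- function(scheme, file) {
  obj <- list(states = scheme@states, transitions = scheme@transitions,
              init_prob = as.list(scheme@initProb),
              ntp_branching = scheme@ntpBranching)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname writeScheme
#' @export
readScheme <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("KineticScheme",
      states = as.data.frame(obj$states, stringsAsFactors = FALSE),
      transitions = as.data.frame(obj$transitions, stringsAsFactors = FALSE),
      initProb = unlist(obj$init_prob),
      ntpBranching = as.list(obj$ntp_branching))
}

#' Write segment and dwell tables
#'
#' `writeSegments()` emits `trace_id, start_frame, n_frames, level`;
#' `writeDwells()` emits `state, tau_s, censored, trace_id`.
#'
#' @param segs list of [SegmentedTrace-class] objects.
#' @param dwells a [DwellSet-class].
#' @param file path to a CSV file.
#' @return `file`, invisibly.
#' @export
writeSegments <- function(segs, file) {
  out <- do.call(rbind, lapply(segs, function(s) {
    cbind(data.frame(trace_id = s@traceId, stringsAsFactors = FALSE),
          s@segments)
  }))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSegments
#' @export
writeDwells <- function(dwells, file) {
  utils::write.csv(data.frame(state = dwells@state, tau_s = dwells@tau,
                              censored = dwells@censored,
                              trace_id = dwells@traceId),
                   file, row.names = FALSE)
  invisible(file)
}

#' JSON-ready summary of an exponential-mixture fit
#'
#' @param fit an [ExpMixtureFit-class].
#' @return a plain list (m, k, p, logLik, BIC, sd).
#' @export
fitReport <- function(fit) {
  list(m = fit@m, k = fit@rates, p = fit@weights, logLik = fit@logLik,
       BIC = fit@bic, N = fit@n, sd_k = fit@sdRates, sd_p = fit@sdWeights)
}
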