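#' @include AllClasses.R
NULL

#' Accessors for scrunchFRET objects
#'
#' `traceId()` returns the molecule identifier, `frameTime()` the frame
#' duration in seconds, `segments()` the segment table of a path-like object,
#' `dwellTimes()` the dwell-time vector of a [DwellSet-class], `rates()` and
#' `mixWeights()` the parameters of an [ExpMixtureFit-class], and
#' `levelTable()` the peak table of a [LevelTable-class].
#'
#' @param object a scrunchFRET S4 object.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traceId", function(object) standardGeneric("traceId"))
#' @rdname accessors
#' @export
setGeneric("frameTime", function(object) standardGeneric("frameTime"))
#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("dwellTimes", function(object) standardGeneric("dwellTimes"))
#' @rdname accessors
#' @export
setGeneric("stateLabel", function(object) standardGeneric("stateLabel"))
#' @rdname accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))
#' @rdname accessors
#' @export
setGeneric("mixWeights", function(object) standardGeneric("mixWeights"))
#' @rdname accessors
#' @export
setGeneric("levelTable", function(object) standardGeneric("levelTable"))

#' @rdname accessors
setMethod("traceId", "StatePath", function(object) object@traceId)
#' @rdname accessors
setMethod("traceId", "IntensityTrace", function(object) object@traceId)
#' @rdname accessors
setMethod("traceId", "FretTrace", function(object) object@traceId)
#' @rdname accessors
setMethod("traceId", "SegmentedTrace", function(object) object@traceId)
#' @rdname accessors
setMethod("traceId", "LabeledPath", function(object) object@traceId)

#' @rdname accessors
setMethod("frameTime", "IntensityTrace", function(object) object@frameTime)
#' @rdname accessors
setMethod("frameTime", "FretTrace", function(object) object@frameTime)
#' @rdname accessors
setMethod("frameTime", "SegmentedTrace", function(object) object@frameTime)
#' @rdname accessors
setMethod("frameTime", "LabeledPath", function(object) object@frameTime)

#' @rdname accessors
setMethod("segments", "StatePath", function(object) object@segments)
#' @rdname accessors
setMethod("segments", "SegmentedTrace", function(object) object@segments)
#' @rdname accessors
setMethod("segments", "LabeledPath", function(object) object@segments)

#' @rdname accessors
setMethod("dwellTimes", "DwellSet", function(object) object@tau)
#' @rdname accessors
setMethod("stateLabel", "DwellSet", function(object) object@state)

#' @rdname accessors
setMethod("rates", "ExpMixtureFit", function(object) object@rates)
#' @rdname accessors
setMethod("mixWeights", "ExpMixtureFit", function(object) object@weights)
#' @rdname accessors
setMethod("levelTable", "LevelTable", function(object) object@table)

#' @describeIn accessors number of dwells in a [DwellSet-class].
#' @export
setMethod("length", "DwellSet", function(x) length(x@tau))

#' Log-likelihood of an exponential-mixture fit
#' @param object an [ExpMixtureFit-class].
#' @param ... ignored.
#' @return an object of class `logLik` with `df = 2m - 1`.
#' @export
setMethod("logLik", "ExpMixtureFit", function(object, ...) {
  structure(object@logLik, df = 2L * object@m - 1L, nobs = object@n,
            class = "logLik")
})

#' @describeIn accessors BIC of an exponential-mixture fit.
#' @param object an [ExpMixtureFit-class].
#' @export
setMethod("BIC", "ExpMixtureFit", function(object, ...) object@bic)

setMethod("show", "KineticScheme", function(object) {
  cat(sprintf("KineticScheme: %d states (%d absorbing), %d transitions\n",
              nrow(object@states), sum(object@states$absorbing),
              nrow(object@transitions)))
  obs <- unique(object@states[, c("observable", "fret")])
  cat("  observables:",
      paste(sprintf("%s (E=%.2f)", obs$observable, obs$fret), collapse = ", "),
      "\n")
  nb <- object@ntpBranching
  if (length(nb) && !is.null(nb$K_ntp))
    cat(sprintf("  escape isotherm: P_max=%.2f, K_NTP=%.3g uM, [NTP]=%.3g uM\n",
                nb$P_max, nb$K_ntp, nb$ntp))
})

setMethod("show", "StatePath", function(object) {
  sg <- object@segments
  cat(sprintf("StatePath %s: %d segments, %.1f s, truncation: %s\n",
              object@traceId, nrow(sg),
              if (nrow(sg)) sum(sg$duration_s) else 0, object@truncation))
})

setMethod("show", "IntensityTrace", function(object) {
  cat(sprintf("IntensityTrace %s: %d frames @ %.3g s\n",
              object@traceId, length(object@IDD), object@frameTime))
})

setMethod("show", "FretTrace", function(object) {
  cat(sprintf("FretTrace %s: %d frames (%d analyzable) @ %.3g s\n",
              object@traceId, length(object@E), sum(object@mask),
              object@frameTime))
})

setMethod("show", "LevelTable", function(object) {
  cat("LevelTable (Gaussian peaks of segment-mean FRET):\n")
  print(object@table, row.names = FALSE)
  if (object@merged) cat("  [warning] unresolved peaks were merged\n")
})

setMethod("show", "SegmentedTrace", function(object) {
  cat(sprintf("SegmentedTrace %s: %d segments over %d frames\n",
              object@traceId, nrow(object@segments),
              if (nrow(object@segments)) sum(object@segments$n_frames) else 0L))
})

setMethod("show", "LabeledPath", function(object) {
  sg <- object@segments
  cat(sprintf("LabeledPath %s: %s (truncation: %s%s)\n", object@traceId,
              if (nrow(sg)) paste(sg$label, collapse = " > ") else "<empty>",
              object@truncation,
              if (object@flagged) ", flagged" else ""))
})

setMethod("show", "DwellSet", function(object) {
  cat(sprintf("DwellSet[%s]: N=%d dwells from %d traces, mean %.3g s\n",
              object@state, length(object@tau),
              length(unique(object@traceId)),
              if (length(object@tau)) mean(object@tau) else NA_real_))
})

setMethod("show", "ExpMixtureFit", function(object) {
  cat(sprintf("ExpMixtureFit: m=%d, N=%d, logLik=%.2f, BIC=%.2f\n",
              object@m, object@n, object@logLik, object@bic))
  for (i in seq_len(object@m)) {
    cat(sprintf("  k%d = %.4g s^-1 (SD %.3g), p%d = %.3f (SD %.3g)\n",
                i, object@rates[i], object@sdRates[i],
                i, object@weights[i], object@sdWeights[i]))
  }
})

setMethod("show", "IsothermFit", function(object) {
  cat(sprintf("IsothermFit: K_NTP = %.3g +/- %.2g uM, P_max,esc = %.3f +/- %.2g\n",
              object@Kntp, object@sd[["Kntp"]],
              object@Pmax, object@sd[["Pmax"]]))
})

setMethod("show", "TransitionCounts", function(object) {
  cat("TransitionCounts (row = from, col = to):\n")
  print(object@counts)
})
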