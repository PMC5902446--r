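#' @import methods
NULL

OBSERVABLES <- c("PS", "US", "FS")

#' Branching kinetic scheme for initial transcription
#'
#' A continuous-time Markov scheme over hidden states, each carrying an
#' observable scrunching label (\code{"US"}, \code{"PS"}, \code{"FS"}) and the
#' FRET efficiency emitted while the molecule resides in it.  Hidden substates
#' sharing one observable allow multi-exponential observable dwell times while
#' the process itself stays memory-less.
#'
#' @slot states data.frame with columns \code{label}, \code{observable},
#'   \code{fret}, \code{absorbing}.
#' @slot transitions data.frame with columns \code{from}, \code{to},
#'   \code{rate} (s^-1).
#' @slot initProb named numeric, initial occupancy per state label, sums to 1.
#' @slot ntpBranching list with elements \code{K_ntp} (uM), \code{P_max}
#'   (dimensionless) and \code{ntp} (uM): parameters of the escape isotherm
#'   p(NTP) = P_max * NTP / (NTP + K_ntp) used when the scheme was built.
#'
#' @seealso [buildDefaultScheme()], [buildWithdrawalScheme()],
#'   [gillespieSimulate()]
#' @export
setClass("KineticScheme", slots = c(
  states = "data.frame",
  transitions = "data.frame",
  initProb = "numeric",
  ntpBranching = "list"
))

setValidity("KineticScheme", function(object) {
  st <- object@states
  tr <- object@transitions
  msg <- character()
  need <- c("label", "observable", "fret", "absorbing")
  if (!all(need %in% names(st)))
    return(paste("states must have columns", paste(need, collapse = ", ")))
  if (!all(c("from", "to", "rate") %in% names(tr)))
    return("transitions must have columns from, to, rate")
  if (anyDuplicated(st$label)) msg <- c(msg, "duplicated state labels")
  if (any(tr$rate < 0)) msg <- c(msg, "negative transition rate")
  if (!all(tr$from %in% st$label) || !all(tr$to %in% st$label))
    msg <- c(msg, "transition endpoints must be declared states")
  if (abs(sum(object@initProb) - 1) > 1e-12)
    msg <- c(msg, "initial distribution must sum to 1 (tol 1e-12)")
  if (!all(names(object@initProb) %in% st$label))
    msg <- c(msg, "initProb names must be state labels")
  if (!all(st$observable %in% OBSERVABLES))
    msg <- c(msg, "observable must be one of US, PS, FS")
  if (any(st$fret < 0 | st$fret > 1)) msg <- c(msg, "FRET levels must lie in [0, 1]")
  # one FRET level per observable tag
  for (obs in unique(st$observable)) {
    lv <- unique(st$fret[st$observable == obs])
    if (length(lv) != 1L)
      msg <- c(msg, sprintf("observable %s maps to %d FRET levels", obs, length(lv)))
  }
  exit <- vapply(st$label, function(s) sum(tr$rate[tr$from == s]), numeric(1))
  bad <- !st$absorbing & exit <= 0
  if (any(bad))
    msg <- c(msg, sprintf("non-absorbing state(s) without exit: %s",
                          paste(st$label[bad], collapse = ", ")))
  nb <- object@ntpBranching
  if (length(nb)) {
    if (!is.null(nb$K_ntp) && !(is.numeric(nb$K_ntp) && nb$K_ntp > 0))
      msg <- c(msg, "K_ntp must be > 0")
    if (!is.null(nb$P_max) && !(is.numeric(nb$P_max) && nb$P_max >= 0 && nb$P_max <= 1))
      msg <- c(msg, "P_max must lie in [0, 1]")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Emission parameters for rendering intensity traces
#'
#' @slot totalIntensity expected summed donor-excitation intensity per frame
#'   (arbitrary units).
#' @slot noiseSd additive zero-mean Gaussian noise SD per channel (a.u.).
#' @slot donorBleachRate,acceptorBleachRate single-step photobleaching rates
#'   (s^-1); 0 disables bleaching of that dye.
#' @slot frameTime frame duration in seconds.
#' @slot alexDuty fraction of each frame spent on each excitation (metadata;
#'   intensities are reported per frame).
#' @export
setClass("EmissionParams", slots = c(
  totalIntensity = "numeric", noiseSd = "numeric",
  donorBleachRate = "numeric", acceptorBleachRate = "numeric",
  frameTime = "numeric", alexDuty = "numeric"
))

setValidity("EmissionParams", function(object) {
  msg <- character()
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@donorBleachRate < 0 || object@acceptorBleachRate < 0)
    msg <- c(msg, "bleaching rates must be >= 0")
  if (object@frameTime <= 0) msg <- c(msg, "frameTime must be > 0")
  if (object@totalIntensity <= 0) msg <- c(msg, "totalIntensity must be > 0")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Constructor for [EmissionParams-class]
#'
#' Defaults give a per-frame FRET efficiency SD of about 0.05 at the default
#' total intensity and bleach-limited observation windows of several hundred
#' seconds, with 200 ms frames (100 ms per excitation in ALEX).
#'
#' @param totalIntensity expected I_DD + I_DA per frame (a.u.).
#' @param noiseSd per-channel Gaussian noise SD (a.u.).
#' @param donorBleachRate,acceptorBleachRate bleaching rates (s^-1).
#' @param frameTime frame duration (s).
#' @param alexDuty excitation duty fraction.
#' @return an [EmissionParams-class] object.
#' @examples
#' emissionParams(frameTime = 0.08)
#' @export
emissionParams <- function(totalIntensity = 1000, noiseSd = 70,
                           donorBleachRate = 0.001, acceptorBleachRate = 0.001,
                           frameTime = 0.2, alexDuty = 0.5) {
  new("EmissionParams", totalIntensity = totalIntensity, noiseSd = noiseSd,
      donorBleachRate = donorBleachRate, acceptorBleachRate = acceptorBleachRate,
      frameTime = frameTime, alexDuty = alexDuty)
}

#' Continuous-time state path of one molecule
#'
#' Ground-truth (or inferred, see [LabeledPath-class]) piecewise-constant
#' trajectory.  Segments are contiguous and adjacent hidden-state labels
#' always differ; adjacent *observables* differ too for the schemes built by
#' this package, since hidden substates are only entered from other
#' observables.
#'
#' @slot traceId character scalar.
#' @slot segments data.frame with columns \code{state}, \code{observable},
#'   \code{fret}, \code{start_s}, \code{duration_s}.
#' @slot truncation one of \code{"end-of-record"}, \code{"bleach"},
#'   \code{"escape"}.
#' @export
setClass("StatePath", slots = c(
  traceId = "character", segments = "data.frame", truncation = "character"
))

setValidity("StatePath", function(object) {
  sg <- object@segments
  msg <- character()
  need <- c("state", "observable", "fret", "start_s", "duration_s")
  if (!all(need %in% names(sg)))
    return(paste("segments must have columns", paste(need, collapse = ", ")))
  if (nrow(sg)) {
    if (any(sg$duration_s <= 0)) msg <- c(msg, "durations must be > 0")
    if (nrow(sg) > 1L) {
      gaps <- sg$start_s[-1L] - (sg$start_s[-nrow(sg)] + sg$duration_s[-nrow(sg)])
      if (any(abs(gaps) > 1e-9)) msg <- c(msg, "segments must be contiguous")
      if (any(sg$state[-1L] == sg$state[-nrow(sg)]))
        msg <- c(msg, "adjacent segments must differ in state")
    }
  }
  if (!object@truncation %in% c("end-of-record", "bleach", "escape"))
    msg <- c(msg, "unknown truncation cause")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Three-channel intensity trace of one molecule
#'
#' @slot traceId character scalar.
#' @slot frameTime frame duration (s).
#' @slot IDD,IDA,IAA numeric vectors of equal length: donor-excitation donor
#'   and acceptor intensities and acceptor-excitation acceptor intensity.
#' @slot meta list of experiment metadata (e.g. \code{ntp} in uM,
#'   \code{substrate}, \code{promoter}).
#' @export
setClass("IntensityTrace", slots = c(
  traceId = "character", frameTime = "numeric",
  IDD = "numeric", IDA = "numeric", IAA = "numeric", meta = "list"
))

setValidity("IntensityTrace", function(object) {
  n <- length(object@IDD)
  if (n < 1L) return("trace must contain at least one frame")
  if (length(object@IDA) != n || length(object@IAA) != n)
    return("channel arrays must have equal length")
  if (object@frameTime <= 0) return("frameTime must be > 0")
  TRUE
})

#' Per-frame FRET efficiency trajectory
#'
#' @slot traceId character scalar.
#' @slot frameTime frame duration (s).
#' @slot E numeric vector of FRET efficiencies; may stray outside [0, 1]
#'   through noise (values are deliberately not clipped).
#' @slot mask logical vector, TRUE for analyzable frames.
#' @export
setClass("FretTrace", slots = c(
  traceId = "character", frameTime = "numeric", E = "numeric", mask = "logical"
))

setValidity("FretTrace", function(object) {
  if (length(object@mask) != length(object@E))
    return("mask length must equal trace length")
  if (any(!is.finite(object@E[object@mask])))
    return("masked-in frames must have finite E")
  TRUE
})

#' Calibrated FRET levels
#'
#' Gaussian peak parameters per scrunching level, from least-squares fits to
#' the pooled histogram of segment mean FRET values.
#'
#' @slot table data.frame with columns \code{label}, \code{center}, \code{sd},
#'   \code{se_center}; rows ordered PS < US < FS by center.
#' @slot merged logical: TRUE when two candidate peaks could not be resolved
#'   and were merged.
#' @export
setClass("LevelTable", slots = c(table = "data.frame", merged = "logical"))

setValidity("LevelTable", function(object) {
  tb <- object@table
  if (!all(c("label", "center", "sd") %in% names(tb)))
    return("table must have columns label, center, sd")
  if (any(tb$center < 0 | tb$center > 1)) return("centers must lie in [0, 1]")
  if (any(tb$sd <= 0)) return("peak SDs must be > 0")
  if (is.unsorted(tb$center, strictly = TRUE))
    return("centers must be strictly increasing")
  TRUE
})

#' HMM-segmented FRET trace
#'
#' @slot traceId character scalar.
#' @slot frameTime frame duration (s).
#' @slot segments data.frame with columns \code{level} (fitted E),
#'   \code{start_frame} (0-based), \code{n_frames}, \code{confidence}
#'   (mean posterior probability of the assigned state).  Intervals are
#'   half-open \[start, start + n).
#' @export
setClass("SegmentedTrace", slots = c(
  traceId = "character", frameTime = "numeric", segments = "data.frame"
))

setValidity("SegmentedTrace", function(object) {
  sg <- object@segments
  if (!all(c("level", "start_frame", "n_frames") %in% names(sg)))
    return("segments must have columns level, start_frame, n_frames")
  if (nrow(sg)) {
    if (any(sg$n_frames < 1L)) return("segment lengths must be >= 1 frame")
    if (nrow(sg) > 1L) {
      if (any(sg$start_frame[-1L] !=
              sg$start_frame[-nrow(sg)] + sg$n_frames[-nrow(sg)]))
        return("segments must be contiguous and non-overlapping")
      if (any(sg$level[-1L] == sg$level[-nrow(sg)]))
        return("adjacent fitted levels must differ")
    }
  }
  TRUE
})

#' State-labeled dwell path of one trace
#'
#' Segments carry observable labels from a [LevelTable-class]; the first and
#' last segment of each trace are flagged so dwell pooling can drop them
#' (the first dwell precedes NTP addition, the last is cut short by
#' photobleaching or by reaching the absorbing FS level).
#'
#' @slot traceId character scalar.
#' @slot frameTime frame duration (s).
#' @slot segments data.frame with columns \code{label} (US/PS/FS/unassigned),
#'   \code{start_s}, \code{duration_s}, \code{is_first}, \code{is_last}.
#' @slot truncation truncation cause.
#' @slot flagged TRUE when more than half the frames were unassigned.
#' @export
setClass("LabeledPath", slots = c(
  traceId = "character", frameTime = "numeric", segments = "data.frame",
  truncation = "character", flagged = "logical"
))

setValidity("LabeledPath", function(object) {
  sg <- object@segments
  need <- c("label", "start_s", "duration_s", "is_first", "is_last")
  if (!all(need %in% names(sg)))
    return(paste("segments must have columns", paste(need, collapse = ", ")))
  if (nrow(sg)) {
    if (sum(sg$is_first) != 1L || sum(sg$is_last) != 1L)
      return("exactly one first and one last segment must be flagged")
    if (any(sg$duration_s <= 0)) return("durations must be > 0")
  }
  TRUE
})

#' Pooled dwell times for one state
#'
#' @slot state observable label.
#' @slot tau dwell times in seconds, strictly positive.
#' @slot censored logical per dwell; interior dwells are complete (FALSE).
#' @slot traceId source trace of each dwell.
#' @export
setClass("DwellSet", slots = c(
  state = "character", tau = "numeric", censored = "logical",
  traceId = "character"
))

setValidity("DwellSet", function(object) {
  if (any(object@tau <= 0)) return("dwell times must be > 0")
  if (length(object@censored) != length(object@tau) ||
      length(object@traceId) != length(object@tau))
    return("censored/traceId must parallel tau")
  TRUE
})

#' Exponential-mixture dwell-time fit
#'
#' Maximum-likelihood fit of the density
#' p(tau) = sum_n p_n k_n exp(-k_n tau).
#'
#' @slot m number of exponential components.
#' @slot rates exit rates k_n in s^-1, sorted descending.
#' @slot weights component probabilities p_n (sum to 1).
#' @slot logLik maximized log-likelihood.
#' @slot bic -2 logLik + (2m - 1) log N.
#' @slot n number of dwells fitted.
#' @slot sdRates,sdWeights bootstrap standard deviations (NA before
#'   [bootstrapSd()] is run).
#' @slot convergence list of optimizer diagnostics.
#' @export
setClass("ExpMixtureFit", slots = c(
  m = "integer", rates = "numeric", weights = "numeric",
  logLik = "numeric", bic = "numeric", n = "integer",
  sdRates = "numeric", sdWeights = "numeric", convergence = "list"
))

setValidity("ExpMixtureFit", function(object) {
  msg <- character()
  if (length(object@rates) != object@m || length(object@weights) != object@m)
    msg <- c(msg, "rates/weights must have length m")
  if (any(object@rates <= 0)) msg <- c(msg, "rates must be > 0")
  if (object@m > 1L && any(diff(object@rates) >= 0))
    msg <- c(msg, "rates must be strictly decreasing")
  if (any(object@weights <= 0 | object@weights > 1) ||
      abs(sum(object@weights) - 1) > 1e-10)
    msg <- c(msg, "weights must lie in (0, 1] and sum to 1 (tol 1e-10)")
  if (!is.finite(object@bic)) msg <- c(msg, "BIC must be finite")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' NTP escape-isotherm fit
#'
#' Fit of p(NTP) = P_max * NTP / (NTP + K_ntp) to first-attempt escape
#' probabilities.
#'
#' @slot Kntp apparent half-saturation constant (uM).
#' @slot Pmax saturating escape probability.
#' @slot sd named numeric, standard errors of K_ntp and P_max from the fit
#'   covariance.
#' @slot residuals data.frame with columns \code{ntp}, \code{p},
#'   \code{fitted}, \code{residual}.
#' @export
setClass("IsothermFit", slots = c(
  Kntp = "numeric", Pmax = "numeric", sd = "numeric", residuals = "data.frame"
))

setValidity("IsothermFit", function(object) {
  if (object@Kntp <= 0) return("K_ntp must be > 0")
  if (object@Pmax < 0 || object@Pmax > 1) return("P_max must lie in [0, 1]")
  TRUE
})

#' Consecutive-dwell transition counts
#'
#' @slot counts 3x3 integer matrix of ordered US/PS/FS label pairs for
#'   consecutive dwells; the diagonal is structurally zero.
#' @slot freq counts normalized by their total (all-zero when no transitions).
#' @slot meta list of per-condition metadata.
#' @export
setClass("TransitionCounts", slots = c(
  counts = "matrix", freq = "matrix", meta = "list"
))

setValidity("TransitionCounts", function(object) {
  cn <- object@counts
  if (!identical(dim(cn), c(3L, 3L))) return("counts must be 3x3")
  if (any(diag(cn) != 0)) return("diagonal must be zero (adjacent dwells differ)")
  if (any(cn < 0)) return("counts must be >= 0")
  TRUE
})
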