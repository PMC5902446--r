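#' @include AllClasses.R
NULL

#' Escape-isotherm probability
#'
#' Probability that a pause exit is productive (continues to the fully
#' scrunched FS level) rather than abortive, as a hyperbolic function of NTP
#' concentration: p(NTP) = P_max * NTP / (NTP + K_ntp).
#'
#' @param ntp NTP concentration (uM), >= 0.
#' @param K_ntp apparent half-saturation constant (uM), > 0.
#' @param P_max saturating escape probability in [0, 1].
#' @return escape probability in [0, P_max].
#' @examples
#' escapeProbability(28, K_ntp = 28, P_max = 0.79)  # P_max / 2
#' @export
escapeProbability <- function(ntp, K_ntp, P_max) {
  if (any(ntp < 0)) stop("ntp must be >= 0")
  if (K_ntp <= 0) stop("K_ntp must be > 0")
  if (P_max < 0 || P_max > 1) stop("P_max must lie in [0, 1]")
  P_max * ntp / (ntp + K_ntp)
}

.checkRate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite rate", name))
  x
}

.checkProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name))
  x
}

#' Default FRET levels of the scrunching states
#'
#' Calibrated efficiencies of the partly scrunched paused complex (PS), the
#' unscrunched open complex (US) and the fully scrunched pause-cleared
#' complex (FS).
#'
#' @return named numeric vector c(PS, US, FS).
#' @export
defaultFretLevels <- function() c(PS = 0.37, US = 0.49, FS = 0.80)

#' Build the branching initiation scheme
#'
#' Constructs the continuous-time Markov scheme of initial transcription with
#' NTPs present: the open complex (US) scrunches into the initial-transcription
#' pause (PS, exit rate `k_itc6`); every pause exit escapes productively to
#' the absorbing fully scrunched state (FS) with the isotherm probability
#' p(NTP) = `P_max` * ntp / (ntp + `K_ntp`) and otherwise unscrunches into a
#' cycling subsystem.  Cycling US and PS observables are each backed by two
#' hidden substates with exit rates `k1` (fast) and `k2` (slow), entered
#' independently at every visit with probabilities `P_k1` and 1 - `P_k1`,
#' which produces two-exponential observable dwell times while keeping the
#' process memory-less.  Cycling PS exits branch through the same isotherm.
#'
#' @param k_itc6 exit rate of the initial pause (s^-1).
#' @param K_ntp apparent NTP half-saturation of the escape isotherm (uM).
#' @param P_max saturating escape probability.
#' @param k1,k2 fast and slow cycling exit rates (s^-1), `k1 > k2`.
#' @param P_k1 probability of entering the fast substate at each visit.
#' @param ntp NTP concentration (uM) at which to resolve the branching.
#' @param k_entry scrunching rate from the open complex into the pause after
#'   NTP addition (s^-1).
#' @param fret named FRET levels per observable, see [defaultFretLevels()].
#' @return a [KineticScheme-class].
#' @examples
#' sc <- buildDefaultScheme(ntp = 80)
#' sc
#' @export
buildDefaultScheme <- function(k_itc6 = 0.11, K_ntp = 28, P_max = 0.79,
                               k1 = 0.15, k2 = 0.02, P_k1 = 0.6,
                               ntp = 80, k_entry = 0.2,
                               fret = defaultFretLevels()) {
  .checkRate(k_itc6, "k_itc6"); .checkRate(k1, "k1"); .checkRate(k2, "k2")
  .checkRate(k_entry, "k_entry"); .checkRate(K_ntp, "K_ntp")
  .checkProb(P_max, "P_max"); .checkProb(P_k1, "P_k1")
  if (k1 <= k2) stop("'k1' must exceed 'k2'")
  if (ntp < 0) stop("'ntp' must be >= 0")
  p <- escapeProbability(ntp, K_ntp, P_max)

  states <- data.frame(
    label = c("US0", "PSpause", "UScyc_f", "UScyc_s", "PScyc_f", "PScyc_s", "FS"),
    observable = c("US", "PS", "US", "US", "PS", "PS", "FS"),
    fret = unname(fret[c("US", "PS", "US", "US", "PS", "PS", "FS")]),
    absorbing = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  # branch to the cycling US substates, re-sampled at each entry
  toUScyc <- function(from, k) data.frame(
    from = from, to = c("UScyc_f", "UScyc_s"), rate = k * c(P_k1, 1 - P_k1))
  toPScyc <- function(from, k) data.frame(
    from = from, to = c("PScyc_f", "PScyc_s"), rate = k * c(P_k1, 1 - P_k1))
  transitions <- rbind(
    data.frame(from = "US0", to = "PSpause", rate = k_entry),
    data.frame(from = "PSpause", to = "FS", rate = k_itc6 * p),
    toUScyc("PSpause", k_itc6 * (1 - p)),
    toPScyc("UScyc_f", k1),
    toPScyc("UScyc_s", k2),
    data.frame(from = c("PScyc_f", "PScyc_s"), to = "FS", rate = c(k1, k2) * p),
    toUScyc("PScyc_f", k1 * (1 - p)),
    toUScyc("PScyc_s", k2 * (1 - p))
  )
  transitions <- transitions[transitions$rate > 0, , drop = FALSE]
  rownames(transitions) <- NULL
  initProb <- c(US0 = 1)
  new("KineticScheme", states = states, transitions = transitions,
      initProb = initProb,
      ntpBranching = list(K_ntp = K_ntp, P_max = P_max, ntp = ntp))
}

# two-substate cycling transitions between a set of observables with given
# observable-level branching fractions; kin = c(k1, k2), entry prob P
.cyclingBlock <- function(prefix, obsFrom, targets, frac, k1, k2, P_k1) {
  out <- list()
  for (sub in c("f", "s")) {
    k <- if (sub == "f") k1 else k2
    from <- paste0(prefix, obsFrom, "_", sub)
    for (i in seq_along(targets)) {
      out[[length(out) + 1L]] <- data.frame(
        from = from,
        to = paste0(prefix, targets[i], "_", c("f", "s")),
        rate = k * frac[i] * c(P_k1, 1 - P_k1))
    }
  }
  do.call(rbind, out)
}

#' Build the NTP-withdrawal cycling scheme
#'
#' After NTPs are withdrawn, cycling molecules fall into two subpopulations:
#' molecules that shuttle between US and PS only, and molecules that
#' additionally visit FS with roughly an order of magnitude faster kinetics,
#' whose dominant exchange is US <-> FS (about 4-fold more frequent than
#' US <-> PS, with PS <-> FS rare).  Both subpopulations use two hidden
#' substates per observable so dwell times are two-exponential.
#'
#' @param frac_usps fraction of cyclers in the US/PS-only subpopulation.
#' @param slow named list/vector with `k1`, `k2`, `P_k1` for the US/PS
#'   subpopulation (s^-1, s^-1, probability).
#' @param fast same for the US/PS/FS subpopulation.
#' @param branch_fs length-3 numeric: within the US/PS/FS subpopulation, the
#'   branching fractions US->FS, PS->US, FS->US (complements go to the
#'   remaining observable).  Defaults reproduce a ~4:1 US<->FS : US<->PS
#'   transition ratio at stationarity.
#' @param fret named FRET levels, see [defaultFretLevels()].
#' @return a [KineticScheme-class] with two disconnected cycling subsystems.
#' @export
buildWithdrawalScheme <- function(frac_usps = 0.48,
                                  slow = c(k1 = 0.16, k2 = 0.02, P_k1 = 0.57),
                                  fast = c(k1 = 0.96, k2 = 0.07, P_k1 = 0.79),
                                  branch_fs = c(0.82, 0.93, 0.93),
                                  fret = defaultFretLevels()) {
  .checkProb(frac_usps, "frac_usps")
  slow <- as.list(slow); fast <- as.list(fast)
  for (par in list(slow, fast)) {
    .checkRate(par$k1, "k1"); .checkRate(par$k2, "k2"); .checkProb(par$P_k1, "P_k1")
    if (par$k1 <= par$k2) stop("'k1' must exceed 'k2'")
  }
  subStates <- function(prefix, obs) data.frame(
    label = as.vector(outer(paste0(prefix, obs), c("_f", "_s"), paste0)),
    observable = rep(obs, 2L),
    fret = rep(unname(fret[obs]), 2L),
    absorbing = FALSE, stringsAsFactors = FALSE)
  statesA <- subStates("a.", c("US", "PS"))
  statesB <- subStates("b.", c("US", "PS", "FS"))
  trA <- rbind(
    .cyclingBlock("a.", "US", "PS", 1, slow$k1, slow$k2, slow$P_k1),
    .cyclingBlock("a.", "PS", "US", 1, slow$k1, slow$k2, slow$P_k1))
  trB <- rbind(
    .cyclingBlock("b.", "US", c("FS", "PS"), c(branch_fs[1], 1 - branch_fs[1]),
                  fast$k1, fast$k2, fast$P_k1),
    .cyclingBlock("b.", "PS", c("US", "FS"), c(branch_fs[2], 1 - branch_fs[2]),
                  fast$k1, fast$k2, fast$P_k1),
    .cyclingBlock("b.", "FS", c("US", "PS"), c(branch_fs[3], 1 - branch_fs[3]),
                  fast$k1, fast$k2, fast$P_k1))
  states <- rbind(statesA, statesB)
  transitions <- rbind(trA, trB)
  transitions <- transitions[transitions$rate > 0, , drop = FALSE]
  rownames(transitions) <- NULL
  # initial occupancy: start in US, substate by entry probability
  initProb <- c(frac_usps * c(slow$P_k1, 1 - slow$P_k1),
                (1 - frac_usps) * c(fast$P_k1, 1 - fast$P_k1))
  names(initProb) <- c("a.US_f", "a.US_s", "b.US_f", "b.US_s")
  new("KineticScheme", states = states, transitions = transitions,
      initProb = initProb, ntpBranching = list())
}
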