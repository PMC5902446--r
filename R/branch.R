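#' @include AllClasses.R
NULL

# collapsed label sequence of a path: unassigned segments dropped,
# consecutive duplicates merged; durations aggregated alongside
.labelSequence <- function(p) {
  sg <- p@segments
  keep <- sg$label != "unassigned"
  lab <- sg$label[keep]
  dur <- sg$duration_s[keep]
  if (!length(lab)) return(data.frame(label = character(0), duration_s = numeric(0)))
  grp <- cumsum(c(1L, as.integer(lab[-1L] != lab[-length(lab)])))
  data.frame(label = lab[!duplicated(grp)],
             duration_s = as.numeric(tapply(dur, grp, sum)),
             stringsAsFactors = FALSE)
}

#' Classify trajectories into reaction pathways
#'
#' Deterministic rules on the post-filter label sequence: molecules that
#' reach FS without any PS-to-US return took the single-scrunch pathway
#' (with or without a detectable pause, depending on whether a PS dwell of at
#' least `min_pause_frames` frames precedes FS); molecules that return from
#' PS to US at least once before FS are cycling-then-FS; molecules that
#' transition but never reach FS are cycling-only (including molecules
#' truncated by bleaching mid-cycle); molecules with no transitions are
#' inactive.  The outcome of the *first* pause-exit attempt (success =
#' straight to FS, failure = return to US, unresolved = record ends during
#' the first pause) is reported separately so escape probabilities are not
#' biased by truncation.
#'
#' @param paths list of [LabeledPath-class] objects.
#' @param min_pause_frames minimum PS length (frames) counting as a detected
#'   pause (default 2, the step-filter minimum).
#' @return data.frame with columns `trace_id`, `class`, `n_attempts`,
#'   `first_outcome` (success/failure/unresolved/none) and `subpopulation`
#'   (visited-label set: US/PS, US/PS/FS, or none); flagged traces get class
#'   `"withheld"`.
#' @export
classifyTrajectories <- function(paths, min_pause_frames = 2L) {
  if (!length(paths)) stop("no paths supplied")
  rows <- lapply(paths, function(p) {
    if (p@flagged)
      return(data.frame(trace_id = p@traceId, class = "withheld",
                        n_attempts = NA_integer_, first_outcome = "none",
                        subpopulation = "none", stringsAsFactors = FALSE))
    sq <- .labelSequence(p)
    lab <- sq$label
    minPause_s <- min_pause_frames * p@frameTime
    fs <- which(lab == "FS")[1L]
    # PS -> US returns before the first FS entry (all of them when FS absent)
    upto <- if (is.na(fs)) length(lab) else fs
    ret <- 0L
    if (upto >= 2L)
      ret <- sum(lab[seq_len(upto - 1L)] == "PS" & lab[2:upto] == "US")
    ps1 <- which(lab == "PS")[1L]
    firstOutcome <- if (is.na(ps1)) {
      if (!is.na(fs)) "success" else "none"  # pause below detection floor
    } else if (ps1 < length(lab)) {
      if (lab[ps1 + 1L] == "FS") "success" else "failure"
    } else "unresolved"
    cls <- if (length(lab) < 2L) {
      "inactive"
    } else if (!is.na(fs) && ret == 0L) {
      pauseDetected <- !is.na(ps1) && ps1 < fs && sq$duration_s[ps1] >= minPause_s
      if (pauseDetected) "single_scrunch_with_pause" else "single_scrunch_no_pause"
    } else if (!is.na(fs)) {
      "cycling_then_FS"
    } else {
      "cycling_only"
    }
    visited <- unique(lab)
    subpop <- if ("FS" %in% visited && length(visited) >= 2L) {
      "US/PS/FS"
    } else if (all(c("US", "PS") %in% visited)) "US/PS" else "none"
    data.frame(trace_id = p@traceId, class = cls, n_attempts = ret,
               first_outcome = firstOutcome, subpopulation = subpop,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' First-attempt pause-escape probability
#'
#' Probability that a molecule reaches the fully scrunched FS level on its
#' first pause-exit attempt: successes over resolved first attempts, with a
#' Wilson 95% confidence interval.  Trajectories whose first attempt was
#' unresolved (record truncated during the first pause) or that never engaged
#' (inactive) are excluded.
#'
#' @param classes data.frame from [classifyTrajectories()].
#' @return list with `p`, `ci`, `n_success`, `n`.
#' @export
firstAttemptProbability <- function(classes) {
  res <- classes$first_outcome %in% c("success", "failure")
  n <- sum(res)
  if (n == 0L) stop("no resolved first attempts")
  if (n < 20L)
    warning(sprintf("only %d resolved trajectories; estimate will be unstable", n))
  k <- sum(classes$first_outcome[res] == "success")
  list(p = k / n, ci = wilsonCI(k, n), n_success = k, n = n)
}

#' Pause-escape probability from pooled PS-exit transitions
#'
#' Every detected exit from the partly scrunched (PS) level either continues
#' to FS (productive escape) or returns to US (abortive unscrunching), and in
#' the branching model each exit is an independent Bernoulli trial with the
#' isotherm probability p(NTP).  Pooling all detected PS exits therefore
#' estimates p(NTP) with many more events than the per-trace first-attempt
#' count and is far less sensitive to cycling visits hidden below the
#' detection floor (a missed short US return merges two PS dwells and erases
#' one return, but leaves PS-to-FS transitions intact).
#'
#' @param paths list of [LabeledPath-class] objects from one NTP condition.
#' @return list with `p`, `ci` (Wilson 95%), `n_fs` (PS to FS counts),
#'   `n_us` (PS to US counts).
#' @export
escapeFraction <- function(paths) {
  tc <- transitionHistogram(paths)
  fs <- tc@counts["PS", "FS"]
  us <- tc@counts["PS", "US"]
  n <- fs + us
  if (n == 0L) stop("no PS exits observed")
  list(p = fs / n, ci = wilsonCI(fs, n), n_fs = fs, n_us = us)
}

#' Fit the NTP escape isotherm
#'
#' Weighted least squares of p(NTP) = P_max * NTP / (NTP + K_ntp) to
#' first-attempt escape probabilities measured at several NTP
#' concentrations.
#'
#' @param points data.frame with columns `ntp` (uM), `p`, and optionally
#'   `ci_lo`/`ci_hi` (95% interval bounds used for inverse-variance weights)
#'   or `weight`.
#' @param weighted use weights (default TRUE when intervals are supplied).
#' @return an [IsothermFit-class].
#' @examples
#' pts <- data.frame(ntp = c(1, 5, 10, 30, 80, 500))
#' pts$p <- 0.79 * pts$ntp / (pts$ntp + 28)
#' fitIsotherm(pts)
#' @export
fitIsotherm <- function(points, weighted = TRUE) {
  stopifnot(all(c("ntp", "p") %in% names(points)))
  if (length(unique(points$ntp)) < 4L)
    stop("need >= 4 distinct NTP concentrations")
  if (diff(range(points$p)) < 0.1 * max(points$p))
    stop("K not constrained: all points saturated")
  w <- rep(1, nrow(points))
  if (weighted) {
    if (all(c("ci_lo", "ci_hi") %in% names(points))) {
      half <- pmax((points$ci_hi - points$ci_lo) / 2, 1e-3)
      w <- 1 / half^2
    } else if ("weight" %in% names(points)) {
      w <- points$weight
    }
  }
  df <- data.frame(ntp = points$ntp, p = points$p)
  fit <- minpack.lm::nlsLM(
    p ~ Pmax * ntp / (ntp + K), data = df, weights = w,
    start = list(Pmax = min(max(points$p), 1), K = stats::median(points$ntp)),
    lower = c(Pmax = 0, K = 1e-6), upper = c(Pmax = 1, K = 1e6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(Pmax = NA_real_, K = NA_real_))
  fitted <- cf[["Pmax"]] * df$ntp / (df$ntp + cf[["K"]])
  new("IsothermFit", Kntp = cf[["K"]], Pmax = cf[["Pmax"]],
      sd = c(Kntp = unname(se[["K"]]), Pmax = unname(se[["Pmax"]])),
      residuals = data.frame(ntp = df$ntp, p = df$p, fitted = fitted,
                             residual = df$p - fitted))
}

#' Count transitions between consecutive dwells
#'
#' Tallies ordered label pairs of consecutive dwells (US/PS/FS) over all
#' paths; the diagonal is structurally zero because adjacent dwells differ.
#'
#' @param paths list of [LabeledPath-class] objects.
#' @param meta metadata list stored on the result.
#' @return a [TransitionCounts-class].
#' @export
transitionHistogram <- function(paths, meta = list()) {
  labs <- c("US", "PS", "FS")
  cn <- matrix(0L, 3L, 3L, dimnames = list(from = labs, to = labs))
  for (p in paths) {
    sq <- .labelSequence(p)$label
    if (length(sq) < 2L) next
    for (i in seq_len(length(sq) - 1L))
      cn[sq[i], sq[i + 1L]] <- cn[sq[i], sq[i + 1L]] + 1L
  }
  tot <- sum(cn)
  fq <- if (tot > 0) cn / tot else matrix(0, 3L, 3L, dimnames = dimnames(cn))
  new("TransitionCounts", counts = cn, freq = fq, meta = meta)
}

#' Test successive dwell times for memory
#'
#' Rank (Spearman) correlation between the durations of successive visits to
#' one state within each trace, with a permutation null: memory-less kinetics
#' give correlations near zero.  Only interior (complete) dwells enter.
#'
#' @param paths list of [LabeledPath-class] objects.
#' @param state observable label whose successive dwells are paired.
#' @param n_perm number of permutations for the null distribution.
#' @param seed integer seed.
#' @param min_pairs minimum number of successive-dwell pairs required.
#' @return list with `rho`, `p_value`, `n_pairs`; `rho` is NA with a
#'   `reason` element for degenerate (constant) dwell lists.
#' @export
dwellMemoryTest <- function(paths, state, n_perm = 1e4L, seed = 1L,
                            min_pairs = 50L) {
  x <- numeric(0); y <- numeric(0)
  for (p in paths) {
    sg <- p@segments
    interior <- !sg$is_first & !sg$is_last & sg$label == state
    d <- sg$duration_s[interior]
    if (length(d) >= 2L) {
      x <- c(x, d[-length(d)])
      y <- c(y, d[-1L])
    }
  }
  n <- length(x)
  if (n < min_pairs)
    stop(sprintf("need >= %d successive-dwell pairs, got %d", min_pairs, n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n_pairs = n,
                reason = "degenerate: constant dwell times"))
  rho <- stats::cor(x, y, method = "spearman")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rx <- rank(x); ry <- rank(y)
  null <- replicate(n_perm, stats::cor(rx, sample(ry)))
  p <- (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p, n_pairs = n)
}

#' Subpopulations in NTP-withdrawal experiments
#'
#' Splits cycling molecules from NTP-withdrawn runs by their visited-label
#' set — US/PS-only cyclers versus US/PS/FS cyclers — and reports the
#' subpopulation fractions with Wilson 95% CIs plus per-subpopulation
#' two-exponential dwell kinetics per state.
#'
#' @param paths list of [LabeledPath-class] objects from no-NTP runs.
#' @param m mixture order for the dwell fits (default 2).
#' @param restarts,seed passed to [fitExpMixture()].
#' @param min_dwells minimum dwell count per fit; smaller pools are skipped.
#' @return list with `fractions` (data.frame subpopulation, n, fraction,
#'   ci_lo, ci_hi over cycling molecules) and `fits` (nested list
#'   fits\[\[subpop\]\]\[\[state\]\] of [ExpMixtureFit-class]).
#' @export
withdrawalSubpopulations <- function(paths, m = 2L, restarts = 20L, seed = 1L,
                                     min_dwells = 15L) {
  cls <- classifyTrajectories(paths)
  sub <- cls$subpopulation
  cyc <- sub %in% c("US/PS", "US/PS/FS")
  nCyc <- sum(cyc)
  fracs <- do.call(rbind, lapply(c("US/PS", "US/PS/FS"), function(s) {
    k <- sum(sub == s)
    ci <- if (nCyc > 0) wilsonCI(k, nCyc) else c(NA_real_, NA_real_)
    data.frame(subpopulation = s, n = k,
               fraction = if (nCyc > 0) k / nCyc else NA_real_,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  }))
  fits <- list()
  for (s in c("US/PS", "US/PS/FS")) {
    ids <- cls$trace_id[sub == s]
    ps <- Filter(function(p) p@traceId %in% ids, paths)
    states <- if (s == "US/PS") c("US", "PS") else c("US", "PS", "FS")
    fits[[s]] <- list()
    for (st in states) {
      d <- tryCatch(extractDwells(ps, st), error = function(e) NULL)
      if (is.null(d) || length(d) < max(min_dwells, 5L * (2L * m - 1L))) next
      fits[[s]][[st]] <- fitExpMixture(d, m, restarts = restarts, seed = seed)
    }
  }
  list(fractions = fracs, fits = fits)
}
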