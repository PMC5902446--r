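#' @include AllClasses.R
NULL

#' Exponential-mixture dwell-time density
#'
#' p(tau) = sum_n p_n k_n exp(-k_n tau); integrates to 1 for any valid
#' parameter set.
#'
#' @param tau dwell times (s).
#' @param rates exit rates k_n (s^-1).
#' @param weights component probabilities p_n (sum to 1).
#' @param log return log-density.
#' @return density values.
#' @export
dExpMixture <- function(tau, rates, weights, log = FALSE) {
  stopifnot(length(rates) == length(weights))
  lw <- base::log(weights) + base::log(rates)
  M <- outer(tau, rates, function(t, k) -k * t)
  M <- sweep(M, 2L, lw, "+")
  ll <- .logRowSumExp(M)
  if (log) ll else exp(ll)
}

.logRowSumExp <- function(M) {
  mx <- do.call(pmax, c(as.data.frame(M), na.rm = TRUE))
  mx + base::log(rowSums(exp(M - mx)))
}

.mixLogLik <- function(tau, rates, weights) sum(dExpMixture(tau, rates, weights, log = TRUE))

# rate bounds: frame time and record length bound observable exit rates
.K_MIN <- 1e-4
.K_MAX <- 1e3

#' Pool interior dwell times for one state
#'
#' Pools dwells of the requested state across traces, dropping the first
#' dwell of each trace (which precedes NTP addition) and the last (which is
#' cut short by photobleaching or by reaching the FS level).  Remaining
#' dwells are complete.
#'
#' @param paths list of [LabeledPath-class] objects.
#' @param state observable label (`"US"`, `"PS"` or `"FS"`).
#' @param drop_flagged skip traces dominated by unassigned segments.
#' @param skip_first_visit also drop the first visit to `state` in each
#'   trace.  Used when pooling cycling PS dwells: the first PS dwell is the
#'   initial-transcription pause, whose single-exponential exit kinetics
#'   differ from the two-exponential cycling kinetics and would contaminate
#'   the mixture.
#' @param censor_last also include each trace's final dwell of the state,
#'   flagged right-censored (its end is set by photobleaching or the end of
#'   the record, not by a transition).  Interior dwells alone are a
#'   length-biased sample — long dwells are more likely to be cut off — so
#'   fits that support survival terms can use these censored dwells to
#'   remove the bias.
#' @return a [DwellSet-class].
#' @examples
#' # a path A(5 s) B(3 s) A(7 s) queried for B yields the single 3 s dwell
#' @export
extractDwells <- function(paths, state, drop_flagged = TRUE,
                          skip_first_visit = FALSE, censor_last = FALSE) {
  if (!length(paths)) stop("at least one path is required")
  taus <- numeric(0); ids <- character(0); cens <- logical(0)
  for (p in paths) {
    if (drop_flagged && p@flagged) next
    sg <- p@segments
    interior <- !sg$is_first & !sg$is_last & sg$label == state
    if (skip_first_visit) {
      first <- which(sg$label == state)[1L]
      if (!is.na(first)) interior[first] <- FALSE
    }
    if (any(interior)) {
      taus <- c(taus, sg$duration_s[interior])
      ids <- c(ids, rep(p@traceId, sum(interior)))
      cens <- c(cens, rep(FALSE, sum(interior)))
    }
    if (censor_last) {
      last <- which(sg$is_last & !sg$is_first & sg$label == state &
                      p@truncation != "escape")
      if (length(last)) {
        taus <- c(taus, sg$duration_s[last])
        ids <- c(ids, p@traceId)
        cens <- c(cens, TRUE)
      }
    }
  }
  if (!length(taus)) stop("no interior dwells for state ", state)
  new("DwellSet", state = state, tau = taus, censored = cens, traceId = ids)
}

# theta = (log k_1..k_m, w_2..w_m); weights via softmax with w_1 = 0
.thetaToPar <- function(theta, m) {
  k <- exp(theta[seq_len(m)])
  w <- c(0, theta[-seq_len(m)])
  p <- exp(w - max(w)); p <- p / sum(p)
  list(k = k, p = p)
}

.negLogLik <- function(theta, tau, m, censored = NULL, t_min = 0) {
  par <- .thetaToPar(theta, m)
  ll <- .mixLogLik(tau, par$k, par$p)
  if (!is.null(censored) && any(censored)) {
    # survival terms for right-censored dwells (optional, off by default)
    S <- rowSums(sweep(exp(outer(-tau[censored], par$k)), 2L, par$p, "*"))
    ll <- .mixLogLik(tau[!censored], par$k, par$p) + sum(log(S))
  }
  if (t_min > 0) {
    # left truncation: dwells below the detection floor are unobservable
    S0 <- sum(par$p * exp(-par$k * t_min))
    ll <- ll - length(tau) * log(S0)
  }
  -ll
}

#' Fit an m-exponential mixture to dwell times by maximum likelihood
#'
#' Maximizes sum_i ln sum_n p_n k_n exp(-k_n tau_i) over the rates and
#' weights, working in log-rate / softmax-weight space with multiple random
#' restarts; the best restart is returned with rates sorted descending.
#' Rates are bounded to \[1e-4, 1e3\] s^-1 (frame time and record length
#' bound the observable rates).  For m = 1 the closed form k = 1/mean(tau)
#' is used.
#'
#' @param dwells a [DwellSet-class].
#' @param m number of exponential components, >= 1.
#' @param restarts number of random initializations.
#' @param seed integer seed for the initializations.
#' @param use_censoring include survival terms for right-censored dwells
#'   (default FALSE: censored dwells are excluded, matching the exclusion of
#'   last dwells from the pooled distribution).
#' @param t_min detection floor in seconds: dwells at or below `t_min` are
#'   dropped and the likelihood is left-truncated (conditioned on
#'   `tau > t_min`).  Segmented data cannot contain dwells shorter than the
#'   step-filter minimum, so fitting without this correction biases fast
#'   rates downward.  Default 0 (no truncation), for dwell sets that carry
#'   no floor.
#' @param init optional list(k, p) initial values (used by the bootstrap).
#' @return an [ExpMixtureFit-class].
#' @examples
#' d <- new("DwellSet", state = "PS", tau = c(2, 2, 2),
#'          censored = rep(FALSE, 3), traceId = rep("t", 3))
#' rates(fitExpMixture(d, m = 1))  # 0.5 exactly
#' @export
fitExpMixture <- function(dwells, m, restarts = 20L, seed = 1L,
                          use_censoring = FALSE, t_min = 0, init = NULL) {
  stopifnot(is(dwells, "DwellSet"))
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be >= 1")
  tau <- dwells@tau
  cens <- dwells@censored
  if (!use_censoring) {
    tau <- tau[!cens]
    cens <- NULL
  }
  if (t_min > 0) {
    keep <- tau > t_min
    tau <- tau[keep]
    if (!is.null(cens)) cens <- cens[keep]
  }
  N <- length(tau)
  # the closed form below is defined for any N >= 1, so the sample-size
  # guard applies to genuine mixtures only
  if (m > 1L && N < 5L * (2L * m - 1L))
    stop(sprintf("need N >= %d dwells for m = %d, got %d",
                 5L * (2L * m - 1L), m, N))
  if (N < 1L) stop("no dwells to fit")
  if (m == 1L) {
    # truncated (and optionally right-censored) exponential MLE
    nEvents <- if (is.null(cens)) N else sum(!cens)
    if (nEvents == 0L) stop("no complete dwells")
    k <- nEvents / max(sum(tau) - N * t_min, 1e-12)
    k <- min(max(k, .K_MIN), .K_MAX)
    ll <- nEvents * log(k) - k * sum(tau) + N * k * t_min
    return(new("ExpMixtureFit", m = 1L, rates = k, weights = 1,
               logLik = ll, bic = -2 * ll + log(N), n = as.integer(N),
               sdRates = NA_real_, sdWeights = NA_real_,
               convergence = list(method = "closed-form", t_min = t_min)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  base <- 1 / mean(tau)
  lower <- c(rep(log(.K_MIN), m), rep(-20, m - 1L))
  upper <- c(rep(log(.K_MAX), m), rep(20, m - 1L))
  best <- NULL
  fails <- 0L
  for (r in seq_len(restarts)) {
    if (r == 1L && !is.null(init)) {
      k0 <- pmin(pmax(init$k, .K_MIN * 2), .K_MAX / 2)
      w0 <- log(pmax(init$p, 1e-8)); w0 <- (w0 - w0[1L])[-1L]
    } else if (r == 1L) {
      # quantile-spread rates around 1/mean
      q <- stats::quantile(tau, probs = seq(0.15, 0.85, length.out = m),
                           names = FALSE)
      k0 <- sort(pmin(pmax(1 / q, .K_MIN * 2), .K_MAX / 2), decreasing = TRUE)
      w0 <- rep(0, m - 1L)
    } else {
      k0 <- sort(base * exp(stats::runif(m, -2.5, 2.5)), decreasing = TRUE)
      k0 <- pmin(pmax(k0, .K_MIN * 2), .K_MAX / 2)
      w0 <- stats::runif(m - 1L, -1, 1)
    }
    theta0 <- c(log(k0), w0)
    opt <- tryCatch(
      stats::optim(theta0, .negLogLik, tau = tau, m = m, censored = cens,
                   t_min = t_min,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) {
      fails <- fails + 1L
      next
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop(sprintf("mixture MLE failed to converge in all %d restarts (%d errors)",
                 restarts, fails))
  par <- .thetaToPar(best$par, m)
  o <- order(par$k, decreasing = TRUE)
  k <- par$k[o]; p <- par$p[o]
  # enforce strict rate ordering for identifiability of the report
  if (any(diff(k) == 0)) k <- k * (1 + 1e-9 * (seq_len(m) - 1))
  p <- p / sum(p)
  ll <- -best$value
  npar <- 2L * m - 1L
  new("ExpMixtureFit", m = m, rates = k, weights = p, logLik = ll,
      bic = -2 * ll + npar * log(N), n = as.integer(N),
      sdRates = rep(NA_real_, m), sdWeights = rep(NA_real_, m),
      convergence = list(code = best$convergence, counts = best$counts,
                         restarts = restarts, failed_restarts = fails))
}

#' Choose the number of exponentials by BIC
#'
#' Fits m = 1..`m_max` mixtures and returns the m minimizing
#' BIC_m = -2 L_m + (2m - 1) ln N; ties break to the smaller m.  Values of m
#' whose sample-size precondition N >= 5 (2m - 1) fails are skipped with a
#' message.
#'
#' @param dwells a [DwellSet-class].
#' @param m_max largest mixture order to try.
#' @param restarts,seed,t_min,use_censoring passed to [fitExpMixture()].
#' @return list with `m` (selected order), `fits` (per-m list) and `bic`
#'   (named numeric).
#' @export
selectMBic <- function(dwells, m_max = 3L, restarts = 20L, seed = 1L,
                       t_min = 0, use_censoring = FALSE) {
  if (m_max < 1L) stop("'m_max' must be >= 1")
  N <- sum((use_censoring | !dwells@censored) & dwells@tau > t_min)
  fits <- vector("list", m_max)
  bic <- rep(NA_real_, m_max)
  for (m in seq_len(m_max)) {
    if (N < 5L * (2L * m - 1L)) {
      message(sprintf("m = %d skipped: needs N >= %d, have %d",
                      m, 5L * (2L * m - 1L), N))
      next
    }
    fits[[m]] <- fitExpMixture(dwells, m, restarts = restarts, seed = seed,
                               t_min = t_min, use_censoring = use_censoring)
    bic[m] <- fits[[m]]@bic
  }
  if (all(is.na(bic))) stop("no mixture order satisfied its sample-size guard")
  mstar <- which.min(bic)  # ties and NA resolve to the smallest feasible m
  list(m = mstar, fits = fits, bic = stats::setNames(bic, paste0("m", seq_len(m_max))))
}

#' Bootstrap standard deviations of mixture parameters
#'
#' Draws `B` nonparametric resamples of the dwell set (with replacement, same
#' size), refits the m-exponential mixture on each, matches components by
#' descending rate, and reports the SD of every parameter over the
#' resamples.
#'
#' @param dwells a [DwellSet-class].
#' @param m mixture order.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @param restarts restarts per refit (each refit is also warm-started from
#'   the full-data estimate).
#' @return list with `sdRates`, `sdWeights`, `estimates` (B x 2m matrix of
#'   successful refits) and `failures`; a warning is raised when more than 5%
#'   of refits fail.
#' @export
bootstrapSd <- function(dwells, m, B = 1000L, seed = 1L, restarts = 3L,
                        t_min = 0) {
  fit <- fitExpMixture(dwells, m, seed = seed, t_min = t_min)
  tau <- dwells@tau[!dwells@censored & dwells@tau > t_min]
  N <- length(tau)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  est <- matrix(NA_real_, nrow = B, ncol = 2L * m)
  for (b in seq_len(B)) {
    idx <- sample.int(N, N, replace = TRUE)
    ds <- new("DwellSet", state = dwells@state, tau = tau[idx],
              censored = rep(FALSE, N), traceId = dwells@traceId[idx])
    fb <- tryCatch(
      fitExpMixture(ds, m, restarts = restarts,
                    seed = sample.int(.Machine$integer.max, 1L),
                    t_min = t_min,
                    init = list(k = fit@rates, p = fit@weights)),
      error = function(e) NULL)
    if (!is.null(fb)) est[b, ] <- c(fb@rates, fb@weights)
  }
  ok <- stats::complete.cases(est)
  failures <- sum(!ok)
  if (failures > 0.05 * B)
    warning(sprintf("%d of %d bootstrap refits failed", failures, B))
  sds <- apply(est[ok, , drop = FALSE], 2L, stats::sd)
  list(sdRates = sds[seq_len(m)], sdWeights = sds[m + seq_len(m)],
       estimates = est[ok, , drop = FALSE], failures = failures)
}

#' Attach bootstrap SDs to a fit
#'
#' Convenience wrapper running [bootstrapSd()] and stamping the result onto
#' the [ExpMixtureFit-class].
#'
#' @inheritParams bootstrapSd
#' @return the refit [ExpMixtureFit-class] with `sdRates`/`sdWeights` filled.
#' @export
fitWithBootstrap <- function(dwells, m, B = 1000L, seed = 1L, restarts = 20L,
                             t_min = 0) {
  fit <- fitExpMixture(dwells, m, restarts = restarts, seed = seed,
                       t_min = t_min)
  bs <- bootstrapSd(dwells, m, B = B, seed = seed, t_min = t_min)
  fit@sdRates <- as.numeric(bs$sdRates)
  fit@sdWeights <- as.numeric(bs$sdWeights)
  fit
}

#' Initial-pause exit rate from single-scrunch trajectories
#'
#' Restricts the paths to trajectories classified as single-scrunch with a
#' detectable pause, pools their pause dwell (the PS dwell immediately
#' preceding the first FS entry), and fits a single exponential by MLE with
#' bootstrap SD — the exit rate of the initial-transcription pause.
#'
#' @param paths list of [LabeledPath-class] objects.
#' @param min_pause_frames minimum detectable pause length in frames.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param t_min detection floor (s) for the left-truncated exponential MLE;
#'   0 gives the plain closed form 1/mean.  Pass the segmentation detection
#'   floor (one frame above the step-filter minimum) when the paths come
#'   from segmented data.
#' @return list with `fit` (an [ExpMixtureFit-class], m = 1, SD filled),
#'   `dwells` (the pooled pause [DwellSet-class]) and `n_traces`.
#' @export
pauseExitRate <- function(paths, min_pause_frames = 2L, B = 1000L, seed = 1L,
                          t_min = 0) {
  cls <- classifyTrajectories(paths, min_pause_frames = min_pause_frames)
  use <- cls$class == "single_scrunch_with_pause"
  if (!any(use)) stop("no single-scrunch trajectories with a detectable pause")
  ids <- cls$trace_id[use]
  taus <- numeric(0); src <- character(0)
  for (p in paths) {
    if (!(p@traceId %in% ids)) next
    sg <- p@segments
    fs <- which(sg$label == "FS")[1L]
    if (is.na(fs) || fs < 2L) next
    ps <- max(which(sg$label[seq_len(fs - 1L)] == "PS"))
    taus <- c(taus, sg$duration_s[ps])
    src <- c(src, p@traceId)
  }
  if (length(taus) < 30L)
    stop(sprintf("need >= 30 pause dwells, got %d", length(taus)))
  d <- new("DwellSet", state = "PS", tau = taus,
           censored = rep(FALSE, length(taus)), traceId = src)
  fit <- fitWithBootstrap(d, m = 1L, B = B, seed = seed, t_min = t_min)
  list(fit = fit, dwells = d, n_traces = length(taus))
}
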