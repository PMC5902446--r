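#' @include AllClasses.R
#' @useDynLib scrunchFRET, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# deterministic EM initializations: spread quantiles, an even grid over the
# data range, and k-means centers (seeded locally); EM keeps the best
.hmmInits <- function(xs, K) {
  x <- unlist(xs)
  sticky <- function(mu) {
    mu <- sort(as.numeric(mu))
    if (anyDuplicated(mu)) mu <- mu + seq_len(K) * 1e-6
    A <- matrix(0.05 / max(K - 1, 1), K, K)
    diag(A) <- 0.95
    list(mu = mu, sigma = rep(max(stats::sd(x) / K, 1e-3), K),
         pi0 = rep(1 / K, K), A = A)
  }
  inits <- list(
    sticky(stats::quantile(x, probs = seq(0.5, K - 0.5, by = 1) / K,
                           names = FALSE)),
    sticky(seq(stats::quantile(x, 0.005), stats::quantile(x, 0.995),
               length.out = K)))
  km <- tryCatch({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(20L + K)
    xs_sub <- if (length(x) > 5e4) x[seq(1L, length(x), length.out = 5e4)] else x
    stats::kmeans(xs_sub, centers = K, nstart = 5)$centers
  }, error = function(e) NULL)
  if (!is.null(km)) inits[[3L]] <- sticky(km)
  inits
}

# EM for a Gaussian-emission HMM over a list of series with pooled
# (ensemble) emission and transition parameters.  Each deterministic
# initialization gets a short warm run; only the best is iterated to
# convergence (short-runs/long-run strategy).
.hmmEM <- function(xs, K, max_iter = 500, tol = 1e-6, warm_iter = 15) {
  warm <- list()
  for (init in .hmmInits(xs, K)) {
    fit <- tryCatch(.hmmEMone(xs, K, init, warm_iter, tol, warm_only = TRUE),
                    error = function(e) NULL)
    if (!is.null(fit)) warm[[length(warm) + 1L]] <- fit
  }
  if (!length(warm)) stop("HMM EM failed for every initialization")
  best <- warm[[which.max(vapply(warm, `[[`, numeric(1), "loglik"))]]
  .hmmEMone(xs, K, best[c("mu", "sigma", "pi0", "A")], max_iter, tol)
}

.hmmEMone <- function(xs, K, par, max_iter = 500, tol = 1e-6,
                      warm_only = FALSE) {
  llTrace <- numeric(0)
  llOld <- -Inf
  converged <- FALSE
  xcat <- unlist(xs, use.names = FALSE)
  starts <- cumsum(c(0L, lengths(xs)[-length(xs)]))
  for (it in seq_len(max_iter)) {
    st <- .fbGaussMulti(xcat, as.integer(starts), par$mu, par$sigma,
                        par$pi0, par$A)
    ll <- st$loglik
    sw <- st$sw; swx <- st$swx; swx2 <- st$swx2
    xi <- st$xi; pi0n <- st$pi0n
    llTrace <- c(llTrace, ll)
    if (is.finite(llOld) && abs(ll - llOld) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    llOld <- ll
    ok <- sw > 1e-8
    mu <- par$mu; sigma <- par$sigma
    mu[ok] <- swx[ok] / sw[ok]
    v <- swx2[ok] / sw[ok] - mu[ok]^2
    sigma[ok] <- sqrt(pmax(v, 1e-6))
    rs <- rowSums(xi)
    A <- par$A
    nz <- rs > 1e-12
    A[nz, ] <- xi[nz, , drop = FALSE] / rs[nz]
    pi0 <- pi0n / sum(pi0n)
    par <- list(mu = mu, sigma = sigma, pi0 = pi0, A = A)
  }
  if (!converged && !warm_only)
    stop(sprintf(
      "HMM EM did not converge after %d iterations; last log-likelihoods: %s",
      max_iter, paste(sprintf("%.4f", utils::tail(llTrace, 5)), collapse = ", ")))
  c(par, list(loglik = ll, iterations = it, llTrace = llTrace))
}

.viterbiSegments <- function(x, par) {
  path <- .viterbiGauss(x, par$mu, par$sigma, par$pi0, par$A)
  fb <- .fbGauss(x, par$mu, par$sigma, par$pi0, par$A)
  g <- fb$gamma
  runs <- rle(path)
  start <- cumsum(c(0L, runs$lengths[-length(runs$lengths)]))
  conf <- numeric(length(runs$values))
  lvl <- numeric(length(runs$values))
  for (i in seq_along(runs$values)) {
    fr <- (start[i] + 1L):(start[i] + runs$lengths[i])
    conf[i] <- mean(g[fr, runs$values[i]])
    lvl[i] <- mean(x[fr])  # empirical segment mean, not the pooled state mean
  }
  sg <- data.frame(level = lvl, start_frame = start,
                   n_frames = runs$lengths, confidence = conf)
  .mergeEqualLevels(sg)
}

# states with numerically identical means decode to equal adjacent levels;
# collapse them so segment tables satisfy the class invariant
.mergeEqualLevels <- function(sg) {
  if (nrow(sg) < 2L) return(sg)
  grp <- cumsum(c(1L, as.integer(sg$level[-1L] != sg$level[-nrow(sg)])))
  if (max(grp) == nrow(sg)) return(sg)
  out <- do.call(rbind, lapply(split(sg, grp), function(g) data.frame(
    level = g$level[1L], start_frame = g$start_frame[1L],
    n_frames = sum(g$n_frames),
    confidence = sum(g$confidence * g$n_frames) / sum(g$n_frames))))
  rownames(out) <- NULL
  out
}

#' Segment FRET traces with a Gaussian-emission hidden Markov model
#'
#' Fits an HMM by maximum-likelihood EM and decodes each trace by Viterbi,
#' returning piecewise-constant fitted levels.  With `shared = TRUE`
#' (ensemble mode) emission and transition parameters are pooled across all
#' traces; otherwise each trace is fit independently.  The number of states
#' is chosen by BIC between 2 and `max_states`.  Initialization is
#' deterministic (data quantiles), so repeated runs give identical
#' segmentations.
#'
#' @param fretTraces list of [FretTrace-class] objects.
#' @param max_states maximum number of HMM states (2..6).
#' @param shared pool parameters across traces (ensemble mode).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return list of [SegmentedTrace-class]; the selected state count and the
#'   fitted parameters are attached as attributes `"K"` and `"hmm"`.
#' @export
segmentHmm <- function(fretTraces, max_states = 4L, shared = TRUE,
                       max_iter = 500L, tol = 1e-6) {
  if (!length(fretTraces)) stop("at least one trace is required")
  if (max_states < 2L || max_states > 6L)
    stop("'max_states' must lie in 2..6")
  xs <- lapply(fretTraces, function(f) f@E[f@mask])
  keep <- vapply(xs, length, integer(1)) >= 2L
  if (!any(keep)) stop("no trace has >= 2 analyzable frames")

  fitSet <- function(series) {
    n <- sum(lengths(series))
    fits <- list()
    bic <- rep(Inf, max_states)
    for (K in 2:max_states) {
      fit <- tryCatch(.hmmEM(series, K, max_iter, tol),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        if (K == 2L) stop(fit)
        next
      }
      npar <- K * K + 2L * K - 1L  # K-1 init + K(K-1) trans + K mu + K sigma
      bic[K] <- -2 * fit$loglik + npar * log(n)
      fits[[K]] <- fit
    }
    K <- which.min(bic)
    list(par = fits[[K]], K = K)
  }

  if (shared) {
    ens <- fitSet(xs[keep])
    segs <- vector("list", length(fretTraces))
    for (i in seq_along(fretTraces)) {
      if (!keep[i]) {
        segs[[i]] <- NULL
        next
      }
      sg <- .viterbiSegments(xs[[i]], ens$par)
      # map positions in the masked series back to original frames
      frames <- which(fretTraces[[i]]@mask) - 1L
      sg$start_frame <- frames[sg$start_frame + 1L]
      segs[[i]] <- new("SegmentedTrace", traceId = fretTraces[[i]]@traceId,
                       frameTime = fretTraces[[i]]@frameTime, segments = sg)
    }
    segs <- segs[!vapply(segs, is.null, logical(1))]
    attr(segs, "K") <- ens$K
    attr(segs, "hmm") <- ens$par
    return(segs)
  }
  segs <- list()
  for (i in seq_along(fretTraces)) {
    if (!keep[i]) next
    one <- fitSet(xs[i])
    sg <- .viterbiSegments(xs[[i]], one$par)
    frames <- which(fretTraces[[i]]@mask) - 1L
    sg$start_frame <- frames[sg$start_frame + 1L]
    segs[[length(segs) + 1L]] <-
      new("SegmentedTrace", traceId = fretTraces[[i]]@traceId,
          frameTime = fretTraces[[i]]@frameTime, segments = sg)
  }
  segs
}
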