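#' @include AllClasses.R
NULL

#' Render a three-channel intensity trace from a state path
#'
#' Generates per-frame intensities on the ALEX frame grid.  While both dyes
#' are intact the expected intensities are \code{I_DA = total * E},
#' \code{I_DD = total * (1 - E)} and \code{I_AA = total}, each with
#' independent zero-mean Gaussian noise.  Donor and acceptor bleach times are
#' drawn exponentially from their rates; after acceptor bleaching
#' \code{I_DA} falls to noise only and \code{I_DD} rises to the full total
#' (no transfer), after donor bleaching both donor-excitation channels are
#' noise only.  Each frame takes the FRET level of the state occupying the
#' majority of the frame, so sub-frame events shorter than half a frame are
#' invisible by construction (the detection floor).
#'
#' @param path a [StatePath-class].
#' @param em an [EmissionParams-class].
#' @param seed integer seed for noise and bleach times.
#' @param meta metadata list copied onto the trace.
#' @return an [IntensityTrace-class]; bleach times (s, possibly `Inf`) are
#'   stored in `meta$donorBleach_s` / `meta$acceptorBleach_s`.
#' @export
renderTrace <- function(path, em, seed, meta = list()) {
  stopifnot(is(path, "StatePath"), is(em, "EmissionParams"))
  validObject(em)
  sg <- path@segments
  total_s <- sum(sg$duration_s)
  dt <- em@frameTime
  n_frames <- floor(total_s / dt + 1e-9)
  if (n_frames < 1L) stop("path must span at least one frame")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  E_frame <- .majorityFret(sg, dt, n_frames)

  donorBleach <- if (em@donorBleachRate > 0)
    stats::rexp(1L, em@donorBleachRate) else Inf
  acceptorBleach <- if (em@acceptorBleachRate > 0)
    stats::rexp(1L, em@acceptorBleachRate) else Inf

  tmid <- (seq_len(n_frames) - 0.5) * dt
  tot <- em@totalIntensity
  IDA <- tot * E_frame
  IDD <- tot * (1 - E_frame)
  IAA <- rep(tot, n_frames)
  accOff <- tmid >= acceptorBleach
  donOff <- tmid >= donorBleach
  IDA[accOff] <- 0
  IDD[accOff] <- tot
  IAA[accOff] <- 0
  IDA[donOff] <- 0
  IDD[donOff] <- 0
  if (em@noiseSd > 0) {
    IDD <- IDD + stats::rnorm(n_frames, sd = em@noiseSd)
    IDA <- IDA + stats::rnorm(n_frames, sd = em@noiseSd)
    IAA <- IAA + stats::rnorm(n_frames, sd = em@noiseSd)
  }
  meta$donorBleach_s <- donorBleach
  meta$acceptorBleach_s <- acceptorBleach
  new("IntensityTrace", traceId = path@traceId, frameTime = dt,
      IDD = IDD, IDA = IDA, IAA = IAA, meta = meta)
}

# FRET level per frame by majority occupancy within [f*dt, (f+1)*dt)
.majorityFret <- function(sg, dt, n_frames) {
  lvl <- unique(sg$fret)
  occ <- matrix(0, nrow = n_frames, ncol = length(lvl))
  for (i in seq_len(nrow(sg))) {
    a <- sg$start_s[i]; b <- a + sg$duration_s[i]
    f0 <- max(0L, floor(a / dt))
    f1 <- min(n_frames - 1L, ceiling(b / dt) - 1L)
    if (f1 < f0) next
    fr <- f0:f1
    overlap <- pmin(b, (fr + 1) * dt) - pmax(a, fr * dt)
    j <- match(sg$fret[i], lvl)
    occ[fr + 1L, j] <- occ[fr + 1L, j] + overlap
  }
  lvl[max.col(occ, ties.method = "first")]
}
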