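#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' Bundles every stage's settings with a single root seed; per-stage seeds
#' are derived from the root so stages can be re-run independently yet
#' reproducibly.
#'
#' @param seed root integer seed, recorded in all outputs.
#' @param frame_time frame duration (s).
#' @param injection_frame frame (0-based) of NTP addition.
#' @param max_states,shared HMM settings, see [segmentHmm()].
#' @param allan_block block length (frames) for [allanDeviation()].
#' @param min_len_frames step-filter minimum segment length.
#' @param tol_sd level-assignment tolerance, see [mapStates()].
#' @param min_pause_frames detectable-pause threshold, see
#'   [classifyTrajectories()].
#' @param m_max largest mixture order for [selectMBic()].
#' @param restarts MLE restarts.
#' @param B bootstrap resamples.
#' @param censor_last include each trace's final dwell as right-censored
#'   (survival terms in the mixture likelihood); removes the length bias of
#'   interior-only pooling.
#' @param pool_conditions pool cycling dwells across NTP conditions before
#'   fitting instead of fitting per condition and averaging.
#' @param out_dir optional output directory for tables and the JSON report.
#' @return a list with class `"RunConfig"`.
#' @export
runConfig <- function(seed = 1L, frame_time = 0.2, injection_frame = 0L,
                      max_states = 4L, shared = TRUE, allan_block = 5L,
                      min_len_frames = 2L, tol_sd = 3, min_pause_frames = 2L,
                      m_max = 2L, restarts = 20L, B = 200L,
                      censor_last = TRUE, pool_conditions = FALSE,
                      out_dir = NULL) {
  structure(list(seed = as.integer(seed), frame_time = frame_time,
                 injection_frame = as.integer(injection_frame),
                 max_states = as.integer(max_states), shared = shared,
                 allan_block = as.integer(allan_block),
                 min_len_frames = as.integer(min_len_frames),
                 tol_sd = tol_sd, min_pause_frames = as.integer(min_pause_frames),
                 m_max = as.integer(m_max), restarts = as.integer(restarts),
                 B = as.integer(B), censor_last = censor_last,
                 pool_conditions = pool_conditions,
                 out_dir = out_dir),
            class = "RunConfig")
}

# deterministic per-stage substream seeds below 2^31
.stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage * 7919L
}

# group sorted values into n clusters by cutting at the n-1 largest gaps;
# used to map several HMM state means onto the physical FRET levels
.gapCutCenters <- function(mu, n) {
  mu <- sort(mu)
  if (length(mu) <= n) return(mu)
  gaps <- diff(mu)
  cuts <- sort(order(gaps, decreasing = TRUE)[seq_len(n - 1L)])
  grp <- cumsum(c(1L, as.integer(seq_along(gaps) %in% cuts)))
  as.numeric(tapply(mu, grp, mean))
}

#' Run the full analysis pipeline
#'
#' Executes selection, FRET computation, HMM segmentation, step filtering,
#' level calibration and state mapping, then per-NTP-condition dwell pooling,
#' mixture fits, pathway classification, first-attempt probabilities, the
#' escape-isotherm fit (when at least four conditions are present) and the
#' initial-pause exit rate.  Identical config and seed give identical
#' outputs.
#'
#' @param traces list of [IntensityTrace-class] objects (NTP concentration
#'   read from `meta$ntp`, NA treated as a single unnamed condition), or a
#'   path to a trace CSV readable by [readTraces()].
#' @param config a [runConfig()].
#' @return a RunReport: list with elements `config`, `counts`, `levels`,
#'   `paths`, `classes`, `conditions` (per-condition classification and
#'   first-attempt estimates), `cycling` (per-state mixture fits),
#'   `pause` (k_ITC6 fit) and `isotherm`; stage failures are reported with
#'   the stage name.
#' @export
runPipeline <- function(traces, config = runConfig()) {
  if (is.character(traces)) traces <- readTraces(traces, config$frame_time)
  report <- list(config = unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sel <- stage("select", selectTraces(traces))
  report$counts <- list(traces_in = length(traces),
                        traces_kept = length(sel$kept))
  report$selection <- sel$report
  if (!length(sel$kept)) stop("stage 'select' failed: no traces kept")

  fret <- stage("fret", lapply(sel$kept, computeFret))
  segs <- stage("segment",
                segmentHmm(fret, max_states = config$max_states,
                           shared = config$shared))

  filt <- stage("filter", {
    lapply(seq_along(segs), function(i) {
      f <- fret[[match(segs[[i]]@traceId, vapply(fret, traceId, character(1)))]]
      x <- f@E[f@mask]
      # noise floor from the longest constant-level stretch: estimating the
      # Allan deviation across real level steps would inflate the merge
      # threshold and erase genuine transitions
      sg <- segs[[i]]@segments
      j <- which.max(sg$n_frames)
      pos <- match(sg$start_frame[j],
                   which(f@mask) - 1L)  # back to masked-series coordinates
      base <- x[pos:(pos + sg$n_frames[j] - 1L)]
      sA <- if (length(base) >= 2L * config$allan_block) {
        allanDeviation(base, config$allan_block)
      } else if (length(x) >= 2L) {
        # too short for block means: white-noise equivalent from differences
        stats::sd(diff(x)) / sqrt(2) / sqrt(config$allan_block)
      } else 0
      filterSteps(segs[[i]], sigma_A = sA, min_len = config$min_len_frames)
    })
  })

  levels <- stage("levels", {
    hmmPar <- attr(segs, "hmm")
    c0 <- if (!is.null(hmmPar)) .gapCutCenters(hmmPar$mu, 3L) else NULL
    if (length(c0) != 3L) c0 <- NULL
    fitFretLevels(filt, fret = fret, centers0 = c0)
  })
  report$levels <- levels@table

  meta <- lapply(sel$kept, function(t) t@meta)
  names(meta) <- vapply(sel$kept, traceId, character(1))
  paths <- stage("map", lapply(filt, function(s) {
    w <- meta[[s@traceId]]$windowFrames
    n <- sum(s@segments$n_frames)
    trunc <- if (!is.null(w) && w <= n) "bleach" else "end-of-record"
    mapStates(s, levels, tol_sd = config$tol_sd, truncation = trunc)
  }))
  report$paths <- paths

  classes <- stage("classify",
                   classifyTrajectories(paths, config$min_pause_frames))
  ntps <- vapply(paths, function(p) {
    v <- meta[[p@traceId]]$ntp
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  classes$ntp <- ntps
  report$classes <- classes

  conds <- sort(unique(ntps), na.last = TRUE)
  tmin <- (config$min_len_frames + 1L) * config$frame_time
  condRows <- list(); cycFits <- list()
  for (cc in conds) {
    inCond <- if (is.na(cc)) is.na(ntps) else !is.na(ntps) & ntps == cc
    cl <- classes[inCond, , drop = FALSE]
    fa <- tryCatch(suppressWarnings(firstAttemptProbability(cl)),
                   error = function(e) NULL)
    esc <- tryCatch(escapeFraction(paths[inCond]), error = function(e) NULL)
    condRows[[length(condRows) + 1L]] <- data.frame(
      ntp = cc, n_traces = sum(inCond),
      p_first = if (is.null(fa)) NA_real_ else fa$p,
      ci_lo = if (is.null(fa)) NA_real_ else fa$ci[1],
      ci_hi = if (is.null(fa)) NA_real_ else fa$ci[2],
      n_resolved = if (is.null(fa)) 0L else fa$n,
      p_escape = if (is.null(esc)) NA_real_ else esc$p,
      esc_lo = if (is.null(esc)) NA_real_ else esc$ci[1],
      esc_hi = if (is.null(esc)) NA_real_ else esc$ci[2],
      n_exits = if (is.null(esc)) 0L else esc$n_fs + esc$n_us)
    if (!config$pool_conditions) {
      for (st in c("US", "PS")) {
        d <- tryCatch(extractDwells(paths[inCond], st,
                                    skip_first_visit = st == "PS",
                                    censor_last = config$censor_last),
                      error = function(e) NULL)
        if (is.null(d) || sum(!d@censored) < 5L * (2L * config$m_max - 1L)) next
        sel_m <- selectMBic(d, config$m_max, restarts = config$restarts,
                            seed = .stageSeed(config$seed, 4L), t_min = tmin,
                            use_censoring = config$censor_last)
        cycFits[[sprintf("ntp%s_%s", format(cc), st)]] <-
          list(ntp = cc, state = st, fit = sel_m$fits[[sel_m$m]],
               bic = sel_m$bic)
      }
    }
  }
  if (config$pool_conditions) {
    for (st in c("US", "PS")) {
      d <- tryCatch(extractDwells(paths, st, skip_first_visit = st == "PS",
                                  censor_last = config$censor_last),
                    error = function(e) NULL)
      if (is.null(d)) next
      sel_m <- selectMBic(d, config$m_max, restarts = config$restarts,
                          seed = .stageSeed(config$seed, 4L), t_min = tmin,
                          use_censoring = config$censor_last)
      cycFits[[paste0("pooled_", st)]] <-
        list(ntp = NA_real_, state = st, fit = sel_m$fits[[sel_m$m]],
             bic = sel_m$bic)
    }
  }
  report$conditions <- do.call(rbind, condRows)
  report$cycling <- cycFits

  report$pause <- tryCatch(
    pauseExitRate(paths, config$min_pause_frames, B = config$B,
                  seed = .stageSeed(config$seed, 5L), t_min = tmin),
    error = function(e) list(error = conditionMessage(e)))
  # per-condition pause lifetimes (conditions with too few single-scrunch
  # traces are skipped); the across-condition mean mirrors how per-promoter
  # exit rates are summarized
  pc <- list()
  for (cc in conds[!is.na(conds)]) {
    inCond <- !is.na(ntps) & ntps == cc
    pr <- tryCatch(
      pauseExitRate(paths[inCond], config$min_pause_frames, B = config$B,
                    seed = .stageSeed(config$seed, 5L), t_min = tmin),
      error = function(e) NULL)
    if (!is.null(pr))
      pc[[length(pc) + 1L]] <- data.frame(ntp = cc, k = pr$fit@rates,
                                          sd = pr$fit@sdRates, n = pr$fit@n)
  }
  if (length(pc)) {
    pc <- do.call(rbind, pc)
    report$pause$per_condition <- pc
    # precision-weighted mean across conditions (pause exit is
    # NTP-independent; sparse low-NTP conditions carry little weight)
    w <- ifelse(is.finite(pc$sd) & pc$sd > 0, 1 / pc$sd^2, 0)
    report$pause$k_mean <- if (any(w > 0)) sum(w * pc$k) / sum(w) else mean(pc$k)
  }

  # isotherm on the pooled PS-exit escape fractions, which are robust to
  # cycling events hidden below the detection floor
  pts <- report$conditions[!is.na(report$conditions$p_escape) &
                             !is.na(report$conditions$ntp), , drop = FALSE]
  report$isotherm <- if (nrow(pts) >= 4L) {
    tryCatch(fitIsotherm(data.frame(ntp = pts$ntp, p = pts$p_escape,
                                    ci_lo = pts$esc_lo, ci_hi = pts$esc_hi)),
             error = function(e) list(error = conditionMessage(e)))
  } else NULL

  if (!is.null(config$out_dir)) .writeReport(report, config)
  report
}

.writeReport <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(config$out_dir, x)
  utils::write.csv(report$selection, f("selection.csv"), row.names = FALSE)
  utils::write.csv(report$classes, f("classes.csv"), row.names = FALSE)
  utils::write.csv(report$conditions, f("conditions.csv"), row.names = FALSE)
  utils::write.csv(report$levels, f("levels.csv"), row.names = FALSE)
  js <- list(seed = config$seed, counts = report$counts,
             levels = report$levels,
             conditions = report$conditions,
             cycling = lapply(report$cycling, function(cf)
               c(list(ntp = cf$ntp, state = cf$state), fitReport(cf$fit))),
             pause = if (!is.null(report$pause$fit))
               fitReport(report$pause$fit) else report$pause,
             isotherm = if (is(report$isotherm, "IsothermFit"))
               list(K_ntp = report$isotherm@Kntp, P_max = report$isotherm@Pmax,
                    sd = as.list(report$isotherm@sd)) else report$isotherm)
  jsonlite::write_json(js, f("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(config$out_dir)
}

#' Generate deterministic fixture bundles
#'
#' Writes four small trace sets with ground-truth sidecar files:
#' productive-dominated (saturating NTP), cycling-heavy (low NTP),
#' NTP-withdrawal cyclers, and an artifact-doped set in which a labeled
#' subset of traces carries two dye pairs (multistep photobleaching).
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @param n_traces traces per bundle.
#' @param duration record length (s).
#' @return invisibly, a data.frame listing the files written.
#' @export
makeFixtures <- function(seed, dir, n_traces = 20L, duration = 120L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  em <- emissionParams()
  bundles <- list(
    productive = buildDefaultScheme(ntp = 500),
    cycling = buildDefaultScheme(ntp = 5),
    withdrawal = buildWithdrawalScheme()
  )
  files <- list()
  i <- 0L
  for (nm in names(bundles)) {
    i <- i + 1L
    sc <- bundles[[nm]]
    ntp <- if (nm == "withdrawal") 0 else sc@ntpBranching$ntp
    paths <- gillespieSimulate(sc, duration, n_traces,
                               seed = .stageSeed(seed, i), injectionTime = 20,
                               idPrefix = paste0(nm, "_"))
    traces <- lapply(seq_along(paths), function(j)
      renderTrace(paths[[j]], em, seed = .stageSeed(seed, i) + j,
                  meta = list(ntp = ntp)))
    tf <- file.path(dir, paste0(nm, "_traces.csv"))
    pf <- file.path(dir, paste0(nm, "_truth.csv"))
    writeTraces(traces, tf)
    writePaths(paths, pf)
    files[[nm]] <- data.frame(bundle = nm, traces = tf, truth = pf)
  }
  # artifact-doped: 10% of traces summed with a second, independent FRET pair
  sc <- buildDefaultScheme(ntp = 80)
  paths <- gillespieSimulate(sc, duration, n_traces,
                             seed = .stageSeed(seed, 9L), injectionTime = 20,
                             idPrefix = "doped_")
  traces <- lapply(seq_along(paths), function(j)
    renderTrace(paths[[j]], em, seed = .stageSeed(seed, 9L) + j,
                meta = list(ntp = 80)))
  nDope <- max(1L, round(0.1 * n_traces))
  extra <- gillespieSimulate(sc, duration, nDope,
                             seed = .stageSeed(seed, 10L), injectionTime = 20,
                             idPrefix = "extra_")
  doped <- integer(0)
  for (j in seq_len(nDope)) {
    tr2 <- renderTrace(extra[[j]], em, seed = .stageSeed(seed, 10L) + j)
    k <- j  # dope the first nDope traces; ids recorded in the sidecar
    n <- min(length(traces[[k]]@IDD), length(tr2@IDD))
    traces[[k]]@IDD <- traces[[k]]@IDD[1:n] + tr2@IDD[1:n]
    traces[[k]]@IDA <- traces[[k]]@IDA[1:n] + tr2@IDA[1:n]
    traces[[k]]@IAA <- traces[[k]]@IAA[1:n] + tr2@IAA[1:n]
    doped <- c(doped, k)
  }
  tf <- file.path(dir, "doped_traces.csv")
  writeTraces(traces, tf)
  df <- file.path(dir, "doped_labels.csv")
  utils::write.csv(data.frame(
    trace_id = vapply(traces, traceId, character(1)),
    doped = seq_along(traces) %in% doped), df, row.names = FALSE)
  files$doped <- data.frame(bundle = "doped", traces = tf, truth = df)
  invisible(do.call(rbind, files))
}
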