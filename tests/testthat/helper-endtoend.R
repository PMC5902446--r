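# simulate the standard multi-concentration experiment and analyze it with
# the full pipeline; used by the acceptance checks
simulateExperiment <- function(ntps, n_traces, duration = 600, seed = 1,
                               em = emissionParams()) {
  traces <- list()
  for (i in seq_along(ntps)) {
    sc <- buildDefaultScheme(ntp = ntps[i])
    paths <- gillespieSimulate(sc, duration, n_traces,
                               seed = seed * 100L + i, injectionTime = 20,
                               idPrefix = sprintf("c%d_", i))
    traces <- c(traces, lapply(seq_along(paths), function(j)
      renderTrace(paths[[j]], em, seed = seed * 100L + i * 10000L + j,
                  meta = list(ntp = ntps[i]))))
  }
  traces
}

# average the per-condition two-exponential cycling fits of one state
averageCycling <- function(report, state) {
  rows <- Filter(function(cf) cf$state == state && cf$fit@m == 2L,
                 report$cycling)
  est <- vapply(rows, function(cf) c(cf$fit@rates, cf$fit@weights[1]),
                numeric(3))
  rowMeans(est)
}
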