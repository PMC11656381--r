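setMethod("show", "Spectrum", function(object) {
  n <- length(object@x)
  cat("Spectrum with", n, "points\n")
  cat("  ", object@xLabel, ": [", format(object@x[1L]), ", ",
      format(object@x[n]), "]\n", sep = "")
  cat("  ", object@yLabel, ": [", format(min(object@y)), ", ",
      format(max(object@y)), "]\n", sep = "")
})

setMethod("show", "BaselineResult", function(object) {
  cat("BaselineResult [", object@method, "]\n", sep = "")
  if (object@method %in% c("airpls", "arpls"))
    cat("  lambda =", object@lam, " ratio =", object@ratio, "\n")
  cat("  iterations:", object@nIter,
      " converged:", object@converged, "\n")
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet with", nrow(object@peaks), "peaks",
      "(window =", object@windowSize,
      ", threshold =", object@threshold,
      ", min amplitude =", object@minAmplitude, ")\n")
  if (nrow(object@peaks))
    print(utils::head(object@peaks, 10L), row.names = FALSE)
})

setMethod("show", "Decomposition", function(object) {
  cat("Decomposition:", nrow(object@components), "components,",
      "loss =", object@loss, "\n")
  cat("  cost =", format(object@cost),
      " iterations =", object@nIter, "\n")
  print(object@components, row.names = FALSE)
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@components), "components,",
      "baseline =", object@baselineSpec$type,
      ", noise sigma =", object@noiseSigma,
      ", seed =", object@seed, "\n")
})
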