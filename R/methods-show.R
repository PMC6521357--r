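setMethod("show", "Methylome", function(object) {
  cat(sprintf("Methylome '%s' (%s context): %d sites on %d sequence(s)\n",
              object@sampleId, object@context, length(object@sites),
              length(unique(as.character(
                GenomicRanges::seqnames(object@sites))))))
  if (length(object@sites)) {
    t <- mcols(object@sites)$t
    cat(sprintf("  coverage: median %s, %.1f%% sites covered\n",
                stats::median(t), 100 * mean(t > 0)))
  }
})

setMethod("show", "FeatureParams", function(object) {
  cat(sprintf(
    "FeatureParams: w=%d cytosines, d=%g bp, %d bins, smooth span %d\n",
    object@w, object@d, object@bins, object@smoothSpan))
})

setMethod("show", "CallParams", function(object) {
  cat(sprintf(
    "CallParams: score>%g, gap<%g bp, k=%d, b>=%g; minSites=%s minDelta=%s\n",
    object@scoreCutoff, object@maxGap, object@k, object@bThreshold,
    ifelse(is.na(object@minSites), "off", object@minSites),
    ifelse(is.na(object@minDelta), "off", object@minDelta)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig class %d: %d DMRs + %d non-DMRs, %d reps/group, cov %g\n",
    object@simClass, object@nDmr, object@nNonDmr, object@repsPerGroup,
    object@coverageMean))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf(
    "TrainedModel (%s, v%s): %d-bin linear classifier\n",
    object@context, object@version, length(object@weights)))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
      "\n")
  cat(sprintf("  intercept %.4f; calibration score = plogis(%.3f*dec %+.3f)\n",
              object@intercept, object@calibA, object@calibB))
})
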