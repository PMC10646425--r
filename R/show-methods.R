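setMethod("show", "AcquisitionParams", function(object) {
  cat("SPGR acquisition: FA {",
      paste(object@flipAnglesDeg, collapse = ", "), "} deg, TR ",
      object@trMs, " ms, ", object@matrixSize, "x", object@matrixSize, "x",
      object@nSlices, ", FOV ", object@fovMm, " mm\n", sep = "")
})

setMethod("show", "GasSchedule", function(object) {
  ph <- object@phases
  cat("Gas schedule (imaging every", object@imagingIntervalMin, "min):\n")
  for (i in seq_len(nrow(ph)))
    cat(sprintf("  %d. %-12s %-8s %g min\n", i, ph$label[i], ph$gas[i],
                ph$durationMin[i]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", length(object@tissues), "tissues,",
      "noise sigma", object@noiseSigma, ", seed", object@seed, "\n")
  cat("  tissues:",
      paste(vapply(object@tissues, function(t) t@label, character(1)),
            collapse = ", "), "\n")
  show(object@cine)
})

setMethod("show", "T1Map", function(object) {
  ok <- object@validMask
  cat("T1Map ", paste(dim(object@t1Ms), collapse = "x"), ": ",
      sum(ok), "/", length(ok), " valid voxels", sep = "")
  if (any(ok))
    cat(sprintf("; T1 range %.0f-%.0f ms", min(object@t1Ms[ok]),
                max(object@t1Ms[ok])))
  cat("\n")
})

setMethod("show", "T1TimeCourse", function(object) {
  cat("T1TimeCourse over", length(object@timepointsMin), "timepoints (",
      paste(object@timepointsMin, collapse = ", "), "min )\n")
  cat("  pooled myocardial T1 (ms):",
      paste(sprintf("%.1f", object@pooled), collapse = ", "), "\n")
  if (nrow(object@percentChanges)) {
    cat("  percent changes:\n")
    pc <- object@percentChanges
    for (i in seq_len(nrow(pc)))
      cat(sprintf("    %-22s %+6.1f%%\n", pc$interval[i], pc$percent[i]))
  }
})

setMethod("show", "DopplerTrace", function(object) {
  cat("DopplerTrace: ", length(object@bpu), " samples @ ",
      object@sampleRateHz, " Hz (", max(object@timeS) + 0.1, " s)",
      sep = "")
  if (nrow(object@quality))
    cat(";", sum(!object@quality$ok), "of", nrow(object@quality),
        "windows flagged")
  cat("\n")
})

setMethod("show", "StatsResult", function(object) {
  a <- object@anova
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              a$dfBetween, a$dfWithin, a$F, a$p))
  cat("Fisher LSD:", sum(object@lsd$significant), "of",
      nrow(object@lsd), "pairs significant at P < 0.05\n")
})
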