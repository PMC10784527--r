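setMethod("show", "ChromCountTable", function(object) {
    cat("ChromCountTable:", sampleId(object), "\n")
    cat("  total reads:", nTotal(object),
        "| Na:", autosomalBaseline(object), "\n")
    cat("  X:", counts(object)[["X"]], " Y:", counts(object)[["Y"]],
        " | MAPQ >=", mapqMin(object),
        if (maskApplied(object)) "| masked" else "", "\n")
})

setMethod("show", "CalibrationTable", function(object) {
    cat("CalibrationTable (", calibrationMode(object), " mode)\n", sep = "")
    cat(sprintf("  centroids: rX(1)=%.4g rX(2)=%.4g rY(1)=%.4g\n",
                centroid(object, "X", 1), centroid(object, "X", 2),
                centroid(object, "Y", 1)))
})

setMethod("show", "RatioEstimate", function(object) {
    cat(sprintf("RatioEstimate: %.5g (se %.3g) = %d / %d\n",
                object@value, object@se, object@nC, object@nA))
})

setMethod("show", "CopyCall", function(object) {
    cat(sprintf("CopyCall %s: k=%d (%s), value %.5g, z=%+.2f%s\n",
                object@axis, object@kHat, object@status, object@value,
                object@z,
                if (!is.na(object@mosaicFraction))
                    sprintf(", mosaic fraction %.2f", object@mosaicFraction)
                else ""))
})

setMethod("show", "KaryotypeCall", function(object) {
    cat("KaryotypeCall:", sampleId(object), "->", iscn(object), "\n")
    cat(sprintf("  Rx %.5g (X: %d, %s) | Ry %.5g (Y: %d, %s)\n",
                ratioValue(object@rx), kHat(object@xCall),
                callStatus(object@xCall),
                ratioValue(object@ry), kHat(object@yCall),
                callStatus(object@yCall)))
    if (length(trisomies(object)))
        cat("  trisomies:", paste(trisomies(object), collapse = ", "), "\n")
    if (length(callFlags(object)))
        cat("  flags:", paste(callFlags(object), collapse = ", "), "\n")
})

setMethod("show", "ChromCopyProfile", function(object) {
    cat("ChromCopyProfile:", sampleId(object), "\n")
    print(utils::head(profileTable(object), 5L))
    cat("  ...", nrow(profileTable(object)), "chromosomes\n")
})

setMethod("show", "SimSpec", function(object) {
    cat(sprintf("SimSpec: %dX %dY%s, %d reads, seed %d\n",
                object@xCopies, object@yCopies,
                if (length(object@trisomies))
                    paste0(" +", paste(object@trisomies, collapse = " +"))
                else "",
                object@nReads, object@seed))
    if (object@contamFraction > 0)
        cat(sprintf("  contaminant: %dX %dY at alpha=%.2f\n",
                    object@contamXCopies, object@contamYCopies,
                    object@contamFraction))
})

setMethod("show", "PowerResult", function(object) {
    cat("PowerResult:", nrow(object@replicates), "replicates over",
        nrow(object@summary), "levels\n")
    print(object@summary)
})
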