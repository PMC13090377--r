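#' @rdname ContingencyResult-class
#' @param x,object a result object.
#' @export
setGeneric("observed", function(x) standardGeneric("observed"))

#' @rdname ContingencyResult-class
#' @export
setGeneric("expectedCounts", function(x) standardGeneric("expectedCounts"))

#' @rdname ContingencyResult-class
#' @export
setGeneric("chiSquare", function(x) standardGeneric("chiSquare"))

#' @rdname ContingencyResult-class
#' @export
setGeneric("effectSize", function(x) standardGeneric("effectSize"))

#' @rdname ContingencyResult-class
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname ContingencyResult-class
#' @export
setGeneric("perBinTests", function(x) standardGeneric("perBinTests"))

#' @rdname SexQCResult-class
#' @param x a result object.
#' @export
setGeneric("perCellQC", function(x) standardGeneric("perCellQC"))

#' @rdname SexQCResult-class
#' @export
setGeneric("perSampleQC", function(x) standardGeneric("perSampleQC"))

#' @rdname SpatialBinProfile-class
#' @param x a result object.
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname SpatialBinProfile-class
#' @param scaled return the row-scaled matrix instead of raw counts?
#' @export
setGeneric("cellTypeMatrix",
    function(x, scaled = FALSE) standardGeneric("cellTypeMatrix"))

#' @rdname SpatialBinProfile-class
#' @export
setGeneric("geneMatrix", function(x) standardGeneric("geneMatrix"))

#' @rdname DensityMap-class
#' @param x a \code{DensityMap}.
#' @export
setGeneric("densityGrid", function(x) standardGeneric("densityGrid"))

# ---- accessors ----

#' @rdname ContingencyResult-class
#' @export
setMethod("observed", "ContingencyResult", function(x) x@observed)

#' @rdname ContingencyResult-class
#' @export
setMethod("expectedCounts", "ContingencyResult", function(x) x@expected)

#' @rdname ContingencyResult-class
#' @export
setMethod("chiSquare", "ContingencyResult",
    function(x) c(chi2 = x@chi2, df = x@df, p = x@pValue))

#' @rdname ContingencyResult-class
#' @export
setMethod("effectSize", "ContingencyResult", function(x) x@cramersV)

#' @rdname ContingencyResult-class
#' @export
setMethod("confInt", "ContingencyResult", function(x) x@vCI)

#' @rdname ContingencyResult-class
#' @export
setMethod("perBinTests", "ContingencyResult", function(x) x@perBin)

#' @rdname SexQCResult-class
#' @export
setMethod("perCellQC", "SexQCResult", function(x) x@perCell)

#' @rdname SexQCResult-class
#' @export
setMethod("perSampleQC", "SexQCResult", function(x) x@perSample)

#' @rdname SpatialBinProfile-class
#' @export
setMethod("binEdges", "SpatialBinProfile", function(x) x@binEdges)

#' @rdname SpatialBinProfile-class
#' @export
setMethod("cellTypeMatrix", "SpatialBinProfile",
    function(x, scaled = FALSE) if (scaled) x@cellTypeScaled else x@cellTypeCounts)

#' @rdname SpatialBinProfile-class
#' @export
setMethod("geneMatrix", "SpatialBinProfile", function(x) x@geneMeans)

#' @rdname DensityMap-class
#' @export
setMethod("densityGrid", "DensityMap", function(x) x@grid)

# ---- show methods ----

#' @rdname ContingencyResult-class
#' @export
setMethod("show", "ContingencyResult", function(object) {
    cat(sprintf("ContingencyResult: %d x %d table, N = %d\n",
        nrow(object@observed), ncol(object@observed), sum(object@observed)))
    cat(sprintf("  chi2 = %.4f (df = %d), p = %.3g\n",
        object@chi2, object@df, object@pValue))
    if (all(is.na(object@vCI)))
        cat(sprintf("  Cramer's V = %.3f\n", object@cramersV))
    else
        cat(sprintf("  Cramer's V = %.3f (95%% CI %.3f-%.3f)\n",
            object@cramersV, object@vCI[1L], object@vCI[2L]))
    if (nrow(object@perBin) > 0) {
        cat("  per-bin post-hoc (BH-adjusted):\n")
        for (i in seq_len(nrow(object@perBin)))
            cat(sprintf("    %-6s padj = %-10.3g %s\n",
                object@perBin$bin[i], object@perBin$padj[i],
                object@perBin$label[i]))
    }
    invisible(NULL)
})

#' @rdname SexQCResult-class
#' @export
setMethod("show", "SexQCResult", function(object) {
    cat(sprintf("SexQCResult: %d cells, %d samples, %d flagged contaminated\n",
        nrow(object@perCell), nrow(object@perSample),
        sum(object@perCell$contaminated)))
    invisible(NULL)
})

#' @rdname SpatialBinProfile-class
#' @export
setMethod("show", "SpatialBinProfile", function(object) {
    cat(sprintf(
        "SpatialBinProfile: %d bins, %d cell types, %d genes, %d cells binned\n",
        object@nBins, nrow(object@cellTypeCounts), nrow(object@geneMeans),
        sum(object@cellTypeCounts)))
    invisible(NULL)
})

#' @rdname DensityMap-class
#' @export
setMethod("show", "DensityMap", function(object) {
    cat(sprintf("DensityMap: %d x %d pixels (%.1f um), total mass %.1f%s\n",
        nrow(object@grid), ncol(object@grid), object@pixelSize,
        sum(object@grid),
        if (is.na(object@bandwidth)) "" else
            sprintf(", smoothed (bw = %.1f um)", object@bandwidth)))
    invisible(NULL)
})
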