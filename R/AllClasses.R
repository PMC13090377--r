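#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ContingencyResult: association between cell identity and OR-count category
#'
#' Container for the contingency analysis linking cell identity (e.g. INP vs
#' iOSN) to OR-count categories (0/1/2/3+): the observed and expected tables,
#' the Pearson chi-square statistic (no continuity correction), Cramer's V with
#' an optional bootstrap confidence interval, and per-bin post-hoc tests with
#' Benjamini-Hochberg adjusted p-values and significance labels.
#'
#' @slot observed non-negative integer matrix of observed counts.
#' @slot expected numeric matrix of expected counts under independence.
#' @slot chi2 Pearson chi-square statistic.
#' @slot df degrees of freedom, \eqn{(r-1)(c-1)}.
#' @slot pValue two-sided p-value from the chi-square survival function.
#' @slot cramersV effect size \eqn{V = \sqrt{\chi^2 / (N \min(r-1, c-1))}}.
#' @slot vCI numeric length-2 bootstrap percentile CI for V, or NA.
#' @slot perBin \code{DataFrame} of per-bin post-hoc results (bin, chi2, p,
#'   padj, label), possibly with zero rows.
#'
#' @seealso \code{\link{orContingencyTest}}, \code{\link{cramersV}},
#'   \code{\link{posthocPerBin}}
#' @export
setClass("ContingencyResult",
    slots = c(
        observed = "matrix",
        expected = "matrix",
        chi2     = "numeric",
        df       = "integer",
        pValue   = "numeric",
        cramersV = "numeric",
        vCI      = "numeric",
        perBin   = "DataFrame"
    )
)

setValidity("ContingencyResult", function(object) {
    msg <- character()
    obs <- object@observed
    if (any(obs < 0) || any(obs != round(obs)))
        msg <- c(msg, "'observed' must hold non-negative integers")
    if (!all(dim(object@expected) == dim(obs)))
        msg <- c(msg, "'expected' dimensions must match 'observed'")
    if (sum(obs) > 0 &&
        !isTRUE(all.equal(rowSums(object@expected), rowSums(obs + 0),
                          check.attributes = FALSE)))
        msg <- c(msg, "expected row sums must equal observed row sums")
    if (!is.na(object@cramersV) &&
        (object@cramersV < 0 || object@cramersV > 1 + 1e-12))
        msg <- c(msg, "'cramersV' must lie in [0, 1]")
    if (length(object@vCI) != 2L)
        msg <- c(msg, "'vCI' must have length 2 (use c(NA, NA) if absent)")
    if (nrow(object@perBin) > 0 &&
        any(object@perBin$padj + 1e-12 < object@perBin$p, na.rm = TRUE))
        msg <- c(msg, "adjusted p-values must be >= raw p-values")
    if (length(msg)) msg else TRUE
})

#' SexQCResult: sex- and erythroid-based contamination QC
#'
#' Per-cell sex scores and calls, erythroid scores and flags, and per-sample
#' inferred sex with removal fractions, as produced by \code{\link{runSexQC}}.
#'
#' @slot perCell \code{DataFrame} with one row per cell: \code{cell_id},
#'   \code{sample}, \code{sex_score}, \code{sex_call}, \code{erythroid_score},
#'   \code{erythroid_high}, \code{contaminated}.
#' @slot perSample \code{DataFrame} with one row per sample:
#'   \code{sample}, \code{inferred_sex}, \code{n_cells}, \code{n_flagged},
#'   \code{removal_fraction}.
#'
#' @export
setClass("SexQCResult",
    slots = c(perCell = "DataFrame", perSample = "DataFrame")
)

setValidity("SexQCResult", function(object) {
    pc <- object@perCell
    ps <- object@perSample
    msg <- character()
    need <- c("cell_id", "sample", "sex_score", "sex_call",
              "erythroid_score", "erythroid_high", "contaminated")
    if (!all(need %in% colnames(pc)))
        msg <- c(msg, "perCell lacks required columns")
    else if (any(pc$contaminated & !pc$erythroid_high))
        msg <- c(msg, "contaminated cells must be erythroid_high")
    if (nrow(ps) > 0 && (any(ps$removal_fraction < 0) ||
                         any(ps$removal_fraction > 1)))
        msg <- c(msg, "removal_fraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' SpatialBinProfile: axis-binned cell-type and gene profiles
#'
#' Profiles along a normalized epithelial axis split into equal-width bins:
#' cell-type occupancy (raw and row-scaled, cell types as rows) and mean gene
#' expression per bin (genes as rows). Empty bins carry NA in the gene matrix.
#'
#' @slot axis numeric matrix of polyline vertices (x, y) in micrometres.
#' @slot nBins number of equal-width bins on normalized arc length [0, 1].
#' @slot binEdges numeric vector of length nBins + 1 spanning [0, 1].
#' @slot cellTypeCounts cell types x bins matrix of raw counts.
#' @slot cellTypeScaled cell types x bins matrix, each row divided by its
#'   maximum (all-zero rows left at zero).
#' @slot geneMeans genes x bins matrix of per-bin mean expression (NA for
#'   empty bins); may have zero rows.
#'
#' @export
setClass("SpatialBinProfile",
    slots = c(
        axis           = "matrix",
        nBins          = "integer",
        binEdges       = "numeric",
        cellTypeCounts = "matrix",
        cellTypeScaled = "matrix",
        geneMeans      = "matrix"
    )
)

setValidity("SpatialBinProfile", function(object) {
    msg <- character()
    e <- object@binEdges
    if (length(e) != object@nBins + 1L || any(diff(e) <= 0) ||
        abs(e[1L]) > 1e-12 || abs(e[length(e)] - 1) > 1e-12)
        msg <- c(msg, "binEdges must strictly increase and cover [0, 1]")
    if (ncol(object@cellTypeCounts) != object@nBins)
        msg <- c(msg, "cellTypeCounts must have nBins columns")
    sc <- object@cellTypeScaled
    if (nrow(sc) > 0) {
        mx <- apply(sc, 1L, max)
        if (any(mx > 1 + 1e-12))
            msg <- c(msg, "row-scaled rows must have maximum <= 1")
    }
    if (length(msg)) msg else TRUE
})

#' DensityMap: 2-D transcript density grid
#'
#' A pixel grid of summed transcript counts (typically olfactory-receptor
#' transcripts) over segmented spatial cells, with optional Gaussian
#' smoothing. The unsmoothed grid conserves the total transcript count of the
#' assigned cells.
#'
#' @slot grid numeric matrix, rows indexing y pixels, columns x pixels.
#' @slot xBreaks,yBreaks pixel edges in micrometres.
#' @slot pixelSize pixel edge length in micrometres.
#' @slot bandwidth Gaussian smoothing bandwidth (sd, micrometres); NA if
#'   unsmoothed.
#'
#' @export
setClass("DensityMap",
    slots = c(
        grid      = "matrix",
        xBreaks   = "numeric",
        yBreaks   = "numeric",
        pixelSize = "numeric",
        bandwidth = "numeric"
    )
)

setValidity("DensityMap", function(object) {
    msg <- character()
    if (object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be positive")
    if (nrow(object@grid) != length(object@yBreaks) - 1L ||
        ncol(object@grid) != length(object@xBreaks) - 1L)
        msg <- c(msg, "grid dimensions must match pixel breaks")
    if (length(msg)) msg else TRUE
})
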