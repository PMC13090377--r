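#' Remove low-count spatial cells
#'
#' Keeps cells whose total transcript count is at least
#' \code{minTranscripts} (cells with fewer are removed; the boundary cell is
#' kept). The default of 12 is the usual floor for MERFISH-style
#' segmented-cell tables.
#'
#' @param sce a spatial cohort.
#' @param minTranscripts minimum total transcripts (default 12).
#' @return the filtered cohort; \code{metadata()$lowCountRemoval} records
#'   counts kept/removed and the threshold.
#' @export
filterLowCountCells <- function(sce, minTranscripts = 12) {
    tot <- Matrix::colSums(assay(sce, "counts"))
    keep <- tot >= minTranscripts
    out <- sce[, keep]
    metadata(out)$lowCountRemoval <- c(
        threshold = minTranscripts, kept = sum(keep), removed = sum(!keep))
    out
}

#' Project positions onto an axis polyline
#'
#' Maps each cell position to the normalized arc length \eqn{s \in [0, 1]}
#' of the nearest point on a user-supplied polyline (the anatomical axis,
#' e.g. anterior-posterior through the epithelium). Ties between segments
#' resolve to the lower-s segment.
#'
#' @param positions n x 2 matrix of (x, y) in micrometres.
#' @param polyline m x 2 matrix of ordered vertices (m >= 2, positive total
#'   length).
#' @return numeric vector of s values in [0, 1].
#' @export
projectToAxis <- function(positions, polyline) {
    positions <- as.matrix(positions); polyline <- as.matrix(polyline)
    if (nrow(polyline) < 2L) stop("polyline needs at least 2 vertices")
    seg <- diff(polyline)
    len <- sqrt(rowSums(seg^2))
    if (sum(len) <= 0) stop("degenerate polyline (zero length)")
    cum <- c(0, cumsum(len))
    total <- cum[length(cum)]
    n <- nrow(positions)
    bestD <- rep(Inf, n); bestS <- numeric(n)
    for (k in seq_len(nrow(seg))) {
        if (len[k] == 0) next
        a <- polyline[k, ]; d <- seg[k, ]
        t <- ((positions[, 1L] - a[1L]) * d[1L] +
              (positions[, 2L] - a[2L]) * d[2L]) / (len[k]^2)
        t <- pmin(1, pmax(0, t))
        px <- a[1L] + t * d[1L]; py <- a[2L] + t * d[2L]
        dist <- sqrt((positions[, 1L] - px)^2 + (positions[, 2L] - py)^2)
        s <- (cum[k] + t * len[k]) / total
        upd <- dist < bestD - 1e-12  # strict: ties keep the lower-s segment
        bestD[upd] <- dist[upd]; bestS[upd] <- s[upd]
    }
    bestS
}

#' Assign axis positions to equal-width bins
#'
#' Bins \eqn{[i/n, (i+1)/n)} with the last bin closed at 1; 1-based indices.
#'
#' @param s normalized positions in [0, 1].
#' @param nBins number of bins (default 50).
#' @return integer bin index per position.
#' @export
binAxis <- function(s, nBins = 50) {
    if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
    pmin(nBins, floor(s * nBins) + 1L)
}

#' Cell-type occupancy along the axis
#'
#' Tabulates cells per (cell type, bin) and produces a row-scaled version in
#' which each cell-type row is divided by its maximum (all-zero rows stay
#' zero), the usual display normalization for axis profile heatmaps.
#'
#' @param bins integer bin indices (\code{\link{binAxis}}).
#' @param cellTypes per-cell identity labels.
#' @param nBins total number of bins.
#' @return list of two cell-types x bins matrices: \code{raw}, \code{scaled}.
#' @export
cellTypeBinMatrix <- function(bins, cellTypes, nBins = 50) {
    ct <- if (is.factor(cellTypes)) cellTypes else factor(cellTypes)
    tab <- table(ct, factor(bins, levels = seq_len(nBins)))
    raw <- matrix(as.integer(tab), nrow = nrow(tab), ncol = nBins,
                  dimnames = dimnames(tab))
    mx <- apply(raw, 1L, max)
    scaled <- raw / ifelse(mx > 0, mx, 1)
    list(raw = raw, scaled = scaled)
}

#' Mean gene expression per axis bin
#'
#' @param sce a cohort with a \code{logcounts} assay (computed with defaults
#'   if absent).
#' @param bins integer bin index per cell.
#' @param genes gene ids to profile (must exist).
#' @param nBins total number of bins.
#' @return genes x bins matrix of per-bin means; empty bins yield NA.
#' @export
geneBinProfile <- function(sce, bins, genes, nBins = 50) {
    if (!"logcounts" %in% assayNames(sce)) sce <- logNormalizeCounts(sce)
    bad <- setdiff(genes, rownames(sce))
    if (length(bad)) stop("unknown gene id: ", paste(bad, collapse = ", "))
    v <- as.matrix(assay(sce, "logcounts")[genes, , drop = FALSE])
    out <- matrix(NA_real_, length(genes), nBins,
                  dimnames = list(genes, seq_len(nBins)))
    for (b in seq_len(nBins)) {
        i <- which(bins == b)
        if (length(i)) out[, b] <- rowMeans(v[, i, drop = FALSE])
    }
    out
}

#' Build a combined axis-bin profile
#'
#' Projects spatial cells onto the axis polyline, bins them, and assembles a
#' \code{\link{SpatialBinProfile-class}} with cell-type occupancy (raw and
#' row-scaled) and optional per-bin gene means.
#'
#' @param sce a spatial cohort with \code{x}, \code{y} in \code{colData}.
#' @param polyline axis vertices (m x 2 matrix, micrometres).
#' @param nBins number of equal-width bins (default 50).
#' @param genes optional gene ids to profile.
#' @return a \code{SpatialBinProfile}.
#' @export
spatialBinProfile <- function(sce, polyline, nBins = 50, genes = NULL) {
    cd <- colData(sce)
    s <- projectToAxis(cbind(cd$x, cd$y), polyline)
    bins <- binAxis(s, nBins)
    ctm <- cellTypeBinMatrix(bins, cd$cell_type, nBins)
    gm <- if (is.null(genes))
        matrix(numeric(0), 0L, nBins)
    else geneBinProfile(sce, bins, genes, nBins)
    new("SpatialBinProfile", axis = as.matrix(polyline),
        nBins = as.integer(nBins),
        binEdges = seq(0, 1, length.out = nBins + 1L),
        cellTypeCounts = ctm$raw, cellTypeScaled = ctm$scaled,
        geneMeans = gm)
}

# separable Gaussian blur with zero padding; conserves mass for
# interior-supported fields up to truncation of the kernel tails
.gaussBlur <- function(g, sigmaPix) {
    r <- max(1L, ceiling(3 * sigmaPix))
    k <- stats::dnorm(seq(-r, r), sd = sigmaPix)
    k <- k / sum(k)
    convRows <- function(m) {
        out <- matrix(0, nrow(m), ncol(m))
        for (i in seq_along(k)) {
            off <- i - r - 1L
            src <- seq_len(nrow(m)) + off
            ok <- src >= 1L & src <= nrow(m)
            out[ok, ] <- out[ok, ] + k[i] * m[src[ok], , drop = FALSE]
        }
        out
    }
    t(convRows(t(convRows(g))))
}

#' Olfactory-receptor transcript density map
#'
#' Sums OR transcript counts per cell into a 2-D pixel grid over the tissue,
#' optionally Gaussian-smoothed. The unsmoothed grid conserves the total OR
#' transcript count of the assigned cells.
#'
#' @param sce a spatial cohort with \code{x}, \code{y} positions and
#'   \code{is_or} gene annotation.
#' @param pixelSize pixel edge length in micrometres (> 0).
#' @param bandwidth optional Gaussian sd in micrometres.
#' @return a \code{\link{DensityMap-class}}.
#' @export
orDensityMap <- function(sce, pixelSize = 10, bandwidth = NULL) {
    if (pixelSize <= 0) stop("pixelSize must be positive")
    cd <- colData(sce)
    orSub <- orGenes(sce)
    w <- Matrix::colSums(assay(orSub, "counts"))
    x <- cd$x; y <- cd$y
    # pad the grid by the kernel radius so smoothing cannot clip mass
    pad <- if (!is.null(bandwidth) && bandwidth > 0)
        ceiling(3 * bandwidth / pixelSize) * pixelSize else 0
    xb <- seq(floor(min(x) / pixelSize) * pixelSize - pad,
              ceiling(max(x) / pixelSize) * pixelSize + pixelSize + pad,
              by = pixelSize)
    yb <- seq(floor(min(y) / pixelSize) * pixelSize - pad,
              ceiling(max(y) / pixelSize) * pixelSize + pixelSize + pad,
              by = pixelSize)
    xi <- findInterval(x, xb, rightmost.closed = TRUE)
    yi <- findInterval(y, yb, rightmost.closed = TRUE)
    g <- matrix(0, length(yb) - 1L, length(xb) - 1L)
    for (j in seq_along(w))
        g[yi[j], xi[j]] <- g[yi[j], xi[j]] + w[j]
    bw <- NA_real_
    if (!is.null(bandwidth) && bandwidth > 0) {
        g <- .gaussBlur(g, bandwidth / pixelSize)
        bw <- bandwidth
    }
    new("DensityMap", grid = g, xBreaks = xb, yBreaks = yb,
        pixelSize = pixelSize, bandwidth = bw)
}

#' Counts of high-dominance spatial cells per cell type
#'
#' Within a domain mask (e.g. the olfactory plus respiratory epithelium
#' domains), counts cells whose dominance score strictly exceeds the
#' threshold, per cell type.
#'
#' @param summary per-cell OR summary (\code{\link{orCellSummary}}) for
#'   spatial cells, carrying a \code{cell_type} column.
#' @param domainMask logical vector selecting the cells inside the domain
#'   (default all).
#' @param threshold dominance-score cutoff (default 3, strict >).
#' @return named integer vector of counts per cell type.
#' @export
spatialHighDominanceSummary <- function(summary, domainMask = NULL,
                                        threshold = 3) {
    if (is.null(domainMask)) domainMask <- rep(TRUE, nrow(summary))
    sel <- domainMask & summary$dominance > threshold
    tab <- table(factor(summary$cell_type)[sel])
    stats::setNames(as.integer(tab), names(tab))
}
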