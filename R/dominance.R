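#' Per-cell OR expression statistics
#'
#' For each cell of an OR-restricted count matrix, returns the counts of the
#' most- and second-most-expressed receptor, the number of expressed
#' receptors (count >= 1), and the dominant receptor's gene id. Ties at the
#' top are broken lexicographically by gene id; cells without detectable OR
#' expression have no dominant receptor.
#'
#' @param orSce an OR-only cohort (see \code{\link{orGenes}}), or a genes x
#'   cells count matrix restricted to OR genes.
#' @return \code{DataFrame}: \code{cell_id}, \code{x1}, \code{x2},
#'   \code{n_expressed}, \code{dominant_or}.
#' @export
perCellORStats <- function(orSce) {
    m <- if (is(orSce, "SummarizedExperiment")) assay(orSce, "counts") else orSce
    m <- as.matrix(m)
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("g%d", seq_len(nrow(m)))
    ord <- order(ids)  # lexicographic tie-break
    m <- m[ord, , drop = FALSE]
    ids <- ids[ord]
    nc <- ncol(m)
    x1 <- numeric(nc); x2 <- numeric(nc); nex <- integer(nc)
    dom <- rep(NA_character_, nc)
    for (j in seq_len(nc)) {
        v <- m[, j]
        nex[j] <- sum(v >= 1)
        if (nrow(m) == 0L) next
        top <- which.max(v)  # first max = lexicographically first gene
        x1[j] <- v[top]
        x2[j] <- if (nrow(m) > 1L) max(v[-top]) else 0
        if (x1[j] > 0) dom[j] <- ids[top]
    }
    DataFrame(cell_id = colnames(m) %||% sprintf("c%d", seq_len(nc)),
              x1 = x1, x2 = x2, n_expressed = nex, dominant_or = dom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scaled OR dominance score
#'
#' \deqn{D = \frac{x_1 - x_2}{x_1 + x_2 + \varepsilon} \cdot \log(1 + x_1)}
#' where \eqn{x_1 \ge x_2 \ge 0} are the counts of the top and second OR and
#' \eqn{\varepsilon} is a small stabilizing constant. The relative-difference
#' factor captures how strongly one receptor dominates; the log factor
#' down-weights cells whose top receptor is weakly expressed. Cells without
#' detectable OR expression (\eqn{x_1 = 0}) score zero. Natural logarithm by
#' default; the base is configurable.
#'
#' @param x1,x2 numeric vectors of top and second OR counts.
#' @param epsilon stabilizing constant (default 1e-9).
#' @param logBase base of the logarithm (default \code{exp(1)}).
#' @return numeric vector of scores in \eqn{[0, \log(1 + x_1)]}.
#' @export
dominanceScore <- function(x1, x2, epsilon = 1e-9, logBase = exp(1)) {
    if (any(x2 > x1)) stop("x2 must not exceed x1")
    if (any(x2 < 0)) stop("counts must be non-negative")
    (x1 - x2) / (x1 + x2 + epsilon) * log(1 + x1, base = logBase)
}

.DOM_BINS <- c("<=0.5", "0.5-1", "1-1.5", "1.5-2", ">2")

#' Bin dominance scores at fixed thresholds
#'
#' Intervals [0, 0.5], (0.5, 1], (1, 1.5], (1.5, 2], (2, Inf): each boundary
#' belongs to the lower-labelled bin.
#'
#' @param D numeric scores, all >= 0.
#' @return factor with levels \code{"<=0.5", "0.5-1", "1-1.5", "1.5-2", ">2"}.
#' @export
binDominance <- function(D) {
    if (any(D < 0)) stop("dominance scores must be non-negative")
    cut(D, breaks = c(-Inf, 0.5, 1, 1.5, 2, Inf), labels = .DOM_BINS,
        right = TRUE)
}

#' Classify high-dominance cells
#'
#' TRUE iff dominance score strictly exceeds \code{dMin}, the top OR count is
#' at least \code{xMin}, and at most \code{maxCo} receptors are co-expressed.
#'
#' @param D,x1,nExpressed per-cell score, top OR count, number of expressed
#'   ORs.
#' @param dMin,xMin,maxCo rule thresholds (defaults 1, 1, 3).
#' @return logical vector.
#' @export
classifyHighDominance <- function(D, x1, nExpressed, dMin = 1, xMin = 1,
                                  maxCo = 3) {
    D > dMin & x1 >= xMin & nExpressed <= maxCo
}

#' OR-count category
#'
#' Maps the number of expressed receptors to the categories 0, 1, 2, 3+.
#'
#' @param n integer counts of expressed ORs.
#' @return factor with levels \code{"0", "1", "2", "3+"}.
#' @export
orCountCategory <- function(n) {
    if (any(n < 0)) stop("counts must be non-negative")
    factor(ifelse(n >= 3, "3+", as.character(n)),
           levels = c("0", "1", "2", "3+"))
}

#' Full per-cell OR summary
#'
#' Combines \code{\link{perCellORStats}}, \code{\link{dominanceScore}},
#' \code{\link{binDominance}}, \code{\link{classifyHighDominance}} and
#' \code{\link{orCountCategory}} over a cohort, restricted to its OR genes.
#'
#' @param sce a cohort with \code{is_or} annotated (the OR submatrix is taken
#'   internally), or an already OR-restricted cohort/matrix.
#' @param epsilon,logBase passed to \code{\link{dominanceScore}}.
#' @param dMin,xMin,maxCo passed to \code{\link{classifyHighDominance}}.
#' @param requireTwoTranscripts if TRUE, cells with fewer than two OR
#'   transcripts in total score zero (the stricter reading used for
#'   imaging-based panels); default FALSE scores every OR-positive cell.
#' @return \code{DataFrame} with columns \code{cell_id}, \code{x1},
#'   \code{x2}, \code{n_expressed}, \code{dominant_or}, \code{dominance},
#'   \code{dominance_bin}, \code{high_dominance}, \code{or_category}, plus
#'   \code{cell_type}/\code{stage}/\code{donor} when available.
#' @export
orCellSummary <- function(sce, epsilon = 1e-9, logBase = exp(1), dMin = 1,
                          xMin = 1, maxCo = 3, requireTwoTranscripts = FALSE) {
    orSub <- if (is(sce, "SummarizedExperiment") &&
                 "is_or" %in% colnames(rowData(sce)) &&
                 !all(rowData(sce)$is_or)) orGenes(sce) else sce
    st <- perCellORStats(orSub)
    D <- dominanceScore(st$x1, st$x2, epsilon, logBase)
    if (requireTwoTranscripts)
        D[st$x1 + st$x2 < 2] <- 0
    st$dominance <- D
    st$dominance_bin <- binDominance(D)
    st$high_dominance <- classifyHighDominance(D, st$x1, st$n_expressed,
                                               dMin, xMin, maxCo)
    st$or_category <- orCountCategory(st$n_expressed)
    if (is(sce, "SummarizedExperiment")) {
        cd <- colData(sce)
        for (col in intersect(c("cell_type", "stage", "donor"), colnames(cd)))
            st[[col]] <- cd[[col]]
    }
    st
}

#' Frequency table of dominant receptors in high-dominance cells
#'
#' Counts, per dominant OR gene, the high-dominance cells carrying it,
#' sorted descending with lexicographic tie-break; optionally stratified.
#'
#' @param summary output of \code{\link{orCellSummary}}.
#' @param topK number of receptors to keep (default 20).
#' @param groupBy optional column of \code{summary} to stratify by (e.g.
#'   "stage"); counts are then reported per group.
#' @return \code{DataFrame} of (\code{or_gene}, \code{n_cells}) rows, plus a
#'   \code{group} column when stratified. Empty when no high-dominance cell
#'   exists.
#' @export
dominantORFrequency <- function(summary, topK = 20, groupBy = NULL) {
    hd <- summary[summary$high_dominance & !is.na(summary$dominant_or), ,
                  drop = FALSE]
    tallyOne <- function(d) {
        if (nrow(d) == 0L)
            return(DataFrame(or_gene = character(0), n_cells = integer(0)))
        tab <- table(d$dominant_or)
        ord <- order(-as.integer(tab), names(tab))
        tab <- tab[ord][seq_len(min(topK, length(tab)))]
        DataFrame(or_gene = names(tab), n_cells = as.integer(tab))
    }
    if (is.null(groupBy)) return(tallyOne(hd))
    groups <- split(seq_len(nrow(hd)), hd[[groupBy]])
    out <- lapply(names(groups), function(g) {
        t <- tallyOne(hd[groups[[g]], , drop = FALSE])
        t$group <- rep(g, nrow(t))
        t
    })
    do.call(rbind, out)
}

#' Diagonal ordering of cells by dominant receptor
#'
#' Orders cells by (dominant OR, descending top-OR count) and receptors by
#' first appearance in that cell ordering, so that cells sharing a dominant
#' receptor form contiguous blocks and the cell-by-OR matrix shows a
#' diagonal pattern. OR-negative cells are placed last, in input order.
#'
#' @param summary output of \code{\link{orCellSummary}} (or
#'   \code{\link{perCellORStats}}).
#' @return list with integer \code{cellOrder} and character \code{orOrder}.
#' @export
diagonalOrder <- function(summary) {
    pos <- !is.na(summary$dominant_or)
    posIdx <- which(pos)
    o <- posIdx[order(summary$dominant_or[posIdx], -summary$x1[posIdx])]
    cellOrder <- c(o, which(!pos))
    orOrder <- unique(summary$dominant_or[o])
    list(cellOrder = cellOrder, orOrder = orOrder)
}

#' Per-chromosome OR gene counts and expression totals
#'
#' @param sce a cohort (restricted internally to OR genes).
#' @return \code{DataFrame}: \code{chromosome}, \code{n_or_genes},
#'   \code{total_expression} (summed raw counts). Genes without a chromosome
#'   label are bucketed as "unknown". Totals are conserved: the expression
#'   column sums to the cohort's total OR counts.
#' @export
chromosomeProfile <- function(sce) {
    orSub <- if ("is_or" %in% colnames(rowData(sce))) orGenes(sce) else sce
    chrom <- as.character(rowData(orSub)$chromosome)
    chrom[is.na(chrom) | chrom == ""] <- "unknown"
    expr <- Matrix::rowSums(assay(orSub, "counts"))
    byChr <- split(seq_along(chrom), chrom)
    DataFrame(
        chromosome = names(byChr),
        n_or_genes = unname(vapply(byChr, length, integer(1))),
        total_expression = unname(vapply(byChr, function(i) sum(expr[i]),
                                         numeric(1))))
}
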