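#' @importFrom Matrix readMM writeMM sparseMatrix t colSums rowSums Diagonal
#' @importFrom SummarizedExperiment assay assay<- assayNames rowData colData colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom utils read.delim write.table
NULL

.GENE_COLS <- c("gene_id", "symbol", "is_or", "or_class", "chromosome",
                "marker_role")
.CELL_COLS <- c("cell_id", "donor", "stage", "cell_type", "modality")

#' Validate a cohort object
#'
#' Checks the invariants of the count container: non-negative integral counts,
#' unique gene and cell identifiers, consistent gene annotation (an OR class
#' implies the OR flag), and positions present exactly for spatial cells.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay, gene
#'   annotation columns in \code{rowData} and cell annotation columns in
#'   \code{colData}.
#' @return \code{sce}, invisibly; errors describe the first violated invariant.
#' @export
validateCohort <- function(sce) {
    counts <- assay(sce, "counts")
    if (any(counts@x < 0))
        stop("counts must be non-negative")
    if (any(counts@x != round(counts@x)))
        stop("counts must be integral")
    if (anyDuplicated(rownames(sce)))
        stop("gene ids must be unique")
    if (anyDuplicated(colnames(sce)))
        stop("cell ids must be unique")
    rd <- rowData(sce)
    if (all(c("is_or", "or_class") %in% colnames(rd)) &&
        any(rd$or_class != "none" & !rd$is_or))
        stop("or_class other than 'none' requires is_or = TRUE")
    cd <- colData(sce)
    if ("modality" %in% colnames(cd) && "x" %in% colnames(cd)) {
        sp <- cd$modality == "spatial"
        if (any(sp & (is.na(cd$x) | is.na(cd$y))))
            stop("spatial cells must carry (x, y) positions")
        if (any(!sp & !(is.na(cd$x) & is.na(cd$y))))
            stop("positions are only allowed for spatial cells")
    }
    invisible(sce)
}

.asSparseCounts <- function(m) {
    m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    m
}

#' Assemble a cohort from counts and annotations
#'
#' @param counts genes x cells matrix of non-negative integer counts.
#' @param genes data.frame-like gene annotation with at least \code{gene_id};
#'   missing standard columns (\code{symbol}, \code{is_or}, \code{or_class},
#'   \code{chromosome}, \code{marker_role}) are filled with defaults.
#' @param cells data.frame-like cell annotation with at least \code{cell_id}.
#' @return a validated \code{SingleCellExperiment}.
#' @export
makeCohort <- function(counts, genes, cells) {
    genes <- as.data.frame(genes)
    cells <- as.data.frame(cells)
    if (!"gene_id" %in% colnames(genes)) stop("genes must contain 'gene_id'")
    if (!"cell_id" %in% colnames(cells)) stop("cells must contain 'cell_id'")
    if (!"symbol" %in% colnames(genes)) genes$symbol <- genes$gene_id
    if (!"is_or" %in% colnames(genes)) genes$is_or <- rep(FALSE, nrow(genes))
    if (!"or_class" %in% colnames(genes))
        genes$or_class <- rep("none", nrow(genes))
    if (!"chromosome" %in% colnames(genes))
        genes$chromosome <- rep("unknown", nrow(genes))
    if (!"marker_role" %in% colnames(genes))
        genes$marker_role <- rep("none", nrow(genes))
    if (!"modality" %in% colnames(cells))
        cells$modality <- rep("snrna", nrow(cells))
    counts <- .asSparseCounts(counts)
    if (nrow(counts) != nrow(genes))
        stop(sprintf("dimension mismatch: %d matrix rows vs %d genes",
                     nrow(counts), nrow(genes)))
    if (ncol(counts) != nrow(cells))
        stop(sprintf("dimension mismatch: %d matrix columns vs %d cells",
                     ncol(counts), nrow(cells)))
    dimnames(counts) <- list(genes$gene_id, cells$cell_id)
    sce <- SingleCellExperiment(assays = list(counts = counts),
                                rowData = genes, colData = cells)
    validateCohort(sce)
    sce
}

#' Read a cohort from Matrix Market plus sidecar tables
#'
#' Reads a sparse count matrix in Matrix Market coordinate format together
#' with tab-delimited gene and cell annotation sidecars (header row, UTF-8).
#' Both orientations found in the wild are accepted: genes-as-rows or
#' cells-as-rows; the orientation is resolved against the sidecar row counts
#' (and, for square matrices, an \code{orientation:} header comment). A
#' dimension mismatch is an error, never a silent truncation.
#'
#' @param matrixPath path to the \code{.mtx} file.
#' @param genesPath path to the tab-delimited gene annotation.
#' @param cellsPath path to the tab-delimited cell annotation.
#' @return a validated \code{SingleCellExperiment} (genes as rows).
#' @export
readCohort <- function(matrixPath, genesPath, cellsPath) {
    for (p in c(matrixPath, genesPath, cellsPath))
        if (!file.exists(p)) stop("file not found: ", p)
    m <- readMM(matrixPath)
    genes <- read.delim(genesPath, stringsAsFactors = FALSE)
    cells <- read.delim(cellsPath, stringsAsFactors = FALSE)
    ng <- nrow(genes); nc <- nrow(cells)
    d <- dim(m)
    if (all(d == c(nc, ng)) && !all(d == c(ng, nc))) {
        m <- Matrix::t(m)
    } else if (all(d == c(ng, nc)) && !all(d == c(nc, ng))) {
        # genes-as-rows, nothing to do
    } else if (all(d == c(ng, nc))) {
        # square (ng == nc): fall back to the header comment, default
        # cells-as-rows (the orientation this package writes)
        hdr <- readLines(matrixPath, n = 5L)
        cellRows <- !any(grepl("orientation:\\s*genes_x_cells", hdr))
        if (cellRows) m <- Matrix::t(m)
    } else {
        stop(sprintf(
            "dimension mismatch: matrix is %d x %d but sidecars describe %d genes and %d cells",
            d[1L], d[2L], ng, nc))
    }
    makeCohort(m, genes, cells)
}

#' Write a cohort as Matrix Market plus sidecar tables
#'
#' Writes \code{matrix.mtx} in coordinate format (1-based, cells as rows,
#' with the orientation recorded in a header comment), plus tab-delimited
#' \code{genes.tsv} and \code{cells.tsv}. Lossless under
#' \code{\link{readCohort}}.
#'
#' @param sce a validated cohort.
#' @param outDir output directory, created if absent.
#' @return named character vector of the three file paths, invisibly.
#' @export
writeCohort <- function(sce, outDir) {
    validateCohort(sce)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
    mtx <- file.path(outDir, "matrix.mtx")
    writeMM(Matrix::t(assay(sce, "counts")), mtx)
    lines <- readLines(mtx)
    writeLines(c(lines[1L], "% orientation: cells_x_genes", lines[-1L]), mtx)
    gf <- file.path(outDir, "genes.tsv")
    cf <- file.path(outDir, "cells.tsv")
    write.table(as.data.frame(rowData(sce)), gf, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    cd <- as.data.frame(colData(sce))
    write.table(cd, cf, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(c(matrix = mtx, genes = gf, cells = cf))
}

#' Per-cell depth normalization with log transform
#'
#' Scales each cell to a common depth and applies \code{log1p}:
#' \eqn{v = \log(1 + s \cdot x / t)} for count \eqn{x}, cell total \eqn{t}
#' and scale factor \eqn{s}. Cells with zero total yield all-zero columns.
#' The raw counts are left untouched; dominance scoring and low-count
#' filtering are defined on raw counts.
#'
#' @param sce a cohort.
#' @param scaleFactor target depth \eqn{s > 0} (default 10,000, the common
#'   single-cell convention).
#' @return \code{sce} with a \code{logcounts} assay added.
#' @export
logNormalizeCounts <- function(sce, scaleFactor = 1e4) {
    if (scaleFactor <= 0) stop("scaleFactor must be positive")
    counts <- assay(sce, "counts")
    tot <- Matrix::colSums(counts)
    scl <- ifelse(tot > 0, scaleFactor / tot, 0)
    ln <- counts %*% Diagonal(x = scl)
    ln@x <- log1p(ln@x)
    dimnames(ln) <- dimnames(counts)
    assay(sce, "logcounts") <- ln
    sce
}

#' Subset genes by an annotation predicate
#'
#' @param sce a cohort.
#' @param predicate either a logical vector over genes or a function mapping
#'   \code{rowData(sce)} to one (e.g. \code{function(g) g$is_or}).
#' @return the gene-subset cohort; cell order and counts are unchanged. A
#'   predicate matching no gene yields a 0-gene cohort with a warning.
#' @export
subsetGenes <- function(sce, predicate) {
    keep <- if (is.function(predicate)) predicate(rowData(sce)) else predicate
    keep[is.na(keep)] <- FALSE
    if (!is.logical(keep) || length(keep) != nrow(sce))
        stop("predicate must yield one logical per gene")
    if (!any(keep)) warning("predicate matches no genes; returning 0-gene cohort")
    sce[keep, ]
}

#' Restrict a cohort to its olfactory-receptor genes
#'
#' @param sce a cohort whose \code{rowData} carries the \code{is_or} flag.
#' @return the OR-only cohort.
#' @export
orGenes <- function(sce) {
    subsetGenes(sce, function(g) g$is_or)
}
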