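#' @importFrom stats median mad quantile setNames
NULL

#' Basic per-cell quality filters
#'
#' Removes cells with too few detected genes or UMIs, excessive mitochondrial
#' content, or outlying library complexity / mitochondrial content under a
#' median-absolute-deviation rule. A cell is removed iff
#' \code{n_genes < minGenes}, \code{n_umis < minUMIs},
#' \code{pct_mito > maxMitoPct}, or any of log10(n_umis), log10(n_genes),
#' pct_mito deviates from its cohort median by more than \code{madK} MADs
#' (\code{stats::mad}, with its standard 1.4826 normal-consistency scaling).
#' Boundary cells (exactly at a threshold) are kept: the inequalities are
#' strict as stated.
#'
#' @param sce a cohort; mitochondrial genes identified by
#'   \code{marker_role == "mitochondrial"} (absent annotation skips the
#'   mitochondrial rules with a warning).
#' @param minGenes,minUMIs,maxMitoPct,madK thresholds (defaults 500, 500,
#'   5 percent, 5).
#' @return \code{DataFrame} per cell: \code{cell_id}, \code{n_genes},
#'   \code{n_umis}, \code{pct_mito}, per-rule flags, and \code{kept};
#'   per-rule removal counts in \code{metadata()$removedPerRule}.
#' @export
basicCellFilters <- function(sce, minGenes = 500, minUMIs = 500,
                             maxMitoPct = 5, madK = 5) {
    counts <- assay(sce, "counts")
    nUMIs <- Matrix::colSums(counts)
    nGenes <- Matrix::colSums(counts > 0)
    mtRows <- rowData(sce)$marker_role == "mitochondrial"
    haveMito <- any(mtRows)
    pctMito <- if (haveMito) {
        mt <- Matrix::colSums(counts[mtRows, , drop = FALSE])
        ifelse(nUMIs > 0, 100 * mt / nUMIs, 0)
    } else {
        warning("no mitochondrial genes annotated; mitochondrial rules skipped")
        rep(NA_real_, ncol(sce))
    }
    madFlag <- function(x) {
        if (all(is.na(x))) return(rep(FALSE, length(x)))
        m <- median(x); s <- mad(x)
        abs(x - m) > madK * s
    }
    lowGenes <- nGenes < minGenes
    lowUMIs <- nUMIs < minUMIs
    highMito <- if (haveMito) pctMito > maxMitoPct else rep(FALSE, ncol(sce))
    madOut <- madFlag(log10(nUMIs + 1)) | madFlag(log10(nGenes + 1)) |
        (if (haveMito) madFlag(pctMito) else rep(FALSE, ncol(sce)))
    kept <- !(lowGenes | lowUMIs | highMito | madOut)
    out <- DataFrame(cell_id = colnames(sce), n_genes = unname(as.integer(nGenes)),
                     n_umis = unname(as.numeric(nUMIs)),
                     pct_mito = unname(pctMito),
                     low_genes = unname(lowGenes), low_umis = unname(lowUMIs),
                     high_mito = unname(highMito),
                     mad_outlier = unname(madOut), kept = unname(kept))
    metadata(out)$removedPerRule <- c(
        low_genes = sum(lowGenes), low_umis = sum(lowUMIs),
        high_mito = sum(highMito), mad_outlier = sum(madOut),
        total_removed = sum(!kept))
    out
}

.markerValues <- function(sce, role) {
    if (!"logcounts" %in% assayNames(sce))
        stop("log-normalized values required; run logNormalizeCounts() first")
    rows <- rowData(sce)$marker_role == role
    assay(sce, "logcounts")[rows, , drop = FALSE]
}

#' Per-cell sex score
#'
#' \eqn{S = \log_2((v_{XIST} + c) / (\sum v_Y + c))} on log-normalized
#' values, where the Y panel holds the annotated Y-linked genes (canonically
#' UTY, RPS4Y1, ZFY, DDX3Y, KDM5D). The pseudocount keeps the score finite
#' when one side is zero.
#'
#' @param sce a cohort with a \code{logcounts} assay and \code{xist} /
#'   \code{y_linked} marker roles annotated.
#' @param pseudocount additive constant \eqn{c} (default 1).
#' @return named numeric vector of scores, one per cell.
#' @export
sexScore <- function(sce, pseudocount = 1) {
    xist <- .markerValues(sce, "xist")
    if (nrow(xist) == 0L) stop("no gene annotated with marker_role 'xist'")
    yv <- .markerValues(sce, "y_linked")
    x <- Matrix::colSums(xist)
    y <- Matrix::colSums(yv)
    setNames(log2((x + pseudocount) / (y + pseudocount)), colnames(sce))
}

#' Classify per-cell sex from the sex score
#'
#' Female-like if \eqn{S \ge t_{female}}, male-like if \eqn{S \le t_{male}},
#' ambiguous in between. Thresholds are boundary-inclusive.
#'
#' @param S numeric sex scores.
#' @param tFemale,tMale thresholds with \code{tFemale > tMale}
#'   (defaults +1 / -1).
#' @return character vector in \code{{"female_like", "male_like",
#'   "ambiguous"}}.
#' @export
classifySex <- function(S, tFemale = 1, tMale = -1) {
    if (tFemale <= tMale) stop("tFemale must exceed tMale")
    ifelse(S >= tFemale, "female_like",
           ifelse(S <= tMale, "male_like", "ambiguous"))
}

#' Per-cell erythroid score
#'
#' Summed log-normalized expression of the annotated hemoglobin panel
#' (canonically HBB, HBA1, HBA2, HBE1, HBG1, HBG2, HBM), which marks
#' maternal erythrocyte-derived ambient RNA.
#'
#' @param sce a cohort with a \code{logcounts} assay and \code{hemoglobin}
#'   marker roles annotated.
#' @return named numeric vector of scores.
#' @export
erythroidScore <- function(sce) {
    hb <- .markerValues(sce, "hemoglobin")
    if (nrow(hb) == 0L) stop("no genes annotated with marker_role 'hemoglobin'")
    setNames(Matrix::colSums(hb), colnames(sce))
}

#' Flag erythroid-high cells
#'
#' Flags cells whose erythroid score strictly exceeds the given percentile of
#' the global score distribution (linear-interpolation percentile,
#' \code{quantile} type 7). On a constant vector nothing strictly exceeds
#' the percentile, so nothing is flagged.
#'
#' @param E numeric erythroid scores.
#' @param percentile percentile threshold (default 95).
#' @return logical vector of flags.
#' @export
flagErythroidHigh <- function(E, percentile = 95) {
    if (length(E) == 0L) return(logical(0))
    E > quantile(E, percentile / 100, type = 7, names = FALSE)
}

#' Infer sample sex by majority vote
#'
#' A sample is called female (male) if strictly more than half of all its
#' cells, ambiguous calls included in the denominator, are female-like
#' (male-like); otherwise undetermined.
#'
#' @param calls character vector of per-cell sex calls for one sample.
#' @return one of "female", "male", "undetermined".
#' @export
inferSampleSex <- function(calls) {
    n <- length(calls)
    if (n == 0L) return("undetermined")
    if (sum(calls == "female_like") > n / 2) return("female")
    if (sum(calls == "male_like") > n / 2) return("male")
    "undetermined"
}

#' Flag maternal-contamination candidates
#'
#' A cell is contaminated iff its sex call is discordant with the inferred
#' sample sex AND it is erythroid-high. Ambiguous calls are never discordant;
#' with \code{dropAmbiguous} they are additionally marked for exclusion.
#' An undetermined sample sex yields zero flags with a warning.
#'
#' @param sexCall per-cell calls ("female_like"/"male_like"/"ambiguous").
#' @param erythroidHigh per-cell logical flags.
#' @param inferredSex the sample's inferred sex.
#' @param dropAmbiguous also exclude ambiguous cells?
#' @return \code{DataFrame} with \code{contaminated} and \code{excluded}
#'   logical columns (excluded = contaminated, plus ambiguous cells when
#'   \code{dropAmbiguous}).
#' @export
flagContaminated <- function(sexCall, erythroidHigh, inferredSex,
                             dropAmbiguous = FALSE) {
    stopifnot(length(sexCall) == length(erythroidHigh))
    if (inferredSex == "undetermined") {
        warning("sample sex undetermined; no discordance computable, zero flags")
        discordant <- rep(FALSE, length(sexCall))
    } else {
        concordant <- if (inferredSex == "female") "female_like" else "male_like"
        discordant <- sexCall != concordant & sexCall != "ambiguous"
    }
    contaminated <- discordant & erythroidHigh
    excluded <- contaminated | (dropAmbiguous & sexCall == "ambiguous")
    DataFrame(contaminated = contaminated, excluded = excluded)
}

#' Run the full sex/erythroid contamination QC
#'
#' Computes per-cell sex and erythroid scores, classifies sex, infers each
#' sample's sex by majority vote, flags erythroid-high cells against the
#' global percentile, and flags contaminated cells (discordant sex AND
#' erythroid-high).
#'
#' @param sce a cohort; log-normalized values are computed with defaults if
#'   absent. Samples are the \code{donor} column of \code{colData}.
#' @param pseudocount,tFemale,tMale,percentile,dropAmbiguous parameters of
#'   the component steps.
#' @return a \code{\link{SexQCResult-class}} object.
#' @export
runSexQC <- function(sce, pseudocount = 1, tFemale = 1, tMale = -1,
                     percentile = 95, dropAmbiguous = FALSE) {
    if (!"logcounts" %in% assayNames(sce))
        sce <- logNormalizeCounts(sce)
    S <- sexScore(sce, pseudocount)
    call <- classifySex(S, tFemale, tMale)
    E <- erythroidScore(sce)
    eHigh <- flagErythroidHigh(E, percentile)
    sample <- as.character(colData(sce)$donor)
    inferred <- vapply(split(call, sample), inferSampleSex, character(1))
    contaminated <- logical(ncol(sce))
    excluded <- logical(ncol(sce))
    for (s in names(inferred)) {
        i <- which(sample == s)
        fl <- flagContaminated(call[i], eHigh[i], inferred[[s]], dropAmbiguous)
        contaminated[i] <- fl$contaminated
        excluded[i] <- fl$excluded
    }
    perCell <- DataFrame(
        cell_id = colnames(sce), sample = sample, sex_score = unname(S),
        sex_call = unname(call), erythroid_score = unname(E),
        erythroid_high = eHigh, contaminated = contaminated,
        excluded = excluded)
    nBySample <- table(sample)
    flBySample <- vapply(names(nBySample),
        function(s) sum(contaminated[sample == s]), numeric(1))
    perSample <- DataFrame(
        sample = names(nBySample),
        inferred_sex = unname(inferred[names(nBySample)]),
        n_cells = as.integer(nBySample),
        n_flagged = as.integer(flBySample),
        removal_fraction = unname(flBySample / as.integer(nBySample)))
    new("SexQCResult", perCell = perCell, perSample = perSample)
}
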