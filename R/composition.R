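#' @importFrom stats kruskal.test wilcox.test
NULL

#' Donor-level pseudobulk cell-type proportions
#'
#' For each donor d and cell type c, \eqn{P(d,c) = N(d,c) / \sum_{c'}
#' N(d,c')}: every donor contributes a single independent composition
#' estimate. Donors with zero cells are omitted with a warning.
#'
#' @param cellMeta data.frame-like per-cell annotation with \code{donor} and
#'   \code{cell_type} columns (e.g. \code{colData} of a cohort).
#' @return donors x cell-types proportion matrix; rows sum to 1.
#' @export
pseudobulkProportions <- function(cellMeta) {
    cellMeta <- as.data.frame(cellMeta)
    stopifnot(all(c("donor", "cell_type") %in% colnames(cellMeta)))
    counts <- table(cellMeta$donor, cellMeta$cell_type)
    tot <- rowSums(counts)
    if (any(tot == 0)) {
        warning("omitting donors with zero cells: ",
                paste(rownames(counts)[tot == 0], collapse = ", "))
        counts <- counts[tot > 0, , drop = FALSE]
        tot <- tot[tot > 0]
    }
    m <- sweep(matrix(as.numeric(counts), nrow(counts),
                      dimnames = dimnames(counts)), 1L, tot, "/")
    m
}

#' Log transform of proportions for visualization
#'
#' \code{log10(P + offset)}; the offset keeps zero proportions plottable.
#' For display only — the rank-based tests operate on untransformed
#' proportions (and are invariant to this transform anyway).
#'
#' @param P proportion matrix.
#' @param offset additive constant (default 1e-4).
#' @return transformed matrix.
#' @export
logProportions <- function(P, offset = 1e-4) log10(P + offset)

#' Stage-wise Kruskal-Wallis tests on cell-type proportions
#'
#' For each cell type, compares donor-level proportions across developmental
#' stages with the Kruskal-Wallis test. A cell type is excluded when, at any
#' stage with donors, it is present (proportion > 0) in fewer than
#' \code{minDonors} donors; types observed in fewer than two stages are
#' skipped. FDR across the retained cell types by Benjamini-Hochberg.
#'
#' @param P donors x cell-types proportion matrix
#'   (\code{\link{pseudobulkProportions}}).
#' @param donorMeta data.frame with \code{donor} and \code{stage}, one row
#'   per donor.
#' @param minDonors minimum donors per stage (default 3).
#' @return \code{DataFrame}: \code{cell_type}, \code{statistic}, \code{df},
#'   \code{p}, \code{fdr}, \code{excluded} (TRUE rows carry NA statistics).
#' @export
stagewiseTest <- function(P, donorMeta, minDonors = 3) {
    donorMeta <- as.data.frame(donorMeta)
    stage <- donorMeta$stage[match(rownames(P), donorMeta$donor)]
    if (any(is.na(stage))) stop("every donor needs a stage")
    res <- lapply(colnames(P), function(ct) {
        x <- P[, ct]
        present <- tapply(x > 0, stage, sum)
        if (any(present < minDonors, na.rm = TRUE))
            return(list(ct = ct, stat = NA_real_, df = NA_integer_,
                        p = NA_real_, excluded = TRUE))
        grp <- factor(stage)
        if (nlevels(droplevels(grp)) < 2L)
            return(list(ct = ct, stat = NA_real_, df = NA_integer_,
                        p = NA_real_, excluded = TRUE))
        if (length(unique(x)) == 1L)   # all ties: no rank information
            return(list(ct = ct, stat = 0, df = nlevels(droplevels(grp)) - 1L,
                        p = 1, excluded = FALSE))
        kw <- kruskal.test(x, grp)
        list(ct = ct, stat = unname(kw$statistic),
             df = as.integer(unname(kw$parameter)), p = kw$p.value,
             excluded = FALSE)
    })
    out <- DataFrame(
        cell_type = vapply(res, `[[`, character(1), "ct"),
        statistic = vapply(res, `[[`, numeric(1), "stat"),
        df = vapply(res, `[[`, integer(1), "df"),
        p = vapply(res, `[[`, numeric(1), "p"),
        excluded = vapply(res, `[[`, logical(1), "excluded"))
    out$fdr <- NA_real_
    keep <- !out$excluded & !is.na(out$p)
    out$fdr[keep] <- bhAdjust(out$p[keep])
    out
}

#' Sex differences in cell-type fractions
#'
#' Two-sided Wilcoxon rank-sum tests on donor-level fractions per cell type
#' (female vs male donors). Log transforms are for visualization only and do
#' not enter the test. Types with a missing sex are skipped; comparisons with
#' a single donor on either side are reported but flagged underpowered.
#'
#' @param P donors x cell-types proportion matrix.
#' @param donorMeta data.frame with \code{donor} and \code{sex}
#'   ("F"/"M" or "female"/"male"), one row per donor.
#' @return \code{DataFrame}: \code{cell_type}, \code{statistic}, \code{p},
#'   \code{underpowered}.
#' @export
sexFractionTest <- function(P, donorMeta) {
    donorMeta <- as.data.frame(donorMeta)
    sex <- donorMeta$sex[match(rownames(P), donorMeta$donor)]
    sex <- toupper(substr(as.character(sex), 1L, 1L))
    if (!all(c("F", "M") %in% sex))
        stop("both sexes must be represented among donors")
    res <- lapply(colnames(P), function(ct) {
        f <- P[sex == "F", ct]; m <- P[sex == "M", ct]
        if (length(unique(c(f, m))) == 1L) {   # all ties
            return(list(ct = ct, stat = length(f) * length(m) / 2, p = 1,
                        up = min(length(f), length(m)) < 2L))
        }
        wt <- suppressWarnings(wilcox.test(f, m, exact = TRUE))
        list(ct = ct, stat = unname(wt$statistic), p = wt$p.value,
             up = min(length(f), length(m)) < 2L)
    })
    DataFrame(cell_type = vapply(res, `[[`, character(1), "ct"),
              statistic = vapply(res, `[[`, numeric(1), "stat"),
              p = vapply(res, `[[`, numeric(1), "p"),
              underpowered = vapply(res, `[[`, logical(1), "up"))
}
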