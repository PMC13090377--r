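#' @importFrom stats chisq.test p.adjust pchisq rmultinom quantile
NULL

#' Build the cell-identity by OR-count contingency table
#'
#' Cross-tabulates OR-count categories (0/1/2/3+) against cell identity for
#' the requested cell types (other cells are excluded). Empty categories are
#' retained as zero columns.
#'
#' @param category per-cell OR-count categories (see
#'   \code{\link{orCountCategory}}).
#' @param cellType per-cell identity labels.
#' @param types the identities to tabulate, in row order (default INP, iOSN).
#' @return types x categories integer matrix.
#' @export
buildContingency <- function(category, cellType,
                             types = c("INP", "iOSN")) {
    stopifnot(length(category) == length(cellType))
    missing <- setdiff(types, unique(cellType))
    if (length(missing))
        stop("requested cell type absent: ", paste(missing, collapse = ", "))
    keep <- cellType %in% types
    category <- factor(category, levels = levels(orCountCategory(0L)))
    tab <- table(factor(cellType[keep], levels = types), category[keep])
    m <- matrix(as.integer(tab), nrow = length(types),
                dimnames = list(types, colnames(tab)))
    m
}

.checkTable <- function(observed) {
    if (nrow(observed) < 2L || ncol(observed) < 2L)
        stop("table needs at least 2 rows and 2 columns")
    if (sum(observed) <= 0) stop("table has zero grand total")
    if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
        stop("zero margin: expected counts undefined")
}

#' Pearson chi-square test of independence
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with expected counts from the row and
#' column margins, \eqn{df = (r-1)(c-1)}, and the p-value from the chi-square
#' survival function. No continuity correction by default (two-sided by
#' construction of the statistic).
#'
#' @param observed matrix of non-negative counts.
#' @param yates apply the Yates continuity correction (2x2 tables only)?
#' @return list with \code{chi2}, \code{df}, \code{p}, \code{expected}.
#' @export
pearsonChi2 <- function(observed, yates = FALSE) {
    observed <- as.matrix(observed)
    .checkTable(observed)
    ht <- suppressWarnings(chisq.test(observed, correct = yates))
    list(chi2 = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
         p = ht$p.value, expected = ht$expected)
}

#' Cramer's V effect size
#'
#' \deqn{V = \sqrt{\chi^2 / (N \cdot \min(r-1, c-1))}}
#' using the Pearson chi-square without continuity correction.
#'
#' @param observed matrix of non-negative counts.
#' @return V in [0, 1].
#' @export
cramersV <- function(observed) {
    observed <- as.matrix(observed)
    ct <- pearsonChi2(observed)
    N <- sum(observed)
    k <- min(nrow(observed), ncol(observed)) - 1L
    sqrt(ct$chi2 / (N * k))
}

#' Bootstrap percentile confidence interval for Cramer's V
#'
#' Resamples the table as a single multinomial draw at fixed grand total and
#' takes the percentile interval of V over the replicates. Replicates whose
#' resampled table has a zero margin are skipped. Deterministic under the
#' seed.
#'
#' @param observed matrix of non-negative counts.
#' @param B number of bootstrap replicates (>= 100, default 10,000).
#' @param level coverage (default 0.95).
#' @param seed integer seed.
#' @return numeric length-2 vector (lower, upper).
#' @export
bootstrapVCI <- function(observed, B = 10000, level = 0.95, seed = 1L) {
    observed <- as.matrix(observed)
    .checkTable(observed)
    if (B < 100) stop("B must be at least 100")
    oldSeed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
    set.seed(seed)
    N <- sum(observed)
    p <- as.vector(observed) / N
    draws <- rmultinom(B, N, p)
    vs <- apply(draws, 2L, function(v) {
        tab <- matrix(v, nrow(observed))
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
        cramersV(tab)
    })
    vs <- vs[!is.na(vs)]
    alpha <- (1 - level) / 2
    unname(quantile(vs, c(alpha, 1 - alpha), type = 7))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement and
#' capping at 1; input order is preserved.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

.starLabel <- function(padj) {
    ifelse(padj < 0.001, "***",
           ifelse(padj < 0.01, "**", ifelse(padj < 0.05, "*", "ns")))
}

#' Per-bin post-hoc chi-square tests
#'
#' For each category column of a 2-row table, tests that column against the
#' pooled remaining columns in a 2x2 Pearson chi-square without continuity
#' correction, then adjusts the per-bin p-values with Benjamini-Hochberg.
#' Significance labels: *** padj < 0.001, ** < 0.01, * < 0.05, ns otherwise.
#' A degenerate 2x2 margin yields p = 1 with a warning.
#'
#' @param observed 2 x c matrix of counts.
#' @return \code{DataFrame}: \code{bin}, \code{chi2}, \code{p}, \code{padj},
#'   \code{label}.
#' @export
posthocPerBin <- function(observed) {
    observed <- as.matrix(observed)
    if (nrow(observed) != 2L) stop("post-hoc tests require exactly 2 rows")
    bins <- colnames(observed) %||% sprintf("bin%d", seq_len(ncol(observed)))
    res <- lapply(seq_len(ncol(observed)), function(j) {
        t2 <- cbind(observed[, j], rowSums(observed[, -j, drop = FALSE]))
        if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) {
            warning("degenerate 2x2 margins for bin ", bins[j],
                    "; p recorded as 1")
            return(c(NA_real_, 1))
        }
        ct <- pearsonChi2(t2)
        c(ct$chi2, ct$p)
    })
    chi2 <- vapply(res, `[`, numeric(1), 1L)
    p <- vapply(res, `[`, numeric(1), 2L)
    padj <- bhAdjust(p)
    DataFrame(bin = bins, chi2 = chi2, p = p, padj = padj,
              label = .starLabel(padj))
}

#' Full contingency analysis of OR-count categories vs cell identity
#'
#' Convenience wrapper running \code{\link{buildContingency}} (unless a
#' prebuilt table is supplied), \code{\link{pearsonChi2}},
#' \code{\link{cramersV}}, optionally \code{\link{bootstrapVCI}}, and
#' \code{\link{posthocPerBin}}.
#'
#' @param category,cellType,types as in \code{\link{buildContingency}};
#'   alternatively pass a prebuilt table via \code{observed}.
#' @param observed optional prebuilt counts matrix (overrides the first
#'   three arguments).
#' @param bootstrapCI compute the bootstrap CI for V?
#' @param B,level,seed bootstrap parameters.
#' @return a \code{\link{ContingencyResult-class}} object.
#' @export
orContingencyTest <- function(category = NULL, cellType = NULL,
                              types = c("INP", "iOSN"), observed = NULL,
                              bootstrapCI = FALSE, B = 10000, level = 0.95,
                              seed = 1L) {
    if (is.null(observed))
        observed <- buildContingency(category, cellType, types)
    observed <- as.matrix(observed)
    ct <- pearsonChi2(observed)
    v <- cramersV(observed)
    ci <- if (bootstrapCI) bootstrapVCI(observed, B, level, seed)
          else c(NA_real_, NA_real_)
    pb <- if (nrow(observed) == 2L) posthocPerBin(observed)
          else DataFrame(bin = character(0), chi2 = numeric(0),
                         p = numeric(0), padj = numeric(0),
                         label = character(0))
    new("ContingencyResult", observed = observed, expected = ct$expected,
        chi2 = ct$chi2, df = ct$df, pValue = ct$p, cramersV = v, vCI = ci,
        perBin = pb)
}

#' Bundled worked-example OR-category counts
#'
#' Loads the package's worked-example contingency table: the distribution of
#' OR-count categories (0/1/2/3+) in immediate neuronal precursors (INP) and
#' immature olfactory sensory neurons (iOSN) of a developing human olfactory
#' epithelium cohort. Useful for demonstrating
#' \code{\link{orContingencyTest}} without any data download.
#'
#' @return 2 x 4 integer matrix (rows INP, iOSN; columns 0, 1, 2, 3+).
#' @export
exampleORCategoryCounts <- function() {
    path <- system.file("extdata", "or_category_counts_example.tsv",
                        package = "singulOR", mustWork = TRUE)
    d <- read.delim(path, row.names = 1L, check.names = FALSE)
    as.matrix(d)
}
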