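#' @importFrom stats rpois runif rmultinom qpois ppois rbinom quantile
NULL

# zero-truncated Poisson: inverse-CDF conditioned on >= 1, vectorized over n
.rztpois <- function(n, lambda) {
    if (n == 0L) return(integer(0))
    if (lambda <= 0) return(rep(1L, n))
    u <- runif(n, ppois(0, lambda), 1)
    pmax(1L, qpois(u, lambda))
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the generative model. All defaults are
#' documented stand-ins for a developing olfactory-epithelium cohort (the
#' generative rates of real tissue are unknown): eight donors across four
#' post-conceptional-week stages, a 169-gene OR panel, a monogenic-choice
#' fraction that ramps up with developmental stage, minority OR co-expression,
#' and housekeeping/sex/hemoglobin/mitochondrial marker panels.
#'
#' @param seed integer seed controlling all randomness.
#' @param stages ordered, unique stage labels.
#' @param donorSex donor sexes ("F"/"M"); donors are assigned to stages in
#'   order, two per stage by default.
#' @param cellsPerStage named integer vector: cells per cell type per stage.
#' @param nORGenes size of the OR panel.
#' @param monogenicFraction per-stage probability that an iOSN commits to a
#'   single OR (scalar or named per stage); the default ramp 0.2 to 0.9
#'   emulates the near-absence of committed cells at the earliest stage.
#' @param coExpressionRate probability that a committed iOSN co-expresses a
#'   second, weaker OR.
#' @param backgroundORRate mean total stray OR counts per cell, spread as
#'   independent Poisson draws of mean \code{backgroundORRate/nORGenes} per
#'   OR gene (exactly the superposition of a Poisson total scattered over
#'   random receptors).
#' @param dominantMean mean transcript count of the chosen OR
#'   (zero-truncated Poisson).
#' @param secondaryRatio the co-expressed OR's mean is
#'   \code{dominantMean/secondaryRatio}.
#' @param inpORPositiveRate probability that an immediate neuronal precursor
#'   expresses a (single, weak) OR.
#' @param inpORMean mean count of the OR expressed by an OR-positive INP.
#' @param contaminationFraction fraction of cells planted as maternal-blood
#'   contamination (hemoglobin burst plus flipped sex signature).
#' @param hbMean mean total hemoglobin counts in a contaminated cell.
#' @param hbBackground mean total stray hemoglobin counts in clean cells.
#' @param sexSignalMean mean XIST count (female cells) or mean summed Y-panel
#'   count (male cells).
#' @param sexBackground mean total counts of the discordant sex marker panel.
#' @param nHousekeeping,housekeepingMean size and per-gene Poisson mean of the
#'   filler housekeeping panel that provides library depth.
#' @param mitoMean per-gene Poisson mean of the 13-gene mitochondrial panel.
#' @return a validated \code{SimulationConfig} (classed list).
#' @export
simulationConfig <- function(seed = 1L,
                             stages = c("PCW7", "PCW8", "PCW10", "PCW12"),
                             donorSex = c("F", "F", "F", "M", "F", "M", "F", "M"),
                             cellsPerStage = c(INP = 90, iOSN = 150, GBC = 60,
                                               SUS = 60),
                             nORGenes = 169L,
                             monogenicFraction = c(PCW7 = 0.2, PCW8 = 0.45,
                                                   PCW10 = 0.7, PCW12 = 0.9),
                             coExpressionRate = 0.1,
                             backgroundORRate = 0.05,
                             dominantMean = 5,
                             secondaryRatio = 4,
                             inpORPositiveRate = 0.33,
                             inpORMean = 1.5,
                             contaminationFraction = 0,
                             hbMean = 20,
                             hbBackground = 0.07,
                             sexSignalMean = 8,
                             sexBackground = 0.02,
                             nHousekeeping = 60L,
                             housekeepingMean = 8,
                             mitoMean = 0.5) {
    if (anyDuplicated(stages)) stop("stage labels must be unique")
    if (length(monogenicFraction) == 1L)
        monogenicFraction <- stats::setNames(
            rep(monogenicFraction, length(stages)), stages)
    if (!all(stages %in% names(monogenicFraction)))
        stop("monogenicFraction must cover every stage")
    probs <- c(monogenicFraction, coExpressionRate, inpORPositiveRate,
               contaminationFraction)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    means <- c(backgroundORRate, dominantMean, inpORMean, hbMean, hbBackground,
               sexSignalMean, sexBackground, housekeepingMean, mitoMean)
    if (any(means < 0)) stop("means must be non-negative")
    if (dominantMean <= 0) stop("dominantMean must be positive")
    if (sum(cellsPerStage) * length(stages) == 0)
        stop("zero cells requested")
    cfg <- list(seed = as.integer(seed), stages = stages, donorSex = donorSex,
                cellsPerStage = cellsPerStage, nORGenes = as.integer(nORGenes),
                monogenicFraction = monogenicFraction[stages],
                coExpressionRate = coExpressionRate,
                backgroundORRate = backgroundORRate,
                dominantMean = dominantMean, secondaryRatio = secondaryRatio,
                inpORPositiveRate = inpORPositiveRate, inpORMean = inpORMean,
                contaminationFraction = contaminationFraction, hbMean = hbMean,
                hbBackground = hbBackground, sexSignalMean = sexSignalMean,
                sexBackground = sexBackground,
                nHousekeeping = as.integer(nHousekeeping),
                housekeepingMean = housekeepingMean, mitoMean = mitoMean)
    class(cfg) <- "SimulationConfig"
    cfg
}

.Y_GENES <- c("UTY", "RPS4Y1", "ZFY", "DDX3Y", "KDM5D")
.HB_GENES <- c("HBB", "HBA1", "HBA2", "HBE1", "HBG1", "HBG2", "HBM")
.MT_GENES <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6",
                             "CO3", "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB"))

# deterministic synthetic gene panel; OR chromosome assignment follows the
# real family's skew towards chr11 and chr1
.genePanel <- function(cfg) {
    nOR <- cfg$nORGenes
    orIds <- sprintf("ORS%03d", seq_len(nOR))
    orChrom <- rep(c("chr11", "chr11", "chr1", "chr6", "chr9", "chr14",
                     "chr17", "chr19"), length.out = nOR)
    orClass <- rep("II", nOR)
    orClass[seq_len(min(nOR, ceiling(nOR * 0.1)))] <- "I"
    hk <- sprintf("HK%03d", seq_len(cfg$nHousekeeping))
    data.frame(
        gene_id = c(orIds, "XIST", .Y_GENES, .HB_GENES, .MT_GENES, hk),
        symbol = c(orIds, "XIST", .Y_GENES, .HB_GENES, .MT_GENES, hk),
        is_or = c(rep(TRUE, nOR),
                  rep(FALSE, 1L + 5L + 7L + 13L + cfg$nHousekeeping)),
        or_class = c(orClass,
                     rep("none", 1L + 5L + 7L + 13L + cfg$nHousekeeping)),
        chromosome = c(orChrom, "chrX", rep("chrY", 5L), rep("chr11", 3L),
                       rep("chr16", 4L), rep("chrM", 13L),
                       rep("chr2", cfg$nHousekeeping)),
        marker_role = c(rep("none", nOR), "xist", rep("y_linked", 5L),
                        rep("hemoglobin", 7L), rep("mitochondrial", 13L),
                        rep("none", cfg$nHousekeeping)),
        stringsAsFactors = FALSE
    )
}

#' Closed-form single-OR fraction under the generative model
#'
#' Probability that an OR-positive iOSN expresses exactly one distinct OR
#' gene, given the monogenic-choice fraction, the co-expression rate and the
#' per-gene background rate \code{backgroundORRate/nORGenes}. Exact for the
#' generator's independent-Poisson background.
#'
#' @param monogenicFraction,coExpressionRate,backgroundORRate,nORGenes the
#'   generative parameters (see \code{\link{simulationConfig}});
#'   \code{monogenicFraction} may be a vector.
#' @return probability (vectorized over \code{monogenicFraction}).
#' @export
expectedSingleORFraction <- function(monogenicFraction,
                                     coExpressionRate = 0.1,
                                     backgroundORRate = 0.05,
                                     nORGenes = 169L) {
    pi <- monogenicFraction
    p0 <- 1 - exp(-backgroundORRate / nORGenes)  # P(a given OR gene has background)
    qRest <- (1 - p0)^(nORGenes - 1L)            # no background on the other genes
    num <- pi * (1 - coExpressionRate) * qRest +
        (1 - pi) * nORGenes * p0 * (1 - p0)^(nORGenes - 1L)
    den <- pi + (1 - pi) * (1 - (1 - p0)^nORGenes)
    ifelse(den == 0, NA_real_, num / den)
}

# contamination planting on a raw dense counts matrix (genes x cells);
# returns the modified matrix. Planted cells get a zero-truncated-Poisson
# hemoglobin burst scattered multinomially over the panel, and their sex
# signature is flipped: the summed Y-panel counts move onto XIST and the old
# XIST count moves onto the first Y gene.
.plantOnMatrix <- function(m, genes, idx, hbMean) {
    if (length(idx) == 0L) return(m)
    hbRows <- which(genes$marker_role == "hemoglobin")
    xistRow <- which(genes$marker_role == "xist")
    yRows <- which(genes$marker_role == "y_linked")
    tot <- .rztpois(length(idx), hbMean)
    for (k in seq_along(idx)) {
        j <- idx[k]
        m[hbRows, j] <- m[hbRows, j] +
            as.integer(rmultinom(1L, tot[k], rep(1, length(hbRows))))
        ySum <- sum(m[yRows, j])
        oldX <- m[xistRow, j]
        m[xistRow, j] <- ySum
        m[yRows, j] <- 0L
        m[yRows[1L], j] <- oldX
    }
    m
}

#' Simulate a single-nucleus cohort with recorded ground truth
#'
#' Generates a multi-donor, multi-stage cohort with the statistical structure
#' the downstream analyses assume: iOSN commit to one OR with a stage-ramped
#' probability and express it at zero-truncated-Poisson depth, a minority
#' co-express a second weaker OR, all cells carry faint OR background, INP
#' are mostly OR-negative, sex markers follow donor sex, hemoglobin is near
#' zero except in planted maternal-contamination cells. Deterministic under
#' the config seed. Draw order: housekeeping, mitochondrial, sex, hemoglobin
#' background, OR background, per-cell OR choices (cells in column order),
#' contamination planting.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return a validated \code{SingleCellExperiment}; ground truth lives in
#'   \code{colData} columns \code{true_or}, \code{true_second_or},
#'   \code{true_sex}, \code{true_contaminated}, and
#'   \code{metadata()$expectedSingleORFraction} holds the per-stage
#'   closed-form single-OR fraction among OR-positive iOSN.
#' @export
simulateCohort <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    oldSeed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
    set.seed(cfg$seed)

    genes <- .genePanel(cfg)
    nStages <- length(cfg$stages)
    donorsPerStage <- max(1L, length(cfg$donorSex) %/% nStages)
    donorIds <- sprintf("S%d", seq_along(cfg$donorSex))

    cells <- do.call(rbind, lapply(seq_len(nStages), function(si) {
        dIdx <- ((si - 1L) * donorsPerStage + 1L):(si * donorsPerStage)
        dIdx <- dIdx[dIdx <= length(donorIds)]
        do.call(rbind, lapply(names(cfg$cellsPerStage), function(ct) {
            n <- cfg$cellsPerStage[[ct]]
            if (n == 0) return(NULL)
            data.frame(stage = cfg$stages[si], cell_type = ct,
                       donor = donorIds[rep(dIdx, length.out = n)],
                       stringsAsFactors = FALSE)
        }))
    }))
    nCells <- nrow(cells)
    cells$cell_id <- sprintf("cell%05d", seq_len(nCells))
    cells$modality <- "snrna"
    sexOf <- stats::setNames(cfg$donorSex, donorIds)
    cells$true_sex <- unname(sexOf[cells$donor])

    nGenes <- nrow(genes)
    m <- matrix(0L, nGenes, nCells)
    hkRows <- grep("^HK", genes$gene_id)
    mtRows <- which(genes$marker_role == "mitochondrial")
    orRows <- which(genes$is_or)
    xistRow <- which(genes$marker_role == "xist")
    yRows <- which(genes$marker_role == "y_linked")
    hbRows <- which(genes$marker_role == "hemoglobin")

    m[hkRows, ] <- rpois(length(hkRows) * nCells, cfg$housekeepingMean)
    m[mtRows, ] <- rpois(length(mtRows) * nCells, cfg$mitoMean)

    isF <- cells$true_sex == "F"
    m[xistRow, isF] <- .rztpois(sum(isF), cfg$sexSignalMean)
    m[xistRow, !isF] <- rpois(sum(!isF), cfg$sexBackground)
    m[yRows, isF] <- rpois(length(yRows) * sum(isF),
                           cfg$sexBackground / length(yRows))
    m[yRows, !isF] <- rpois(length(yRows) * sum(!isF),
                            cfg$sexSignalMean / length(yRows))

    m[hbRows, ] <- rpois(length(hbRows) * nCells,
                         cfg$hbBackground / length(hbRows))
    m[orRows, ] <- rpois(length(orRows) * nCells,
                         cfg$backgroundORRate / cfg$nORGenes)

    cells$true_or <- NA_character_
    cells$true_second_or <- NA_character_
    piOf <- cfg$monogenicFraction
    for (j in seq_len(nCells)) {
        ct <- cells$cell_type[j]
        if (ct == "iOSN") {
            if (runif(1) < piOf[[cells$stage[j]]]) {
                g <- sample(orRows, 1L)
                m[g, j] <- m[g, j] + .rztpois(1L, cfg$dominantMean)
                cells$true_or[j] <- genes$gene_id[g]
                if (runif(1) < cfg$coExpressionRate) {
                    g2 <- sample(orRows[orRows != g], 1L)
                    m[g2, j] <- m[g2, j] +
                        .rztpois(1L, cfg$dominantMean / cfg$secondaryRatio)
                    cells$true_second_or[j] <- genes$gene_id[g2]
                }
            }
        } else if (ct == "INP") {
            if (runif(1) < cfg$inpORPositiveRate) {
                g <- sample(orRows, 1L)
                m[g, j] <- m[g, j] + .rztpois(1L, cfg$inpORMean)
                cells$true_or[j] <- genes$gene_id[g]
            }
        }
    }

    cells$true_contaminated <- FALSE
    if (cfg$contaminationFraction > 0) {
        idx <- sample(nCells, round(cfg$contaminationFraction * nCells))
        m <- .plantOnMatrix(m, genes, idx, cfg$hbMean)
        cells$true_contaminated[idx] <- TRUE
    }

    sce <- makeCohort(m, genes,
                      cells[, c("cell_id", "donor", "stage", "cell_type",
                                "modality", "true_sex", "true_or",
                                "true_second_or", "true_contaminated")])
    metadata(sce)$config <- cfg
    metadata(sce)$expectedSingleORFraction <- expectedSingleORFraction(
        piOf, cfg$coExpressionRate, cfg$backgroundORRate, cfg$nORGenes)
    sce
}

#' Plant maternal-blood contamination into an existing cohort
#'
#' Selects a fraction of cells uniformly at random, adds a hemoglobin burst
#' (zero-truncated Poisson total scattered over the hemoglobin panel) and
#' flips the sex signature (XIST and Y-panel counts are swapped). All other
#' cells are untouched.
#'
#' @param sce a cohort with \code{xist}, \code{y_linked} and
#'   \code{hemoglobin} marker roles annotated.
#' @param fraction fraction of cells to contaminate, in [0, 1].
#' @param hbMean mean hemoglobin burst size.
#' @param seed optional seed for the selection and burst draws.
#' @return \code{sce} with modified counts and the \code{true_contaminated}
#'   column set in \code{colData}.
#' @export
plantContamination <- function(sce, fraction, hbMean = 20, seed = NULL) {
    stopifnot(fraction >= 0, fraction <= 1)
    if (!is.null(seed)) {
        oldSeed <- if (exists(".Random.seed", .GlobalEnv))
            get(".Random.seed", .GlobalEnv) else NULL
        on.exit(if (!is.null(oldSeed))
            assign(".Random.seed", oldSeed, .GlobalEnv))
        set.seed(seed)
    }
    m <- as.matrix(assay(sce, "counts"))
    idx <- if (fraction > 0) sample(ncol(m), round(fraction * ncol(m)))
           else integer(0)
    m <- .plantOnMatrix(m, as.data.frame(rowData(sce)), idx, hbMean)
    assay(sce, "counts") <- .asSparseCounts(m)
    flags <- rep(FALSE, ncol(sce))
    flags[idx] <- TRUE
    colData(sce)$true_contaminated <- flags
    sce
}

#' Simulate a 1-D respiratory-to-olfactory epithelial strip
#'
#' Places cells of several types along a strip of given length, with
#' respiratory populations (RHBC, MV) enriched at low axial position and
#' olfactory populations (INP, iOSN, SUS) enriched at high position, per
#' user-supplied axial density profiles. Per-cell transcript totals are
#' \code{totalFloor + Poisson(meanTotal)}, so the expected number of cells
#' removed by a minimum-transcript filter is known in closed form. iOSN
#' commit to one OR of a compact spatial panel and give it a fixed share of
#' their transcripts.
#'
#' @param nCells number of cells to place.
#' @param stripLength,stripWidth strip dimensions in micrometres
#'   (length must be positive).
#' @param typeProportions named probabilities of each cell type.
#' @param densities named list of non-negative density functions on [0, 1]
#'   (normalized arc position); types missing from the list get a uniform
#'   density. Must not be empty if supplied.
#' @param meanTotal,totalFloor per-cell transcript total parameters.
#' @param nORGenes size of the spatial OR panel (a MERFISH-style codebook
#'   carries only the most-expressed receptors).
#' @param orShare fraction of a committed iOSN's transcripts on its chosen OR.
#' @param stage stage label recorded for all cells.
#' @param seed integer seed.
#' @return a validated spatial \code{SingleCellExperiment} with \code{x},
#'   \code{y} positions and \code{true_or} ground truth in \code{colData}.
#' @export
simulateSpatialStrip <- function(nCells = 2000L,
                                 stripLength = 1000,
                                 stripWidth = 100,
                                 typeProportions = c(RHBC = 0.15, MV = 0.10,
                                                     INP = 0.20, iOSN = 0.35,
                                                     SUS = 0.20),
                                 densities = NULL,
                                 meanTotal = 30,
                                 totalFloor = 0L,
                                 nORGenes = 57L,
                                 orShare = 0.3,
                                 stage = "PCW9",
                                 seed = 1L) {
    if (stripLength <= 0) stop("stripLength must be positive")
    if (!is.null(densities) && length(densities) == 0L)
        stop("empty density profile")
    if (is.null(densities))
        densities <- list(RHBC = function(s) (1 - s)^2,
                          MV   = function(s) (1 - s)^2,
                          INP  = function(s) s^2,
                          iOSN = function(s) s^2,
                          SUS  = function(s) s^2)
    oldSeed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
    set.seed(seed)

    types <- names(typeProportions)
    ct <- sample(types, nCells, replace = TRUE,
                 prob = typeProportions / sum(typeProportions))

    grid <- seq(0, 1, length.out = 1001L)
    sampleS <- function(type, n) {
        f <- densities[[type]]
        d <- if (is.null(f)) rep(1, length(grid)) else pmax(0, f(grid))
        if (all(d == 0)) stop("density profile for ", type, " is zero everywhere")
        cdf <- cumsum(d); cdf <- cdf / cdf[length(cdf)]
        stats::approx(cdf, grid, runif(n), ties = "ordered", rule = 2)$y
    }
    s <- numeric(nCells)
    for (ty in types) {
        i <- which(ct == ty)
        if (length(i)) s[i] <- sampleS(ty, length(i))
    }

    nFiller <- 30L
    orIds <- sprintf("ORS%03d", seq_len(nORGenes))
    filler <- sprintf("MRK%03d", seq_len(nFiller))
    genes <- data.frame(
        gene_id = c(orIds, filler), symbol = c(orIds, filler),
        is_or = c(rep(TRUE, nORGenes), rep(FALSE, nFiller)),
        or_class = c(rep("II", nORGenes), rep("none", nFiller)),
        chromosome = "unknown",
        marker_role = "none", stringsAsFactors = FALSE)

    tot <- totalFloor + rpois(nCells, meanTotal)
    m <- matrix(0L, nrow(genes), nCells)
    trueOR <- rep(NA_character_, nCells)
    fillerRows <- nORGenes + seq_len(nFiller)
    for (j in seq_len(nCells)) {
        if (tot[j] == 0L) next
        w <- numeric(nrow(genes))
        w[fillerRows] <- 1
        if (ct[j] == "iOSN") {
            g <- sample(nORGenes, 1L)
            trueOR[j] <- orIds[g]
            w[g] <- orShare / (1 - orShare) * nFiller
        }
        m[, j] <- as.integer(rmultinom(1L, tot[j], w))
    }

    cells <- data.frame(
        cell_id = sprintf("sp%05d", seq_len(nCells)),
        donor = "SP1", stage = stage, cell_type = ct, modality = "spatial",
        x = s * stripLength, y = runif(nCells, 0, stripWidth),
        true_or = trueOR, stringsAsFactors = FALSE)
    makeCohort(m, genes, cells)
}
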