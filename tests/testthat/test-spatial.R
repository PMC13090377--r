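test_that("the 12-transcript filter removes strictly below the floor", {
    genes <- tinyGenePanel()
    m <- matrix(0, nrow(genes), 3)
    m[1, 1] <- 11     # removed
    m[1, 2] <- 12     # kept (boundary)
    m[1:2, 3] <- c(30, 10)
    sce <- tinyCohort(m, genes)
    SummarizedExperiment::colData(sce)$modality <- "snrna"
    f <- filterLowCountCells(sce)
    expect_equal(colnames(f), c("c002", "c003"))
    rep <- S4Vectors::metadata(f)$lowCountRemoval
    expect_equal(unname(rep[c("kept", "removed")]), c(2, 1))
    # empty input stays empty
    empty <- tinyCohort(matrix(0, nrow(genes), 0), genes)
    expect_equal(ncol(filterLowCountCells(empty)), 0L)
})

test_that("axis projection matches the definition on simple geometries", {
    poly <- rbind(c(0, 0), c(10, 0), c(10, 10))   # L-shaped, length 20
    # at a vertex: cumulative length / total
    expect_equal(projectToAxis(rbind(c(10, 0)), poly), 0.5)
    expect_equal(projectToAxis(rbind(c(0, 0)), poly), 0)
    expect_equal(projectToAxis(rbind(c(10, 10)), poly), 1)
    # straight axis, foot of perpendicular at midpoint
    straight <- rbind(c(0, 0), c(10, 0))
    expect_equal(projectToAxis(rbind(c(5, 3)), straight), 0.5)
    expect_error(projectToAxis(rbind(c(0, 0)), rbind(c(1, 1), c(1, 1))),
                 "degenerate")
})

test_that("axis projection agrees with a dense-sampling oracle", {
    set.seed(11)
    poly <- rbind(c(0, 0), c(40, 10), c(60, 50), c(100, 60))
    pts <- cbind(runif(150, -5, 105), runif(150, -5, 65))
    s <- projectToAxis(pts, poly)
    # oracle: nearest of 200k points densely sampled along the polyline
    seg <- diff(poly)
    len <- sqrt(rowSums(seg^2)); cum <- c(0, cumsum(len)); tot <- sum(len)
    sDense <- seq(0, 1, length.out = 200000)
    arc <- sDense * tot
    k <- findInterval(arc, cum, rightmost.closed = TRUE)
    k <- pmin(k, nrow(seg))
    frac <- (arc - cum[k]) / len[k]
    px <- poly[k, 1] + frac * seg[k, 1]
    py <- poly[k, 2] + frac * seg[k, 2]
    for (i in seq_len(nrow(pts))) {
        d2 <- (px - pts[i, 1])^2 + (py - pts[i, 2])^2
        expect_lt(abs(s[i] - sDense[which.min(d2)]), 1e-3)
    }
})

test_that("axis bins are half-open with a closed last bin", {
    expect_equal(binAxis(0), 1L)
    expect_equal(binAxis(1), 50L)
    expect_equal(binAxis(0.5), 26L)
    expect_equal(binAxis(c(0.02 - 1e-9, 0.02)), c(1L, 2L))
    expect_error(binAxis(1.01), "\\[0, 1\\]")
    # every retained cell maps to exactly one bin; occupancy sums to N
    set.seed(12)
    s <- runif(500)
    b <- binAxis(s)
    expect_true(all(b >= 1 & b <= 50))
    expect_equal(sum(tabulate(b, 50)), 500L)
})

test_that("cell-type bin matrices row-scale by the row maximum", {
    bins <- c(1, 2, 3, 3, 2, 3)
    types <- c("A", "A", "A", "B", "B", "B")
    ctm <- cellTypeBinMatrix(bins, types, nBins = 3)
    expect_equal(unname(ctm$raw["A", ]), c(1L, 1L, 1L))
    expect_equal(unname(ctm$raw["B", ]), c(0L, 1L, 2L))
    expect_equal(unname(ctm$scaled["B", ]), c(0, 0.5, 1))
    expect_equal(sum(ctm$raw), length(bins))        # conservation
    # all-zero row stays zero
    ctm2 <- cellTypeBinMatrix(integer(0), factor(character(0), "A"), 3)
    expect_equal(unname(ctm2$scaled["A", ]), c(0, 0, 0))
})

test_that("gene bin profiles average per bin and mark empty bins NA", {
    genes <- tinyGenePanel()
    m <- matrix(0, nrow(genes), 4)
    m[1, ] <- c(2, 2, 2, 2)      # constant gene
    m[2, 4] <- 6                 # expressed only in the last cell
    sce <- tinyCohort(m, genes)
    SummarizedExperiment::assay(sce, "logcounts") <-
        SummarizedExperiment::assay(sce, "counts")
    bins <- c(1L, 1L, 2L, 3L)
    prof <- geneBinProfile(sce, bins, c("ORS001", "ORS002"), nBins = 4)
    expect_equal(unname(prof["ORS001", 1:3]), c(2, 2, 2))  # flat profile
    expect_true(all(is.na(prof[, 4])))                     # empty bin
    expect_equal(unname(prof["ORS002", 1:3]), c(0, 0, 6))
    expect_error(geneBinProfile(sce, bins, "NOPE", 4), "unknown gene")
    # linearity: profile of a summed meta-gene = sum of member profiles
    m2 <- m; m2[3, ] <- m[1, ] + m[2, ]
    sce2 <- tinyCohort(m2, genes)
    SummarizedExperiment::assay(sce2, "logcounts") <-
        SummarizedExperiment::assay(sce2, "counts")
    prof2 <- geneBinProfile(sce2, bins, c("ORS001", "ORS002", "ORS003"), 4)
    expect_equal(prof2["ORS003", ], prof2["ORS001", ] + prof2["ORS002", ])
})

test_that("spatial bin profiles pass validity and conserve counts", {
    sp <- simulateSpatialStrip(nCells = 600, seed = 13)
    poly <- rbind(c(0, 50), c(1000, 50))
    prof <- spatialBinProfile(sp, poly, nBins = 50, genes = "ORS001")
    expect_s4_class(prof, "SpatialBinProfile")
    expect_true(validObject(prof))
    expect_equal(sum(cellTypeMatrix(prof)), 600)
    expect_true(all(apply(cellTypeMatrix(prof, scaled = TRUE), 1, max) <= 1))
    # respiratory types sit low on the axis, olfactory types high
    raw <- cellTypeMatrix(prof)
    mid <- 25
    expect_gt(sum(raw["RHBC", 1:mid]), sum(raw["RHBC", (mid + 1):50]))
    expect_gt(sum(raw["iOSN", (mid + 1):50]), sum(raw["iOSN", 1:mid]))
})

test_that("density maps conserve transcript mass", {
    sp <- simulateSpatialStrip(nCells = 400, seed = 14)
    dm <- orDensityMap(sp, pixelSize = 20)
    orTotal <- sum(SummarizedExperiment::assay(orGenes(sp), "counts"))
    expect_equal(sum(densityGrid(dm)), orTotal)
    expect_error(orDensityMap(sp, pixelSize = 0), "positive")
    # single cell: one pixel holds its OR count
    genes <- tinyGenePanel()
    m <- matrix(0, nrow(genes), 1); m[1, 1] <- 5
    one <- tinyCohort(m, genes)
    SummarizedExperiment::colData(one)$x <- 55
    SummarizedExperiment::colData(one)$y <- 23
    dm1 <- orDensityMap(one, pixelSize = 10)
    expect_equal(sum(densityGrid(dm1)), 5)
    expect_equal(max(densityGrid(dm1)), 5)
    # smoothing preserves interior-supported mass within 0.1%
    set.seed(15)
    n <- 200
    mi <- matrix(0, nrow(genes), n); mi[1, ] <- rpois(n, 4)
    interior <- tinyCohort(mi, genes)
    SummarizedExperiment::colData(interior)$x <- runif(n, 400, 600)
    SummarizedExperiment::colData(interior)$y <- runif(n, 400, 600)
    raw <- orDensityMap(interior, pixelSize = 10)
    sm <- orDensityMap(interior, pixelSize = 10, bandwidth = 15)
    expect_lt(abs(sum(densityGrid(sm)) - sum(densityGrid(raw))) /
              sum(densityGrid(raw)), 0.001)
    # empty OR panel gives an all-zero map
    mz <- matrix(0, nrow(genes), 3)
    zero <- tinyCohort(mz, genes)
    SummarizedExperiment::colData(zero)$x <- c(1, 2, 3)
    SummarizedExperiment::colData(zero)$y <- c(1, 2, 3)
    expect_equal(sum(densityGrid(orDensityMap(zero, pixelSize = 5))), 0)
})

test_that("spatial high-dominance summaries count cells above threshold", {
    sm <- S4Vectors::DataFrame(
        cell_id = sprintf("c%d", 1:6),
        dominance = c(0, 2, 3, 3.5, 4, 5),
        cell_type = c("SUS", "iOSN", "iOSN", "iOSN", "INP", "iOSN"))
    counts <- spatialHighDominanceSummary(sm, threshold = 3)
    expect_equal(counts[["iOSN"]], 2L)   # strict >: the 3.0 cell is out
    expect_equal(counts[["INP"]], 1L)
    expect_equal(counts[["SUS"]], 0L)
    # threshold 0 with strict > counts every positive-score cell
    expect_equal(sum(spatialHighDominanceSummary(sm, threshold = 0)), 5L)
    # additivity under a domain partition
    maskA <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    a <- spatialHighDominanceSummary(sm, maskA, 3)
    b <- spatialHighDominanceSummary(sm, !maskA, 3)
    expect_equal(a + b, spatialHighDominanceSummary(sm, threshold = 3))
    # nothing above threshold: all-zero table
    expect_equal(sum(spatialHighDominanceSummary(sm, threshold = 10)), 0L)
})
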