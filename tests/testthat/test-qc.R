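test_that("basic filters apply the printed thresholds with strict boundaries", {
    genes <- data.frame(
        gene_id = c(sprintf("G%04d", 1:600), sprintf("MT%02d", 1:25)),
        marker_role = rep(c("none", "mitochondrial"), c(600, 25)))
    m <- matrix(0, 625, 3)
    # cell 1: 499 detected genes / 499 UMIs -> removed by both count rules
    m[1:499, 1] <- 1
    # cell 2: exactly 500 genes, 500 UMIs, 5.0% mito -> kept (boundaries pass)
    m[1:475, 2] <- 1
    m[601:625, 2] <- 1
    # cell 3: 600 genes, 1000 UMIs, 40% mito -> removed (mito rule)
    m[1:600, 3] <- 1
    m[601:625, 3] <- 16
    sce <- makeCohort(m, genes,
                      data.frame(cell_id = c("lowG", "boundary", "hiMito")))
    rep <- basicCellFilters(sce, madK = 50)
    expect_false(rep$kept[1])
    expect_true(rep$low_genes[1] && rep$low_umis[1])
    expect_true(rep$kept[2])
    expect_false(rep$kept[3])
    expect_true(rep$high_mito[3])
    expect_equal(S4Vectors::metadata(rep)$removedPerRule[["total_removed"]], 2)
})

test_that("the printed 500-gene / 500-UMI boundary is exact", {
    genes <- data.frame(gene_id = sprintf("G%04d", 1:600),
                        marker_role = "none")
    m <- matrix(0, 600, 2)
    m[1:499, 1] <- 1   # 499 genes, 499 UMIs -> removed by both rules
    m[1:500, 2] <- 1   # 500 genes, 500 UMIs -> kept
    sce <- makeCohort(m, genes, data.frame(cell_id = c("c499", "c500")))
    rep <- suppressWarnings(basicCellFilters(sce, madK = 50))
    expect_equal(rep$kept, c(FALSE, TRUE))
    expect_true(rep$low_genes[1] && rep$low_umis[1])
})

test_that("identical cells give MAD = 0 and no MAD removals", {
    genes <- tinyGenePanel()
    m <- matrix(2, nrow(genes), 6)
    rep <- basicCellFilters(tinyCohort(m, genes), minGenes = 1, minUMIs = 1,
                            maxMitoPct = 100)
    expect_false(any(rep$mad_outlier))
    expect_true(all(rep$kept))
})

test_that("sex score follows the log2 pseudocount formula", {
    genes <- tinyGenePanel()
    m <- matrix(0, nrow(genes), 3)
    xistRow <- which(genes$marker_role == "xist")
    yRow <- which(genes$marker_role == "y_linked")[1]
    m[xistRow, 1] <- 3                      # XIST 3, Y 0
    m[xistRow, 2] <- 2; m[yRow, 2] <- 2     # equal
    m[yRow, 3] <- 3                         # swapped version of cell 1
    sce <- tinyCohort(m, genes)
    # use raw counts as "values" by normalizing with cell totals themselves
    SummarizedExperiment::assay(sce, "logcounts") <-
        SummarizedExperiment::assay(sce, "counts")
    S <- sexScore(sce, pseudocount = 1)
    expect_equal(unname(S[1]), log2(4))     # (3+1)/(0+1)
    expect_equal(unname(S[2]), 0)           # symmetry at equality
    expect_equal(unname(S[3]), -unname(S[1]))  # antisymmetry under swap
})

test_that("sex classification thresholds are boundary-inclusive", {
    expect_equal(classifySex(c(2, 0, -1, 1, -0.99)),
                 c("female_like", "ambiguous", "male_like", "female_like",
                   "ambiguous"))
    expect_error(classifySex(0, tFemale = -1, tMale = 1), "exceed")
})

test_that("erythroid score is additive over the hemoglobin panel", {
    genes <- tinyGenePanel()
    m <- matrix(0, nrow(genes), 2)
    hbRows <- which(genes$marker_role == "hemoglobin")
    m[hbRows[1:3], 2] <- c(12, 8, 0)
    sce <- tinyCohort(m, genes)
    SummarizedExperiment::assay(sce, "logcounts") <-
        SummarizedExperiment::assay(sce, "counts")
    E <- erythroidScore(sce)
    expect_equal(unname(E), c(0, 20))
    # conservation under panel partition
    v <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
    expect_equal(unname(E[2]),
                 sum(v[hbRows[1:2], 2]) + sum(v[hbRows[-(1:2)], 2]))
})

test_that("the percentile flag uses strict exceedance", {
    expect_equal(sum(flagErythroidHigh(1:100)), 5)      # distinct values
    expect_equal(sum(flagErythroidHigh(rep(3, 50))), 0) # constant vector
    expect_equal(sum(flagErythroidHigh(7)), 0)          # single cell
})

test_that("sample sex requires a strict majority over all cells", {
    expect_equal(inferSampleSex(rep(c("female_like", "male_like"), c(6, 4))),
                 "female")
    expect_equal(inferSampleSex(rep(c("female_like", "male_like"), c(5, 5))),
                 "undetermined")
    expect_equal(inferSampleSex(rep("ambiguous", 8)), "undetermined")
    expect_equal(inferSampleSex(rep(c("male_like", "ambiguous"), c(6, 4))),
                 "male")
})

test_that("contamination needs discordance AND erythroid burden", {
    calls <- c("male_like", "male_like", "female_like", "ambiguous")
    eh <- c(TRUE, FALSE, TRUE, TRUE)
    fl <- flagContaminated(calls, eh, "female")
    expect_equal(fl$contaminated, c(TRUE, FALSE, FALSE, FALSE))
    fl2 <- flagContaminated(calls, eh, "female", dropAmbiguous = TRUE)
    expect_equal(fl2$excluded, c(TRUE, FALSE, FALSE, TRUE))
    expect_warning(fl3 <- flagContaminated(calls, eh, "undetermined"),
                   "undetermined")
    expect_false(any(fl3$contaminated))
})

test_that("planted contamination is recovered with high sensitivity", {
    cfg <- simulationConfig(seed = 31, contaminationFraction = 0.02,
                            cellsPerStage = c(INP = 40, iOSN = 60, GBC = 25,
                                              SUS = 25))
    sce <- simulateCohort(cfg)
    qc <- runSexQC(sce)
    pc <- perCellQC(qc)
    truth <- sce$true_contaminated
    sens <- sum(pc$contaminated & truth) / sum(truth)
    fpr <- sum(pc$contaminated & !truth) / sum(!truth)
    expect_gte(sens, 0.9)
    expect_lte(fpr, 0.01)
    # contaminated flags are a subset of erythroid-high flags
    expect_true(all(pc$erythroid_high[pc$contaminated]))
    # per-sample removal fractions reproducible from per-cell flags
    ps <- perSampleQC(qc)
    for (i in seq_len(nrow(ps))) {
        sel <- pc$sample == ps$sample[i]
        expect_equal(ps$removal_fraction[i],
                     sum(pc$contaminated[sel]) / sum(sel))
    }
})

test_that("an all-concordant cohort yields zero contamination flags", {
    cfg <- simulationConfig(seed = 13, contaminationFraction = 0,
                            cellsPerStage = c(INP = 30, iOSN = 40, GBC = 15,
                                              SUS = 15))
    qc <- runSexQC(simulateCohort(cfg))
    expect_equal(sum(perCellQC(qc)$contaminated), 0)
})
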