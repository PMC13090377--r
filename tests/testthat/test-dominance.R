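orOnlyMatrix <- function(...) {
    rows <- list(...)
    m <- do.call(cbind, rows)
    rownames(m) <- sprintf("ORS%03d", seq_len(nrow(m)))
    colnames(m) <- sprintf("c%d", seq_len(ncol(m)))
    m
}

test_that("per-cell OR statistics pick the two top receptors", {
    m <- orOnlyMatrix(c(5, 3, 0, 0), c(4, 4, 0, 0), c(0, 0, 0, 0))
    st <- perCellORStats(m)
    expect_equal(st$x1, c(5, 4, 0))
    expect_equal(st$x2, c(3, 4, 0))
    expect_equal(st$n_expressed, c(2L, 2L, 0L))
    expect_equal(as.character(st$dominant_or),
                 c("ORS001", "ORS001", NA))   # tie -> lexicographically first
})

test_that("tie at the top goes to the lexicographically first gene id", {
    m <- matrix(c(4, 4), nrow = 2,
                dimnames = list(c("ORZ9", "ORA1"), "c1"))
    st <- perCellORStats(m)
    expect_equal(as.character(st$dominant_or), "ORA1")
    expect_equal(st$x1, 4)
    expect_equal(st$x2, 4)
})

test_that("dominance score matches hand-evaluated cases", {
    expect_equal(dominanceScore(5, 5), 0, tolerance = 1e-9)
    expect_equal(dominanceScore(10, 0), log(11), tolerance = 1e-6)
    expect_equal(dominanceScore(8, 2), 0.6 * log(9), tolerance = 1e-6)
    expect_equal(dominanceScore(0, 0), 0)       # zero-OR rule
    expect_error(dominanceScore(2, 3), "exceed")
    # configurable log base
    expect_equal(dominanceScore(10, 0, logBase = 2), log2(11),
                 tolerance = 1e-6)
})

test_that("dominance score obeys its bounds and monotonicity", {
    set.seed(1)
    x1 <- sample(0:50, 300, replace = TRUE)
    x2 <- vapply(x1, function(a) sample(0:a, 1), numeric(1))
    D <- dominanceScore(x1, x2)
    expect_true(all(D >= 0))
    expect_true(all(D <= log(1 + x1) + 1e-12))
    # identity D = log(1+x1) * (1 - 2 x2 / (x1+x2+eps))
    eps <- 1e-9
    expect_equal(D, log(1 + x1) * (1 - 2 * x2 / (x1 + x2 + eps)),
                 tolerance = 1e-8)
    # strict monotonicity
    expect_true(all(dominanceScore(x1 + 1, pmin(x2, x1)) >
                    dominanceScore(x1, pmin(x2, x1))))
    i <- x2 < x1
    expect_true(all(dominanceScore(x1[i], x2[i] + 1) <
                    dominanceScore(x1[i], x2[i])))
})

test_that("dominance bins use the fixed thresholds, boundaries downward", {
    D <- c(0, 0.3, 0.5, 0.7, 1.0, 1.2, 1.5, 1.9, 2.0, 2.5)
    expect_equal(as.character(binDominance(D)),
                 c("<=0.5", "<=0.5", "<=0.5", "0.5-1", "0.5-1", "1-1.5",
                   "1-1.5", "1.5-2", "1.5-2", ">2"))
    expect_error(binDominance(-0.1), "non-negative")
})

test_that("high-dominance classification equals the three-clause predicate", {
    # truth table around each clause boundary
    expect_true(classifyHighDominance(1.2, 3, 2))
    expect_false(classifyHighDominance(1.2, 3, 4))   # too many co-expressed
    expect_false(classifyHighDominance(1.0, 3, 2))   # strict > on the score
    expect_false(classifyHighDominance(1.2, 0, 1))   # top OR below minimum
    expect_true(classifyHighDominance(1.01, 1, 3))
    # brute-force over a random grid
    set.seed(2)
    D <- runif(200, 0, 3); x1 <- sample(0:6, 200, TRUE)
    n <- sample(0:6, 200, TRUE)
    expect_equal(classifyHighDominance(D, x1, n),
                 vapply(seq_len(200), function(i)
                     D[i] > 1 && x1[i] >= 1 && n[i] <= 3, logical(1)))
})

test_that("OR count categories pool at three and above", {
    expect_equal(as.character(orCountCategory(c(0, 1, 2, 3, 7))),
                 c("0", "1", "2", "3+", "3+"))
    expect_error(orCountCategory(-1), "non-negative")
})

test_that("pure monogenic cohorts are category-1 with exact log scores", {
    sce <- simulateCohort(simulationConfig(
        seed = 21, monogenicFraction = 1, coExpressionRate = 0,
        backgroundORRate = 0,
        cellsPerStage = c(INP = 0, iOSN = 60, GBC = 0, SUS = 0)))
    sm <- orCellSummary(sce)
    pos <- sm$n_expressed > 0
    expect_true(all(sm$or_category[pos] == "1"))
    big <- pos & sm$x1 >= 2
    expect_equal(sm$dominance[big], log(1 + sm$x1[big]), tolerance = 1e-6)
})

test_that("strict two-transcript scoring zeroes single-molecule cells", {
    m <- orOnlyMatrix(c(1, 0, 0, 0), c(2, 0, 0, 0), c(1, 1, 0, 0))
    sm <- orCellSummary(m, requireTwoTranscripts = TRUE)
    expect_equal(sm$dominance[1], 0)            # one transcript in total
    expect_equal(sm$dominance[2], log(3), tolerance = 1e-9)
    expect_equal(sm$dominance[3], 0)            # 1+1 with eps: near-zero anyway
    smDefault <- orCellSummary(m)
    expect_equal(smDefault$dominance[1], log(2), tolerance = 1e-6)
})

test_that("dominant OR frequency tables count high-dominance cells", {
    sm <- S4Vectors::DataFrame(
        cell_id = sprintf("c%d", 1:6),
        dominant_or = c("A", "A", "A", "B", "B", NA),
        high_dominance = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
        stage = c("PCW7", "PCW7", "PCW10", "PCW10", "PCW10", "PCW10"))
    tab <- dominantORFrequency(sm)
    expect_equal(as.character(tab$or_gene), c("A", "B"))
    expect_equal(tab$n_cells, c(3L, 1L))
    top1 <- dominantORFrequency(sm, topK = 1)
    expect_equal(as.character(top1$or_gene), "A")
    grouped <- dominantORFrequency(sm, groupBy = "stage")
    expect_equal(sum(grouped$n_cells), sum(tab$n_cells))
    empty <- dominantORFrequency(sm[!sm$high_dominance, ])
    expect_equal(nrow(empty), 0L)
})

test_that("diagonal ordering makes dominant-OR blocks contiguous", {
    m <- orOnlyMatrix(c(3, 0), c(0, 2), c(4, 0), c(0, 5))
    sm <- orCellSummary(m)
    ord <- diagonalOrder(sm)
    dom <- as.character(sm$dominant_or)[ord$cellOrder]
    expect_equal(rle(dom)$values, unique(dom))      # contiguous blocks
    expect_equal(ord$orOrder, unique(dom))
    # 2x2 block-diagonal: first two cells share OR 1, last two OR 2
    expect_equal(dom, c("ORS001", "ORS001", "ORS002", "ORS002"))
    # within a block, descending x1
    expect_equal(sm$x1[ord$cellOrder][1:2], c(4, 3))
    # all-negative cohort: input order preserved, empty OR axis
    mneg <- orOnlyMatrix(c(0, 0), c(0, 0))
    ordneg <- diagonalOrder(orCellSummary(mneg))
    expect_equal(ordneg$cellOrder, 1:2)
    expect_equal(length(ordneg$orOrder), 0L)
})

test_that("chromosome profiles conserve gene counts and expression", {
    genes <- tinyGenePanel(nOR = 4)
    genes$chromosome[genes$gene_id == "ORS004"] <- "chr7"
    m <- matrix(0, nrow(genes), 3)
    m[1:4, ] <- rpois(12, 2)
    sce <- tinyCohort(m, genes)
    prof <- chromosomeProfile(sce)
    expect_equal(sum(prof$n_or_genes), 4L)
    expect_equal(prof$n_or_genes[prof$chromosome == "chr7"], 1L)
    expect_equal(prof$n_or_genes[prof$chromosome == "chr11"], 3L)
    expect_equal(sum(prof$total_expression), sum(m[1:4, ]))
})
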