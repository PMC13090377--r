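# small in-code fixtures shared across test files

# cohort with nOR OR genes plus the marker panels, counts supplied as a
# genes x cells matrix (rows: ORs, XIST, 5 Y, 7 HB, 2 MT, rest filler)
tinyGenePanel <- function(nOR = 4, nFiller = 2) {
    yG <- c("UTY", "RPS4Y1", "ZFY", "DDX3Y", "KDM5D")
    hbG <- c("HBB", "HBA1", "HBA2", "HBE1", "HBG1", "HBG2", "HBM")
    mtG <- c("MT-ND1", "MT-CO1")
    orIds <- sprintf("ORS%03d", seq_len(nOR))
    fil <- sprintf("FIL%02d", seq_len(nFiller))
    data.frame(
        gene_id = c(orIds, "XIST", yG, hbG, mtG, fil),
        is_or = c(rep(TRUE, nOR), rep(FALSE, 15 + nFiller)),
        or_class = c(rep("II", nOR), rep("none", 15 + nFiller)),
        chromosome = c(rep("chr11", nOR), "chrX", rep("chrY", 5),
                       rep("chr11", 7), rep("chrM", 2), rep("chr1", nFiller)),
        marker_role = c(rep("none", nOR), "xist", rep("y_linked", 5),
                        rep("hemoglobin", 7), rep("mitochondrial", 2),
                        rep("none", nFiller)),
        stringsAsFactors = FALSE)
}

tinyCohort <- function(counts, genes = NULL, cellType = "iOSN",
                       donor = "S1", stage = "PCW10") {
    if (is.null(genes)) genes <- tinyGenePanel()
    stopifnot(nrow(counts) == nrow(genes))
    nc <- ncol(counts)
    cells <- data.frame(
        cell_id = sprintf("c%03d", seq_len(nc)),
        donor = rep_len(donor, nc), stage = rep_len(stage, nc),
        cell_type = rep_len(cellType, nc),
        modality = rep_len("snrna", nc),
        stringsAsFactors = FALSE)
    makeCohort(counts, genes, cells)
}

# independent chi-square oracle: brute-force sum((O-E)^2/E)
chi2Oracle <- function(obs) {
    E <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    sum((obs - E)^2 / E)
}

# the worked-example table used throughout
workedExampleTable <- function() {
    matrix(c(233, 166, 87, 208, 21, 47, 9, 15), nrow = 2,
           dimnames = list(c("INP", "iOSN"), c("0", "1", "2", "3+")))
}
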