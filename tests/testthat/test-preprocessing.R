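test_that("QC filter applies the three gates and is idempotent", {
    set.seed(1)
    # 3 engineered cells: low-gene, high-mito, clean
    nG <- 600
    genes <- c(paste0("MT-", 1:10), sprintf("G%03d", seq_len(nG - 10)))
    counts <- matrix(0L, nG, 3, dimnames = list(genes, c("lowG", "hiMT", "ok")))
    counts[sample(11:nG, 150), "lowG"] <- 10L       # 150 genes, 1500 UMI
    counts[11:510, "hiMT"] <- 2L                    # 500 genes
    counts[1:10, "hiMT"] <- 30L                     # 300/1300 mito > 20%
    counts[11:510, "ok"] <- 4L                      # 500 genes, 2000 UMI
    counts[1:2, "ok"] <- 50L                        # 100/2100 mito < 20%
    sce <- makeSCE(counts, cluster = "A")
    kept <- suppressMessages(filterCells(sce))
    expect_equal(colnames(kept), "ok")
    again <- suppressMessages(filterCells(kept))
    expect_equal(colnames(again), colnames(kept))
    expect_error(suppressMessages(
        filterCells(sce, minGenes = 1e6)), "all cells removed")
})

test_that("log normalization matches the closed form and is library-size invariant", {
    counts <- matrix(c(10, 9990, 20, 19980), 2, 2,
                     dimnames = list(c("g1", "g2"), c("c1", "c2")))
    sce <- normalizeLog(makeSCE(counts, "A"), scale = 1e4)
    lg <- assay(sce, "logcounts")
    expect_equal(lg["g1", "c1"], log2(11), tolerance = 1e-12)
    # proportional columns normalize identically
    expect_equal(lg[, "c1"], lg[, "c2"], ignore_attr = TRUE)
    # zero counts map to exactly 0
    counts2 <- matrix(c(0, 5, 3, 2), 2, 2,
                      dimnames = list(c("g1", "g2"), NULL))
    lg2 <- assay(normalizeLog(makeSCE(counts2, "A")), "logcounts")
    expect_identical(lg2[1, 1], 0)
    expect_true(all((lg2 == 0) == (counts2 == 0)))
    # zero-total cell is an error
    counts3 <- matrix(c(0, 0, 1, 2), 2, 2)
    expect_error(normalizeLog(makeSCE(counts3, "A")), "zero total")
})

test_that("profiles hold group means of normalized values and expressing fractions", {
    counts <- matrix(c(0, 5,   0, 5,   7, 5,   2, 2), 2, 4,
                     dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
    sce <- normalizeLog(makeSCE(counts, cluster = c("A", "A", "A", "B"),
                                tissue = "tumor"))
    prof <- computeProfiles(sce, groupBy = "cluster")
    lg <- assay(sce, "logcounts")
    expect_equal(meanExpression(prof)["g1", "A"], mean(lg["g1", 1:3]))
    expect_equal(pctExpressed(prof)["g1", "A"], 1 / 3)
    expect_equal(nCells(prof), c(3L, 1L))
    # single-cell group equals the cell itself
    expect_equal(meanExpression(prof)[, "B"], lg[, 4], ignore_attr = TRUE)
    # permuting cells leaves profiles unchanged
    perm <- sample(ncol(sce))
    prof2 <- computeProfiles(sce[, perm], groupBy = "cluster")
    expect_equal(meanExpression(prof2), meanExpression(prof))
    expect_equal(pctExpressed(prof2), pctExpressed(prof))
})

test_that("min-pct filter zeroes means only below the strict 10% bound, per group", {
    m <- matrix(c(2, 3, 4, 5), 2, 2,
                dimnames = list(c("g1", "g2"), c("A", "B")))
    p <- matrix(c(0.05, 0.10, 0.40, 0.099), 2, 2, dimnames = dimnames(m))
    prof <- makeProfiles(m, p)
    filt <- applyMinPctFilter(prof, c("g1", "g2"))
    expect_equal(meanExpression(filt)["g1", "A"], 0)    # 0.05 < 0.10
    expect_equal(meanExpression(filt)["g2", "A"], 3)    # exactly 0.10 kept
    expect_equal(meanExpression(filt)["g1", "B"], 4)    # 0.40 kept
    expect_equal(meanExpression(filt)["g2", "B"], 0)    # 0.099 < 0.10
    # untouched when the gene is not listed
    filt2 <- applyMinPctFilter(prof, "g1")
    expect_equal(meanExpression(filt2)["g2", "B"], 5)
    # never increases means; absent genes are skipped with a message
    expect_true(all(meanExpression(filt) <= meanExpression(prof)))
    expect_message(applyMinPctFilter(prof, c("g1", "NOPE")), "absent")
})

test_that("MTX round-trip through the dataset readers preserves counts and labels", {
    db <- syntheticInteractionDB(5, heterodimer = FALSE)
    dir <- withr::local_tempdir()
    runSimulate(list(out_dir = dir, db = db, nGenes = 20,
                     nClusters = 2, cellsPerCluster = 5, seed = 3))
    sce <- readSCDataset(dir, file.path(dir, "metadata.tsv"))
    expect_equal(dim(sce), c(20L, 20L))
    expect_setequal(unique(colData(sce)$tissue), c("tumor", "juxtatumor"))
    cfg <- simConfig(nGenes = 20, nClusters = 2, cellsPerCluster = 5,
                     seed = 3)
    ref <- simulateSCDataset(cfg, db)
    expect_equal(as.matrix(assay(sce, "counts")),
                 as.matrix(assay(ref$sce, "counts")), ignore_attr = TRUE)
})
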