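## Cell QC, log normalization, per-group expression profiles.

#' @importFrom SummarizedExperiment assay assay<- assays assayNames colData
#'   colData<- rowData
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Read a single-cell dataset with cell metadata
#'
#' Builds a [SingleCellExperiment::SingleCellExperiment] from either a
#' 10x-style MatrixMarket triple (\code{matrix.mtx}, \code{genes.tsv},
#' \code{barcodes.tsv}, genes x cells) or a dense TSV (genes in rows, first
#' column gene symbol), plus a metadata TSV keyed by barcode with columns
#' \code{cluster}, \code{tissue}, \code{patient}, \code{dataset}.
#'
#' @param path Directory containing the MTX triple, or a dense TSV file.
#' @param metadata Path to the per-cell metadata TSV.
#' @return A \code{SingleCellExperiment} with assay \code{counts} and the
#'   four metadata columns in \code{colData}.
#' @export
readSCDataset <- function(path, metadata) {
    if (dir.exists(path)) {
        m <- Matrix::readMM(file.path(path, "matrix.mtx"))
        genes <- utils::read.table(file.path(path, "genes.tsv"), sep = "\t",
                                   header = FALSE, colClasses = "character")
        barcodes <- utils::read.table(file.path(path, "barcodes.tsv"),
                                      sep = "\t", header = FALSE,
                                      colClasses = "character")
        rownames(m) <- genes[[ncol(genes)]]
        colnames(m) <- barcodes[[1]]
        m <- methods::as(m, "CsparseMatrix")
    } else {
        tab <- utils::read.table(path, sep = "\t", header = TRUE,
                                 check.names = FALSE)
        m <- as.matrix(tab[, -1, drop = FALSE])
        rownames(m) <- tab[[1]]
    }
    meta <- utils::read.table(metadata, sep = "\t", header = TRUE,
                              check.names = FALSE, colClasses = "character")
    need <- c("barcode", "cluster", "tissue", "patient", "dataset")
    if (!all(need %in% colnames(meta)))
        stop("metadata must have columns: ", paste(need, collapse = ", "))
    rownames(meta) <- meta$barcode
    absent <- setdiff(colnames(m), meta$barcode)
    if (length(absent))
        stop(length(absent), " cell(s) missing from metadata")
    meta <- meta[colnames(m), need[-1], drop = FALSE]
    SingleCellExperiment(assays = list(counts = m),
                         colData = S4Vectors::DataFrame(meta))
}

#' Quality-control filter on cells
#'
#' Retains cells expressing at least \code{minGenes} genes, with at least
#' \code{minUMI} total counts, and with a mitochondrial fraction strictly
#' below \code{maxMitoFrac} (mitochondrial genes identified by symbol
#' prefix). The gene set is unchanged; removal counts per criterion are
#' reported via \code{message()}. Applying the filter twice is a no-op.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay.
#' @param minGenes Minimum number of detected genes per cell.
#' @param minUMI Minimum total UMI count per cell.
#' @param maxMitoFrac Maximum tolerated mitochondrial count fraction
#'   (exclusive bound).
#' @param mitoPrefix Gene-symbol prefix marking mitochondrial genes.
#' @return The filtered \code{SingleCellExperiment}.
#' @export
filterCells <- function(sce, minGenes = 200, minUMI = 1000,
                        maxMitoFrac = 0.20, mitoPrefix = "MT-") {
    stopifnot(minGenes >= 0, minUMI >= 0, maxMitoFrac >= 0)
    counts <- assay(sce, "counts")
    nGenes <- Matrix::colSums(counts > 0)
    totals <- Matrix::colSums(counts)
    mito <- startsWith(rownames(counts), mitoPrefix)
    mitoFrac <- if (any(mito))
        Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1)
    else rep(0, ncol(counts))
    keep <- nGenes >= minGenes & totals >= minUMI & mitoFrac < maxMitoFrac
    message("filterCells: removed ", sum(nGenes < minGenes), " (genes), ",
            sum(totals < minUMI), " (UMI), ",
            sum(mitoFrac >= maxMitoFrac), " (mito); kept ",
            sum(keep), "/", ncol(counts))
    if (!any(keep))
        stop("all cells removed by QC filter")
    sce[, keep]
}

#' Library-size log normalization
#'
#' Adds a \code{logcounts} assay with
#' \code{log2(count / cell_total * scale + pseudocount)}; with the default
#' pseudocount of 1, zero counts map exactly to 0 and sparsity is preserved.
#' Normalization parameters are recorded in \code{metadata(sce)$normalization}.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{counts} assay.
#' @param scale Library-size scale factor (counts per \code{scale} total).
#' @param pseudocount Added inside the log.
#' @return The \code{SingleCellExperiment} with a \code{logcounts} assay.
#' @export
normalizeLog <- function(sce, scale = 1e4, pseudocount = 1) {
    counts <- assay(sce, "counts")
    totals <- Matrix::colSums(counts)
    if (any(totals == 0))
        stop(sum(totals == 0), " cell(s) with zero total counts; ",
             "run filterCells() first")
    cpx <- counts %*% Matrix::Diagonal(x = scale / totals)
    dimnames(cpx) <- dimnames(counts)
    if (pseudocount == 1) {
        lg <- log1p(cpx) / log(2)
    } else {
        lg <- log2(as.matrix(cpx) + pseudocount)
    }
    assay(sce, "logcounts") <- lg
    S4Vectors::metadata(sce)$normalization <-
        list(scale = scale, pseudocount = pseudocount, log_base = 2)
    sce
}

.groupFactor <- function(cd, groupBy) {
    miss <- setdiff(groupBy, colnames(cd))
    if (length(miss))
        stop("colData lacks grouping column(s): ", paste(miss, collapse = ", "))
    vals <- lapply(groupBy, function(g) as.character(cd[[g]]))
    if (any(vapply(vals, anyNA, TRUE)))
        stop("NA in grouping labels")
    interaction(vals, drop = TRUE, sep = "|", lex.order = TRUE)
}

#' Per-group average expression profiles
#'
#' Computes, for each group of cells (by default cluster within tissue), the
#' arithmetic mean of log-normalized expression and the fraction of cells
#' with a raw count above 0, per gene. These profiles carry the
#' \eqn{l_i^C} and \eqn{r_j^C} terms of the communication scores.
#'
#' @param sce A \code{SingleCellExperiment} with \code{counts} and
#'   \code{logcounts} assays and grouping columns in \code{colData}.
#' @param groupBy Character vector of \code{colData} columns;
#'   \code{c("cluster")} or \code{c("cluster", "tissue")}.
#' @return A [ClusterProfiles-class].
#' @export
computeProfiles <- function(sce, groupBy = c("cluster", "tissue")) {
    if (!"logcounts" %in% assayNames(sce))
        stop("run normalizeLog() first ('logcounts' assay missing)")
    grp <- .groupFactor(colData(sce), groupBy)
    counts <- assay(sce, "counts")
    lg <- assay(sce, "logcounts")
    levs <- levels(grp)
    meanMat <- matrix(0, nrow(sce), length(levs),
                      dimnames = list(rownames(sce), levs))
    pctMat <- meanMat
    nCells <- integer(length(levs))
    for (i in seq_along(levs)) {
        idx <- which(grp == levs[i])
        nCells[i] <- length(idx)
        meanMat[, i] <- Matrix::rowMeans(lg[, idx, drop = FALSE])
        pctMat[, i] <- Matrix::rowMeans(counts[, idx, drop = FALSE] > 0)
    }
    parts <- do.call(rbind, strsplit(levs, "|", fixed = TRUE))
    cd <- S4Vectors::DataFrame(cluster = parts[, 1], n_cells = nCells,
                               row.names = levs)
    if (length(groupBy) > 1) cd$tissue <- parts[, 2]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(mean = meanMat, pct = pctMat), colData = cd)
    S4Vectors::metadata(se)$min_pct_filter <- NULL
    new("ClusterProfiles", se)
}

#' @describeIn ClusterProfiles Mean log-normalized expression matrix
#'   (genes x groups).
#' @param x A [ClusterProfiles-class].
#' @export
meanExpression <- function(x) assay(x, "mean")

#' @describeIn ClusterProfiles Fraction of cells expressing each gene
#'   (genes x groups).
#' @export
pctExpressed <- function(x) assay(x, "pct")

#' @describeIn ClusterProfiles Number of cells per group.
#' @export
nCells <- function(x) colData(x)$n_cells

#' Minimum-percent-expressed filter for communication genes
#'
#' For each listed gene and each group in which it is expressed by strictly
#' less than \code{minPct} of the group's cells, the group's mean expression
#' is set to 0 (that group only). Genes not listed are untouched; listed
#' genes absent from the profile universe are reported and skipped. The
#' filter precedes communication scoring so that rarely expressed molecules
#' cannot drive cluster-pair scores.
#'
#' @param profiles A [ClusterProfiles-class].
#' @param genes Character vector of communication genes to filter.
#' @param minPct Exclusive lower bound on the expressing fraction.
#' @return The filtered [ClusterProfiles-class]; the applied threshold is
#'   recorded in \code{metadata()$min_pct_filter}.
#' @export
applyMinPctFilter <- function(profiles, genes, minPct = 0.10) {
    genes <- unique(genes)
    absent <- setdiff(genes, rownames(profiles))
    if (length(absent))
        message("applyMinPctFilter: ", length(absent),
                " gene(s) absent from profiles, skipped")
    genes <- intersect(genes, rownames(profiles))
    m <- assay(profiles, "mean")
    p <- assay(profiles, "pct")
    sub <- m[genes, , drop = FALSE]
    sub[p[genes, , drop = FALSE] < minPct] <- 0
    m[genes, ] <- sub
    assay(profiles, "mean") <- m
    S4Vectors::metadata(profiles)$min_pct_filter <-
        list(min_pct = minPct, n_genes = length(genes))
    profiles
}
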