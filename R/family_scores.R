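## Family-level global expression scores, cross-group z-scores, and
## tumor vs adjacent-tissue contrasts.

#' Per-cell family expression scores
#'
#' For each cell, the sum of its log-normalized expression over all genes of
#' one communication-molecule family (cytokines, chemokines, immune
#' checkpoints, growth factors, cell adhesion molecules, ...). Symbols in a
#' family set that do not resolve against the matrix are reported and
#' skipped; a family with no resolvable gene is an error.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{logcounts} assay.
#' @param sets Named list of gene sets, as from [familyGeneSets()].
#' @return A families x cells numeric matrix of raw scores (all >= 0).
#' @export
perCellFamilyScores <- function(sce, sets) {
    lg <- assay(sce, "logcounts")
    out <- matrix(0, length(sets), ncol(lg),
                  dimnames = list(names(sets), colnames(lg)))
    for (f in names(sets)) {
        genes <- intersect(sets[[f]], rownames(lg))
        skipped <- length(sets[[f]]) - length(genes)
        if (skipped > 0)
            message("perCellFamilyScores: ", skipped, " symbol(s) of '", f,
                    "' not in matrix, skipped")
        if (length(genes) == 0L)
            stop("family '", f, "' has no resolvable gene")
        out[f, ] <- Matrix::colSums(lg[genes, , drop = FALSE])
    }
    out
}

#' Cross-group z-scores of family scores
#'
#' Averages per-cell family scores within each group (e.g. cluster, or
#' cluster within a tissue) and centers/reduces the group means per family:
#' \code{z = (group mean - mean of group means) / sample SD of group means}.
#' A family whose group means have zero variance gets z = 0 for every group,
#' with a warning.
#'
#' @param cellScores Families x cells matrix from [perCellFamilyScores()].
#' @param groups Factor (or coercible) of length \code{ncol(cellScores)}
#'   assigning each cell to a group; at least 2 groups required.
#' @return List with \code{mean} and \code{z}, both families x groups
#'   matrices.
#' @export
clusterFamilyZscores <- function(cellScores, groups) {
    groups <- droplevels(as.factor(groups))
    if (nlevels(groups) < 2L)
        stop("need at least 2 groups to compute z-scores")
    gm <- vapply(levels(groups), function(g)
        rowMeans(cellScores[, groups == g, drop = FALSE]),
        numeric(nrow(cellScores)))
    gm <- matrix(gm, nrow = nrow(cellScores),
                 dimnames = list(rownames(cellScores), levels(groups)))
    sds <- apply(gm, 1, stats::sd)
    z <- (gm - rowMeans(gm)) / sds
    if (any(sds == 0)) {
        warning("zero-variance family (z set to 0): ",
                paste(rownames(gm)[sds == 0], collapse = ", "))
        z[sds == 0, ] <- 0
    }
    list(mean = gm, z = z)
}

#' Tumor vs adjacent-tissue contrast of family scores
#'
#' For each cluster and family, compares per-cell family scores between
#' tumor and juxtatumor cells of that cluster with a two-sided Wilcoxon
#' rank-sum test; Benjamini-Hochberg correction is applied across the whole
#' cluster x family grid in one batch. The fold change is
#' \code{log2((mean_tumor + eps) / (mean_juxta + eps))}; a contrast is
#' flagged significant when the adjusted p-value is below \code{alpha} and
#' \code{|log2FC|} exceeds \code{minAbsLog2fc}.
#'
#' Clusters that are renamed across tissues (a malignant cluster versus its
#' presumed cell of origin in adjacent tissue) are handled through
#' \code{pairing}: a named character vector mapping a tumor cluster label to
#' the juxtatumor cluster it should be contrasted with. Clusters without a
#' counterpart in the other tissue are skipped with a warning.
#'
#' @param cellScores Families x cells matrix from [perCellFamilyScores()].
#' @param meta Data frame (or DataFrame) with per-cell \code{cluster} and
#'   \code{tissue} (\code{"tumor"} / \code{"juxtatumor"}) columns, rows
#'   aligned with \code{cellScores} columns.
#' @param pairing Optional named character vector,
#'   \code{c(tumor_cluster = juxtatumor_cluster)}; defaults to matching
#'   labels.
#' @param alpha Significance level on the BH-adjusted p-value.
#' @param minAbsLog2fc Minimum absolute log2 fold change.
#' @param eps Guard added to both means inside the ratio.
#' @return data.frame with one row per (cluster, family): mean scores per
#'   tissue, \code{log2FC}, \code{p}, \code{p_adj}, \code{significant}.
#' @export
tissueContrast <- function(cellScores, meta, pairing = NULL,
                           alpha = 0.001, minAbsLog2fc = 0.25, eps = 1e-9) {
    cl <- as.character(meta$cluster)
    ti <- as.character(meta$tissue)
    tumorClusters <- unique(cl[ti == "tumor"])
    if (is.null(pairing))
        pairing <- setNames(tumorClusters, tumorClusters)
    rows <- list()
    for (tc in names(pairing)) {
        jc <- pairing[[tc]]
        i1 <- which(cl == tc & ti == "tumor")
        i2 <- which(cl == jc & ti == "juxtatumor")
        if (!length(i1) || !length(i2)) {
            warning("no cells for contrast ", tc, " (tumor) vs ", jc,
                    " (juxtatumor); skipped")
            next
        }
        for (f in rownames(cellScores)) {
            s1 <- cellScores[f, i1]
            s2 <- cellScores[f, i2]
            p <- if (all(s1 == s1[1]) && all(s2 == s2[1]) && s1[1] == s2[1]) 1
            else suppressWarnings(
                stats::wilcox.test(s1, s2, exact = FALSE)$p.value)
            rows[[length(rows) + 1L]] <- data.frame(
                cluster = tc, reference_cluster = jc, family = f,
                mean_tumor = mean(s1), mean_juxtatumor = mean(s2),
                log2FC = log2((mean(s1) + eps) / (mean(s2) + eps)),
                p = p)
        }
    }
    if (!length(rows)) stop("no contrastable cluster had cells in both tissues")
    out <- do.call(rbind, rows)
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < alpha & abs(out$log2FC) > minAbsLog2fc
    out
}
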