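## Bulk RNA-seq validation: median-of-ratios normalization, per-gene
## scaling, per-sample ligand x receptor products, tumor vs normal testing.

#' Median-of-ratios size factors
#'
#' Per-sample size factors estimated as the median, over reference genes,
#' of the ratio of the sample's count to the gene's geometric mean across
#' samples (the DESeq2 estimator; genes with a zero in any sample drop out
#' of the reference set). Dividing counts by these factors equalizes
#' sequencing depth.
#'
#' @param counts Genes x samples matrix of non-negative counts.
#' @return Named positive numeric vector, one factor per sample.
#' @export
bulkSizeFactors <- function(counts) {
    counts <- as.matrix(counts)
    if (!any(apply(counts, 1, function(r) all(r > 0))))
        stop("no gene has nonzero counts in every sample; ",
             "median-of-ratios is undefined (consider a pseudo-reference)")
    sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
    setNames(as.numeric(sf), colnames(counts))
}

#' Per-gene centering and scaling
#'
#' Centers each gene at mean 0 and scales to unit sample standard deviation
#' across samples. Zero-variance genes are set to 0 and listed in the
#' \code{"flagged_genes"} attribute.
#'
#' @param mat Genes x samples numeric matrix (normalized counts).
#' @return Matrix of the same shape; attribute \code{flagged_genes} names
#'   the constant genes.
#' @export
scaleGenes <- function(mat) {
    stopifnot(ncol(mat) >= 2L)
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1, stats::sd)
    out <- (mat - mu) / ifelse(sdv == 0, 1, sdv)
    out[sdv == 0, ] <- 0
    attr(out, "flagged_genes") <- rownames(mat)[sdv == 0]
    out
}

#' Ligand x receptor product test on bulk samples
#'
#' For each candidate interaction, computes a per-sample expression product:
#' the complex-level value of the ligand times that of the receptor, on the
#' per-gene scaled layer. Tumor and normal products are compared with a
#' two-sided Wilcoxon rank-sum test, Bonferroni-corrected across the tested
#' pairs. Because products of centered values can be negative, the fold
#' change is computed on the normalized (non-centered) layer's products with
#' a +1 shift: \code{log2((mean_tumor + 1) / (mean_normal + 1))}. A pair is
#' \code{significant} when the adjusted p-value is below \code{alpha} and
#' the fold change is at least \code{minLog2fc}. Pairs with a subunit absent
#' from the matrix are skipped and reported.
#'
#' @param counts Genes x samples raw count matrix.
#' @param condition Per-sample labels, \code{"tumor"} / \code{"normal"};
#'   each condition needs at least 2 samples.
#' @param db [InteractionDB-class] of candidate pairs to test.
#' @param rule Complex aggregation rule, see [complexExpression()].
#' @param alpha Threshold on the Bonferroni-adjusted p-value.
#' @param minLog2fc Minimum product fold change.
#' @return data.frame with one row per tested pair: \code{log2FC}, \code{p},
#'   \code{p_adj}, \code{significant}, plus mean products per condition on
#'   both layers.
#' @export
pairProductTest <- function(counts, condition, db,
                            rule = c("minimum", "mean"),
                            alpha = 0.001, minLog2fc = 1) {
    rule <- match.arg(rule)
    condition <- as.character(condition)
    stopifnot(length(condition) == ncol(counts))
    if (sum(condition == "tumor") < 2L || sum(condition == "normal") < 2L)
        stop("each condition needs at least 2 samples")
    sf <- bulkSizeFactors(counts)
    norm <- sweep(as.matrix(counts), 2, sf, "/")
    scaled <- scaleGenes(norm)

    present <- vapply(seq_len(nInteractions(db)), function(i)
        all(c(ligandSubunits(db)[[i]], receptorSubunits(db)[[i]]) %in%
                rownames(counts)), TRUE)
    if (any(!present))
        message("pairProductTest: ", sum(!present),
                " pair(s) with absent gene(s) skipped")
    idx <- which(present)
    if (!length(idx)) stop("no testable pair (all have absent genes)")

    keepDb <- db
    keepDb@records <- db@records[idx, ]
    Ls <- .complexMatrix(scaled, ligandSubunits(keepDb), rule)
    Rs <- .complexMatrix(scaled, receptorSubunits(keepDb), rule)
    Ln <- .complexMatrix(norm, ligandSubunits(keepDb), rule)
    Rn <- .complexMatrix(norm, receptorSubunits(keepDb), rule)
    prodScaled <- Ls * Rs     # [pair, sample]
    prodNorm <- Ln * Rn
    isT <- condition == "tumor"

    res <- lapply(seq_along(idx), function(i) {
        x <- prodScaled[i, isT]; y <- prodScaled[i, !isT]
        p <- if (all(c(x, y) == x[1])) 1 else
            suppressWarnings(stats::wilcox.test(x, y)$p.value)
        mt <- mean(prodNorm[i, isT]); mn <- mean(prodNorm[i, !isT])
        data.frame(interaction_id = interactionIds(keepDb)[i],
                   mean_product_tumor = mt, mean_product_normal = mn,
                   mean_scaled_tumor = mean(x), mean_scaled_normal = mean(y),
                   log2FC = log2((mt + 1) / (mn + 1)), p = p)
    })
    out <- do.call(rbind, res)
    out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
    out$significant <- out$p_adj < alpha & out$log2FC >= minLog2fc
    rownames(out) <- NULL
    out
}
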