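## Per-interaction emitter/receiver-summed scores, the fold-ratio
## specificity rule, Wilcoxon DE gates, and cross-dataset intersection.

#' Emitter-summed per-interaction scores
#'
#' For every interaction (i, j) and every candidate emitting cluster C, the
#' outgoing score is the emitter's ligand-complex mean times the sum of the
#' receptor-complex means over all K receiving clusters (self included by
#' default, so autocrine channels count):
#' \code{S_C(i,j) = l_i^C * sum_k r_j^k}. Computing the score for every
#' candidate emitter is what makes the downstream specificity comparison
#' possible.
#'
#' @param db An [InteractionDB-class].
#' @param profiles A [ClusterProfiles-class], minimum-percent filter already
#'   applied.
#' @param rule Complex aggregation rule, see [complexExpression()].
#' @param includeFocal Logical; keep each candidate cluster itself inside
#'   the receiver (resp. emitter) sum.
#' @return Interactions x clusters numeric matrix of scores.
#' @export
outgoingInteractionScores <- function(db, profiles,
                                      rule = c("minimum", "mean"),
                                      includeFocal = TRUE) {
    m <- meanExpression(profiles)
    L <- .complexMatrix(m, ligandSubunits(db), rule)
    R <- .complexMatrix(m, receptorSubunits(db), rule)
    vals <- if (includeFocal) L * rowSums(R)
            else L * (rowSums(R) - R)
    dimnames(vals) <- list(interactionIds(db), colnames(m))
    vals
}

#' Receiver-summed per-interaction scores
#'
#' Mirror of [outgoingInteractionScores()] for incoming communication: the
#' candidate cluster carries the receptor and the ligand-complex means are
#' summed over all emitting clusters,
#' \code{S_C(i,j) = (sum_k l_i^k) * r_j^C}.
#'
#' @inheritParams outgoingInteractionScores
#' @return Interactions x clusters numeric matrix of scores.
#' @export
incomingInteractionScores <- function(db, profiles,
                                      rule = c("minimum", "mean"),
                                      includeFocal = TRUE) {
    m <- meanExpression(profiles)
    L <- .complexMatrix(m, ligandSubunits(db), rule)
    R <- .complexMatrix(m, receptorSubunits(db), rule)
    vals <- if (includeFocal) R * rowSums(L)
            else R * (rowSums(L) - L)
    dimnames(vals) <- list(interactionIds(db), colnames(m))
    vals
}

#' Specificity filter on one interaction's scores
#'
#' An interaction is focal-specific when the focal cluster's score is at
#' least \code{ratio} times the largest score among all competing clusters
#' (inclusive bound). When every competitor scores 0, the ratio is undefined
#' and the interaction passes whenever the focal score is positive; the
#' realized ratio is then reported as \code{Inf}.
#'
#' @param scores Named numeric vector of one interaction's scores, one entry
#'   per candidate cluster.
#' @param focal Name of the focal cluster (must be present).
#' @param ratio Required fold margin over the best competitor.
#' @return List with \code{pass} (logical) and \code{ratio} (realized
#'   focal / max-competitor ratio, \code{Inf} when all competitors are 0).
#' @export
specificityFilter <- function(scores, focal, ratio = 1.5) {
    if (!focal %in% names(scores))
        stop("focal cluster '", focal, "' not among the scored clusters")
    f <- scores[[focal]]
    others <- scores[setdiff(names(scores), focal)]
    mx <- if (length(others)) max(others) else 0
    if (mx == 0)
        return(list(pass = f > 0, ratio = if (f > 0) Inf else NA_real_))
    list(pass = f >= ratio * mx, ratio = f / mx)
}

## Seurat-convention fold change on log2-normalized data: back-transform,
## average, re-log with a +1 guard on both means.
.log2FC <- function(lg, i1, i2) {
    m1 <- Matrix::rowMeans(2^lg[, i1, drop = FALSE] - 1)
    m2 <- Matrix::rowMeans(2^lg[, i2, drop = FALSE] - 1)
    log2((m1 + 1) / (m2 + 1))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene: fold change on de-logged means (\code{log2((mean(2^x - 1) + 1)
#' / (mean(2^x - 1) + 1))}), pre-filtering to genes with
#' \code{|log2FC| >= minLog2fc} before testing, a two-sided Wilcoxon
#' rank-sum test on the log-normalized values, and Bonferroni correction
#' over the tested genes. A gene is \code{selected} when its fold change is
#' at least \code{minLog2fc} (up in group 1) and its adjusted p-value is
#' below \code{alpha}.
#'
#' @param sce A \code{SingleCellExperiment} with a \code{logcounts} assay
#'   (raw counts used for the percent-expressed columns when present).
#' @param cells1,cells2 Indices or logical vectors selecting the two groups.
#' @param genes Optional gene subset to test (default: all genes).
#' @param minLog2fc Fold-change pre-filter and selection threshold.
#' @param alpha Selection threshold on the Bonferroni-adjusted p-value.
#' @return data.frame with \code{gene}, \code{log2FC}, \code{p},
#'   \code{p_adj}, \code{pct1}, \code{pct2}, \code{selected}; one row per
#'   tested gene.
#' @export
wilcoxonDE <- function(sce, cells1, cells2, genes = NULL,
                       minLog2fc = 0.25, alpha = 0.05) {
    lg <- assay(sce, "logcounts")
    counts <- if ("counts" %in% assayNames(sce)) assay(sce, "counts") else lg
    if (is.logical(cells1)) cells1 <- which(cells1)
    if (is.logical(cells2)) cells2 <- which(cells2)
    if (!length(cells1) || !length(cells2))
        stop("both cell groups must be non-empty")
    if (!is.null(genes)) {
        genes <- intersect(genes, rownames(lg))
        lg <- lg[genes, , drop = FALSE]
        counts <- counts[genes, , drop = FALSE]
    }
    fc <- .log2FC(lg, cells1, cells2)
    keep <- which(abs(fc) >= minLog2fc)
    if (!length(keep))
        return(data.frame(gene = character(0), log2FC = numeric(0),
                          p = numeric(0), p_adj = numeric(0),
                          pct1 = numeric(0), pct2 = numeric(0),
                          selected = logical(0)))
    x1 <- as.matrix(lg[keep, cells1, drop = FALSE])
    x2 <- as.matrix(lg[keep, cells2, drop = FALSE])
    p <- vapply(seq_along(keep), function(i) {
        a <- x1[i, ]; b <- x2[i, ]
        if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
        suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }, 0)
    out <- data.frame(
        gene = rownames(lg)[keep],
        log2FC = fc[keep],
        p = p,
        p_adj = stats::p.adjust(p, method = "bonferroni"),
        pct1 = Matrix::rowMeans(counts[keep, cells1, drop = FALSE] > 0),
        pct2 = Matrix::rowMeans(counts[keep, cells2, drop = FALSE] > 0),
        row.names = NULL)
    out$selected <- out$log2FC >= minLog2fc & out$p_adj < alpha
    out
}

#' Focal-cluster-specific communication vocabulary
#'
#' Pairwise differential expression of communication genes between the focal
#' cluster and every other cluster. Against each competitor, a gene
#' qualifies either with (branch 1) a fold change of at least 0.25, or
#' (branch 2) a fold change of at least 0.1 together with a competitor
#' expressing fraction below 10 percent and an expressing-fraction gap above
#' 5 points; both branches additionally require an adjusted p-value below
#' \code{alpha}. The vocabulary is the intersection of the qualifying sets
#' over all pairwise comparisons.
#'
#' @param sce A \code{SingleCellExperiment} with \code{logcounts}.
#' @param focal Focal cluster label.
#' @param others Character vector of competitor cluster labels (non-empty,
#'   focal excluded).
#' @param commGenes Communication genes to which the comparison is
#'   restricted.
#' @param alpha Adjusted p-value threshold.
#' @param cluster Per-cell cluster labels; defaults to
#'   \code{colData(sce)$cluster}.
#' @return Character vector of vocabulary genes.
#' @export
vocabularyGenes <- function(sce, focal, others, commGenes, alpha = 0.05,
                            cluster = colData(sce)$cluster) {
    others <- setdiff(others, focal)
    if (!length(others)) stop("'others' must contain at least one cluster")
    cl <- as.character(cluster)
    i1 <- which(cl == focal)
    vocab <- NULL
    for (oc in others) {
        de <- wilcoxonDE(sce, i1, which(cl == oc), genes = commGenes,
                         minLog2fc = 0.1, alpha = alpha)
        sig <- de$p_adj < alpha
        b1 <- sig & de$log2FC >= 0.25
        b2 <- sig & de$log2FC >= 0.1 & de$pct2 < 0.10 &
            (de$pct1 - de$pct2) > 0.05
        hits <- de$gene[b1 | b2]
        vocab <- if (is.null(vocab)) hits else intersect(vocab, hits)
        if (!length(vocab)) break
    }
    sort(vocab)
}

#' Screen one dataset for focal-cluster-specific interactions
#'
#' Runs the full per-dataset screen for both directions: (1) per-interaction
#' emitter-summed (outgoing) and receiver-summed (incoming) scores on
#' tumor-tissue profiles after the minimum-percent filter; (2) the
#' fold-ratio specificity rule against every competing cluster; (3) a
#' Wilcoxon differential-expression gate requiring the focal-side molecule
#' (every ligand subunit for outgoing, every receptor subunit for incoming;
#' both sides with \code{deGate = "both"}) to be up-regulated in the focal
#' cluster's tumor cells versus the reference cluster's juxtatumor cells.
#' An interaction is a final hit when it passes both gates.
#'
#' With \code{perPair = TRUE} the specificity rule is instead evaluated on
#' the individual cluster-pair contributions: the focal cluster's best pair
#' contribution must exceed \code{ratio} times every pair contribution not
#' involving the focal cluster on the scored side.
#'
#' @param db An [InteractionDB-class].
#' @param sce A \code{SingleCellExperiment} with \code{counts},
#'   \code{logcounts}, and \code{colData} columns \code{cluster} and
#'   \code{tissue}.
#' @param focal Focal cluster label (tumor tissue).
#' @param reference Reference cluster label (juxtatumor tissue), e.g. the
#'   presumed cell of origin.
#' @param ratio Specificity fold margin.
#' @param minPct Minimum expressing fraction for communication genes.
#' @param deLog2fc,deAlpha Thresholds of the DE gate.
#' @param rule Complex aggregation rule.
#' @param deGate \code{"focal_side"} (default) or \code{"both"}.
#' @param includeFocal Keep the focal cluster inside the Eq.-2 sum.
#' @param perPair Use the per-cluster-pair specificity variant.
#' @param dataset Dataset label recorded in the result.
#' @return data.frame with one row per interaction x direction: focal
#'   score, best competitor, realized ratio, specificity and DE flags, and
#'   \code{final}.
#' @export
screenDataset <- function(db, sce, focal, reference, ratio = 1.5,
                          minPct = 0.10, deLog2fc = 0.25, deAlpha = 0.05,
                          rule = c("minimum", "mean"),
                          deGate = c("focal_side", "both"),
                          includeFocal = TRUE, perPair = FALSE,
                          dataset = "dataset1") {
    rule <- match.arg(rule)
    deGate <- match.arg(deGate)
    cl <- as.character(colData(sce)$cluster)
    ti <- as.character(colData(sce)$tissue)
    if (!any(cl == focal & ti == "tumor"))
        stop("focal cluster '", focal, "' has no tumor cells")
    if (!any(cl == reference & ti == "juxtatumor"))
        stop("reference cluster '", reference, "' has no juxtatumor cells")

    tumor <- sce[, ti == "tumor"]
    profiles <- computeProfiles(tumor, groupBy = "cluster")
    profiles <- applyMinPctFilter(profiles, dbGenes(db), minPct = minPct)

    out <- outgoingInteractionScores(db, profiles, rule, includeFocal)
    inc <- incomingInteractionScores(db, profiles, rule, includeFocal)

    ## DE gate: focal tumor cells vs reference juxtatumor cells, restricted
    ## to the genes that can gate an interaction.
    de <- wilcoxonDE(sce, which(cl == focal & ti == "tumor"),
                     which(cl == reference & ti == "juxtatumor"),
                     genes = dbGenes(db), minLog2fc = deLog2fc,
                     alpha = deAlpha)
    upGenes <- de$gene[de$selected]
    allUp <- function(subunits) all(subunits %in% upGenes)

    m <- meanExpression(profiles)
    L <- .complexMatrix(m, ligandSubunits(db), rule)
    R <- .complexMatrix(m, receptorSubunits(db), rule)

    oneDirection <- function(vals, direction) {
        spec <- lapply(seq_len(nrow(vals)), function(i)
            specificityFilter(vals[i, ], focal, ratio))
        if (perPair) {
            spec <- lapply(seq_len(nrow(vals)), function(i) {
                contrib <- outer(L[i, ], R[i, ])  # [emitter, receiver]
                fvals <- if (direction == "outgoing") contrib[focal, ]
                         else contrib[, focal]
                comp <- if (direction == "outgoing")
                    contrib[setdiff(rownames(contrib), focal), , drop = FALSE]
                else contrib[, setdiff(colnames(contrib), focal), drop = FALSE]
                mx <- max(comp)
                if (mx == 0)
                    list(pass = max(fvals) > 0,
                         ratio = if (max(fvals) > 0) Inf else NA_real_)
                else list(pass = max(fvals) >= ratio * mx,
                          ratio = max(fvals) / mx)
            })
        }
        gated <- vapply(seq_len(nInteractions(db)), function(i) {
            lig <- ligandSubunits(db)[[i]]
            rec <- receptorSubunits(db)[[i]]
            side <- if (direction == "outgoing") allUp(lig) else allUp(rec)
            if (deGate == "both") side <- allUp(lig) && allUp(rec)
            side
        }, TRUE)
        competitors <- setdiff(colnames(vals), focal)
        data.frame(
            dataset = dataset,
            interaction_id = rownames(vals),
            direction = direction,
            focal_score = vals[, focal],
            max_competitor = if (length(competitors))
                apply(vals[, competitors, drop = FALSE], 1, max) else 0,
            ratio = vapply(spec, function(s) s$ratio, 0),
            passes_specificity = vapply(spec, function(s) s$pass, TRUE),
            passes_de = gated,
            row.names = NULL)
    }
    res <- rbind(oneDirection(out, "outgoing"), oneDirection(inc, "incoming"))
    res$final <- res$passes_specificity & res$passes_de
    res
}

#' Intersect screen results across datasets
#'
#' Per interaction and direction, counts in how many datasets it is a final
#' hit and assigns a tier: \code{"all"} (every dataset), \code{">=min"}
#' (at least \code{minDatasets}), hits below that threshold are dropped from
#' the reported table (kept in the \code{"full"} attribute).
#'
#' @param results Named list of [screenDataset()] data.frames, one per
#'   dataset; names must be unique.
#' @param minDatasets Minimum number of datasets for a reported hit.
#' @return data.frame sorted by tier then interaction id, with one
#'   membership column per dataset, \code{n_datasets} and \code{tier}.
#' @export
intersectScreens <- function(results, minDatasets = 2) {
    if (length(results) < 2L) stop("need at least 2 datasets")
    if (is.null(names(results)) || anyDuplicated(names(results)))
        stop("results must be a uniquely named list (one entry per dataset)")
    hits <- lapply(results, function(r)
        unique(paste(r$interaction_id[r$final], r$direction[r$final],
                     sep = "\r")))
    universe <- sort(unique(unlist(hits)))
    if (!length(universe))
        return(data.frame(interaction_id = character(0),
                          direction = character(0),
                          n_datasets = integer(0), tier = character(0)))
    member <- vapply(hits, function(h) universe %in% h,
                     logical(length(universe)))
    member <- matrix(member, nrow = length(universe),
                     dimnames = list(NULL, names(results)))
    parts <- do.call(rbind, strsplit(universe, "\r", fixed = TRUE))
    out <- data.frame(interaction_id = parts[, 1], direction = parts[, 2],
                      member, n_datasets = rowSums(member),
                      check.names = FALSE)
    out$tier <- ifelse(out$n_datasets == length(results), "all",
                       ifelse(out$n_datasets >= minDatasets, ">=min",
                              "below"))
    out <- out[order(match(out$tier, c("all", ">=min", "below")),
                     out$interaction_id), ]
    reported <- out[out$n_datasets >= minDatasets, , drop = FALSE]
    rownames(reported) <- NULL
    attr(reported, "full") <- out
    reported
}
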