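#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
NULL

## Controlled vocabulary for communication-molecule families.
.FAMILY_LEVELS <- c("cytokine", "chemokine", "immune_checkpoint",
                    "growth_factor", "cell_adhesion", "other")

#' Ligand-receptor interaction database
#'
#' Holds a directed ligand-to-receptor interaction dictionary. Each record
#' has 1-2 ligand subunit genes and 1-3 receptor subunit genes (heterodimeric
#' complexes), a molecule-family label from a controlled vocabulary
#' (cytokine, chemokine, immune_checkpoint, growth_factor, cell_adhesion,
#' other), an optional free-text subfamily, and a provenance flag
#' (\code{original} or \code{curated_addition}). The number of records is the
#' summation length of the cluster-pair communication score.
#'
#' @slot records A [S4Vectors::DataFrame] with columns \code{interaction_id}
#'   (character), \code{ligand} and \code{receptor}
#'   ([IRanges::CharacterList] of subunit gene symbols), \code{family},
#'   \code{subfamily} and \code{provenance} (character).
#'
#' @seealso [readInteractionTable()], [mergeDatabases()], [familyGeneSets()],
#'   [validateDB()]
#' @export
setClass("InteractionDB", slots = c(records = "DataFrame"))

setValidity("InteractionDB", function(object) {
    rec <- object@records
    need <- c("interaction_id", "ligand", "receptor", "family",
              "subfamily", "provenance")
    if (!all(need %in% colnames(rec)))
        return(paste("records must have columns:",
                     paste(setdiff(need, colnames(rec)), collapse = ", ")))
    if (nrow(rec) == 0L) return(TRUE)
    nl <- S4Vectors::elementNROWS(rec$ligand)
    nr <- S4Vectors::elementNROWS(rec$receptor)
    if (any(nl < 1L) || any(nr < 1L))
        return("every record needs at least one ligand and one receptor subunit")
    syms <- c(unlist(rec$ligand), unlist(rec$receptor))
    if (any(is.na(syms)) || any(!nzchar(syms)))
        return("subunit symbols must be non-empty")
    if (any(!rec$family %in% .FAMILY_LEVELS))
        return(paste("family labels must be in:",
                     paste(.FAMILY_LEVELS, collapse = ", ")))
    TRUE
})

#' Per-group expression profiles for communication scoring
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding, per
#' (cluster, tissue) group of cells, the arithmetic mean of log-normalized
#' expression (assay \code{"mean"}) and the fraction of the group's cells
#' with a raw count above zero (assay \code{"pct"}). Columns are groups;
#' \code{colData} carries \code{cluster}, \code{tissue} and \code{n_cells}.
#' The mean layer is what enters the communication-score products; the pct
#' layer drives the minimum-percent-expressed filter.
#'
#' @seealso [computeProfiles()], [applyMinPctFilter()]
#' @export
setClass("ClusterProfiles", contains = "SummarizedExperiment")

setValidity("ClusterProfiles", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("mean", "pct") %in% a))
        return("assays 'mean' and 'pct' are required")
    pct <- SummarizedExperiment::assay(object, "pct")
    if (any(pct < 0 | pct > 1))
        return("pct values must lie in [0, 1]")
    if (any(SummarizedExperiment::assay(object, "mean") < 0))
        return("mean expression must be non-negative")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("cluster", "n_cells") %in% colnames(cd)))
        return("colData needs 'cluster' and 'n_cells'")
    TRUE
})

#' Cluster-pair communication score matrix
#'
#' Result container for all ordered cluster-pair communication scores
#' (self-pairs included, so autocrine signalling is scored). Slot
#' \code{scores} is the K x K total-score matrix (rows emit, columns
#' receive); \code{contributions} is the long per-interaction decomposition
#' (emitter, receiver, interaction_id, family, contribution) that sums to
#' the totals; \code{rescaled} records whether scores were mapped to the
#' 0-100 scale.
#'
#' @seealso [allPairScores()], [rescaleTo100()]
#' @export
setClass("CommScoreMatrix",
         slots = c(scores = "matrix", contributions = "DataFrame",
                   rule = "character", rescaled = "logical"))

setValidity("CommScoreMatrix", function(object) {
    if (nrow(object@scores) != ncol(object@scores))
        return("scores must be a square emitter x receiver matrix")
    if (any(object@scores < 0))
        return("communication scores are non-negative")
    TRUE
})
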