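## Negative-binomial single-cell and bulk simulators with planted
## communication channels and known ground truth.

#' Simulation configuration for the single-cell generator
#'
#' Validated parameter list for [simulateSCDataset()]. The defaults describe
#' the generator's reference scenario: 6 tumor-tissue clusters (a malignant
#' focal cluster plus 5 shared microenvironment clusters, each of which also
#' exists in the adjacent tissue, where a reference cluster stands in for
#' the focal population's cell of origin), 400 cells per (cluster, tissue)
#' group, gene baseline means log-normal around \code{mu} with
#' negative-binomial dispersion \code{theta}, and independent Bernoulli
#' dropout.
#'
#' @param nClusters Number of tumor-tissue clusters, focal included (>= 2).
#' @param cellsPerCluster Cells per (cluster, tissue) group.
#' @param nGenes Total gene universe (database genes are embedded first,
#'   filler genes complete the universe). The default of 1000 keeps
#'   per-cell totals above the 1000-UMI quality gate the pipeline itself
#'   applies, so normalized values sit in the same regime as real data.
#' @param mu Baseline negative-binomial mean.
#' @param theta Negative-binomial dispersion (\code{size} parameter).
#' @param dropout Bernoulli zero-inflation probability.
#' @param focal,reference Labels of the focal (tumor-only) and reference
#'   (juxtatumor-only) clusters.
#' @param nPatients Patients cycled over cells.
#' @param dataset Dataset label.
#' @param plantedChannels List of channels, each
#'   \code{list(interaction_id =, f_L =, f_R =, direction =)}; ligand fold
#'   \code{f_L} is applied to the ligand subunits in the focal cluster,
#'   receptor fold \code{f_R} to the receptor subunits in the focal cluster
#'   (folds >= 1).
#' @param plantedFamilyShift Optional \code{list(cluster =, family =,
#'   fold =)} multiplying all genes of one family in one tumor cluster.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nClusters = 6, cellsPerCluster = 400, nGenes = 1000,
                      mu = 2, theta = 2, dropout = 0.3,
                      focal = "cancer", reference = "PT",
                      nPatients = 3, dataset = "sim1",
                      plantedChannels = list(),
                      plantedFamilyShift = NULL, seed = 1) {
    stopifnot(nClusters >= 2, cellsPerCluster >= 1, nGenes >= 1,
              mu > 0, theta > 0, dropout >= 0, dropout <= 1)
    for (ch in plantedChannels) {
        stopifnot(!is.null(ch$interaction_id))
        if (!is.null(ch$f_L)) stopifnot(ch$f_L >= 1)
        if (!is.null(ch$f_R)) stopifnot(ch$f_R >= 1)
    }
    structure(list(nClusters = nClusters, cellsPerCluster = cellsPerCluster,
                   nGenes = nGenes, mu = mu, theta = theta,
                   dropout = dropout, focal = focal, reference = reference,
                   nPatients = nPatients, dataset = dataset,
                   plantedChannels = plantedChannels,
                   plantedFamilyShift = plantedFamilyShift, seed = seed),
              class = "SimConfig")
}

#' Simulate an annotated single-cell dataset with planted channels
#'
#' Draws genes x cells counts from a negative binomial with gene-level
#' baseline means (log-normal around \code{mu}) and dispersion \code{theta},
#' thinned by independent Bernoulli dropout. Cluster structure is planted
#' only where a channel specifies it: ligand (and/or receptor) subunit genes
#' of the channel's interaction are multiplied by the configured fold in the
#' focal cluster's tumor cells. The focal cluster exists only in tumor
#' tissue and the reference cluster only in juxtatumor tissue (mirroring a
#' malignant population and its presumed cell of origin); all other clusters
#' exist in both tissues at baseline.
#'
#' @param cfg A [simConfig()] object.
#' @param db An [InteractionDB-class]; planted channels must reference its
#'   interaction ids, and all database genes are embedded in the gene
#'   universe.
#' @return List with \code{sce} (a \code{SingleCellExperiment} with
#'   \code{counts} and colData \code{cluster}, \code{tissue},
#'   \code{patient}, \code{dataset}) and \code{truth} (planted folds per
#'   gene x cluster, channel expectations, gene baseline means).
#' @export
simulateSCDataset <- function(cfg, db) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    commGenes <- dbGenes(db)
    if (length(commGenes) > cfg$nGenes)
        stop("nGenes smaller than the database gene universe")
    genes <- c(commGenes,
               sprintf("FILLER%03d", seq_len(cfg$nGenes - length(commGenes))))
    baseMu <- cfg$mu * exp(stats::rnorm(length(genes), 0, 0.25))
    names(baseMu) <- genes

    shared <- paste0("TME", seq_len(cfg$nClusters - 1L))
    groups <- rbind(
        data.frame(cluster = c(cfg$focal, shared), tissue = "tumor"),
        data.frame(cluster = c(cfg$reference, shared), tissue = "juxtatumor"))

    ## fold matrix: genes x (cluster|tissue) groups, default 1
    gkey <- paste(groups$cluster, groups$tissue, sep = "|")
    fold <- matrix(1, length(genes), nrow(groups),
                   dimnames = list(genes, gkey))
    ids <- interactionIds(db)
    channels <- list()
    for (ch in cfg$plantedChannels) {
        i <- match(ch$interaction_id, ids)
        if (is.na(i))
            stop("planted channel references unknown interaction: ",
                 ch$interaction_id)
        fkey <- paste(cfg$focal, "tumor", sep = "|")
        f_L <- if (is.null(ch$f_L)) 1 else ch$f_L
        f_R <- if (is.null(ch$f_R)) 1 else ch$f_R
        lig <- ligandSubunits(db)[[i]]
        rec <- receptorSubunits(db)[[i]]
        fold[lig, fkey] <- fold[lig, fkey] * f_L
        fold[rec, fkey] <- fold[rec, fkey] * f_R
        channels[[length(channels) + 1L]] <- list(
            interaction_id = ch$interaction_id,
            direction = if (is.null(ch$direction)) "outgoing" else ch$direction,
            f_L = f_L, f_R = f_R,
            expected_hit = max(f_L, f_R) >= 1.5)
    }
    if (!is.null(cfg$plantedFamilyShift)) {
        fs <- cfg$plantedFamilyShift
        fg <- intersect(familyGeneSets(db)[[fs$family]], genes)
        key <- paste(fs$cluster, "tumor", sep = "|")
        fold[fg, key] <- fold[fg, key] * fs$fold
    }

    nc <- cfg$cellsPerCluster
    mats <- vector("list", nrow(groups))
    for (g in seq_len(nrow(groups))) {
        mu_g <- baseMu * fold[, gkey[g]]
        m <- matrix(stats::rnbinom(length(genes) * nc,
                                   mu = rep(mu_g, nc), size = cfg$theta),
                    nrow = length(genes))
        if (cfg$dropout > 0)
            m <- m * matrix(stats::rbinom(length(m), 1, 1 - cfg$dropout),
                            nrow = nrow(m))
        mats[[g]] <- m
    }
    counts <- do.call(cbind, mats)
    rownames(counts) <- genes
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
    cd <- S4Vectors::DataFrame(
        cluster = rep(groups$cluster, each = nc),
        tissue = rep(groups$tissue, each = nc),
        patient = paste0("patient", (seq_len(ncol(counts)) %% cfg$nPatients) + 1L),
        dataset = cfg$dataset,
        row.names = colnames(counts))
    sce <- SingleCellExperiment(assays = list(counts = counts), colData = cd)
    list(sce = sce,
         truth = list(fold = fold, channels = channels, base_mu = baseMu,
                      dropout = cfg$dropout))
}

#' Simulation configuration for the bulk generator
#'
#' @param nGenes Gene universe size (database genes embedded first).
#' @param nTumor,nNormal Samples per condition (>= 2).
#' @param mu Baseline mean before library-size scaling.
#' @param theta Negative-binomial dispersion.
#' @param libSdLog Log-normal standard deviation of per-sample library-size
#'   factors.
#' @param plantedPairs List of \code{list(interaction_id =, fold =)}; the
#'   fold multiplies both the ligand and receptor subunit genes in tumor
#'   samples.
#' @param seed Integer seed.
#' @return A validated list of class \code{BulkSimConfig}.
#' @export
bulkSimConfig <- function(nGenes = 200, nTumor = 60, nNormal = 60,
                          mu = 100, theta = 4, libSdLog = 0.3,
                          plantedPairs = list(), seed = 1) {
    stopifnot(nTumor >= 2, nNormal >= 2, mu > 0, theta > 0, libSdLog >= 0)
    for (pp in plantedPairs) stopifnot(pp$fold >= 1)
    structure(list(nGenes = nGenes, nTumor = nTumor, nNormal = nNormal,
                   mu = mu, theta = theta, libSdLog = libSdLog,
                   plantedPairs = plantedPairs, seed = seed),
              class = "BulkSimConfig")
}

#' Simulate a bulk count matrix with condition labels
#'
#' Negative-binomial counts with per-sample library-size factors drawn
#' log-normally; planted pairs get their ligand and receptor subunit genes
#' multiplied by the configured fold in tumor samples only.
#'
#' @param cfg A [bulkSimConfig()] object.
#' @param db An [InteractionDB-class] the planted pairs refer to.
#' @return List with \code{counts} (genes x samples), \code{condition}
#'   (per-sample \code{"tumor"} / \code{"normal"}), \code{lib_factors}, and
#'   \code{truth} (planted fold per gene).
#' @export
simulateBulkDataset <- function(cfg, db) {
    stopifnot(inherits(cfg, "BulkSimConfig"))
    set.seed(cfg$seed)
    commGenes <- dbGenes(db)
    if (length(commGenes) > cfg$nGenes)
        stop("nGenes smaller than the database gene universe")
    genes <- c(commGenes,
               sprintf("FILLER%03d", seq_len(cfg$nGenes - length(commGenes))))
    baseMu <- cfg$mu * exp(stats::rnorm(length(genes), 0, 0.5))
    names(baseMu) <- genes
    foldT <- setNames(rep(1, length(genes)), genes)
    ids <- interactionIds(db)
    for (pp in cfg$plantedPairs) {
        i <- match(pp$interaction_id, ids)
        if (is.na(i))
            stop("planted pair references unknown interaction: ",
                 pp$interaction_id)
        gset <- c(ligandSubunits(db)[[i]], receptorSubunits(db)[[i]])
        foldT[gset] <- foldT[gset] * pp$fold
    }
    n <- cfg$nTumor + cfg$nNormal
    condition <- rep(c("tumor", "normal"), c(cfg$nTumor, cfg$nNormal))
    lib <- exp(stats::rnorm(n, 0, cfg$libSdLog))
    counts <- matrix(0L, length(genes), n,
                     dimnames = list(genes, sprintf("sample%03d", seq_len(n))))
    for (s in seq_len(n)) {
        mu_s <- baseMu * lib[s] * (if (condition[s] == "tumor") foldT else 1)
        counts[, s] <- stats::rnbinom(length(genes), mu = mu_s,
                                      size = cfg$theta)
    }
    list(counts = counts, condition = condition, lib_factors = lib,
         truth = list(fold_tumor = foldT, base_mu = baseMu))
}

#' Small synthetic ligand-receptor database
#'
#' Programmatically built interaction dictionary used by the simulator,
#' examples and tests: \code{n} single-subunit interactions
#' (\code{LG#} -> \code{RC#}) cycled over the five molecule families, plus
#' optionally a heterodimeric receptor interaction
#' (\code{HLG1 -> HRC1+HRC2}). Entirely synthetic gene symbols; not a
#' curated resource.
#'
#' @param n Number of single-subunit interactions.
#' @param heterodimer Add one two-subunit receptor record.
#' @return An [InteractionDB-class].
#' @export
syntheticInteractionDB <- function(n = 20, heterodimer = TRUE) {
    fams <- rep(c("cytokine", "chemokine", "immune_checkpoint",
                  "growth_factor", "cell_adhesion"), length.out = n)
    lig <- as.list(sprintf("LG%02d", seq_len(n)))
    rec <- as.list(sprintf("RC%02d", seq_len(n)))
    if (heterodimer) {
        lig <- c(lig, list("HLG1"))
        rec <- c(rec, list(c("HRC1", "HRC2")))
        fams <- c(fams, "growth_factor")
    }
    InteractionDB(ligand = lig, receptor = rec, family = fams)
}
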