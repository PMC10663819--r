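suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(SingleCellExperiment)
})

## Build a ClusterProfiles object directly from matrices (bypasses the
## count-level pipeline so scoring can be tested in isolation).
makeProfiles <- function(meanMat, pctMat = NULL, nCells = NULL) {
    if (is.null(pctMat))
        pctMat <- matrix(1, nrow(meanMat), ncol(meanMat),
                         dimnames = dimnames(meanMat))
    if (is.null(nCells)) nCells <- rep(10L, ncol(meanMat))
    se <- SummarizedExperiment(
        assays = list(mean = meanMat, pct = pctMat),
        colData = S4Vectors::DataFrame(cluster = colnames(meanMat),
                                       n_cells = nCells,
                                       row.names = colnames(meanMat)))
    new("ClusterProfiles", se)
}

## Minimal SingleCellExperiment from a counts matrix and labels.
makeSCE <- function(counts, cluster, tissue = "tumor",
                    patient = "p1", dataset = "d1") {
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("c", seq_len(ncol(counts)))
    SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            cluster = rep_len(cluster, ncol(counts)),
            tissue = rep_len(tissue, ncol(counts)),
            patient = rep_len(patient, ncol(counts)),
            dataset = rep_len(dataset, ncol(counts)),
            row.names = colnames(counts)))
}

## Independent brute-force oracle for the cluster-pair communication score:
## explicit loops over records and subunits, no shared code with the
## package's matrix implementation.
oraclePairScore <- function(db, meanMat, emitter, receiver,
                            rule = "minimum") {
    total <- 0
    lig <- as.list(ligandSubunits(db))
    rec <- as.list(receptorSubunits(db))
    agg <- function(subunits, group) {
        vals <- numeric(length(subunits))
        for (k in seq_along(subunits)) {
            g <- subunits[k]
            vals[k] <- if (g %in% rownames(meanMat)) meanMat[g, group] else 0
        }
        if (rule == "minimum") min(vals) else mean(vals)
    }
    for (i in seq_along(lig))
        total <- total + agg(lig[[i]], emitter) * agg(rec[[i]], receiver)
    total
}

## Random small scoring instance: genes, clusters, interactions with
## occasional heterodimers; returns db + profiles.
randomInstance <- function(seed, maxGenes = 25, maxClusters = 6,
                           maxInteractions = 20) {
    set.seed(seed)
    nG <- sample(6:maxGenes, 1)
    nK <- sample(2:maxClusters, 1)
    nI <- sample(3:maxInteractions, 1)
    genes <- sprintf("G%02d", seq_len(nG))
    lig <- lapply(seq_len(nI), function(i)
        sample(genes, sample(1:2, 1, prob = c(0.8, 0.2))))
    rec <- lapply(seq_len(nI), function(i)
        sample(genes, sample(1:3, 1, prob = c(0.7, 0.2, 0.1))))
    db <- InteractionDB(
        ligand = lig, receptor = rec,
        family = sample(c("cytokine", "chemokine", "growth_factor"),
                        nI, replace = TRUE),
        interaction_id = sprintf("int%02d", seq_len(nI)))
    m <- matrix(round(stats::rexp(nG * nK, 1), 4), nG, nK,
                dimnames = list(genes, paste0("K", seq_len(nK))))
    list(db = db, profiles = makeProfiles(m), mean = m)
}

## One full synthetic screen run under a given seed; shared by the
## recovery and null-calibration suites.
runScenarioSeed <- function(seed, planted = TRUE, db = NULL) {
    if (is.null(db)) db <- syntheticInteractionDB()
    channels <- if (planted)
        list(list(interaction_id = interactionIds(db)[1], f_L = 8))
    else list()
    cfg <- simConfig(plantedChannels = channels, seed = seed)
    sim <- simulateSCDataset(cfg, db)
    sce <- suppressMessages(normalizeLog(sim$sce))
    scr <- suppressMessages(
        screenDataset(db, sce, focal = cfg$focal, reference = cfg$reference))
    scr
}
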