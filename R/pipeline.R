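## Orchestration: end-to-end screen run with config, TSV outputs and a JSON
## run manifest.

#' @importFrom jsonlite write_json
NULL

.writeTSV <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

.manifest <- function(outDir, cfg, inputs = list()) {
    checksums <- lapply(inputs, function(p)
        if (is.character(p) && file.exists(p))
            as.character(tools::md5sum(p)) else NULL)
    man <- list(package = "CCCscreen",
                version = as.character(utils::packageVersion("CCCscreen")),
                r_version = as.character(getRversion()),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                config = cfg, input_md5 = checksums)
    jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
}

.defaultThresholds <- function() list(
    min_pct = 0.10, specificity_ratio = 1.5,
    de_log2fc = 0.25, de_alpha = 0.05,
    family_alpha = 0.001, family_log2fc = 0.25,
    bulk_alpha = 0.001, bulk_log2fc = 1,
    complex_rule = "minimum",
    qc_min_genes = 200, qc_min_umi = 1000, qc_max_mito = 0.20)

.loadConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(.defaultThresholds(), config)
    cfg
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full communication screen
#'
#' Orchestrates QC filtering, log normalization, per-cluster profiles,
#' family scores with the tumor vs adjacent-tissue contrast, the cluster-pair
#' communication matrix, and the focal-cluster specificity screen; writes all
#' result tables as TSV plus a JSON manifest (thresholds, versions, seed,
#' input checksums) to \code{out_dir}.
#'
#' @param config Either a named list or a YAML file path. Required entries:
#'   \code{focal}, \code{reference}, \code{out_dir}, and either
#'   \code{db_path} + \code{sc_path} + \code{meta_path} (file inputs) or
#'   \code{db} + \code{sce} (in-memory objects). Optional entries override
#'   the default thresholds (\code{min_pct}, \code{specificity_ratio},
#'   \code{de_log2fc}, \code{de_alpha}, \code{family_alpha},
#'   \code{family_log2fc}, \code{complex_rule}, QC thresholds).
#' @return The output directory, invisibly; side effect: \code{profiles.tsv},
#'   \code{family_scores.tsv}, \code{family_contrast.tsv},
#'   \code{pair_scores.tsv}, \code{screen.tsv}, \code{manifest.json}.
#' @export
runScreen <- function(config) {
    cfg <- .loadConfig(config)
    for (k in c("focal", "reference", "out_dir"))
        if (is.null(cfg[[k]])) stop("config entry '", k, "' is required")
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

    db <- .stage("lr_database", {
        if (!is.null(cfg[["db"]])) cfg[["db"]]
        else readInteractionTable(cfg$db_path)
    })
    sce <- .stage("preprocessing", {
        x <- if (!is.null(cfg[["sce"]])) cfg[["sce"]]
             else readSCDataset(cfg$sc_path, cfg$meta_path)
        x <- filterCells(x, cfg$qc_min_genes, cfg$qc_min_umi,
                         cfg$qc_max_mito)
        normalizeLog(x)
    })

    profiles <- .stage("profiles", {
        p <- computeProfiles(sce, groupBy = c("cluster", "tissue"))
        applyMinPctFilter(p, dbGenes(db), minPct = cfg$min_pct)
    })
    .writeTSV(profilesToTable(profiles), file.path(cfg$out_dir, "profiles.tsv"))

    fam <- .stage("family_scores", {
        sets <- familyGeneSets(db)
        cs <- perCellFamilyScores(sce, sets)
        cl <- colData(sce)$cluster
        ti <- colData(sce)$tissue
        tumorOnly <- ti == "tumor"
        zs <- clusterFamilyZscores(cs[, tumorOnly, drop = FALSE],
                                   cl[tumorOnly])
        pairing <- setNames(
            ifelse(unique(cl[tumorOnly]) == cfg$focal, cfg$reference,
                   unique(cl[tumorOnly])),
            unique(cl[tumorOnly]))
        contrast <- tissueContrast(cs, data.frame(cluster = cl, tissue = ti),
                                   pairing = pairing,
                                   alpha = cfg$family_alpha,
                                   minAbsLog2fc = cfg$family_log2fc)
        list(z = zs, contrast = contrast)
    })
    zlong <- data.frame(
        family = rep(rownames(fam$z$z), ncol(fam$z$z)),
        cluster = rep(colnames(fam$z$z), each = nrow(fam$z$z)),
        mean_score = as.vector(fam$z$mean), z = as.vector(fam$z$z))
    .writeTSV(zlong, file.path(cfg$out_dir, "family_scores.tsv"))
    .writeTSV(fam$contrast, file.path(cfg$out_dir, "family_contrast.tsv"))

    .stage("comm_scoring", {
        tumorProfiles <- computeProfiles(sce[, colData(sce)$tissue == "tumor"],
                                         groupBy = "cluster")
        tumorProfiles <- applyMinPctFilter(tumorProfiles, dbGenes(db),
                                           minPct = cfg$min_pct)
        sm <- allPairScores(db, tumorProfiles, rule = cfg$complex_rule)
        .writeTSV(as.data.frame(scoreContributions(sm)),
                  file.path(cfg$out_dir, "pair_scores.tsv"))
    })

    screen <- .stage("specificity_screen",
        screenDataset(db, sce, focal = cfg$focal, reference = cfg$reference,
                      ratio = cfg$specificity_ratio, minPct = cfg$min_pct,
                      deLog2fc = cfg$de_log2fc, deAlpha = cfg$de_alpha,
                      rule = cfg$complex_rule,
                      dataset = if (is.null(cfg[["dataset"]])) "dataset1"
                                else cfg[["dataset"]]))
    .writeTSV(screen, file.path(cfg$out_dir, "screen.tsv"))

    .manifest(cfg$out_dir,
              cfg[setdiff(names(cfg), c("db", "sce"))],
              inputs = cfg[intersect(names(cfg),
                                     c("db_path", "sc_path", "meta_path"))])
    invisible(cfg$out_dir)
}

#' Long-format table of cluster profiles
#'
#' @param profiles A [ClusterProfiles-class].
#' @return data.frame (group, cluster, tissue, gene, mean, pct, n_cells).
#' @export
profilesToTable <- function(profiles) {
    cd <- colData(profiles)
    k <- ncol(profiles)
    g <- nrow(profiles)
    data.frame(
        group = rep(colnames(profiles), each = g),
        cluster = rep(cd$cluster, each = g),
        tissue = if ("tissue" %in% colnames(cd))
            rep(cd$tissue, each = g) else NA,
        gene = rep(rownames(profiles), k),
        mean = as.vector(meanExpression(profiles)),
        pct = as.vector(pctExpressed(profiles)),
        n_cells = rep(cd$n_cells, each = g))
}

#' Simulate a dataset and write it in pipeline input formats
#'
#' Thin orchestration over [simulateSCDataset()]: writes the MatrixMarket
#' triple, the metadata TSV, the database TSV and the ground truth JSON to
#' \code{out_dir}, with a manifest.
#'
#' @param config Named list or YAML path; entries are [simConfig()]
#'   arguments plus \code{out_dir} and optionally \code{db} (defaults to
#'   [syntheticInteractionDB()]).
#' @return The output directory, invisibly.
#' @export
runSimulate <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config$out_dir)) stop("config entry 'out_dir' is required")
    outDir <- config$out_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    db <- if (!is.null(config$db)) config$db else syntheticInteractionDB()
    args <- config[intersect(names(config), names(formals(simConfig)))]
    sim <- simulateSCDataset(do.call(simConfig, args), db)
    counts <- methods::as(methods::as(assay(sim$sce, "counts"), "sparseMatrix"),
                          "generalMatrix")
    Matrix::writeMM(counts, file.path(outDir, "matrix.mtx"))
    utils::write.table(data.frame(rownames(counts), rownames(counts)),
                       file.path(outDir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(colnames(counts)),
                       file.path(outDir, "barcodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    meta <- cbind(barcode = colnames(counts),
                  as.data.frame(colData(sim$sce)))
    .writeTSV(meta, file.path(outDir, "metadata.tsv"))
    writeInteractionTable(db, file.path(outDir, "lr_db.tsv"))
    jsonlite::write_json(
        list(channels = sim$truth$channels, dropout = sim$truth$dropout),
        file.path(outDir, "ground_truth.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    .manifest(outDir, config[setdiff(names(config), "db")])
    invisible(outDir)
}

#' Run the bulk ligand x receptor validation
#'
#' Thin orchestration over [pairProductTest()]: reads (or takes) a bulk
#' count matrix and condition labels, tests the candidate pairs, writes the
#' result TSV and a manifest.
#'
#' @param config Named list or YAML path with \code{out_dir}, candidate
#'   database (\code{db} or \code{db_path}), and either in-memory
#'   \code{counts} + \code{condition} or \code{counts_path} (genes x samples
#'   TSV, first column gene) + \code{condition_path} (TSV with columns
#'   \code{sample}, \code{condition}); optional \code{bulk_alpha},
#'   \code{bulk_log2fc}, \code{complex_rule}.
#' @return The result data.frame, invisibly; side effect:
#'   \code{bulk_pairs.tsv} and \code{manifest.json} in \code{out_dir}.
#' @export
runBulk <- function(config) {
    cfg <- .loadConfig(config)
    if (is.null(cfg$out_dir)) stop("config entry 'out_dir' is required")
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    db <- if (!is.null(cfg[["db"]])) cfg[["db"]] else readInteractionTable(cfg$db_path)
    if (!is.null(cfg$counts_path)) {
        tab <- utils::read.table(cfg$counts_path, sep = "\t", header = TRUE,
                                 check.names = FALSE)
        counts <- as.matrix(tab[, -1]); rownames(counts) <- tab[[1]]
        cond <- utils::read.table(cfg$condition_path, sep = "\t",
                                  header = TRUE, check.names = FALSE)
        condition <- cond$condition[match(colnames(counts), cond$sample)]
    } else {
        counts <- cfg[["counts"]]
        condition <- cfg[["condition"]]
    }
    res <- .stage("bulk_validation",
                  pairProductTest(counts, condition, db,
                                  rule = cfg$complex_rule,
                                  alpha = cfg$bulk_alpha,
                                  minLog2fc = cfg$bulk_log2fc))
    .writeTSV(res, file.path(cfg$out_dir, "bulk_pairs.tsv"))
    .manifest(cfg$out_dir,
              cfg[setdiff(names(cfg), c("db", "counts", "condition"))],
              inputs = cfg[intersect(names(cfg),
                                     c("db_path", "counts_path",
                                       "condition_path"))])
    invisible(res)
}
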