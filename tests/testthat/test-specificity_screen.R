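test_that("emitter- and receiver-summed interaction scores follow the closed form", {
    db <- InteractionDB(ligand = list("L1"), receptor = list("R1"),
                        family = "cytokine", interaction_id = "i1")
    m <- matrix(c(2, 1, 0, 2, 0, 3), 2, 3,
                dimnames = list(c("L1", "R1"), c("A", "B", "C")))
    prof <- makeProfiles(m)
    out <- outgoingInteractionScores(db, prof)
    # ligand 2 at A; receptor means {1,2,3} across clusters -> 2 * 6
    expect_equal(out["i1", "A"], 12)
    expect_equal(out["i1", "B"], 0)   # ligand 0 -> 0
    inc <- incomingInteractionScores(db, prof)
    # receptor 3 at C; ligand means {2,0,0} -> 2 * 3
    expect_equal(inc["i1", "C"], 6)
    # excluding the focal cluster from the sum removes its own term
    out2 <- outgoingInteractionScores(db, prof, includeFocal = FALSE)
    expect_equal(out2["i1", "A"], 2 * (2 + 3))
})

test_that("interaction-score additivity ties the per-interaction sums to pair-score totals", {
    for (seed in c(3, 17, 29)) {
        inst <- randomInstance(seed)
        sm <- scoreMatrix(allPairScores(inst$db, inst$profiles))
        out <- outgoingInteractionScores(inst$db, inst$profiles)
        # sum over interactions of S_C(i,j) == sum over receivers of S_{C->k}
        expect_equal(colSums(out), rowSums(sm), tolerance = 1e-10)
        inc <- incomingInteractionScores(inst$db, inst$profiles)
        expect_equal(colSums(inc), colSums(sm), tolerance = 1e-10)
    }
})

test_that("outgoing and incoming coincide for a purely autocrine instance", {
    db <- InteractionDB(ligand = list("L1"), receptor = list("R1"),
                        family = "cytokine", interaction_id = "i1")
    m <- matrix(c(2, 3, 0, 0), 2, 2,
                dimnames = list(c("L1", "R1"), c("focal", "other")))
    prof <- makeProfiles(m)
    out <- outgoingInteractionScores(db, prof)
    inc <- incomingInteractionScores(db, prof)
    expect_equal(out["i1", "focal"], inc["i1", "focal"], tolerance = 1e-12)
})

test_that("specificity filter applies the inclusive 1.5x bound and degenerate rule", {
    s <- c(focal = 9, a = 6, b = 5)
    expect_true(specificityFilter(s, "focal")$pass)          # 9 >= 1.5*6
    expect_equal(specificityFilter(s, "focal")$ratio, 1.5)
    s2 <- c(focal = 8.9, a = 6, b = 5)
    expect_false(specificityFilter(s2, "focal")$pass)        # 8.9 < 9
    s3 <- c(focal = 0.2, a = 0, b = 0)
    f3 <- specificityFilter(s3, "focal")
    expect_true(f3$pass)                                      # all competitors 0
    expect_equal(f3$ratio, Inf)
    expect_false(specificityFilter(c(focal = 0, a = 0), "focal")$pass)
    expect_error(specificityFilter(c(a = 1, b = 2), "focal"), "focal")
    # scale invariance of the decision
    for (c_ in c(0.01, 3, 1e4))
        expect_equal(specificityFilter(s2 * c_, "focal")$pass,
                     specificityFilter(s2, "focal")$pass)
})

test_that("Wilcoxon DE selects a planted shift and respects Bonferroni arithmetic", {
    db <- syntheticInteractionDB(5, heterodimer = FALSE)
    cfg <- simConfig(nClusters = 2, cellsPerCluster = 200, nGenes = 300,
                     plantedChannels = list(list(
                         interaction_id = interactionIds(db)[1], f_L = 4)),
                     seed = 5)
    sim <- simulateSCDataset(cfg, db)
    sce <- suppressMessages(normalizeLog(sim$sce))
    cl <- colData(sce)$cluster; ti <- colData(sce)$tissue
    de <- wilcoxonDE(sce, which(cl == "cancer" & ti == "tumor"),
                     which(cl == "PT" & ti == "juxtatumor"),
                     genes = dbGenes(db))
    expect_true("LG01" %in% de$gene[de$selected])
    expect_true(all(de$p_adj >= de$p))
    expect_true(all(de$p_adj <= 1))
    # identical groups: nothing selected
    half <- which(cl == "PT")[1:100]
    other <- which(cl == "PT")[101:200]
    de0 <- wilcoxonDE(sce, half, other, genes = dbGenes(db))
    expect_false(any(de0$selected))
    # Bonferroni arithmetic: p = 0.001 over 100 tests -> 0.1, not selected
    expect_equal(p.adjust(rep(0.001, 100), "bonferroni")[1], 0.1)
})

test_that("vocabulary genes honor the two qualifying branches and the intersection", {
    # engineered log-normalized values; 60 cells per cluster
    set.seed(8)
    n <- 60
    mk <- function(p, mu) rbinom(n, 1, p) * (mu + runif(n, 0, 0.2))
    lg <- rbind(
        strong = c(mk(0.9, 2.0), mk(0.9, 1.2), mk(0.9, 1.2)),  # branch 1 vs both
        rare   = c(mk(0.5, 1.2), mk(0.05, 1.0), mk(0.06, 1.0)),# branch 2 vs both
        onlyA  = c(mk(0.9, 2.0), mk(0.9, 1.0), mk(0.9, 2.0)),  # fails vs C
        flat   = c(mk(0.8, 1.0), mk(0.8, 1.0), mk(0.8, 1.0)))
    colnames(lg) <- paste0("c", seq_len(3 * n))
    sce <- makeSCE(matrix(round(2^lg - 1), nrow(lg), ncol(lg),
                          dimnames = dimnames(lg)),
                   cluster = rep(c("F", "B", "C"), each = n))
    assay(sce, "logcounts") <- lg
    vocab <- vocabularyGenes(sce, focal = "F", others = c("B", "C"),
                             commGenes = rownames(lg))
    expect_true("strong" %in% vocab)
    expect_true("rare" %in% vocab)
    expect_false("onlyA" %in% vocab)   # passes 1 of 2 pairs only
    expect_false("flat" %in% vocab)
    expect_error(vocabularyGenes(sce, "F", character(0), rownames(lg)),
                 "at least one")
})

test_that("dataset screen recovers a planted outgoing channel and gates the rest", {
    db <- syntheticInteractionDB()
    id1 <- interactionIds(db)[1]
    scr <- runScenarioSeed(1, planted = TRUE, db = db)
    hit <- scr[scr$interaction_id == id1 & scr$direction == "outgoing", ]
    expect_true(hit$final)
    expect_gte(hit$ratio, 1.5)
    # no other interaction is a final outgoing hit in this run
    others <- scr[scr$interaction_id != id1 & scr$direction == "outgoing", ]
    expect_false(any(others$final))
    # ubiquitous molecules fail specificity by construction
    expect_true(all(others$ratio < 1.5 | !others$passes_specificity))
    expect_error(
        suppressMessages(screenDataset(db, normalizeLog(
            simulateSCDataset(simConfig(nGenes = 60, cellsPerCluster = 4,
                                        seed = 1), db)$sce),
            focal = "nope", reference = "PT")),
        "focal cluster")
})

test_that("per-pair specificity variant and 'both-sides' DE gate are stricter or equal", {
    db <- syntheticInteractionDB()
    id1 <- interactionIds(db)[1]
    cfg <- simConfig(plantedChannels = list(list(interaction_id = id1,
                                                 f_L = 8)), seed = 2)
    sim <- simulateSCDataset(cfg, db)
    sce <- suppressMessages(normalizeLog(sim$sce))
    base <- suppressMessages(screenDataset(db, sce, "cancer", "PT"))
    both <- suppressMessages(screenDataset(db, sce, "cancer", "PT",
                                           deGate = "both"))
    expect_true(all(both$passes_de <= base$passes_de))
    pp <- suppressMessages(screenDataset(db, sce, "cancer", "PT",
                                         perPair = TRUE))
    hit <- pp[pp$interaction_id == id1 & pp$direction == "outgoing", ]
    expect_true(hit$passes_specificity)
})

test_that("screen intersection tiers hits by dataset membership", {
    mk <- function(ids) data.frame(
        interaction_id = c(ids, "never"), direction = "outgoing",
        final = c(rep(TRUE, length(ids)), FALSE))
    res <- list(d1 = mk(c("a", "b", "c")), d2 = mk(c("a", "b")),
                d3 = mk("a"))
    tab <- intersectScreens(res)
    expect_equal(tab$tier[tab$interaction_id == "a"], "all")
    expect_equal(tab$tier[tab$interaction_id == "b"], ">=min")
    expect_false("c" %in% tab$interaction_id)       # 1/3 datasets: dropped
    expect_true("c" %in% attr(tab, "full")$interaction_id)
    expect_equal(tab$n_datasets, c(3, 2))           # sorted by tier
    expect_error(intersectScreens(res[1]), "at least 2")
    expect_error(intersectScreens(setNames(res, c("d", "d", "e"))),
                 "uniquely named")
})
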