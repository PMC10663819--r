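test_that("interaction tables read with heterodimers, case cleanup and family mapping", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(
        paste("Ligand 1", "Ligand 2", "Receptor 1", "Receptor 2",
              "Receptor 3", "Family", "Subfamily", sep = "\t"),
        paste("ANG", "", "PLXNB2", "", "", "growth factor", "", sep = "\t"),
        paste("vegfa", "", "FLT1", "KDR", "", "Growth factors", "VEGF",
              sep = "\t"),
        paste("IL6", "", "IL6R", "", "", "mystery", "", sep = "\t")),
        path)
    db <- suppressWarnings(readInteractionTable(path))
    expect_s4_class(db, "InteractionDB")
    expect_equal(nInteractions(db), 3L)
    expect_equal(ligandSubunits(db)[[1]], "ANG")
    expect_equal(receptorSubunits(db)[[1]], "PLXNB2")
    # heterodimeric receptor kept as two subunits, symbols upper-cased
    expect_equal(ligandSubunits(db)[[2]], "VEGFA")
    expect_setequal(receptorSubunits(db)[[2]], c("FLT1", "KDR"))
    expect_equal(interactionFamilies(db)[1:2],
                 c("growth_factor", "growth_factor"))
    # unknown family string falls back to other, with a warning
    expect_warning(readInteractionTable(path), "other")
    expect_equal(interactionFamilies(db)[3], "other")
})

test_that("reader rejects schema and record-level problems, accepts empty tables", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(paste("Ligand 1", "Foo", sep = "\t"), path)
    expect_error(readInteractionTable(path), "mandatory column")

    writeLines(c(paste("Ligand 1", "Receptor 1", "Family", sep = "\t"),
                 paste("A", "B", "cytokine", sep = "\t"),
                 paste("", "B", "cytokine", sep = "\t")), path)
    expect_error(readInteractionTable(path), "row\\(s\\): 2")

    writeLines(paste("Ligand 1", "Receptor 1", "Family", sep = "\t"), path)
    empty <- readInteractionTable(path)
    expect_equal(nInteractions(empty), 0L)
})

test_that("write/read round-trips an identical database", {
    db <- InteractionDB(
        ligand = list("ANG", "VEGFA", c("IL12A", "IL12B")),
        receptor = list("PLXNB2", c("FLT1", "KDR"), c("IL12RB1", "IL12RB2")),
        family = c("growth_factor", "growth_factor", "cytokine"),
        subfamily = c(NA, "VEGF", NA))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeInteractionTable(db, path)
    back <- readInteractionTable(path)
    expect_equal(nInteractions(back), nInteractions(db))
    expect_equal(as.list(ligandSubunits(back)), as.list(ligandSubunits(db)))
    expect_equal(as.list(receptorSubunits(back)),
                 as.list(receptorSubunits(db)))
    expect_equal(interactionFamilies(back), interactionFamilies(db))
})

test_that("merge keeps base on collisions, is idempotent and size-additive on disjoint inputs", {
    a <- InteractionDB(ligand = list("A"), receptor = list("B"),
                       family = "cytokine")
    dup <- InteractionDB(ligand = list("A"), receptor = list("B"),
                         family = "cytokine")
    more <- InteractionDB(ligand = list("A", "C"), receptor = list("X", "D"),
                          family = "chemokine")
    expect_equal(nInteractions(suppressMessages(mergeDatabases(a, dup))), 1L)
    expect_equal(suppressMessages(mergeDatabases(a, dup))@records$provenance,
                 "original")
    m <- mergeDatabases(a, more)
    expect_equal(nInteractions(m), 3L)
    expect_equal(m@records$provenance, c("original", "curated_addition",
                                         "curated_addition"))
    # empty base
    e <- InteractionDB(list(), list(), character(0))
    expect_equal(nInteractions(mergeDatabases(e, more)), 2L)
    # idempotent: merge(x, x) == x
    self <- suppressMessages(mergeDatabases(m, m))
    expect_equal(nInteractions(self), nInteractions(m))
    # subunit order within a side does not create a new key
    swapped <- InteractionDB(ligand = list("VEGFA"),
                             receptor = list(c("KDR", "FLT1")),
                             family = "growth_factor")
    base <- InteractionDB(ligand = list("VEGFA"),
                          receptor = list(c("FLT1", "KDR")),
                          family = "growth_factor")
    expect_equal(
        nInteractions(suppressMessages(mergeDatabases(base, swapped))), 1L)
    # directionality matters: A->B and B->A are distinct
    rev <- InteractionDB(ligand = list("B"), receptor = list("A"),
                         family = "cytokine")
    expect_equal(nInteractions(mergeDatabases(a, rev)), 2L)
})

test_that("family gene sets union ligand and receptor genes per family", {
    db <- InteractionDB(ligand = list("ANG"), receptor = list("PLXNB2"),
                        family = "growth_factor")
    expect_equal(familyGeneSets(db),
                 list(growth_factor = c("ANG", "PLXNB2")))
    db2 <- InteractionDB(ligand = list("A", "A"), receptor = list("B", "C"),
                         family = "cytokine")
    expect_equal(familyGeneSets(db2), list(cytokine = c("A", "B", "C")))
    # invariant under record permutation
    db3 <- InteractionDB(ligand = list("A", "A")[2:1],
                         receptor = list("C", "B"),
                         family = "cytokine")
    expect_equal(familyGeneSets(db3), familyGeneSets(db2))
    # a gene annotated to two families appears in both sets
    db4 <- InteractionDB(ligand = list("A", "A"), receptor = list("B", "C"),
                         family = c("cytokine", "chemokine"))
    sets <- familyGeneSets(db4)
    expect_true("A" %in% sets$cytokine && "A" %in% sets$chemokine)
})

test_that("validateDB reports duplicates, arity and symbol findings without modifying", {
    ok <- syntheticInteractionDB(5)
    expect_equal(nrow(validateDB(ok)), 0L)
    rec <- ok@records[c(1, 1, 2), ]
    dupdb <- new("InteractionDB", records = rec)
    rep <- validateDB(dupdb)
    expect_equal(sum(rep$type == "duplicate_key"), 1L)
    bad <- InteractionDB(ligand = list("L1"),
                         receptor = list(c("R1", "R2", "R3", "R4")),
                         family = "cytokine")
    rep2 <- validateDB(bad)
    expect_equal(sum(rep2$type == "arity"), 1L)
    expect_equal(nInteractions(bad), 1L)  # reported, not truncated
})
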