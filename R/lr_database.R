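## Ligand-receptor database: construction, IO, merging, family gene sets.

.cleanSymbols <- function(x) {
    x <- toupper(trimws(as.character(x)))
    x <- x[!is.na(x) & nzchar(x)]
    unique(x)
}

## Family strings from curated tables come in many spellings; map onto the
## controlled vocabulary, unknowns fall through to "other" (caller warns).
.normalizeFamily <- function(x) {
    key <- gsub("[^a-z]+", "_", tolower(trimws(as.character(x))))
    key <- gsub("_+$|^_+", "", key)
    map <- c(cytokine = "cytokine", cytokines = "cytokine",
             chemokine = "chemokine", chemokines = "chemokine",
             checkpoint = "immune_checkpoint",
             checkpoints = "immune_checkpoint",
             immune_checkpoint = "immune_checkpoint",
             immune_checkpoints = "immune_checkpoint",
             growth_factor = "growth_factor",
             growth_factors = "growth_factor",
             cell_adhesion = "cell_adhesion",
             cell_adhesion_molecule = "cell_adhesion",
             cell_adhesion_molecules = "cell_adhesion",
             adhesion = "cell_adhesion",
             other = "other", unclassified = "other",
             other_unclassified = "other", notclassified = "other",
             not_classified = "other")
    out <- unname(map[key])
    out[is.na(key) | !nzchar(key)] <- "other"
    out
}

.sideKey <- function(subunits) {
    vapply(subunits, function(s) paste(sort(unique(s)), collapse = "+"), "")
}

## Dedup key: unordered within a side, directed across sides.
.dbKeys <- function(db) {
    rec <- db@records
    paste(.sideKey(as.list(rec$ligand)), .sideKey(as.list(rec$receptor)),
          sep = ">")
}

#' Construct a ligand-receptor interaction database
#'
#' Builds a validated [InteractionDB-class] from per-record subunit lists.
#' Gene symbols are upper-cased, whitespace-stripped and de-duplicated
#' within a side; unknown family strings are mapped to \code{"other"} with
#' a warning. Directionality is fixed ligand to receptor, so A->B and B->A
#' are distinct records, while subunit order within a complex is ignored.
#'
#' @param ligand,receptor Lists (or [IRanges::CharacterList]) of subunit
#'   gene symbols, one element per record.
#' @param family Character vector of family labels (free strings accepted).
#' @param subfamily Optional character vector of subfamily labels.
#' @param provenance \code{"original"} or \code{"curated_addition"}, recycled.
#' @param interaction_id Optional record identifiers; defaults to
#'   \code{"L1+L2 / R1+R2"} built from the cleaned subunits.
#' @return An [InteractionDB-class].
#' @examples
#' db <- InteractionDB(ligand = list("ANG", "VEGFA"),
#'                     receptor = list("PLXNB2", c("FLT1", "KDR")),
#'                     family = c("growth factor", "growth factor"))
#' nInteractions(db)
#' @export
InteractionDB <- function(ligand, receptor, family,
                          subfamily = NA_character_,
                          provenance = "original",
                          interaction_id = NULL) {
    ligand <- lapply(ligand, .cleanSymbols)
    receptor <- lapply(receptor, .cleanSymbols)
    n <- length(ligand)
    stopifnot(length(receptor) == n)
    fam_in <- rep_len(as.character(family), n)
    fam <- .normalizeFamily(fam_in)
    if (any(is.na(fam))) {
        warning(sum(is.na(fam)), " unknown family label(s) mapped to 'other': ",
                paste(unique(fam_in[is.na(fam)]), collapse = ", "))
        fam[is.na(fam)] <- "other"
    }
    if (is.null(interaction_id))
        interaction_id <- paste(.sideKey(ligand), .sideKey(receptor),
                                sep = " / ")
    rec <- S4Vectors::DataFrame(
        interaction_id = as.character(interaction_id),
        ligand = IRanges::CharacterList(ligand),
        receptor = IRanges::CharacterList(receptor),
        family = fam,
        subfamily = rep_len(as.character(subfamily), n),
        provenance = rep_len(as.character(provenance), n))
    new("InteractionDB", records = rec)
}

#' @describeIn InteractionDB Number of interaction records (the summation
#'   length of the communication score).
#' @param db An [InteractionDB-class].
#' @export
nInteractions <- function(db) nrow(db@records)

#' @describeIn InteractionDB Record identifiers.
#' @export
interactionIds <- function(db) db@records$interaction_id

#' @describeIn InteractionDB Ligand subunit lists.
#' @export
ligandSubunits <- function(db) db@records$ligand

#' @describeIn InteractionDB Receptor subunit lists.
#' @export
receptorSubunits <- function(db) db@records$receptor

#' @describeIn InteractionDB Family label per record.
#' @export
interactionFamilies <- function(db) db@records$family

#' @describeIn InteractionDB All distinct gene symbols in the database.
#' @export
dbGenes <- function(db)
    unique(c(unlist(db@records$ligand), unlist(db@records$receptor)))

setMethod("show", "InteractionDB", function(object) {
    cat("InteractionDB with", nInteractions(object), "interactions\n")
    if (nInteractions(object) > 0) {
        cat("families:", paste(names(table(object@records$family)),
                               table(object@records$family),
                               collapse = ", "), "\n")
        cat("genes:", length(dbGenes(object)), "\n")
    }
})

.defaultDialect <- function() list(
    ligand = c("Ligand 1", "Ligand 2"),
    receptor = c("Receptor 1", "Receptor 2", "Receptor 3"),
    family = "Family", subfamily = "Subfamily")

#' Read a ligand-receptor interaction table
#'
#' Reads a delimited text table (TSV by default, CSV for \code{.csv} paths)
#' with one interaction per row into an [InteractionDB-class]. Column names
#' are configurable through \code{dialect}; blank subunit slots are dropped.
#' Rows with no ligand or no receptor symbol raise an error listing the
#' offending rows; duplicate (ligand-set, receptor-set) keys keep the first
#' record with a warning.
#'
#' @param path Path to the delimited file.
#' @param dialect Named list with entries \code{ligand}, \code{receptor}
#'   (character vectors of subunit column names), \code{family} and
#'   optionally \code{subfamily} (single column names).
#' @param provenance Provenance label assigned to all records.
#' @param sep Field separator; guessed from the file extension by default.
#' @return An [InteractionDB-class].
#' @export
readInteractionTable <- function(path, dialect = .defaultDialect(),
                                 provenance = "original", sep = NULL) {
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                             check.names = FALSE, colClasses = "character",
                             fileEncoding = "UTF-8")
    need <- c(dialect$ligand[1], dialect$receptor[1], dialect$family)
    missing_cols <- setdiff(need, colnames(tab))
    if (length(missing_cols))
        stop("missing mandatory column(s): ",
             paste(missing_cols, collapse = ", "))
    lig_cols <- intersect(dialect$ligand, colnames(tab))
    rec_cols <- intersect(dialect$receptor, colnames(tab))
    if (nrow(tab) == 0L)
        return(InteractionDB(ligand = list(), receptor = list(),
                             family = character(0)))
    lig <- lapply(seq_len(nrow(tab)),
                  function(i) .cleanSymbols(unlist(tab[i, lig_cols])))
    rec <- lapply(seq_len(nrow(tab)),
                  function(i) .cleanSymbols(unlist(tab[i, rec_cols])))
    bad <- which(lengths(lig) == 0L | lengths(rec) == 0L)
    if (length(bad))
        stop("record(s) with no ligand or no receptor symbol at row(s): ",
             paste(bad, collapse = ", "))
    subfam <- if (!is.null(dialect$subfamily) &&
                  dialect$subfamily %in% colnames(tab))
        tab[[dialect$subfamily]] else NA_character_
    db <- InteractionDB(ligand = lig, receptor = rec,
                        family = tab[[dialect$family]],
                        subfamily = subfam, provenance = provenance)
    keys <- .dbKeys(db)
    if (anyDuplicated(keys)) {
        warning("dropping ", sum(duplicated(keys)),
                " duplicate interaction(s), keeping first occurrence")
        db@records <- db@records[!duplicated(keys), ]
    }
    db
}

#' Write an interaction database as canonical TSV
#'
#' Fixed column order (\code{Ligand 1..2}, \code{Receptor 1..3},
#' \code{Family}, \code{Subfamily}, \code{Provenance}, \code{Interaction ID})
#' so that written files diff reproducibly and round-trip through
#' [readInteractionTable()].
#'
#' @param db An [InteractionDB-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeInteractionTable <- function(db, path) {
    rec <- db@records
    pad <- function(lst, k) t(vapply(as.list(lst), function(s)
        c(s, rep("", k))[seq_len(k)], character(k)))
    n <- nrow(rec)
    lig <- if (n) pad(rec$ligand, 2L) else matrix("", 0, 2)
    rcp <- if (n) pad(rec$receptor, 3L) else matrix("", 0, 3)
    out <- data.frame(lig[, 1], lig[, 2], rcp[, 1], rcp[, 2], rcp[, 3],
                      rec$family,
                      ifelse(is.na(rec$subfamily), "", rec$subfamily),
                      rec$provenance, rec$interaction_id,
                      check.names = FALSE)
    colnames(out) <- c("Ligand 1", "Ligand 2", "Receptor 1", "Receptor 2",
                       "Receptor 3", "Family", "Subfamily", "Provenance",
                       "Interaction ID")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Merge two interaction databases
#'
#' Union keyed on the unordered (ligand-set, receptor-set) pair. On key
#' collision the base record wins and the collision is reported; surviving
#' additions get provenance \code{"curated_addition"}. Merging a database
#' with itself is a no-op.
#'
#' @param base,additions [InteractionDB-class] objects.
#' @return An [InteractionDB-class] with
#'   \code{|base| + |non-duplicate additions|} records.
#' @export
mergeDatabases <- function(base, additions) {
    stopifnot(is(base, "InteractionDB"), is(additions, "InteractionDB"))
    add <- additions@records
    if (nrow(add)) add$provenance <- "curated_addition"
    dup <- .dbKeys(additions) %in% .dbKeys(base)
    if (any(dup))
        message(sum(dup), " addition(s) collide with base records; ",
                "base kept: ",
                paste(utils::head(add$interaction_id[dup], 5), collapse = ", "))
    out <- base
    out@records <- rbind(base@records, add[!dup, , drop = FALSE])
    out
}

#' Family-wise communication gene sets
#'
#' For each molecule family, the set of distinct gene symbols occurring as
#' any ligand or receptor subunit of that family's interactions. A gene
#' annotated to interactions of two families appears in both sets. These
#' sets drive the per-cell family expression scores.
#'
#' @param db An [InteractionDB-class].
#' @return Named list of character vectors, one per family present.
#' @export
familyGeneSets <- function(db) {
    rec <- db@records
    if (nrow(rec) == 0L) return(setNames(list(), character(0)))
    genes <- mapply(function(l, r) unique(c(l, r)),
                    as.list(rec$ligand), as.list(rec$receptor),
                    SIMPLIFY = FALSE)
    fams <- sort(unique(rec$family))
    out <- lapply(fams, function(f)
        sort(unique(unlist(genes[rec$family == f]))))
    names(out) <- fams
    out
}

#' Validate an interaction database
#'
#' Report-only structural audit: duplicate (ligand-set, receptor-set) keys,
#' malformed gene symbols, family-vocabulary violations, and subunit-arity
#' violations (more than 2 ligand or 3 receptor subunits). The database is
#' not modified.
#'
#' @param db An [InteractionDB-class].
#' @return A data.frame with columns \code{type}, \code{record},
#'   \code{message}; zero rows when the database is well formed.
#' @export
validateDB <- function(db) {
    rec <- db@records
    findings <- list()
    add <- function(type, record, msg)
        findings[[length(findings) + 1L]] <<-
            data.frame(type = type, record = record, message = msg)
    keys <- .dbKeys(db)
    for (k in unique(keys[duplicated(keys)]))
        add("duplicate_key", paste(which(keys == k), collapse = ","),
            paste("records share key", k))
    nl <- S4Vectors::elementNROWS(rec$ligand)
    nr <- S4Vectors::elementNROWS(rec$receptor)
    for (i in which(nl > 2L))
        add("arity", as.character(i),
            paste("ligand complex has", nl[i], "subunits (max 2)"))
    for (i in which(nr > 3L))
        add("arity", as.character(i),
            paste("receptor complex has", nr[i], "subunits (max 3)"))
    for (i in seq_len(nrow(rec))) {
        syms <- c(rec$ligand[[i]], rec$receptor[[i]])
        bad <- syms[!grepl("^[A-Z0-9][A-Z0-9._-]*$", syms)]
        if (length(bad))
            add("malformed_symbol", as.character(i),
                paste("symbol(s):", paste(bad, collapse = ", ")))
    }
    for (i in which(!rec$family %in% .FAMILY_LEVELS))
        add("family_vocabulary", as.character(i),
            paste("unknown family", rec$family[i]))
    if (length(findings)) do.call(rbind, findings)
    else data.frame(type = character(0), record = character(0),
                    message = character(0))
}
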