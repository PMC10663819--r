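## Cluster-pair communication scores: sum over the interaction database of
## (emitter ligand mean) x (receiver receptor mean), with heterodimer
## aggregation and 0-100 rescaling.

## Complex-level expression per group: rows = db records, columns = groups.
## A subunit absent from the gene universe contributes 0 (and, under the
## "minimum" rule, zeroes the whole complex).
.complexMatrix <- function(meanMat, subunitList, rule = c("minimum", "mean")) {
    rule <- match.arg(rule)
    subunitList <- as.list(subunitList)
    genes <- rownames(meanMat)
    out <- matrix(0, length(subunitList), ncol(meanMat),
                  dimnames = list(NULL, colnames(meanMat)))
    missing_seen <- character(0)
    for (i in seq_along(subunitList)) {
        s <- subunitList[[i]]
        hit <- s %in% genes
        missing_seen <- c(missing_seen, s[!hit])
        vals <- matrix(0, length(s), ncol(meanMat))
        vals[hit, ] <- meanMat[s[hit], , drop = FALSE]
        out[i, ] <- if (rule == "minimum") apply(vals, 2, min)
                    else colMeans(vals)
    }
    if (length(missing_seen))
        attr(out, "missing_genes") <- unique(missing_seen)
    out
}

#' Complex-level expression of a ligand or receptor
#'
#' Expression of a (possibly heterodimeric) molecule complex in each profile
#' group: a single subunit returns its filtered mean expression; multiple
#' subunits are aggregated by the complex rule — \code{"minimum"}
#' (limiting-subunit semantics, the default) or \code{"mean"}. A subunit
#' absent from the gene universe counts as 0.
#'
#' @param profiles A [ClusterProfiles-class].
#' @param subunits Character vector of subunit gene symbols (non-empty).
#' @param rule \code{"minimum"} or \code{"mean"}.
#' @return Named numeric vector, one value per profile group.
#' @export
complexExpression <- function(profiles, subunits,
                              rule = c("minimum", "mean")) {
    stopifnot(length(subunits) >= 1L)
    m <- .complexMatrix(meanExpression(profiles), list(subunits), rule)
    if (!is.null(attr(m, "missing_genes")))
        message("complexExpression: subunit(s) absent, treated as 0: ",
                paste(attr(m, "missing_genes"), collapse = ", "))
    setNames(m[1, ], colnames(m))
}

#' Communication score between one emitter and one receiver cluster
#'
#' Sums, over all database interactions, the product of the emitter's
#' ligand-complex mean expression and the receiver's receptor-complex mean
#' expression. Profiles are expected to already carry the
#' minimum-percent-expressed filter ([applyMinPctFilter()]).
#'
#' @param db An [InteractionDB-class].
#' @param profiles A [ClusterProfiles-class].
#' @param emitter,receiver Group (column) names in \code{profiles}.
#' @param rule Complex aggregation rule, see [complexExpression()].
#' @return List with \code{total}, \code{contributions} (named per
#'   interaction) and \code{family} (named per-family decomposition);
#'   \code{total == sum(contributions) == sum(family)}.
#' @export
pairScore <- function(db, profiles, emitter, receiver,
                      rule = c("minimum", "mean")) {
    stopifnot(emitter %in% colnames(profiles),
              receiver %in% colnames(profiles))
    if (nInteractions(db) == 0L) {
        warning("empty interaction database; score is 0")
        return(list(total = 0, contributions = numeric(0),
                    family = numeric(0)))
    }
    m <- meanExpression(profiles)
    L <- .complexMatrix(m, ligandSubunits(db), rule)
    R <- .complexMatrix(m, receptorSubunits(db), rule)
    contrib <- setNames(L[, emitter] * R[, receiver], interactionIds(db))
    fam <- vapply(split(contrib, interactionFamilies(db)), sum, 0)
    list(total = sum(contrib), contributions = contrib, family = fam)
}

#' Communication scores for all ordered cluster pairs
#'
#' Computes the emitter-to-receiver communication score for every ordered
#' pair of profile groups, self-pairs included (autocrine signalling).
#'
#' @inheritParams pairScore
#' @return A [CommScoreMatrix-class].
#' @export
allPairScores <- function(db, profiles, rule = c("minimum", "mean")) {
    rule <- match.arg(rule)
    m <- meanExpression(profiles)
    K <- ncol(m)
    if (K < 1L) stop("need at least one profile group")
    L <- .complexMatrix(m, ligandSubunits(db), rule)
    R <- .complexMatrix(m, receptorSubunits(db), rule)
    scores <- crossprod(L, R)  # [emitter, receiver]
    dimnames(scores) <- list(colnames(m), colnames(m))
    grid <- expand.grid(e = seq_len(K), r = seq_len(K))
    long <- S4Vectors::DataFrame(
        emitter = rep(colnames(m)[grid$e], each = nInteractions(db)),
        receiver = rep(colnames(m)[grid$r], each = nInteractions(db)),
        interaction_id = rep(interactionIds(db), nrow(grid)),
        family = rep(interactionFamilies(db), nrow(grid)),
        contribution = as.vector(vapply(seq_len(nrow(grid)), function(i)
            L[, grid$e[i]] * R[, grid$r[i]],
            numeric(nInteractions(db)))))
    new("CommScoreMatrix", scores = as.matrix(scores), contributions = long,
        rule = rule, rescaled = FALSE)
}

#' @describeIn CommScoreMatrix Emitter x receiver total-score matrix.
#' @param x A [CommScoreMatrix-class].
#' @export
scoreMatrix <- function(x) x@scores

#' @describeIn CommScoreMatrix Long per-interaction contribution table.
#' @export
scoreContributions <- function(x) x@contributions

setMethod("show", "CommScoreMatrix", function(object) {
    cat("CommScoreMatrix:", nrow(object@scores), "x", ncol(object@scores),
        "cluster pairs (rule:", object@rule,
        if (object@rescaled) ", rescaled 0-100" else "", ")\n")
    print(round(object@scores, 3))
})

#' Rescale communication scores to the 0-100 range
#'
#' Divides scores by the maximum in scope and multiplies by 100, so the
#' strongest signal reads 100 and zeros stay 0. Scope \code{"global"}
#' rescales the K x K totals by their overall maximum; scope
#' \code{"per_interaction"} rescales each interaction's contributions across
#' all cluster pairs by that interaction's maximum (the heatmap convention
#' for displaying one interaction across receivers). Rescaling twice is a
#' no-op; an all-zero scope is returned unchanged with a warning.
#'
#' @param x A [CommScoreMatrix-class] or a plain numeric matrix.
#' @param scope \code{"global"} or \code{"per_interaction"} (matrix input
#'   supports \code{"global"} only).
#' @return Same shape as the input, rescaled.
#' @export
rescaleTo100 <- function(x, scope = c("global", "per_interaction")) {
    scope <- match.arg(scope)
    rescale <- function(v) {
        mx <- max(v)
        if (mx <= 0) {
            warning("all scores zero; nothing to rescale")
            return(v)
        }
        v / mx * 100
    }
    if (is.matrix(x)) return(rescale(x))
    stopifnot(is(x, "CommScoreMatrix"))
    if (scope == "global") {
        x@scores <- rescale(x@scores)
    } else {
        co <- x@contributions
        rescale0 <- function(v) if (max(v) <= 0) v else v / max(v) * 100
        co$contribution <- unsplit(
            lapply(split(co$contribution, co$interaction_id), rescale0),
            co$interaction_id)
        if (max(co$contribution) <= 0)
            warning("all scores zero; nothing to rescale")
        x@contributions <- co
    }
    x@rescaled <- TRUE
    x
}
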