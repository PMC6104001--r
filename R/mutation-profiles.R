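## mutation_profiles: pyrimidine-normalized trinucleotide profiles with a
## reversed/unreversed split, duplex context groups, opposing-pair rate
## tables, TS/TV summaries.

.ALTERATIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.CONTEXTS <- paste(rep(.BASES, each = 4), rep(.BASES, 4), sep = ".")
.DUPLEX_CANONICAL <- c("A.A", "C.C", "A.G", "C.A", "A.C", "G.A",
                       "C.G", "A.T", "T.A", "G.C")

#' Alteration types and flank contexts
#'
#' The six pyrimidine-normalized alteration types and the 16 ordered flank
#' contexts ("X.Y" = 5' flank X, 3' flank Y) used by mutational profiles.
#'
#' @return Character vector.
#' @export
alterationTypes <- function() .ALTERATIONS

#' @rdname alterationTypes
#' @export
flankContexts <- function() .CONTEXTS

#' Pyrimidine-normalize a base substitution with its flanks
#'
#' If the mutated base is a purine, the substitution and its flanks are
#' replaced by their reverse complement (flanks complemented and swapped),
#' so the reported reference base is always C or T. Ambiguous bases yield
#' NA entries (callers skip and count them).
#'
#' @param ref,alt The mutated-from and mutated-to bases.
#' @param flank5,flank3 Immediate 5' and 3' neighbours of the mutated base.
#' @return data.frame with \code{alteration} (one of C>A, C>G, C>T, T>A,
#'   T>C, T>G) and \code{context} ("X.Y").
#' @examples
#' normalizeMutation("G", "A", "C", "A")  # C>T in context T.G
#' @export
normalizeMutation <- function(ref, alt, flank5, flank3) {
    n <- max(length(ref), length(alt), length(flank5), length(flank3))
    ref <- rep_len(as.character(ref), n)
    alt <- rep_len(as.character(alt), n)
    flank5 <- rep_len(as.character(flank5), n)
    flank3 <- rep_len(as.character(flank3), n)
    ok <- ref %in% .BASES & alt %in% .BASES &
        flank5 %in% .BASES & flank3 %in% .BASES & ref != alt
    flip <- ok & ref %in% c("A", "G")
    r <- ref; a <- alt; f5 <- flank5; f3 <- flank3
    r[flip] <- .COMP[ref[flip]]
    a[flip] <- .COMP[alt[flip]]
    f5[flip] <- .COMP[flank3[flip]]
    f3[flip] <- .COMP[flank5[flip]]
    out <- data.frame(alteration = ifelse(ok, paste(r, a, sep = ">"),
                                          NA_character_),
                      context = ifelse(ok, paste(f5, f3, sep = "."),
                                       NA_character_),
                      stringsAsFactors = FALSE)
    out
}

#' Build a reversal-split mutational profile
#'
#' Tallies labelled SNVs (e.g. from \code{\link{mutationTable}}) into the
#' 6 x 16 alteration-by-context matrix, split into mutations reversed at
#' the next stage tier and unreversed mutations. Counts are raw, with no
#' normalization for genomic trinucleotide frequencies. Records with
#' ambiguous bases are skipped and counted in the \code{"skipped"}
#' attribute.
#'
#' @param snvs data.frame with columns \code{fromBase, toBase, flank5,
#'   flank3} and optionally \code{reversedNext} (NA treated as
#'   unreversed).
#' @param tier Tier label stored in the profile (e.g. "dNB").
#' @return A \linkS4class{MutationProfile}.
#' @export
buildProfile <- function(snvs, tier = "tier") {
    dims <- list(.ALTERATIONS, .CONTEXTS)
    revMat <- matrix(0, 6, 16, dimnames = dims)
    unrevMat <- matrix(0, 6, 16, dimnames = dims)
    skipped <- 0L
    if (nrow(snvs)) {
        norm <- normalizeMutation(snvs$fromBase, snvs$toBase,
            snvs$flank5, snvs$flank3)
        ok <- !is.na(norm$alteration)
        skipped <- sum(!ok)
        rev <- if ("reversedNext" %in% names(snvs))
            snvs$reversedNext & !is.na(snvs$reversedNext) else
            rep(FALSE, nrow(snvs))
        rev[is.na(rev)] <- FALSE
        tally <- function(sel) {
            if (!any(sel)) return(matrix(0, 6, 16, dimnames = dims))
            t0 <- table(factor(norm$alteration[sel], .ALTERATIONS),
                        factor(norm$context[sel], .CONTEXTS))
            matrix(as.numeric(t0), 6, 16, dimnames = dims)
        }
        revMat <- tally(ok & rev)
        unrevMat <- tally(ok & !rev)
    }
    out <- methods::new("MutationProfile", tier = tier,
        reversed = revMat, unreversed = unrevMat)
    attr(out, "skipped") <- skipped
    out
}

#' Duplex context groups
#'
#' The 16 ordered flank contexts collapse into 10 duplex groups: context
#' X.Y is grouped with its duplex mate comp(Y).comp(X) (the context seen
#' on the opposite strand read 5' to 3'). Four groups are self-paired
#' (C.G, A.T, T.A, G.C); the other six contain two contexts each. The
#' canonical group names are A.A, C.C, A.G, C.A, A.C, G.A, C.G, A.T, T.A,
#' G.C.
#'
#' @param context A context string "X.Y" (vectorized for
#'   \code{duplexGroupId}).
#' @return \code{duplexGroup}: list with \code{id} and \code{members};
#'   \code{duplexGroupId}: character vector of group names;
#'   \code{duplexGroups}: data.frame of all 16 contexts with their groups.
#' @export
duplexGroup <- function(context) {
    if (length(context) != 1L || !context %in% .CONTEXTS)
        stop("invalid context: ", paste(context, collapse = ","))
    mate <- .duplexMate(context)
    id <- if (context %in% .DUPLEX_CANONICAL) context else mate
    if (!id %in% .DUPLEX_CANONICAL)
        stop("context maps to no canonical group: ", context)
    list(id = id, members = unique(c(id, .duplexMate(id))))
}

.duplexMate <- function(context) {
    parts <- strsplit(context, ".", fixed = TRUE)
    vapply(parts, function(p) paste(.COMP[p[2L]], .COMP[p[1L]], sep = "."),
           character(1))
}

#' @rdname duplexGroup
#' @export
duplexGroupId <- function(context) {
    vapply(context, function(x) duplexGroup(x)$id, character(1),
           USE.NAMES = FALSE)
}

#' @rdname duplexGroup
#' @export
duplexGroups <- function() {
    data.frame(context = .CONTEXTS, group = duplexGroupId(.CONTEXTS),
        stringsAsFactors = FALSE)
}

## The opposing mutation of (alteration, context): the substitution that
## converts the product base back, pyrimidine-normalized.
.opposingCell <- function(alteration, context) {
    x <- substr(alteration, 1L, 1L)
    y <- substr(alteration, 3L, 3L)
    f5 <- substr(context, 1L, 1L)
    f3 <- substr(context, 3L, 3L)
    norm <- normalizeMutation(y, x, f5, f3)
    list(alteration = norm$alteration, context = norm$context)
}

#' Opposing-pair rate table of a mutational profile
#'
#' Pairs the rate of each mutation X>Y with the rate of the opposing
#' mutation Y>X on the same triplet duplex (rates are raw counts). Each
#' unordered pair appears once; pairs whose two directions coincide on the
#' duplex (self-inverse cells, e.g. C>G at a self-paired context) carry a
#' single rate and no ratio. The ratio is max/min (>= 1, Inf when one
#' direction is unobserved); pairs with both rates zero get an NA ratio
#' and are counted in the \code{"zeroPairs"} attribute.
#'
#' @param profile A \linkS4class{MutationProfile}, or a 6 x 16 count
#'   matrix with alteration rows and context columns.
#' @return data.frame: \code{group, alteration1, context1, rate1,
#'   alteration2, context2, rate2, selfInverse, ratio}.
#' @export
opposingPairTable <- function(profile) {
    m <- if (methods::is(profile, "MutationProfile"))
        profileCounts(profile, "total") else profile
    stopifnot(identical(dim(m), c(6L, 16L)))
    dimnames(m) <- list(.ALTERATIONS, .CONTEXTS)
    cells <- expand.grid(alteration = .ALTERATIONS, context = .CONTEXTS,
        stringsAsFactors = FALSE)
    opp <- .opposingCell(cells$alteration, cells$context)
    key1 <- paste(cells$alteration, cells$context)
    key2 <- paste(opp$alteration, opp$context)
    pairKey <- ifelse(key1 <= key2, paste(key1, key2, sep = " / "),
                      paste(key2, key1, sep = " / "))
    first <- !duplicated(pairKey)
    out <- data.frame(
        group = duplexGroupId(cells$context[first]),
        alteration1 = cells$alteration[first],
        context1 = cells$context[first],
        rate1 = m[cbind(cells$alteration[first], cells$context[first])],
        alteration2 = opp$alteration[first],
        context2 = opp$context[first],
        rate2 = m[cbind(opp$alteration[first], opp$context[first])],
        selfInverse = key1[first] == key2[first],
        stringsAsFactors = FALSE)
    hi <- pmax(out$rate1, out$rate2)
    lo <- pmin(out$rate1, out$rate2)
    out$ratio <- ifelse(out$selfInverse, NA_real_,
        ifelse(hi == 0, NA_real_, hi / ifelse(lo == 0, NA, lo)))
    out$ratio[!out$selfInverse & lo == 0 & hi > 0] <- Inf
    attr(out, "zeroPairs") <- sum(!out$selfInverse & hi == 0)
    out
}

#' Opposing-pair ratio between two rates
#'
#' @param rate1,rate2 Non-negative rates (raw counts).
#' @return max/min ratio (>= 1; Inf if one rate is 0, NA if both are).
#' @examples
#' pairRatio(1617, 1558)  # 1.04 to 2 dp
#' pairRatio(229, 95)     # 2.41 to 2 dp
#' @export
pairRatio <- function(rate1, rate2) {
    hi <- pmax(rate1, rate2); lo <- pmin(rate1, rate2)
    ifelse(hi == 0, NA_real_, ifelse(lo == 0, Inf, hi / lo))
}

#' Distribution of opposing-pair ratios
#'
#' Histogram of pair ratios on unit bins [1,2], (2,3], ... and the
#' fraction of ratios exceeding 2 (the summary separating the divergent
#' opposing-GOH rates from the near-equal opposing-LOH rates).
#'
#' @param ratios Numeric vector of pair ratios (NA dropped; Inf counted
#'   as > 2 and placed in the last bin), or an \code{opposingPairTable}
#'   data.frame.
#' @return List: \code{fractionAbove2}, \code{breaks}, \code{counts},
#'   \code{n}.
#' @export
ratioDistribution <- function(ratios) {
    if (is.data.frame(ratios)) ratios <- ratios$ratio
    ratios <- ratios[!is.na(ratios)]
    if (!length(ratios)) stop("no defined ratios")
    finite <- ratios[is.finite(ratios)]
    top <- max(2, if (length(finite)) ceiling(max(finite)) else 2) + 1
    breaks <- c(1, seq(2, top))
    counts <- as.numeric(table(cut(pmin(ratios, top - 0.5), breaks,
        include.lowest = TRUE)))
    list(fractionAbove2 = sum(ratios > 2) / length(ratios),
         breaks = breaks, counts = counts, n = length(ratios))
}

#' Transition/transversion ratio of a set of mutation rates
#'
#' Sums the transition rates (C>T and T>C classes, which cover their
#' purine duplex equivalents after normalization) and divides by the
#' summed transversion rates.
#'
#' @param rates Numeric rates.
#' @param alterations Alteration type of each rate (same length).
#' @return List: \code{tsSum}, \code{tvSum}, \code{ratio} (0 when tsSum
#'   is 0; NA with \code{defined = FALSE} when tvSum is 0).
#' @export
tsTvRatio <- function(rates, alterations) {
    stopifnot(length(rates) == length(alterations),
              all(alterations %in% .ALTERATIONS))
    ts <- sum(rates[alterations %in% c("C>T", "T>C")])
    tv <- sum(rates[!alterations %in% c("C>T", "T>C")])
    list(tsSum = ts, tvSum = tv,
         ratio = if (tv > 0) ts / tv else if (ts == 0) 0 else NA_real_,
         defined = tv > 0)
}

#' Mutation-rate diagram for one duplex context group
#'
#' Collects the opposing pairs of one duplex group together with the
#' group's TS/TV summary (all cell rates of the group's contexts enter the
#' sums).
#'
#' @param profile A \linkS4class{MutationProfile} or 6 x 16 matrix.
#' @param group Canonical duplex group name (see
#'   \code{\link{duplexGroups}}).
#' @return List: \code{group}, \code{pairs} (subset of
#'   \code{\link{opposingPairTable}}), \code{tsSum}, \code{tvSum},
#'   \code{tsTv}.
#' @export
rateDiagram <- function(profile, group) {
    if (!group %in% .DUPLEX_CANONICAL) stop("unknown duplex group: ", group)
    m <- if (methods::is(profile, "MutationProfile"))
        profileCounts(profile, "total") else profile
    dimnames(m) <- list(.ALTERATIONS, .CONTEXTS)
    pairs <- opposingPairTable(m)
    pairs <- pairs[pairs$group == group, , drop = FALSE]
    members <- duplexGroup(group)$members
    sub <- m[, members, drop = FALSE]
    tt <- tsTvRatio(as.vector(sub), rep(rownames(sub), ncol(sub)))
    list(group = group, pairs = pairs, tsSum = tt$tsSum, tvSum = tt$tvSum,
         tsTv = tt$ratio)
}

#' Share of an alteration's counts at N.G contexts
#'
#' The fraction of C>T (or T>C) mutations whose 3' flank is G — the
#' summary statistic for the CpG-deamination peak pattern (elevated C>T at
#' the four N.G trinucleotides, and its mirrored T>C counterpart among
#' reversals). A uniform context distribution gives 0.25.
#'
#' @param profile A \linkS4class{MutationProfile}.
#' @param alteration "C>T" or "T>C".
#' @param which Count layer: "total", "reversed" or "unreversed".
#' @return List: \code{share}, \code{total}, \code{defined} (FALSE when
#'   the alteration has no counts).
#' @export
ncgPeakShare <- function(profile, alteration = "C>T", which = "total") {
    stopifnot(alteration %in% c("C>T", "T>C"))
    m <- profileCounts(profile, which)
    row <- m[alteration, ]
    ng <- grepl("\\.G$", .CONTEXTS)
    tot <- sum(row)
    list(share = if (tot > 0) sum(row[ng]) / tot else NA_real_,
         total = tot, defined = tot > 0)
}

#' Plot a reversal-split mutational profile
#'
#' Stacked barplot of the 96 alteration-by-context cells: solid (dark)
#' segments are mutations reversed in the next tier, light segments
#' unreversed, grouped by the six alteration types.
#'
#' @param profile A \linkS4class{MutationProfile}.
#' @param main Plot title.
#' @return Invisibly, the 2 x 96 matrix plotted.
#' @export
plotMutationProfile <- function(profile, main = profile@tier) {
    rev <- as.vector(t(profile@reversed))
    unrev <- as.vector(t(profile@unreversed))
    h <- rbind(reversed = rev, unreversed = unrev)
    cols <- rep(c("#1f78b4", "#33a02c", "#e31a1c", "#ff7f00", "#6a3d9a",
                  "#b15928"), each = 16)
    graphics::barplot(h, col = c("grey20", NA), border = cols,
        names.arg = rep(.CONTEXTS, 6), las = 2, cex.names = 0.45,
        main = main, ylab = "SNV count")
    graphics::mtext(.ALTERATIONS, side = 3, line = -1,
        at = seq(8, by = 16 * 1.2, length.out = 6) * 1.0)
    invisible(h)
}
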