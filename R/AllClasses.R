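#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## Genotype vocabulary used throughout: MM (homozygous reference-matching
## major allele), Mm (reference/non-reference heterozygote), mm (homozygous
## non-reference), mn (heterozygote of two non-reference alleles).
## "EXCLUDED" marks per-sample calls failing the genotype-class filters.
.GT_LEVELS <- c("MM", "Mm", "mm", "mn")
.GT_EXCLUDED <- "EXCLUDED"
.TRANSITION_LEVELS <- c("NONE", "GOH_M", "GOH_m", "LOH_M", "LOH_m", "OTHER")
.BASES <- c("A", "C", "G", "T")

#' Genotype levels
#'
#' Vocabulary helpers: the four genotype classes assigned by the calling
#' filters and the six transition labels used by the stage tracker.
#'
#' @return Character vector of levels.
#' @export
genotypeLevels <- function() .GT_LEVELS

#' @rdname genotypeLevels
#' @export
transitionLevels <- function() .TRANSITION_LEVELS

#' CaseSampleSet: per-stage variant calls for one patient
#'
#' Holds the filtered site calls for every staged sample of a single case
#' (e.g. blood B, nontumor N, paratumor P, tumor T). Each element of
#' \code{calls} is a data.frame of site calls with columns \code{chrom, pos,
#' ref, alleleM, allelem, majorAF, minorAF, depth, qd, fs, genotype}, where
#' \code{genotype} is one of MM/Mm/mm/mn or EXCLUDED.
#'
#' @slot caseId Case identifier.
#' @slot stages Ordered stage labels (unique, length >= 2).
#' @slot calls Named list of per-stage site-call data.frames.
#' @slot reference A \linkS4class{DNAStringSet} with the reference sequence
#'   fragment (possibly empty when flanks are supplied externally).
#'
#' @export
setClass("CaseSampleSet",
    representation(caseId = "character", stages = "character",
                   calls = "list", reference = "ANY"),
    prototype(caseId = NA_character_, stages = character(0),
              calls = list(), reference = NULL))

setValidity("CaseSampleSet", function(object) {
    msg <- character(0)
    if (length(object@stages) < 2L)
        msg <- c(msg, "a case needs at least 2 stages")
    if (anyDuplicated(object@stages))
        msg <- c(msg, "stage labels must be unique")
    if (!identical(names(object@calls), object@stages))
        msg <- c(msg, "names(calls) must equal stages, in order")
    need <- c("chrom", "pos", "ref", "genotype")
    for (s in names(object@calls)) {
        if (!all(need %in% names(object@calls[[s]])))
            msg <- c(msg, sprintf("calls[['%s']] lacks required columns", s))
    }
    if (length(msg)) msg else TRUE
})

#' StagedLoci: loci callable in every stage of a case
#'
#' The multi-stage intersection of filtered calls: one row per genomic
#' position with a non-EXCLUDED genotype in every stage, plus the reference
#' base, the non-reference allele observed at the site, and the immediate
#' 5' and 3' flanking bases. Genotype columns are named after the stages.
#'
#' @slot caseId Case identifier.
#' @slot stages Ordered stage labels.
#' @slot loci data.frame with columns \code{chrom, pos, ref, alt, flank5,
#'   flank3} and one genotype column per stage.
#'
#' @export
setClass("StagedLoci",
    representation(caseId = "character", stages = "character",
                   loci = "data.frame"),
    prototype(caseId = NA_character_, stages = character(0),
              loci = data.frame()))

setValidity("StagedLoci", function(object) {
    msg <- character(0)
    fixed <- c("chrom", "pos", "ref", "alt", "flank5", "flank3")
    if (!all(fixed %in% names(object@loci)))
        msg <- c(msg, "loci must have chrom,pos,ref,alt,flank5,flank3")
    if (!all(object@stages %in% names(object@loci)))
        msg <- c(msg, "loci must carry one genotype column per stage")
    else {
        g <- unlist(object@loci[object@stages], use.names = FALSE)
        if (length(g) && !all(g %in% .GT_LEVELS))
            msg <- c(msg, "genotypes must be MM/Mm/mm/mn (no EXCLUDED rows)")
    }
    if (length(msg)) msg else TRUE
})

#' DeltaSummary: transition counts between two stages
#'
#' Counts of genotype transitions (the paper-style delta of one stage
#' against another, e.g. N vs B) broken down by transition label, with the
#' at-risk denominators per origin genotype. \code{sigma} is the total
#' number of changed loci (all non-NONE labels); \code{lohTotal} is
#' LOH_M + LOH_m. Loci whose transition involves an mn genotype are labelled
#' like heterozygotes but tallied separately in \code{mnInvolved}.
#'
#' @slot fromStage,toStage The compared stage labels (to vs from).
#' @slot counts Named numeric over the six transition labels.
#' @slot denominators Named numeric: loci at risk per origin genotype.
#' @slot sigma Total changed loci.
#' @slot lohTotal LOH_M + LOH_m.
#' @slot mnInvolved Number of transitions involving an mn genotype.
#'
#' @export
setClass("DeltaSummary",
    representation(fromStage = "character", toStage = "character",
                   counts = "numeric", denominators = "numeric",
                   sigma = "numeric", lohTotal = "numeric",
                   mnInvolved = "numeric"))

setValidity("DeltaSummary", function(object) {
    msg <- character(0)
    if (!identical(names(object@counts), .TRANSITION_LEVELS))
        msg <- c(msg, "counts must be named by the six transition labels")
    if (length(object@lohTotal) &&
        !isTRUE(all.equal(unname(object@lohTotal),
                          unname(object@counts["LOH_M"] + object@counts["LOH_m"]))))
        msg <- c(msg, "lohTotal must equal LOH_M + LOH_m")
    if (length(msg)) msg else TRUE
})

#' PatchDiagram: rooted genotype tree across stages
#'
#' One diagram per origin genotype at the first stage. Nodes are identified
#' by the full genotype path from the root (e.g. \code{"MM|Mm|MM"}); each
#' locus of the origin contributes exactly one root-to-leaf path. Edges
#' carry the transition label, a deterministic step identifier (G1, G2, ...
#' for gain-of-heterozygosity steps; L1, L2, ... for loss-of-heterozygosity
#' steps, numbered in traversal order: stage level ascending, parent
#' genotype in order MM, Mm, mm, child genotype in order MM, Mm, mm), the
#' locus count, and the rate = edge count / parent node count.
#'
#' @slot origin Genotype at the first stage ("MM", "Mm" or "mm").
#' @slot stages Ordered stage labels.
#' @slot nodes data.frame: \code{id, level, genotype, count}.
#' @slot edges data.frame: \code{parent, child, level, from, to, label,
#'   step, count, rate}.
#'
#' @export
setClass("PatchDiagram",
    representation(origin = "character", stages = "character",
                   nodes = "data.frame", edges = "data.frame"))

setValidity("PatchDiagram", function(object) {
    msg <- character(0)
    if (!object@origin %in% c("MM", "Mm", "mm"))
        msg <- c(msg, "origin must be MM, Mm or mm")
    e <- object@edges
    n <- object@nodes
    if (nrow(e)) {
        if (any(e$rate < 0 | e$rate > 1, na.rm = TRUE))
            msg <- c(msg, "edge rates must lie in [0, 1]")
        ## child edge counts must sum to the parent node count
        agg <- tapply(e$count, e$parent, sum)
        par <- n$count[match(names(agg), n$id)]
        if (any(abs(agg - par) > 1e-8))
            msg <- c(msg, "child edge counts must sum to parent node count")
    }
    if (length(msg)) msg else TRUE
})

#' MutationProfile: reversal-split trinucleotide mutation counts
#'
#' A 6 x 16 count matrix over the pyrimidine-normalized alteration types
#' (C>A, C>G, C>T, T>A, T>C, T>G) and the 16 ordered flank contexts
#' ("X.Y" = 5' flank X, 3' flank Y), split into mutations that were
#' reversed in the next stage tier and mutations that were not. Counts are
#' raw (unnormalized for genomic trinucleotide frequencies).
#'
#' @slot tier Tier label, e.g. "dNB".
#' @slot reversed,unreversed 6 x 16 numeric matrices (rows = alteration
#'   types, columns = contexts).
#'
#' @export
setClass("MutationProfile",
    representation(tier = "character", reversed = "matrix",
                   unreversed = "matrix"))

setValidity("MutationProfile", function(object) {
    msg <- character(0)
    for (nm in c("reversed", "unreversed")) {
        m <- slot(object, nm)
        if (!identical(dim(m), c(6L, 16L)))
            msg <- c(msg, sprintf("%s must be 6 x 16", nm))
        else if (any(m < 0))
            msg <- c(msg, sprintf("%s counts must be >= 0", nm))
    }
    if (length(msg)) msg else TRUE
})

#' WindowSeries: per-window copy-number status across stage comparisons
#'
#' Fixed-size, non-overlapping genome windows with a copy-number status
#' (U = unaltered, G = gain, L = loss) for each stage-versus-baseline
#' comparison (columns of \code{status}, e.g. "NB", "PB", "TB").
#'
#' @slot windows data.frame with \code{chrom, start, end} (0-based
#'   half-open, per BED convention).
#' @slot windowSize Window size in bp (50e3 to 500e3 supported).
#' @slot status Character matrix, rows = windows, columns = comparisons.
#'
#' @export
setClass("WindowSeries",
    representation(windows = "data.frame", windowSize = "numeric",
                   status = "matrix"))

setValidity("WindowSeries", function(object) {
    msg <- character(0)
    if (length(object@windowSize) != 1L ||
        object@windowSize < 5e4 || object@windowSize > 5e5)
        msg <- c(msg, "windowSize must lie in [50000, 500000]")
    if (nrow(object@status) != nrow(object@windows))
        msg <- c(msg, "status must have one row per window")
    if (length(object@status) && !all(object@status %in% c("U", "G", "L")))
        msg <- c(msg, "status values must be U, G or L")
    w <- object@windows
    if (nrow(w) && any(w$end - w$start != object@windowSize))
        msg <- c(msg, "all windows must have width windowSize")
    if (length(msg)) msg else TRUE
})

#' SimTruth: ground truth emitted by the simulator
#'
#' @slot genotypes Character matrix, loci x stages: the true genotype path.
#' @slot events data.frame event log (locus, stage, kind, from, to,
#'   restoredOrigin): replaying it reproduces the genotype paths.
#' @slot windowOrders Character vector of true serial-order codes for
#'   simulated CNV windows (empty for SNV-only simulations).
#' @slot params The simulation parameter list actually used.
#'
#' @export
setClass("SimTruth",
    representation(genotypes = "matrix", events = "data.frame",
                   windowOrders = "character", params = "list"))
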