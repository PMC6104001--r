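## stage_tracker: transition labels, delta summaries, patch diagrams,
## lineage-effect ratios, serial SNV types, reversal fractions.

.GT_ORDER <- c("MM", "Mm", "mm")        # canonical traversal order

## mn participates as a heterozygote in labelling (tallied separately
## by callers); collapse it onto Mm for the transition table.
.hetCollapse <- function(g) ifelse(g == "mn", "Mm", g)

#' Label a genotype transition between two stages
#'
#' GOH_M for MM to Mm (gain of heterozygosity at a reference-homozygous
#' site), GOH_m for mm to Mm, LOH_M for Mm to MM, LOH_m for Mm to mm,
#' NONE when unchanged, OTHER for the remaining pairs (direct MM/mm
#' jumps). mn genotypes are treated as heterozygotes.
#'
#' @param prev,next. Genotype classes (MM/Mm/mm/mn); EXCLUDED is an error.
#' @return Character vector of transition labels.
#' @export
labelTransition <- function(prev, next.) {
    if (any(prev == .GT_EXCLUDED) || any(next. == .GT_EXCLUDED))
        stop("EXCLUDED genotypes cannot be labelled")
    ok <- prev %in% .GT_LEVELS & next. %in% .GT_LEVELS
    if (!all(ok)) stop("unknown genotype class")
    a <- .hetCollapse(prev)
    b <- .hetCollapse(next.)
    out <- rep("OTHER", length(a))
    out[a == b] <- "NONE"
    out[a == "MM" & b == "Mm"] <- "GOH_M"
    out[a == "mm" & b == "Mm"] <- "GOH_m"
    out[a == "Mm" & b == "MM"] <- "LOH_M"
    out[a == "Mm" & b == "mm"] <- "LOH_m"
    out
}

.stageGenotypes <- function(loci, stage) {
    tab <- lociTable(loci)
    if (!stage %in% stages(loci)) stop("unknown stage label: ", stage)
    tab[[stage]]
}

#' Summarize genotype transitions between two stages
#'
#' Counts each transition label for the comparison of \code{toStage}
#' against \code{fromStage} (the paper-style delta, e.g. N vs B).
#' Denominators give the loci at risk per origin genotype (mn counted with
#' Mm); \code{sigma} is the total number of changed loci.
#'
#' @param loci A \linkS4class{StagedLoci}.
#' @param fromStage,toStage Stage labels present in \code{loci}.
#' @return A \linkS4class{DeltaSummary}.
#' @export
deltaSummary <- function(loci, fromStage, toStage) {
    g0 <- .stageGenotypes(loci, fromStage)
    g1 <- .stageGenotypes(loci, toStage)
    lab <- if (length(g0)) labelTransition(g0, g1) else character(0)
    counts <- sapply(.TRANSITION_LEVELS, function(l) sum(lab == l))
    origin <- .hetCollapse(g0)
    denom <- sapply(.GT_ORDER, function(g) sum(origin == g))
    methods::new("DeltaSummary", fromStage = fromStage, toStage = toStage,
        counts = as.numeric(counts) |> stats::setNames(.TRANSITION_LEVELS),
        denominators = as.numeric(denom) |> stats::setNames(.GT_ORDER),
        sigma = sum(counts) - counts[["NONE"]],
        lohTotal = counts[["LOH_M"]] + counts[["LOH_m"]],
        mnInvolved = sum(g0 == "mn" | g1 == "mn"))
}

#' @rdname deltaSummary
#' @param object A \linkS4class{DeltaSummary}.
#' @export
deltaCounts <- function(object) {
    stopifnot(methods::is(object, "DeltaSummary"))
    object@counts
}

## Enumerate the complete genotype tree for one origin across K stages,
## with deterministic step identifiers. Counts come from observed paths.
.originTree <- function(origin, paths, nStages) {
    nodes <- data.frame(id = origin, level = 1L, genotype = origin,
        count = 0, stringsAsFactors = FALSE)
    edges <- data.frame(parent = character(0), child = character(0),
        level = integer(0), from = character(0), to = character(0),
        label = character(0), step = character(0), count = numeric(0),
        rate = numeric(0), stringsAsFactors = FALSE)
    prefixCounts <- function(k) {
        if (!length(paths)) return(integer(0))
        pre <- vapply(strsplit(paths, "|", fixed = TRUE),
            function(p) paste(p[seq_len(k)], collapse = "|"), character(1))
        table(pre)
    }
    cnt1 <- prefixCounts(1L)
    nodes$count <- if (origin %in% names(cnt1)) as.numeric(cnt1[[origin]]) else 0
    parents <- nodes
    for (k in 2L:nStages) {
        cnt <- prefixCounts(k)
        ## traversal: parent genotype in order MM,Mm,mm, then parent path
        ## order, then child genotype in order MM,Mm,mm
        ord <- order(match(parents$genotype, .GT_ORDER),
                     seq_len(nrow(parents)))
        newNodes <- list(); newEdges <- list()
        for (i in ord) {
            par <- parents[i, ]
            for (child in .GT_ORDER) {
                id <- paste(par$id, child, sep = "|")
                n <- if (id %in% names(cnt)) as.numeric(cnt[[id]]) else 0
                lab <- labelTransition(par$genotype, child)
                newNodes[[length(newNodes) + 1L]] <- data.frame(
                    id = id, level = k, genotype = child, count = n,
                    stringsAsFactors = FALSE)
                newEdges[[length(newEdges) + 1L]] <- data.frame(
                    parent = par$id, child = id, level = k,
                    from = par$genotype, to = child, label = lab,
                    step = NA_character_, count = n,
                    rate = if (par$count > 0) n / par$count else NA_real_,
                    stringsAsFactors = FALSE)
            }
        }
        newNodes <- do.call(rbind, newNodes)
        newEdges <- do.call(rbind, newEdges)
        nodes <- rbind(nodes, newNodes)
        edges <- rbind(edges, newEdges)
        ## next level's parents, in this level's enumeration order
        parents <- newNodes
    }
    list(nodes = nodes, edges = edges)
}

#' Build patch diagrams tracing genotype paths across stages
#'
#' One rooted diagram per origin genotype (MM, mm, Mm) at the first stage.
#' Every locus contributes exactly one root-to-leaf path; node counts are
#' path-prefix counts and edge rates are edge count divided by parent node
#' count. All potential mutation edges of the complete genotype tree are
#' enumerated (count 0 allowed) so that step identifiers are stable across
#' datasets: diagrams are numbered in origin order MM, mm, Mm; within a
#' diagram, stage level ascending, then parent genotype in order MM, Mm,
#' mm, then parent path order, then child genotype in order MM, Mm, mm.
#' GOH steps receive G1, G2, ...; LOH steps L1, L2, ...; direct MM/mm
#' jumps O1, O2, ...; no-change edges carry no step identifier. Loci whose
#' path contains an mn genotype are omitted from the diagrams and counted
#' in the \code{"mnExcluded"} attribute of the returned list.
#'
#' @param loci A \linkS4class{StagedLoci}.
#' @param stageOrder Ordered stage labels (default: all stages of the
#'   object).
#' @return Named list of three \linkS4class{PatchDiagram}s ("MM", "mm",
#'   "Mm").
#' @export
buildPatchDiagram <- function(loci, stageOrder = stages(loci)) {
    if (length(stageOrder) < 2L) stop("need at least 2 stages")
    if (length(stageOrder) > 8L) stop("at most 8 stages supported")
    tab <- lociTable(loci)
    gmat <- as.matrix(tab[stageOrder])
    hasMn <- if (nrow(gmat)) apply(gmat == "mn", 1L, any) else logical(0)
    gmat <- gmat[!hasMn, , drop = FALSE]
    pathsAll <- if (nrow(gmat)) apply(gmat, 1L, paste, collapse = "|")
                else character(0)

    diagrams <- list()
    gCounter <- 0L; lCounter <- 0L; oCounter <- 0L
    for (origin in c("MM", "mm", "Mm")) {
        sel <- if (nrow(gmat)) gmat[, 1L] == origin else logical(0)
        tree <- .originTree(origin, pathsAll[sel], length(stageOrder))
        ## assign global step identifiers in enumeration order
        steps <- tree$edges$label
        for (j in seq_along(steps)) {
            tree$edges$step[j] <- switch(steps[j],
                GOH_M = , GOH_m = {
                    gCounter <- gCounter + 1L; paste0("G", gCounter)
                },
                LOH_M = , LOH_m = {
                    lCounter <- lCounter + 1L; paste0("L", lCounter)
                },
                OTHER = {
                    oCounter <- oCounter + 1L; paste0("O", oCounter)
                },
                NA_character_)
        }
        diagrams[[origin]] <- methods::new("PatchDiagram", origin = origin,
            stages = stageOrder, nodes = tree$nodes, edges = tree$edges)
    }
    attr(diagrams, "mnExcluded") <- sum(hasMn)
    diagrams[c("MM", "mm", "Mm")]
}

#' Lineage partition of a heterozygous patch-diagram node
#'
#' For a heterozygous (Mm) node, returns the counts of loci partitioned to
#' MM versus mm at the next stage and their quotient. The quotient is
#' reported as \code{Inf} when the mm count is 0 and the MM count positive,
#' and as 0 when the MM count is 0 (the lineage-effect sentinel values).
#'
#' @param diagram A \linkS4class{PatchDiagram}.
#' @param node Node identifier (full path string, e.g. "MM|Mm").
#' @return List with \code{countMM}, \code{countmm}, \code{ratio}.
#' @export
lineageRatio <- function(diagram, node) {
    stopifnot(methods::is(diagram, "PatchDiagram"))
    nd <- diagram@nodes[diagram@nodes$id == node, ]
    if (!nrow(nd)) stop("no such node: ", node)
    if (nd$genotype != "Mm") stop("node is not heterozygous: ", node)
    e <- diagram@edges[diagram@edges$parent == node, ]
    cMM <- sum(e$count[e$to == "MM"])
    cmm <- sum(e$count[e$to == "mm"])
    ratio <- if (cMM == 0) 0 else if (cmm == 0) Inf else cMM / cmm
    list(countMM = cMM, countmm = cmm, ratio = ratio)
}

#' LOH partition ratios of surviving germline heterozygotes
#'
#' For the germline-Mm diagram, follows the all-Mm path and reports, at
#' each stage level, the partition of first-time LOH products of surviving
#' germline heterozygotes between MM and mm (the paper-style stage-wise
#' LOH-M/LOH-m ratios whose decline reflects diminishing positive
#' selection for reference homozygotes).
#'
#' @param diagram A \linkS4class{PatchDiagram} with origin "Mm".
#' @return data.frame with \code{level, stage, countMM, countmm, ratio,
#'   defined}; \code{defined} is FALSE when both counts are 0.
#' @export
lohPartitionRatios <- function(diagram) {
    stopifnot(methods::is(diagram, "PatchDiagram"))
    if (diagram@origin != "Mm") stop("diagram origin must be Mm")
    K <- length(diagram@stages)
    if (K < 2L) stop("need at least 2 stages")
    out <- lapply(2L:K, function(k) {
        node <- paste(rep("Mm", k - 1L), collapse = "|")
        lr <- lineageRatio(diagram, node)
        data.frame(level = k, stage = diagram@stages[k],
            countMM = lr$countMM, countmm = lr$countmm,
            ratio = if (lr$countMM == 0 && lr$countmm == 0) NA_real_
                    else lr$countMM / lr$countmm,
            defined = !(lr$countMM == 0 && lr$countmm == 0))
    })
    do.call(rbind, out)
}

#' Classify the serial SNV pattern of a four-stage locus
#'
#' Assigns the serial type of a B-N-P-T genotype quadruple: Type I when
#' B = N (no change in the first transition); Type IVa when
#' B != N != P = T with B = T (forward mutation reversed at P and stable
#' thereafter); Type IVb when B != N = P != T with B = T (reversed only at
#' T); otherwise Type II when N = T; otherwise Type III when N != T and
#' B != T; UNCLASSIFIED for quadruples matching none (IVa/IVb are
#' evaluated before II/III to resolve pattern overlap).
#'
#' @param b,n,p,t Genotype class vectors for the four stages (equal
#'   length).
#' @return Character vector over I, II, III, IVa, IVb, UNCLASSIFIED.
#' @export
classifySerialSNV <- function(b, n, p, t) {
    ln <- unique(c(length(b), length(n), length(p), length(t)))
    if (length(ln) != 1L) stop("exactly 4 equal-length stage vectors required")
    out <- rep("UNCLASSIFIED", length(b))
    isI <- b == n
    isIVa <- !isI & n != p & p == t & b == t
    isIVb <- !isI & !isIVa & n == p & p != t & b == t
    isII <- !isI & !isIVa & !isIVb & n == t
    isIII <- !isI & !isIVa & !isIVb & !isII & n != t & b != t
    out[isIII] <- "III"; out[isII] <- "II"
    out[isIVb] <- "IVb"; out[isIVa] <- "IVa"; out[isI] <- "I"
    out
}

#' @rdname classifySerialSNV
#' @param loci A \linkS4class{StagedLoci} with exactly 4 stages.
#' @return \code{serialSNVTypes} returns the per-locus type vector.
#' @export
serialSNVTypes <- function(loci) {
    st <- stages(loci)
    if (length(st) != 4L) stop("serial typing requires exactly 4 stages")
    tab <- lociTable(loci)
    classifySerialSNV(tab[[st[1L]]], tab[[st[2L]]], tab[[st[3L]]],
        tab[[st[4L]]])
}

#' Fraction of forward mutations reversed at the next stage
#'
#' Among loci whose genotype changed between \code{forwardPair[1]} and
#' \code{forwardPair[2]}, the fraction whose genotype at
#' \code{reversePair[2]} equals the pre-mutation genotype (a completed
#' forward-reverse cycle).
#'
#' @param loci A \linkS4class{StagedLoci}.
#' @param forwardPair Character vector c(s0, s1): the forward transition.
#' @param reversePair Character vector c(s1, s2): the candidate reversal
#'   transition (must start where the forward pair ends; both pairs must
#'   be consecutive in the case's stage order).
#' @return List with \code{fraction}, \code{numerator},
#'   \code{denominator}, \code{defined} (FALSE when no forward mutations
#'   exist, in which case \code{fraction} is NA).
#' @export
reversalFraction <- function(loci, forwardPair, reversePair) {
    st <- stages(loci)
    if (!identical(forwardPair[2L], reversePair[1L]))
        stop("reversePair must start at the end of forwardPair")
    i0 <- match(forwardPair[1L], st); i1 <- match(forwardPair[2L], st)
    i2 <- match(reversePair[2L], st)
    if (anyNA(c(i0, i1, i2))) stop("unknown stage label")
    if (i1 != i0 + 1L || i2 != i1 + 1L)
        stop("stage pairs must be consecutive in the case's stage order")
    g0 <- .stageGenotypes(loci, forwardPair[1L])
    g1 <- .stageGenotypes(loci, forwardPair[2L])
    g2 <- .stageGenotypes(loci, reversePair[2L])
    fwd <- g0 != g1
    num <- sum(fwd & g2 == g0)
    den <- sum(fwd)
    list(fraction = if (den > 0) num / den else NA_real_,
         numerator = num, denominator = den, defined = den > 0)
}

#' Mutation table for a stage transition
#'
#' Extracts the changed loci between two stages as a labelled SNV table
#' with base changes and flanks, ready for
#' \code{\link{buildProfile}}. The base change follows the residue
#' convention: a gained non-reference allele is ref>alt (GOH_M, LOH_m and
#' MM-to-mm jumps), a restored/gained reference allele is alt>ref (GOH_m,
#' LOH_M, mm-to-MM jumps). When \code{nextStage} is given, each mutation
#' is flagged as reversed if the genotype at \code{nextStage} equals the
#' pre-mutation genotype. Heterozygote-to-heterozygote changes (mn
#' involvement) carry no defined base change and are dropped, counted in
#' the \code{"dropped"} attribute.
#'
#' @param loci A \linkS4class{StagedLoci}.
#' @param fromStage,toStage The transition to extract.
#' @param nextStage Optional stage for the reversed-next flag.
#' @return data.frame: \code{chrom, pos, fromBase, toBase, flank5, flank3,
#'   label, reversedNext}.
#' @export
mutationTable <- function(loci, fromStage, toStage, nextStage = NULL) {
    tab <- lociTable(loci)
    g0 <- .stageGenotypes(loci, fromStage)
    g1 <- .stageGenotypes(loci, toStage)
    changed <- which(g0 != g1)
    lab <- if (length(changed)) labelTransition(g0[changed], g1[changed])
           else character(0)
    ref <- tab$ref[changed]; alt <- tab$alt[changed]
    toRefDir <- lab %in% c("GOH_m", "LOH_M") |
        (lab == "OTHER" & g1[changed] == "MM")
    fromBase <- ifelse(toRefDir, alt, ref)
    toBase <- ifelse(toRefDir, ref, alt)
    reversedNext <- if (!is.null(nextStage)) {
        g2 <- .stageGenotypes(loci, nextStage)
        g2[changed] == g0[changed]
    } else rep(NA, length(changed))
    out <- data.frame(chrom = tab$chrom[changed], pos = tab$pos[changed],
        fromBase = fromBase, toBase = toBase,
        flank5 = tab$flank5[changed], flank3 = tab$flank3[changed],
        label = lab, reversedNext = reversedNext,
        stringsAsFactors = FALSE)
    ok <- !is.na(out$fromBase) & !is.na(out$toBase) &
        out$fromBase != out$toBase & lab != "NONE"
    dropped <- sum(!ok)
    out <- out[ok, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "dropped") <- dropped
    out
}
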