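#' Accessors for frcycle classes
#'
#' \code{stages} returns the ordered stage labels; \code{caseId} the case
#' identifier; \code{nLoci} the number of loci; \code{lociTable} the
#' underlying data.frame of a \linkS4class{StagedLoci}; \code{lociRanges}
#' the loci as a \linkS4class{GRanges}; \code{profileCounts} the 6 x 16
#' count matrix of a \linkS4class{MutationProfile} (total, reversed or
#' unreversed); \code{diagramNodes}/\code{diagramEdges} the node and edge
#' tables of a \linkS4class{PatchDiagram}; \code{windowStatus} the status
#' matrix of a \linkS4class{WindowSeries}.
#'
#' @param object An frcycle object.
#' @param ... Further arguments for methods.
#' @return The accessed component.
#' @name frcycle-accessors
#' @aliases stages caseId nLoci lociTable lociRanges profileCounts
#'   diagramNodes diagramEdges windowStatus
NULL

#' @rdname frcycle-accessors
#' @export
setGeneric("stages", function(object) standardGeneric("stages"))

#' @rdname frcycle-accessors
#' @export
setGeneric("caseId", function(object) standardGeneric("caseId"))

#' @rdname frcycle-accessors
#' @export
setGeneric("nLoci", function(object) standardGeneric("nLoci"))

#' @rdname frcycle-accessors
#' @export
setGeneric("lociTable", function(object) standardGeneric("lociTable"))

#' @rdname frcycle-accessors
#' @export
setGeneric("lociRanges", function(object) standardGeneric("lociRanges"))

#' @rdname frcycle-accessors
#' @export
setGeneric("profileCounts",
    function(object, ...) standardGeneric("profileCounts"))

#' @rdname frcycle-accessors
#' @export
setGeneric("diagramNodes", function(object) standardGeneric("diagramNodes"))

#' @rdname frcycle-accessors
#' @export
setGeneric("diagramEdges", function(object) standardGeneric("diagramEdges"))

#' @rdname frcycle-accessors
#' @export
setGeneric("windowStatus", function(object) standardGeneric("windowStatus"))

## ---- methods ----

#' @rdname frcycle-accessors
setMethod("stages", "CaseSampleSet", function(object) object@stages)

#' @rdname frcycle-accessors
setMethod("stages", "StagedLoci", function(object) object@stages)

#' @rdname frcycle-accessors
setMethod("stages", "PatchDiagram", function(object) object@stages)

#' @rdname frcycle-accessors
setMethod("caseId", "CaseSampleSet", function(object) object@caseId)

#' @rdname frcycle-accessors
setMethod("caseId", "StagedLoci", function(object) object@caseId)

#' @rdname frcycle-accessors
setMethod("nLoci", "StagedLoci", function(object) nrow(object@loci))

#' @rdname frcycle-accessors
setMethod("lociTable", "StagedLoci", function(object) object@loci)

#' @rdname frcycle-accessors
setMethod("lociRanges", "StagedLoci", function(object) {
    df <- object@loci
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = df$pos, width = 1L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        df[setdiff(names(df), c("chrom", "pos"))])
    gr
})

#' @rdname frcycle-accessors
#' @param which One of "total", "reversed", "unreversed".
setMethod("profileCounts", "MutationProfile",
    function(object, which = c("total", "reversed", "unreversed")) {
        which <- match.arg(which)
        switch(which,
            total = object@reversed + object@unreversed,
            reversed = object@reversed,
            unreversed = object@unreversed)
    })

#' @rdname frcycle-accessors
setMethod("diagramNodes", "PatchDiagram", function(object) object@nodes)

#' @rdname frcycle-accessors
setMethod("diagramEdges", "PatchDiagram", function(object) object@edges)

#' @rdname frcycle-accessors
setMethod("windowStatus", "WindowSeries", function(object) object@status)

## ---- show ----

setMethod("show", "CaseSampleSet", function(object) {
    cat("CaseSampleSet:", object@caseId, "\n")
    cat("  stages:", paste(object@stages, collapse = " -> "), "\n")
    for (s in object@stages) {
        calls <- object@calls[[s]]
        ok <- sum(calls$genotype != .GT_EXCLUDED)
        cat(sprintf("  %s: %d sites (%d callable)\n", s, nrow(calls), ok))
    }
})

setMethod("show", "StagedLoci", function(object) {
    cat("StagedLoci:", object@caseId, "-", nrow(object@loci),
        "loci callable in all of", paste(object@stages, collapse = ","), "\n")
    if (nrow(object@loci)) {
        tab <- table(object@loci[[object@stages[1L]]])
        cat("  genotypes at", object@stages[1L], ":",
            paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    }
})

setMethod("show", "DeltaSummary", function(object) {
    cat(sprintf("DeltaSummary d%s%s:", object@toStage, object@fromStage), "\n")
    print(object@counts)
    cat("  LOH total:", object@lohTotal, "| sigma (changed loci):",
        object@sigma, "| mn-involved:", object@mnInvolved, "\n")
})

setMethod("show", "PatchDiagram", function(object) {
    cat(sprintf("PatchDiagram (origin %s) over stages %s\n", object@origin,
        paste(object@stages, collapse = " -> ")))
    cat(sprintf("  %d nodes, %d edges, %g loci\n", nrow(object@nodes),
        nrow(object@edges), object@nodes$count[object@nodes$level == 1L]))
    e <- object@edges[!is.na(object@edges$step) & object@edges$count > 0, ]
    if (nrow(e))
        print(e[, c("step", "level", "from", "to", "count", "rate")],
              row.names = FALSE)
})

setMethod("show", "MutationProfile", function(object) {
    tot <- object@reversed + object@unreversed
    cat(sprintf("MutationProfile tier %s: %g mutations (%g reversed next)\n",
        object@tier, sum(tot), sum(object@reversed)))
    print(rowSums(tot))
})

setMethod("show", "WindowSeries", function(object) {
    cat(sprintf("WindowSeries: %d windows of %g bp, comparisons: %s\n",
        nrow(object@windows), object@windowSize,
        paste(colnames(object@status), collapse = ", ")))
})

setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth: %d loci x %d stages, %d events, %d CNV windows\n",
        nrow(object@genotypes), ncol(object@genotypes),
        nrow(object@events), length(object@windowOrders)))
})
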