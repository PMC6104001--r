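## colocalization: SNV-to-recurrent-CNV distances, age correlations, and
## the 2000-bp decile density co-localization analysis.

#' Distances from classed SNVs to their nearest recurrent CNV
#'
#' For each SNV class (e.g. trinucleotide-context GOH classes of one
#' stage comparison), the distance in bp from each SNV to the edge of the
#' nearest recurrent-CNV window (0 when the SNV lies inside a window).
#' The focal class is compared to every other class with a two-tailed
#' t test on the per-SNV distances.
#'
#' @param snvs data.frame with \code{chrom, pos, class}.
#' @param rcnv Recurrent-CNV windows: data.frame \code{chrom, start, end}
#'   (0-based half-open) or a \linkS4class{GRanges}.
#' @param focalClass Class compared against the others (default: the
#'   class with the smallest mean distance).
#' @return List: \code{summary} (per-class n and mean distance),
#'   \code{pvalues} (focal vs each other class), \code{distances} (named
#'   list of per-SNV distances), \code{focalClass}.
#' @export
nearestRcnvDistances <- function(snvs, rcnv, focalClass = NULL) {
    stopifnot(all(c("chrom", "pos", "class") %in% names(snvs)))
    zones <- .asRanges(rcnv)
    if (!length(zones)) stop("empty recurrent-CNV set")
    gr <- GenomicRanges::GRanges(snvs$chrom,
        IRanges::IRanges(start = snvs$pos, width = 1L))
    hits <- GenomicRanges::distanceToNearest(gr, zones)
    d <- rep(NA_real_, length(gr))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
    byClass <- split(d, snvs$class)
    summary <- data.frame(class = names(byClass),
        n = vapply(byClass, function(x) sum(!is.na(x)), numeric(1)),
        meanDistance = vapply(byClass, function(x) mean(x, na.rm = TRUE),
                              numeric(1)),
        stringsAsFactors = FALSE)
    rownames(summary) <- NULL
    if (is.null(focalClass))
        focalClass <- summary$class[which.min(summary$meanDistance)]
    if (!focalClass %in% names(byClass)) stop("unknown focal class")
    others <- setdiff(names(byClass), focalClass)
    pvals <- vapply(others, function(cl) {
        x <- byClass[[focalClass]]; y <- byClass[[cl]]
        if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) return(NA_real_)
        stats::t.test(x, y, alternative = "two.sided")$p.value
    }, numeric(1))
    list(summary = summary,
         pvalues = data.frame(class = others, p = unname(pvals),
                              stringsAsFactors = FALSE),
         distances = byClass, focalClass = focalClass)
}

#' Pearson correlation of per-case mutation fractions with patient age
#'
#' E.g. the percentage of CpG-context C>T gains among all gains of a
#' stage comparison, against age at diagnosis.
#'
#' @param fractions Per-case fractions (numeric).
#' @param ages Patient ages in years (same length, >= 3 finite pairs).
#' @return List: \code{r}, \code{p}, \code{n}, \code{defined} (FALSE when
#'   either vector has zero variance).
#' @export
ageFractionCorrelation <- function(fractions, ages) {
    ok <- is.finite(fractions) & is.finite(ages)
    x <- fractions[ok]; y <- ages[ok]
    if (length(x) < 3L) stop("need at least 3 cases with finite values")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(r = NA_real_, p = NA_real_, n = length(x),
                    defined = FALSE))
    ct <- stats::cor.test(x, y, method = "pearson",
        alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
         defined = TRUE)
}

#' Decile density co-localization of breakpoints with an annotation
#'
#' The genome is tiled into tandem fixed-size windows (default 2000 bp);
#' per window, the breakpoint count and the annotation density (annotated
#' bp per window bp) are computed. Windows with zero annotation density
#' are removed, the remainder are split into ten near-even groups by
#' annotation-density percentile (ties broken by a stable sort on window
#' coordinate), and the mean breakpoint density per decile is correlated
#' (Pearson) with the decile index.
#'
#' @param breakpoints data.frame with \code{chrom, pos} (1-based).
#' @param annotation data.frame \code{chrom, start, end} (0-based
#'   half-open) or \linkS4class{GRanges}.
#' @param genomeLengths Named numeric vector of chromosome lengths.
#' @param windowSize Window size in bp (default 2000).
#' @return List: \code{table} (decile, nWindows, annotationDensity,
#'   breakpointDensity), \code{r}, \code{p}, \code{nWindowsRetained}.
#' @export
decileDensityCorrelation <- function(breakpoints, annotation,
                                     genomeLengths, windowSize = 2000) {
    win <- tileWindows(genomeLengths, windowSize)
    gwin <- .asRanges(win)
    bp <- GenomicRanges::GRanges(breakpoints$chrom,
        IRanges::IRanges(start = breakpoints$pos, width = 1L))
    bpCount <- GenomicRanges::countOverlaps(gwin, bp)
    annot <- GenomicRanges::reduce(.asRanges(annotation))
    ov <- GenomicRanges::findOverlaps(gwin, annot)
    covBp <- numeric(length(gwin))
    if (length(ov)) {
        inter <- GenomicRanges::pintersect(
            gwin[S4Vectors::queryHits(ov)], annot[S4Vectors::subjectHits(ov)])
        covBp <- as.numeric(tapply(GenomicRanges::width(inter),
            factor(S4Vectors::queryHits(ov), levels = seq_along(gwin)),
            sum))
        covBp[is.na(covBp)] <- 0
    }
    dens <- covBp / windowSize
    keep <- dens > 0
    if (sum(keep) < 10L) stop("fewer than 10 windows with annotation")
    dens <- dens[keep]
    bpd <- bpCount[keep] / windowSize
    chrom <- win$chrom[keep]; start <- win$start[keep]
    ord <- order(dens, chrom, start)        # stable tie-break on coordinate
    n <- length(ord)
    sizes <- rep(floor(n / 10), 10)
    extra <- n - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    decile <- integer(n)
    decile[ord] <- rep(seq_len(10), times = sizes)
    tab <- data.frame(decile = seq_len(10),
        nWindows = as.numeric(table(factor(decile, 1:10))),
        annotationDensity = as.numeric(tapply(dens, factor(decile, 1:10),
                                              mean)),
        breakpointDensity = as.numeric(tapply(bpd, factor(decile, 1:10),
                                              mean)))
    if (stats::sd(tab$breakpointDensity) == 0) {
        r <- NA_real_; p <- NA_real_
    } else {
        ct <- stats::cor.test(tab$breakpointDensity, tab$decile,
            method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
    }
    list(table = tab, r = r, p = p, nWindowsRetained = n)
}
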