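## cnv_serial: window CN-status calling, the 26-order serial taxonomy,
## order frequencies, lineage Q statistics, recurrent CNVs, and LOH
## overlap with copy-number states.

## Canonical arrangement: class I (exactly two U), then class II, then
## class III; within each class the order below is fixed so that
## downstream tables and figures are reproducible.
.SERIAL_ORDERS <- list(
    I   = c("ULU", "LUU", "UGU", "GUU", "UUL", "UUG"),
    II  = c("GUG", "LUL", "GGU", "LLU", "UGG", "ULL", "GGG", "LLL"),
    III = c("LUG", "GUL", "UGL", "ULG", "GLU", "LGU",
            "GGL", "GLL", "LGG", "LLG", "GLG", "LGL"))

#' Enumerate the 26 CNV serial orders
#'
#' All 3-letter codes over {U, G, L} for the copy-number status of a
#' window at the N, P and T stages relative to B, except UUU (no CNV at
#' any stage). The 26 orders partition into class I (a U status at exactly
#' two stages; 6 orders), class II (at most one U and no lineage
#' disadvantage; 8 orders, including the reversion orders GUG and LUL)
#' and class III (disadvantaged; 12 orders, of which 10 contain an abrupt
#' double-dose change directly between G and L, plus LUG and GUL whose
#' T-stage status fails to restore the N-stage status). The arrangement
#' within classes is fixed and documented in the source.
#'
#' @return data.frame with \code{code} and \code{class}.
#' @export
enumerateSerialOrders <- function() {
    data.frame(code = unlist(.SERIAL_ORDERS, use.names = FALSE),
        class = rep(names(.SERIAL_ORDERS),
                    lengths(.SERIAL_ORDERS)),
        stringsAsFactors = FALSE)
}

#' Classify a serial-order code
#'
#' Class I when exactly two of the three stages are U; class III when the
#' code contains an adjacent G-to-L or L-to-G change or is LUG or GUL;
#' class II otherwise. "UUU" and invalid codes are errors.
#'
#' @param code Character vector of 3-letter codes over {U, G, L}.
#' @return Character vector: "I", "II" or "III".
#' @export
classifyOrder <- function(code) {
    if (any(!grepl("^[UGL]{3}$", code))) stop("invalid serial-order code")
    if (any(code == "UUU")) stop("UUU is not a serial order (no CNV)")
    nU <- vapply(strsplit(code, ""), function(x) sum(x == "U"), integer(1))
    out <- rep("II", length(code))
    out[nU == 2L] <- "I"
    out[grepl("GL|LG", code) | code %in% c("LUG", "GUL")] <- "III"
    out[nU == 2L] <- "I"   # class I takes precedence (no 2-U code is III)
    out
}

#' Call the copy-number status of a window from paired read counts
#'
#' Library-size-normalized log2 ratio r = log2((countA/libA)/(countB/libB));
#' G (gain) when r >= threshold, L (loss) when r <= -threshold, else U.
#' Windows with both counts zero are called U and flagged in the
#' \code{"lowCoverage"} attribute. This is a deliberately simple,
#' pluggable caller: precomputed U/G/L status series are accepted
#' everywhere downstream so published callers can be substituted.
#'
#' @param countA,countB Window read counts for the test and baseline
#'   samples.
#' @param libA,libB Library sizes (total counts) of the two samples.
#' @param threshold Absolute log2-ratio threshold (default 0.35).
#' @return Character vector over U/G/L with a logical
#'   \code{"lowCoverage"} attribute.
#' @export
callWindowStatus <- function(countA, countB, libA, libB,
                             threshold = 0.35) {
    if (any(countA < 0 | countB < 0)) stop("counts must be >= 0")
    if (any(libA <= 0 | libB <= 0)) stop("library sizes must be > 0")
    r <- log2((countA / libA) / (countB / libB))
    out <- rep("U", length(r))
    out[r >= threshold] <- "G"
    out[r <= -threshold] <- "L"
    low <- countA == 0 & countB == 0
    out[low] <- "U"
    attr(out, "lowCoverage") <- low
    out
}

#' Construct a WindowSeries
#'
#' @param windows data.frame with \code{chrom, start, end} (0-based
#'   half-open).
#' @param status Character matrix (windows x comparisons) over U/G/L with
#'   comparison column names (e.g. "NB", "PB", "TB").
#' @param windowSize Window size in bp.
#' @return A \linkS4class{WindowSeries}.
#' @export
windowSeries <- function(windows, status, windowSize) {
    methods::new("WindowSeries", windows = windows,
        status = as.matrix(status), windowSize = windowSize)
}

#' Call a WindowSeries from a window read-count table
#'
#' @param counts data.frame with \code{chrom, start, end} and one count
#'   column per sample.
#' @param baseline Baseline sample column (default "B").
#' @param testStages Test sample columns (default c("N", "P", "T")).
#' @param windowSize Window size in bp (default inferred from the first
#'   window).
#' @param threshold Log2-ratio threshold passed to
#'   \code{\link{callWindowStatus}}.
#' @return A \linkS4class{WindowSeries} with one comparison column per
#'   test stage ("NB", "PB", ...).
#' @export
callWindowSeries <- function(counts, baseline = "B",
                             testStages = c("N", "P", "T"),
                             windowSize = NULL, threshold = 0.35) {
    stopifnot(all(c("chrom", "start", "end", baseline, testStages) %in%
                  names(counts)))
    if (is.null(windowSize))
        windowSize <- counts$end[1L] - counts$start[1L]
    libB <- sum(counts[[baseline]])
    status <- vapply(testStages, function(s) {
        callWindowStatus(counts[[s]], counts[[baseline]],
            sum(counts[[s]]), libB, threshold)
    }, character(nrow(counts)))
    colnames(status) <- paste0(testStages, baseline)
    windowSeries(counts[c("chrom", "start", "end")], status, windowSize)
}

#' Serial-order frequencies across window series
#'
#' Tallies the (N, P, T vs baseline) status codes of all windows over the
#' 26 serial orders; UUU windows are excluded from the tally. All series
#' must share one window size.
#'
#' @param series A \linkS4class{WindowSeries} or list of them.
#' @param comparisons The three status columns forming the code, in
#'   stage order (default c("NB", "PB", "TB")).
#' @return Named numeric vector of counts over the 26 codes (canonical
#'   order).
#' @export
orderFrequencies <- function(series, comparisons = c("NB", "PB", "TB")) {
    if (methods::is(series, "WindowSeries")) series <- list(series)
    sizes <- unique(vapply(series, function(s) s@windowSize, numeric(1)))
    if (length(sizes) > 1L) stop("mixed window sizes")
    codes <- unlist(lapply(series, function(s) {
        st <- windowStatus(s)
        if (!all(comparisons %in% colnames(st)))
            stop("missing comparison columns")
        paste0(st[, comparisons[1L]], st[, comparisons[2L]],
               st[, comparisons[3L]])
    }))
    codes <- codes[codes != "UUU"]
    all26 <- enumerateSerialOrders()$code
    out <- table(factor(codes, levels = all26))
    stats::setNames(as.numeric(out), all26)
}

#' Lineage Q statistics of serial-order frequencies
#'
#' Q = freq(GUG)/freq(GUL) and freq(LUL)/freq(LUG): under no lineage
#' effect the T-stage status of a window that reverted to U at P should
#' restore or oppose the N-stage status equally often, so both quotients
#' have null expectation 1. Each Q is tested with a two-cell chi-square
#' goodness-of-fit against equal expectation (no continuity correction).
#' A zero denominator adds a 0.5 pseudocount to both terms and flags the
#' row.
#'
#' @param freqs Named frequency vector as returned by
#'   \code{\link{orderFrequencies}}.
#' @return data.frame with \code{quotient, numerator, denominator, Q,
#'   pseudocount, p}.
#' @export
qStatistics <- function(freqs) {
    one <- function(num, den) {
        a <- freqs[[num]]; b <- freqs[[den]]
        pseudo <- b == 0
        if (pseudo) { a <- a + 0.5; b <- b + 0.5 }
        p <- if (freqs[[num]] + freqs[[den]] > 0)
            stats::chisq.test(c(freqs[[num]], freqs[[den]]),
                p = c(0.5, 0.5), correct = FALSE)$p.value
        else NA_real_
        data.frame(quotient = paste0(num, "/", den),
            numerator = freqs[[num]], denominator = freqs[[den]],
            Q = a / b, pseudocount = pseudo, p = p,
            stringsAsFactors = FALSE)
    }
    rbind(one("GUG", "GUL"), one("LUL", "LUG"))
}

#' Recurrent CNV windows
#'
#' Windows altered (non-U status in any of the per-patient stage
#' comparisons) in at least \code{minPatients} patients, minus windows
#' overlapping the optional exclusion zones.
#'
#' @param altered Logical matrix, windows x patients: TRUE when the
#'   window carries a CNV in any of the patient's stage comparisons.
#' @param windows data.frame with \code{chrom, start, end} (0-based
#'   half-open), one row per row of \code{altered}.
#' @param minPatients Recurrence threshold (default 6).
#' @param exclusionZones Optional data.frame \code{chrom, start, end} or
#'   \linkS4class{GRanges}: overlapping windows are removed.
#' @return data.frame of recurrent windows with \code{patientCount}.
#' @export
recurrentCNVs <- function(altered, windows, minPatients = 6,
                          exclusionZones = NULL) {
    altered <- as.matrix(altered)
    stopifnot(nrow(altered) == nrow(windows))
    if (minPatients > ncol(altered)) {
        warning("minPatients exceeds the patient count; empty set")
        return(cbind(windows[0, , drop = FALSE], patientCount = numeric(0)))
    }
    cnt <- rowSums(altered)
    keep <- cnt >= minPatients
    out <- windows[keep, , drop = FALSE]
    out$patientCount <- cnt[keep]
    if (!is.null(exclusionZones) && nrow(out)) {
        zones <- .asRanges(exclusionZones)
        gr <- .asRanges(out)
        hit <- GenomicRanges::countOverlaps(gr, zones) > 0
        out <- out[!hit, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

## data.frame (BED-style 0-based half-open) -> GRanges (1-based)
.asRanges <- function(x) {
    if (methods::is(x, "GRanges")) return(x)
    GenomicRanges::GRanges(x$chrom,
        IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Overlap of LOH sites with window copy-number states
#'
#' Fractions of LOH sites falling in copy-neutral (U), gain (G) and loss
#' (L) windows of the relevant stage comparison; sites outside every
#' window are counted as uncovered.
#'
#' @param sites data.frame with \code{chrom, pos} (1-based positions).
#' @param windows data.frame with \code{chrom, start, end} (0-based
#'   half-open) and \code{status} over U/G/L.
#' @return List: \code{fractions} (named over U/G/L, of covered sites),
#'   \code{counts}, \code{uncovered}, \code{n}.
#' @export
lohCopyStateOverlap <- function(sites, windows) {
    stopifnot(all(c("chrom", "pos") %in% names(sites)),
              all(c("chrom", "start", "end", "status") %in% names(windows)))
    gr <- GenomicRanges::GRanges(sites$chrom,
        IRanges::IRanges(start = sites$pos, width = 1L))
    win <- .asRanges(windows)
    hits <- GenomicRanges::findOverlaps(gr, win, select = "first")
    covered <- !is.na(hits)
    st <- windows$status[hits[covered]]
    counts <- vapply(c("U", "G", "L"), function(s) sum(st == s), numeric(1))
    nCov <- sum(covered)
    list(fractions = if (nCov > 0) counts / nCov else counts * NA_real_,
         counts = counts, uncovered = sum(!covered), n = nrow(sites))
}

#' Tile a genome into fixed-size windows
#'
#' Non-overlapping windows anchored at position 0 of each chromosome;
#' partial terminal windows are dropped.
#'
#' @param genomeLengths Named numeric vector of chromosome lengths.
#' @param windowSize Window size in bp.
#' @return data.frame with \code{chrom, start, end} (0-based half-open).
#' @export
tileWindows <- function(genomeLengths, windowSize) {
    out <- lapply(names(genomeLengths), function(ch) {
        nwin <- floor(genomeLengths[[ch]] / windowSize)
        if (nwin < 1L) return(NULL)
        start <- (seq_len(nwin) - 1L) * windowSize
        data.frame(chrom = ch, start = start, end = start + windowSize,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
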