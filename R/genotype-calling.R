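## variant_io: genotype-class filters, VCF reading, per-case intersection.

#' Classify a site call into a genotype class
#'
#' Applies the per-sample calling filters: a site is EXCLUDED unless read
#' depth exceeds 8; MM requires the reference-matching major allele at
#' frequency >= 0.95 with strand-bias FS <= 20; heterozygotes (Mm, or mn
#' when both observed alleles mismatch the reference) require the most
#' frequent allele between 0.30 and 0.70 with quality-by-depth QD >= 4 and
#' FS <= 20; mm requires the non-reference allele at frequency >= 0.95 with
#' QD >= 20 and FS <= 20. Calls falling in none of these windows (e.g.
#' major allele fraction in (0.70, 0.95)) are EXCLUDED. A missing QD or FS
#' value fails every criterion that bounds it.
#'
#' @param majorAF Fraction of reads supporting the most frequent allele.
#' @param minorAF Fraction supporting the second most frequent allele.
#' @param qd Quality-by-depth score (NA allowed).
#' @param fs Phred-scaled Fisher strand-bias score (NA allowed).
#' @param depth Read depth.
#' @param majorIsRef Logical: does the most frequent allele match the
#'   reference?
#' @param bothNonRef Logical: do both observed alleles mismatch the
#'   reference (distinguishes mn from Mm)?
#' @return Character vector of genotype classes
#'   (MM/Mm/mm/mn/EXCLUDED). All arguments are recycled to a common length.
#' @examples
#' classifyGenotype(0.96, 0.04, qd = 30, fs = 5, depth = 8)   # EXCLUDED
#' classifyGenotype(0.50, 0.50, qd = 6, fs = 10, depth = 30)  # Mm
#' @export
classifyGenotype <- function(majorAF, minorAF, qd = NA_real_, fs = NA_real_,
                             depth, majorIsRef = TRUE, bothNonRef = FALSE) {
    n <- max(length(majorAF), length(minorAF), length(qd), length(fs),
             length(depth))
    if (n == 0L) return(character(0))
    majorAF <- rep_len(as.numeric(majorAF), n)
    minorAF <- rep_len(as.numeric(minorAF), n)
    qd <- rep_len(as.numeric(qd), n)
    fs <- rep_len(as.numeric(fs), n)
    depth <- rep_len(as.numeric(depth), n)
    majorIsRef <- rep_len(as.logical(majorIsRef), n)
    bothNonRef <- rep_len(as.logical(bothNonRef), n)

    if (any(!is.finite(majorAF) | !is.finite(minorAF)))
        stop("allele fractions must be finite")
    if (any(majorAF < 0 | majorAF > 1 | minorAF < 0 | minorAF > 1))
        stop("allele fractions must lie in [0, 1]")
    if (any(majorAF + minorAF > 1 + 1e-9))
        stop("allele fractions must sum to at most 1")
    if (any(is.na(depth)) || any(depth < 0))
        stop("depth must be a non-negative read count")

    fsOK <- !is.na(fs) & fs <= 20
    out <- rep(.GT_EXCLUDED, n)
    isMM <- majorAF >= 0.95 & fsOK & majorIsRef & !bothNonRef
    isHet <- majorAF >= 0.30 & majorAF <= 0.70 &
        !is.na(qd) & qd >= 4 & fsOK
    ismm <- majorAF >= 0.95 & !is.na(qd) & qd >= 20 & fsOK &
        !majorIsRef & !bothNonRef
    out[isMM] <- "MM"
    out[ismm] <- "mm"
    out[isHet & !bothNonRef] <- "Mm"
    out[isHet & bothNonRef] <- "mn"
    out[depth <= 8] <- .GT_EXCLUDED
    out
}

.readReference <- function(referenceFasta) {
    if (is.null(referenceFasta)) return(NULL)
    if (methods::is(referenceFasta, "DNAStringSet")) return(referenceFasta)
    Biostrings::readDNAStringSet(referenceFasta)
}

## Parse one single-sample VCF into a SiteCall data.frame.
.readStageVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    inf <- VariantAnnotation::info(vcf)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    ref <- as.character(rr$REF)

    alt <- rr$ALT                       # DNAStringSetList, >= 0 alts per row
    naltAll <- S4Vectors::elementNROWS(alt)
    afRaw <- inf$AF                     # NumericList or numeric
    af <- if (is.null(afRaw)) {
        lapply(naltAll, function(k) rep(NA_real_, k))
    } else as.list(afRaw)

    keep <- rep(TRUE, length(rr))
    skipped <- 0L
    multi <- 0L
    n <- length(rr)
    majorAF <- minorAF <- numeric(n)
    alleleM <- allelem <- character(n)
    majorIsRef <- rep(TRUE, n)
    bothNonRef <- rep(FALSE, n)

    for (i in seq_len(n)) {
        alts <- as.character(alt[[i]])
        isSnv <- nchar(ref[i]) == 1L && ref[i] %in% .BASES &&
            all(alts %in% .BASES)      # indels and symbolic alleles: skip
        afs <- suppressWarnings(as.numeric(af[[i]]))[seq_along(alts)]
        if (!isSnv || (anyNA(afs) && length(alts))) {
            keep[i] <- FALSE; skipped <- skipped + 1L; next
        }
        fr <- c(max(0, 1 - sum(afs)), afs)
        al <- c(ref[i], alts)
        ord <- order(fr, decreasing = TRUE)
        fr <- fr[ord]; al <- al[ord]
        ## multi-allelic guard: a third allele above 5% voids the site
        if (length(fr) > 2L && fr[3L] > 0.05) {
            keep[i] <- FALSE; multi <- multi + 1L; next
        }
        majorAF[i] <- fr[1L]
        minorAF[i] <- if (length(fr) > 1L) fr[2L] else 0
        alleleM[i] <- al[1L]
        allelem[i] <- if (length(al) > 1L) al[2L] else NA_character_
        majorIsRef[i] <- al[1L] == ref[i]
        bothNonRef[i] <- al[1L] != ref[i] &&
            (length(al) > 1L && al[2L] != ref[i]) && minorAF[i] >= 0.30
    }
    if (skipped)
        warning(sprintf("%s: skipped %d malformed records", path, skipped))

    getInfo <- function(field) {
        v <- inf[[field]]
        if (is.null(v)) rep(NA_real_, n) else as.numeric(v)
    }
    depth <- getInfo("DP")
    depth[is.na(depth)] <- 0
    qd <- getInfo("QD")
    fs <- getInfo("FS")

    gt <- rep(.GT_EXCLUDED, n)
    gt[keep] <- classifyGenotype(majorAF[keep], minorAF[keep], qd[keep],
        fs[keep], depth[keep], majorIsRef[keep], bothNonRef[keep])

    df <- data.frame(chrom = chrom, pos = pos, ref = ref,
        alleleM = alleleM, allelem = allelem,
        majorAF = majorAF, minorAF = minorAF,
        depth = depth, qd = qd, fs = fs,
        genotype = gt, stringsAsFactors = FALSE)
    attr(df, "skipped") <- skipped
    attr(df, "multiallelicExcluded") <- multi
    df
}

#' Read staged variant calls for one case
#'
#' Reads one VCF per stage (paths named by their stage labels), applies the
#' genotype-class filters via \code{\link{classifyGenotype}}, and returns a
#' \linkS4class{CaseSampleSet}. Only single-base SNV records are kept;
#' indels and malformed records are skipped with a warning and counted.
#' Sites where a third allele exceeds 5\% frequency are EXCLUDED.
#'
#' @param vcfPaths Named character vector of VCF paths; names are the stage
#'   labels in their biological order (e.g. c(B=..., N=..., P=..., T=...)).
#' @param referenceFasta Path to the reference FASTA, or a
#'   \linkS4class{DNAStringSet} (used later for flanking bases); may be NULL.
#' @param caseId Case identifier.
#' @return A \linkS4class{CaseSampleSet}.
#' @export
readCase <- function(vcfPaths, referenceFasta = NULL, caseId = "case") {
    stageLabels <- names(vcfPaths)
    if (is.null(stageLabels) || any(!nzchar(stageLabels)))
        stop("vcfPaths must be named by stage labels")
    if (anyDuplicated(stageLabels))
        stop("duplicate stage label")
    if (length(vcfPaths) < 2L)
        stop("a case needs at least 2 stages")
    missing <- !file.exists(vcfPaths)
    if (any(missing))
        stop("missing VCF file(s): ", paste(vcfPaths[missing], collapse = ", "))
    calls <- lapply(vcfPaths, .readStageVcf)
    names(calls) <- stageLabels
    methods::new("CaseSampleSet", caseId = caseId, stages = stageLabels,
        calls = calls, reference = .readReference(referenceFasta))
}

## Flanking bases from the reference for 1-based positions.
.flanksFromReference <- function(reference, chrom, pos) {
    f5 <- f3 <- rep(NA_character_, length(pos))
    for (ch in unique(chrom)) {
        if (!ch %in% names(reference))
            stop("contig missing from reference: ", ch)
        seq <- reference[[ch]]
        idx <- which(chrom == ch)
        p <- pos[idx]
        bad <- p <= 1L | p >= length(seq)
        pin <- p[!bad]
        if (length(pin)) {
            f5[idx[!bad]] <- as.character(Biostrings::extractAt(
                seq, IRanges::IRanges(pin - 1L, pin - 1L)))
            f3[idx[!bad]] <- as.character(Biostrings::extractAt(
                seq, IRanges::IRanges(pin + 1L, pin + 1L)))
        }
    }
    list(flank5 = f5, flank3 = f3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intersect a case to loci callable in every stage
#'
#' Retains only positions with a non-EXCLUDED genotype class in every stage
#' of the case (positions absent from any stage's calls are dropped),
#' attaches 5'/3' flanking bases from the reference, and returns the loci
#' sorted by (chrom, pos). The non-reference allele recorded for a locus is
#' the first non-reference allele observed across stages.
#'
#' @param case A \linkS4class{CaseSampleSet}.
#' @param referenceFasta Optional reference override (path or
#'   DNAStringSet); defaults to the reference stored in the case.
#' @return A \linkS4class{StagedLoci}.
#' @export
intersectCase <- function(case, referenceFasta = NULL) {
    stopifnot(methods::is(case, "CaseSampleSet"))
    stages <- case@stages
    keyed <- lapply(stages, function(s) {
        df <- case@calls[[s]]
        df <- df[df$genotype != .GT_EXCLUDED, , drop = FALSE]
        df$key <- paste(df$chrom, df$pos, sep = ":")
        df
    })
    names(keyed) <- stages
    common <- Reduce(intersect, lapply(keyed, `[[`, "key"))
    empty <- data.frame(chrom = character(0), pos = integer(0),
        ref = character(0), alt = character(0),
        flank5 = character(0), flank3 = character(0),
        stringsAsFactors = FALSE)
    for (s in stages) empty[[s]] <- character(0)
    if (!length(common))
        return(methods::new("StagedLoci", caseId = case@caseId,
            stages = stages, loci = empty))

    first <- keyed[[1L]][match(common, keyed[[1L]]$key), ]
    loci <- data.frame(chrom = first$chrom, pos = first$pos, ref = first$ref,
        alt = NA_character_, flank5 = NA_character_, flank3 = NA_character_,
        stringsAsFactors = FALSE)
    for (s in stages) {
        df <- keyed[[s]]
        idx <- match(common, df$key)
        loci[[s]] <- df$genotype[idx]
        alt <- df$allelem[idx]
        alt[!is.na(alt) & alt == loci$ref] <- NA_character_
        fill <- is.na(loci$alt) & !is.na(alt)
        loci$alt[fill] <- alt[fill]
    }
    reference <- .readReference(referenceFasta) %||% case@reference
    if (!is.null(reference)) {
        fl <- .flanksFromReference(reference, loci$chrom, loci$pos)
        loci$flank5 <- fl$flank5
        loci$flank3 <- fl$flank3
    }
    loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
    rownames(loci) <- NULL
    methods::new("StagedLoci", caseId = case@caseId, stages = stages,
        loci = loci)
}

#' Read or write a StagedLoci table as TSV
#'
#' The TSV carries chrom, pos (1-based), ref, alt, flank5, flank3 and one
#' genotype column per stage.
#'
#' @param object A \linkS4class{StagedLoci}.
#' @param path Output (or input) TSV path.
#' @param stages Stage labels (for reading; all trailing columns by default).
#' @param caseId Case identifier (for reading).
#' @return \code{writeStagedLoci} returns \code{path} invisibly;
#'   \code{readStagedLoci} returns a \linkS4class{StagedLoci}.
#' @export
writeStagedLoci <- function(object, path) {
    stopifnot(methods::is(object, "StagedLoci"))
    utils::write.table(object@loci, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' @rdname writeStagedLoci
#' @export
readStagedLoci <- function(path, stages = NULL, caseId = "case") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE, colClasses = "character")
    df$pos <- as.integer(df$pos)
    fixed <- c("chrom", "pos", "ref", "alt", "flank5", "flank3")
    if (is.null(stages)) stages <- setdiff(names(df), fixed)
    methods::new("StagedLoci", caseId = caseId, stages = stages, loci = df)
}
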