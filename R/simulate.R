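## synthetic_data: multi-stage genotype evolution with forward mutations,
## reversals, lineage fidelity and CpG context bias; window CN-status
## series with configurable serial-order frequencies; standard-format
## emission (VCF/FASTA/TSV/JSON) with ground truth.

.defaultOrderProbs <- function() {
    p <- c(GUG = 0.016, LUL = 0.016, GUL = 0.004, LUG = 0.004,
           ULU = 0.008, LUU = 0.008, UGU = 0.008, GUU = 0.008,
           UUL = 0.008, UUG = 0.008,
           GGU = 0.004, LLU = 0.004, UGG = 0.004, ULL = 0.004,
           GGG = 0.006, LLL = 0.006,
           UGL = 0.001, ULG = 0.001, GLU = 0.001, LGU = 0.001,
           GGL = 0.001, GLL = 0.001, LGG = 0.001, LLG = 0.001,
           GLG = 0.001, LGL = 0.001)
    p
}

#' Simulation parameters
#'
#' Builds the parameter list for \code{\link{simulateCase}} and
#' \code{\link{simulateCnvCase}}. Defaults emulate the staged-sample
#' study conditions at a scaled-down locus panel: a germline mixture with
#' 30\% heterozygous (Mm) and 5\% non-reference homozygous (mm) callable
#' loci; per-transition forward rates chosen so that a 20,000-locus case
#' carries on the order of 10^2 forward mutations per transition
#' (dominated by heterozygote losses, then mm-origin gains, then
#' MM-origin gains); strong reversal at the paratumor-like stage and weak
#' reversal at the tumor-like stage; near-perfect lineage fidelity; and a
#' CpG (N.G-context) gain-rate multiplier producing the
#' deamination-signature peak pattern.
#'
#' @param nLoci Number of simulated loci.
#' @param stages Ordered stage labels (first = germline baseline).
#' @param hetFraction,mmFraction Germline Mm and mm fractions (rest MM).
#' @param rGOHM,rGOHm,rLOH Per-locus forward mutation probabilities for
#'   each transition (named by the destination stage): MM-origin gain,
#'   mm-origin gain, heterozygote loss.
#' @param pRev Per-stage probability that an inherited (extant) mutation
#'   reverts at that stage (named by destination stage).
#' @param lineageFidelity Probability that a reverting loss of
#'   heterozygosity restores the pre-mutation homozygote rather than the
#'   opposite one.
#' @param mmPreference Probability that a fresh loss at a germline
#'   heterozygote yields MM rather than mm (reference homozygotes are
#'   favored).
#' @param contextBias Multiplier on the gain rate at CpG-dimer loci,
#'   where the gained allele is the deamination product (C>T / G>A).
#' @param cpgFraction Fraction of simulated loci placed on a CpG dimer.
#' @param depthMean,depthDispersion Negative-binomial read-depth model.
#' @param errorRate Non-reference read fraction at homozygous loci.
#' @param qdHetMean,qdHomMean,qdSd Normal models for the quality-by-depth
#'   annotation of heterozygous and homozygous-variant calls.
#' @param fsMean Mean of the exponential strand-bias (FS) annotation.
#' @param nWindows,windowSize CNV simulation: window count and size (bp).
#' @param orderProbs Named probabilities over the 26 serial orders
#'   (remainder = UUU, no CNV).
#' @param log2Gain Absolute true log2 ratio of a G or L window.
#' @param countNoiseSd Log-normal sd of multiplicative read-count noise.
#' @return A validated parameter list of class "fr_simParams".
#' @export
simParams <- function(nLoci = 20000,
                      stages = c("B", "N", "P", "T"),
                      hetFraction = 0.30, mmFraction = 0.05,
                      rGOHM = c(N = 0.010, P = 0.010, T = 0.010),
                      rGOHm = c(N = 0.020, P = 0.020, T = 0.020),
                      rLOH = c(N = 0.047, P = 0.047, T = 0.047),
                      pRev = c(N = 0, P = 0.9, T = 0.05),
                      lineageFidelity = 0.99,
                      mmPreference = 0.85,
                      contextBias = 8,
                      cpgFraction = 0.10,
                      depthMean = 50, depthDispersion = 10,
                      errorRate = 0.005,
                      qdHetMean = 25, qdHomMean = 32, qdSd = 6,
                      fsMean = 3,
                      nWindows = 10000, windowSize = 5e5,
                      orderProbs = .defaultOrderProbs(),
                      log2Gain = 0.8, countNoiseSd = 0.08) {
    p <- list(nLoci = nLoci, stages = stages, hetFraction = hetFraction,
        mmFraction = mmFraction, rGOHM = rGOHM, rGOHm = rGOHm,
        rLOH = rLOH, pRev = pRev, lineageFidelity = lineageFidelity,
        mmPreference = mmPreference, contextBias = contextBias,
        cpgFraction = cpgFraction, depthMean = depthMean,
        depthDispersion = depthDispersion, errorRate = errorRate,
        qdHetMean = qdHetMean, qdHomMean = qdHomMean, qdSd = qdSd,
        fsMean = fsMean, nWindows = nWindows, windowSize = windowSize,
        orderProbs = orderProbs, log2Gain = log2Gain,
        countNoiseSd = countNoiseSd)
    .validateSimParams(p)
    class(p) <- "fr_simParams"
    p
}

.validateSimParams <- function(p) {
    later <- p$stages[-1L]
    probs <- c(p$hetFraction, p$mmFraction, p$pRev, p$lineageFidelity,
               p$mmPreference, p$cpgFraction, p$errorRate,
               p$rGOHM, p$rGOHm, p$rLOH)
    if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
        stop("probabilities must lie in [0, 1]")
    if (p$hetFraction + p$mmFraction > 1)
        stop("hetFraction + mmFraction must be <= 1")
    if (length(p$stages) < 2L || anyDuplicated(p$stages))
        stop("stages must be >= 2 unique labels")
    for (nm in c("rGOHM", "rGOHm", "rLOH", "pRev"))
        if (!all(later %in% names(p[[nm]])))
            stop(nm, " must be named by the non-baseline stages")
    valid <- enumerateSerialOrders()$code
    if (!all(names(p$orderProbs) %in% valid))
        stop("orderProbs names must be valid serial orders")
    if (any(p$orderProbs < 0) || sum(p$orderProbs) > 1 + 1e-9)
        stop("orderProbs must be non-negative and sum to <= 1")
    invisible(TRUE)
}

## Synthetic reference: iid sequence with CpG dimers forced at a subset
## of locus positions (controllable CG-dimer density at the loci).
.makeReference <- function(n, cpgFraction, spacing = 10L) {
    len <- n * spacing + spacing
    seqChars <- sample(.BASES, len, replace = TRUE)
    pos <- seq(spacing, by = spacing, length.out = n)
    nCpg <- round(cpgFraction * n)
    if (nCpg > 0) {
        cpg <- sample.int(n, nCpg)
        seqChars[pos[cpg]] <- "C"
        seqChars[pos[cpg] + 1L] <- "G"
        ## avoid accidental 5'-C at forced sites changing the G-strand case
    }
    seq <- Biostrings::DNAStringSet(paste(seqChars, collapse = ""))
    names(seq) <- "chrS"
    list(reference = seq, chrom = rep("chrS", n), pos = pos,
         ref = seqChars[pos], flank5 = seqChars[pos - 1L],
         flank3 = seqChars[pos + 1L])
}

#' Simulate a multi-stage case with forward-reverse mutation cycles
#'
#' Draws germline genotypes from the MM/Mm/mm mixture (major alleles match
#' the synthetic reference), then for each later stage first reverts each
#' extant non-germline mutation with the stage's reversal probability (a
#' reverting loss restores the pre-mutation homozygote with probability
#' \code{lineageFidelity}, otherwise the opposite homozygote; a reverting
#' gain is restored to the origin heterozygote), and then applies fresh
#' forward mutations at the stage's rates, with the gain rate multiplied
#' by \code{contextBias} at CpG-dimer loci where the gained allele is the
#' deamination product. Per-stage read evidence (negative-binomial depth,
#' binomial allele counts, QD and FS annotations) is attached so the
#' calling filters are exercised; \code{noise = FALSE} gives the
#' depth-to-infinity limit (exact allele fractions, permissive
#' annotations).
#'
#' @param params A parameter list from \code{\link{simParams}}.
#' @param seed Integer seed; the simulation is fully reproducible from
#'   (params, seed).
#' @param caseId Case identifier.
#' @param noise Emit noisy read evidence (TRUE) or the noiseless limit.
#' @return List with \code{case} (a \linkS4class{CaseSampleSet}) and
#'   \code{truth} (a \linkS4class{SimTruth}).
#' @export
simulateCase <- function(params = simParams(), seed = 1L,
                         caseId = "sim", noise = TRUE) {
    .validateSimParams(params)
    set.seed(seed)
    n <- params$nLoci
    stages <- params$stages
    K <- length(stages)
    refInfo <- .makeReference(n, params$cpgFraction)

    ## m allele: deamination product at CpG loci, random elsewhere
    isCpgC <- refInfo$ref == "C" & refInfo$flank3 == "G"
    isCpgG <- refInfo$ref == "G" & refInfo$flank5 == "C"
    altAllele <- vapply(refInfo$ref, function(r)
        sample(setdiff(.BASES, r), 1L), character(1))
    altAllele[isCpgC] <- "T"
    altAllele[isCpgG] <- "A"
    cpg <- isCpgC | isCpgG

    germ <- sample(c("Mm", "mm", "MM"), n, replace = TRUE,
        prob = c(params$hetFraction, params$mmFraction,
                 1 - params$hetFraction - params$mmFraction))
    gmat <- matrix(NA_character_, n, K, dimnames = list(NULL, stages))
    gmat[, 1L] <- germ
    mutOrigin <- rep(NA_character_, n)   # origin genotype of extant mutation
    events <- list()

    for (k in 2L:K) {
        st <- stages[k]
        cur <- gmat[, k - 1L]
        ## 1) reversal of extant mutations; loci reverting this stage do
        ## not also receive a fresh mutation (one net event per stage)
        freeAtEntry <- is.na(mutOrigin)
        extant <- which(!freeAtEntry)
        if (length(extant)) {
            doRev <- extant[stats::runif(length(extant)) < params$pRev[[st]]]
            for (i in doRev) {
                if (cur[i] == "Mm") {      # reverting a gain: a loss step
                    faithful <- stats::runif(1L) < params$lineageFidelity
                    restored <- if (faithful) mutOrigin[i] else
                        setdiff(c("MM", "mm"), mutOrigin[i])
                    events[[length(events) + 1L]] <- data.frame(
                        locus = i, stage = st, kind = "reversal",
                        from = cur[i], to = restored,
                        restoredOrigin = faithful)
                    cur[i] <- restored
                } else {                    # reverting a loss: a gain step
                    events[[length(events) + 1L]] <- data.frame(
                        locus = i, stage = st, kind = "reversal",
                        from = cur[i], to = mutOrigin[i],
                        restoredOrigin = TRUE)
                    cur[i] <- mutOrigin[i]
                }
                mutOrigin[i] <- NA_character_
            }
        }
        ## 2) fresh forward mutations at loci that entered the stage
        ## mutation-free
        free <- freeAtEntry
        u <- stats::runif(n)
        gainRate <- ifelse(cpg, pmin(1, params$rGOHM[[st]] *
                                        params$contextBias),
                           params$rGOHM[[st]])
        fwdGOHM <- free & cur == "MM" & u < gainRate
        fwdGOHm <- free & cur == "mm" & u < params$rGOHm[[st]]
        fwdLOH <- free & cur == "Mm" & u < params$rLOH[[st]]
        for (i in which(fwdGOHM | fwdGOHm)) {
            events[[length(events) + 1L]] <- data.frame(locus = i,
                stage = st, kind = "forward", from = cur[i], to = "Mm",
                restoredOrigin = NA)
            mutOrigin[i] <- cur[i]
            cur[i] <- "Mm"
        }
        if (any(fwdLOH)) {
            toMM <- stats::runif(sum(fwdLOH)) < params$mmPreference
            dest <- ifelse(toMM, "MM", "mm")
            idx <- which(fwdLOH)
            for (j in seq_along(idx)) {
                i <- idx[j]
                events[[length(events) + 1L]] <- data.frame(locus = i,
                    stage = st, kind = "forward", from = "Mm",
                    to = dest[j], restoredOrigin = NA)
                mutOrigin[i] <- "Mm"
                cur[i] <- dest[j]
            }
        }
        gmat[, k] <- cur
    }

    eventLog <- if (length(events)) do.call(rbind, events) else
        data.frame(locus = integer(0), stage = character(0),
            kind = character(0), from = character(0), to = character(0),
            restoredOrigin = logical(0))

    calls <- lapply(seq_len(K), function(k)
        .readEvidence(gmat[, k], refInfo, altAllele, params, noise))
    names(calls) <- stages
    case <- methods::new("CaseSampleSet", caseId = caseId, stages = stages,
        calls = calls, reference = refInfo$reference)
    truth <- methods::new("SimTruth", genotypes = gmat, events = eventLog,
        windowOrders = character(0),
        params = c(params, list(seed = seed)))
    list(case = case, truth = truth)
}

## Noisy (or limit-case) read evidence for one stage.
.readEvidence <- function(gt, refInfo, altAllele, params, noise) {
    n <- length(gt)
    if (noise) {
        depth <- stats::rnbinom(n, mu = params$depthMean,
            size = params$depthDispersion)
        pAlt <- ifelse(gt == "Mm", 0.5,
                ifelse(gt == "mm", 1 - params$errorRate, params$errorRate))
        altReads <- stats::rbinom(n, depth, pAlt)
        altFrac <- ifelse(depth > 0, altReads / depth, 0)
        qd <- stats::rnorm(n, ifelse(gt == "Mm", params$qdHetMean,
            params$qdHomMean), params$qdSd)
        qd <- pmax(qd, 0)
        fs <- stats::rexp(n, rate = 1 / params$fsMean)
    } else {
        depth <- rep(1000L, n)
        altFrac <- ifelse(gt == "Mm", 0.5, ifelse(gt == "mm", 1, 0))
        qd <- rep(30, n)
        fs <- rep(0, n)
    }
    refFrac <- 1 - altFrac
    majorIsRef <- refFrac >= altFrac
    majorAF <- pmax(refFrac, altFrac)
    minorAF <- pmin(refFrac, altFrac)
    genotype <- classifyGenotype(majorAF, minorAF, qd, fs, depth,
        majorIsRef, bothNonRef = FALSE)
    data.frame(chrom = refInfo$chrom, pos = refInfo$pos, ref = refInfo$ref,
        alleleM = ifelse(majorIsRef, refInfo$ref, altAllele),
        allelem = ifelse(majorIsRef, altAllele, refInfo$ref),
        majorAF = majorAF, minorAF = minorAF, depth = depth,
        qd = round(qd, 2), fs = round(fs, 2), altFrac = altFrac,
        altAllele = altAllele, genotype = genotype,
        stringsAsFactors = FALSE)
}

#' Simulate window copy-number serial orders
#'
#' Assigns each window a serial order drawn from \code{orderProbs}
#' (remaining mass = UUU) and emits either a status series directly or a
#' window read-count table whose normalized log2 ratios are consistent
#' with the threshold caller (true |log2 ratio| of \code{log2Gain} for
#' G/L, 0 for U, with multiplicative log-normal noise).
#'
#' @inheritParams simulateCase
#' @param asCounts Emit read counts (TRUE) or a
#'   \linkS4class{WindowSeries} of true statuses.
#' @return List with \code{data} (count data.frame or
#'   \linkS4class{WindowSeries}) and \code{truth} (a
#'   \linkS4class{SimTruth} with \code{windowOrders}).
#' @export
simulateCnvCase <- function(params = simParams(), seed = 1L,
                            asCounts = TRUE) {
    .validateSimParams(params)
    set.seed(seed)
    n <- params$nWindows
    probs <- params$orderProbs
    codes <- sample(c(names(probs), "UUU"), n, replace = TRUE,
        prob = c(probs, max(0, 1 - sum(probs))))
    win <- data.frame(chrom = "chrW",
        start = (seq_len(n) - 1) * params$windowSize,
        end = seq_len(n) * params$windowSize, stringsAsFactors = FALSE)
    letters3 <- do.call(rbind, strsplit(codes, ""))
    colnames(letters3) <- c("NB", "PB", "TB")
    truth <- methods::new("SimTruth",
        genotypes = matrix(character(0), 0, 0),
        events = data.frame(), windowOrders = codes,
        params = c(params, list(seed = seed)))
    if (!asCounts) {
        series <- windowSeries(win, letters3, params$windowSize)
        return(list(data = series, truth = truth))
    }
    base <- stats::rnbinom(n, mu = 500, size = 20) + 1L
    noiseFor <- function() exp(stats::rnorm(n, 0, params$countNoiseSd))
    mkCount <- function(statusCol) {
        delta <- ifelse(statusCol == "G", params$log2Gain,
                 ifelse(statusCol == "L", -params$log2Gain, 0))
        pmax(0L, as.integer(round(base * 2^delta * noiseFor())))
    }
    counts <- data.frame(win, B = as.integer(round(base * noiseFor())),
        N = mkCount(letters3[, "NB"]), P = mkCount(letters3[, "PB"]),
        T = mkCount(letters3[, "TB"]), stringsAsFactors = FALSE)
    list(data = counts, truth = truth)
}

#' Write simulated inputs as standard files
#'
#' Emits one VCF 4.x per stage (with DP, AF, QD and FS INFO fields), the
#' synthetic reference FASTA, the window count TSV when CNV truth is
#' present, and a ground-truth JSON; returns the file manifest. Reading
#' the VCFs back with \code{\link{readCase}} reproduces the intended
#' genotype classes for loci passing the filters.
#'
#' @param case A \linkS4class{CaseSampleSet} from
#'   \code{\link{simulateCase}}.
#' @param truth The matching \linkS4class{SimTruth}.
#' @param dir Output directory (created if needed).
#' @param cnvData Optional window count data.frame from
#'   \code{\link{simulateCnvCase}}.
#' @return Named character vector of written paths (the manifest),
#'   invisibly.
#' @export
emitStandardFiles <- function(case, truth, dir, cnvData = NULL) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", dir)
    manifest <- character(0)
    fastaPath <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(case@reference, fastaPath)
    manifest["reference"] <- fastaPath
    for (s in case@stages) {
        path <- file.path(dir, paste0("stage_", s, ".vcf"))
        .writeStageVcf(case@calls[[s]], path,
            contigs = names(case@reference))
        manifest[paste0("vcf_", s)] <- path
    }
    truthPath <- file.path(dir, "truth.json")
    tr <- list(stages = case@stages,
        genotypes = apply(truth@genotypes, 1L, paste, collapse = "|"),
        events = truth@events, windowOrders = truth@windowOrders)
    jsonlite::write_json(tr, truthPath, auto_unbox = TRUE, digits = NA)
    manifest["truth"] <- truthPath
    if (!is.null(cnvData)) {
        cnvPath <- file.path(dir, "window_counts.tsv")
        utils::write.table(cnvData, cnvPath, sep = "\t", quote = FALSE,
            row.names = FALSE)
        manifest["window_counts"] <- cnvPath
    }
    manifestPath <- file.path(dir, "manifest.json")
    jsonlite::write_json(as.list(manifest), manifestPath,
        auto_unbox = TRUE)
    manifest["manifest"] <- manifestPath
    invisible(manifest)
}

## Write one stage's calls as a minimal VCF 4.2 via VariantAnnotation.
.writeStageVcf <- function(calls, path, contigs = NULL) {
    n <- nrow(calls)
    gr <- GenomicRanges::GRanges(calls$chrom,
        IRanges::IRanges(start = calls$pos, width = 1L))
    if (!is.null(contigs) && length(contigs))
        GenomeInfoDb::seqlevels(gr) <-
            unique(c(GenomeInfoDb::seqlevels(gr), contigs))
    alt <- if ("altAllele" %in% names(calls)) calls$altAllele else
        ifelse(is.na(calls$allelem), calls$ref, calls$allelem)
    af <- if ("altFrac" %in% names(calls)) calls$altFrac else
        ifelse(calls$alleleM == calls$ref, calls$minorAF, calls$majorAF)
    fixed <- S4Vectors::DataFrame(
        REF = Biostrings::DNAStringSet(calls$ref),
        ALT = IRanges::relist(Biostrings::DNAStringSet(alt),
            IRanges::PartitioningByEnd(seq_len(n))),
        QUAL = rep(NA_real_, n), FILTER = rep("PASS", n))
    info <- S4Vectors::DataFrame(DP = as.integer(calls$depth),
        AF = round(af, 6), QD = calls$qd, FS = calls$fs)
    hdr <- VariantAnnotation::VCFHeader(samples = character(0))
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
        fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
            row.names = "fileformat"))
    VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
        Number = rep("1", 4),
        Type = c("Integer", "Float", "Float", "Float"),
        Description = c("Read depth", "Non-reference allele fraction",
            "Quality by depth", "Phred-scaled Fisher strand bias"),
        row.names = c("DP", "AF", "QD", "FS"))
    vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed,
        info = info, collapsed = TRUE)
    S4Vectors::metadata(vcf)$header <- hdr
    VariantAnnotation::writeVcf(vcf, path)
    invisible(path)
}
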