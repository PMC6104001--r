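## Test helpers: construct StagedLoci and cases directly in code.

## A StagedLoci from a matrix/data.frame of genotype paths (one row per
## locus, one column per stage). Reference/alt/flanks filled with fixed
## bases unless supplied.
makeLoci <- function(paths, stages = colnames(paths), ref = "C", alt = "T",
                     flank5 = "A", flank3 = "G", caseId = "toy") {
    paths <- as.data.frame(paths, stringsAsFactors = FALSE)
    if (is.null(stages)) stages <- paste0("S", seq_along(paths))
    names(paths) <- stages
    n <- nrow(paths)
    loci <- data.frame(chrom = rep("chr1", n), pos = seq_len(n) * 10L,
        ref = rep_len(ref, n), alt = rep_len(alt, n),
        flank5 = rep_len(flank5, n), flank3 = rep_len(flank3, n),
        stringsAsFactors = FALSE)
    loci <- cbind(loci, paths)
    methods::new("StagedLoci", caseId = caseId, stages = stages, loci = loci)
}

## Random genotype paths over MM/Mm/mm.
randomPaths <- function(n, nStages = 4L, seed = 1L,
                        levels = c("MM", "Mm", "mm")) {
    set.seed(seed)
    m <- matrix(sample(levels, n * nStages, replace = TRUE), n, nStages)
    colnames(m) <- c("B", "N", "P", "T", "M", "S6", "S7", "S8")[seq_len(nStages)]
    m
}

## Independent brute-force tally of patch-diagram node and edge counts:
## prefix counting over path strings, done with plain string operations.
bruteForceTree <- function(paths, origin, nStages) {
    paths <- paths[substr(paths, 1L, nchar(origin)) == origin &
                   (nchar(paths) == nchar(origin) |
                    substr(paths, nchar(origin) + 1L,
                           nchar(origin) + 1L) == "|")]
    nodeCount <- function(prefix) {
        k <- nchar(prefix)
        sum(substr(paths, 1L, k) == prefix &
            (nchar(paths) == k | substr(paths, k + 1L, k + 1L) == "|"))
    }
    list(count = nodeCount)
}
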