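test_that("genotype-class filter windows behave as specified", {
    ## depth gate: depth must exceed 8
    expect_equal(classifyGenotype(0.96, 0.04, qd = 30, fs = 5, depth = 8),
                 "EXCLUDED")
    expect_equal(classifyGenotype(0.96, 0.04, qd = 30, fs = 5, depth = 9),
                 "MM")
    ## heterozygote window with QD gate
    expect_equal(classifyGenotype(0.50, 0.50, qd = 6, fs = 10, depth = 30),
                 "Mm")
    expect_equal(classifyGenotype(0.50, 0.50, qd = 3.9, fs = 10, depth = 30),
                 "EXCLUDED")
    ## the undefined band (0.70, 0.95)
    expect_equal(classifyGenotype(0.85, 0.15, qd = 30, fs = 5, depth = 30),
                 "EXCLUDED")
    ## mm: near-fixed non-reference allele, QD >= 20
    expect_equal(classifyGenotype(0.97, 0.03, qd = 25, fs = 5, depth = 30,
                                  majorIsRef = FALSE), "mm")
    expect_equal(classifyGenotype(0.97, 0.03, qd = 15, fs = 5, depth = 30,
                                  majorIsRef = FALSE), "EXCLUDED")
    ## strand-bias gate applies to every class
    expect_equal(classifyGenotype(0.97, 0.03, qd = 30, fs = 25, depth = 30),
                 "EXCLUDED")
    expect_equal(classifyGenotype(0.50, 0.50, qd = 30, fs = 21, depth = 30),
                 "EXCLUDED")
    ## mn: heterozygote of two non-reference alleles
    expect_equal(classifyGenotype(0.52, 0.45, qd = 10, fs = 5, depth = 30,
                                  majorIsRef = FALSE, bothNonRef = TRUE),
                 "mn")
})

test_that("missing QD or FS annotations fail the criteria that bound them", {
    expect_equal(classifyGenotype(0.50, 0.50, qd = NA, fs = 5, depth = 30),
                 "EXCLUDED")
    expect_equal(classifyGenotype(0.97, 0.03, qd = NA, fs = 5, depth = 30,
                                  majorIsRef = FALSE), "EXCLUDED")
    ## FS bounds all classes, including MM
    expect_equal(classifyGenotype(0.97, 0.03, qd = 30, fs = NA, depth = 30),
                 "EXCLUDED")
    ## MM has no QD criterion, so a missing QD does not exclude it
    expect_equal(classifyGenotype(0.97, 0.03, qd = NA, fs = 5, depth = 30),
                 "MM")
})

test_that("classification validates its inputs", {
    expect_error(classifyGenotype(1.2, 0, qd = 5, fs = 5, depth = 30),
                 "fractions")
    expect_error(classifyGenotype(0.9, 0.2, qd = 5, fs = 5, depth = 30),
                 "sum")
    expect_error(classifyGenotype(0.5, 0.5, qd = 5, fs = 5, depth = -1),
                 "depth")
})

test_that("acceptance windows are mutually exclusive on random inputs", {
    set.seed(7)
    major <- runif(500, 0.5, 1)
    minor <- pmin(runif(500, 0, 0.5), 1 - major)
    for (i in seq_len(500)) {
        inMM <- major[i] >= 0.95
        inHet <- major[i] >= 0.30 & major[i] <= 0.70
        expect_false(inMM && inHet)   # windows cannot overlap
    }
    ## classification is a pure function
    g1 <- classifyGenotype(major, minor, qd = 10, fs = 5, depth = 30)
    g2 <- classifyGenotype(major, minor, qd = 10, fs = 5, depth = 30)
    expect_identical(g1, g2)
})

## A handcrafted VCF for parsing edge cases.
writeTestVcf <- function(path, records) {
    hdr <- c("##fileformat=VCFv4.2",
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
        "##INFO=<ID=AF,Number=A,Type=Float,Description=\"a\">",
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
        "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
        "##contig=<ID=chrT>",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    writeLines(c(hdr, records), path)
    path
}

test_that("readCase parses VCFs, handles multi-allelics, indels and stages", {
    d <- withr::local_tempdir()
    v1 <- writeTestVcf(file.path(d, "a.vcf"), c(
        "chrT\t5\t.\tC\tT\t.\tPASS\tDP=40;AF=0.5;QD=10;FS=2",
        "chrT\t9\t.\tA\tG,T\t.\tPASS\tDP=60;AF=0.45,0.45;QD=10;FS=2",
        "chrT\t13\t.\tG\tA,C\t.\tPASS\tDP=60;AF=0.50,0.02;QD=10;FS=2",
        "chrT\t17\t.\tC\tCT\t.\tPASS\tDP=60;AF=0.5;QD=10;FS=2",
        "chrT\t21\t.\tT\tC\t.\tPASS\tDP=60;AF=0.02;QD=10;FS=2"))
    v2 <- writeTestVcf(file.path(d, "b.vcf"), c(
        "chrT\t5\t.\tC\tT\t.\tPASS\tDP=40;AF=0.98;QD=25;FS=2",
        "chrT\t21\t.\tT\tC\t.\tPASS\tDP=60;AF=0.01;QD=10;FS=2"))
    ref <- Biostrings::DNAStringSet(paste(rep("ACGT", 10), collapse = ""))
    names(ref) <- "chrT"
    case <- suppressWarnings(
        readCase(c(X = v1, Y = v2), referenceFasta = ref, caseId = "t"))
    cx <- case@calls$X
    ## het site
    expect_equal(cx$genotype[cx$pos == 5], "Mm")
    ## two non-reference alleles at ~0.45 each: ref residue at 0.10 is a
    ## third allele above 5% -> excluded as multi-allelic
    expect_equal(cx$genotype[cx$pos == 9], "EXCLUDED")
    expect_equal(attr(cx, "multiallelicExcluded"), 1L)
    ## a trace second alt (2%) does not void the heterozygote
    expect_equal(cx$genotype[cx$pos == 13], "Mm")
    ## indel skipped
    expect_equal(cx$genotype[cx$pos == 17], "EXCLUDED")
    expect_equal(attr(cx, "skipped"), 1L)
    ## reference-homozygous site
    expect_equal(cx$genotype[cx$pos == 21], "MM")
    ## stage-Y site 5 is near-fixed non-reference: mm
    expect_equal(case@calls$Y$genotype[case@calls$Y$pos == 5], "mm")

    expect_error(readCase(c(X = v1, X = v2)), "duplicate")
    expect_error(readCase(c(A = v1, B = file.path(d, "nope.vcf"))),
                 "missing")
})

test_that("intersectCase keeps only loci callable in every stage", {
    d <- withr::local_tempdir()
    ## pos 5 callable in both; pos 21 callable only in X (missing in Y);
    ## pos 25 EXCLUDED in Y by depth
    v1 <- writeTestVcf(file.path(d, "a.vcf"), c(
        "chrT\t5\t.\tC\tT\t.\tPASS\tDP=40;AF=0.5;QD=10;FS=2",
        "chrT\t21\t.\tT\tC\t.\tPASS\tDP=60;AF=0.02;QD=10;FS=2",
        "chrT\t25\t.\tA\tG\t.\tPASS\tDP=60;AF=0.5;QD=10;FS=2"))
    v2 <- writeTestVcf(file.path(d, "b.vcf"), c(
        "chrT\t5\t.\tC\tT\t.\tPASS\tDP=40;AF=0.5;QD=25;FS=2",
        "chrT\t25\t.\tA\tG\t.\tPASS\tDP=5;AF=0.5;QD=10;FS=2"))
    ref <- Biostrings::DNAStringSet(paste(rep("ACGT", 10), collapse = ""))
    names(ref) <- "chrT"
    case <- readCase(c(X = v1, Y = v2), referenceFasta = ref)
    loci <- intersectCase(case)
    expect_equal(nLoci(loci), 1L)
    tab <- lociTable(loci)
    expect_equal(tab$pos, 5L)
    expect_equal(tab$X, "Mm")
    ## flanks come from the reference: position 5 of ACGTACGT... is A,
    ## flanked by T and C
    expect_equal(tab$flank5, "T")
    expect_equal(tab$flank3, "C")
    ## output size is bounded by the smallest per-stage callable count
    callable <- vapply(case@calls, function(df)
        sum(df$genotype != "EXCLUDED"), numeric(1))
    expect_lte(nLoci(loci), min(callable))
})

test_that("stricter filtering never adds loci (monotonicity)", {
    sim <- simulateCase(simParams(nLoci = 500), seed = 11)
    loci0 <- intersectCase(sim$case)
    stricter <- sim$case
    for (s in stages(stricter)) {
        df <- stricter@calls[[s]]
        drop <- df$depth <= 15       # pretend a higher depth threshold
        df$genotype[drop] <- "EXCLUDED"
        stricter@calls[[s]] <- df
    }
    loci1 <- intersectCase(stricter)
    key0 <- paste(lociTable(loci0)$chrom, lociTable(loci0)$pos)
    key1 <- paste(lociTable(loci1)$chrom, lociTable(loci1)$pos)
    expect_true(all(key1 %in% key0))
})

test_that("StagedLoci TSV round-trips", {
    loci <- makeLoci(randomPaths(20, 4, seed = 3))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeStagedLoci(loci, path)
    back <- readStagedLoci(path)
    expect_equal(lociTable(back), lociTable(loci))
    expect_equal(stages(back), stages(loci))
})
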