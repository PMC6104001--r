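## Exhaustive expected transition table, written out independently of the
## implementation (mn acts as a heterozygote).
.expectedTransitions <- local({
    tab <- matrix("OTHER", 4, 4,
        dimnames = list(c("MM", "Mm", "mm", "mn"),
                        c("MM", "Mm", "mm", "mn")))
    tab["MM", "MM"] <- "NONE"; tab["Mm", "Mm"] <- "NONE"
    tab["mm", "mm"] <- "NONE"; tab["mn", "mn"] <- "NONE"
    tab["Mm", "mn"] <- "NONE"; tab["mn", "Mm"] <- "NONE"
    tab["MM", "Mm"] <- "GOH_M"; tab["MM", "mn"] <- "GOH_M"
    tab["mm", "Mm"] <- "GOH_m"; tab["mm", "mn"] <- "GOH_m"
    tab["Mm", "MM"] <- "LOH_M"; tab["mn", "MM"] <- "LOH_M"
    tab["Mm", "mm"] <- "LOH_m"; tab["mn", "mm"] <- "LOH_m"
    tab
})

test_that("transition labels match the exhaustive genotype-pair table", {
    gts <- c("MM", "Mm", "mm", "mn")
    for (a in gts) for (b in gts)
        expect_equal(labelTransition(a, b), .expectedTransitions[a, b],
            info = paste(a, "->", b))
    expect_error(labelTransition("EXCLUDED", "MM"), "EXCLUDED")
    expect_error(labelTransition("MM", "EXCLUDED"), "EXCLUDED")
    expect_error(labelTransition("MM", "XX"), "unknown")
    ## symmetry: a gain read backwards is the corresponding loss
    expect_equal(labelTransition("MM", "Mm"), "GOH_M")
    expect_equal(labelTransition("Mm", "MM"), "LOH_M")
})

test_that("deltaSummary counts a hand-enumerated toy table", {
    paths <- rbind(c("MM", "Mm"), c("MM", "Mm"), c("Mm", "mm"),
                   c("MM", "MM"), c("mm", "mm"))
    colnames(paths) <- c("B", "N")
    loci <- makeLoci(paths)
    ds <- deltaCounts(deltaSummary(loci, "B", "N"))
    expect_equal(unname(ds[c("GOH_M", "LOH_m", "NONE")]), c(2, 1, 2))
    expect_equal(sum(ds), 5)
    ## denominators: loci at risk per origin genotype
    d <- deltaSummary(loci, "B", "N")@denominators
    expect_equal(unname(d), c(3, 1, 1))
    ## same stage against itself: everything NONE
    expect_equal(unname(deltaCounts(deltaSummary(loci, "B", "B"))["NONE"]),
                 5)
    ## empty input: all zeros
    empty <- makeLoci(matrix(character(0), 0, 2,
        dimnames = list(NULL, c("B", "N"))))
    expect_equal(sum(deltaCounts(deltaSummary(empty, "B", "N"))), 0)
    expect_error(deltaSummary(loci, "B", "Z"), "unknown stage")
})

test_that("delta summaries mirror between directions", {
    loci <- makeLoci(randomPaths(200, 2, seed = 5))
    fwd <- deltaCounts(deltaSummary(loci, "B", "N"))
    bwd <- deltaCounts(deltaSummary(loci, "N", "B"))
    expect_equal(fwd[["GOH_M"]], bwd[["LOH_M"]])
    expect_equal(fwd[["GOH_m"]], bwd[["LOH_m"]])
    expect_equal(fwd[["LOH_M"]], bwd[["GOH_M"]])
    expect_equal(fwd[["NONE"]], bwd[["NONE"]])
})

test_that("a single unchanged locus gives a trivial patch diagram", {
    loci <- makeLoci(matrix(rep("MM", 4), 1,
        dimnames = list(NULL, c("B", "N", "P", "T"))))
    pd <- buildPatchDiagram(loci)
    e <- diagramEdges(pd$MM)
    expect_equal(sum(e$count[e$label != "NONE"]), 0)
    leafId <- paste(rep("MM", 4), collapse = "|")
    expect_equal(diagramNodes(pd$MM)$count[
        diagramNodes(pd$MM)$id == leafId], 1)
    ## the other origins are empty
    expect_equal(diagramNodes(pd$Mm)$count[1], 0)
    expect_equal(diagramNodes(pd$mm)$count[1], 0)
})

test_that("reverting-edge counts reproduce a constructed one-sided reversal", {
    ## 273 gains at the second stage; 263 revert to MM, none to mm
    paths <- rbind(
        matrix(rep(c("MM", "Mm", "MM"), 263), ncol = 3, byrow = TRUE),
        matrix(rep(c("MM", "Mm", "Mm"), 10), ncol = 3, byrow = TRUE),
        matrix(rep(c("MM", "MM", "MM"), 50), ncol = 3, byrow = TRUE))
    colnames(paths) <- c("D5", "D10", "D14")
    pd <- buildPatchDiagram(makeLoci(paths))
    n <- diagramNodes(pd$MM)
    expect_equal(n$count[n$id == "MM|Mm"], 273)
    lr <- lineageRatio(pd$MM, "MM|Mm")
    expect_equal(lr$countMM, 263)
    expect_equal(lr$countmm, 0)
    expect_equal(lr$ratio, Inf)
})

test_that("patch diagrams match a brute-force per-path tally", {
    paths <- randomPaths(50, 4, seed = 17)
    loci <- makeLoci(paths)
    pd <- buildPatchDiagram(loci)
    pathStr <- apply(paths, 1, paste, collapse = "|")
    for (origin in c("MM", "Mm", "mm")) {
        oracle <- bruteForceTree(pathStr, origin, 4)
        nodes <- diagramNodes(pd[[origin]])
        for (i in seq_len(nrow(nodes)))
            expect_equal(nodes$count[i], oracle$count(nodes$id[i]),
                info = nodes$id[i])
        edges <- diagramEdges(pd[[origin]])
        for (i in seq_len(nrow(edges)))
            expect_equal(edges$count[i], oracle$count(edges$child[i]))
    }
})

test_that("patch diagrams conserve locus counts and normalize rates", {
    loci <- makeLoci(randomPaths(120, 4, seed = 23))
    pd <- buildPatchDiagram(loci)
    for (origin in names(pd)) {
        n <- diagramNodes(pd[[origin]])
        e <- diagramEdges(pd[[origin]])
        ## child sums equal the parent count at every node
        for (id in n$id[n$level < 4]) {
            expect_equal(sum(e$count[e$parent == id]),
                         n$count[n$id == id])
        }
        ## leaves sum to the origin total
        expect_equal(sum(n$count[n$level == 4]), n$count[n$level == 1])
        ## rates are edge / parent and lie in [0,1]
        ok <- !is.na(e$rate)
        expect_true(all(e$rate[ok] >= 0 & e$rate[ok] <= 1))
        parentCount <- n$count[match(e$parent, n$id)]
        expect_equal(e$count[ok] / parentCount[ok], e$rate[ok])
    }
    ## step identifiers are unique and deterministic
    allSteps <- unlist(lapply(pd, function(d) {
        s <- diagramEdges(d)$step
        s[!is.na(s)]
    }))
    expect_false(any(duplicated(allSteps)))
    pd2 <- buildPatchDiagram(makeLoci(randomPaths(120, 4, seed = 23)))
    expect_identical(lapply(pd, diagramEdges), lapply(pd2, diagramEdges))
})

test_that("lineage ratios report sentinel quotients", {
    mk <- function(nMM, nmm, nStay = 5) {
        paths <- rbind(
            matrix(rep(c("Mm", "MM"), nMM), ncol = 2, byrow = TRUE),
            matrix(rep(c("Mm", "mm"), nmm), ncol = 2, byrow = TRUE),
            matrix(rep(c("Mm", "Mm"), nStay), ncol = 2, byrow = TRUE))
        colnames(paths) <- c("B", "N")
        buildPatchDiagram(makeLoci(paths))$Mm
    }
    expect_equal(lineageRatio(mk(1518, 1), "Mm")$ratio, 1518)
    expect_equal(lineageRatio(mk(0, 357), "Mm")$ratio, 0)
    expect_equal(lineageRatio(mk(5, 5), "Mm")$ratio, 1)
    expect_error(lineageRatio(mk(5, 5), "Mm|MM"), "not heterozygous")
    expect_error(lineageRatio(mk(5, 5), "nope"), "no such node")
})

test_that("germline-het LOH partitions track the surviving-Mm path", {
    ## first partition constructed as 57 MM vs 10 mm -> ratio 5.7
    paths <- rbind(
        matrix(rep(c("Mm", "MM", "MM"), 57), ncol = 3, byrow = TRUE),
        matrix(rep(c("Mm", "mm", "mm"), 10), ncol = 3, byrow = TRUE),
        matrix(rep(c("Mm", "Mm", "MM"), 29), ncol = 3, byrow = TRUE),
        matrix(rep(c("Mm", "Mm", "mm"), 10), ncol = 3, byrow = TRUE),
        matrix(rep(c("Mm", "Mm", "Mm"), 61), ncol = 3, byrow = TRUE))
    colnames(paths) <- c("B", "N", "P")
    pr <- lohPartitionRatios(buildPatchDiagram(makeLoci(paths))$Mm)
    expect_equal(pr$ratio[pr$stage == "N"], 5.7)
    expect_equal(pr$countMM[pr$stage == "P"], 29)
    expect_equal(pr$ratio[pr$stage == "P"], 2.9)
    ## a level with no LOH products is flagged undefined
    paths2 <- matrix(rep(c("Mm", "Mm"), 10), ncol = 2, byrow = TRUE,
        dimnames = list(NULL, c("B", "N")))
    pr2 <- lohPartitionRatios(buildPatchDiagram(makeLoci(paths2))$Mm)
    expect_false(pr2$defined[1])
})

test_that("an unbiased partition is statistically symmetric", {
    set.seed(41)
    n <- 10000
    toMM <- rbinom(1, n, 0.5)
    paths <- rbind(
        matrix(rep(c("Mm", "MM"), toMM), ncol = 2, byrow = TRUE),
        matrix(rep(c("Mm", "mm"), n - toMM), ncol = 2, byrow = TRUE))
    colnames(paths) <- c("B", "N")
    lr <- lineageRatio(buildPatchDiagram(makeLoci(paths))$Mm, "Mm")
    se <- sqrt(0.25 / n)
    expect_lt(abs(lr$countMM / n - 0.5), 3 * se)
})

## Independent serial-type oracle: a literal transcription of the pattern
## definitions, evaluated per quadruple.
.serialOracle <- function(b, n, p, t) {
    if (b == n) return("I")
    if (n != p && p == t && b == t) return("IVa")
    if (n == p && p != t && b == t) return("IVb")
    if (n == t) return("II")
    if (n != t && b != t) return("III")
    "UNCLASSIFIED"
}

test_that("serial SNV types match exhaustive enumeration of 3^4 quadruples", {
    gts <- c("MM", "Mm", "mm")
    grid <- expand.grid(b = gts, n = gts, p = gts, t = gts,
        stringsAsFactors = FALSE)
    got <- classifySerialSNV(grid$b, grid$n, grid$p, grid$t)
    want <- mapply(.serialOracle, grid$b, grid$n, grid$p, grid$t)
    expect_equal(got, unname(want))
    ## spot checks of the printed patterns
    expect_equal(classifySerialSNV("MM", "MM", "Mm", "Mm"), "I")
    expect_equal(classifySerialSNV("MM", "Mm", "MM", "MM"), "IVa")
    expect_equal(classifySerialSNV("MM", "Mm", "Mm", "MM"), "IVb")
    expect_equal(classifySerialSNV("MM", "Mm", "mm", "MM"), "UNCLASSIFIED")
})

test_that("serial types partition the loci", {
    loci <- makeLoci(randomPaths(300, 4, seed = 31))
    types <- serialSNVTypes(loci)
    expect_equal(length(types), 300)
    tab <- lociTable(loci)
    expect_equal(sum(types == "I"), sum(tab$B == tab$N))
    expect_equal(sum(table(types)), 300)
})

test_that("reversal fractions count completed forward-reverse cycles", {
    paths <- rbind(
        matrix(rep(c("MM", "Mm", "MM"), 96), ncol = 3, byrow = TRUE),
        matrix(rep(c("MM", "Mm", "Mm"), 4), ncol = 3, byrow = TRUE),
        matrix(rep(c("MM", "MM", "MM"), 30), ncol = 3, byrow = TRUE))
    colnames(paths) <- c("B", "N", "P")
    loci <- makeLoci(paths)
    rf <- reversalFraction(loci, c("B", "N"), c("N", "P"))
    expect_equal(rf$fraction, 0.96)
    expect_equal(rf$denominator, 100)
    ## no forward mutations: flagged undefined
    quiet <- makeLoci(matrix(rep("MM", 3 * 5), ncol = 3,
        dimnames = list(NULL, c("B", "N", "P"))))
    expect_false(reversalFraction(quiet, c("B", "N"), c("N", "P"))$defined)
    ## stage pairs must chain and be consecutive
    loci4 <- makeLoci(randomPaths(10, 4, seed = 2))
    expect_error(reversalFraction(loci4, c("B", "N"), c("P", "T")),
                 "must start")
    expect_error(reversalFraction(loci4, c("B", "P"), c("P", "T")),
                 "consecutive")
})

test_that("reversal fractions agree with a brute-force per-locus check", {
    paths <- randomPaths(400, 4, seed = 13)
    loci <- makeLoci(paths)
    rf <- reversalFraction(loci, c("N", "P"), c("P", "T"))
    fwd <- paths[, "N"] != paths[, "P"]
    rev <- fwd & paths[, "T"] == paths[, "N"]
    expect_equal(rf$numerator, sum(rev))
    expect_equal(rf$denominator, sum(fwd))
    expect_equal(rf$fraction, sum(rev) / sum(fwd))
})
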