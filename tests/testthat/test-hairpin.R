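# a clean constructed hairpin: 24-bp GC/AU stem, 6-nt loop; the 21-nt
# "mature" sits on the 5' arm
makeStemLoop <- function(stemLen = 24, loop = "AACAAC") {
    set.seed(99)
    arm <- paste(sample(c("G", "C", "A", "U"), stemLen,
        replace = TRUE, prob = c(.35, .35, .15, .15)), collapse = "")
    rcArm <- as.character(Biostrings::reverseComplement(
        Biostrings::RNAString(arm)))
    paste0(arm, loop, rcArm)
}

test_that("candidate windows ladder, clip and cover the truth", {
    aln <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(1000, 1020), strand = "+")
    w <- extractCandidateWindows(aln, contigLength = 5000)
    expect_gte(length(w), 6)
    expect_true(all(GenomicRanges::width(w) >= 50))
    # symmetric 250-flank window present
    expect_true(any(GenomicRanges::start(w) == 750 &
        GenomicRanges::end(w) == 1270))

    # contig edge: clipped, nothing below position 1
    alnEdge <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(3, 23), strand = "+")
    wEdge <- extractCandidateWindows(alnEdge, contigLength = 5000)
    expect_true(all(GenomicRanges::start(wEdge) >= 1))
    expect_true(all(GenomicRanges::end(wEdge) <= 5000))

    # planted locus: some window fully contains the true precursor
    refs <- refSet()
    gen <- generateGenome(length = 20000, nMir = 2, nNcrna = 0,
        referenceSet = refs, seed = 51)
    tr <- gen$mirTruth[1]
    m5 <- S4Vectors::mcols(tr)$mature_5p
    a0 <- S4Vectors::mcols(tr)$mature5p_start0
    if (as.character(GenomicRanges::strand(tr)) == "+") {
        ms <- GenomicRanges::start(tr) + a0
        alnT <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(ms, ms + nchar(m5) - 1), strand = "+")
    } else {
        me <- GenomicRanges::end(tr) - a0
        alnT <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(me - nchar(m5) + 1, me), strand = "-")
    }
    wT <- extractCandidateWindows(alnT, contigLength = 20000)
    contains <- GenomicRanges::start(wT) <= GenomicRanges::start(tr) &
        GenomicRanges::end(wT) >= GenomicRanges::end(tr)
    expect_true(any(contains))
})

test_that("hairpin criteria measure and fail as specified", {
    prec <- makeStemLoop()
    st <- foldRNA(prec)
    tags <- data.frame(sequence = substr(prec, 2, 22), start0 = 1,
        width = 21, count = 12)
    ev <- evaluateHairpin(st, tags)
    expect_true(ev$verdict)
    expect_equal(nrow(ev$report), 14)   # every criterion reported
    expect_equal(ev$measures$stemBp, 24)
    expect_equal(ev$measures$terminalLoop, 6)
    expect_equal(ev$measures$pm, 1)

    # raising the stem requirement above the measured value fails it
    ev2 <- evaluateHairpin(st, tags,
        hairpinCriteria(minStemBp = 25))
    expect_false(ev2$verdict)
    expect_equal(ev2$report$criterion[!ev2$report$pass], "min_stem_bp")

    # read support below the stringent floor
    tags9 <- transform(tags, count = 9)
    ev3 <- evaluateHairpin(st, tags9)
    expect_false(ev3$verdict)
    expect_true("min_total_reads" %in%
        ev3$report$criterion[!ev3$report$pass])

    # a weak stem fails the energy bounds
    weak <- "AAUAAUAAUAAUAAUAAACAACAUUAUUAUUAUUAUUA"
    stw <- foldRNA(weak)
    evw <- evaluateHairpin(stw,
        data.frame(sequence = substr(weak, 1, 18), start0 = 0,
            width = 18, count = 50))
    expect_false(evw$verdict)
    expect_true(any(c("max_free_energy", "stringent_max_mfe") %in%
        evw$report$criterion[!evw$report$pass]))

    # multi-hairpin structure is rejected outright (a GC and an AU
    # stem-loop that cannot cross-pair into one chain)
    multi <- paste0("GGGGGGGGAAAACCCCCCCC", "AAAA",
        "UUUUUUUUCCCCAAAAAAAA")
    stm <- foldRNA(multi)
    evm <- evaluateHairpin(stm,
        data.frame(sequence = substr(multi, 1, 20), start0 = 0,
            width = 20, count = 50))
    expect_false(evm$verdict)
    expect_equal(evm$report$criterion, "not a single hairpin")
})

test_that("hairpin verdict is monotone under threshold relaxation", {
    prec <- makeStemLoop()
    st <- foldRNA(prec)
    tags <- data.frame(sequence = substr(prec, 2, 22), start0 = 1,
        width = 21, count = 12)
    base <- hairpinCriteria()
    evBase <- evaluateHairpin(st, tags, base)
    relaxed <- hairpinCriteria(minStemBp = 10, minTotalReads = 5,
        maxFreeEnergy = -10, stringentMaxMfe = -20, minMfei = 0.5,
        minMatureBp = 8)
    evRel <- evaluateHairpin(st, tags, relaxed)
    # relaxing never flips pass -> fail
    expect_true(!evBase$verdict || evRel$verdict)
    expect_true(all(evRel$report$pass[evBase$report$pass]))
})

test_that("duplex detection demands exactly 2-nt 3' overhangs", {
    prec <- makeStemLoop(stemLen = 30)
    st <- foldRNA(prec)
    n <- nchar(prec)
    # planted geometry: 5p at [3, 23], partner with +2 shift
    t1 <- 3; t2 <- 23
    q1 <- n - t2 + 1 + 2; q2 <- n - t1 + 1 + 2
    tags <- data.frame(
        sequence = c(substr(prec, t1, t2), substr(prec, q1, q2)),
        start0 = c(t1 - 1, q1 - 1), width = c(21, 21),
        count = c(40, 15))
    ev <- evaluateHairpin(st, tags, hairpinCriteria(minTotalReads = 5))
    dup <- detectDuplex(st, tags, ev$measures$loopSpan)
    expect_false(is.null(dup))
    expect_equal(dup$overhangs, c(2L, 2L))
    expect_equal(dup$five_p, 1L)
    expect_equal(dup$three_p, 2L)

    # shifting the 3p tag one further makes a 3-nt overhang: absent
    tags3 <- tags
    tags3$start0[2] <- tags3$start0[2] + 1
    tags3$sequence[2] <- substr(prec, q1 + 1, q2 + 1)
    expect_null(detectDuplex(st, tags3, ev$measures$loopSpan))

    # tags on one arm only: absent, but the candidate itself stands
    tags5 <- tags[1, , drop = FALSE]
    expect_null(detectDuplex(st, tags5, ev$measures$loopSpan))
    ev5 <- evaluateHairpin(st, tags5, hairpinCriteria(minTotalReads = 5))
    expect_true(ev5$verdict)
})

test_that("accepted candidates always satisfy every criteria bound", {
    disc <- sharedDiscovery()
    cands <- disc$candidates
    expect_gt(length(cands), 0)
    crit <- hairpinCriteria()
    for (cand in cands) {
        expect_true(cand$evaluation$verdict)
        expect_true(all(cand$evaluation$report$pass))
        m <- cand$evaluation$measures
        expect_lte(m$mfe, crit@stringentMaxMfe)
        expect_gte(m$mfei, crit@minMfei)
        expect_gte(m$stemBp, crit@minStemBp)
        expect_gte(m$totalReads, crit@minTotalReads)
        w <- cand$end - cand$start + 1
        expect_gte(w, 57)
        expect_lte(w, 264)
        if (!is.null(cand$duplex))
            expect_equal(cand$duplex$overhangs, c(2L, 2L))
    }
})
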