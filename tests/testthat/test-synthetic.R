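test_that("generated genomes honor the planted-locus contracts", {
    refs <- refSet()
    gen <- generateGenome(length = 30000, gcContent = 0.45, nMir = 6,
        nNcrna = 4, referenceSet = refs, seed = 7)
    tr <- as.data.frame(S4Vectors::mcols(gen$mirTruth))
    expect_equal(nrow(tr), 6)
    expect_equal(length(gen$ncrnaTruth), 4)

    gseq <- as.character(gen$genome[[1]])
    for (i in seq_len(nrow(tr))) {
        N <- nchar(tr$precursor_seq[i])
        expect_gte(N, 57)
        expect_lte(N, 264)
        # matures are exact substrings on their arms
        p5 <- regexpr(tr$mature_5p[i], tr$precursor_seq[i],
            fixed = TRUE)[1]
        p3 <- regexpr(tr$mature_3p[i], tr$precursor_seq[i],
            fixed = TRUE)[1]
        expect_gt(p5, 0)
        expect_gt(p3, 0)
        expect_lte(p5 + nchar(tr$mature_5p[i]) - 1, ceiling(N / 2))
        expect_gte(p3, floor(N / 2))
        # class consistent with planted mismatches
        cls <- tr$class_truth[i]
        if (cls == "conserved") expect_equal(tr$planted_mismatches[i], 0)
        if (cls == "variant")
            expect_true(tr$planted_mismatches[i] %in% 1:2)
        if (cls == "novel") expect_true(is.na(tr$planted_mismatches[i]))
        # the planted precursor is really in the genome
        gr <- gen$mirTruth[i]
        sub <- substr(gseq, GenomicRanges::start(gr),
            GenomicRanges::end(gr))
        placed <- if (as.character(GenomicRanges::strand(gr)) == "+")
            sub else as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(sub)))
        expect_equal(chartr("T", "U", placed), tr$precursor_seq[i])
    }
})

test_that("planted precursors pass the hairpin evaluator", {
    # the generator validates by folding; the full criteria must hold
    # for a pseudo-tag at the planted mature with ample reads
    refs <- refSet()
    gen <- generateGenome(length = 30000, nMir = 5, nNcrna = 0,
        referenceSet = refs, seed = 21)
    tr <- as.data.frame(S4Vectors::mcols(gen$mirTruth))
    for (i in seq_len(nrow(tr))) {
        st <- foldRNA(tr$precursor_seq[i])
        tags <- data.frame(
            sequence = c(tr$mature_5p[i], tr$mature_3p[i]),
            start0 = c(tr$mature5p_start0[i],
                regexpr(tr$mature_3p[i], tr$precursor_seq[i],
                    fixed = TRUE)[1] - 1L),
            width = c(nchar(tr$mature_5p[i]), nchar(tr$mature_3p[i])),
            count = c(20, 10))
        ev <- evaluateHairpin(st, tags)
        expect_true(ev$verdict, info = paste("locus", tr$locus_id[i],
            paste(ev$report$criterion[!ev$report$pass],
                collapse = ",")))
        # planted duplex has the canonical 2-nt 3' overhangs
        dup <- detectDuplex(st, tags, ev$measures$loopSpan)
        expect_false(is.null(dup))
        expect_equal(dup$overhangs, c(2L, 2L))
    }
})

test_that("degenerate and deterministic generator contracts hold", {
    # no MIR loci: empty truth, ncRNA annotation only
    gen0 <- generateGenome(length = 20000, nMir = 0, nNcrna = 3,
        seed = 3)
    expect_equal(length(gen0$mirTruth), 0)
    expect_equal(length(gen0$ncrnaTruth), 3)

    # undersized genome refused
    expect_error(generateGenome(length = 500, nMir = 4,
        referenceSet = refSet(), seed = 1), "10x")
    # conserved loci without references refused
    expect_error(generateGenome(length = 30000, nMir = 4,
        referenceSet = NULL, seed = 1), "referenceSet")

    # bit-identical regeneration under the same seed
    g1 <- generateGenome(length = 20000, nMir = 4, nNcrna = 2,
        referenceSet = refSet(), seed = 9)
    g2 <- generateGenome(length = 20000, nMir = 4, nNcrna = 2,
        referenceSet = refSet(), seed = 9)
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    expect_identical(
        as.data.frame(S4Vectors::mcols(g1$mirTruth)),
        as.data.frame(S4Vectors::mcols(g2$mirTruth)))
})

test_that("library simulation conserves reads and obeys its noise model", {
    refs <- refSet()
    gen <- generateGenome(length = 30000, nMir = 4, nNcrna = 3,
        referenceSet = refs, seed = 5)

    # dispersion 0: counts are exactly the rounded expectations
    d0 <- list(libraryDesign("lib_a", depth = 5000, dispersion = 0,
        ncrnaFraction = 0, seed = 2))
    sim0 <- simulateLibraries(gen$mirTruth, d0, gen$ncrnaTruth)
    tc <- sim0$truthCounts
    expect_true(all(tc$emitted == floor(tc$expected + 0.5)))
    expect_equal(length(sim0$libraries$lib_a$sequences),
        sum(tc$emitted))

    # truth-table totals equal FASTQ read counts per library
    designs <- defaultLibraryDesigns(depths = c(leaf_control = 3000,
        leaf_nacl = 2500, root_control = 2100, root_nacl = 2800),
        seed = 4)
    sim <- simulateLibraries(gen$mirTruth, designs, gen$ncrnaTruth)
    for (l in names(sim$libraries)) {
        expect_equal(length(sim$libraries[[l]]$sequences),
            sum(sim$truthCounts$emitted[
                sim$truthCounts$library_id == l]))
    }

    # same seeds reproduce byte-identical reads
    sim2 <- simulateLibraries(gen$mirTruth, designs, gen$ncrnaTruth)
    expect_identical(sim$libraries, sim2$libraries)

    # adaptor guard
    expect_error(libraryDesign("x", adaptor3p = "ACGT"), "6 nt")
})

test_that("planted fold changes and ncRNA fractions are respected", {
    refs <- refSet()
    gen <- generateGenome(length = 20000, nMir = 1, nNcrna = 2,
        referenceSet = refs, seed = 8,
        classMix = c(conserved = 1, variant = 0, novel = 0))
    fc <- matrix(c(1, 4), 1, 2,
        dimnames = list("MIR001", c("ctrl", "salt")))

    # Monte-Carlo: mean count ratio approximates the planted 4-fold
    nrep <- 100
    ra <- rb <- numeric(nrep)
    for (r in seq_len(nrep)) {
        designs <- list(
            libraryDesign("ctrl", depth = 2000, ncrnaFraction = 0,
                seed = 1000 + r),
            libraryDesign("salt", depth = 2000, ncrnaFraction = 0,
                seed = 5000 + r))
        sim <- simulateLibraries(gen$mirTruth, designs,
            foldChanges = fc)
        t5 <- sim$truthCounts[sim$truthCounts$arm == "5p", ]
        ra[r] <- t5$emitted[t5$library_id == "ctrl"]
        rb[r] <- t5$emitted[t5$library_id == "salt"]
    }
    ratio <- mean(rb) / mean(ra)
    se <- ratio * sqrt(var(rb) / mean(rb)^2 + var(ra) / mean(ra)^2) /
        sqrt(nrep)
    expect_lt(abs(ratio - 4), 3 * max(se, 0.05))

    # ncrna_fraction ~ 0.3 of emitted reads within binomial tolerance
    d <- list(libraryDesign("lib", depth = 6000, ncrnaFraction = 0.3,
        dispersion = 0, seed = 77))
    sim <- simulateLibraries(gen$mirTruth, d, gen$ncrnaTruth)
    tc <- sim$truthCounts
    frac <- sum(tc$emitted[tc$origin == "ncrna"]) / sum(tc$emitted)
    expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 6000) + 0.01)
})
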