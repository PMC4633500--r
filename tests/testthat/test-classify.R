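test_that("reference matching finds the best containment placement", {
    refs <- refSet()
    # exact conserved sequence from the catalogue
    m <- matchReference("UGACAGAAGAGAGUGAGCAC", refs)
    expect_equal(m$reference_id, "pda-miR156a")
    expect_equal(m$mismatches, 0)

    # two planted substitutions
    q <- "UGACAGAAGAGAGUGAGCAC"
    substr(q, 3, 3) <- "U"; substr(q, 15, 15) <- "C"
    m2 <- matchReference(q, refs)
    expect_equal(m2$mismatches, 2)

    # nothing within reach
    expect_null(matchReference(strrep("AC", 10), refs))
    expect_error(matchReference("ACGU", character(0)), "empty")

    # random queries equal the exhaustive all-placements oracle
    set.seed(61)
    rr <- setNames(vapply(1:8, function(i) randomRNA(sample(18:24, 1)),
        ""), paste0("ref", 1:8))
    for (i in 1:40) {
        q <- if (i %% 2 == 0) randomRNA(sample(16:25, 1)) else {
            base <- rr[[sample(8, 1)]]
            nm <- sample(0:3, 1)
            for (k in seq_len(nm)) {
                p <- sample(nchar(base), 1)
                substr(base, p, p) <- sample(c("A", "C", "G", "U"), 1)
            }
            base
        }
        got <- matchReference(q, rr)
        want <- matchOracle(q, as.list(rr))
        if (is.null(want)) {
            expect_null(got, info = q)
        } else {
            expect_equal(got$reference_id, want$id, info = q)
            expect_equal(got$mismatches, want$mm, info = q)
        }
    }
})

test_that("class assignment follows the mismatch and read-floor rules", {
    refs <- refSet()
    mk <- function(q, reads) classifyMirna(q, reads,
        matchReference(q, refs))
    expect_equal(mk("UGACAGAAGAGAGUGAGCAC", 50)$class, "conserved")
    q1 <- "UGACAGAAGAGAGUGAGCAC"; substr(q1, 5, 5) <- "C"
    expect_equal(mk(q1, 50)$class, "variant")
    # unmatched below and at the novel read floor
    novel <- strrep("AC", 10)   # far from every reference
    expect_equal(mk(novel, 9)$class, "discarded")
    expect_equal(mk(novel, 10)$class, "novel")
    # the optional 1-3 band turns a 3-mismatch query into a variant
    q3 <- "UGACAGAAGAGAGUGAGCAC"
    substr(q3, 2, 2) <- "C"; substr(q3, 8, 8) <- "C"
    substr(q3, 12, 12) <- "C"
    m3 <- matchReference(q3, refs, maxMismatches = 3)
    expect_equal(classifyMirna(q3, 50, m3,
        variantMaxMismatches = 3)$class, "variant")
})

test_that("family names parse from miRBase-style identifiers", {
    expect_equal(assignFamily("osa-miR156a-5p"), "miR156")
    expect_equal(assignFamily("ath-miR396b"), "miR396")
    expect_equal(assignFamily("pda-MIR156h-p3"), "miR156")
    expect_warning(f <- assignFamily("unparseable"), "cannot parse")
    expect_true(is.na(f))
    # family sizes on a constructed set equal the hand count
    ids <- c("ath-miR156a", "osa-miR156b-5p", "pda-miR166a",
        "zma-miR166b", "ath-miR166c-3p", "osa-miR396a")
    fams <- vapply(ids, assignFamily, "")
    expect_equal(sort(as.integer(table(fams)), decreasing = TRUE),
        c(3L, 2L, 1L))
})

test_that("presence sets satisfy set algebra on random matrices", {
    set.seed(71)
    m <- matrix(rpois(80, 2), 20, 4,
        dimnames = list(paste0("m", 1:20), paste0("lib", 1:4)))
    ps <- presenceSets(m)
    sets <- apply(m >= 1, 2, which)
    if (is.matrix(sets)) sets <- asplit(sets, 2)
    for (i in 1:4) for (j in 1:4)
        expect_equal(ps$pairwise[i, j],
            length(intersect(sets[[i]], sets[[j]])))
    expect_equal(ps$commonAll,
        length(Reduce(intersect, sets)))
    expect_equal(unname(ps$perLibrary), unname(colSums(m >= 1)))
    # inclusion-exclusion for two libraries: |A u B| = |A|+|B|-|A^B|
    union12 <- sum(m[, 1] >= 1 | m[, 2] >= 1)
    expect_equal(union12,
        ps$perLibrary[[1]] + ps$perLibrary[[2]] - ps$pairwise[1, 2])
    # single-library presence
    one <- matrix(c(5, 0, 0, 0), 1, dimnames = list("x", paste0("l", 1:4)))
    pso <- presenceSets(one)
    expect_equal(unname(pso$perLibrary), c(1L, 0L, 0L, 0L))
    expect_equal(pso$commonAll, 0L)
})

test_that("planted classes are recovered end to end", {
    disc <- sharedDiscovery()
    bundle <- disc$bundle
    tr <- as.data.frame(S4Vectors::mcols(bundle$genome$mirTruth))
    refs <- refSet()
    ann <- classifyCandidates(disc$candidates, disc$tags, refs)
    expect_gt(nrow(ann), 0)
    # every planted locus is rediscovered with the correct class for
    # its 5p mature (unambiguous by generator construction)
    for (i in seq_len(nrow(tr))) {
        hit <- ann[ann$mature_seq == tr$mature_5p[i], , drop = FALSE]
        expect_gte(nrow(hit), 1)
        expect_true(all(hit$class == tr$class_truth[i]),
            info = tr$locus_id[i])
        if (tr$class_truth[i] %in% c("conserved", "variant"))
            expect_true(all(hit$mismatches ==
                tr$planted_mismatches[i]), info = tr$locus_id[i])
        if (tr$class_truth[i] == "novel")
            expect_match(hit$mirna_id[1],
                "^pda-(5p|3p)-[0-9]+_[0-9]+$")
    }
    # {conserved, variant, novel} partitions the annotated matures
    expect_true(all(ann$class %in% c("conserved", "variant", "novel")))
    # duplex partners are reciprocal within each candidate
    for (ci in unique(ann$candidate)) {
        rows <- ann[ann$candidate == ci, , drop = FALSE]
        if (nrow(rows) == 2 && !anyNA(rows$duplex_partner)) {
            expect_equal(rows$duplex_partner[1], rows$mirna_id[2])
            expect_equal(rows$duplex_partner[2], rows$mirna_id[1])
        }
    }
})
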