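rcRNA <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(x)))

test_that("site scoring applies the stated penalty scheme", {
    m <- randomRNA(21)
    # perfect complement: zero expectation, cleavage
    s <- scoreSite(m, rcRNA(m))
    expect_equal(s$expectation, 0)
    expect_equal(s$mode, "cleavage")
    expect_true(all(s$states == "WC"))

    # single mismatch opposite miRNA position 10: doubled penalty,
    # central window -> translation
    m2 <- "UGACAGAAGAGAGUGAGCACA"
    site <- rcRNA(m2)
    p <- nchar(m2) - 10 + 1   # site position pairing miRNA pos 10
    old <- substr(site, p, p)
    # replace with a base that neither pairs nor wobbles miRNA pos 10
    mb <- substr(m2, 10, 10)
    bad <- setdiff(c("A", "C", "G", "U"),
        c(old, switch(mb, G = "U", U = "G", character(0)), mb))
    substr(site, p, p) <- bad[1]
    s2 <- scoreSite(m2, site)
    expect_equal(s2$expectation, 2)
    expect_equal(s2$mode, "translation")
    expect_equal(s2$states[10], "MM")

    # G:U wobble at position 20 (outside the doubled band): 0.5,
    # cleavage
    m3 <- paste0(strrep("A", 19), "G", "A")   # position 20 is G
    site3 <- rcRNA(m3)
    p3 <- nchar(m3) - 20 + 1
    substr(site3, p3, p3) <- "U"              # G:U instead of G:C
    s3 <- scoreSite(m3, site3)
    expect_equal(s3$expectation, 0.5)
    expect_equal(s3$mode, "cleavage")
    expect_equal(s3$states[20], "GU")

    expect_error(scoreSite("", "ACGU"), "empty")
    expect_error(scoreSite(randomRNA(21), randomRNA(26)), "within 4")
})

test_that("expectation is monotone in added mismatches", {
    set.seed(101)
    m <- randomRNA(21)
    site <- rcRNA(m)
    prev <- scoreSite(m, site)$expectation
    positions <- sample(21, 6)
    for (p in positions) {
        sp <- nchar(m) - p + 1
        cur <- substr(site, sp, sp)
        repl <- setdiff(c("A", "C", "G", "U"), cur)[1]
        substr(site, sp, sp) <- repl
        e <- scoreSite(m, site)$expectation
        expect_gte(e, prev)
        prev <- e
    }
})

test_that("transcript scanning equals exhaustive per-window scoring", {
    set.seed(103)
    m <- randomRNA(21)
    tx <- paste0(randomRNA(150), rcRNA(m), randomRNA(150))
    hits <- scanTranscript(m, tx)
    expect_gte(nrow(hits), 1)
    perfect <- hits[hits$expectation == 0, ]
    expect_equal(perfect$start0, 150)
    expect_equal(perfect$mode, "cleavage")

    # oracle: score every placement independently with scoreSite
    L <- nchar(m)
    all <- vapply(seq_len(nchar(tx) - L + 1), function(i)
        scoreSite(m, substr(tx, i, i + L - 1))$expectation, numeric(1))
    # every reported hit has the oracle expectation and the threshold
    for (r in seq_len(nrow(hits))) {
        expect_equal(hits$expectation[r], all[hits$start0[r] + 1])
        expect_lte(hits$expectation[r], 3)
    }
    # no non-overlapping placement better than every reported hit was
    # missed: any placement scoring <= 3 overlaps a reported hit with
    # an expectation at least as good
    ok <- which(all <= 3)
    for (i in ok) {
        overl <- hits$start0 < (i - 1 + L) & (hits$start0 + L) > (i - 1)
        expect_true(any(overl) || FALSE, info = i)
        expect_lte(min(hits$expectation[overl]), all[i])
    }
    # reported hits never overlap
    if (nrow(hits) > 1) {
        o <- order(hits$start0)
        expect_true(all(hits$start0[o][-1] >=
            hits$end0[o][-nrow(hits)]))
    }

    # a transcript with no qualifying window yields no hits
    set.seed(104)
    none <- scanTranscript(randomRNA(21), randomRNA(400))
    expect_true(all(none$expectation <= 3))
})

test_that("context flanks are 17 nt upstream and 13 nt downstream", {
    m <- randomRNA(20)
    tx <- paste0(randomRNA(100), rcRNA(m), randomRNA(100))
    hits <- scanTranscript(m, tx)
    h <- hits[hits$expectation == 0, ]
    expect_equal(nchar(h$context), 17 + 20 + 13)
    expect_equal(h$context,
        substr(tx, h$start0 + 1 - 17, h$end0 + 13))
})

test_that("target summaries reproduce mode percentages", {
    h <- data.frame(
        mode = rep(c("cleavage", "translation"), c(660, 238)),
        mirna_id = "m", transcript_id = "t")
    ts <- summarizeTargets(h)
    expect_equal(ts$nHits, 898)
    expect_equal(ts$pctCleavage, 73.5)
    one <- summarizeTargets(data.frame(mode = "translation",
        mirna_id = "m", transcript_id = "t"))
    expect_equal(one$pctTranslation, 100)
    # multiplicity tables count per miRNA and per transcript
    hh <- data.frame(mode = "cleavage",
        mirna_id = c("a", "a", "b"),
        transcript_id = c("t1", "t2", "t1"))
    tss <- summarizeTargets(hh)
    expect_equal(as.integer(tss$perMirna[c("a", "b")]), c(2L, 1L))
    expect_equal(as.integer(tss$perTranscript[c("t1", "t2")]),
        c(2L, 1L))
})

test_that("planted transcript sites are recovered through the bundle", {
    bundle <- syntheticBundle()
    tr <- as.data.frame(S4Vectors::mcols(bundle$genome$mirTruth))
    tx <- Biostrings::readDNAStringSet(
        file.path(dirname(bundle$config), "transcripts.fa"))
    mirs <- setNames(tr$mature_5p[1:3], tr$locus_id[1:3])
    hits <- predictTargets(mirs, tx)
    expect_gte(nrow(hits), 3)
    expect_true(all(hits$expectation <= 3))
    # locus 1: perfect site, cleavage; locus 2: central mismatch,
    # translation
    h1 <- hits[hits$mirna_id == tr$locus_id[1] &
        hits$transcript_id == "TX001", ]
    expect_true(any(h1$expectation == 0 & h1$mode == "cleavage"))
    h2 <- hits[hits$mirna_id == tr$locus_id[2] &
        hits$transcript_id == "TX002", ]
    expect_true(any(h2$mode == "translation"))
})
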