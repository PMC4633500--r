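test_that("size factors follow the printed median-of-ratios equation", {
    # identical libraries: unit factors
    m <- cbind(a = c(5, 10, 50), b = c(5, 10, 50))
    expect_equal(unname(medianRatioSizeFactors(m)$sizeFactors),
        c(1, 1))
    # doubling one library: (1/sqrt(2), sqrt(2)) exactly
    m2 <- cbind(a = c(10, 20, 35), b = 2 * c(10, 20, 35))
    expect_equal(unname(medianRatioSizeFactors(m2)$sizeFactors),
        c(1 / sqrt(2), sqrt(2)))
    # rows with zeros are excluded from the median, not the matrix
    m3 <- rbind(m2, c(0, 100))
    expect_equal(medianRatioSizeFactors(m3)$sizeFactors,
        medianRatioSizeFactors(m2)$sizeFactors)
    expect_error(medianRatioSizeFactors(cbind(c(0, 1), c(1, 0))),
        "no row")

    # random matrices match the independent direct coding
    set.seed(81)
    for (i in 1:25) {
        mm <- matrix(rpois(200, 20) + 1, 50, 4,
            dimnames = list(NULL, paste0("l", 1:4)))
        expect_equal(unname(medianRatioSizeFactors(mm)$sizeFactors),
            sizeFactorsOracle(mm))
    }
})

test_that("size factors are scale-equivariant and normalization idempotent", {
    set.seed(83)
    m <- matrix(rpois(200, 30) + 1, 50, 4,
        dimnames = list(NULL, paste0("l", 1:4)))
    sf <- medianRatioSizeFactors(m)$sizeFactors
    m2 <- m; m2[, 2] <- m2[, 2] * 5
    sf2 <- medianRatioSizeFactors(m2)$sizeFactors
    # multiplying library 2 by c multiplies its ratio column by c and
    # scales the geometric mean by c^(1/m)
    expect_equal(sf2[[2]] / sf[[2]], 5 / 5^(1 / 4), tolerance = 1e-9)

    norm <- normalizeCounts(m, sf)
    refit <- medianRatioSizeFactors(norm)$sizeFactors
    expect_lt(max(abs(refit / refit[1] - 1)), 1e-9)
    expect_equal(normalizeCounts(cbind(a = 10), list(sizeFactors = 2)),
        cbind(a = 5))
})

test_that("the exact test matches enumeration and edgeR's small-p rule", {
    # symmetry: equal pseudo-counts
    r <- nbExactTest(50, 50)
    expect_equal(r$p_value, 1)
    expect_equal(r$log2FC, 0)
    # swapping groups negates the fold change, preserves p
    r1 <- nbExactTest(30, 90); r2 <- nbExactTest(90, 30)
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$log2FC, -r2$log2FC)
    expect_error(nbExactTest(0, 0), "both be zero")
    expect_error(nbExactTest(1, 2, dispersion = -1), "nonnegative")

    # enumeration oracle over all splits, sums <= 200
    set.seed(91)
    for (i in 1:40) {
        a <- sample(0:100, 1); b <- sample(0:100, 1)
        if (a + b == 0) a <- 1
        phi <- sample(c(0, 0.04, 0.2), 1)
        expect_equal(nbExactTest(a, b, dispersion = phi)$p_value,
            nbExactOracle(a, b, phi), tolerance = 1e-9,
            info = paste(a, b, phi))
    }

    # independent cross-check against edgeR's exact small-p test at
    # equal library sizes
    skip_if_not_installed("edgeR")
    set.seed(92)
    for (i in 1:10) {
        a <- sample(5:400, 1); b <- sample(5:400, 1)
        y <- matrix(c(a, b), 1)
        et <- edgeR::exactTest(
            edgeR::DGEList(counts = y, group = factor(1:2),
                lib.size = rep(1e6, 2)),
            dispersion = 0.04, rejection.region = "smallp")
        expect_equal(nbExactTest(a, b, dispersion = 0.04)$p_value,
            et$table$PValue, tolerance = 1e-6, info = paste(a, b))
    }
})

test_that("BH adjustment equals the textbook step-up", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    set.seed(93)
    for (i in 1:20) {
        p <- runif(sample(3:50, 1))
        expect_equal(bhAdjust(p), bhOracle(p))
    }
})

test_that("complete linkage reproduces brute-force agglomeration", {
    set.seed(95)
    m <- matrix(rnorm(10), 5, 2)
    cl <- completeLinkageOrder(m, transform = identity)
    expect_equal(sort(cl$rowHeight), sort(completeLinkageOracle(m)))
    # identical rows merge first at distance zero
    m2 <- rbind(c(1, 1), c(1, 1), c(5, 9), c(-3, 2))
    cl2 <- completeLinkageOrder(m2, transform = identity)
    expect_equal(cl2$rowHeight[1], 0)
    expect_equal(sort(cl2$rowMerge[1, ]), c(-2, -1))
    # duplicating every row leaves between-cluster heights intact
    m3 <- m[rep(1:5, each = 2), ]
    cl3 <- completeLinkageOrder(m3, transform = identity)
    expect_equal(sort(round(cl3$rowHeight[cl3$rowHeight > 0], 9)),
        sort(round(completeLinkageOracle(m), 9)))
})

test_that("qPCR fold changes follow 2^-ddCt", {
    expect_equal(ddctFoldChange(20, 18, 22, 20), 1)
    expect_equal(ddctFoldChange(20, 19, 22, 20), 2)
    expect_equal(ddctFoldChange(24.32, 20, 21, 20), 2^-3.32)
    expect_error(ddctFoldChange(NA, 1, 1, 1))
})

test_that("the DE table flags planted responders", {
    disc <- sharedDiscovery()
    bundle <- disc$bundle
    refs <- refSet()
    ann <- classifyCandidates(disc$candidates, disc$tags, refs)
    annU <- ann[!duplicated(ann$mirna_id), , drop = FALSE]
    cm <- tagCounts(disc$tags)[
        match(annU$mature_seq, as.character(tagSequences(disc$tags))), ,
        drop = FALSE]
    rownames(cm) <- annU$mirna_id
    tab <- exactTestTable(cm, "leaf_control", "leaf_nacl",
        dispersion = 0.04)
    # significance is the conjunction of both thresholds
    expect_equal(tab$significant, tab$p_value < 0.05 & tab$fdr < 0.05)
    # planted 4x-up loci are called with positive fold change
    tr <- as.data.frame(S4Vectors::mcols(bundle$genome$mirTruth))
    up <- rownames(bundle$foldChanges)[
        bundle$foldChanges[, "leaf_nacl"] > 1]
    upSeqs <- tr$mature_5p[tr$locus_id %in% up]
    upIds <- annU$mirna_id[annU$mature_seq %in% upSeqs]
    hit <- tab[tab$mirna_id %in% upIds, , drop = FALSE]
    expect_gt(nrow(hit), 0)
    expect_true(all(hit$significant))
    expect_true(all(hit$log2FC > 0))
})
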