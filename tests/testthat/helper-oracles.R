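# Independent oracles used across the suite.  Everything here is coded
# from the model definitions alone, separately from the package
# implementations it checks.

refSet <- function() {
    fa <- Biostrings::readRNAStringSet(system.file("extdata",
        "mature_reference.fa", package = "plantsrna"))
    setNames(as.character(fa), names(fa))
}

randomRNA <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## ---- secondary-structure enumeration oracle ------------------------

.canPair <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("GC", "CG", "AU", "UA", "GU", "UG")
}

# all non-crossing structures over chars[i..j] with canonical pairs and
# hairpin loops of >= 3 nt, as lists of rbind(i, j) pair matrices
enumStructures <- function(chars, i, j) {
    if (j - i < 4) return(list(matrix(integer(0), nrow = 2)))
    out <- list()
    # i unpaired
    for (s in enumStructures(chars, i + 1, j)) out[[length(out) + 1]] <- s
    # i paired with k
    for (k in (i + 4):j) {
        if (!.canPair(chars[i], chars[k])) next
        inner <- enumStructures(chars, i + 1, k - 1)
        rest <- enumStructures(chars, k + 1, j)
        for (si in inner) for (sr in rest)
            out[[length(out) + 1]] <- cbind(matrix(c(i, k), nrow = 2),
                si, sr)
    }
    out
}

# energy of one structure under the published model: pair energies
# GC -3, AU -2, GU -1; -0.5 per stacked pair; hairpin loop +3; any
# other loop (bulge, internal, multiloop) +1
structureEnergy <- function(chars, pairs) {
    if (ncol(pairs) == 0) return(0)
    pt <- integer(length(chars))
    pt[pairs[1, ]] <- pairs[2, ]
    pt[pairs[2, ]] <- pairs[1, ]
    pairE <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
    e <- 0
    for (c1 in seq_len(ncol(pairs))) {
        i <- pairs[1, c1]; j <- pairs[2, c1]
        e <- e + pairE[[paste0(chars[i], chars[j])]]
        # children: maximal pairs directly inside (i, j)
        kids <- 0L; firstKid <- NULL
        p <- i + 1L
        while (p < j) {
            if (pt[p] > p) {
                kids <- kids + 1L
                if (kids == 1L) firstKid <- c(p, pt[p])
                p <- pt[p] + 1L
            } else p <- p + 1L
        }
        if (kids == 0L) {
            e <- e + 3
        } else if (kids == 1L && firstKid[1] == i + 1L &&
                   firstKid[2] == j - 1L) {
            e <- e - 0.5
        } else {
            e <- e + 1
        }
    }
    unname(e)
}

# minimum over complete enumeration (0 for the empty structure)
enumMinEnergy <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    structs <- enumStructures(chars, 1L, length(chars))
    min(vapply(structs, function(s) structureEnergy(chars, s),
        numeric(1)))
}

## ---- mapping brute-force oracle ------------------------------------

# all ungapped alignments of tag (DNA) to genome string, both strands,
# <= 1 mismatch at 0-based offsets < 16 and none beyond; returns a
# data.frame(start0 forward, strand) sorted
bruteMap <- function(tag, genomeStr) {
    n <- nchar(tag)
    L <- nchar(genomeStr)
    tagc <- utf8ToInt(tag)
    hitsFwd <- function(s) {
        gc <- utf8ToInt(s)
        nPos <- L - n + 1
        mmSeed <- integer(nPos)   # mismatches at 0-based offsets < 16
        mmTail <- integer(nPos)   # mismatches at offsets >= 16
        for (k in seq_len(n)) {
            diff <- gc[k:(k + nPos - 1)] != tagc[k]
            if (k <= 16) mmSeed <- mmSeed + diff
            else mmTail <- mmTail + diff
        }
        which(mmSeed <= 1 & mmTail == 0) - 1L
    }
    fwd <- hitsFwd(genomeStr)
    rcg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(genomeStr)))
    revStarts <- hitsFwd(rcg)
    revFwd <- L - (revStarts + n)
    df <- rbind(
        data.frame(start0 = fwd,
            strand = rep("+", length(fwd))),
        data.frame(start0 = revFwd,
            strand = rep("-", length(revFwd))))
    df[order(df$start0, df$strand), , drop = FALSE]
}

## ---- statistics oracles --------------------------------------------

# size factors coded directly from the printed equation
sizeFactorsOracle <- function(m) {
    keep <- apply(m, 1, function(r) all(r > 0))
    mm <- m[keep, , drop = FALSE]
    geo <- apply(mm, 1, function(r) prod(r)^(1 / length(r)))
    vapply(seq_len(ncol(mm)), function(j) median(mm[, j] / geo),
        numeric(1))
}

# textbook BH step-up
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    prev <- 1
    for (k in n:1) {
        val <- min(prev, p[o[k]] * n / k)
        adj[o[k]] <- val
        prev <- val
    }
    adj
}

# exact conditional NB test by explicit enumeration over all splits
nbExactOracle <- function(a, b, phi) {
    s <- a + b
    mu <- s / 2
    pm <- function(k) {
        if (phi == 0) return(choose(s, k) * 0.5^s)
        r <- 1 / phi
        pr <- r / (r + mu)
        f <- function(x) exp(lgamma(x + r) - lgamma(r) - lfactorial(x) +
            r * log(pr) + x * log(1 - pr))
        f(k) * f(s - k)
    }
    probs <- vapply(0:s, pm, numeric(1))
    probs <- probs / sum(probs)
    sum(probs[probs <= probs[a + 1] * (1 + 1e-10)])
}

# brute-force complete-linkage agglomeration: returns merge heights
completeLinkageOracle <- function(m) {
    d <- as.matrix(dist(m))
    clusters <- as.list(seq_len(nrow(m)))
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (j <= i) next
            dd <- max(d[clusters[[i]], clusters[[j]]])
            if (dd < bestD) { bestD <- dd; best <- c(i, j) }
        }
        heights <- c(heights, bestD)
        clusters[[best[1]]] <- c(clusters[[best[1]]],
            clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    heights
}

# best containment match by exhaustive scan over all placements
matchOracle <- function(query, refs, maxMismatches = 2,
                        minOverlap = 16) {
    best <- NULL
    for (id in names(refs)) {
        r <- refs[[id]]
        short <- if (nchar(query) <= nchar(r)) query else r
        long <- if (nchar(query) <= nchar(r)) r else query
        ov <- nchar(short)
        if (ov < minOverlap) next
        sc <- utf8ToInt(short); lc <- utf8ToInt(long)
        for (off in 0:(nchar(long) - ov)) {
            mm <- sum(sc != lc[(off + 1):(off + ov)])
            if (mm > maxMismatches) next
            if (is.null(best) || mm < best$mm ||
                (mm == best$mm && (ov > best$ov ||
                    (ov == best$ov && id < best$id))))
                best <- list(id = id, mm = mm, ov = ov)
        }
    }
    best
}

## ---- shared fixtures ------------------------------------------------

syntheticBundle <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            dir <- file.path(tempdir(), "plantsrna-bundle")
            cache <<- makeFixtures(dir, seed = 1)
        }
        cache
    }
})

# preprocess + map + discover on the shared bundle, computed once
sharedDiscovery <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        bundle <- syntheticBundle()
        gen <- bundle$genome
        sim <- bundle$simulation
        d <- bundle$designs[[1]]
        inserts <- lapply(sim$libraries, function(l) {
            x <- trimAdaptor(l$sequences, d$adaptor_3p)
            x[!is.na(x)]
        })
        tags <- collapseReads(inserts)
        nc <- as.data.frame(S4Vectors::mcols(gen$ncrnaTruth))
        fa <- filterAnnotated(tags,
            split(chartr("U", "T", nc$sequence), nc$category))
        gi <- buildGenomeIndex(gen$genome)
        mp <- mapTags(fa$kept, gi)
        cands <- discoverHairpins(mp$tags, mp$alignments, gen$genome)
        cache <<- list(bundle = bundle, tags = mp$tags,
            alignments = mp$alignments, candidates = cands)
        cache
    }
})
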