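#' Candidate precursor windows around an alignment
#'
#' Builds a ladder of genomic windows extending an alignment by 20, 60,
#' 120 and 250 nt on each side, plus asymmetric variants placing the
#' aligned read near the 5' or the 3' end of the window.  Windows are
#' clipped to contig bounds and must be at least 50 nt.
#'
#' @param alignment A single-row \code{GRanges} alignment (from
#'   \code{\link{mapTag}}).
#' @param contigLength Length of the alignment's contig.
#' @param maxFlank Largest flank in the ladder (default 250 nt).
#' @return A \code{GRanges} of distinct candidate windows (same strand
#'   as the alignment).
#' @export
extractCandidateWindows <- function(alignment, contigLength,
                                    maxFlank = 250) {
    stopifnot(length(alignment) == 1)
    ladder <- c(20, 60, 120, 250)
    ladder <- ladder[ladder <= maxFlank]
    flanks <- rbind(cbind(ladder, ladder))
    asym <- ladder[ladder >= 60]
    flanks <- rbind(flanks, cbind(asym, 10), cbind(10, asym))
    s <- GenomicRanges::start(alignment)
    e <- GenomicRanges::end(alignment)
    starts <- pmax(1L, s - flanks[, 1])
    ends <- pmin(contigLength, e + flanks[, 2])
    keep <- (ends - starts + 1L) >= 50L
    if (!any(keep)) return(GenomicRanges::GRanges())
    gr <- GenomicRanges::GRanges(
        seqnames = as.character(GenomicRanges::seqnames(alignment)),
        ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
        strand = as.character(GenomicRanges::strand(alignment)))
    unique(gr)
}

# maximal runs of unpaired positions within [from, to] (1-based),
# bounded on both sides by paired positions or the interval edge
.unpairedRuns <- function(pt, from, to) {
    if (from > to) return(list())
    unp <- which(pt[from:to] == 0) + from - 1L
    if (!length(unp)) return(list())
    breaks <- c(0L, which(diff(unp) != 1L), length(unp))
    lapply(seq_len(length(breaks) - 1L), function(i)
        unp[(breaks[i] + 1L):breaks[i + 1L]])
}

# is an unpaired run opposed by unpaired positions on the partner arm?
# the opposing region lies between the partners of the run's flanking
# paired positions.
.runIsBiased <- function(run, pt, n) {
    lo <- run[1] - 1L
    hi <- run[length(run)] + 1L
    while (lo >= 1L && pt[lo] == 0L) lo <- lo - 1L
    while (hi <= n && pt[hi] == 0L) hi <- hi + 1L
    if (lo < 1L || hi > n) return(TRUE)      # run at helix edge: unopposed
    a <- pt[hi]; b <- pt[lo]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    if (b - a <= 1L) return(TRUE)            # no room opposite
    all(pt[(a + 1L):(b - 1L)] != 0L)
}

#' Evaluate a folded candidate window against the hairpin criteria
#'
#' Measures the structural and read-support properties of a folded
#' window and compares each against the \code{\linkS4class{HairpinCriteria}}
#' thresholds.  Measured values: stem base pairs are all pairs enclosing
#' the terminal loop; the terminal loop is the unpaired span inside the
#' innermost pair; errors are unpaired nucleotides; a bulge is a maximal
#' unpaired run on one arm; a biased bulge has no opposing unpaired run
#' on the partner arm; pm is the fraction of supporting-tag nucleotides
#' lying on the stem arms; total reads sums supporting-tag counts over
#' all libraries.  The mature region is the span of the highest-count
#' supporting tag.  Structures with more than one terminal loop fail
#' with reason \code{"not a single hairpin"}.
#'
#' @param structure A \code{\linkS4class{SecondaryStructure}} of the
#'   window sequence.
#' @param tags Data frame of supporting tags with columns \code{start0}
#'   (0-based offset of the tag within the window, on the window
#'   strand), \code{width} and \code{count} (total reads over all
#'   libraries); at least one row.
#' @param criteria A \code{\linkS4class{HairpinCriteria}}.
#' @return A list with \code{verdict} (logical), \code{report} (data
#'   frame: criterion, value, threshold, comparator, pass),
#'   \code{measures} (named list incl. \code{mfei}, \code{gcFraction},
#'   \code{hairpinSpan} = 1-based window coordinates of the hairpin),
#'   and \code{matureSpan5p}/\code{matureSpan3p} (1-based spans or
#'   \code{NULL}).
#' @export
evaluateHairpin <- function(structure, tags,
                            criteria = hairpinCriteria()) {
    stopifnot(is(structure, "SecondaryStructure"), nrow(tags) >= 1)
    pt <- pairTable(structure)
    n <- length(pt)
    seqc <- structure@sequence
    gc <- .gcFraction(seqc)
    mfeVal <- mfe(structure)

    fail <- function(reason) list(verdict = FALSE, report = data.frame(
        criterion = reason, value = NA_real_, threshold = NA_real_,
        comparator = "", pass = FALSE), measures = list(
            mfe = mfeVal, gcFraction = gc), matureSpan5p = NULL,
        matureSpan3p = NULL)

    paired <- which(pt > 0)
    if (!length(paired)) return(fail("no hairpin"))
    # terminal loops: pairs with no paired position strictly inside
    closing <- which(pt > seq_len(n))
    isTerminal <- vapply(closing, function(i) {
        j <- pt[i]
        j - i <= 1L || !any(pt[(i + 1L):(j - 1L)] > 0L)
    }, logical(1))
    nHairpins <- sum(isTerminal)
    if (nHairpins != 1L) return(fail("not a single hairpin"))

    iStar <- closing[isTerminal]
    jStar <- pt[iStar]
    terminalLoop <- jStar - iStar - 1L
    iOut <- min(paired)
    jOut <- max(paired)
    hairpinLen <- jOut - iOut + 1L
    stemBp <- length(closing)
    arm5 <- c(iOut, iStar)
    arm3 <- c(jStar, jOut)

    stemRuns <- c(.unpairedRuns(pt, iOut, iStar),
                  .unpairedRuns(pt, jStar, jOut))
    maxStemBulge <- if (length(stemRuns))
        max(vapply(stemRuns, length, integer(1))) else 0L

    # tag placement: arm assignment and pm
    t1 <- tags$start0 + 1L
    t2 <- tags$start0 + tags$width
    onStemNt <- vapply(seq_len(nrow(tags)), function(k) {
        pos <- t1[k]:t2[k]
        sum((pos >= arm5[1] & pos <= arm5[2]) |
            (pos >= arm3[1] & pos <= arm3[2]))
    }, numeric(1))
    pm <- sum(onStemNt * tags$count) / sum(tags$width * tags$count)
    totalReads <- sum(tags$count)

    arm <- ifelse(t2 <= iStar & t1 >= iOut, "5p",
        ifelse(t1 >= jStar & t2 <= jOut, "3p", "loop"))
    matureSpan <- function(a) {
        sel <- which(arm == a)
        if (!length(sel)) return(NULL)
        k <- sel[order(-tags$count[sel], tags$start0[sel])][1]
        c(t1[k], t2[k])
    }
    m5 <- matureSpan("5p")
    m3 <- matureSpan("3p")
    # the putative mature = highest-count tag lying on an arm
    onArm <- which(arm != "loop")
    matureMeasures <- list(errors = NA_real_, maxBulge = NA_real_,
        maxBiasedBulge = 0, nBiasedBulges = 0, bp = NA_real_)
    if (length(onArm)) {
        k <- onArm[order(-tags$count[onArm], tags$start0[onArm])][1]
        span <- t1[k]:t2[k]
        runs <- .unpairedRuns(pt, t1[k], t2[k])
        biased <- if (length(runs))
            vapply(runs, .runIsBiased, logical(1), pt = pt, n = n)
            else logical(0)
        matureMeasures <- list(
            errors = sum(pt[span] == 0),
            maxBulge = if (length(runs))
                max(vapply(runs, length, integer(1))) else 0,
            maxBiasedBulge = if (any(biased))
                max(vapply(runs[biased], length, integer(1))) else 0,
            nBiasedBulges = sum(biased),
            bp = sum(pt[span] > 0))
    }

    mfei <- if (gc > 0) computeMfei(mfeVal, n, gc) else NA_real_

    rows <- list(
        list("max_errors_one_bulge_stem", maxStemBulge,
            criteria@maxErrorsOneBulgeStem, "<="),
        list("min_stem_bp", stemBp, criteria@minStemBp, ">="),
        list("max_free_energy", mfeVal, criteria@maxFreeEnergy, "<="),
        list("min_hairpin_len", hairpinLen, criteria@minHairpinLen, ">="),
        list("max_terminal_loop", terminalLoop,
            criteria@maxTerminalLoop, "<="),
        list("max_errors_one_bulge_mature", matureMeasures$maxBulge,
            criteria@maxErrorsOneBulgeMature, "<="),
        list("max_biased_errors_one_bulge_mature",
            matureMeasures$maxBiasedBulge,
            criteria@maxBiasedErrorsOneBulgeMature, "<="),
        list("max_biased_bulges_mature", matureMeasures$nBiasedBulges,
            criteria@maxBiasedBulgesMature, "<="),
        list("min_mature_bp", matureMeasures$bp, criteria@minMatureBp,
            ">="),
        list("min_pm_stem_fraction", pm, criteria@minPmStemFraction,
            ">="),
        list("max_errors_mature", matureMeasures$errors,
            criteria@maxErrorsMature, "<="),
        list("min_total_reads", totalReads, criteria@minTotalReads,
            ">="),
        list("stringent_max_mfe", mfeVal, criteria@stringentMaxMfe,
            "<="),
        list("min_mfei", mfei, criteria@minMfei, ">=")
    )
    report <- data.frame(
        criterion = vapply(rows, `[[`, "", 1),
        value = vapply(rows, function(r) as.numeric(r[[2]] %||% NA),
            numeric(1)),
        threshold = vapply(rows, `[[`, numeric(1), 3),
        comparator = vapply(rows, `[[`, "", 4))
    report$pass <- !is.na(report$value) & ifelse(report$comparator == "<=",
        report$value <= report$threshold,
        report$value >= report$threshold)
    list(
        verdict = all(report$pass),
        report = report,
        measures = list(mfe = mfeVal, mfei = mfei, gcFraction = gc,
            stemBp = stemBp, terminalLoop = terminalLoop,
            hairpinLen = hairpinLen, hairpinSpan = c(iOut, jOut),
            loopSpan = c(iStar, jStar), pm = pm,
            totalReads = totalReads, mature = matureMeasures),
        matureSpan5p = m5,
        matureSpan3p = m3
    )
}

#' Detect a 5p/3p mature duplex with 2-nt 3' overhangs
#'
#' Searches the supporting tags on the two arms of an accepted hairpin
#' for the highest-count pair whose projection through the pair table
#' leaves exactly 2 unpaired nt at each 3' end -- the signature of DCL
#' processing.  Absence of a qualifying partner does not invalidate the
#' candidate; the duplex is corroborating evidence only.
#'
#' @param structure The window's \code{\linkS4class{SecondaryStructure}}.
#' @param tags Supporting-tag data frame as in
#'   \code{\link{evaluateHairpin}} (columns \code{start0}, \code{width},
#'   \code{count}, optionally \code{sequence}).
#' @param loopSpan 1-based \code{c(iStar, jStar)} innermost-pair span
#'   (from \code{evaluateHairpin} measures).
#' @return A list with \code{five_p}, \code{three_p} (row indices into
#'   \code{tags}), \code{overhangs} (both 2), and the tag spans; or
#'   \code{NULL} when no pair qualifies.
#' @export
detectDuplex <- function(structure, tags, loopSpan) {
    pt <- pairTable(structure)
    n <- length(pt)
    t1 <- tags$start0 + 1L
    t2 <- tags$start0 + tags$width
    is5p <- t2 <= loopSpan[1]
    is3p <- t1 >= loopSpan[2]
    if (!any(is5p) || !any(is3p)) return(NULL)

    # partner of a position, projected through the nearest paired
    # position at or after it (offset-corrected)
    project <- function(pos, dir) {
        p <- pos
        while (p >= 1L && p <= n && pt[p] == 0L) p <- p + dir
        if (p < 1L || p > n) return(NA_integer_)
        pt[p] + dir * (p - pos)
    }
    cand <- expand.grid(i5 = which(is5p), i3 = which(is3p))
    cand$count <- tags$count[cand$i5] + tags$count[cand$i3]
    cand <- cand[order(-cand$count, cand$i5, cand$i3), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
        i5 <- cand$i5[r]; i3 <- cand$i3[r]
        # 3' overhang of the 5p strand: its 3' end extends past the
        # partner of the 3p strand's 5' end
        o1 <- t2[i5] - project(t1[i3], +1L)
        o2 <- t2[i3] - project(t1[i5], +1L)
        if (!is.na(o1) && !is.na(o2) && o1 == 2L && o2 == 2L) {
            return(list(five_p = i5, three_p = i3,
                span5p = c(t1[i5], t2[i5]), span3p = c(t1[i3], t2[i3]),
                overhangs = c(2L, 2L)))
        }
    }
    NULL
}

# stem-loop substructures of a fold: for every terminal loop, the
# maximal chain of enclosing pairs each of which encloses only that
# hairpin (optionally capped at maxSpan nt); returns a list of 1-based
# c(iOut, jOut) spans
.hairpinSpans <- function(pt, maxSpan = Inf) {
    n <- length(pt)
    closing <- which(pt > seq_len(n))
    if (!length(closing)) return(list())
    parent <- rep(NA_integer_, n)
    nChildren <- rep(0L, n)
    stack <- integer(0)
    for (i in seq_len(n)) {
        if (pt[i] > i) {
            if (length(stack)) {
                parent[i] <- stack[length(stack)]
                nChildren[stack[length(stack)]] <-
                    nChildren[stack[length(stack)]] + 1L
            }
            stack <- c(stack, i)
        } else if (pt[i] > 0L && pt[i] < i) {
            stack <- stack[-length(stack)]
        }
    }
    terminal <- closing[nChildren[closing] == 0L]
    lapply(terminal, function(i) {
        while (!is.na(parent[i]) && nChildren[parent[i]] == 1L &&
               pt[parent[i]] - parent[i] + 1L <= maxSpan)
            i <- parent[i]
        c(i, pt[i])
    })
}

#' Discover hairpin precursors from alignments
#'
#' For every alignment, excises the candidate-window ladder and folds
#' each distinct window.  Each stem-loop substructure of a window fold
#' that contains supporting tags is excised as a candidate precursor,
#' refolded on its own, and evaluated against the full hairpin criteria;
#' overlapping accepted candidates are deduplicated keeping the
#' lowest-MFE precursor.
#'
#' @param tags A \code{\linkS4class{TagSet}} (mapped tags).
#' @param alignments \code{GRanges} from \code{\link{mapTags}}.
#' @param genome \code{DNAStringSet} of contigs.
#' Since a perfect inverted repeat is a hairpin on both strands,
#' deduplication ignores strand; ties on MFE keep the first candidate
#' encountered (deterministic ordering).
#'
#' @param criteria A \code{\linkS4class{HairpinCriteria}}.
#' @param maxFlank Window-ladder bound (default 250 nt).
#' @param maxPrecursorLen Cap on the excised precursor length in nt
#'   (default 264, the upper end of known plant precursor lengths).
#' @return A list of accepted candidates; each holds \code{seqnames},
#'   \code{start}, \code{end}, \code{strand} (1-based window and
#'   precursor coordinates), \code{precursorSeq}, \code{structure},
#'   \code{evaluation} (from \code{\link{evaluateHairpin}}),
#'   \code{tags} (supporting-tag data frame with window offsets) and
#'   \code{duplex} (from \code{\link{detectDuplex}}, possibly NULL).
#' @export
discoverHairpins <- function(tags, alignments, genome,
                             criteria = hairpinCriteria(),
                             maxFlank = 250, maxPrecursorLen = 264) {
    if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
    contigLen <- setNames(Biostrings::width(genome),
        names(genome) %||% paste0("contig_", seq_along(genome)))
    counts <- rowSums(tagCounts(tags))
    tagTotal <- setNames(counts, as.character(tagSequences(tags)))
    if (length(alignments) == 0) return(list())

    alnDf <- data.frame(
        seqnames = as.character(GenomicRanges::seqnames(alignments)),
        start = GenomicRanges::start(alignments),
        end = GenomicRanges::end(alignments),
        strand = as.character(GenomicRanges::strand(alignments)),
        tag = S4Vectors::mcols(alignments)$tag)

    # window ladder over all alignments, deduplicated
    winKey <- character(0)
    windows <- list()
    for (r in seq_len(nrow(alnDf))) {
        ws <- extractCandidateWindows(alignments[r],
            contigLen[[alnDf$seqnames[r]]], maxFlank = maxFlank)
        for (w in seq_along(ws)) {
            key <- paste(alnDf$seqnames[r],
                GenomicRanges::start(ws)[w], GenomicRanges::end(ws)[w],
                alnDf$strand[r])
            if (key %in% winKey) next
            winKey <- c(winKey, key)
            windows[[length(windows) + 1L]] <- list(
                seqnames = alnDf$seqnames[r],
                start = GenomicRanges::start(ws)[w],
                end = GenomicRanges::end(ws)[w],
                strand = alnDf$strand[r])
        }
    }

    # stage 1: fold windows, excise stem-loop spans holding tags
    foldCache <- new.env(hash = TRUE, parent = emptyenv())
    winFold <- function(rseq) {
        st <- foldCache[[rseq]] %||% foldRNA(rseq)
        foldCache[[rseq]] <- st
        st
    }
    windowSeq <- function(seqname, start, end, strand) {
        gseq <- as.character(Biostrings::subseq(
            genome[[seqname]], start, end))
        if (strand == "-") gseq <- .revcompDNA(gseq)
        .asRNA(gseq)
    }
    supportIn <- function(seqname, start, end, strand) {
        sup <- alnDf[alnDf$seqnames == seqname & alnDf$strand == strand &
            alnDf$start >= start & alnDf$end <= end, , drop = FALSE]
        if (nrow(sup) == 0) return(sup)
        start0 <- if (strand == "+") sup$start - start else end - sup$end
        out <- data.frame(sequence = sup$tag, start0 = start0,
            width = sup$end - sup$start + 1L,
            count = unname(tagTotal[sup$tag]))
        out[!duplicated(out[c("sequence", "start0")]), , drop = FALSE]
    }
    precKeys <- character(0)
    precursors <- list()
    for (w in windows) {
        supTags <- supportIn(w$seqnames, w$start, w$end, w$strand)
        if (nrow(supTags) == 0) next
        st <- winFold(windowSeq(w$seqnames, w$start, w$end, w$strand))
        for (span in .hairpinSpans(pairTable(st),
                maxSpan = maxPrecursorLen)) {
            if (span[2] - span[1] + 1L < 50L) next
            inSpan <- supTags$start0 + 1L >= span[1] &
                supTags$start0 + supTags$width <= span[2]
            if (!any(inSpan)) next
            # back to genomic coordinates of the excised precursor
            if (w$strand == "+") {
                ps <- w$start + span[1] - 1L
                pe <- w$start + span[2] - 1L
            } else {
                ps <- w$end - span[2] + 1L
                pe <- w$end - span[1] + 1L
            }
            key <- paste(w$seqnames, ps, pe, w$strand)
            if (key %in% precKeys) next
            precKeys <- c(precKeys, key)
            precursors[[length(precursors) + 1L]] <- list(
                seqnames = w$seqnames, start = ps, end = pe,
                strand = w$strand)
        }
    }

    # stage 2: refold each excised precursor and apply the criteria
    accepted <- list()
    for (p in precursors) {
        supTags <- supportIn(p$seqnames, p$start, p$end, p$strand)
        if (nrow(supTags) == 0) next
        rseq <- windowSeq(p$seqnames, p$start, p$end, p$strand)
        st <- winFold(rseq)
        ev <- evaluateHairpin(st, supTags, criteria)
        if (!ev$verdict) next
        dup <- detectDuplex(st, supTags, ev$measures$loopSpan)
        accepted[[length(accepted) + 1L]] <- list(
            seqnames = p$seqnames, start = p$start, end = p$end,
            strand = p$strand, precursorSeq = rseq, structure = st,
            evaluation = ev, tags = supTags, duplex = dup,
            mfe = ev$measures$mfe, mfei = ev$measures$mfei)
    }
    if (!length(accepted)) return(list())

    # dedupe overlapping accepted candidates: keep lowest MFE
    ord <- order(vapply(accepted, `[[`, numeric(1), "mfe"))
    kept <- list()
    occupied <- GenomicRanges::GRanges()
    for (k in ord) {
        a <- accepted[[k]]
        gr <- GenomicRanges::GRanges(a$seqnames,
            IRanges::IRanges(a$start, a$end), strand = a$strand)
        if (length(occupied) == 0 ||
            !any(IRanges::overlapsAny(gr, occupied,
                ignore.strand = TRUE))) {
            kept[[length(kept) + 1L]] <- a
            occupied <- c(occupied, gr)
        }
    }
    kept
}
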