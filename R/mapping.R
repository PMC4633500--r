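#' Build an exact seed index over a genome
#'
#' Indexes every \code{seedLength}-mer of both strands of the genome for
#' seed-and-verify tag mapping.  Contigs shorter than the seed length are
#' skipped with a warning.
#'
#' @param genome A \code{\link[Biostrings]{DNAStringSet}} (or named
#'   character vector) of contigs.
#' @param seedLength Seed length in nt; mismatches are only permitted
#'   within the first \code{seedLength} positions of a tag (default 16).
#' @return A \code{\linkS4class{GenomeIndex}}.
#' @examples
#' gi <- buildGenomeIndex(Biostrings::DNAStringSet(c(chr1 =
#'     paste(rep("ACGT", 25), collapse = ""))))
#' gi
#' @export
buildGenomeIndex <- function(genome, seedLength = 16) {
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(genome)
    if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0)
        stop("genome is empty")
    seedLength <- as.integer(seedLength)
    lens <- Biostrings::width(genome)
    short <- lens < seedLength
    if (any(short)) {
        warning("skipping ", sum(short), " contig(s) shorter than the seed")
        genome <- genome[!short]
        lens <- lens[!short]
        if (length(genome) == 0)
            stop("no contig is at least as long as the seed")
    }
    nm <- names(genome) %||% paste0("contig_", seq_along(genome))
    fwd <- as.character(genome)
    rev <- .revcompDNA(fwd)
    allK <- character(0); allC <- integer(0); allS <- integer(0)
    allP <- integer(0)
    for (ci in seq_along(fwd)) {
        for (strand in 1:2) {
            s <- if (strand == 1) fwd[ci] else rev[ci]
            np <- lens[ci] - seedLength + 1L
            starts <- seq_len(np)
            allK <- c(allK, substring(s, starts, starts + seedLength - 1L))
            allC <- c(allC, rep.int(ci, np))
            allS <- c(allS, rep.int(strand, np))
            allP <- c(allP, starts - 1L)
        }
    }
    packed <- split(seq_along(allK), allK)
    env <- new.env(hash = TRUE, parent = emptyenv(),
        size = length(packed))
    for (k in names(packed)) {
        idx <- packed[[k]]
        assign(k, rbind(allC[idx], allS[idx], allP[idx]), envir = env)
    }
    new("GenomeIndex", kmers = env, seedLength = seedLength,
        seqs = list(fwd = fwd, rev = rev), seqnames = nm,
        seqlengths = as.integer(lens),
        nForwardSeeds = sum(lens - seedLength + 1L))
}

# all single-substitution variants of the seed plus the seed itself
.seedVariants <- function(seed) {
    bases <- c("A", "C", "G", "T")
    chars <- strsplit(seed, "")[[1]]
    out <- seed
    for (i in seq_along(chars)) {
        for (b in bases[bases != chars[i]]) {
            v <- chars
            v[i] <- b
            out <- c(out, paste(v, collapse = ""))
        }
    }
    out
}

#' Map a tag to the genome under the seed mismatch rule
#'
#' Reports all ungapped alignments of a tag, on both strands, with at
#' most one mismatch restricted to the first \code{seedLength} (16)
#' positions of the tag and no mismatches beyond them.  Tags with no
#' alignment are unmapped.
#'
#' @param tag A single tag sequence (RNA or DNA alphabet), 18--25 nt.
#' @param index A \code{\linkS4class{GenomeIndex}}.
#' @return A \code{\link[GenomicRanges]{GRanges}} of alignments with
#'   metadata columns \code{tag} and \code{mismatch_positions} (comma-
#'   separated 0-based offsets within the tag; empty when exact).
#' @export
mapTag <- function(tag, index) {
    stopifnot(is(index, "GenomeIndex"))
    tag <- .asDNA(tag)
    n <- nchar(tag)
    if (n < 18 || n > 25)
        stop("tag length must lie in [18, 25]")
    if (grepl("[^ACGT]", tag))
        stop("tag contains characters outside ACGU/T")
    sl <- index@seedLength
    tcodes <- .seqCodes(tag)
    hits <- list()
    seen <- character(0)
    for (variant in .seedVariants(substr(tag, 1, sl))) {
        occ <- get0(variant, envir = index@kmers)
        if (is.null(occ)) next
        for (col in seq_len(ncol(occ))) {
            ci <- occ[1, col]; strand <- occ[2, col]; p0 <- occ[3, col]
            key <- paste(ci, strand, p0)
            if (key %in% seen) next
            seen <- c(seen, key)
            clen <- index@seqlengths[ci]
            if (p0 + n > clen) next
            s <- if (strand == 1) index@seqs$fwd[ci] else index@seqs$rev[ci]
            sub <- substr(s, p0 + 1, p0 + n)
            mm <- which(.seqCodes(sub) != tcodes) - 1L
            if (length(mm) > 1 || any(mm >= sl)) next
            startFwd0 <- if (strand == 1) p0 else clen - (p0 + n)
            hits[[length(hits) + 1L]] <- list(ci = ci,
                strand = if (strand == 1) "+" else "-",
                start0 = startFwd0, mm = mm)
        }
    }
    if (length(hits) == 0)
        return(.emptyAlignments())
    gr <- GenomicRanges::GRanges(
        seqnames = factor(
            index@seqnames[vapply(hits, `[[`, 1L, "ci")],
            levels = index@seqnames),
        ranges = IRanges::IRanges(
            start = vapply(hits, `[[`, 1L, "start0") + 1L, width = n),
        strand = vapply(hits, `[[`, "", "strand"),
        tag = .asRNA(tag),
        mismatch_positions = vapply(hits,
            function(h) paste(h$mm, collapse = ","), ""))
    sort(gr, ignore.strand = TRUE)
}

#' Map all tags of a TagSet
#'
#' Applies \code{\link{mapTag}} to every tag and updates tag categories
#' to \code{mapped}/\code{unmapped} (tags already assigned an ncRNA
#' category are left untouched).
#'
#' @param tags A \code{\linkS4class{TagSet}}.
#' @param index A \code{\linkS4class{GenomeIndex}}.
#' @return A list with \code{alignments} (a \code{GRanges} with
#'   \code{tag} metadata) and \code{tags} (the recategorized
#'   \code{TagSet}).
#' @export
mapTags <- function(tags, index) {
    seqs <- as.character(tagSequences(tags))
    grl <- lapply(seqs, mapTag, index = index)
    mapped <- vapply(grl, function(g) length(g) > 0, logical(1))
    cat0 <- tagCategory(tags)
    untouched <- cat0 %in% c("unassigned", "mapped", "unmapped")
    cat0[untouched] <- ifelse(mapped[untouched], "mapped", "unmapped")
    tagCategory(tags) <- cat0
    aln <- suppressWarnings(do.call(c, grl[mapped]))
    if (is.null(aln))
        aln <- .emptyAlignments()
    list(alignments = aln, tags = tags)
}

.emptyAlignments <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        tag = character(0), mismatch_positions = character(0))
    gr
}
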