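#' Trim the 3' sequencing adaptor from reads
#'
#' Returns, for each read, the prefix preceding the leftmost occurrence
#' of the 3' adaptor whose overlap with the read is at least
#' \code{minOverlap} nt and whose mismatch fraction over the overlap is
#' at most \code{maxMismatchRate}; reads with no such occurrence are
#' rejected (\code{NA}), the insert being presumed longer than the read.
#'
#' @param reads Character vector of read sequences (DNA alphabet).
#' @param adaptor3p The 3' adaptor sequence.
#' @param minOverlap Minimum read/adaptor overlap in nt (>= 6).
#' @param maxMismatchRate Maximum mismatch fraction over the overlap.
#' @return Character vector of inserts, \code{NA} where rejected.
#' @examples
#' trimAdaptor("ACGTACGTACGTACGTACGTATCGTATGCCG", "TCGTATGCCG")
#' @export
trimAdaptor <- function(reads, adaptor3p, minOverlap = 6,
                        maxMismatchRate = 0.1) {
    if (length(reads) == 0) return(character(0))
    if (any(!nzchar(reads)) || anyNA(reads))
        stop("empty read")
    if (length(adaptor3p) != 1 || !nzchar(adaptor3p))
        stop("empty adaptor")
    if (minOverlap < 6)
        stop("minOverlap must be at least 6")
    reads <- .asDNA(reads)
    adaptor3p <- .asDNA(adaptor3p)
    la <- nchar(adaptor3p)
    acodes <- .seqCodes(adaptor3p)
    out <- rep(NA_character_, length(reads))
    for (len in sort(unique(nchar(reads)))) {
        sel <- which(nchar(reads) == len & is.na(out))
        if (!length(sel)) next
        grp <- reads[sel]
        m <- matrix(utf8ToInt(paste(grp, collapse = "")), ncol = len,
            byrow = TRUE)
        resolved <- rep(FALSE, length(grp))
        for (p in seq_len(len)) {
            ov <- min(la, len - p + 1L)
            if (ov < minOverlap) break
            cols <- p:(p + ov - 1L)
            mism <- rowSums(m[, cols, drop = FALSE] !=
                matrix(acodes[seq_len(ov)], nrow = nrow(m), ncol = ov,
                    byrow = TRUE))
            ok <- !resolved & (mism / ov) <= maxMismatchRate
            if (any(ok)) {
                out[sel[ok]] <- substr(grp[ok], 1L, p - 1L)
                resolved <- resolved | ok
            }
            if (all(resolved)) break
        }
    }
    out[!is.na(out) & !nzchar(out)] <- NA_character_   # adaptor at pos 1
    out
}

#' Filter inserts on length and mean base quality
#'
#' Keeps inserts whose length lies in \code{[minLen, maxLen]} and, when
#' quality strings are supplied, whose mean Phred score reaches
#' \code{minMeanQuality}.  Kept and rejected reads partition the input.
#'
#' @param inserts Character vector of insert sequences.
#' @param minLen,maxLen Length bounds in nt (defaults 18 and 25).
#' @param minMeanQuality Minimum mean Phred score (default 20).
#' @param qualities Optional character vector of Phred+33 quality strings
#'   (trimmed to the insert lengths by the caller).
#' @return List with \code{kept} (inserts), \code{keptQualities},
#'   \code{rejects} (named counts by reason: \code{length},
#'   \code{quality}).
#' @export
filterReads <- function(inserts, minLen = 18, maxLen = 25,
                        minMeanQuality = 20, qualities = NULL) {
    if (minLen <= 0 || maxLen <= 0 || minMeanQuality < 0)
        stop("thresholds must be positive")
    if (length(inserts) == 0)
        return(list(kept = character(0), keptQualities = character(0),
            rejects = c(length = 0L, quality = 0L)))
    len <- nchar(inserts)
    lenOK <- len >= minLen & len <= maxLen
    qualOK <- rep(TRUE, length(inserts))
    if (!is.null(qualities))
        qualOK[lenOK] <- .meanPhred(substr(qualities[lenOK], 1L,
            len[lenOK])) >= minMeanQuality
    keep <- lenOK & qualOK
    list(
        kept = inserts[keep],
        keptQualities = if (is.null(qualities)) character(0)
            else substr(qualities[keep], 1L, len[keep]),
        rejects = c(length = sum(!lenOK),
            quality = sum(lenOK & !qualOK))
    )
}

#' Collapse filtered inserts into unique tags
#'
#' One tag per distinct sequence across all libraries, with per-library
#' read counts; per-library counts sum to the per-library input sizes.
#' T/U is normalized to the RNA alphabet.
#'
#' @param insertsPerLibrary Named list of character vectors, one per
#'   library.
#' @return A \code{\linkS4class{TagSet}}.
#' @examples
#' collapseReads(list(leaf = c("ACGUACGUACGUACGUACG", "ACGUACGUACGUACGUACG")))
#' @export
collapseReads <- function(insertsPerLibrary) {
    stopifnot(is.list(insertsPerLibrary), length(insertsPerLibrary) >= 1)
    libs <- names(insertsPerLibrary) %||%
        paste0("library_", seq_along(insertsPerLibrary))
    norm <- lapply(insertsPerLibrary, .asRNA)
    all <- sort(unique(unlist(norm, use.names = FALSE)))
    counts <- vapply(norm, function(x) {
        tb <- table(factor(x, levels = all))
        as.integer(tb)
    }, integer(length(all)))
    if (is.null(dim(counts)))
        counts <- matrix(counts, nrow = length(all))
    colnames(counts) <- libs
    TagSet(all, counts)
}

.NCRNA_PRIORITY <- c("rRNA", "tRNA", "snoRNA", "snRNA")

#' Partition tags by annotated non-miRNA small-RNA classes
#'
#' A tag is assigned the category of the first annotation sequence that
#' contains it as an exact substring, scanning categories in the fixed
#' priority order rRNA, tRNA, snoRNA, snRNA; remaining tags pass through
#' unassigned.  Annotated tags are removed from the miRNA-bound set, as
#' small RNAs mapping to these classes are discarded before genome
#' mapping.
#'
#' @param tags A \code{\linkS4class{TagSet}}.
#' @param annotation A named list mapping category (subset of rRNA, tRNA,
#'   snoRNA, snRNA) to a character vector or
#'   \code{\link[Biostrings]{DNAStringSet}} of annotated sequences.
#' @return List with \code{kept} (unassigned \code{TagSet}),
#'   \code{removed} (annotated \code{TagSet}, or \code{NULL} when
#'   empty), \code{all} (the full recategorized \code{TagSet}) and
#'   \code{summary} (per-category redundant/unique tallies).
#' @export
filterAnnotated <- function(tags, annotation) {
    stopifnot(is(tags, "TagSet"))
    if (!all(names(annotation) %in% .NCRNA_PRIORITY))
        stop("annotation categories must be among: ",
            paste(.NCRNA_PRIORITY, collapse = ", "))
    cat <- tagCategory(tags)
    seqs <- .asDNA(as.character(tagSequences(tags)))
    for (cls in intersect(.NCRNA_PRIORITY, names(annotation))) {
        subjects <- .asDNA(as.character(annotation[[cls]]))
        open <- which(cat == "unassigned")
        if (!length(open)) break
        hay <- paste(subjects, collapse = "#")
        hit <- open[vapply(seqs[open], function(s)
            grepl(s, hay, fixed = TRUE), logical(1))]
        cat[hit] <- cls
    }
    tagCategory(tags) <- cat
    annotated <- cat %in% .NCRNA_PRIORITY
    tallies <- vapply(.NCRNA_PRIORITY, function(cls) {
        sel <- cat == cls
        c(redundant = sum(tagCounts(tags)[sel, , drop = FALSE]),
          unique = sum(sel))
    }, numeric(2))
    list(
        kept = tags[!annotated],
        removed = if (any(annotated)) tags[annotated] else NULL,
        all = tags,
        summary = data.frame(category = .NCRNA_PRIORITY,
            redundant = tallies["redundant", ],
            unique = tallies["unique", ], row.names = NULL)
    )
}

#' Length distribution of tags, redundant and unique
#'
#' Per-library percentage of reads (redundant) and of distinct tags
#' (unique) at each length 18--25 nt; every library column sums to 100.
#'
#' @param tags A \code{\linkS4class{TagSet}}.
#' @return A long-format data frame with columns \code{library},
#'   \code{length}, \code{redundant_pct}, \code{unique_pct}.  Empty
#'   input yields an empty data frame.
#' @export
lengthDistribution <- function(tags) {
    stopifnot(is(tags, "TagSet"))
    if (length(tags) == 0)
        return(data.frame(library = character(0), length = integer(0),
            redundant_pct = numeric(0), unique_pct = numeric(0)))
    lens <- 18:25
    libs <- libraryNames(tags)
    w <- tagLength(tags)
    counts <- tagCounts(tags)
    out <- do.call(rbind, lapply(libs, function(lib) {
        cl <- counts[, lib]
        red <- vapply(lens, function(L) sum(cl[w == L]), numeric(1))
        uni <- vapply(lens, function(L) sum(w == L & cl > 0), numeric(1))
        data.frame(library = lib, length = lens,
            redundant_pct = if (sum(red) > 0) 100 * red / sum(red)
                else rep(0, length(lens)),
            unique_pct = if (sum(uni) > 0) 100 * uni / sum(uni)
                else rep(0, length(lens)))
    }))
    rownames(out) <- NULL
    out
}
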