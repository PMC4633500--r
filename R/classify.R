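#' Match a mature sequence against a reference miRNA catalogue
#'
#' Scans all ungapped placements in which the shorter of query and
#' reference is fully contained in the longer, with overlap at least
#' \code{minOverlap} nt, and returns the best match: minimum mismatch
#' count, ties broken by longer overlap then lexicographically smallest
#' reference id.  U/T is normalized before comparison.
#'
#' @param query Mature sequence (RNA or DNA alphabet).
#' @param referenceSet Named character vector or
#'   \code{\link[Biostrings]{RNAStringSet}} of reference matures.
#' @param maxMismatches Maximum mismatches for a reportable match
#'   (default 2).
#' @param minOverlap Minimum containment overlap in nt (default 16).
#' @return List with \code{reference_id} and \code{mismatches}, or
#'   \code{NULL} when no placement qualifies.
#' @examples
#' matchReference("UGACAGAAGAGAGUGAGCAC",
#'     c(`osa-miR156a` = "UGACAGAAGAGAGUGAGCAC"))
#' @export
matchReference <- function(query, referenceSet, maxMismatches = 2,
                           minOverlap = 16) {
    refs <- .asRNA(as.character(referenceSet))
    ids <- names(referenceSet)
    if (length(refs) == 0) stop("reference set is empty")
    if (is.null(ids)) stop("reference set must be named")
    query <- .asRNA(query)
    best <- NULL
    for (k in seq_along(refs)) {
        ov <- min(nchar(query), nchar(refs[k]))
        if (ov < minOverlap) next
        mm <- .minContainDist(query, refs[k])
        if (mm > maxMismatches) next
        if (is.null(best) || mm < best$mismatches ||
            (mm == best$mismatches && (ov > best$overlap ||
                (ov == best$overlap && ids[k] < best$reference_id)))) {
            best <- list(reference_id = ids[k], mismatches = mm,
                overlap = ov)
        }
    }
    if (is.null(best)) return(NULL)
    best[c("reference_id", "mismatches")]
}

#' Classify a mature miRNA as conserved, variant, novel or discarded
#'
#' Exact reference matches are conserved; matches within the variant
#' band (1--2 mismatches by default; a 1--3 band is available via
#' \code{variantMaxMismatches = 3}) are variants; unmatched sequences
#' with at least \code{minNovelReads} total reads from a
#' criteria-passing precursor are novel; unmatched sequences below the
#' read floor are discarded.
#'
#' @param matureSeq Mature sequence (RNA alphabet).
#' @param totalReads Total reads over all libraries.
#' @param match Result of \code{\link{matchReference}} (or \code{NULL}).
#' @param arm \code{"5p"}, \code{"3p"} or \code{"unknown"}.
#' @param variantMaxMismatches Upper edge of the variant band (2 or 3).
#' @param minNovelReads Read floor for novel annotation (default 10).
#' @return List with \code{class}, \code{reference_match},
#'   \code{mismatches}, \code{family}, \code{arm}.
#' @export
classifyMirna <- function(matureSeq, totalReads, match, arm = "unknown",
                          variantMaxMismatches = 2, minNovelReads = 10) {
    stopifnot(variantMaxMismatches %in% c(2, 3))
    if (!is.null(match) && match$mismatches <= variantMaxMismatches) {
        cls <- if (match$mismatches == 0) "conserved" else "variant"
        return(list(class = cls, reference_match = match$reference_id,
            mismatches = match$mismatches,
            family = assignFamily(match$reference_id), arm = arm))
    }
    if (totalReads >= minNovelReads)
        return(list(class = "novel", reference_match = NA_character_,
            mismatches = NA_integer_, family = NA_character_,
            arm = arm))
    list(class = "discarded", reference_match = NA_character_,
        mismatches = NA_integer_, family = NA_character_, arm = arm)
}

#' miRNA family from a miRBase-style identifier
#'
#' The family is \code{"miR"} plus the leading digits of the numeric
#' field; suffix letters and arm labels are stripped
#' (\code{osa-miR156a-5p} and \code{pda-MIR156h-p3} both give
#' \code{miR156}).
#'
#' @param referenceId miRBase-style id
#'   (\code{species-miRNNN[letter][-arm]}).
#' @return Family name, or \code{NA} with a warning when unparseable.
#' @export
assignFamily <- function(referenceId) {
    if (is.na(referenceId) ||
        !grepl("[mM][iI][rR]-?[0-9]+", referenceId)) {
        warning("cannot parse miRNA family from id: ", referenceId)
        return(NA_character_)
    }
    m <- regmatches(referenceId,
        regexpr("[mM][iI][rR]-?([0-9]+)", referenceId))
    paste0("miR", gsub("[^0-9]", "", m))
}

#' Classify all accepted precursor candidates
#'
#' Applies \code{\link{matchReference}} and \code{\link{classifyMirna}}
#' to the mature sequence(s) of every accepted candidate from
#' \code{\link{discoverHairpins}}, assigns novel serial names of the
#' form \code{prefix-{5p|3p}-{serial}_{totalreads}}, and links duplex
#' partners.
#'
#' @param candidates List of accepted candidates
#'   (\code{\link{discoverHairpins}}).
#' @param tags The mapped \code{\linkS4class{TagSet}} (for per-library
#'   counts).
#' @param referenceSet Named reference mature catalogue.
#' @param prefix Species prefix for novel names (default \code{"pda"}).
#' @param variantMaxMismatches Variant band edge (2, the default, or 3).
#' @param minNovelReads Read floor for novel annotation (default 10).
#' @return A data frame with one row per annotated mature: mirna_id,
#'   mature_seq, arm, class, reference_match, mismatches, family,
#'   duplex_partner, total_reads, precursor coordinates, mfe, mfei.
#' @export
classifyCandidates <- function(candidates, tags, referenceSet,
                               prefix = "pda", variantMaxMismatches = 2,
                               minNovelReads = 10) {
    rows <- list()
    serial <- 0L
    for (ci in seq_along(candidates)) {
        cand <- candidates[[ci]]
        dup <- cand$duplex
        matureIdx <- list()
        if (!is.null(dup)) {
            matureIdx <- list(`5p` = dup$five_p, `3p` = dup$three_p)
        } else {
            ev <- cand$evaluation
            spans <- list(`5p` = ev$matureSpan5p, `3p` = ev$matureSpan3p)
            for (arm in names(spans)) {
                sp <- spans[[arm]]
                if (is.null(sp)) next
                hit <- which(cand$tags$start0 + 1L == sp[1] &
                    cand$tags$start0 + cand$tags$width == sp[2])
                if (length(hit)) matureIdx[[arm]] <- hit[1]
            }
        }
        ids <- character(0)
        for (arm in names(matureIdx)) {
            k <- matureIdx[[arm]]
            seqk <- cand$tags$sequence[k]
            totalReads <- cand$tags$count[k]
            match <- matchReference(seqk, referenceSet,
                maxMismatches = variantMaxMismatches)
            cl <- classifyMirna(seqk, totalReads, match, arm = arm,
                variantMaxMismatches = variantMaxMismatches,
                minNovelReads = minNovelReads)
            if (cl$class == "discarded") {
                ids[arm] <- NA_character_
                next
            }
            if (cl$class == "novel") {
                serial <- serial + 1L
                id <- sprintf("%s-%s-%d_%d", prefix, arm, serial,
                    totalReads)
            } else {
                id <- cl$reference_match
            }
            ids[arm] <- id
            rows[[length(rows) + 1L]] <- data.frame(
                mirna_id = id, mature_seq = seqk, arm = arm,
                class = cl$class,
                reference_match = cl$reference_match %||% NA_character_,
                mismatches = cl$mismatches %||% NA_integer_,
                family = cl$family %||% NA_character_,
                duplex_partner = NA_character_,
                total_reads = totalReads,
                candidate = ci,
                seqnames = cand$seqnames, start = cand$start,
                end = cand$end, strand = cand$strand,
                mfe = cand$mfe, mfei = cand$mfei)
        }
        if (!is.null(dup) && length(ids) == 2 && !anyNA(ids)) {
            for (r in seq_along(rows)) {
                if (rows[[r]]$candidate == ci) {
                    other <- setdiff(c("5p", "3p"), rows[[r]]$arm)
                    rows[[r]]$duplex_partner <- ids[[other]]
                }
            }
        }
    }
    if (!length(rows))
        return(data.frame(mirna_id = character(0),
            mature_seq = character(0), arm = character(0),
            class = character(0), reference_match = character(0),
            mismatches = integer(0), family = character(0),
            duplex_partner = character(0), total_reads = integer(0),
            candidate = integer(0), seqnames = character(0),
            start = integer(0), end = integer(0), strand = character(0),
            mfe = numeric(0), mfei = numeric(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-library presence sets and their intersections
#'
#' A miRNA is present in a library when its count reaches
#' \code{minCount}.  Returns per-library presence, all pairwise
#' intersection counts and the common (all-library) intersection; the
#' counts satisfy inclusion-exclusion by construction.
#'
#' @param counts Count matrix (miRNAs x libraries, >= 2 libraries).
#' @param minCount Presence threshold (default 1).
#' @return List with \code{presence} (logical matrix),
#'   \code{perLibrary} (named counts), \code{pairwise} (matrix of
#'   intersection counts) and \code{commonAll}.
#' @export
presenceSets <- function(counts, minCount = 1) {
    stopifnot(ncol(counts) >= 2)
    pres <- counts >= minCount
    libs <- colnames(counts)
    pw <- matrix(0L, ncol(counts), ncol(counts),
        dimnames = list(libs, libs))
    for (i in seq_along(libs))
        for (j in seq_along(libs))
            pw[i, j] <- sum(pres[, i] & pres[, j])
    list(presence = pres,
        perLibrary = colSums(pres),
        pairwise = pw,
        commonAll = sum(rowSums(pres) == ncol(counts)))
}
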