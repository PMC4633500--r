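#' Target-scan parameter set
#'
#' Defaults mirror a psRNAtarget-style configuration: hits are reported
#' up to a maximum expectation of 3; the complementarity window
#' (hspsize) is 20; site context is extracted with 17 nt upstream and
#' 13 nt downstream flanks; a non-Watson-Crick position within miRNA
#' positions 9--11 signals translational inhibition.  The target-site
#' unpairing energy bound (UPE 25) is recorded for provenance but never
#' computed or filtered on -- accessibility analysis is out of scope.
#'
#' @param maxExpectation Maximum reported expectation (default 3).
#' @param hspSize Complementarity-scoring window (default 20; recorded).
#' @param flankUp,flankDown Context flanks in nt (defaults 17 and 13).
#' @param centralWindow 1-based miRNA positions whose non-WC pairing
#'   flips the mode to translation (default 9:11).
#' @param upeMax Recorded accessibility bound (default 25; unused).
#' @param weightWC,weightGU,weightMismatch,weightGap Per-position
#'   penalties (defaults 0, 0.5, 1, 2).
#' @param doubledBand 1-based miRNA positions with doubled penalties
#'   (default 2:13).
#' @return A named list of parameters.
#' @export
targetParams <- function(maxExpectation = 3, hspSize = 20, flankUp = 17,
                         flankDown = 13, centralWindow = 9:11,
                         upeMax = 25, weightWC = 0, weightGU = 0.5,
                         weightMismatch = 1, weightGap = 2,
                         doubledBand = 2:13) {
    stopifnot(maxExpectation >= 0)
    list(maxExpectation = maxExpectation, hspSize = hspSize,
        flankUp = flankUp, flankDown = flankDown,
        centralWindow = centralWindow, upeMax = upeMax,
        weightWC = weightWC, weightGU = weightGU,
        weightMismatch = weightMismatch, weightGap = weightGap,
        doubledBand = doubledBand)
}

# per-position pairing states of miRNA (5'->3') against a site
# (transcript subsequence, 5'->3'): miRNA position k pairs the site
# position L - k + 1.  States: WC, GU, MM, gap.
.pairStates <- function(mirna, site) {
    lm <- nchar(mirna)
    ls <- nchar(site)
    L <- max(lm, ls)
    mc <- strsplit(mirna, "")[[1]]
    sc <- rev(strsplit(site, "")[[1]])   # site read 3'->5'
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    states <- character(L)
    for (k in seq_len(L)) {
        if (k > lm || k > ls) {
            states[k] <- "gap"
        } else if (sc[k] == comp[[mc[k]]]) {
            states[k] <- "WC"
        } else if ((mc[k] == "G" && sc[k] == "U") ||
                   (mc[k] == "U" && sc[k] == "G")) {
            states[k] <- "GU"
        } else {
            states[k] <- "MM"
        }
    }
    states
}

#' Score a miRNA against a candidate target site
#'
#' Aligns the miRNA (5' to 3') against the site's reverse complement,
#' position by position, without internal gaps (length differences are
#' end gaps).  Penalties: Watson-Crick 0, G:U wobble 0.5, mismatch 1,
#' gap 2, doubled at miRNA positions 2--13; the expectation is the
#' penalty total.  The mode is translation when at least one
#' non-Watson-Crick position falls in the central window (miRNA
#' positions 9--11), cleavage otherwise.
#'
#' @param mirna Mature miRNA sequence (5' to 3', RNA alphabet).
#' @param site Transcript site (5' to 3'), within 4 nt of the miRNA
#'   length.
#' @param params \code{\link{targetParams}}.
#' @return List with \code{expectation}, \code{mode} and \code{states}
#'   (per-position pairing states).
#' @examples
#' m <- "UGACAGAAGAGAGUGAGCAC"
#' scoreSite(m, as.character(
#'     Biostrings::reverseComplement(Biostrings::RNAString(m))))
#' @export
scoreSite <- function(mirna, site, params = targetParams()) {
    mirna <- .asRNA(mirna)
    site <- .asRNA(site)
    if (!nzchar(mirna) || !nzchar(site))
        stop("empty sequences")
    if (abs(nchar(site) - nchar(mirna)) > 4)
        stop("site length must be within 4 nt of the miRNA length")
    states <- .pairStates(mirna, site)
    w <- c(WC = params$weightWC, GU = params$weightGU,
        MM = params$weightMismatch, gap = params$weightGap)
    pen <- unname(w[states])
    doubled <- seq_along(states) %in% params$doubledBand
    pen[doubled] <- pen[doubled] * 2
    centralHit <- any(states[intersect(params$centralWindow,
        seq_along(states))] != "WC")
    list(expectation = sum(pen),
        mode = if (centralHit) "translation" else "cleavage",
        states = states)
}

#' Scan a transcript for target sites of one miRNA
#'
#' Slides a window of the miRNA's length along the transcript, scores
#' every placement with \code{\link{scoreSite}}, and reports
#' non-overlapping hits with expectation at or below the maximum,
#' selected greedily by ascending expectation with ties to the leftmost
#' site.  Context is the site extended by the upstream/downstream
#' flanks, clipped to the transcript.
#'
#' @param mirna Mature miRNA sequence.
#' @param transcript Transcript sequence (at least as long as the
#'   miRNA).
#' @param params \code{\link{targetParams}}.
#' @param mirnaId,transcriptId Labels carried into the hit table.
#' @return Data frame of hits: mirna_id, transcript_id, start0, end0
#'   (0-based half-open site span), expectation, mode, context.
#' @export
scanTranscript <- function(mirna, transcript, params = targetParams(),
                           mirnaId = "mirna",
                           transcriptId = "transcript") {
    mirna <- .asRNA(mirna)
    transcript <- .asRNA(transcript)
    L <- nchar(mirna)
    n <- nchar(transcript)
    if (n < L) stop("transcript is shorter than the miRNA")
    nPos <- n - L + 1L

    # vectorized per-placement penalty and central-window state
    tcode <- strsplit(transcript, "")[[1]]
    mc <- strsplit(mirna, "")[[1]]
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    expect <- numeric(nPos)
    central <- logical(nPos)
    for (k in seq_len(L)) {
        # miRNA position k pairs transcript position i + L - k
        tpos <- seq_len(nPos) + L - k
        tb <- tcode[tpos]
        wc <- tb == comp[[mc[k]]]
        gu <- (mc[k] == "G" & tb == "U") | (mc[k] == "U" & tb == "G")
        pen <- ifelse(wc, params$weightWC,
            ifelse(gu, params$weightGU, params$weightMismatch))
        if (k %in% params$doubledBand) pen <- pen * 2
        expect <- expect + pen
        if (k %in% params$centralWindow) central <- central | !wc
    }

    ok <- which(expect <= params$maxExpectation)
    ok <- ok[order(expect[ok], ok)]
    hits <- list()
    taken <- rep(FALSE, n)
    for (i in ok) {
        span <- i:(i + L - 1L)
        if (any(taken[span])) next
        taken[span] <- TRUE
        ctx <- substr(transcript, max(1L, i - params$flankUp),
            min(n, i + L - 1L + params$flankDown))
        hits[[length(hits) + 1L]] <- data.frame(
            mirna_id = mirnaId, transcript_id = transcriptId,
            start0 = i - 1L, end0 = i + L - 1L,
            expectation = expect[i],
            mode = if (central[i]) "translation" else "cleavage",
            context = ctx)
    }
    if (!length(hits))
        return(data.frame(mirna_id = character(0),
            transcript_id = character(0), start0 = integer(0),
            end0 = integer(0), expectation = numeric(0),
            mode = character(0), context = character(0)))
    out <- do.call(rbind, hits)
    out <- out[order(out$start0), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Predict targets for a set of miRNAs over a set of transcripts
#'
#' @param mirnas Named character vector or RNAStringSet of matures.
#' @param transcripts Named character vector or DNAStringSet/RNAStringSet
#'   of transcripts.
#' @param params \code{\link{targetParams}}.
#' @return Combined hit table from \code{\link{scanTranscript}}.
#' @export
predictTargets <- function(mirnas, transcripts,
                           params = targetParams()) {
    mseq <- .asRNA(as.character(mirnas))
    tseq <- .asRNA(as.character(transcripts))
    mids <- names(mirnas) %||% paste0("mirna_", seq_along(mseq))
    tids <- names(transcripts) %||% paste0("tx_", seq_along(tseq))
    out <- list()
    for (i in seq_along(mseq)) {
        for (j in seq_along(tseq)) {
            if (nchar(tseq[j]) < nchar(mseq[i])) next
            h <- scanTranscript(mseq[i], tseq[j], params,
                mirnaId = mids[i], transcriptId = tids[j])
            if (nrow(h)) out[[length(out) + 1L]] <- h
        }
    }
    if (!length(out)) return(scanTranscript(.asRNA("A"),
        .asRNA("A"))[0, ])
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Summarize a target-hit table
#'
#' Counts cleavage versus translational-inhibition hits (percentages to
#' one decimal) and tabulates per-miRNA and per-transcript target
#' multiplicities.
#'
#' @param hits Hit table with columns \code{mode}, \code{mirna_id},
#'   \code{transcript_id}.
#' @return List with \code{nHits}, \code{nCleavage},
#'   \code{nTranslation}, \code{pctCleavage}, \code{pctTranslation},
#'   \code{perMirna}, \code{perTranscript}.
#' @examples
#' h <- data.frame(mode = rep(c("cleavage", "translation"), c(660, 238)),
#'     mirna_id = "m", transcript_id = "t")
#' summarizeTargets(h)$pctCleavage   # 73.5
#' @export
summarizeTargets <- function(hits) {
    n <- nrow(hits)
    nC <- sum(hits$mode == "cleavage")
    nT <- sum(hits$mode == "translation")
    list(nHits = n, nCleavage = nC, nTranslation = nT,
        pctCleavage = if (n) round(100 * nC / n, 1) else NA_real_,
        pctTranslation = if (n) round(100 * nT / n, 1) else NA_real_,
        perMirna = if (n) table(hits$mirna_id) else table(character(0)),
        perTranscript = if (n) table(hits$transcript_id)
            else table(character(0)))
}
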