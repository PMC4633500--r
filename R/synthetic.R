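.randomSeq <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

# hamming distance of q to its best ungapped containment placement in r
.minContainDist <- function(q, r) {
    lq <- nchar(q); lr <- nchar(r)
    if (lq > lr) { tmp <- q; q <- r; r <- tmp; tmp <- lq; lq <- lr
        lr <- tmp }
    qc <- .seqCodes(q); rc <- .seqCodes(r)
    best <- lq
    for (off in 0:(lr - lq))
        best <- min(best, sum(qc != rc[(off + 1):(off + lq)]))
    best
}

.minDistToSet <- function(q, refs) {
    if (!length(refs)) return(Inf)
    min(vapply(refs, function(r) .minContainDist(q, r), numeric(1)))
}

# plant k substitutions into an RNA sequence
.mutate <- function(seq, k) {
    chars <- strsplit(seq, "")[[1]]
    pos <- sample(length(chars), k)
    for (p in pos) {
        alt <- setdiff(c("A", "C", "G", "U"), chars[p])
        chars[p] <- sample(alt, 1)
    }
    paste(chars, collapse = "")
}

#' Generate a genome with planted MIR and ncRNA loci
#'
#' Builds a random-background genome of the requested GC content, plants
#' \code{nMir} MIR hairpin loci with known mature sequences, classes and
#' duplex geometry, and \code{nNcrna} non-miRNA small-RNA loci (rRNA,
#' tRNA, snoRNA, snRNA in rotation).  Hairpins are constructed by
#' concatenating a 5' arm containing the mature sequence, a random
#' terminal loop, and the arm's reverse complement, so the planted
#' duplex carries 2-nt 3' overhangs by construction; precursors always
#' span 57--264 nt.  Conserved loci copy a reference mature exactly;
#' variant loci plant 1--2 substitutions (verified unambiguous against
#' the whole reference set); novel loci draw random matures at least 3
#' substitutions from every reference.
#'
#' @param length Genome length in nt; must be at least 10x the summed
#'   planted locus lengths.
#' @param gcContent Background GC fraction in (0, 1).
#' @param nMir,nNcrna Numbers of planted MIR and ncRNA loci.
#' @param referenceSet Named character vector or
#'   \code{\link[Biostrings]{RNAStringSet}} of reference mature miRNAs
#'   (miRBase-style names); required when conserved/variant loci are
#'   requested.
#' @param seed Integer seed; identical arguments and seed give
#'   byte-identical output.
#' @param classMix Proportions of conserved/variant/novel among MIR loci.
#' @return A list with \code{genome} (\code{DNAStringSet}, one contig),
#'   \code{mirTruth} (\code{GRanges} with per-locus metadata: locus_id,
#'   class_truth, planted_mismatches, reference_id, precursor_seq,
#'   mature_5p, mature_3p, mature5p_start0 (offset in precursor),
#'   arm_abundance_ratio), and \code{ncrnaTruth} (\code{GRanges} with
#'   category and sequence).
#' @export
generateGenome <- function(length = 50000, gcContent = 0.45, nMir = 10,
                           nNcrna = 5, referenceSet = NULL, seed = 1,
                           classMix = c(conserved = 0.4, variant = 0.3,
                               novel = 0.3)) {
    if (gcContent <= 0 || gcContent >= 1)
        stop("gcContent must lie strictly between 0 and 1")
    set.seed(seed)

    refs <- character(0)
    if (!is.null(referenceSet)) {
        refs <- .asRNA(as.character(referenceSet))
        names(refs) <- names(referenceSet)
        refs <- refs[nchar(refs) >= 18 & nchar(refs) <= 25]
    }
    classes <- character(0)
    if (nMir > 0) {
        nCons <- round(nMir * classMix[["conserved"]])
        nVar <- round(nMir * classMix[["variant"]])
        nNov <- nMir - nCons - nVar
        classes <- c(rep("conserved", nCons), rep("variant", nVar),
            rep("novel", nNov))
        if ((nCons + nVar) > 0 && length(refs) == 0)
            stop("referenceSet is required for conserved/variant loci")
    }

    loci <- vector("list", nMir)
    for (i in seq_len(nMir)) {
        cls <- classes[i]
        if (cls == "conserved") {
            refIdx <- sample(length(refs), 1)
            m5 <- unname(refs[refIdx])
            refId <- names(refs)[refIdx]
            planted <- 0L
        } else if (cls == "variant") {
            planted <- sample(1:2, 1)
            repeat {
                refIdx <- sample(length(refs), 1)
                m5 <- .mutate(unname(refs[refIdx]), planted)
                if (.minDistToSet(m5, refs) == planted) break
            }
            refId <- names(refs)[refIdx]
        } else {
            planted <- NA_integer_
            repeat {
                m5 <- .asRNA(.randomSeq(sample(c(21, 24), 1),
                    gc = gcContent))
                if (.minDistToSet(m5, refs) >= 3) break
            }
            refId <- NA_character_
        }
        L5 <- nchar(m5)
        # the terminal loop is drawn over {A, C} so it cannot pair with
        # itself; each construct is validated by folding (the planted
        # stem must be the MFE structure, preserving duplex geometry)
        # and the loop redrawn on the rare failure
        precursorDNA <- NULL
        for (try in 1:50) {
            a <- sample(2:8, 1)      # pad 5' of the mature on its arm
            d <- sample(2:8, 1)      # pad between mature and the loop
            S <- a + L5 + d
            loopLen <- sample(max(8, 57 - 2 * S):40, 1)
            arm5 <- paste0(.randomSeq(a, gcContent), .asDNA(m5),
                .randomSeq(d, gcContent))
            loopSeq <- paste(sample(c("A", "C"), loopLen,
                replace = TRUE), collapse = "")
            cand <- paste0(arm5, loopSeq, .revcompDNA(arm5))
            N <- nchar(cand)
            pt <- pairTable(foldRNA(.asRNA(cand)))
            spans <- .hairpinSpans(pt)
            m5pos <- (a + 1):(a + L5)
            if (length(spans) == 1 &&
                all(pt[m5pos] == N + 1 - m5pos)) {
                precursorDNA <- cand
                break
            }
        }
        if (is.null(precursorDNA))
            stop("could not construct a clean hairpin for locus ", i)
        # 3p partner with 2-nt 3' overhangs on both strands (0-based
        # [N-a-L5+2, N-a+2) within the precursor)
        m3 <- .asRNA(substr(precursorDNA, N - a - L5 + 3, N - a + 2))
        loci[[i]] <- list(
            locus_id = sprintf("MIR%03d", i), class_truth = cls,
            planted_mismatches = planted, reference_id = refId,
            precursor_dna = precursorDNA,
            mature_5p = m5, mature_3p = m3,
            mature5p_start0 = a,
            arm_abundance_ratio = 2^runif(1, -1, 3),
            strand = sample(c("+", "-"), 1))
    }

    ncCats <- rep(c("rRNA", "tRNA", "snoRNA", "snRNA"),
        length.out = max(nNcrna, 0))
    ncLens <- c(rRNA = 250, tRNA = 80, snoRNA = 120, snRNA = 160)
    ncLoci <- lapply(seq_len(nNcrna), function(i) {
        L <- ncLens[[ncCats[i]]] + sample(0:50, 1)
        list(locus_id = sprintf("NC%03d", i), category = ncCats[i],
            seq_dna = .randomSeq(L, gcContent))
    })

    lociLens <- c(vapply(loci, function(l) nchar(l$precursor_dna),
            numeric(1)),
        vapply(ncLoci, function(l) nchar(l$seq_dna), numeric(1)))
    if (length(lociLens) && length < 10 * sum(lociLens))
        stop("genome length must be at least 10x the planted loci (",
            10 * sum(lociLens), " nt)")

    genome <- .randomSeq(length, gcContent)
    # non-overlapping placement with clearance for candidate windows
    nLoci <- nMir + nNcrna
    placements <- integer(0)
    if (nLoci > 0) {
        slotWidth <- floor(length / nLoci)
        order <- sample(nLoci)
        for (k in seq_len(nLoci)) {
            slot <- which(order == k)
            maxLen <- max(lociLens)
            off <- sample(seq_len(max(1, slotWidth - maxLen - 600)), 1)
            placements[k] <- (slot - 1L) * slotWidth + off + 300L
        }
    }
    insert <- function(genome, pos, seq) {
        paste0(substr(genome, 1, pos - 1), seq,
            substr(genome, pos + nchar(seq), length))
    }
    mirRows <- list()
    for (i in seq_len(nMir)) {
        l <- loci[[i]]
        placed <- if (l$strand == "+") l$precursor_dna
            else .revcompDNA(l$precursor_dna)
        pos <- placements[i]
        genome <- insert(genome, pos, placed)
        mirRows[[i]] <- data.frame(start = pos,
            end = pos + nchar(placed) - 1L, strand = l$strand,
            locus_id = l$locus_id, class_truth = l$class_truth,
            planted_mismatches = l$planted_mismatches,
            reference_id = l$reference_id,
            precursor_seq = .asRNA(l$precursor_dna),
            mature_5p = l$mature_5p, mature_3p = l$mature_3p,
            mature5p_start0 = l$mature5p_start0,
            arm_abundance_ratio = l$arm_abundance_ratio)
    }
    ncRows <- list()
    for (i in seq_len(nNcrna)) {
        l <- ncLoci[[i]]
        pos <- placements[nMir + i]
        genome <- insert(genome, pos, l$seq_dna)
        ncRows[[i]] <- data.frame(start = pos,
            end = pos + nchar(l$seq_dna) - 1L,
            locus_id = l$locus_id, category = l$category,
            sequence = .asRNA(l$seq_dna))
    }

    toGR <- function(rows, stranded) {
        if (!length(rows))
            return(GenomicRanges::GRanges())
        df <- do.call(rbind, rows)
        gr <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(df$start, df$end),
            strand = if (stranded) df$strand else "*")
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            df[setdiff(colnames(df), c("start", "end", "strand"))])
        gr
    }
    list(
        genome = Biostrings::DNAStringSet(c(chr1 = genome)),
        mirTruth = toGR(mirRows, stranded = TRUE),
        ncrnaTruth = toGR(ncRows, stranded = FALSE)
    )
}

#' Describe one simulated sequencing library
#'
#' @param libraryId Library label (e.g. \code{leaf_control}).
#' @param depth Total reads to draw (> 0).
#' @param adaptor3p 3' adaptor appended to each insert (>= 6 nt).
#' @param dispersion Negative-binomial dispersion phi (variance
#'   mu + phi mu^2); 0 gives deterministic rounded counts.
#' @param ncrnaFraction Fraction of reads drawn from ncRNA loci.
#' @param lengthPeakWeights Named weights over fragment lengths 18--25
#'   for ncRNA fragments (must sum to 1); defaults put peaks at 21 and
#'   24 nt as observed in plant small-RNA libraries.
#' @param seed Per-library seed; identical designs give byte-identical
#'   FASTQ output.
#' @return A \code{library_design} list.
#' @export
libraryDesign <- function(libraryId, depth = 20000,
                          adaptor3p = "TGGAATTCTCGGGTGCCAAGG",
                          dispersion = 0.04, ncrnaFraction = 0.1,
                          lengthPeakWeights = c(`18` = 0.03, `19` = 0.05,
                              `20` = 0.07, `21` = 0.50, `22` = 0.05,
                              `23` = 0.05, `24` = 0.20, `25` = 0.05),
                          seed = 1) {
    if (depth <= 0) stop("depth must be positive")
    if (nchar(adaptor3p) < 6)
        stop("adaptor must be at least 6 nt")
    if (abs(sum(lengthPeakWeights) - 1) > 1e-8)
        stop("lengthPeakWeights must sum to 1")
    if (dispersion < 0) stop("dispersion must be nonnegative")
    structure(list(library_id = libraryId, depth = as.integer(depth),
        adaptor_3p = .asDNA(adaptor3p), dispersion = dispersion,
        ncrna_fraction = ncrnaFraction,
        length_peak_weights = lengthPeakWeights,
        seed = as.integer(seed)), class = "library_design")
}

#' Default four-library leaf/root x control/NaCl design
#'
#' Four libraries of unequal depth mirroring a two-tissue, two-condition
#' salt-stress design.
#'
#' @param depths Named depths for the four libraries.
#' @param dispersion,ncrnaFraction,seed Passed to
#'   \code{\link{libraryDesign}} (seeds are offset per library).
#' @return List of four \code{library_design}s.
#' @export
defaultLibraryDesigns <- function(depths = c(leaf_control = 28000,
        leaf_nacl = 23000, root_control = 21500, root_nacl = 28100),
        dispersion = 0.04, ncrnaFraction = 0.1, seed = 1) {
    lapply(seq_along(depths), function(i)
        libraryDesign(names(depths)[i], depth = depths[i],
            dispersion = dispersion, ncrnaFraction = ncrnaFraction,
            seed = seed + i))
}

#' Simulate small-RNA libraries from planted truth
#'
#' Draws reads for each library design: mature miRNA reads from the
#' planted loci (negative-binomial counts around depth x baseline x
#' fold change, split between arms by the locus arm-abundance ratio)
#' and ncRNA fragments from the annotated loci.  Each read is the
#' insert plus the 3' adaptor, truncated to the read length.
#'
#' @param truth \code{mirTruth} GRanges from \code{\link{generateGenome}}.
#' @param designs List of \code{\link{libraryDesign}} objects (>= 1).
#' @param ncrnaTruth \code{ncrnaTruth} GRanges from
#'   \code{\link{generateGenome}}.
#' @param foldChanges Optional numeric matrix (locus_id x library_id) of
#'   positive fold changes; missing entries default to 1.
#' @param readLength Sequencer read length before trimming (default 36).
#' @return A list with \code{libraries} (per library: \code{sequences},
#'   \code{qualities}, \code{ids}) and \code{truthCounts} (data frame of
#'   exact per-library emissions per locus and arm).
#' @export
simulateLibraries <- function(truth, designs, ncrnaTruth = NULL,
                              foldChanges = NULL, readLength = 36) {
    stopifnot(length(designs) >= 1)
    if (!is.null(foldChanges) && any(foldChanges <= 0))
        stop("fold changes must be positive")
    tr <- as.data.frame(S4Vectors::mcols(truth))
    nc <- if (!is.null(ncrnaTruth) && length(ncrnaTruth))
        as.data.frame(S4Vectors::mcols(ncrnaTruth)) else NULL

    # deterministic per-locus baseline abundances (shared across
    # libraries so fold changes act on a common scale)
    nL <- nrow(tr)
    baseline <- if (nL) {
        b <- exp(seq(log(0.4), log(2.5), length.out = nL))
        b / sum(b)
    } else numeric(0)

    libs <- list()
    truthRows <- list()
    for (d in designs) {
        set.seed(d$seed)
        reads <- character(0); origins <- character(0)
        mirBudget <- d$depth * (1 - d$ncrna_fraction)
        for (i in seq_len(nL)) {
            fc <- 1
            if (!is.null(foldChanges) &&
                tr$locus_id[i] %in% rownames(foldChanges) &&
                d$library_id %in% colnames(foldChanges))
                fc <- foldChanges[tr$locus_id[i], d$library_id]
            r <- tr$arm_abundance_ratio[i]
            for (arm in c("5p", "3p")) {
                mature <- if (arm == "5p") tr$mature_5p[i]
                    else tr$mature_3p[i]
                armW <- if (arm == "5p") r / (1 + r) else 1 / (1 + r)
                mu <- mirBudget * baseline[i] * fc * armW
                k <- if (d$dispersion == 0) .roundHalfUp(mu)
                    else rnbinom(1, mu = mu, size = 1 / d$dispersion)
                if (k > 0) {
                    reads <- c(reads, rep(.asDNA(mature), k))
                    origins <- c(origins,
                        rep(paste0(tr$locus_id[i], "_", arm), k))
                }
                truthRows[[length(truthRows) + 1L]] <- data.frame(
                    library_id = d$library_id, origin = "mir",
                    locus_id = tr$locus_id[i], arm = arm,
                    expected = mu, emitted = k)
            }
        }
        nNcReads <- .roundHalfUp(d$depth * d$ncrna_fraction)
        if (!is.null(nc) && nNcReads > 0) {
            li <- sample(nrow(nc), nNcReads, replace = TRUE)
            fragLen <- as.integer(sample(
                names(d$length_peak_weights), nNcReads, replace = TRUE,
                prob = d$length_peak_weights))
            starts <- vapply(seq_len(nNcReads), function(k)
                sample(nchar(nc$sequence[li[k]]) - fragLen[k] + 1L, 1),
                integer(1))
            frags <- .asDNA(substr(nc$sequence[li], starts,
                starts + fragLen - 1L))
            reads <- c(reads, frags)
            origins <- c(origins, nc$locus_id[li])
            ncTab <- table(nc$locus_id[li])
            for (id in names(ncTab))
                truthRows[[length(truthRows) + 1L]] <- data.frame(
                    library_id = d$library_id, origin = "ncrna",
                    locus_id = id, arm = NA_character_,
                    expected = nNcReads / nrow(nc),
                    emitted = as.integer(ncTab[[id]]))
        }
        full <- substr(paste0(reads, d$adaptor_3p,
            strrep(d$adaptor_3p, ceiling(readLength / nchar(
                d$adaptor_3p)))), 1, readLength)
        libs[[d$library_id]] <- list(
            sequences = full,
            qualities = rep(strrep("I", readLength), length(full)),
            ids = sprintf("%s.%06d %s", d$library_id,
                seq_along(full), origins))
    }
    list(libraries = libs,
        truthCounts = if (length(truthRows)) do.call(rbind, truthRows)
            else data.frame())
}
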