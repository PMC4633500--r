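.RUN_SUMMARY_ROWS <- c("total_reads", "reads_after_filtration",
    "mapped", "known_small_rna", "known_mirna", "predicted_mirna",
    "rRNA", "tRNA", "snoRNA", "snRNA", "no_hit")

#' Build the run-summary table (sequencing-data accounting)
#'
#' Lays out per-library redundant and unique read tallies with total
#' columns computed as row sums, mirroring the standard summary table
#' of a small-RNA sequencing study (total reads, reads after
#' filtration, mapped reads, annotated small-RNA classes, known and
#' predicted miRNA, no hit).
#'
#' @param redundantCounts,uniqueCounts Numeric matrices with identical
#'   dimnames: rows are summary rows, columns are libraries.
#' @return Data frame with one row per summary row: per-library
#'   redundant cells, \code{redundant_total}, per-library unique cells,
#'   \code{unique_total}; every total equals the sum of its per-library
#'   cells.
#' @examples
#' m <- rbind(total_reads = c(69820252, 57749080, 53893175, 70138817))
#' colnames(m) <- paste0("lib", 1:4)
#' summarizeRun(m, m)$redundant_total   # 251601324
#' @export
summarizeRun <- function(redundantCounts, uniqueCounts) {
    redundantCounts <- as.matrix(redundantCounts)
    uniqueCounts <- as.matrix(uniqueCounts)
    stopifnot(identical(dimnames(redundantCounts),
        dimnames(uniqueCounts)))
    libs <- colnames(redundantCounts)
    out <- data.frame(row = rownames(redundantCounts))
    for (l in libs) out[[paste0("redundant_", l)]] <- redundantCounts[, l]
    out$redundant_total <- rowSums(redundantCounts)
    for (l in libs) out[[paste0("unique_", l)]] <- uniqueCounts[, l]
    out$unique_total <- rowSums(uniqueCounts)
    rownames(out) <- NULL
    out
}

#' Read a flat-key pipeline configuration file
#'
#' One \code{key: value} pair per line; \code{#} starts a comment.
#' Numeric-looking values are converted; referenced files must exist.
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values.
#' @export
readPipelineConfig <- function(path) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
    bad <- vapply(kv, length, integer(1)) != 3
    if (any(bad))
        stop("malformed config line(s): ",
            paste(lines[bad], collapse = "; "))
    cfg <- lapply(kv, function(x) {
        v <- trimws(x[3])
        num <- suppressWarnings(as.numeric(v))
        if (!is.na(num)) num else v
    })
    names(cfg) <- vapply(kv, function(x) trimws(x[2]), "")
    base <- dirname(normalizePath(path))
    pathKeys <- c("genome", "ncrna_fasta", "reference_fasta",
        "transcripts", grep("^reads_", names(cfg), value = TRUE))
    for (k in intersect(pathKeys, names(cfg))) {
        p <- cfg[[k]]
        if (!file.exists(p) && file.exists(file.path(base, p)))
            cfg[[k]] <- file.path(base, p)
        if (!file.exists(cfg[[k]]))
            stop("config path for '", k, "' does not exist: ", p)
    }
    libs <- sub("^reads_", "", grep("^reads_", names(cfg), value = TRUE))
    if (anyDuplicated(libs)) stop("library ids must be unique")
    cfg$libraries <- libs
    cfg
}

# ncRNA FASTA headers carry "category=<cls>" after the record id
.readNcrnaFasta <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    cat <- sub(".*category=([A-Za-z]+).*", "\\1", names(x))
    ann <- split(as.character(x), cat)
    ann[intersect(.NCRNA_PRIORITY, names(ann))]
}

.exportAlignmentsBED <- function(alignments, path) {
    gr <- alignments
    if (length(gr)) {
        S4Vectors::mcols(gr)$name <- S4Vectors::mcols(gr)$tag
        S4Vectors::mcols(gr)$score <- vapply(
            S4Vectors::mcols(gr)$mismatch_positions,
            function(m) if (nzchar(m)) length(strsplit(m, ",")[[1]])
                else 0L, integer(1))
        S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[c("name", "score")]
    }
    rtracklayer::export(gr, path, format = "BED")
}

.exportCandidatesGFF3 <- function(candidates, annotations, path) {
    if (!length(candidates)) {
        rtracklayer::export(GenomicRanges::GRanges(), path,
            format = "GFF3")
        return(invisible(path))
    }
    feats <- list()
    for (ci in seq_along(candidates)) {
        cand <- candidates[[ci]]
        pid <- sprintf("precursor_%03d", ci)
        gr <- GenomicRanges::GRanges(cand$seqnames,
            IRanges::IRanges(cand$start, cand$end),
            strand = cand$strand)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            type = "miRNA_primary_transcript", ID = pid,
            Parent = NA_character_,
            mfe = cand$mfe, mfei = round(cand$mfei, 3))
        feats[[length(feats) + 1L]] <- gr
        ann <- annotations[annotations$candidate == ci, , drop = FALSE]
        for (r in seq_len(nrow(ann))) {
            sp <- if (ann$arm[r] == "5p")
                cand$evaluation$matureSpan5p
                else cand$evaluation$matureSpan3p
            if (is.null(sp) && !is.null(cand$duplex))
                sp <- if (ann$arm[r] == "5p") cand$duplex$span5p
                    else cand$duplex$span3p
            if (is.null(sp)) next
            if (cand$strand == "+") {
                gs <- cand$start + sp[1] - 1L
                ge <- cand$start + sp[2] - 1L
            } else {
                gs <- cand$end - sp[2] + 1L
                ge <- cand$end - sp[1] + 1L
            }
            mg <- GenomicRanges::GRanges(cand$seqnames,
                IRanges::IRanges(gs, ge), strand = cand$strand)
            S4Vectors::mcols(mg) <- S4Vectors::DataFrame(
                type = "miRNA", ID = ann$mirna_id[r], Parent = pid,
                mfe = NA_real_, mfei = NA_real_)
            feats[[length(feats) + 1L]] <- mg
        }
    }
    all <- do.call(c, feats)
    names(all) <- NULL
    rtracklayer::export(all, path, format = "GFF3")
    invisible(path)
}

# per-candidate measured criteria (TSV) and structures (Vienna text)
.exportCandidateTables <- function(candidates, outputDir) {
    rows <- list()
    vienna <- character(0)
    for (ci in seq_along(candidates)) {
        cand <- candidates[[ci]]
        id <- sprintf("precursor_%03d", ci)
        rep <- cand$evaluation$report
        rows[[ci]] <- data.frame(candidate = id,
            seqnames = cand$seqnames, start = cand$start,
            end = cand$end, strand = cand$strand,
            criterion = rep$criterion, value = rep$value,
            threshold = rep$threshold, comparator = rep$comparator,
            pass = rep$pass)
        vienna <- c(vienna, paste0(">", id, " ", cand$seqnames, ":",
            cand$start, "-", cand$end, "(", cand$strand, ")"),
            cand$precursorSeq,
            sprintf("%s (%.1f)", dotBracket(cand$structure),
                mfe(cand$structure)))
    }
    if (length(rows))
        .writeTSV(do.call(rbind, rows),
            file.path(outputDir, "candidates.tsv"))
    writeLines(vienna, file.path(outputDir, "hairpins.vienna"))
    invisible(NULL)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates preprocessing, mapping, hairpin discovery,
#' classification, differential expression and (optionally) target
#' prediction, writing all stage outputs plus a manifest to the output
#' directory.  The pipeline is deterministic: re-running an identical
#' configuration reproduces identical files.
#'
#' @param config Path to a configuration file (see
#'   \code{\link{readPipelineConfig}}) or an equivalent list.
#' @param outputDir Output directory (created if absent).
#' @return Invisibly, a list with the principal stage objects
#'   (\code{tags}, \code{alignments}, \code{candidates},
#'   \code{annotations}, \code{counts}, \code{de}, \code{targets},
#'   \code{runSummary}).
#' @export
runPipeline <- function(config, outputDir) {
    cfg <- if (is.character(config)) readPipelineConfig(config)
        else config
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    getp <- function(key, default) cfg[[key]] %||% default

    genome <- Biostrings::readDNAStringSet(cfg$genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    annotation <- .readNcrnaFasta(cfg$ncrna_fasta)
    refFa <- Biostrings::readRNAStringSet(cfg$reference_fasta)
    referenceSet <- setNames(as.character(refFa),
        sub("\\s.*", "", names(refFa)))
    libs <- cfg$libraries

    # stage 1: preprocess
    message("stage preprocess: ", length(libs), " libraries")
    rawCounts <- integer(0)
    uniqueRaw <- integer(0)
    keptPerLib <- list()
    trimReject <- integer(0); lenReject <- integer(0)
    qualReject <- integer(0)
    for (l in libs) {
        fq <- .readFastq(cfg[[paste0("reads_", l)]])
        rawCounts[l] <- length(fq$sequences)
        uniqueRaw[l] <- length(unique(fq$sequences))
        inserts <- trimAdaptor(fq$sequences, cfg$adaptor_3p,
            minOverlap = getp("min_overlap", 6),
            maxMismatchRate = getp("max_mismatch_rate", 0.1))
        ok <- !is.na(inserts)
        trimReject[l] <- sum(!ok)
        fr <- filterReads(inserts[ok], minLen = getp("min_len", 18),
            maxLen = getp("max_len", 25),
            minMeanQuality = getp("min_mean_quality", 20),
            qualities = fq$qualities[ok])
        lenReject[l] <- fr$rejects[["length"]]
        qualReject[l] <- fr$rejects[["quality"]]
        keptPerLib[[l]] <- fr$kept
    }
    tags <- collapseReads(keptPerLib)
    fa <- filterAnnotated(tags, annotation)
    dist <- lengthDistribution(tags)
    .writeTSV(dist, file.path(outputDir, "length_distribution.tsv"))

    # stage 2: map
    message("stage map: ", length(fa$kept), " unannotated tags")
    index <- buildGenomeIndex(genome,
        seedLength = getp("seed_length", 16))
    mp <- mapTags(fa$kept, index)
    .exportAlignmentsBED(mp$alignments,
        file.path(outputDir, "alignments.bed"))

    # stage 3: discover hairpins
    message("stage discover: ", length(mp$alignments), " alignments")
    criteria <- hairpinCriteria()
    candidates <- discoverHairpins(mp$tags, mp$alignments, genome,
        criteria = criteria, maxFlank = getp("max_flank", 250))

    # stage 4: classify
    message("stage classify: ", length(candidates),
        " accepted precursors")
    annotations <- classifyCandidates(candidates, mp$tags, referenceSet,
        prefix = getp("prefix", "pda"),
        variantMaxMismatches = getp("variant_max_mismatches", 2),
        minNovelReads = getp("min_novel_reads", 10))
    .writeTSV(annotations, file.path(outputDir, "annotations.tsv"))
    .exportCandidatesGFF3(candidates, annotations,
        file.path(outputDir, "candidates.gff3"))
    .exportCandidateTables(candidates, outputDir)

    # stage 5: expression
    tagSeqs <- as.character(tagSequences(mp$tags))
    annUniq <- annotations[!duplicated(annotations$mirna_id), ,
        drop = FALSE]
    cm <- tagCounts(mp$tags)[match(annUniq$mature_seq, tagSeqs), ,
        drop = FALSE]
    rownames(cm) <- annUniq$mirna_id
    cm <- cm[rowSums(cm) > 0, , drop = FALSE]
    .writeTSV(data.frame(mirna_id = rownames(cm), cm,
        check.names = FALSE), file.path(outputDir, "counts.tsv"))
    ctStr <- getp("contrasts", "")
    contrasts <- if (nzchar(ctStr))
        strsplit(strsplit(ctStr, ",")[[1]], ":") else list()
    de <- list()
    if (nrow(cm) >= 2 && length(contrasts)) {
        message("stage de: ", nrow(cm), " miRNAs, ",
            length(contrasts), " contrasts")
        sf <- tryCatch(medianRatioSizeFactors(cm)$sizeFactors,
            error = function(e) setNames(rep(1, ncol(cm)),
                colnames(cm)))
        for (ct in contrasts) {
            treated <- trimws(ct[1]); control <- trimws(ct[2])
            tab <- exactTestTable(cm, control, treated,
                dispersion = getp("bcv", 0.2)^2,
                alpha = getp("alpha", 0.05),
                fdrAlpha = getp("fdr_alpha", 0.05),
                sizeFactors = sf)
            de[[paste(treated, "vs", control)]] <- tab
            .writeTSV(tab, file.path(outputDir,
                sprintf("de_%s_vs_%s.tsv", treated, control)))
        }
        norm <- normalizeCounts(cm, sf)
        cl <- completeLinkageOrder(norm)
        .writeTSV(data.frame(
            mirna_id = rownames(norm)[cl$rowOrder],
            round(norm[cl$rowOrder, cl$colOrder, drop = FALSE], 4),
            check.names = FALSE),
            file.path(outputDir, "normalized_ordered.tsv"))
    }

    # stage 6: targets
    targets <- NULL
    if (!is.null(cfg$transcripts) && nrow(annotations)) {
        tx <- Biostrings::readDNAStringSet(cfg$transcripts)
        names(tx) <- sub("\\s.*", "", names(tx))
        mirs <- setNames(annotations$mature_seq, annotations$mirna_id)
        mirs <- mirs[!duplicated(names(mirs))]
        message("stage targets: ", length(mirs), " miRNAs vs ",
            length(tx), " transcripts")
        targets <- predictTargets(mirs, tx)
        .writeTSV(targets, file.path(outputDir, "targets.tsv"))
        ts <- summarizeTargets(targets)
        .writeTSV(data.frame(metric = c("n_hits", "n_cleavage",
                "n_translation", "pct_cleavage", "pct_translation"),
            value = c(ts$nHits, ts$nCleavage, ts$nTranslation,
                ts$pctCleavage, ts$pctTranslation)),
            file.path(outputDir, "target_summary.tsv"))
    }

    # stage 7: run summary (sequencing-data accounting)
    tagSeqAll <- as.character(tagSequences(fa$all))
    mapSeqs <- as.character(tagSequences(mp$tags))
    catAll <- tagCategory(fa$all)
    catAll[match(mapSeqs, tagSeqAll)] <- tagCategory(mp$tags)
    counts <- tagCounts(fa$all)
    knownSeqs <- annotations$mature_seq[
        annotations$class %in% c("conserved", "variant")]
    novelSeqs <- annotations$mature_seq[annotations$class == "novel"]
    tally <- function(perLibCounts) {
        red <- matrix(0, length(.RUN_SUMMARY_ROWS), length(libs),
            dimnames = list(.RUN_SUMMARY_ROWS, libs))
        uni <- red
        for (l in libs) {
            cl <- perLibCounts[, l]
            present <- cl > 0
            red["total_reads", l] <- rawCounts[l]
            uni["total_reads", l] <- uniqueRaw[l]
            red["reads_after_filtration", l] <- sum(cl)
            uni["reads_after_filtration", l] <- sum(present)
            for (cls in .NCRNA_PRIORITY) {
                sel <- catAll == cls & present
                red[cls, l] <- sum(cl[sel])
                uni[cls, l] <- sum(sel)
            }
            selM <- catAll == "mapped" & present
            red["mapped", l] <- sum(cl[selM])
            uni["mapped", l] <- sum(selM)
            selK <- tagSeqAll %in% knownSeqs & present
            red["known_mirna", l] <- sum(cl[selK])
            uni["known_mirna", l] <- sum(selK)
            selN <- tagSeqAll %in% novelSeqs & present
            red["predicted_mirna", l] <- sum(cl[selN])
            uni["predicted_mirna", l] <- sum(selN)
            red["known_small_rna", l] <- sum(red[.NCRNA_PRIORITY, l]) +
                red["known_mirna", l]
            uni["known_small_rna", l] <- sum(uni[.NCRNA_PRIORITY, l]) +
                uni["known_mirna", l]
            selU <- catAll == "unmapped" & present
            red["no_hit", l] <- sum(cl[selU])
            uni["no_hit", l] <- sum(selU)
        }
        list(red = red, uni = uni)
    }
    tl <- tally(counts)
    runSummary <- summarizeRun(tl$red, tl$uni)
    .writeTSV(runSummary, file.path(outputDir, "run_summary.tsv"))

    # manifest
    params <- cfg[!vapply(cfg, is.list, logical(1))]
    manifest <- data.frame(
        key = c("package_version", names(params)),
        value = c(as.character(packageVersion("plantsrna")),
            vapply(params, function(x)
                paste(as.character(x), collapse = ","), "")))
    .writeTSV(manifest, file.path(outputDir, "manifest.tsv"))

    invisible(list(tags = tags, filtered = fa, alignments =
        mp$alignments, candidates = candidates,
        annotations = annotations, counts = cm, de = de,
        targets = targets, runSummary = runSummary,
        lengthDistribution = dist))
}

#' Generate the default synthetic analysis bundle
#'
#' Creates a complete, self-contained input set under \code{dir}:
#' genome with planted MIR and ncRNA loci, four FASTQ libraries with
#' planted salt-responsive fold changes, the reference mature-miRNA
#' catalogue, target transcripts with planted sites, truth tables and a
#' ready-to-run configuration file.
#'
#' @param dir Output directory.
#' @param seed Master seed (all sub-seeds derive from it).
#' @param nMir,nNcrna Numbers of planted loci.
#' @param genomeLength Genome length in nt.
#' @param depths Per-library read depths.
#' @param dispersion NB dispersion of the simulated counts.
#' @param ncrnaFraction Fraction of reads drawn from ncRNA loci.
#' @return Path to the written configuration file (invisibly, the
#'   bundle object list).
#' @export
makeFixtures <- function(dir, seed = 1, nMir = 10, nNcrna = 5,
                         genomeLength = 50000,
                         depths = c(leaf_control = 28000,
                             leaf_nacl = 23000, root_control = 21500,
                             root_nacl = 28100),
                         dispersion = 0.04, ncrnaFraction = 0.1) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    refPath <- system.file("extdata", "mature_reference.fa",
        package = "plantsrna")
    refFa <- Biostrings::readRNAStringSet(refPath)
    referenceSet <- setNames(as.character(refFa),
        sub("\\s.*", "", names(refFa)))

    gen <- generateGenome(length = genomeLength, gcContent = 0.45,
        nMir = nMir, nNcrna = nNcrna, referenceSet = referenceSet,
        seed = seed)
    tr <- as.data.frame(S4Vectors::mcols(gen$mirTruth))

    # planted salt response: two loci induced 4-fold, one repressed
    # 4-fold, in the NaCl libraries of both tissues
    fc <- matrix(1, nrow(tr), length(depths),
        dimnames = list(tr$locus_id, names(depths)))
    up <- tr$locus_id[seq_len(min(2, nrow(tr)))]
    dn <- tr$locus_id[min(3, nrow(tr))]
    fc[up, c("leaf_nacl", "root_nacl")] <- 4
    fc[dn, c("leaf_nacl", "root_nacl")] <- 0.25

    designs <- defaultLibraryDesigns(depths = depths,
        dispersion = dispersion, ncrnaFraction = ncrnaFraction,
        seed = seed * 101)
    sim <- simulateLibraries(gen$mirTruth, designs, gen$ncrnaTruth,
        foldChanges = fc)

    Biostrings::writeXStringSet(gen$genome,
        file.path(dir, "genome.fa"))
    file.copy(refPath, file.path(dir, "reference.fa"),
        overwrite = TRUE)

    nc <- as.data.frame(S4Vectors::mcols(gen$ncrnaTruth))
    ncSet <- Biostrings::DNAStringSet(.asDNA(nc$sequence))
    names(ncSet) <- sprintf("%s category=%s", nc$locus_id, nc$category)
    Biostrings::writeXStringSet(ncSet, file.path(dir, "ncrna.fa"))
    ncBed <- gen$ncrnaTruth
    S4Vectors::mcols(ncBed) <- S4Vectors::DataFrame(name = nc$locus_id)
    rtracklayer::export(ncBed, file.path(dir, "ncrna.bed"),
        format = "BED")
    mirBed <- gen$mirTruth
    S4Vectors::mcols(mirBed) <- S4Vectors::DataFrame(
        name = tr$locus_id)
    rtracklayer::export(mirBed, file.path(dir, "mir_truth.bed"),
        format = "BED")
    .writeTSV(tr, file.path(dir, "mir_truth.tsv"))
    .writeTSV(sim$truthCounts, file.path(dir, "truth_counts.tsv"))

    for (l in names(sim$libraries)) {
        lib <- sim$libraries[[l]]
        .writeFastq(lib$sequences, lib$qualities, lib$ids,
            file.path(dir, paste0(l, ".fastq")))
    }

    # transcripts with planted target sites for the first matures:
    # perfect complement (cleavage) and one with a central mismatch
    # (translational inhibition)
    set.seed(seed * 313)
    txs <- character(0)
    for (i in seq_len(min(3, nrow(tr)))) {
        m <- tr$mature_5p[i]
        site <- .revcompDNA(.asDNA(m))
        if (i == 2) {   # mismatch opposite miRNA position 10
            L <- nchar(m)
            p <- L - 10 + 1
            ch <- substr(site, p, p)
            substr(site, p, p) <- setdiff(c("A", "C", "G", "T"), ch)[1]
        }
        bg <- .randomSeq(300, 0.45)
        txs[sprintf("TX%03d", i)] <- paste0(substr(bg, 1, 150), site,
            substr(bg, 151, 300))
    }
    txSet <- Biostrings::DNAStringSet(txs)
    Biostrings::writeXStringSet(txSet, file.path(dir, "transcripts.fa"))

    adaptor <- designs[[1]]$adaptor_3p
    cfgLines <- c(
        "# synthetic bundle configuration",
        "genome: genome.fa",
        "ncrna_fasta: ncrna.fa",
        "reference_fasta: reference.fa",
        "transcripts: transcripts.fa",
        paste0("reads_", names(depths), ": ", names(depths), ".fastq"),
        paste0("adaptor_3p: ", adaptor),
        "min_len: 18", "max_len: 25", "min_mean_quality: 20",
        "seed_length: 16", "max_flank: 250", "bcv: 0.2",
        "alpha: 0.05", "fdr_alpha: 0.05",
        "contrasts: leaf_nacl:leaf_control,root_nacl:root_control",
        "prefix: pda", "variant_max_mismatches: 2",
        "min_novel_reads: 10",
        paste0("seed: ", seed))
    cfgPath <- file.path(dir, "config.txt")
    writeLines(cfgLines, cfgPath)
    invisible(list(config = cfgPath, genome = gen, simulation = sim,
        foldChanges = fc, designs = designs))
}
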