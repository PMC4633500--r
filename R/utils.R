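`%||%` <- function(a, b) if (is.null(a)) b else a

# alphabet normalization: the pipeline stores tags and matures as RNA,
# the genome as DNA; comparisons always go through one of these two.
.asRNA <- function(x) chartr("Tt", "Uu", toupper(as.character(x)))

.asDNA <- function(x) chartr("Uu", "Tt", toupper(as.character(x)))

.revcompDNA <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.revcompRNA <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

# integer codes for vectorized per-position comparison
.seqCodes <- function(x) utf8ToInt(toupper(x))

.gcFraction <- function(x) {
    codes <- .seqCodes(x)
    sum(codes == utf8ToInt("G") | codes == utf8ToInt("C")) / length(codes)
}

# round half up, as used for pseudo-counts
.roundHalfUp <- function(x) floor(x + 0.5)

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
}

# FASTQ written through Biostrings with per-read quality strings
.writeFastq <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::PhredQuality(quals)
    qx <- Biostrings::QualityScaledDNAStringSet(x, q)
    Biostrings::writeQualityScaledXStringSet(qx, path)
    invisible(path)
}

.readFastq <- function(path) {
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    list(sequences = as.character(x),
        qualities = as.character(Biostrings::quality(x)),
        ids = names(x))
}

# mean Phred score of a quality string (Phred+33)
.meanPhred <- function(qual) {
    vapply(qual, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
        USE.NAMES = FALSE)
}
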