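#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Unique small-RNA tags with per-library counts
#'
#' A \code{TagSet} holds the distinct 18--25 nt sequences observed after
#' adaptor trimming, quality/length filtering and collapsing, together with
#' the number of reads supporting each sequence in every library and a
#' per-tag annotation category.
#'
#' @slot sequences An \code{\link[Biostrings]{RNAStringSet}} of distinct
#'   tag sequences (RNA alphabet; T is normalized to U on construction).
#' @slot counts Integer matrix, one row per tag and one column per library;
#'   all entries nonnegative and no row entirely zero.
#' @slot category Character vector, one of \code{unassigned}, \code{rRNA},
#'   \code{tRNA}, \code{snoRNA}, \code{snRNA}, \code{mapped},
#'   \code{unmapped}.
#'
#' @seealso \code{\link{collapseReads}}, \code{\link{filterAnnotated}}
#' @export
setClass("TagSet",
    representation(
        sequences = "RNAStringSet",
        counts = "matrix",
        category = "character"
    )
)

.TAG_CATEGORIES <- c("unassigned", "rRNA", "tRNA", "snoRNA", "snRNA",
    "mapped", "unmapped")

setValidity("TagSet", function(object) {
    msg <- character(0)
    n <- length(object@sequences)
    w <- Biostrings::width(object@sequences)
    if (n > 0 && (any(w < 18) || any(w > 25)))
        msg <- c(msg, "tag lengths must lie in [18, 25]")
    if (nrow(object@counts) != n)
        msg <- c(msg, "counts must have one row per tag")
    if (n > 0 && is.null(colnames(object@counts)))
        msg <- c(msg, "counts must have library ids as column names")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be nonnegative")
    if (n > 0 && any(rowSums(object@counts) == 0))
        msg <- c(msg, "every tag must have at least one nonzero count")
    if (length(object@category) != n)
        msg <- c(msg, "category must have one entry per tag")
    if (!all(object@category %in% .TAG_CATEGORIES))
        msg <- c(msg, sprintf("category values must be among: %s",
            paste(.TAG_CATEGORIES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a TagSet
#'
#' @param sequences Character vector or XStringSet of tag sequences
#'   (DNA or RNA alphabet; normalized to RNA).
#' @param counts Integer matrix (tags x libraries) with library ids as
#'   column names; a vector is accepted for a single library.
#' @param category Optional character vector of per-tag categories
#'   (default \code{"unassigned"}).
#' @return A \code{\linkS4class{TagSet}}.
#' @examples
#' ts <- TagSet("UUGACAGAAGAUAGAGAGCAC", counts = cbind(leaf = 5L))
#' tagLength(ts)
#' @export
TagSet <- function(sequences, counts, category = NULL) {
    seqs <- Biostrings::RNAStringSet(chartr("Tt", "Uu",
        toupper(as.character(sequences))))
    if (is.null(dim(counts)))
        counts <- matrix(counts, ncol = 1,
            dimnames = list(NULL, names(counts) %||% "library_1"))
    storage.mode(counts) <- "integer"
    rownames(counts) <- NULL
    if (is.null(category))
        category <- rep("unassigned", length(seqs))
    new("TagSet", sequences = seqs, counts = counts, category = category)
}

#' Hairpin precursor acceptance thresholds
#'
#' Thresholds applied to a folded candidate precursor window: structural
#' bounds on the stem, terminal loop and mature region, minimum read
#' support, and the stringent MFE/MFEI filter.  Defaults are the pipeline
#' defaults used for plant MIR annotation (see the methods vignette).
#'
#' @slot maxErrorsOneBulgeStem Max unpaired nt in any one stem bulge (12).
#' @slot minStemBp Min base pairs in the stem (16).
#' @slot maxFreeEnergy Max folding free energy, kcal/mol (-15).
#' @slot minHairpinLen Min hairpin span, stem plus terminal loop, nt (50).
#' @slot maxTerminalLoop Max terminal-loop length, nt (350).
#' @slot maxErrorsOneBulgeMature Max unpaired nt in one mature-region
#'   bulge (8).
#' @slot maxBiasedErrorsOneBulgeMature Max unpaired nt in one biased
#'   (unopposed) mature-region bulge (4).
#' @slot maxBiasedBulgesMature Max number of biased bulges in the mature
#'   region (2).
#' @slot minMatureBp Min base pairs within the mature region (12).
#' @slot minPmStemFraction Min fraction of supporting-tag nucleotides on
#'   the stem arms (0.80).
#' @slot maxErrorsMature Max unpaired nt in the mature region (7).
#' @slot minTotalReads Min total supporting reads over all libraries (10).
#' @slot stringentMaxMfe Stringent MFE cutoff, kcal/mol (-40).
#' @slot minMfei Minimum folding free energy index (0.85).
#' @export
setClass("HairpinCriteria",
    representation(
        maxErrorsOneBulgeStem = "numeric",
        minStemBp = "numeric",
        maxFreeEnergy = "numeric",
        minHairpinLen = "numeric",
        maxTerminalLoop = "numeric",
        maxErrorsOneBulgeMature = "numeric",
        maxBiasedErrorsOneBulgeMature = "numeric",
        maxBiasedBulgesMature = "numeric",
        minMatureBp = "numeric",
        minPmStemFraction = "numeric",
        maxErrorsMature = "numeric",
        minTotalReads = "numeric",
        stringentMaxMfe = "numeric",
        minMfei = "numeric"
    ),
    prototype(
        maxErrorsOneBulgeStem = 12,
        minStemBp = 16,
        maxFreeEnergy = -15,
        minHairpinLen = 50,
        maxTerminalLoop = 350,
        maxErrorsOneBulgeMature = 8,
        maxBiasedErrorsOneBulgeMature = 4,
        maxBiasedBulgesMature = 2,
        minMatureBp = 12,
        minPmStemFraction = 0.80,
        maxErrorsMature = 7,
        minTotalReads = 10,
        stringentMaxMfe = -40,
        minMfei = 0.85
    )
)

setValidity("HairpinCriteria", function(object) {
    msg <- character(0)
    vals <- vapply(slotNames(object), function(s) slot(object, s), numeric(1))
    if (any(!is.finite(vals)))
        msg <- c(msg, "all thresholds must be finite")
    if (object@maxFreeEnergy >= 0 || object@stringentMaxMfe >= 0)
        msg <- c(msg, "energy thresholds must be negative")
    if (object@minPmStemFraction <= 0 || object@minPmStemFraction > 1)
        msg <- c(msg, "minPmStemFraction must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' @param ... Named threshold overrides (see the class slots).
#' @return A \code{\linkS4class{HairpinCriteria}} object.
#' @examples
#' hairpinCriteria()
#' hairpinCriteria(minTotalReads = 5)
#' @rdname HairpinCriteria-class
#' @export
hairpinCriteria <- function(...) new("HairpinCriteria", ...)

#' RNA secondary structure with folding free energy
#'
#' Minimum-energy non-crossing structure of an RNA sequence under the
#' package's built-in energy model (see \code{\link{foldRNA}}).
#'
#' @slot sequence RNA sequence (character).
#' @slot dotBracket Balanced dot-bracket string, same length as the
#'   sequence; no pseudoknots.
#' @slot mfe Folding free energy in kcal/mol; \code{<= 0}, and \code{0}
#'   exactly when no base pairs are formed.
#' @slot pairTable Integer vector: 1-based partner of each position,
#'   0 when unpaired.
#' @export
setClass("SecondaryStructure",
    representation(
        sequence = "character",
        dotBracket = "character",
        mfe = "numeric",
        pairTable = "integer"
    )
)

setValidity("SecondaryStructure", function(object) {
    msg <- character(0)
    n <- nchar(object@sequence)
    if (nchar(object@dotBracket) != n)
        msg <- c(msg, "dotBracket length must equal sequence length")
    if (length(object@pairTable) != n)
        msg <- c(msg, "pairTable length must equal sequence length")
    db <- strsplit(object@dotBracket, "")[[1]]
    depth <- cumsum((db == "(") - (db == ")"))
    if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0))
        msg <- c(msg, "unbalanced dot-bracket string")
    pt <- object@pairTable
    paired <- which(pt > 0)
    if (any(pt[pt > 0] > n) || !all(pt[pt[paired]] == paired))
        msg <- c(msg, "pairTable is not an involution")
    if (object@mfe > 0)
        msg <- c(msg, "mfe must be <= 0")
    if (object@mfe == 0 && length(paired) > 0)
        msg <- c(msg, "mfe of 0 implies an unpaired structure")
    if (object@mfe < 0 && length(paired) == 0)
        msg <- c(msg, "negative mfe requires at least one pair")
    if (length(msg)) msg else TRUE
})

#' Exact k-mer index of a genome for seed-and-verify mapping
#'
#' Lookup structure over all \code{seedLength}-mers of both strands of a
#' genome, used by \code{\link{mapTag}}.
#'
#' @slot kmers Environment mapping each seed k-mer to an integer matrix of
#'   occurrence triples (contig index, strand code, 0-based start on the
#'   strand sequence).
#' @slot seedLength Seed length in nt (default 16).
#' @slot seqs List of per-contig forward and reverse-complement sequences.
#' @slot seqnames,seqlengths Contig names and lengths.
#' @slot nForwardSeeds Number of forward-strand seed positions indexed.
#' @export
setClass("GenomeIndex",
    representation(
        kmers = "environment",
        seedLength = "integer",
        seqs = "list",
        seqnames = "character",
        seqlengths = "integer",
        nForwardSeeds = "integer"
    )
)
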