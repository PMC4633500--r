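#' @rdname TagSet-class
#' @param x,object A \code{TagSet}.
#' @export
setGeneric("tagSequences", function(x) standardGeneric("tagSequences"))

#' @rdname TagSet-class
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @rdname TagSet-class
#' @export
setGeneric("tagCategory", function(x) standardGeneric("tagCategory"))

#' @rdname TagSet-class
#' @export
setGeneric("tagCategory<-",
    function(x, value) standardGeneric("tagCategory<-"))

#' @rdname TagSet-class
#' @export
setGeneric("tagLength", function(x) standardGeneric("tagLength"))

#' @rdname TagSet-class
#' @export
setGeneric("libraryNames", function(x) standardGeneric("libraryNames"))

#' @rdname SecondaryStructure-class
#' @param x A \code{SecondaryStructure}.
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("mfe", function(x) standardGeneric("mfe"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @describeIn TagSet-class Tag sequences as an RNAStringSet.
setMethod("tagSequences", "TagSet", function(x) x@sequences)

#' @describeIn TagSet-class Per-library count matrix.
setMethod("tagCounts", "TagSet", function(x) x@counts)

#' @describeIn TagSet-class Per-tag annotation category.
setMethod("tagCategory", "TagSet", function(x) x@category)

#' @param value Replacement category vector.
#' @describeIn TagSet-class Replace the per-tag category.
setMethod("tagCategory<-", "TagSet", function(x, value) {
    x@category <- value
    validObject(x)
    x
})

#' @describeIn TagSet-class Tag lengths in nt.
setMethod("tagLength", "TagSet", function(x)
    Biostrings::width(x@sequences))

#' @describeIn TagSet-class Library identifiers.
setMethod("libraryNames", "TagSet", function(x) colnames(x@counts))

#' @describeIn TagSet-class Number of tags.
#' @export
setMethod("length", "TagSet", function(x) length(x@sequences))

#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @describeIn TagSet-class Subset tags.
#' @export
setMethod("[", "TagSet", function(x, i, j, ..., drop = TRUE) {
    new("TagSet", sequences = x@sequences[i],
        counts = x@counts[i, , drop = FALSE],
        category = x@category[i])
})

setMethod("show", "TagSet", function(object) {
    cat(sprintf("TagSet with %d tags over %d libraries\n",
        length(object@sequences), ncol(object@counts)))
    if (ncol(object@counts))
        cat("  libraries:", paste(colnames(object@counts), collapse = ", "),
            "\n")
    if (length(object@sequences)) {
        cat(sprintf("  lengths: %d..%d nt; total reads: %d\n",
            min(Biostrings::width(object@sequences)),
            max(Biostrings::width(object@sequences)),
            sum(object@counts)))
        tb <- table(object@category)
        cat("  categories:", paste(sprintf("%s=%d", names(tb), tb),
            collapse = ", "), "\n")
    }
})

setMethod("show", "SecondaryStructure", function(object) {
    cat(sprintf("SecondaryStructure (%d nt, MFE %.1f kcal/mol)\n",
        nchar(object@sequence), object@mfe))
    cat(" ", object@sequence, "\n ", object@dotBracket, "\n")
})

#' @describeIn SecondaryStructure-class Dot-bracket string.
setMethod("dotBracket", "SecondaryStructure", function(x) x@dotBracket)

#' @describeIn SecondaryStructure-class Folding free energy (kcal/mol).
setMethod("mfe", "SecondaryStructure", function(x) x@mfe)

#' @describeIn SecondaryStructure-class 1-based partner table (0 =
#'   unpaired).
setMethod("pairTable", "SecondaryStructure", function(x) x@pairTable)

setMethod("show", "HairpinCriteria", function(object) {
    cat("HairpinCriteria:\n")
    for (s in slotNames(object))
        cat(sprintf("  %s = %s\n", s, format(slot(object, s))))
})

setMethod("show", "GenomeIndex", function(object) {
    cat(sprintf(
        "GenomeIndex: %d contig(s), seed length %d, %d forward seeds\n",
        length(object@seqnames), object@seedLength, object@nForwardSeeds))
})
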