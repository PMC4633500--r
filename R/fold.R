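#' Fold an RNA sequence into its minimum-energy secondary structure
#'
#' Computes the minimum-energy non-crossing (pseudoknot-free) secondary
#' structure of an RNA sequence by dynamic programming under the
#' package's built-in surrogate energy model: pair energies GC -3.0,
#' AU -2.0, GU -1.0 kcal/mol; a stacking bonus of -0.5 for each pair
#' stacked directly on another; a hairpin-loop penalty of +3.0; +1.0 for
#' each bulge or internal-loop occurrence (and, as a package choice, for
#' each multiloop); hairpin loops enclose at least 3 nt.  The traceback
#' is deterministic.
#'
#' The model is a pluggable surrogate for a full thermodynamic folding
#' engine: any backend returning a dot-bracket string and an MFE can be
#' substituted upstream of \code{\link{evaluateHairpin}}.
#'
#' @param sequence RNA string (ACGU; T is accepted and read as U), at
#'   least 10 nt for precursor work.
#' @param minLength Minimum accepted sequence length (default 10).
#' @return A \code{\linkS4class{SecondaryStructure}}.
#' @examples
#' foldRNA("GGGGAAAACCCC")   # 4 GC pairs closing a 4-nt loop, MFE -10.5
#' @export
foldRNA <- function(sequence, minLength = 10) {
    sequence <- .asRNA(sequence)
    if (nchar(sequence) < minLength)
        stop("sequence must be at least ", minLength, " nt")
    if (grepl("[^ACGU]", sequence))
        stop("sequence contains characters outside ACGU")
    res <- .fold_rna_cpp(sequence)
    new("SecondaryStructure",
        sequence = sequence,
        dotBracket = res$dot_bracket,
        mfe = res$mfe,
        pairTable = as.integer(res$pair_table))
}

#' Minimum folding free energy index (MFEI)
#'
#' MFEI adjusts the folding free energy for sequence length and GC
#' content: \code{(|MFE| / length * 100) / (GC% )} with GC% on the 0-100
#' scale.  Values above 0.85 discriminate miRNA precursors from other
#' small RNAs.
#'
#' @param mfe Folding free energy in kcal/mol (<= 0).
#' @param length Sequence length in nt (> 0).
#' @param gcFraction GC fraction in (0, 1].
#' @return The MFEI (nonnegative numeric).
#' @examples
#' computeMfei(-60, 100, 0.50)   # 1.2
#' @export
computeMfei <- function(mfe, length, gcFraction) {
    if (length <= 0)
        stop("length must be positive")
    if (any(gcFraction <= 0) || any(gcFraction > 1))
        stop("MFEI is undefined for gcFraction outside (0, 1]")
    (abs(mfe) / length * 100) / (gcFraction * 100)
}
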