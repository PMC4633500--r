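#' Median-of-ratios library size factors
#'
#' For each library j, the size factor is the median over rows i (with
#' all counts positive) of c_ij divided by the row geometric mean over
#' all m libraries -- the ratio of each sample to a pseudo-reference
#' sample.  The median of an even-length list is the mean of the middle
#' two values.
#'
#' @param counts Count matrix (miRNAs x libraries), nonnegative.
#' @return List with \code{sizeFactors} (named positive numerics) and
#'   \code{pseudoReference} (per-row geometric means; \code{NA} for
#'   rows containing zeros).
#' @examples
#' m <- cbind(a = c(10, 20), b = c(20, 40))
#' medianRatioSizeFactors(m)$sizeFactors   # 1/sqrt(2), sqrt(2)
#' @export
medianRatioSizeFactors <- function(counts) {
    counts <- as.matrix(counts)
    allPos <- rowSums(counts > 0) == ncol(counts)
    if (!any(allPos))
        stop("no row with all counts positive; size factors undefined")
    geo <- rep(NA_real_, nrow(counts))
    geo[allPos] <- exp(rowMeans(log(counts[allPos, , drop = FALSE])))
    sf <- apply(counts[allPos, , drop = FALSE] / geo[allPos], 2, median)
    names(sf) <- colnames(counts)
    list(sizeFactors = sf, pseudoReference = geo)
}

#' Normalize counts by size factors
#'
#' @param counts Count matrix.
#' @param model Output of \code{\link{medianRatioSizeFactors}} (or a
#'   numeric vector of size factors).
#' @return Matrix of normalized counts \code{c_ij / s_j}.
#' @export
normalizeCounts <- function(counts, model) {
    sf <- if (is.list(model)) model$sizeFactors else model
    stopifnot(length(sf) == ncol(counts))
    sweep(as.matrix(counts), 2, sf, "/")
}

#' Fixed-dispersion negative-binomial exact test
#'
#' Two-sided exact conditional test of equal means for one count per
#' condition.  Counts are scaled to a common effective library size
#' (pseudo-counts = count / size factor, rounded half up); conditioning
#' on the pseudo-count sum s, the two-sided p-value sums the
#' probabilities of all splits of s no more probable than the observed
#' one, under NB(mean mu, variance mu + phi mu^2) in both groups.  With
#' phi = 0 the conditional law is Binomial(s, 1/2).  The fold change is
#' log2((count_b/s_b + 0.5) / (count_a/s_a + 0.5)).
#'
#' @param countA,countB Observed counts (nonnegative, not both zero).
#' @param sA,sB Size factors (default 1).
#' @param dispersion NB dispersion phi (default 0.04, i.e. BCV 0.2).
#' @return List with \code{log2FC} and \code{p_value}.
#' @export
nbExactTest <- function(countA, countB, sA = 1, sB = 1,
                        dispersion = 0.04) {
    if (dispersion < 0) stop("dispersion must be nonnegative")
    if (countA < 0 || countB < 0) stop("counts must be nonnegative")
    if (countA + countB == 0) stop("counts must not both be zero")
    a <- .roundHalfUp(countA / sA)
    b <- .roundHalfUp(countB / sB)
    log2FC <- log2((countB / sB + 0.5) / (countA / sA + 0.5))
    s <- a + b
    if (s == 0) return(list(log2FC = log2FC, p_value = 1))
    mu <- s / 2
    k <- 0:s
    logp <- if (dispersion == 0) {
        dbinom(k, s, 0.5, log = TRUE)
    } else {
        dnbinom(k, mu = mu, size = 1 / dispersion, log = TRUE) +
            dnbinom(s - k, mu = mu, size = 1 / dispersion, log = TRUE)
    }
    prob <- exp(logp - max(logp))
    prob <- prob / sum(prob)
    pObs <- prob[a + 1]
    p <- sum(prob[prob <= pObs * (1 + 1e-10)])
    list(log2FC = log2FC, p_value = min(1, p))
}

#' Exact-test differential expression over a count matrix
#'
#' Runs \code{\link{nbExactTest}} for every row of a count matrix on
#' one treated-vs-control library pair, with median-of-ratios size
#' factors and Benjamini-Hochberg adjustment.  A miRNA is significant
#' when both the p-value and the FDR fall below their thresholds.
#'
#' @param counts Count matrix (all-zero rows are removed first).
#' @param control,treated Library (column) names of the contrast.
#' @param dispersion NB dispersion phi (default 0.04 = BCV 0.2).
#' @param alpha,fdrAlpha Significance thresholds (defaults 0.05).
#' @param sizeFactors Optional precomputed size factors.
#' @return Data frame: mirna_id, contrast, log2FC, p_value, fdr,
#'   significant, dispersion.
#' @export
exactTestTable <- function(counts, control, treated, dispersion = 0.04,
                           alpha = 0.05, fdrAlpha = 0.05,
                           sizeFactors = NULL) {
    counts <- as.matrix(counts)
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    if (is.null(sizeFactors))
        sizeFactors <- medianRatioSizeFactors(counts)$sizeFactors
    sA <- sizeFactors[[control]]
    sB <- sizeFactors[[treated]]
    usable <- counts[, control] + counts[, treated] > 0
    res <- lapply(which(usable), function(i)
        nbExactTest(counts[i, control], counts[i, treated], sA, sB,
            dispersion))
    p <- vapply(res, `[[`, numeric(1), "p_value")
    fdr <- bhAdjust(p)
    out <- data.frame(
        mirna_id = rownames(counts)[usable] %||%
            as.character(which(usable)),
        contrast = paste(treated, "vs", control),
        log2FC = vapply(res, `[[`, numeric(1), "log2FC"),
        p_value = p, fdr = fdr,
        significant = p < alpha & fdr < fdrAlpha,
        dispersion = dispersion)
    rownames(out) <- NULL
    out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment with monotonicity enforcement; inputs outside
#' [0, 1] are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted FDR values in [0, 1].
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Complete-linkage hierarchical clustering order
#'
#' Agglomerative clustering under maximum inter-cluster distance on
#' Euclidean distances of log2(n + 1)-transformed normalized counts;
#' returns row and column leaf orders for heatmap rendering along with
#' the merge trees.
#'
#' @param normalized Normalized count matrix (>= 2 rows).
#' @param transform Transformation applied before distances (default
#'   \code{log2(x + 1)}).
#' @return List with \code{rowOrder}, \code{colOrder}, \code{rowMerge},
#'   \code{rowHeight}, \code{colMerge}, \code{colHeight}.
#' @export
completeLinkageOrder <- function(normalized,
                                 transform = function(x) log2(x + 1)) {
    m <- transform(as.matrix(normalized))
    stopifnot(nrow(m) >= 2)
    hr <- hclust(dist(m), method = "complete")
    out <- list(rowOrder = hr$order, rowMerge = hr$merge,
        rowHeight = hr$height)
    if (ncol(m) >= 2) {
        hc <- hclust(dist(t(m)), method = "complete")
        out$colOrder <- hc$order
        out$colMerge <- hc$merge
        out$colHeight <- hc$height
    } else {
        out$colOrder <- seq_len(ncol(m))
    }
    out
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold of control from qPCR cycle thresholds of a target and a
#' reference gene under treated and control conditions.
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl
#'   Finite Ct values.
#' @return Fold change \code{2^-ddCt}.
#' @examples
#' ddctFoldChange(20, 18, 22, 19)   # ddCt = -1, fold change 2
#' @export
ddctFoldChange <- function(ctTargetTreated, ctRefTreated,
                           ctTargetControl, ctRefControl) {
    stopifnot(is.finite(ctTargetTreated), is.finite(ctRefTreated),
        is.finite(ctTargetControl), is.finite(ctRefControl))
    ddct <- (ctTargetTreated - ctRefTreated) -
        (ctTargetControl - ctRefControl)
    2^(-ddct)
}
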