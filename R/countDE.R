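#' RPKM normalisation
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \eqn{RPKM_{g,s} = 10^9 \, c_{g,s} / (L_g \, T_s)} with gene length
#' \eqn{L_g} in bp and library total \eqn{T_s}. For every sample the
#' identity \eqn{\sum_g RPKM_{g,s} \cdot L_g/10^3 = 10^6} holds when
#' \code{libraryTotals} are the column sums.
#'
#' @param counts genes x samples matrix of nonnegative read counts, or a
#'   [HeatCountSet-class].
#' @param geneLengths gene lengths in bp (ignored for a \code{HeatCountSet}).
#' @param libraryTotals per-sample totals; default column sums of
#'   \code{counts}.
#' @return matrix of RPKM values, same dimensions as \code{counts}.
#' @examples
#' rpkm(matrix(10), geneLengths = 1000, libraryTotals = 1e6)  # 10
#' @export
rpkm <- function(counts, geneLengths = NULL, libraryTotals = NULL) {
  if (is(counts, "HeatCountSet")) {
    geneLengths <- geneLengths(counts)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (is.null(libraryTotals)) libraryTotals <- colSums(counts)
  if (any(geneLengths <= 0)) stop("gene lengths must be positive")
  if (any(libraryTotals <= 0)) stop("library totals must be positive")
  if (length(geneLengths) != nrow(counts))
    stop("one gene length per row required")
  1e9 * sweep(counts / geneLengths, 2, libraryTotals, "/")
}

#' Median-of-ratios scaling factors
#'
#' One scaling factor per sample: the median across genes of the ratio of
#' the sample's counts to the gene-wise geometric-mean reference profile,
#' using only genes with strictly positive counts in every sample, then
#' normalised so the factors have geometric mean 1. When no gene is
#' positive in all samples, library-size factors are returned with a
#' warning.
#'
#' @param counts genes x samples count matrix (>= 2 samples) or a
#'   [HeatCountSet-class].
#' @return named numeric vector of positive per-sample factors.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' scalingFactors(m)  # (1/sqrt(2), sqrt(2))
#' @export
scalingFactors <- function(counts) {
  if (is(counts, "HeatCountSet"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("at least 2 samples required")
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    warning("no gene with all-positive counts; using library-size factors")
    f <- colSums(counts)
  } else {
    logref <- rowMeans(log(counts[ok, , drop = FALSE]))
    f <- apply(counts[ok, , drop = FALSE], 2,
               function(s) exp(stats::median(log(s) - logref)))
  }
  f / exp(mean(log(f)))
}

#' Log2 fold change of two group means
#'
#' @param meanA,meanB positive group means (vectorised); direction is
#'   \code{meanA} over \code{meanB}.
#' @param pseudocount optional nonnegative value added to both means
#'   (default 0; required when a mean is zero).
#' @return numeric log2(meanA/meanB).
#' @examples
#' log2fc(259.96, 121.66)  # 1.0954...
#' @export
log2fc <- function(meanA, meanB, pseudocount = 0) {
  meanA <- meanA + pseudocount
  meanB <- meanB + pseudocount
  if (any(meanA <= 0) || any(meanB <= 0))
    stop("means must be positive (use a pseudocount for zeros)")
  log2(meanA / meanB)
}

#' Round half away from zero
#'
#' Fixed-decimal rounding in which ties go away from zero (the convention
#' of the printed expression tables), unlike base \code{round}'s
#' round-half-even.
#'
#' @param x numeric.
#' @param digits number of decimal places.
#' @return rounded numeric.
#' @examples
#' roundHalfAway(2.345, 2)   # 2.35
#' roundHalfAway(-2.345, 2)  # -2.35
#' @export
roundHalfAway <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Differential-expression screen on a count matrix
#'
#' Normalises counts by [scalingFactors()], sums the normalised counts
#' within each of two groups, applies the two-library exact Poisson test
#' ([twoSidedP()]) to the rounded group totals, adjusts by
#' Benjamini-Hochberg and flags genes with \code{p_adj < alpha} and
#' \code{|log2 fold change| > minAbsLfc}. The exact test on pooled
#' normalised counts is a deliberately simple screen statistic: it shares
#' the fold-change arithmetic and thresholds of negative-binomial tools
#' without their dispersion shrinkage, so its p-values are anti-conservative
#' under biological replication and should be read as a screen, not an
#' inference.
#'
#' @param x a [HeatCountSet-class], or a genes x samples count matrix.
#' @param groups per-sample group labels (two groups; taken from
#'   \code{colData} for a \code{HeatCountSet}). The first group in factor
#'   order is the baseline: fold changes are group 2 over group 1.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param minAbsLfc minimum |log2 fold change| (default 1).
#' @param pseudocount added to group means for the fold change (default 0;
#'   genes with a zero group mean get NA fold change when 0).
#' @return data.frame: \code{gene_id}, \code{mean_1}, \code{mean_2}
#'   (normalised group means), \code{log2_fold_change}, \code{p_value},
#'   \code{p_adj}, \code{is_deg}, \code{direction}.
#' @examples
#' sim <- simCountMatrix(nGenes = 100, deFraction = 0.2, effectLog2 = 2,
#'                       seed = 7)
#' head(deScreen(sim$cset))
#' @export
deScreen <- function(x, groups = NULL, alpha = 0.05, minAbsLfc = 1,
                     pseudocount = 0) {
  if (is(x, "HeatCountSet")) {
    if (is.null(groups)) groups <- sampleGroups(x)
    x <- SummarizedExperiment::assay(x, "counts")
  }
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 1L)) stop("each group needs at least one sample")
  f <- scalingFactors(x)
  norm <- sweep(x, 2, f, "/")
  g1 <- norm[, groups == levels(groups)[1], drop = FALSE]
  g2 <- norm[, groups == levels(groups)[2], drop = FALSE]
  s1 <- round(rowSums(g1))
  s2 <- round(rowSums(g2))
  N1 <- sum(s1); N2 <- sum(s2)
  p <- twoSidedP(s1, s2, N1, N2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  lfc <- ifelse(m1 + pseudocount > 0 & m2 + pseudocount > 0,
                log2((m2 + pseudocount) / (m1 + pseudocount)), NA_real_)
  padj <- bhFdr(p)
  deg <- !is.na(lfc) & padj < alpha & abs(lfc) > minAbsLfc
  data.frame(gene_id = rownames(x), mean_1 = m1, mean_2 = m2,
             log2_fold_change = lfc, p_value = p, p_adj = padj,
             is_deg = deg,
             direction = ifelse(deg, ifelse(lfc > 0, "up", "down"),
                                NA_character_),
             row.names = NULL)
}
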