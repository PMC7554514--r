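#' Equal-expression probability term of the two-library exact test
#'
#' For a gene with \code{x} clean tags in library 1 (total \code{N1}) the
#' probability of observing \code{i} tags in library 2 (total \code{N2})
#' under equal expression is
#' \deqn{p(i\mid x) = (N2/N1)^i \frac{(x+i)!}{x!\,i!} (1+N2/N1)^{-(x+i+1)}}
#' evaluated in log space with \code{lgamma} so that large counts do not
#' overflow. Over all \code{i} the terms sum to 1.
#'
#' @param i nonnegative integer (vectorised), tag count in library 2.
#' @param x nonnegative integer, tag count in library 1.
#' @param N1,N2 positive totals of clean tags in libraries 1 and 2.
#' @param log logical, return the log probability.
#' @return numeric, \code{p(i|x)} (or its log).
#' @examples
#' pEqualTerm(0, 0, 1e6, 1e6)   # 0.5
#' sum(pEqualTerm(0:400, 50, 1e6, 2e6))  # ~1
#' @export
pEqualTerm <- function(i, x, N1, N2, log = FALSE) {
  if (any(i < 0) || any(x < 0)) stop("tag counts must be nonnegative")
  if (N1 <= 0 || N2 <= 0) stop("library totals must be positive")
  logr <- base::log(N2) - base::log(N1)
  lp <- i * logr + lgamma(x + i + 1) - lgamma(x + 1) - lgamma(i + 1) -
    (x + i + 1) * log1p(exp(logr))
  if (log) lp else exp(lp)
}

## cumulative sum S = sum_{i=0}^{y} p(i|x), scalar x, y
.pEqualCumsum <- function(x, y, N1, N2) {
  sum(pEqualTerm(0:y, x, N1, N2))
}

#' Two-sided p-value of the two-library exact Poisson test
#'
#' The probability that a gene with \code{x} tags in library 1 and \code{y}
#' tags in library 2 is equally expressed, computed as
#' \eqn{2\sum_{i=0}^{y} p(i|x)}, or \eqn{2(1 - \sum_{i=0}^{y} p(i|x))} when
#' the cumulative sum exceeds 0.5, clipped to \[0, 1\].
#'
#' @param x,y nonnegative integer tag counts (vectorised in parallel).
#' @param N1,N2 positive library totals of clean tags.
#' @return numeric p-values in \[0, 1\].
#' @examples
#' twoSidedP(0, 0, 1e6, 1e6)    # 1
#' twoSidedP(10, 200, 1e6, 1e6) # tiny
#' @export
twoSidedP <- function(x, y, N1, N2) {
  if (length(y) != length(x)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("tag counts must be nonnegative")
  if (any(x != floor(x)) || any(y != floor(y)))
    stop("tag counts must be integers")
  p <- mapply(function(xi, yi) {
    S <- .pEqualCumsum(xi, yi, N1, N2)
    if (S > 0.5) 2 * (1 - S) else 2 * S
  }, x, y)
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' \code{stats::p.adjust(method = "BH")}; \code{method = "BY"} gives the
#' Benjamini-Yekutieli variant).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param method \code{"BH"} (default) or \code{"BY"}.
#' @return adjusted p-values, same length and order as \code{p}.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Library-size normalised fold change between two libraries
#'
#' \eqn{fold = ((y + c)/N2) / ((x + c)/N1)} with pseudocount \code{c}
#' (default 0). With \code{c = 0} a zero in one library yields an infinite
#' (or zero) fold; both zero is undefined and flagged \code{NA}.
#'
#' @param x,y tag counts (vectorised).
#' @param N1,N2 library totals.
#' @param pseudocount nonnegative count added to both sides before
#'   normalisation.
#' @return list with components \code{fold} and \code{log2_ratio}
#'   (direction: library 2 over library 1).
#' @examples
#' foldChange(100, 200, 1e6, 1e6)  # fold 2, log2 1
#' @export
foldChange <- function(x, y, N1, N2, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  num <- (y + pseudocount) / N2
  den <- (x + pseudocount) / N1
  fold <- ifelse(num == 0 & den == 0, NA_real_, num / den)
  list(fold = fold, log2_ratio = log2(fold))
}

#' Candidate screen on differential-expression results
#'
#' Flags candidates at \code{fdr <= fdrMax} with fold change above
#' \code{minFold} (up) or below \code{1/minFold} (down); genes with
#' undefined fold (both libraries zero, no pseudocount) are never
#' candidates.
#'
#' @param results data.frame carrying columns \code{fdr} and
#'   \code{fold_change} (as produced by [tagDGE()]).
#' @param fdrMax FDR threshold (default 0.001).
#' @param minFold fold-change threshold (default 2).
#' @return \code{results} with logical \code{is_candidate} and character
#'   \code{direction} (\code{"up"}, \code{"down"} or \code{NA}) columns.
#' @export
screenCandidates <- function(results, fdrMax = 0.001, minFold = 2) {
  stopifnot(all(c("fdr", "fold_change") %in% colnames(results)))
  up <- !is.na(results$fold_change) & results$fold_change > minFold
  down <- !is.na(results$fold_change) & results$fold_change < 1 / minFold
  results$is_candidate <- results$fdr <= fdrMax & (up | down)
  results$direction <- ifelse(results$is_candidate,
                              ifelse(up, "up", "down"), NA_character_)
  results
}

#' Two-library digital gene expression screen
#'
#' Runs the exact Poisson test gene-by-gene on a [TagLibraryPair-class],
#' adjusts p-values by Benjamini-Hochberg, computes library-size normalised
#' fold changes and applies the candidate screen
#' (default FDR <= 0.001 and fold change > 2 or < 1/2).
#'
#' @param pair a [TagLibraryPair-class].
#' @param fdrMax,minFold screen thresholds, see [screenCandidates()].
#' @param pseudocount passed to [foldChange()].
#' @return data.frame with one row per gene: \code{gene_id}, \code{x},
#'   \code{y}, \code{p_value}, \code{fdr}, \code{fold_change},
#'   \code{log2_ratio}, \code{is_candidate}, \code{direction}.
#' @examples
#' sim <- simTagLibraries(nGenes = 200, deFraction = 0.1, effectLog2 = 2,
#'                        librarySizes = c(1e5, 1e5), seed = 1)
#' res <- tagDGE(sim$pair)
#' table(res$direction, useNA = "ifany")
#' @export
tagDGE <- function(pair, fdrMax = 0.001, minFold = 2, pseudocount = 0) {
  stopifnot(is(pair, "TagLibraryPair"))
  cnt <- tagCounts(pair)
  N <- libSizes(pair)
  p <- twoSidedP(cnt[, 1], cnt[, 2], N[1], N[2])
  fc <- foldChange(cnt[, 1], cnt[, 2], N[1], N[2], pseudocount = pseudocount)
  res <- data.frame(gene_id = rownames(cnt), x = cnt[, 1], y = cnt[, 2],
                    p_value = p, fdr = bhFdr(p), fold_change = fc$fold,
                    log2_ratio = fc$log2_ratio, row.names = NULL)
  screenCandidates(res, fdrMax = fdrMax, minFold = minFold)
}
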