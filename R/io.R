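#' Read a two-library tag-count table
#'
#' TSV with columns \code{gene_id} and one count column per library
#' (exactly two). Library totals default to the column sums.
#'
#' @param file path to the TSV.
#' @param libSizes optional explicit totals of clean tags (length 2).
#' @return a [TagLibraryPair-class].
#' @export
readTagCounts <- function(file, libSizes = NULL) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (ncol(tab) != 3L)
    stop("expected columns: gene_id, count_lib1, count_lib2")
  cnt <- as.matrix(tab[, 2:3])
  rownames(cnt) <- tab[[1]]
  if (is.null(libSizes)) libSizes <- colSums(cnt)
  TagLibraryPair(cnt, libSizes = libSizes)
}

#' Read a count matrix with gene lengths
#'
#' TSV with columns \code{gene_id}, \code{length_bp}, then one count
#' column per sample; \code{groups} assigns each sample column to a
#' group.
#'
#' @param file path to the TSV.
#' @param groups named character (sample -> group) or character vector
#'   in column order.
#' @return a [HeatCountSet-class].
#' @export
readCountMatrix <- function(file, groups) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    stop("expected gene_id, length_bp and at least two sample columns")
  cnt <- as.matrix(tab[, -(1:2)])
  rownames(cnt) <- tab[[1]]
  if (!is.null(names(groups))) groups <- groups[colnames(cnt)]
  if (length(groups) != ncol(cnt))
    stop("one group label per sample column required")
  HeatCountSet(cnt, geneLength = tab[[2]], group = groups)
}

#' Read a qPCR Ct table
#'
#' TSV with columns \code{sample}, \code{gene}, \code{replicate},
#' \code{ct}, as consumed by [ddct()].
#'
#' @param file path to the TSV.
#' @return data.frame.
#' @export
readCtTable <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "ct")
  if (!all(need %in% colnames(tab)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  tab
}

#' Read an injury-level tally
#'
#' TSV with columns \code{level} (0..max) and \code{count}.
#'
#' @param file path to the TSV.
#' @return named integer vector of counts ordered by level, as consumed
#'   by [heatInjuryIndex()].
#' @export
readInjuryTally <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("level", "count") %in% colnames(tab)))
    stop("tally needs columns: level, count")
  tab <- tab[order(tab$level), ]
  if (!identical(as.integer(tab$level), seq_len(nrow(tab)) - 1L))
    stop("levels must be contiguous from 0")
  setNames(as.integer(tab$count), paste0("level", tab$level))
}
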