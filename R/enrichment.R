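#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for drawing \code{n} genes from a universe of \code{N}
#' containing \code{K} pathway members, i.e.
#' \eqn{\sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}}
#' (computed with \code{stats::phyper}).
#'
#' @param k observed overlap (vectorised).
#' @param n query size.
#' @param K pathway size.
#' @param N universe size.
#' @return probability in \[0, 1\].
#' @examples
#' hypergeomP(5, 5, 5, 10)  # 1/252
#' hypergeomP(0, 5, 5, 10)  # 1
#' @export
hypergeomP <- function(k, n, K, N) {
  if (any(k < 0) || n < 0 || K < 0 || N <= 0)
    stop("counts must be nonnegative, N positive")
  if (n > N || K > N) stop("n and K cannot exceed N")
  if (any(k > pmin(n, K))) stop("k cannot exceed min(n, K)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation analysis
#'
#' Hypergeometric test of a query gene list against every pathway of a
#' [GeneSetCollection-class]; one record per pathway overlapping the query,
#' Benjamini-Hochberg adjusted across the reported pathways, sorted by
#' \code{(q, p)}. Query genes outside the universe are dropped with a
#' warning.
#'
#' @param query character vector of gene ids.
#' @param collection a [GeneSetCollection-class].
#' @param qMax significance threshold on the adjusted p (default 0.05).
#' @return data.frame: \code{pathway_id}, \code{k} (overlap), \code{n}
#'   (query size), \code{K} (pathway size), \code{N} (universe size),
#'   \code{p}, \code{q}, \code{significant}.
#' @examples
#' gsc <- GeneSetCollection(list(a = paste0("g", 1:5),
#'                               b = paste0("g", 6:10)),
#'                          universe = paste0("g", 1:100))
#' enrich(paste0("g", 1:5), gsc)
#' @export
enrich <- function(query, collection, qMax = 0.05) {
  stopifnot(is(collection, "GeneSetCollection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, geneUniverse(collection))
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  sets <- pathwaySets(collection)
  N <- length(geneUniverse(collection))
  n <- length(query)
  if (n == 0L) {
    return(data.frame(pathway_id = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p = numeric(), q = numeric(),
                      significant = logical()))
  }
  k <- vapply(sets, function(s) length(intersect(query, s)), integer(1))
  keep <- k > 0L
  res <- data.frame(pathway_id = names(sets)[keep], k = k[keep], n = n,
                    K = lengths(sets)[keep], N = N, row.names = NULL)
  res$p <- mapply(hypergeomP, res$k, n, res$K, N)
  res$q <- bhFdr(res$p)
  res$significant <- res$q <= qMax
  res[order(res$q, res$p, res$pathway_id), , drop = FALSE]
}

#' Overlap of the top-k pathways of two ranked lists
#'
#' @param listA,listB character vectors of pathway ids, most enriched
#'   first (e.g. \code{pathway_id} columns of two [enrich()] results).
#' @param k depth of comparison (default 20).
#' @return integer, \eqn{|top_k(A) \cap top_k(B)|}.
#' @examples
#' topKOverlap(letters[1:20], letters[11:30], k = 20)  # 10
#' @export
topKOverlap <- function(listA, listB, k = 20) {
  if (k > length(listA) || k > length(listB))
    stop("k exceeds a list length")
  length(intersect(head(listA, k), head(listB, k)))
}

#' Read a GMT pathway file
#'
#' Parses the tab-separated GMT gene-set format (one pathway per line:
#' id, description, genes...) via \code{fgsea::gmtPathways}.
#'
#' @param file path to a GMT file.
#' @param universe gene universe; defaults to the union of all sets.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(file, universe = NULL) {
  sets <- fgsea::gmtPathways(file)
  if (is.null(universe)) universe <- unique(unlist(sets))
  GeneSetCollection(sets, universe = universe)
}

#' Write a GMT pathway file
#'
#' @param collection a [GeneSetCollection-class].
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeGmt <- function(collection, file) {
  stopifnot(is(collection, "GeneSetCollection"))
  sets <- pathwaySets(collection)
  lines <- vapply(names(sets), function(id)
    paste(c(id, id, sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, file)
  invisible(file)
}
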