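#' Pairwise p-distance of an alignment
#'
#' Proportion of mismatching sites between every pair of aligned
#' sequences, excluding (pairwise) any position where either sequence has
#' a gap character (\code{-}, \code{.} or \code{?}).
#'
#' @param alignment an \code{AAStringSet}/\code{DNAStringSet} or named
#'   character vector of equal-length aligned sequences (>= 2).
#' @return symmetric numeric matrix of distances with zero diagonal.
#' @examples
#' pDistance(c(a = "AAAA", b = "AATT"))["a", "b"]  # 0.5
#' @export
pDistance <- function(alignment) {
  if (is(alignment, "XStringSet")) alignment <- as.character(alignment)
  if (is.null(names(alignment)))
    names(alignment) <- paste0("t", seq_along(alignment))
  n <- length(alignment)
  if (n < 2L) stop("at least 2 sequences required")
  if (length(unique(nchar(alignment))) != 1L)
    stop("sequences must be aligned (equal length)")
  m <- do.call(rbind, strsplit(alignment, ""))
  gap <- m %in% c("-", ".", "?")
  dim(gap) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) stop("no comparable sites between sequences ", i, " and ", j)
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

## canonical lowest-(i,j) argmin over the upper triangle of Q
.minPair <- function(Q) {
  n <- nrow(Q)
  best <- c(NA, NA); bestv <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (Q[i, j] < bestv - 1e-12) { bestv <- Q[i, j]; best <- c(i, j) }
  }
  best
}

.fmtLen <- function(b) sprintf("%.10g", b)

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix: at each step the pair
#' minimising \eqn{Q_{ij} = (n-2)d_{ij} - r_i - r_j} is joined (ties broken
#' by the lowest index pair), with branch lengths
#' \eqn{b_i = d_{ij}/2 + (r_i - r_j)/(2(n-2))} and the reduced distances
#' \eqn{d_{uk} = (d_{ik} + d_{jk} - d_{ij})/2}. Negative branch-length
#' estimates are clamped to 0 with the deficit moved to the sibling edge
#' (the pair's path length is preserved); the number of clamped edges is
#' recorded in \code{attr(tree, "clamped")}. For an additive matrix the
#' tree's leaf-to-leaf path lengths reproduce the input exactly.
#'
#' @param d symmetric distance matrix (or \code{dist}) over >= 3 taxa,
#'   with taxon names.
#' @return an unrooted \code{ape::phylo} tree (trifurcating root node).
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' njTree(d)$edge.length  # 1, 1, 2
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("at least 3 taxa required")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  labs <- rownames(d)
  nodes <- labs                 # newick fragment per active cluster
  clamped <- 0L
  clampPair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0; clamped <<- clamped + 1L }
    if (bj < 0) { bi <- bi + bj; bj <- 0; clamped <<- clamped + 1L }
    c(max(bi, 0), max(bj, 0))
  }
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- .minPair(Q)
    i <- ij[1]; j <- ij[2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    b <- clampPair(bi, bj)
    newnode <- paste0("(", nodes[i], ":", .fmtLen(b[1]), ",",
                      nodes[j], ":", .fmtLen(b[2]), ")")
    others <- setdiff(seq_len(m), c(i, j))
    du <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- d[others, others, drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    nodes <- c(nodes[others], newnode)
    rownames(d) <- colnames(d) <- NULL
  }
  # final 3-way join: closed-form branch lengths
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  cc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (a < 0 || b < 0 || cc < 0) clamped <- clamped + sum(c(a, b, cc) < 0)
  nwk <- paste0("(", nodes[1], ":", .fmtLen(max(a, 0)), ",",
                nodes[2], ":", .fmtLen(max(b, 0)), ",",
                nodes[3], ":", .fmtLen(max(cc, 0)), ");")
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

## descendant tip sets for every node of a phylo
.tipSets <- function(tr) {
  nt <- length(tr$tip.label)
  sets <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- tr$tip.label[i]
  eo <- ape::reorder.phylo(tr, "postorder")$edge
  for (k in seq_len(nrow(eo)))
    sets[[eo[k, 1]]] <- c(sets[[eo[k, 1]]], sets[[eo[k, 2]]])
  sets
}

## canonical keys of the non-trivial bipartitions, named by internal node
.bipartitionKeys <- function(tr) {
  nt <- length(tr$tip.label)
  root <- nt + 1L
  allTips <- sort(tr$tip.label)
  sets <- .tipSets(tr)
  internal <- setdiff(seq_len(nt + tr$Nnode)[-seq_len(nt)], root)
  keys <- vapply(internal, function(nd) {
    s <- sets[[nd]]
    side <- if (allTips[1] %in% s) s else setdiff(allTips, s)
    paste(sort(side), collapse = "|")
  }, character(1))
  names(keys) <- internal
  keys
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree from [pDistance()] + [njTree()], then
#' resamples alignment columns with replacement \code{nReps} times,
#' rebuilds the tree per replicate, and reports for each internal edge of
#' the full tree the percentage of replicates containing the same
#' bipartition. Supports are stored in \code{tree$node.label}
#' (root label empty).
#'
#' @param alignment aligned sequences, see [pDistance()].
#' @param nReps bootstrap replicates (default 1000; 0 skips supports).
#' @param seed RNG seed for resampling.
#' @return an \code{ape::phylo} with percentage supports as node labels.
#' @export
njBootstrap <- function(alignment, nReps = 1000, seed = NULL) {
  if (is(alignment, "XStringSet")) alignment <- as.character(alignment)
  full <- njTree(pDistance(alignment))
  if (nReps == 0) return(full)
  keys <- .bipartitionKeys(full)
  counts <- setNames(numeric(length(keys)), names(keys))
  L <- unique(nchar(alignment))
  m <- do.call(rbind, strsplit(alignment, ""))
  runBoot <- function() {
    for (b in seq_len(nReps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- setNames(apply(m[, cols, drop = FALSE], 1, paste,
                                collapse = ""), names(alignment))
      rt <- tryCatch(njTree(pDistance(rep_aln)), error = function(e) NULL)
      if (is.null(rt)) next
      repkeys <- .bipartitionKeys(rt)
      counts <<- counts + (keys %in% repkeys)
    }
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  }
  runBoot()
  nt <- length(full$tip.label)
  lab <- rep("", full$Nnode)
  idx <- as.integer(names(keys)) - nt
  lab[idx] <- format(100 * counts / nReps, trim = TRUE, digits = 4)
  full$node.label <- lab
  full
}
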