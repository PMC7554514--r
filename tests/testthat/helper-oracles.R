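# Independent brute-force oracles used across tests. These deliberately
# avoid the code paths they check (regex instead of matchPattern,
# combinatorial sums instead of phyper, dnbinom instead of the log-gamma
# term).

IUPAC_RE <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
              S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
              B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
              N = "[ACGT]")

iupacToRegex <- function(pat) {
  paste(IUPAC_RE[strsplit(pat, "")[[1]]], collapse = "")
}

revcompChr <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# all (overlapping) 1-based match starts of an IUPAC pattern in a string
oracleMatchStarts <- function(seqstr, pattern) {
  re <- paste0("(?=", iupacToRegex(pattern), ")")
  m <- gregexpr(re, seqstr, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# sliding-window scan equivalent of scanDre for one sequence
oracleScan <- function(seqstr, elements) {
  out <- list()
  for (el in names(elements)) {
    w <- nchar(elements[[el]])
    fw <- oracleMatchStarts(seqstr, elements[[el]])
    if (length(fw))
      out[[length(out) + 1L]] <- data.frame(element = el, start = fw,
                                            end = fw + w - 1L, strand = "+")
    rv <- oracleMatchStarts(seqstr, revcompChr(elements[[el]]))
    if (length(rv))
      out[[length(out) + 1L]] <- data.frame(element = el, start = rv,
                                            end = rv + w - 1L, strand = "-")
  }
  if (!length(out))
    return(data.frame(element = character(), start = integer(),
                      end = integer(), strand = character()))
  do.call(rbind, out)
}

# exact upper-tail hypergeometric by direct combinatorial summation
oracleHyperTail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# random CDS: ATG + (nCodons - 2) non-stop codons + TAA
makeCds <- function(nCodons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  all3 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
  body <- sample(setdiff(all3, stops), nCodons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

# random additive distance matrix from a random unrooted tree; returns
# both for round-trip checks
randomAdditive <- function(nTaxa, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(nTaxa, br = function(n) runif(n, 0.1, 1)))
  d <- ape::cophenetic.phylo(tr)
  d <- d[sort(rownames(d)), sort(rownames(d))]
  list(tree = tr, d = d)
}
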