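#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   reverseComplement matchPattern translate pairwiseAlignment
#'   subseq readAAStringSet readDNAStringSet writeXStringSet pid score
#' @importFrom IRanges start end width
NULL

#' DRE/CRT cis-element patterns
#'
#' The dehydration-responsive element core (IUPAC \code{RCCGAC}, i.e.
#' \code{[A/G]CCGAC}) together with the three promoter-derived 9-mers
#' (DRE1 \code{GACCGACGA}, DRE2 \code{AGCCGACAC}, DRE3 \code{CGCCGACTT})
#' and the non-binding mutant control (mDRE \code{TATTTTCAT}).
#'
#' @return named character vector of IUPAC patterns.
#' @examples
#' dreElements()
#' @export
dreElements <- function() {
  c(core = "RCCGAC", DRE1 = "GACCGACGA", DRE2 = "AGCCGACAC",
    DRE3 = "CGCCGACTT", mDRE = "TATTTTCAT")
}

.asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(DNAStringSet(setNames(list(x), "seq1")))
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(DNAStringSet(x))
  }
  stop("expected a DNAStringSet, DNAString or character vector")
}

#' Translate a coding sequence
#'
#' Validates and translates a CDS with the standard genetic code: the
#' length must be a multiple of 3, a non-ATG start triggers a warning, an
#' internal stop codon is an error (reporting the codon position), and a
#' terminal stop is stripped, so a CDS of 3(L+1) nt with terminal stop
#' encodes L residues (579 nt -> 192 aa).
#'
#' @param nuc a \code{DNAString}, single-sequence \code{DNAStringSet} or
#'   character CDS.
#' @return an \code{AAString} protein (no stop symbol).
#' @examples
#' as.character(translateCds("ATGGCCTAA"))  # "MA"
#' @export
translateCds <- function(nuc) {
  if (is(nuc, "DNAStringSet")) {
    if (length(nuc) != 1L) stop("one CDS at a time")
    nuc <- nuc[[1]]
  }
  if (is.character(nuc)) nuc <- DNAString(nuc)
  n <- length(nuc)
  if (n == 0L) stop("empty CDS")
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  if (as.character(subseq(nuc, 1, 3)) != "ATG")
    warning("CDS does not start with ATG")
  aa <- Biostrings::translate(nuc, no.init.codon = TRUE)
  stops <- which(strsplit(as.character(aa), "")[[1]] == "*")
  ncod <- n %/% 3L
  if (any(stops < ncod))
    stop("internal stop codon at codon position ", stops[stops < ncod][1])
  if (length(stops) && stops[length(stops)] == ncod)
    aa <- subseq(aa, 1, ncod - 1L)
  aa
}

## brute-force-free IUPAC scan of one pattern over one strand
.scanOne <- function(subject, pattern) {
  m <- matchPattern(DNAString(pattern), subject, fixed = FALSE)
  data.frame(start = start(m), end = end(m),
             matched = as.character(m), stringsAsFactors = FALSE)
}

#' Scan sequences for DRE/CRT cis-elements
#'
#' Finds every (possibly overlapping) match of a set of IUPAC patterns on
#' one or both strands. Reverse-strand matches are located by matching the
#' reverse-complemented pattern against the forward strand; all
#' coordinates are forward-strand, 1-based inclusive, and
#' \code{matched} reports the forward-strand text of the site.
#'
#' @param seqs a \code{DNAStringSet} (or character vector) of promoter or
#'   other nucleotide sequences.
#' @param elements named character vector of IUPAC patterns
#'   (default [dreElements()]).
#' @param bothStrands scan the reverse strand too (default TRUE).
#' @return data.frame of hits: \code{seq_id}, \code{element},
#'   \code{start}, \code{end}, \code{strand}, \code{matched}.
#' @examples
#' scanDre("GACCGACGA", elements = c(core = "RCCGAC"))
#' @export
scanDre <- function(seqs, elements = dreElements(), bothStrands = TRUE) {
  seqs <- .asDNAStringSet(seqs)
  if (is.null(names(elements)))
    names(elements) <- paste0("custom", seq_along(elements))
  out <- list()
  for (sid in names(seqs)) {
    subject <- seqs[[sid]]
    for (el in names(elements)) {
      fwd <- .scanOne(subject, elements[[el]])
      if (nrow(fwd))
        out[[length(out) + 1L]] <- data.frame(
          seq_id = sid, element = el, fwd, strand = "+")
      if (bothStrands) {
        rcpat <- as.character(reverseComplement(DNAString(elements[[el]])))
        rev <- .scanOne(subject, rcpat)
        if (nrow(rev))
          out[[length(out) + 1L]] <- data.frame(
            seq_id = sid, element = el, rev, strand = "-")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(), element = character(),
                      start = integer(), end = integer(),
                      strand = character(), matched = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$element, res$start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("seq_id", "element", "start", "end", "strand", "matched")]
}

#' Iterated local-alignment domain search
#'
#' Smith-Waterman local alignment (via
#' \code{Biostrings::pairwiseAlignment}) of a domain consensus against a
#' protein, iterated: the best hit is recorded, its region is masked with
#' \code{X}, and the search repeats until the best score drops below
#' \code{minScore}. Hits are therefore non-overlapping; they are returned
#' sorted by position (1-based inclusive residue coordinates).
#'
#' @param prot an \code{AAString} / single \code{AAStringSet} / character
#'   protein sequence.
#' @param consensus the domain consensus (same types accepted).
#' @param substitutionMatrix scoring matrix name or matrix
#'   (default \code{"BLOSUM62"}).
#' @param gapOpening,gapExtension gap penalties (defaults 11 and 1).
#' @param minScore minimum alignment score for a reported hit.
#' @param maxHits safety cap on the number of iterations (default 25).
#' @return data.frame of hits: \code{start}, \code{end}, \code{score},
#'   \code{identity} (fraction of identical aligned positions).
#' @seealso [singleDomainFilter()], [calibrateDomainScore()]
#' @export
findDomains <- function(prot, consensus, substitutionMatrix = "BLOSUM62",
                        gapOpening = 11, gapExtension = 1, minScore = 60,
                        maxHits = 25) {
  if (is(prot, "AAStringSet")) {
    if (length(prot) != 1L) stop("one protein at a time; see singleDomainFilter")
    prot <- prot[[1]]
  }
  if (is.character(prot)) prot <- AAString(prot)
  if (is(consensus, "AAStringSet")) consensus <- consensus[[1]]
  if (is.character(consensus)) consensus <- AAString(consensus)
  if (length(prot) == 0L || length(consensus) == 0L)
    stop("empty sequence")
  if (minScore <= 0) stop("minScore must be positive")
  hits <- data.frame(start = integer(), end = integer(),
                     score = numeric(), identity = numeric())
  masked <- prot
  repeat {
    pa <- pairwiseAlignment(consensus, masked, type = "local",
                            substitutionMatrix = substitutionMatrix,
                            gapOpening = gapOpening,
                            gapExtension = gapExtension)
    if (score(pa) < minScore || nrow(hits) >= maxHits) break
    s <- start(Biostrings::subject(pa))
    e <- end(Biostrings::subject(pa))
    hits <- rbind(hits, data.frame(start = s, end = e, score = score(pa),
                                   identity = pid(pa) / 100))
    masked <- Biostrings::replaceAt(
      masked, IRanges::IRanges(s, e),
      paste(rep("X", e - s + 1L), collapse = ""))
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Filter proteins carrying exactly one domain copy
#'
#' Runs [findDomains()] over a set of proteins and returns the ids of
#' those with exactly one hit — the screen used to isolate DREB-type
#' factors, which carry a single AP2 domain.
#'
#' @param proteins an \code{AAStringSet} (or named character vector).
#' @param consensus domain consensus, see [findDomains()].
#' @param ... further arguments to [findDomains()].
#' @return character vector of protein ids with exactly one domain hit.
#' @export
singleDomainFilter <- function(proteins, consensus, ...) {
  if (is.character(proteins)) {
    if (is.null(names(proteins)))
      names(proteins) <- paste0("prot", seq_along(proteins))
    proteins <- AAStringSet(proteins)
  }
  counts <- vapply(seq_along(proteins), function(i)
    nrow(findDomains(proteins[[i]], consensus, ...)), integer(1))
  as.character(names(proteins)[counts == 1L])
}

#' Calibrate the domain-search score threshold on null proteins
#'
#' Simulates random proteins with no planted domain, records the best
#' local-alignment score of the consensus against each, and returns the
#' requested quantile — a data-driven \code{minScore} with a controlled
#' false-positive rate (default 99th percentile, i.e. <1% of null
#' proteins produce a hit).
#'
#' @param consensus domain consensus sequence.
#' @param nNull number of null proteins (default 200).
#' @param protLength length of each null protein (default 200).
#' @param probs quantile (default 0.99).
#' @param seed RNG seed.
#' @param substitutionMatrix,gapOpening,gapExtension alignment scoring,
#'   as in [findDomains()].
#' @return numeric score threshold.
#' @export
calibrateDomainScore <- function(consensus, nNull = 200, protLength = 200,
                                 probs = 0.99, seed = NULL,
                                 substitutionMatrix = "BLOSUM62",
                                 gapOpening = 11, gapExtension = 1) {
  nulls <- simProteins(nNull, length = protLength, domainCopies = 0,
                       consensus = consensus, seed = seed)$proteins
  if (is.character(consensus)) consensus <- AAString(consensus)
  best <- vapply(seq_len(length(nulls)), function(i)
    score(pairwiseAlignment(consensus, nulls[[i]], type = "local",
                            substitutionMatrix = substitutionMatrix,
                            gapOpening = gapOpening,
                            gapExtension = gapExtension)), numeric(1))
  as.numeric(stats::quantile(best, probs))
}

#' Extract promoter sequences upstream of genes
#'
#' Returns the \code{upstreamBp} bases 5' of each gene start,
#' reverse-complemented for minus-strand genes so every promoter reads
#' 5'->3' toward the gene. Promoters running off a contig edge are
#' truncated with a warning. Gene coordinates are 1-based inclusive.
#'
#' @param genome a named \code{DNAStringSet} of contigs.
#' @param genes data.frame with columns \code{seqid}, \code{start},
#'   \code{end}, \code{strand} (\code{"+"}/\code{"-"}), \code{gene_id}.
#' @param upstreamBp promoter window in bp (default 2000).
#' @return a \code{DNAStringSet} named by \code{gene_id}.
#' @export
extractPromoters <- function(genome, genes, upstreamBp = 2000) {
  genome <- .asDNAStringSet(genome)
  need <- c("seqid", "start", "end", "strand", "gene_id")
  if (!all(need %in% colnames(genes)))
    stop("genes table needs columns: ", paste(need, collapse = ", "))
  proms <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$seqid %in% names(genome)) stop("unknown contig: ", g$seqid)
    contig <- genome[[g$seqid]]
    clen <- length(contig)
    if (g$start < 1 || g$end > clen || g$start > g$end)
      stop("coordinates of ", g$gene_id, " outside contig bounds")
    if (g$strand == "+") {
      from <- g$start - upstreamBp
      to <- g$start - 1L
      if (from < 1L) {
        warning("promoter of ", g$gene_id, " truncated at contig edge")
        from <- 1L
      }
      p <- if (to < from) DNAString("") else subseq(contig, from, to)
    } else if (g$strand == "-") {
      from <- g$end + 1L
      to <- g$end + upstreamBp
      if (to > clen) {
        warning("promoter of ", g$gene_id, " truncated at contig edge")
        to <- clen
      }
      p <- if (to < from) DNAString("") else
        reverseComplement(subseq(contig, from, to))
    } else stop("strand must be '+' or '-'")
    proms[[i]] <- p
  }
  names(proms) <- genes$gene_id
  DNAStringSet(proms)
}

#' Concatenate tandem repeats of an element
#'
#' Builds the n-times tandem repeat of a cis-element (optionally spaced),
#' as used for yeast one-hybrid bait construction (three tandem DRE
#' copies).
#'
#' @param element a \code{DNAString} or character element.
#' @param n number of copies (default 3).
#' @param spacer sequence between copies (default none).
#' @return a \code{DNAString}.
#' @examples
#' as.character(buildTandem("GACCGACGA"))  # 27 nt
#' @export
buildTandem <- function(element, n = 3, spacer = "") {
  if (n < 1) stop("n must be >= 1")
  if (!is.character(element)) element <- as.character(element)
  DNAString(paste(rep(element, n), collapse = as.character(spacer)))
}
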