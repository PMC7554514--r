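## scoped RNG: run expr under a seed without disturbing the caller's stream
.withSeed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fun()
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate a two-library tag-count experiment
#'
#' Generates per-gene clean-tag counts for a control and a treated
#' library. Gene relative abundances are lognormal (sdlog
#' \code{abundanceSdLog}) normalised to sum 1; library-1 means are
#' abundance x \code{librarySizes[1]}; a fraction \code{deFraction} of
#' genes is differentially expressed with log2 fold change
#' \code{+/- effectLog2} (random sign) applied to the library-2 mean.
#' Counts are Poisson, or gamma-Poisson with variance
#' \eqn{\mu + \phi\mu^2} when \code{dispersion} \eqn{\phi > 0}. The
#' realized library totals reported by the returned
#' [TagLibraryPair-class] are the column sums.
#'
#' @param nGenes number of genes.
#' @param deFraction fraction of genes differentially expressed, in
#'   \[0, 1\].
#' @param effectLog2 |log2 fold change| of DE genes.
#' @param librarySizes expected total tags of the two libraries.
#' @param dispersion gamma-Poisson dispersion (0 = pure Poisson).
#' @param abundanceSdLog spread of gene abundances (default 1).
#' @param seed RNG seed (caller's RNG state is untouched).
#' @return list: \code{pair} (a [TagLibraryPair-class]) and \code{truth}
#'   (data.frame \code{gene_id}, \code{is_de}, \code{true_log2fc}).
#' @examples
#' sim <- simTagLibraries(nGenes = 500, deFraction = 0.1, seed = 1)
#' sum(sim$truth$is_de)
#' @export
simTagLibraries <- function(nGenes, deFraction = 0.1, effectLog2 = 2,
                            librarySizes = c(1e6, 1e6), dispersion = 0,
                            abundanceSdLog = 1, seed = NULL) {
  if (deFraction < 0 || deFraction > 1) stop("deFraction must be in [0, 1]")
  if (dispersion < 0) stop("dispersion must be nonnegative")
  if (length(librarySizes) != 2L || any(librarySizes <= 0))
    stop("exactly two positive library sizes required")
  .withSeed(seed, function() {
    a <- rlnorm(nGenes, 0, abundanceSdLog)
    a <- a / sum(a)
    isde <- runif(nGenes) < deFraction
    lfc <- ifelse(isde, sample(c(-1, 1), nGenes, replace = TRUE) *
                    effectLog2, 0)
    mu1 <- a * librarySizes[1]
    mu2 <- a * librarySizes[2] * 2^lfc
    draw <- function(mu) {
      if (dispersion == 0) rpois(nGenes, mu)
      else rnbinom(nGenes, mu = mu, size = 1 / dispersion)
    }
    cnt <- cbind(lib1 = draw(mu1), lib2 = draw(mu2))
    rownames(cnt) <- sprintf("gene%05d", seq_len(nGenes))
    list(pair = TagLibraryPair(cnt),
         truth = data.frame(gene_id = rownames(cnt), is_de = isde,
                            true_log2fc = lfc))
  })
}

#' Simulate a multi-sample count matrix with gene lengths
#'
#' Two groups of \code{nSamplesPerGroup} samples with negative-binomial
#' (or Poisson) counts; DE genes have their group-2 means shifted by
#' \code{+/- effectLog2}. Gene lengths are sampled uniformly from
#' 200-3000 bp.
#'
#' @inheritParams simTagLibraries
#' @param nSamplesPerGroup samples per group (>= 1).
#' @param librarySize expected per-sample total (recycled over samples).
#' @param groupLabels labels of the two groups.
#' @return list: \code{cset} (a [HeatCountSet-class]) and \code{truth}.
#' @examples
#' sim <- simCountMatrix(nGenes = 50, seed = 1)
#' dim(sim$cset)
#' @export
simCountMatrix <- function(nGenes, deFraction = 0.1, effectLog2 = 1,
                           nSamplesPerGroup = 3, librarySize = 5e5,
                           dispersion = 0.05, abundanceSdLog = 1,
                           groupLabels = c("control", "treated"),
                           seed = NULL) {
  if (nSamplesPerGroup < 1) stop("need at least 1 sample per group")
  if (dispersion < 0) stop("dispersion must be nonnegative")
  .withSeed(seed, function() {
    ns <- 2L * nSamplesPerGroup
    group <- rep(groupLabels, each = nSamplesPerGroup)
    L <- rep_len(librarySize, ns)
    a <- rlnorm(nGenes, 0, abundanceSdLog)
    a <- a / sum(a)
    isde <- runif(nGenes) < deFraction
    lfc <- ifelse(isde, sample(c(-1, 1), nGenes, replace = TRUE) *
                    effectLog2, 0)
    glen <- sample(200:3000, nGenes, replace = TRUE)
    cnt <- sapply(seq_len(ns), function(s) {
      mu <- a * L[s] * if (group[s] == groupLabels[2]) 2^lfc else 1
      if (dispersion == 0) rpois(nGenes, mu)
      else rnbinom(nGenes, mu = mu, size = 1 / dispersion)
    })
    dimnames(cnt) <- list(sprintf("gene%05d", seq_len(nGenes)),
                          paste0(group, "_", rep(seq_len(nSamplesPerGroup), 2)))
    list(cset = HeatCountSet(cnt, geneLength = glen, group = group),
         truth = data.frame(gene_id = rownames(cnt), is_de = isde,
                            true_log2fc = lfc))
  })
}

#' Simulate promoter sequences with planted cis-elements
#'
#' Uniform i.i.d. ACGT background of the given length; when
#' \code{element} is supplied, one copy is planted per sequence at
#' \code{position} (1-based; random when NULL), reverse-complemented
#' first when the planting strand is \code{"-"}. The truth table records
#' every planting.
#'
#' @param n number of promoters.
#' @param length promoter length in bp.
#' @param element element to plant (character, e.g. \code{"GACCGACGA"});
#'   NULL for background-only sequences.
#' @param position 1-based planting start (recycled; NULL = random).
#' @param strand planting strand, \code{"+"} or \code{"-"} (recycled).
#' @param baseProbs background composition over A, C, G, T
#'   (default uniform).
#' @param seed RNG seed.
#' @return list: \code{promoters} (\code{DNAStringSet}) and \code{truth}
#'   (data.frame \code{seq_id}, \code{element}, \code{start},
#'   \code{strand}; zero rows when nothing is planted).
#' @examples
#' sim <- simPromoters(3, length = 100, element = "GACCGACGA",
#'                     position = 20, seed = 1)
#' sim$truth
#' @export
simPromoters <- function(n, length = 500, element = NULL, position = NULL,
                         strand = "+", baseProbs = rep(0.25, 4),
                         seed = NULL) {
  if (!is.null(element) && nchar(element) > length)
    stop("element longer than the promoter")
  .withSeed(seed, function() {
    ids <- sprintf("prom%04d", seq_len(n))
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                   prob = baseProbs), collapse = ""), character(1))
    truth <- data.frame(seq_id = character(), element = character(),
                        start = integer(), strand = character())
    if (!is.null(element) && n > 0) {
      w <- nchar(element)
      str <- rep_len(strand, n)
      pos <- if (is.null(position))
        sample.int(length - w + 1L, n, replace = TRUE)
      else rep_len(position, n)
      if (any(pos < 1 | pos + w - 1 > length))
        stop("planting position outside the promoter")
      for (i in seq_len(n)) {
        ins <- if (str[i] == "-")
          as.character(reverseComplement(DNAString(element))) else element
        substr(seqs[i], pos[i], pos[i] + w - 1L) <- ins
      }
      truth <- data.frame(seq_id = ids, element = element, start = pos,
                          strand = str)
    }
    proms <- DNAStringSet(seqs)
    names(proms) <- ids
    list(promoters = proms, truth = truth)
  })
}

#' Simulate proteins with planted domain copies
#'
#' Random 20-letter backgrounds with 0, 1 or 2 copies of a domain
#' consensus planted at non-overlapping positions; each planted residue
#' is mutated to a different residue with probability
#' \code{mutationRate}.
#'
#' @param n number of proteins.
#' @param length protein length (residues); must fit
#'   \code{max(domainCopies)} copies.
#' @param domainCopies integer copies per protein (recycled; values >= 0).
#' @param consensus domain consensus (character or \code{AAString}).
#' @param mutationRate per-residue mutation probability in \[0, 0.5\].
#' @param seed RNG seed.
#' @return list: \code{proteins} (\code{AAStringSet}) and \code{truth}
#'   (data.frame \code{prot_id}, \code{copies}, \code{starts}
#'   (comma-separated 1-based)).
#' @examples
#' sim <- simProteins(4, domainCopies = c(0, 1, 2, 1),
#'                    consensus = strrep("ACDEFGHIKL", 3), seed = 1)
#' sim$truth
#' @export
simProteins <- function(n, length = 200, domainCopies = 1, consensus,
                        mutationRate = 0, seed = NULL) {
  if (mutationRate < 0 || mutationRate > 0.5)
    stop("mutationRate must be in [0, 0.5]")
  consensus <- as.character(consensus)
  w <- nchar(consensus)
  copies <- rep_len(as.integer(domainCopies), n)
  if (any(copies < 0)) stop("domain copies must be nonnegative")
  if (max(c(copies, 0L)) * w > length)
    stop("domain copies do not fit in the protein length")
  .withSeed(seed, function() {
    ids <- sprintf("prot%04d", seq_len(n))
    consChars <- strsplit(consensus, "")[[1]]
    seqs <- character(n)
    starts <- character(n)
    for (i in seq_len(n)) {
      s <- sample(.AA20, length, replace = TRUE)
      k <- copies[i]
      pos <- integer(0)
      if (k > 0) {
        # one copy per equal-width block keeps copies non-overlapping
        block <- as.integer(length %/% k)
        pos <- vapply(seq_len(k), function(j)
          (j - 1L) * block + sample.int(block - w + 1L, 1L), integer(1))
        for (p in pos) {
          dom <- consChars
          mut <- runif(w) < mutationRate
          if (any(mut))
            dom[mut] <- vapply(dom[mut], function(aa)
              sample(setdiff(.AA20, aa), 1L), character(1))
          s[p:(p + w - 1L)] <- dom
        }
      }
      seqs[i] <- paste(s, collapse = "")
      starts[i] <- paste(pos, collapse = ",")
    }
    prots <- AAStringSet(seqs)
    names(prots) <- ids
    list(proteins = prots,
         truth = data.frame(prot_id = ids, copies = copies,
                            starts = starts))
  })
}

#' Simulate a qPCR Ct table with known relative quantities
#'
#' Target-gene Ct values are shifted by \eqn{-\log_2(RQ)} relative to the
#' first (calibrator) sample while the reference gene stays constant, so
#' [ddct()] with the first sample as calibrator recovers
#' \code{trueRq / trueRq[1]}. Gaussian noise of SD \code{noiseSd} cycles
#' is added to every well; \code{nRep} replicate wells per (sample,
#' gene).
#'
#' @param trueRq named positive numeric: relative quantity per sample,
#'   first entry the calibrator.
#' @param nRep replicate wells (default 3).
#' @param noiseSd Ct noise SD in cycles (default 0).
#' @param baseCt baseline Ct of target and reference (cycles).
#' @param targetGene,referenceGene gene names written in the table.
#' @param seed RNG seed.
#' @return data.frame: \code{sample}, \code{gene}, \code{replicate},
#'   \code{ct}.
#' @examples
#' simCtTable(trueRq = c(Control = 1, Heat = 8))
#' @export
simCtTable <- function(trueRq, nRep = 3, noiseSd = 0,
                       baseCt = c(target = 24, reference = 18),
                       targetGene = "target", referenceGene = "reference",
                       seed = NULL) {
  if (any(trueRq <= 0)) stop("relative quantities must be positive")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  if (is.null(names(trueRq)))
    names(trueRq) <- paste0("sample", seq_along(trueRq))
  .withSeed(seed, function() {
    rows <- lapply(names(trueRq), function(s) {
      tct <- baseCt[["target"]] - log2(trueRq[[s]] / trueRq[[1]])
      rbind(
        data.frame(sample = s, gene = targetGene, replicate = seq_len(nRep),
                   ct = tct + rnorm(nRep, 0, noiseSd)),
        data.frame(sample = s, gene = referenceGene,
                   replicate = seq_len(nRep),
                   ct = baseCt[["reference"]] + rnorm(nRep, 0, noiseSd)))
    })
    do.call(rbind, rows)
  })
}

#' Simulate an injury-level tally
#'
#' Multinomial plant counts over ordinal injury levels
#' 0..\code{length(levelProbs) - 1}.
#'
#' @param nPlants cohort size.
#' @param levelProbs probabilities per level (must sum to 1); the number
#'   of levels is \code{length(levelProbs)}.
#' @param seed RNG seed.
#' @return named integer vector of counts (\code{level0}, \code{level1},
#'   ...), summing to \code{nPlants}.
#' @examples
#' simInjuryTally(30, c(0, 0, 0, 1))  # all plants at level 3
#' @export
simInjuryTally <- function(nPlants, levelProbs, seed = NULL) {
  if (abs(sum(levelProbs) - 1) > 1e-8) stop("levelProbs must sum to 1")
  if (length(levelProbs) < 2) stop("need at least levels 0 and 1")
  .withSeed(seed, function() {
    cnt <- as.integer(rmultinom(1, nPlants, levelProbs))
    names(cnt) <- paste0("level", seq_along(levelProbs) - 1L)
    cnt
  })
}

#' Simulate aligned sequences along a tree
#'
#' Evolves a uniform-random DNA sequence site-independently along a tree
#' under the Jukes-Cantor model: along a branch of length \eqn{b}
#' (expected substitutions per site) each site changes with probability
#' \eqn{\frac{3}{4}(1 - e^{-4b/3})}, to one of the other three bases
#' uniformly. No indels, so the tip sequences are an alignment.
#'
#' @param tree an \code{ape::phylo} with branch lengths, or a newick
#'   string.
#' @param seqLen alignment length (sites).
#' @param seed RNG seed.
#' @return a \code{DNAStringSet} named by tip labels.
#' @examples
#' aln <- simAlignment("((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);", 300,
#'                     seed = 1)
#' pDistance(aln)
#' @export
simAlignment <- function(tree, seqLen, seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  if (seqLen <= 0) stop("seqLen must be positive")
  .withSeed(seed, function() {
    bases <- c("A", "C", "G", "T")
    nt <- length(tree$tip.label)
    nnode <- nt + tree$Nnode
    seqs <- vector("list", nnode)
    root <- nt + 1L
    seqs[[root]] <- sample(bases, seqLen, replace = TRUE)
    # preorder: parents before children
    eo <- ape::reorder.phylo(tree, "postorder")$edge
    el <- ape::reorder.phylo(tree, "postorder")$edge.length
    ord <- rev(seq_len(nrow(eo)))
    for (k in ord) {
      par <- eo[k, 1]; ch <- eo[k, 2]; b <- el[k]
      p <- seqs[[par]]
      pchg <- 0.75 * (1 - exp(-4 * b / 3))
      hit <- runif(seqLen) < pchg
      child <- p
      if (any(hit))
        child[hit] <- vapply(p[hit], function(x)
          sample(setdiff(bases, x), 1L), character(1))
      seqs[[ch]] <- child
    }
    tips <- vapply(seq_len(nt), function(i)
      paste(seqs[[i]], collapse = ""), character(1))
    out <- DNAStringSet(tips)
    names(out) <- tree$tip.label
    out
  })
}
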