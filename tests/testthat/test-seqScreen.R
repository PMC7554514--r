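test_that("CDS translation enforces the reading frame and strips the terminal stop", {
  expect_equal(as.character(translateCds("ATGGCCTAA")), "MA")
  expect_equal(as.character(translateCds("ATGTAA")), "M")
  # a CDS of 3(L+1) nt with terminal stop encodes L residues
  cds <- makeCds(193, seed = 91)
  expect_equal(nchar(cds), 579)
  expect_equal(length(translateCds(cds)), 192)
  for (nc in c(5, 20, 80)) {
    cds <- makeCds(nc, seed = nc)
    expect_equal(length(translateCds(cds)), nchar(cds) / 3 - 1)
  }
  expect_error(translateCds("ATGTAAGGGTAA"), "codon position 2")
  expect_error(translateCds("ATGGC"), "multiple of 3")
  expect_warning(translateCds("CCCTAA"), "ATG")
})

test_that("DRE scanning reports the printed 9-mers' core content", {
  els <- dreElements()
  nine <- els[c("DRE1", "DRE2", "DRE3", "mDRE")]
  hits <- scanDre(setNames(unname(nine), names(nine)),
                  elements = els["core"])
  withCore <- unique(hits$seq_id)
  expect_setequal(withCore, c("DRE1", "DRE2", "DRE3"))
  # the DRE1 core sits at positions 2..7 on the forward strand
  d1 <- hits[hits$seq_id == "DRE1" & hits$strand == "+", ]
  expect_equal(d1$start, 2)
  expect_equal(d1$end, 7)
  expect_equal(d1$matched, "ACCGAC")
})

test_that("motif scanner equals the sliding-window oracle on random sequences", {
  set.seed(92)
  els <- dreElements()
  n <- 250
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0("s", seq_len(n))
  hits <- scanDre(seqs, elements = els)
  for (i in seq_len(n)) {
    ref <- oracleScan(seqs[[i]], els)
    got <- hits[hits$seq_id == names(seqs)[i],
                c("element", "start", "end", "strand")]
    ord <- function(d) {
      d <- d[order(d$element, d$start, d$strand), , drop = FALSE]
      rownames(d) <- NULL
      d
    }
    expect_equal(ord(got), ord(ref))
  }
})

test_that("a sequence and its reverse complement yield mirrored hit sets", {
  sim <- simPromoters(5, length = 300, element = "GACCGACGA", seed = 93)
  for (i in seq_len(5)) {
    s <- as.character(sim$promoters[[i]])
    rc <- revcompChr(s)
    h1 <- scanDre(c(fwd = s))
    h2 <- scanDre(c(rev = rc))
    L <- nchar(s)
    mirrored <- data.frame(element = h2$element,
                           start = L - h2$end + 1L,
                           end = L - h2$start + 1L,
                           strand = ifelse(h2$strand == "+", "-", "+"))
    ord <- function(d) {
      d <- d[order(d$element, d$start, d$strand), , drop = FALSE]
      rownames(d) <- NULL
      d
    }
    expect_equal(ord(h1[, c("element", "start", "end", "strand")]),
                 ord(mirrored))
  }
  expect_error(scanDre("ACGT", elements = c(bad = "AZ")), "")
})

test_that("tandem bait construction repeats the element", {
  t3 <- buildTandem("GACCGACGA", 3)
  expect_equal(length(t3), 27)
  hits <- scanDre(as.character(t3), elements = dreElements()["core"],
                  bothStrands = FALSE)
  expect_equal(nrow(hits), 3)
  expect_equal(as.character(buildTandem("GACCGACGA", 1)), "GACCGACGA")
  expect_equal(length(buildTandem("AC", 3, spacer = "TT")), 10)
  expect_error(buildTandem("AC", 0), ">= 1")
})

test_that("domain search recovers planted copy numbers", {
  set.seed(94)
  cons <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 58,
                       replace = TRUE), collapse = "")
  sim <- simProteins(12, length = 250, domainCopies = c(0, 1, 2),
                     consensus = cons, mutationRate = 0, seed = 95)
  counts <- vapply(seq_len(12), function(i)
    nrow(findDomains(sim$proteins[[i]], cons, minScore = 100)),
    integer(1))
  expect_equal(counts, sim$truth$copies)
  one <- singleDomainFilter(sim$proteins, cons, minScore = 100)
  expect_setequal(one, sim$truth$prot_id[sim$truth$copies == 1])
  expect_equal(singleDomainFilter(Biostrings::AAStringSet(), cons),
               character(0))
})

test_that("calibrated threshold keeps nulls clean while mutated domains are found", {
  set.seed(96)
  cons <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 58,
                       replace = TRUE), collapse = "")
  thr <- calibrateDomainScore(cons, nNull = 100, protLength = 200,
                              seed = 97)
  sim <- simProteins(30, length = 250, domainCopies = c(0, 1, 2),
                     consensus = cons, mutationRate = 0.1, seed = 98)
  counts <- vapply(seq_len(30), function(i)
    nrow(findDomains(sim$proteins[[i]], cons, minScore = thr)),
    integer(1))
  expect_gte(mean(counts == sim$truth$copies), 0.99)
})

test_that("promoter extraction follows strand-aware coordinate arithmetic", {
  set.seed(99)
  contig <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  genes <- data.frame(seqid = "chr1",
                      start = c(3000, 1200), end = c(3500, 1800),
                      strand = c("+", "-"),
                      gene_id = c("gPlus", "gMinus"))
  pr <- extractPromoters(genome, genes, upstreamBp = 2000)
  expect_equal(as.character(pr[["gPlus"]]), substr(contig, 1000, 2999))
  expect_equal(as.character(pr[["gMinus"]]),
               revcompChr(substr(contig, 1801, 3800)))
  # strand symmetry: reverse-complement the genome, flip strands and
  # mirror coordinates -> identical promoters
  L <- nchar(contig)
  genomeRC <- Biostrings::DNAStringSet(c(chr1 = revcompChr(contig)))
  genesRC <- data.frame(seqid = "chr1",
                        start = L - genes$end + 1L,
                        end = L - genes$start + 1L,
                        strand = ifelse(genes$strand == "+", "-", "+"),
                        gene_id = genes$gene_id)
  prRC <- extractPromoters(genomeRC, genesRC, upstreamBp = 2000)
  expect_equal(as.character(prRC), as.character(pr))
  # truncation at the contig edge
  edge <- data.frame(seqid = "chr1", start = 500, end = 600,
                     strand = "+", gene_id = "gEdge")
  expect_warning(pe <- extractPromoters(genome, edge, 2000), "truncated")
  expect_equal(length(pe[["gEdge"]]), 499)
  expect_error(extractPromoters(genome,
                                data.frame(seqid = "chrX", start = 1,
                                           end = 2, strand = "+",
                                           gene_id = "g")),
               "unknown contig")
})
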