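test_that("generators are deterministic under a fixed seed and leave the caller's RNG alone", {
  a <- simTagLibraries(nGenes = 100, seed = 7)
  b <- simTagLibraries(nGenes = 100, seed = 7)
  expect_identical(tagCounts(a$pair), tagCounts(b$pair))
  expect_identical(a$truth, b$truth)
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(simPromoters(5, seed = 3)); after <- runif(1)
  expect_identical(before, after)
  expect_identical(as.character(simProteins(3, consensus = "ACDEF",
                                            seed = 9)$proteins),
                   as.character(simProteins(3, consensus = "ACDEF",
                                            seed = 9)$proteins))
  expect_identical(simAlignment("(a:0.2,b:0.2,c:0.2);", 50, seed = 5),
                   simAlignment("(a:0.2,b:0.2,c:0.2);", 50, seed = 5))
})

test_that("tag-library simulation honours the DE fraction and reports realized totals", {
  null <- simTagLibraries(nGenes = 1000, deFraction = 0, seed = 1)
  expect_equal(sum(null$truth$is_de), 0)
  expect_true(all(null$truth$true_log2fc == 0))
  sim <- simTagLibraries(nGenes = 1000, deFraction = 0.1, effectLog2 = 2,
                         seed = 2)
  nde <- sum(sim$truth$is_de)
  expect_lt(abs(nde - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  # |true_log2fc| > 0 iff is_de
  expect_identical(sim$truth$is_de, abs(sim$truth$true_log2fc) > 0)
  # realized totals are the column sums
  expect_equal(libSizes(sim$pair), unname(colSums(tagCounts(sim$pair))))
  expect_error(simTagLibraries(100, deFraction = 1.5), "deFraction")
  expect_error(simTagLibraries(100, dispersion = -1), "dispersion")
  expect_error(simTagLibraries(100, librarySizes = c(1e6, 1e6, 1e6)),
               "two positive")
})

test_that("count-matrix simulation plants recoverable fold changes", {
  null <- simCountMatrix(nGenes = 300, deFraction = 0, dispersion = 0,
                         librarySize = 1e6, seed = 3)
  m <- SummarizedExperiment::assay(null$cset, "counts")
  g <- sampleGroups(null$cset)
  ratio <- sum(m[, g == "treated"]) / sum(m[, g == "control"])
  expect_lt(abs(log2(ratio)), 0.05)
  sim <- simCountMatrix(nGenes = 300, deFraction = 0.2, effectLog2 = 1,
                        dispersion = 0.005, librarySize = 2e6, seed = 4)
  m <- SummarizedExperiment::assay(sim$cset, "counts")
  g <- sampleGroups(sim$cset)
  de <- sim$truth$is_de
  lfc <- log2(rowMeans(m[de, g == "treated"]) /
                rowMeans(m[de, g == "control"]))
  expect_lt(abs(mean(abs(lfc)) - 1), 0.1)
  expect_equal(length(geneLengths(sim$cset)), 300)
  expect_true(all(geneLengths(sim$cset) > 0))
})

test_that("promoter simulation plants elements where it says it does", {
  sim <- simPromoters(5, length = 200, element = "GACCGACGA",
                      position = 100, seed = 11)
  expect_equal(nrow(sim$truth), 5)
  hits <- scanDre(sim$promoters, elements = c(core = "RCCGAC"),
                  bothStrands = FALSE)
  # planted 9-mer at 100 carries the ACCGAC core at 101..106
  expect_true(all(vapply(names(sim$promoters), function(id)
    any(hits$seq_id == id & hits$start == 101 & hits$end == 106),
    logical(1))))
  # minus-strand planting is reverse-complemented into the sequence
  simM <- simPromoters(5, length = 200, element = "GACCGACGA",
                       position = 50, strand = "-", seed = 12)
  hitsM <- scanDre(simM$promoters, elements = c(core = "RCCGAC"))
  expect_true(all(vapply(names(simM$promoters), function(id)
    any(hitsM$seq_id == id & hitsM$strand == "-"), logical(1))))
  expect_equal(length(simPromoters(0, length = 50)$promoters), 0L)
  expect_error(simPromoters(1, length = 5, element = "GACCGACGA"),
               "longer")
})

test_that("background promoters match the combinatorial core-hit expectation", {
  n <- 10000; L <- 100
  sim <- simPromoters(n, length = L, seed = 13)
  hits <- Biostrings::vcountPattern(Biostrings::DNAString("RCCGAC"),
                                    sim$promoters, fixed = FALSE)
  # per-sequence forward-strand expectation: (L-5) * (2/4) * (1/4)^5
  expected <- n * (L - 5) * (2 / 4) * (1 / 4)^5
  expect_lt(abs(sum(hits) - expected), 3 * sqrt(expected))
})

test_that("protein simulation plants the requested domain copies", {
  cons <- strrep("ACDEFGHIKL", 5)
  sim <- simProteins(9, length = 250, domainCopies = c(0, 1, 2),
                     consensus = cons, mutationRate = 0, seed = 21)
  expect_equal(sim$truth$copies, rep(c(0L, 1L, 2L), 3))
  for (i in seq_len(9)) {
    starts <- as.integer(strsplit(sim$truth$starts[i], ",")[[1]])
    expect_equal(length(starts), sim$truth$copies[i])
    for (p in starts)
      expect_equal(substr(as.character(sim$proteins[[i]]), p,
                          p + nchar(cons) - 1), cons)
  }
  expect_error(simProteins(2, length = 10, domainCopies = 2,
                           consensus = strrep("A", 9)), "fit")
  expect_error(simProteins(2, consensus = "ACD", mutationRate = 0.9),
               "mutationRate")
})

test_that("Ct tables encode the requested relative quantities", {
  tab <- simCtTable(trueRq = c(ctrl = 1, trt = 1), noiseSd = 0)
  expect_equal(ddct(tab, "ctrl")$rq, c(1, 1))
  tab8 <- simCtTable(trueRq = c(ctrl = 1, trt = 8), noiseSd = 0)
  expect_equal(ddct(tab8, "ctrl")$rq, c(1, 8))
  # modest Ct noise keeps the recovered RQ within 20%
  tabN <- simCtTable(trueRq = c(ctrl = 1, trt = 4), noiseSd = 0.1,
                     nRep = 3, seed = 31)
  rq <- ddct(tabN, "ctrl")$rq[2]
  expect_lt(abs(rq - 4) / 4, 0.2)
  expect_error(simCtTable(trueRq = c(a = -1)), "positive")
})

test_that("injury tallies are multinomial and feed the index correctly", {
  t0 <- simInjuryTally(30, c(1, 0, 0, 0), seed = 41)
  expect_equal(sum(t0), 30)
  expect_equal(heatInjuryIndex(t0), 0)
  t3 <- simInjuryTally(30, c(0, 0, 0, 1), seed = 42)
  expect_equal(heatInjuryIndex(t3), 100)
  tmix <- simInjuryTally(2000, c(0, 0.5, 0, 0.5), seed = 43)
  expect_lt(abs(heatInjuryIndex(tmix) - 200 / 3), 2)
  expect_error(simInjuryTally(10, c(0.5, 0.4)), "sum to 1")
})

test_that("alignment simulation respects the generating tree", {
  same <- simAlignment("((a:0,b:0):0,(c:0,d:0):0);", 100, seed = 51)
  expect_equal(length(unique(as.character(same))), 1L)
  star <- simAlignment("(a:0.3,b:0.3,c:0.3,d:0.3);", 5000, seed = 52)
  d <- pDistance(star)
  off <- d[upper.tri(d)]
  expect_lt(max(off) - min(off), 0.05)
})
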