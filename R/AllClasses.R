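#' @import methods
#' @importFrom stats rpois rnbinom rgamma rlnorm rnorm rmultinom runif
#'   p.adjust phyper pt sd t.test setNames complete.cases
#' @importFrom utils head read.delim write.table
NULL

#' Two-library tag-count container
#'
#' Holds per-gene unambiguous clean-tag counts for two sequencing libraries
#' (e.g. a control and a heat-treated library) together with the total clean
#' tag number of each library, the substrate of the exact Poisson test for
#' digital gene expression.
#'
#' @slot counts integer matrix, genes x 2 libraries; rownames are gene ids.
#' @slot libSizes numeric of length 2, total clean tags per library
#'   (defaults to the column sums of \code{counts}).
#'
#' @seealso [tagDGE()], [simTagLibraries()]
#' @export
setClass("TagLibraryPair",
  representation(counts = "matrix", libSizes = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@counts) != 2L)
      msg <- c(msg, "counts must have exactly 2 columns (libraries)")
    if (length(object@libSizes) != 2L)
      msg <- c(msg, "libSizes must have length 2")
    if (any(object@libSizes <= 0))
      msg <- c(msg, "library sizes must be positive")
    if (any(object@counts < 0))
      msg <- c(msg, "counts must be nonnegative")
    if (is.null(rownames(object@counts)))
      msg <- c(msg, "counts must carry gene ids as rownames")
    if (ncol(object@counts) == 2L && length(object@libSizes) == 2L &&
        any(colSums(object@counts) > object@libSizes))
      msg <- c(msg, "per-gene counts cannot exceed the library total")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a TagLibraryPair
#'
#' @param counts genes x 2 matrix of nonnegative integer tag counts with
#'   gene ids as rownames.
#' @param libSizes total clean tags per library; defaults to column sums.
#' @return A [TagLibraryPair-class] object.
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 20L), ncol = 2,
#'             dimnames = list(c("g1", "g2"), c("lib1", "lib2")))
#' TagLibraryPair(m)
#' @export
TagLibraryPair <- function(counts, libSizes = colSums(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  new("TagLibraryPair", counts = counts, libSizes = as.numeric(libSizes))
}

#' @describeIn TagLibraryPair-class tag count matrix accessor
#' @param x a \code{TagLibraryPair}
#' @export
tagCounts <- function(x) {
  stopifnot(is(x, "TagLibraryPair"))
  x@counts
}

#' @describeIn TagLibraryPair-class library total accessor
#' @export
libSizes <- function(x) {
  stopifnot(is(x, "TagLibraryPair"))
  x@libSizes
}

setMethod("show", "TagLibraryPair", function(object) {
  cat("TagLibraryPair with", nrow(object@counts), "genes\n")
  cat("  library totals (N1, N2):",
      format(object@libSizes, big.mark = ","), "\n")
})

#' Count matrix with gene lengths and sample groups
#'
#' A \linkS4class{SummarizedExperiment} subclass for genes x samples
#' read-count matrices: gene lengths (bp) live in \code{rowData(x)$gene_length}
#' and the two-group design in \code{colData(x)$group}. This is the substrate
#' of RPKM normalisation and the differential-expression screen.
#'
#' @seealso [rpkm()], [deScreen()], [simCountMatrix()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("HeatCountSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    rd <- SummarizedExperiment::rowData(object)
    cd <- SummarizedExperiment::colData(object)
    if (!"gene_length" %in% colnames(rd))
      msg <- c(msg, "rowData must contain a 'gene_length' column")
    else if (any(rd$gene_length <= 0))
      msg <- c(msg, "gene lengths must be positive")
    if (!"group" %in% colnames(cd))
      msg <- c(msg, "colData must contain a 'group' column")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "assay 'counts' is required")
    else if (any(SummarizedExperiment::assay(object, "counts") < 0))
      msg <- c(msg, "counts must be nonnegative")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a HeatCountSet
#'
#' @param counts genes x samples matrix of nonnegative read counts with
#'   gene ids as rownames and sample ids as colnames.
#' @param geneLength numeric, gene (transcript) length in bp per gene.
#' @param group factor or character of per-sample group labels.
#' @return A [HeatCountSet-class] object.
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' HeatCountSet(m, geneLength = c(500, 1500, 3000),
#'              group = c("EV", "EV", "OE", "OE"))
#' @export
HeatCountSet <- function(counts, geneLength, group) {
  counts <- as.matrix(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_length = as.numeric(geneLength)),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(counts)))
  new("HeatCountSet", se)
}

#' @describeIn HeatCountSet-class gene length accessor (bp)
#' @param x a \code{HeatCountSet}
#' @export
geneLengths <- function(x) {
  stopifnot(is(x, "HeatCountSet"))
  SummarizedExperiment::rowData(x)$gene_length
}

#' @describeIn HeatCountSet-class per-sample group label accessor
#' @export
sampleGroups <- function(x) {
  stopifnot(is(x, "HeatCountSet"))
  SummarizedExperiment::colData(x)$group
}

#' Pathway gene-set collection
#'
#' Maps pathway ids to gene-id sets over a fixed gene universe, the substrate
#' of hypergeometric over-representation analysis.
#'
#' @slot sets named list of character vectors (pathway id -> gene ids).
#' @slot pathwayNames named character, optional human-readable names.
#' @slot universe character, all assayable gene ids.
#' @seealso [enrich()], [readGmt()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", pathwayNames = "character",
                 universe = "character"),
  validity = function(object) {
    msg <- NULL
    if (is.null(names(object@sets)) || any(names(object@sets) == ""))
      msg <- c(msg, "every pathway must have an id")
    if (any(lengths(object@sets) == 0L))
      msg <- c(msg, "empty pathways are not allowed")
    if (!all(unlist(object@sets) %in% object@universe))
      msg <- c(msg, "every pathway gene must belong to the universe")
    if (anyDuplicated(names(object@sets)))
      msg <- c(msg, "duplicated pathway ids")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors mapping pathway ids to genes.
#' @param universe character vector of all gene ids; defaults to the union
#'   of the sets.
#' @param pathwayNames optional named character of display names.
#' @return A [GeneSetCollection-class] object.
#' @examples
#' GeneSetCollection(list(p1 = c("g1", "g2"), p2 = c("g2", "g3")),
#'                   universe = paste0("g", 1:10))
#' @export
GeneSetCollection <- function(sets, universe = unique(unlist(sets)),
                              pathwayNames = character()) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  new("GeneSetCollection", sets = sets,
      pathwayNames = pathwayNames, universe = unique(as.character(universe)))
}

#' @describeIn GeneSetCollection-class pathway list accessor
#' @param x a \code{GeneSetCollection}
#' @export
pathwaySets <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@sets
}

#' @describeIn GeneSetCollection-class gene universe accessor
#' @export
geneUniverse <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@universe
}

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "pathways over",
      length(object@universe), "genes\n")
  cat("  set sizes:", paste(range(lengths(object@sets)), collapse = "-"),
      "\n")
})
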