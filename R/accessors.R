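#' Accessors for chipsmith containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a chipsmith S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @return `catalogInfo`: the per-gene metadata data.frame.
#' @export
setGeneric("catalogInfo", function(x) standardGeneric("catalogInfo"))

#' @rdname accessors
#' @export
setMethod("catalogInfo", "GeneCatalog", function(x) x@info)

#' @rdname accessors
#' @return `catalogSequences`: the extracted [Biostrings::DNAStringSet].
#' @export
setGeneric("catalogSequences", function(x) standardGeneric("catalogSequences"))

#' @rdname accessors
#' @export
setMethod("catalogSequences", "GeneCatalog", function(x) x@sequences)

#' @rdname accessors
#' @return `catalogExons`: named list of exon interval matrices in extracted
#'   coordinates.
#' @export
setGeneric("catalogExons", function(x) standardGeneric("catalogExons"))

#' @rdname accessors
#' @export
setMethod("catalogExons", "GeneCatalog", function(x) x@exons)

#' @rdname accessors
#' @return `genotypeCalls`: the integer samples-by-SNPs call matrix.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname accessors
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname accessors
#' @return `snpInfo`: the per-SNP map data.frame.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname accessors
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(x) x@snpInfo)

#' @rdname accessors
#' @return `sampleNames`: sample identifiers (matrix row names).
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname accessors
#' @export
setMethod("sampleNames", "GenotypeMatrix", function(x) rownames(x@calls))

#' @rdname accessors
#' @return `haplotypes`: named haplotype allele strings.
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setMethod("haplotypes", "HaplotypeTable", function(x) x@haplotypes)

#' @rdname accessors
#' @return `haplotypeFreqs`: named haplotype frequency vector.
#' @export
setGeneric("haplotypeFreqs", function(x) standardGeneric("haplotypeFreqs"))

#' @rdname accessors
#' @export
setMethod("haplotypeFreqs", "HaplotypeTable", function(x) x@freqs)

#' @rdname accessors
#' @return `haplotypeAssignment`: named sample-to-haplotype vector.
#' @export
setGeneric("haplotypeAssignment",
           function(x) standardGeneric("haplotypeAssignment"))

#' @rdname accessors
#' @export
setMethod("haplotypeAssignment", "HaplotypeTable", function(x) x@assignment)

#' @rdname accessors
#' @return `networkGraph`: the underlying [igraph::igraph].
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setMethod("networkGraph", "HaploNetwork", function(x) x@graph)

#' @rdname accessors
#' @return `networkNodes`: node table (name, seq, freq, median flag).
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setMethod("networkNodes", "HaploNetwork", function(x) x@nodes)

#' Subset a GenotypeMatrix
#'
#' `[` subsets samples (rows) and SNPs (columns) keeping the SNP map in step.
#'
#' @param x a [GenotypeMatrix-class].
#' @param i,j sample and SNP indices (any form `[` accepts).
#' @param ... ignored.
#' @param drop ignored; the result is always a GenotypeMatrix.
#' @export
setMethod("[", c("GenotypeMatrix", "ANY", "ANY", "ANY"),
  function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@calls))
    if (missing(j)) j <- seq_len(ncol(x@calls))
    sub <- x@calls[i, j, drop = FALSE]
    info <- x@snpInfo[match(colnames(sub), x@snpInfo$snp_id), , drop = FALSE]
    genotypeMatrix(sub, info)
  })
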