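## Central S4 containers. Genotype calls are coded throughout as
## 0 = AA, 1 = AB, 2 = BB, -1 = NoCall.

GENO_CODES <- c(-1L, 0L, 1L, 2L)

GENE_CATEGORIES <- c("SCP", "CSCSP", "AGCP", "DRDRP", "MCP", "UNCLASSIFIED")

#' GeneCatalog: categorised, flank-extracted reference genes
#'
#' Holds one extracted, gene-oriented sequence per reference gene (full gene
#' span plus upstream/downstream flanks, reverse-complemented for minus-strand
#' genes), its exon geometry in extracted coordinates, and the chip design
#' category assigned to the gene.
#'
#' @slot info data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (1-based inclusive genomic span), `category`,
#'   `up_flank`, `down_flank` (requested flank lengths, bp),
#'   `up_trunc`, `down_trunc` (bp of flank lost to contig ends),
#'   `length_bp` (length of the extracted sequence).
#' @slot sequences [Biostrings::DNAStringSet] of extracted sequences, named
#'   by `gene_id`, oriented 5' to 3' along the gene.
#' @slot exons named list (by `gene_id`) of two-column integer matrices
#'   (`start`, `end`) giving exon intervals in 1-based extracted coordinates,
#'   ordered 5' to 3'.
#'
#' @seealso [buildReferenceCatalog()], [annotateFeature()]
#' @exportClass GeneCatalog
setClass("GeneCatalog",
  representation(info = "data.frame", sequences = "DNAStringSet",
                 exons = "list"))

setValidity("GeneCatalog", function(object) {
  msg <- character()
  need <- c("gene_id", "chrom", "strand", "start", "end", "category",
            "up_flank", "down_flank", "up_trunc", "down_trunc", "length_bp")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info lacks columns:",
                        paste(setdiff(need, names(object@info)), collapse = ", ")))
  else {
    ids <- object@info$gene_id
    if (anyDuplicated(ids)) msg <- c(msg, "duplicated gene ids")
    if (!identical(names(object@sequences), ids))
      msg <- c(msg, "sequence names do not match info$gene_id")
    if (!identical(names(object@exons), ids))
      msg <- c(msg, "exon list names do not match info$gene_id")
    if (length(object@sequences) &&
        !all(Biostrings::width(object@sequences) == object@info$length_bp))
      msg <- c(msg, "length_bp disagrees with extracted sequence widths")
    if (!all(object@info$category %in% GENE_CATEGORIES))
      msg <- c(msg, "unknown category label")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: samples-by-SNPs biallelic chip calls
#'
#' @slot calls integer matrix, rows = samples, columns = SNPs, values in
#'   `{-1, 0, 1, 2}` meaning NoCall, AA, AB, BB. Row and column names are
#'   required and are the sample and SNP identifiers.
#' @slot snpInfo data.frame with one row per SNP column: `snp_id`, `chrom`,
#'   `pos`, `gene_id`. `chrom`/`pos` may be NA when no map is available.
#'
#' @seealso [genotypeMatrix()], [callRate()], [ibsDistance()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(calls = "matrix", snpInfo = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  m <- object@calls
  if (!is.integer(m)) msg <- c(msg, "calls must be an integer matrix")
  if (length(m) && (is.null(rownames(m)) || is.null(colnames(m))))
    msg <- c(msg, "calls must carry sample row names and SNP column names")
  if (length(m) && !all(m %in% GENO_CODES))
    msg <- c(msg, "calls outside {-1, 0, 1, 2}")
  if (nrow(object@snpInfo) != ncol(m))
    msg <- c(msg, "snpInfo rows must match SNP columns")
  else if (!is.null(colnames(m)) &&
           !identical(object@snpInfo$snp_id, colnames(m)))
    msg <- c(msg, "snpInfo$snp_id must equal colnames(calls)")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix (samples x SNPs) coded `{-1, 0, 1, 2}`; row
#'   and column names are used as sample and SNP identifiers.
#' @param snpInfo optional data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `gene_id`; defaults to an all-NA map in column order.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' m <- matrix(c(0L, 2L, 1L, -1L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("snp1", "snp2")))
#' genotypeMatrix(m)
#' @export
genotypeMatrix <- function(calls, snpInfo = NULL) {
  storage.mode(calls) <- "integer"
  if (is.null(snpInfo)) {
    k <- ncol(calls)
    ids <- colnames(calls)
    if (is.null(ids)) ids <- character(k)
    snpInfo <- data.frame(snp_id = ids,
                          chrom = rep(NA_character_, k),
                          pos = rep(NA_integer_, k),
                          gene_id = rep(NA_character_, k),
                          stringsAsFactors = FALSE)
  }
  for (col in c("chrom", "pos", "gene_id"))
    if (is.null(snpInfo[[col]])) snpInfo[[col]] <- NA
  rownames(snpInfo) <- NULL
  new("GenotypeMatrix", calls = calls,
      snpInfo = snpInfo[, c("snp_id", "chrom", "pos", "gene_id"), drop = FALSE])
}

#' HaplotypeTable: per-gene haplotype assignments and frequencies
#'
#' @slot geneId gene identifier.
#' @slot haplotypes named character vector (H1, H2, ...) of allele strings
#'   over the gene's SNPs, in decreasing frequency order.
#' @slot assignment named character vector mapping each assigned sample to a
#'   haplotype name.
#' @slot freqs named numeric vector of haplotype frequencies (sums to 1).
#' @slot n integer, number of samples assigned.
#' @slot snpIds SNP identifiers, in the column order the strings follow.
#'
#' @seealso [extractGeneHaplotypes()], [haplotypeDiversity()]
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(geneId = "character", haplotypes = "character",
                 assignment = "character", freqs = "numeric",
                 n = "integer", snpIds = "character"))

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@haplotypes))
    msg <- c(msg, "freqs and haplotypes differ in length")
  if (length(object@freqs) && abs(sum(object@freqs) - 1) > 1e-8)
    msg <- c(msg, "frequencies must sum to 1")
  if (!all(object@assignment %in% names(object@haplotypes)))
    msg <- c(msg, "assignment refers to unknown haplotype")
  if (object@n != length(object@assignment))
    msg <- c(msg, "n must equal number of assigned samples")
  if (length(msg)) msg else TRUE
})

#' HaploNetwork: median-joining haplotype network
#'
#' @slot graph [igraph::igraph] with vertex attributes `name`, `seq`,
#'   `freq` and `median` (logical: inferred median vector) and edge
#'   attribute `weight` (mutation count, Hamming distance).
#' @slot nodes data.frame mirror of the vertex table.
#'
#' @seealso [medianJoiningNetwork()]
#' @exportClass HaploNetwork
setClass("HaploNetwork",
  representation(graph = "ANY", nodes = "data.frame"))

setValidity("HaploNetwork", function(object) {
  msg <- character()
  if (!igraph::is_igraph(object@graph)) msg <- c(msg, "graph must be an igraph")
  else {
    if (igraph::vcount(object@graph) > 1 &&
        !igraph::is_connected(object@graph))
      msg <- c(msg, "network must be connected")
    w <- igraph::E(object@graph)$weight
    if (length(w) && any(w < 1)) msg <- c(msg, "edge weights must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneCatalog", function(object) {
  cat("GeneCatalog with", nrow(object@info), "genes\n")
  tab <- table(factor(object@info$category, levels = GENE_CATEGORIES))
  tab <- tab[tab > 0]
  if (length(tab))
    cat("  categories:",
        paste(names(tab), as.integer(tab), sep = ":", collapse = "  "), "\n")
  cat("  total extracted length:", sum(object@info$length_bp), "bp\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  m <- object@calls
  cat("GenotypeMatrix:", nrow(m), "samples x", ncol(m), "SNPs\n")
  if (length(m)) {
    cat(sprintf("  missing: %.2f%%  het: %.2f%%\n",
                100 * mean(m == -1L), 100 * mean(m[m != -1L] == 1L)))
  }
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable for gene", object@geneId, "\n")
  cat(" ", length(object@haplotypes), "haplotypes over",
      length(object@snpIds), "SNPs;", object@n, "samples assigned\n")
})

setMethod("show", "HaploNetwork", function(object) {
  nmed <- sum(object@nodes$median)
  cat("HaploNetwork:", nrow(object@nodes) - nmed, "observed haplotypes,",
      nmed, "median vectors,", igraph::ecount(object@graph), "edges\n")
})
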