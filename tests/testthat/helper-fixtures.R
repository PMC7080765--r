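# Shared in-code fixtures: a tiny hand-constructed genome/catalog and
# genotype matrices small enough to verify by eye.

# genome with one plus-strand and one minus-strand gene; exon geometry
# chosen so every feature class is reachable
toyGenomeModels <- function(seed = 101) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ctg1 <- paste(sample(bases, 3000, replace = TRUE), collapse = "")
  ctg2 <- paste(sample(bases, 2500, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(ctg1 = ctg1, ctg2 = ctg2))
  info <- data.frame(
    gene_id = c("gPlus", "gMinus"),
    chrom = c("ctg1", "ctg2"),
    strand = c("+", "-"),
    start = c(1001L, 801L),
    end = c(2000L, 1800L),
    stringsAsFactors = FALSE)
  exons <- list(
    gPlus = cbind(start = c(1001L, 1301L, 1701L),
                  end = c(1100L, 1500L, 2000L)),
    gMinus = cbind(start = c(801L, 1201L), end = c(1000L, 1800L)))
  list(info = info, exons = exons, genome = genome)
}

toyCatalog <- function(seed = 101, categories = c(gPlus = "SCP",
                                                  gMinus = "MCP")) {
  tg <- toyGenomeModels(seed)
  buildReferenceCatalog(list(info = tg$info, exons = tg$exons),
                        tg$genome, categories)
}

# random hit table for one gene, self-match included
randomHitTable <- function(gene, n_other = sample(0:6, 1)) {
  others <- if (n_other) sprintf("o%02d", sample(99, n_other)) else character()
  data.frame(query_id = gene,
             subject_id = c(gene, others),
             bitscore = c(runif(1, 500, 4000),
                          runif(n_other, 0, 400)),
             stringsAsFactors = FALSE)
}

# genotype matrix with exact hand-checkable content
toyGenotype <- function() {
  m <- rbind(
    s1 = c(0L, 0L, 1L, 2L, -1L),
    s2 = c(0L, 2L, 1L, 2L, 0L),
    s3 = c(2L, 2L, 0L, 0L, 0L),
    s4 = c(0L, 0L, 0L, 2L, 0L))
  colnames(m) <- paste0("snp", 1:5)
  genotypeMatrix(m, data.frame(snp_id = colnames(m),
                               chrom = c("c1", "c1", "c1", "c2", "c2"),
                               pos = c(10L, 50L, 90L, 20L, 80L),
                               gene_id = c("gA", "gA", "gA", "gB", "gB"),
                               stringsAsFactors = FALSE))
}

# random genotype matrix with controlled missing/het rates
randomGenotype <- function(n_samples, n_snps, miss = 0.05, het = 0.1) {
  g <- sample(c(0L, 2L), n_samples * n_snps, replace = TRUE)
  g[runif(n_samples * n_snps) < het] <- 1L
  g[runif(n_samples * n_snps) < miss] <- -1L
  m <- matrix(g, n_samples, n_snps,
              dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                              sprintf("m%03d", seq_len(n_snps))))
  genotypeMatrix(m)
}

# independent haplotype grouping oracle: split samples by their call
# strings, homozygous-complete samples only
haplotypeOracle <- function(gm, snps) {
  m <- genotypeCalls(gm)[, snps, drop = FALSE]
  ok <- rowSums(m == 0L | m == 2L) == ncol(m)
  strings <- apply(m[ok, , drop = FALSE], 1, paste, collapse = "/")
  split(names(strings), strings)
}
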