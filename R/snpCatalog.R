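SNP_FEATURES <- c("exon", "intron", "five_prime", "three_prime")

#' Read a per-site pileup summary table
#'
#' Tab-separated site summaries with columns `gene_id`, `position` (1-based
#' within the extracted gene sequence), `ref_allele`, `alt_allele`, `depth`,
#' `alt_reads`, `avg_base_quality`, `alt_frequency`.
#'
#' @param file TSV path (header required).
#' @return data.frame of site summaries.
#' @export
readSiteSummaries <- function(file) {
  read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read candidate sites from a VCF
#'
#' Reads a VCF 4.2 file whose INFO field carries the pileup summary the
#' site filter needs: `DP` (depth), `AR` (alt-supporting reads), `ABQ`
#' (average base quality) and `AF` (alt allele fraction). The CHROM column
#' is interpreted as the gene id and POS as the 1-based position within the
#' extracted gene sequence.
#'
#' @param file VCF path.
#' @return data.frame in the same layout as [readSiteSummaries()].
#' @export
readSiteVcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  num <- function(tag) as.numeric(vcfR::extract.info(v, element = tag))
  data.frame(gene_id = fix$CHROM, position = as.integer(fix$POS),
             ref_allele = fix$REF, alt_allele = fix$ALT,
             depth = as.integer(num("DP")), alt_reads = as.integer(num("AR")),
             avg_base_quality = num("ABQ"), alt_frequency = num("AF"),
             stringsAsFactors = FALSE)
}

#' Filter candidate variant sites on pileup-summary thresholds
#'
#' A site passes when simultaneously `depth >= min_coverage`,
#' `alt_reads >= min_reads`, `avg_base_quality >= min_avg_qual` and
#' `alt_frequency >= min_var_freq` (all comparisons inclusive; defaults
#' 10, 2, 25, 0.05). Sites whose alleles are not a simple biallelic
#' substitution are rejected with reason `"multiallelic"`.
#'
#' @param sites data.frame of site summaries (see [readSiteSummaries()]).
#' @param min_coverage,min_reads,min_avg_qual,min_var_freq thresholds.
#' @return data.frame of passing sites; attribute `"reasons"` holds one
#'   comma-joined reason string per input site (`"pass"` when kept).
#' @examples
#' s <- data.frame(gene_id = "g", position = 1, ref_allele = "A",
#'                 alt_allele = "G", depth = 10, alt_reads = 2,
#'                 avg_base_quality = 25, alt_frequency = 0.05)
#' nrow(filterSites(s))  # 1: every threshold is met exactly on its boundary
#' @export
filterSites <- function(sites, min_coverage = 10, min_reads = 2,
                        min_avg_qual = 25, min_var_freq = 0.05) {
  base <- c("A", "C", "G", "T")
  bad_allele <- !(sites$ref_allele %in% base) |
    !(sites$alt_allele %in% base) |
    sites$ref_allele == sites$alt_allele
  fails <- cbind(multiallelic = bad_allele,
                 low_coverage = sites$depth < min_coverage,
                 low_reads = sites$alt_reads < min_reads,
                 low_quality = sites$avg_base_quality < min_avg_qual,
                 low_frequency = sites$alt_frequency < min_var_freq)
  reasons <- apply(fails, 1, function(f)
    if (any(f)) paste(colnames(fails)[f], collapse = ",") else "pass")
  out <- sites[!rowSums(fails), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reasons") <- unname(reasons)
  out
}

#' Classify a SNP position into a gene feature
#'
#' Positions are 1-based within the extracted, gene-oriented sequence.
#' Anything 5' of the first exon (including the upstream flank) is
#' `five_prime`; inside an exon interval, `exon`; between exons, `intron`;
#' 3' of the last exon (including the downstream flank), `three_prime`.
#'
#' @param position integer vector of positions.
#' @param exons two-column matrix of exon intervals in extracted
#'   coordinates, sorted 5' to 3' (as stored in a [GeneCatalog-class]).
#' @param length_bp length of the extracted sequence (bounds check).
#' @return character vector over
#'   `c("exon", "intron", "five_prime", "three_prime")`.
#' @export
annotateFeature <- function(position, exons, length_bp = NULL) {
  chk(nrow(exons) >= 1, "gene model without exons")
  if (!is.null(length_bp))
    chk(all(position >= 1 & position <= length_bp), "position out of bounds")
  vapply(position, function(p) {
    if (p < exons[1, 1]) return("five_prime")
    if (p > exons[nrow(exons), 2]) return("three_prime")
    if (any(p >= exons[, 1] & p <= exons[, 2])) return("exon")
    "intron"
  }, "")
}

#' Annotate passing sites against the gene catalog
#'
#' Joins filtered sites to the catalog, assigns each SNP its gene feature
#' and inherits the gene's category.
#'
#' @param sites data.frame of (filtered) site summaries.
#' @param catalog a [GeneCatalog-class]; every site's gene must be present.
#' @return data.frame of SNP records: `snp_id`, `gene_id`, `position`,
#'   `ref_allele`, `alt_allele`, `feature`, `category`.
#' @export
snpRecords <- function(sites, catalog) {
  info <- catalogInfo(catalog)
  i <- match(sites$gene_id, info$gene_id)
  chk(!anyNA(i), "sites refer to genes absent from the catalog: ",
      paste(unique(sites$gene_id[is.na(i)]), collapse = ", "))
  exons <- catalogExons(catalog)
  feature <- character(nrow(sites))
  for (g in unique(sites$gene_id)) {
    sel <- sites$gene_id == g
    feature[sel] <- annotateFeature(sites$position[sel], exons[[g]],
                                    info$length_bp[match(g, info$gene_id)])
  }
  data.frame(snp_id = paste0(sites$gene_id, "_", sites$position),
             gene_id = sites$gene_id, position = sites$position,
             ref_allele = sites$ref_allele, alt_allele = sites$alt_allele,
             feature = feature, category = info$category[i],
             stringsAsFactors = FALSE)
}

#' Derived per-category design statistics from count columns
#'
#' Computes every derived column of a chip-design category summary from its
#' raw counts: SNP density per kbp, average gene size, SNPs per gene, and --
#' when chip-content counts are supplied -- the category's share of chip
#' genes and chip SNPs, the inclusion rates relative to the reference set,
#' and SNPs per chip gene. A `Total` row aggregates the inputs. Division by
#' zero yields 0 (empty categories stay well-defined).
#'
#' @param counts data.frame with columns `category`, `n_genes`,
#'   `total_length_bp`, `n_snps`, and optionally `n_genes_chip`,
#'   `n_snps_chip`.
#' @return data.frame with the input counts plus derived columns
#'   `snp_density_per_kbp`, `avg_gene_size_bp`, `snps_per_gene`,
#'   `bp_per_snp`, and with chip counts also `pct_genes_of_chip`,
#'   `gene_inclusion_pct`, `snps_per_gene_chip`, `pct_snps_of_chip`,
#'   `snp_inclusion_pct`. Values are unrounded; see [roundHalfUp()] for
#'   reporting precision.
#' @export
summarizeCategories <- function(counts) {
  chk(all(c("category", "n_genes", "total_length_bp", "n_snps") %in%
            names(counts)), "missing count columns")
  has_chip <- all(c("n_genes_chip", "n_snps_chip") %in% names(counts))
  tot <- counts[1, , drop = FALSE]
  tot$category <- "Total"
  for (col in setdiff(names(counts), "category"))
    tot[[col]] <- sum(counts[[col]])
  out <- rbind(counts, tot)
  sdiv <- function(a, b) ifelse(b == 0, 0, a / b)
  out$snp_density_per_kbp <- sdiv(1000 * out$n_snps, out$total_length_bp)
  out$avg_gene_size_bp <- sdiv(out$total_length_bp, out$n_genes)
  out$snps_per_gene <- sdiv(out$n_snps, out$n_genes)
  out$bp_per_snp <- sdiv(out$total_length_bp, out$n_snps)
  if (has_chip) {
    chip_genes <- sum(counts$n_genes_chip)
    chip_snps <- sum(counts$n_snps_chip)
    out$pct_genes_of_chip <- sdiv(100 * out$n_genes_chip, chip_genes)
    out$gene_inclusion_pct <- sdiv(100 * out$n_genes_chip, out$n_genes)
    out$snps_per_gene_chip <- sdiv(out$n_snps_chip, out$n_genes_chip)
    out$pct_snps_of_chip <- sdiv(100 * out$n_snps_chip, chip_snps)
    out$snp_inclusion_pct <- sdiv(100 * out$n_snps_chip, out$n_snps)
  }
  rownames(out) <- NULL
  out
}

#' Summarise a SNP catalog per category
#'
#' Tallies genes, extracted length and SNPs per category over the whole
#' catalog (genes without SNPs still count toward gene numbers and length)
#' and derives the design statistics via [summarizeCategories()], together
#' with the SNP feature distribution.
#'
#' @param records SNP records from [snpRecords()].
#' @param catalog the [GeneCatalog-class] the records were annotated
#'   against.
#' @return list with `categories` (data.frame incl. `Total` row) and
#'   `features` (data.frame: `feature`, `n_snps`, `pct`).
#' @export
summarizeCatalog <- function(records, catalog) {
  info <- catalogInfo(catalog)
  cats <- intersect(GENE_CATEGORIES, unique(info$category))
  counts <- data.frame(
    category = cats,
    n_genes = vapply(cats, function(k) sum(info$category == k), 0L),
    total_length_bp = vapply(cats, function(k)
      sum(info$length_bp[info$category == k]), 0),
    n_snps = vapply(cats, function(k) sum(records$category == k), 0L),
    stringsAsFactors = FALSE)
  feat <- vapply(SNP_FEATURES, function(f) sum(records$feature == f), 0L)
  features <- data.frame(feature = SNP_FEATURES, n_snps = as.integer(feat),
                         pct = if (sum(feat)) 100 * feat / sum(feat) else 0,
                         stringsAsFactors = FALSE)
  rownames(features) <- NULL
  list(categories = summarizeCategories(counts), features = features)
}

#' Histogram of genes by SNP count
#'
#' @param records SNP records (or any data.frame with a `gene_id` column).
#' @return named integer vector: names are SNPs-per-gene values, entries the
#'   number of genes with that many SNPs; total equals the number of
#'   distinct genes carrying at least one SNP.
#' @export
snpsPerGeneDistribution <- function(records) {
  if (!nrow(records)) return(setNames(integer(), character()))
  per_gene <- table(records$gene_id)
  tab <- table(factor(as.integer(per_gene)))
  setNames(as.integer(tab), names(tab))
}
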