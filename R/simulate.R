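## Seeded generators for every input the pipeline consumes. All defaults
## are the study conditions the toolkit is calibrated around: five gene
## categories with the published per-category SNP densities and gene sizes,
## a 95-sample population split into two subpopulations with admixture and
## ~9.8% mean heterozygosity, and a 94-line F8 RIL population.

#' Default per-category fixture parameters
#'
#' Category-level SNP densities (SNPs per kbp of extracted sequence) and
#' mean gene sizes matching the published design summary of the pigeonpea
#' 62K genic chip reference set.
#'
#' @return data.frame: `category`, `snp_density_per_kbp`,
#'   `mean_gene_bp`.
#' @export
fixtureCategoryDefaults <- function() {
  data.frame(
    category = c("SCP", "CSCSP", "AGCP", "DRDRP", "MCP"),
    snp_density_per_kbp = c(35.2, 6.9, 22.7, 16.6, 111.8),
    mean_gene_bp = c(1214, 3175, 3214, 3326, 2095),
    stringsAsFactors = FALSE)
}

#' Simulate a genome with planted gene models
#'
#' Generates random-base contigs (one per gene, with enough padding for the
#' 500/100 bp flanks), plants a multi-exon gene model on each, assigns the
#' requested categories, and optionally writes `genome.fa`, `genes.gff3`
#' and `categories.tsv` in the dialect the package readers consume.
#' Byte-for-byte reproducible per seed.
#'
#' @param n_genes named integer vector of genes per category.
#' @param mean_gene_bp named numeric vector of mean gene span per category;
#'   defaults from [fixtureCategoryDefaults()].
#' @param upstream,downstream flank lengths the catalog will use (contigs
#'   are padded so they fit).
#' @param seed RNG seed.
#' @param out_dir optional directory to write the three files into.
#' @return list: `genome` ([Biostrings::DNAStringSet]), `models` (as from
#'   [readGeneModels()]), `categories` (named vector), `paths` (written
#'   files or NULL).
#' @export
simulateGenomeAndCatalog <- function(n_genes = c(SCP = 6, CSCSP = 6,
                                                 AGCP = 3, DRDRP = 3,
                                                 MCP = 2),
                                     mean_gene_bp = NULL,
                                     upstream = 500, downstream = 100,
                                     seed = 1, out_dir = NULL) {
  set.seed(seed)
  defaults <- fixtureCategoryDefaults()
  if (is.null(mean_gene_bp))
    mean_gene_bp <- setNames(defaults$mean_gene_bp, defaults$category)
  cats <- rep(names(n_genes), n_genes)
  total <- length(cats)
  chk(total > 0, "no genes requested")
  ids <- sprintf("%s-%03d", cats, unlist(lapply(n_genes, seq_len)))
  bases <- c("A", "C", "G", "T")
  info <- data.frame(gene_id = ids, chrom = paste0("ctg", seq_len(total)),
                     strand = ifelse(runif(total) < 0.5, "+", "-"),
                     start = NA_integer_, end = NA_integer_,
                     stringsAsFactors = FALSE)
  exons <- vector("list", total)
  contigs <- character(total)
  for (i in seq_len(total)) {
    target <- mean_gene_bp[[cats[i]]]
    n_ex <- sample(1:4, 1)
    ex_len <- pmax(60L, rpois(n_ex, target * 0.6 / n_ex))
    in_len <- if (n_ex > 1) pmax(50L, rpois(n_ex - 1, target * 0.4 /
                                              max(1, n_ex - 1)))
              else integer()
    span <- sum(ex_len) + sum(in_len)
    pad_l <- upstream + sample(50:300, 1)
    pad_r <- downstream + sample(50:300, 1)
    clen <- pad_l + span + pad_r
    contigs[i] <- paste(sample(bases, clen, replace = TRUE), collapse = "")
    gs <- pad_l + 1L
    info$start[i] <- gs
    info$end[i] <- gs + span - 1L
    es <- gs + cumsum(c(0L, head(ex_len, -1) + in_len))
    exons[[i]] <- cbind(start = as.integer(es),
                        end = as.integer(es + ex_len - 1L))
  }
  names(exons) <- ids
  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- info$chrom
  categories <- setNames(cats, ids)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    gff <- file.path(out_dir, "genes.gff3")
    cat_tsv <- file.path(out_dir, "categories.tsv")
    Biostrings::writeXStringSet(genome, fa)
    writeGff3(info, exons, gff)
    write.table(data.frame(gene_id = ids, category = cats), cat_tsv,
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(genome = fa, gff = gff, categories = cat_tsv)
  }
  list(genome = genome, models = list(info = info, exons = exons),
       categories = categories, paths = paths)
}

## minimal GFF3 emitter for gene + exon features
writeGff3 <- function(info, exons, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(info))) {
    g <- info$gene_id[i]
    writeLines(paste(info$chrom[i], "chipsmith", "gene", info$start[i],
                     info$end[i], ".", info$strand[i], ".",
                     paste0("ID=", g), sep = "\t"), con)
    em <- exons[[g]]
    for (k in seq_len(nrow(em)))
      writeLines(paste(info$chrom[i], "chipsmith", "exon", em[k, 1],
                       em[k, 2], ".", info$strand[i], ".",
                       paste0("ID=", g, ".e", k, ";Parent=", g),
                       sep = "\t"), con)
  }
  invisible(file)
}

#' Simulate candidate variant sites over a catalog
#'
#' Places SNPs along each extracted gene sequence as a Poisson process at
#' its category's density and draws pileup summaries such that configured
#' fractions fail each site filter (low coverage, low alt reads, low
#' quality, low frequency); the remainder pass all four. `alt_frequency`
#' is always `alt_reads / depth`.
#'
#' @param catalog a [GeneCatalog-class].
#' @param densities named vector, SNPs per kbp per category; defaults from
#'   [fixtureCategoryDefaults()].
#' @param fail_fracs named numeric: fractions of sites drawn to fail
#'   `depth`, `reads`, `qual`, `freq`.
#' @param seed RNG seed.
#' @param out_tsv,out_vcf optional output paths.
#' @return data.frame of site summaries (layout of
#'   [readSiteSummaries()]).
#' @export
simulateSnpSites <- function(catalog, densities = NULL,
                             fail_fracs = c(depth = 0.05, reads = 0.05,
                                            qual = 0.05, freq = 0.05),
                             seed = 1, out_tsv = NULL, out_vcf = NULL) {
  set.seed(seed)
  defaults <- fixtureCategoryDefaults()
  if (is.null(densities))
    densities <- setNames(defaults$snp_density_per_kbp, defaults$category)
  info <- catalogInfo(catalog)
  seqs <- as.character(catalogSequences(catalog))
  bases <- c("A", "C", "G", "T")
  out <- NULL
  for (i in seq_len(nrow(info))) {
    dens <- densities[[info$category[i]]]
    if (is.null(dens) || is.na(dens)) dens <- 0
    lam <- dens / 1000 * info$length_bp[i]
    k <- min(rpois(1, lam), info$length_bp[i])
    if (k == 0) next
    pos <- sort(sample.int(info$length_bp[i], k))
    ref <- strsplit(seqs[[info$gene_id[i]]], "")[[1]][pos]
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    u <- runif(k)
    cls <- rep("pass", k)
    edges <- cumsum(fail_fracs)
    cls[u < edges["freq"]] <- "freq"
    cls[u < edges["qual"]] <- "qual"
    cls[u < edges["reads"]] <- "reads"
    cls[u < edges["depth"]] <- "depth"
    depth <- 10L + rpois(k, 20)
    depth[cls == "depth"] <- sample(1:9, sum(cls == "depth"),
                                    replace = TRUE)
    qual <- runif(k, 25, 40)
    qual[cls == "qual"] <- runif(sum(cls == "qual"), 5, 24.9)
    frac <- runif(k, 0.10, 1)
    frac[cls == "freq"] <- runif(sum(cls == "freq"), 0, 0.049)
    alt_reads <- pmax(0L, as.integer(floor(frac * depth)))
    low <- cls == "pass" & alt_reads < 2L
    alt_reads[low] <- pmin(2L, depth[low])
    alt_reads[cls == "reads"] <- sample(0:1, sum(cls == "reads"),
                                        replace = TRUE)
    alt_reads[cls == "freq"] <- pmin(alt_reads[cls == "freq"],
                                     as.integer(floor(0.049 *
                                                        depth[cls == "freq"])))
    out <- rbind(out, data.frame(
      gene_id = info$gene_id[i], position = pos, ref_allele = unname(ref),
      alt_allele = unname(alt), depth = depth, alt_reads = alt_reads,
      avg_base_quality = round(qual, 1),
      alt_frequency = round(alt_reads / depth, 4),
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(gene_id = character(), position = integer(),
                      ref_allele = character(), alt_allele = character(),
                      depth = integer(), alt_reads = integer(),
                      avg_base_quality = numeric(),
                      alt_frequency = numeric(), stringsAsFactors = FALSE)
  if (!is.null(out_tsv))
    write.table(out, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out_vcf)) writeSiteVcf(out, out_vcf)
  out
}

#' Write site summaries as a minimal VCF 4.2
#'
#' CHROM carries the gene id and POS the position within the extracted
#' sequence; pileup summaries go into INFO as `DP`, `AR`, `ABQ`, `AF`
#' (the fields [readSiteVcf()] consumes).
#'
#' @param sites site-summary data.frame.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeSiteVcf <- function(sites, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##INFO=<ID=AR,Number=1,Type=Integer,Description=\"Alt-supporting reads\">",
               "##INFO=<ID=ABQ,Number=1,Type=Float,Description=\"Average base quality\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele fraction\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(sites))
    writeLines(paste(sites$gene_id, sites$position, ".", sites$ref_allele,
                     sites$alt_allele, ".", ".",
                     sprintf("DP=%d;AR=%d;ABQ=%s;AF=%s", sites$depth,
                             sites$alt_reads, sites$avg_base_quality,
                             sites$alt_frequency),
                     sep = "\t"), con)
  invisible(file)
}

#' Simulate a structured chip genotype panel
#'
#' Two-subpopulation panel with Balding-Nichols allele-frequency
#' divergence: per SNP an ancestral frequency is drawn uniformly on
#' `[0.1, 0.9]` and each subpopulation's frequency from a Beta with
#' parameters `p (1 - Fst) / Fst`. Admixed individuals use a per-individual
#' mixture of the two subpopulation frequencies. Genotypes are drawn
#' homozygous by default with an explicit heterozygote probability
#' (selfing-species chip data), so realized mean heterozygosity matches
#' `het_rate`; calls are masked to NoCall at `nocall_rate`. Defaults mirror
#' a 95-variety panel: 56/39 split, 18 and 16 admixed individuals, 9.79%
#' heterozygosity, 99.27% call rate, 11 chromosomes.
#'
#' @param n_samples total samples.
#' @param subpop_sizes length-2 split (sums to `n_samples`).
#' @param n_admixed length-2 count of admixed individuals per subpopulation.
#' @param n_snps number of SNPs.
#' @param n_chrom chromosomes (SNPs assigned in equal blocks, positions
#'   increasing).
#' @param fst divergence parameter in (0, 1).
#' @param het_rate per-call heterozygote probability.
#' @param nocall_rate per-call missing probability.
#' @param seed RNG seed.
#' @return list: `matrix` ([GenotypeMatrix-class]), `labels` (data.frame:
#'   `sample`, `subpop`, `admixed`).
#' @export
simulatePopulation <- function(n_samples = 95, subpop_sizes = c(56, 39),
                               n_admixed = c(18, 16), n_snps = 1000,
                               n_chrom = 11, fst = 0.2,
                               het_rate = 0.0979, nocall_rate = 0.0073,
                               seed = 1) {
  chk(sum(subpop_sizes) == n_samples, "subpopulation sizes must sum")
  set.seed(seed)
  p_anc <- runif(n_snps, 0.1, 0.9)
  shape <- (1 - fst) / fst
  p1 <- rbeta(n_snps, p_anc * shape, (1 - p_anc) * shape)
  p2 <- rbeta(n_snps, p_anc * shape, (1 - p_anc) * shape)
  subpop <- rep(1:2, subpop_sizes)
  admixed <- c(seq_len(n_samples) %in%
                 c(sample(which(subpop == 1), n_admixed[1]),
                   sample(which(subpop == 2), n_admixed[2])))
  samples <- sprintf("V%02d", seq_len(n_samples))
  m <- matrix(-1L, n_samples, n_snps)
  for (i in seq_len(n_samples)) {
    q <- if (!admixed[i]) {
      if (subpop[i] == 1) p1 else p2
    } else {
      a <- runif(1, 0.2, 0.8)
      a * p1 + (1 - a) * p2
    }
    het <- runif(n_snps) < het_rate
    hom <- ifelse(runif(n_snps) < q, 2L, 0L)
    g <- ifelse(het, 1L, hom)
    g[runif(n_snps) < nocall_rate] <- -1L
    m[i, ] <- g
  }
  snp_ids <- sprintf("S%05d", seq_len(n_snps))
  dimnames(m) <- list(samples, snp_ids)
  chrom <- paste0("chr", rep(seq_len(n_chrom), length.out = n_snps))
  chrom <- chrom[order(rep(seq_len(n_chrom), length.out = n_snps))]
  pos <- unlist(lapply(table(chrom)[unique(chrom)], function(k)
    sort(sample.int(1e6, k))), use.names = FALSE)
  gm <- genotypeMatrix(m, data.frame(snp_id = snp_ids, chrom = chrom,
                                     pos = pos, gene_id = NA_character_,
                                     stringsAsFactors = FALSE))
  list(matrix = gm,
       labels = data.frame(sample = samples, subpop = subpop,
                           admixed = admixed, stringsAsFactors = FALSE))
}

#' Simulate an F-generation RIL genotype matrix
#'
#' Biallelic markers for a recombinant inbred population plus its two
#' inbred parents (coded 0 and 2 at every marker). Lines carry residual
#' heterozygosity `(1/2)^(generation - 1)` per locus (F8 default:
#' `(1/2)^7`). Markers segregate 1:1 except a planted fraction distorted
#' to `p_AA = distortion_p` (default 0.75, i.e. 3:1). Markers are
#' independent; no linkage map is imposed.
#'
#' @param n_lines RIL count (default 94).
#' @param n_markers marker count.
#' @param generation selfing generation F (default 8).
#' @param distortion_frac fraction of markers distorted.
#' @param distortion_p homozygous-class AA probability at distorted
#'   markers.
#' @param nocall_rate per-call missing probability.
#' @param seed RNG seed.
#' @return list: `matrix` ([GenotypeMatrix-class] with parents "P1", "P2"
#'   as the last rows), `parents`, `distorted` (marker ids).
#' @export
simulateRil <- function(n_lines = 94, n_markers = 1000, generation = 8,
                        distortion_frac = 0, distortion_p = 0.75,
                        nocall_rate = 0.005, seed = 1) {
  set.seed(seed)
  h <- 0.5^(generation - 1)
  n_dist <- round(distortion_frac * n_markers)
  distorted <- sort(sample.int(n_markers, n_dist))
  p_AA <- rep(0.5, n_markers)
  p_AA[distorted] <- distortion_p
  m <- matrix(-1L, n_lines, n_markers)
  for (i in seq_len(n_lines)) {
    het <- runif(n_markers) < h
    hom <- ifelse(runif(n_markers) < p_AA, 0L, 2L)
    g <- ifelse(het, 1L, hom)
    g[runif(n_markers) < nocall_rate] <- -1L
    m[i, ] <- g
  }
  marker_ids <- sprintf("M%05d", seq_len(n_markers))
  m <- rbind(m, matrix(rep(c(0L, 2L), each = n_markers), 2,
                       byrow = TRUE))
  dimnames(m) <- list(c(sprintf("RIL%03d", seq_len(n_lines)), "P1", "P2"),
                      marker_ids)
  list(matrix = genotypeMatrix(m), parents = c("P1", "P2"),
       distorted = marker_ids[distorted])
}
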