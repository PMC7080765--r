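#' Read a 12-column tabular similarity-hit file
#'
#' Reads the standard 12-column tabular output of a nucleotide similarity
#' search (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`), keeping the columns the categorisation rules use.
#'
#' @param file path to the tabular hit file (no header, tab-separated).
#' @param species optional label attached to every hit (e.g. `"self-db"`,
#'   `"glycine"`); kept as a `species` column.
#' @return data.frame with columns `query_id`, `subject_id`, `bitscore`,
#'   `species`.
#' @export
readSimilarityHits <- function(file, species = NA_character_) {
  hits <- read.table(file, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE,
                     col.names = c("qseqid", "sseqid", "pident", "length",
                                   "mismatch", "gapopen", "qstart", "qend",
                                   "sstart", "send", "evalue", "bitscore"))
  data.frame(query_id = hits$qseqid, subject_id = hits$sseqid,
             bitscore = as.numeric(hits$bitscore), species = species,
             stringsAsFactors = FALSE)
}

## deterministic hit order: bitscore descending, subject id ascending
orderHits <- function(hits) {
  hits[order(-hits$bitscore, hits$subject_id), , drop = FALSE]
}

#' Single-copy test from self-database similarity hits
#'
#' A gene is single copy when, searched against the full gene set, it matches
#' only itself, or its best match to any *other* gene scores below the
#' bitscore cutoff (default 200). All non-self hits are inspected, which is
#' equivalent to inspecting the top-ranked non-self hit after the
#' deterministic sort.
#'
#' @param hits data.frame of hits for **one** query gene (`query_id`,
#'   `subject_id`, `bitscore`); must include the self match
#'   (`subject_id == query_id`).
#' @param cutoff best non-self bitscore at or above this fails the test
#'   (default 200, i.e. single copy requires `< 200`).
#' @return `TRUE` if the gene is single copy.
#' @examples
#' h <- data.frame(query_id = "g1", subject_id = c("g1", "g7"),
#'                 bitscore = c(3000, 199))
#' classifySingleCopy(h)  # TRUE: best non-self hit scores below 200
#' @export
classifySingleCopy <- function(hits, cutoff = 200) {
  chk(nrow(hits) >= 1, "empty hit table")
  qid <- unique(hits$query_id)
  chk(length(qid) == 1, "hits must belong to a single query gene")
  self <- hits$subject_id == qid
  chk(any(self), "malformed input: self-match missing for gene ", qid)
  non_self <- hits$bitscore[!self]
  length(non_self) == 0L || max(non_self) < cutoff
}

#' Cross-species class for a single-copy gene
#'
#' Splits single-copy genes by conservation against three reference legumes
#' (chickpea *Cicer arietinum*, soybean *Glycine max*, barrel medic
#' *Medicago truncatula*): no significant hit to any species gives SCP
#' (single copy, lineage specific); a significant soybean hit gives CSCSP
#' (conserved single copy); significant hits only to the other two species
#' leave the gene UNCLASSIFIED. "Significant" is an explicit bitscore cutoff.
#'
#' @param gene_id the query gene.
#' @param cross_hits data.frame (`query_id`, `subject_id`, `bitscore`,
#'   `species` in `c("cicer", "glycine", "medicago")`); hits for other genes
#'   are ignored. An empty table is valid.
#' @param cutoff significance bitscore (default 100).
#' @return one of `"SCP"`, `"CSCSP"`, `"UNCLASSIFIED"`.
#' @export
classifyCrossSpecies <- function(gene_id, cross_hits, cutoff = 100) {
  if (nrow(cross_hits))
    cross_hits <- cross_hits[cross_hits$query_id == gene_id &
                               cross_hits$bitscore >= cutoff, , drop = FALSE]
  if (!nrow(cross_hits)) return("SCP")
  if (any(cross_hits$species == "glycine")) return("CSCSP")
  "UNCLASSIFIED"
}

#' Agronomic-gene homolog set from curated-query hits
#'
#' Given similarity hits of a curated list of cloned agronomic genes against
#' the full gene database, returns the database genes hit at or above the
#' bitscore cutoff (default `>= 100`).
#'
#' @param curated_hits data.frame (`query_id` = curated gene, `subject_id` =
#'   database gene, `bitscore`).
#' @param cutoff inclusion bitscore, boundary included (default 100).
#' @return character vector of AGCP gene ids (sorted, unique).
#' @export
matchAgronomicGenes <- function(curated_hits, cutoff = 100) {
  if (!nrow(curated_hits)) return(character())
  sort(unique(curated_hits$subject_id[curated_hits$bitscore >= cutoff]))
}

#' Assign every gene its chip design category
#'
#' Combines the similarity-based rules with the curated lists into the final
#' partition over `{AGCP, DRDRP, MCP, SCP, CSCSP, UNCLASSIFIED}`. Precedence
#' when memberships overlap: AGCP > DRDRP > MCP > single-copy classes;
#' overlaps are reported in the `overlaps` attribute.
#'
#' @param gene_ids all gene identifiers to classify.
#' @param self_hits self-database hits (all genes in one data.frame).
#' @param cross_hits cross-species hits with a `species` column.
#' @param agronomic_hits curated-gene hits (see [matchAgronomicGenes()]).
#' @param drdrp_ids,mcp_ids curated id lists for the disease-resistance /
#'   defense-response and multi-copy control categories.
#' @param sc_cutoff,cross_cutoff,agcp_cutoff bitscore cutoffs (200, 100, 100).
#' @return named character vector of categories, one per gene, with an
#'   `overlaps` attribute (data.frame of genes claimed by several lists).
#' @export
classifyGenes <- function(gene_ids, self_hits, cross_hits,
                          agronomic_hits = NULL, drdrp_ids = character(),
                          mcp_ids = character(), sc_cutoff = 200,
                          cross_cutoff = 100, agcp_cutoff = 100) {
  agcp <- if (is.null(agronomic_hits)) character()
          else matchAgronomicGenes(agronomic_hits, agcp_cutoff)
  cat <- setNames(rep("UNCLASSIFIED", length(gene_ids)), gene_ids)
  split_hits <- split(self_hits, self_hits$query_id)
  for (g in gene_ids) {
    h <- split_hits[[g]]
    if (!is.null(h) && classifySingleCopy(h, sc_cutoff))
      cat[g] <- classifyCrossSpecies(g, cross_hits, cross_cutoff)
  }
  overlaps <- data.frame(gene_id = character(), kept = character(),
                         also = character(), stringsAsFactors = FALSE)
  claim <- function(ids, label) {
    ids <- intersect(ids, gene_ids)
    prior <- ids[cat[ids] %in% c("AGCP", "DRDRP", "MCP")]
    if (length(prior))
      overlaps <<- rbind(overlaps,
                         data.frame(gene_id = prior, kept = cat[prior],
                                    also = label, stringsAsFactors = FALSE))
    cat[setdiff(ids, prior)] <<- label
  }
  claim(agcp, "AGCP")
  claim(drdrp_ids, "DRDRP")
  claim(mcp_ids, "MCP")
  attr(cat, "overlaps") <- overlaps
  cat
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` and `exon` records and returns the plain geometry the
#' catalog builder needs. Exons are attached to genes via `Parent` (directly
#' or through an mRNA) or, failing that, by containment within the gene span
#' on the same strand.
#'
#' @param file GFF3 path.
#' @return list with `info` (data.frame: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`) and `exons` (named list of genomic-coordinate interval
#'   matrices, 1-based inclusive, sorted).
#' @export
readGeneModels <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  genes <- gr[gr$type == "gene"]
  ex <- gr[gr$type == "exon"]
  gene_ids <- as.character(genes$ID)
  info <- data.frame(gene_id = gene_ids,
                     chrom = as.character(GenomicRanges::seqnames(genes)),
                     strand = as.character(GenomicRanges::strand(genes)),
                     start = GenomicRanges::start(genes),
                     end = GenomicRanges::end(genes),
                     stringsAsFactors = FALSE)
  parent <- if (length(ex)) vapply(ex$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "") else character()
  ## resolve mRNA parents one level up
  mrna <- gr[gr$type %in% c("mRNA", "transcript")]
  if (length(mrna)) {
    mp <- setNames(vapply(mrna$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, ""),
      as.character(mrna$ID))
    hit <- parent %in% names(mp)
    parent[hit] <- mp[parent[hit]]
  }
  exons <- lapply(seq_along(gene_ids), function(i) {
    g <- gene_ids[i]
    sel <- which(parent == g)
    if (!length(sel) && length(ex))
      sel <- which(as.character(GenomicRanges::seqnames(ex)) == info$chrom[i] &
                     GenomicRanges::start(ex) >= info$start[i] &
                     GenomicRanges::end(ex) <= info$end[i])
    m <- cbind(start = GenomicRanges::start(ex)[sel],
               end = GenomicRanges::end(ex)[sel])
    m[order(m[, 1]), , drop = FALSE]
  })
  names(exons) <- gene_ids
  list(info = info, exons = exons)
}

#' Build the flanked reference-sequence catalog
#'
#' Extracts each gene's full span plus an upstream and downstream flank from
#' the genome, reverse-complementing minus-strand genes so every catalog
#' sequence runs 5' to 3' along the gene. Flanks that run off a contig end
#' are truncated and the lost length recorded. Exon intervals are mapped
#' into 1-based extracted coordinates.
#'
#' @param models list as returned by [readGeneModels()] (`info` + `exons`).
#' @param genome [Biostrings::DNAStringSet] named by chromosome/contig.
#' @param categories named character vector of categories per gene (e.g. from
#'   [classifyGenes()]); missing genes get `UNCLASSIFIED`.
#' @param upstream,downstream requested flank lengths in bp (defaults 500
#'   and 100, measured from the translation start and stop).
#' @return A [GeneCatalog-class].
#' @export
buildReferenceCatalog <- function(models, genome, categories = NULL,
                                  upstream = 500, downstream = 100) {
  info <- models$info
  n <- nrow(info)
  chk(n > 0, "no gene models")
  seqs <- vector("list", n)
  exons_ext <- vector("list", n)
  out <- info
  out$category <- if (is.null(categories)) "UNCLASSIFIED" else
    ifelse(is.na(categories[info$gene_id]), "UNCLASSIFIED",
           categories[info$gene_id])
  out$up_flank <- upstream; out$down_flank <- downstream
  out$up_trunc <- 0L; out$down_trunc <- 0L
  out$ext_start <- NA_integer_; out$ext_end <- NA_integer_
  out$length_bp <- NA_integer_
  for (i in seq_len(n)) {
    g <- info$gene_id[i]
    chrom <- info$chrom[i]
    chk(chrom %in% names(genome),
        "gene ", g, ": chromosome ", chrom, " absent from genome")
    clen <- Biostrings::width(genome[chrom])
    chk(info$start[i] >= 1 && info$end[i] <= clen &&
          info$start[i] <= info$end[i],
        "gene ", g, ": span outside source sequence")
    plus <- info$strand[i] != "-"
    up_g <- as.integer(if (plus) upstream else downstream)   # genomic left
    down_g <- as.integer(if (plus) downstream else upstream) # genomic right
    rs <- as.integer(info$start[i]) - up_g
    re <- as.integer(info$end[i]) + down_g
    left_trunc <- max(0L, 1L - rs)
    right_trunc <- max(0L, re - clen)
    rs <- rs + left_trunc
    re <- re - right_trunc
    s <- Biostrings::subseq(genome[[chrom]], rs, re)
    ex <- models$exons[[g]]
    if (is.null(ex)) ex <- cbind(start = info$start[i], end = info$end[i])
    if (plus) {
      em <- cbind(start = ex[, 1] - rs + 1L, end = ex[, 2] - rs + 1L)
      out$up_trunc[i] <- left_trunc; out$down_trunc[i] <- right_trunc
    } else {
      s <- Biostrings::reverseComplement(s)
      em <- cbind(start = re - ex[, 2] + 1L, end = re - ex[, 1] + 1L)
      out$up_trunc[i] <- right_trunc; out$down_trunc[i] <- left_trunc
    }
    em <- em[order(em[, 1]), , drop = FALSE]
    chk(all(em[, 1] >= 1) && all(em[, 2] <= length(s)),
        "gene ", g, ": exons outside gene span")
    seqs[[i]] <- s
    exons_ext[[i]] <- em
    out$ext_start[i] <- rs; out$ext_end[i] <- re
    out$length_bp[i] <- length(s)
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- info$gene_id
  names(exons_ext) <- info$gene_id
  new("GeneCatalog",
      info = out[, c("gene_id", "chrom", "strand", "start", "end", "category",
                     "up_flank", "down_flank", "up_trunc", "down_trunc",
                     "ext_start", "ext_end", "length_bp")],
      sequences = dss, exons = exons_ext)
}

#' Lift an extracted-coordinate position back to the genome
#'
#' Inverse of the catalog extraction: maps a 1-based position within a
#' gene's extracted (gene-oriented) sequence to its genomic coordinate.
#'
#' @param catalog a [GeneCatalog-class].
#' @param gene_id gene identifier.
#' @param pos position(s) in extracted coordinates.
#' @return genomic coordinate(s), 1-based.
#' @export
extractedToGenomic <- function(catalog, gene_id, pos) {
  info <- catalogInfo(catalog)
  i <- match(gene_id, info$gene_id)
  chk(!is.na(i), "unknown gene ", gene_id)
  chk(all(pos >= 1 & pos <= info$length_bp[i]), "position out of bounds")
  if (info$strand[i] != "-") info$ext_start[i] + pos - 1L
  else info$ext_end[i] - pos + 1L
}

#' Write the catalog manifest TSV
#'
#' One row per gene: id, category, extracted length and flank truncation
#' flags, mirroring the design-pipeline bookkeeping format.
#'
#' @param catalog a [GeneCatalog-class].
#' @param file output path.
#' @return the manifest data.frame, invisibly.
#' @export
writeCatalogManifest <- function(catalog, file) {
  info <- catalogInfo(catalog)
  man <- info[, c("gene_id", "category", "length_bp", "up_trunc",
                  "down_trunc")]
  write.table(man, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}
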