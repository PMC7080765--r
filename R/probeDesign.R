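#' Probe design configuration
#'
#' Axiom-style assay geometry: a 72-bp plex with the target SNP at base 36
#' (35 bases of 5' flank, 36 of 3' flank), a 10-bp interference window on
#' either side of the target, and a 0.50 designability gate.
#'
#' @param plex_length plex length in bp (72).
#' @param snp_offset 1-based SNP position within the plex (36).
#' @param interference_window interfering-SNP distance in bp (10): another
#'   SNP at positional distance `<= interference_window` disqualifies the
#'   target.
#' @param score_threshold designability gate; a candidate is
#'   `recommended` only when its score is strictly greater (0.50).
#' @return list of class `probeConfig`.
#' @export
probeConfig <- function(plex_length = 72, snp_offset = 36,
                        interference_window = 10, score_threshold = 0.50) {
  chk(snp_offset >= 1 && snp_offset <= plex_length,
      "snp_offset must lie within the plex")
  chk(interference_window >= 0, "window must be non-negative")
  structure(list(plex_length = plex_length, snp_offset = snp_offset,
                 interference_window = interference_window,
                 score_threshold = score_threshold),
            class = "probeConfig")
}

#' Remove SNPs with interfering neighbours
#'
#' A target SNP survives iff no other SNP of the same gene lies within
#' `window` bp on either side (positional distance `<= window` interferes;
#' at the default 10, neighbours 10 bp apart remove each other, 11 bp apart
#' do not). Each SNP is evaluated independently, so interference is
#' symmetric: both members of a close pair are removed.
#'
#' @param positions integer vector of SNP positions within one gene
#'   (gene-oriented, 1-based). Duplicates are a malformed catalog.
#' @param window interference distance in bp (default 10).
#' @return logical vector parallel to `positions`: `TRUE` = survives.
#' @export
interferingFilter <- function(positions, window = 10) {
  chk(!anyDuplicated(positions), "duplicate SNP positions in gene")
  n <- length(positions)
  if (n <= 1L) return(rep(TRUE, n))
  p <- sort(positions)
  gap_prev <- c(Inf, diff(p))
  gap_next <- c(diff(p), Inf)
  ok_sorted <- gap_prev > window & gap_next > window
  ok_sorted[match(positions, p)]
}

#' Extract the 72-bp SNP plex
#'
#' Builds the assay context string: `snp_offset - 1` bases of 5' flank, the
#' two alleles in bracket notation (`"[A/G]"`), then
#' `plex_length - snp_offset` bases of 3' flank. SNPs too close to the ends
#' of the extracted gene sequence cannot fill the window and come back with
#' status `not_possible`.
#'
#' @param sequence the gene's extracted sequence (character or
#'   [Biostrings::DNAString]).
#' @param position SNP position within the sequence (1-based).
#' @param ref,alt the two alleles.
#' @param config a [probeConfig()].
#' @return list: `plex` (bracket notation or NA), `forward_probe` (72-mer
#'   with the reference allele substituted), `reverse_probe` (its reverse
#'   complement), `status` (`"ok"` or `"not_possible"`), `reason`.
#' @export
extractPlex <- function(sequence, position, ref, alt,
                        config = probeConfig()) {
  s <- as.character(sequence)
  n <- nchar(s)
  left <- config$snp_offset - 1L
  right <- config$plex_length - config$snp_offset
  if (position - left < 1L || position + right > n)
    return(list(plex = NA_character_, forward_probe = NA_character_,
                reverse_probe = NA_character_, status = "not_possible",
                reason = "insufficient flank"))
  lf <- substr(s, position - left, position - 1L)
  rf <- substr(s, position + 1L, position + right)
  fwd <- paste0(lf, ref, rf)
  list(plex = paste0(lf, "[", ref, "/", alt, "]", rf),
       forward_probe = fwd,
       reverse_probe = as.character(Biostrings::reverseComplement(
         Biostrings::DNAString(fwd))),
       status = "ok", reason = "pass")
}

#' k-mer occurrence index over the catalog
#'
#' Counts every k-mer across all extracted catalog sequences; used by the
#' designability score to penalise plex flanks whose 16-mers occur more
#' than once in the design space (cross-hybridisation proxy).
#'
#' @param catalog a [GeneCatalog-class] (or [Biostrings::DNAStringSet]).
#' @param k k-mer length (default 16).
#' @return named integer vector of k-mer counts.
#' @export
catalogKmerIndex <- function(catalog, k = 16) {
  seqs <- if (is(catalog, "GeneCatalog")) catalogSequences(catalog)
          else catalog
  kmers <- unlist(lapply(as.character(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  tab <- table(kmers)
  setNames(as.integer(tab), names(tab))
}

## parse "LLLL[A/G]RRRR" -> list(left, right, ref, alt) or NULL
parsePlex <- function(plex) {
  m <- regmatches(plex, regexec("^([ACGTN]*)\\[([A-Z])/([A-Z])\\]([ACGTN]*)$",
                                plex))[[1]]
  if (length(m) != 5) return(NULL)
  list(left = m[2], ref = m[3], alt = m[4], right = m[5])
}

#' Surrogate designability score for a plex
#'
#' Deterministic score in `[0, 1]` built from documented multiplicative
#' penalties (0.5 each) on the 71 flank bases: GC fraction outside
#' `[0.30, 0.70]`; a homopolymer run of 6 or more; any flank 16-mer that is
#' non-unique in the catalog k-mer index; any ambiguity (non-ACGT)
#' character. A candidate is `recommended` when the score is strictly
#' greater than the threshold (default 0.50), `not_recommended` otherwise.
#'
#' @param plex bracket-notation plex string from [extractPlex()].
#' @param kmer_index optional index from [catalogKmerIndex()]; without it
#'   the uniqueness penalty is skipped.
#' @param config a [probeConfig()].
#' @param gc_range,max_homopolymer,k penalty parameters.
#' @return list: `score`, `status`, `penalties` (character vector of fired
#'   penalties).
#' @export
scoreCandidate <- function(plex, kmer_index = NULL, config = probeConfig(),
                           gc_range = c(0.30, 0.70), max_homopolymer = 6,
                           k = 16) {
  p <- parsePlex(plex)
  chk(!is.null(p), "malformed plex: ", plex)
  flanks <- paste0(p$left, p$right)
  chk(nchar(flanks) == config$plex_length - 1L,
      "plex has wrong length: ", plex)
  fired <- character()
  bases <- strsplit(flanks, "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  if (gc < gc_range[1] || gc > gc_range[2]) fired <- c(fired, "gc_content")
  if (grepl(sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}", max_homopolymer,
                    max_homopolymer, max_homopolymer, max_homopolymer),
            flanks))
    fired <- c(fired, "homopolymer")
  if (any(!bases %in% c("A", "C", "G", "T"))) fired <- c(fired, "ambiguity")
  if (!is.null(kmer_index)) {
    km <- c(if (nchar(p$left) >= k)
              substring(p$left, 1:(nchar(p$left) - k + 1), k:nchar(p$left)),
            if (nchar(p$right) >= k)
              substring(p$right, 1:(nchar(p$right) - k + 1),
                        k:nchar(p$right)))
    counts <- kmer_index[km]
    counts[is.na(counts)] <- 0L
    if (any(counts > 1L)) fired <- c(fired, "non_unique_flank")
  }
  score <- 0.5^length(fired)
  list(score = score,
       status = if (score > config$score_threshold) "recommended"
                else "not_recommended",
       penalties = fired)
}

#' End-to-end probe design over a SNP catalog
#'
#' Runs the full funnel -- interfering-SNP exclusion per gene, plex
#' extraction, designability scoring -- and records survivor counts at every
#' stage so attrition is auditable.
#'
#' @param catalog a [GeneCatalog-class].
#' @param records SNP records from [snpRecords()].
#' @param config a [probeConfig()].
#' @param kmer_index optional [catalogKmerIndex()]; by default built from
#'   the catalog.
#' @return list: `manifest` (data.frame: `snp_id`, `gene_id`, `category`,
#'   `position`, `plex`, `forward_probe`, `reverse_probe`,
#'   `surrogate_score`, `status`) and `attrition` (named counts:
#'   `identified`, `interference_filtered`, `plex_extracted`,
#'   `recommended`).
#' @export
designPipeline <- function(catalog, records, config = probeConfig(),
                           kmer_index = catalogKmerIndex(catalog)) {
  seqs <- as.character(catalogSequences(catalog))
  attrition <- c(identified = nrow(records), interference_filtered = 0L,
                 plex_extracted = 0L, recommended = 0L)
  if (!nrow(records))
    return(list(manifest = data.frame(), attrition = attrition))
  keep <- logical(nrow(records))
  for (g in unique(records$gene_id)) {
    sel <- which(records$gene_id == g)
    keep[sel] <- interferingFilter(records$position[sel],
                                   config$interference_window)
  }
  surv <- records[keep, , drop = FALSE]
  attrition["interference_filtered"] <- nrow(surv)
  rows <- lapply(seq_len(nrow(surv)), function(i) {
    r <- surv[i, ]
    px <- extractPlex(seqs[[r$gene_id]], r$position, r$ref_allele,
                      r$alt_allele, config)
    if (px$status == "not_possible")
      return(data.frame(snp_id = r$snp_id, gene_id = r$gene_id,
                        category = r$category, position = r$position,
                        plex = NA_character_, forward_probe = NA_character_,
                        reverse_probe = NA_character_, surrogate_score = NA,
                        status = "not_possible", stringsAsFactors = FALSE))
    sc <- scoreCandidate(px$plex, kmer_index, config)
    data.frame(snp_id = r$snp_id, gene_id = r$gene_id,
               category = r$category, position = r$position,
               plex = px$plex, forward_probe = px$forward_probe,
               reverse_probe = px$reverse_probe,
               surrogate_score = sc$score, status = sc$status,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  attrition["plex_extracted"] <- sum(manifest$status != "not_possible")
  attrition["recommended"] <- sum(manifest$status == "recommended")
  list(manifest = manifest, attrition = attrition)
}

#' Write the probe manifest and attrition report
#'
#' @param design result of [designPipeline()].
#' @param manifest_file CSV path for the probe manifest.
#' @param attrition_file JSON path for the stage counts (optional).
#' @return `design`, invisibly.
#' @export
writeProbeManifest <- function(design, manifest_file,
                               attrition_file = NULL) {
  write.table(design$manifest, manifest_file, sep = ",", quote = FALSE,
              row.names = FALSE)
  if (!is.null(attrition_file))
    jsonlite::write_json(as.list(design$attrition), attrition_file,
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(design)
}
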