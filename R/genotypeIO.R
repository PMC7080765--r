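#' Genotype matrix TSV I/O
#'
#' The TSV dialect is samples x SNPs with a `sample` id column and one
#' column per SNP carrying the `{0, 1, 2, -1}` codes.
#'
#' @param x a [GenotypeMatrix-class].
#' @param file path.
#' @return `writeGenotypeTSV`: `x` invisibly; `readGenotypeTSV`: a
#'   [GenotypeMatrix-class] (map columns NA unless `map_file` is given).
#' @param map_file optional TSV with columns `snp_id`, `chrom`, `pos`,
#'   `gene_id`.
#' @export
writeGenotypeTSV <- function(x, file) {
  m <- genotypeCalls(x)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname writeGenotypeTSV
#' @export
readGenotypeTSV <- function(file, map_file = NULL) {
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  info <- NULL
  if (!is.null(map_file)) {
    info <- read.table(map_file, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
    info <- info[match(colnames(m), info$snp_id), , drop = FALSE]
  }
  genotypeMatrix(m, info)
}

#' PLINK ped/map export and import
#'
#' Writes the classic whitespace-separated PLINK text pair: `.ped` with
#' family/individual ids, zeroed parent/sex/phenotype columns and two
#' allele letters (A/B) per SNP (`0 0` when missing), and `.map` with
#' chromosome, SNP id, genetic distance 0 and position. The importer
#' reverses the coding, so export followed by import is lossless.
#'
#' @param x a [GenotypeMatrix-class].
#' @param prefix output path prefix (writes `prefix.ped`, `prefix.map`).
#' @return `exportPlink`: the two paths, invisibly; `importPlink`: a
#'   [GenotypeMatrix-class].
#' @export
exportPlink <- function(x, prefix) {
  m <- genotypeCalls(x)
  info <- snpInfo(x)
  alleles <- list(`-1` = c("0", "0"), `0` = c("A", "A"),
                  `1` = c("A", "B"), `2` = c("B", "B"))
  ped <- vapply(seq_len(nrow(m)), function(i) {
    gg <- unlist(alleles[as.character(m[i, ])], use.names = FALSE)
    paste(c(rownames(m)[i], rownames(m)[i], "0", "0", "0", "-9", gg),
          collapse = " ")
  }, "")
  writeLines(ped, paste0(prefix, ".ped"))
  map <- data.frame(chrom = ifelse(is.na(info$chrom), "0", info$chrom),
                    snp_id = info$snp_id, gd = 0,
                    pos = ifelse(is.na(info$pos), 0L, info$pos))
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' @rdname exportPlink
#' @export
importPlink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "gd", "pos"))
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  n_snp <- nrow(map)
  chk(ncol(ped) == 6 + 2 * n_snp, "ped/map column mismatch")
  geno <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- geno[, seq(1, 2 * n_snp, by = 2), drop = FALSE]
  a2 <- geno[, seq(2, 2 * n_snp, by = 2), drop = FALSE]
  code <- matrix(-1L, nrow(ped), n_snp)
  code[a1 == "A" & a2 == "A"] <- 0L
  code[(a1 == "A" & a2 == "B") | (a1 == "B" & a2 == "A")] <- 1L
  code[a1 == "B" & a2 == "B"] <- 2L
  dimnames(code) <- list(ped[[2]], map$snp_id)
  chrom <- as.character(map$chrom)
  chrom[chrom == "0"] <- NA_character_
  genotypeMatrix(code, data.frame(snp_id = map$snp_id, chrom = chrom,
                                  pos = ifelse(map$pos == 0, NA_integer_,
                                               map$pos),
                                  gene_id = NA_character_,
                                  stringsAsFactors = FALSE))
}

#' Export a STRUCTURE main input file
#'
#' Two rows per individual (one allele per row), alleles coded 1/2 and
#' missing as -9, preceded by a header line of SNP ids -- the main-input
#' layout STRUCTURE's admixture model reads.
#'
#' @param x a [GenotypeMatrix-class].
#' @param file output path.
#' @param subset optional SNP ids/indices (e.g. from
#'   [selectUnlinkedSubset()]).
#' @return the path, invisibly.
#' @export
exportStructure <- function(x, file, subset = NULL) {
  m <- genotypeCalls(x)
  if (!is.null(subset)) m <- m[, subset, drop = FALSE]
  first <- list(`-1` = "-9", `0` = "1", `1` = "1", `2` = "2")
  second <- list(`-1` = "-9", `0` = "1", `1` = "2", `2` = "2")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = " "), con)
  for (i in seq_len(nrow(m))) {
    g <- as.character(m[i, ])
    writeLines(paste(c(rownames(m)[i],
                       unlist(first[g], use.names = FALSE)),
                     collapse = " "), con)
    writeLines(paste(c(rownames(m)[i],
                       unlist(second[g], use.names = FALSE)),
                     collapse = " "), con)
  }
  invisible(file)
}
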