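#' Call rates per sample or per SNP
#'
#' Fraction of non-missing calls along the chosen axis, plus the count of
#' units clearing a high-call-rate gate (default 0.955, the usual
#' chip-validation threshold).
#'
#' @param x a [GenotypeMatrix-class].
#' @param axis `"sample"` or `"snp"`.
#' @param threshold gate for the `n_above` count (strictly greater).
#' @return list: `rates` (named numeric in `[0, 1]`), `n_above`,
#'   `threshold`.
#' @export
callRate <- function(x, axis = c("sample", "snp"), threshold = 0.955) {
  axis <- match.arg(axis)
  m <- genotypeCalls(x)
  chk(length(m) > 0, "empty genotype matrix")
  called <- m != -1L
  rates <- if (axis == "sample") rowMeans(called) else colMeans(called)
  list(rates = rates, n_above = sum(rates > threshold),
       threshold = threshold)
}

#' Per-sample heterozygosity
#'
#' AB calls as a fraction of non-missing calls per sample; samples with no
#' called genotypes come back NA.
#'
#' @param x a [GenotypeMatrix-class].
#' @return named numeric vector in `[0, 1]` (NA where undefined).
#' @export
heterozygosity <- function(x) {
  m <- genotypeCalls(x)
  het <- rowSums(m == 1L)
  called <- rowSums(m != -1L)
  ifelse(called == 0, NA_real_, het / called)
}

#' Concordance between two samples
#'
#' Fraction of identical calls over SNPs where both samples are called;
#' the duplicate-sample reproducibility metric.
#'
#' @param x a [GenotypeMatrix-class].
#' @param sample_a,sample_b sample identifiers.
#' @return numeric in `[0, 1]`.
#' @export
concordance <- function(x, sample_a, sample_b) {
  m <- genotypeCalls(x)
  chk(all(c(sample_a, sample_b) %in% rownames(m)), "unknown sample")
  a <- m[sample_a, ]; b <- m[sample_b, ]
  both <- a != -1L & b != -1L
  chk(any(both), "samples ", sample_a, " and ", sample_b,
      " share no called SNPs")
  mean(a[both] == b[both])
}

#' Minor allele frequencies
#'
#' Allele counts from genotype codes (`2*AA + AB` A alleles, `AB + 2*BB` B
#' alleles) over non-missing calls; MAF is the smaller fraction.
#' Monomorphic or fully missing SNPs give 0.
#'
#' @param x a [GenotypeMatrix-class].
#' @param snps SNP ids or indices (default: all).
#' @return named numeric vector in `[0, 0.5]`.
#' @export
minorAlleleFrequency <- function(x, snps = NULL) {
  m <- genotypeCalls(x)
  if (!is.null(snps)) m <- m[, snps, drop = FALSE]
  nAA <- colSums(m == 0L); nAB <- colSums(m == 1L); nBB <- colSums(m == 2L)
  a <- 2 * nAA + nAB
  b <- nAB + 2 * nBB
  tot <- a + b
  ifelse(tot == 0, 0, pmin(a, b) / tot)
}

#' Chi-square test of 1:1 segregation
#'
#' Two-class goodness-of-fit without continuity correction:
#' `chisq = (n_AA - n_BB)^2 / (n_AA + n_BB)`, df = 1.
#'
#' @param n_AA,n_BB homozygous class counts (vectors allowed).
#' @return data.frame: `n_AA`, `n_BB`, `chi_square`, `p_value`.
#' @export
chiSquare1to1 <- function(n_AA, n_BB) {
  tot <- n_AA + n_BB
  chi <- ifelse(tot == 0, NA_real_, (n_AA - n_BB)^2 / tot)
  data.frame(n_AA = n_AA, n_BB = n_BB, chi_square = chi,
             p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Segregation-distortion marker filter for a RIL population
#'
#' For an F-generation recombinant inbred population: keeps markers that
#' are homozygous and polymorphic between the two parents, treats residual
#' heterozygous RIL calls as missing, and discards markers whose
#' homozygous-class counts depart from the expected 1:1 ratio by the
#' chi-square test at `alpha` (kept iff `p >= alpha`).
#'
#' @param x a [GenotypeMatrix-class] containing the RILs and both parents.
#' @param parents length-2 character vector of parent sample ids.
#' @param alpha significance cutoff (default 0.05).
#' @return list: `kept` (character vector of retained marker ids), `tests`
#'   (data.frame per testable marker: `marker_id`, `n_AA`, `n_BB`,
#'   `chi_square`, `p_value`, `keep`), `excluded` (data.frame of markers
#'   dropped before testing, with reasons).
#' @export
rilMarkerFilter <- function(x, parents, alpha = 0.05) {
  chk(length(parents) == 2, "exactly two parents required")
  m <- genotypeCalls(x)
  chk(all(parents %in% rownames(m)), "parents absent from matrix")
  p1 <- m[parents[1], ]; p2 <- m[parents[2], ]
  rils <- m[!rownames(m) %in% parents, , drop = FALSE]
  hom_poly <- p1 %in% c(0L, 2L) & p2 %in% c(0L, 2L) & p1 != p2
  reason <- rep(NA_character_, ncol(m))
  reason[p1 == 1L | p2 == 1L] <- "parent_heterozygous"
  reason[is.na(reason) & (p1 == -1L | p2 == -1L)] <- "parent_missing"
  reason[is.na(reason) & !hom_poly] <- "monomorphic_parents"
  excluded <- data.frame(marker_id = colnames(m)[!hom_poly],
                         reason = reason[!hom_poly],
                         stringsAsFactors = FALSE)
  test_idx <- which(hom_poly)
  nAA <- colSums(rils[, test_idx, drop = FALSE] == 0L)
  nBB <- colSums(rils[, test_idx, drop = FALSE] == 2L)
  tests <- chiSquare1to1(nAA, nBB)
  tests <- cbind(marker_id = colnames(m)[test_idx], tests,
                 stringsAsFactors = FALSE)
  tests$keep <- !is.na(tests$p_value) & tests$p_value >= alpha
  rownames(tests) <- NULL
  list(kept = tests$marker_id[tests$keep], tests = tests,
       excluded = excluded)
}

#' QC report for a genotype matrix
#'
#' Bundles the headline chip QC metrics (per-sample and per-SNP call rates,
#' heterozygosity range and mean, gate counts) into one list, suitable for
#' JSON export.
#'
#' @param x a [GenotypeMatrix-class].
#' @param threshold high-call-rate gate (default 0.955).
#' @return list of summary statistics.
#' @export
qcReport <- function(x, threshold = 0.955) {
  cr_s <- callRate(x, "sample", threshold)
  cr_m <- callRate(x, "snp", threshold)
  het <- heterozygosity(x)
  list(n_samples = nrow(genotypeCalls(x)),
       n_snps = ncol(genotypeCalls(x)),
       sample_call_rate_mean = mean(cr_s$rates),
       samples_above_gate = cr_s$n_above,
       snp_call_rate_mean = mean(cr_m$rates),
       snps_above_gate = cr_m$n_above,
       call_rate_gate = threshold,
       het_mean = mean(het, na.rm = TRUE),
       het_min = min(het, na.rm = TRUE),
       het_max = max(het, na.rm = TRUE))
}
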