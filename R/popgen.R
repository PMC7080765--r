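#' SNPs with complete call rates
#'
#' @param x a [GenotypeMatrix-class].
#' @return character vector of SNP ids with no missing call in any sample.
#' @export
selectFullCallrateSnps <- function(x) {
  m <- genotypeCalls(x)
  colnames(m)[colSums(m == -1L) == 0L]
}

#' Identity-by-state distance matrix
#'
#' `d(i, j) = 1 -` the proportion of alleles shared between samples i and j,
#' averaged over jointly called SNPs: identical homozygotes share 1,
#' homozygote vs heterozygote 0.5, opposite homozygotes 0 (equivalently
#' `|g_i - g_j| / 2` mismatch on the 0/1/2 coding).
#'
#' @param x a [GenotypeMatrix-class].
#' @param subset optional SNP ids/indices to restrict to.
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
ibsDistance <- function(x, subset = NULL) {
  m <- genotypeCalls(x)
  if (!is.null(subset)) m <- m[, subset, drop = FALSE]
  chk(ncol(m) > 0, "empty SNP subset")
  g <- m
  g[g == -1L] <- NA_integer_
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diff <- abs(g[i, ] - g[j, ])
    ok <- !is.na(diff)
    chk(any(ok), "samples ", rownames(g)[i], " and ", rownames(g)[j],
        " share no called SNPs")
    d[i, j] <- d[j, i] <- mean(diff[ok]) / 2
  }
  d
}

## deterministic argmin over the upper triangle: smallest (i, j) on ties
whichMinPair <- function(Q) {
  Q[lower.tri(Q, diag = TRUE)] <- Inf
  hits <- which(Q == min(Q), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  hits[1, ]
}

#' Neighbor-joining tree
#'
#' Classic Saitou-Nei agglomeration: repeatedly join the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j`, with branch lengths
#' `l_i = d(i,j)/2 + (r_i - r_j) / (2(n-2))`, reducing the matrix by
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in Q are broken
#' deterministically by the lowest index pair, so the result is a pure
#' function of the input ordering. The final three clusters are resolved by
#' the three-point formulas.
#'
#' @param d symmetric distance matrix with sample ids as dimnames
#'   (`n >= 3`).
#' @return an unrooted [ape::phylo] tree (export with [ape::write.tree]).
#' @export
neighborJoining <- function(d) {
  chk(is.matrix(d) && nrow(d) == ncol(d), "distance matrix must be square")
  chk(max(abs(d - t(d))) < 1e-8, "distance matrix must be symmetric")
  n <- nrow(d)
  chk(n >= 3, "need at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.12g", x)
  reps <- labs
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    ij <- whichMinPair(Q)
    i <- ij[1]; j <- ij[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newrep <- paste0("(", reps[i], ":", fmt(li), ",",
                     reps[j], ":", fmt(lj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    reps <- c(reps[keep], newrep)
    D <- D2
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", reps[1], ":", fmt(l1), ",", reps[2], ":", fmt(l2),
                ",", reps[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Select genome-wide unlinked SNPs
#'
#' Per chromosome, takes the candidate SNP with minor allele frequency at
#' or above `maf_min` nearest each of three anchor points -- the two ends
#' and the midpoint of the chromosome's covered interval (a proxy for
#' telomeric and centromeric placement) -- then de-duplicates. With 11
#' chromosomes and dense candidates this yields 33 SNPs.
#'
#' @param x a [GenotypeMatrix-class] whose `snpInfo` carries `chrom` and
#'   `pos`.
#' @param maf_min minimum minor allele frequency (default 0.30, boundary
#'   included).
#' @param per_chrom anchors per chromosome (default 3).
#' @return character vector of selected SNP ids; chromosomes with no
#'   qualifying candidate raise a warning and contribute fewer SNPs.
#' @export
selectUnlinkedSubset <- function(x, maf_min = 0.30, per_chrom = 3) {
  info <- snpInfo(x)
  chk(!anyNA(info$chrom) && !anyNA(info$pos),
      "snpInfo must carry chrom and pos for every SNP")
  maf <- minorAlleleFrequency(x)
  picked <- character()
  for (chr in unique(info$chrom)) {
    on_chr <- info$chrom == chr
    span <- range(info$pos[on_chr])
    anchors <- seq(span[1], span[2], length.out = per_chrom)
    cand <- which(on_chr & maf >= maf_min)
    if (!length(cand)) {
      warning("chromosome ", chr, ": no SNP with MAF >= ", maf_min)
      next
    }
    sel <- vapply(anchors, function(a) {
      off <- abs(info$pos[cand] - a)
      cand[order(off, info$pos[cand])[1]]
    }, 0L)
    picked <- c(picked, info$snp_id[unique(sel)])
  }
  picked
}

#' Agreement between a tree bipartition and known group labels
#'
#' Scans every internal edge of an unrooted tree and returns the best
#' agreement between the bipartition the edge induces and a two-group
#' labelling of (a subset of) the tips; used to score whether a
#' neighbor-joining tree separates known subpopulations. Tips without a
#' label (e.g. admixed samples) are ignored.
#'
#' @param tree an [ape::phylo].
#' @param labels named vector (tip label -> group) with exactly two groups
#'   among the labelled tips.
#' @return best fraction of labelled tips classified consistently, in
#'   `[0.5, 1]`.
#' @export
treeBipartitionAccuracy <- function(tree, labels) {
  labels <- labels[names(labels) %in% tree$tip.label]
  groups <- unique(labels)
  chk(length(groups) == 2, "labels must define exactly two groups")
  truth <- labels == groups[1]
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tipsUnder <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], tipsUnder))
  }
  best <- 0.5
  for (node in unique(tree$edge[, 2])) {
    if (node <= ntip) next
    side <- names(truth) %in% tipsUnder(node)
    acc <- mean(side == truth)
    best <- max(best, acc, 1 - acc)
  }
  best
}
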