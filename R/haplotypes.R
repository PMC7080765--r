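#' Extract per-gene haplotypes from chip genotypes
#'
#' Concatenates each sample's alleles across a gene's SNPs into a haplotype
#' string (A = reference homozygote, B = alternate homozygote). The default
#' policy `"exclude"` assigns only samples that are fully called and
#' homozygous at every gene SNP (chip haplotyping convention for a selfing
#' species); `"het_as_missing"` first recodes heterozygous calls to `N` and
#' then applies the completeness requirement, so with `max_missing > 0`
#' haplotype strings may carry `N`s.
#'
#' @param x a [GenotypeMatrix-class].
#' @param gene gene id; its SNPs are looked up in `snpInfo(x)$gene_id`
#'   unless `snps` is given.
#' @param snps optional explicit SNP ids (in order).
#' @param policy `"exclude"` or `"het_as_missing"`.
#' @param max_missing maximum fraction of `N` sites tolerated per sample
#'   (default 0).
#' @return a [HaplotypeTable-class]; haplotypes are named H1, H2, ... in
#'   decreasing frequency (ties broken by string order).
#' @export
extractGeneHaplotypes <- function(x, gene = NULL, snps = NULL,
                                  policy = c("exclude", "het_as_missing"),
                                  max_missing = 0) {
  policy <- match.arg(policy)
  info <- snpInfo(x)
  if (is.null(snps)) {
    chk(!is.null(gene), "give a gene id or explicit SNP ids")
    snps <- info$snp_id[!is.na(info$gene_id) & info$gene_id == gene]
    chk(length(snps) > 0, "no SNPs recorded for gene ", gene)
  }
  chk(all(snps %in% colnames(genotypeCalls(x))),
      "SNPs absent from the matrix")
  m <- genotypeCalls(x)[, snps, drop = FALSE]
  al <- matrix("N", nrow(m), ncol(m), dimnames = dimnames(m))
  al[m == 0L] <- "A"
  al[m == 2L] <- "B"
  if (policy == "exclude") {
    keep <- rowSums(m == 0L | m == 2L) == ncol(m)
  } else {
    keep <- rowMeans(al == "N") <= max_missing
  }
  chk(any(keep), "no sample assignable under policy ", policy)
  strings <- apply(al[keep, , drop = FALSE], 1, paste, collapse = "")
  counts <- table(strings)
  ord <- order(-as.integer(counts), names(counts))
  haps <- setNames(names(counts)[ord],
                   paste0("H", seq_along(counts)))
  lookup <- setNames(names(haps), haps)
  assignment <- lookup[strings]
  names(assignment) <- names(strings)
  freqs <- as.integer(counts)[ord] / sum(counts)
  names(freqs) <- names(haps)
  new("HaplotypeTable", geneId = if (is.null(gene)) NA_character_ else gene,
      haplotypes = haps, assignment = assignment, freqs = freqs,
      n = sum(keep), snpIds = snps)
}

#' Nei haplotype diversity
#'
#' `Hd = n / (n - 1) * (1 - sum(p_i^2))` over haplotype frequencies `p_i`
#' among `n` assigned samples (the unbiased gene-diversity estimator).
#'
#' @param x a [HaplotypeTable-class], or a numeric frequency vector (then
#'   `n` must be given).
#' @param n number of samples (ignored when `x` is a table).
#' @return Hd in `[0, 1]`.
#' @examples
#' haplotypeDiversity(c(0.5, 0.25, 0.25), n = 8)  # 8/7 * (1 - 0.375)
#' @export
haplotypeDiversity <- function(x, n = NULL) {
  if (is(x, "HaplotypeTable")) {
    p <- x@freqs
    n <- x@n
  } else p <- x
  chk(!is.null(n) && n >= 2, "haplotype diversity undefined for n < 2")
  chk(abs(sum(p) - 1) < 1e-8, "frequencies must sum to 1")
  n / (n - 1) * (1 - sum(p^2))
}

## Hamming distance matrix between equal-length strings
hammingMatrix <- function(seqs) {
  chk(length(unique(nchar(seqs))) == 1, "haplotypes of unequal length")
  chars <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
  d
}

#' Minimum-spanning-network edges
#'
#' Union of all minimum spanning trees of a distance matrix: Kruskal over
#' ascending weight classes, admitting every edge of a class that links two
#' components as they stood when the class opened (so co-minimal
#' alternatives are all kept), then merging.
#'
#' @param d symmetric distance matrix.
#' @return integer matrix with columns `i`, `j`, `w` (i < j).
#' @export
msnEdges <- function(d) {
  n <- nrow(d)
  if (n < 2) return(cbind(i = integer(), j = integer(), w = integer()))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  w <- d[pairs]
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  out <- NULL
  for (lev in unique(w)) {
    cls <- which(w == lev)
    comp_before <- vapply(seq_len(n), find, 0L)
    accepted <- cls[comp_before[pairs[cls, 1]] != comp_before[pairs[cls, 2]]]
    for (e in accepted) {
      out <- rbind(out, c(pairs[e, 1], pairs[e, 2], lev))
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  colnames(out) <- c("i", "j", "w")
  out
}

## majority-consensus of three aligned strings; ties resolved toward the
## first sequence (deterministic)
tripleMedian <- function(a, b, c_) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  cc <- strsplit(c_, "")[[1]]
  out <- ca
  agree_bc <- cb == cc
  out[agree_bc] <- cb[agree_bc]
  paste(out, collapse = "")
}

#' Median-joining haplotype network
#'
#' Builds the genealogical network of a haplotype table: the
#' minimum-spanning network over observed haplotypes, augmented by inferred
#' intermediate ("median") haplotypes wherever the per-site majority
#' consensus of a connected triple shortens its spanning cost, iterated to
#' convergence (tolerance parameter fixed at 0, keeping the network
#' sparse), with unused medians pruned. Deterministic under a fixed input
#' ordering. Edge weights are mutation counts (Hamming distances); node
#' frequencies carry over from the table, medians get frequency 0.
#'
#' @param x a [HaplotypeTable-class], or a named character vector of
#'   equal-length haplotype strings (frequencies then taken as equal).
#' @param max_iter safety cap on median-addition rounds.
#' @return a [HaploNetwork-class].
#' @export
medianJoiningNetwork <- function(x, max_iter = 25) {
  if (is(x, "HaplotypeTable")) {
    seqs <- x@haplotypes
    freqs <- x@freqs
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- paste0("H", seq_along(seqs))
    freqs <- setNames(rep(1 / length(seqs), length(seqs)), names(seqs))
  }
  chk(length(seqs) >= 1, "need at least one haplotype")
  chk(length(unique(nchar(seqs))) == 1, "haplotypes of unequal length")
  is_median <- rep(FALSE, length(seqs))
  n_mv <- 0L
  for (iter in seq_len(max_iter)) {
    d <- hammingMatrix(seqs)
    ed <- msnEdges(d)
    adj <- matrix(FALSE, length(seqs), length(seqs))
    adj[ed[, c("i", "j"), drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    new_seqs <- character()
    nn <- length(seqs)
    for (v in seq_len(nn)) {
      nb <- which(adj[v, ])
      nb <- nb[nb != v]
      if (length(nb) < 2) next
      cmb <- utils::combn(nb, 2)
      for (k in seq_len(ncol(cmb))) {
        u <- cmb[1, k]; w <- cmb[2, k]
        m <- tripleMedian(seqs[v], seqs[u], seqs[w])
        if (m %in% seqs || m %in% new_seqs) next
        span_now <- sum(sort(c(d[u, v], d[v, w], d[u, w]))[1:2])
        dm <- c(sum(strsplit(m, "")[[1]] != strsplit(seqs[u], "")[[1]]),
                sum(strsplit(m, "")[[1]] != strsplit(seqs[v], "")[[1]]),
                sum(strsplit(m, "")[[1]] != strsplit(seqs[w], "")[[1]]))
        if (sum(dm) < span_now) new_seqs <- c(new_seqs, m)
      }
    }
    if (!length(new_seqs)) break
    new_seqs <- unique(new_seqs)
    names(new_seqs) <- paste0("MV", n_mv + seq_along(new_seqs))
    n_mv <- n_mv + length(new_seqs)
    seqs <- c(seqs, new_seqs)
    is_median <- c(is_median, rep(TRUE, length(new_seqs)))
  }
  ## final network + pruning of dead-end medians
  repeat {
    d <- hammingMatrix(seqs)
    ed <- msnEdges(d)
    deg <- tabulate(c(ed[, "i"], ed[, "j"]), nbins = length(seqs))
    drop <- which(is_median & deg <= 1)
    if (!length(drop)) break
    seqs <- seqs[-drop]
    is_median <- is_median[-drop]
  }
  nodes <- data.frame(name = names(seqs), seq = unname(seqs),
                      freq = ifelse(is_median, 0,
                                    freqs[names(seqs)]),
                      median = is_median, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    d = if (nrow(ed)) data.frame(from = names(seqs)[ed[, "i"]],
                                 to = names(seqs)[ed[, "j"]],
                                 weight = ed[, "w"]) else
      data.frame(from = character(), to = character(), weight = numeric()),
    directed = FALSE, vertices = nodes)
  new("HaploNetwork", graph = g, nodes = nodes)
}

#' Haplotype counts under random SNP subsets
#'
#' Draws seeded random subsets of a gene's SNPs and counts the haplotypes
#' each subset resolves, to show how haplotype information saturates with
#' SNP number (the full-size subset returns the gene's total count). The
#' analysis is restricted to the samples assignable over the *full* SNP set
#' (chip haplotyping is run on fully called genes), so every subset
#' partition is a coarsening of the full partition and subset counts can
#' never exceed the full-set count.
#'
#' @param x a [GenotypeMatrix-class].
#' @param gene gene id (SNPs from `snpInfo`), or pass `snps` explicitly.
#' @param snps optional explicit SNP ids.
#' @param sizes subset sizes to draw.
#' @param replicates number of random draws per size (recycled along
#'   `sizes`).
#' @param seed RNG seed governing all draws.
#' @param policy passed to [extractGeneHaplotypes()].
#' @return data.frame: `size`, `replicate`, `n_haplotypes`.
#' @export
subsetSaturation <- function(x, gene = NULL, snps = NULL,
                             sizes, replicates = 1, seed = 42,
                             policy = "exclude") {
  if (is.null(snps)) {
    info <- snpInfo(x)
    snps <- info$snp_id[!is.na(info$gene_id) & info$gene_id == gene]
  }
  chk(all(sizes <= length(snps)),
      "subset size exceeds available SNPs (", length(snps), ")")
  replicates <- rep_len(replicates, length(sizes))
  full <- extractGeneHaplotypes(x, gene = gene, snps = snps,
                                policy = policy)
  x <- x[names(haplotypeAssignment(full)), ]
  set.seed(seed)
  out <- NULL
  for (k in seq_along(sizes)) {
    for (r in seq_len(replicates[k])) {
      sub <- if (sizes[k] == length(snps)) snps
             else sample(snps, sizes[k])
      ht <- extractGeneHaplotypes(x, gene = gene, snps = sub,
                                  policy = policy)
      out <- rbind(out, data.frame(size = sizes[k], replicate = r,
                                   n_haplotypes = length(ht@haplotypes)))
    }
  }
  out
}

#' Write haplotype table and network exports
#'
#' @param x a [HaplotypeTable-class].
#' @param file TSV path (per-sample assignment plus per-haplotype
#'   frequency block).
#' @return the path, invisibly.
#' @export
writeHaplotypeTable <- function(x, file) {
  df <- data.frame(sample = names(x@assignment),
                   haplotype = unname(x@assignment),
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @param net a [HaploNetwork-class].
#' @param graphml_file GraphML output path.
#' @param edges_file optional edge-list TSV path.
#' @rdname writeHaplotypeTable
#' @export
writeNetworkGraphML <- function(net, graphml_file, edges_file = NULL) {
  igraph::write_graph(networkGraph(net), graphml_file, format = "graphml")
  if (!is.null(edges_file)) {
    el <- igraph::as_data_frame(networkGraph(net), what = "edges")
    write.table(el, edges_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(graphml_file)
}
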