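test_that("haplotype extraction groups homozygous-complete samples", {
  m <- rbind(s1 = c(0L, 0L), s2 = c(0L, 0L), s3 = c(2L, 2L),
             s4 = c(2L, 2L))
  colnames(m) <- c("a", "b")
  ht <- extractGeneHaplotypes(genotypeMatrix(m), snps = c("a", "b"))
  expect_length(haplotypes(ht), 2)
  expect_equal(unname(haplotypeFreqs(ht)), c(0.5, 0.5))
  expect_identical(ht@n, 4L)

  # NoCall drops the sample under the default policy
  m["s4", 1] <- -1L
  ht2 <- extractGeneHaplotypes(genotypeMatrix(m), snps = c("a", "b"))
  expect_identical(ht2@n, 3L)
  expect_false("s4" %in% names(haplotypeAssignment(ht2)))

  # heterozygous calls drop the sample too
  m["s3", 1] <- 1L
  ht3 <- extractGeneHaplotypes(genotypeMatrix(m), snps = c("a", "b"))
  expect_identical(ht3@n, 2L)

  all_bad <- genotypeMatrix(matrix(1L, 2, 2,
                                   dimnames = list(c("x", "y"),
                                                   c("a", "b"))))
  expect_error(extractGeneHaplotypes(all_bad, snps = c("a", "b")),
               "no sample assignable")
})

test_that("haplotype partition equals the string-grouping oracle", {
  set.seed(61)
  for (k in 1:50) {
    gm <- randomGenotype(20, 6, miss = 0.05, het = 0.15)
    snps <- colnames(genotypeCalls(gm))
    oracle <- haplotypeOracle(gm, snps)
    if (!length(oracle)) next
    ht <- extractGeneHaplotypes(gm, snps = snps)
    expect_identical(length(haplotypes(ht)), length(oracle))
    got <- split(names(haplotypeAssignment(ht)),
                 unname(haplotypeAssignment(ht)))
    expect_setequal(unname(lapply(got, sort)), unname(lapply(oracle, sort)))
  }
})

test_that("Nei haplotype diversity matches closed forms", {
  expect_equal(haplotypeDiversity(c(1), n = 10), 0)
  expect_equal(haplotypeDiversity(c(0.5, 0.5), n = 2), 1.0)
  expect_equal(haplotypeDiversity(c(0.5, 0.25, 0.25), n = 8),
               8 / 7 * (1 - 0.375))
  expect_equal(haplotypeDiversity(c(0.5, 0.25, 0.25), n = 8),
               0.714286, tolerance = 1e-5)
  expect_error(haplotypeDiversity(c(1), n = 1), "n < 2")

  # relabelling invariance; equal frequencies maximise Hd
  set.seed(62)
  for (k in 1:20) {
    cnt <- as.numeric(table(sample(5, 30, replace = TRUE)))
    p <- cnt / sum(cnt)
    expect_equal(haplotypeDiversity(p, n = 30),
                 haplotypeDiversity(sample(p), n = 30))
    even <- rep(1 / length(p), length(p))
    expect_lte(haplotypeDiversity(p, n = 30),
               haplotypeDiversity(even, n = 30) + 1e-12)
  }
})

test_that("median-joining network: elementary cases", {
  one <- medianJoiningNetwork(c(H1 = "AAAA"))
  expect_identical(nrow(networkNodes(one)), 1L)

  pair <- medianJoiningNetwork(c(H1 = "AAAA", H2 = "AABA"))
  g <- networkGraph(pair)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1)
  expect_false(any(networkNodes(pair)$median))

  # three haplotypes pairwise distance 2 around an unobserved centre
  tri <- medianJoiningNetwork(c(H1 = "BAA", H2 = "ABA", H3 = "AAB"))
  nodes <- networkNodes(tri)
  expect_identical(sum(nodes$median), 1L)
  expect_identical(nodes$seq[nodes$median], "AAA")
  gt <- networkGraph(tri)
  expect_equal(igraph::ecount(gt), 3)
  expect_true(all(igraph::E(gt)$weight == 1))

  # collinear haplotypes need no median
  line <- medianJoiningNetwork(c(H1 = "AA", H2 = "AB", H3 = "BB"))
  expect_false(any(networkNodes(line)$median))
  expect_equal(igraph::ecount(networkGraph(line)), 2)

  expect_error(medianJoiningNetwork(c(H1 = "AA", H2 = "A")), "unequal")
})

test_that("network contains an MST, respects Hamming geometry, and only
          adds nodes", {
  set.seed(63)
  for (k in 1:25) {
    L <- sample(5:9, 1)
    n <- sample(3:8, 1)
    haps <- unique(vapply(seq_len(n), function(i)
      paste(sample(c("A", "B"), L, replace = TRUE), collapse = ""), ""))
    names(haps) <- paste0("H", seq_along(haps))
    net <- medianJoiningNetwork(haps)
    nodes <- networkNodes(net)
    g <- networkGraph(net)

    # medians only add nodes; observed haplotypes all present
    expect_gte(nrow(nodes), length(haps))
    expect_true(all(haps %in% nodes$seq))
    expect_true(igraph::is_connected(g))

    # edge weights equal Hamming distances of their endpoints
    el <- igraph::as_data_frame(g, what = "edges")
    seqs <- setNames(nodes$seq, nodes$name)
    hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(el$weight,
                 mapply(function(a, b) hd(seqs[[a]], seqs[[b]]),
                        el$from, el$to), ignore_attr = TRUE)

    # an MST over the final node set is a subgraph of the network
    # (independent oracle: igraph's MST on the complete Hamming graph)
    nn <- nrow(nodes)
    dm <- matrix(0, nn, nn)
    for (i in seq_len(nn - 1)) for (j in (i + 1):nn)
      dm[i, j] <- dm[j, i] <- hd(nodes$seq[i], nodes$seq[j])
    cg <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                              weighted = TRUE)
    mst <- igraph::mst(cg, algorithm = "prim")
    mel <- igraph::as_edgelist(mst)
    in_net <- apply(mel, 1, function(e)
      igraph::are_adjacent(g, nodes$name[as.integer(e[1])],
                           nodes$name[as.integer(e[2])]))
    expect_true(all(in_net))

    # MST minimax property: any two observed haplotypes are connected
    # using only edges no heavier than their direct Hamming distance
    for (i in seq_along(haps)) for (j in seq_along(haps)) {
      if (i >= j) next
      t <- hd(haps[[i]], haps[[j]])
      sub <- igraph::subgraph_from_edges(
        g, igraph::E(g)[igraph::E(g)$weight <= t],
        delete.vertices = FALSE)
      comp <- igraph::components(sub)$membership
      expect_identical(unname(comp[names(haps)[i]]),
                       unname(comp[names(haps)[j]]))
    }
  }
})

test_that("subset saturation: bounds, monotone expectation, full-set
          equality", {
  # low het/no-call so enough samples stay assignable at 40 SNPs
  pop <- simulatePopulation(n_snps = 200, het_rate = 0.02,
                            nocall_rate = 0.01, seed = 64)
  gm <- pop$matrix
  info <- snpInfo(gm)
  info$gene_id <- rep("geneX", nrow(info))
  gm <- genotypeMatrix(genotypeCalls(gm), info)
  snps <- info$snp_id[1:40]

  full <- extractGeneHaplotypes(gm, snps = snps)
  sat <- subsetSaturation(gm, snps = snps, sizes = c(5, 10, 20, 40),
                          replicates = c(3, 3, 3, 1), seed = 65)
  expect_identical(sat$n_haplotypes[sat$size == 40],
                   length(haplotypes(full)))
  expect_true(all(sat$n_haplotypes <= length(haplotypes(full))))

  single <- subsetSaturation(gm, snps = snps, sizes = 1, replicates = 5,
                             seed = 66)
  expect_true(all(single$n_haplotypes <= 2))

  expect_error(subsetSaturation(gm, snps = snps, sizes = 41, seed = 1),
               "exceeds")

  # counts rise (weakly) with subset size in the mean over replicates
  means <- tapply(sat$n_haplotypes, sat$size, mean)
  expect_true(all(diff(means[order(as.integer(names(means)))]) >= 0))
})

test_that("haplotype table and network exports are readable", {
  m <- rbind(s1 = c(0L, 0L, 0L), s2 = c(0L, 2L, 0L), s3 = c(2L, 2L, 2L),
             s4 = c(0L, 0L, 0L))
  colnames(m) <- paste0("v", 1:3)
  ht <- extractGeneHaplotypes(genotypeMatrix(m), snps = colnames(m))
  tf <- tempfile(fileext = ".tsv")
  writeHaplotypeTable(ht, tf)
  tab <- read.table(tf, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_identical(nrow(tab), 4L)
  expect_identical(sort(unique(tab$haplotype)),
                   sort(names(haplotypes(ht))))

  net <- medianJoiningNetwork(ht)
  gml <- tempfile(fileext = ".graphml")
  elf <- tempfile(fileext = ".tsv")
  writeNetworkGraphML(net, gml, elf)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::vcount(g2),
                   igraph::vcount(networkGraph(net)))
  expect_identical(nrow(read.table(elf, header = TRUE, sep = "\t")),
                   as.integer(igraph::ecount(networkGraph(net))))
})
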