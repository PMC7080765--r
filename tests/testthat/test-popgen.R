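test_that("full-call-rate SNP selection equals a brute-force scan", {
  gm <- toyGenotype()
  expect_identical(selectFullCallrateSnps(gm), paste0("snp", 1:4))

  set.seed(51)
  for (k in 1:20) {
    gm <- randomGenotype(15, 40, miss = 0.1)
    m <- genotypeCalls(gm)
    oracle <- colnames(m)[apply(m, 2, function(col) all(col != -1L))]
    expect_identical(selectFullCallrateSnps(gm), oracle)
  }
  nomiss <- randomGenotype(5, 10, miss = 0)
  expect_length(selectFullCallrateSnps(nomiss), 10)
})

test_that("IBS distance implements allele-sharing arithmetic", {
  m <- rbind(a = rep(0L, 10), b = rep(0L, 10), c = rep(2L, 10),
             d = rep(1L, 10))
  colnames(m) <- paste0("p", 1:10)
  d <- ibsDistance(genotypeMatrix(m))
  expect_equal(d["a", "b"], 0)      # identical
  expect_equal(d["a", "c"], 1)      # opposite homozygotes
  expect_equal(d["a", "d"], 0.5)    # AA vs AB shares half
  expect_equal(d["d", "d"], 0)
  expect_equal(d, t(d))

  # pair with zero overlap errors with the pair named
  m2 <- rbind(x = c(0L, -1L), y = c(-1L, 2L), z = c(0L, 2L))
  colnames(m2) <- c("p1", "p2")
  expect_error(ibsDistance(genotypeMatrix(m2)), "x and y")

  # missing calls drop out of the denominator pairwise
  m3 <- rbind(u = c(0L, 2L, -1L, 0L), v = c(0L, 0L, 2L, -1L))
  colnames(m3) <- paste0("p", 1:4)
  d3 <- ibsDistance(genotypeMatrix(m3))
  expect_equal(d3["u", "v"], 0.5)   # one match, one mismatch counted
})

test_that("neighbor joining solves the three-point formulas at n = 3", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  ed <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(ed[["A"]], (5 + 9 - 10) / 2)
  expect_equal(ed[["B"]], (5 + 10 - 9) / 2)
  expect_equal(ed[["C"]], (9 + 10 - 5) / 2)
})

test_that("neighbor joining recovers random additive trees exactly", {
  set.seed(52)
  for (k in 1:30) {
    n <- sample(4:8, 1)
    t0 <- ape::rtree(n)
    t0$edge.length <- runif(nrow(t0$edge), 0.1, 1)
    D <- ape::cophenetic.phylo(t0)
    tr <- neighborJoining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(t0), tr)), 0)
    # path distances on the NJ tree reproduce the input matrix
    back <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(back - D)), 1e-8)
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(53)
  gm <- randomGenotype(12, 200, miss = 0)
  D <- ibsDistance(gm)
  mine <- neighborJoining(D)
  theirs <- ape::nj(as.dist(D))
  expect_equal(as.numeric(ape::dist.topo(mine, theirs)), 0)
  expect_error(neighborJoining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("equidistant taxa give a star with zero internal branches", {
  d <- matrix(1, 5, 5) - diag(5)
  dimnames(d) <- list(letters[1:5], letters[1:5])
  tr <- neighborJoining(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
})

test_that("unlinked subset: three per chromosome at the MAF gate", {
  pop <- simulatePopulation(seed = 54)
  sub <- selectUnlinkedSubset(pop$matrix)
  expect_length(sub, 33)            # 3 x 11 chromosomes
  expect_true(all(minorAlleleFrequency(pop$matrix, sub) >= 0.30))
  info <- snpInfo(pop$matrix)
  expect_identical(as.integer(table(info$chrom[match(sub, info$snp_id)])),
                   rep(3L, 11))

  # a chromosome whose only qualifying SNP is picked once, not thrice
  m <- matrix(rep(c(0L, 0L, 2L, 2L, 1L), 4), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("q", 1:4)))
  m[, 2] <- c(0L, 0L, 0L, 0L, 2L)   # MAF 0.2: disqualified
  m[, 3] <- 0L                      # monomorphic: disqualified
  m[, 4] <- 0L
  gm <- genotypeMatrix(m, data.frame(snp_id = paste0("q", 1:4),
                                     chrom = "chr1",
                                     pos = c(10L, 20L, 30L, 40L),
                                     gene_id = NA))
  expect_identical(selectUnlinkedSubset(gm), "q1")

  m[, 1] <- 0L
  gm0 <- genotypeMatrix(m, snpInfo(gm))
  expect_warning(got <- selectUnlinkedSubset(gm0), "no SNP with MAF")
  expect_length(got, 0)
})

test_that("NJ tree bipartitions simulated subpopulations at the documented
          divergence", {
  pop <- simulatePopulation(seed = 55)
  gm <- pop$matrix
  full <- selectFullCallrateSnps(gm)
  expect_gt(length(full), 100)
  tr <- neighborJoining(ibsDistance(gm, full))
  pure <- with(pop$labels, setNames(subpop, sample))[!pop$labels$admixed]
  expect_gte(treeBipartitionAccuracy(tr, pure), 0.95)

  # divergence 0: no bipartition should separate the labels cleanly
  null_pop <- simulatePopulation(fst = 1e-6, seed = 56)
  tr0 <- neighborJoining(ibsDistance(null_pop$matrix))
  pure0 <- with(null_pop$labels,
                setNames(subpop, sample))[!null_pop$labels$admixed]
  expect_lt(treeBipartitionAccuracy(tr0, pure0), 0.9)
})

test_that("STRUCTURE export writes the two-row -9-coded layout", {
  m <- matrix(c(0L, 1L, 2L, -1L), 2, 2, byrow = TRUE,
              dimnames = list(c("ind1", "ind2"), c("s1", "s2")))
  f <- tempfile()
  exportStructure(genotypeMatrix(m), f)
  expect_identical(readLines(f),
                   c("s1 s2",
                     "ind1 1 1", "ind1 1 2",
                     "ind2 2 -9", "ind2 2 -9"))
})

test_that("PLINK ped/map round-trips losslessly", {
  set.seed(57)
  gm <- randomGenotype(8, 12, miss = 0.1, het = 0.2)
  info <- snpInfo(gm)
  info$chrom <- rep(c("chr1", "chr2"), each = 6)
  info$pos <- rep(1:6 * 100L, 2)
  gm <- genotypeMatrix(genotypeCalls(gm), info)
  pre <- file.path(tempdir(), "rt")
  exportPlink(gm, pre)
  back <- importPlink(pre)
  expect_identical(genotypeCalls(back), genotypeCalls(gm))
  expect_identical(snpInfo(back)$chrom, snpInfo(gm)$chrom)
  expect_identical(snpInfo(back)$pos, snpInfo(gm)$pos)
  # missing calls encode as "0 0"
  ped <- readLines(paste0(pre, ".ped"))
  any_missing <- any(genotypeCalls(gm) == -1L)
  expect_identical(any(grepl(" 0 0", ped)), any_missing)
})
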