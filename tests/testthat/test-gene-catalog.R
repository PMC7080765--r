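test_that("single-copy rule: self-only or best non-self bitscore < 200", {
  self_only <- data.frame(query_id = "g1", subject_id = "g1", bitscore = 3000)
  expect_true(classifySingleCopy(self_only))

  at199 <- data.frame(query_id = "g1", subject_id = c("g1", "g2"),
                      bitscore = c(3000, 199))
  at200 <- data.frame(query_id = "g1", subject_id = c("g1", "g2"),
                      bitscore = c(3000, 200))
  expect_true(classifySingleCopy(at199))
  expect_false(classifySingleCopy(at200))

  no_self <- data.frame(query_id = "g1", subject_id = "g2", bitscore = 50)
  expect_error(classifySingleCopy(no_self), "self-match")
})

test_that("single-copy call agrees with a brute-force re-scan and is order
          invariant", {
  set.seed(42)
  for (k in 1:1000) {
    h <- randomHitTable("gene")
    oracle <- all(h$bitscore[h$subject_id != "gene"] < 200)
    expect_identical(classifySingleCopy(h), oracle)
    expect_identical(classifySingleCopy(h[sample(nrow(h)), , drop = FALSE]),
                     oracle)
  }
})

test_that("cross-species split: SCP / CSCSP / UNCLASSIFIED", {
  none <- data.frame(query_id = character(), subject_id = character(),
                     bitscore = numeric(), species = character())
  expect_identical(classifyCrossSpecies("g", none), "SCP")

  soy <- data.frame(query_id = "g", subject_id = "gm1", bitscore = 500,
                    species = "glycine")
  expect_identical(classifyCrossSpecies("g", soy), "CSCSP")

  cicer <- data.frame(query_id = "g", subject_id = "ca1", bitscore = 500,
                      species = "cicer")
  expect_identical(classifyCrossSpecies("g", cicer), "UNCLASSIFIED")

  # below the significance cutoff, hits do not count
  weak <- data.frame(query_id = "g", subject_id = "gm1", bitscore = 99.9,
                     species = "glycine")
  expect_identical(classifyCrossSpecies("g", weak), "SCP")
  weak$bitscore <- 100
  expect_identical(classifyCrossSpecies("g", weak), "CSCSP")
})

test_that("agronomic-gene matching includes the >= 100 boundary", {
  hits <- data.frame(query_id = c("q1", "q1", "q2"),
                     subject_id = c("gA", "gB", "gC"),
                     bitscore = c(100, 99.9, 250))
  expect_identical(matchAgronomicGenes(hits), c("gA", "gC"))
  empty <- hits[0, ]
  expect_identical(matchAgronomicGenes(empty), character())

  set.seed(7)
  for (k in 1:200) {
    h <- data.frame(query_id = "q",
                    subject_id = sprintf("g%02d", sample(50, 10)),
                    bitscore = runif(10, 0, 300))
    expect_identical(matchAgronomicGenes(h),
                     sort(unique(h$subject_id[h$bitscore >= 100])))
  }
})

test_that("category assignment partitions the gene set with the stated
          precedence", {
  genes <- sprintf("g%02d", 1:10)
  self_hits <- do.call(rbind, lapply(genes, function(g)
    data.frame(query_id = g, subject_id = g, bitscore = 2000)))
  # g1 gets a strong paralog -> not single copy
  self_hits <- rbind(self_hits,
                     data.frame(query_id = "g01", subject_id = "g02",
                                bitscore = 900))
  cross <- data.frame(query_id = c("g03", "g04"),
                      subject_id = c("x", "y"), bitscore = c(400, 400),
                      species = c("glycine", "medicago"))
  agro <- data.frame(query_id = "q", subject_id = c("g05", "g06"),
                     bitscore = c(150, 150))
  cat <- classifyGenes(genes, self_hits, cross, agro,
                       drdrp_ids = c("g06", "g07"), mcp_ids = c("g07", "g08"))
  expect_identical(unname(cat[c("g01", "g02", "g03", "g04")]),
                   c("UNCLASSIFIED", "SCP", "CSCSP", "UNCLASSIFIED"))
  # precedence AGCP > DRDRP > MCP
  expect_identical(unname(cat[c("g05", "g06", "g07", "g08")]),
                   c("AGCP", "AGCP", "DRDRP", "MCP"))
  expect_length(cat, length(genes))
  expect_true(all(cat %in% c("SCP", "CSCSP", "AGCP", "DRDRP", "MCP",
                             "UNCLASSIFIED")))
  ov <- attr(cat, "overlaps")
  expect_true(all(c("g06", "g07") %in% ov$gene_id))
})

test_that("flank extraction: coordinates, strand symmetry, truncation", {
  tg <- toyGenomeModels()
  catalog <- toyCatalog()
  info <- catalogInfo(catalog)

  # plus-strand gene 1001-2000 with 500/100 flanks -> genomic 501-2100
  i <- which(info$gene_id == "gPlus")
  expect_identical(info$ext_start[i], 501L)
  expect_identical(info$ext_end[i], 2100L)
  expect_identical(info$length_bp[i], 1600L)
  expect_identical(as.character(catalogSequences(catalog)[["gPlus"]]),
                   substr(as.character(tg$genome[["ctg1"]]), 501, 2100))

  # minus-strand extraction equals revcomp of the plus extraction with
  # flanks swapped: genomic window [801-100, 1800+500]
  j <- which(info$gene_id == "gMinus")
  expect_identical(info$ext_start[j], 701L)
  expect_identical(info$ext_end[j], 2300L)
  fwd <- Biostrings::subseq(tg$genome[["ctg2"]], 701, 2300)
  expect_identical(as.character(catalogSequences(catalog)[["gMinus"]]),
                   as.character(Biostrings::reverseComplement(fwd)))

  # gene starting at position 200: upstream flank truncated to 199 bp
  near_edge <- list(info = data.frame(gene_id = "gEdge", chrom = "ctg1",
                                      strand = "+", start = 200L,
                                      end = 400L, stringsAsFactors = FALSE),
                    exons = list(gEdge = cbind(start = 200L, end = 400L)))
  ce <- buildReferenceCatalog(near_edge, tg$genome,
                              c(gEdge = "SCP"))
  ei <- catalogInfo(ce)
  expect_identical(ei$up_trunc, 301L)      # 500 requested, 199 available
  expect_identical(ei$length_bp, 199L + 201L + 100L)

  bad <- list(info = data.frame(gene_id = "gBad", chrom = "ctg1",
                                strand = "+", start = 2900L, end = 3200L,
                                stringsAsFactors = FALSE),
              exons = list(gBad = cbind(start = 2900L, end = 3200L)))
  expect_error(buildReferenceCatalog(bad, tg$genome), "gBad")
})

test_that("extraction then lift-back is the identity on exon sequences", {
  tg <- toyGenomeModels()
  catalog <- toyCatalog()
  for (g in c("gPlus", "gMinus")) {
    ex <- catalogExons(catalog)[[g]]
    seq_ext <- as.character(catalogSequences(catalog)[[g]])
    gex <- toyGenomeModels()$exons[[g]]
    strand <- catalogInfo(catalog)$strand[
      catalogInfo(catalog)$gene_id == g]
    for (k in seq_len(nrow(ex))) {
      from_ext <- substr(seq_ext, ex[k, 1], ex[k, 2])
      gpos <- extractedToGenomic(catalog, g, ex[k, 1]:ex[k, 2])
      chrom <- catalogInfo(catalog)$chrom[
        catalogInfo(catalog)$gene_id == g]
      genomic <- strsplit(as.character(tg$genome[[chrom]]), "")[[1]][gpos]
      # gpos is already ordered along the gene; minus strand needs only
      # the base complement
      if (strand == "-") genomic <- chartr("ACGT", "TGCA", genomic)
      expect_identical(from_ext, paste(genomic, collapse = ""))
    }
  }
})

test_that("similarity-hit reader keeps the 12-column layout straight", {
  f <- tempfile()
  writeLines(c("g1\tg1\t100.0\t500\t0\t0\t1\t500\t1\t500\t0.0\t923",
               "g1\tg2\t88.5\t300\t30\t2\t1\t300\t10\t310\t1e-50\t199"),
             f)
  h <- readSimilarityHits(f, species = "self-db")
  expect_identical(h$query_id, c("g1", "g1"))
  expect_identical(h$bitscore, c(923, 199))
  expect_true(classifySingleCopy(h))
})
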