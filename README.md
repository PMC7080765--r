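# chipsmith

Design pipeline and downstream analyses for **genic SNP genotyping
arrays**, written for geneticists and breeders working on predominantly
selfing crop species (the motivating case is a pigeonpea 62K genic chip,
but nothing in the code is species-specific).

Genic arrays are built from a categorised reference gene set rather than
from genome-wide intergenic markers, which is what makes per-gene
haplotype analysis possible downstream. chipsmith covers both sides of
that workflow:

**Design**

* Gene categorisation from similarity-hit tables:
  single-copy test (best non-self bitscore < 200), cross-species split
  into lineage-specific (SCP) vs soybean-conserved (CSCSP) single-copy
  genes, curated agronomic-gene homologs at bitscore ≥ 100 (AGCP), and
  curated disease-resistance (DRDRP) and multi-copy control (MCP) lists,
  with precedence AGCP > DRDRP > MCP.
* Flanked reference extraction (gene span + 500 bp upstream / 100 bp
  downstream, strand-aware) from FASTA + GFF3.
* Variant-site filtering on pileup summaries (depth ≥ 10, alt reads ≥ 2,
  mean base quality ≥ 25, alt fraction ≥ 0.05) and geometric
  exon / intron / 5′ / 3′ feature annotation.
* Axiom-style probe candidates: interfering-SNP exclusion (no second SNP
  within 10 bp), 72-bp plex with the SNP at base 36 in `[A/G]` bracket
  notation, and a documented surrogate designability score with the
  production `> 0.50` gate, plus a per-stage attrition report.

**Analysis**

* Chip genotype QC: call rates (0.955 gate on both axes),
  heterozygosity, duplicate concordance, minor allele frequency.
* RIL segregation filter: parent-orientation, residual-het masking, and
  the two-class chi-square test against 1:1,
  `χ² = (n_AA − n_BB)² / (n_AA + n_BB)`, keep iff p ≥ 0.05.
* Identity-by-state distances and Saitou–Nei neighbor joining with
  deterministic tie-breaks (Newick via `ape`), unlinked-SNP subset
  selection (3 per chromosome, MAF ≥ 0.3), STRUCTURE and PLINK export.
* Per-gene haplotypes with Nei diversity
  `Hd = n/(n−1)(1 − Σ pᵢ²)`, median-joining haplotype networks
  (ε = 0, GraphML export), and SNP-subset saturation curves.
* Seeded synthetic-fixture generators (genome + GFF3, variant sites at
  published per-category densities, a structured 95-sample panel with
  ~9.8 % heterozygosity, an F8 RIL matrix) so the entire pipeline runs
  and is tested offline.

See `vignettes/chipsmith-methods.Rmd` for the methods, conventions and
design decisions in detail.

## Worked example

```r
library(chipsmith)

## a small synthetic reference set: 20 genes across the five categories
sim     <- simulateGenomeAndCatalog(seed = 42)
catalog <- buildReferenceCatalog(sim$models, sim$genome, sim$categories)
catalog
#> GeneCatalog with 20 genes
#>   categories: SCP:6  CSCSP:6  AGCP:3  DRDRP:3  MCP:2
#>   total extracted length: 49795 bp

## candidate sites -> filtered SNP records -> probe design funnel
sites <- simulateSnpSites(catalog, seed = 43)
kept  <- filterSites(sites)          # 988 of 1215 sites pass
rec   <- snpRecords(kept, catalog)
design <- designPipeline(catalog, rec)
design$attrition
#>            identified interference_filtered        plex_extracted
#>                   988                   496                   482
#>           recommended
#>                   460

summarizeCatalog(rec, catalog)$categories[
  , c("category", "n_genes", "n_snps", "snp_density_per_kbp")]
#>   category n_genes n_snps snp_density_per_kbp
#> 1      SCP       6    236               29.91
#> 2    CSCSP       6    103                5.06
#> ...
#> 6    Total      20    988               19.84
```

The attrition line is the design funnel: 988 filtered SNPs, 496 left
after removing pairs closer than 10 bp, 482 with room for the 72-bp
plex, 460 scoring above the 0.50 designability gate. The density column
recovers the planted per-category SNP densities (high for multi-copy
genes, lowest for conserved single-copy genes).

```r
## diversity analysis on a simulated two-subpopulation panel
pop  <- simulatePopulation(seed = 44)            # 95 samples, 1000 SNPs
tree <- neighborJoining(ibsDistance(pop$matrix,
                                    selectFullCallrateSnps(pop$matrix)))
pure <- with(pop$labels, setNames(subpop, sample))[!pop$labels$admixed]
treeBipartitionAccuracy(tree, pure)
#> [1] 1                      # the NJ tree splits the two subpopulations
length(selectUnlinkedSubset(pop$matrix))
#> [1] 33                     # 3 unlinked SNPs x 11 chromosomes

## RIL segregation-distortion filter under fair 1:1 segregation
ril <- simulateRil(seed = 45)
res <- rilMarkerFilter(ril$matrix, ril$parents)
length(res$kept)
#> [1] 939                    # ~6% rejected, near the nominal 5% level
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "chipsmith.R", package = "chipsmith")`, with
subcommands `classify`, `snps`, `design`, `qc`, `tree`, `subset`,
`haplo` and `simulate`.

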