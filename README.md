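# gc3sig

Wobble-position GC composition, genome signatures and GC3 gene classes for
coding sequences.

## The problem

The third ("wobble") position of a codon tolerates most synonymous change,
so its per-gene G+C fraction — **GC3** — is a sensitive readout of the
forces shaping sequence composition. In grasses and warm-blooded
vertebrates the gene-level GC3 distribution is bimodal, and the two gene
classes separated by the inter-peak valley (operating point GC3 ≥ 0.8 in
rice) differ systematically: high-GC3 genes carry more methylatable CG
dinucleotides, show more variable expression, carry upstream TATA boxes
more often, have fewer introns and shorter ORFs, accumulate SNPs faster,
and show a 5′→3′ composition gradient with a positive CG3 skew
(C3 − G3)/(C3 + G3).

`gc3sig` is for computational biologists who want to reproduce this style
of analysis on any CDS collection: it computes the per-gene statistics,
assigns classes, and runs the covariate battery. Its core quantities, in
the field's notation:

- **Composition**: GC1, GC2, GC3, GC12, CG3 skew, and the overlapping
  dinucleotide ratio f(CG)/f(GC).
- **Genome signatures**: ρ<sub>XY</sub> = f(XY)/(f(X)·f(Y)) for all 16
  dinucleotides; ρ<sub>CWG</sub> = f(CWG)/(f(C)·f(W)·f(G)) with W ∈ {A,T};
  position-specific ρ<sub>C2G3</sub> (within codon) and ρ<sub>C3G1</sub>
  (across the codon boundary); conditional preference ratios
  P(G3|C2)/P(C3|C2) and P(C3|G1)/P(G3|G1).
- **Classification**: boundary-reflected kernel density of GC3 on [0,1],
  valley thresholding between the two main modes, adjacent-gene
  correlation, clump detection, flanking-GC association.
- **Associations**: z-scored equal-count binned regression of expression
  SD on GC3; SNP/kb vs GC3; intron-density Pearson correlation; TATA-box
  frequency curves; P(high class | covariate) with chi-squared tests;
  per-category GC3/GC12 profiles; centred PCA of within-amino-acid codon
  usage.

Because the original gene sets, promoter and expression databases are not
bundled, the package ships a seeded synthetic-data generator
(`simulate_dataset()`) that plants all of these effects with known
parameters; every estimator is validated by recovering them.

## Worked example

```r
library(gc3sig)

cfg <- synthetic_config(n_genes = 5000, seed = 42)
sim <- simulate_dataset(cfg)                      # in-memory dataset
res <- run_pipeline(sim, analyses = "pca")        # composition -> classes -> associations -> PCA

res$classes
#> <class_assignment> threshold = 0.7769 (valley): 3547 low, 1453 high
```

The recovered quantities sit on the planted values:

```
planted valley: 0.772   recovered: 0.777
expression-SD slope (planted 0.228): 0.201
SNP/kb line (planted 1.114 + 0.583 GC3): 1.108 + 0.589 GC3
intron-density Pearson (planted -0.30): -0.293
TATA+ fraction, GC3 < 0.45 vs > 0.95: 0.15 / 0.48
adjacent-gene GC3 correlation (null layout): 0.022
PC1: 48% of codon-usage variance, |cor(PC1, GC3)| = 0.995
```

Reading: the density valley splits the 5,000 genes into 3,547 low- and
1,453 high-GC3 genes at GC3 ≈ 0.78, within 0.005 of the generative
mixture's true valley. The binned regression of z-scored expression SD on
z-scored GC3 recovers the planted slope (the small shortfall is SD
estimation noise across the 106 simulated conditions), the SNP line and
intron correlation come back on target, TATA frequency rises across GC3
as planted, genes placed in random genomic order show no adjacent-gene
GC3 correlation, and the first principal component of codon usage is GC3
itself.

Real data enter through the same path:

```r
cds <- read_cds_fasta("cds.fasta")
tab <- read_gene_table(cds, layout = "genes.gff3",
                       covariates = "covariates.tsv",
                       promoters = "promoters.fasta")
res <- run_pipeline(list(cds = cds, table = tab), out_dir = "results/")
```

`run_pipeline()` writes `composition.tsv`, `signatures.tsv`, `classes.tsv`,
`clumps.tsv`, `associations/*.tsv`, `pca/*.tsv` and a `summary.json` with
every scalar statistic; stages whose inputs are missing are skipped with a
logged reason.

See `vignettes/gc3-analysis.Rmd` for the models, parameter choices,
numerical details and the limits of what the synthetic validation shows.

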