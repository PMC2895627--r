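---
title: "Wobble-position GC analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wobble-position GC analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gc3sig)
```

## The biology and the statistics

The third position of a codon is largely free of protein-level constraint:
most synonymous substitutions happen there. The per-gene fraction of G or C
at that wobble position, GC3, is therefore a sensitive marker of
composition-shaping forces — mutation bias, GC-biased gene conversion,
methylation and transcriptional regime. In grasses (and warm-blooded
vertebrates) the gene-level GC3 distribution is *bimodal*: a broad low-GC3
class and a sharp high-GC3 class separated by a density valley near
GC3 ≈ 0.8. The two classes differ consistently in

* methylatable CG-dinucleotide density (the CG/GC ratio and the genome
  signature ρ~CG~ = f(CG)/(f(C)·f(G))),
* variability of expression across conditions,
* frequency of canonical TATA boxes within 50 nt of the TSS,
* intron density and ORF length (both negatively associated with GC3),
* SNP density (linear in GC3, a proxy for recombination), and
* 5′→3′ composition gradients, including the CG3 skew
  (C3 − G3)/(C3 + G3).

`gc3sig` computes all of these statistics per gene, assigns classes by
valley thresholding of a kernel density estimate, and summarises codon usage
by PCA, where the first component is essentially GC3 itself.

## Per-gene statistics

A validated coding sequence is split into consecutive codons; all counts use
retained codons only. The `validation_policy()` governs out-of-frame
records (`reject` by default, `trim_tail` optionally), ambiguous codons
(`drop_codon` removes any codon containing an N) and a short-gene flag
(`min_codons = 30`, chosen so that window statistics are defined; short
genes keep their composition values but are excluded from gradient profiles
and the codon-usage matrix). Stop codons are retained and counted like any
codon: third-position statistics are defined over all codons and no
exclusion rule is imposed.

Definitions, all exact ratios of integer counts:

* `gc3 = (C3 + G3) / n`, `gc12` over positions 1 and 2, `gc_total` over all
  three.
* `cg3_skew = (C3 − G3)/(C3 + G3)`. The orientation is fixed by the
  observation that the high-GC3 class prefers C at the wobble position, so
  its skew must come out positive. The skew is reported as undefined (`NA`)
  when no third position carries C or G — never silently zero.
* `cg_gc_ratio = f(CG)/f(GC)` over *overlapping* dinucleotides of the whole
  CDS, codon boundaries included: methylation targets do not respect the
  reading frame, so no boundary restriction is applied.

### Genome signatures

Relative abundances are odds ratios of observed to composition-expected
frequency, computed from overlapping counts on the forward strand:
ρ~XY~ = f(XY)/(f(X)f(Y)), and for the plant methylation context CWG
(W ∈ {A, T}), ρ~CWG~ = f(CWG)/(f(C)·f(W)·f(G)) with
f(CWG) = f(CAG) + f(CTG). A homopolymer's sole dinucleotide has ρ = 1
exactly, and on i.i.d. sequences every ρ tends to 1 — both properties are
enforced in the test suite. Because the observed/expected CG ratio
understates CpG depletion in GC-rich sequences, a GC correction can be
divided out; the correction function is pluggable (`gc_corrected_rho_cg()`),
defaults to the identity, and the output is explicitly flagged uncorrected
in that case rather than silently guessing a functional form.

Position-specific variants isolate where CG dinucleotides can be created
silently: ρ~C2G3~ within a codon (positions 2–3) and ρ~C3G1~ across the
codon boundary (position 3 to the next codon's position 1); the conditional
preference ratios P(G3|C2)/P(C3|C2) and P(C3|G1)/P(G3|G1) ask the same
question as odds among the eligible codons. Degenerate cases are flagged
symbolically (`NA` for 0/0 or an absent conditioning event, `Inf` for x/0)
so that downstream histograms can exclude them explicitly.

Pooling across genes is defined as concatenation in input order — the only
definition under which pooled counts and the concatenated sequence agree
exactly for overlapping k-mers.

## Class assignment

`estimate_density()` uses a Gaussian kernel on a fixed 512-point grid over
[0, 1] with *boundary reflection* at both ends (GC3 is a fraction; an
unreflected kernel leaks mass and biases the modes). Bandwidth defaults to
Silverman's rule on the raw scale. `find_valley_threshold()` keeps strict
local maxima reaching at least 5% of the primary mode's height — without
this prominence filter, kernel wiggles produce spurious valleys — and
returns the density minimum strictly between the two highest surviving
modes. Fewer than two modes is a *valid* outcome reported as unimodal, in
which case the pipeline falls back to the fixed operating point GC3 = 0.8,
the canonical grass threshold. The class boundary is inclusive to the high
side: `high ⇔ gc3 ≥ threshold`.

Spatial structure is probed three ways: the Pearson correlation of GC3
between chromosome-adjacent genes (annotation order by start coordinate,
strand ignored, pairs never spanning chromosomes); a clump scan reporting
maximal runs of high-class genes allowing up to `max_gap_genes` (default 2)
interposed low genes, with `min_size` (default 10) high genes required — the
gap parameter is exposed precisely because no canonical clump definition
exists; and the correlation of GC3 with flanking-region GC, tested by
permutation (10,000 permutations by default).

## Covariate analyses

Expression variability is the per-gene sample SD of log intensities across
conditions (at least 3 required). Both it and GC3 are converted to
z-scores ((x − μ)/σ, sample σ) before the binned fit. `binned_fit()` sorts
genes by x, cuts them into equal-count bins (≈200 genes per bin by default,
so each point has a small standard error), and fits OLS to the bin means.
The reported R² is that of the *binned* fit; per-gene R² for the same data
is far lower, and outputs say so prominently. The SNP analysis uses the
same engine on raw scales. Intron-density and length associations are plain
per-gene Pearson correlations (a binned variant is available); the length
association is intended to be computed on user-stated GC3 strata, since it
is concentrated in the mid-GC3 range.

The TATA scan matches an IUPAC motif (default `TATAWAW`; the motif is a
configuration value recorded in the output, since "canonical TATA box" is
not a unique string) on the forward strand within the 50 nt upstream of the
TSS; promoters are TSS-anchored with the 3′ end at position −1.
`frequency_by_gc3()` then reports the TATA+ fraction per equal-count GC3 bin
(700 genes per point by default). `high_class_probability()` gives
P(high | covariate bin) plus a 2×2 chi-squared test after dichotomising the
covariate at its median; Yates correction is off by default (the intended
regime is thousands of genes) and togglable.

The codon-usage matrix defaults to within-amino-acid frequencies (each
codon's share among its synonyms in that gene; Met, Trp and stops excluded,
59 columns). Amino acids absent from a gene leave an undefined block; PCA
needs a complete matrix, so those cells are imputed with the ensemble-mean
usage of the amino acid and flagged per cell. The alternative `global`
scheme (count/total, 64 columns) is available. PCA is centred and
unscaled; because the sign of a component is arbitrary, the absolute
correlation of PC1 with GC3 is reported alongside the signed value.

## The synthetic-data generator

`simulate_dataset()` realises a planted-truth dataset: CDS FASTA, promoter
FASTA, GFF3 layout, covariate TSV and a truth JSON sufficient to recompute
every planted quantity. The generator is a *test harness* that plants the
effect structure the pipeline estimates; it makes no claim to be a
generative model of any real genome.

The defaults are the validation conditions:

* GC3 mixture: 70% from a Beta component with mean 0.60, sd 0.06, 30% from
  mean 0.90, sd 0.04 (Beta components re-parameterised by mean and sd;
  Gaussians would leak outside [0, 1]). The planted valley is the density
  minimum of this mixture, ≈ 0.77.
* Proteins are drawn uniformly over the 18 amino acids with synonym choice
  (no Met/Trp beyond the forced start); for each residue a GC-ending
  synonym is chosen with probability equal to the local target (gene target
  plus a 5′→3′ ramp, default ±0.05 by class), and C-vs-G is resolved by the
  class skew (target realized plateaus +0.05 high, −0.10 low). Amino acids
  offering only a C- or only a G-ending synonym force the choice, and under
  a uniform protein those forcings split 7 C : 3 G, so the generator
  inverts the closed form (realized = (8·s + 4)/18) to find the choice-level
  skew s that lands the realized whole-gene skew on the configured target;
  eligibility is also bookkept per gene so skew tests can compare against
  achievable values. Translating every generated CDS reproduces its protein
  exactly.
* Expression: the per-gene SD follows
  z(SD) = 0.228·z(GC3) + 0.0294 + ε with ε chosen by default to complete
  the linear term to unit variance — that calibration is what makes the
  recovered binned slope equal the planted coefficient. The latent value
  maps affinely to a positive SD (centre 1.0, scale 0.3; the scale is large
  relative to the SD-estimation noise of ~106 conditions, keeping
  attenuation of the recovered slope below the test tolerance). Mean
  expression is drawn independently of GC3: the mean-expression
  relationship seen in real data is non-monotone and is deliberately not
  planted.
* Introns: Poisson counts with rate linear in z(GC3); the coefficient is
  solved in closed form so the GC3 × intron-density Pearson correlation
  hits the target (−0.3). Targets too strong to achieve under Poisson
  noise raise an error stating the bound.
* SNPs/kb: 1.114 + 0.583·GC3 plus Gaussian noise (sd 0.1), floored at 0.
* TATA: probability interpolated from 0.18 below GC3 0.45 to 0.52 above
  0.95; positive genes get the motif inserted at −35 ± 5 nt, and chance
  motifs are scrubbed from the scan window of negative promoters so the
  realised indicator equals the planted one.
* Layout: genes are placed in a random order over 12 chromosomes, making
  the adjacent-gene GC3 correlation zero by construction; `clump_spec`
  optionally plants runs of consecutive high-class genes.
* Promoter background GC (0.40) is independent of the gene's GC3, so the
  flanking-GC association is null by construction.

One global seed drives everything through deterministic per-gene
substreams, so regeneration is order-independent and a (config, seed) pair
reproduces the dataset byte for byte.

What the generator does **not** emulate: real codon-level dinucleotide
avoidance (so conditional ratios such as P(G3|C2)/P(C3|C2) reflect only the
planted skew, not biological CpG suppression), protein-composition
differences between functional categories (GC12 varies only by sampling
noise, so the across-category CV contrast is much larger than in real
data), orthology/paralogy structure, isochores, or methylation states.
Passing recovery tests therefore demonstrates estimator correctness under
the planted model, not biological realism.

## Validation design and problem sizes

The test suite validates four layers, at sizes chosen to keep the full run
comfortably interactive:

1. *Oracle equivalence*: composition and signature statistics agree with
   independent character-by-character brute-force counters on 1,000 random
   sequences — integer counts exactly, fractions to 1e−12.
2. *Parameter recovery*: 20 seeds of the default generator at 15,000 genes;
   the valley threshold must land within ±0.03 of the planted valley in at
   least 18 of 20 seeds, the expression slope within ±0.03 of 0.228, SNP
   coefficients within ±10%, the intron correlation within ±0.05, TATA
   endpoint fractions within ±0.05 (pooled across seeds, because the
   default mixture puts only a few dozen genes per run below GC3 0.45), and
   the null-layout adjacent correlation below 0.05 in absolute value.
3. *Construction properties*: codon usage driven by a single GC3 parameter
   yields |cor(PC1, GC3)| > 0.99; skew plants of ±1 force per-gene skew of
   exactly ±1 on degeneracy-unconstrained proteins; the clump finder
   matches a regex-based enumeration oracle on random label strings.
4. *Determinism*: datasets and pipeline summaries are byte-identical across
   regeneration.

`scripts/acceptance.R` reruns the study-scale pipeline from scratch for a
given `--seed` and writes every recovered headline quantity as JSON.

## Known limitations

* The GC correction for ρ~CG~ ships as an identity placeholder; a concrete
  correction curve must be supplied by the user and is recorded in output
  metadata.
* The valley threshold inherits kernel-density bias: very unequal component
  weights shift the estimated valley slightly toward the minor mode;
  the prominence filter (5%) is a heuristic with no optimality claim.
* Clump definitions are parameterised, not canonical; reported clump counts
  are only comparable under identical `min_size`/`max_gap_genes`.
* Binned-fit R² depends on the bin count as well as the underlying
  relationship; compare R² values only at matched binning.
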