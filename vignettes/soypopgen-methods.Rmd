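---
title: "Methods and design of soypopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of soypopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soypopgen)
```

soypopgen implements the population-genomic analysis workflow used for
structured crop resequencing panels — the motivating system is a soybean
mini-core collection of 198 accessions that separates into three
subgroups ("Primitive", "World", "Japan") — as a set of small, testable
components: genotype-panel I/O and filtering, subgroup diversity and
differentiation statistics in genomic windows, distance-based structure
analysis, a mixed-model association scan, codon-aware variant-effect
annotation, and structural-variant/CNV summarization.  A synthetic-data
generator with known ground truth ties the pieces together so that every
stage can be validated without any external download.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic
validation demonstrates.

## The genotype panel and site filters

All statistics operate on a `genotype_panel`: a samples x variants
matrix of alternate-allele dosages (0/1/2, `NA` for missing) plus
variant metadata and subgroup labels.  Only biallelic sites are
represented; `read_vcf()` drops multiallelic records and counts them,
because every downstream statistic (frequencies, theta, r^2, kinship)
assumes a single alternate allele.  Half-calls are treated as missing.

`filter_variants()` applies the association-side site filters with the
convention that the printed thresholds are the *edge of the retained
region*: a site is kept iff MAF >= 2.5% and missingness <= 5% (defaults).
MAF is computed from non-missing calls, so removal reasons are counted
with missingness taking precedence over MAF; the filter report then
partitions the input exactly, and filtering is idempotent.

Imputation (`impute_missing()`) is deliberately naive — per-site mean or
major-genotype replacement.  It exists to complete the dosage matrix for
kinship and association analysis only; diversity statistics always use
the unimputed panel.  LD-aware imputation is out of scope, and the
fractional dosages it produces cannot be written back to VCF.

## Synthetic data: what is emulated, and what is not

`simulate_structured_genotypes()` draws, per site, an ancestral
frequency p from `maf_law` (default Uniform(0.05, 0.95), which
guarantees polymorphism at the scale of thousands of sites) and
per-subgroup frequencies from the Balding-Nichols distribution
Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is p and variance
F p (1-p).  Frequencies are clipped to [0.001, 0.999] to avoid
degenerate Beta draws.  The default configuration mirrors the
motivating panel's shape — subgroups of 20/58/120 diploids, one
chromosome — with F = 0.1; the source study does not state its
subgroups' differentiation magnitudes, so F is a package default chosen
once to produce clearly structured but not fixed subpopulations, not a
soybean-calibrated value.

Linkage disequilibrium comes from a first-order haplotype-copying
chain: each haplotype carries a latent uniform per site which is, with
probability `rho`, copied from the previous site; alleles are the
indicator `u < p_group`.  This yields r^2 decaying geometrically with
site-index distance — enough to exercise the LD machinery — but it is
*not* a coalescent: there is no recombination map, no allele-frequency
spectrum realism, no mutation model.  Consequently, passing recovery
tests demonstrates correctness of the estimators under the stated
sampling model, not realism of soybean LD.

`simulate_phenotype()` builds the genetic value from the configured
causal sites, then adds Gaussian noise that is orthogonalized against
the genetic value in-sample and rescaled so the realized
var(g)/var(y) equals the requested h2 exactly.  The orthogonalization
removes replicate-to-replicate leakage between "genetic" and
"environmental" variance, which makes heritability-recovery tests
sharp; it also means the noise is not literally i.i.d., a deliberate
trade towards testability.

The SV generator draws per-type event counts Poisson(rate x genome
length) with log-uniform lengths (50 bp-100 kb), and the CNV generator
produces paired Poisson window counts with the test mean scaled by
copy_number/2.  `mean_depth` is a sequencing depth (x coverage); the
expected reads per window is `mean_depth * window / read_length`
(about 20,000 per 100 kb window at 30x and 150 bp reads), the count
scale on which read-depth CNV detection actually operates.
`simulate_gene_models()` writes genes whose CDS is built from sense
codons (start codon, no internal stop, length divisible by 3) with
GT..AG introns that may interrupt codons, on either strand — the
properties the annotator and its oracle need.

All generators take explicit seeds and never touch global random state
beyond `set.seed()` at entry; fixed seeds give bit-identical output.

## Windowed diversity, differentiation and LD

Windows are half-open, 0-based, of nominal width W = 500 kb, tiling
each chromosome; the final short window is retained and flagged.  Per
group, nucleotide diversity is the unbiased per-site heterozygosity
`[n/(n-1)] 2 p (1-p)` summed over sites and divided by the *nominal*
window width (resequencing convention: the denominator is genomic bp,
not callable or segregating sites).  Hence absolute pi values depend on
the variant density the panel carries; the estimator is validated
against an exhaustive allele-pair counting oracle.

F_ST uses the Weir & Cockerham (1984) theta estimator — chosen because
the source analysis only says an in-house program computed "pairwise
and total F_ST" without naming an estimator — with per-site variance
components a, b, c and ratio-of-sums aggregation over each window
(`sum(a)/sum(a+b+c)`), which is the standard way to stabilize
multi-site theta.  "Total" theta uses all groups jointly; pairwise
columns restrict the estimator to each pair.  Sites monomorphic across
the compared groups are skipped; negative windowed theta is reported
as-is rather than clamped, since truncation would bias genome-wide
averages.  Under Balding-Nichols sampling, theta is a consistent
estimator of F, which is the basis of the parameter-recovery test
(windowed theta within +/-0.02 of F = 0.1 at 3 x 50 samples and 20,000
sites).

LD r^2 is the squared Pearson correlation of *unimputed* dosage vectors
over pairwise-complete samples (the composite, unphased measure;
phasing is out of scope).  All intra-window pairs are used up to
`max_pairs` (default 10,000), beyond which pairs are subsampled with a
seeded draw (uniform random pairs, duplicates possible).  Zero-variance
members make a pair undefined and it is skipped.

Sharing classification follows the verbatim definition "observed in a
group" = alternate-allele count > 0, with no frequency floor; the
categories (private per group, shared by each pair, shared by all,
absent) are mutually exclusive and exhaustive over the panel's sites.
Per-accession private variants are sites whose alternate allele has
exactly one carrier.

## Distances, trees, ordination

Jukes-Cantor distances are computed on a genotype-mismatch proportion
over variant sites, with heterozygote weights equal to expected allele
sharing under a random draw (hom-vs-other-hom 1, het-vs-hom 0.5,
het-vs-het 0), then corrected by `d = -(3/4) log(1 - (4/3) p)`.  The
source analysis used whole-genome distances; whether invariant sites
diluted p there is unrecoverable, so the package default uses variant
sites only and exposes `n_invariant` to inflate the denominator when a
per-bp scale is wanted.

`neighbor_joining()` is the canonical O(n^3) Saitou-Nei algorithm —
trivial at panel scale (n around 200).  Two degenerate-input rules are
fixed: ties in the Q criterion break to the lexicographically lowest
original-index pair, making the output deterministic even on all-equal
distances; and a negative branch length from the two-point formulas is
truncated to zero with the deficit moved to its sibling branch, so the
joined path length is preserved.  Trees are returned as `ape` `phylo`
objects, rooted on the outgroup's pendant edge when one is given (the
motivating analysis roots on the single wild relative in the panel).
NJ correctness is tested by exact topology recovery on random additive
metrics (n = 4..8) and cross-checked against `ape::nj`.

Ordination is classical MDS (`stats::cmdscale`, the same route the
motivating analysis used) on Euclidean distances of mean-imputed,
centred dosages.  Percent variance per axis is computed over positive
eigenvalues only; requesting more axes than there are positive
eigenvalues truncates with a warning.  On Euclidean input this
reproduces principal components up to sign, which is how the GWAS
covariates (`panel_pcs()`) are obtained — from the same filtered,
imputed marker set used for the scan.

## The mixed-model association scan

The model is `y = X b + g + e` with `g ~ N(0, sigma_g^2 K)` and
`e ~ N(0, sigma_e^2 I)`; K is the VanRaden method-1 genomic
relationship matrix `Z Z' / (2 sum p(1-p))`.  Variance components are
estimated once under the null by REML — the EMMAX/P3D approximation —
and reused for every marker; at panel scale the approximation is
standard and per-marker REML buys nothing.  The 1-D REML surface over
`log10(delta)` (`delta = sigma_e^2/sigma_g^2`) is scanned on a
100-point grid in [-5, 5] and refined by golden-section search to
1e-6, which is robust to the surface's occasional flatness (with K = I
the likelihood is constant in delta and the fit correctly degenerates
to OLS).

Each marker is then tested by generalized least squares in the
whitened space (rotate by K's eigenvectors, scale by
`(sigma_g^2 d_i + sigma_e^2)^{-1/2}`), with the Wald statistic
`(beta/se)^2` referred to chi-square(1), two-sided.  Markers with zero
variance after whitening (e.g. constant dosage) get p = 1 and a flag.
P-values are floored at the smallest positive double so they stay in
(0, 1].  Significance uses Benjamini-Hochberg step-up control at
q = 1% by default; the scan reports the step-up threshold (the largest
significant p), which is undefined when nothing passes.

Calibration is validated by KS-uniformity of null-scan p-values and a
type-I-error check at nominal 0.05; power by top-hit recovery of a
single causal site (beta = 1.5, h2 = 0.4, n = 300).  The scan's
p-values agree to 1e-6 with an explicit per-marker GLS oracle that
inverts the full covariance; agreement with classical per-marker
regression (K = I) is asymptotic only, because the EMMAX Wald test
fixes the residual variance at the null fit and uses a chi-square
reference, while the t^2 test re-estimates variance per marker — the
two differ at order 1/n by construction.

## Variant-effect annotation

`annotate_variants()` is a deliberately small, transparent
reimplementation of the SnpEff classification logic with one canonical
transcript per gene.  Coding SNVs mutate their codon (strand-aware)
and are translated under the standard nuclear code; indels in CDS are
frameshift unless the length change is a multiple of 3; intronic
positions within 2 bp of an exon boundary are splice sites (the
standard donor/acceptor window; the source is silent on it); exonic
non-coding positions are UTR; everything outside genes is intergenic.
Overlapping gene models resolve by severity (High > Moderate > Low >
Modifier), ties by lowest gene id.  Start-codon loss is distinguished
as its own High-impact term.  Functional classes follow SnpEff:
stop_gained is Nonsense, missense *and stop_lost* are Missense,
synonymous is Silent.

Because one effect is counted per variant, the published effect total
that exceeds its variant total (SnpEff's per-transcript accounting)
is intentionally not reproduced.  The classifier is validated against
an oracle that rebuilds the entire mutated CDS, translates both
sequences (with initiator-codon special-casing disabled, so start-codon
changes are visible) and diffs the proteins, over >1,000 random coding
SNVs on simulated gene models of both strands, plus a strand-symmetry
property (annotating a variant equals annotating its
reverse-complement against the mirrored models).

## SV summaries and CNV detection

SV call sets store the six long-read caller types (INS, DEL, DUP, INV,
TRA, INVDUP) with absolute lengths.  The genome-distribution filter
keeps insertions, deletions and duplications of 1-50 kb inclusive;
translocations have no meaningful linear length and are exempt from the
length bounds whenever they are explicitly included.  Windowed SV
density per subgroup uses the same half-open tiling as the diversity
tracks.

The CNV test follows the read-depth ratio logic of CNV-seq on 100 kb
windows: the depth-normalized ratio `r = (x1/N1)/(x2/N2)` is tested
with the Geary-Hinkley transformation
`t = (mu2 r - mu1)/sqrt(mu2 r^2 + mu1)`, where the window means
(= variances, Poisson approximation) are the genome-average expected
counts `N_i / n_windows`, referred two-tailed to N(0,1).  The Poisson
mean-variance approximation is validated by Monte-Carlo: a copy-number-4
segment at 30x depth is called gain in essentially all affected
windows, and the false-call rate on a pure null stays below twice the
nominal level.  P-values are BH-corrected across windows before the
gain/loss call (alpha applies post-correction); no field-standard
alpha exists for this test, so it is an explicit argument (0.01 in the
examples).  A zero reference count makes the ratio undefined; such
windows are flagged `loss-candidate/undefined` rather than raising.
Note that total-count normalization makes calls relative: if a large
genome fraction is duplicated, unaffected windows shift visibly in the
opposite direction — an intrinsic property of ratio-based CNV
detection, which is why validation uses realistic small CNV fractions.

## Problem sizes and scope

The validation suites run at deliberate desk scale, chosen once as
representative: 3 x 50 samples and 20,000 sites for F_ST recovery;
n = 300 and m = 5,000 markers for GWAS calibration/power (20 phenotype
replicates); >= 1,000 random coding SNVs for the annotation oracle;
10,000 windows for CNV null calibration.  Headline counts from the
motivating study (tens of millions of variants from 25 billion reads)
are inputs to aggregation checks, not recomputation targets.

Out of scope by design: read trimming/mapping/variant calling,
haplotype phasing and LD-aware imputation, ADMIXTURE-style ancestry
models, coalescent simulation, SV calling from alignments, gene-based
association tests, and per-transcript effect multiplicity.  The
exported functions are the package's interface; no shell entry point is
provided because every operation is a few lines of R on the panel
object, as the examples in the README show.
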