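# soypopgen

Population genomics and mixed-model association analysis for structured
resequencing panels, written for the kind of data a crop mini-core
collection produces: a few hundred accessions, whole-genome SNP/indel
calls, subgroup structure (in the motivating soybean panel: "Primitive",
"World" and "Japan"), long-read structural-variant call sets, and
windowed read-depth data for CNV detection.

The package covers the full downstream workflow once variants have been
called:

- **Genotype panels** — biallelic dosage matrices from VCF
  (`read_vcf`/`write_vcf`), minor-allele-frequency and missingness
  filters with an exact accounting report (`filter_variants`), naive
  single-site imputation (`impute_missing`).
- **Diversity and differentiation** — per-subgroup allele frequencies,
  private/shared variant classification, and non-overlapping 500 kb
  window tracks of nucleotide diversity π, Weir–Cockerham
  F<sub>ST</sub> (pairwise and total, ratio-of-sums
  `Σa / Σ(a+b+c)`), and composite LD r².
- **Structure** — Jukes–Cantor distances
  `d = −(3/4)·log(1 − (4/3)p)` on genotype mismatch proportions,
  a deterministic neighbour-joining tree with outgroup rooting, and
  classical MDS ordination with percent-variance per axis.
- **GWAS** — EMMAX-style linear mixed model
  `y = Xb + g + e`, `g ~ N(0, σ²_g K)` with a VanRaden kinship matrix,
  two ordination axes as fixed covariates, REML variance components
  estimated once under the null, per-marker Wald χ²₁ tests, and
  Benjamini–Hochberg FDR control at 1%.
- **Effect annotation** — a transparent SnpEff-style classifier
  (stop gained/lost, start lost, frameshift, splice site, missense,
  synonymous, UTR/intronic/intergenic) with
  High/Moderate/Low/Modifier impacts and
  Nonsense/Missense/Silent functional classes.
- **SV / CNV** — per-accession × per-type SV summaries, the 1–50 kb
  INS/DEL/DUP length filter, windowed SV density per subgroup, and a
  CNV-seq-style read-depth ratio test (Geary–Hinkley transform of the
  normalized ratio, BH-corrected across windows).
- **Synthetic data** — a Balding–Nichols structured-population
  generator (subgroup frequencies `Beta(p(1−F)/F, (1−p)(1−F)/F)`),
  quantitative traits with exactly realized heritability, SV call
  sets, CNV window counts and toy gene models, all with known ground
  truth so every stage above is testable offline.

See `vignettes/soypopgen-methods.Rmd` for the models, parameter
defaults, numerical choices and limitations.

## Worked example

Simulate a 198-accession panel shaped like the motivating collection,
filter it, compute diversity tracks, and run a mixed-model scan on a
trait with one strong and ten weak causal sites:

```r
library(soypopgen)

cfg <- sim_config(n_per_group = c(Primitive = 20, World = 58, Japan = 120),
                  n_variants = 8000, chrom_length = 4e7, F = 0.1,
                  missing_rate = 0.02, seed = 7)
sim <- simulate_structured_genotypes(cfg)
flt <- filter_variants(sim$panel, maf_min = 0.025, missing_max = 0.05)
flt$report
#> variant filter report
#>   input:                8000
#>   removed multiallelic: 0 (at VCF read)
#>   removed missingness:  61
#>   removed MAF:          202
#>   retained:             7737

imp <- impute_missing(flt$panel)
K   <- compute_grm(imp)
pcs <- panel_pcs(imp, 2)

set.seed(10)
cs <- flt$panel$variants$id[c(2000, seq(500, 7000, by = 750))]
tr <- set_trait_truth(sim$truth, cs, c(1.5, rnorm(length(cs) - 1, 0, 0.25)),
                      h2 = 0.5)
y   <- simulate_phenotype(imp, tr, seed = 11)
fit <- fit_null_lmm(y, pcs, K)
fit
#> null LMM fit (REML)
#>   sigma_g2 = 0.5443, sigma_e2 = 0.2569, lambda = 0.472
#>   h2 = 0.679, restricted logLik = -262.64

scan <- association_scan(imp, y, pcs, fit, q = 0.01)
head(manhattan_table(scan)[order(scan$p), ], 3)
#>      chrom      pos            p neglog10p significant
#> 2000 Chr01 10449726 1.565139e-16 15.805447        TRUE
#> 6500 Chr01 33787768 1.900589e-06  5.721112        TRUE
#> 2513 Chr01 13129217 1.254028e-04  3.901693       FALSE
attr(scan, "threshold")
#> [1] 1.900589e-06
```

The strongest causal site (`Chr01_10449726`, β = 1.5) tops the scan and
passes the 1% FDR threshold; the fitted variance components put most of
the trait variance on the genomic random effect, as simulated.
Structure analysis on the same panel:

```r
jc   <- jc69_distances(subset_panel(sim$panel, samples = seq(1, 198, by = 6)))
tree <- neighbor_joining(jc, outgroup = "Primitive_1")   # ape "phylo" object
ord  <- pcoa(imp, k = 2)
round(ord$percent_var[1:2], 1)
#> [1] 8.3 3.1
```

PC1 separates the three subgroups and carries ~8% of the variance —
the same order as reported for real structured soybean panels.

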