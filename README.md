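# cagtools

Continental ancestry groups for biobank-style cohorts: supervised
admixture assignment, within-group population structure, and
differentiation — with a synthetic-cohort generator so the whole workflow
runs and validates without restricted data.

## Who this is for

Large cohort studies routinely need to split a genetically diverse sample
into relatively homogeneous ancestry groups before association analyses:
population stratification confounds genotype–phenotype associations, and
the usual corrections (principal components, relatedness matrices) may not
absorb the structure present at continental scale. `cagtools` implements
the standard workflow end to end:

1. **Supervised admixture.** Each individual's ancestry proportions
   `q` over K reference populations are estimated by maximising the
   binomial likelihood with reference allele frequencies `f` held fixed
   (per-individual EM):
   `ℓ(q) = Σⱼ [ gⱼ ln Σₖ qₖ fₖⱼ + (2−gⱼ) ln Σₖ qₖ(1−fₖⱼ) ]`.
   Individuals with max `q ≥ 0.8` join that continental ancestry group
   (CAG); the rest stay unassigned.
2. **Within-group structure.** Per CAG: genomic-relationship-based
   unrelated selection, windowed LD pruning (50 kb / 10 kb / r² 0.025),
   Patterson-normalised PCA (`x = (g − μ)/√(p(1−p))`) with projection of
   relatives and reference panels and 10-PC / 6-SD / 5-iteration outlier
   removal, then K-means over the top PCs with silhouette-selected k
   (scanned 2..20).
3. **Interpretation.** Correspondence analysis of cluster × birth-region
   tables (categories under 10 observations excluded; total inertia =
   X²/n), and pairwise Hudson Fst between clusters,
   `Fst = Σⱼ Nⱼ / Σⱼ Dⱼ` with
   `Nⱼ = (p₁−p₂)² − p₁(1−p₁)/(2n₁−1) − p₂(1−p₂)/(2n₂−1)` and
   `Dⱼ = p₁(1−p₂) + p₂(1−p₁)` (ratio of averages), reported as
   min/mean/max plus a phylip distance matrix.

Genotypes come in and out as GT-only VCF or PLINK text PED/MAP (binary
BED read-only); datasets merge by shared variant id with duplicate,
allele-mismatch and ref/alt-swap handling. The generator simulates
hierarchical Balding–Nichols cohorts (continents, subpopulations, admixed
individuals, parent–offspring pairs, noisy birth labels) with full truth
tables, so every stage is testable against known answers.

## Worked example

A four-continent synthetic cohort (pairwise continental Fst 0.1; three
subpopulations per continent at within-group Fst 0.008–0.013; reference
panels; Dirichlet(0.3) admixed individuals; parent–offspring pairs; 90%
birth-label concordance), pushed through the full pipeline and scored
against the generator's truth:

```r
library(cagtools)
spec <- default_rehearsal_spec(n_snps = 12000, n_per_subpop = 40,
                               n_reference = 60, n_admixed = 40,
                               relative_pairs = 5, seed = 42)
cfg <- pipeline_config(spec = spec, seed = 42,
                       out_dir = file.path(tempdir(), "cag_demo"),
                       min_cag_size = 20)
report <- rehearse(cfg)   # ~3 minutes on one core
print(report)
```

```
rehearsal evaluation:
  admixture q MAE:                 0.0293
  assignment accuracy (qmax>=0.9): 1.0000
  unassigned rate    (qmax<=0.7):  1.0000
  continental Fst max |error|:     0.0033
  AFR: k=3 ARI=1.000 Dim1+2=1.000 max Fst err=0.0009 outliers=0
  EAS: k=3 ARI=1.000 Dim1+2=1.000 max Fst err=0.0026 outliers=0
  EUR: k=3 ARI=1.000 Dim1+2=1.000 max Fst err=0.0006 outliers=0
  SAS: k=3 ARI=1.000 Dim1+2=1.000 max Fst err=0.0020 outliers=0
```

Reading this: estimated ancestry proportions are within 0.03 of truth on
average; every sample that is truly ≥90% one ancestry lands in the right
CAG and every strongly admixed sample (max q ≤ 0.7) is left unassigned;
the silhouette scan recovers the three planted subpopulations in each
group (adjusted Rand index 1.0 against truth); and Hudson Fst reproduces
the generating divergences to well within ±0.01, both between continents
(truth 0.1) and within groups (truth 0.008–0.013).

The per-stage manifest tracks sample/variant counts through all 11
stages (`check_manifest()` verifies the flow conserves):

```
  stage                 name n_samples_in n_samples_out n_variants_in n_variants_out
1     1                merge          765           765         12000          12000
2     2      ld_prune_global          765           765         12000           2619
3     3 supervised_admixture          525           525          2619           2619
4     4       cag_assignment          525           498          2619           2619
5     5        unrelated_AFR          185           143         12000          12000
6     6            prune_AFR          143           143         12000           5909
```

and the AFR group's cluster differentiation comes back as

```r
round(report$run$cags$AFR$fst$fst, 4)      #      K1     K2     K3
                                           # K1 0.0000 0.0068 0.0069
                                           # K2 0.0068 0.0000 0.0070
                                           # K3 0.0069 0.0070 0.0000
round(summarize_pairs(report$run$cags$AFR$fst), 4)
#    min   mean    max
# 0.0068 0.0069 0.0070
```

against a generating within-AFR Fst of 0.008.

Artifacts land in `out_dir`: `admixture.Q.tsv` (proportions + CAG),
per-group `.evec.tsv` scores, silhouette tables, cluster labels, phylip
Fst matrices, `manifest.tsv` and `run.log`. Reruns under the same config
and seed are bit-identical.

## Command line

```sh
Rscript inst/cli/cagtools.R simulate  --config cohort.json --out sim/
Rscript inst/cli/cagtools.R run-all   --config pipeline.json
Rscript inst/cli/cagtools.R rehearse  --config pipeline.json
```

Configs are JSON mirrors of `pipeline_config()` /
`population_spec()` (see `?read_pipeline_config`).

## Vignette

`vignettes/methods.Rmd` documents the models, the synthetic world and its
limits, numerical choices, and known limitations.
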