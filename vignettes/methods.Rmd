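---
title: "Methods: continental ancestry groups, structure and differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continental ancestry groups, structure and differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`cagtools` implements a complete biobank-style ancestry workflow: assign
each genotyped individual to a continental ancestry group (CAG) by
supervised admixture against reference-population allele frequencies, then
characterise the population structure *within* each group — principal
components with projection and outlier removal, K-means clustering with
silhouette-guided choice of k, correspondence analysis of clusters against
place-of-birth labels, and pairwise Hudson Fst between clusters. Because
the cohorts this workflow targets are access-restricted, the package also
contains a first-class synthetic-cohort generator with known ancestry,
relatedness and birth-place truth, so every stage can be exercised and
validated end to end on a laptop.

## The models

### Supervised admixture

For individual $i$ with genotypes $g_{ij} \in \{0,1,2\}$ (alt-allele
counts, missing omitted) and fixed reference frequencies $f_{kj}$ for $K$
source populations, the ancestry vector $q_i$ on the simplex maximises the
binomial log-likelihood

$$\ell(q_i) = \sum_j \Big[ g_{ij}\,\ln \textstyle\sum_k q_{ik} f_{kj}
  + (2-g_{ij})\,\ln \sum_k q_{ik} (1-f_{kj}) \Big].$$

We fit by per-individual EM: the E-step allocates each allele copy to
source $k$ proportionally to $q_{ik} f_{kj}$ (alt copies) or
$q_{ik}(1-f_{kj})$ (reference copies); the M-step divides the allocated
copies by $2 \times$ the number of non-missing SNPs. The likelihood is
non-decreasing and every M-step lands exactly on the simplex; both are
asserted in the tests. $q$ is initialised uniform at $1/K$, so the fit is
deterministic and needs no seed.

Design notes:

* **Two-stage, not joint.** $f$ is estimated once from labelled reference
  samples (clamped to $[10^{-6}, 1-10^{-6}]$ so $\ell$ is finite) and held
  fixed. The joint supervised objective in which target samples also
  inform $f$ is deliberately not implemented: at realistic reference-panel
  sizes the difference is negligible and the two-stage objective is the
  one actually stated above.
* **Convergence.** Per-individual tolerance $10^{-6}$ on
  $\max_k |\Delta q_{ik}|$, capped at 1000 iterations. Interior maxima
  (individuals whose best fit keeps several small components) approach
  their optimum at a linear rate close to 1, so the cap is routinely hit;
  the attained $q$ is nevertheless accurate to well under 0.01, which the
  recovery tests quantify. Converged individuals are frozen and dropped
  from later sweeps; the likelihood trace records each row at the start of
  its last evaluated iteration, preserving monotonicity of the total.
* **Assignment.** A sample joins the CAG of its largest component when
  that component is at least the threshold (default 0.8, inclusive);
  otherwise it is `unassigned`.

### Principal components

Genotypes are normalised the standard way for genotype PCA: centre by the
per-variant mean call $\mu_j$ and scale by $\sqrt{p_j(1-p_j)}$ with
$p_j = \mu_j/2$, both computed **on the fit samples only**; missing calls
become 0 after centring; variants monomorphic on the fit set are dropped.
PCs come from the eigen-decomposition of the $n \times n$ cross-product, so
wide matrices stay cheap; sample score variance along PC $p$ equals
$\lambda_p$, and signs are fixed (largest-magnitude loading positive) so
results are reproducible. Held-out samples — relatives and reference
panels — are projected using the fit samples' normalisation constants and
loadings. Projected scores shrink toward the origin relative to fit
scores, a known property of out-of-sample projection; the tests therefore
assert nearest-centroid placement for projected groups rather than exact
distances.

Outlier removal mirrors the usual smartpca settings: up to 5 iterations,
each refitting the PCs and dropping any fit sample more than 6 SD from the
per-PC mean on any of the top 10 PCs, stopping early when nothing is
flagged and always refitting once at the end. Under a Gaussian score
distribution the expected false-flag count is $n \cdot 10 \cdot 2\Phi(-6)
\approx 10^{-5} n$, i.e. none at desk scale.

The number of "top PCs" carried into clustering is chosen from the scree
spectrum. In practice analysts choose the elbow by eye; as an automated
stand-in we take the index maximising the second forward difference of the
descending variance-explained fractions, with a configuration override for
deliberate choices. A flat spectrum returns the minimum of 2 with a
warning.

### K-means and silhouette

K-means is run on the top PCs only, equally weighted: Lloyd's algorithm
with k-means++-style seeding, 25 restarts by default, best solution by
within-cluster sum of squares, and empty clusters re-seeded from the point
farthest from its centroid. k is scanned over 2..20 and chosen by the
largest average silhouette width (singletons score 0); the full
silhouette-vs-k table is always reported so that a deliberate second-best
choice for one group remains an explicit, recorded override rather than a
hidden re-run. We compute silhouettes on the K-means partitions
themselves; selecting k with a separate PAM-based routine, as some
workflows do, would mix two clustering models, a discrepancy we avoid for
the sake of one model end to end.

### Correspondence analysis

Cluster and birth-region labels are cross-tabulated after dropping samples
missing either label; birth categories with fewer than 10 observations are
excluded (exactly 10 is kept), and the filter applies to birth categories
only, never to clusters. Standard CA follows: SVD of
$S = D_r^{-1/2}(P - rc^{\top})D_c^{-1/2}$, principal (mass-scaled)
coordinates for the symmetric map, per-dimension inertia
$\sigma_d^2/\sum\sigma^2$, and the identity
$n \times \text{total inertia} = X^2$ (Pearson, no continuity correction),
asserted to $10^{-8}$. Because CA figure axes often quote Dim1/Dim2
percentages that sum to 100 even when more dimensions exist, both the raw
fractions and the two-dimension renormalised pair are reported. An exact
independence table yields zero inertia and zero coordinates without error.

### Hudson Fst

Per SNP, with sample frequencies $p_1, p_2$ from $n_1, n_2$ diploids:

$$N_j = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{2n_1-1} - \frac{p_2(1-p_2)}{2n_2-1},
\qquad D_j = p_1(1-p_2) + p_2(1-p_1),$$

combined across SNPs as the ratio of averages $\sum N_j / \sum D_j$ —
never the average of ratios, and the tests assert the two genuinely
differ. The Hudson form was chosen because the genotyping arrays this
workflow targets carry a European ascertainment bias, under which Hudson
is the recommended estimator; smartpca's own internal Fst estimator is
undocumented. Weir-Cockerham could be slotted in behind the same
interface if desired. Negative pair estimates (sampling noise around zero) are
reported raw and clamped to $[0,1]$ in the summary view, which is the
range the statistic is defined on. Output includes min/mean/max over
pairs and a phylip-format distance matrix (names longer than 10
characters switch to a relaxed dialect with a warning).

### Relatedness

The genomic relationship matrix is the standard variance-normalised
estimator $\mathrm{mean}_j\,(g_{ij}-2p_j)(g_{i'j}-2p_j)/(2p_j(1-p_j))$
with missing calls mean-imputed and a MAF floor (default 0.05) applied
first. Note the estimator uses sample frequencies, so off-diagonal entries
carry a $-1/n$ centring bias; tests use cohorts large enough that this
stays inside the stated tolerances. The relatedness cutoff defaults to
0.025 — PLINK's `--rel-cutoff` default, a value applied analyses rarely
state. Unrelated-subset selection is greedy: repeatedly
drop the individual in the most remaining related pairs (ties: the
lexicographically larger id). Greedy selection is not guaranteed maximum;
the tests certify the kept set induces no related pairs and measure the
gap to a brute-force maximum independent set on small random graphs.

### LD pruning

Windowed greedy pruning with kilobase windows (default 50 kb, 10 kb step,
$r^2 > 0.025$): within a window, while any retained pair exceeds the
threshold, the lower-MAF member is removed (tie: larger position — tools leave this
tie-break unspecified; keeping the more informative SNP mimics common
tool behaviour). $r^2$ is the genotypic
(composite) correlation — phase is unavailable on array data — and can be
restricted to a reference sample subset, the common practice of
estimating LD on a single unrelated reference panel. A stepped grid alone can miss pairs
separated by more than window − step, so a sweep of windows anchored at
every variant follows the grid; the post-condition — no retained
same-chromosome pair within the window exceeds the threshold — is then
guaranteed, verified in tests by an independent exhaustive scan, and makes
pruning idempotent. SNP-count windows are available behind a flag for
users who expect plain-number tool semantics.

## The synthetic world

The generator draws a hierarchical Balding–Nichols world: ancestral
frequencies $p_j \sim \mathrm{Uniform}(\text{maf\_range})$ (default
0.05–0.5); continent frequencies
$\mathrm{Beta}\!\big(p(1-F_c)/F_c,\,(1-p)(1-F_c)/F_c\big)$; subpopulation
frequencies likewise around their continent with $F_s$; everything clamped
to $[10^{-6}, 1-10^{-6}]$. Unadmixed genotypes are
$\mathrm{Binomial}(2, p_{sj})$; admixed individuals draw each allele copy
from continent $k$ with probability $q_k$ ($q \sim$ Dirichlet), at the
continent-level frequency — admixture is modelled at the global-proportion
level, with no local-ancestry tracts, because that is exactly the model
the estimator fits. Parent–offspring pairs are appended by Mendelian
transmission from two same-subpopulation parents. Birth labels match the
true subpopulation's region with a configurable concordance (default 0.9
in the rehearsal world), otherwise draw uniformly from the other regions;
a configurable fraction is missing. All randomness flows from one seed.

Useful closed forms under this model (used as truth in the tests): two
populations diverged $F_1$ and $F_2$ from a common ancestor have expected
Hudson Fst $(F_1+F_2)/2$; subpopulations of *different* continents have
approximately $F_c + (F_{s1}+F_{s2})(1-F_c)/2$.

Linkage is off by default (independent SNPs). An optional LD-block mode
duplicates a fraction of SNPs 500 bp away with per-copy flip probability
$\varepsilon$ (pair $r^2 \approx (1-2\varepsilon)^2$), giving the pruner
something real to remove.

**What the generator does not emulate:** realistic site-frequency spectra,
recombination maps and genuine LD decay, selection, and the messy
sample-exclusion bookkeeping of real biobanks. A green end-to-end test
therefore establishes that the estimators recover the truth of *this*
stated world at desk scale — not that they reproduce any restricted
cohort's reported numbers, which depend on data this package cannot
ship.

### The default rehearsal world

`default_rehearsal_spec()` states: four continental groups each diverged
$F_c = 0.1$ from the global ancestor (pairwise continental Fst
$\approx 0.1$, the scale separating continental reference panels); three
subpopulations per continent with pairwise within-group Fst of
0.008 / 0.009 / 0.010 / 0.013 for the four groups — inside the
0.003–0.015 range typical of within-continental-group differentiation on
European-ascertained arrays, ordered AFR < EUR < SAS < EAS as such
cohorts show, but sized toward the upper half of the range: at desk
scale ($n = 60$ per subpopulation, $\sim$20k SNPs) the bottom of that
range sits only a few multiples above the PCA detectability threshold
$1/\sqrt{nM}$, and cluster recovery is not a property of that corner of
the range at this sample size. One reference panel of 100 per continent
(the size of a typical public reference population sample), 60 admixed
individuals with $q \sim \mathrm{Dirichlet}(0.3\cdot\mathbf{1})$ — the
concentration is a free parameter; strongly admixed cohort members have
no canonical distribution to calibrate against — and 10
parent–offspring pairs. These values were fixed from the power argument
above before the acceptance tests were first run, and have not been
revisited since.

## The pipeline

`run_framework()` executes the workflow's canonical order: merge by variant id
(dropping within-input duplicates and irreconcilable allele pairs,
recoding clean ref/alt swaps $0\leftrightarrow 2$, keeping literal-match
strand-ambiguous SNPs with a warning) → global LD prune with $r^2$ on one
reference panel → supervised admixture (references donate frequencies;
targets are fitted) → CAG assignment at 0.8 → per CAG: MAF-0.05 GRM and
greedy unrelated selection → MAF-0.01 per-group LD prune → PCA fit on
unrelated targets with 10-PC/6-SD/5-iteration outlier removal, relatives
and cognate references projected → variance explained and top-PC choice →
K-means with silhouette scan (2..20) → correspondence analysis against
birth regions → pairwise Fst between clusters with min/mean/max and
phylip output. Reference samples never enter clustering or CA. Every
stage logs sample/variant counts to a manifest whose count-flow is
machine-checked, and a rerun under the same configuration and seed is
bit-identical (no timestamps enter any artifact). Accounts of this
workflow differ on the exact position of the two MAF filters relative to
the relatedness and pruning steps; both are applied exactly where each is
described above, and both appear in the manifest.

`rehearse()` adds truth-based scoring: mean $|\hat q - q|$; assignment
accuracy among samples with true $q_{\max} \ge 0.9$ and unassignment among
$q_{\max} \le 0.7$; per-group ARI of cluster labels against true
subpopulations (admixed samples carry no subpopulation truth and are
excluded from ARI); CA Dim1+Dim2 inertia; and Hudson Fst recovery against
the closed-form expectations above, within groups and between continents.
Admixed individuals that pass the 0.8 threshold are genuine PCA outliers
in their group, so the outlier count is reported and bounded rather than
required to be zero.

## Numerical choices and degenerate inputs

* Frequencies clamped at $10^{-6}$; an all-missing group/SNP frequency
  becomes 0.5 with a warning.
* `ld_r2` returns 0 for constant vectors and errors below 2
  pairwise-complete samples; zero-denominator SNPs are excluded from Fst
  sums; groups under 2 samples are excluded from Fst with a warning.
* `fit_pcs` returns fewer PCs with a warning when rank falls short; an
  all-monomorphic fit set errors.
* A rank-0 (independence) contingency table yields zero inertia without
  error; an empty post-filter table errors.
* K-means ties in silhouette go to the smaller k; PC and CA axis signs are
  fixed deterministically.
* Tolerances in tests follow each criterion's stated value; sampling
  checks use 3–3.5 standard-error envelopes.

## Known limitations

* EM convergence at $10^{-6}$ is frequently capped at 1000 iterations for
  interior optima; accuracy is unaffected at the tested scales but the
  `converged` flag is honest about it.
* The greedy unrelated selection and the silhouette scan are heuristics;
  both are certified (no related pairs kept; full scan table reported)
  but not optimal.
* PED files carry no allele orientation; reading PED infers alt = minor
  allele unless the caller pins orientations, so a write→read round trip
  is exact only with the orientation supplied.
* Strand-ambiguous (A/T, C/G) SNPs are kept on literal allele match with
  a warning, never strand-resolved.
* No haplotype phase, no imputation, no indels or multi-allelic splitting,
  no coalescent simulation.
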