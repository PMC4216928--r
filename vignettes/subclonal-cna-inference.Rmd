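---
title: "Methods: joint subclonal CNA/LOH inference from tumor-normal sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint subclonal CNA/LOH inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

cloneCN infers segmental copy-number alterations (CNA) and loss of
heterozygosity (LOH) from two per-SNP signals extracted at germline
heterozygous positions of a matched tumor/normal pair: the tumor
reference-allele read count $a_t$ out of depth $N_t$, and the
bias-corrected depth log ratio $l_t$ between tumor and normal.

The central modelling assumption is that the sequenced sample is an
aggregate of three cell populations at every locus: normal cells
(proportion $n$, diploid heterozygous), tumor cells *without* the local
event (proportion $(1-n)\,s_z$, also diploid heterozygous) and tumor
cells *carrying* the event (proportion $(1-n)(1-s_z)$, the **sample
cellular prevalence**). $1-s_z$ is the **tumor cellular prevalence**.
Events are grouped into a small number of clonal clusters $z \in
\{1,\dots,Z\}$ sharing one prevalence each, on the reasoning that
aberrations at the same prevalence plausibly arose in the same clone.

Each somatic genotype $g$ is an allele string over $\{A, B\}$ with copy
number $c_g$ and $k_g$ reference copies (21 states up to copy number 5,
from homozygous deletion through balanced and unbalanced
amplifications). The population mixture gives closed-form emission
parameters

$$\mu_{g,z} = \log_2\frac{2n + 2(1-n)s_z + (1-n)(1-s_z)c_g}
                         {2n + (1-n)\phi}, \qquad
\omega_{g,z} = \frac{n + (1-n)s_z + (1-n)(1-s_z)k_g}
                    {2n + 2(1-n)s_z + (1-n)(1-s_z)c_g},$$

with $l_t \sim \mathcal N(\mu_{g,z}, \sigma^2_g)$ and
$a_t \sim \mathrm{Bin}(N_t, \omega_{g,z})$, where $\phi$ is the average
tumor ploidy entering only the log-ratio denominator. Because CNA/LOH
events span tens to thousands of contiguous SNPs, the hidden genotype
and cluster sequences form the two chains of a factorial HMM over
$|G|\times|Z|$ state tuples (plus one outlier state), fit by MAP
expectation maximization; chromosomes are independent chains sharing the
global parameters $(n, \phi, s_{1:Z}, \sigma^2_{1:G})$.

# Parameters, defaults, and why

* **Log base.** Log ratios are base 2 throughout (model and simulator),
  so the choice cancels internally.
* **`max_copy = 5`** gives the 21-state genotype panel; higher copies
  are representable but rarely identifiable at 30x.
* **$c_N = 2$**: autosomes only by default; sex chromosomes need a
  different normal copy number and are excluded unless the user supplies
  data for them deliberately.
* **Allelic-ratio clamp $\varepsilon = 0.01$** absorbs sequencing error
  at homozygous states (an $\omega$ of exactly 1 would zero out the
  likelihood of any non-reference read).
* **Homozygous-deletion floor**: the aggregate copy number is floored at
  0.05 copies before the log, keeping $\mu$ finite for EM in the
  degenerate pure-tumor clonal case.
* **Transitions.** Both chains are sticky and position-independent:
  genotype self-transition $1 - 1/L_G$ with $L_G = 10^6$ SNP steps and
  cluster self-transition $1 - 1/L_Z$ with $L_Z = 10^5$; the joint
  matrix is the product, so a cluster switch without a genotype switch
  is doubly rare — prevalence changes accompany event boundaries. An
  outlier state (entry probability $10^{-3}$, self-transition 0.1) with
  a uniform emission absorbs isolated aberrant observations; decoded
  outliers are bridged into their flanking segments.
* **Priors.** Beta(2,2) on $n$ and each $s_z$; Normal(2, 0.5$^2$) on
  $\phi$ truncated to [1, 8]; inverse-gamma shrinkage on the
  per-genotype variances anchored at the empirical log-ratio variance.
  Weakly informative; they keep the bounded 1-D M-step updates away
  from degenerate boundaries.
* **EM budget**: `max_iter = 20`, relative log-posterior tolerance
  `1e-4`. The fit is deterministic — there are no stochastic steps
  inside EM.
* **Depth filter**: SNPs with tumor depth below 10 are excluded before
  inference.

# Identifiability and the clonal anchor

The emission parameters depend on $(n, s_z)$ only through the sample
prevalences $q_z = (1-n)(1-s_z)$ (substitute $n + (1-n)s_z = 1 - q_z$
above). The likelihood therefore identifies the $q_z$ — and, through the
neutral background, the average-ploidy denominator — but *not* $n$
itself unless some cluster is clonal ($q_1 = 1-n$). This is a property
of the model class, not of the optimizer.

Two design choices handle it. First, EM is initialized with the most
prevalent cluster at tumor prevalence ~1 (the even grid $1, \tfrac{Z-1}{Z},
\dots$), which, combined with bounded coordinate updates, pins $\hat n$
at the feasibility boundary $1 - \hat q_1$: the standard assumption that
the most aberrant cluster is clonal. When that assumption holds, $n$ and
all prevalences are recovered accurately (see the parameter-recovery
tests); when no clonal cluster exists, $\hat n$ absorbs the gap and the
$\hat q_z$ remain accurate — calls and segment boundaries are
unaffected, only the split of $q$ into $n$ versus $s$ shifts.

Second, the default initialization estimates the purity scale from the
data rather than fixing $n_0 = 0.5$: symmetric allelic ratios are
smoothed with a running median (window 51 SNPs); within clearly
imbalanced stretches (smoothed ratio $\ge 0.55$) an LOH region at
prevalence $q$ has expected symmetric ratio $1/(2-q)$, so $q = 2 -
1/\mathrm{ratio}$; the 95th percentile of these $q$ values is taken as
the clonal prevalence and $n_0 = 1 - q$. Without this, the even
prevalence grid can sit on the wrong scale and EM converges to
cluster-merged local optima (we observed prevalence errors up to ~0.5 on
two-sample mixture simulations that drop below 0.03 with the
pre-estimate). `initialize_params()` called directly still uses the
neutral default $n_0 = 0.5$.

# The amplification degeneracy and the parsimony prior

The amplified states contain exact confounds: a one-copy gain (AAB) at
prevalence $q$ and a two-copy allele-specific amplification (AAAB) at
$q/2$ imply *identical* $(\mu, \omega)$, and the same relation continues
up the copy-number ladder. No amount of data separates the pair; this is
the model-class reason amplification prevalences are intrinsically
harder to estimate than deletions (deletions have no such twin: the
homozygous-deletion allelic ratio pins them apart). cloneCN resolves the
tie with a weak per-SNP parsimony log-prior on genotype states,
`genotype_penalty * |c_g - 2|` with a default of 0.05 per SNP —
orders of magnitude below the per-SNP evidence separating genuinely
different states, but decisive across a segment for an otherwise exact
tie, always toward the lower copy number.

# Normalization front end

Read counts in fixed 1-kb bins are corrected by loess (span 0.3, degree
2, one robustness iteration) against GC fraction and then mappability,
for tumor and normal separately. Bins with mappability below 0.9,
missing GC, or counts outside the 1%–99% quantiles are excluded from
both fit and output — routine outlier guarding. Corrected counts keep
the raw count scale (count divided by fitted value, rescaled by the
median usable count), so correction is scale-equivariant and the
log ratio is unchanged by global scaling. Each SNP then takes
$l_t = \log_2$ of the corrected tumor/normal counts of its overlapping
bin; SNPs in bins missing from either track are dropped and reported.

# Choosing the number of clusters

The model is fit once per $Z$ in a range (default 1–4) and the run with
the minimum S\_Dbw validity index is selected. The index (scatter +
between-cluster density) works on two features — depth log ratio and
symmetric allelic ratio $\max(a_t, N_t - a_t)/N_t$ — restricted to
non-neutral decoded calls, because cluster membership is meaningless for
diploid-heterozygous loci. Features are standardized to unit variance
(the two axes have incomparable scales); for a single cluster the
density term is defined as 0; ties resolve toward fewer clusters, and if
no aberrant SNPs were decoded at all the single-cluster run is selected
by convention.

`sdbw_index()` implements the standard Halkidi form. `sdbw_of_fit()`
applies it with two deliberate choices that depart from a naive per-SNP
computation. First, the features are *segment medians*, not per-SNP
values: at 30x the per-SNP log ratio (sd ~0.25) of two prevalence
levels separated by ~0.5 log units overlaps so strongly that every
multi-cluster run scores worse than a single cluster even when the
clusters are real — it is segment-level pooling that resolves
prevalence. Second, the index is computed within each genotype call
class and averaged across classes weighted by SNP count: deletions and
gains differ far more in feature space than prevalence levels do, and
would otherwise dominate the scatter term. A single-cluster run scores
exactly 1 under this construction, so extra clusters are accepted
precisely when they explain within-class segment structure. Published
variants of this workflow modify the index in ways that are not fully
specified; this is our documented resolution.

# The simulator and its fidelity boundary

`simulate_dataset()` samples from the model's own generative process:
SNP positions with geometric spacing (mean 1.3 kb, about the genome-wide
heterozygous-SNP density), depth $N_t \sim
\mathrm{Pois}(\mathrm{coverage} \times \text{aggregate copy}/2)$,
reference counts $\mathrm{Bin}(N_t, \omega_{g,z})$ and log ratios
$\mathcal N(\mu_{g,z}, \sigma^2)$ with $\sigma = 0.25$ at 30x, scaled by
$1/\sqrt{\text{coverage}}$. Two benchmark designs are built in:

* **Spike-in**: four deletions (DLOH) and four amplifications (GAIN)
  for each size in {10, 100, 1000} SNPs plus one 10,000-SNP deletion and
  amplification — 26 events — embedded in four otherwise diploid
  chromosomes (~150k SNPs) and alternately assigned to two clusters at
  tumor prevalences 0.52 and 0.39. The background normal proportion is
  0.25, a representative contamination chosen once (the corresponding
  real-data design mixes a tumor of unreported cellularity, so the
  scenario targets the two expected prevalences directly).
* **Serial mixtures**: two tumor samples of cellularity 0.67 and 0.56
  mixed at fractions $f$ and $1-f$; shared events are clonal (prevalence
  1), events unique to one sample sit at the prevalence given by the
  mixture arithmetic `expected_prevalences()`, and the normal proportion
  is $1 - \sum_i f_i c_i$. Default layout: 3 shared + 4 + 4 unique
  events of 400–600 SNPs over two 10,000-SNP chromosomes.

Because the simulator draws from the same emission family the model
fits, passing benchmarks demonstrates correct inference, segmentation
and selection machinery — not robustness to real-data pathologies
(wavy coverage, mapping artifacts, over-dispersed allele counts,
subclonal structure that violates the one-aberrant-genotype-per-locus
assumption). That boundary is intentional: the corresponding real-data
experiments mix actual read sets, which is out of scope here.

Problem sizes for the shipped benchmark suite were chosen to exercise
the full pipeline at realistic signal strength while completing a desk
run: ~150k SNPs for the spike-in (all four cluster numbers fit and
selected), nine 20k-SNP mixtures fit at the engineered three clusters,
and smaller simulations (thousands of SNPs) for the unit-level
recovery properties.

# Single-nucleus LOH classification

Targeted single-nucleus data carry allelic dropout: whole-genome
amplification can fail one allele at a heterozygous site, mimicking
LOH. Two tests are calibrated on the normal nuclei: the dropout rate
DOR (fraction of adequate-coverage known-heterozygous positions that
look homozygous: minor-allele fraction < 0.1 at depth >= 10) and the
heterozygous allelic-ratio reference HAR (pooled symmetric ratios of
the non-dropout positions; dropout positions are excluded because the
dropout process is handled by the binomial test and the reference
should represent the heterozygous signal). Per nucleus and event, a
one-tailed binomial test asks whether the homozygous-position count
exceeds DOR, and a rank-sum test compares the event's symmetric ratios
against HAR; the rank test is two-sided (identical distributions give
p near 1, and symmetric ratios can only shift upward under LOH, so the
two-sided test loses nothing). Both p-value families are
Benjamini-Hochberg adjusted across the whole nucleus-by-event batch,
and LOH requires the *maximum* of the two adjusted p-values below 0.05;
non-significant events with at least one heterozygous position are HET,
the rest unknown. Classification is invariant to input order.

# Numerical choices

* Forward–backward uses per-position scaling (implemented in C++); the
  log-likelihood is invariant to the scaling scheme and is checked
  against exhaustive path enumeration on small chains.
* Viterbi ties break toward the lower tuple index, making decodes
  deterministic.
* The M-step maximizes the expected complete-data log-posterior from
  per-tuple sufficient statistics; variance updates are closed-form
  (inverse-gamma MAP), the remaining parameters use bounded
  one-dimensional golden-section updates in two sweeps, each accepted
  only on improvement — EM monotonicity is asserted in the tests.
* Proportions are kept in [0.001, 0.999] so Beta priors stay finite.
* At $s_z = 1$ every genotype collapses to the neutral emission
  (non-identifiable by design); the fit tolerates such degenerate
  clusters and simply reports them at prevalence ~0.

# Known limitations

* One aberrant genotype per locus: coexisting subclones with different
  aberrations at the same position produce aggregate signals the model
  cannot decompose.
* Normal proportion is only set-identified without a clonal cluster
  (see above); reported $n$ then reflects the clonal-anchor convention.
* Amplification prevalences are harder to estimate than deletions (the
  log-ratio response flattens with copy number), mirroring the
  behaviour reported for this model class.
* Ten-SNP events sit at the detection limit at 30x: the per-event
  evidence (~a few log units) is comparable to the transition cost.
* The S\_Dbw selection can prefer an extra cluster when shared
  ancestral events form their own prevalence level; ties and
  near-ties resolve toward fewer clusters.
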