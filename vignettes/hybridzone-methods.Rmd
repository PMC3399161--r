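---
title: "Methods: classification, clonal structure, and niche tests in a cattail hybrid zone"
author: "typhaniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classification, clonal structure, and niche tests in a cattail hybrid zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(typhaniche)
```

This vignette is the package's account of its methods: what each stage
assumes, which knobs matter, what the synthetic-data generator does and does
not emulate, and where we made judgement calls.

## 1. Species and hybrid classification

Each ramet carries a six-locus codominant microsatellite genotype: an
unordered pair of integer allele sizes (base pairs) per locus, stored sorted
ascending. Allele identity is the fragment size as scored upstream; no
binning is applied here, because sizing and binning belong to the
fragment-calling stage that precedes this package.

Classification rests on a *diagnostic key*: per-locus sets of alleles
private to *T. latifolia* (species A) and to *T. angustifolia* (species B).
A locus scores `AA` when both alleles are private to A, `BB` when both are
private to B, `AB` when one comes from each species, and `ambiguous` when
any allele is absent from the key. The ramet-level rule is deterministic in
the evidence vector:

* `PURE_A` — `AA` at all six loci;
* `PURE_B` — `BB` at all six loci;
* `F1` — `AB` at all six loci (one allele from each parent everywhere);
* `UNRESOLVED` — any ambiguous locus;
* `LATER_GEN` — every other pattern (backcrosses and advanced
  intercrosses, pooled).

Two choices deserve comment. First, the key is an *input*, not a constant:
real keys are assembled from reference collections and can miss rare
alleles, which is why `UNRESOLVED` is a first-class category rather than an
error — silently pooling off-key ramets with `LATER_GEN` would fabricate
hybrids out of key gaps. Second, `LATER_GEN` is not subdivided into
backcross directions or F2s: with six dominant-information loci the
subclasses are not reliably separable, so we pool them and retain the
per-locus evidence matrix for users who want to subdivide.

Genotypes with any missing locus are removed before classification
(`drop_incomplete()`), mirroring the usual practice of excluding samples
that did not amplify across all loci; the removal report lists the dropped
ramets. Partially amplified loci are treated as missing — any missing locus
is grounds for exclusion.

### Ordination corroboration

The private-allele calls are corroborated with a principal coordinates
analysis of the pairwise Smouse–Peakall squared genotypic distance, the
standard codominant-genotype metric: per locus the squared distance is 0
(identical genotypes), 1 (one shared allele), 2 (heterozygotes sharing
none), 3 (homozygote vs a heterozygote sharing none), or 4 (opposite
homozygotes), summed over loci. This equals the squared Euclidean distance
between half-scaled allele-count vectors, so the matrix is embeddable and
the eigenvalues are non-negative; the decomposition itself is Gower double
centering + eigen-decomposition via `stats::cmdscale()`. Axis signs are
arbitrary, so `corroborate()` fixes the orientation by putting the
`PURE_A` mean on the negative side of axis 1 and then reports the fraction
of each class inside its band relative to a threshold (default 0.4, the
customary cutoff for this system). Variance-explained fractions are taken
over the positive eigenvalues.

## 2. Genets and genotypic richness

Cattail ramets are clones; treating them as independent would
pseudo-replicate every test. Within each site, ramets whose genotypes
differ by at most `max_mismatch` allele copies are linked and genets are
the connected components. Choices:

* **"Differing by one allele" counts allele copies, not loci.** The
  mismatch distance is the summed multiset difference of allele pairs per
  locus (0–12 over six diploid loci). A single mis-called allele copy —
  the canonical genotyping-error event — moves a ramet exactly distance 1
  from its clone-mates, which is what the default `max_mismatch = 1`
  absorbs.
* **Transitive closure.** Chains (A–B at distance 1, B–C at distance 1,
  A–C at 2) merge into one genet. Any non-transitive rule would make the
  partition depend on record order; connected components are the only
  order-free completion. Internally this is single-linkage clustering cut
  at the tolerance, which is identical to graph components at that
  threshold; the test suite checks it against an independent union-find
  brute force on random instances.
* **Genets never span sites**, because the error-tolerance argument is
  about repeated genotyping of the same local clone, and because
  cross-site identity of a multilocus genotype is better treated as a
  dispersal question than assumed away.
* **Canonical IDs.** A genet is labelled by the lexicographically smallest
  ramet ID it contains, prefixed by the site, making the whole assignment
  invariant to shuffling.

Genotypic richness per species per site is $R = (G-1)/(n-1)$: 0 when all
$n$ ramets are one clone, 1 when all are distinct. For $n = 1$ the index is
undefined (0/0) and is recorded as `NA`; such cells are excluded from
per-species means of $R$ but still enter the GLMM, whose response is the
$G$-of-$n$ count, not $R$. Per-species summaries are unweighted means over
sites with the standard error $\mathrm{sd}/\sqrt{\#\text{sites}}$.

## 3. Elevation standardization and the three tests

Shoot elevation is measured in integer millimetres (instrument scale) and
standardized by subtracting the per-site **median** elevation, computed on
all ramets of the site before any filtering — the median is a property of
the sampled stand, not of a species subset. Standardized values are
reported in cm. Medians use the usual midpoint convention for even $n$;
adding a constant to one site's elevations provably leaves its standardized
values unchanged, and the tests assert this exactly.

**Elevation LMM.** `fit_elevation_lmm()` fits, by REML via `nlme::lme`,

$$\text{elev}_{ijk} = \mu + \text{species}_i + \beta\,\text{height}_{ijk}
  + s_j + g_{jk} + \varepsilon_{ijk}$$

with random intercepts for site $s_j$ and genet-within-site $g_{jk}$. Only
`PURE_A`, `PURE_B`, and `F1` ramets enter; later-generation and unresolved
ramets are excluded from all three tests, since the question is about
species-level differences. Marginal F tests use nlme's containment
denominator degrees of freedom — species varies at the genet level, so the
denominator reflects the number of genets, not ramets, which is the
appropriate unit count for a genet-level predictor. The response defaults
to standardized elevation; a `response = "raw"` flag exists because
raw-vs-standardized is genuinely ambiguous in this design (the site random
intercept absorbs site level shifts either way), and the two give
essentially the same species test. Lineages with fewer than two ramets are
dropped with a warning; fits whose random-effect variance collapses to ~0
are flagged `singular`, not failed.

**Richness GLMM.** `fit_richness_glmm()` models $G$ successes of $n$
trials per (species, site) cell as binomial-logit with a site random
intercept (`lme4::glmer`), which is likelihood-equivalent to the weighted
ratio formulation but has a cleaner contract. The reference level is
`PURE_B` (*T. angustifolia*), so the Wald contrasts read
*T. angustifolia* vs *T. latifolia* and vs *T. × glauca*. With a single
site the model reduces to a plain binomial GLM.

**KS comparisons.** `ks_compare()` computes
$D = \max_t |\hat F_x(t) - \hat F_y(t)|$ by direct ECDF evaluation over the
pooled points, with the asymptotic two-sample p-value at effective size
$mn/(m+n)$. The statistic is implemented here (and cross-checked against
`stats::ks.test` in the tests) because $D$ on the pooled-point grid is the
quantity the distributional comparison is defined by; ties across samples —
rare at mm resolution but possible — trigger a warning since the asymptotic
p-value is then conservative. No multiple-testing correction is applied
anywhere; the report prints raw p-values.

## 4. The synthetic hybrid-zone generator

`simulate_community()` produces communities with known truth for every
stage: true lineage, true genet partition, and every elevation component.
Per site, genets are drawn from the lineage mixture and replicated into
ramets with genet size $1 + \mathrm{Poisson}(\text{clonality} - 1)$;
genotypes follow the genetic model (pure parents: two draws from their own
allele pool per locus; F1: one draw from each; later-generation: a
first-generation backcross with a 50/50 heterospecific/recurrent pattern
per locus). Two deliberate simplifications:

* Later-generation hybrids are **first-generation backcrosses only**, and
  their per-locus pattern is constrained to contain at least one
  heterospecific and one homospecific locus. Deeper pedigrees are not
  distinguishable by a private-allele key anyway, and the constraint makes
  the truth label recoverable — an unconstrained backcross has a ~3%
  chance of mimicking an F1 or a pure parent exactly, which would put an
  irreducible floor under classification error that is a property of the
  marker system, not of the code being validated.
* Genotyping error is a per-allele-copy replacement (probability
  `genotyping_error_rate`, default 0.005) by a different allele from the
  same locus's union pool — the single-miscall model the one-allele genet
  rule is designed to absorb.

Elevations are generated in cm as site effect (SD 25) + lineage offset
(default 0) + genet effect (SD 6) + residual (SD 10), then stored as
integer mm (rounded half away from zero) to match the measurement pipeline;
heights follow a linear model on elevation with slope 0 by default, since a
height–elevation association is plausible but not assumed. The whole
simulation is a deterministic function of the configuration, including its
seed.

`paper_scale_preset()` pins the study-scale conditions used for
validation: 18 sites × 13–17 ramets (~265 total), mixture
`PURE_A = 0.30, PURE_B = 0.20, F1 = 0.465, LATER_GEN = 0.035` (F1s most
common, later-generation hybrids rare), clonality 3 for the three species
(which places per-species mean $R$ in roughly 0.1–0.3), six fully
diagnostic loci with four private alleles per species each, and the null
elevation model. Allele frequencies are flat-Dirichlet draws within each
species pool; a `shared_fraction` knob adds alleles private to neither
species for stress-testing the `UNRESOLVED` path (the preset keeps it at 0,
a fully diagnostic key).

What the generator does **not** emulate: spatial transect geometry and
autocorrelation within sites, non-normal elevation microtopography,
population structure within species, allele-size homoplasy between the
species pools, null alleles and allelic dropout, and real key gaps. Passing
tests therefore show that the pipeline recovers truth under its own
statistical assumptions at field scale — not that those assumptions hold in
any particular wetland.

## 5. Validation design and problem sizes

The test suite validates each stage against an independent oracle:
classification against a brute-force rule table over all $4^6$ evidence
patterns; genet inference against a union-find brute force on 500 random
instances of up to 12 ramets (plus shuffle-invariance and monotonicity in
the tolerance); ordination against a hand-rolled double-centering
eigen-decomposition, with exact distance reconstruction; the KS statistic
against exhaustive ECDF evaluation on 200 random small samples; and the
richness endpoints $R = 0$ and $R = 1$ through the full inference path.
The mixed models are validated by simulation at the preset scale: 200 null
replicates for the type-I error of the species F test (the rejection rate
must sit inside the binomial 95% CI of 0.05), 200 replicates with lineage
offsets (−5, 0, +5) cm and residual SD 2 cm for power > 0.95, and 200
replicates with per-species genet fractions 0.3 vs 0.15 for sign recovery
of the GLMM contrast. These replicate counts keep the whole suite to a few
minutes while leaving the Monte-Carlo error well inside the asserted
margins.

## 6. Known limitations

* The classification rule is deterministic; no posterior assignment of
  hybrid classes (NewHybrids/STRUCTURE-style) is attempted, so a backcross
  that happens to look like an F1 at all six loci *is* an F1 to this
  pipeline.
* The genet rule's tolerance is a hard threshold, not a probabilistic
  model of error; with very high error rates, transitive chains can merge
  distinct genets.
* The containment denominator df is a convention; other df methods
  (Satterthwaite, Kenward–Roger) would give slightly different p-values in
  small samples, and the choice is exposed rather than hidden.
* The asymptotic KS p-value is approximate for small samples and
  conservative under ties.

```{r example}
sim <- simulate_community(paper_scale_preset(seed = 42))
fit <- hz_analyze(sim$collection, sim$key)
fit
```
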