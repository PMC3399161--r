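# typhaniche

Niche-segregation analysis for sympatric cattail (*Typha*) hybrid zones
from codominant microsatellite genotypes and shoot elevations.

## The problem

Broad-leaved cattail (*Typha latifolia*) and narrow-leaved cattail
(*T. angustifolia*) co-occur widely in North American wetlands, where they
hybridize to form *T. × glauca* — mostly F1s, with occasional backcrosses
and advanced intercrosses. A long-standing hypothesis holds that the
parental species (and perhaps the hybrid) partition sites along the
water-depth gradient, which would help maintain the species boundary.
Testing it requires three things done carefully:

1. **Species identity from molecular markers.** Morphology is unreliable in
   this complex, so each sampled shoot (ramet) is genotyped at six
   microsatellite (SSR) loci and classified from *private alleles* — alleles
   found in only one parental species. With a diagnostic key of per-locus
   private allele sets, a ramet carrying only *T. latifolia* alleles is pure
   *T. latifolia*; only *T. angustifolia* alleles, pure *T. angustifolia*;
   one allele from each species at **all six loci**, an F1; any other
   mixed pattern, a later-generation hybrid.
2. **Clonal structure.** Cattails spread by rhizomes, so ramets are not
   independent: ramets of the same *genet* (clone) share a multilocus
   genotype, up to genotyping error. Genotypes from the same site differing
   by at most one allele copy are treated as the same genet, and
   genotypic richness per species per site is
   *R* = (*G* − 1)/(*n* − 1), where *G* is the number of genets among *n*
   ramets (0 = monoclonal, 1 = all distinct).
3. **The elevation test.** Shoot elevation (a within-site proxy for water
   depth) is standardized by subtracting each site's median, then compared
   between lineages with (i) a linear mixed model — lineage fixed effect,
   shoot height covariate, site and genet-within-site random intercepts;
   (ii) a binomial GLMM on *G*-of-*n* genet counts (logit link, site random
   intercept) for diversity differences; and (iii) two-sample
   Kolmogorov–Smirnov comparisons of the standardized elevation
   distributions.

The package implements this whole pipeline — GenAlEx-style genotype I/O,
private-allele classification corroborated by a principal-coordinates
ordination of Smouse–Peakall genotypic distances, error-tolerant genet
inference, richness, and the three tests — plus a synthetic hybrid-zone
generator with known truth labels (species, genets, elevation effects) used
to validate every stage.

## Worked example

```r
library(typhaniche)

# a synthetic community at the scale of a typical field study:
# 18 sites, ~265 ramets, F1-dominated mixture, clonal replication,
# occasional single-allele genotyping errors, null elevation model
sim <- simulate_community(paper_scale_preset(seed = 42))
fit <- hz_analyze(sim$collection, sim$key)
summary(fit)
```

```
Hybrid-zone niche analysis
  ramets analysed: 267 (0 removed for missing loci)
  lineages: PURE_A=64 PURE_B=48 F1=143 LATER_GEN=12 UNRESOLVED=0 
  genets: 101 (max_mismatch = 1)
  elevation LMM species test: F_2,77 = 0.36, P = 0.702
  KS PURE_A_vs_PURE_B: D = 0.18, P = 0.356
  KS PURE_A_vs_F1: D = 0.11, P = 0.62

Richness per species (mean R +/- SE over sites):
  PURE_A: R = 0.19 +/- 0.05 SE (15 sites)
  PURE_B: R = 0.15 +/- 0.06 SE (9 sites)
  F1: R = 0.27 +/- 0.03 SE (17 sites)

Standardized elevations (cm):
  PURE_A: mean 0.7 cm (sd 10.8, n = 64)
  PURE_B: mean -1.4 cm (sd 12.3, n = 48)
  F1: mean -0.6 cm (sd 10.6, n = 143)

Genotypic-diversity binomial GLMM 
  T. angustifolia vs. T. latifolia: estimate = 0.286 +/- 0.394 SE, Wald Z = 0.73, P = 0.468
  T. angustifolia vs. T. x glauca: estimate = 0.071 +/- 0.348 SE, Wald Z = 0.20, P = 0.838
  note: site variance estimated at ~0

Ordination concordance (threshold 0.4): PURE_A=1.00 PURE_B=1.00 F1=0.97; axis 1 explains 23%
```

Reading this: `PURE_A` is *T. latifolia*, `PURE_B` is *T. angustifolia*,
`F1` is *T. × glauca*. The simulated community has no lineage elevation
offsets, and the analysis correctly finds none (LMM *P* = 0.70; both KS
tests non-significant); the one-allele-mismatch rule collapses the
error-split clones back to 101 genets; and the ordination places every
parental ramet on its own side of the ±0.4 band on axis 1.

To analyse real data instead, read a genotype table and a diagnostic key
(CSV layouts are documented in `?read_genotype_table` and
`?read_diagnostic_key`; a small synthetic example ships under
`inst/extdata/`):

```r
col <- read_genotype_table(system.file("extdata", "synthetic_genotypes.csv",
                                       package = "typhaniche"))
key <- read_diagnostic_key(system.file("extdata", "synthetic_key.csv",
                                       package = "typhaniche"))
fit <- hz_analyze(col, key)
```

`run_pipeline()` wraps the same analysis behind a YAML/list configuration
and writes a reproducible report bundle (tidy CSVs, `report.json`,
`report.md`, and a manifest with the seed and configuration checksum);
reruns with the same configuration are byte-identical.

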