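---
title: "Methods: combining-ability genetics and QTL mapping in gcamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining-ability genetics and QTL mapping in gcamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In hybrid crop breeding, the value of an inbred line is not its own (*per
se*) performance but its **general combining ability (GCA)** — the average
deviation of its hybrid progeny from the population mean — while **specific
combining ability (SCA)** captures the non-additive remainder of individual
crosses.  `gcamap` implements the full quantitative-genetic workflow for
dissecting GCA in a biparental recombinant inbred line (RIL) population
crossed to a small set of testers under the North Carolina Design II (NCII):
every line is crossed to every tester, hybrids and lines are evaluated in
multi-environment trials, and QTL are mapped both for line per se values and
for the lines' estimated GCA effects, then compared under explicit
co-localization rules.

Because field phenotypes for such experiments are rarely deposited, the
package ships a first-class generative model (`simulate_ril_genomes()`,
`simulate_phenotypes()`) whose defaults mirror a realistic maize experiment:
328 F11 RILs, 2 testers (656 hybrids), 2 locations x 2 years, 2 replicates,
a 10-chromosome map of roughly 1500 cM, and trait heritabilities in the
0.5-0.9 range.  Every downstream stage is therefore testable against known
truth.

## Genome and phenotype model

**Meiosis.**  Crossovers are a Poisson process on the centiMorgan scale
(mean `length/100` Morgans per chromosome) with no interference — the
Haldane model, so map distance `d` cM implies a single-meiosis
recombination fraction `r = (1 - exp(-2d/100))/2`.  RILs are produced by
single-seed descent: `generations - 1` rounds of selfing from the F1
(default F11).  Residual heterozygotes are retained, coded `Het`, and enter
all regressions with additive dosage 0.5; their expected frequency
`(1/2)^(generations-1)` is a tested invariant.  Between fixed lines, the
observed recombination fraction follows the Haldane-Waddington expansion
`r* = 2r/(1 + 2r)`.

**Physical coordinates.**  Simulated maps place markers uniformly in cM and
derive strictly increasing Mb positions through a smooth sinusoidal
distortion of a 1 cM ~ 1 Mb baseline.  This is deliberate: the QTL
comparison rules are stated in Mb (interval overlap, 20-Mb peak distance),
so the generator must produce a physical axis that is monotone in cM but
not trivially identical to it.

**Phenotypes.**  The per se model for line *i* in location *l*, year *y*,
replicate *r* is additive:

```
value = mu + sum_q a_q s_qi + env_ly + block_lyr + GL_il + GY_iy + GLY_ily + e
```

with `s_qi` in {-1, 0, +1} (signed genotype at QTL q) so that an additive
effect `a` is half the difference between homozygote classes — positive
values mean the male-parent (P2) allele raises the trait, matching the sign
convention of the reported `ADD` column.  Hybrid records use tester-specific
effects `a_q^(t)` plus a tester main effect; the line's **true GCA** is the
tester average of its testcross genetic value, centered over lines (it sums
to zero by construction and is returned as ground truth).  There is no
dominance or epistasis in the generative model: GCA-only architecture is
expressed through `a_q^(t)` with zero per se effect, and SCA through
between-tester differences in `a_q^(t)`.  Environment and block effects are
drawn once per location-year and per replicate-within-environment
respectively.

**Heritability targeting.**  Residual SDs may be given directly or solved
from a target heritability given the realized genetic variance
(`resid_sd_for_h2()`).  Two bases are supported and the distinction
matters.  The Knapp formula used throughout the estimation side,

```
H2 = s2_G / (s2_G + s2_GL/L + s2_GY/Y + s2_GLY/(LY) + s2_E/(LYR))
```

is an **entry-mean** heritability: it is also the squared expected
correlation between an entry mean and its genetic value, so the
true-vs-estimated GCA correlation can never exceed `sqrt(H2)` on this
basis.  A recovery requirement like "r >= 0.9 at testcross H2 = 0.6" is
therefore only attainable when the 0.6 refers to the **plot-level**
heritability (one observation), which over 2 testers x 4 environments x 2
replicates yields an entry-mean reliability near 0.96 and an expected
correlation near 0.98.  `trait_arch(h2_tc_basis = "plot")` selects that
reading; `contrast_architecture()` uses it by default for the testcross
side while keeping the per se target on the Knapp entry-mean basis.

**What the generator does not emulate.**  No genotyping error, no
segregation distortion, no missing-plot patterns, no spatial field trends,
no selection during line development, and no dominance.  A green recovery
test therefore establishes the correctness of the estimators under the
stated additive world, not robustness to those artefacts.

## Estimation

**BLUEs.**  Per-entry adjusted means come from fixed-effect least squares
of `value ~ entry + block`, where a block is one replicate within a
location-year cell (blocks absorb environment main effects).  Estimates are
reported on the grand-mean scale (entry effect plus the average block
contribution), so balanced data reduce exactly to arithmetic entry means;
unbalanced data are handled by the same normal equations.  A mixed-model
solver is intentionally not used: for the balanced and near-balanced designs
in scope, fixed-effect BLUEs coincide with the mixed-model line means, and
the closed-form path is testable against explicit design-matrix algebra.

**Variance components.**  Sums of squares for the genotype x location x
year factorial with blocks are computed by the Moebius (inclusion-exclusion)
identity over cell totals — exact for balanced data and orders of magnitude
faster than building the dense design matrix — and converted to
method-of-moments component estimates via expected mean squares.  Negative
solutions truncate to zero (standard practice; keeps `H2` in [0, 1]).
Components whose stratum has fewer than two levels are reported `NA` (not
estimable) and treated as zero inside the Knapp formula.

**GCA/SCA.**  On balanced data the estimators are the classical margins:
`GCA_k = xbar_k.. - xbar...`, `GCA_l = xbar_.l. - xbar...`,
`SCA_kl = xbar_kl. - GCA_k - GCA_l - xbar...`; unbalanced cells are
BLUE-adjusted before the margins are taken.  The NCII joint ANOVA estimates
variance components for lines, testers, SCA and all location/year
interactions (all random) by solving the triangular EMS system; the
reported ratio is line-side `s2_GCA / s2_SCA`, flagged undefined (rather
than infinite) when the SCA component truncates to zero.  The testcross
heritability applies the Knapp formula to the line-side components, with
SCA-by-environment terms and error additionally averaged over testers.
The per-line **GCA phenotype** used as the QTL-scan response is the line
margin of (BLUE-corrected) hybrid values, centered per dataset — one vector
per environment plus a joint vector.  Whether to pool testers was an open
choice; pooling is the default because it is the balanced-data GCA
estimator of the joint model.

## QTL mapping

Scans use **Haley-Knott regression** on expected genotype dosages rather
than EM interval mapping: for dense maps and nearly homozygous RILs the two
are practically identical, and the regression form is testable against an
exhaustive per-marker OLS oracle (an equivalence the suite checks to 1e-8).
Ancestry probabilities at markers and pseudomarkers (default 1-cM step)
come from a two-state forward-backward pass with RIL-scale stepwise
transition probabilities; observed `P1`/`P2` markers fix the state, `Het`
and `Missing` are uninformative, and a line missing a whole chromosome gets
0.5 everywhere on it.  The full HMM (rather than literal nearest-flanking
conditioning over total distance) was chosen because `r*` does not compose
over adjacent intervals; the two agree in all informative-flank cases, and
the HMM matches exact enumeration over the chain.

`LOD = (n/2) log10(RSS0/RSS1)`; zero-residual fits are capped at LOD 50 to
avoid infinities while preserving peak order.  **CIM** adds forward-stepwise
cofactor markers (default 3, ties broken toward the lower marker index) as
covariates, excluding any cofactor within 10 cM of the test position on the
same chromosome; with no cofactors it is exactly the plain scan.  Defaults
of 3 cofactors / 10 cM follow common CIM practice since the source analyses
do not state theirs; both are configurable.

**Thresholds.**  Genome-wide significance uses permutation of the response
over lines (>= 100 permutations; type-7 quantile of the max-LOD null
distribution).  One threshold is computed per response vector (trait x
dataset).  A fixed declaration threshold of LOD 3.0 — the conventional
value the original analyses adopted from 1000 permutations — is available
as an override and is the pipeline default (`n_perm = 0`).  At a realistic
scale (328 lines, 15.3 Morgans, dense map) the package's own
1000-permutation 5% threshold lands near 3.2, inside the expected 2.5-4.0
vicinity.

**QTL records.**  Peaks are local maxima above threshold, merged within
20 cM (keeping the higher LOD).  Support intervals use the 1.5-LOD drop
rule: the contiguous region within `drop` of the peak, expanded outward one
evaluated position on each side (the R/qtl `lodint` convention); `drop = 0`
is special-cased to the degenerate peak interval.  PVE comes from the joint
linear model on all peak dosages (model PVE = `100(1 - RSS_full/RSS_null)`,
per-QTL PVE by drop-one decrease in explained SS, near-collinear peaks
merged), and the signed additive effect is half the marginal dosage slope.
Names are auto-generated `q<TRAIT><chrom>-<ordinal>`.

## Comparison rules

Two QTL co-localize when they sit on the same chromosome and their physical
support intervals overlap (closed intervals) **or** their peaks lie within
20 Mb.  Environment consolidation keeps a locus only if it is detected in
two or more environments (clusters under the same rule) or appears in the
joint analysis; the representative record is the joint one when available,
else the highest-LOD environment record.  Per se versus GCA classification
labels consolidated loci `both` / `per-se-only` / `GCA-only`, with a
sign-concordance flag for shared loci.  Pleiotropy grouping takes the
transitive closure of pairwise matches across traits — chained overlaps
join one component even when the extremes do not match directly, a
deterministic and order-independent convention the sources leave open.

## Numerical and design choices

- All intervals are closed; cM positions are 0-based per chromosome, Mb
  positions 1-based physical.
- Mean marker spacing uses `total / (markers - chromosomes)` because
  spacing is undefined across chromosome breaks; the naive `total/markers`
  is also reported (for the published totals both round to 0.33 cM).
- Mean-spacing, probability-sum and zero-sum identities are enforced to
  1e-9; the scan/oracle equivalence to 1e-8.
- Sub-seeds for pipeline stages derive deterministically from the root seed
  (kept below 2^31), so stage re-runs and full runs agree and manifests are
  byte-identical across re-runs of the same configuration.
- Configs are JSON; tables are TSV with a one-line comment header (version,
  seed, config hash) and MD5 checksums in `manifest.tsv`.

## Known limitations

Single-trait scans only (no multi-QTL model search, no epistasis, no
binary traits); no REML/spatial models; no reciprocal or maternal effects;
no SCA QTL mapping; unbalanced designs are handled by least squares but the
EMS coefficients assume balance, so severe unbalance degrades the component
estimates (a warning is raised).  The acceptance-grade recovery claims are
statements about the stated simulation world at the stated sizes, not about
arbitrary field data.
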