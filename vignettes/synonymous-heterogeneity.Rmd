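---
title: "Diagnosing and filtering synonymous-site compositional heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing and filtering synonymous-site compositional heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degenphy)
```

## The problem

In multi-gene protein-coding data sets spanning deep divergences, third
codon positions (and the synonymously variable first positions of leucine
and arginine codons) evolve fast enough to saturate, and their base
composition — conveniently summarized by GC3, the G+C content at third
positions — often drifts apart among lineages. Substitution models such as
GTR+Γ+I assume compositional stationarity, so a lineage with strongly
divergent synonymous-site composition can be pulled away from its true
relatives and toward compositionally similar but unrelated taxa. The
nonsynonymous signal, carried by the remaining sites, is typically far
cleaner at depth.

`degenphy` implements a diagnostic-and-filter workflow around this
phenomenon:

1. **Character treatments.** A codon supermatrix can be recoded as
   `nt123` (identity), codon-position subsets (`nt1`, `nt2`, `nt3`),
   amino acids (`aa`), the mostly-nonsynonymous / mostly-synonymous
   partition halves `noLRall1_nt2` and `LRall1_nt3`, and **degen1**, which
   replaces every codon by the fully degenerate IUPAC triplet of its
   synonymous family and thereby erases all synonymous signal.
2. **Composition diagnostics.** Per-taxon nucleotide composition tables,
   an R×C chi-square test of among-taxon homogeneity, and Euclidean
   distances between the taxa's composition vectors (which reflect
   composition only).
3. **Distance trees.** Neighbor-joining on GTR maximum-likelihood
   distances (affected by both history and composition) versus on the
   compositional distances (affected by composition only), with
   site- or codon-unit bootstrap support, compared across taxon-by-gene
   sampling designs.
4. **Topology tests.** Site log-likelihoods under GTR+Γ(+I) by the pruning
   algorithm, branch-length optimization, and the approximately unbiased
   (AU) test via multiscale RELL bootstrap for constrained versus
   unconstrained topologies.
5. **A ground-truth simulator** that generates codon alignments in which
   the strength and location of compositional heterogeneity is known
   exactly.

## The degen1 recoding

A *synonymous family* is a set of sense codons interconvertible by chains
of single-nucleotide synonymous substitutions. Under the standard code
this yields 21 families: one per amino acid, except that serine's two
codon blocks (TCN and AGY) form two separate families — no single
synonymous change connects them — while leucine's blocks (TTR and CTN)
and arginine's (CGN and AGR) each merge through synonymous first-position
changes. Every codon maps to the positionwise IUPAC cover of its family:

```{r degen-table}
head(subset(degen1_table(), amino_acid %in% c("L", "R", "S", "M")), 16)
```

Two consequences matter. First, two sequences that differ only by
synonymous substitutions recode identically, so degen1 pairwise
differences are purely nonsynonymous. Second, the leucine and arginine
covers (`YTN`, `MGN`) also match codons of other families; the package's
translation therefore resolves family covers by lookup, keeping
translation and recoding consistent. In-frame stop codons indicate an
upstream error and recode to `NNN` with a warning. Codons containing `?`,
`-` or ambiguity codes are expanded to their compatible sense codons;
determinable positions are degenerated and undeterminable positions become
`N`.

The implementation derives families from the genetic-code table
(selectable by code id); the test suite re-derives the mapping with an
independent graph-connectivity oracle and checks, exhaustively over the 61
sense codons, that single-step synonymous neighbors recode identically,
that translation is preserved, and that recoding is idempotent.

## Composition tests

Counts include unambiguous A/C/G/T only; ambiguity codes, `?` and `-` are
excluded entirely (no fractional allocation). The chi-square statistic is
the standard contingency value with df = (taxa − 1) × 3 and an upper-tail
p-value; expected cells below 5 raise a validity flag rather than an
error, mirroring the conventional whole-table test. "Eliminating
invariable sites in the degen1 data set" is implemented as a reusable
column mask: a column is invariable when the degen1-recoded symbols of the
taxa with data there are all identical (no nonsynonymous variation); the
mask transfers to any character set through its source-column mapping.

The chi-square compares taxa as if they were independent multinomial
samples. Under a homogeneous stationary process the test is calibrated on
independent count tables (the suite verifies the 5% level against the
exact binomial interval over 1,000 simulated tables); on phylogenetically
correlated data it tends to be conservative, which is the safe direction
for a heterogeneity alarm.

## Distances, neighbor joining, bootstrap

GTR maximum-likelihood distances use a *shared* parameterization:
equilibrium frequencies are the matrix-wide empirical frequencies, and the
six exchangeabilities maximize the sum of pairwise log-likelihoods
(composite likelihood) with each pair's branch length profiled out. Only
the per-pair branch length is then re-optimized per pair. This stabilizes
sparse pairs under block-missing designs. Saturated pairs are capped at
t_max = 10 substitutions/site and flagged. In the equal-frequency,
equal-rate case the distance reduces to the JC69 closed form (verified to
1e−6).

Neighbor joining is the standard Q-criterion agglomeration with two-point
branch-length formulas; taxa are processed in lexicographic order with
lowest-index tie-breaking, so results are deterministic; negative branch
estimates are clamped to zero without redistribution. On additive
matrices the algorithm is exact (RF = 0, branch lengths to 1e−9 over 100
random 8-taxon trees in the suite).

Bootstrap resampling draws sites, or whole codons for codon-structured
treatments (degen1, nt123), with replacement to the original width; model
parameters are estimated once on the original matrix and replicates
re-estimate distances only. Support is the percentage of replicate trees
containing each internal bipartition of the reference tree. The verbal
scale — 70–79% moderate, 80–89% strong, ≥90% very strong — is exposed via
`support_category()`.

## Likelihoods and the AU test

Site log-likelihoods use Felsenstein pruning over compressed site
patterns with per-pattern scaling; ambiguity codes are partial state
sets. Discrete-Γ uses median-of-bin rates renormalized to mean 1
(phangorn and PAUP* use mean-of-bin, so Γ log-likelihoods differ slightly
across programs by construction; the plain-GTR case matches phangorn to
1e−6 and the exhaustive-enumeration oracle to 1e−10). The
proportion-invariable mixture adds `p_inv` times the constant-pattern
probability. Branch-length optimization profiles each branch against
inside and outside partial likelihoods, accepting a simultaneous sweep
only when the total log-likelihood improves and falling back to strict
coordinate ascent otherwise; the reported log-likelihood is
non-decreasing, with a warning after 50 cycles.

The AU test follows the multiscale-bootstrap recipe: RELL resampling at
ten scale factors (0.5–1.4), `round(r·n)` sites per replicate, ties split
equally; the probit-transformed winning proportions are fitted by
weighted least squares to z(r) = d·√r + c/√r, and
p_AU = P(Z > d − c). Scales with proportions exactly 0 or 1 are excluded
from the fit; with fewer than two usable scales the degenerate path
returns 0 or 1 outright (a tree that never or always wins). Proportions
and p-values are bit-reproducible from (seed, scales, reps). Identical
candidate topologies are deduplicated before scoring, so pooled
constrained/unconstrained sets are tested once per distinct topology.
Candidate sets for constrained tests are, by default, the NJ tree plus
its one-step NNI neighborhood — a deliberate desk-scale substitute for
heuristic ML search; on five-taxon data the constrained choice matches
exhaustive search over all 15 topologies in the suite.

## The simulator and what it emulates

`simulate_supermatrix()` runs a two-layer codon process along a tree:

- **Layer 1 (nonsynonymous):** per codon, amino-acid replacement events
  are Poisson with rate `nonsyn_rate` per unit branch length; the jump
  chain is uniform over the other 19 residues. This layer carries clean
  tree signal.
- **Layer 2 (synonymous):** per codon, resampling events are Poisson with
  rate `syn_rate`; each event redraws the codon within its *current
  synonymous family* (chains of single-site synonymous changes never
  leave the family, so a TCN serine codon cannot become AGY), from the
  lineage's codon-usage distribution, tilted so that the *expected* GC3
  of a freshly drawn codon equals the lineage's target. A nonsynonymous
  event chooses freely among the new amino acid's families.
  The tilt weights each synonymously variable position by g (G/C) or
  1 − g (A/T), and the effective g solves the expected-GC3 equation for
  the target — methionine and tryptophan fix their third position, so
  targets outside the code's reachable range raise a configuration error.

Per-taxon GC3 targets come in three tiers: a shared `base_gc3`, optional
per-taxon background overrides (`gc3_targets`, applied on terminal
branches), and `shifted_taxa` whose subtending branches use
`shifted_gc3`. Realized GC3 converges to the target as codons accumulate
(checked at 3,000 codons to within 0.02). Simulated sequences contain no
in-frame stops by construction, and identical configuration plus seed
reproduces byte-identical output; per-gene substreams are derived
deterministically from the root seed.

The simulator deliberately omits realistic codon models (GY94/MG94),
indels, and within-gene rate heterogeneity: layer 1 only needs to carry
resolvable tree signal, and layer 2 directly controls the quantity the
diagnostics measure (GC3), rather than inducing it indirectly through a
mutation-bias substitution model. Passing tests therefore demonstrate the
*mechanism* — synonymous compositional attraction and its removal by
degen1 — not model adequacy for any particular empirical data set.

## The rogue-taxon benchmark

The `rogue_taxon` preset encodes the study conditions used throughout the
acceptance checks: 12 taxa, 6 genes totalling 3,000 codons (9,000 bp,
within the multi-kilobase range of real multi-gene matrices), a fixed
truth tree with radiation-like internal branches (0.015 amino-acid
replacements/site), ordinary terminals (0.1), a deep outgroup stem (0.5),
and one nested fast-evolving taxon `ROGUE` (terminal 0.3) whose branch
carries an extreme GC3 target of 0.9 against a 0.4 background;
`syn_rate = 20` saturates third positions (synonymous events account for
roughly 90% of all changes, as in deep insect data sets). The background
is not perfectly homogeneous: three taxa carry moderate GC3 targets
(0.75, 0.65, 0.3), emulating the lineage-to-lineage GC3 variation that
compositional chi-square tests detect in real data even outside the focal
taxon.

That background variation is load-bearing. A *single* compositional
outlier against a perfectly homogeneous background inflates its distance
row almost uniformly — which is additive-compatible, so neighbor joining
simply lengthens its terminal branch and keeps the placement. Misplacement
arises from compositional *attraction*: the rogue's third-position states
match elevated-GC background lineages more often than its true sister,
and with short internodes this systematic bias outweighs the genuine
signal. Because the bias is systematic, adding sequence does not rescue
the nt123 tree — but it does shrink the noise in the degen1 tree, whose
signal is purely nonsynonymous. At the preset's settings the degen1
GTR-distance NJ tree recovers the true topology and the nt123
GTR-distance NJ tree misplaces the rogue in the large majority of seeds,
while the composition chi-square rejects on nt3 (p < 0.001) and does not
reject on noLRall1+nt2 — the same three-way pattern the diagnostics are
designed to reveal. degen1 trees use GTR-ML distances estimated on the
recoded matrix (multiple-hit corrected); a plain p-distance variant is
available but more prone to long-branch artifacts.

The `design_abcd` preset provides the four taxon-by-gene sampling masks
(taxon subset × gene subset, taxon subset × all genes, all taxa × gene
subset, and their union with its missing block) on a homogeneous
20-taxon, 8-gene matrix, for studying support across designs;
`homogeneous_null` provides the no-shift calibration case.

## Numerical and reporting choices

- Coordinates are half-open and 0-based internally; NEXUS charsets are
  rendered 1-based inclusive only at serialization.
- `?` means unsequenced, `-` alignment gap; `missing_fraction()` counts
  `?` by default with a flag for gaps.
- Taxon order after concatenation is lexicographic; all tie-breaks
  (NJ joins, RELL ties) are documented and deterministic.
- Bootstrap default is 200 replicates (support standard errors ≈ 3.5% at
  worst), AU default 10,000 RELL replicates per scale; the pipeline's
  desk-scale defaults use fewer and are overridable.
- Support cells below 50% print as `"<50"`; clades with fewer than two
  sampled taxa in a design print as `"N/A"`.

## Limitations

- The chi-square treats taxa as independent samples; its p-values on real
  (phylogenetically correlated) data are approximate.
- The AU implementation follows the standard two-parameter (signed
  distance, curvature) fit; p-values from very small candidate sets, or
  from trees at the boundary of the bootstrap simplex, rely on the
  degenerate-path conventions above.
- Heuristic ML tree search is out of scope by design; NJ plus the NNI
  neighborhood stands in for it at desk scale, and conclusions about
  support should be read accordingly.
- The GTR distance uses shared composite-likelihood parameters; per-pair
  frequency estimation (a documented alternative) may behave differently
  under extreme heterogeneity.
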