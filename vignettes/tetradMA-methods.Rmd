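---
title: "Modelling mutation accumulation under intra-tetrad mating"
author: "tetradMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mutation accumulation under intra-tetrad mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradMA)
```

## The experimental system

Diploid, homothallic *Saccharomyces cerevisiae* mutation accumulation (MA)
lines come in two designs. Vegetative ("B") lines are bottlenecked to a single
cell every ~20 mitotic divisions, 87 times (~1740 generations): new base
substitutions arise heterozygous and stay heterozygous, because there is no
sexual cycle. Meiotic ("T") lines interleave the same 20-division growth
phases with a meiosis: a single complete tetrad is carried through each of 50
bottlenecks (~1000 vegetative plus 50 meiotic divisions), and the germinating
spores re-diploidise either by mating with another spore of the same tetrad
(inter-spore mating) or by HO-mediated mating-type switching of a single spore
lineage (self-mating). Both routes are intense inbreeding, and they decide the
fate of every segregating mutation. `tetradMA` implements the genetics of that
decision exactly, wraps it in a forward Monte-Carlo simulator of the two
bottleneck regimens, and provides the rate estimators and assay analyses that
sit on top.

## Fate of a mutation at one meiotic bottleneck

A mutation heterozygous in the diploid entering meiosis segregates 2:2: two of
the four spores carry it. Because the tracked loci are unlinked to *MAT*,
every subset of carrier spores is equally likely. `enumerateMatingOutcomes()`
enumerates all carrier placements and all legal matings with integer counting
(exact rational probabilities): under pure inter-spore mating a 2:2 mutation
is fixed with probability 1/6, stays heterozygous with probability 2/3 and is
lost with probability 1/6; a self-mated spore resolves it immediately, fixed
or lost with equal odds. Mixing with self-mating fraction $s$ gives the closed
forms in `analyticFateProbs()`:

$$P_H = (1-s)\tfrac{2}{3},\qquad P_F = P_L = \tfrac{s}{2} + \tfrac{1-s}{6}
\qquad (\text{2 carrier spores}),$$

$$P_F = \tfrac{s}{4},\qquad P_H = \tfrac{1-s}{2},\qquad
P_L = \tfrac{3s}{4} + \tfrac{1-s}{2} \qquad (\text{1 carrier spore}).$$

The single-carrier forms (a mutation arising during or after meiotic
replication, present on one chromatid) are derived by the enumeration oracle,
not read from a published equation; the test suite proves the closed forms
equal the enumeration mixture at every $s$, and that drawing one of the four
MATa × MATα pairs is equivalent to drawing any two distinct spores — a
consequence of *MAT*-independence that the implementation is free to exploit.

Iterating $P_H$ gives the resolution law `fixOrLossProbAfterN()`:
$1-((1-s)\cdot 2/3)^n$. At the observed $s = 0.17$ a heterozygous mutation
has a >99% probability of being fixed or lost within nine meiotic
bottlenecks — the mechanism behind every T-line mutation being homozygous.

```{r fate}
analyticFateProbs(2, s = 0.17)
fixOrLossProbAfterN(9, s = 0.17)
```

## The forward simulator

`simulateEnsemble()` runs replicate lines under a `SimConfig`. Per bottleneck:
a Poisson$(20\,m\,G)$ number of new heterozygous mutations from the mitotic
phase (rate $m$ per base per division, diploid genome $G = 24{,}483{,}546$
bp), a Poisson$(\mu G)$ number of meiotic mutations, one mating-mode draw
(self with probability $s$), and independent resolution of every segregating
mutation with the exact conditional distributions above. Two timing scenarios
are modelled: *pre-replication* meiotic mutations sit on two chromatids
(carriage 2, resolved like standing heterozygotes, immediate fixation
probability 0.223 at $s=0.17$), *post-replication* mutations on one chromatid
(carriage 1, immediate fixation probability $s/4 = 0.0425$; "one strand" is
treated as one chromatid, ignoring half-strand resolution at the spore's
first division). Survivors of either kind are ordinary heterozygotes at the
next meiosis.

Choices worth stating:

* **Poisson counts.** The sources describe "a random number of base
  substitutions given the rate"; Poisson is the standard thinning of a
  per-base Bernoulli process at rates of $10^{-10}$.
* **Counts, not sequences.** Mutations are mutually unlinked and carry no
  positions in the simulator; the synthetic mutation tables decorate counts
  with positions afterwards, and those positions are cosmetic.
* **No selection.** The lines showed no viability loss; all mutations are
  neutral.
* **Independent vs joint resolution.** By default mutations resolve
  independently given the shared mating-mode draw (vectorised across
  replicates). A stricter `matingModel = "joint"` simulates explicit carrier
  spore subsets and one shared mated pair per bottleneck, with one derived RNG
  substream per replicate. For unlinked mutations the two are statistically
  indistinguishable, which the tests check on both scenarios.
* **Meioses are charged only at rate $\mu$**; no extra mitotic-rate mutations
  are added for the meiotic division itself.
* **Conservation is tracked**: every replicate satisfies
  generated = fixed + heterozygous + lost, and the class validity methods
  enforce it.

Because fates are independent thinnings of Poisson inputs, the final
homozygous count of a replicate is itself exactly Poisson; its mean has a
closed form that the test suite uses as an independent oracle (~3.46 at
$\mu = 0$ with defaults; 3.55 at $s = 1$).

```{r sim}
ens <- simulateEnsemble(simConfigNew(nReplicates = 2000, seed = 1))
mean(finalHom(ens))
ensemblePValue(ens, observedHom = 5)
```

## Rate estimators and the meiotic-rate upper limit

`vegetativeRateFromSpore()` doubles the count of a single sequenced spore
clone (half the diploid genome observed), `vegetativeRateFromDiploid()`
applies no correction, and `meioticLineRate()` doubles the homozygous count of
a T line because intra-tetrad mating purges half of the vegetative-phase
mutations. The raw genome size is the denominator: reproducing the reported
two-significant-figure rates (3.8, 2.8, 2.0, 3.9 × 10⁻¹⁰) requires *not*
dividing by the 96% callable fraction, which is exposed as an optional
`coverage` argument instead. The reported average 2.9 × 10⁻¹⁰ is the mean of
the *rounded* per-line rates ((3.8 + 2.8 + 2.0)/3 = 2.87); the full-precision
mean is 2.845 × 10⁻¹⁰, which would display as 2.8. `averageRate(..., sigfigs
= 2)` reproduces the printed arithmetic; the default reproduces the
full-precision mean. With zero 1–2 nt in-dels observed, `indelRateBound()`
turns the 154,850 homopolymeric tracts and 1740 generations into the bound
1/(154850 × 1740) < 3.7 × 10⁻⁹ per tract per division.

`scanUpperLimit()` asks how large the meiotic rate $\mu$ could be and still be
consistent with the observed 5 homozygous substitutions per T line: for each
multiplier on a grid (default 0–100 in steps of 5, refined to step 1 around
the crossing) it simulates an ensemble and computes the inclusive lower-tail
empirical P-value, `ensemblePValue()`. A multiplier is inconsistent when
P < 0.05.

**A known, deliberate discrepancy.** Under this package's stated world the
final homozygous count is Poisson with mean $3.46 + 0.173\,f$
(pre-replication) or $3.46 + 0.0855\,f$ (post-replication) at multiplier $f$,
and $P(X \le 5) < 0.05$ first happens near mean 10.5 — i.e. at ~41-fold
(pre-replication) and ~82-fold (post-replication). The original study printed
30-fold and ~55-fold for the same construction; its exact simulation
internals (grid, count definition) are not recoverable, and no parameter here
was adjusted to chase the printed thresholds. The package therefore treats
the printed values as approximate targets and backs the scan with properties
that must hold regardless: P-values monotone in $\mu$, ensemble means within
3 SE of the closed-form oracle, conservation in every replicate, and a
strictly higher consistency threshold for post- than for pre-replication
mutations.

## The mating assay and its crossover correction

Diploids from germinated tetrads of a strain carrying *kanMX* and *natMX* on
opposite homologs next to *MAT* are classified by `classifyDiploid()`: doubly
drug-resistant means inter-spore mating, singly resistant means self-mating
(resistance to neither flags an assay failure, not a mating class).
`pooledFrequencies()` pools colonies across scoring methods; with the
published per-method tallies this gives 82% inter-spore / 18% self. The
per-method table prints percentages rather than counts, so the bundled
fixture reconstructs counts (168/32 of 200; 115/30 of 145) — a one-unit
rounding assumption on the second method.

A single crossover between marker and *MAT* (1.0 cM, `perkinsDistance()` on
PD/TT/NPD counts: $50(TT + 6\,NPD)/(PD+TT+NPD)$) can leave both mated spores
with the same marker, mis-scoring an inter-spore mating as self. With
per-spore recombination frequency $Rf$ the tetratype frequency is $2\,Rf$ and
half of the four MATa × MATα pairings in a tetratype are same-marker, so the
misclassification probability per inter-spore mating is $q = Rf$. The
correction solves $f_{\text{self}}^{\text{obs}} = s + (1-s)q$ for $s$
(`correctMatingFrequencies()`); the correction algebra was not published, and
this model is adopted because it reproduces the published revision 82/18 →
83/17 at $Rf = 0.01$. Observed self fractions at or below the floor $q$
return $s = 0$ with a warning. `generateMatingAssay()` is the matching
forward model, and the round trip recovers the true $s$ within binomial
error.

```{r assay}
tab <- readMatingAssay(system.file("extdata", "mating_assay.tsv",
                                   package = "tetradMA"))
pooledFrequencies(tab)[c("percentInter", "percentSelf")]
correctedFrequencies(tab, rf = 0.01)[c("percentInter", "percentSelf")]
```

## Synthetic data: what it does and does not establish

The generators (`generateMutationTable()`, `generateMatingAssay()`,
`generateTetradClasses()`) are deterministic given a `SyntheticTruth` and
emulate the three input-table shapes with known ground truth, so every
estimator can be tested by parameter recovery without any external data.
Defaults are the study's stated world: $m = 2.9\times10^{-10}$, $s = 0.17$,
$Rf = 0.01$ (1.0 cM). Mutation-table positions use 16 fixed plausible
chromosome lengths (~12.1 Mb haploid) and a substitution spectrum biased
toward A-T, matching the pooled observed spectrum; both are decorative for
the count-based analyses and carry no linkage — green tests establish the
count dynamics and the estimator algebra, not anything about genomic
placement, spectra, structural variation or sequencing error, all of which
are out of scope. Tetrad classes default to the single-crossover regime
(tetratype probability $cm/50$, NPD = 0, appropriate at ≤ ~10 cM); a
non-zero-NPD variant preserving the Perkins expectation is available for
testing the estimator.

## Numerical and interface conventions

Enumeration outputs are exact (integer counting); closed forms are checked to
1e-12. Empirical P-values use the inclusive comparison (simulated ≤
observed). Stochastic tests use fixed seeds and 3-standard-error tolerances;
ensembles in the test suite are scaled down (10³–10⁴ replicates) relative to
the 10,000-replicate analysis scale to keep runtimes short. Tables travel as
TSV with headers (1-based coordinates), configs and reports as JSON; every
command wrapper (`cmdSimulate()`, `cmdScan()`, `cmdRates()`, `cmdMating()`)
writes a manifest recording command, config, seed and package version, and a
thin Rscript dispatcher over the same functions is installed under
`inst/scripts/tetradma.R`. Display rounding follows the sources: rates to two
significant figures, assay percentages to whole percent.

## Known limitations

* The simulator is count-based: no positions, linkage, gene conversion,
  structural variants, aneuploidy or mitochondrial genome.
* The crossover-correction model ($q = Rf$) is a reconstruction; a
  tetrad-count-based correction could differ in the third decimal.
* The scan's consistency thresholds depend on the Poisson/independence
  modelling choices; see the discrepancy note above.
* Within-colony drift during the 20-division growth phases is not modelled;
  the bottlenecked lineage is treated as a single cell line.
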