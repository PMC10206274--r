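---
title: "Simulating long-term genomic selection in a layer breeding programme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating long-term genomic selection in a layer breeding programme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Closed-nucleus layer chicken breeding programmes select intensely: about
1,080 dams and 40–120 sires are chosen from 14,040 candidates every cycle.
Genomic selection raises the rate of gain — young males can be selected at
half a year of age on genomic breeding values — but genetic gain is paid for
with genetic variance. `ocsim` simulates 30-year programmes to quantify that
trade-off and to evaluate optimal contribution selection (OCS) as a way to
manage it. Five selection regimes are built in: conventional truncation on
pedigree BLUP (PTS), genomic truncation on single-step GBLUP (GTS), GTS with
minimum-progeny-inbreeding mate allocation (GTSMF), genomic OCS at a fixed
sire count (GOCS), OCS with a free sire count in a 20–200 window (UGOCS),
and a random-selection control (RANDOM) used to validate effective
population size estimates.

## The simulated world

**Genome.** 39 equal autosomes, 30 Morgans and 1.2 Gb in total,
recombination rate 2.5e-8 per bp. 2,250 segregating sites are retained per
chromosome (87,750 genome-wide) and partitioned at random into 250 QTL,
1,000 SNP markers, and 1,000 neutral monitoring loci per chromosome, with no
overlap.

**Founders.** 2,500 base individuals are drawn from a neutral coalescent
with a piecewise-constant effective size declining from 500,000 at about one
million generations ago to 100 recently. Only the endpoints of this
decline are fixed; the default interpolates log-linearly through
`{0: 100, 1e4: 1e3, 1e5: 1e4, 1e6: 5e5}`; the anchor grid is configurable.
Each retained site carries one mutation placed proportionally to branch
length, so every site segregates and the site-frequency spectrum is the
rare-variant-heavy spectrum this demography implies. Two deliberate
simplifications: sites are simulated independently (no base-population LD —
linkage disequilibrium then accumulates during the ten burn-in years from
drift and selection on linked loci), and mutation is absent after the base
population.

**Traits.** Three purely additive egg-production traits (early/mid/late)
with base heritabilities 0.18/0.22/0.25 at phenotypic variance 1, genetic
correlations 0.75 (T1–T2), 0.70 (T2–T3), 0.60 (T1–T3), and exactly zero
residual covariances. QTL effects are drawn multivariate normal and then
linearly rescaled so the founder genic covariance `2 Σ p(1-p) α α'` equals
the target matrix exactly. Selection acts on an index with weights
0.20/0.35/0.45.

**Phenotyping schedule.** Only females are recorded. Early and mid
production (25 and 52 weeks) are available when a female is a selection
candidate; late production (~100 weeks) is recorded only for selected dams
and enters the data `t3_lag = 1` year after selection (the measurement age
pins down when the trait is recorded, not when the record reaches the
evaluation, so the lag is configurable).

## The year cycle

A conventional year runs one evaluation–selection–mating round: candidates
are one year old, dams have two phenotypes, and the realized generation
interval is exactly 1.00 year. Genomic programmes run two rounds per year:
sires are selected among half-year-old genotyped males without phenotypes,
dams among one-year-old females, giving L = (0.5 + 1.0)/2 = 0.75 years.
The half-year bookkeeping at the burn-in/evaluation transition admits more
than one reading; this scheduler's interpretation is that
the first genomic round falls back to the youngest eligible cohort (so one
transition cohort has parental ages 1.0/1.5), and steady state — every
cohort at 0.75 — is reached one year later. Reported generation intervals
exclude the transition year.

**Genotyping policy.** Each genomic evaluation sees the 4,320 current male
candidates plus the selected sires and dams of the previous four selection
rounds — at most 8,800 genotypes with 40 sires and 9,120 with 120. Burn-in
parents are never genotyped retroactively; the policy intersects past
parents with the genotype bank, so the cap fills over the first four
genomic rounds.

## Breeding-value estimation

A three-trait animal model `y_t = X_t b_t + Z_t a_t + e_t` with one overall
mean per trait, diagonal residual covariance, `Var(a) = G0 ⊗ K`, and
variance components fixed at the base-population values. `K` is the pedigree
relationship A (conventional) or the single-step H (genomic). The equations
are solved directly with a sparse supernodal Cholesky factorisation; animals
outside the ancestor closure of the data and candidate sets are pruned, an
exact reduction. The genomic block uses
`H^{-1} = A^{-1} + [0 0; 0 Gb^{-1} − A22^{-1}]`, where `Gb` is the marker
matrix `G = WW'/(2Σp(1−p))` (observed frequencies) tuned to the A22 base by
matching mean diagonal and mean off-diagonal, blended `0.95 G + 0.05 A22`,
plus a 1e-6 ridge. Tuning matters: without it the genotyped males and
non-genotyped females sit on different bases and pooled candidate accuracy
collapses; blend, ridge and tuning are all arguments of `solve_mme()`. Note
the widely printed simplified form `H = A + [0 0; 0 G − A22]` (implemented
literally by `build_H()`) is not the matrix whose inverse appears in the
equations; the inverse identity is used, as in single-step practice.

## Optimal contributions and the penalty frontier

Contributions are integer mating counts on the male side (a dam is one
mating), so any solution converts directly into a mating plan. The 1,080
dams are fixed at equal contributions by prior truncation selection; the
male-side optimization still sees the full candidate relationship matrix
(male–male, male–female, female–female), which is how the female selection
is accounted for. Group coancestry uses the pedigree A, and
`ΔC = (c̄_{t+1} − c̄_t)/(1 − c̄_t)` with `c̄_{t+1} = x'Ax`,
`c̄_t = 1'A1/(4m²)`, `Ne = 1/(2ΔC)`.

The gain/diversity balance is parameterised by trigonometric penalty degrees
between two endpoints. The mate-selection tools that introduced this
parameterisation do not publish its algebra, so this package uses an
operational construction, stated here as such: gain
and coancestry are rescaled to [0, 1] between the endpoints, a solution's
angle is `atan2(normalized coancestry reduction, normalized gain)`, and the
fitness is the projection onto the target direction minus a penalty of 5 per
90 degrees of angular deviation, with solutions outside the endpoint box
rejected. The 0-degree endpoint is the *truncation* solution (top sires at
equal quotas; the window minimum for UGOCS) — operationally, 0 degrees *is*
truncation selection, and this choice, rather than the
unconstrained argmax of `x'a` (which would pile matings on one sire up to
the 0.5 bound), makes the frontier start where the comparison programmes
stand. The 90-degree endpoint minimizes `x'Ax` alone. Optimization is a
seeded (mu+lambda) evolutionary algorithm over count vectors (transfer,
swap, and support-size mutations; count-mixing crossover; infeasible sire
counts rejected outright). Mate pairing after OCS is random; GTSMF instead
keeps truncation selection and minimizes mean pair coancestry by a seeded
hill-climb over dam swaps.

## Metrics

All series are normalized to the last burn-in year (mean genetic value 0,
SD 1), so gains are in year-10 genetic SD units. Genic variance is
`2 Σ p(1−p) α²` at the current QTL frequencies — the variance without
linkage-disequilibrium (Bulmer) contributions. Conversion efficiency is the
OLS slope of gain on lost genic SD over all evaluation-phase cohorts
(intercept free; the slope is the reported quantity), with `extrapolate_gain()` projecting to 50% or 100% of
genic variance lost. Genomic inbreeding is `F_t = 1 − Ho_t` per loci class
(QTL, SNP, neutral) over each newborn candidate cohort; pedigree F uses the
Meuwissen–Luo algorithm. `ΔF = 1 − exp(β)` from regressing `log(1 − F_t)` on
birth year; per-generation rates compound the per-year rate by L;
`Ne = 1/(2LΔF)`; Wright's `4 N_m N_f/(N_m + N_f)` is the drift expectation
checked by the RANDOM control. Accuracy is the correlation between index
EBV and index true value over the current candidates.

## Scale, budgets, and what a green test establishes

Full scale (39 chromosomes, 14,040 candidates/cycle, 30 years, 10
replicates) is the programme at its stated size but takes hours to days on one
CPU; it is not exercised by the test suite. The tested world is a
proportional shrink — `reduced_config()`: 5 chromosomes, 108 dams, 12 sires
(1:9 ratio kept), 250 founders, 5 + 10 years, 3 replicates, and 750 retained
sites per chromosome (75/300/300 per class, 30% of the full per-chromosome
density; chosen once for the compute budget). At that scale the suite checks
*orderings and laws*, not full-scale magnitudes: GTS outgains PTS,
GOCS trades gain for ΔF and Ne in the right direction and order, GTSMF is
equivalent to GTS, genome-based ΔF exceeds pedigree-based ΔF under
selection, and the RANDOM control's Ne sits near Wright's prediction (the
a-priori acceptance band is a 0.6–1.6 ratio, reflecting drift noise with 3
replicates and 1,500 markers). A green suite therefore establishes that the
machinery implements the stated model and reproduces its qualitative
structure at reduced scale; it does not certify full-scale magnitudes.
Synthetic data also simplify real layer data in ways worth naming: no
mutation after the base population, no SNP ascertainment bias (markers share
the rare-variant spectrum of the sequence), equal chromosome sizes, no
microchromosome structure, and no mortality or fertility variation.

## Numerical choices and degenerate inputs

Seeds: every stochastic stage derives its own seed from the replicate seed
and a stage label (`derive_seed()`), so runs are bit-reproducible and
scenarios sharing a replicate seed share the burn-in exactly. Monomorphic
QTL make effect rescaling impossible and raise an error; fully monomorphic
marker sets are an error in `build_G()`. A frontier whose endpoints coincide
(e.g. all-equal index values) returns the common solution with a warning.
`ΔF` regressions refuse series containing `F = 1`; `Ne` is reported missing
when `ΔF ≤ 0`. Truncation ties break by animal id. The EA is elitist, so
its objective never decreases; its budget (`mu`, `lambda`, `generations`,
`stagnation`) is configurable per scenario.
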