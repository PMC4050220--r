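---
title: "Finding SNP barcodes with a particle swarm: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding SNP barcodes with a particle swarm: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpbarcode)
```

## The problem

Single-SNP association tests often miss joint effects: no individual SNP
separates two phenotype groups, yet a specific *combination* of genotypes
does. `snpbarcode` searches for such combinations, called **SNP barcodes**:
a set of `k >= 2` distinct SNPs, each pinned to one of its three genotype
states (the two homozygotes and the heterozygote, coded 1/2/3). A subject
*carries* a barcode if its genotype equals the barcode's code at every
selected SNP — exact equality, with no dominant or recessive collapsing,
because the object of interest is the genotype-specific pattern itself.

The phenotype is a continuous score (the motivating application is a facial
emotion perception score in a 182-subject, five-SNP panel of the MET and
AKT1 genes). Subjects are dichotomized at the arithmetic mean of the whole
sample: strictly above the mean is `HIGH`, at or below is `LOW`. The
quality of a barcode `X` is the signed difference in carrier counts,

\[ F(X) = |\{\text{HIGH carriers of } X\}| - |\{\text{LOW carriers of } X\}|, \]

so a barcode carried by 30 HIGH and 18 LOW subjects scores 12. An
`objective = "absolute"` mode maximizes `|F|` instead, for searches where
enrichment in either group is interesting; the signed form is the default
because reported best barcodes favor the HIGH group.

A subject with a missing genotype at any barcode SNP counts as a
non-carrier of that barcode. This is deliberately conservative: a missing
call can never create evidence for an interaction.

## The swarm search

For `m` SNPs the space of size-`k` barcodes holds `choose(m, k) * 3^k`
candidates — trivial for `m = 5`, hopeless to enumerate for large panels.
The search is a global-best particle swarm optimization (PSO) over a
continuous encoding. Each particle's position is a vector of length `2k`:
`k` SNP-slot coordinates in `[1, m]` followed by `k` genotype-slot
coordinates in `[1, 3]`. The classic update equations are used verbatim:

\[ w(t) = (w_{max} - w_{min})\,\frac{T - t}{T} + w_{min} \]
\[ v_{id} \leftarrow w\,v_{id} + c_1 r_1 (pbest_{id} - x_{id})
                              + c_2 r_2 (gbest_d - x_{id}) \]
\[ x_{id} \leftarrow x_{id} + v_{id} \]

with `pbest` the particle's own best position, `gbest` the swarm's, and
`r1, r2 ~ U(0,1)` drawn fresh at each update. Personal and global bests are
replaced only on *strict* improvement, which makes `gbest` fitness monotone
non-decreasing and seeded runs exactly reproducible.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `population_size` | 50 | particles per swarm |
| `max_iterations` | 100 | iteration budget `T` (sole stopping rule) |
| `w_max`, `w_min` | 0.9, 0.4 | inertia endpoints; linear decay over `T` |
| `c1`, `c2` | 2, 2 | pull toward `pbest` / `gbest` |
| `v_max` | dimension range | per-dimension velocity clamp (`m - 1` for SNP slots, 2 for genotype slots) |
| `objective` | `signed` | `signed` or `absolute` difference |
| `stochastic_scope` | `per_particle` | `r1, r2` drawn once per particle per update, or per dimension |

The defaults are the standard settings for this problem class; on a 90-
to 243-barcode space the swarm performs 5,050 evaluations, oversampling
the space more than 20-fold. `k` is fixed per run; sweep `k = 2..5` with
one independent swarm per `k` (the CLI's `--k 2..5`).

### From continuous positions to discrete barcodes

The update equations are continuous, the solutions discrete. The mapping
is:

* **Rounding.** Each slot is rounded to the nearest integer, halves away
  from zero (so a genotype coordinate of exactly 2.5 decodes to 3), and
  clamped into its range.
* **Duplicate repair.** If a decoded SNP index collides with an earlier
  slot, the later slot is redrawn uniformly from the indices not yet used,
  and the particle's continuous coordinate is overwritten with the repaired
  integer. Every decoded barcode therefore has distinct SNPs, always.
* **Continuous state is kept.** Apart from repair, positions stay
  continuous between iterations; rounding happens only at evaluation time.

### Boundary handling: reflection, not clamping

A design point that turned out to matter. The natural choice — hard-clamp
positions into the box after each move — has a degenerate failure mode on
this encoding: attractive solutions often sit on *corners* of the box
(e.g., the barcode "SNPs(1,5) 3-1" has all four coordinates on bounds for
`m = 5`). With hard clamping, every particle that overshoots such a
`gbest` is projected exactly onto it; both attraction terms then vanish,
velocities decay under `w < 1`, and the swarm freezes within a few
iterations. In instrumented runs this cut the number of distinct barcodes
visited to ~65 of 90 and left a flat best-fitness trace from iteration 1.
Positions are therefore *reflected* off the walls instead
(`x -> 2*bound - x`, repeated while out of bounds); overshooting particles
keep oscillating around boundary attractors, and agreement with the
exhaustive optimum on five-SNP instances rose from ~91% to ~98% of seeded
runs. Velocity clamping at the full dimension range is retained; smaller
clamps (half or quarter range) were tried and degraded performance.

### Validation against an exhaustive oracle

For small panels, `exhaustive_best()` evaluates every barcode and ranks by
fitness, ties broken lexicographically by SNP indices then genotype codes,
so rankings are deterministic. It provides two guarantees used throughout
the test suite: the swarm can never exceed the enumerated maximum (oracle
dominance), and on five-SNP synthetic instances the swarm should match it
in nearly all seeded runs. The enumeration refuses beyond a configurable
cap (`1e6` barcodes) and points the user to the swarm instead.

## Statistical evaluation of a barcode

A selected barcode is summarized by the 2x2 table of carriers vs.
non-carriers across the two groups; with `a, b, c, d` = HIGH carriers, LOW
carriers, HIGH others, LOW others:

* **Odds ratio** `OR = ad / bc`, with the opt-in Haldane–Anscombe +0.5
  correction for zero cells (never triggered by default).
* **Woolf 95% CI**: `exp(log OR ± z * sqrt(1/a + 1/b + 1/c + 1/d))`. The
  log-normal (Woolf) interval, not an exact conditional one: it reproduces
  the reference tables' printed bounds to three decimals.
* **Pearson chi-square**, 1 df, *without* Yates continuity correction by
  default — the uncorrected statistic reproduces the reference P values
  (0.028, 0.023, 0.032, 0.048); a `yates = TRUE` flag exists.
* **Post-hoc power**: the power of the 1-df chi-square test at level
  `alpha` taking the observed statistic as the noncentrality parameter,
  `P(chi2_1(lambda) > q_{1, 1-alpha})` with `lambda` = observed chi2. This
  is the standard observed-power convention; it satisfies
  `power(lambda = 0) = alpha` and increases to 1 with the observed effect.
  Published power figures computed with external point-and-click tools
  whose settings are unknown are not chased; this package's convention is
  analytic, documented, and tested against direct numerical integration of
  the noncentral density.
* **Bonferroni column**: the report includes a Bonferroni-adjusted P value
  across the barcodes actually evaluated, as a clearly-marked extension —
  headline P values stay unadjusted for comparability.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` describes a two-group study with a *planted* epistatic
barcode: carriers arise with probability `carrier_prob_high` in the HIGH
group and `carrier_prob_low` in the LOW group; carriers receive the planted
genotypes exactly; non-carriers draw the planted SNPs from background with
the exact planted combination rejected, so the planted carrier rates are
exact rather than lower bounds. All other SNPs are independent draws from
per-SNP background genotype frequencies.

Defaults mirror the motivating panel: group sizes 89/93, five SNPs,
planted barcode `SNPs(1,4) 3-3`, carrier rates 30/89 ≈ 0.337 and
18/93 ≈ 0.194, and background frequencies equal to the panel's pooled
marginal genotype counts. Phenotypes are drawn per intended group from
Normal(100, 3) and Normal(80, 3); with a >6-sigma separation the mean
split recovers the intended groups with per-subject misassignment
probability below 1e-3, so the dichotomization step is exercised without
materially corrupting the planted rates.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (backgrounds are independent), Hardy–Weinberg constraints,
genotyping-error or missingness processes, and quantitative effect-size
models linking genotype to phenotype (group membership, not genotype,
drives the phenotype draw). Passing tests on this generator therefore
demonstrate the search and statistics machinery, not robustness to the
correlation structure of real panels.

One sobering property, measured rather than assumed: with the default
carrier rates, the planted barcode's expected difference is 12 with a
standard deviation near 6, while ~89 competing two-SNP barcodes each have
differences with standard deviations of 4–6. The planted barcode is
therefore the *top-ranked* barcode in only ~60–65% of seeded datasets —
the signal is real but not dominant at this sample size, which is exactly
the regime the method is meant for. Tests and the acceptance report state
the measured recovery rate; no parameter was adjusted to inflate it.

`fixture_table1_marginals()` is a separate, deterministic dataset whose
per-SNP, per-group genotype counts equal the published single-SNP table of
the motivating panel exactly (30 cells). Only marginals are constrained:
the joint structure is filled by a seeded within-group shuffle, so
multi-SNP carrier counts are *not* reproducible from it and are not
claimed — published 2x2 tables are used directly where joint counts are
needed. (The published table's HIGH columns sum to 93 and LOW to 89,
opposite to the stated group sizes 89/93 — an internal inconsistency of
the source; the fixture reproduces the printed cells.)

## Numerical and design choices, collected

* Mean split: strict `>` goes HIGH; ties at the mean go LOW. All-equal
  phenotypes put everyone LOW.
* Rounding: halves away from zero, everywhere a continuous slot is
  discretized.
* Tie-breaks: rankings order by fitness, then SNP indices, then genotype
  codes, lexicographically; `pbest`/`gbest` retain the incumbent on ties.
* RNG: one seedable stream per run; the seed is recorded in report
  sidecars. Problem sizes used by the validation suite: 100 seeded
  datasets at `m = 5`, `n = 182`, swarm 50 x 100 — chosen to oversample
  the 90-barcode space heavily while keeping a full validation sweep in
  the order of a minute.
* Degenerate inputs: empty datasets, `k > m`, out-of-range codes, zero
  cells and zero margins all raise informative errors rather than NaNs.

## Known limitations

* The swarm is stochastic: on needle-like landscapes (a unique optimum
  with no gradient toward it, common at `k = m` where only genotype codes
  vary) a seeded run can miss the optimum; validation bounds the miss rate
  rather than excluding it.
* Carrier counting is exact-match only; dominance-coded or dosage models
  are out of scope.
* The report's statistics are per-barcode and unadjusted except for the
  marked Bonferroni column; barcodes selected by maximizing the group
  difference are subject to winner's-curse bias, and their P values should
  be read as descriptive, not confirmatory.
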