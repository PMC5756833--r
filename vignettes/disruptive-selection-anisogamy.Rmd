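---
title: "Disruptive selection and the evolution of anisogamy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disruptive selection and the evolution of anisogamy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisogamy)
```

## The model

Under the disruptive-selection (gamete competition) account, anisogamy
evolves because selection for a large zygote creates an opportunity for one
mating type to produce many small gametes, forcing the other to produce few
large ones. The package implements this as a haploid game: a mutant
producing gametes of volume $m_1$ in a population producing gametes of
volume $m_2$ has fitness

$$w_1(m_1, m_2) = \frac{M}{m_1}\, g(m_1)\, f(m_1 + m_2),$$

the product of fertility (the fixed budget $M$ cut into gametes of volume
$m_1$), gamete survival $g$, and the survival $f$ of the zygote of volume
$S = m_1 + m_2$. Two survival variants are provided:

* **levitan** (the default): $g(m) = e^{-\alpha/m}$ and
  $f(S) = e^{-\beta/S}$, sigmoidal in size with inflection at $\alpha/2$
  (resp. $\beta/2$);
* **threshold**: the same $f$, but gametes survive with probability one at
  or above a viability threshold $\delta$ and die below it.

All volumes are in $\mu m^3$ throughout; no unit conversion happens
anywhere. $\alpha$, $\beta$ and $\delta$ are volume scales in the same
units; fitness is dimensionless and never normalized outside the selection
step of the simulator.

## ESS analysis

Setting $\partial w_1/\partial m_1 = 0$ against an identical resident gives
the optimal isogamete volume $m^* = \alpha + \beta/4$ (levitan) or
$\beta/4$ (threshold). Isogamy is continuously evolutionarily stable iff
$\beta < 4\alpha$ (resp. $4\delta$).

For the dimorphic equilibrium (levitan), requiring stationarity of
$\log w_1$ at both sizes with a common zygote volume $S$ gives
$(m - \alpha)/m^2 = \beta/S^2$ for both sizes; since the roots of the
resulting quadratic must sum to $S$, the zygote volume equals $\beta$ and
the ESS micro- and macrogamete volumes $a < b$ are the roots of

$$m^2 - \beta m + \alpha\beta = 0 .$$

`solve_anisogamous_ess()` uses these closed forms; the threshold variant
fixes $a = \delta$ (microgametes evolve to the smallest viable size) and
finds the macrogamete volume from $(\delta + b)^2 = \beta b$ by bisection
to relative tolerance $10^{-10}$. As $\beta$ grows, $a \to \alpha$ and
$b \to \beta - \alpha$, so the large-$\beta$ anisogamy ratio is
$(\beta - \alpha)/\alpha$; at the stability boundary $\beta = 4\alpha$ this
equals exactly 3, which is the testable prediction that anisogamous species
have ratios above three. The *exact* ESS ratio crosses 3 only at
$\beta = 16\alpha/3$; between $4\alpha$ and $16\alpha/3$ anisogamy is
stable with a ratio below 3. The package therefore exposes the exact
solver and the large-$\beta$ approximation as separate functions and makes
no claim about a cutoff where the approximation becomes adequate.

Every ESS claim is checked against a brute-force standard,
`invasion_sweep()`: $10^4$ log-spaced mutant sizes on
$[\beta \times 10^{-4}, \beta]$ (gamete volumes span orders of magnitude,
so the grid is logarithmic), invading either mating type, must gain at most
$10^{-9}$ fitness. A point worth noting, because it is easy to get wrong:
at *unstable* isogamy no single mutant invades either — the own-size
curvature of log fitness at the symmetric optimum is $-\alpha/m^{*3} < 0$
for every parameter choice. The instability is transverse: a joint
deviation, one mating type larger and the other smaller, gains fitness iff
$\beta > 4\alpha$. `critical_beta_ratio()` accordingly locates the boundary
by bisection on the sign of the numerically computed transverse eigenvalue
of the Hessian of log fitness at the symmetric optimum (central
differences; the optimum itself is located by a numeric root of the
selection gradient), rather than using the closed form it reproduces.

## The population-genetic simulator

The simulator makes the game concrete with mutation, drift and selection.
A gamete-size locus, physically linked to the mating-type locus, determines
the number of gametogenic mitoses: allele $i \in \{0, \dots, d\}$ produces
$2^i$ gametes of volume $m_i = M/2^i$. Defaults follow the study
conditions for the volvocine algae: $d = 9$ (the deepest division count
observed in the dataset), mutation rate $\mu = 10^{-3}$ per generation,
population size $N = 10^4$, $10^4$ generations, with $M$, $\alpha = a$ and
$\beta = S$ estimated per species from the trait table.

Each generation applies, in order:

1. **selection** within mating types,
   $y_i^+ = x_i^+ w_i^+/\bar w^+$ with
   $w_i^+ = (M/m_i)\, g(m_i) \sum_j f(m_i + m_j)\, x_j^-$;
2. **mutation**, symmetric and stepwise: probability $\mu/2$ to each
   neighbouring rung, so edge alleles 0 and $d$ lose only $\mu/2$;
3. **drift**: each type's frequencies are replaced by multinomial counts
   over $N$ trials divided by $N$, sampled independently per type so the
   "sex ratio" stays one.

Runs start from macrogamete isogamy (both types fixed on allele 0). Two
interpretation choices are documented and configurable rather than silently
assumed. First, $N$ is the population size *per mating type* ($2N$
individuals in all); the alternative reading (total) only rescales drift.
Second, the reported gamete size per type is the modal allele of the
frequencies *time-averaged over the final 10% of generations* — a single
final generation is noisy under drift, and the estimator used in the
original analyses is not specified. Drift is mandatory by default (it is
what statistically links a gamete size to a mating type); `N = Inf`
switches to the deterministic recursion used in tests, where, with
$\mu = 0$ and a slightly perturbed start, the recursion converges to the
ladder pair nearest the exact ESS (alleles $\{0, 7\}$, ratio 128, for the
*Volvox carteri* parameters).

## The motility locus

The motility extension crosses the ladder with a motile/nonmotile flag.
Motility costs a fraction $p$ of gamete volume: a motile gamete's
*facultative* volume — what counts for its own survival and its zygote's —
is $m(1-p)$. Nonmotile gametes fuse only with motile partners; the lost
fusions are a genuine fitness loss (the partner sum is *not*
renormalized), which is the mechanism that keeps at least one type motile.
Mutation adds a motility flip at $\mu/2$ per direction alongside the size
steps. Survival scales estimated from observed gamete volumes are adjusted
for the motile microgamete: $\alpha = a(1-p)$, $\beta = a(1-p) + b$, the
macrogamete being taken as nonmotile at full volume
(`adjust_params_for_motility()`; the precise adjustment is not fully pinned
down by its verbal description, so this one admissible reading is kept in a
single replaceable function). Outcomes are classified from the modal sizes
and the time-averaged nonmotile fraction of the macrogamete-producing type
(the type with larger time-averaged mean volume): equal sizes is isogamy;
otherwise a nonmotile fraction $\le 5\%$ is anisogamy, $\ge 95\%$ oogamy,
and anything between pseudooogamy.

A limitation worth stating plainly: under this fitness structure the
selective advantage of a nonmotile macrogamete is approximately
$p \cdot b/S \approx p$, opposed only by the tiny nonmotile fraction of the
micro type (itself held at mutation balance). The sweep in
`analysis/04_motility_sweep.R` therefore finds the nonmotile macrogamete
fraction rising toward one whenever $p$ clearly exceeds $\mu$ — near 0.85
on average at $p = 0.01$ (where $p$ is only an order of magnitude above
$\mu$ and mutation-drift balance keeps a visible motile minority, with
individual runs spanning anisogamy to oogamy) and above 0.99 at $p = 0.1$
and $p = 0.5$. Stable intermediate pseudooogamy over a broad range of
moderate costs is *not* an equilibrium of this model as specified; only a
narrow band of $p$ near $\mu$ produces it. Costly motility robustly
produces oogamy, and the fraction is monotone in $p$, but users should not
expect a wide pseudooogamous regime.

## Species table and volume rules

The packaged table (`volvocine_table()`) contains 45 Chlamydomonadales
species with cell counts, structural grade, gamete dimorphism class,
protoplasmic volume, reproductive-cell volume $M$, gamete volumes $b$ and
$a$, inferred zygote volume $S$ and the anisogamy ratio, exactly as
printed in the source compilation (thousands separators stripped). The
printed $S$ and ratio columns are kept authoritative; the loader checks
$|a + b - S| \le 2\ \mu m^3$ (printed rounding produces off-by-one cases)
and that the ratio equals $b/a$ snapped to a power of two, reporting any
violation as a per-row diagnostic rather than an error. "Anisogamous" in
all counts means dimorphism in {anisogamy, anisogamy with internal
fertilization, oogamy}. Protoplasmic volume is consumed as given — the
per-cell inventories behind it are not reproduced.

Volume rules: cells are spheroids, $V = \tfrac43 \pi r_1 r_2 r_3$, with the
third dimension assumed equal to the width; measured macro-/isogamete
volumes are snapped so $M/b$ is the nearest power of two
(`snap_power_of_two()`), with exact half-integer ties in $\log_2$ rounded
toward the *larger* gamete, consistent with measuring mature cells at their
largest dimensions (a $10^{-9}$ slack absorbs floating-point error at exact
ties); microgamete volume is $M/2^{k}$ for $k$ sequential gametogenic
divisions.

The cost of sex compares the macrogamete producer's equilibrium fitness
with a hypothetical isogamous population investing the same total volume,
isogamete $m = (a+b)/2$: $C = (b/m)\, g(m)/g(b)$ (levitan), or
$C = b/m = 2(b/a)/(1 + b/a)$ (threshold), which rises to the classic
twofold cost as the ratio grows; the levitan cost is strictly smaller
because macrogametes out-survive isogametes.

## Synthetic data

`generate_species_table()` draws $\alpha$ log-uniformly on
$[20, 200]\ \mu m^3$ (bracketing the observed microgamete volumes, which
are the $\alpha$ estimates, 18–20,469 with most below 500) and
$\beta/\alpha$ log-uniformly on $[1, 256]$ so one table spans stable
isogamy, the near-boundary regime, and strong anisogamy. Each species'
record is its equilibrium: isogamous draws get $m^* = \alpha + \beta/4$
produced by direct transformation; anisogamous draws get the exact ESS
sizes with the budget set to the macrogamete volume and the microgamete
snapped to the ladder (a draw whose ESS ratio snaps to 1 is recorded as
isogamous — the ladder cannot express its dimorphism). Ground-truth
parameters are returned alongside. Measurement noise is multiplicative
lognormal per radius with unit mean and configurable coefficient of
variation (scale-free and positivity-preserving); at cv = 0.1 the
macrogamete volume snaps back to the correct rung in about 95% of draws,
which is the designed margin: three radii at cv 0.1 give a volume log-sd of
about 0.25 in $\log_2$, so half-rung errors sit at about two standard
deviations.

What the generator does *not* emulate: phylogenetic correlation among
species, measurement bias (only unbiased noise), colonial/multicellular
structure (synthetic species are unicellular), and any discrepancy between
equilibrium and observed sizes. Passing recovery tests therefore show the
estimation-simulation pipeline is self-consistent, not that real species
are at equilibrium.

`parameter_recovery_experiment()` runs the full loop — estimate
$\hat\alpha = a$, $\hat\beta = S$ from each synthetic anisogamous record,
simulate, compare the evolved ratio to the ground-truth exact ESS ratio —
and reports the fraction recovered within one ladder step (factor 2).
Recovery is reliable for clearly anisogamous species ($\beta/\alpha$ well
above the boundary, as in the recovery tests, which use
$\beta/\alpha \in [16, 256]$); near the bifurcation the ESS ratio is below
2 and the ladder cannot resolve it, so near-boundary draws legitimately
fail the factor-2 criterion and are reported as such.

## Numerical choices and test scales

Degenerate inputs: selection raises an extinction error when a type's mean
fitness is zero (e.g. all gametes below threshold); frequency vectors are
validated to sum to one within $10^{-12}$ at every step boundary; modal
ties break toward the smaller allele index; the threshold optimum is
clipped at $\delta$ and flagged. The stability bisection uses 40–50 steps
on $\beta/\alpha \in [2, 8]$, far below rounding error at the reported
3-decimal precision.

The test suite runs full-scale study conditions where they matter (the
*Volvox carteri* reproduction uses $N = 10^4$ and $10^4$ generations over
10 seeds; the motility sweep likewise) and reduced sizes
($N = 10^3$, a few thousand generations) for property-style checks where
the asserted behaviour is scale-free; each test states its sizes inline.

## Known limitations

* The exact ESS ratio is below 3 for $4 < \beta/\alpha < 16/3$; the
  threshold-of-3 prediction is an asymptotic statement.
* The motility model has no stable wide pseudooogamous regime (see above).
* No phylogenetic correction is applied to the species analysis, and none
  is attempted for synthetic data.
* The model ignores gamete-encounter kinetics entirely; fertilization is
  implicit and mass-action within permitted pairings.
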