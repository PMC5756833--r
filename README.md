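# anisogamy

Models and analyses for the disruptive-selection (gamete competition)
account of how anisogamy — small microgametes and large macrogametes, the
defining asymmetry of the sexes — evolves from isogamy, tested on the
volvocine green algae.

## Who this is for

Evolutionary biologists working on the origin of the sexes, gamete
dimorphism, or the volvocine model system, and anyone who wants a tested,
reproducible implementation of the gamete-competition ESS analysis and its
population-genetic verification.

## The model

A haploid mutant producing gametes of volume *m*₁ against residents
producing *m*₂ has fitness

    w₁(m₁, m₂) = (M/m₁) · g(m₁) · f(m₁ + m₂)

with budget *M*, gamete survival g(m) = exp(−α/m) and zygote survival
f(S) = exp(−β/S) (or a survival threshold δ for gametes). Isogamy at
m\* = α + β/4 is continuously evolutionarily stable iff β < 4α; beyond
that, the ESS is a dimorphic pair — the roots of m² − βm + αβ = 0 — and
for large β the anisogamy ratio approaches (β − α)/α, which is **exactly 3
at the stability boundary**. Hence the testable prediction: anisogamous
species should have macrogamete/microgamete volume ratios above 3.

The package provides:

* survival and fitness functions, both variants (`gamete_survival`,
  `zygote_survival`, `mutant_fitness`);
* exact and approximate ESS analysis with a brute-force invasion oracle
  and a numerically located stability boundary (`solve_anisogamous_ess`,
  `invasion_sweep`, `critical_beta_ratio`);
* a two-mating-type simulator of gamete-size evolution on the
  power-of-two gametogenesis ladder mᵢ = M/2ⁱ, with selection within
  types, symmetric stepwise mutation, and per-type multinomial drift
  (`sim_config`, `run_simulation`);
* a gamete-motility extension producing anisogamy, pseudooogamy or oogamy
  as the motility cost rises (`run_motility_simulation`);
* the 45-species volvocine trait table with its volume-adjustment rules,
  the anisogamy-ratio test, and cost-of-sex calculations
  (`volvocine_table`, `anisogamy_test`, `cost_of_sex`);
* synthetic species generators with known ground truth and a
  parameter-recovery harness (`generate_species_table`,
  `parameter_recovery_experiment`).

## Worked example

```r
library(anisogamy)

tbl <- volvocine_table()
anisogamy_test(tbl)
#> $n_total
#> [1] 45
#> $n_anisogamous
#> [1] 21
#> $n_anisogamous_ratio_gt_3
#> [1] 21
#> $pass
#> [1] TRUE
```

All 21 anisogamous (including oogamous) species of the 45 have ratios
above 3: the prediction holds with no exceptions.

```r
vc <- tbl[tbl$species == "Volvox carteri", ]
params <- estimate_params(vc)   # alpha = a = 80, beta = S = 10380
solve_anisogamous_ess(params, M = vc$M)
#> Anisogamous ESS (levitan variant)
#>   a = 80.6263  b = 10299.4  S = 10380  b/a = 127.742  epsilon = 0.626
```

The exact ESS for the *Volvox carteri* parameters is a ~80.6 µm³
microgamete and a ~10,299 µm³ macrogamete — ratio 127.7, which the
gametogenesis ladder rounds to the observed 128 (seven sperm-producing
divisions, 2⁷ = 128 sperm per reproductive cell). The full
population-genetic simulation, started from isogamy, finds the same
answer:

```r
run_simulation(sim_config(M = vc$M, params = params, seed = 1))
#> Gamete-size simulation outcome
#>   modal alleles: {7, 0}  sizes: {80.47, 1.03e+04} um^3
#>   ratio: 128  classification: anisogamy
```

One mating type slid down the ladder to allele 7 (80 µm³ sperm) while the
other stayed at allele 0 (the full 10,300 µm³ egg). The fold cost of sex
for this species is 1.97 (levitan) or 1.98 (threshold) — essentially the
classic twofold cost, because the anisogamy ratio is large.

## The analysis workflow

The numbered scripts under `analysis/` run the full species analysis and
write TSV/JSON tables under `results/`:

1. `01_table_analysis.R` — table validation and the anisogamy-ratio test;
2. `02_ess_analysis.R` — stability boundary and per-species ESS solutions
   with invasion-oracle checks;
3. `03_simulate_species.R` — population-genetic runs for every anisogamous
   species, plus a 10-seed *Volvox carteri* replication;
4. `04_motility_sweep.R` — the motility-cost sweep (p = 0.01, 0.1, 0.5);
5. `05_cost_of_sex.R` — per-species costs of sex and the cost curves.

Run each as `Rscript analysis/01_table_analysis.R` (order does not
matter). The methods vignette
(`vignettes/disruptive-selection-anisogamy.Rmd`) documents the models,
parameter choices, numerical decisions and known limitations.

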