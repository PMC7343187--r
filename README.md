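# rimabk

Kinetic, stochastic and translatome models of ribosomal protein glutamation
by the bacterial RimABK system.

In *Pseudomonas fluorescens*, the glutamate ligase **RimK** appends
C-terminal poly-glutamate tails to ribosomal protein **RpsF** (S6). RimK is
stimulated by the second messenger **cyclic-di-GMP** (cdG, Kd ≈ 1 μM) and by
the phosphodiesterase **RimA**; the protease **RimB** trims the tails one
glutamate at a time down to a floor of four residues. The balance of ligase
and protease activity sets both the length of the tails and the fraction of
the cell's ribosomes that carry them, and thereby reprograms translation.

`rimabk` is an R package for researchers modelling this (or any similar)
ligand-regulated enzyme system and its translatome readout. It provides:

* **Binding networks** (`reaction_network`, `build_odes`,
  `solve_steady_state`): mass-action ODE models of reversible bimolecular
  binding with derived reverse rates (`kr = kf·Kd`), symbolic moiety
  conservation, thermodynamic cycle consistency checked and imposed at
  construction (`check_thermodynamic_consistency`), and steady states via
  both high-accuracy integration and direct equilibrium speciation.
* **Model variants** (`make_model`): two-state, four-state, RimB-extended
  and cdG-trigger models of RimK activation, with
  `state_weights()` giving per-state steady-state occupancies.
* **Multi-state enzymology** (`composite_rate`, `michaelis_menten_fit`,
  `fit_model_params`, `compare_models`): occupancy-weighted
  Michaelis–Menten rates,
  `v(S) = Σ_s w_s · kcat_s · S / (Km_s + S)`,
  and seeded global fitting (differential evolution over log Kd/Km with the
  kcat vector profiled out by linear least squares, then an L-BFGS-B
  polish).
* **Stochastic chain simulation** (`chain_config`,
  `chain_length_distribution`, `simulate_population`): a discrete-time
  Markov model of tail extension, end-cleavage (floor 4) and release
  (cap 100), with a capped-geometric closed form as independent oracle and
  a cell-population mode sharing one RimABK complex and a finite glutamate
  pool across 500 RpsF copies.
* **Ribo-seq quantification** (`filter_reads`, `center_weighted_coverage`,
  `rpkm_table`, `classify_regulon`, `differential_protein_filter`):
  23–41 nt footprint filtering, strand-specific centre-weighted coverage
  (11 nt trimmed from each alignment end), RPKM, two-contrast regulon
  classification at τ = 1 log₂, and the quantitative-proteomics
  significance filter.
* **Synthetic data** (`gen_rate_data`, `gen_progress_curves`,
  `gen_alignments`, `gen_contrast_tables`, `gen_protein_table`):
  seed-deterministic generators for every input — NADH-coupled assay rates
  and progress curves, SAM/GFF3 footprints over a toy genome, and contrast
  and protein tables with known ground truth — so the full pipeline is
  testable without downloads.

## Worked example

How occupied is RimK by cdG under assay conditions (2.5 μM RimK, 25 μM cdG,
Kd = 1 μM)?

```r
library(rimabk)
pairwise_bound_fraction(total_receptor = 2.5, total_ligand = 25, Kd = 1)
#> [1] 0.9576377
```

95.8% of RimK is cdG-bound — it rounds to 96%, which is why adding RimA on
top of saturating cdG discriminates between a shared-active-state model and
one with independently activating ligands. The four-state occupancies and
the composite ATPase rate under the same condition:

```r
m <- make_model("four_state", overrides = list(cdG = 25))
w <- state_weights(m, normalize = TRUE)
w
#> # A tibble: 4 × 4
#>   state     kcat    Km weight
#>   <chr>    <dbl> <dbl>  <dbl>
#> 1 apo         20   500 0.0143
#> 2 rima        60   500 0.0256
#> 3 cdg         60   500 0.344
#> 4 rima_cdg   100   500 0.616
composite_rate(w, 500)   # nmol ATP/min/mg at 500 uM ATP
#> [1] 42.03612
```

With 1 μM each of RimK and RimA plus 25 μM cdG, 62% of RimK sits in the
doubly-bound, most active state, and the observed specific activity at half-
saturating ATP is 42 nmol/min/mg — the occupancy-weighted mixture of the
four states.

What do the tails look like when protease activity dominates (activity ratio
ρ = p_cut/p_add = 10)?

```r
d <- chain_length_distribution(
  chain_config(p_add = 0.05, rho = 10, n_sims = 1e5), seed = 1)
d
#> <chain_length_distribution> n_sims: 100000  mode: 4  mean: 4.111
round(d$prob[5:9], 4)   # lengths 4..8
#> [1] 0.9000 0.0901 0.0089 0.0009 0.0001
```

The distribution collapses onto the protease floor: 90% of chains sit at
exactly four glutamates, the experimentally observed resultant length.

See the vignette (`vignettes/rimabk-methods.Rmd`) for the model structure,
fitting design, simulator conventions and the exact coverage/classification
rules.

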