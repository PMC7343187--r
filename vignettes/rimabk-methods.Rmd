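---
title: "Modelling RimABK-mediated glutamation of ribosomal protein RpsF"
author: "rimabk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RimABK-mediated glutamation of ribosomal protein RpsF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimabk)
```

## The system

In *Pseudomonas fluorescens*, the glutamate ligase RimK appends C-terminal
poly-glutamate tails to ribosomal protein RpsF (S6). Its activity is tuned by
three regulators: the second messenger cyclic-di-GMP (cdG), which binds RimK
with Kd about 1 uM; the phosphodiesterase RimA, which stimulates RimK by
direct interaction but, when loaded with cdG, switches to degrading the
nucleotide; and the protease RimB, which trims poly-glutamate tails one
residue at a time down to a floor of four. The net output — what fraction of
the cell's RpsF carries tails, and how long they are — reprograms translation.

`rimabk` implements the computational layers of this picture: equilibrium and
kinetic models of RimK activation, multi-state Michaelis-Menten fitting of
ATPase data, a stochastic simulator of tail dynamics, the ribosome-profiling
quantification used to read out the translatome, and synthetic-data
generators that emulate each input so the full pipeline runs and is tested
without any external dataset.

## Binding networks and steady states

Models are reversible bimolecular binding networks. Each reaction
`A + B <-> AB` carries a dissociation constant Kd (uM) and a diffusion-limited
forward rate constant, 1e9 M^-1 s^-1 by default; the reverse rate is always
derived as `kr = kf * Kd`, so equilibria are set by the Kds alone.
Concentrations are handled internally in uM (so kf becomes 1e3 uM^-1 s^-1),
which keeps all quantities near unity and away from float underflow.

Mass-action ODEs are assembled per reaction. Because every complex is the
composition of elementary species, the net stoichiometry of each reaction in
moiety counts is identically zero — `moiety_balance()` exposes this as an
exact, symbolic property, and conservation of moiety totals under the flow
follows by construction rather than by numerical accident.

Thermodynamic consistency is both checked and imposed. For any closed binding
cycle, detailed balance requires the product of Kds to be route-independent;
`check_thermodynamic_consistency()` evaluates this over the null space of the
reaction stoichiometry matrix and reports the offending ratio per cycle. In
the model constructors the closing Kd of each cycle is *derived* from the
others rather than exposed as a free parameter, which removes one degree of
freedom per cycle from every fit.

Steady states are computed by two routes:

* `method = "ode"`: a high-accuracy explicit Runge-Kutta integration
  (rtol 1e-8, atol 1e-10) with a growing horizon, finished by Gauss-Newton
  refinement. The refinement solves the derivative equations *augmented with
  the moiety conservation equations*: the root set of a mass-action binding
  system is a manifold, and the augmentation pins the unique root belonging
  to the initial totals.
* `method = "equilibrium"`: direct equilibrium speciation — Newton iteration
  on the log free concentrations of the conserved moieties, with every
  complex expressed as a product of free concentrations over formation Kds.

The two routes agree to better than 1e-6 relative on detailed-balanced
networks (tested), which makes the algebraic route a safe fast path inside
fitting loops while the ODE route remains the reference implementation.

At the ATPase assay concentrations (2.5 uM RimK, 25 uM cdG, Kd = 1 uM) the
exact quadratic solution of the single-site equilibrium gives a bound
fraction of 0.9576 — 96% of RimK cdG-bound:

```{r}
pairwise_bound_fraction(total_receptor = 2.5, total_ligand = 25, Kd = 1)
```

The quadratic is used rather than the excess-ligand approximation; at these
concentrations both round to 96%, but the quadratic remains exact when
receptor and ligand are comparable.

## Model variants

`make_model()` builds four variants of RimK activation:

* **two_state** — basal RimK and one shared active conformation reached by
  binding either cdG or RimA (two activity states, one Kd per ligand);
* **four_state** — apo, RimK·RimA, RimK·cdG and RimK·cdG·RimA, each with its
  own kcat and Km, on a thermodynamically closed binding square;
* **rimb_extended** — adds a RimK·RimB complex as a further level of ATPase
  activation. How RimB-containing states would cycle with cdG and RimA is
  not constrained by any measurement, so the complex is formed from apo RimK
  only; this is an implementer-defined topology and is flagged as such.
* **trigger** — adds cdG binding to RimA (Kd 5 uM), modelling the switch of
  RimA from RimK stimulation to cdG degradation. Because the attenuating
  effect of cdG on RimA stimulation is only observed when RimB is present,
  the RimA·cdG complex is included only when total RimB > 0; with RimB
  absent the trigger model reduces *exactly* to the four-state model. How a
  cdG-loaded RimA interacts with RimK is genuinely open, so the variant
  exposes an `arrangement` switch rather than deciding intent:
  `"sequester"` (default) makes RimA·cdG unable to hold RimK, while
  `"competent"` lets it bind RimK like free RimA, with the closing Kd
  derived from the cycle.

Default parameters: Kd(RimK·cdG) = 1 uM, Kd(RimK·RimA) = 0.2 uM,
Kd(RimA·cdG) = 5 uM, remaining Kds 1 uM (the standard initial estimate), and
1 uM initial concentrations for all proteins and cdG unless a condition
overrides them.

## Composite kinetics and fitting

The observed ATPase specific activity of a RimK population is additive over
activation states,

$$v(S) \;=\; \sum_s w_s\, k_{\mathrm{cat},s}\, \frac{S}{K_{\mathrm{m},s}+S},$$

with weights $w_s$ the steady-state occupancies from the binding model.
Specific activities are carried in the assay's native unit
(nmol ATP min^-1 mg^-1); occupancies are normalised to fractions of total
RimK, so kcat values are per-state specific activities and no molar mass
conversion is needed for synthetic data.

`fit_model_params()` fits the free Kds and per-state (kcat, Km) to rate data
from all conditions jointly by pooled least squares. The search has a
deliberate structure:

* state occupancies depend only on the Kds, and for fixed Km the kcat vector
  enters the model linearly — so kcats are profiled out by linear least
  squares at every candidate point (aliased, never-populated states get 0);
* the remaining log10(Kd), log10(Km) space is searched by a seeded
  differential-evolution stage (rand/1/bin, population 36, 100 generations
  by default) followed by an L-BFGS-B polish. Default bounds are
  Kd in [1e-3, 1e3] uM, Km in [1, 1e5] uM, kcat in [0, 1e5]; explicit
  bounds and an explicit seed make every fit bitwise reproducible.

The generator's default kinetic truth (kcat 20/60/60/100 for
apo/·RimA/·cdG/·cdG·RimA, shared Km 500 uM ATP, Kd(cdG) = 1 uM,
Kd(RimA) = 0.2 uM) encodes the observed pattern: RimA and cdG each stimulate,
and their effects are approximately additive — which is exactly the pattern a
two-state model cannot reproduce, since in a two-state model saturation by
one ligand leaves no headroom for the other. On data generated from the
four-state truth, the four-state fit attains a strictly lower pooled residual
than the best two-state fit (tested); only residuals are compared, as no
significance procedure is defined for this comparison.

The default condition registry pairs the canonical combinations (basal,
+RimA, +cdG 25 uM, +both) with RimA and cdG titrations spanning and
saturating their Kds (RimA up to 3 uM, cdG up to 25 uM). A titration without
a saturating anchor leaves the Kd-kcat pair nearly unidentifiable — the
plateau pins kcat, the sub-Kd points then pin Kd — so the saturating points
are part of the design, as they would be in the wet assay. With 2% noise,
the median recovered Kds across 20 seeded fits fall within a few percent of
the truth (tested against a 20% criterion).

## Stochastic chain dynamics

The tail simulator is a discrete-time Markov chain, matching the verbal
model: per step a chain gains a glutamate with probability `p_add`, loses its
terminal glutamate with probability `p_cut`, or does nothing. Cleavage is a
no-op at or below the floor of four residues; chains are capped at 100
residues. The probabilities depend on the concentrations of the RimK species
and RimB, but no functional form for that dependence is specified anywhere —
so the activity ratio `rho = p_cut / p_add` is the primary user-facing
control, and `chain_probs_from_activities()` offers a proportional mapping
with a single scale factor for users coming from the kinetic layer.

Numerical conventions, chosen once and tested:

* **Capping**: probability mass accumulates at the cap (a chain reaching 100
  stays there); the distribution is not renormalised.
* **Recording**: processive chains (release probability > 0) record at
  release; protease-mode chains record at a fixed horizon of 1e4 steps.
  Released chains are final — they are not re-entered as substrates.
* **Mode tie-break**: toward the smaller length, for determinism.
* **Replicates**: the population-average default is 1e6 chains; tests and
  examples use 1e5, which already gives multinomial errors well below the
  features of interest.

In the no-protease limit the model is processive extension with geometric
termination and admits the closed form `P(L = k) = q^k (1 - q)` (capped),
implemented independently as `geometric_oracle()`; the simulator matches it
bin-by-bin within 3 sigma and by chi-square goodness of fit (tested). With
protease active and a high activity ratio the distribution collapses onto
the floor: the mode is exactly four.

```{r}
d <- chain_length_distribution(
  chain_config(p_add = 0.05, rho = 10, n_sims = 1e4), seed = 1)
distribution_mode(d)
```

The population simulator shares one RimABK complex and a finite glutamate
pool across 500 RpsF copies (the estimated cellular ratio). The complex
extends its bound chain processively and unbinds with the release
probability; cleavage events strike a uniformly chosen chain and return the
removed glutamate to the pool, since liberated glutamate is re-usable by the
ligase. Pool conservation — incorporated plus remaining equals initial —
is asserted in the C++ kernel at every event, not merely at the end. Low
protease activity concentrates the pool into a few long tails and leaves
most RpsF unmodified; high protease activity spreads the same pool as
near-floor-length tails over almost `pool / 4` chains.

## Ribosome-profiling quantification

The quantification follows the study design it reimplements, stated here as
exact coordinate rules:

* alignments are kept iff their reference span is 23–41 nt, bounds
  inclusive; spans come from the CIGAR reference walk, so soft clips are
  excluded (footprints rarely contain indels, and the reference span is the
  well-defined choice);
* a kept read covering 0-based positions `[s, s + l)` increments the
  `l - 22` positions `[s + 11, s + l - 11)` — 11 nt trimmed from either end;
  the centre weight is +1 per position within the trimmed window;
* coverage accumulates separately per strand; SAM's 1-based coordinates and
  GFF3's 1-based inclusive intervals are converted at the boundary and
  tested at the boundaries (a 23 nt read contributes exactly one position);
* a gene's count is the coverage sum on its own strand within its interval;
  partial overlaps contribute only in-gene positions. RPKM divides by gene
  length in kb and by the genome-wide total of counted positions over both
  strands in millions. Using the genome-wide rather than genic total is a
  convention choice, noted because the original description does not decide
  it.

Contrast ratios use a pseudocount of 0.5 RPKM on both sides before log2
(zero-handling is otherwise unspecified). Regulon classification takes two
contrasts per gene — A, deletion mutant versus wild type; B, glutamation
allele versus the deletion mutant — and the threshold tau = 1.0 log2:
class 1 is significant in A only, class 2 significant in both with the same
sign, class 3 significant in both with opposite signs (the direct
glutamation-regulon candidates), glutamation-only significant in B only;
everything else is unaffected. The five labels partition every finite input
(tested). The proteomic filter keeps records with at least 2 unique
peptides, at least a 2-fold (1 log2) difference between the wild-type and
mutant condition ratios, and at least one adjusted p-value at or below 0.05;
p-values arrive pre-adjusted and are consumed as-is. Whether "at least one
p-value" refers to the per-condition tests or a difference test is not
stated; the filter takes the minimum over the provided p-values.

## What the synthetic data do and do not show

The generators emulate the *statistical structure* each stage assumes:
occupancy-driven Michaelis-Menten rates with multiplicative Gaussian noise
(heavier-tailed noise is deliberately not the default); footprints placed
uniformly within genes, multinomially across genes proportional to
rate x length, with a triangular length distribution peaked at 30 nt — any
in-window distribution would do — plus an out-of-window contaminant
fraction; contrast tables and protein tables whose effects sit strictly
beyond (or below) the thresholds by a margin.

They do not emulate real sequence content, positional bias within genes,
overdispersion between biological replicates, or any genome's actual gene
structure. Passing tests therefore demonstrate that the implementation is
faithful to its stated rules and recovers known truth under those rules —
not that the rules themselves are optimal for any particular real dataset.
Likewise, the counts of regulated genes reported for the real deposited
datasets depend on those data and are out of scope here; the corresponding
logic is validated on generated inputs with known labels instead.

## Problem sizes and runtime choices

Simulation sizes in the test suite are chosen to keep statistical power
while remaining desk-scale: 1e5 replicate chains for distribution-level
checks (the full 1e6 is a flag away), 1e5 synthetic footprints for the
RPKM rank-correlation round trip, 20 seeded fits for parameter recovery,
and 1000 replicate Michaelis-Menten fits for the noisy-recovery check.
The differential-evolution defaults (population 36, 100 generations) sit
where the recovery studies converge reliably; halving them is noticeably
less reliable on the flattest direction of the objective (the RimA Kd).

## Known limitations

* The mapping from kinetic-model occupancies to chain-step probabilities is
  proportional by assumption; no data constrain its functional form.
* The rimb_extended topology beyond "a further level of activation" is
  implementer-defined, as discussed above.
* The unidentified second ("reset") protease that returns RpsF to the
  unmodified ground state is not modelled; the simulator's release/cleavage
  channels do not stand in for it.
* Whether RpsF presence modifies the ATPase parameters is observed
  experimentally but not modelled, so fitted parameters describe the
  RpsF-free assay.
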