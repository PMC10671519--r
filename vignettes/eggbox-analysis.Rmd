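---
title: "Egg-box analysis of divalent-metal alginate gels from elemental composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egg-box analysis of divalent-metal alginate gels from elemental composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggboxr)
```

## The problem

Alginate, an irregular linear copolymer of β-D-mannuronate (M) and
α-L-guluronate (G), gels in the presence of divalent cations: the cations
cross-link pairs of chains by sitting in cavities ("egg-box cells") formed by
two opposed two-monomer blocks, and the resulting dimers laterally associate
into flat junction-zone sheets. Energy-dispersive X-ray spectroscopy (EDX) of
freeze-dried gel microspheres yields the atomic-percent elemental composition
of the gel — but EDX sees neither hydrogen nor the *positions* of the atoms
it counts. In nearly every measured gel the metal content per chain segment
exceeds what a sheet of egg-box cells can hold, because part of the metal is
present as physically adsorbed neutral salt, or as hydrated salt complexes
sitting inside cells. `eggboxr` implements the bookkeeping that turns a raw
EDX table into a structurally interpretable chemical formula, and the
combinatorial model that predicts how full the cells should be.

## The C12 block and the occupancy X

All compositions are referred to the block of two monomer residues,
C~12~H~14~O~12~ in the fully exchanged metal form (C~12~H~14~O~12~Me~X~)~n~.
Given a sample's atomic percents, every element is multiplied by
$12 / K_C$, where $K_C$ is the carbon atomic percent, making carbon exactly
12 while preserving all element ratios ([rescale_to_c12()]). Hydrogen, which
EDX cannot see, is imputed as 14 per block. The metal coefficient of this
rescaled formula is the average occupancy $X$, the number of cations per C12
block; complete cross-linking corresponds to $X = 1$.

Junction zones come in three types, classified from $X$
(`classify_junction_zone()`):

* $X \le 0.5$ — cations only bridge chains *within* dimers; dimers stack by
  van der Waals contacts and hydrogen bonds (weak gels; calcium).
* $0.5 < X < 1$ — electrostatic assembly, with ions fastening each dimer to
  the growing sheet (barium, strontium, zinc).
* $X = 1$ — every cell filled (transition metals); a measured 0.99 counts as
  1 under the default boundary tolerance of 0.05.

## Cell combinatorics for arbitrary μ = M/G

Under the i.i.d. sequence model each monomer is M with probability
$\mu/(1+\mu)$. The four ordered blocks of a chain then have probabilities
$P(GG) = 1/(1+\mu)^2$, $P(GM) = P(MG) = \mu/(1+\mu)^2$,
$P(MM) = \mu^2/(1+\mu)^2$, and a cell — an ordered pair of blocks, 16
configurations — falls into one of seven symmetry classes with
multiplicities (1, 4, 2, 2, 2, 4, 1):

```{r}
cell_probabilities(1.56)
```

The symmetry rule is that swapping the two chains, or reversing the reading
direction of both chains simultaneously, yields the same cell; GM–GM
(parallel reading) remains distinct from GM–MG (antiparallel). This is the
only grouping whose multiplicities reproduce the $4\mu$ and $4\mu^3$
numerators, and `enumerate_cells_oracle()` verifies the closed forms by
brute-force enumeration of all 16 configurations — exactly, in integer
rational arithmetic, when μ is given as a fraction:

```{r}
cell_probabilities(monomer_ratio(1.5, exact = "3/2"))[1, ]  # GG-GG = 16/625
```

The theoretical occupancy $X_T$ of a cation is the summed probability of the
cell classes it is thought (from the structural literature) to occupy
(`occupancy()`, `preference_sets()`). For the reference sample (μ = 1.56):
Ba and Zn prefer GG/MM-type cells, $X_T = (1 + 2\mu^2 + 4\mu^3 +
\mu^4)/(1+\mu)^4 = 0.63$; Sr (tentatively) $X_T = (1 + 4\mu + 2\mu^2 +
4\mu^3)/(1+\mu)^4 = 0.64$; Ca binds only GG-containing cells, $X_T = (1 +
4\mu + 2\mu^2)/(1+\mu)^4 = 0.28$; the GG–GG nucleation cell alone occurs
with probability $1/(1+\mu)^4 \approx 2.3\%$.

## Separating adsorbed and structural metal

`decompose()` splits the measured metal coefficient into bare in-cell
cations (`structural_x`), adsorbed neutral associates (`associates`, e.g.
SrCl~2~ or NiSO~4~·4H~2~O on the sheet faces, capped at 2 per block — one
per face), and in-cell hydrated complexes (`in_cell_complex_fraction`, e.g.
CuSO~4~·8H~2~O). Policies:

* **anion_driven** — all anion belongs to adsorbed associates
  (associates = anion/ν); the remainder of the metal is structural.
* **full_occupancy** — cells are full ($X = 1$); excess metal is adsorbed;
  anion imbalance is reported as a residual, never silently absorbed.
* **complex_in_cell** — cells are full; excess metal is adsorbed; anion
  beyond the adsorbed share sits in in-cell complexes. If the remaining
  anion matches the in-cell metal (within 0.05), every occupied cell is
  taken to hold a complex.
* **auto** — no anion → purely structural; backbone oxygen < 8 (a strong
  deficit signalling dehydrogenation/decarboxylation of degraded chains) →
  full_occupancy; anion/ν ≥ metal − 1 with metal within 0.05 of an integer
  ≥ 1 → complex_in_cell; metal − anion/ν in (0, 1] → anion_driven. Each
  choice is logged in `$notes`.

Metal conservation — structural + adsorbed + complexed = total metal — holds
exactly (pre-rounding) under every policy and is asserted in the tests.
Sodium is carried as an inert counterion.

Hydration water is inferred afterwards (`infer_hydration()`): oxygen beyond
the backbone and the anion oxygens is divided among the salt units and
rounded to an integer. Water is only invoked when the anhydrous reading
would leave the backbone with more than its theoretical 12 oxygens —
otherwise measured oxygen (typically 10.7–11.7) is simply the backbone, as
EDX undercounts light elements. The water carrier defaults to adsorbed
associates when present, else in-cell complexes; `carrier = "all"` gives
the alternative reading in which in-cell complexes are hydrated too (for
nickel this lowers the backbone oxygen from ≈11.7 to ≈10.6 — the data do
not decide between the two, so both are exposed).

```{r}
report <- run_pipeline(pipeline_config())
report$summary[, c("sample_id", "structural_x", "associates",
                   "in_cell_complex_fraction", "water", "zone")]
report$comparison[, c("sample_id", "component", "x_experimental",
                      "x_theoretical", "difference")]
```

## Numerical choices

* **Rounding** is half away from zero (`round_half_up()`), to two decimals
  for coefficients; internal arithmetic is never rounded. Reproduction
  tests use an absolute ±0.01 band because the source tables themselves
  round inconsistently (1.545 appears as 1.54).
* **Trace cutoff** 0.10 at%: the smallest cutoff that reproduces the
  published retained/discarded split (drops Al/Si sputtering traces and the
  0.05 at% residual Cl of the Ba gel; keeps Na 0.12 in the Mn gel). Applied
  to raw at%, before rescaling; retained values are not renormalized since
  only ratios enter the rescaling.
* **Occupancy boundary tolerance** 0.05, so X = 0.99 classifies as a
  complete sheet.
* **Exact arithmetic**: when μ is rational, probabilities are reduced
  integer fractions (p, q ≤ a few hundred keeps every intermediate integer
  far below 2^53, so doubles hold them exactly); no external bignum
  dependency is needed.
* **Decomposition precision**: the reference analyses are run on
  coefficients rounded to two decimals (the published table form) via
  `round_coefficients()`; `pipeline_config(decimals = NA)` analyses
  unrounded values instead. Exact arithmetic on rounded inputs explains
  small deviations from the published splits (Ni 0.72/0.28 vs the published
  0.73/0.27, which assumed occupied cells exactly 1).

## The synthetic-data generator

`generate_edx_table()` inverts the whole pipeline: from a known gel model
(μ, structural X, associates, complex fraction, hydration, residual sodium)
it builds exact per-block element counts, drops hydrogen (EDX blindness),
converts to atomic percent and applies per-element multiplicative lognormal
noise (mean-one, CV default 0.02) before renormalizing to 100. Multiplicative
noise reflects that EDX quantification errors scale with the signal; the true
error magnitude of the instruments is not reported, so the default CV is a
documented placeholder. The generator's defaults mirror the measured world
(μ = 1.56, the salt registry of the seven reference gels, occupancies and
associate counts in the measured ranges).

What the generator does *not* emulate: systematic light-element bias
(oxygen/carbon undercounting), spatial heterogeneity of the microspheres,
and detector physics. A green round-trip test therefore establishes the
algebraic consistency of rescaling and decomposition, not the accuracy of
EDX itself.

`simulate_chain_cells()` complements it on the combinatorics side: Monte
Carlo sampling of cells under the i.i.d. model, or under a single-parameter
correlated ("markov") variant in which the second monomer of a block copies
the first with a weight chosen so that the marginal same-neighbour
probability equals `p_stay`. This preserves the M/G marginal, reduces
bit-identically to i.i.d. when `p_stay` equals the i.i.d. same-probability,
and rejects `p_stay` below it (anticorrelated chains are out of scope).
Real alginates have block structure; the i.i.d. assumption is exactly what
the closed-form tables encode, and the markov knob exists to probe how
sensitive the class frequencies are to that assumption.

## Known limitations

* The Sr preference set is tentative (the literature is contradictory), as
  is the GM–MM membership in the Ba/Zn set; the registry records these as
  notes rather than certainties.
* The Mn gel's chlorine exceeds the 2 × associates implied by its formula
  (4.51 vs 4.18); the surplus is reported as a residual, consistent with
  partial chain degradation, and not reconciled.
* The Zn associate count follows the measured sulfur (0.85) for exact
  conservation; the published formula's 0.8 is within the rounding band.
* μ itself is an input (from chemical characterization of the alginate),
  not estimated from the EDX data.
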