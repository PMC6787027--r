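---
title: "Inferring codon-anticodon free energies from -1 frameshifting efficiencies"
author: "fsthermo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring codon-anticodon free energies from -1 frameshifting efficiencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsthermo)
```

## The model

A ribosome paused on a slippery heptamer X XXY YYZ can carry its P- and
A-site tRNAs from the 0-frame codons (heptamer positions 2–4 and 5–7)
onto the −1-frame codons (positions 1–3 and 4–6). If the pause is long
compared to the time needed for the tRNAs to re-pair back and forth, the
two frames equilibrate, and the probability of ending in the −1 frame —
the frameshifting efficiency — is a Boltzmann two-state occupancy:

$$\mathrm{FS}_i \;=\; \frac{e^{-\Delta G_i/kT}}{1 + e^{-\Delta G_i/kT}},
\qquad \Delta G_i = G_{-1,i} - G_{0,i}.$$

Only the difference $\Delta G_i$ is ever represented; the absolute frame
free energies are not identifiable from efficiencies and do not appear
anywhere in the package. The second modelling assumption is
*additivity*: $\Delta G_i$ is a sum of the free-energy differences of
the individual base-pair changes between the frames,
$\Delta G_i = \sum_j M_{ij}\, \Delta G_{\mathrm{bp},j}$, with
$M_{ij} \in \{-1, 0, +1\}$ a signed incidence matrix. A change variable
is written by codon position and pair, codon base first —
`P1 A·U→G·U` means the first position of the first codon goes from an
A·U Watson–Crick pair to a G·U mismatch upon slippage. A change
occurring in its canonical direction enters with $+1$; the reverse
change enters with $-1$ (none of the shipped designs happens to contain
a reverse occurrence, which a test asserts, but the machinery supports
them).

Given measured efficiencies with replicate standard deviations, Bayes'
rule combines a Gaussian likelihood per variant with a uniform prior on
each $\Delta G_{\mathrm{bp},j}$ over $[-25, 25]$ kJ/mol, and the
posterior is sampled by Metropolis-within-Gibbs: per step, one Gaussian
proposal (sd 0.2 kJ/mol) per free variable in sequence, accepted with
probability $\min(1, f_\mathrm{new}/f_\mathrm{old})$ evaluated in log
space.

### The kinetic extension

To test the equilibration assumption itself, the model can be extended
by a kinetic factor derived from a two-state master equation with
Arrhenius rates over a slippage barrier:
$\mathrm{FS}_\mathrm{kinetic} = \mathrm{FS}\cdot(1-\kappa)$ with
$\kappa = \exp\!\left(-C\,[1 + e^{\Delta G/kT}]\right)$. Attempt
frequency, pause duration and barrier height are deliberately lumped
into the single nonnegative parameter $C$ — they are not separately
identifiable and the package never represents them individually. Rather
than sampling $C$, the *mean* kinetic factor $\bar\kappa$ over the
dataset is sampled as a nuisance parameter (uniform prior on $[0,1]$,
Gaussian proposals of sd 0.001); at every likelihood evaluation $C$ is
re-solved from $\bar\kappa$ by bisection so that the per-variant
$\kappa_i$ average to it. Data generated in equilibrium concentrate
$\bar\kappa$ against zero; damped data recover the generating value
(both are test-asserted).

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `temperature` | 310 | K | physiological; $kT$ realized as $RT$ = 2.5773 kJ/mol because free energies are per mole |
| `n_steps` | 10⁶ | steps | the scale at which all posterior summaries, including prior-wide flat directions, are converged |
| `n_chains` | 2 | — | two independent chains; summaries pool post-burn-in samples (flagged in the output) |
| `proposal_sigma` | 0.2 | kJ/mol | matches the posterior width of determined variables; part of the algorithm's definition, not auto-tuned |
| `prior` | [−25, 25] | kJ/mol | generous box: ±10 kT, far beyond any plausible single-pair energy |
| `burn_in` | 0.20 | fraction | discarded from every chain (and from every prefix in convergence curves) |
| `kappa_proposal_sigma` | 0.001 | — | $\bar\kappa$ needs fine steps since its posterior is extremely narrow near 0 |
| `kappa_init` | 0.01 | — | exactly 0 makes $C$ degenerate, so the kinetic chain starts just above it |
| `sd_threshold` | 2 | kJ/mol | determined/underdetermined boundary: determined sds are sub-kJ/mol, prior-scale sd is ≈ 14.4, so any threshold of a few kJ/mol separates the regimes |
| `strong_r` | 0.9 | — | correlation magnitude treated as strong coupling |

## Numerical choices

* **Overflow-safe logistic.** `fs_from_dg()` uses
  $1/(1+e^{\Delta G/kT})$ (via `plogis`), stable for
  $|\Delta G| \gg kT$. `dg_from_fs()` rejects FS of exactly 0 or 1:
  such values only bound $\Delta G$ and have no finite inverse.
* **Closed prior box.** Proposals landing outside $[-25,25]$ are
  rejected through the prior (the acceptance uniform is still drawn so
  the RNG stream layout is fixed); the boundary itself is included.
* **Initialisation.** All free energies start at 0 kJ/mol.
* **RNG discipline.** Chain $c$ is seeded with `seed + c − 1`. Each
  sub-step consumes exactly two draws — proposal, then acceptance
  uniform — in that order, so runs are bit-reproducible and the
  compiled sampler is bit-identical to the pure-R reference
  implementation on the same seed (test-asserted).
* **Bisection for $C$.** The mean-$\kappa$ curve is strictly decreasing
  in $C$; the inversion brackets by doubling and bisects to relative
  tolerance 1e−10. $\bar\kappa$ of exactly 0 (or 1) is handled as the
  exact limit $\kappa_i \equiv 0$ (or 1) rather than through the
  degenerate $C$.
* **Rank.** Design-matrix rank uses SVD with relative tolerance 1e−8 —
  integer matrices with a well-separated spectrum make this
  unambiguous.
* **Replicate sigmas of 0** are floored at 0.005 with a warning: the
  Gaussian likelihood is undefined at 0 and replicate scatter below
  half a percentage point is beyond the assay's resolution.
* **Percent vs fraction.** All internal efficiencies are fractions;
  conversion happens only in the table reader (a column whose maximum
  exceeds 1.5 is interpreted as percent) and rmsd, which is reported in
  percentage points.
* **Pin tie-break.** The pinning representative is the persistent
  underdetermined variable with the most strong couplings; ties are
  broken deterministically by reverse-alphabetical label. On both
  shipped registries every coupled variable ties at two couplings, and
  this rule pins the wobble-position (P3) representatives — the
  scientifically natural choice, since the first-position variables are
  the quantities of interest.

## Identifiability and mixing

The 64-variant Lys/Phe design spans 16 change variables of which 14 are
independent: the P3 wobble change of each tRNA family co-occurs with
one of two A1 changes, so only the pairwise sums are determined. In the
posterior this appears as near-perfect *anti*-correlation between the
P3 representative and each partner (the sum is fixed) together with
near-perfect positive correlation between the two partners. Pinning a
representative to 0 kJ/mol collapses the flat direction, and the
partner's posterior then measures the free energy of the *combination*.
`iterative_pinning()` automates the cycle: fit, flag persistent
large-sd variables, pin one, repeat, then pin all representatives
simultaneously; the data rmsd is unchanged across steps because the
flat directions carry no signal (test-asserted).

Flat directions also set the package's convergence scale. A
single-variable random walk with 0.2 kJ/mol proposals crosses the
50 kJ/mol prior box only diffusively, with a mixing time of order 10⁶
steps — the default chain length. The test suite therefore chooses its
problem sizes deliberately: determined posteriors are exercised with
2–5 × 10⁴ steps; identifiability analyses (which must let
underdetermined sds grow past the 2 kJ/mol threshold) use 1.5 × 10⁵;
grid-oracle comparisons check determined quantities (marginals of
identifiable problems, or the determined sum of a degenerate one) where
mixing is fast, and treat means of prior-wide marginals — the slowest
statistic of the walk — with correspondingly coarse tolerances. These
sizes are statements about the sampler's physics, and the vignette
records them so users scale expectations to their own data.

## The synthetic-data generator

`simulate_fs_dataset()` emulates the structure the inference assumes: a
variant design, ground-truth per-change free energies, optional kinetic
damping via a true $\bar\kappa$, and Gaussian replicate noise (default
sd 0.02, the scale of replicate scatter in in-vitro frameshifting
assays) truncated to $[0.001, 0.999]$ by resampling — truncation rather
than clipping avoids point masses at the boundaries that the Gaussian
likelihood could not represent. Ground truths in recovery tests are
drawn in $[-6, 6]$ kJ/mol, the range of fitted single-pair energies.

What the generator does *not* emulate: per-variant heteroscedastic
replicate sds (real assays vary severalfold between variants), model
misfit (real pairing energetics need not be exactly additive), and
measurement error correlated across variants sharing reagents. Passing
recovery tests therefore demonstrates the estimator's correctness under
its own assumptions, not the adequacy of those assumptions for any
particular dataset.

```{r, eval = FALSE}
design <- enumerate_invitro_design()
truth  <- setNames(runif(16, -6, 6), invitro_registry())
dat    <- simulate_fs_dataset(design, truth, sigma = 0.02, seed = 1)
fit    <- fs_fit(dat, pin = c("P3 G.S->A.S", "P3 C.G->U.G"),
                 n_steps = 5e4, seed = 1)
summary(fit)
```

## Design choices on open points

* **Pooling.** Posterior summaries pool the chains after burn-in; the
  summary carries a `pooled` flag. Per-chain behaviour remains
  inspectable through `convergence_curve()`, which requires the chains
  to plateau at a common rmsd.
* **Out-of-box proposals** are rejected (not resampled); with a
  symmetric proposal either convention targets the same distribution,
  and rejection keeps the per-sub-step RNG cost fixed.
* **Predictions for uncovered variables.** Predicting a variant whose
  changes the fit never saw draws those variables from the prior, with
  a warning — the prediction honestly carries prior-wide uncertainty
  instead of failing or silently extrapolating.
* **Leave-one-out refits** default to 2 × 10⁵ steps so that N refits
  stay desk-scale; the full 10⁶ is available through `n_steps`.
* **No shell entry point.** The package follows the R modelling idiom
  (fit object + methods); file-based workflows go through
  `read_variant_table()`, `write_posterior_csv()`,
  `write_fit_summary_json()`, `write_predictions_tsv()` and
  `write_manifest()`, which serialize everything a rerun needs.

## Limitations

* The stimulatory element (stem-loop or pseudoknot) is outside the
  model: it sets the pause that justifies the equilibrium assumption
  but contributes no term. Only −1 slippage on X XXY YYZ heptamers is
  modelled — no +1/−2 events, no non-heptamer sites.
* Efficiencies of exactly 0 or 1 carry only one-sided information; the
  likelihood handles them gracefully only insofar as replicate noise
  keeps measured values inside the open interval.
* Base-pair identity is literal character equality of codon and
  anticodon codes; wobble/Watson–Crick classification is annotation,
  never an energetic input.
* The pairwise additivity assumption is untestable from designs in
  which second-position pairs never change; coupling between
  simultaneous first/second-position changes would require new data.
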