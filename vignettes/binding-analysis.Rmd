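---
title: "Models and methods: fitting bipartite nucleosome-binding titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: fitting bipartite nucleosome-binding titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindfit)
```

# The problem

A reader domain that recognises a methylated lysine close to the nucleosome
core can bind the isolated histone-tail peptide with an affinity in the tens
of millimolar and duplex DNA in the hundreds of micromolar, yet bind the
methylated nucleosome at low micromolar affinity, because the aromatic-cage
and DNA-binding surfaces engage simultaneously. Measuring the three
affinities requires three experimental regimes, and each regime dictates a
different fitting model:

* the peptide and DNA titrations are in **fast exchange** — a single
  population-averaged resonance shifts continuously, and the combined
  chemical shift perturbation (CSP) traces fractional saturation;
* the nucleosome titration is in **intermediate-fast exchange** — peak
  positions, widths and shapes all carry information, so the full
  Bloch–McConnell line shape must be fitted;
* the gel-shift (EMSA) titration resolves the species with 0, 1 and 2
  bound domains per nucleosome — two H3 tails give two equivalent sites —
  and is fitted with a 2:1 binding model.

This vignette records the models, the numerical choices, the synthetic-data
conditions under which the package validates itself, and the design
decisions that were genuinely open.

# Equilibrium models

## 1:1 binding with depletion

For receptor total $P_0$, ligand total $L_0$ and dissociation constant
$K_D$, the complex concentration is the admissible root of
$[PL]^2 - (P_0 + L_0 + K_D)[PL] + P_0 L_0 = 0$. `solve_1to1_complex()`
always evaluates the stable product/sum form
$[PL] = 2 P_0 L_0 / (b + \sqrt{b^2 - 4 P_0 L_0})$, $b = P_0 + L_0 + K_D$,
which remains accurate in the stoichiometric limit $K_D \to 0$ where the
textbook quadratic root cancels catastrophically. The depletion-corrected
form is used unconditionally, even deep in the weak-binding regime where the
hyperbolic approximation would suffice: one code path, no regime bugs.

## Two equivalent sites

The nucleosome carries two H3 tails. They are modelled as equivalent and
independent: nothing in the data demands cooperativity, the two tails are
related by the particle's pseudo-symmetry, and the same model must serve
both the EMSA fit and the line-shape fit. Free ligand $x$ solves
$x + 2N_0\,x/(K_D + x) = L_0$ (a quadratic, again evaluated in stable
form), the per-site occupancy is $\theta = x/(K_D + x)$, and independence
makes the species distribution binomial,
$(f_0, f_1, f_2) = ((1-\theta)^2,\, 2\theta(1-\theta),\, \theta^2)$.
`solve_two_site()` returns all of these; the tests cross-check the
fractions against an exhaustive enumeration of the four site
configurations and the free-ligand root against bisection.

## Avidity

When two linked epitopes with site affinities $K_{D,tail}$ and $K_{D,DNA}$
combine into one complex of affinity $K_{D,complex}$, the enhancement can be
summarised as an effective concentration
$C_{eff} = K_{D,tail} K_{D,DNA} / K_{D,complex}$ — the apparent local
concentration one epitope presents to its partner once the other is bound.
`effective_concentration()`, `fold_enhancement()` and `complex_lifetime()`
implement this arithmetic; with site affinities of 17 mM and 150 µM
combining into a 1.5 µM complex the effective concentration evaluates to
1.7 M, far above the mM range typical of linked DNA-binding domains, and
the enhancement over the peptide alone rounds to 10,000-fold.

# CSP analysis

`combined_csp()` uses $\sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_X)^2}$
with $w = 0.2$ for amide ¹⁵N and $0.3$ for ¹³C — the conventional scalings;
the weight is configurable because no universal value exists.
`csp_threshold()` implements the customary significance cutoff, trimmed
mean + 2σ with 10% trimmed from each tail. The σ is computed on the trimmed
set by default (an untrimmed option exists): the cutoff's purpose is to
flag outliers against the bulk, so the bulk statistics should not be
contaminated by the outliers being flagged.

`fit_csp()` fits all residue curves *globally*: one shared $K_D$, one
$\Delta\delta_{max,r}$ per residue, residuals on the combined CSP. In the
weak-binding regime no single residue approaches saturation, so pooling
residues is what makes the estimate usable at all. For fixed $K_D$ the
amplitudes are linear and solved in closed form, reducing the optimisation
to one dimension; a 25-point log-spaced grid over $10^{-7}$–$1$ M followed
by golden-section refinement makes the search deterministic and immune to
local minima. Degenerate inputs error early: all-zero curves ("no binding
signal"), fewer than four titration points ("under-determined").

Confidence intervals are profile-likelihood: the 95% interval contains all
$K_D$ with $RSS(K_D) \le RSS_{min}(1 + F_{1,df;0.05}/df)$. On an
unsaturated, truncated titration the interval is strongly asymmetric
(upper/lower span ratio above 2), mirroring the behaviour of weak-peptide
fits restricted to low ligand concentrations; an upper crossing that does
not exist within the searched range is reported as `Inf` rather than a
fabricated number. `truncate_series()` restricts a curve set to points at
or below a ligand cutoff (the free point always survives), for titrations
in which only the initial interval is comparable between experiments.

# Exchange line-shape analysis

The observed spin is a methyl group on the H3 tail near the methylation
site. Because the two tails are treated as identical independent reporters,
a **two-state** (free/bound site) exchange matrix suffices; the 1:2 binding
scheme enters through the mass balance that sets the populations, not
through a third exchange state. The evolution operator is

$$ L = \begin{pmatrix} i\Omega_f - R_{2,f} - k_{on}' & k_{off} \\
k_{on}' & i\Omega_b - R_{2,b} - k_{off} \end{pmatrix}, \qquad
k_{on}' = k_{off}\, x / K_D, $$

whose kinetic part has zero column sums by construction (population
conservation), and whose equilibrium $p_{bound} = x/(K_D+x)$ equals the
mass-balance occupancy exactly. The FID is propagated by closed-form
eigendecomposition of the 2×2 complex matrix — exact and step-size-free;
the degenerate (exceptional-point) case falls back to stepwise propagation
with the analytic 2×2 exponential. Spectra are produced by exponential
apodization, first-point halving, two-fold zero filling and FFT, scaled so
the unapodized spectral integral equals FID(0). The tests require agreement
with an independently coded frequency-domain (resolvent) solution to 0.1%
RMS across slow, intermediate and fast regimes, integral conservation to
0.5%, and the textbook coalescence behaviour on a rate scan.

`fit_exchange()` fits a titration series jointly: shared $(K_D, k_{off},
\Delta\omega, R_{2,free}, R_{2,bound})$ plus a closed-form per-trace scale.
The free-state offset is pinned by the zero-ratio reference trace.
Optimisation is Nelder–Mead over $(\log K_D, \log k_{off}, \Delta\omega,
\log R_2)$ from six log-spaced starts ($K_D \in \{0.1, 1, 10\}$ µM ×
$k_{off} \in \{100, 1000\}$ s⁻¹, a generic decade grid), then a tighter
polish of the best start — deterministic, no RNG. The trace axis is ¹³C by
default at a 900 MHz ¹H field (¹³C frequency 226.19 MHz via the fixed
gyromagnetic ratio 0.2513222); the axis nucleus is explicit in
`acquisition_params()` rather than guessed, since a 1D trace through a 2D
cross-peak could run along either dimension.

95% intervals come from a likelihood-ratio threshold on warm-started
profile grids over $\log K_D$ and $\log k_{off}$ (nuisance parameters
re-optimised at each grid point). When the χ² surface stays below threshold
out to a grid edge the corresponding bound is flagged
(`kd_lower_open` etc.) instead of being reported as a number: with
near-stoichiometric binding a titration genuinely determines only an upper
bound on $K_D$, and the fit says so. An alternative to the grid —
posterior sampling — was considered and rejected: the likelihood-ratio grid
is deterministic, cheap at this dimensionality, and its one-sided flags map
directly onto how such bounds are reported.

# EMSA analysis

`lane_fractions()` converts the three band densities of a lane into
fractions. Equal detection response per nucleosome across bands is assumed
because the intercalator stains the same DNA in every species; a per-band
response-correction vector is accepted for cases where that fails.
`fit_emsa()` fits fractions, not raw densities: normalisation removes the
per-lane loading factor that would otherwise be a nuisance parameter per
lane, and the fit is provably invariant to lane rescaling (tested). The
predicted fractions are binomial in θ from the two-site model; the residual
is summed over all three species and lanes, minimised over $\log K_D$ by
the same grid-plus-refinement search as the CSP fit, with profile
intervals. Each lane contributes two independent observations (the three
fractions sum to one), which sets the degrees of freedom. A titration whose
equivalents never reach 0.5 is rejected ("titration does not constrain
kd"). Receptor concentrations from gel loads are converted by
`amount_to_molar()`; 1.5 pmol and 3 pmol in 8 µL (0.1875 and 0.375 µM) are
the documented presets.

# Synthetic data: what it emulates and what it does not

The generators produce data with the statistical structure the fitters
assume, at the concentrations of the emulated study conditions:

* **CSP** (`csp_defaults()`): receptor 0.3 mM. Peptide schedule 0, 0.5, 1,
  2, 4, 8, 16, 30 mM ($K_D$ 17 mM; ~64% bound at the top point); DNA
  schedule 0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.2 mM ($K_D$ 150 µM; ~86%
  saturated); MLA-peptide schedule 0, 0.25, 0.5, 1, 2, 4 mM ($K_D$ 11 mM,
  fitted with the 4 mM truncation). The exact numbers of additions are
  assumptions — only stock concentrations and the truncation point are
  stated conditions — chosen as what a titration limited by those stocks
  can realistically reach. Noise is Gaussian on the combined CSP, σ =
  0.004 ppm (0.003 ppm for the MLA series), a typical read-off precision
  for well-resolved amide peaks; peak-list emission splits each CSP
  between ¹H and ¹⁵N at a fixed 35° angle so the curves are exactly
  recoverable from the lists.
* **Line shapes** (`exchange_defaults()`): nucleosome 116 µM, ratios 0,
  0.5, 1, 1.8, 2.7, truth $K_D$ 1.5 µM / $k_{off}$ 500 s⁻¹, Δω 0.35 ppm
  ¹³C, $R_2$ 8 s⁻¹ (mobile free tail) and 40 s⁻¹ (rigidified bound state),
  2% multiplicative peak-height noise. Δω and the $R_2$ values are not
  experimental constants but generator defaults chosen to reproduce the
  qualitative appearance of a sharp tail resonance broadening on binding;
  the intermediate ratios are assumptions (only the 2.7 endpoint is a
  stated condition).
* **EMSA** (`emsa_defaults()`): nucleosome 0.375 µM, equivalents 0, 0.5,
  1, 2, 3, truth $K_D$ 0.5 µM, 5% truncated-at-zero fraction noise and a
  uniform 0.8–1.2 lane-loading factor.

Every generator is a single seeded RNG stream: identical (spec, seed) give
byte-identical output, and at σ = 0 every dataset round-trips through its
fitter with exact recovery.

What passing the recovery tests does **not** show about real data: the
generators draw i.i.d. noise, so they cannot expose systematic errors —
peak overlap and tracking mistakes in crowded spectra, baseline and phase
distortions in the traces, smeared or partially resolved gel bands,
concentration errors in the stocks, or a genuinely anti-cooperative second
site. The recovery tolerances quantify statistical, not systematic,
uncertainty.

# Problem sizes and runtimes

The validation suite uses 100 replicates for each CSP and EMSA recovery, 50
for the line-shape recovery, and 512-point traces (zero-filled to 1024)
over a 2 ppm window — sizes at which the full suite and the recovery
script each complete in a few minutes on a single core while leaving the
medians stable to well within the acceptance tolerances. Oracle
comparisons use finer 2048-point acquisitions so that discretisation does
not limit the 0.1% agreement requirement.

# Known limitations

* Two exchange states only: a ternary pathway in which the domain binds
  DNA before capturing the tail (a third NMR state) is not modelled; if
  present it would be absorbed into the effective two-state rates.
* Sites are strictly equivalent and independent; anti-cooperativity between
  the two tails would bias the EMSA $K_D$ and is deliberately not modelled
  without evidence for it.
* No Hill models, no more than two sites, no kinetic (pre-equilibrium)
  titrations, no 2D spectra, no relaxation dispersion, no multiplet
  structure, and no gel image segmentation — lane densities are taken as
  given.
* The line-shape χ² treats every spectral point as independent; correlated
  baseline noise would make the likelihood-ratio intervals optimistic.
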