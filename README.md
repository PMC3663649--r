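# bindfit

Equilibrium binding analysis for bipartite nucleosome recognition.

Reader domains that recognise histone marks near the nucleosome core often
bind the isolated methylated peptide astonishingly weakly (tens of mM) and
naked DNA only modestly better (hundreds of µM), yet engage the methylated
nucleosome with µM affinity. Quantifying that avidity requires three
different titration read-outs, each with its own fitting model, and this
package implements all three for the practising spectroscopist or
biochemist:

1. **CSP isotherms** — combined chemical shift perturbations
   Δδ = √(Δδ_H² + (w·Δδ_X)²) fitted globally (one shared K_D, one Δδ_max
   per residue) to the depletion-corrected 1:1 fast-exchange model, with the
   bound fraction from the exact mass-balance quadratic
   [PL]² − (P₀+L₀+K_D)[PL] + P₀L₀ = 0. Profile-likelihood 95% intervals,
   trimmed-mean + 2σ significance thresholds, and truncation of unsaturated
   schedules are included.
2. **Bloch–McConnell line shapes** — 1D traces of a reporter spin in
   two-state exchange are simulated by explicit evaluation of the 2×2
   complex exchange matrix (eigendecomposition, then FID and FFT) with the
   free/bound populations tied to a two-equivalent-site (1:2
   receptor:ligand) mass balance: free ligand x solves
   x + 2N₀·x/(K_D+x) = L₀, site occupancy θ = x/(K_D+x), pseudo-first-order
   on-rate k_off·x/K_D. Joint fitting over a titration series yields the
   microscopic K_D and k_off with likelihood-ratio intervals that are
   flagged one-sided when a saturating titration only bounds K_D from
   above.
3. **EMSA densitometry** — free/+1/+2 band densities are normalised to
   species fractions and fitted to the same two-site model, whose species
   distribution is binomial in θ: ((1−θ)², 2θ(1−θ), θ²).

The avidity arithmetic connects the pieces: the effective concentration
C_eff = (K_D,tail × K_D,DNA)/K_D,complex, the fold enhancement
K_D,ref/K_D,complex, and the complex lifetime 1/k_off.

Seeded generators (`simulate_csp_titration()`, `simulate_exchange_titration()`,
`simulate_emsa_titration()`) emulate each experiment, so every fitter is
validated by parameter recovery, and a config-driven `run_pipeline()` plus a
thin CLI (`inst/scripts/bindfit.R`) cover file-based workflows (Sparky-style
peak lists, TSV curve/lane/manifest tables, two-column traces, JSON
reports).

## Worked example

```r
library(bindfit)

# a DNA-binding CSP titration: 0.3 mM receptor, Kd truth 150 uM
sim <- simulate_csp_titration(csp_defaults("csp_dna"), seed = 1)
fit <- fit_csp(sim$curves, receptor_total = sim$spec$receptor_total)
summary(fit)
#> Global 1:1 fast-exchange CSP isotherm fit
#>   Kd: 0.0001491 M (0.1491 mM)
#>   6 residues, 7 titration points, residual RMSD 0.003222 ppm
#>   95% CI (profile likelihood): 0.1283 - 0.1726 mM
#>   Saturation CSPs (ppm):
#>     18     21     44     46     49     74
#> 0.2225 0.2490 0.1835 0.1198 0.0771 0.0483

# an EMSA titration: 0.375 uM nucleosome, 0-3 equivalents, Kd truth 0.5 uM
lanes <- simulate_emsa_titration(emsa_defaults(), seed = 1)
fit_emsa(lanes, attr(lanes, "receptor_total"))
#> 2:1 EMSA band-density fit (two equivalent sites)
#>   microscopic Kd: 5.273e-07 M (0.5273 uM)
#>   95% CI: 0.377 - 0.73 uM; RSS 0.03789 on 5 lanes

# avidity arithmetic for site affinities 17 mM (tail) and 150 uM (DNA)
# combining into a 1.5 uM complex with koff 500 1/s
effective_concentration(17e-3, 150e-6, 1.5e-6)   # 1.7 M
fold_enhancement(17e-3, 1.5e-6)$nearest_power_of_ten  # 10000
complex_lifetime(500)                            # 0.002 s
```

The recovered K_D values sit within the profile intervals of their
generator truths (150 µM and 0.5 µM); the avidity numbers say that once one
epitope is engaged, the second sees its partner at an apparent local
concentration of 1.7 M — a ~10,000-fold affinity enhancement over the
isolated peptide — while the complex itself turns over every 2 ms.

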