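# deerens

Solution-state conformational ensembles of homodimeric membrane proteins
from DEER (PELDOR) distance distributions.

Membrane-bound pyrophosphatases and other homodimeric transporters work by
switching protomers between *open* and *closed* conformations, and a central
mechanistic question is whether the two protomers move together or break
symmetry (one open, one closed). Pulsed EPR double electron-electron
resonance (DEER) answers this in solution: spin labels attached at one
residue of each protomer report the inter-label distance distribution, which
can be compared with distributions predicted from candidate atomic models.
`deerens` implements that complete analysis for practitioners:

* **Forward model** — the four-pulse DEER dipolar kernel
  `K(t, r) = ∫₀¹ cos[(1 − 3x²) ω(r) t] dx` with
  `ω(r) = 2π · 52.04 MHz·nm³ / r³`, stretched-exponential intermolecular
  background `B(t) = exp(−k t^{d/3})`, modulation depth λ, and trace
  simulation `V(t) = [(1 − λ) + λ K P] B(t) + ε`.
* **Inversion** — phase and background correction, then non-negative
  Tikhonov regularisation
  `min_{P≥0} ‖K P − S‖² + α²‖L P‖²` with the regularisation parameter α
  selected at the L-curve corner, an automated background-start scan with a
  pruned consensus, a 16 + 50 trial background/noise validation ensemble
  yielding 2σ confidence bands, reliability zones, and modal/FWHM/σ summary
  statistics.
* **In-silico labelling** — accessible-volume R1 (MTSSL) rotamer clouds on
  PDB/mmCIF structures with a zero-clash "tight" mode, predicted inter-label
  distance distributions, Kabsch superposition and per-Cα RMSD, and
  asymmetric hybrid dimers assembled from one chain of each of two
  structures.
* **Model selection** — the Bhattacharyya coefficient
  `BC = Σₙ √(P(n)·Q(n))` on a reconciled common grid, ranking candidate
  conformational models against each experimental distribution.
* **Synthetic study** — a generator reproducing the full study design
  (sixteen ligand/site conditions with stated acquisition windows, truth
  distributions at the reported modal/σ values, and toy labelled dimers in
  open/closed/hybrid states) so every stage is testable without downloads.

## Worked example

Simulate an apo-state periplasmic-site measurement (truth: modal 3.8 nm,
σ = 0.60 nm), invert it, and rank conformational models built from the toy
dimer:

```r
library(deerens)

truth <- gaussian_mixture(data.frame(modal = 3.8, sigma = 0.60, weight = 1))
trace <- simulate_trace(truth, background_fit(k = 5e-5, lambda_mod = 0.3),
                        acquisition_params(tau2 = 5000, dt = 4),
                        noise_sd = 0.01, seed = 7)
inv <- invert_trace(trace, t_cut = 4000)
unlist(inv$stats)
#>     modal      fwhm     sigma      mean
#> 3.8000000 1.5453146 0.6562347 3.8198382
```

The modal distance is recovered exactly on the grid and the width to
within ten percent.
Ranking toy-dimer models against a closed-open mixture (the signature of an
asymmetrically inhibited dimer):

```r
models <- list(
  open_open     = gaussian_mixture(data.frame(modal = 6.8, sigma = 0.3, weight = 1)),
  closed_open   = gaussian_mixture(data.frame(modal = 5.8, sigma = 0.3, weight = 1)),
  closed_closed = gaussian_mixture(data.frame(modal = 4.8, sigma = 0.3, weight = 1)))
experimental <- gaussian_mixture(data.frame(modal = c(5.8, 5.0),
                                            sigma = c(0.51, 0.30),
                                            weight = c(0.8, 0.2)))
rank_models(experimental, models, condition = "+IDP-like")
#>   condition         model   bc n_grid
#> 1 +IDP-like   closed_open 0.88    326
#> 2 +IDP-like closed_closed 0.61    326
#> 3 +IDP-like     open_open 0.41    326
```

Higher coefficients (closer to unity) signify better overlap; the
closed-open model wins, i.e. the data favour one closed and one open
protomer.

The `analysis/` directory holds the full workflow as numbered drivers —
`01_simulate_study.R` (generate the sixteen-condition study),
`02_invert_conditions.R` (invert every trace and tabulate recovered vs true
statistics), `03_predict_models.R` (accessible-volume labelling of the toy
dimers), `04_compare_models.R` (Bhattacharyya ranking per condition) — each
writing its tables under `results/`.

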