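---
title: "DEER conformational-ensemble analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DEER conformational-ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(deerens)
```

This vignette is the package's account of the science it implements: the
forward and inverse models, the parameters that matter and their defaults,
what the synthetic study does and does not emulate, the numerical choices,
and the known limitations.

## The measurement and its forward model

Four-pulse DEER measures the dipolar coupling between two unpaired
electrons — here, nitroxide spin labels (R1, from MTSSL) attached to the
same residue on the two protomers of a homodimeric membrane protein. After
powder (orientation) averaging, a pair at distance $r$ contributes

$$K(t, r) = \int_0^1 \cos\!\big[(1 - 3x^2)\,\omega(r)\,t\big]\,dx,
\qquad \omega(r) = \frac{2\pi \cdot 52.04\ \mathrm{MHz\,nm^3}}{r^3},$$

the 52.04 MHz nm$^3$ constant being the electron–electron dipolar frequency
for nitroxide $g \approx g_e$ (the test suite re-derives it from CODATA
constants). An ensemble with distance distribution $P(r)$ gives the form
factor $F(t) = \int K(t,r)P(r)\,dr$; the recorded echo amplitude adds an
intermolecular background and a modulation depth $\lambda$:

$$V(t) = \big[(1 - \lambda) + \lambda\,F(t)\big]\,B(t) + \varepsilon,
\qquad B(t) = e^{-k t^{d/3}}.$$

$d = 3$ (plain exponential) describes a homogeneous three-dimensional spin
bath and is the default; membrane-confined samples can be modelled with
$1 \le d \le 6$. The deposited acquisition settings of the emulated study
are built in: interpulse delays $\tau_1 = 380$ ns and $\tau_2$ of
4000–5000 ns, dipolar increments of 4 ns (periplasmic site) or 12 ns
(cytoplasmic site and the second-instrument conditions), with the
periplasmic traces truncated to 4000 ns during processing to suppress the
'2+1' pulse-overlap artefact.

Numerically the kernel is evaluated by Gauss–Legendre quadrature over the
orientation variable with the node count scaled to each distance column's
maximum dipolar phase (about 1.35 nodes per radian of phase span plus
margin). This reproduces the Fresnel-integral closed form to better than
$10^{-9}$ everywhere on the default grids — the closed form stays in the
test suite as an independent oracle — while being an order of magnitude
faster than evaluating Fresnel integrals element-wise, which matters
because the validation ensemble inverts thousands of kernels.

## Inversion

The distance distribution is recovered by non-negative Tikhonov
regularisation,

$$\min_{P \ge 0}\ \|K P - S\|^2 + \alpha^2 \|L P\|^2,$$

with $L$ the second-difference (roughness) operator and $S$ the
background-corrected form factor. The default distance grid is 1.5–8.0 nm
in 0.02 nm steps, covering the 3.4–6.8 nm range of the study with margin.
The solver is an active-set non-negative least-squares method (FNNLS) on
the normal equations, warm-started from the support of the solution at the
neighbouring regularisation parameter; a KKT check with cold-restart
fallback guards against floating-point cycling on ill-conditioned systems.

**Choosing $\alpha$.** Candidates span $10^0$–$10^4$ on a quarter-decade
ladder. The corner of the log–log misfit/roughness curve is located as the
point nearest the lower-left corner after normalising both axes to [0, 1].
Discrete maximum curvature — the other common convention — was evaluated
and rejected: with the non-negativity constraint the small-$\alpha$ branch
of the L is too shallow, and maximum curvature lands on the over-smoothed
upper bend, inflating recovered widths by tens of percent. Two
refinements stabilise the corner: points whose misfit exceeds 1.2× the
misfit floor are excluded from the search (they belong to the deep
over-smoothed branch and only stretch the normalisation), and near-ties —
corner-distance within 10% of the minimum, common because the corner
region is flat — resolve to the smoother solution.

**Background determination.** A stretched-exponential tail fit is linear in
log-space and is computed at every candidate start fraction (10–80% of the
window). Each candidate is scored by how well its resulting inversion
reconstructs the *raw* trace, plus a penalty of $0.1 \times$ the
probability mass in the top 5% of the distance range: mass piling up at the
long-distance edge is the signature of background decay leaking into the
distribution, and raw misfit alone cannot see it because the leaked
solution fits equally well. Candidates whose fit window is shorter than one
dipolar period of the (pilot) modal distance are excluded — over such
windows the oscillation cannot average out of a least-squares fit, which
biases the modulation depth; this matters for modal distances above
~5 nm, where the period approaches the acquisition window itself.
Surviving candidates within 1.15× of the best raw misfit are re-inverted
at the selected $\alpha$ and averaged into a consensus distribution
(members whose global mode collapsed onto the grid edge are excluded as
leak artifacts), so the headline estimate is insensitive to the exact
background-start choice.

**Validation.** `validate_trace()` implements the two-round protocol: a
first round varies the background start over 16 equally spaced fractions of
5–80% of the window; the trace is reprocessed with the best start; the full
round varies the start again and adds white Gaussian noise at 1.50× the
estimated noise level for 50 replicates. "Level 1.50" is interpreted as a
multiple of the noise standard deviation estimated from the data (from the
quadrature channel where present, else from second differences of the
corrected trace tail) — the only dimensionless reading. Trials whose misfit
exceeds 1.15× the best trial's are pruned (the unperturbed base trial is
always kept), and the consensus is the pointwise mean ± 2 standard
deviations over kept trials, the 2σ (95%) band.

**Reliability zones.** For a window of length $t_{\max}$, a feature of the
distribution at distance $r$ is only determined if enough dipolar
oscillation periods fit in the window. The boundaries are
$r_{\max} = (52.04 \cdot t_{\max}/n)^{1/3}$ nm with $t_{\max}$ in µs and
$n = 2$ periods for the full peak shape, $1$ for the width, $1/2$ for the
mean distance and $1/4$ for mere detectability. For a 4 µs window the shape
is reliable to 4.7 nm; for 5 µs, to 5.1 nm — which is why width estimates
at 5.8–6.0 nm from a 5 µs window are intrinsically marginal (they sit
between the shape and width bounds), and why the background consensus
above earns its keep there.

**Summary statistics.** The modal distance is the grid argmax (ties to the
smaller distance); the FWHM is the half-maximum interval around the global
mode with interpolated crossings, and $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$.
For multimodal densities the FWHM describes the main peak only; note the
inherent discontinuity when a secondary mode's dip sits near half-maximum —
an inversion that resolves the dip reports the narrow main-peak width,
one that merges it reports the broad envelope width.

## In-silico labelling

`label_site()` implements the accessible-volume approach: the R1 side
chain is reduced to its five rotatable bonds carrying SG, SD, a methylene
carbon, the ring-attachment carbon and the nitroxide N–O (idealised
internal geometry; the reporter point is the N–O bond midpoint, the
convention of the standard labelling tools). Dihedrals are drawn uniformly
at random — accessible-volume, not rotamer-library weighting — with 2000
samples per site under a fixed seed. In the default `"tight"` mode a
conformer is retained only with zero heavy-atom contacts below 2.5 Å
against the structure; `"loose"` tolerates up to five. The labelled residue
itself is excluded from the clash environment (its own side chain is being
replaced, and its backbone is bonded to the label stem); CB is built from
idealised tetrahedral backbone geometry when absent. Retained reporter
points enter a weighted pairwise-distance histogram convolved with a
0.05 nm Gaussian (2.5 grid steps, enough to suppress spurious
multimodality from finite sampling).

Predicted modal distances carry a method dependence of roughly 0.1–0.3 nm
relative to other labelling tools (different internal geometries and clash
criteria), which is why comparisons against predictions should use
tolerances of that order.

Hybrid (asymmetric) dimers are assembled by superposing each source dimer
onto a reference via shared Cα atoms (Kabsch, proper rotation enforced) and
extracting one assigned chain from each source post-transform; by
construction the hybrid's inter-site separations lie between the two
symmetric extremes.

## Model comparison

Distributions are compared with the Bhattacharyya coefficient
$BC = \sum_n \sqrt{P(n) Q(n)}$ after converting both densities to
probability vectors on a common grid: the union of the two ranges at the
finer step, linear interpolation, zero outside each distribution's own
support, then normalisation to unit sum. This reconciliation is stated
explicitly because comparisons are undefined when two distributions live on
different axes; the choice of common grid is the main source of ±0.01–0.03
variation in coefficients. Coefficients are printed to two decimals; full
precision is kept internally. Ranking is deterministic, ties breaking
alphabetically.

## The synthetic study

`default_conditions()` encodes the sixteen study conditions — eight ligand
states at each of two labelling sites — with truth distributions that are
Gaussian mixtures at the reported per-condition modal/σ values. They are
*inputs*: the study's truth statistics equal the reported values by
construction, and the round-trip tests measure how well the inversion
returns them. The cytoplasmic +IDP and +ETD conditions carry a 20% minor
component at 5.0 nm representing the fully-closed subpopulation, which
exercises multimodal statistics and model ranking. Defaults chosen where
the design left them open: noise at 1% of the zero-time amplitude
(overnight-averaged Q-band signal averaging), background $\lambda = 0.30$,
$k = 5\times10^{-5}$ ns$^{-1}$, $d = 3$ — typical for detergent-solubilised
membrane-protein samples at Q band.

The toy dimer is a ~200-atom two-chain structure with idealised helical
scaffolds, labelable residues (backbone N/CA/CB) at a periplasmic-like and
a cytoplasmic-like site whose inter-chain separations are fixed exactly by
construction (open 4.0/6.8 nm, closed 3.4/4.8 nm), a partially buried site
caged by decoration atoms, and scaffolds that are state-independent so the
open/closed models superpose cleanly. It stands in for the real open- and
closed-state structures: it reproduces their *geometry* of site
separations, not their fold, so passing tests demonstrate the labelling,
hybrid-assembly and ranking machinery — not agreement with any deposited
coordinates, which require the accession-gated checks with locally fetched
files.

What the generator does not emulate: orientation selection, multi-spin
effects, the '2+1' artefact itself (only its mitigation by truncation is
exercised), ESEEM residues, and instrument drifts. Conclusions about those
effects cannot be drawn from the synthetic study.

## Numerical choices and degenerate inputs

* Kernel tolerance $10^{-9}$ against the Fresnel closed form; small-phase
  series below $\varphi = 10^{-3}$ avoids cancellation.
* FNNLS dual tolerance scales with the gradient norm; a tiny relative ridge
  ($10^{-12}$) stabilises passive-set Cholesky solves.
* Traces must be uniformly sampled (checked; the offending index is named);
  truncation below ten sampling steps, all-zero densities, empty models,
  collinear superposition selections and sites without backbone N/CA are
  rejected with specific errors.
* Background underflow ($B < 10^{-6}$) aborts the correction rather than
  amplifying noise without bound.
* All randomness (trace noise, rotamer dihedrals, validation replicates)
  is funnelled through explicit integer seeds; identical inputs give
  byte-identical outputs.

## Problem sizes

The sixteen-condition round trip (simulate and invert at full protocol)
runs in about twenty seconds; a full 66-trial validation ensemble on a
1000-point trace takes a few tens of seconds; a 2000-sample rotamer cloud
under a second. These sizes were chosen so that the complete workflow,
tests included, runs comfortably on a laptop.

## Known limitations

* Width (σ) estimates beyond the shape-reliability bound — e.g. 5.9–6.0 nm
  peaks from a 5 µs window — carry errors up to ~30% even at high SNR;
  this is an information limit of the acquisition window, visible in the
  reliability zones, not a solver property.
* The background model is a single stretched exponential; bimodal
  backgrounds or strong ESEEM residues are outside the model.
* The reduced R1 representation does not weight rotamers energetically;
  strongly buried sites where only strained rotamers survive will be
  predicted with uniform weights.
* Parametric (Gaussian) model-based fitting of traces and simultaneous
  background+distribution optimisation are deliberately out of scope; the
  pipeline follows the two-step correct-then-invert protocol with
  validation.
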