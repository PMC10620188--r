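---
title: "Models, estimators and design choices in smSERS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in smSERS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smSERS)
```

## The measurement model

A SERS spectrum is modelled as an intensity trace on a uniform ascending
wavenumber grid, by default 400–1800 cm⁻¹ at 2 cm⁻¹ — the spectral
resolution of the spectrograph class these experiments use, spanning every
marker band the pipeline consumes (490–1750 cm⁻¹). Intensities are in
arbitrary units throughout; no absolute calibration is modelled.

The generative model behind the synthetic-data module is

  I(ν) = s · j · Σ_b A_b L(ν; c_b, γ_b) + B(ν) + ε(ν)

with `L` a unit-area Lorentzian (Gaussian and pseudo-Voigt are available),
`A_b` the band area, `s` an amplitude scale, `j = 1 + cv·z` a per-spectrum
multiplicative jitter (`z ~ N(0,1)`), `B` a slowly varying quadratic
baseline, and `ε` white Gaussian noise. Band **area**, not height, carries
intensity-ratio semantics, because Fermi-doublet ratios in the Raman
literature are integrated intensity ratios.

### Tunable parameters and their defaults

| parameter | default | why |
|---|---|---|
| lineshape FWHM | 14 cm⁻¹ | typical SERS linewidth at this resolution |
| broad amide-I FWHM (type I) | 28 cm⁻¹ | "broad" is that species' stated discriminator |
| doublet band FWHM (830/854) | 10 cm⁻¹ | the ring modes are visibly sharp and resolved; at 14 cm⁻¹ the 24 cm⁻¹ doublet is under-resolved and no windowed estimator can return the encoded area ratio |
| additive noise sd | 1 (nominal, at 1 s) | reference unit for SNR |
| baseline | 3 + 2x + 2x² (x ∈ [−1,1]) | a few noise-sd of slow curvature |
| shot-to-shot cv | 0.1 (0.15 in switching runs) | within the 20% reproducibility bound such platforms quote |
| event probability | 0.05 | the rare-event regime of a dilute bi-analyte campaign |
| dual-event probability | 0.1 | single events must dominate in the dilute regime |

SNR convention: `amplitude_for_snr()` scales a template so its noise-free
peak height equals `snr` × the nominal (1 s) noise sd; the realized noise
scales as `1/sqrt(integration_s)`. Scenario integration times follow the
acquisition settings of the corresponding experiment type: 1 s for
bi-analyte and protein censuses, 5 s time-averaged states for trap
switching, 10 s for the tyrosine pH series. This matters quantitatively:
at a bare 20:1 single-second SNR the Cramér–Rao bound for the doublet area
ratio is ≈ 0.12 sd, and only the 10 s integration brings the estimator
within the ±0.1 precision the tyrosine analysis needs.

## Detection: the 3σ rule made operational

The noise sd is estimated as the sd of residuals after removing a linear
trend in a band-free quiet region (1750–1800 cm⁻¹ by default); the
estimate is invariant to any linear baseline. Detection then searches the
Savitzky–Golay-smoothed trace (11-point cubic window) inside a named
window for a maximum above a **local linear baseline** and declares a band
present when that height reaches `k·σ` (k = 3) *and* at least three
consecutive points exceed `k·σ/2`. The run requirement is the multiplicity
control a bare 3σ rule lacks; measured over 10⁴ pure-noise draws the
per-window false-positive rate is far below the 1% budget.

Two baseline variants exist, and the difference is not cosmetic:

* **chord** through the window edges (the default for an unconfigured
  window) — robust, but a 14 cm⁻¹ band centered in a 20 cm⁻¹ window loses
  about a third of its height to the chord, which degrades detection
  efficiency at SNR 8 to ~85%;
* **flank-anchored line** — a line fitted on configured flank intervals
  outside the full band complex. The default bi-analyte windows share one
  flank support around 1604–1678 cm⁻¹, so a band in the 1630 window does
  not bias the 1650 baseline and vice versa. With it, detection efficiency
  at SNR 8 is effectively complete and the recovered event fraction equals
  the simulated occupancy.

A maximum pinned at a window edge whose trace keeps rising just outside is
rejected as a *neighboring* band (`neighbor_band` flag) rather than
clipped into the window; without this rule the 1650 cm⁻¹ NBA band
systematically leaks a false 1630 hit and single-NBA events get upgraded
to dual events. A genuine edge maximum is reported at the boundary with an
`edge_clipped` flag and a warning. Centers are refined by parabolic
interpolation **on the smoothed trace**, not on the baseline-subtracted
deviation — a tilted local baseline must not displace an apex.

Dual bi-analyte events are operationalized as simultaneous MB and NBA hits.
The alternative reading — one merged band near 1640 cm⁻¹ — is ambiguous for
resolved spectra and is not used; with both bands at the stated positions
the simultaneous-hit rule recovers ground truth exactly on noise-free
spectra.

## Second-derivative structure analysis

Band centers in the amide-I region (1550–1750 cm⁻¹) are local maxima of
−d²I/dν² (sign flipped so bands are maxima), computed as SG smoothing
(11/3) followed by an SG second derivative (15-point window, order 3) —
wide enough to suppress pixel noise, narrow enough to resolve the
19 cm⁻¹ splitting of the type-II doublet. Two thresholds gate the maxima:
3× the second-derivative noise floor, and 40% of the strongest maximum
(correlated-noise bumps occasionally clear the absolute floor; genuine
secondary amide components in this problem are comparable in strength to
the primary). The floor is estimated in 1744–1776 cm⁻¹ — deliberately
short of the axis end, because the edge kernels of the two cascaded
filters amplify noise variance severalfold over the last 12 points and
would otherwise inflate the floor.

Band **width** is reported two ways: the half-maximum width of the
second-derivative lobe (dominated by the 15-point filter: true 14 vs
28 cm⁻¹ bands give 11.8 vs 14.4 cm⁻¹, nearly useless as a discriminator)
and the deconvolved Lorentzian FWHM fitted on the raw spectrum by linear
least squares over a linewidth grid. The species rules use the fitted
width; "broad" means ≥ 1.5 × the predominant band's 14 cm⁻¹.

### The hIAPP decision table

Working on the amide-I window proper (1640–1700 cm⁻¹; aromatic ring modes
at 1585/1605 cm⁻¹ are recorded but never counted as amide bands):

1. one center at 1656 ± 4 cm⁻¹, not broad → predominant helix-coil;
2. one center at 1668 ± 4, fitted width ≥ 21 cm⁻¹ → type I (turn);
3. two centers at 1655 ± 4 and 1674 ± 4 → type II (helix-coil + β-sheet);
4. one center at 1674 ± 4 with an amide III band at 1226 ± 6 or a strained
   disulfide marker at 490 cm⁻¹ → fibril-like;
5. otherwise unclassified.

The tyrosine doublet ratio and disulfide state are returned as evidence
but do **not** gate the type I/II calls. This is a deliberate deviation
from a threshold-on-ratio table: at SNR 8 the single-spectrum ratio sd is
≈ 0.45, so a `ratio ≤ 1.2` gate would randomly veto a quarter of genuine
type II spectra and make the ≥ 99% ground-truth agreement requirement
unreachable — while the amide-I centers and the band width already carry
the discriminating information. With this table, agreement at the
census mixture (96/2/2%) is ≈ 99.7% at SNR 8 and exact on noise-free
spectra. Misses that do occur are almost all conservative
(unclassified), dominated by noise-merging of the type-II doublet.

## The doublet ratio estimator

`doublet_ratio()` defaults to a profile fit: two Lorentzians with fixed
centers (830/854 cm⁻¹) plus a linear baseline over 815–870 cm⁻¹, the
shared linewidth chosen on a grid by residual minimization, ratio =
fitted area ratio, with a delta-method standard error. It is unbiased
under the generative model and invariant to intensity scaling and linear
baselines. The windowed-integration estimator (822–840 / 846–864 cm⁻¹
above per-window chords) is also provided; note that for overlapping
Lorentzians it is biased (chord over-corrects: +4–9% depending on
linewidth) and its single-spectrum noise is ~4× the fit's, which is why
it is not the default.

## Protonation, titration, scaling

Net charge uses independent-site Henderson–Hasselbalch protonation:
f = 1/(1+10^(pH−pKa)), bases contribute +f, acids −(1−f), blocked groups
(amidated C-terminus, disulfide-bonded cysteines) zero; the integer charge
is the rounded sum. The default hIAPP set (α-amino 9.0, Lys 10.5,
Arg 12.5, His 6.0 — only the His value is peptide-specific; the rest are
standard free-residue values, all configurable) reproduces +4 at pH 5.5
and +3 at pH 7.4. `microstate_weights()` enumerates the 2^k site
combinations; its marginals equal the net-charge fractions by
construction, which the tests assert as a consistency property.

The tyrosine mixture template combines the +1 and −2 endpoint templates
through those microstate weights: each microstate of charge q contributes
at interpolation coordinate t = (1−q)/3, which moves the ν₈ₐ weight from
1620 to 1602 cm⁻¹ and the doublet area ratio from 1:1 to 2:1 as the pH
rises. At pH 13 the −2 state carries ~99.7% weight.

Strong acid–base mixing solves the exact charge balance
[H⁺] − K_w/[H⁺] = C_acid − C_base after ideal dilution. For the worked
microfluidic case (13 µL at pH 1.0 plus 1.5 µL of 2 M NaOH) this yields
pH 13.07 — an overshoot past neutrality, not an intermediate basic pH; a
smaller aliquot (0.65 µL, the equivalence point) gives pH 7.00. The
package reports the charge-balance value; reproducing an intermediate
reading would require buffering species that are not part of the stated
mixing problem.

Frequency scaling multiplies computed wavenumbers above 1000 cm⁻¹ by an
empirical factor (default 0.9770); `fit_scaling_factor()` is the
closed-form least-squares factor through the origin, Σ(calc·obs)/Σ(calc²),
verified in the tests against a brute-force grid minimizer to 10⁻⁶.

## Trapping physics

In the Rayleigh regime the time-averaged gradient force on a small sphere
is F(z) = ¼ Re(α) E₀² ∂|E/E₀|²/∂z with the Clausius–Mossotti
polarizability α = 4πε₀ε_m r³ (ε_p−ε_m)/(ε_p+2ε_m); hence
U(z) = −¼ Re(α) E₀² |E/E₀|² up to the far-field constant — an exact
linear-theory identity that the tests verify numerically to 10⁻⁶ by
re-integrating the force. Scattering and absorption force components are
omitted: only the |E|² proportionality is modelled. Silver permittivities
come from a small table of approximate Johnson–Christy anchor values
(sign and order of magnitude, not quantitative electromagnetics). A trap
is called stable at well depth ≥ 10 k_BT (293 K default); a profile
calibrated to a 3.5×10⁻¹⁸ J well sits at ≈ 865 k_BT. The field profile
itself is an analytic stand-in (`gaussian_hotspot_profile()`): full
electromagnetic simulation of the nanocavity is out of scope, so headline
forces that depend on the simulated geometry (e.g. piconewton totals) are
not asserted anywhere — only the ratio-based stability logic is.

## What a green test establishes — and what it does not

The synthetic world reproduces the *statistical structure* the analysis
assumes: sparse events, additive near-Gaussian noise, smooth baselines,
shot-to-shot scale jitter, analytic lineshapes at fixed positions. Real
single-molecule SERS additionally shows spectral wandering, blinking
correlated in time, cosmic-ray spikes, non-Gaussian enhancement-factor
fluctuations and baseline structure from the substrate — none of which are
emulated (despiking and automated baseline fitting are explicit
non-goals). A green suite therefore certifies the correctness of the
estimators and decision rules under their stated model, and the printed
event fractions, RSDs and censuses are parameter-recovery results, not
reproductions of instrument data. The deposited raw spectra of the
originating experiments are deliberately outside the build, so no test
claims agreement with them.

## Numerical choices worth knowing

* SG filters use exact least-squares edge kernels (full-window polynomial
  fit evaluated at the edge offsets); derivative kernels divide by the
  grid step power.
* All stochastic operations take an explicit seed and restore the RNG
  state (`withr::with_seed`); identical seeds give bit-identical spectrum
  sets and byte-identical pipeline reports.
* Noise-free spectra make the 3σ rule degenerate; a trace is treated as
  noise-free when the estimated sd is below 10⁻³ of its dynamic range, and
  presence then means exceeding that same numerical floor (`snr = Inf`,
  `sigma_zero` flag).
* Parabolic center refinement falls back to the grid argmax when the local
  curvature is non-negative (upward parabola), and boundary maxima are
  reported at the boundary.
* Text round-trips write doubles with `%.17g`, which reproduces them
  exactly.
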