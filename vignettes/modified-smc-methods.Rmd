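---
title: "The modified simplified Monte Carlo dose algorithm: models, parameters, and design choices"
author: "smcdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The modified simplified Monte Carlo dose algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcdose)
```

## The algorithm in one page

Simplified Monte Carlo (SMC) dose calculation tracks individual protons
through a voxelized map of water-equivalent ratios (WER), but never
simulates energy-deposition events. Instead, each voxel crossing of
geometric length $dL$ contributes a water-equivalent step
$dL_w = \mathrm{WER}\cdot dL$, and the dose scored in the voxel is

$$ D\,dx\,dy\,dz = dL_w \cdot T(L'_w), $$

where $T$ is a precomputed integrated depth-dose (IDD) table --- the dose
integrated over an infinite lateral plane per incident proton --- evaluated
at the particle's *projected* water-equivalent depth $L'_w$ (the
water-equivalent path length projected onto the beam axis). The residual
range $R$ decreases by $dL_w$ each step; tracking stops when $R$ falls
below a cutoff. Direction changes come from multiple Coulomb scattering
(MCS), sampled per voxel crossing from the Lynch--Dahl form of the Highland
formula. Because the only loss mechanism is range-out, the conventional
algorithm keeps the primary fluence constant at every water-equivalent
depth, and its lateral profiles are single Gaussians.

The *modified* algorithm adds one stochastic channel: large-angle
scattering (LAS), standing in for hadron-elastic interactions (and, through
tuned cross-section correction factors, for inelastic channels and
secondaries). Per step, an interaction occurs with probability

$$ P = \frac{N_A \rho_w}{M} \, dL_w \, \sigma_\mathrm{LAS}, \qquad
   \sigma_\mathrm{LAS}(E) = 2 F_{pH}(E)\,\sigma_{pH}(E) +
   F_{pO}(E)\,\sigma_{pO}(E), $$

the factor 2 counting the two hydrogen atoms per water molecule. A
scattered proton is deflected by a polar angle drawn from the configured
angular model and loses energy according to classical two-body elastic
kinematics (hydrogen target: $E' = E\cos^2\theta$; oxygen target via the
centre-of-mass relation), so its residual range shrinks and the track ends
a short distance downstream. The fluence therefore *decreases* with depth,
and the IDD tables would under-dose if used directly. The fix is the
modified IDD (m-IDD):

$$ \mathrm{mIDD}(z) = C(z)\,\mathrm{IDD}(z), \qquad
   C^{-1}(z) \approx \frac{\sum_i dL_{w,i}(z)}{N_0\,dz} \approx
   \frac{N(z)}{N_0}, $$

the inverse of the Monte-Carlo-estimated surviving-fluence bracket. With
matched tables, the laterally integrated dose of a modified-mode run
reproduces the original IDD at every depth --- the package's central
consistency guarantee, tested to within 3 Monte-Carlo standard errors.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Bragg--Kleeman $\alpha$, $p$ | $2.0722\times10^{-3}$, $1.7779$ | g/cm$^2$/MeV$^p$, -- | fitted through the study's anchor points (118 MeV, 10 g/cm$^2$) and (218.9 MeV, 30 g/cm$^2$); gives 20.81 g/cm$^2$ at 178.2 MeV |
| MCS constant, $X_0$ | 13.6 MeV, 36.08 g/cm$^2$ | | Lynch--Dahl fit with the $1+0.088\log_{10}$ correction, water radiation length |
| $F_{pH}$, $F_{pO}$ anchors | $\{3, 8, 17\}$, $\{1,1,1\}$ at $\{10,100,250\}$ MeV | -- | published correction-factor table; linear interpolation, clamped outside |
| $\sigma_{pH}$, $\sigma_{pO}$ | smooth parameterization, 0.1--1 barn over 10--250 MeV | barn | the reference implementation's values are only published graphically; a pluggable CSV table is the interface, the default is a declared approximation |
| LAS angles | exponential, $\theta_s(E)=0.35\,(178.2/E)$ rad on $[0.05, \pi/2]$ | rad | broad slope: the channel mostly represents p--H elastic scattering, near-isotropic in the centre of mass, so laboratory angles are wide and scattered protons terminate quickly; $\theta_{\min}$ marks the hand-over to the Gaussian MCS regime |
| Range cutoff | 0.1 | g/cm$^2$ | track termination; value not critical, configurable |
| Phase space | single Gaussian, $\sigma_x$ = 4 mm, $\sigma_\theta$ = 3 mrad, no correlation | | typical scanned-beam optics; double-Gaussian and correlations supported |
| SAD | 2500 | mm | scanning-magnet to isocenter distance |
| IDD grid | $dz$ = 0.1 | g/cm$^2$ | 1 mm of water; survival bins use the same spacing, since the bracket estimate divides by exactly this grid interval |

Because the correction factors were originally tuned against a full
Monte Carlo simulator that is out of scope here, the *absolute* halo
magnitude produced by the default cross-sections is calibration-dependent.
Every shipped check of the LAS channel is therefore structural: support and
shape of the angular distribution, linearity of the interaction
probability, presence and ordering of the halo, and the exactness of the
m-IDD bookkeeping --- not absolute halo dose.

## The synthetic IDD generator

Measured or full-Monte-Carlo IDD tables are inputs the package cannot
obtain, so `generate_synthetic_idd()` builds an analytic stand-in: the
Bragg--Kleeman stopping power $S(z)\propto(R_0-z)^{1/p-1}$, multiplied by a
mild linear fluence-reduction factor (default 25% over the full range,
controlling the entrance-to-peak ratio), convolved with a Gaussian range
straggle of $\sigma_R = 1.1\%\,R_0$, and re-anchored so the grid maximum
sits exactly at $R_0$. This reproduces the features downstream code
depends on --- a single peak at the model range, a straggled distal
falloff, a plausible entrance-to-peak ratio --- but not the fine shape of
a measured curve (no nuclear buildup bump, no chamber-size effects).
Passing tests therefore demonstrate the *bookkeeping* of the algorithm on
realistic curve shapes, not agreement with any particular beamline's data.

## Estimating the survival fraction: the matched-stream ratio

The bracket $\sum_i dL_{w,i}(z) / (N_0\,dz)$ is computed by running the
engine with all table values set to one and histogramming each step's
$dL_w$ over the projected-depth interval it spans (spreading across bins
removes bin/voxel commensurability artifacts; the table factor, where
present, is evaluated at each sub-segment's own midpoint, which is exact
for a piecewise-linear table).

Two subtleties make the *raw* bracket unsuitable as $C^{-1}$ directly:

* Oblique tracks deposit more path length per unit projected depth, so the
  bracket exceeds 1 by up to a few tenths of a percent even with no
  fluence loss at all (pure MCS), and by more where halo particles crawl
  sideways. Clipping at 1 would bias the conversion by more than the
  Monte-Carlo error; not clipping would make the no-interaction limit
  produce $C \ne 1$.
* In the last bins before range-out every primary dies regardless of
  scattering; that cliff belongs to the transport, not to scattering
  losses.

`estimate_survival()` therefore runs the engine **twice with the same
seed** --- once with the LAS channel on, once off --- and reports the
per-bin ratio of the two brackets. The obliquity baseline and the
range-out cliff appear identically in numerator and denominator and
cancel; when the LAS cross-section is zero the two runs are bitwise
identical, so the estimate is *exactly* one and the m-IDD conversion is
*exactly* the identity. The conventional-mode bracket plays the role of
the fluence-invariance idealization on which the conventional algorithm
rests. The lateral-integration identity is correspondingly tested in its
paired form: a modified-mode run scored with the matched m-IDD must
laterally integrate to the same depth dose as a same-seed conventional run
scored with the unmodified IDD, within 3 standard errors propagating both
runs' Monte-Carlo uncertainty and that of the estimated conversion factor
(the conventional realization itself stays within $\sim$0.1% median of
the analytic table, its obliquity excess reaching $\sim$0.2% only at the
range end). A consequence of not clipping the ratio is that $C$ may dip a few
tenths of a percent *below* one proximally; an optional non-increasing
isotonic smoothing is available but off by default, because the true
bracket ratio is genuinely non-monotone at that scale and forcing
monotonicity would reintroduce the bias.

The conversion beam carries a Gaussian energy spread matched to the
tables' range straggle ($\sigma_E = \sigma_R / (dR/dE)$, about 1.1 MeV at
178.2 MeV). The conversion run should present the same distal fluence
falloff as the table it converts; with it, $C(z)$ keeps rising through the
Bragg peak, which is what makes the m-IDD peak measurably sharper than the
IDD peak (80% width 0.48 vs 0.52 g/cm$^2$ at 178.2 MeV). A strictly
mono-energetic conversion beam would freeze $C$ just short of the peak.
The curve's support ends where the conventional bracket falls below 0.05
(too few primaries to normalize); beyond it, the conversion holds $C$ at
its last value. Those distal table nodes are never looked up by live
particles of a matched beam.

## Numerical choices and conventions

* **Coordinates**: 0-based voxel indices, half-open voxel boxes, beam axis
  $+z$; the grid is laterally positioned so the beam axis passes through a
  voxel *centre* (an axis on a voxel face splits an axial pencil over four
  columns).
* **Traversal**: exact Siddon face-to-face stepping, not fixed steps;
  particle state updates at voxel borders.
* **Projected depth**: the typographically ambiguous in-progress term of
  the depth-projection sum is read as $dL_w^{(n)}\cos\theta_n/2$
  (half-weight midpoint). The alternative $\cos^2$ reading is implemented
  behind `transport_physics(projection = "cos2")`.
* **Per-step table evaluation**: the table is evaluated at each step's own
  $L'_w$, not once per voxel: particles reach the same voxel with
  different projected depths.
* **Flowchart order**: score, update $R$ and $L'_w$, MCS deflection, then
  the LAS trial. The LAS uniform is drawn in both modes so that the
  conventional and modified random streams stay aligned; this is what
  makes the degenerate limit ($\sigma_\mathrm{LAS}=0$) bitwise exact.
* **Termination**: no special rule after a large-angle event; the reduced
  residual range ends the track naturally. Particles leaving the grid are
  terminated (no re-entry).
* **Reproducibility**: every particle owns a counter-based splitmix64
  substream keyed by (seed, global particle index); results are bitwise
  reproducible for a fixed seed and independent of batching.
* **Target choice in a LAS event**: hydrogen vs oxygen is sampled
  proportionally to the adjusted partial cross-sections
  $2F_{pH}\sigma_{pH} : F_{pO}\sigma_{pO}$ --- the only choice consistent
  with the summed total.
* **Gamma index**: global normalization (reference maximum by default,
  isocenter or explicit value configurable), reference upsampled 10$\times$
  by bilinear interpolation, search radius 3$\times$DTA; both knobs
  configurable, and with interpolation off the implementation agrees with
  an exhaustive brute-force search to $10^{-6}$.
* **SOBP weights**: non-negative least squares on the plateau of the IDD
  superposition (the central-axis depth dose of a broad field);
  achieved flatness is reported and warned about beyond 2%.

## Problem sizes used by the shipped tests

The test-suite and the acceptance script run at desk scale, chosen so the
whole suite finishes in a few minutes while keeping Monte-Carlo standard
errors small enough for the stated tolerances: $10^5$ histories for the
lateral-integration identity, the halo comparison and the scanned-field
profiles ($2\times10^5$ for survival estimation), $2\times10^4$--$5\times10^4$
for structural checks, 1--2 mm voxels, and $50\times50$ grids for the
gamma brute-force comparison. The published evaluations behind the method
used $10^7$--$10^8$ histories; nothing in the implementation changes with
history count except statistical error.

## Known limitations

* No full Monte Carlo comparator: the published gamma pass rates against a
  Geant4-based reference are benchmarks of that specific calibration and
  cannot be recomputed here. The package ships self-consistency and
  structural checks instead.
* The far-field "aura" is not modeled (the reference algorithm does not
  reproduce it either); inelastic channels, explicit secondaries, delta
  rays are all folded into the tuned LAS channel.
* Default elastic cross-sections and the angular slope are declared
  approximations of values only published graphically; both are pluggable
  (CSV / constructor arguments) and should be re-fitted against a local
  reference before any quantitative halo use.
* CT ingestion is a hook only: `hu_to_wer()` applies a user-supplied
  piecewise-linear calibration; no calibration derivation, no DICOM.
* Dose is per incident particle in arbitrary consistent units; no absolute
  MU calibration.

## A worked pipeline

```{r pipeline, eval = FALSE}
E <- 178.2
idd  <- generate_synthetic_idd(E)
surv <- estimate_survival(E, n_histories = 2e5, seed = 1)
midd <- convert_idd_to_midd(idd, surv)

phantom <- build_water_phantom(c(200, 200, 250), voxel_size = 2)
plan    <- build_scanned_field(field_size = 50, spot_spacing = 5, energy = E)
dose_m  <- run_simulation(plan, phantom, tables = list(midd),
                          n_particles = 1e5, seed = 2, mode = "modified")
dose_c  <- run_simulation(plan, phantom, tables = list(idd),
                          n_particles = 1e5, seed = 2, mode = "conventional")

add <- extract_add(dose_m)                     # central depth dose
ocr <- extract_ocr(dose_m, depth = 105)        # lateral profile, mid range

pm <- extract_zx_plane(dose_m); pc <- extract_zx_plane(dose_c)
g  <- gamma_index_2d(pc$values, pm$values, pc$x, pc$z,
                     crit = gamma_criteria(2, 2, 20))
pass_rate(g)   # how far conventional mode is from the halo-bearing field
```
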