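---
title: "Model-independent recovery of interfacial SLD and hydration profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-independent recovery of interfacial SLD and hydration profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflift)
```

## The problem

A specular neutron reflectivity measurement records the reflectivity
$R(q)$ of a stratified interface as a function of momentum transfer
$q = 4\pi\sin\theta/\lambda$. Because only intensities are measured, a
single curve does not determine the scattering-length-density (SLD)
profile: many profiles reproduce the same $|R|$. Repeating the
measurement with different H~2~O/D~2~O solvent mixtures changes the
solvent SLD while the film stays put, and the joint information content
of three or more such contrasts is enough in practice to pin down two
depth profiles simultaneously: the non-solvent (material) SLD
$\rho(z)$ and the hydration (solvent volume fraction) $h(z)$.

`reflift` recovers these two profiles without assuming a layer model, in
two stages:

1. an **indirect Fourier transform (IFT)** of each extreme-contrast curve
   estimates the overall extension $D$ of the interfacial layer;
2. a **simulated-annealing** search reconstructs $\rho(z)$ and $h(z)$ on
   $[0, D]$ against all contrasts at once.

## The interfacial model

The film is divided into $N = 50$ equally thick sub-layers spanning
$[0, D]$. Layer $n$ carries a non-solvent SLD $\rho_n$ (bounded by
`rho_min`, `rho_max`, by default the H~2~O and D~2~O values, the natural
range when nothing in the film is deuterated) and a hydration
$h_n \in [0, 1]$. Hydration is pinned by virtual outer layers to 0 on
the fronting side and 1 in the bulk solvent. Both step profiles are
blended across every layer boundary with an error function,

$$v(z) = v_0 + \sum_j (v_{j+1} - v_j)\,\tfrac12\left[1 +
  \operatorname{erf}\!\left(\frac{z - z_j}{\sigma}\right)\right],$$

with a single global smoothing length $\sigma$ shared by both profiles.
Note the convention: the erf argument is $(z - z_j)/\sigma$, so $\sigma$
is $\sqrt2$ times the width of the equivalent Gaussian interface. With
this convention the admissible range
$\pi/4q_{max} \le \sigma \le \pi/2q_{max}$ — the spatial resolution
limits implied by the largest measured momentum transfer — reproduces
the published recoveries of $\sigma$ on the validation systems, which
consistently sit near the upper limit (6 Å at $q_{max}=0.25$ Å⁻¹; 15 Å
for the nanoparticle system whose curves truncate at lower $q_{max}$).
The composite profile seen by neutrons at solvent SLD
$\rho_{solv}$ is

$$\rho'(z) = \rho(z)\,[1 - h(z)] + h(z)\,\rho_{solv}.$$

Reflectivity is computed exactly (no Born approximation) by the Abelès
characteristic-matrix method on the discretized composite profile
(slab thickness $d = D/N$, padded by $3\sigma_{max}$ so the smeared
tails are captured), and smeared with the instrumental resolution: each
point is replaced by a 17-point Gaussian average spanning
$\pm2.5$ standard deviations of a Gaussian whose FWHM is
$\delta q/q \cdot q$ (default $\delta q/q = 0.10$). Within the
annealing inner loop the algebraically equivalent Parratt recursion is
used for speed; unit tests pin both paths to closed-form single-interface
and single-slab results at $10^{-10}$ relative tolerance.

## The score

Agreement between the $M_c$ measured contrast curves and the model is

$$f = \frac{1}{M_c}\sum_c\left[
  \overline{\left(\frac{q^4R_{exp} - q^4R_{th}}{\langle q^4R_{exp}\rangle}\right)^2}
  + \overline{\left(\ln R_{exp} - \ln R_{th}\right)^2}\,\right],$$

where overbars and angle brackets are means over the points of one
curve. The first term sees the $q^4$-weighted (Porod-like) view, the
second the logarithmic view; together they treat the whole $q$ range
evenly. The logarithm requires $R > 0$: points with non-positive
reflectivity (possible after background subtraction) are dropped at
load time with a warning count. Per-point means (rather than sums) keep
$f$ of order unity for a random starting profile, so the published
starting temperature $T_0 = 1$ gives a sensible initial acceptance
rate.

## Annealing

Moves pick one free parameter uniformly at random — each unfrozen
$\rho_n$, each unfrozen $h_n$, and $\sigma$ — so the move-type mix is
proportional to the free-parameter counts. The chosen parameter receives
"a random change within its admissible interval": with probability 0.2 a
fresh uniform draw over the whole interval, otherwise a local uniform
step of half-width $\max(0.02, \sqrt{T/T_0})$ times the interval,
reflected at the bounds. The local component matters: with fresh draws
only, the probability of improving a nearly converged parameter shrinks
linearly with the remaining error, and on the three-layer validation
system the search stalls around $f \approx 2\times10^{-2}$ — an order of
magnitude above solutions that demonstrably exist — and the hydration
split is not recovered. With the hybrid move the same schedule reaches
$f \sim 10^{-4}$.

The schedule is the published one: $T_0 = 1$, $100N$ trials per
temperature, $T' = 0.9T$, stop after 100 consecutive rejections (a
global counter that does not reset on cooling). A trial is accepted
when $\Delta f \le 0$, else with probability $\exp(-\Delta f/T)$.
`anneal_schedule(fast = TRUE)` is a reduced preset ($20N$ trials,
cooling 0.85) used by the test-suite and acceptance runs; it passes the
hydration-recovery checks in roughly a tenth of the full-schedule time.
Initialization is random: $\rho_n \sim U[\rho_{min}, \rho_{max}]$,
$h_n \sim U[0,1]$, $\sigma = \pi/4q_{max}$.

Ten independent runs are the standard protocol (`multi_run()`); the
lowest-$f$ run is the solution, and `average_profiles()` averages the
runs within 20% of the best $f$ to suppress the truncation ripple and
estimate the pointwise spread. Region constraints (`constraint()`)
freeze the hydration or SLD of the sub-layers whose centres fall in a
given $z$ range — e.g. the native \~10 Å silicon oxide with $h = 0$ and
$\rho = 3.5\times10^{-6}$ Å⁻² — and those parameters leave the move set.

## The IFT stage

In the kinematic (Born) approximation
$q^4R(q)/16\pi^2 = 2\int_0^D p(z)\cos(qz)\,dz$, where $p(z)$ is the
autocorrelation of $d\rho'/dz$. `reflift` expands $p(z)$ in 25 uniform
cubic B-splines on $[0, D]$ whose supports all end at or before $D$, so
every candidate solution satisfies $p(D) = p'(D) = 0$ — the "smooth
approach to the axis" is built into the basis, and the question a trial
$D$ answers is purely whether the data can be described with that
extension. Coefficients minimize $\chi^2 + \Lambda N_c$ with
$N_c = \sum_i (c_{i+1} - c_i)^2$ (a second-difference penalty is
available). The fit variable is the Fresnel-normalized reflectivity
$\Delta\rho^2 R/R_F$ ($R_F$: the bare fronting/solvent step), which
absorbs most of the dynamical distortion near the critical edge; points
below $3q_c$ of the strongest interface are excluded, where
$q_c = 4\sqrt{\pi\,\Delta\rho}$. Weights come from `dR` when present,
else a constant relative error. A tiny ridge ($10^{-12}$ of the normal
matrix diagonal) keeps the unregularized reference fit solvable.

$\Lambda$ is scanned over 40 log-spaced values spanning
$10^{-4}$–$10^{4}$ times the self-normalizing scale
$\chi^2(0)/N_c(0)$; the selected $\Lambda$ is the last inflection of
$\log N_c$ vs $\log\Lambda$ (zero crossing of the second derivative of
a smoothing-spline fit) within the region where $\chi^2$ stays within
10% of its small-$\Lambda$ plateau. A featureless scan falls back to
the widest flat stretch and is flagged.

For the extension itself, trial values of $D$ are scanned
(`estimate_D()`), normally on the two extreme contrasts (D~2~O and
H~2~O) separately. The regularized misfit falls steeply while $D$
underestimates the true extent and flattens once it is covered; the
per-curve estimate is the knee of $\log\chi^2$ vs $D$ — the smallest
$D$ from which the improvement rate stays below 0.025 per Å for three
consecutive grid steps (a single flat step can be a shelf on the way
down). The overall $D$ is the largest per-curve knee, since the
extension must accommodate every contrast. The full diagnostic table
(misfit, tail amplitude of $p$, oscillation counts per trial $D$) is
returned so the scan can be audited the way stability plots are read by
eye. On the regenerated validation systems this procedure gives 160 Å
for the rough three-layer stack (reference reading: 170 Å, one grid
step away, the excess over the nominal 150 Å reflecting the interfacial
roughness) and 480 Å for the 500 Å nanoparticle layer, and is stable
under 20% extra grid headroom.

## The synthetic systems

`three_layer_system()`: silicon substrate, three 50 Å layers with
non-solvent SLDs 5, 0, 2 $\times10^{-6}$ Å⁻², the third 50% hydrated,
all interfaces 5 Å rough, rendered at D~2~O (6.35), silicon-matched
water (2.07) and H~2~O (−0.56 $\times10^{-6}$ Å⁻²) with the Névot–Croce
roughness approximation. `parabolic_nanoparticle_system()`: a
close-packed monolayer of 250 Å-radius silica spheres
($\rho = 3.5\times10^{-6}$ Å⁻²) producing a parabolic volume-fraction
profile $\phi(z) = \phi_{max}[1 - (z - R_p)^2/R_p^2]$ over 500 Å,
approximated for curve generation by 20 slabs with 10 Å roughness under
the Névot–Croce factor, the standard convention for that system. The
peak packing fraction is not fixed by the geometry argument alone;
0.9069 (the 2-D hexagonal packing of the equatorial cross-section) is
the default and the extension estimate is insensitive to it.

Slab systems, in contrast, are rendered **exactly**: the roughened
composite profile is evaluated on a 1 Å grid and pushed through the
dynamical engine. The Névot–Croce approximation is deliberately avoided
for ground-truth generation there, because at
$q\sigma_r \gtrsim 1$ its error is appreciable **and
contrast-dependent**, so a multi-contrast fit against NC-generated
curves absorbs the inconsistency into the hydration/SLD split: on the
three-layer system, annealing against NC curves converges to a
third-layer hydration near 0.35 with *better* scores than truth-like
profiles, whereas against exactly rendered curves it recovers the true
0.5. `nevot_croce_reflectivity()` remains a public engine operation.

Rendering mimics desk-quality simulated data: 150 log-spaced points
over 0.005–0.25 Å⁻¹ (two-wavelength reflectometer coverage),
$\delta q/q = 10\%$ smearing, truncation at $q \le 0.25$ Å⁻¹ and at the
typical background level $R \ge 10^{-6}$ (which carves the
characteristic gap into the contrast-matched SMW curve). Optional
multiplicative Gaussian noise (3% relative is the suggested level for
stochastic tests) fills the `dR` column. These fixtures emulate
smearing, truncation, background and counting noise; they do not
emulate labile-hydrogen exchange (the non-solvent SLD is assumed
contrast-independent), instrument backgrounds that vary with $q$,
off-specular scattering, or imperfect footprint corrections — passing
tests say nothing about those effects on real data.

## Numerical choices and limitations

* Wavevectors use the principal square root with non-negative imaginary
  part (decaying evanescent waves). The matrix product runs from the
  fronting medium toward the backing; a single interface reproduces the
  textbook Fresnel coefficient (regression-tested).
* erf step terms are truncated beyond $7.5$ widths; the tails reach
  their plateaus to better than one part in $10^{12}$.
* The annealing loop, Abelès/Parratt kernels, smearing and profile
  evaluation are compiled (Rcpp); one full three-contrast score of the
  three-layer system costs under a millisecond, and a fast-schedule run
  about 90 s on one core. Full-schedule runs take roughly 5–15 min,
  matching the reported order of magnitude for the original Fortran
  implementation.
* Problem sizes used by the shipped tests: the best-of-10 reconstruction
  runs the fast schedule on the real 50-layer system; the round-trip and
  constraint properties use 12–50 layer models with full or reduced
  schedules. These sizes keep the whole suite in the tens of minutes on
  a single core while still exercising every stage at realistic scale.
* $\sigma$ is weakly identified: a finely graded staircase can absorb
  interfacial width that $\sigma$ would otherwise supply, so recovered
  $\sigma$ scatters by roughly ±1 Å between equally good runs. The
  reported value is whatever the best-$f$ run chose.
* Reconstructed profiles ripple at the scale set by the accessible
  $q_{max}$ (data truncation); `average_profiles()` suppresses but does
  not remove this.
* Labile-hydrogen exchange biases hydration upward for protein-like
  films, as discussed for the experimental systems; per-contrast
  non-solvent SLD constraints are out of scope here.

## A complete run

```{r, eval = FALSE}
curves <- render_contrast_series(three_layer_system())
D <- estimate_D(list(curves$D2O, curves$H2O), seq(80, 300, 10))$D_best
mr <- multi_run(score_config(curves), D = D,
                schedule = anneal_schedule(fast = TRUE), n_runs = 10,
                seed = 1)
avg <- average_profiles(mr)
profile_table(mr$best$model, curves)
```

The same pipeline is scriptable from a shell through `exec/reflift`
(`fixtures`, `ift`, `fit`, `forward`, `report` subcommands) with a YAML
configuration; every run artifact embeds the config MD5 and the seeds
for exact replay.
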