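---
title: "Models and methods: quenching, binding, thermodynamics and cocrystal physicochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

# Scope

`quenchbind` analyses the interaction of a small-molecule ligand — here the
1:1 apigenin–nicotinamide pharmaceutical cocrystal (AP-Nico) and its parent
flavonoid — with human serum albumin (HSA) from fluorescence quenching
titrations, and complements this with the physicochemical checks used to
characterize the cocrystal itself: CHN elemental composition, apparent
solubility enhancement, volume-corrected cumulative dissolution, and PXRD
new-phase detection. A forward simulator produces titration, competition
and dissolution data with known ground truth, so every analysis stage can
be validated end to end.

# The fluorescence titration and its correction

HSA's intrinsic fluorescence comes mainly from Trp-214, which sits in the
Sudlow site I pocket. Titrating a ligand into a fixed protein concentration
quenches this emission; the analysis consumes one intensity per quencher
concentration, with the zero-quencher point defining the reference
intensity $F_0$.

When the ligand absorbs at the excitation or emission wavelength, measured
intensities are depressed by the inner-filter effect. The correction is
multiplicative,

$$F_\mathrm{corr} = F_\mathrm{meas}\cdot b^{(A_\mathrm{ex}+A_\mathrm{em})/2},$$

with $A_\mathrm{ex}$, $A_\mathrm{em}$ the absorbances at the two
wavelengths. The conventional correction takes $b = 10$, because
absorbances are decadic; some presentations write the same formula with
$b = e$. Both bases are implemented; **base ten is the default**, the base
is recorded on every series and fit, and the simulator's
`distort_inner_filter()` is the exact inverse, which the test suite
exploits as a round-trip identity. We deliberately did not guess which
base any particular published analysis used: with absorbances of order
0.1 the two differ by ~12% in the correction factor, which matters for
absolute $K_{SV}$ values but not for any of the classifications below.

Concentrations are normalized to mol/L at the reader
(`read_titration()` accepts `mol/L`, `umol/L` and `1e-5 mol/L` column
units). Duplicate concentration rows are rejected rather than averaged —
the supported design has one measurement per level — and $F_0$ is always
the corrected intensity of the $Q=0$ row, never a separately supplied
number.

# Stern–Volmer analysis

```{r}
ts <- simulate_titration(model = "stern_volmer", ksv = 5.54e5)
sv_fit(ts)
```

The quenching regression is ordinary least squares of $F_0/F$ on $[Q]$:

$$F_0/F = 1 + K_{SV}[Q] = 1 + K_q\tau_0[Q].$$

Defaults and the reasoning behind them:

* **Free intercept** (default): real titrations carry small baseline
  offsets; forcing the intercept to 1 would fold such offsets into the
  slope. A fitted intercept deviating from 1 by more than 10% is flagged
  in the fit's warnings. The `fixed_at_one` mode regresses $F_0/F - 1$
  through the origin for users who prefer the textbook form; on noiseless
  model data the two agree exactly.
* **$\tau_0 = 10^{-8}$ s**: the intrinsic lifetime of the tryptophan
  fluorophore, overridable.
* **Mechanism threshold $2\times10^{10}$ L mol$^{-1}$ s$^{-1}$**: the
  diffusion-controlled limit of bimolecular quenching. $K_q$ strictly
  above it implies the quencher cannot be reaching the fluorophore by
  diffusion alone — static quenching via a ground-state complex. The rule
  is deliberately strict at the boundary (a value *at* the limit
  classifies dynamic), since the classification is justified only for
  values significantly above it.
* `temperature_trend()` corroborates the classification across
  temperatures: $K_{SV}$ falling with rising temperature is consistent
  with static quenching (complex dissociation), rising with dynamic
  (faster diffusion).
* $R^2$ is computed as $1 - SS_\mathrm{res}/SS_\mathrm{tot}$ on the
  regressed variable.

# Double-log binding analysis

```{r}
td <- simulate_titration(model = "double_log", k = 4.57e6, n = 1.48)
dlog_fit(td)
```

For static quenching the binding constant $K_b$ and apparent site number
$n$ come from

$$\lg\frac{F_0-F}{F} = \lg K_b + n\,\lg[Q],$$

fit by OLS in log–log space. Design choices:

* $K_b$ is **always** $10^{\text{intercept}}$. Published tables sometimes
  carry a $K_b$ column inconsistent with their own printed intercepts;
  deriving from the fitted intercept keeps the object self-consistent,
  and the invariant `k_b == 10^log_k` is enforced by tests.
* Points with $F \ge F_0$ at $Q>0$ (possible under noise when quenching
  is weak) carry no information in log space; they are dropped with a
  warning rather than failing the fit. At least three usable points are
  required.
* $K_b$ is reported in L/mol by field convention even when $n \ne 1$,
  with a note recording the dimensional inconsistency of that convention.
* Affinity classes: $K_b < 10^5$ weak, $10^5 \le K_b \le 10^6$ good
  (boundaries inclusive — the canonical "good affinity" range),
  $K_b > 10^6$ strong. The mapping is monotone.

## Site-marker competition

`site_competition()` compares the free binding constant with constants
measured in the presence of site markers (warfarin for Sudlow site I,
ibuprofen for site II). The marker whose presence causes the larger
relative change $|K_\mathrm{free}-K_m|/K_\mathrm{free}$ marks the
occupied site. Because both markers typically cause *some* change, the
assignment is only made when the top two relative changes are separated
by more than a tie margin, default 0.02. For the bundled AP-Nico
constants the two changes are 0.977 and 0.962 — a 0.015 separation — so
the default margin reports an honest near-tie; at a margin of 0.01 the
assignment is Sudlow site I. We kept the conservative default: a 1.5%
separation between two ~97% displacements is thin evidence on its own,
and the site-I call is corroborated independently by the magnitude of
the warfarin displacement.

# Van't Hoff thermodynamics

```{r}
tp <- thermo_profile(c("298" = 4.57e6, "310" = 5.01e6),
                     reported_delta_h = -14450, reported_delta_s = -21.36)
tp
```

From binding constants at two temperatures,

$$\ln(K_2/K_1) = \frac{\Delta H}{R}\Big(\frac1{T_1}-\frac1{T_2}\Big),\qquad
\Delta G = -RT\ln K,\qquad \Delta S = \frac{\Delta H-\Delta G}{T},$$

with $R = 8.314$ J mol$^{-1}$ K$^{-1}$. The identity
$\Delta G = \Delta H - T\Delta S$ then holds at every temperature by
construction, and $\mathrm{sign}(\Delta H)$ always equals
$\mathrm{sign}(\ln K_2/K_1)$ for $T_2 > T_1$ — both are enforced as
invariant tests. With more than two temperatures $\Delta H$ comes from an
OLS fit of $\ln K$ on $1/T$, flagged as an extension beyond the two-point
design.

Force classification follows the standard sign rules: $\Delta H>0,
\Delta S>0$ → hydrophobic; $\Delta H<0,\Delta S<0$ → hydrogen bond + van
der Waals; $\Delta S>0$ with $\Delta H\le0$ → hydrophobic +
electrostatic; $\Delta S<0$ with $\Delta H\ge0$ → hydrogen bond + van der
Waals; an exactly zero value is unclassifiable.

Reported literature $\Delta H/\Delta S$ values can be supplied alongside
the computed profile. When they disagree by more than 1% the profile
carries a consistency warning and *both* classifications (computed and
reported), rather than silently preferring either. This matters for the
bundled reference system: its reported binding constants *rise* from
298 K to 310 K, which forces a positive Van't Hoff enthalpy, while its
reported $\Delta H$ is negative and its reported
$\Delta G/\Delta H/\Delta S$ do not jointly satisfy
$\Delta G=\Delta H-T\Delta S$. The package computes from the equations
and flags the contradiction; it makes no attempt to reverse-engineer the
reported numbers.

# Cocrystal physicochemistry

* **Elemental composition**: theoretical mass fractions use IUPAC 2021
  standard atomic weights (C 12.011, H 1.008, N 14.007, O 15.999). The
  acceptance bound for measured-vs-theoretical relative error defaults to
  5%. (Reference tables computed with H = 1.000 differ in the second
  decimal of hydrogen fractions for small molecules; standard weights are
  used regardless.)
* **Cumulative release**: dissolution sampling with volume replacement
  removes analyte at each draw, so
  $Q_n = (A_n + \frac{V_1}{V_2}\sum_{i<n}A_i)\times100$, with $A_i$ the
  fraction of the dose measured at draw $i$, $V_1$ the sampled volume and
  $V_2$ the vessel volume. $A_i$ is read as a dose fraction (concentration
  × vessel volume / dose), the interpretation under which $Q_1 = A_1$ and
  later draws are credited for earlier removals — standard dissolution
  practice. With $V_1=0$ the profile is the raw series.
* **Solubility enhancement**: a plain ratio with a nearest-integer fold
  label for headline statements. The bundled reference solubilities are
  keyed at 298 K and 310 K; a source table labelling its lower row 278 K
  against surrounding text saying 298 K is carried as 298 K.
* **PXRD new-phase detection**: a product peak with no parent peak within
  the angular tolerance (default 0.2° 2θ, ten times a typical 0.02°
  instrument step; configurable) cannot arise from a physical mixture, so
  one or more unmatched peaks yield the `new_phase` verdict. Widening the
  tolerance can only demote peaks from "new" to "matched" — a monotone
  property enforced by tests.

# The forward simulator

`simulate_titration()` inverts the two analysis models exactly
($F = F_0/(1+K_{SV}Q)$ or $F = F_0/(1+KQ^n)$) on the default grid
$\{0, 0.40, 0.80, 1.00, 1.60, 2.40, 3.20, 4.00\}\times10^{-5}$ mol/L —
the eight-point design of the supported titration protocol — with
$F_0 = 1000$ a.u. (arbitrary; every analysis is scale-invariant, which is
itself a test). Noise is **multiplicative Gaussian on intensities only**
(fluorescence error scales with intensity; volumetric preparation is
treated as exact), default 1% when enabled, and fully seed-deterministic.
`simulate_dissolution()` plants a first-order release curve
$C(t)=q_\infty(1-e^{-kt})$ — a deliberately simple stand-in whose job is
to exercise the volume-correction formula exactly, not to model real
dissolution kinetics — and constructs per-draw fractions so the
cumulative-release formula recovers $C(t)$ to $10^{-9}$ in the noiseless
case.

What the simulator does *not* emulate: photobleaching, drift, scattering,
emission band shapes or blue shifts, combined static+dynamic (upward
curving) quenching, or multi-site binding. Passing tests therefore
demonstrate correctness of the estimators under the stated models, not
robustness to every artefact of real spectra.

## Statistical behaviour of the double-log fit

A numerical property worth knowing: the double-log intercept is an
extrapolation to $[Q] = 1$ mol/L, about five decades outside the
titration window. Intensity noise at the lowest concentration — where the
quenched fraction may be only a few percent — therefore produces
lognormally spread $K_b$ estimates: at 1% intensity noise on the default
grid with $K_b=4.57\times10^6$, $n=1.48$, the per-replicate spread is
$\mathrm{sd}(\log_{10}K_b)\approx0.6$ while $n$ is recovered to ~1%. The
median across replicates is essentially unbiased, but medians of a few
hundred replicates still carry ~10% sampling error on $K_b$. The test
suite sizes its recovery check accordingly (1000 replicates, 20% band on
$K_b \approx 3\sigma$, 2.5% on $n$); single fitted $K_b$ values from real
eight-point titrations should be read with the same caution, and $n$ and
$\lg K_b$ quoted in preference to $K_b$ itself when comparing conditions.
These problem sizes keep the full suite in the tens of seconds.

# Pipeline and reports

`run_pipeline()` chains correction → Stern–Volmer → mechanism →
double-log → thermodynamics → classifications per temperature, plus the
independent competition, composition, release and PXRD stages. Stages
fail independently: an error is recorded in the report without aborting
the rest. Reports serialize to schema-stable JSON
(`write_report(..., format = "json")`) or to a tabular text layout with
an explicit WARNINGS section; every numeric block carries its units in
the provenance entry, and all randomness flows from per-scenario seeds so
identical configurations give identical reports.

# Known limitations

* Single-mechanism Stern–Volmer only; upward-curving combined quenching
  is out of scope.
* Two-temperature Van't Hoff assumes temperature-independent $\Delta H$
  (no heat-capacity term).
* The dissolution model is a first-order stand-in; the release formula,
  not the kinetics, is the validated component.
* PXRD comparison operates on peak lists, not full patterns (no profile
  fitting, background subtraction or indexing).
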