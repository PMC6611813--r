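---
title: "Simulating ZULF NMR J-spectra under chemical exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ZULF NMR J-spectra under chemical exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zulfspin)
```

## The physical model

`zulfspin` simulates nuclear spin dynamics of small spin-1/2 systems whose
members are exchanged between chemical species by reversible association,
A + B ⇌ C. Two ingredients are combined in one generator:

1. **Chemical kinetics.** With B in excess, the two-species kinetics are
   linear, `d/dt ([A],[C]) = ((-W_a, k_d), (W_a, -k_d)) ([A],[C])`, with
   dissociation rate constant $k_d$ and pseudo-first-order association rate
   $W_a = k_a[\mathrm{B}]$. For acid–base systems the mole fractions follow
   from pH and $K_a$: $x_C = 10^{-\mathrm{pH}}/(10^{-\mathrm{pH}} + K_a)$
   and $x_A = 1 - x_C$, and $W_a = k_d\,10^{\mathrm{p}K_a - \mathrm{pH}}$
   satisfies detailed balance with them.

2. **Spin dynamics in Liouville space.** Each species' density matrix is
   column-vectorized (the normative convention is
   $\mathrm{vec}(P\rho Q) = (Q^\top \otimes P)\,\mathrm{vec}(\rho)$, which
   is unit-tested). Coherent evolution enters as $-i[\hat H,\cdot]$,
   relaxation as a superoperator $R$, and exchange as two rectangular maps:
   a partial trace $T$ (dissociation removes subsystem B) and an attachment
   map $D$ (association adds B in a **fixed bath state**, by default
   maximally mixed — solvated protons relax fast enough that they carry no
   spin memory, and their state is never tracked dynamically).

The combined generator on the stacked state $(\rho_A, \rho_C)$ is

$$
M \;=\;
\begin{pmatrix}
L_A - W_a \mathbb{1} & +k_d\, T \\
+W_a\, D & L_C - k_d \mathbb{1}
\end{pmatrix},
\qquad \rho(t) = e^{Mt}\rho(0),
$$

which conserves $\mathrm{Tr}\,\rho_A + \mathrm{Tr}\,\rho_C$ exactly and has
the equilibrium mixed state (block identities weighted by the equilibrium
mole fractions) as a fixed point of its exchange part. Both properties are
asserted to near machine precision in the test suite.

### Hamiltonians and units

Internally all Hamiltonians are in rad/s; every user-facing coupling,
field-derived frequency and spectral axis is in Hz. At zero field
$H = 2\pi\sum_{i<j} J_{ij}\, \mathbf{I}_i\cdot\mathbf{I}_j$; in the
high-field (doubly rotating, on-resonance) frame heteronuclear couplings
are truncated to $2\pi J_{ij} I_{iz}I_{jz}$ while couplings between spins
of the same isotope keep the full scalar form (they commute with the
detection operator at zero shift difference and do not move lines). The
supported isotopes are ¹H, ¹³C, ¹⁵N, ¹⁹F and ³¹P with signed gyromagnetic
ratios; spins > 1/2 are rejected.

### Relaxation

Only the isotropic fluctuating-field model is implemented:
$R = -\sum_i b_i \sum_{q\in\{x,y,z\}} [I_{iq},[I_{iq},\cdot]]$ with
$b_i = 1/(2\,T_{1,i})$, so that an isolated spin relaxes its longitudinal
magnetization with exactly the high-field $T_1$ supplied by the user — no
further motional parameters are needed. The calibration is verified by
propagation in the tests rather than trusted algebraically. Local fields on
different spins are taken uncorrelated and isotropic; dipole–dipole and
cross-correlated mechanisms are out of scope. Finite-temperature
(thermalizing) relaxation is deliberately absent: the thermal-polarization
terms vanish at zero field and do not affect the spin evolution simulated
here.

### Exchange mechanisms for ammonium

¹⁵NH₄⁺ (A₄X) supports two dissociation mechanisms:

* **single** — one *random* proton leaves at a time. In a deterministic
  master equation this is the ensemble average: $T$ and $D$ are uniform
  averages of the four per-site trace/attach superoperators, applied at
  rate $k_d$ through the ¹⁵NH₃ bookkeeping species (Hilbert dimension 16).
* **all** — all four protons leave simultaneously (residual species: bare
  ¹⁵N). Simplistic, but a useful limiting case.

Both conserve trace. In the fast-exchange (motional-narrowing) regime the
coalesced ¹⁵N line of the two mechanisms has equal width when the
**all**-sites rate is set four times smaller than the **single**-site rate
— one exchange event that replaces all four protons decorrelates the
proton configuration as much as four single replacements. The acceptance
suite recovers this factor within 10% by matching full widths at half
height (FWHH) with a root search over the rate.

## Measurement protocols

**ZULF:** (i) both species start in high-temperature thermal states at the
polarizing field (default 2 T, 298 K), weighted by equilibrium mole
fractions; (ii) the sample shuttles for $t_s$ (default 0.5 s) under the
guiding field (default 30 µT along z) with exchange and relaxation active;
(iii) the field drops suddenly to the residual field — the density matrix
is continuous across the ~50 µs switch, which is treated as instantaneous;
(iv) the magnetometer observable $\sum_i (\gamma_i/\gamma_H)\, I_{iz}$ is
recorded (default 1 kHz sampling). Amplitudes are arbitrary units
throughout; only positions, widths and ratios are meaningful, which is also
why peak metrics default to the magnitude spectrum. Shuttling is modeled as
evolution at the constant guiding field for the whole $t_s$; the real
trajectory through intermediate fields is not specified by typical
experimental descriptions, and the dominant effect — exchange-driven
equilibration with the unpolarized bath — is captured by the constant-field
approximation.

**High field:** an ideal, instantaneous 90° pulse creates unit transverse
magnetization on the observed isotope; the complex FID
$\mathrm{Tr}\,(\sum I_i^+ \rho(t))$ evolves under the secular Hamiltonians
plus exchange and relaxation. A transmitter offset (`offset_Hz`) shifts the
multiplet away from zero frequency so that a symmetric multiplet's center
line does not sit on the spectrum edge; 200 Hz is used for the ammonium
quintet analyses. Because the initial deviation and the detection operator
make the FID cosine-phased by construction, high-field peak metrics can use
the absorption (`mode = "real"`) representation without a phasing model.

Validation: before detection the largest possible transition frequency
(eigenvalue spread of the detection-stage Hamiltonian) is checked against
the Nyquist frequency, and a violation raises a typed error naming the
offending frequency.

## Numerical choices

* **Propagation.** On the uniform acquisition grid the single-step
  propagator $U = e^{M\Delta t}$ is built once (complex scaling-and-squaring
  Padé-13; `Matrix::expm` does not accept complex input) and applied
  iteratively. When only a scalar signal is needed and the generator is
  large, an eigendecomposition route evaluates
  $s(t_k) = \sum_j c_j e^{\lambda_j t_k}$ directly; it verifies the
  eigenbasis by a solve-residual check and falls back to the propagator
  route if the basis is ill-conditioned. Both routes are cross-checked
  against each other and against a fixed-step RK4 integrator oracle
  (agreement ≤ 1e-8).
* **Deviation-only propagation.** Experiments propagate the traceless
  deviation of the initial state. The uniform (identity) component of each
  block remains in the identity sector under every generator used here and
  is invisible to the detection operators, so this is exact, makes the
  signal exactly linear in the polarizing field, and avoids double-precision
  cancellation against the unit matrix.
* **Fast re-association regime.** For strongly acidic ammonium solutions
  the pH-derived $W_a$ can exceed $k_d$ by ~9 orders of magnitude. Spin
  observables stop depending on $W_a$ once the residence time $1/W_a$ is
  far below all spin-evolution timescales (all relevant frequencies are a
  few hundred Hz), so fast-exchange studies use the explicit override
  $W_a = 100\,k_d$: the residual-species fraction is ~1% and the generator
  stays well-conditioned for the exponential. Slow-exchange runs use the
  honest pH-derived rate (the eigendecomposition route is insensitive to
  that stiffness).
* **Lineshape metrics.** Peak positions are refined by three-point
  parabolic interpolation, FWHH by linear interpolation at half height, and
  integrals by the trapezoid rule over the peak support. Exponential
  apodization defaults to $1/T_\mathrm{acq}$ and is recorded in the
  spectrum metadata (it adds $\lambda/\pi$ Hz to every Lorentzian width —
  accounted for when widths are compared against theory). The
  zero-frequency exclusion window defaults to 2 Hz, because the static
  sample magnetization produces a non-oscillating component; spectra whose
  information sits at zero offset (high field) use a window of 0.
* **Problem sizes.** The largest generator used anywhere is the single-site
  ammonium mechanism, 256 + 1024 = 1280 Liouville dimensions; a spectrum
  simulation at that size takes seconds. Acquisition lengths in the tests
  (2–16 s at 0.5–1 kHz sampling) are chosen so that interpolation error is
  well below the tolerance being asserted.

## What the fixtures emulate — and what they do not

The built-in fixtures (AX 120 Hz, AXB 120/3/0 Hz, formate 222/3/0 Hz,
ammonium A₄X 73.4 Hz, pyruvate A₃X 6.25 Hz, and the hydrated-pyruvate
(A₃X)B₂ pair) reproduce coupling topologies and exchange connectivity of
real chemical systems under idealized conditions: perfectly homogeneous
fields, instantaneous field switching, a noiseless magnetometer, constant
temperature, and no paramagnetic impurities. Passing tests therefore
demonstrate correctness of the exchange/spin-dynamics model, not agreement
with any particular instrument: real ZULF spectra additionally contain
field-gradient smoothing, sensor response, and temperature-dependent rate
variations that are out of scope. The quintet amplitude-ratio check is a
case in point: the simulated ratio is ~5.9 rather than exactly 6 because
proton T1 flips broaden the outer lines slightly more than the center line
— a physical feature of the relaxation model, within the test tolerance
but distinguishable from the idealized 1:4:6:4:1 multiplet.

The hydrate fixture is provided for completeness and is structurally
validated (trace/attachment identities), but its Liouville dimension
(4096 + 256) makes full spectrum simulations expensive; none of the
standard checks require one.

## The Markov spin-memory chain

The Monte-Carlo chain replaces one uniformly chosen site's proton per event
with a bath proton (spin-up probability 1/2 for an unpolarized bath) and
reports three metrics side by side: the surviving-original-site fraction
(analytically $(1-1/n)^k$), the probability of re-occupying the initial
configuration, and the normalized Shannon entropy of the configuration
distribution. A single scalar "memory" can be defined from any of these;
the package reports all three rather than privileging one. On four sites
with an unpolarized bath, ten events drive the survival fraction to ~0.056
and the entropy close to saturation — the order-of-magnitude statement
behind shuttle-induced signal loss. The chain is classical (product
configurations only); coherent or entangled initial states, which lose
memory even faster, are the province of the Liouville machinery.

## Known limitations

* No dipole–dipole or cross-correlated relaxation; no chemical-shift
  anisotropy; no quadrupolar nuclei.
* High-field simulations are strictly on-resonance secular; no lab-frame
  propagation, pulse imperfections or decoupling.
* The field drop is strictly sudden; adiabatic and intermediate ramps are
  not modeled.
* $k_d$ is an input: the package does not model the pH dependence of the
  dissociation rate constant itself (only the equilibrium speciation).
* Exchange with more than two spin-bearing species (parallel pathways,
  multi-step ladders) is not composed automatically.

```{r quick-demo, eval = FALSE}
# one-line reproduction of the headline ZULF ammonium spectrum
model <- exchange_model(zulf_fixture("ammonium")$system)
traj  <- zulf_experiment(model, zulf_protocol(dwell_s = 1e-3, n_points = 8000))
find_peaks(fft_spectrum(traj, apodization_s = 0.5))
```
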