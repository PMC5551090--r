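---
title: "Methods: coevolutionary dynamics of egg-phenotype polymorphism"
author: "eggmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coevolutionary dynamics of egg-phenotype polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggmorph)
```

## The biological question

Hosts of brood-parasitic cuckoos can evolve polymorphic egg
phenotypes: a rare egg type is hard for the parasite to mimic, and a
parasite laying a rare egg type is hard for the host to single out.
`eggmorph` models the simplest two-trait version of this arms race: an
egg is white or blue (color) and immaculate or spotted (spottiness),
giving four phenotypes, indexed 1 = immaculate white, 2 = immaculate
blue, 3 = spotted white, 4 = spotted blue. The question the package
answers quantitatively is under what conditions all four types persist
— at a stationary equilibrium, or through never-ending frequency
oscillations — and what happens to phenotypes currently missing from
the parasite population.

## Model and assumptions

The model is a deterministic, discrete-time recursion for the
phenotype-frequency vectors $\mathbf h$ (host) and $\mathbf p$
(parasite):

$$\mathbf h' = \frac{1}{\bar w_H}\,M\,W_H\,\mathbf h, \qquad
  \mathbf p' = \frac{1}{\bar w_P}\,M\,W_P\,\mathbf p.$$

Assumptions, in the order they shape the equations:

* **Maternal inheritance.** Egg phenotype passes from mother to
  daughter with no paternal contribution, so each phenotype behaves as
  a clonal lineage and frequencies suffice as state.
* **Random parasitism at rate $P$.** A fraction $P$ of host nests
  receives exactly one parasite egg, independent of either party's
  phenotype. Multiple parasitism and host-egg removal by the parasite
  are excluded.
* **Mismatch-graded acceptance.** A host laying type $i$ accepts a
  foreign egg of type $j$ with probability $A(i,j)$: $A_0$ on a full
  match, $A_c$ when only color differs, $A_s$ when only spottiness
  differs, $A_{cs}$ when both differ, with
  $1 \ge A_0 \ge A_c, A_s \ge A_{cs} \ge 0$ (mismatch can only lower
  acceptance; the constructor enforces this).
* **Brood loss on acceptance.** An accepted parasite chick destroys
  the host brood; a rejected parasite egg dies. This gives the
  selection (fitness) diagonals
  $w_H(i) = 1 - P\sum_j p_j A(i,j)$ and $w_P(j) = \sum_i h_i A(i,j)$.
  This all-or-nothing brood accounting is the minimal formulation
  consistent with the assumptions above; it is corroborated
  quantitatively by the critical-mutation-rate computation below,
  which lands on the published threshold value to four significant
  digits.
* **Independent reciprocal mutation.** Color flips with probability
  $m_c$ per generation, spottiness with $m_s$, independently (the two
  traits are plausibly controlled by separate genes), so a double flip
  has probability $m_c m_s$ and the 4×4 mutation matrix is the
  Kronecker product of two 2×2 reciprocal-mutation matrices. $M$ is
  symmetric and doubly stochastic; mutation acts after selection.
* **Infinite population, non-overlapping generations.** Frequencies
  are real numbers; there is no random number generator anywhere in
  the dynamics.

## Parameters

| Parameter | Meaning | Range | Standard value |
|---|---|---|---|
| $A_0$ | acceptance of a matching egg | $[0,1]$ | 0.8 |
| $A_c$ | acceptance, color mismatch only | $[0,A_0]$ | 0.1 |
| $A_s$ | acceptance, spottiness mismatch only | $[0,A_0]$ | 0.1 |
| $A_{cs}$ | acceptance, both mismatch | $[0,\min(A_c,A_s)]$ | 0.01 |
| $P$ | parasitized fraction of nests per generation | $(0,1)$ | 0.05 |
| $m_c$ | color mutation probability per lineage per generation | $[0,0.5]$ | $10^{-10}$–$4\times10^{-3}$ |
| $m_s$ | spottiness mutation probability | $[0,0.5]$ | as $m_c$ |

The "standard values" are the field-calibrated setting used by every
built-in preset: strong rejection of doubly mismatched eggs, moderate
parasitism, and mutation probabilities spanning the empirically
plausible $10^{-4}$–$10^{-6}$ per-locus range and beyond, because the
dynamics change qualitatively across it.

## Equilibria and stability

Two fixed points organize the dynamics.

* The **internal equilibrium** $\mathbf h = \mathbf p =
  (\tfrac14,\tfrac14,\tfrac14,\tfrac14)$ exists for every parameter
  set (`internal_equilibrium()`), by the model's label symmetries
  (white↔blue and immaculate↔spotted relabelings commute with the
  update; the test suite asserts this to machine precision).
* The **spotted-parasite equilibrium** $\mathbf h$ uniform,
  $\mathbf p = (0,0,\tfrac12,\tfrac12)$ — the state matching field
  observations, with no immaculate parasite eggs — exists *only* when
  spottiness is invisible to the host ($A_0 = A_s$, $A_c = A_{cs}$,
  checked to a tolerance of $10^{-9}$ by
  `semi_internal_equilibrium()`). For a spot-discriminating host it is
  not an equilibrium at all: spotted host types are strictly
  disadvantaged and go extinct, and immaculate parasite mutants
  invade. Both of these consequences are exercised by the preset
  scenarios.

Local stability is decided on the spectrum of the linearized map.
`map_jacobian()` differentiates the one-generation update by central
finite differences (perturbation $10^{-7}$ per coordinate — roughly
the cube root of machine epsilon, balancing truncation against
round-off for a map with $O(1)$ curvature). Each population is reduced
to its first three frequencies via the unit-sum constraint, giving a
6×6 Jacobian whose spectral radius $\rho$ decides stability
($\rho < 1$, the discrete-time multiplier criterion — not the
sign-of-real-part rule, which belongs to continuous time). The raw
8×8 Jacobian is also returned for diagnostics; its extra modes lie
along the constraint directions and the test suite checks that every
reduced eigenvalue reappears in the raw spectrum to $10^{-8}$. The
fixed-point precondition is verified to $10^{-10}$ before
differentiating.

**Critical mutation rate.** Increasing mutation mixes lineages faster
than frequency-dependent selection can separate them, so $\rho$
decreases with $m$ and crosses 1 at a threshold $m^*$.
`mutation_threshold()` brackets the crossing (default bracket
$[10^{-8}, 0.2]$) and bisects to a $10^{-9}$ bracket width, recording
every evaluated $(m, \rho)$ pair; monotonicity of $\rho$ across the
evaluated points is checked empirically (with an $10^{-8}$ slack for
the finite-difference noise floor), not assumed. At the standard
acceptance values and $P = 0.05$, varying $m_c = m_s = m$ jointly,
the bisection yields $m^* = 1.9443\times10^{-3}$.

## Dynamical regimes and their classification

Below $m^*$ the equilibrium is unstable and the asymptotic behavior
depends on how far below:

* **Heteroclinic-like cycling** (vanishing mutation, e.g.
  $m = 10^{-10}$): the system lingers ever longer near
  near-monomorphic states, each eventually displaced by the next rare
  type.
* **Sustained oscillation** (small but appreciable mutation, e.g.
  $m = 10^{-4}$): bounded, complex multi-mode oscillation.
* **Stable coexistence** ($m > m^*$): convergence to the uniform
  equilibrium.

`classify_regime()` operationalizes the distinction with two module
constants. A run is *converged* when the final per-generation change
(max norm over both populations) is below $10^{-10}$ — judged on the
final step rather than over a whole trailing window, because
near-critical parameters approach the fixed point slowly (at
$m = 4\times10^{-3}$ the change only crosses $10^{-10}$ around
generation 4,500) and a whole-window criterion would postpone the
verdict long after the state is numerically stationary. A
non-converged run is *heteroclinic-like* when any frequency exceeds
0.99 inside the trailing window (a near-fixation excursion), else
*oscillating*. The 0.99 cutoff and the default window (the trailing
half) translate a visual distinction into reproducible rules; at the
standard parameters the three mutation settings above classify
cleanly, with near-fixation maxima of about 0.998, 0.967 and 0.25
respectively, so the classification is not sitting on the cutoff.

**Period estimation.** `estimate_period()` measures the mean spacing
of local maxima of one frequency series over the trailing window,
after discarding peaks of prominence below $10^{-4}$ (numerical
ripple); fewer than three peaks is an explicit no-period error, never
a fabricated number. Peak spacing was preferred over spectral
(Fourier) estimation because trajectories are short (hundreds of
cycles at most) and non-stationary near the heteroclinic regime.

A subtlety worth knowing: in the sustained-oscillation setting the
linearization carries *two* unstable complex pairs (at the standard
parameters with $m = 10^{-4}$: periods 71.2 and 92.1 generations), so
the nonlinear oscillation is genuinely multi-mode and different
components emphasize different mixtures — per-component estimates over
the trailing 500 generations of a 1,000-generation run range from
about 81 (first host component) to about 105 generations (fourth).
The default series (host component 1) tracks the leading,
fastest-growing eigenmode, and agrees with the eigenvalue prediction
$2\pi/|\arg\lambda|$ to within the 25% one should expect this deep in
the unstable regime; close to the threshold (e.g. $m = 1.5\times
10^{-3}$) the agreement tightens to under 10%.

**Amplitudes.** `oscillation_amplitudes()` reports the max-minus-min
of the dominant (largest-range) component per population. The parasite
always swings harder: every parasite egg faces a host decision, while
only a fraction $P$ of host nests is under parasitic pressure.

**Period scaling.** `period_scaling()` sweeps $P$, takes the
linear-theory period at the uniform equilibrium for each value, and
fits the log-log slope (`power_law_exponent()`, self-tested on exact
synthetic laws). Over $P \in \{0.0125, 0.025, 0.05, 0.1, 0.2\}$ the
fitted exponent is $-0.50$: the oscillation period scales as
$1/\sqrt P$, which is why a low-parasitism population can take
centuries to cycle a rare egg type back into view.

## Preset scenarios

Six presets pin the standard parameter values with the host always
starting at $(0.225, 0.275, 0.2, 0.3)$:

| Preset | $m_c$ | $m_s$ | Parasite start | Horizon | Regime |
|---|---|---|---|---|---|
| fig2a | $10^{-10}$ | $10^{-10}$ | all four types | 1,000 | heteroclinic-like |
| fig2b | $10^{-4}$ | $10^{-4}$ | all four types | 1,000 | oscillating |
| fig2c | $4\times10^{-3}$ | $4\times10^{-3}$ | all four types | 5,000 | converged |
| fig3a | $10^{-4}$ | 0 | spotted only | 1,000 | oscillating |
| fig3b | $4\times10^{-3}$ | 0 | spotted only | 3,000 | converged |
| fig4  | $10^{-4}$ | $10^{-4}$ | spotted only | 1,000 | oscillating |

Two deliberate choices here. First, the spotted-only parasite start is
conventionally quoted as $(0, 0, 0.3, 0.2)$, which carries total mass
0.5; the presets rescale it to $(0, 0, 0.6, 0.4)$. Because both halves
of the recursion divide by their own weighted mean, the update is
scale-invariant within each population and the rescaling changes
nothing from generation 1 onward. Second, the stationary presets run
longer than the 1,000-generation standard horizon (5,000 for fig2c,
3,000 for fig3b) so that their slow approach to equilibrium actually
crosses the $10^{-10}$ convergence tolerance; the oscillatory presets
keep the standard horizon. The fig4 preset pairs the spotted-only
start with the oscillatory mutation setting $m = 10^{-4}$ (the
convergent variant is available through `run_custom()`); it
demonstrates that immaculate parasite eggs, once created by
spottiness mutation, invade — reaching frequency 0.01 within about 30
generations at these parameters.

## Numerical choices

* **Renormalization.** Outputs of every step are divided by their
  exact sum, so mass drift cannot accumulate over $10^4$-generation
  runs. Input vectors within $10^{-9}$ of unit mass are renormalized;
  worse is a validation error.
* **Degenerate inputs.** A parasite pool rejected with certainty by
  every host ($\bar w_P = 0$) makes the recursion undefined; this
  raises an explicit error (with the failing generation attached
  during simulation), never a silent NaN.
* **Ties in peak detection** resolve to the first index of a plateau.
* **Bisection over grid search** for $m^*$: the radius is smooth and
  empirically monotone in $m$ within the default bracket, and
  bisection gives a guaranteed bracket at ~30 Jacobian evaluations.
* **Problem sizes.** The analyses in this vignette and the test suite
  use horizons of 1,000–5,000 generations and 5-point $P$ sweeps;
  these are the sizes at which every reported quantity is already
  stable to well within its assessment tolerance.

## What the model does not capture

Everything here is an infinite-population mean-field statement:
genetic drift, demographic stochasticity and finite-sample detection
effects are outside the model — relevant when interpreting the
apparent absence of a type in a small field sample, since a type can
persist at low frequency for centuries in the oscillatory regimes.
Parasitism is phenotype-blind; phenotype-matching (nonrandom) laying
would change the selection structure qualitatively. There is no
spatial structure or gene flow, no multiple parasitism, no host-egg
removal, and no diploid genetics behind the maternally inherited
phenotype. Consequently, agreement of the package's tests with the
model's predicted regimes demonstrates correctness of the
implementation, not realism of the assumptions; the scientific value
of the tool is in making the assumptions' consequences exact and
explorable.
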