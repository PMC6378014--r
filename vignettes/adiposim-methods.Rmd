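---
title: "Modelling adipose-tissue growth and metabolic inflammation with adiposim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adipose-tissue growth and metabolic inflammation with adiposim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiposim)
```

# The model

adiposim follows a small, well-mixed volume (by default 1 uL) of visceral
adipose tissue in discrete 8-hour steps. The agents are individual
adipocytes, represented by their volumes, and a resident pool of
macrophages, represented by their polarization states. A sustained caloric
surplus drives two modes of tissue expansion — hypertrophy (cells swell) and
hyperplasia (new cells are recruited) — and, through cytokine signalling, a
slow drift of the macrophage pool toward the proinflammatory M1 phenotype:
the cellular signature of chronic low-grade metabolic inflammation
("metaflammation"), the hypothesized bridge from sustained overfeeding to
insulin resistance.

## Anthropometry

A subject is described by body weight $BW$ (kg), height $H$ (m), age $A$
(years) and gender. Three closed-form relations anchor the simulation to the
subject:

* **Initial cell size.** The mean diameter of visceral adipocytes is tied to
  body mass index by the saturating relation
  $\phi(\mathrm{BMI}) = \phi_c - \lambda e^{-\delta\,\mathrm{BMI}}$, with
  gender-specific parameters ($\phi_c$ = 120 um and 123 um for males and
  females; `diameter_params()`). $\phi_c$ is also the *critical diameter*:
  cells beyond the corresponding spherical volume
  $v_c = \tfrac{\pi}{6}\phi_c^3$ signal for new-cell recruitment and secrete
  proinflammatory cytokines.
* **Fat mass.** Fat-free mass follows the adult regression
  $\mathrm{FFM} = \alpha + \beta A + \gamma H + \delta\,BW$
  (`ffm_params()`), and $\mathrm{FM} = BW - \mathrm{FFM}$. Profiles whose
  computed fat mass is non-positive (or below 1 kg at simulation start) are
  rejected: they are outside the regression's validity range and have no fat
  reservoir to simulate.
* **Weight read-out.** Body weight is an affine function of the *relative*
  simulated tissue volume,
  $BW(t) = BW(0) + \frac{\mathrm{FM}(0)}{1-\delta}\,\frac{V(t)-V_0}{V_0}$,
  so the small simulated volume stands in proportionally for the whole
  visceral depot. Fat-free mass is held constant over the simulation.

Units: diameters are um, volumes uL ($1\,\mathrm{uL} = 10^9\,\mathrm{um}^3$);
the conversion lives only inside `sphere_volume()`/`sphere_diameter()`.

## Adipocyte dynamics

Each cell carries a volume $v$ with the *swelling factor*
$\vartheta = 1 - v/v_c$. Per step a cell swells with probability

$$p_s = \tfrac12\left(1 + \tanh(k_1\vartheta + k_2)\right),$$

so small cells almost surely take up lipid while cells near $2v_c$
essentially never do ($p_s \approx 0.982$ at $v_c$, $0.018$ at $2v_c$); this
is what bounds cell size. A cell that passes the draw gains an
energy-derived increment plus Gaussian noise
$\eta \sim \mathcal N(0, k_4 v_0^2)$, with a hard floor at the baseline
volume $v_0 = 8.181\times10^{-6}$ uL (the size of a newly recruited cell):
updates that would cross the floor are rejected, so volumes never fall below
$v_0$ no matter how hypocaloric the diet.

The fraction $\zeta$ of supercritical cells ($v > v_c$) drives recruitment:
per step, with probability

$$p_a = \tfrac12\left(\tanh(k_5\zeta + k_6) + \tanh 1\right),$$

`round(V)` new cells (one per uL of current tissue) are created at $v_0$.
With the defaults ($k_6=-1$) $p_a$ is exactly zero in an all-subcritical
tissue and saturates near $0.88$. Defaults $k_1=4$, $k_2=2$,
$k_3=8\times10^{-6}$ uL day/kcal, $k_4=2\times10^{-5}$, $k_5=5$, $k_6=-1$.

### How surplus energy becomes volume

The surplus energy $E$ (kcal/day) converts to a daily lipid-volume influx
$s \cdot k_3 E$ per uL of simulated tissue, where $s$ is the single
calibration factor `energy_partition_scale`. Three partition rules are
implemented (`growth_params(partition=)`); the default, `"per_capita"`,
offers every cell an equal share $s\,k_3 E / (N\,\mathrm{steps/day})$ per
step, accepted with probability $p_s$. Total daily uptake is therefore
$s\,k_3 E\,\overline{p_s}$ — it never exceeds what the diet supplies
(the surplus is fixed by the diet, not compounding with tissue size), and it
is throttled by the swelling probability as the population fills up. This
yields the characteristic two-phase weight curve: a faster initial phase
while the starting cells swell freely, then a slower phase carried by
recruitment once the original cells crowd the critical size.

The alternatives are kept for comparison: `"tissue"` scales the influx by
current relative tissue volume and splits it over the passing cells (total
uptake is then forced in regardless of $p_s$ and compounds exponentially
with tissue growth — it cannot produce the two-phase shape and is not
recommended beyond short horizons), and `"per_cell"` applies the literal
fixed increment $s\,k_3 E/\mathrm{steps}$ to every passing cell (total
uptake then scales with cell number, again compounding through
recruitment).

On the noise convention: the variance of $\eta$ is taken as $k_4 v_0^2$,
making $k_4$ dimensionless. Reading it as $k_4 v_0$ (units uL) would give a
per-step standard deviation of $1.6\,v_0$ — a reflected diffusion that
grows every cell to near-critical size within a few simulated years even at
zero surplus, which contradicts the intended zero-surplus behaviour of the
model; the dimensionally coherent form is used instead.

### Calibration

The single scale $s$ was calibrated once, with
`calibrate_energy_scale()`, so that the 42-day, 1506 kcal/day overfeeding
protocol (`overfeeding_fixture("diaz")`, 50 replicates) reproduces the
observed mean gain of 7.6 kg; the resulting default is $s = 0.743$. It is
deliberately not retuned for any other protocol: the 100-day intermittent
protocol (`overfeeding_fixture("tremblay")`) is simulated with the same
value as an out-of-sample check.

That check is informative about the model's limits. The weight map requires
a relative volume change of $8.1/8.95 = 0.905$ to reproduce the second
study's 8.1 kg gain (its subject's regression fat mass is only 6.3 kg),
while the first study fixes $\Delta V/V_0 = 7.6/20.9 = 0.364$; since the
second protocol supplies only 1.37 times the cumulative surplus energy of
the first, any energy-proportional storage rule lands near
$\Delta V/V_0 \approx 0.50$, i.e. a final weight of about 64.8 kg against
the observed 68.4 kg. The two studies are mutually inconsistent under this
model family with a single calibration; adiposim reports the discrepancy
rather than absorbing it into per-protocol retuning.

## Inflammation

Supercritical adipocytes secrete into a lumped proinflammatory cytokine
pool (TNF-alpha + IL-6 + IL-1beta, arbitrary units) at rate
$s_\mathrm{adipo} \cdot p_a$ per supercritical cell per step — secretion
rides on the same signalling event that drives adipogenesis — and M1
macrophages add $s_{M1}$ each (the positive feedback of inflammation on
itself). M2 cells feed an anti-inflammatory pool at $s_{M2}$. Both pools
decay by a fraction (default 0.1) per step, so a constant total source $S$
has steady state $S/\mathrm{decay}$.

The macrophage pool (100 cells per uL, all initially resting M0) polarizes
by a phenomenological saturating rule: per step, an M0 cell switches to M1
with probability
$\tfrac12\left(1+\tanh(a\,\log_{10}(1+\mathrm{pro})+b)\right)$, and —
failing that — to M2 with the analogous function of the anti pool; M1/M2
revert to M0 with constant probability. This deliberately replaces the
Boolean gene-regulatory machinery used in earlier macrophage-differentiation
models with a two-parameter switch per phenotype: the observable claims
(M1 drift, dose dependence, delayed emergence) do not depend on the
network's wiring, and the module boundary lets a network rule drop in later.

The four free rates were fixed by two timescale requirements and then left
alone:

* the switch midpoint (equilibrium M1 fraction 0.5) sits at a
  proinflammatory level of $\sim 2\times10^4$ a.u., inside the band the
  adipocyte source actually spans between year 1 and year 5 across surplus
  levels of 500–2000 kcal/day ($\sim 8\times10^3$ to $3.5\times10^4$), so
  that onset is graded by diet rather than all-or-nothing
  ($a = 3$, $b = -16.7$);
* the pool responds on the year scale (reversion $5\times10^{-4}$ per step,
  a mean polarized dwell of roughly 1.8 years), so the M1 fraction
  integrates the cytokine history instead of tracking the transient spike
  in supercritical cells that accompanies the first wave of hypertrophy.
  With a fast pool (2-month dwell) that spike ignites full M1 polarization
  within the first year at every surplus level, erasing the
  "quiet first year, pronounced from year three" pattern the model is
  meant to exhibit.

Because the anti pool is sourced only by M2 cells, and M2 cells need the
anti pool to polarize, the M2 arm stays at its (near-zero) baseline under
the defaults: the model does not reproduce a late M2 counter-response at
high surplus. A coupling of the anti source to the inflammatory state would
be needed for that; the rates are exposed in `inflammation_params()`.

**Onset and survival.** The inflammation-onset event is defined as the M1
fraction reaching 0.5 and staying there for 30 consecutive days (both
configurable); replicates that never trigger are censored at the horizon.
`km_curve()` is a standard product-limit estimator over replicate onset
times (cross-checked in the test suite against `survival::survfit`).

## The engine

One step applies, in order: swelling → supercritical fraction and
adipogenesis probability → recruitment → cytokine secretion and decay →
polarization. The ordering is a convention (it shifts same-step feedback by
at most one 8-hour step) and is fixed for reproducibility. The day's
surplus is split evenly over the 3 steps; weekly diet patterns use a
repeating 7-day mask with the first `days_on_per_week` days on, and the
trajectory records the realized on-day count (the 100-day, 6-of-7 protocol
realizes 86 on-days). Each replicate $r$ of a run with base seed $S$ is
seeded $S + r$; a run replayed from its JSON manifest
(`write_run_manifest()` / `adiposim_from_manifest()`) is bit-identical.

## Initial conditions

The initial cell-volume distribution is a truncated normal on *diameter*
(mean from the diameter–BMI relation, CV 0.1, truncated to
$[\,\phi(v_0),\,2\phi_c\,]$), converted to volumes; the cell count is
`round(sim_volume / sphere_volume(mean diameter))` (about 2100 cells per uL
for a BMI-24 male). The CV is a configuration knob: some spread is needed
for the supercritical fraction to grow gradually rather than as a step.

# What the simulations do and do not show

The replicate SD of the simulated mean gain is a few hundredths of a
kilogram — far smaller than the inter-subject SDs of the clinical studies
(±1.6 kg and ±8 kg), because the model simulates one fixed subject profile,
not a cohort. Agreement with a study mean therefore tests the energy
bookkeeping, not population variability. Absolute macrophage counts depend
on the assumed 100 cells/uL pool and are not comparable across models; only
fractions, orderings and timings are meaningful. Long-horizon weights at
large sustained surpluses grow unrealistically because the surplus is
exogenous: real subjects' maintenance energy rises with weight, a feedback
outside this model's scope (as are adipocyte death/turnover, spatial
structure, physical exercise, drug treatment and any insulin–glucose
dynamics).

# Problem sizes used by the checks

The packaged tests run the two clinical fixtures at the study-faithful 50
replicates (42 and 100 days; seconds each), and the five-year qualitative
checks (two-phase weight dynamics, energy-ordered weight curves, year-5 M1
dose response, year-1 vs year-3 emergence contrast, onset-curve separation)
on a reduced grid of 4 replicates per surplus level in
{0, 500, 1000, 1500, 2000} kcal/day — orderings of replicate means
stabilize at this size, and the grid is the package's standard qualitative
configuration.

# Worked example

```{r example, eval = FALSE}
fx <- overfeeding_fixture("diaz")
fit <- adiposim(fx$subject, fx$protocol, replicates = 50, seed = 1)
summary(fit)
plot(fit)                      # mean weight curve with replicate band
fit_check("tremblay")          # out-of-sample check, same calibration
sw <- energy_sweep(lean <- adipose_subject(60, 1.70, 35, "male"),
                   c(0, 500, 1000, 1500, 2000),
                   duration_days = 5 * 365, replicates = 4, seed = 101)
plot(sw, "km")                 # onset curves graded by surplus energy
```
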