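---
title: "Forest-cover dynamics under incentive-based governance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forest-cover dynamics under incentive-based governance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestgov)
```

## The model

`forestgov` couples a two-state landscape Markov chain to a social-learning
decision process. A region consists of `N` land parcels, each forested or
deforested. Every year, the owner of a forested parcel deforests it with
probability given by a logit (quantal-response) rule on the net expected
gain of deforestation,

$$r(t) = \frac{1}{1 + e^{-(V_D(t) - V_F(t))}},$$

and every deforested parcel recovers to forest with probability $\mu$
(so $1/\mu$ is the expected recovery time). Utilities are dimensionless:
the temperature of the logit rule is absorbed by rescaling into the three
utility parameters, which is why no separate stochasticity parameter
appears. Realized utilities are $b'$ for each year a parcel spends
forested, $c'$ once at the moment of deforestation, and $0$ for bare land.

Landowners do not know these values; they learn them from each other.
The society-averaged *experienced* utilities in year $t$ are

$$\pi_F(t) = b', \qquad \pi_D(t) = c'\,\frac{y(t)}{1 - x(t)},$$

where $x$ is the forested density and $y$ the just-deforested density:
among the deforested class, only owners who cut this year earned anything,
so the experienced value of deforestation *rises* with the fraction of
fresh cutting — the core feedback of the model. Expected utilities then
update by exponential smoothing with the forgetting coefficient
$\alpha \in [0, 1]$:

$$V(t) = (1 - \alpha)V(t-1) + \alpha\,\pi(t).$$

$\alpha = 0$ freezes beliefs (only prior knowledge counts; the dynamics are
then always stable), $\alpha = 1$ uses only the current year's information
(maximally myopic).

### Governance instruments

Three instruments modify what landowners experience, each controlled by a
single magnitude $g'$ on the same rescaled utility scale:

* **Yearly conservation incentive** — every forested parcel receives $g'$
  per year. The experienced incentive among forest holders is exactly
  $g'$, so it enters the forested-side belief additively; at equilibrium
  the instrument is equivalent to raising $b'$ to $b' + g'$.
* **One-time deforestation penalty** — $g'$ is charged at the moment of
  cutting. Averaged over the deforested class the experienced penalty is
  $g' y/(1 - x)$, exactly paralleling $\pi_D$, so at equilibrium the
  instrument is equivalent to lowering $c'$ to $c' - g'$. Because the
  penalty is experienced *at the decision*, it never fades from memory,
  however myopic the learners — the mechanism behind its stabilizing
  effect.
* **One-time reforestation incentive** — $g'$ is paid when a parcel
  recovers. The just-reforested density $w(t) = \mu(1 - x(t-1))$ is
  tracked, and the experienced incentive among forest holders is
  $g'\,w/x$. At a fixed point $w/x = r$, so the equilibrium condition
  $r^* = \mathrm{plogis}(c'\mu - b' - g' r^*)$ is transcendental: no
  closed form exists and the package locates the fixed point numerically.

### Landscape bookkeeping

The density map is

$$x(t+1) = (1 - r(t))\,x(t) + \mu\,(1 - x(t)), \qquad y(t+1) = r(t)\,x(t),$$

i.e. recovery applies to *every* deforested parcel, including those cut
this very year. This convention was a genuinely open design point; it is
the one under which the equilibrium ratio of forested to deforested land is
exactly $\mu/r^*$, the equilibrium net gain is $c'_{\mathrm{eff}}\mu -
b'_{\mathrm{eff}}$, and the two governance substitution identities
($b' \to b' + g'$, $c' \to c' - g'$) hold exactly — the algebraic
signatures this model family is characterized by. The alternative (recovery
only for parcels bare for at least a full year) rescales the equilibrium
net gain by $\mu/(1+\mu)$ and breaks those identities.

Within a year, beliefs are updated first, from the landscape that exists as
the year begins, and transitions follow: decisions in year $t$ use
information available in year $t$. When a class is empty (a fully forested
landscape has no deforested parcels to learn from), its experienced value
carries forward unchanged — learning requires someone to learn from.

## Parameters

| Parameter | Meaning | Range | Default |
|---|---|---|---|
| `b` | yearly utility of a forested parcel (rescaled) | $\ge 0$ | 5 |
| `c` | one-time gain from deforestation (rescaled) | $\ge 0$ | 20 |
| `g` | governance magnitude (rescaled) | $\ge 0$ | 0 |
| `alpha` | forgetting coefficient (weight on current information) | $[0,1]$ | 0.2 |
| `mu` | yearly forest recovery probability | $(0,1]$ | 0.1 |

The defaults `b = 5`, `c = 20` put the system in the intermediate-utility
regime where both the utility gap and decision noise matter; governance
levels of interest run from 0 to 10, i.e. up to 50% of the deforestation
gain. Initial beliefs default to an "informed" start, $V_F(0) = b'/\mu$
(the value of a recovery cycle of ecosystem services) and $V_D(0) = c'$;
they are overridable and only affect transients.

## Engines

The **mean-field engine** iterates the density map deterministically — no
random numbers at all — and is the reference for equilibrium and stability
analysis.

The **agent engine** simulates all `N` parcels explicitly: each forested
parcel deforests independently with probability $r(t)$, each deforested
parcel recovers with probability $\mu$, with draws taken in fixed parcel
order from a single seeded generator, so trajectories are bit-reproducible.
It emulates demographic (finite-`N`) noise around the mean-field flow and
nothing else: landowners are identical, parcels have no spatial
arrangement, and there is no parameter heterogeneity, so agreement between
the two engines demonstrates internal consistency, not realism of any
spatial or behavioural detail beyond the shared decision rule. Default
problem sizes are `N = 10,000` parcels and horizons of 1,000–2,000 years;
the tests use smaller landscapes (hundreds to thousands of parcels, horizons
of 100–3,000 years) which are ample for the moments they check.

## Analysis conventions

* **Equilibria.** Closed form for the no-governance, yearly-incentive and
  penalty modes. For the reforestation mode a damped fixed-point iteration
  (damping 0.2, tolerance $10^{-12}$, at most $10^4$ iterations) solves the
  transcendental condition; the iteration is a contraction for any $g'$ at
  that damping, but `exists = FALSE` is reported if it fails.
* **Local stability** is the spectral radius of the Jacobian of the full
  coupled map — densities plus both belief variables (dimension 4, or 5
  with $w$) — at the equilibrium, by central finite differences with step
  $10^{-6}$. The density steps are shrunk near the simplex boundary so
  perturbed states remain feasible, and equilibria within $10^{-6}$ of
  full or zero cover are refused outright: the map divides by $1 - x$, and
  no finite-difference linearization is meaningful there (such equilibria
  are effectively absorbing anyway).
* **Regime classification** works on the second half of a trajectory. A
  run has *converged* when cover varies less than $10^{-6}$ over the final
  200 years; converged runs split into stationary-forested versus
  stationary-deforested at 50% mean cover. Non-converged runs are
  *cyclic-forested* when the amplitude is at least 0.05 and the
  autocorrelation function has a clear interior peak (which defines the
  dominant period; robust for the square-wave-like relaxation cycles this
  model produces), and *unstable-fluctuating* otherwise. The 0.05 and
  $10^{-6}$ thresholds are declared conventions — the four-regime taxonomy
  itself fixes only the 50% criterion.
* **Best-choice ties** (the informed comparison of $c'$ against the
  long-run forested value) resolve to conserve; the tie is a measure-zero
  boundary and the conservative default is the safer report.
* **Scaled-up (deterministic-decision) scenarios** multiply $b'$ and $c'$
  by $10^6$. When a governance threshold such as $c'\mu - b'$ is crossed
  "with margin", the margin must itself be at the utility scale (the
  package uses 10% of the threshold, with a floor of 10% of $b'$ when the
  threshold is at or below zero), otherwise the logit rule sits on its
  knife edge and the limit is not deterministic at all.

## What the model predicts, and two caveats

With long memories and slow recovery ($\alpha = 0.05$, $\mu = 0.1$) every
yearly-incentive level yields a stable forested landscape. With myopic
learners and fast recovery ($\alpha = 0.2$, $\mu = 0.5$) a weak incentive
converges below half cover, while a strong one pushes the equilibrium high
*and destabilizes it*, producing synchronized deforestation cycles — a
boom-bust feedback in which a nearly full forest makes fresh cutting look
lucrative to everyone at once. Under these conventions the loss of
stability on that parameter slice occurs between $g' = 6.25$ and
$g' = 6.5$ on a 0.25-step grid (the spectral radius reaches 1 near
$g' \approx 6.3$); published analyses of this model family place the
threshold at $g' = 5$ on the coarser grid $\{0, 2.5, 5, 7.5, 10\}$, with
which our stable-at-5, unstable-at-7.5 classification agrees. The exact
crossing point is sensitive to the within-year information timing, which a
density-map formulation cannot pin down more finely.

Second, under the reforestation incentive at $\alpha = 0.2$, $\mu = 0.1$,
$g' = 5$ the package finds an interior equilibrium near 72% cover that is
locally unstable, and the trajectory from half cover settles into a
persistent cycle averaging about 67% cover rather than saturating at a
stable fully forested state. Saturation at full cover would require the
experienced incentive to remain large when almost no land is recovering
($w \to 0$), which no class-average formulation of $\pi_{gF}$ delivers.
Relatedly, the penalty instrument stabilizes monotonically on the patient
panels ($\alpha \le 0.2$), but at the most myopic corner ($\alpha = 0.9$,
$\mu = 0.5$) the largest penalty ($g' = 10$) lands the equilibrium exactly
on the knife edge $(c' - g')\mu = b'$ and destabilizes it. Both behaviours
are properties of this implementation's (declared) experienced-utility
conventions and should be kept in mind when comparing against other
accounts of the same model family.

## Limitations

Landowners are homogeneous; there is no spatial structure, no land-quality
or price heterogeneity, no agricultural opportunity cost, and no strategic
anticipation — learning is purely imitative. Oscillation periods can be
long (decades to centuries), so the cyclic regimes here would be hard to
identify in real land-cover records against policy and demographic drift.
The regime thresholds (0.05 amplitude, $10^{-6}$ convergence) are
conventions: trajectories near a bifurcation can be classified either way,
which is why the test suite excludes a narrow band around spectral radius
1 when checking that classification agrees with the linearization.
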