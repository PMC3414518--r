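---
title: "Stochastic mechanism-fitting models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic mechanism-fitting models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(smfm)
```

This vignette documents the statistical model behind `smfm`, the choices
made where the design was genuinely open, and what the simulation-based
validation does and does not establish.

## 1. The data model

A diffusion experiment is recorded as four tables: an individual roster
(age class, sex, dominance, demonstrator status), the sessions run at
each group, every *interaction bout* (who, which option-type, which box,
start/end time, whether the box was entered and food obtained), and
every *observation event* (who watched which bout, and whether box entry
and feeding were visible to them).  Times are seconds on each session's
own clock.  The invariants enforced by `validate_event_log()` encode the
semantics: a bout is *solved* exactly when food was obtained; feeding
can only be seen if entry was seen; entry can only be seen if it
happened; an individual's bouts never overlap; observations lie inside
the bout they watch.

Experience is compiled by `build_experience_timeline()` into
left-continuous step functions: all counters step at bout/observation
**end** times, so a covariate evaluated at a bout's start can never
reflect the bout itself.  Counters (rewards `R`, failures `F`,
observation classes `O`) carry over across sessions; the transient
clocks `tau` (time of the most recent qualifying observation per
option-and-box) reset at each session start, because the transient
effects they drive are within-session by construction.  Observation
classes are *nested*: every observation counts as "manipulation seen",
those with visible entry additionally as "entry seen", and those with
visible feeding as "feeding seen" — so `s_entry` measures the increment
of witnessing entry beyond witnessing a manipulation.  Bouts at contact
locations other than the two modelled option-types are retained in the
data (the actor is off-risk during them) but generate no events,
counters or clocks.

## 2. The rate model

The initiation rate for individual `i`, option-type `k`, box `l` is

    rate = r_k * exp(beta.x_i + u_i + v_j) * (1 + gamma*A_ik + T_ikl)

The composition of the learning and transient terms is the one design
choice that could not be taken from a printed formula, so it is isolated
in one place (`src/smfm_loglik.cpp`, mirrored by `interaction_rate()`):
the default treats the transient term as *additive relative to
baseline* — consistent with reporting transient effects as multiples of
the baseline rate — while a fully multiplicative composition
`(1 + gamma*A)(1 + T)` is available via
`smfm_variant(composition = "multiplicative")`.

The association `A` uses the count-based closed form of the
Rescorla–Wagner rule, `A = 1 - (1-lambda_a)^R * prod_c (1-s_c)^{O_c}`,
with the asocial rate `lambda_a` per dominance class (dominant animals
are routinely found to be less shapeable by reward) and one social rate
per observation class.

Transient social effects are parameterized hierarchically: a general
kernel (any observed manipulation, anywhere), a box-level kernel (same
box — local enhancement at the box), an optional same-option-type kernel
(stimulus enhancement), and a specific kernel (same option *and* box —
specific local enhancement), each attached to the **most recent**
qualifying observation and decaying as `exp(-rho dt)` with a shared
decay rate.  `kernel_contrasts()` maps these to the raw
SOSB/SODB/DOSB/DODB contrasts; stimulus enhancement corresponds to
SODB > DODB, i.e. a positive same-type strength.  One shared `rho` is
used because a single half-life is the natural summary and per-kernel
decay rates are weakly identified at realistic data sizes; the same
reasoning led us to drop a sum-over-history kernel variant (the
most-recent-observation form keeps the likelihood closed-form and is the
stated model).  Strengths may differ between adults,
juveniles/sub-adults and pups, the age resolution at which transient
effects plausibly differ.

*Condition variants*: which events refresh the clocks is a scientific
question (is seeing a manipulation enough? seeing entry? seeing the
reward? or mere presence?).  These are implemented as event-class
filters (`smfm_variant(tau_condition = ...)`) and compared by DIC.

## 3. Likelihood

Bout initiations form a competing-risks inhomogeneous point process.
For each non-demonstrator and session, the log-likelihood is the sum of
log rates at that individual's initiations minus the integrated hazard
of all four options over its at-risk time (attending, not mid-bout).
Between state changes the learning multiplier is constant and each
kernel integrates analytically, so the likelihood is exact; segments are
precompiled once (`prepare_likelihood_data()`) and evaluated in C++.
Trained demonstrators contribute observations to others but are excluded
from the fitted likelihood, since their scripted behaviour is not
generated by the model.  The test suite checks the analytic likelihood
against dense numerical integration of the rate function on dozens of
simulated small logs (absolute tolerance 1e-4).

## 4. Inference

The paper-and-pencil posterior is not conjugate, so fitting uses blocked
adaptive random-walk Metropolis on log/logit-transformed parameters
(random effects, when freed, form their own block).  Adaptation — a
Robbins–Monro global scale and a running proposal covariance — happens
during burn-in only.  Priors default to half-normal(0, scale) for
positive parameters (baseline rates 0.01 events/s, transient strengths
50 baseline multiples, decay rate 1/s, learning influence 10),
uniform(0,1) for the learning rates, normal(0, 2) for covariate
effects, and hierarchical normals for random effects; all are
overridable via `prior_spec()` and none are claims about any original
analysis.  Summaries report medians, exact shortest-window 95% HPD
intervals, split R-hat and an autocorrelation-based ESS; a convergence
gate (R-hat < 1.05, ESS > 200) attaches a warning, never silently
alters results.  DIC uses `pD = Dbar - D(theta_hat)` with `theta_hat`
the posterior mean of the transformed parameters (median available).

## 5. Bout outcomes

Within a bout, solving and abandonment are competing terminal events.
Each is analysed as a Cox proportional-hazards model on the bout
duration, the other outcome censored.  Covariates are frozen at bout
start: prior successes/failures at the same and the other option-type, a
solved-ever flag, observed feeding successes per option-type, and a
transient recency term encoded as `exp(-rho dt)` with `dt` the time
since another individual last interacted with the same option at the
same box ("never this session" maps to 0, "ongoing" to 1) — a bounded
transform that avoids an arbitrary cap on `dt`, with `rho` taken from
the rate-model fit.  The partial likelihood (Efron ties by default,
Breslow by flag) and its Newton–Raphson maximizer are implemented
in-package with analytic derivatives, because the all-subsets AIC
averaging over up to 2^20 models needs many cheap, fully controlled
fits; the `survival` package serves as an independent oracle in the
tests, and the averaging follows Burnham & Anderson (Akaike weights,
model-averaged coefficients with zeros where absent, unconditional
standard errors, back-transformed 95% unconditional CIs).  The
mixed-effects Cox formulation (nested group/individual frailties) is
*not* reproduced; this is a known limitation — with one bout table per
experiment and moderate per-individual bout counts the fixed-effects
averaging answers the same which-covariates-matter question, but
clustered heterogeneity will widen true intervals somewhat.

## 6. Traditions

The option-bias test asks whether groups are more polarized towards one
option-type than chance allows: the statistic is the group-size-weighted
sum of absolute deviations of group flap-proportions from the pooled
proportion; the null reallocates each unit's option as an independent
draw at the pooled proportion, preserving group sizes, with the add-one
Monte-Carlo p-value.  The resampling unit (individuals or
manipulations) and the inclusion of unseeded control groups are
configurable, since reasonable analyses differ on both.

## 7. The simulator and what validation shows

`simulate_experiment()` inverts the fitted model: initiations are drawn
by Ogata thinning (the bound is the current total rate, valid because
the learning state is constant and the kernels only decay between state
changes), the option by the rate ratios, bout durations and outcomes
from the competing log-linear hazards of `outcome_model()` with
covariates frozen at bout start, and observers independently with
probability `p_obs` among attendees not mid-bout.  Demonstrators perform
only scripted, always-successful demonstrations (four per session by
default), mirroring trained proficient demonstrators.

The default study conditions (`sim_design()`, `study_params()`) emulate
the design that motivated the package: nine groups of 12–24 individuals
(176 in total), demonstrators seeded in six of nine groups (three per
technique), eight sessions per group of 1140 s (the observed mean
session length), observation probability 0.3.  Generating parameters:
subordinate asocial learning rate 0.05 per reward, dominant near zero,
social learning from witnessed entries 0.004 per observation, transient
half-life 20 s, and strongly specific enhancement (specific 10, box 2,
general 1 baseline multiples, relative influence of learning 5).  The
baseline rate (6e-5 events/s per option) was calibrated once so that a
simulated experiment yields totals of the same order as a real
deployment (~500 manipulations, ~270 successes) and then left alone.

What the simulator does *not* emulate: individual heterogeneity beyond
age/sex/dominance (no random effects in the default truth — simulated
activity therefore spreads across more individuals than field data,
where a minority does most of the manipulating), spatial structure and
movement, attendance variation across sessions, observation errors, and
demonstrator behaviour beyond the script.  Passing recovery tests
therefore show that the estimator recovers the mechanisms *under the
model's own assumptions at realistic scale* — they do not certify
robustness to the richer structure of real field data.

The recovery harness (`recovery_harness()`, exercised in the acceptance
tests) simulates 20 replicate experiments at the conditions above and
refits each with a reduced free-parameter set — the two baselines, the
subordinate learning rate, the entry social-learning rate, the three
kernel strengths (age-uniform) and the decay rate — with covariate
effects, random effects and `gamma` fixed at their generating values.
That reduction is deliberate: those are the parameters of scientific
interest, and `gamma` is only weakly separated from the learning rates
at 20-replicate desk scale.  Chains are 2 x 8000 iterations (3500
burn-in), sized so the full harness runs on one CPU in well under half
an hour; the companion no-transient fit per replicate uses the same
settings without the kernel parameters.

## 8. Numerical notes and degenerate inputs

* Counter and clock queries are left-continuous (`<`); ties between an
  event end and a query time resolve to "not yet seen".  Exact ties have
  probability zero in simulated data.
* Zero-length at-risk intervals (a bout starting exactly at session
  start or at the end of the previous bout) contribute an event term
  with a zero integral.
* Bouts running at session close are truncated and recorded as
  abandoned.
* Invalid parameters make the likelihood return `-Inf` with a flag
  instead of erroring, for sampler robustness; the samplers themselves
  operate on transformed scales so constraint violations cannot arise
  from proposals.
* `hpd_interval()` requires at least 100 draws and returns the exact
  shortest window containing `ceiling(mass * n)` sorted draws.
* Cox fits refuse rank-deficient designs; non-converged subset fits are
  excluded from model averaging with a warning and the weights
  renormalized.
* The option-bias p-value uses the add-one correction, so it can never
  be exactly zero.

## 9. Known limitations

* The additive-vs-multiplicative composition of learning and transient
  effects is a reconstruction (Section 2); both forms are implemented
  and the choice is documented, but only the additive default is
  exercised by the validation harness.
* Random effects are sampled with a centred parameterization; with very
  sparse per-individual data a non-centred variant would mix better and
  is not yet provided.
* DIC is reported with a negative-pD warning rather than an alternative
  criterion; heavily skewed posteriors can make the plug-in deviance
  unstable.
* The mixed-effects Cox formulation is replaced by fixed-effects
  averaging (Section 5).
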