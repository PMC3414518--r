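# smfm: stochastic mechanism-fitting models for learning in animal groups

`smfm` identifies **social and asocial learning mechanisms** from
time-structured event records of group diffusion experiments — the kind of
data produced when wild or captive animal groups are presented with a
novel two-option foraging task (two techniques, here called *flap* and
*tube*, on two identical boxes) and every bout of interaction and every
observation of another individual's bout is transcribed from video.

It is aimed at behavioural ecologists and social-learning researchers who
want to go beyond "did the seeded option spread?" and ask *which*
mechanisms — operant conditioning, emulation-like direct social learning,
local or stimulus enhancement, observational perseverance — shaped the
diffusion, how strong each one was, and how long transient social effects
lasted.

## The model

The rate at which individual *i* initiates a bout with option-type
*k* ∈ {flap, tube} on box *l* ∈ {left, right} at time *t* of session *s*
is modelled as

```
rate_ikl(t) = r_k · exp(β·x_i + u_i + v_j) · (1 + γ·A_ik(t) + T_ikl(t))
```

* `r_k` — baseline initiation rate per option-type (events/s);
* `β·x_i + u_i + v_j` — log-linear effects of age class, sex and
  dominance, plus individual- and group-level random effects;
* `A_ik(t)` — the Rescorla–Wagner association of option-type *k* with
  reward, in its count-based closed form extended with the permanent
  effects of observation:
  `A = 1 − (1−λ_a)^R · Π_c (1−s_c)^{O_c}`, where `R` counts *i*'s own
  rewarded manipulations, `O_c` counts its observations of others per
  class *c* (manipulation seen / box entry seen / feeding seen), `λ_a`
  is the asocial learning rate per dominance class and `s_c` the social
  learning rate per observation class;
* `γ` — the relative influence of learning;
* `T_ikl(t)` — transient social enhancement: exponentially decaying
  kernels (shared decay rate ρ, half-life `ln 2 / ρ`) attached to the
  most recent qualifying observation — a **general** kernel (any option,
  either box), a **box-level** kernel (same box), an optional
  **stimulus** kernel (same option-type) and a **specific** kernel (same
  option and box), with strengths allowed to differ between adults,
  juveniles/sub-adults and pups.

The likelihood treats bout initiations as a competing-risks
inhomogeneous point process (exact closed-form integrals per
constant-state segment), fitted by blocked adaptive Metropolis MCMC with
median/95% HPD summaries, inequality probabilities and DIC for comparing
*condition variants* (which observation class triggers the transient
effect).  Within-bout outcomes (solving vs abandonment) are modelled by
Cox proportional hazards with all-subsets AIC model averaging and
unconditional confidence intervals, and group-level traditions are
tested with a randomization option-bias test.  A forward simulator
(Ogata thinning) generates complete, valid experiments from known ground
truth, so every stage of the pipeline is testable without field data.

## Worked example

```r
library(smfm)

# simulate a nine-group seeded diffusion experiment at study scale
sim <- simulate_experiment(study_params(), outcome_model(), sim_design(),
                           seed = 7)
sim$log
#> <smfm_event_log>
#>   176 individuals in 9 groups, 72 sessions
#>   690 interaction bouts (458 solved), 3882 observations

# fit the rate model (free: baselines, learning rates, transient kernels)
ch <- run_mcmc(sim$log,
               config = mcmc_config(n_chains = 2, n_iter = 9000,
                                    n_burn = 4500, seed = 3),
               init_params = study_params())
summarize_posterior(ch)$parameters[, 1:4]
#>            parameter  median hpd_lower hpd_upper
#> 1             r_flap 5.9e-05   4.8e-05   6.8e-05
#> 2             r_tube 5.7e-05   4.7e-05   6.6e-05
#> 3 lambda_subordinate 5.1e-02   1.0e-02   9.5e-02
#> 4            s_entry 3.4e-03   1.0e-05   9.6e-03
#> 5          g_general 6.6e-01   2.0e-02   1.6e+00
#> 6              g_box 2.6e+00   6.2e-01   4.7e+00
#> 7         g_specific 6.0e+00   2.8e+00   1.0e+01
#> 8                rho 2.8e-02   1.8e-02   3.8e-02
half_life(0.028)   # seconds; the transient effect halves every ~25 s
#> [1] 24.8

# which observation class triggers the transient effect?
compare_variants(sim$log, list(manipulation = smfm_variant(),
                               no_transient = smfm_variant(transient = FALSE)))

# within-bout outcomes: model-averaged hazard multipliers
tab <- build_bout_table(sim$log, outcome = "abandonment", rho = 0.028)
all_subsets_average(tab)[, c("covariate", "weight", "multiplier")]
#>          covariate weight multiplier
#> 1        succ_same   0.51       0.83
#> ...
#> 5 solved_ever_same   0.79       0.48
#> 6    obs_feed_same   1.00       0.82
#> 7   obs_feed_other   1.00       0.86
#> 8          recency   0.45       0.90

# did the seeded techniques form group-level traditions?
option_bias_test(count_option_use(sim$log, "individuals"), seed = 1)
#> <smfm_option_bias> statistic = 10.333, P = 0.8459 (9 groups, individuals, 9999 permutations)
```

The posterior medians land near the generating values of
`study_params()` (subordinate λ = 0.05 estimated 0.051, s entry = 0.004
estimated 0.0034, half-life 20 s estimated ~25 s, specific enhancement
dominating the box-level and general kernels), observing others' feeding
lowers the abandonment hazard (×0.82 per observation), having solved
before lowers it strongly (×0.48), and no group-level tradition is
detected — the same qualitative picture the model family was built to
resolve.

A command-line front-end mirroring these steps is installed at
`exec/smfm` (subcommands `validate`, `simulate`, `fit`, `summarize`,
`dic-compare`, `cox`, `option-bias`, `recover`).

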