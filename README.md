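# leadsim

Event-driven simulation of emergent leadership in collective animal
movement, with the changepoint analysis that detects when a group of
initially identical individuals differentiates into stable leaders and
followers.

## The problem

Groups of capuchin monkeys, sheep, and many other social animals start
collective movements without any fixed leader: someone initiates, others
follow mimetically, and the initiator may give up and cancel. Field
observations yield a three-rule stochastic model of this process —
initiation, following, and cancellation as competing exponential clocks
whose rates depend on how many individuals have already departed. leadsim
implements that model and extends each individual with an adaptive
**leadership tendency** (LT) $L_i \in [0.1, 0.9]$ that is reinforced by
the individual's own initiation successes and failures:

* rates are modulated by a logistic factor
  $k(L') = 2 / (1 + e^{(0.5 - L')\cdot 10})$, with $L' = L$ for initiating
  and $L' = 1 - L$ for following/cancelling, so $k(0.5) = 1$ recovers the
  baseline model and $k(L) + k(1-L) = 2$ keeps the machinery unbiased;
* following joins at rate $1/\tau_r$ with
  $\tau_r = \frac{1}{k}(\alpha_f + \beta_f (N-r)/r)$ and the initiator
  cancels at rate $C_r = k\,\alpha_c / (1 + (r/\gamma_c)^{\varepsilon_c})$,
  using observed constants ($\tau_o = 1290$, $\alpha_f = 162.3$,
  $\beta_f = 75.4$, $\alpha_c = 0.009$, $\gamma_c = 2$,
  $\varepsilon_c = 2.3$);
* after every attempt the initiator updates
  $L \leftarrow \mathrm{clip}(L(1-\lambda) + \lambda \rho)$ with
  $\lambda = 0.02$, reward $\rho = 1$ on success and $0$ on failure.

The nonlinear feedback between tendency and success differentiates the
group: a few individuals rise to the upper bound and dominate initiations,
the rest become followers, and group-level initiation success roughly
doubles relative to the fixed-tendency baseline. The package's analysis
side segments each individual's LT history with exact least-squares
changepoint detection (Bai–Perron-style dynamic programming, BIC model
selection) to date the emergence of leader roles (segment mean ≥ 0.775)
and count later role reversals.

It is written tidyverse-style: simulators return tibbles, analysis
functions are data-frame-first and pipeable, results have `tidy()`,
`glance()`, and `autoplot()` methods.

## A worked example

Run one desk-scale evaluation — a group of 10 starting at moderate
tendency, 5,000 attempts with tendencies carried across attempts — and
summarize its differentiation:

```r
library(leadsim)
cfg <- evaluation_config(
  group_size = 10, initial_lt = 0.5,
  attempts_multiplier = 500, seed = 1L
)
ev <- run_evaluation(cfg, replicate = 1)
glance(ev)
#>   group_size initial_lt n_attempts success_pct final_lt_min final_lt_max
#> 1         10        0.5       5000          66        0.107          0.9
```

66% of attempts ended with the whole group departing, and the final
tendencies span the clip bounds: the group has split. The changepoint
summary shows one agent's LT history contains a high plateau (segment mean
≥ 0.775) beginning at attempt 1,200 — differentiation cost 24% of this
short evaluation — with one leader (10% of the group) at the end and no
role reversals afterwards:

```r
summarize_evaluation(ev)
#>   differentiation_attempt differentiation_fraction low_to_high high_to_low
#> 1                    1200                     0.24           0           0
#>   final_high_count high_lt_pct
#> 1                1          10
```

`autoplot(ev)` draws the per-agent LT trajectories;
`run_treatment_grid()` crosses group sizes with initial tendencies under
matched replicate seeds, and `aggregate_treatments()` produces
treatment-level means, standard errors, and pairwise t tests.
`run_pipeline()` binds simulation, analysis, and reporting into one
reproducible run writing CSV logs and a JSON manifest; the same stages are
available from a shell via `inst/scripts/leadsim
{simulate,analyze,report,all}`.

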