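---
title: "Emergent leadership in collective movement: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent leadership in collective movement: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leadsim)
library(dplyr)
```

## The scientific question

Many animal groups coordinate departures without any fixed leader, and in
many of them individuals look essentially interchangeable. leadsim asks how
stable leader and follower roles can nevertheless emerge in a group of
initially *identical* individuals, purely through the experience each
individual accumulates in trying to start collective movements. The package
simulates a continuous-time, event-driven model of collective movement
initiation — initiation, mimetic following, and cancellation governed by
exponential clocks — augmented with an adaptive *leadership tendency* (LT)
per individual, and provides the changepoint analysis used to detect when
and how the group differentiates into roles.

## The decision model

A group of $N$ identical agents repeatedly attempts collective movements.
One *attempt* proceeds as follows.

**Initiation.** Every agent $i$ carries an exponential clock with rate
$k(L_i)/\tau_o$. The earliest clock fires, that agent departs, and all other
initiation clocks are discarded: exactly one initiator per attempt.

**Following.** While $r$ of $N$ individuals have departed (the initiator
counts towards $r$), each remaining candidate $j$ follows after an
exponential waiting time with rate $1/\tau_r^{(j)}$,

$$\tau_r^{(j)} = \frac{1}{k(1 - L_j)}\left(\alpha_f + \beta_f\,\frac{N - r}{r}\right),$$

so following accelerates as the departed group grows (anonymous mimetism:
only the count $r$ matters, not identities). Decisions to follow are
irreversible within an attempt.

**Cancellation.** Simultaneously the initiator may abort, with rate

$$C_r = k(1 - L_\mathrm{init}) \, \frac{\alpha_c}{1 + (r/\gamma_c)^{\varepsilon_c}}.$$

The earliest pending event is applied, the departed count updated, and all
remaining clocks are redrawn — by memorylessness of the exponential this is
equivalent to letting the pending clocks run. An attempt ends in *success*
when all $N$ agents have departed, or in *failure* the moment the
cancellation clock fires. Since $C_r > 0$ for every $r < N$, attempts can
fail even with a single holdout, and termination is guaranteed.

The rate constants (defaults of `model_params()`) come from direct
observation of collective movement attempts in a group of ten white-faced
capuchin monkeys, later corroborated in sheep groups:
$\tau_o = 1290$, $\alpha_f = 162.3$, $\beta_f = 75.4$, $\alpha_c = 0.009$,
$\gamma_c = 2$, $\varepsilon_c = 2.3$ (time units: seconds in the original
observations; the model only depends on rate ratios). With these values and
$k = 1$ the per-candidate follow rate first exceeds the cancellation rate
once two followers have joined the initiator ($r = 3$):

```{r crossover}
r <- 1:9
tibble(
  r,
  follow = 1 / following_time_constant(0.5, n = 10, r = r),
  cancel = cancel_rate(0.5, r = r)
)
```

## Leadership tendencies

Each agent's LT $L_i \in [0.1, 0.9]$ modulates its rates through the
logistic "k factor"

$$k(L') = \frac{k_{\max}}{1 + e^{(c - L')\,s}}, \qquad c = 0.5,\; s = 10,\; k_{\max} = 2,$$

with $L' = L$ for initiating and $L' = 1 - L$ for following and cancelling:
a high-LT agent initiates more and follows/cancels less. Two structural
properties matter and are asserted in the tests:

* **Neutrality.** $k(0.5) = 1$, so an all-moderate group reproduces the
  unmodified baseline model exactly.
* **Symmetry.** $k(L) + k(1-L) = k_{\max}$, so low and high tendencies
  perturb the rates with equal magnitude in opposite directions — the
  tendency machinery itself cannot bias the group either way. A corollary
  (checked bit-exactly in the tests): in a group with *uniform* fixed LT,
  every competition is scaled by a common constant, so the event sequence —
  and hence the success rate — is identical across fixed LT values under
  matched seeds.

After every attempt the **initiator** (and only the initiator) updates its
tendency by the bounded linear reinforcement rule

$$L \leftarrow \mathrm{clip}\big(L\,(1-\lambda) + \lambda\, \rho,\; 0.1,\; 0.9\big),$$

with reward $\rho = 1$ on success and $\rho = 0$ on failure and learning
rate $\lambda = 0.02$ by default — small, so tendencies track long-run
initiation success rather than the last outcome. The clip bounds keep $k$
strictly positive in both directions. The sigmoid's steep center is the
engine of differentiation: small perturbations around $L = 0.5$ have large
rate consequences, while perturbations near the bounds have almost none, so
moderate tendencies are unstable and extreme ones are sticky.

## Evaluations, treatments, and seeding

An *evaluation* is a sequence of $2000 \times N$ attempts with LT values
carried from one attempt to the next; a *treatment* is a (group size,
initial LT) cell, replicated (50 times at study scale) with LTs reset at
each replicate's start. Replicate $r$ of *every* cell derives its RNG seed
from the base seed and $r$ only (`derive_seed()`), never from the treatment
parameters, so treatments are compared under matched initial random states.
The event engine is compiled (C++) and draws all clocks from R's RNG, so a
`(seed, configuration)` pair reproduces every output byte.

At desk scale the defaults are reducible: all grid dimensions
(`group_sizes`, `initial_lts`, `attempts_multiplier`, `replicate_count`)
are configuration, not constants. The analyses in the package's tests and
acceptance script use the smallest study cells (group sizes 10–40, 10–50
replicates, $500\times N$ to $2000 \times N$ attempts), chosen so each
statistic stabilizes at a few percent relative error while a full run stays
in the minutes range on one core.

## Detecting differentiation

Each agent's LT history is piecewise constant (it changes only at attempts
the agent initiated), reconstructed densely by carry-forward. To quantify
*when* roles emerged, `segment_series()` fits a piecewise-constant model by
exact dynamic programming over candidate breakpoints — the least-squares
segmentation family of Bai and Perron — with:

* **minimum segment length** 5% of the series (trimming), so detected
  plateaus are sustained, not single excursions;
* **break count** 0–5 selected by BIC, with the residual sum of squares
  floored at a scale-aware epsilon so exact fits are compared by the
  penalty alone;
* for a forced break count the optimum is exact, verified in the tests
  against exhaustive enumeration of all placements.

A segment is classified *high* when its mean is at least 0.775 — an
emerged leader plateau; *low* at or below the mirror-image threshold 0.225;
*intermediate* otherwise. The low threshold is this package's symmetric
choice; only the high one is fixed by the analysis the package reproduces.
`first_high_emergence()` reports the observations preceding the earliest
high segment (0 if the series is high from the start),
`count_transitions()` counts post-differentiation class flips, and
`summarize_evaluation()` rolls an evaluation into one tidy row:
differentiation attempt (earliest high emergence over agents), its fraction
of the evaluation, transition counts, and the share of agents ending high.

**Binning.** Before segmentation, long histories are aggregated into
fixed-width bins (mean per bin, targeting ~400 bins; `bin_width`
overridable). Exact DP on a $2000 \times N$-point series would cost
$O(T^2)$ per agent for no benefit: at the default width the attempt-scale
resolution is 0.25% of an evaluation, an order of magnitude finer than the
differentiation statistics reported. Tests confirm breakpoints map back to
attempt units within one bin.

## What the simulations show, and numerical caveats

Under the defaults, small adaptive groups split rapidly and permanently:
one or a few agents reach the 0.9 bound and dominate initiations, the rest
pin near 0.1, and no stable moderate plateau survives (asserted across
initial LT values in the acceptance tests). Adaptive groups initiate
successfully far more often than the fixed-moderate baseline — the
acceptance suite's matched-seed comparison at $N = 30$ rejects equality at
$p < 10^{-12}$ — because high-LT initiators rarely cancel while low-LT
members follow quickly.

Three behaviours deserve flagging, all reproducible with the package:

* **Group-size dependence of the follower equilibrium.** In groups of ~20
  and larger, followers do not sit at the 0.1 bound: a follower's rare
  initiations succeed often enough (the cancellation rate decays like
  $r^{-\varepsilon_c}$ while mimetic following accelerates) that its
  tendency equilibrates near its initiation success rate, around 0.25–0.35.
  Leaders still sit at 0.9 and the distribution remains sharply bimodal —
  the gap between roles is wide — but "low" is not the clip bound at scale.
* **Sensitivity of the differentiation-cost statistic.** The reported
  "percentage of attempts to first high emergence" depends strongly on the
  segmentation convention. With the convention implemented here (earliest
  high segment; an initial segment already at or above 0.775 counts as
  emergence at zero experience), groups started at LT 0.8 register near-zero
  differentiation cost, because the eventual leader's early segment mean
  stays above the threshold. Conventions that instead require a breakpoint
  *into* the high class, or that date differentiation by the settlement of
  the follower side, give values an order of magnitude larger for that one
  treatment while leaving the others essentially unchanged. Comparisons of
  this statistic across studies are only meaningful with the convention
  stated; ours is stated above and fixed in code.
* **Trimming floor.** With 5% minimum segment length, no breakpoint can be
  placed before 5% of the series, so very early differentiation (common at
  larger group sizes) is reported as exactly 5%. This is a floor of the
  detector, not of the dynamics.

## Scope and limitations

The model deliberately excludes spatial movement, limited or local
communication, and partial success (an attempt succeeds only if all $N$
depart); these follow the scope of the model the package implements.
`simulate_attempt()` is a readable R reference implementation of a single
attempt with a full event log; evaluations use the compiled engine, and the
two are cross-checked statistically (together with a Gillespie
direct-method oracle) in the test suite. Degenerate inputs are rejected
rather than reinterpreted: groups need $N \ge 2$, rates must be strictly
positive, impossible events (rate zero) must not draw clocks, and
floating-point ties in event times resolve deterministically to the lowest
agent index.

## A worked example

```{r example}
cfg <- evaluation_config(
  group_size = 10, initial_lt = 0.5,
  attempts_multiplier = 500, seed = 1L
)
ev <- run_evaluation(cfg, replicate = 1)
glance(ev)
summarize_evaluation(ev) |> select(-agents)
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(ev)
```
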