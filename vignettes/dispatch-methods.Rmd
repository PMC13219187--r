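---
title: "Models and methods behind cfrdispatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cfrdispatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfrdispatch)
```

## The dispatch problem

When an out-of-hospital cardiac arrest (OHCA) is reported, smartphone apps
can alert community first responders (CFRs) — trained volunteers near the
patient — to start CPR before the ambulance arrives. Alerting many
volunteers raises the chance that one arrives quickly, but most of those
who accept will reach the scene after someone else is already treating the
patient. Such *redundant* arrivals are this package's proxy for volunteer
fatigue: people repeatedly dispatched to no purpose may disengage from the
program. The design question is therefore how many volunteers to alert,
and when, for each individual incident.

Every component works with the same scalarised objective

$$\text{objective} = \phi(t_{CPR}, t_{EMS}) \;-\; \gamma \cdot
  \#\{\text{redundant volunteers}\},$$

where survival follows a logistic model in the time to first CPR and the
residual gap until the ambulance brings advanced care,

$$\phi(t_{CPR}, t_{EMS}) = \bigl(1 + \exp\{0.04 + 0.3\,t_{CPR} +
  0.14\,(t_{EMS} - t_{CPR})\}\bigr)^{-1},$$

with both times in minutes from OHCA onset. The coefficients come from a
published fit on incidents where volunteers carried no defibrillator; the
package deliberately does not refit them (`survival_params()` lets a user
substitute their own). A fixed 1-minute onset-to-call delay shifts all
call-clock times onto the onset clock. The default trade-off
$\gamma = 0.01$ equates 100 redundant arrivals with one survival
(`tradeoff_params()`).

Time conventions: everything internal is in minutes; seconds appear only
at configuration boundaries (MDP step length, batch intervals). When a
"volunteer response" would be slower than the ambulance, $t_{CPR}$ is
clamped at $t_{EMS}$ rather than raising an error, because the ambulance
crew are themselves responders.

## The exact MDP

`mdp_config()` / `solve_backward_induction()` implement a finite-horizon
MDP over 5-second steps. The state is the step index, one status per
volunteer (unalerted / pending / accepted / rejected), and the residual
time until the current fastest responder arrives. Pending volunteers
accept with per-step probability $p_a$ and reject with $p_b$,
independently across steps — i.e. view times are geometric, hence
memoryless. That assumption is what makes the state space finite and
small; it is also the model's main idealisation, since real view-delay
distributions are heavier-tailed.

Decisions are restricted to a batch of any size at activation and at most
one additional alert per subsequent step, always to the nearest unalerted
volunteer; with 5-second steps this loses essentially nothing and keeps
the action space tiny. The only reward is granted on entry into a terminal
state (residual 0): survival minus $\gamma$ times the expected redundancy
count, where every accepted volunteer other than a strictly-first CFR is
redundant, a CFR arriving exactly with the ambulance is redundant, and
each still-pending alert contributes its probability of a future
acceptance before the 15-minute cancellation horizon.

Conventions chosen where several were defensible:

* alerts issued at step $t$ can first be answered in the transition to
  $t+1$ (including the activation batch);
* on acceptance by volunteer $n$ the residual becomes
  $\min(r-1, D_n)$, so simultaneous arrival with the ambulance is a tie
  and ties count as redundant;
* travel minutes convert to steps by the ceiling (`minutes_to_steps()`),
  a conservative choice that never lets a volunteer arrive early;
* action ties in the Bellman maximisation break toward *fewer* alerts,
  so indifference never generates extra fatigue;
* the exact solver refuses more than `n_cap = 6` volunteers by default —
  the state space grows as $4^N$ and six is where exactness stays
  comfortably interactive. Larger pools belong to the simulation side.

Inside MDP experiments the triage delay defaults to zero, so a 12-minute
EMS response from the call is exactly $T = 144$ steps; a nonzero
`triage_delay` aligns the MDP clock with the simulator when needed.

Two structural facts about the optimum are exposed as functions and
verified empirically in the test suite rather than re-proved: once any
volunteer has accepted, the optimal policy sends no further alerts; and a
volunteer is never alerted whose travel time meets or exceeds the
threshold `alert_threshold(t, config)`, the smallest distance at which the
closed-form marginal benefit `single_volunteer_stats()` drops below
$\gamma$ times the marginal redundancy probability. The survival/fatigue
frontier traced by sweeping $\gamma$ (`mdp_frontier_concavity()`) is
concave, with a slope-violation tolerance of $10^{-9}$ for floating-point
noise.

### Calibrating the per-step probabilities

`calibrate_step_probabilities()` inverts the memoryless trichotomy in
closed form: the total per-step response probability is
$1-(1-c_a-c_b)^{1/H}$ for cumulative targets $(c_a, c_b)$ over horizon
$H$, split proportionally. The default horizon is 180 steps — the
15-minute alert-cancellation window — because the operational per-step
pair (0.00105, 0.00221) reproduces the observed 14% acceptance / 30%
rejection rates under that horizon (to within ~1% relative); a 144-step
horizon, the bare 12-minute EMS window, does not. Both are expressible
through the `horizon` argument, and `cumulative_response_probabilities()`
is the exact inverse for round-trip checking.

## The discrete-event simulator

`simulate_incident()` executes one incident under one policy with
pre-drawn volunteer responses. Each volunteer owns exactly one
(outcome, view delay) draw per replication, *independent of whether or
when they are alerted*; unalerted volunteers' draws are simply unused.
This is what makes common random numbers (CRN) work: every policy
compared on the same `(seed, instance, rep)` tuple sees identical
volunteer behaviour, so policy differences are estimated without response
noise, and two policies that take identical actions on an incident get
exactly equal outcomes (which is also how labeling ties are defined).

Event-ordering rules, fixed for determinism: simultaneous events process
as arrivals, then responses, then batch timers; ties within a class break
by volunteer index; replacement alerts go to the nearest unalerted
volunteer. The 15-minute cancellation applies both to issuing alerts and
to counting acceptances toward redundancy. A CFR arriving simultaneously
with an earlier CFR is treated as redundant, symmetric with the
ambulance-tie rule (the data cannot distinguish these cases, so symmetry
was the natural choice). Only the first-arriving CFR contributes to
survival; nobody drops out after accepting.

The policy families (`policy_spec()`) are: send all at activation; send
$n$ at activation; keep $n$ active until minute $t$ (replace every
incoming *rejection* — silent non-response is not replaced, and no
timer-based top-ups exist in this family); and phased batches every 30 s
(the operational baseline, `sjas_policy()`), which repeats until an
acceptance or pool exhaustion — no batch cap, since none is documented.
The default label set (`build_default_policy_set()`) is send 0–10, keep
1–10 until minute 3, and send-all: 22 policies with stable ids 0–21; the
phased baseline is id 22 and excluded from the classifier's classes.

## The synthetic incident generator

No incident-level data ships with the package, so `make_instances()`
emulates the study conditions parametrically:

* **Volunteer field** — a spatial Poisson process: counts Poisson with
  mean (density $\times$ disc area) and positions uniform on the 1 km
  dispatch disc, walking at 6 km/h as the crow flies, so travel times are
  at most 10 minutes. Densities come from a `region_model()` table at
  0.1% CFR registration; a one-unit `toy_region()` with density 1/km²
  (mean disc count $\pi$) anchors the tests.
* **Triage delay** — lognormal with median 2 minutes, truncated at 10 by
  resampling. The shape `sdlog = 0.9` is not pinned by any published
  summary; it was chosen once to give the strong right skew typical of
  dispatch triage histograms and is exposed as a parameter.
* **Responses** — accept 14.24%, reject 30.02% (the recorded alert
  outcome counts, with dropped acceptances counted as acceptances),
  remainder silent with infinite view delay. Responder view delays are
  lognormal, fitted exactly to the two published quantiles (84% within
  5 minutes, 95% within 10), giving a mode near 33 s — inside the
  reported 20–50 s band. Accepters get a scale shrunk by 10% relative to
  rejecters (the direction is documented, the magnitude is not; 10% is
  our choice and `accept_speedup` exposes it), with the mixture centred
  so the joint responder quantiles are preserved.
* **Acceptance boosting** — `boost_acceptance_rate()` reweights outcome
  marginals to a target (e.g. 50%) while leaving the view-delay law given
  each outcome untouched: the exact equivalent of drawing a Bernoulli
  accept/decline flag and resampling historical responses until they
  match.
* **Eligibility** — volunteers who could not beat the ambulance even by
  departing at activation are dropped, and travel times are sorted
  nearest-first.

What passing tests on this generator do *not* show: the synthetic region
has no spatial incident-rate heterogeneity, the parametric view-delay tail
is only calibration-faithful at the two published quantiles, and real
triage/view dependence structures are absent. Results on synthetic data
reproduce signs and orderings (adaptive beats static; higher acceptance
rates shift optima toward fewer alerts), not any city's exact numbers.
`empirical_response_sampler()` accepts a user's own alert table when one
is available.

## The classification-tree strategy

`label_instances()` evaluates all 22 policies on every training incident
under CRN and labels each incident with the argmax mean objective (ties to
the lowest policy id, i.e. fewest alerts). Features are the volunteer
count, the triage delay, and the *response times* (triage delay + travel)
of the ten nearest volunteers — response times rather than raw travel
times, because a long triage delay plus a short walk is equivalent to the
reverse — with absent volunteers padded by a 999-minute sentinel so trees
split cleanly on "volunteer $i$ exists and is near".

`train_tree()` fits a CART tree (`rpart`, Gini splits) and prunes at the
complexity value with minimal cross-validated error under a fixed fold
seed; depth and leaf-size bounds are exposed since no canonical
hyperparameters exist for this problem. The fitted tree is converted to a
dependency-free structure (`tree_strategy()`) whose traversal convention
is frozen: strictly-less goes left, equality goes right. That structure is
what gets exported to JSON, re-imported, and traversed by
`predict_policy()`, so a deployed tree does not depend on rpart
internals.

`evaluate_strategy()` reports accuracy against freshly labeled test
instances (a "misclassification" is any prediction that is not the
simulation-best policy, however small the gap), the tree's mean
objective/survival/redundancy, the best *static* policy (highest mean
objective applied uniformly), and the per-instance oracle that picks each
incident's labeled best. Under CRN the oracle weakly dominates every
static policy by construction; a well-trained tree lands between the best
static policy and the oracle.

`static_frontier()` and `gamma_sweep()` position strategies in the
(survival, redundancy) plane; the sweep re-scores cached pairs rather
than re-simulating, which is exact because the objective is linear in
$\gamma$ and the simulator output is $\gamma$-free.

## Numerical and testing choices

Backward induction is validated against an independently written
exhaustive-enumeration oracle on all-volunteer-count/horizon combinations
up to $N = 2$, $T = 6$ at $10^{-10}$, against a closed-form alert-plan
enumeration for single-volunteer instances, and against the discrete-event
simulator (which shares no code with the solver) under the memoryless
sampler within three standard errors at $10^5$ replications. The test
suite's simulation studies use a few hundred instances at 40–100
replications — sizes chosen so the whole suite documents the properties
in about a minute — while `run_config()` defaults to the full study sizes
(10,000 training and 2,000 test instances, fixed 6/9/12-minute EMS
scenarios). With small replication counts labels are noisy; that noise is
part of the method (the paper's labels are simulation-based too), and the
accuracy metric is always computed against labels generated at the same
replication budget.

Degenerate inputs are first-class: zero volunteers reduces every policy
to the ambulance baseline; `p_accept = 0` yields zero benefit and zero
redundancy; a unanimous training label produces a single-leaf tree; an
empty action set at exhausted pools collapses to "do nothing".

## Limitations

Ambulance travel times are deterministic per scenario; volunteer speed is
a single constant; there is one volunteer class, no AED pickup, no
CPR-handover accounting (redundancy counted from the first arrival, not
the $k$-th), and no alert retraction. The MDP's memoryless view times
understate the value of waiting for slow responders. All are deliberate
scope boundaries, not accidents of implementation.
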