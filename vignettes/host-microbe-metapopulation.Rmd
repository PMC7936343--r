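---
title: "Host-microbe metapopulation dynamics on ephemeral patches: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-microbe metapopulation dynamics on ephemeral patches: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropatch)
```

## The model

`micropatch` simulates two populations sharing a landscape of `M` ephemeral
habitat patches (think rotting fruit): a microbial population of two types -
a fast grower and a slow grower whose per-event birth rate is reduced by a
factor `1 - c` - and a population of animal hosts (think drosophilid flies)
that develop inside patches and act as the microbes' dispersal vectors.

**Within-patch microbial growth** is a discrete-time stochastic pure-birth
(urn) process. At each time step one cell is chosen to reproduce with
probability proportional to its growth rate:

$$P(N_f \to N_f + 1) = \frac{N_f}{N_f + (1-c)N_s}, \qquad
  P(N_s \to N_s + 1) = \frac{(1-c)N_s}{N_f + (1-c)N_s},$$

for $N_f + N_s < K$, and both probabilities are zero at carrying capacity
$K$ (growth halts; there is no microbial death). With small founder numbers
the early draws are strongly stochastic, so the final composition of a patch
varies widely around the fast type's expected dominance. An alternative
density-dependent kernel (`kernel = "logistic"`) accepts each birth attempt
only with probability $1 - (N_f+N_s)/K$, the standard stochastic analogue of
logistic growth; it slows the clock without changing which type wins any
given accepted birth, so final compositions are distributed identically and
only time-dependent quantities (host survival against a slower-filling
patch) shift.

**Patch decay and host mortality.** Microbial load degrades the patch for
developing hosts. Each host alive in a patch dies in a given step with
probability

$$\delta = \delta_K\,\frac{N_f + \delta_s N_s}{K},$$

where $\delta_K$ is the maximal per-step decay (patch full of the fast
type) and $\delta_s \le 1$ discounts the slow type's contribution - both
types harm the host, the slow one less. The number of deaths per step is
binomial, $\mathrm{Bin}(H, \delta)$. The rescaling $\rho = 1 - \delta/\delta_K$
is the patch quality: 1 for a sterile patch, 0 for a fast-saturated one, and
$(1-\delta_s)N_s/K$ at full occupancy in general. When $\delta_K = 0$ hosts
never decay and we define $\rho = 1$ rather than leave a 0/0.

**The life cycle.** Hosts take `tau` steps to mature. Each survivor then
ingests a uniform sample of `b` cells of its patch's final community
(`b` is a severe bottleneck, $b \ll K$); at most `D` survivors, picked
uniformly across all patches, enter a common dispersal pool; pooled hosts
are assigned uniformly at random to `M` brand-new patches, each laying `H0`
eggs and releasing its carried cells as the founding microbial population.
Optionally, `m` host-independent migrant cells are drawn abundance-weighted
from the old generation and scattered uniformly over the new patches; the
ratio $p = m/(bD)$ measures this flux against the maximal host-carried one.

The emergent effect the package exists to expose: patches rich in the slow
type decay more slowly, so they contribute disproportionately many hosts to
the pool, and those hosts carry correspondingly slow-rich samples. Averaged
over replicates, the slow type's relative abundance among dispersing hosts
exceeds its abundance in the patches (`f_host > f_patch`), without any host
preference or microbial benefit to the host - and this enrichment can carry
a single slow invader cell all the way to fixation despite its growth
disadvantage.

## Parameters

| name | meaning | default | units |
|------|---------|---------|-------|
| `M` | number of patches | 50 | patches |
| `K` | patch carrying capacity | 10^4 | cells |
| `c` | slow type's fitness cost | 0.15 | - |
| `delta_K` | maximal per-step host decay | 0.1 | probability/step |
| `delta_s` | slow type's decay discount | 0.1 | - |
| `b` | cells carried per host | 5 | cells |
| `D` | dispersal-pool cap | 100 | hosts |
| `H0` | eggs per colonising host | 100 | hosts |
| `tau` | host development time | 10^3 | steps |
| `N0` | founder cells per colonised patch | 5 | cells |
| `m` | host-independent migrants | 0 | cells |
| `colonized_fraction` | initially colonised patches | 1 | - |
| `tau_d` | development-time jitter half-width | 0 | steps |
| `M0` | patches replaced per renewal | `M` | patches |
| `renewal_mean` | mean steps between renewals | `tau` | steps |

The defaults are the reference set used for every experiment unless a
function argument overrides them. They put the dynamics in the interesting
regime: `tau` is long enough that decay matters but short enough that some
hosts mature, and `b = 5` makes the uptake bottleneck severe enough that
pure-slow carrier lineages arise by chance.

## Numerical and design choices

**Event order within a step.** Each time step performs exactly one
microbial birth attempt and then one host-mortality draw at the *post-birth*
abundances, so $\delta$ always reflects the current load. The interleaving
matters only at the margin (one cell out of up to $K$), but fixing it makes
runs reproducible bit-for-bit.

**Composed mortality draw.** `run_patch_cycle()` draws the survivor count as
a single $\mathrm{Bin}(H_0, \prod_t(1-\delta_t))$ on the realised microbial
trajectory rather than looping `tau` binomial draws. Sequential binomial
thinning composes exactly, so the joint law of (final state, survivors) is
identical to the step-by-step loop; only the final state and survivor count
are exposed, so there is no observable difference - just a large speedup.
Pure single-type patches additionally take a closed-form trajectory (the
birth sequence is deterministic), which is why experiments on all-fast
landscapes run cheaply even at the full reference scale.

**Uptake on proportions.** Carried cells are $\mathrm{Bin}(b, f)$ on the
source patch's final slow fraction, valid because $b \ll K$; a
hypergeometric option on absolute counts exists for tiny patches
(`host_uptake(method = "hypergeometric")`). Hosts from sterile patches carry
nothing but still lay `H0` eggs.

**Founder overflow.** If a new patch's combined founders (carried cells plus
migrants) exceed `K`, they are subsampled uniformly without replacement to
`K`. With the defaults this guard never binds; it exists so extreme
configurations (huge `m`, many co-colonisers) cannot violate the capacity
invariant.

**Sterile-patch sentinel.** The slow fraction of an empty patch is `NA`, not
0, and all averages (`f_patch`, `f_host`) skip the sentinel; coding sterility
as 0 would spuriously drag enrichment means toward the fast type.

**Fixation bookkeeping.** Fixation is checked at cycle boundaries, when all
carried cells have been deposited into patches, so cells in transit can
never cause a false extinction call. Runs hitting `max_cycles` are reported
as `censored` and excluded from both the numerator and denominator of
fixation estimates; a run cap is an engineering necessity, not part of the
model. Under full neutrality (`c = 0`, `delta_s = 1`) the estimate matches
the invader's initial metapopulation frequency, which is the standard
sanity check for the whole engine.

**Averaging convention.** `f_patch` gives each occupied patch equal weight
by default; `weighting = "cell"` switches to abundance-weighted pooling.
The two differ when patch sizes differ; the package exposes both because
either convention is defensible for "average relative abundance".

**Seed discipline.** Everything stochastic flows through R's global RNG.
Top-level functions take a `seed`; replicate `i` of a master seed `s` runs
on `derive_seed(s, i - 1)` = `(s + 1000003 i) mod (2^31 - 2) + 1`, and every
replicate's derived seed is logged in the output, so any single run of a
sweep can be reproduced in isolation.

**Initialisation.** Each colonised patch starts with `N0` founder cells and
every patch with one clutch of `H0` developing hosts. `invader = "one"`
converts a single founder cell in one patch to the slow type (invasion
experiments, initial metapopulation frequency $1/(N_0 \cdot
\mathrm{colonised\ patches})$); `invader = "all"` converts one cell in every
colonised patch (sustained-coexistence experiments, which need both types
present at appreciable frequency).

**Asynchronous generalisation.** `asynchronous_run()` replaces the
synchronous cycle with a single global clock: each host gets an integer
development time uniform on $[\tau - \tau_d, \tau + \tau_d]$, disperses
individually on maturation (there is no pooling stage, so `D` plays no role
in this engine), and lays `H0` eggs on arrival; renewal events replace `M0`
random patches with empty ones (their microbes and any hosts still
developing there are lost), at geometric inter-event times with mean
`renewal_mean` or exactly periodically. With $\tau_d = 0$, $M_0 = M$ and
periodic renewal at $\tau$, the model reduces to the synchronous engine
with an unbounded pool - the degenerate limit used to cross-validate the
two engines (the comparison must lift the pool cap on the synchronous side,
since the asynchronous model has nothing corresponding to it). Snapshots
are taken after a step's growth and mortality but before its dispersal, so
in the degenerate limit the snapshot at $t = k\tau$ describes the same
end-of-growth moment as the synchronous cycle-$(k-1)$ record.

## What the simulations do and do not show

All experiments are self-generated Monte-Carlo runs; there is no external
data. The simulator *is* the study system, so passing tests certify the
internal consistency of the implementation (oracle equivalence, neutrality
controls, engine cross-validation) and the model's qualitative predictions
(enrichment, bottleneck and cost monotonicity, sterile-landscape
extinction), not anything about real host-microbe systems. Real microbiomes
have many interacting taxa, within-patch death and dormancy, host choice,
and spatial structure among patches - all deliberately absent here so that
the enrichment mechanism can be isolated.

The test suite runs at desk scale: `M = 20`, `K = 10^3`, `tau = 200` for
metapopulation experiments (200-500 replicates), against the reference
scale's `M = 50`, `K = 10^4`, `tau = 10^3` and 10,000-replicate sweeps.
Scaling down weakens the survival contrast between slow-rich and fast-rich
patches (the per-cycle decay exponent scales like $\delta_K \tau^2 / K$),
so desk-scale effect sizes are smaller than reference-scale ones. Two
consequences are worth recording. First, the sterile-landscape extinction
experiment is run at the full reference scale - affordable because an
all-fast landscape takes the closed-form trajectory path - where sterile
patches overwhelm the dispersal pool and the microbes die out within a few
cycles in every replicate. Second, in the enrichment experiment the
per-cycle *mean* of `f_host - f_patch` stays positive through all recorded
cycles, but its per-cycle significance fades late in the window as more
replicates reach fixation (a fixed replicate's difference is identically
zero, diluting the signal without ever opposing it); significance is
therefore certified on the window as a whole while the sign is checked
cycle by cycle.

The exact enumeration oracle (`exact_final_composition_distribution()`)
deliberately refuses $K > 100$: its forward recursion is meant to validate
the stochastic kernel on small patches, not to replace it.

`expected_host_survival()` is a numerical mean-trajectory calculation, not
a closed-form result: for single-type founders the trajectory is
deterministic and the value is the exact per-host survival probability; for
mixed founders it is an approximation that ignores trajectory variance.

## Known limitations

* Two microbial types only; no within-patch microbial death, dormancy, or
  mutation between types.
* Hosts never choose patches or microbes; mortality during dispersal is
  not modelled.
* The asynchronous engine ignores `D` (no pooling stage exists there) and
  kills developing hosts in renewed patches; both are modelling choices
  where the synchronous description has no direct analogue.
* Fixation runs need a `max_cycles` cap; near-neutral parameter sets can
  produce noticeable censoring, which the estimates report but cannot
  remove.
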