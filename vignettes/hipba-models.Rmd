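---
title: "Modeling persistence in the HipBA toxin-antitoxin circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling persistence in the HipBA toxin-antitoxin circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question

Bacterial persisters are phenotypic variants — not mutants — that survive
antibiotic treatment by entering a dormant state. In *Escherichia coli* the
hipBA operon is a canonical persistence module: the HipA toxin arrests
growth, while the HipB antitoxin dimerizes (B2), sequesters two HipA copies
in an inert AB2A complex, and, together with that complex, autorepresses
the operon's promoter. Because both genes share one promoter and one
transcript, their expression noise is correlated; because the circuit is
autorepressed, expression is low and therefore noisy.

`hipbasim` implements a mechanistic mass-action model of this circuit and
asks two questions of it:

1. Is persistence the signature of deterministic **bistability** (two stable
   expression states), or of **stochastic threshold crossings** in a
   monostable system?
2. How does the **regulatory architecture** — operonic cotranscription and
   negative autoregulation — shape the amount of phenotypic noise, and
   hence the frequency of persistence?

## The model

Eight species are tracked in the wild-type network: the promoter in its
free (`P`), B2-bound (`Pp`) and AB2A-bound (`Ppp`) states, the shared
transcript `M`, free HipA (`A`), free HipB monomer (`B`), the HipB dimer
(`B2`), and the toxin-antitoxin complex (`AB2A`). Seventeen mass-action
reactions connect them: transcription from each promoter state (at rates
$\alpha > \alpha_{B2} = \alpha_{AB2A}$, so bound repressor lowers
transcription tenfold), repressor binding/unbinding, translation of both
proteins from the shared transcript ($\beta_B = 60$, $\beta_A = 12$
molecules per mRNA-hour — the antitoxin is made faster but degraded much
faster, $\delta_B = 18\,h^{-1}$ versus $\delta_A = 1.2\,h^{-1}$),
irreversible HipB dimerization, reversible complex assembly
$2A + B_2 \leftrightarrow AB_2A$, and first-order degradation of every
free species. Promoter-bound complexes are protected from degradation.
All amounts are molecule counts per cell; the chromosomal operon
contributes one promoter copy (configurable).

Three conventions deserve explicit statement:

* **Event-rate half factors.** Dimerization, complex association and
  complex dissociation carry a factor ½ in the deterministic equations:
  one dimerization event consumes two B and produces one B2 at rate
  $\tfrac12\beta_{B2}[B]^2$, one association event consumes two A and one
  B2 at rate $\tfrac12\mu[A]^2[B_2]$, and one dissociation event releases
  them at rate $\tfrac12\mu_R[AB_2A]$. The stochastic engine uses the
  matching combinatorial propensities ($\beta_{B2}B(B-1)/2$, etc.), so the
  two backends agree in the large-count limit — an invariant the test
  suite checks by extensive volume scaling.
* **HipA translation uses its own constant.** The reaction table lists
  HipA translation at $\beta_A = 12$; the package uses that value (one
  printed reaction line reuses the HipB symbol, which we treat as a
  typographical slip).
* **Counts, not concentrations.** The stochastic model requires integer
  counts, and the deterministic model shares its parameters for controlled
  comparison, so "per mol" rate units are read as "per molecule".

```{r}
library(hipbasim)
p <- hipba_params()
net <- build_network("wild_type")
net
round(find_equilibrium(net, p), 3)
```

## Monostability: reduction and scans

The promoter states, mRNA, HipB monomer and dimer equilibrate on minute
timescales; free HipA and the complex evolve over hours ($\delta_A =
\delta_{AB2A} = 1.2\,h^{-1}$, and complex turnover couples them). The
quasi-steady-state reduction therefore solves the six fast balance
equations at fixed $(A, AB_2A)$. The promoter and mRNA balances are linear
given B2, and the HipB balance is an explicit quadratic, so the whole fast
system collapses to one strictly decreasing scalar balance in B2 with a
unique nonnegative root, found by bracketed bisection on
$[0, g(0)/\delta_{B2} + 1]$ — a deliberately robust alternative to
multidimensional root finding. Nullclines of the resulting planar system
are traced on a geometric grid (the default spans 0.01–1000 molecules,
bracketing the nominal equilibrium by over a factor of 30 each way, with
intersection counts checked to be stable under grid doubling), and
intersections are polished by damped Newton iteration, merged below 0.5%
relative distance.

```{r, eval = FALSE}
ncs <- count_equilibria(p)   # 1 intersection, stable
ncs$points
```

Two Monte-Carlo studies guard against the conclusion being an artifact of
the nominal parameter choice. Each rate constant's tested range spans a
decade either side of its nominal value; draws are log-normal with median
at the nominal and the central 95% mass matching that range
($\sigma_{\log} = \ln 10 / 1.96$), untruncated. For each draw the full
model is integrated from random initial conditions (mRNA uniform on
[0, 100], proteins uniform on [0, 1000] — the dimer and complex included,
since all non-promoter proteins are randomized — promoters held at the
free state) to 1000 h, accepted as converged when the right-hand side
falls below $10^{-4}$ molecules/hour, and final states are clustered by
single linkage under the largest per-species relative difference, with a
$10^{-6}$-molecule floor so the 1% criterion is defined at zero amounts.
One cluster across all starts is the monostability verdict. The package
defaults run 50 draws × 50 initial conditions for the joint scan (the
single-parameter design iterates the 17 constants in table order); the
published design (100 × 500 per parameter, 1000 joint combinations) is a
larger instance of the same configuration. A planted bistable control —
the Schlögl network, with stable states near 87 and 563 — must always be
flagged multistable, which bounds the power of the 1% metric from below.

## The stochastic model and the persistence ratio

The Gillespie direct method (implemented in C++, driven by R's RNG so
`set.seed()` governs reproducibility) simulates the same reaction network
exactly. Statistics are dwell-time weighted — each state counts in
proportion to the time the cell spends in it, not the number of events —
and are accumulated exactly during simulation over the post-burn-in
window, so they do not depend on how the trajectory is stored. The default
initial condition is the deterministic equilibrium rounded to integers and
the default burn-in discards the first 100 h, a conservative allowance
for relaxing the rounding transient given the slowest timescale
($1/\delta_A \approx 0.8$ h) of the system.

Entry into persistence is scored by the ratio
$$R = \frac{\text{free HipA}}{\text{free HipA} + \text{free HipB}},$$
with $R > 0.5$ — free toxin outnumbering free antitoxin — defining the
persister state. **Free antitoxin accounting** is the one genuinely open
modeling choice here. The package counts each unbound HipB dimer as two
free antitoxin molecules (`antitoxin = "with_dimer"`): the dimer is
neither neutralizing HipA in the AB2A complex nor bound to the promoter,
and it is the dimer that actually binds and disables the toxin. The
alternative — counting only monomeric B (`antitoxin = "monomer"`) — is
retained as a sensitivity flag, but it makes wild-type persistence the
*majority* state (mean R ≈ 0.6), because rapid dimerization keeps the
monomer pool tiny; that is irreconcilable with persistence being a rare
excursion, so the dimer-inclusive accounting is the default. Intervals
with no free molecules of either kind leave R undefined; they are
excluded from all statistics (a fraction of dwell time that the wild type
spends near 12%, dominated by states where all antitoxin is complexed or
promoter-bound and no free toxin is present).

```{r, eval = FALSE}
run <- gillespie_run(net, p, t_end = 600, seed = 1, burn_in = 100)
time_weighted_stats(run, "R")
detect_persistence(compute_R(run))$fraction
```

## Architecture comparison

Two rewired circuits isolate the contributions of cotranscription and
feedback, each keeping every rate constant at its wild-type value:

* **Uncoupled transcription** gives each gene its own promoter (with its
  own three repression states, both repressors binding both promoters at
  wild-type constants, one copy each) and its own transcript; `M_A`
  translates only HipA and `M_B` only HipB — 12 state variables. Losing
  the shared transcript removes the correlation between toxin and
  antitoxin bursts, so their ratio fluctuates more.
* **No feedback** deletes the repressed promoter states entirely:
  transcription is constitutive at $\alpha$. Expression rises (mRNA
  equilibrium 10 instead of about 1), counts are larger, and relative
  fluctuations — and the ratio's excursions — shrink.

Replicate stochastic runs ("simulated cells", one seed each; the ensemble
reading of independent cells is adopted, with 600 h horizons and 100 h
burn-in as the package's standard problem size) are summarized by the
dwell-weighted mean of R and its Fano factor $\sigma^2/\mu$, the noise
measure applied to R itself (a per-species option exists for
diagnostics). The package's reproducible finding, asserted by one-sided
Wilcoxon rank tests across replicates and reproduced in disjoint seed
batches, is the double ordering

$$\text{uncoupled} \;>\; \text{wild type} \;>\; \text{no feedback}$$

in both mean R and Fano of R: uncoupling pushes the cell toward the
threshold and makes it noisier (more persisters), while removing feedback
does the opposite (fewer). The wild-type architecture sits between the
two, consistent with the view that operon structure plus autorepression
tune the persistence frequency to an evolutionarily favorable
intermediate.

```{r, eval = FALSE}
cmp <- compare_architectures(p, seeds = 1:10)
cmp$summary
test_orderings(cmp)
```

## What the simulations do and do not show

The stochastic trajectories are the study's data — there is no external
dataset — so passing tests demonstrate internal consistency of the model
world, not biological truth. Specifically:

* The model describes **entry into** persistence only. HipA's growth
  arrest feeds back on every rate in a dormant cell, which the model does
  not represent, so persistence **durations** and absolute persister
  frequencies are outside its validity.
* Cell growth, division and dilution are absent; degradation constants
  implicitly absorb them.
* The uncoupled variant necessarily carries two promoter copies against
  the wild type's one — an intrinsic asymmetry of that comparison, not a
  tunable artifact.
* Rate constants are literature-anchored order-of-magnitude estimates;
  the monostability claim is a Monte-Carlo statement over their
  decade-wide ranges, not a proof, and no formal bifurcation analysis is
  attempted.

## Numerical choices

Stiff integration uses `deSolve`'s `lsoda` (relative tolerance $10^{-8}$,
absolute $10^{-10}$); equilibria are located by 1000 h integration
followed by damped Newton polishing, with the singular
promoter-conservation direction replaced by its linear constraint, to a
residual below $10^{-6}$ molecules/hour, and non-convergence raises an
error rather than returning silently. Scan runs failing the steady-state
residual are excluded and counted, never silently dropped. Sub-seeds for
scan draws are derived as `seed + draw index`, so any draw can be rerun
in isolation. Test problem sizes (for example 50 × 50 scan draws, 10-seed
ensembles, 400–600 h horizons) were chosen as the smallest instances at
which the Monte-Carlo assertions have comfortable statistical margins.
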