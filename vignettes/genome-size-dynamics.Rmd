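---
title: "Spontaneous genome size dynamics under indels, duplications and large deletions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spontaneous genome size dynamics under indels, duplications and large deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomesizer)
```

## The model

`genomesizer` studies the size of a genome as a Markov chain on the
nonnegative integers, deliberately ignoring sequence content: every
mutational mechanism is projected onto its effect on length. Four types of
events act on a genome of current size $s$:

* **small insertions** add $1..l_{\mathrm{ins}}$ bp, drawn from a
  size-independent law (this is also how transposable-element insertions
  are folded in, at a per-bp rate);
* **small deletions** remove $1..l_{\mathrm{sdel}}$ bp, floored at 0;
* **segmental duplications** add a rearrangement-sized segment;
* **large deletions** remove a rearrangement-sized segment.

Rearrangement sizes scale with the genome. Under the *uniform* law both
breakpoints are uniform along the chromosome, so the event size is uniform
on $1..s$: gains and losses are multiplicative. Under the *truncated
lognormal* law a fixed lognormal size distribution is redrawn while the
event exceeds the current genome size — the weakest possible coupling of
event size to genome size, motivated by rearrangements observed in
*Escherichia coli* and *Salmonella enterica* cultures.

Each type occurs as an independent Poisson process along the genome with a
per-bp, per-generation rate $\mu_{\mathrm{type}}$, so the number of events
of a type in one generation is Poisson with mean $\mu_{\mathrm{type}}
s_0$, where $s_0$ is the size at the **start** of the generation. Within a
generation the events are applied in a uniformly random order, each acting
on the size left by the previous one; rearrangement sizes are drawn
against the current, mid-generation size (drawing them at generation start
would make "truncated at the current chromosome size" meaningless). A
genome that finishes a generation at size 0 is reassigned size 1, so the
generational chain on $\mathbb{N}^*$ has no absorbing state; mid-generation,
only small insertions can leave size 0.

Two transition kernels describe the process: $\mathbf{M}_1$, the law of a
single mutation on $\mathbb{N}$, and $\mathbf{M}_G$, the law of one full
generation on $\mathbb{N}^*$, obtained by mixing powers of $\mathbf{M}_1$
with Poisson$(\mu s_0)$ weights and rewiring 0 to 1.

## Why sizes stay bounded: drift in the right scale

For multiplicative rearrangements the natural scale is logarithmic. A
single uniform large deletion from a large genome changes $\log s$ by
$-1$ on average ($\int_0^1 \log x\,dx$), a duplication by $2\log 2 - 1
\approx 0.386$ ($\int_1^2 \log x\,dx$), and indels by $O(1/s) \to 0$. So
even at equal rates the duplication/deletion walk drifts downward:
$1/(2\log 2 - 1) \approx 2.59$ duplications are needed to revert one
deletion. The chain has a unique stationary size distribution whenever the
rate-weighted drift is negative,

$$\mu_{\mathrm{ldel}}\delta_{\mathrm{ldel}} +
  \mu_{\mathrm{dup}}\delta_{\mathrm{dup}} +
  \mu_{\mathrm{ins}}\delta_{\mathrm{ins}} +
  \mu_{\mathrm{sdel}}\delta_{\mathrm{sdel}} < 0,$$

which for the uniform model in log scale reduces to $(2\log 2 - 1)
\mu_{\mathrm{dup}} < \mu_{\mathrm{ldel}}$ — genome size remains bounded
without selection even when duplications are up to ~2.59-fold more frequent
than large deletions, and regardless of the indel rates.

`expected_scaled_jump()` evaluates the per-type drift at any size exactly
(log-gamma closed forms for the uniform sums, conditional-mean closed
forms for the lognormal in natural scale, finite sums elsewhere);
`estimate_asymptotic_deltas()` tracks the drifts along a size grid and
requires a plateau before `stationarity_condition()` will give a verdict.

```{r drift}
d <- estimate_asymptotic_deltas(indel_model(), rearrangement_model("uniform"))
stationarity_condition(mutation_rates(), d)
```

Two numerical choices matter here. First, the plateau test accepts a drift
when the change between the two largest grid sizes is below `rel_tol`
relatively *or* `abs_tol` absolutely; the absolute branch is needed for
drifts converging to 0 (indels in log scale), whose relative changes never
settle. Second, the default grid extends to $10^{12}$ bp — far beyond any
genome — because the truncated-lognormal conditional mean with
$\sigma = 2.56$ natural-log units is still ~6% below its limit at
$10^9$ bp and only plateaus beyond ~$10^{11}$ bp. For that law in natural
scale the drifts converge to $\mp e^{\mu + \sigma^2/2}$ (about
$6.6\times 10^5$ bp with the default fit) for deletions/duplications and
to $\mp$ the mean indel size for indels. With the default symmetric rates
the net drift is exactly zero and the condition is honestly reported as
`inconclusive`: boundedness is then a question the analytic machinery
cannot settle, although simulations still show median shrinkage driven by
the size-dependence of the truncated mean at small genome sizes. (With the
default 1..40 bp uniform indels the mean indel effect is exactly 20.5 bp;
reports that quote 20 have rounded.)

## One-generation quantile bounds (continuous approximation)

For large genomes, indels are negligible and the duplication/deletion
process is well approximated by a continuous multiplicative walk: each
event multiplies the size by $\lambda \sim U[0,1]$ (deletion) or
$U[1,2]$ (duplication). Mixing $n$-step walks with Poisson weights gives

$$\mathbb{E}[\log \hat S_f] = \log s_0 - A s_0, \qquad
  \mathrm{sd}[\log \hat S_f] = B\sqrt{s_0},$$

with $A = \mu_{\mathrm{ldel}} - (2\log 2 - 1)\mu_{\mathrm{dup}}$ and
$B = \sqrt{2(\log 2 - 1)^2 \mu_{\mathrm{dup}} + 2\mu_{\mathrm{ldel}}}$.
Cantelli's one-sided inequality then bounds the post-generation quantiles
for *any* starting size through the curve
$Q_k(s_0) = \exp(\log s_0 - A s_0 + k B \sqrt{s_0})$: at least
$1 - 1/(1+k^2)$ of offspring lie at or below $Q_k(s_0)$ (one half for
$k = 1$, 80% for $k = 2$). When $A > 0$ the curve has a unique fixed
point $s_{\mathrm{fixed}}^{(k)} = k^2 B^2 / A^2$ — genomes above it shrink
below it with probability at least $1 - 1/(1+k^2)$ in a single generation,
no matter what selection did beforehand — and a maximizer $s_0^{\max,(k)}
\le s_{\mathrm{fixed}}^{(k)}$ whose image $\tilde s_{\max}^{(k)} =
Q_k(s_0^{\max,(k)})$ bounds the quantile uniformly in $s_0$.

```{r bounds}
continuous_bounds(1, 1e-6, 1e-6)
```

For equal rates $\mu$ the fixed point is
$\frac{k^2}{\mu}\frac{2(\log 2 - 1)^2 + 2}{(2 - 2\log 2)^2} \approx
5.81\,k^2/\mu$: the bound scales inversely with the rearrangement rate.

The maximizer is the root of $A u^2 - \tfrac{kB}{2} u - 1 = 0$ in
$u = \sqrt{s_0}$, i.e.

$$s_0^{\max,(k)} = \frac{1}{A} + \frac{k^2B^2}{8A^2}
  \left(1 + \sqrt{1 + \frac{16A}{k^2B^2}}\right).$$

Note the $k^2$ inside the root: a frequently quoted variant omits it and
coincides with the true maximizer only at $k = 1$. The test suite pins the
closed form against a golden-section maximization of $Q_k$, and validates
the Cantelli bounds by Monte-Carlo of the continuous process
(`sim_continuous_generation()`, the package's internal stochastic oracle)
over starting sizes $10^3$–$10^9$ and $k \in \{1,2,3\}$. If $A \le 0$ the
curve is unbounded and all bound functions fail loudly rather than return
infinities.

## The mutation-accumulation experiment

`run_experiment()` simulates the idealized mutation-accumulation design:
independent single-genome lines through strict one-individual bottlenecks,
so selection is switched off entirely. The defaults *are* the reference
study conditions and are not meant to be tuned casually:

| parameter | default | meaning |
|---|---|---|
| `mu_ldel`, `mu_dup` | $3.778\times 10^{-9}$ /bp/gen | large-deletion rate measured in *S. enterica*; duplication rate set equal to make the process nominally unbiased |
| `mu_ins`, `mu_sdel` | $7.556\times 10^{-9}$ /bp/gen | twice the rearrangement rates |
| indel sizes | uniform 1..40 bp | both directions, size-independent |
| lognormal fit | meanlog 10.1214, sdlog 2.5602 | natural-log scale (4.3957 / 1.1119 in log10), fitted to 127 verified rearrangements |
| initial size | $4\times 10^6$ bp | one *E. coli*-sized chromosome |
| design | 10,000 lines × 1,000 generations | plus 100-line runs to a $10^4$ bp floor |

Under the uniform law, ~99% of lines end below their starting size after
1,000 generations with a median loss of ~3.8 Mb; under the truncated
lognormal, ~61% shrink with a median loss of ~0.6 Mb — in both cases with
identical rates and identical size laws for gains and losses, so the
apparent deletion bias in the observed events is created purely by the
size-dependence of the event-size law. The acceptance script
(`scripts/acceptance.R`) recomputes these numbers at full scale.

What the generator does *not* emulate: laboratory growth phases between
bottlenecks (and the implicit selection against lethals during them),
mutation-rate heterogeneity along the genome or in time, any sequence-level
structure (genes, replication origin, hotspots), and chromosome-count
changes. Passing tests therefore show that the *size projection* of the
mutational process behaves as predicted, not that real MA lines will match
quantitatively. For selection studies, `run_line()` and `one_generation()`
expose every per-generation state so a user-supplied selection step can be
interposed; no selection operator is shipped.

## Numerical and implementation choices

* **Event skipping.** With per-bp rates around $10^{-8}$, more than 90% of
  generations carry no event, and skipping them is what makes 250,000-
  generation floor runs take seconds: the engine draws the geometric gap to
  the next event-bearing generation, then the event count conditioned on
  being positive (Poisson inverse CDF), then types from the conditional
  type law. By Poisson thinning this is distributionally identical to four
  per-type Poisson draws per generation; the naive loop is kept
  (`skip_empty = FALSE`) and the suite checks the two paths against each
  other by a KS test.
* **Truncated-lognormal draws** use inversion of the conditional CDF
  rather than a redraw loop — the same law with bounded runtime. Draws are
  rounded to the nearest bp and clamped to 1 bp *before* the truncation
  test; if the law leaves less than $10^{-12}$ mass at or below the
  current size the sampler errors instead of looping (such states are far
  below any simulated regime).
* **RNG policy.** One sequential stream per experiment, seeded once at
  entry: lines drawn sequentially from a single stream are independent and
  the whole experiment is reproducible from one integer. Per-line
  substreams were considered and rejected as needless complexity; exact
  replay is provided at the event-log level instead (`replay_events()`
  reproduces every trajectory bit-exactly from its log).
* **Finite-window kernels.** `build_m1()` stores the one-mutation kernel
  on `0:s_max` sparsely, recording per-row mass lost above the window;
  `build_mg()` forms each generational row as a Poisson mixture of
  $\mathbf{M}_1$ powers applied row-wise (vector × sparse matrix, never
  materializing $\mathbf{M}_1^n$), cutting the Poisson tail at $10^{-12}$
  per row. Rows near the window top inevitably leak (a duplication from
  $i > s_{\max}/2$ leaves the window), so the stationary solver guards on
  the *stationary-weighted* leak $\sum_i \pi_i\,\mathrm{leak}_i$, which in
  shrink-biased regimes is tiny once the window covers the bulk; windows of
  a few hundred states suffice for the scaled-rate regimes used in the
  tests, and the power iteration's TV trajectory decays geometrically — the
  finite-window echo of the Doeblin-type convergence of the full chain.
* **Stable sums.** Uniform-model log drifts use
  $\sum_{j<s} \log j = \log\Gamma(s)$, exact to ~$10^{-12}$ up to
  $10^9$ bp and beyond, with the convention $\log 0 = 0$ for the
  transition to the empty genome.
* **Shrinkage definition.** A line counts as shrunk when its final size is
  *strictly* below the initial size; exact ties (probability ~0) count as
  not shrunk.
* **Table-style event summaries.** "Median size of events in a line" is
  the median across lines of the per-line mean absolute event size (the
  per-line aggregate first, since the quantity is "in a line"); lines with
  no event of a type are excluded from that type's size summary but
  contribute a zero count. Because the spread convention for such medians
  is ambiguous, both MAD and SD across lines are reported, and a pooled
  per-event median is available via `summarize_events(..., pooled = TRUE)`.

## Problem sizes used by the test suite

The suite runs the full 10,000-line × 1,000-generation experiments (a few
seconds each with event skipping) and the 100-line floor runs; Monte-Carlo
cross-checks use $2\times 10^4$–$2\times 10^5$ replicates, sized so that
the assertion tolerances sit at ~3 Monte-Carlo standard errors (for sd
checks the compound-Poisson kurtosis, not $1/\sqrt{2n}$, sets that error;
for TV comparisons the per-cell binomial noise summed over the support sets
a noise floor, which is why kernel-row comparisons are binned). Stationary
distributions are computed on windows of 240–400 states with rates scaled
up (0.02/bp rearrangements, 0.04/bp indels) so the stationary bulk sits
well inside the window.

## Known limitations

* The stationarity machinery addresses the no-selection chain; with
  selection only the one-generation Cantelli bounds (which hold for any
  starting distribution, hence after any selection step) carry over.
* The floor-crossing times of the reference study have a heavy right tail
  at these rates (waiting times near the floor scale as
  $1/(\mu_{\mathrm{ldel}} s)$ generations per deletion, i.e. tens of
  thousands of generations at $10^4$–$10^5$ bp), so the maximum crossing
  generation over 100 lines varies by tens of thousands of generations
  between seeds.
* Truncated-window stationary vectors are approximations controlled by the
  leak diagnostics; they are meaningful only in shrink-biased regimes.
* Drift estimation for a custom scaling function falls back to exact
  summation (sizes up to $10^7$) or Monte-Carlo; only the log and identity
  scales have closed forms at all sizes.
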