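---
title: "Temporal network measures for dynamic functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal network measures for dynamic functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempnet)
```

## The model

A temporal network extends a static graph $G = (V, E)$ by indexing every
edge with a time point: the data are a stack of symmetric binary
connectivity matrices $A^t_{ij}$ ("t-graphlets"), one per discrete time
index $t = 1, \dots, T$, over $N$ nodes. The equivalent *contact sequence*
lists the events $(i, j, t)$ and is the more compact representation for
sparse networks; `contacts_to_graphlets()` and `graphlets_to_contacts()`
convert losslessly between the two. `tempnet` restricts itself to binary,
undirected, discrete-time networks without self-loops: weighted stacks can
be stored in a `temporal_network`, but every measure consumes the binary
form and refuses anything else. In the intended application the nodes are
parcellated brain regions and the stack is a time-resolved ("dynamic")
functional connectivity estimate derived from fMRI BOLD series, but
nothing in the measures is specific to neuroimaging.

Throughout the package an "edge" in a sum means an **unordered** pair,
accumulated over the upper triangle. The literature is ambiguous on this
point and several constants (volatility, fluctuability denominators)
change by a factor of two under the other convention, so we fix it once
here and use it everywhere.

## Temporal paths and intercontact times

Two primitives underlie most measures.

**Shortest temporal paths.** The duration $d^t_{ij}$ is the number of time
steps needed for node $i$, starting at time $t$, to reach node $j$,
travelling edges only forward in time. Conventions, fixed here and used
consistently downstream:

* the expansion begins in the graphlet at the start time itself, and a hop
  made at the start time costs 1, i.e. $d = (\text{arrival} -
  \text{start}) + 1$; $d^t_{ii} = 0$;
* `steps_per_t` limits how many edges can be travelled within one time
  point. The default is `"unbounded"` (connectivity closure within each
  graphlet), the sensible choice for slow signals such as BOLD where one
  sample spans seconds; for millisecond-scale data an explicit small limit
  is more defensible;
* unreachable targets are `Inf`, never a sentinel integer.

Temporal paths are rarely symmetric even though every graphlet is: once
the relevant edges have passed, the return path may not exist at all.

**Intercontact times.** For each pair, $\tau_{ij}$ is the ordered list of
gaps between consecutive activations (a pair active at time points 2, 4
and 6 has $\tau = (2, 2)$); pairs with fewer than two activations have an
empty list.

## The measures

* **Temporal degree centrality** $D_i = \sum_j \sum_t A^t_{ij}$ — overall
  activity of a node; blind to temporal order.
* **Temporal closeness centrality**
  $C_i = \frac{1}{N-1} \sum_{j \ne i} 1 / \bar d_{ij}$, where
  $\bar d_{ij}$ averages $d^t_{ij}$ over the start times at which a path
  exists. Never-connected pairs contribute 0 (the $1/\infty = 0$
  convention), keeping $C_i \in [0, 1]$ and defined on sparse networks.
* **Burstiness** $B = (\sigma(\tau) - \mu(\tau)) /
  (\sigma(\tau) + \mu(\tau))$, per edge. We use the *population* standard
  deviation: the defining property that identical intercontact times give
  exactly $B = -1$ requires $\sigma = 0$ without a finite-sample
  correction. $B$ is undefined (`NA`) below two intervals and such edges
  are excluded from nodal sums; `pooled_burstiness()` concatenates raw
  $\tau$ lists across subjects (not averages of per-subject $B$), the
  stabilisation strategy for short recordings.
* **Fluctuability** $F$ = (number of pairs ever active) / (total number of
  activations): spatial diversity of connections, order-blind, with
  $F = 1$ exactly when every active pair occurs once.
* **Volatility** $V$ = mean Hamming distance (differing unordered pairs)
  between consecutive graphlets: the rate of reconfiguration.
* **Reachability latency** $R_r$: per source and start time, the sorted
  vector of the $N$ durations (self-distance 0 included) is indexed at
  rank $\lfloor rN \rceil$ (round half-up, 1-based), and defined terms are
  averaged. With $r = 1$ this is the temporal diameter. Terms where the
  rank is unreachable are dropped from the numerator while the denominator
  stays $TN$ — a deliberate penalisation of starts that never reach the
  target fraction; `normalization = "Tstar"` divides by the count of
  defined terms instead.
* **Temporal efficiency**
  $E = \frac{1}{T(N^2-N)} \sum_{i \ne j,\, t} 1 / d^t_{ij}$ with
  $1/\infty = 0$.

A nodal version of temporal efficiency is *not* provided: averaging
inverses (efficiency) and inverting an averaged distance (closeness)
differ by Jensen's inequality, so the claim that the two would coincide
does not hold in general and we prefer not to guess which was intended.

## Deriving t-graphlets from node time series

The estimator produces a *unique connectivity estimate per time point*
without windowing, clustering, or parameter optimisation, via a weighted
Pearson correlation:

$$r(x, y; w) = \frac{\Sigma_{x,y;w}}{\sqrt{\Sigma_{x,x;w}\,\Sigma_{y,y;w}}},
\qquad
\Sigma_{x,y;w} = \frac{\sum_v w_v (x_v - \mu_{x;w})(y_v - \mu_{y;w})}{\sum_v w_v},$$

with weighted means $\mu_{\cdot;w}$. With identical weights this is
exactly the ordinary Pearson coefficient (a property the tests enforce to
$10^{-12}$); a non-tapered sliding window would be just another (binary)
weight vector.

The weight vector for time $t$ scores every other time point $v$ by the
similarity of its *global spatial pattern*:
$w^t_v = 1 / \lVert y^t - y^v \rVert_2$ over the standardized node
activation columns. Numerical choices:

* min–max scaling of the raw weights to $[0, 1]$ is computed over **all**
  off-diagonal entries of the $T \times T$ matrix jointly, not per row,
  so that relative similarity across the whole session is preserved; if
  all off-diagonal weights are equal they are set to 1;
* the diagonal is set to 1 afterwards — the time point of interest always
  participates at full weight;
* two distinct time points with identical columns (zero distance) would
  give an infinite weight; they are capped at the maximum finite raw
  weight, with a warning, preserving "most similar gets most weight";
* `T >= 3` is required, otherwise min–max scaling is vacuous.

Each edge's correlation series is then Fisher-transformed
($z = \operatorname{artanh} r$, $|r|$ clipped to $1 - 10^{-15}$, a value
chosen to keep the transform finite without materially moving any
realistic correlation), shifted so its minimum equals 1 and Box–Cox
transformed with $\lambda$ selected per edge by maximising the profile
log-likelihood over the grid $-5$ to $5$ in steps of $0.1$ (the shift
keeps the power transform acting comparably across series), and finally
standardized to mean 0, SD 1. Binary graphlets set an edge to 1 when its
standardized series *strictly exceeds* `threshold_sd` (default 2) —
one-sided, positive tail, so only unusually strong positive connectivity
survives. This variance-based thresholding prioritises different edges
than magnitude-based thresholding would; the risk of false-positive edges
is inherited by all downstream measures, which is why the null models
below matter.

The whole pipeline is deterministic: identical input and parameters give
bit-identical output at every stage.

## Statistics and null models

`group_permutation_test()` compares paired condition values by
sign-flipping each subject's within-pair difference; the p-value uses the
$+1/+1$ convention ($p = (1 + \#\{|{\rm null}| \ge |{\rm obs}|\}) /
(1 + n_{\rm perm})$), standard exact-test practice that keeps $p > 0$.
Note that with a two-tailed statistic both the identity and the fully
flipped sign pattern reproduce the observed magnitude, so the attainable
floor for a strong effect is about $2/(1 + n_{\rm perm})$.

`nodal_centrality_threshold()` flags nodes with above-chance
subject-averaged centrality: each permutation shuffles every subject's
node order independently and averages, giving one null distribution per
node position; the threshold is the maximum across positions of the
$(1-\alpha)$ quantile, taken as the
$\lceil (1-\alpha)\, n_{\rm perm} \rceil$-th order statistic — with 1000
permutations and $\alpha = 0.05$, the largest 950th value. This is the
natural generalisation of that rule to arbitrary $n_{\rm perm}$ and
$\alpha$.

Three surrogate generators support chance-level arguments:
`time_shuffle` (one joint permutation of the time axis; destroys
autocorrelation, preserves the graphlet multiset, hence leaves
order-blind measures untouched), `phase` (per-edge phase randomisation of
the Fourier spectrum, amplitudes preserved; only meaningful on
pre-threshold edge series, and refused on binary networks), and `block`
(jointly permuted consecutive blocks; inappropriate for seam-sensitive
measures such as volatility). Vector-autoregressive surrogates are out of
scope. All stochastic functions take a `seed` and restore the caller's
RNG state.

## Synthetic data: what it emulates, and what it does not

`gen_multistate_timeseries()` produces node signals with community
structure and state switching: a latent Markov chain with geometric dwell
times (mean `dwell_mean`, default 20 steps — with 2-second sampling this
is in the range reported for fMRI brain-state dwell times; Markov
dynamics rather than fixed blocks were chosen so dwell times vary and the
per-time-point weighting is genuinely exercised), one community per state
sharing a Gaussian factor at within-community correlation `within_cor`
(default 0.8), additive noise (`noise_sd`, default 0.5), and a fixed
node-wise mean activation pattern per state (`state_mean_sd`, default 1).
The state mean patterns are essential, not cosmetic: the weighting scheme
identifies time points by their global spatial pattern, and states that
differ only in covariance while sharing mean and marginal variance leave
Euclidean distances between activation columns statistically
indistinguishable — there would be nothing for the estimator to key on.
Setting `state_mean_sd = 0` recovers the zero-mean construction for tests
of the covariance machinery alone.

`gen_edge_process()` generates single-edge activation series from renewal
processes: `periodic` (downstream $B = -1$ exactly), `geometric`
(minimum-1 discrete memoryless intervals; note the discrete geometric has
$B = (\sqrt{1-p} - 1)/(\sqrt{1-p} + 1) \approx -p/4$, so the memoryless
benchmark $|B| < 0.05$ refers to small rates — the tests use
$p = 0.1$, close to the continuous exponential limit where
$\sigma = \mu$), and `powerlaw` (discrete inverse-transform intervals
$\lceil U^{-1/(\alpha - 1)} \rceil$ with minimum 1; exponent 2.5 in the
tests, squarely in the bursty regime).

What the generators do **not** emulate: hemodynamic response convolution,
realistic fMRI noise spectra (autocorrelated, aliased physiology), head
motion, or spatially correlated noise. Passing tests therefore show that
the estimator and measures behave correctly on data satisfying their own
assumptions — not that those assumptions hold in any particular scanner
session.

## Problem sizes and test design

The bundled verification uses deliberately small problems so the whole
suite runs in well under a minute: the path engine is checked against an
exhaustive shortest-duration search over an explicit time-expanded
layered graph (igraph Dijkstra with zero-weight within-time arcs and
unit-weight waiting arcs) on hundreds of random instances with
$N \le 6$, $T \le 6$ under both hop-limit modes; the derivation pipeline
is exercised at $N = 12$, $T = 120$ over 100 seeds for state recovery;
permutation calibration uses 200 replicate null datasets at
$n_{\rm perm} = 999$. The estimator itself scales comfortably to the
$N = 264$, $T = 200$ regime of a typical parcellated resting-state
session (the per-time-point correlation step is three matrix products).

## Known limitations

* Binary, undirected, discrete time only; no weighted-measure extensions
  (burstiness and reachability in particular have no agreed weighted
  form).
* Temporal betweenness and spectral centrality are not implemented.
* The 2-SD threshold is a convention, not an optimum; conclusions should
  be checked for robustness across thresholds.
* Printed figure-level volatility values from the source literature
  depend on exact edge lists that are not recoverable from text; the
  package pins its own conventions and verifies orderings and worked
  examples instead.
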