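---
title: "Modeling spatial gene expression from an intergenic locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spatial gene expression from an intergenic locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermolocus)
```

## The problem

Developmental genes such as the pair-rule genes of the early fly embryo
are expressed in sharp, multi-stripe patterns along the
anterior-posterior (A/P) axis.  The information for these patterns is
distributed across several ~1 kb enhancers scattered through the gene's
intergenic locus (often 10-50 kb), each enhancer driving one or two
stripes.  `thermolocus` fits a quantitative model that maps the raw
locus sequence, a set of transcription-factor (TF) binding motifs, and
the TFs' spatial concentration profiles onto the gene's spatial
expression profile -- without being told where the enhancers are.

The model is two-tiered:

1. **Enhancer tier.**  The readout of any sequence window is predicted
   by a Shea-Ackers statistical-thermodynamics ensemble over TF binding
   configurations (below).
2. **Locus tier.**  The gene's expression is a learned non-negative
   weighted sum of the readouts of a small set of automatically
   discovered windows, clipped to $[0,1]$.

## The thermodynamic ensemble

Sites are annotated by scanning both strands with position weight
matrices; a site's *relative affinity* is $\exp(\mathrm{LLR} -
\mathrm{LLR}_{max})$ and sites above a configurable floor (default
$10^{-2}$) enter the ensemble.  A *configuration* $\sigma$ is any
subset of sites that do not overlap on the DNA.  Each configuration has

* a Boltzmann weight $W(\sigma) = \prod_{i \in \sigma} q_i \cdot
  \prod \omega$, where $q_i = K_{tf(i)} \, c_{tf(i)}(x) \, a_i$
  combines the TF's binding scale $K$, its local concentration $c(x)$
  at axis position $x$, and the site's relative affinity $a_i$, and a
  cooperativity factor $\omega \ge 1$ multiplies in for every
  consecutively bound same-TF pair within `coop_dist` (default 50 bp);
* a transcriptional effect $Q(\sigma)$ on the basal transcriptional
  machinery (BTM).  In **DIRECT** mode every bound site contributes its
  TF's interaction factor $\alpha$ (activators $\alpha \ge 1$,
  repressors $\alpha \le 1$).  In **SRR** (short-range repression) mode
  only activators contribute $\alpha$, and an activator bound next to a
  repressor within `srr_range` (default 150 bp, the upper end of the
  100-150 bp range reported for short-range repressors) is quenched by
  a factor $1 - \beta$ per such neighbouring repressor.

Expression at axis position $x$ is the BTM occupancy

$$E(x) = \frac{Z_{on}(x)}{Z_{off}(x) + Z_{on}(x)}, \qquad
Z_{off} = \sum_\sigma W(\sigma), \quad
Z_{on} = q_{BTM} \sum_\sigma W(\sigma)\, Q(\sigma),$$

with the empty configuration contributing $W = Q = 1$.  In DIRECT mode
a nine-TF model has $3 \times 9 + 1 = 28$ free parameters
($K, \alpha, \omega$ per TF plus $q_{BTM}$); SRR adds one $\beta$ per
repressor.

**Nearest-neighbour interactions.**  Both cooperativity and quenching
act between *consecutively bound* site pairs.  This choice makes the
partition sums computable exactly by a left-to-right dynamic program
(implemented in C++, linear in site count up to the local interaction
neighbourhood, with periodic rescaling against overflow on long
sequences), and the package ships a pure-R exhaustive enumeration
(`brute_force_partition`) against which the DP is verified to a
relative $10^{-9}$ on randomized ensembles in both modes.  Published
descriptions of short-range quenching leave the exact functional form
open; the nearest-neighbour form is this package's documented
instantiation.

Site-to-site distance is measured as the bp gap between one site's end
and the next site's start (0-based, half-open coordinates throughout).

## Scoring: weighted Pattern Generating Potential

Root-mean-square error rewards flat compromises and misses stripe
boundaries, so fits are scored with a weighted Pattern Generating
Potential (w-PGP).  For predicted $p_i$ and real $r_i$ profiles scaled
to $[0,1]$ on a shared grid:

$$\mathrm{reward} = \frac{\sum_i \min(p_i, r_i)\, r_i}{\sum_i r_i^2},
\qquad
\mathrm{penalty} = \frac{\sum_i \max(p_i - r_i, 0)\,(1 - r_i)}
{\sum_i (1 - r_i)^2},$$

$$\mathrm{score} = \mathrm{clamp}(\mathrm{reward} - \mathrm{penalty},\ 0,\ 1).$$

Reward is weighted by the real expression (getting a stripe's peak
right matters most), penalty by the available headroom (ectopic
expression where the gene is off is what hurts).  The combination by
clamped subtraction, and the exact normalisations, are definitional
choices of this package; the degenerate cases (all-zero or all-one
real profile) are fixed as: all-zero real gives reward 1 iff the
prediction is also all zero, all-one real gives penalty 0.  The score
is 1 iff the prediction matches wherever it matters, is invariant to
duplicating grid bins, and strictly decreases under uniform
over-expression.

## Training the two-tiered model

`fit_locus()` alternates three steps until `outer_iters` (default
$N_I = 100$) or until the score improves by less than `delta`
($10^{-4}$):

* **Phase 1 -- window scan.**  The target profile is decomposed into
  stripes (maximal runs of bins at or above the ON threshold 0.5; a bin
  exactly at threshold is ON).  Every window starting at 100 bp
  intervals with lengths 500-2500 bp in 50 bp steps (all configurable)
  is read out under the current parameters and scored against each
  stripe; the best $N = 5$ windows per stripe are kept.  Ties break to
  the leftmost start, then the shortest length.  An optional
  accessibility mask drops windows less than half-covered by accessible
  intervals.
* **Phase 2 -- greedy inclusion.**  Stripes are processed anterior to
  posterior.  For stripe $i$ the target is the gene profile *as if the
  later stripes were absent* (their extents zeroed; genuine
  sub-threshold signal elsewhere is kept, so correct flank expression
  is never penalised as ectopic).  Each remaining candidate is
  evaluated by re-optimising all window weights (non-negative,
  warm-started, aggregate clipped at 1 before scoring); the best
  candidate is accepted iff it improves the running best score by more
  than `delta`, and the stripe's candidate list is re-scanned until no
  candidate helps.  Because scores computed against different targets
  are not comparable, the running best is re-baselined at the start of
  each stripe as the current window set's re-optimised score on the
  extended target.  The `delta` margin (rather than a bare strict
  inequality) is what keeps model complexity under control: without
  it, optimizer-noise-level "improvements" admit unbounded stacks of
  redundant overlapping windows.
* **Theta re-fit.**  With windows and weights fixed, the thermodynamic
  parameters are re-optimised, each parameter confined to a two-fold
  box around its initial value (the constrained strategy guarding
  against over-fitting a single locus; control experiments lift the
  box).  Optimisation alternates Nelder-Mead and box-constrained
  L-BFGS-B in log-parameter space, where the two-fold box is the
  symmetric interval $\pm\ln 2$.

The initial parameters should come from `fit_enhancer_set()` run on an
external panel of enhancers (excluding the modelled gene), maximising
the mean w-PGP across the panel.

`fit_locus()` returns a `locus_model` object with `print`, `summary`,
`coef`, `predict` (supporting `knockdown = "TF"`), `fitted`,
`residuals` and `plot` methods.  Because the window locations are free
parameters learned from the target profile, the reported score is a
training-data accuracy; the negative controls below are what guard its
interpretation.

## Downstream analyses

**Architecture sampling.**  `mcmc_sample()` explores the space of
window sets and weights with Metropolis-Hastings: a proposal picks two
grid-window bits and toggles each with probability $\tfrac12$ (so the
proposal equals the current bit vector with probability $\tfrac14$,
differs in one bit with probability $\tfrac12$, in two with
$\tfrac14$), active windows draw Dirichlet$(1,\dots,1)$ weights, and
the move is accepted with probability $\min(1, S'/S)$.  The all-zero
architecture's score is floored at $10^{-6}$ to keep ratios finite.
The mean weight per grid window summarises where expression-generating
sequence lives.  The score function is injectable; with a score that
depends only on the bit vector the proposal is symmetric and the
stationary law over bit vectors is exactly score-proportional, which is
how the sampler is validated against an enumerable toy space.

**Knockdown networks.**  `infer_network()` zeroes one TF's
concentration profile at a time, re-evaluates the trained model without
re-fitting, and compares each stripe's predicted peak and half-maximum
boundary positions.  A peak weakened by at least 2% (relative) gives an
activation edge; otherwise a peak strengthened by at least 2% and/or a
boundary shifted by at least 1% of the axis gives a repression edge.
The "otherwise" guard exists because knocking down an activator also
moves the collapsing stripe's boundaries; without it every activator
would also acquire a spurious repression edge.

**Enhancer cross-talk.**  `crosstalk_hypergraph()` asks whether sites
from one model window, interpreted together with another window's
sites, would help or hurt.  For every ordered window pair and every
block of 1-5 contiguous donor sites, the acceptor's site set is
augmented by the block (repositioned just downstream of the acceptor's
sites -- in DIRECT mode only overlap and cooperativity depend on
position, so this realises joint interpretation without artefactual
overlaps), weights and optionally the parameters (two-fold box) are
re-fit, and the hyperedge weight is the new score minus the original.
Negative weights mark *avoided interactions*: evidence that the real
enhancers must act autonomously.  `hypergraph_to_graph()` averages
hyperedge weights into a site-by-enhancer matrix (rows and columns in
5'-to-3' locus order) ready for any heatmap renderer; within-enhancer
entries are zero by construction.

**Promoter competition.**  If two enhancers interact with the promoter
independently and never simultaneously, and each alone drives
expression with probability $p$, the combined readout is $2p/(1+p)$
(`two_enhancer_combined_readout()`): within 20% of the additive $2p$
for $p < 0.2$, and closer to the saturating $1-(1-p)^2$ for large $p$.
The exact curve lies at or below both approximations on $(0,1)$.

## Synthetic data and negative controls

`gen_synthetic_locus()` builds the package's test bed: an i.i.d.
background sequence with planted enhancers, each carrying
consensus-strength sites of a designated activator (plus repressor
sites), read out by bump- or gradient-shaped TF concentration profiles
on a uniform 100-bin axis.  The ground-truth expression is the forward
model itself -- the true-weighted, clipped sum of the planted windows'
readouts -- so recovery tests have an exact oracle.  The standard
validation condition is an 8 kb locus with three 800 bp enhancers and
four TFs (three bump activators at axis positions 0.25/0.50/0.75, one
repressor bump between the first two stripes), with $K = 2$,
$\alpha_{act} = 5$, $\alpha_{rep} = 0.2$, $q_{BTM} = 0.02$ -- chosen
once so that the forward model produces three well-separated stripes
with sub-0.5 valleys at realistic sharpness.

What the generator does *not* emulate: non-uniform background
composition beyond a global base-frequency vector, overlapping or
nested real enhancers, heterotypic cooperativity, concentration noise,
and cross-species divergence.  Passing recovery tests therefore
demonstrates internal consistency of model, objective and optimiser --
not performance on real embryo data.

Four negative controls (`run_negative_controls()`) refit the model,
with unconstrained parameters, on: another gene's locus, a random
expression pattern, a random sequence of the same length and base
composition, and the real locus with its sites relocated uniformly at
random (preserving the site multiset).  Random expression patterns
match the real profile's ON-bin count exactly and draw a stripe count
uniformly between $\lceil N/2 \rceil$ and $N$, laying out stripe and
gap widths by uniform stars-and-bars compositions (interior gaps at
least one bin; leading/trailing gaps may be empty) before logistic
edge smoothing.  The smoothing steepness defaults to 100 per axis
fraction: steep enough that the smoothed pattern retains ON bins at
the 0.5 threshold (a transition width of a few bins), which a slope of
order 10 would not.

## Numerical choices and problem sizes

* Partition sums rescale by $10^{-250}$ whenever running totals exceed
  $10^{250}$; occupancy ratios are unaffected.
* Weight and parameter optimisation: Nelder-Mead (projected into the
  box) alternating with L-BFGS-B on numerical gradients; weights are
  bounded to $[0, 10]$; `fit_enhancer_set()` uses 5 seeded random
  restarts by default.
* The test suite exercises the full default window grid in Phase-1
  assertions but runs end-to-end recoveries at reduced sizes chosen for
  a laptop-scale suite: 10 seeded standard loci at $N_I = 5$ with
  3 candidates per stripe and lengths 500-1500 bp in 250 bp steps, and
  20 negative-control replicates at $N_I = 2$.  Recovery demands an
  aggregate w-PGP of at least 0.85 and a base-pair Jaccard overlap with
  the planted enhancers of at least 0.5, and every control must score
  below the real fit.

## Known limitations

* The model cannot predict an unseen locus's readout from sequence
  alone: window locations and weights are free parameters that require
  the target profile.  Reported scores are training accuracies,
  qualified by the negative controls.
* Overlapping selected windows share no credit correction; the linear
  sum simply adds their readouts.
* TF roles are fixed (one sign per TF), so context-dependent dual
  regulators cannot be represented.
* Heterotypic cooperativity and distance-dependent activation decay are
  out of scope.
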