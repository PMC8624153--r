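---
title: "A stochastic lattice model of multi-type cell sorting and its effective adhesion parameter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic lattice model of multi-type cell sorting and its effective adhesion parameter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmmsort)
```

## The model

Cell sorting — the unmixing of heterotypic cell populations into homotypic
clusters — is a paradigmatic morphogenetic process. The model implemented
here is a probabilistic cellular automaton on a periodic square lattice
$S$ of side $L$ (a torus): every site holds exactly one cell, each cell has
a type $w \in \{0, \dots, N-1\}$, and per-type cell numbers are conserved.
The only elementary event is the position switch of two *adjacent
heterotypic* cells $x, y$ (von Neumann adjacency). A switch occurs at rate

$$
c(x, y, \eta) \;=\;
\exp\!\Big(-\!\!\sum_{z \in N(x)}\!\beta_{\eta(x)\eta(z)}
           \;-\!\!\sum_{z \in N(y)}\!\beta_{\eta(y)\eta(z)}\Big),
$$

where $\eta$ is the current configuration and $\beta_{ij} = \beta_{ji}$ is
the dimensionless bond strength between types $i$ and $j$. Positive
$\beta_{ij}$ is binding (adhesion plus relaxed cortical tension) that
hinders motility; negative $\beta_{ij}$ is repulsion that enhances it. The
parametrization is deliberately agnostic about the molecular mechanism,
which is what lets the model subsume differential adhesion, differential
interfacial tension and heterotypic-repulsion pictures in one family of
rate matrices. Homotypic switches would not change the configuration and
are excluded.

Each neighbourhood sum *includes the partner site*, so the exponent is a sum
of 8 bond terms. This convention is forced by two worked consequences:
a pair at a straight interface between two-type bands switches at
$\exp(-(3\beta_{00} + 3\beta_{11} + 2\beta_{01}))$, a lone cell of type 0
inside a type-1 cluster at $\exp(-(3\beta_{11} + 5\beta_{01}))$, and adding
a constant $\theta$ to every entry multiplies *every* rate by exactly
$e^{-8\theta}$ — a pure rescaling of time that leaves the order of events
untouched. `switchRate()` implements the rate; the tests pin all three
consequences.

Simulation is event-driven (Gillespie): the rates of all adjacent
heterotypic pairs form an event table; one pair is drawn with probability
proportional to its rate, an exponential waiting time with the total rate is
attached, the switch is applied, and only events touching the switched sites
or their neighbourhoods are recomputed. The time axis used throughout is the
*number of switches performed* $t$, not physical time; waiting times are
recorded on request but enter no analysis, because the scaling parameter
(below) makes physical time gauge-dependent.

## Quantifying segregation

With $d(\eta)$ the number of homotypic nearest-neighbour contacts, the order
indicator is

$$\omega(\eta) = \frac{d(\eta) - d_{\min}}{d_{\max} - d_{\min}},$$

normalized by the extreme contact counts attainable at the given side,
number of types and counts. $d_{\max}$ is realized by full phase separation
(horizontal stripes), $d_{\min}$ by alternating patterns: the chessboard for
two types, diagonal stripes $(r + c) \bmod N$ for more. A uniformly random
configuration with near-equal counts sits at $\omega \approx 1/N$.

Two numerical choices matter here. First, on lattices small enough to
enumerate (at most $2 \times 10^5$ configurations), `orderExtremes()`
computes $d_{\min}$ and $d_{\max}$ by exhaustive search, which both
validates the constructive anchors and makes tiny-lattice results exact. On
larger lattices the constructive patterns are used; where a perfect
minimizing pattern cannot tile the torus (e.g. a chessboard on the default
odd side 25) the defective pattern's value is used and the extremes object
is flagged. The anchors 0.5/0.33 (random), above 0.95 (sorted) and below
0.05 (chessboard) are insensitive to these small constant differences.
Second, the asymptotic level $\bar\omega$ is the mean of $\omega$ over the
recorded points in the last 10% of the switch-indexed series; the default
recording stride keeps about 1000 points per run so this window always
averages at least 100 values.

## System parameters

Three scalar functionals of the flat bond-strength vector
$(\beta_{00}, \dots, \beta_{N-1,N-1}, \beta_{01}, \dots)$ organise the
behaviour:

* **Scaling parameter** $\beta^s = \langle \beta, a_s \rangle$ with
  $a_s = (1, \dots, 1)$: sets only the waiting-time scale (the
  $e^{-8\theta}$ gauge above).
* **Effective adhesion parameter (EAP)**
  $\beta^* = \sum_i \beta_{ii} - \frac{2}{N-1}\sum_{i<j}\beta_{ij}$: the
  unique (up to scale) linear functional that is invariant under type
  relabeling and orthogonal to $a_s$; it predicts the asymptotic
  segregation level, with critical value $0$ at which the system stays
  mixed. For two types this is the classical
  $\beta_{00} + \beta_{11} - 2\beta_{01}$. The heuristic behind the
  critical value is the exact identity
  `unmix_mix_ratio = exp(3 beta*)` between the limit-scenario rates
  returned by `heuristicRates()`.
* **Convergence speed parameter** $\beta^\Delta$: for two types
  $|\beta_{00} - \beta_{11}|$; for $N \ge 3$ the Euclidean distance of the
  flat vector to its type-symmetric projection (homotypic entries replaced
  by their mean, heterotypic by theirs). The two-type forms differ by a
  factor $\sqrt 2$; the two-type absolute-difference convention is the
  default because the reference parameter sets (spacing 0, 2, 4, 6, 8) are
  expressed in it. In the distance form the heterotypic entries are counted
  once each, matching the flat-vector ordering. Larger $\beta^\Delta$ means
  more switches are needed to approach the asymptotic level — it does not
  predict wall-clock time, only switch counts.

```{r sysparams}
p <- adhesionParams(c(-0.5, 1.5, -1))
c(beta_s = scalingParam(p), beta_star = effectiveAdhesion(p),
  beta_delta = convergenceSpeed(p))
```

For two cell types the EAP also translates Cellular-Potts-style relative
contact tensions through `tensionToEAP()` (`beta = -T`): high heterotypic
tension and strong differential adhesion are then points on one axis rather
than competing hypotheses.

## Engine correctness: an exact oracle

On a $3 \times 3$ torus with two types and counts $(4, 5)$ there are only
$\binom{9}{4} = 126$ configurations. `jumpChainStationary()` builds the full
transition matrix of the embedded jump chain from the same switch-rate
definition, solves its stationary distribution exactly, and returns
$E[\omega]$. Because the simulation's time axis counts switches, the
switch-averaged $\omega$ of a long run must converge to this expectation;
the test suite requires agreement within a 3-sigma batch-means error over
$10^6$ switches. This is the primary correctness argument for the compiled
event-driven engine — independent of the engine's own bookkeeping, which is
additionally checked by comparing the incrementally maintained event table
against a from-scratch rebuild, and by the exact $e^{-8\theta}$ invariance
of entire switch sequences.

Numerical safety in the engine: rates span $e^{\pm 80}$ at the sweep bounds,
so the sampling tree recomputes every internal node as the exact sum of its
children on each update and is fully rebuilt every $10^4$ switches
(configurable; tests disable it to expose pure incremental updates).
Unordered pairs are single events; the random stream is consumed in a fixed
order (pair, then waiting time), which is what makes runs bit-reproducible
from one seed.

## The estimation pipeline

`sweepRuns()` draws bond-strength vectors uniformly from
$[-10, 10]^{N + N(N-1)/2}$, one seeded simulation per draw from a fresh
random start. The three-type sweep rejects draws until
$\beta^\Delta < 3$; without this restriction the sample is dominated by
slowly converging runs whose $\bar\omega$ still sits near the starting
level, which blurs the dependence on $\beta^*$ (this is the condition the
reference three-type experiments use, and the classification experiments
inherit it). Runs are *not* filtered by convergence afterwards; incomplete
convergence is visible as a depressed rank correlation and a shifted
intercept, and hiding it would overstate the prediction.

Runs are labeled $+1$ when $\bar\omega$ strictly exceeds the random-mixture
level ($1/N$) and $-1$ otherwise. By relabeling invariance the separating
functional can only weight homotypic entries with one coefficient $a$ and
heterotypic entries with another $b$, so `fitHyperplane()` compresses each
run to the two features $(\sum_i \beta_{ii}, \sum_{i<j} \beta_{ij})$ —
equivalent to tying coefficients inside the optimizer, but method-agnostic —
and fits either a linear soft-margin SVM (cost 1, no feature scaling) or an
unpenalized logistic regression. The reported quantities are $b/a$ and
$i/a$; the analytic expectation is $b/a = -2/(N-1)$ and $i/a = 0$. Accuracy
comes from seeded stratified 5-fold cross-validation. On near-separable
data the boundary *direction* is insensitive to the regularization
strength, which is why the default cost is simply 1; the estimator-only
correctness check (labels assigned analytically as $\mathrm{sign}(\beta^*)$,
no simulation) is run in the hard-margin limit instead, because with
noiseless separable labels the soft margin's tolerated near-boundary errors
are a property of the regularizer, not of the estimator being checked.
The orientation of the fitted SVM boundary is normalized against the
training labels, since the underlying library orients its decision values
by order of label appearance.

## Problem sizes and study conditions

The defaults are the reference conditions: lattice side 25 (625 cells;
the remainder of $L^2/N$ is given one cell at a time to the lowest type
indices), termination after 312,499 switches, recording stride
$\lfloor t_{\max}/1000 \rfloor$, sweep box $[-10, 10]$, classification
threshold $1/N$. The bundled experiments (`presetExperiment()`) run 2000
simulations per sweep at full scale. The acceptance script and the test
suite run the same pipeline at 500 runs per sweep with the full 312,499
switches per run — chosen as the package's desk scale — plus 100 seeded
random starts for the order-indicator anchors and 3 replicates for the
mixing-point runs; at this scale the rank correlations are reproduced to
within a few hundredths and the SVM coefficient to within a few percent.

The lattice-size convention deserves one note: the reference description
writes the site set as $\{0, \dots, L\}^2$ with $L = 25$ (which would be
676 sites) while the termination count $312{,}499 = 500 \cdot 625 - 1$
points to $25^2 = 625$ sites. The side is therefore an explicit parameter,
default 25; every quantity reported here is insensitive to this choice at
its stated tolerance.

## What the generator does and does not emulate

The synthetic data are exactly the model's own dynamics: single-site cells
on a torus, conserved type counts, nearest-neighbour exchanges only. Real
tissues violate most of these idealizations — cells are extended and
deformable, divide and die, move collectively, and boundaries are not
periodic. Passing tests therefore validate the implementation and the
internal consistency of the effective-adhesion prediction, not the model's
biological adequacy; the tension mapping in `tensionToEAP()` is the one
bridge toward externally parametrized (Cellular Potts) descriptions, and it
inherits the same caveats.

## Known limitations

* The constructive $d_{\min}$ on sides where no perfect alternating pattern
  tiles the torus is an anchor, not a proven minimum; it is flagged in the
  `OrderExtremes` provenance and exhaustively validated on small lattices.
* Kendall correlations use the $O(n^2)$ exact statistic; for sweeps far
  beyond $10^4$ runs Spearman is the practical choice.
* The logistic fit on (nearly) separable data runs against the usual
  divergence of the maximum-likelihood estimate; coefficients are reported
  after a capped number of scoring iterations, where the *ratios* $b/a$ and
  $i/a$ are stable even though the raw magnitudes are not.
* `jumpChainStationary()` is dense linear algebra over all configurations
  and is only meant for lattices with a few hundred thousand states at most.
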