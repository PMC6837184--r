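---
title: "Methods: information-conserving length distributions for discrete systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-conserving length distributions for discrete systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohsi)
```

## The model

A discrete system is a set of *components*, each an ordered string of
*tokens* drawn from a *unique alphabet*: proteins built from amino acids,
software functions from language tokens, musical compositions from notes.
Two numbers summarize a component: its length $t$ in tokens and its unique
alphabet $a$, the number of distinct tokens actually present. The
Hartley–Shannon information content of a component is the natural log of the
number of distinct admissible arrangements of its tokens — deliberately
blind to what the tokens mean.

For a *heterogeneous* component (distinguishable token order) whose alphabet
must be fully used, the number of admissible strings is

$$N(t, a) = \sum_{k=0}^{a-1} (-1)^k \binom{a}{k} (a-k)^t,$$

a surjection-type count, computed in this package by the equivalent
recursion $N(t,a;a) = a^t - \sum_{i<a} \binom{a}{i} N(t,i;i)$ with exact
arbitrary-precision integers. When $t \gg a$ this approaches $a^t$ and the
information $I = \log N$ approaches $t \log a$; for short components the
obligation to use every letter bends $I$ below that asymptote, and this bend
is the whole story of the sharp unimodal peak in observed length
distributions.

Fixing a system's total token count $T$ and total information $I$ and asking
for the most likely partition of tokens among components (a standard
Lagrange-multiplier variational argument) yields the implicit equation

$$\log t = -\alpha - \beta \, \frac{dI}{dt},$$

whose solution locus in $(t, a)$ is the predicted length–alphabet relation:
a pure power law $t \sim a^{-\beta}$ wherever $dI/dt \to \log a$, departing
from it one-sidedly as $t$ approaches $a$.

For a *homogeneous* system (rank-ordered bins of identical tokens) the same
machinery gives $L'(t_i) = -\kappa - \eta \log i$ with $L(t) = \log t!$:
Stirling's approximation makes this exactly Zipf's law $t_i \propto
i^{-\eta}$, and any better treatment of $\log t!$ (Ramanujan's
approximation, or the exact digamma derivative) pushes sparsely populated
high ranks below the Zipf line — the drooping tail emerges from the
mathematics rather than from any data-specific mechanism.

## Tunable parameters

* `build_info_grid(t_max = 200, a_max = 30)` — grid bounds in tokens.
  The defaults enclose the unimodal peak comfortably before the power-law
  asymptote takes over; the guard `t_max <= 500` keeps exact-integer work
  desk-scale. Counts at the default corner have roughly 300 decimal digits,
  which is why the package carries its own limb-based exact integers:
  doubles fail beyond $t, a \approx 30$ and the partition identity
  $\sum_{a'} \binom{a}{a'} N(t,a';a') = a^t$ must hold exactly.
* `het_params(alpha, beta, convention)` — dimensionless Lagrange
  multipliers; `alpha` scales the locus (total-size constraint), `beta` sets
  the asymptotic slope (information constraint). See the sign note below.
* `solve_hom(kappa, eta, M, approximation)` — `kappa` is the log scale of
  the rank-1 count, `eta > 0` the Zipf decay exponent, `M` the number of
  ranks; `approximation` selects the log-factorial treatment.
* `select_xmin(values, min_tail = 50, max_candidates = 60)` — the minimum
  tail size mirrors common practice for stable discrete MLE; the candidate
  cap bounds the KS scan deterministically (evenly spaced distinct values),
  which matters inside the bootstrap where the scan runs hundreds of times.
* `bootstrap_pvalue(..., n_boot = 1000)` — at least 100 replicates are
  required; the p-value granularity is $1/n_{boot}$. The plausibility rule
  is the conventional cut-off: a power law is rejected when $p < 0.1$.

## Sign convention for the heterogeneous equation

Written exactly as above, positive $(\alpha, \beta)$ put every root at
$t < 1$: no solutions exist on the physical domain $t \ge a \ge 1$.
Illustrative positive values in the literature therefore presuppose an
overall sign reflection. The package exposes both readings:
`convention = "as_printed"` applies the equation literally (use negative
`alpha`, e.g. `het_params(-5.2, 0.5)`), `"reflected"` negates both
multipliers so positive pairs produce an admissible locus. The discrepancy
is surfaced as an option rather than silently patched.

## Numerical choices

* **Continuation of $\log N$.** Exact big-integer evaluation at integer
  nodes plus monotone piecewise-cubic (Fritsch–Carlson) interpolation in
  $t$, rather than unwinding the recursion into gamma functions: the
  alternating closed form suffers catastrophic cancellation near $t \approx
  a$, while interpolation is exact at every node — and the solver only ever
  brackets roots between nodes. $dI/dt$ uses second-order central
  differences on the unit-spaced grid, one-sided second-order stencils at
  the $t = a$ boundary and at `t_max`. Against the analytic $a = 2$
  derivative $\log 2 \cdot 2^t/(2^t-2)$ the truncation error is below
  $2\times 10^{-2}$ for $t \ge 5$ and far smaller away from the boundary.
* **Root finding.** Sign-change bracketing on the grid followed by bisection
  to interval width $10^{-10}$ (so the root location, not merely the
  residual, is resolved; all reported residuals are below $10^{-6}$). If a
  line carries several brackets, all roots are reported and the smallest is
  flagged primary. Lines without a sign change contribute nothing — absence
  of small-$t$ solutions is a real feature of the implicit equation, and an
  entirely empty locus raises a warning, not an error.
* **Resolution floor.** The deficit $t\log a - \log N(t,a)$ decays like
  $a(1-1/a)^t$ and falls below double resolution near $t - a \approx 40$
  (for small $a$); beyond that the stored derivative equals $\log a$ to
  machine precision and the full and pure loci are numerically identical.
  Tests assert strict inequalities only inside the resolvable window.
* **Log-factorials.** Wherever a log of a factorial is needed as a *real*
  ($\log T!$ in the homogeneous information, $\log \Omega$ multinomials),
  the exact log-gamma (`lfactorial`) is used — exact to double precision,
  which is all a log can carry. Exact integers are reserved for quantities
  that must be integer-exact (counts, the partition identity).
* **Digamma inversion.** The `exact` homogeneous variant solves
  $\psi(t+1) = -\kappa - \eta\log i$ by Newton iteration with Minka's
  initialization to $|\psi - y| < 10^{-10}$. Targets below $\psi(1)$ mean
  the rank cannot hold even an infinitesimal bin and are reported as
  unpopulated (`NA`), not as errors. The Ramanujan variant differentiates
  Ramanujan's log-factorial term-wise,
  $L'(t) = \log t + (24t^2+8t+1)/(6(8t^3+4t^2+t))$; this derivative
  diverges at the origin, so the solver brackets on the monotone large-$t$
  branch beyond the derivative's minimum.
* **Exact vs Ramanujan ordering.** Both corrected variants droop below
  Stirling at every populated rank with monotonically deepening ratio. Their
  mutual difference is at the $10^{-9}$ relative level for well-populated
  bins — far inside plotting resolution — with Ramanujan's derivative
  slightly *overshooting* the digamma, so its roots sit a hair below the
  exact ones. Tests pin the meaningful ordering (corrected below Stirling)
  and the near-coincidence, not a sign at machine-noise scale.
* **Ties and conventions.** Rank tables break frequency ties by ascending
  length; ccdfs use the $P(X \ge x)$ convention (required by the discrete
  KS machinery); ranks follow the standard Zipf convention with rank 1
  largest, so decaying laws have positive `eta`.

## The tail-fitting battery

The discrete MLE maximizes the zeta-normalized likelihood; the Hurwitz zeta
is computed by a 50-term direct sum plus an Euler–Maclaurin tail (checked in
tests against bracketed brute-force sums). Threshold selection minimizes the
KS distance between empirical and fitted tail ccdfs over candidate
thresholds. The bootstrap is semi-parametric in the usual way — body
resampled empirically, tail drawn from the fitted law, the *entire*
procedure (threshold re-selection plus MLE) rerun per replicate. A `binned`
mode first collapses the tail onto geometric-bin midpoints; it approximates
the raw bootstrap for inputs too large to resample comfortably and is
labelled approximate. All random draws are seeded through locally scoped
RNG (`withr`), so the global stream is never consumed and seeded runs are
byte-reproducible.

One limitation worth knowing: the zeta-normalized model is not closed under
rescaling. Multiplying integer data by a constant creates support gaps the
model does not describe, so the selected threshold under such a transform
need not scale proportionally; the battery is calibrated for data generated
on a contiguous integer support.

## What the synthetic generators emulate — and what they do not

The generators supply every pipeline stage with desk-scale inputs of known
ground truth: uniform draws over the exactly-counted string ensembles
(rejection sampling, acceptance probability $N(t,a)/a^t$), i.i.d. discrete
power-law lengths via inverse transform on the exact ccdf, note-event
corpora whose two alphabets realize a prescribed power-law relation
$a'' \approx c (a')^{\gamma}$ (for `gamma = 1.5, c = 1` the default
no-duration alphabets 9..49 keep targets inside the feasible band
$a' \le a'' \le 7a'$), and exhaustive microstate censuses of tiny systems.

They deliberately do *not* emulate real corpora: no database curation
artefacts, no correlated residue usage, no compositional structure in the
music, no tokenizer quirks in software. Passing tests therefore demonstrate
that the machinery is correct and calibrated under its own null — that the
MLE recovers known exponents, that the bootstrap accepts data drawn from
the fitted law, that alphabet relations are recovered exactly when planted.
They do not certify that any particular real proteome or corpus follows the
predicted distributions; reproducing the published large-corpus slopes
requires the multi-gigabyte external datasets and is out of desk scale by
design (the readers and CLI accept such inputs unchanged).

## Problem sizes used by the test battery

The seeded calibration battery runs 50 meta-replicates of samples of
$5\times 10^4$ draws at exponent 2.5 with 100 bootstrap replicates each —
sizes at which the MLE's sampling error (about 0.007) sits comfortably
inside the asserted $\pm 0.05$ band and a binomial 80% acceptance bound is
stable. The asymptote check runs on the default 200-by-30 grid with
`het_params(-5.2, 0.5)`, chosen so the asymptotic region ($t/a \ge 40$ on
the $a = 1, 2$ lines, roots near $t = 181$ and $128$) lies inside the
default grid; illustrative parameters whose roots fall beyond `t_max`
(e.g. `alpha = -6`, whose $a = 1$ root is $t = e^6 \approx 403$) simply
need a larger grid, as exercised in the unit tests.

## Known limitations

* The mapping from the $(t, a)$ solution locus to a frequency-vs-length
  histogram is not specified by the theory as implemented here; the package
  emits the locus and its asymptote and stops there. Quantitative fitting
  of $(\alpha, \beta)$ to empirical histograms is likewise out of scope.
* Likelihood-ratio contests against lognormal or stretched-exponential
  alternatives are deliberately not provided; the battery answers only
  whether a power-law tail can be *rejected*.
* `count_table` grows cubically; exporting grids much beyond the defaults
  is better done through `write_info_grid`, which stores logs, not digits.
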