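# cohsi

Information-theoretic analysis of discrete systems built from tokens:
proteins from amino acids, software functions from language tokens, musical
compositions from notes. The package implements the conservation-of-
Hartley–Shannon-information (CoHSI) framework: if a system's total token
count $T$ and total Hartley–Shannon information $I$ are fixed, a standard
statistical-mechanics variational argument predicts the overwhelmingly
likely distribution of component lengths — a sharp unimodal peak
transitioning into a power-law tail for *heterogeneous* systems
(distinguishable token order), and Zipf's law with a drooping tail for
*homogeneous* systems (rank-ordered bins).

## What is inside

* **Exact combinatorics.** $N(t, a)$, the number of length-$t$ strings over
  an $a$-letter alphabet using every letter at least once, via the recursion
  $N(t,a;a) = a^t - \sum_{i<a}\binom{a}{i}N(t,i;i)$ in arbitrary-precision
  integer arithmetic, with an independent inclusion–exclusion oracle, brute
  force enumeration, and the information content $I(t,a) = \log N(t,a)$
  taken directly on the exact integer (no overflow at any grid size).
* **Heterogeneous solver.** The implicit equation
  $\log t = -\alpha - \beta\, dI/dt$ solved on a real-continued information
  grid; solution locus, pure power-law asymptote $t \sim a^{-\beta}$, and
  the one-signed departure between them.
* **Homogeneous solver.** $L'(t_i) = -\kappa - \eta \log i$ under three
  log-factorial treatments: Stirling (exactly Zipf), Ramanujan, and exact
  (inverse digamma) — the latter two produce the drooping tail.
* **Readers.** FASTA proteomes (via Biostrings), whitespace-tokenized
  streams, and note-event tables, all reduced to tidy component tables of
  (length, unique alphabet).
* **Distribution machinery.** ccdfs ($P(X \ge x)$), exponential binning,
  homogeneous rank recategorization of heterogeneous data, dual-alphabet
  tables (pitch vs pitch-and-duration).
* **Tail assessment.** Discrete zeta-normalized MLE, KS-based threshold
  selection, and the Monte Carlo bootstrap plausibility test (power law
  rejected when $p < 0.1$), plus log-log OLS with adjusted $R^2$.
* **Seeded generators** for every input kind, including uniform draws over
  the exactly counted string ensembles and exhaustive microstate censuses
  of tiny systems.

Everything is data-frame-first and pipe-friendly: readers return tibbles,
fitted objects have `tidy()`/`glance()` methods, results have `autoplot()`.
A command-line wrapper (`exec/cohsi`) exposes the pipeline as subcommands
(`count`, `solve-het`, `solve-hom`, `measure`, `ccdf`, `rank`, `alphabets`,
`fit-tail`, `simulate`).

## Worked example

```r
library(cohsi)

count_exact(5, 2)        # strings of 5 tokens using both of 2 letters
#> <exact integer> 30
het_information(5, 2)    # nats; log of the exact count, not t*log(a) = log 32
#> 3.4012

# heterogeneous locus vs its power-law asymptote
g   <- build_info_grid(t_max = 120, a_max = 6)
p   <- het_params(alpha = -4.6, beta = 0.5)
loc <- solve_het_locus(p, g)
departure_profile(loc, pure_power_locus(p, sort(unique(loc$a))))
#> # A tibble: 6 × 5
#>       a t_full t_pure       gap   rel_gap
#>   <int>  <dbl>  <dbl>     <dbl>     <dbl>
#> 1     1   99.5   99.5  1.82e-11  1.83e-13
#> 2     2   70.3   70.3  1.09e-11  1.56e-13
#> 3     3   57.4   57.4 -2.75e- 9 -4.79e-11
#> 4     4   49.7   49.7 -1.77e- 5 -3.56e- 7
#> 5     5   44.5   44.5 -1.22e- 3 -2.75e- 5
#> 6     6   40.6   40.6 -1.37e- 2 -3.36e- 4
```

The full solution tracks the asymptote to machine precision where $t \gg a$
and departs *below* it (never above: $dI/dt > \log a$) as the boundary
$t = a$ approaches — the mechanism behind the unimodal peak.

```r
# Zipf with a droop: exact log-factorial vs Stirling
s <- solve_hom(kappa = -log(1000), eta = 1, M = 12, approximation = "stirling")
e <- solve_hom(kappa = -log(1000), eta = 1, M = 12, approximation = "exact")
droop_profile(e, s)
#> # A tibble: 12 × 4
#>    rank count_num count_den ratio
#>   <int>     <dbl>     <dbl> <dbl>
#> 1     1      999.     1000  0.999
#> 2     2      499.      500  0.999
#> 3     3      333.      333. 0.998
#> 4     4      249.      250  0.998
#> # ℹ 8 more rows

# tail battery on a sample with known truth (exponent 2.5)
v   <- generate_powerlaw_lengths(exponent = 2.5, xmin = 1, n = 2e4, seed = 1)
fit <- fit_power_tail(v, xmin = "auto", n_boot = 200, seed = 2)
fit
#> <cohsi_powerlaw> xmin = 1, exponent = 2.494, KS = 0.00228, n_tail = 20000,
#>   bootstrap p = 0.245 (plausible)
```

The MLE recovers the planted exponent to three figures and the bootstrap
(correctly) fails to reject the power law. `autoplot(fit)` overlays the
fitted tail on the empirical ccdf.

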