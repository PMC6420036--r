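---
title: "Methods: copy-number-structured evolution of plasmid segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number-structured evolution of plasmid segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidseg)
```

## The model and its assumptions

`plasmidseg` models a well-mixed bacterial population structured by the
copy number `z` of a high-copy plasmid that confers antibiotic resistance
at a metabolic cost. Three processes act:

1. **Plasmid replication** within a cell: a logistic birth process with
   per-cell rate `b z (1 − z/ẑ)`, one copy at a time, capped at the
   carrying capacity `ẑ`. Replication control is tight for real high-copy
   origins, which is what the logistic form caricatures.
2. **Cell division** at rate `β(z, α)`: plasmid-free cells divide at `β₀`
   without antibiotics (`α = 0`) and not at all with antibiotics
   (`α = 1`); plasmid-bearing cells are resistant and divide at the
   burden-limited rate `β(z) = β₀ (1 − c·z/ẑ)₊` in either environment.
   The linear burden means each plasmid costs `100·c/ẑ` percent of the
   division rate — 2% per copy at `ẑ = 50` with the full burden `c = 1`,
   in the range measured for recombinant plasmids. The positive-part
   clamp keeps the rate non-negative for any `c`.
3. **Death** only of plasmid-free cells under antibiotics, at rate `μ₀`.

At division each plasmid independently enters a randomly selected
daughter with probability `p_z` (the trait); the other daughter receives
the rest. The two-daughter kernel `k(z; z₀) = g(z; z₀) + g(z₀ − z; z₀)`
(with `g` the binomial mass) has total mass 2, is symmetric in
`z ↔ z₀ − z`, and is invariant under `p ↔ 1 − p`; strategies are
therefore canonicalized to `[0, 1/2]^ẑ`, reflecting entries above one
half.

The population model is linear. Writing `y` for the plasmid-bearing
classes `z = 1..ẑ` and `x₀` for the plasmid-free class,

    y′ = A y,    x₀′ = (β(0, α) − μ(0, α)) x₀ + Bᵀ y,

with `A` and `B` independent of the environment. Mass balance
`colSums(A) + B = β(z)` holds column by column (each division replaces
one cell with two daughters), and is asserted in the test suite.

Modelled away: horizontal plasmid transfer, spatial structure, resource
competition, cell size and age, and antibiotic pharmacokinetics (the
environment is a given binary schedule `α(t)`).

## Parameters

| symbol | meaning | default | unit |
|---|---|---|---|
| `ẑ` (`z_hat`) | maximal copy number | 50 | plasmids |
| `b` | plasmid replication parameter | 1.2 | /h |
| `β₀` (`beta0`) | maximal division rate | 1 | /h |
| `μ₀` (`mu0`) | plasmid-free death rate under antibiotics | 5 | /h |
| `c` (`burden_scale`) | burden scaling on the division rate | 1 | — |

Time can be rescaled so `β₀ = 1/h` without loss; `b = 1.2/h` places
plasmid replication slightly above cell division, the regime in which
high loads actually accumulate. `burden_scale` multiplies only the
division-rate burden, not the plasmid logistic term: it is a knob for
*metabolic* burden sensitivity analyses, and the plasmid's own carrying
capacity is a property of its replication control, not of the host's
economy. Because the dynamics of `y` involve only `b`, `β₀`, `ẑ` and `c`,
`μ₀` matters solely for persistence verdicts and the full-system
integration.

## Growth rates, persistence, stationary composition

`A` is essentially non-negative and irreducible (for `b > 0` and any
strategy that ever splits), so its spectral bound `λ₁` is real with a
strictly positive eigenvector `ŷ` — the asymptotic growth rate and
stationary copy-number composition of the plasmid-bearing subpopulation.
Sizes here are small (`ẑ ≤ a few hundred`), so `spectral_bound()` uses a
dense eigendecomposition; the test suite cross-checks it against an
independent shifted power iteration and against the log-slope of forward
integration.

Two caveats that the tests make explicit:

- Even without any burden (`c = 0`) the bound stays strictly below `β₀`:
  the block constantly leaks plasmid-free daughters (a one-plasmid mother
  *always* loses one daughter to `z = 0`), and `λ₁ → β₀` only as
  `b → ∞`.
- Persistence (`λ̂₀ < λ₁`, with `λ̂₀ = (1 − φ)β₀ − φμ₀` for antibiotic
  fraction `φ`) yields a *positive, periodically oscillating* plasmid-
  bearing fraction, not a fraction near one: segregation losses
  continuously regenerate plasmid-free cells. `persistence_check()`
  reports `"marginal"` within `1e-6/h` of the boundary.

`integrate_population()` propagates the piecewise-constant-environment
system segment by segment with the matrix exponential of the augmented
`(1 + ẑ)`-dimensional generator, which is exact up to the matrix
exponential itself; schedule switch times are hit exactly rather than
stepped over.

`stationary_distribution()` reports modes as strict local maxima of the
exact eigenvector *including the boundary points* `z = 1` and `z = ẑ`:
under the optimized strategy the distribution is U-shaped, with the large
active mode at the lowest loads and the smaller "plasmid dump"
subpopulation exactly at the carrying capacity, so an interior-only
detector would see nothing.

## Finding the evolutionarily stable strategy

The ESSS maximizes `λ₁(p)` over the box `[0, 1/2]^ẑ`. The ascent flow
`dp/ds = ∇λ₁(p)` is discretized as projected gradient ascent with
backtracking: only `λ₁`-improving steps are accepted, the step grows by
1.5× after success and halves on failure, and iteration stops when the
projected-gradient sup-norm falls below `1e-6` (per hour per unit `p`) or
after 5000 iterations. The gradient is the adjoint (first-order
eigenvalue perturbation) formula `wᵀ(∂A/∂p_z)v / (wᵀv)` with the
analytic kernel derivative
`d/dp Bin(z; n, p) = n[Bin(z−1; n−1, p) − Bin(z; n−1, p)]`; a central
finite-difference mode is kept as an independent cross-check (they agree
to `<1e-6` at interior points) and as a fallback near eigenvalue
degeneracy.

Design choices worth recording:

- **Flat coordinates.** `λ₁` provably never depends on `p_1` (the kernel
  of a one-plasmid mother is `p`-independent) nor on any `p_z` with
  `β(z) = 0` (that mother never divides, e.g. `z = ẑ` under the full
  burden). These coordinates are frozen at 0.5 and excluded from
  convergence norms, agreement checks and feature extraction
  (`flat_coordinates()`); they are unidentifiable trait values, and any
  number reported for them would be an artefact of initialization.
- **Initialization.** Uniform `p ≡ 0.5` is an *exact stationary point*
  of the ascent flow — `λ₁` is even under `p_z ↔ 1 − p_z` in each
  coordinate, so the gradient vanishes identically there — and it is a
  saddle, not a maximum, at the default parameters. The multi-start set
  is therefore uniform **0.45** (near-equal), uniform 0.25, and seeded
  uniform-random vectors; `multi_start_ess()` reports how many starts
  agree with the best run (sup-norm `< 0.02` over non-flat
  coordinates).
- **Local-maximum verification.** `verify_local_max()` probes each
  coordinate separately by `±δ` before trying random full-vector
  perturbations: at a saddle like `p ≡ 0.5` the coordinate probes expose
  the second-order ascent directions that random probes average away.
  The improvement tolerance (default `1e-7/h`) absorbs the first-order
  slack `δ × 1e-6` that a converged ascent run may legitimately leave.
- **Degenerate landscapes.** At small `ẑ` with the full burden the cap
  state neither divides nor replicates, an inert class with eigenvalue 0
  dominates, and `λ₁ ≡ 0` for every strategy; the grid-search oracle
  comparisons in the tests therefore run at `burden_scale = 0.5`, where
  all states divide and the landscape is informative.

At the defaults the optimization converges in ~85 iterations
(`λ₁* = 0.5459/h`), all starts agreeing; `onset_threshold()` (deviation
tolerance 0.05, a choice — the plateau is numerically flat to `<1e-3`)
places the switch to unequal segregation at copy number 29, and the
minimum optimized `p_z` over identifiable coordinates is 0.156 at
`z = 49`. `sensitivity_sweep()` re-optimizes over grids of
`(b, ẑ, burden_scale)`; slow replication (`b = 0.5 < β₀`) or a weak
burden (`burden_scale = 0.2`) each collapse the optimum to equal
segregation everywhere, while the unequal-segregation feature persists
across `ẑ`.

## The conceptual two-generation model

The closed-form caricature treats copy number as continuous and ignores
accumulation effects on the division time: a newborn with `z₀` copies
divides after `T(z₀) = 1/(β₀(1 − z₀/ẑ))` with fitness
`f₀ = β₀(1 − z₀/ẑ)`; the load just before division is the logistic flow
evaluated at `T(z₀)`,

    F(z₀) = ẑ z₀ / (z₀ + (ẑ − z₀) e^{−(b/β₀)/(1 − z₀/ẑ)}),  F(z₀) ≤ ẑ.

This closed form is pinned against direct ODE integration of
`z′ = b z (1 − z/ẑ)` (agreement to `1e-8` across `z₀ = 1..49`), which
also fixes its interpretation unambiguously. Splitting the load
`(1 ± a)/2` with asymmetry `a` leaves the first-generation mean fitness
unchanged (the burden is linear) but raises the second-generation mean
fitness for every `a > 0` because `F` is concave — asymmetry pays one
generation later. The protection factor `q(z) = z/(K + z)` (increasing,
concave; `K` = copies at half protection, default 5 in the tabulation)
reverses this at low load: the protected first-generation mean fitness
`½[q((1+a)z₁/2)f₊ + q((1−a)z₁/2)f₋]` is numerically decreasing in `a` on
all tested grids. These two opposed forces are exactly the plateau and
the asymmetric tail of the full model's ESSS. The monotonicity in `a` is
verified numerically on grids here, not proven.

## The lineage simulator and what it does (not) emulate

`simulate_lineages()` is an exact event-driven realization of the
single-cell process: per-cell competing exponential clocks for
replication, division and death. Cells of equal copy number are
exchangeable, so events are drawn per copy-number class and the concrete
cell picked uniformly inside the class — equivalent to the naive
per-cell algorithm at `O(ẑ)` cost per event (implemented in C++ with R's
RNG, so runs are bit-reproducible under a seed). Division records store
the mother's load, both daughters' loads (the binomially "selected"
daughter first) and the founder lineage id; plasmid conservation
`d₁ + d₂ = z₀` holds exactly by construction and is audited in tests.

Population control: when the census exceeds `max_cells` (default `10⁴`),
uniformly random cells are removed down to the cap — unbiased for the
composition in expectation — and the cumulative correction
`Σ log(N/(N−1))` is tracked so `lineage_growth_rate()` estimates refer
to pre-subsampling counts. With `drop_plasmid_free = TRUE` daughters
born without plasmids are discarded (counted in the metadata): the
census then follows the `y`-block alone, which is the right object for
comparing against `ŷ` and `λ₁` — in a capped census under `α = 0` the
faster-growing plasmid-free cells would otherwise crowd the
plasmid-bearing classes out.

The fluorescence proxy is `f = gain·z + N(0, σ)` truncated at zero — a
deliberately minimal readout model. The synthetic records therefore
emulate the *structure* of time-lapse segregation data (per-mother load,
two daughters summing to it, noisy intensity proxy), but not cell-size
dependent partitioning noise, maturation or bleaching of the
fluorophore, segmentation errors, or lineage-correlated measurement
drift. Tests passing on these records validate the estimators and the
model's internal consistency; they do not validate the measurement model
against real microscopy.

Analysis procedures on records:

- `share_histograms()` stratifies mothers by fluorescence relative to
  the observed maximum (default) or by empirical quantiles — both modes
  exist because either stratification is defensible — and histograms
  both daughters' shares `f_i/(f₁ + f₂)`. Bins are filled via the lower
  share and mirrored, with exact halves split over the two central bins,
  so the symmetry about 0.5 is bin-exact by construction (`n_bins` must
  be even). Divisions with `f₁ + f₂ = 0` are dropped and counted.
- `rank_plot_table()` orders mothers by fluorescence (stable sort) and
  returns the ordered daughter pair per mother: a fused branch at low
  ranks that bifurcates where segregation turns unequal.
- `estimate_strategy()` recovers `p̂_z` from the selected daughter's
  pooled binomial counts with Clopper–Pearson intervals, reflected into
  `[0, 1/2]`; if the selected daughter is not identified it falls back
  to the lower share, which is biased low (an order statistic, not the
  role mean) and is flagged as such.

`expected_daughter_loads()` returns both the role-based expectations
`(p z₀, (1 − p) z₀)` and the exact order-statistic means
`E[min(Z, z₀ − Z)]`, `E[max]`; the role-based pair is the default
reported convention.

## Numerical choices and problem sizes

Dense `eigen()` for all spectral work (matrices ≤ a few hundred);
`Matrix::expm()` for forward integration; `stats::dbinom` for all
binomial masses (stable in log space far beyond `z₀ = 1000`);
`stats::binom.test` for interval estimates. Degenerate inputs are
errors, not silent fixes (copy numbers out of range, `z > z₀` in the
kernel, division time at `z₀ = ẑ`), except the end-of-cycle load at the
cap, which returns the limit `ẑ` with a flag.

The test suite runs the full optimization at `ẑ = 50` (seconds per
start), exhaustive grid oracles at `ẑ ∈ {2, 3}`, and simulations of
10⁴ cells for ~60 simulated hours (a few million events, seconds in
C++); the stationary census then sits within total-variation distance
~0.03 of `ŷ`. These sizes are chosen to probe the asymptotic claims
comfortably, with margins, at interactive runtimes.

## Known limitations

- The optimizer certifies local maxima with multi-start agreement, not
  global optimality (impossible in general).
- The persistence theory is deterministic/linear: no finite-population
  extinction probabilities.
- The conceptual model's monotonicity claims are verified numerically on
  grids, not proven symbolically.
- The burden-scaling knob is interpreted as scaling only the division
  burden; interpreting it as also scaling the replication logistic would
  be a different (also defensible) model.
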