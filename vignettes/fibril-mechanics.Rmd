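---
title: "Worm-like-chain mechanics and core geometry of amyloid fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worm-like-chain mechanics and core geometry of amyloid fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alfibril)
```

## The scientific problem

Amyloid fibrils extracted from patient tissue can be traced in electron
tomograms as 3D polygonal chains. Two mechanical summaries are standard:
the **persistence length** $P$, the length scale over which the filament's
tangent direction decorrelates, and the **bending rigidity**
$B = k_B T P$. This package estimates both from traced polylines, and
adds three companion analyses used when characterizing an ex vivo fibril:
helical-parameter arithmetic (rise/twist/pitch/crossover), a
five-predictor consensus aggregation score along the sequence, and
ordered-core/mutation-mapping statistics for the resolved fibril
structure.

Because real trace coordinates are typically distributed as source data
rather than bundled with software, the package carries a first-class
simulator of discrete worm-like chains with *known* persistence length.
Every stage of the pipeline is therefore testable end to end: simulate a
cohort at a known $P$, measure it, fit it, and check that the estimate
recovers the truth.

## The worm-like-chain model and the fit

For a worm-like chain of contour length $L$ and persistence length $P$,
the mean squared end-to-end distance in 3D is

$$\langle R^2 \rangle \;=\; 2PL\left(1 - \frac{P}{L}\left(1 -
e^{-L/P}\right)\right).$$

`wlc_expected_r2()` evaluates this; for $L/P < 10^{-4}$ it switches to
the series $L^2(1 - x/3 + x^2/12)$, $x = L/P$, because the direct form
loses all significant digits to cancellation in the rigid-rod regime.
The two limits are $\langle R^2\rangle \to L^2$ (rigid rod) and
$\to 2PL$ (flexible coil).

`fit_persistence_length()` estimates $P$ by **unweighted** nonlinear
least squares of $R_i^2$ on $L_i$ — the conventional regression for this
quantity, and what a generic curve-fitting tool produces. The starting
value is the flexible-limit moment estimate
$\bar{R^2} / (2\bar{L})$, clipped to the optimization box
$[10^{-3}, 10^{3}]\ \mu m$; positivity is enforced by the box rather
than a reparameterization so the reported optimum is directly the
physical parameter. The objective tolerance is $10^{-10}$ with at most
500 iterations. A flat objective above the optimum (which happens when
all chains are effectively collinear, $R^2 = L^2$) is detected by
checking whether doubling $\hat P$ changes the residual sum of squares;
such fits are flagged `at_boundary` with a warning, because the data
then carry no upper bound on $P$.

### Confidence intervals: linearized vs bootstrap

Two 95% intervals are offered. The default `linearized` interval is the
Jacobian-based standard error with a $t_{n-1}$ quantile — the interval a
standard curve-fitting tool prints. The `bootstrap` interval resamples
fibrils with replacement (default $B = 1000$, seeded) and takes
percentiles.

These are not interchangeable. The variance of $R^2$ grows strongly
with $L$, so the unweighted regression is heteroscedastic, and the
linearized standard error — which assumes iid residuals — is too small
at this study design. The case-resampling bootstrap respects the actual
residual distribution, and it is the interval whose empirical coverage
the test suite verifies to sit in the nominal range over replicated
simulated studies. The linearized interval is retained as the default
*output* for comparability with conventional fits, but inference that
depends on the interval width should use the bootstrap. This is a known
limitation, not a defect the fit can remove: it follows from fitting
$R^2$ unweighted, which is the fidelity-first choice here.

### Bending rigidity

`bending_rigidity()` applies $B = k_B T P$ with $k_B$ fixed at the
exact SI value $1.380649\times 10^{-23}$ J/K and $T = 300$ K by
default; an optional standard error on $P$ propagates linearly. Values
are reported at full precision; presentation rounding (2 significant
figures for $B$, 1 for its SE) is left to the caller, matching how such
values are typically printed.

## The simulator: what it emulates and what it does not

`simulate_study()` emulates a tracing study: a cohort of
`n_fibrils` chains, each a discrete worm-like chain built from segments
of exact length $\ell$ (`seg_nm`). Successive tangents are related by a
polar bend whose cosine is drawn from the equilibrium density
$\propto \exp(a\cos\theta)$ with $a = P/\ell$, via the closed-form
inverse CDF (no rejection sampling), and a uniform azimuth. This gives
$\langle\cos\theta\rangle = \coth a - 1/a \approx e^{-\ell/P}$ with
relative error $O((\ell/P)^2)$; the constructor enforces
$\ell \le P/5$ and the defaults use $\ell = P/74$, where the
discretization error is far below sampling noise. The first tangent is
uniform on the sphere — $R$ and $L$ are rotation invariant, so this
only randomizes raw coordinates. The segment count is
$\mathrm{round}(L/\ell)$, so a realized contour length may differ from
the requested one by up to $\ell/2$; the manifest records both.

Defaults are the study conditions this package targets: $n = 195$
fibrils, $P = 0.74\ \mu m$, 10-nm segments, no tracing noise. No
contour-length distribution is published for such cohorts, so the
default sampler is uniform on $0.3$–$2.0\ \mu m$ — a deliberately broad,
plain stand-in spanning short fragments to multi-micron filaments, and
exposed as configuration. Optional isotropic Gaussian jitter
(`noise_sd_nm`) emulates tracing error; jitter systematically inflates
measured contour length, which is one reason the default is zero.

Reproducibility: each fibril's random stream is derived from the root
seed and the fibril index, so a cohort is bit-identical for a fixed
seed regardless of generation order or subsetting.

The simulator deliberately omits excluded volume (self-avoidance),
surface-adsorption (2D-equilibration) physics, fibril thickness, and
tomogram-level noise structure. Passing recovery tests therefore shows
the estimator is correct *for ideal worm-like chains measured without
error*; on real traces, tracing noise, anisotropic localization error
and length-biased sampling can bias $\hat P$ in ways the synthetic
cohort does not probe.

### Measurement conventions

Internally all coordinates are nm; contour lengths and end-to-end
distances convert to $\mu m$ at the type boundary only. The default
end-to-end mode is 3D (`spatial3d`); a planar projection mode
(`planar_xy`) is provided because 2D measurement of tomogram traces is
a live convention in the field, but it is off by default since the
3D Kratky–Porod form is the model being fitted. Polylines are measured
raw — no resampling or smoothing — and consecutive duplicate points are
merged (with a warning) rather than rejected, which tolerates
hand-traced data. Traces failing validity (one point, non-finite
coordinates, zero-length segments, zero end-to-end in the chosen mode)
are excluded and logged, never silently dropped.

## Helical parameters

For a helix with rise $r$ (Å per subunit) and twist $\omega$ (degrees
per subunit, negative = left-handed): pitch
$= r \cdot 360/|\omega|$, and the projected crossover distance is
pitch$/2$ for a ribbon-like fibril whose width modulates twice per turn
(the single-protofilament case; `crossovers_per_turn` is exposed for
other morphologies). `helix_consistency()` fills in derivable
quantities from any sufficient subset and reports pairwise relative
discrepancies, flagging those above a tolerance (default 10%). It
reports disagreement — e.g. between a measured crossover and the
crossover implied by refined rise/twist — without adjudicating which
measurement is right, since a few-percent gap can be measurement error
or convention. Sign convention (left $\Leftrightarrow$ negative twist)
is preserved through every conversion and round-trips exactly.

## Consensus aggregation score

Five external predictors (TANGO, WALTZ, FoldAmyloid, Aggrescan, PASTA)
produce per-residue values; this package consumes a normalized TSV of
those values rather than parsing each program's native output, which is
unstable and external. Each predictor is binarized at its published
working threshold, with strict inequalities — a value exactly at the
threshold is not flagged, and the boundary behavior is unit-tested.
FoldAmyloid calls additionally require at least five consecutive
flagged residues; the whole qualifying run is kept. The consensus score
of a residue is the count of predictors flagging it (0–5), and segment
calls are maximal runs at a target score.

One genuine ambiguity: the WALTZ rule is stated as a *total sequence
score* above 0. A residue-resolved 0–5 score is only possible under a
per-residue reading, so that is the default; a whole-sequence mode
(flag all residues iff the summed score is positive) is available via
`waltz_mode = "whole_sequence"` for users who prefer the literal
reading. Predictor execution parameters (temperature, pH, etc.)
configure the external programs and are metadata here, not behavior.

## Ordered core and mutation mapping

`core_annotation()` stores 1-based inclusive residue ranges for the
ordered fibril core plus mutation positions; the bundled
`for001_annotation()` encodes the published FOR001 fragment (118
residues, ordered segments 9–52 and 68–108, six mutations).
`ordered_fraction()` and `mutations_in_ordered()` are exact counting
operations; `aggregate_stats()` reports mean and **sample** SD
($n-1$ denominator) across structures — published "±" dispersions of
this kind rarely state their estimator, and sample SD is the assumption
made here. Percentages are rounded to whole percent for display while
full-precision fractions remain in the machine-readable output.
Annotations for fibril structures other than FOR001 live in their
depositions and are user inputs, not bundled facts.

The extinction-coefficient utility implements the additive
Gill–von Hippel estimate
$\varepsilon_{280} = c_W n_W + c_Y n_Y + c_{SS} n_{SS}$ with the
denatured-protein defaults $c_W = 5500$, $c_Y = 1490$, $c_{SS} = 125\
\mathrm{M^{-1}cm^{-1}}$; the coefficient table is configurable because
published coefficients for a specific protein cannot be decomposed
without its full sequence.

## Problem sizes and numerical choices

The test suite and analysis scripts use cohorts of 195 chains (the
study size), 2000-chain ensembles for Monte-Carlo checks of the
$\langle R^2\rangle$ relation at $L/P \in \{0.25, 1, 4\}$, and 200
replicate studies with 200-resample bootstraps for the
interval-coverage check — sizes chosen so Monte-Carlo error is small
against the effects being tested while a full run stays in the
minutes range on one core. Monte-Carlo assertions use $3$–$4$ standard
errors of the simulated quantity, never absolute tolerances, so they
scale correctly if sizes are changed. Geometry identities
(round-trips, rotation invariance) are asserted at $10^{-9}$–$10^{-12}$
relative, i.e. at accumulation-of-rounding level.

## Known limitations

* The linearized CI undercovers at this study design (see above); use
  the bootstrap interval when coverage matters.
* The simulator's contour-length distribution is a configurable
  stand-in, not an empirical fact.
* Only one persistence-length estimator is implemented (the $R^2$-on-$L$
  regression); tangent-correlation and Fourier-mode estimators are out
  of scope, as are mixtures of stiffness populations.
* Binary tomogram model files are not parsed; import is limited to the
  documented text dialects (trace CSV and `object contour x y z` point
  exports with a pixel size).
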