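---
title: "An entropic weighted associative memory: model, operations and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An entropic weighted associative memory: model, operations and protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weam)
```

## The model

An associative memory register (AMR) is an $n \times m$ table of
non-negative integer weights $w_{ij} \in \{0,\dots,l\}$. Columns are the
arguments of a discrete function, rows its possible values (levels). An
object is a function $f : \{1..n\} \to \{0..m-1\}$ and is stored by
marking one cell per column. Because all stored objects share the same
table, traces overlap and cannot be demarcated individually: the
representation is *indeterminate*, and combinations of marked cells that
were never registered — *emerging objects* — are representable alongside
the registered ones. Three declarative operations, all search-free, define
the memory:

* **Register** ($\lambda$): for each defined argument $i$ of the cue with
  level $j$, increment $w_{ij}$ by one (saturating at $l$; the default
  $l = 65535$ corresponds to two-byte cells). Repeated use reinforces
  cells, a Hebbian-style rule.
* **Recognition** ($\eta$): a logical test with three sensitivity
  parameters. Let $\omega_i$ be the mean weight of the *non-zero* cells of
  column $i$, $\Omega$ the mean of the $\omega_i$ over all columns, and
  $\rho$ the mean weight of the cells hit by the cue (over its defined
  arguments). Column $i$ *fails* when its cue cell has weight $0$, or
  weight below $\iota\,\omega_i$. The cue is accepted iff at most $\xi$
  columns fail (material implication relaxed by $\xi$) and
  $\rho \ge \kappa\,\Omega$. The defaults $\iota=\kappa=\xi=0$ impose no
  constraint beyond the zero-weight test; a cue touching any unsupported
  cell is then rejected directly, with no search.
* **Retrieval** ($\beta$): if the cue is rejected the result is undefined
  (`NULL`). Otherwise, per column, the normalized weights form a prior
  $\Psi_i$, the cue a likelihood $\zeta_i$ — a normal density centered at
  the cue level with standard deviation $\sigma m$, evaluated at the
  integer levels — and one level is drawn from the normalized product
  $\Phi_i \propto \Psi_i\,\zeta_i$. Retrieval is therefore constructive
  and Bayesian per column.

Column entropy is the Shannon entropy of $\Psi_i$ (0 for an all-zero
column); the memory entropy $e$ is the mean over columns, bounded by
$\log_2 m$. The number of functions the state can yield is $2^{en}$: at
unit entropy a 256-column register spans $2^{256}$ functions while
occupying 1024 cells. `capacity_log2()` returns $en$;
`capacity_count()` / `productivity_count()` return exact counts through a
small arbitrary-precision decimal routine, since $2^{256}$ overflows
doubles and no big-integer package is part of the package's dependency
set.

## Parameters that matter

| parameter | meaning | unit / range | default | rationale |
|---|---|---|---|---|
| `n` | columns (feature arity) | positive int | domain-set | matches the encoder output dimension |
| `m` | rows (levels) | positive int | 4 (sweeps), 16 (chains) | few levels suffice for recognition; chains need level variability |
| `l` | weight saturation | positive int | 65535 | two-byte cells; silent clamping |
| `iota` | per-cell on-threshold factor | $\ge 0$ | 0 | no constraint |
| `kappa` | cue-weight threshold factor | $\ge 0$ | 0 | no constraint |
| `xi` | columns allowed to fail | $0..n$ | 0 | strict implication |
| `sigma` | cue kernel spread | fraction of $m$ (sd $= \sigma m$) | 0.1 scoring, 0.15 chains | small = remembering, moderate = association, large = imaging |

$\sigma = 0$ makes the kernel a point mass and the memory reproductive: a
stored cue retrieves exactly itself.

## Numerical and degenerate-case choices

* **Kernel discretization.** $\zeta_i$ is the normal density evaluated at
  the integer levels $0..m-1$ without continuity correction; the product
  with $\Psi_i$ is renormalized. This is the simplest scheme consistent
  with a normal kernel centered at the cue value; any smoothing of bin
  edges would be invisible after the product and renormalization.
* **Zero-weight cells are always off.** The failing-column test is
  $w = 0 \;\lor\; w < \iota\,\omega_i$. With $\iota = 0$ alone, $w \ge 0$
  would accept every cue and direct rejection would vanish, contradicting
  the operation's purpose.
* **$\sigma = 0$ in a $\xi$-relaxed column.** If the cue cell of an
  accepted cue has zero weight (possible only when $\xi > 0$), the draw
  falls back to $\Psi_i$ alone so that retrieval of an accepted cue is
  always defined.
* **Partial cues.** Recognition evaluates failing columns and $\rho$ over
  the defined arguments only (the divisor of $\rho$ is the number of
  defined arguments — the natural reading when cues may be occluded;
  the alternative, dividing by $n$, would penalize partial cues by
  construction). Retrieval samples undefined arguments from the prior
  $\Psi_i$; a column with no support leaves that argument `NA` and the
  result partial.
* **$\omega_i$ of an all-zero column is 0** and contributes 0 to
  $\Omega$.
* **Ties and underflow.** Nearest-centroid classification breaks ties
  toward the lowest class id; if $\zeta$ underflows to zero everywhere on
  the support (pathologically small $\sigma$ with a distant cue), the draw
  falls back to $\Psi_i$, preserving support confinement.
* **Randomness.** Operations use R's global RNG; `amr_retrieve()` and the
  protocol runners accept a `seed` and restore the caller's RNG state,
  following the convention of `simulate()` methods. Master seeds derive
  per-item seeds by fixed arithmetic.

## The codec

Encoders produce real vectors; the memory consumes levels. The package's
quantizer is per-argument equal-width binning between the training
minimum and maximum: $level = \lfloor m\,(x - lo)/(hi - lo)\rfloor$
clipped to $[0, m-1]$, with out-of-range values clipping to the boundary
(so unseen objects always quantize) and constant arguments widened by a
small epsilon (all values map to level 0). Dequantization returns bin
midpoints, which makes quantize∘dequantize level-stable and bounds the
reconstruction error by half a bin width. A learned coder/decoder would
adapt the bin placement; linear binning is the minimal stand-in and is the
only part of the pipeline an external encoder replaces — any program may
emit the `features + label` CSV the pipeline consumes.

## The synthetic domain

`generate_domain()` draws one centroid per class from an isotropic
Gaussian (scale `separation`, default 3) and class members isotropically
around it (`noise_sd`, default 1), then partitions the balanced corpus
70/20/10 into train / remember / test. Defaults are 10 classes and 7,000
objects (a tenth of the 70,000-object corpora typical of low-resolution
image benchmarks, keeping the default runs interactive), giving 1,400
remembered and 700 test objects. With 64 features the default geometry is
well separated: the nearest-centroid stand-in classifier is nearly
perfect, so experiment outcomes isolate the memory's contribution rather
than the classifier's.

What the generator emulates is the *geometry* the memory experiments
assume — compact class-conditional clusters in a real-valued feature
space, balanced classes, disjoint partitions. What it does not emulate:
encoder features are neither isotropic nor Gaussian, classes of real
corpora overlap (real classifier ceilings are well below 100%), and
feature dimensions of trained encoders are correlated. Passing tests
therefore validate the memory mechanics and the qualitative entropy
trade-off, not absolute performance numbers on any real corpus.
Cue corruption replaces a chosen fraction of feature positions (exactly
`round(fraction * n)` of them) with uniform noise over the quantizer
range — the feature-space analogue of corrupting half the pixels of an
image.

## Experiment protocols and problem sizes

* `run_fill_sweep()` fills fresh registers with balanced fractions
  (1%–100%, doubling) of the remembered corpus, cues with every test
  object at $\sigma = 0.1$, classifies retrievals, and scores with the
  rejection-aware convention: every cue belongs to some class, so there
  are no true negatives; precision $= right/(right+wrong)$, recall $=$
  accuracy $= right/total$, all as percentages (precision of an
  all-rejecting memory is defined as 0 rather than NaN). Precision can
  never fall below recall; they coincide exactly when nothing is
  rejected. The package's checks run this at $n=64$, $m=4$ on the
  7,000-object domain, where the entropy trade-off shape appears: recall
  near zero at 1% fill rising steeply, precision essentially flat from
  16% fill onward.
* `run_sigma_sweep()` retrieves each cue at $\sigma \in
  \{0.05,0.1,0.2,0.3,0.4,0.5\}$ (optionally corrupting cues first) and
  tabulates class preservation / reassignment / rejection.
* `run_chain()` retrieves, classifies, and feeds the retrieved function
  back as the next cue, up to 6 steps, stopping at the first rejection;
  chains default to $\sigma = 0.15$ on a 16-row register — few-level
  registers leave too little variability for the chain to move, many
  levels dilute support.
* `run_kfold()` repeats the fill protocol over $k$ balanced folds
  (default 10) with per-fold seeds derived from the master seed, reporting
  per-fold scores and their mean and sd.

The bundled acceptance script (`scripts/acceptance.R`) reruns these at the
sizes above; a full run takes a few seconds on one CPU.

## Known limitations

* The memory is auto-associative and single-register; the multi-register
  architecture with system-level class selection, and the
  hetero-associative extension, are out of scope.
* The basic boolean variant exists only as the degenerate case obtained
  by clamping weights to $\{0,1\}$ (used to cross-check capacity against
  exhaustive enumeration); its triangular cue kernel is not implemented.
* Linear quantization cannot reproduce effects that depend on a trained
  coder's nonlinear level placement.
* Weight saturation silently clamps at $l$; extremely long runs at small
  $l$ flatten $\Psi_i$ toward the truncated distribution.
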