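---
title: "Methods: batched eQTM mapping"
author: "eqtmMapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batched eQTM mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtmMapper)
```

# The statistical model

For every selected pair of a CpG methylation locus *j* and a gene *k*,
the mapper fits, by ordinary least squares,

$$ y_k = a_{jk} M_j + X b_{jk} + \beta_0 + \varepsilon, $$

where $y_k$ is the length-$n$ vector of (log) expression levels at gene
$k$, $M_j$ the length-$n$ vector of methylation Beta scores at CpG $j$,
and $X$ the $n \times m$ covariate matrix shared by all pairs. The
reported quantities are the methylation coefficient $\hat a_{jk}$
(expression units per Beta unit), its standard error, the t-statistic
$t = \hat a / \mathrm{se}$, and a two-sided p-value.

Assumptions are those of the linear model: linear mean effect of
methylation on expression, homoscedastic errors, covariates entering
additively and identically for all genes. Inputs are assumed
pre-processed (normalized log expression, Beta scores); the package does
no QC or normalization of its own.

An intercept is always prepended, and a user-supplied constant column is
rejected: without an intercept the model is misspecified for any
non-centered data, and silently accepting a constant covariate would
double it.

## The Gaussian p-value

P-values are computed from the standard normal tail,
$p = 2\,(1 - \Phi(|t|))$, evaluated through the complementary tail so the
far tail does not cancel catastrophically; `stats::pnorm` underflows to
zero near $|t| \approx 37.6$, which is the natural floor of a double.
The Gaussian is used in place of the Student-t distribution with
$df = n - m - 2$. The two agree to within $10^{-3}$ absolute once
$n \approx 1000$, but at $n = 10$ the discrepancy exceeds $10^{-2}$ and
the Gaussian is anti-conservative — below roughly 20 samples the
approximation visibly inflates significance, and results should be read
accordingly. The degrees of freedom still enter the standard error as
$n - m - 2$ (intercept + $m$ covariates + methylation term); they simply
do not parameterize the reference distribution.

Non-finite statistics are handled by intent: NA/NaN (degenerate pairs)
propagate as NaN sentinels, while an infinite $t$ — the exact-fit limit —
maps to $p = 0$.

## Pearson mode

`method = "pearson"` reports the unadjusted correlation $r$ between each
expression and methylation row, with
$t = r\sqrt{(n-2)/(1-r^2)}$ and the same Gaussian two-sided p-value; the
`se` column carries $\sqrt{(1-r^2)/(n-2)}$ for column compatibility. The
$r \to t$ transform is this package's choice of p-value construction for
correlation mode. At $|r| = 1$ the statistic saturates at a fixed,
documented value of $10^8$ with $p = 0$, so outputs remain deterministic.

# Batched computation

Fitting each pair separately repeats the covariate projection
billions of times. Instead, both the expression block and the methylation
block are residualized once against $[\,\mathbf{1} \mid X\,]$
(Frisch–Waugh–Lovell); then for every pair

$$ \hat a_{jk} = \frac{\langle y_k^\perp, M_j^\perp\rangle}{\lVert M_j^\perp\rVert^2},
\qquad
\mathrm{se}_{jk} = \frac{\sqrt{\mathrm{RSS}_{jk}/df}}{\lVert M_j^\perp\rVert},
\qquad
\mathrm{RSS}_{jk} = \lVert y_k^\perp\rVert^2 - \hat a_{jk}^2 \lVert M_j^\perp\rVert^2 .$$

This is algebraically identical to the full per-pair fit, and the test
suite holds the two to a relative error of $10^{-8}$ over a thousand
random designs. Per-covariate coefficients, when requested, are recovered
from the partitioned inverse of the full design rather than refitted.

## Exact determinism across chunkings

Results are required to be *byte-identical* whatever the chunk
decomposition or thread setting. Optimized BLAS routines do not guarantee
this: the gemm kernel chosen for a 1-row block rounds differently from
the one chosen for a 50-row block. The residualization and the pairwise
cross-products are therefore computed with fixed-order elementwise
reductions (`rowSums`, rank-1 accumulation over basis columns), making
every pair's value bitwise independent of the block it happens to land
in. At block scale the cost difference is negligible; determinism is a
correctness feature here, not an optimization casualty.

## Chunking and the memory cost model

The gene × CpG grid is tiled into contiguous blocks. Explicit chunk sizes
are honored verbatim; `"auto"` CpG chunks default to
$\min(C, 10^5)$ and `"auto"` gene chunks invert the documented working-set
model

$$ \mathrm{bytes}(G, C) = b \cdot 1.25 \cdot \left( 2nG + 2nC + 4GC + n(m+2) \right), $$

i.e. input and residualized blocks, the four $G \times C$ result
matrices, the design and its basis, and a 25 % temporary-allocation
overhead. The model is this package's own; it is asserted self-consistent
(the closed formula and the returned count agree exactly, and the count
is monotone in the budget), not calibrated against external hardware.

## Degenerate loci

A methylation row whose residual sum of squares is at most $10^{-20}$ of
its raw sum of squares (or exactly zero) is treated as having no residual
variance — a constant probe, or one absorbed by the covariates. Such loci
yield NaN sentinels for every statistic, are logged once, counted in the
run summary, and excluded by any p-value filter; they never abort a run.
The $10^{-20}$ relative threshold sits far below any informative locus
(double-precision rounding of a truly constant row lands near
$10^{-30}$). The residual RSS is clamped at zero to absorb rounding in
exact-fit cases.

# Mapping modalities

Windows are anchored at the transcript start site: the first base of the
BED interval for + or unknown strand, the last base (end − 1 in 0-based
half-open coordinates) for −. CpG positions are the interval start. All
distances are absolute TSS-to-CpG offsets in 0-based coordinates; there
is no gene-body or probe-overlap logic.

* **cis** — same chromosome and distance ≤ window (default 1 Mb,
  symmetric, boundary inclusive).
* **distal** — same chromosome and distance > window (default 50 kb).
* **trans** — different chromosome.
* **all** — every pair, no annotation consulted.

Because the default distal window (50 kb) is smaller than the cis window
(1 Mb), same-chromosome pairs at distances in (50 kb, 1 Mb] belong to
*both* cis and distal; the definitions are applied literally rather than
inferring an exclusion band. Boundary inclusivity (≤ for cis, > for
distal) is pinned so pair counts are deterministic. Chromosome names are
compared as exact strings; a preflight warning fires when the two
annotations share no chromosome names at all. Loci present in the data
but absent from an annotation are excluded (logged once) in annotated
modes and included in all mode. trans and all runs default to a strict
p < 1e-5 output filter to bound output size; cis and distal default to no
filter.

# Execution contract

Output rows are gene-major in expression-file order, CpGs in
methylation-file order within each gene. The run summary reports pairs
tested, rows written, and degenerate loci; pairs tested always equals the
enumerated selection size, and rows written equals the count of p-values
strictly below the threshold. A failing block aborts the whole run with
the block coordinates, and removes any partial output: no silent partial
results. Numeric output uses 15 significant digits, so files round-trip
and chunk invariance can be checked on the files themselves.

Device selection keeps the execution contract explicit: `"auto"` probes
for an accelerator and falls back to the CPU, `"accelerator"` errors when
none is present. This build's linear algebra is CPU double precision
throughout, so the probe reports no accelerator; the thread count is
recorded in the device descriptor and results are identical for any
setting.

# Synthetic data

`generateDummy()` emulates the *shape* of a methylation–expression study,
not its biology: expression cells are independent standard Gaussians,
methylation cells independent uniforms on [0,1], covariates standard
Gaussians, and loci fall uniformly at random on a configurable layout
(default two 200-Mb chromosomes, 1-kb genes with random strand,
single-base CpGs). These are the simplest seed-stable distributions that
span the valid ranges. `generateWithEffects()` plants known associations
through the generative counterpart of the fitted model,
$y_k = \sum_j a_{jk} M_j + X b + \varepsilon$, $\varepsilon \sim
N(0, sd^2)$, and emits the planted pairs as a separate truth table.

What passing tests on these data do show: the estimator is unbiased with
nominal confidence-interval coverage under the model, p-values are
uniform under the null at the stated calibration ($n = 200$), and the
engine's accounting, filtering and determinism contracts hold exactly.
What they do not show: behavior under real-data features the generator
omits — correlated CpGs and co-expressed genes, bimodal Beta
distributions, batch structure, heteroscedastic or heavy-tailed noise,
non-numeric covariates (which must be encoded by the user; there is no
automatic coding rule).

Missing values in any input matrix are a hard error by default; an
opt-in flag on the matrix readers drops affected loci, logging each.
Per-pair complete-case handling is deliberately not offered — it would
break the batched algebra, which requires one design per block.

# Test and simulation scale

The shipped suite exercises the contracts at desk scale, chosen so the
full suite runs in a couple of minutes: the least-squares oracle over
1000 random designs with $n \in [10, 200]$ and $m \in [0, 5]$; chunk
invariance on a 50 × 200 grid at $n = 100$; modality membership against
an exhaustive double loop on a 1000 × 1000 annotation grid with planted
exact-boundary CpGs; null calibration on $10^4$ pairs at $n = 200$;
recovery of a planted effect $a = 0.5$ (noise sd 1, $n = 500$) over 200
replicates drawn from a single RNG stream; and a runtime-linearity check
over 1000–8000 CpGs. Monte-Carlo replicates share one seeded stream
rather than reseeding per replicate, which guarantees independent draws.

# Known limitations

* The Gaussian p-value is anti-conservative for small $n$ (< 20 samples).
* No multiple-testing correction is applied; filtering is on raw
  p-values, and downstream FDR control is the user's responsibility.
* Only numeric covariates are accepted; factor encoding is the user's.
* cis/distal overlap under the default windows is by design and can
  surprise users expecting a partition.
* The runtime-linearity check is a smoke property on wall-clock time and
  inherits its noise.
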