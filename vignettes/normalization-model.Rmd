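---
title: "A Bayesian model for normalization factors in run-on nascent RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian model for normalization factors in run-on nascent RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsinorm)
```

## The problem

Run-on nascent RNA sequencing assays (GRO-seq, PRO-seq) capture RNA still
engaged with polymerase. Because global transcription levels can change
between conditions — sometimes dramatically — counts cannot be normalized by
total library size, and practitioners rely on an *invariant set*: either
reads from spiked-in nuclei of a second organism (typically *Drosophila*),
or internal regions that a perturbation cannot yet have affected. Whatever
the invariant set, the question is the same: by what factor must sample A's
counts be multiplied to lie on sample B's scale, and — just as important —
how uncertain is that factor? A total-count ratio collapses the set to one
number; least-squares regression of counts on counts uses the whole set but
returns a point estimate with no usable error bound. This package estimates
the factor as a posterior distribution.

## The model

The input is a counts matrix over invariant regions. For a query sample
with counts $x_j$ and a reference with counts $y_j$ over regions
$j = 1,\dots,J$, the generative model is

$$
\begin{aligned}
x_j &\sim \mathrm{NB}(\lambda_j,\ \alpha_x) \\
y_j &\sim \mathrm{NB}\!\left(\lambda_j \cdot
      2^{\,\mu + b\,c_j + \varepsilon_j},\ \alpha_y\right) \\
\log \lambda_j &\sim \mathrm{Normal}(m_0, s_0) \\
\varepsilon_j &\sim \mathrm{Normal}(0, \sigma_{\mathrm{fit}}) \\
\mu &\sim \mathrm{Normal}\!\left(\log_2
      \tfrac{\mathrm{mean}(y)+1}{\mathrm{mean}(x)+1},\ \sigma_{\mathrm{mean}}\right) \\
b &\sim \mathrm{Normal}(0, 1), \qquad
\sigma_{\mathrm{fit}}^2,\ \sigma_{\mathrm{mean}}^2 \sim \mathrm{InvGamma}(1, 1), \qquad
1/\alpha_x,\ 1/\alpha_y \sim \mathrm{HalfNormal}(1)
\end{aligned}
$$

where $\mathrm{NB}(\mu, \alpha)$ is the negative binomial with mean $\mu$
and size $\alpha$ (variance $\mu + \mu^2/\alpha$), and $c_j$ is the
centered log2 mean intensity of region $j$, so the intercept $b$ absorbs
any intensity-dependent offset and $\mu$ is read off at the typical
expression level. $\mu$ is the log2 normalization factor: multiplying the
query counts by $2^\mu$ places them on the reference scale, and the
posterior standard deviation of $\mu$ is the error estimate the package
reports and propagates. The prior on $\mu$ is anchored at the log2 ratio of
Laplace-smoothed sample means — exactly the naive total-count estimate — and
its width $\sigma_{\mathrm{mean}}$ is itself learned.

Two design points deserve emphasis.

**Counts, not ratios, carry the likelihood.** An earlier draft of this
model put a Normal likelihood directly on the per-region smoothed log
ratios $\log_2\frac{y_j + 1}{x_j + 1}$. That formulation is simpler (it is
fully conjugate) but measurably biased: adding a pseudocount to counts of
different magnitudes compresses ratios toward zero at weakly expressed
regions, and with abundances spanning several orders of magnitude the bias
reached ≈ 0.15 log2 units at true factors of ±2 — unacceptable for a
normalization method. Modeling the counts through shared latent abundances
$\lambda_j$ removes the pseudocount from the likelihood entirely (it
survives only in the prior anchor and the covariate $c_j$); recovery error
in the same benchmark drops below 0.03.

**A region-level residual, not just overdispersion.** The residual
$\varepsilon_j$ is the "variance of the line of best fit": it captures
region-specific departures from a single global factor, such as a
perturbation reaching nominally invariant regions. This makes the estimate
of $\mu$ robust to contaminated regions — an outlying region inflates its
own $\varepsilon_j$ rather than dragging the global slope, which is why the
model resists the extreme-value sensitivity of raw-scale least squares.
$\varepsilon_j$ and the NB overdispersion $1/\alpha_y$ both describe
extra-Poisson noise and, with one observation per region, the data cannot
separate them sharply; this is a known, deliberate redundancy (see
*Convergence* below).

## Inference

All conditionals that admit conjugate updates (the two variance
components, the recentering of $\mu$ and $b$ against the residuals) are
Gibbs steps; the remaining parameters use adaptive random-walk Metropolis
within Gibbs, with the per-region latents updated as vectorized
independent proposals. Two moves matter for mixing and are worth naming:
an exact conjugate *recentering* of $\mu$ (and $b$) holding
$\mu + \varepsilon_j$ fixed, which decorrelates the slope from the mean of
the residual field, and a joint *scale* move — slice-sampled — that
multiplies all $\varepsilon_j$ and $\sigma_{\mathrm{fit}}$ together,
traversing the ridge between the residual variance and the NB
overdispersion. Step sizes adapt only during burn-in, so retained draws
target the exact posterior. The sampler core is C++ (Rcpp) and consumes
R's RNG stream, so every fit is exactly reproducible from a seed.

Defaults follow the protocol of 25,000 retained iterations after a burn-in
of 2,500, with two chains started from overdispersed initial values.
Split R-hat and effective sample sizes are reported for the slope, the
intercept and $\sigma_{\mathrm{fit}}$. The convergence flag uses a 1.01
threshold on the slope and intercept only: the split of extra-Poisson
noise between $\sigma_{\mathrm{fit}}$ and $1/\alpha_y$ is weakly
identified by design, its R-hat is reported but routinely above threshold
without affecting the normalization factor, whose own chain mixes with
integrated autocorrelation times of a few tens of iterations.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `laplace_pseudocount` | 1 | counts | smoothing in the prior anchor and ratios |
| `sigma_shape`, `sigma_rate` | 1, 1 | — | InvGamma prior on both variances |
| `dispersion_prior_scale` | 1 | — | half-normal scale on NB overdispersion |
| `draws`, `burn_in`, `chains` | 25000, 2500, 2 | iterations | MCMC protocol |
| elongation rate | 3 | kb/min | polymerase speed for region selection |
| time point | 60 | min | perturbation duration |
| 3' end exclusion | 500 | bp | termination-pileup trim |
| `min_region` | 1000 | bp | smallest emitted invariant region |
| coverage threshold | 10 | fold | spike-in depth QC cutoff |
| transcriptome length | 30 | Mb | *Drosophila* spike-in transcriptome |
| `alpha` | 0.01 | — | adjusted-p cutoff in DE calls |

The 180 kb default length threshold is the product of a 3 kb/min
elongation rate and a 60 min time point; both factors are overridable
because elongation rates vary by organism and condition. The threshold is
measured from the annotated gene 5' end of the selected isoform, the
region stops 500 bp short of the annotated 3' end to avoid the
termination-associated pileup, and regions shorter than 1 kb are dropped
(no stated convention exists for this floor; 1 kb avoids near-empty
regions whose ratios are dominated by shot noise). Reads are assigned to
regions by their 5' end alone, because run-on assays localize the
polymerase position; full-overlap counting is available behind a flag for
other assay types. The spike-in depth rule is strict: coverage of exactly
10× the 30 Mb transcriptome fails QC.

## The synthetic-data generator

`simulate_pair()` draws per-region abundances log10-normally (default mean
2, sd 1, so counts span roughly 1–10⁴), applies a global true log2 factor
to the reference sample, and generates negative binomial counts (default
dispersion 10) at a chosen depth multiplier. Optional contamination gives
a chosen fraction of regions an extra region-specific log2 effect in the
reference sample, emulating a perturbation that reaches "invariant"
regions. `simulate_depth_series()` reuses the same abundances and
contamination across depths so sequencing depth is the only varying
factor.

One comparison in the test suite needs a sharper instrument than
symmetric contamination: the claim that raw-scale least squares is
vulnerable to extreme values where the Bayesian estimate is not. Symmetric
region-level contamination moves the least-squares slope in a direction
set by the sign of the effect that happens to land on the highest-leverage
region, so it produces no systematic contrast. The suite therefore injects
one-sided, pileup-style outliers (counts multiplied 4–16×) into the most
abundant reference regions — precisely the leverage points of a raw-scale
regression, and the kind of artifact (termination pileups, repeats) that
produces one-sided count spikes in practice.

The generator reproduces the statistical shape that matters for the model
— orders-of-magnitude abundance spread, overdispersion, depth, and
violated-invariance contamination. It does not emulate positional
structure (no read-level simulation for the model path), mappability,
GC or length biases, annotation errors, or correlated contamination
across regions. Passing recovery tests on these simulations therefore
demonstrates correctness of the inference under the model's own
assumptions and robustness to region-level contamination; it does not
certify performance on data whose biases are structured in ways the
generator does not produce.

Test problem sizes were chosen to exercise each claim at the smallest
scale where the expected effect is unambiguous: 1000 regions for recovery
(about the size of a real 3' invariant set), 10 seeds for ordering claims,
and reduced MCMC sizes (2000 draws after 500 burn-in) for fits inside the
test suite.

## Downstream differential-expression machinery

Size factors follow the median-of-ratios formula: each sample's factor is
the median over genes of its count divided by the gene's geometric mean
across samples, computed over genes nonzero in every sample. The
implementation matches the reference implementation in DESeq2 to machine
precision and is cross-checked against it in the test suite.

The bundled differential-expression test is deliberately simple: per-gene
negative binomial regression on the condition label with log size factors
as offsets and a Wald z-test. One methodological choice was forced by
measurement: with two replicates per condition, per-gene dispersion
estimates (method of moments, 2 residual degrees of freedom) are so noisy
that the test is either badly anticonservative (normal reference,
~17–20% of null genes at p < 0.05) or powerless (t reference with 2 df
cannot reject anything after multiplicity correction). The package
therefore estimates a single common overdispersion — the average of
per-gene method-of-moments values over reasonably expressed genes — and
uses it for every gene, which measured calibrated (4–6% of null genes at
p < 0.05) while retaining power for strong effects. Per-gene dispersion
heterogeneity is not modeled; this is a stand-in for a full DE framework,
not a replacement for one.

`reproducibility_resampling()` repeats the DE analysis while drawing each
non-reference sample's log2 factor from Normal(`mu_mean`, `mu_sd`) — the
fitted posterior summary — converting draws to size factors ($2^{-f}$,
reference fixed at 1, set rescaled to geometric mean 1), and reports the
fraction of iterations in which each gene is called significant. Genes
whose calls flip across plausible normalization factors are candidate
false positives of the point-estimate analysis.

## Numerical choices and degenerate inputs

Zero-count regions are retained everywhere; the pseudocount keeps the
prior anchor finite, and the latent-abundance prior (empirical:
$m_0, s_0$ from the pooled log counts, with the sd widened 2×) keeps
all-zero regions proper. Isoform selection breaks count ties by longer
transcript, then lexicographically smaller identifier. Genes too short
for the elongation threshold are silently dropped with a logged count.
OLS on raw counts with a non-positive fitted slope is reported as an
estimator failure (the log2 factor is undefined) rather than patched —
one of the situations that motivates the Bayesian estimate. All-zero
genes are excluded from DE and listed in an attribute. Every stochastic
entry point takes an explicit seed; an unseeded fit draws and logs one.

## Known limitations

- The model is pairwise against one reference sample; there is no joint
  multi-sample model, so per-sample posteriors ignore correlations induced
  by the shared reference.
- `sigma_fit` and the reference-sample overdispersion are only weakly
  separable; treat `sigma_fit` as a robustness device, not an estimand.
- The 3' invariant-region logic assumes annotation accuracy, a known and
  roughly constant elongation rate, and no same-strand transcription
  (e.g., intronic bidirectionals) inside the selected windows.
- The DE stand-in uses a common dispersion and no shrinkage of fold
  changes; with more than a handful of replicates a dedicated DE package
  is the right tool.
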