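---
title: "Testing differential transcript usage on RTA-divided counts"
author: "divSplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential transcript usage on RTA-divided counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divSplice)
```

# Scope and model

divSplice tests differential transcript usage (DTU): whether the relative
abundances of a gene's isoforms change between experimental conditions.
The inputs are transcript-level quantifications from a lightweight
quantifier together with technical resamples (bootstrap or Gibbs re-draws
of the quantification), a transcript-to-gene catalog, and a design matrix.

The statistical backbone has three layers.

**1. Divided counts.** Reads compatible with several overlapping
transcripts are assigned probabilistically, which inflates the technical
variance of an estimated count $y_{gti}$ by a transcript-specific
quasi-Poisson factor $\tau_{gt} \ge 1$ (read-to-transcript ambiguity,
RTA). We estimate $\tau_{gt}$ from the resamples by a pooled Pearson
statistic: over samples $i$ whose resample mean $\bar y_{ti}$ is positive,
$$D_t = \sum_i \sum_b (y_{tib} - \bar y_{ti})^2 / \bar y_{ti}, \qquad
  r_t = \sum_i (B - 1),$$
and moderate the raw ratio toward 1 with `priorDF` pseudo-observations,
flooring at 1:
$\hat\tau_t = \max\{1, (D_t + \mathrm{priorDF}) / (r_t + \mathrm{priorDF})\}$.
The divided counts $z_{gti} = y_{gti}/\hat\tau_{gt}$ then behave
approximately as negative binomial counts and enter every downstream step
as if they were ordinary read counts. Moderation toward 1 encodes that
unambiguous transcripts carry no RTA overdispersion; the floor guarantees
that division never inflates a count. `priorDF = 3` is deliberately weak —
with the typical $B = 100$ resamples the data contribute hundreds of df per
transcript and the prior matters only for barely-expressed transcripts.
Samples whose resample mean is zero contribute neither to $D_t$ nor to
$r_t$ (the Pearson term is undefined there); transcripts with no usable
samples sit at the floor.

**2. Transcript-wise models.** After filtering (`filterByExpr` rule,
delegated to edgeR, with defaults `min.count = 10`,
`min.total.count = 15`, or the lenient `1`/`5` variant) and TMM
normalization (trim fractions 0.30/0.05, factors rescaled to geometric
mean 1), each transcript is fit with one of two backends sharing a common
result contract (coefficients $\hat\beta_{gtj}$, unscaled variances
$v_{gt}$, residual variance or mean deviance $s^2_{gt}$, adjusted residual
df $d_{gt}$):

* the **lm** backend models $\log_2$ counts-per-million
  ($\log_2((z + 0.5)/(\mathrm{efflib} + 1) \times 10^6)$) by weighted
  least squares. Precision weights follow the classic mean-variance-trend
  recipe: a lowess (span 0.5) of $\sqrt{s_t}$ on mean log-CPM, observation
  weight = predicted$^{-4}$ at the observation's fitted log-CPM, clipped
  to $[10^{-6}, 10^6]$; one trend pass, one refit, no iteration. The
  residual df are reduced by $m_k - 1$ for every treatment group of size
  $m_k$ whose counts are all zero — those residuals are structurally zero
  and would otherwise fake precision.
* the **nbglm** backend fits log-link negative binomial GLMs with log
  effective library sizes as offsets, a single global dispersion $\phi$,
  IRLS with step halving (max 50 iterations, relative deviance tolerance
  $10^{-8}$). The residual df adjustment is continuous: observation $i$
  contributes $1 - P(Y = 0 \mid \mu_i, \phi)$ df, so tiny-but-positive
  fitted values also lose df; $s^2_{gt}$ is the residual deviance divided
  by this adjusted df. $\phi$ is estimated by maximizing the summed NB
  profile log-likelihood with means held at their fitted values, minus
  half the log-determinant of each transcript's expected information — the
  Cox–Reid-style penalty that removes the downward bias from estimating
  $p$ coefficients per transcript (without it the estimate shrinks by
  roughly $(n-p)/n$). Transcripts with mean count below 1 are excluded
  from this objective, and the search is golden-section over
  $[10^{-6}, 10]$.

**3. Gene-level DTU tests.** For a chosen coefficient, write
$u_{gt} = 1/v_{gt}$, consensus
$\hat\beta_g = \sum_t u_{gt}\hat\beta_{gt} / u_g$ and leverage
$h_{gt} = u_{gt}/u_g$. Genewise pooled variances
$s^2_g = \sum_t d_{gt} s^2_{gt} / d_g$ with $d_g = \sum_t d_{gt}$ are
squeezed by unequal-df empirical Bayes under the scaled-F model
$s^2_g \sim s_0^2 F(d_g, d_0)$, with hyperparameters by moment matching on
$e_g = \log s^2_g - \psi(d_g/2) + \log(d_g/2)$ and trigamma inversion by
Newton (initialized at $0.5 + 1/x$; $d_0$ above $10^7$ is treated as
infinite, in which case $s_0^2$ is the mean of the pooled variances). The
lm backend then uses the moderated statistics
$$\tilde t_{gt} = \frac{(\hat\beta_{gt} - \hat\beta_g)/\sqrt{1 - h_{gt}}}
  {\tilde s_g \sqrt{v_{gt}}}, \qquad
  \tilde F_g = \frac{1}{T_g - 1}\sum_t (1 - h_{gt})\,\tilde t^2_{gt},$$
on $d_{0g} + d_g$ denominator df. The nbglm backend uses quasi-F
statistics from deviance differences: the gene statistic contrasts the
full fit with a null fit constraining the coefficient to one shared value
across the gene's transcripts,
$F_g = \Delta D_g / ((T_g - 1)\tilde s^2_g)$; the transcript statistic
contrasts the all-equal null with a one-removed null that frees only the
transcript of interest, $F_{gt} = \Delta D_{gt}/\tilde s^2_g$ on
$(1, d_{0g} + d_g)$ df, signed into a t-statistic by
$\mathrm{sign}(\hat\beta_{gt} - \hat\beta_g)$. Gene-level Simes p-values
aggregate the transcript p-values; F-based and Simes-based gene p-values
are BH-adjusted separately across genes, transcript p-values
transcriptome-wide. For two-transcript genes the F and Simes p-values are
identical, as are the gene- and transcript-level quasi-F tests.

# Design choices that were genuinely open

*Shared-coefficient null fits.* The null hypothesis fixes one coefficient
to a common value across a gene's transcripts; the hypotheses do not
dictate an optimizer. We keep the fits transcript-separable: each round
refits every transcript's free coefficients with the shared value absorbed
into the offset, then moves the shared value by a damped (0.8) pooled
Fisher-scoring step, to $10^{-6}$ tolerance. This is testable
transcript-by-transcript and converges in a handful of rounds. For genes
with more than 10 transcripts the transcript-level deviance difference is
replaced by the fast approximation that contrasts each transcript's
constrained and unconstrained deviances directly; with one transcript
removed from a two-transcript gene the "shared value over the others" is a
single unconstrained fit, so the exact path reduces to the gene test, which
we exploit as a shortcut.

*Consensus precision weights.* The precision $u_{gt}$ entering the
consensus coefficient for the nbglm backend is the inverse unscaled
variance at IRLS convergence (inverse expected information). Working
weights at intermediate iterates would be an alternative; at convergence
the two coincide for the tested coefficient.

*Transcript-level BH scope.* Transcript p-values are adjusted
transcriptome-wide, not within genes — the discovery unit a user acts on is
a transcript list, and transcriptome-wide adjustment is what the ranked
tables report.

*Robustness.* The empirical Bayes moment matching offers a `winsorize`
flag (e at its 5%/95% quantiles) as light outlier protection, default off.

*Coefficient scale.* The nbglm backend stores coefficients on the natural
log scale (the GLM's native scale) and reports log2 in all result tables;
the lm backend is log2 throughout.

# The simulator

`simulateDTUDataset()` generates data at the count level, emulating RTA
explicitly rather than simulating reads:

* genes carry 1–10 transcripts (zero-truncated geometric, mean ≈ 3.3);
  baseline expected TPMs are log-normal (meanlog 1.5, sdlog 2, a
  heavy-tailed stand-in for observed abundance distributions) normalized
  to 1e6; effective lengths are log-uniform on [300, 10000] nt;
* transcript dispersions (squared BCV) follow a scaled inverse
  chi-squared law, $\nu s_0^2/\phi_t \sim \chi^2_\nu$ with prior BCV 0.25
  and $\nu = 40$ — the biological variability typical of genetically
  identical laboratory mice;
* differential genes split three ways: DTU-only genes have two
  transcripts set to baselines $(a, 2a)$ preserving their combined mass
  and swapped in group B (each changes exactly two-fold, the gene total is
  conserved, and only those two transcripts count as differentially used);
  DGE+DTU genes scale one transcript two-fold (all transcripts count as
  differentially used, since the others' proportions must shift);
  DGE-only genes scale every transcript by the same factor (none count);
  up/down directions are balanced;
* per sample, true TPMs are gamma with squared CV $\phi_t$; expected
  reads allocate the library size proportionally to TPM × effective
  length; counts are $\tau_t \,\mathrm{Poisson}(\mu/\tau_t)$ (variance
  $\tau\mu$), and each of the B resamples re-draws
  $\tau_t\,\mathrm{Poisson}(y/\tau_t)$ around the observed count. True
  $\tau_t$ is 1 with probability 0.5, else $1 + \mathrm{Exp(mean\ 1.5)}$.
  Counts stay fractional, as quantifier estimates are.

The default configuration is desk-scale: 3000 genes with the differential
split scaled proportionally from the full design (12715 genes, 4500
differential split 1500/1500/1500, available via `fullScaleConfig()`),
five samples per group, library size $10^6$, $B = 100$. Library sizes
alternate between the two configured values across samples (the full-scale
design uses 25 and 100 million). These sizes keep a full
simulate-fit-test cycle at a few tens of seconds while leaving hundreds of
multi-transcript genes in every truth category.

What the simulator does *not* emulate: real RTA arises from annotation
topology, so true $\tau$ correlates with transcript overlap structure —
here it is drawn independently; quantifier resamples are correlated draws
from a posterior, not independent Poisson re-draws; baseline abundances
come from a parametric law rather than an empirical reference; and there
is no read-level machinery (fragment bias, mapping error). Passing tests
therefore demonstrate calibration and recovery under the model's own
assumptions, plus robustness of the pipeline plumbing — not performance on
any particular real dataset.

# Numerical notes

Degenerate cases are handled explicitly: all-zero transcripts get clamped
GLM coefficients ($\eta = -745$ on the natural-log scale) with zero
deviance and zero adjusted df; transcripts with non-positive unscaled
variance are excluded from their gene's test, and genes reduced below two
usable transcripts are dropped; single-transcript genes are never tested.
$\phi < 10^{-10}$ switches every NB formula to its Poisson limit. Ranked
tables break p-value ties deterministically by feature id. With fewer
than 10 transcripts the weight trend is unidentifiable and unit weights
are used, with a warning.

# Limitations

Single global $\phi$ (no trend on abundance); no sample quality weights or
random-effect blocks; two-sided tests only; the RTA estimator is a
moderated Pearson statistic, not a likelihood fit to the resample
distribution. Calibration at very small counts relies on the continuous df
adjustment, which is a first-order device; the lenient filtering preset
trades a higher FDR among the extra discoveries for added power, and the
`winsorize` flag is available when variance outliers distort the prior.
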