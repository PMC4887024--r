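---
title: "Spectral-count differential expression with Phenotypic Impact Factors"
author: "pifomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count differential expression with Phenotypic Impact Factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pifomics)
```

## The problem

Label-free shotgun proteomics quantifies each protein by its spectral
count — the number of MS/MS spectra assigned to it — across a handful of
biological replicates per condition. A typical two-group muscle study
yields ~1800 proteins over 4 + 4 samples, with a heavily right-skewed
abundance distribution (a few structural and glycolytic proteins dominate
the spectra) and many zeros at the low-abundance end where proteins sit at
the detection limit. `pifomics` implements a complete analysis for this
design: normalization, a moderated-t differential expression (DE) test,
abundance-weighted ranking by the Phenotypic Impact Factor (PIF),
compartment-proteome skew testing, two-way clustering, set enrichment and
upstream-regulator activation scoring.

## The model and its stages

**Normalization.** Sample $s$'s counts are scaled by
$\bar T / T_s$, where $T_s$ is the sample total and $\bar T$ the grand
mean of totals, so all samples end with equal totals. Any common choice of
target total would shift every log abundance by the same constant, leaving
group differences unchanged; the grand mean keeps the data on its original
scale. The operation is idempotent and a zero-total sample is an error.

**MA representation.** Each normalized value $x$ becomes
$\log_2(x + c)$ with pseudo-count $c = 0.05$ so zeros stay finite. Group
means $\bar h_i$, $\bar l_i$ give $M_i = \bar h_i - \bar l_i$ (high minus
low, always) and $A_i^{raw} = (\bar h_i + \bar l_i)/2$. Abundances are
"justified" as $A_i = A_i^{raw} + 4$, which makes the abundance weight
positive for essentially every observed protein; an all-zero protein would
sit at $\log_2 0.05 + 4 \approx -0.32$, which is why justified A can still
be negative below the pseudo-count scale. The pseudo-count is added after
normalization because the MA plot is built from normalized abundances.
$A^{raw}$ averages the two group means, not the eight samples; with equal
group sizes the two coincide.

**Moderated t.** With $n = 4$ per group, per-protein variances are too
unstable for ordinary t-tests. Writing $s_g^2$ for the pooled within-group
variance on the log2 scale (residual df $d_g = n_h + n_l - 2$), the
empirical-Bayes model treats the true variances as draws from a scaled
inverse chi-square prior with hyperparameters $(d_0, s_0^2)$, estimated by
moments of $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$: $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)$ by monotone root-finding,
and $s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. When
$\mathrm{var}(e) \le \psi'(d_g/2)$ the observed variances are no more
dispersed than sampling noise alone, $d_0 = \infty$, and the common
variance is estimated by the plain mean of the $s_g^2$ (the log-scale bias
correction no longer applies at that boundary). The moderated variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ is a convex
combination of the protein's own variance and the prior;
$t_g = M_g / \sqrt{\tilde s_g^2 (1/n_h + 1/n_l)}$ is referred to a
Student-t with $d_0 + d_g$ df (normal when infinite). At $d_0 = 0$ this is
exactly the pooled two-sample t-test, a limit the test suite checks
against `t.test()`; on full datasets the p-values agree with limma's
`eBayes` to 10 decimal places.

**Fold change and DE filter.** The signed fold is
$r = (\bar h + c)/(\bar l + c)$ on the normalized count scale, reported as
$r$ if $r \ge 1$ and $-1/r$ otherwise, so magnitudes are always $\ge 1$
and the pseudo-count keeps one-group-absent proteins finite. The DE set
keeps proteins with $1.3 \le |fold| \le 15$ (both boundaries inclusive)
and raw $p < 0.05$; no multiplicity correction is applied at this stage,
matching the downstream use of the DE set as input to enrichment and
regulator scoring rather than as a stand-alone discovery list.

**PIF.** $PIF_i = A_i \times M_i$ with the justified A, de-emphasizing
low-abundance proteins whose M estimates are noisiest. The extreme tails
take the `round(0.05 * N)` most positive and most negative PIF values
(half away from zero: $0.05 \times 1817 = 90.85 \to 91$ per tail, 182
total), with boundary ties broken by larger $|M|$ then protein id so
selection is deterministic. The justified (not raw) A is the default
weight because justification is applied expressly before PIF is formed;
raw-A weighting remains available via `use_justified = FALSE`. The
"liberal nominal p" sometimes quoted for such tails is descriptive — no
p-value gate is applied to tail membership.

**Compartment skew.** A user-supplied symbol list (e.g. a mitoproteome
download) is matched case-insensitively after trimming; the matched
proteins' M signs are tested against a 50:50 Binomial null with the exact
two-sided p obtained by doubling the smaller tail (capped at 1). Ties
($M = 0$) carry no direction and are excluded but reported — continuous
abundances make them measure-zero, integer toy fixtures do not. The
minimum-likelihood two-sided convention of `binom.test()` is available via
`method = "minlik"`.

**Clustering.** The top 40 PIF proteins (20 per direction) are
row-standardized (mean 0, sd 1; constant rows dropped) and clustered on
rows and columns with Euclidean distance and average linkage. Neither
distance nor linkage is canonical for this analysis — heat-map tools offer
several — so both are arguments; exact dendrogram reproduction of any
particular published figure is not claimed. The two-cluster sample
partition is read from the final merge of the column tree and its purity
is the best-mapping agreement with the known groups. Optimal leaf ordering
(seriation) is omitted; the leaf order is `hclust`'s deterministic
recursive order.

**Enrichment and regulators.** Tail lists are tested per term with the
upper hypergeometric tail $P[X \ge k]$ against the full quantified
proteome as background, with Benjamini–Hochberg q-values over tested
terms. For upstream regulators, each known target that is in the DE set
and has a known expected regulation direction contributes
$\text{direction} \times \text{observed sign}$; the activation z-score is
$(n_{act} - n_{inh})/\sqrt{N}$, so $|z| = \sqrt N$ exactly when all
informative targets agree ($\sqrt{15} \approx 3.873$, $\sqrt 4 = 2$).
Edges are unweighted — commercial implementations apply proprietary
literature weights, which is why some published z-scores for mixed-sign
regulators cannot be reproduced from target counts alone. A call requires
a Fisher overlap $p < 0.05$; $|z| > 2$ gives activated/inhibited, and
qualified strong/moderate/weak bands at 1.7/1.5/1.0 carry the sign.
$|z| = 2$ exactly is a qualified strong call, not activation ("greater
than" is strict).

## The synthetic-data generator

Raw spectral counts for studies of this kind are rarely publicly
deposited, so the package ships a generator that emulates the data structure with
known ground truth: baseline mean abundances are lognormal
(`meanlog = 2.5`, `sdlog = 1.5` on the natural-log scale — median count
~12, a heavy right tail reaching thousands of counts for the dominant
proteins, and ~5% of proteins with near-zero abundance producing many
zero counts); counts are negative binomial with variance
$\mu + \phi\mu^2$, $\phi = 0.3$, a typical between-bird overdispersion;
8% of proteins carry a planted log2 effect (half-normal with sd 1.5, or a
fixed magnitude via `effect_size`) applied multiplicatively to the high
group only; a 228-protein compartment has planted effects positive with
probability 0.75 (a 3:1 up-bias of the kind seen for mitochondrial
proteins in feed-efficiency muscle); and `simulate_regulator_network()` plants regulator-target
edges whose expected directions agree with a chosen regulator state for a
controllable fraction of edges. One master seed drives per-stage
sub-streams, so identical configurations are bit-identical.

The generator emulates counts, skew and network consistency — it does not
simulate peptide-to-protein inference, shared peptides, gel-slice
structure, or missingness mechanisms beyond sampling zeros. Passing tests
on synthetic data therefore demonstrate the statistical machinery, not
robustness to those real-data artifacts.

## Numerical choices and degenerate inputs

* All-zero proteins are dropped (with a logged count) before fitting;
  zero-total samples, empty groups and duplicate ids are errors.
* `pseudo_count = 0` is rejected whenever a zero count is present.
* Zero pooled variances are excluded from the prior fit (they carry no
  log-scale information); a zero moderated variance with nonzero M yields
  the sentinel $p = 0$ with a warning.
* Tail fractions at or above 0.5 are rejected (tails would overlap), and
  odd `top_k` is rejected.
* Rounding of tail sizes is half-away-from-zero, not banker's rounding.
* All table writers use fixed column order and '.' decimals; a fixed seed
  makes full pipeline runs byte-identical.

## Calibration on the generator's null

Under the generator's null (no planted effects, 2000 proteins) the
moderated t rejects at rate $\approx 0.040$ at nominal $\alpha = 0.05$ —
measured over 20 replicate datasets in the test suite, and numerically
identical to limma's `eBayes` on the same matrices. The slight
conservatism is intrinsic to log-transformed zero-inflated counts: rows
containing zeros acquire enormous log-scale variances and essentially
never reject, diluting the rejection rate. It is a property of the
method on this kind of data, not of this implementation.

## Problem sizes used in the tests

Simulation-based tests use 150–2000 proteins and the 4 + 4 design;
calibration uses 20 replicates of 2000 null proteins, prior recovery 5000
variance draws, and clustering purity 10 seeds of 400-protein datasets.
These sizes give Monte-Carlo errors comfortably below the asserted
tolerances while keeping the suite fast.

## A worked run

```{r example}
sim <- simulate_counts(sim_config(seed = 42))
fit <- pif_fit(sim$counts)
summary(fit)

comp <- sim$truth$protein[sim$truth$compartment]
mito_skew_report(fit$ma, comp, fit$tails)
```

```{r plot, fig.width = 6, fig.height = 5}
plot(fit, compartment = comp)
```

## Known limitations

* Symbol matching is exact (case-insensitive, trimmed); no alias or
  orthology resolution, so annotation lists must use the dataset's
  nomenclature.
* The regulator score treats every edge equally; curated edge weights and
  mixed activation/repression evidence are out of scope.
* The DE filter uses raw p-values by design; `bh_adjust()` is available
  if FDR control over the DE table itself is wanted.
* Exactly two groups, "high" and "low"; multi-group or continuous designs
  need a different linear-model layer.
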