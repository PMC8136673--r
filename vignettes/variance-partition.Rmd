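---
title: "Partitioning genotypic values and genetic variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning genotypic values and genetic variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantvar)
```

## The models

quantvar implements Fisher's analysis-of-variance view of gene action, in
Falconer's notation, for one and two biallelic loci in a random-mating
population.

**Single locus.** Alleles A1 (frequency $p$) and A2 segregate with
Hardy–Weinberg genotype frequencies $(1-p)^2$, $2p(1-p)$, $p^2$. The
genotypes A2A2, A1A2, A1A1 — allelic dosages $x = 0, 1, 2$ — are assigned
genotypic values $-a$, $d$, $a$. The parameter $a$ (trait units) is half the
homozygote difference; $d$ is the dominance deviation of the heterozygote
($d = 0$: pure additivity; $d = a$: complete dominance; $|d| > |a|$:
overdominance). The population mean is $M = (2p-1)a + 2p(1-p)d$. The
frequency-weighted least-squares regression of genotypic value on dosage has
slope

$$\alpha = a + (1 - 2p)\,d,$$

the *average effect of allele substitution*. Its fitted deviations are the
breeding values $\alpha(x - 2p)$ and its residuals the dominance deviations,
giving the orthogonal partition
$V_G = V_A + V_D$ with $V_A = 2p(1-p)\alpha^2 = H\alpha^2$ and
$V_D = (2p(1-p)d)^2 = H^2 d^2$, where $H$ is the heterozygosity. Because
$V_D$ carries $H^2$ against $V_A$'s $H$, dominance variance needs
intermediate frequencies, and $V_A/V_G \to 1$ as $p \to 0$ even under
complete dominance — `frequency_surface()` traces this.

**Two loci, additive × additive.** A second unlinked locus B (allele B1 at
frequency $q$) with no dominance at either locus and interaction effect
$a_{AB}$ gives genotypic values
$a_A(i-1) + a_B(j-1) + a_{AB}(i-1)(j-1)$ at dosage pair $(i, j)$. The
average effects absorb the epistatic effect through the *other* locus's
frequency, $\alpha_A = a_A + (2q-1)a_{AB}$,
$\alpha_B = a_B + (2p-1)a_{AB}$, and
$V_G = V_A + V_{AA}$ with $V_A = H_A\alpha_A^2 + H_B\alpha_B^2$ and
$V_{AA} = H_A H_B a_{AB}^2$.

**General two-locus table.** Any 3×3 table of genotypic values is
partitioned into five components,

$$V_G = V_A + V_D + V_{AA} + V_{AD} + V_{DD},$$

by weighted least squares: project the nine values onto eight per-genotype
contrast scores under the HWE × linkage-equilibrium genotype-frequency
weights.

## The contrast coding, and why the partition is unique

The least-squares machinery needs explicit scores; we use:

* **additive** score at a locus: the centered dosage $x - 2p$, whose
  weighted variance is $H = 2p(1-p)$;
* **dominance** score: the heterozygote indicator orthogonalized (weighted
  Gram–Schmidt) against the intercept and the additive score;
* **interaction** scores: the four products of single-locus scores.

Under HWE and linkage equilibrium every pair of these eight scores is
weighted-orthogonal, so the projection does not depend on fitting order and
the components sum exactly to the direct frequency-weighted variance of the
table. Any other orthogonal coding of the same eight one-degree-of-freedom
contrasts (e.g. the statistical NOIA parameterization) spans the same
subspaces locus by locus and must produce identical components; the test
suite asserts agreement between the closed forms, this projection, and an
independent `lm()`-based fit. With the duplicate-factor table ($c = 4$,
$p = q = 0.5$) the partition is
$0.9375 = 0.25 + 0.125 + 0.25 + 0.25 + 0.0625$, and with the complementary
table $3.9375 = 2.25 + 1.125 + 0.25 + 0.25 + 0.0625$ — at two decimals the
familiar $0.94$ and $3.94$ totals with $V_A/V_G = 0.27$ and $0.57$.

## Numerical choices

* **Degenerate designs.** Boundary frequencies $p, q \in \{0, 1\}$ are legal
  inputs, not errors: a monomorphic locus has zero-variance scores, its
  predictors are dropped (score variance below $10^{-12}$), and every
  component involving it is reported as exactly 0. That matches the biology —
  a fixed locus generates no variance.
* **$V_A/V_G$ at $V_G = 0$** is reported as `NA`, never as $0/0$ or 0.
* **Display rounding.** All inter-module arithmetic is full double
  precision. Rounding happens only at the output layer (TSV writers, print
  methods), to 2 decimals by default, with `round_half_up()` — half away
  from zero, the convention of printed tables — rather than R's half-to-even
  `round()`. Exact halves such as $V_D = 0.125$ therefore display as 0.13.
* **Tolerances.** Conservation ($\sum$ components $= V_G$) and closed-form
  agreement are asserted at relative $10^{-9}$; orthogonality and
  zero-weighted-mean invariants at $10^{-12}$.
* **Frequency surfaces** default to 99 grid points per axis from 0.01 to
  0.99 (configurable, boundaries allowed); two-locus families can sweep the
  full $p \times q$ grid or the diagonal $p = q$.

## The simulator: what it emulates, and what it does not

`sample_population()` draws each individual's dosage independently per locus
as Binomial(2, allele frequency) — panmixia, HWE, linkage equilibrium — and
adds i.i.d. Gaussian environmental noise with variance $V_e$. A single
integer seed controls all draws. `gwas_regression()` is then ordinary least
squares of phenotype on dosage, exactly the single-variant GWAS model
$y = \mu + \beta x + e$; its slope estimates $\alpha$, dominance and
epistatic contributions included. `empirical_components()` rebuilds the
contrast scores from *sample* allele frequencies and orthogonalizes them
in-sample (fixed order: additive A, additive B, dominance A, dominance B,
then products), mirroring what one does with real data; the discrepancy from
the true-frequency scores vanishes asymptotically, and in-sample
orthogonality makes the empirical components sum to the variance explained
by the saturated genotype-class model.

The generator deliberately omits features of real data: linkage
disequilibrium, population structure and relatedness, non-Gaussian or
binary (liability-scale) phenotypes, genotyping error, and ascertainment.
Passing tests therefore demonstrate the estimators' behaviour under the
idealized random-mating model these formulas assume, not robustness to those
complications.

Stochastic checks use populations of $n = 10^5$ (20 replicate seeds for the
recovery of $\alpha = 7.2$ under $a = d = 4$, $p = 0.1$, $V_e = 10$), with
consistency probed at $n \in \{10^3, 10^4, 10^5\}$ and empirical component
convergence at $n = 2 \times 10^5$ noise-free individuals; these sizes put
binomial sampling error well below the asserted 3-standard-error and 5%
bounds.

## Design choices where the design was open

* Dosage always counts the A1 (resp. B1) allele; relabeling alleles flips
  the sign of $\alpha$ but, as a test asserts, leaves every variance
  component unchanged, so the fixed convention loses nothing.
* Model parameters accept any finite real; no slider-style ranges are
  imposed.
* Within-background regressions weight by the conditional locus-A HWE
  frequencies — equivalent under linkage equilibrium to renormalized joint
  frequencies; marginal genotype means average over the other locus with its
  HWE weights.
* The config-driven runner (`run_quantvar()`, `inst/cli/quantvar.R`) writes
  a manifest echoing the resolved configuration so that any run re-executes
  byte-identically from its own output.

## Known limitations

Two loci at most (no third-order interaction components); variance
components are computed from model parameters or simulated individuals, not
estimated from real pedigree/genomic data (no REML or Haseman–Elston, no
standard errors on components); no linkage disequilibrium or inbreeding;
continuous traits only.

## A worked partition

```{r example}
m <- duplicate_factor(c = 4, p = 0.5, q = 0.5)
decompose_variance(m)
glance(decompose_variance(m))
```
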