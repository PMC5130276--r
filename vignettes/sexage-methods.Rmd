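---
title: "Methods: discovery-validation analysis of sex- and age-associated expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovery-validation analysis of sex- and age-associated expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sex and age shape lung physiology, yet both are easy to mishandle in
expression studies: sex effects mix true regulatory differences with the
trivial consequences of sex-chromosome dosage, and age effects are small
per-year slopes that demand large cohorts and honest multiple-testing
control. `sexage` implements a complete discovery-validation workflow for
this setting — one discovery cohort scanned genome-wide, several
independent cohorts used to replicate candidates under a
concordant-direction rule — together with a synthetic-data generator that
plants known effects, so every stage of the pipeline is testable without
access to any clinical dataset.

# The generative model behind the simulator

For sample $i$ and gene $g$ the simulator draws log2 intensity

$$ y_{ig} = \beta_{0g} + \beta_{sex,g}\,[\text{male}_i]
          + \beta_{age,g}\,\text{age}_i + \beta_{smk,g(s_i)}
          + \gamma_{b(i)g} + \varepsilon_{ig},
   \qquad \varepsilon_{ig} \sim N\!\left(0, (\sigma_g\,\delta_{b(i)g})^2\right) $$

with additive batch locations $\gamma$ and multiplicative batch scale
factors $\delta$ — exactly the location-scale model that empirical-Bayes
batch adjustment assumes. Two departures from the linear model are
deliberate:

* **Y-linked genes.** Females do not carry them, so their female values
  are drawn from a dedicated background-intensity Gaussian (configurable
  mean and SD, default mean 6, independent of age and smoking), not from
  the linear model. A planted "48.9-fold male-biased" Y gene therefore
  means: male mean = female background mean + log2(48.9), which is how a
  microarray actually sees such a gene.
* **Detection p-values.** Each probe has an `expressed_fraction` $f$; a
  sample-probe pair is detectable with probability $f$, in which case its
  detection p-value is drawn U(0, 0.01), otherwise U(0.01, 1). The split
  at the conventional 0.01 detection cutoff makes the expected detected
  fraction exactly $f$, which the tests verify at binomial tolerance.

Extra probes of a gene share its effects but carry independent noise, and
their detection fractions decay geometrically (factor 0.9), so the
"keep the probe with the highest detection rate" collapse rule has a
well-defined expected winner.

## Default study conditions

The built-in cohort designs emulate a realistic multi-centre lung study:
a discovery series of 284 samples (202 males, 82 females; ages uniform on
36–85 and 40–83 years respectively; all but one sample from smokers;
processed in two batches of 206 and 78) and three validation series of
409, 339 and 363 samples with roughly balanced sex, wider age ranges and
mixed current/former/never/unknown smoking status.
`default_truth_from_tables()` plants the package's reference catalogs —
25 validated sex-associated genes (17 X-linked, one Y-linked, two
pseudoautosomal, five autosomal; fold changes from 1.08 to 48.9) and 22
autosomal age-associated genes (per-year slopes from 0.003 to 0.029 log2
units) — among a configurable number of null background genes, 11,042 by
default usage for a genome of 11,089.

Choices the designs leave open were fixed once, on field-typical grounds:

* **Ages are uniform** over each per-sex range. Only ranges and medians
  of real cohorts are ever published; uniform matches the range exactly
  and keeps the design spread wide, which is conservative for slope
  estimation. It is a stand-in, not an inference about any real cohort.
* **Planted-gene residual SD defaults to 0.2** (log2 scale). Typical
  array noise for well-expressed transcripts; it is also the regime in
  which effects of fold 1.08 at $n = 284$ are genome-wide significant,
  consistent with such genes being discoverable at all.
* **Background gene baselines** are N(8, 1.5), residual SDs U(0.1, 0.5),
  detection fractions U(0.05, 1); smoking effects default to zero.
* **Sex coding** is female = 0, male = 1 everywhere, so positive
  coefficients mean male-higher and the signed fold change is $2^\beta$
  for $\beta \ge 0$ and $-2^{-\beta}$ otherwise.

What the generator does *not* emulate: bead-level raw data, platform
probe chemistry, gene–gene correlation networks, or heavy-tailed noise.
Passing tests therefore certify the pipeline's statistics under an
idealized independent-Gaussian world; on real data, correlation between
genes mainly widens the permutation null (the study this design emulates
saw *more* zero-discovery permutations than independence predicts, not
fewer).

# Preprocessing

Probes are removed when unannotated or detected (p < 0.01) in fewer than
10% of samples; the boundary case — detected in exactly 10% — is kept,
reading "fewer than 10%" literally. Collapse to genes keeps the probe
with the highest detection rate, ties broken by the lexicographically
smallest probe identifier so reruns are byte-identical.

Normalization is plain quantile normalization (`limma::normalizeQuantiles`
with tie averaging): every sample's distribution becomes the mean
order-statistic distribution; it is idempotent, and a single sample
passes through unchanged. One consequence worth knowing: a gene pinned to
the same extreme rank in every sample (e.g. the overall minimum) is
mapped to a constant and loses its variance. With realistic baseline
spread this is immaterial, but synthetic data in which all genes share
one baseline can hit it; the bundled fixtures therefore draw spread
baselines.

Batch adjustment is the parametric empirical-Bayes location-scale method
(via `sva::ComBat`): gene-wise standardization, moment-matched
normal/inverse-gamma hyperpriors across genes, iterative shrinkage of the
per-batch location and scale parameters, and back-transformation. The
default protects **no** biological covariates, matching the common
practice of combining processing batches of a single cohort before any
modeling. Tests quantify the cost of that default: when the covariate of
interest is imbalanced across batches by chance, a small part of its
effect is absorbed into the batch means (recovery error grows by roughly
40% of the sampling error in our harshest scenario, location shift 1.5
and scale 1.5); passing the covariate through the `covariates` hook makes
recovery near-oracle (within ~20%). Batches always come from an explicit
sample-sheet column, never from inference.

# Association, permutation, validation

Each gene is fit by ordinary least squares on an intercept, the variable
of interest (sex as 0/1, age in years), and any covariates; the t
statistic uses the classical residual-variance estimate (no variance
moderation — the single-gene model is the estimand, and moderation would
change the replication semantics), and p-values are corrected by
Benjamini-Hochberg across whatever family is being tested: genome-wide in
discovery, candidate-set-wide in validation. Smoking enters as indicator
columns with never-smokers as reference; samples with unknown smoking are
dropped (with a logged count) only when smoking is actually in the model.
Discovery models are single-variable by default — sex and age are scanned
in separate arms, not jointly.

The permutation null shuffles **only** the label of interest, leaving
covariates attached to their samples (shuffling both would test a
different null), recomputes the full genome-wide scan per cycle, and
reports the per-cycle significant-gene counts, their mean (the expected
chance discovery count), the number of zero-discovery cycles, and
per-candidate null frequencies. Age labels are shuffled without
stratifying by sex; the output metadata says so. Under a global null with
independent genes, about 95% of cycles yield zero BH discoveries — the
theoretical floor for this statistic — and the per-cycle count vector is
persisted so both summaries can be re-derived.

Validation requires, per cohort, subset-wise FDR < 0.05 **and** a
coefficient sign matching discovery. A gene significant anywhere with the
opposite sign is contra-regulated and globally excluded, even from
cohorts where it agreed. The common set is the intersection of the
per-cohort validated lists; an n-way Venn tally over significance
membership (discovery circle included) is reported, and a zero
coefficient is treated as non-concordant and logged. Chromosomal
bookkeeping distinguishes autosomes (with the count of distinct ones),
non-pseudoautosomal X and Y, and the pseudoautosomal regions coded
`"X;Y"`.

# Gene set enrichment

Genes are ranked by descending association t statistic (ties broken
alphabetically). The enrichment score is the signed extremum of the
classic Kolmogorov-Smirnov running sum — increments $1/N_{set}$ on
members, decrements $1/(N - N_{set})$ elsewhere — with an optional score
weight exponent (weight 1) for parity with weighted GSEA software; the
implementation is checked against a literal enumeration oracle and,
independently, against `fgsea::calcGseaStat` to 1e-12. Set collections
are intersected with the analysis universe **before** the 15–500 size
filter (inclusive bounds), matching how standard GSEA tooling counts
testable sets.

Significance uses phenotype permutation — shuffle the variable, refit all
genes, re-rank, re-score — because the pipeline holds the full matrix and
phenotype permutation preserves gene–gene correlation; p-values carry the
add-one correction $(1 + \#\{|ES_{null}| \ge |ES|\})/(B + 1)$, the
normalized score divides by the mean |null ES| of matching sign, and BH
runs across all tested sets. The enrichment map connects significant sets
whose overlap coefficient $|A \cap B| / \min(|A|,|B|)$ reaches 0.5
(inclusive), with shared-gene counts as edge weights; connected
components of this graph are the "functional themes" a practitioner
reads off the map.

# Numerical and design notes

* Determinism: every stochastic routine takes an explicit integer seed,
  restores the caller's RNG state, and derives any sub-streams
  deterministically; rerunning a pipeline with the same seed produces
  byte-identical tables (verified in tests).
* Degenerate inputs: constant variable of interest, rank-deficient
  designs, batches with fewer than two samples, sets equal to or absent
  from the universe, and zero-permutation requests are refused with
  specific errors; an all-probes-filtered study is a warning, not an
  error.
* Problem sizes in the test suite are chosen to exercise the study's
  stated dimensions where they matter statistically (the 284-sample
  discovery design, the 11,089-gene universe, 1,000 permutation cycles,
  three validation cohorts at 409/339/363) while keeping simulation-only
  properties (ComBat pairing, GSEA calibration) at a few hundred genes
  and tens of samples, the scale at which their expected behavior is
  already sharp.
* The interface is R functions plus TSV/GMT readers and writers;
  `run_full_analysis()` is the one-call driver and writes every table
  with a provenance header (package version, seed, config hash).

# Known limitations

The pipeline treats validation cohorts as already gene-summarized when
they arrive that way and does not re-implement platform-specific
summarization (e.g. RMA). Non-parametric batch adjustment, meta-analytic
effect pooling across cohorts, interaction models (sex × age), and
permutation-based per-gene adjusted p-values are out of scope. The
simulator's independence assumptions mean calibration statements about
correlated real data are qualitative, as discussed above.
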