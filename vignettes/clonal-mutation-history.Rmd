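---
title: "Reconstructing a clonal lineage's mutational history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a clonal lineage's mutational history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonaltrace)
```

# Overview

`clonaltrace` analyses the mutations of a clonally expanding somatic
cell population: a single founder cell divides ~24 times in culture,
clonal lines (e.g. iPSC lines) are derived from the resulting
population, and each stage is sequenced. The package covers five
analysis stages — paired-read consensus error suppression, sub-clonal
variant calling against a matched control genome, a Poisson
molecule-sampling mutation-rate model, lineage reconstruction with MAF
clustering, and trinucleotide-spectrum/NNMF signature analysis — plus a
synthetic generator that produces labelled data with the statistical
structure all of these assume.

This vignette documents the models, the tunable parameters with their
defaults and rationale, the numerical choices, and what the synthetic
data do and do not show about real sequencing data.

# The division model

Every model in the package rests on one idealization: **pure binary
expansion**. One founder divides into 2, 4, ..., 2^G cells; every
daughter cell born at every division acquires `Poisson(mu)` new
heterozygous mutations; there is no cell death, selection, or
bottleneck. Consequences used throughout:

* a mutation arising at generation $n \ge 1$ is carried by $2^{-n}$ of
  the cells and — heterozygous in a diploid genome — by $2^{-(n+1)}$ of
  the allele copies (its *molecule fraction*);
* MAFs of true variants concentrate on the halving series
  $1/2, 1/4, 1/8, \dots$ (clonal, first division, second division, ...);
* the variants carried by a derived clonal line are exactly those on
  the ancestry path of its founding cell, one `Poisson(mu)` batch per
  generation.

No cell death or selection is simulated: over the few dozen generations
modelled here there is no evidence such effects reshape the site
frequency spectrum, and adding them would only *reduce* the carried
fractions, making every detection statement conservative in the
opposite direction. Plating/passaging bottlenecks of real cultures are
likewise not modelled; the generator implements the same idealization
the rate model assumes, which is precisely what makes end-to-end
parameter recovery a meaningful consistency check rather than a
statement about culture dynamics.

`simulate_expansion()` materializes the genealogy exactly and is capped
at 16 generations (~65k leaf cells); the cap is a memory choice, not a
model one. Deeper expansions are handled distributionally:
`simulate_population_mutations()` draws the per-generation
population-wide counts `Poisson(mu * 2^n)`, and
`simulate_lineage_mutations()` draws one sampled cell's ancestry path
(`Poisson(mu)` per generation). The second is what a deep-sequencing
assay of a derived line's variants interrogates, and is the path used
in the rate-recovery experiments.

# The Poisson molecule-sampling rate model

A PCR seeded with $N$ template molecules (default 1500, i.e. 5 ng of
human genomic DNA $\approx$ 750 diploid genomes) samples mutant
templates for a generation-$n$ mutation as
$X \sim \text{Poisson}(\lambda_n)$ with $\lambda_n = N/2^{n+1}$. The
mutation is detectable iff $X > 0$. Summing the detection
probabilities over the division generations gives the *detection
factor*

$$F = \sum_{n=1}^{G} \left(1 - e^{-\lambda_n}\right),$$

the expected number of detectable sub-clonal mutations per unit
per-generation mutation rate. For $N = 1500$, $G = 24$:

```{r factor}
detection_factor(1500, 24)
detection_factor(1500, 24, include_clonal = TRUE)
```

**The clonal term.** The sum deliberately starts at $n = 1$: the
$n = 0$ term describes mutations present in the founder itself, which
are identified separately as the variant set shared by all derived
lines, not through sub-clonal detection. Including it
(`include_clonal = TRUE`) adds exactly $1 - e^{-750} \approx 1$ and
gives 10.88. Only the $n \ge 1$ sum reproduces the factor 9.88 that the
three-line worked example requires, which is why exclusion is the
default and the flag is explicit.

The estimator divides each line's detected count by its assayed
fraction and by $F$; the cross-line mean uses the per-line fractions
(42.1%, 43.8%, 37.2% in the worked example) rather than a rounded flat
40%, and the dispersion is the sample ($n-1$) standard deviation:

```{r rate}
estimate_rate(c(60, 51, 58), c(0.421, 0.438, 0.372),
              factor = detection_factor())
```

The per-nucleotide conversion divides by a **diploid** genome size,
default $6.6 \times 10^9$ — the mutation rate is per cell, so the
denominator is the number of mutable base positions in a diploid cell.
The value is configurable and echoed in every report.

# Consensus error suppression

Deep amplicon sequencing at error rates of $10^{-3}$ per base cannot
see variants at molecule fractions of $10^{-4}$. The amplicons are
designed so that both reads of a pair span the variant; within the
overlap, a base call is accepted only when

* both reads report the same base, **and**
* the summed Phred qualities exceed 40 (strictly, i.e. $Q_1 + Q_2 \ge
  41$ — a literal reading of "higher than 40"; the threshold is a
  parameter).

A pair is discarded entirely when more than 10% (strictly) of the
double-called overlap positions mismatch. Positions failing acceptance
are masked with `N` — a consensus read never contains a guessed base.
Bases read `N` or at quality 0 in either read are masked and do not
count as mismatches (the choice is recorded here because read-pair
merging tools differ on it). Non-overlap flanks are excluded by
default, since only doubly-read bases enjoy the quadratic error
suppression; `include_flanks = TRUE` re-admits them for coverage
studies.

Two independent errors must agree to survive: the residual error rate
is $\approx e^2/3$ per site versus $e$ for a single read — at
$e = 10^{-3}$, three orders of magnitude better. The test suite
verifies both the collision arithmetic and the empirical improvement of
median error rates on simulated Q30 pairs.

# Sub-clonal calling

Each candidate site is a 2×2 contingency table — reference/mutant read
counts in the test population versus the matched control genome —
tested with Pearson's chi-square **without** continuity correction (the
default; a Yates flag exists and is recorded in the output metadata).
Family-wise error is controlled by Bonferroni over all sites tested in
one invocation: the family is therefore explicit in how you batch your
calls, and the batch size $m$ is attached to the result. Direction is
enforced as a post-filter — a site is *detected* only when its adjusted
p-value clears $\alpha$ **and** the test population's mutant fraction
exceeds the control's — giving one-sided semantics over a two-sided
statistic. Tables with an empty margin (no mutant read anywhere) are
flagged degenerate with $p = 1$ rather than raising. Variants are
classed sub-clonal below 30% MAF (strict), clonal at or above; zero
depth is an explicit `unclassified`.

At the design's settings (depth 50,000, post-consensus error
$2\times10^{-4}$) the realized family-wise false-positive rate sits far
below the nominal $\alpha = 0.05$: read counts are discrete and the
Bonferroni bound is conservative. The MAF floor for reporting very rare
calls (<0.1%) is exposed as a parameter, not hard-coded.

# Lineage reconstruction and MAF clustering

`partition_variants()` splits variants by sharing pattern: present in
all lines at clonal bulk MAF (band [0.4, 0.6], i.e. "approximately
50%") → acquired in vivo; present in a proper subset, or in all lines
but only sub-clonally in the bulk → acquired during culture; present in
one line → private.

`build_tree()` turns carrier sets into a genealogy: in a true tree the
carrier sets form a laminar (nested-or-disjoint) family, each set
marking the edge above its clade. Incompatible sets are resolved by a
maximum-compatibility greedy rule — sets are admitted in decreasing
order of supporting variant count (ties: larger sets, then
lexicographic) — and rejected variants are returned as a conflict
report, never dropped; an error is raised if conflicts exceed a
configurable fraction (default 50%). Edge counts are *minimum* mutation
numbers, since sub-clonal detection sensitivity is incomplete. Trees
serialize as newick with edge counts as branch lengths
(`clone_tree_phylo()` bridges to `ape`).

`cluster_mafs()` groups MAFs into division-generation sub-populations.
The reference route is a Dirichlet-process mixture of binomials —
each variant's mutant read count is binomial in its depth — with a
Beta(1,1) base measure and concentration 1.0 (both configurable; the
flat base is the least-informative conjugate choice, and concentration
1 expresses no prior pull toward few or many clusters). Collapsed
Gibbs sampling runs a fixed number of sweeps (default 200) and the
reported partition is the **maximum-posterior state visited**, making
the summary deterministic under a fixed seed. A fully deterministic
fallback (`method = "em"`) fixes the component success probabilities at
the halving series and estimates only mixing weights by EM. Cluster
generation labels come from the nearest halving level:
$g = \mathrm{round}(-\log_2 \hat p) - 1$, floored at 0.

# Spectra and signatures

`classify_96()` maps each substitution to one of 96 channels — six
pyrimidine-strand substitution classes × 16 flanking contexts, labels
like `A[C>T]G` in fixed order (`channel_labels()`). Purine-reference
variants are reverse-complemented (variant and context) before
labelling, so strand description never changes the class. Reference
mismatches are hard errors naming the locus; ambiguous context (`N`,
contig edge) skips the variant with a warning and a count.

`nnmf_extract()` factorizes a catalog $V \approx WH$ by multiplicative
updates minimizing the generalized Kullback–Leibler divergence — the
canonical objective for count matrices (squared Frobenius by flag). The
objective is non-increasing per iteration (asserted in tests).
Restarts (default 50) guard against local minima: the best-objective
run is kept and each signature's *stability* is its mean cosine
similarity to the matched signature across all restarts, matching by
exhaustive assignment (the rank is small). The rank $k$ is **chosen by
the user** with the stability-and-error report as guidance; no
automatic model selection is silently applied, because reconstruction
error alone always favours larger $k$. `attribute()` projects a
spectrum onto fixed signatures by non-negative least squares.

The two bundled `example_signatures()` — CpG-deamination-like C>T and
oxidative-damage-like C>A — are synthetic shapes for simulation and
testing, not fitted reference signatures. External catalogs (e.g.
germline spectra) can be loaded for comparison via `read_catalog_tsv()`.

# The pipeline, reproducibility and problem sizes

`run_pipeline()` chains the stages in dependency order and writes every
artifact plus a structured log, the effective configuration and its md5
hash. Configuration is validated strictly — unknown or missing keys
abort before any stage runs — and every stochastic stage derives its
seed from the single master seed, so identical configurations give
byte-identical outputs.

Defaults mirror the motivating design: mu = 14 mutations per daughter
per division, 24 generations, 1,500 template molecules, three derived
lines, depth 50,000, post-consensus error $2\times10^{-4}$, 40% assay
fraction. Internally all coordinates are 0-based half-open; every
user-facing table and VCF is 1-based.

The test suite exercises the same experimental scales the analysis
targets — e.g. rate recovery over 20 replicate three-line experiments
at depth 50,000, null batches of $m = 1000$ sites for family-wise error,
20 random mixtures of 5,000 mutations for signature recovery, exact
genealogies of 3–8 generations for topology recovery — sizes chosen so
each property is measured with useful Monte-Carlo resolution while the
whole suite stays interactive-fast.

# What the synthetic data do not show

The generator reproduces the *statistical* structure the analysis
assumes, which is what makes its tests sharp: passing them shows the
estimators are correct **under the model**. It does not emulate several
features of real data, and conclusions about them require real inputs:

* alignment and mapping artifacts (reads arrive pre-assigned to
  amplicons; the permissive aligned-input path of real pipelines is out
  of scope here);
* context-dependent and systematic sequencing error (errors are i.i.d.
  uniform over the three non-truth bases; real miscalls are biased,
  which consensus merging suppresses less efficiently);
* copy-number changes, loss of heterozygosity, indels, non-binary
  division, contamination, and culture bottlenecks — all excluded by
  design;
* PCR resampling correlation between reads of the same template beyond
  the two-stage Poisson/binomial draw.

# Known limitations

* The exact-tree simulator is capped at 16 generations; deeper
  expansions use the distributional paths, which are equivalent for
  site-level analyses but carry no explicit genealogy.
* The DP clustering reports a posterior-mode partition, not a full
  posterior; uncertainty in the number of sub-populations is visible
  only across seeds.
* The greedy conflict resolution in `build_tree()` is not guaranteed
  maximum-parsimony when conflicts are heavy; it is intended for the
  low-conflict regime of validated variant sets, and the conflict
  report is the honest output for everything else.
* `estimate_rate()` propagates no uncertainty from the detection step;
  the cross-line SD is an empirical dispersion, not a posterior
  interval.
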