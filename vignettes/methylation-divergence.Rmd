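---
title: "Methylation divergence across population methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation divergence across population methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdiv)
```

## The model

At a cytosine site scanned in a population of $s$ methylomes, methylome
$j$ contributes read counts $n_{j1}$ (methylated) and $n_{j2}$
(unmethylated), with coverage $n_j = n_{j1} + n_{j2}$ and total coverage
$n = \sum_j n_j$. Substituting empirical frequencies for probabilities
gives the plug-in estimates

$$\hat P_j = \left(\frac{n_{j1}}{n_j}, \frac{n_{j2}}{n_j}\right), \qquad
  \hat\pi_j = \frac{n_j}{n},$$

and the plug-in Jensen-Shannon divergence in bits (base-2 logs
throughout):

$$\hat D = H\!\Big(\sum_j \hat\pi_j \hat P_j\Big)
         - \sum_j \hat\pi_j H(\hat P_j)
         = H\langle \hat P\rangle - \langle \hat H\rangle .$$

$\hat D$ is the information lost by pooling the population: zero exactly
when all covered methylomes share one distribution, at most
$\log_2 K$ bits for $K$ states (1 bit for the binary methylation case).
With coverage weights it is also the mutual information between the
"methylome" and "state" margins of the site's $s \times K$ contingency
table — the property the test suite uses as an independent oracle. The
weighted methylation level is the first-state frequency of the pooled
mixture, $\hat\mu = \sum_j n_{j1} / n$, so the mixture entropy is
$H_2(\hat\mu)$ and every site obeys $\hat D \le H_2(\hat\mu)$: in the
(MET, JSD) phase plane all sites sit under the binary-entropy envelope.

The estimator is maximum-likelihood but biased for small coverage (the
plug-in entropy of a finite sample underestimates the true entropy);
bias-corrected or nearest-neighbour entropy estimators are out of scope
here. Coverage weighting also means a methylome that dominates the
coverage at a site drags $\hat D$ towards zero — `site_divergence()`
exposes `weighting = "equal"` for populations with grossly uneven depth.

## Classification

Sites are classified in the phase plane with three thresholds
(`phase_thresholds()`):

| parameter        | default | meaning                                        |
|------------------|---------|------------------------------------------------|
| `met_low`        | 0.2     | below: low-methylated (LMC)                    |
| `met_high`       | 0.8     | above: high-methylated (HMC)                   |
| `jsd_metastable` | 0.7 bit | middle band, above: metastable (MSC); else MMC |

MET exactly at a boundary falls in the middle band (the band is the
closed interval $[0.2, 0.8]$). The 0.7-bit bar sits just below the
$H_2(0.2) \approx 0.72$-bit entropy ceiling that LMC/HMC sites can reach,
so MSC status singles out middle-band sites whose divergence approaches
the theoretical maximum — the signature of a population segregating into
methylated and unmethylated subpopulations.

## The scan and its filters

`scan_methylomes()` merges the per-sample tables position-synchronously.
A sample with no row at a position has zero coverage there and therefore
zero weight — nothing is imputed; `samples_covered` records how many
methylomes contributed at each site. `min_samples` and `min_coverage`
(both default 1, i.e. off) drop sites below a floor; no minimum is
imposed by default because any floor is a study-design decision, and the
reported columns allow filtering after the fact. Divergence differences
below $10^{-12}$ bit are snapped to zero so the "identical distributions
give exactly zero" identity survives floating-point arithmetic.

Context assignment reads the reference genome directly: a `C` is a
forward-strand cytosine whose two following bases decide CG/CHG/CHH; a
`G` is a reverse-strand cytosine decided by the two preceding bases on
the complement. The two cytosines of a symmetric CpG are deliberately
*not* merged — each is an independent site, matching per-cytosine caller
output. Chromosome names match exactly (no `chr` aliasing).

## Binned tracks and clustering

`bin_signal()` averages a per-site signal (or a cytosine-type fraction)
over non-overlapping, half-open, genome-tiling bins; empty bins are `NA`,
never zero, and the last bin truncates at the chromosome end. The default
track width used in the examples is 50 kb; 10-kb bins are equally valid
for local enrichment — bin width is a required, explicit parameter
precisely because both conventions are in use. `correlate_signals()`
computes pairwise Spearman $\rho$ with pairwise-complete bins and
clusters on the distance $1 - \rho$ with average linkage; the distance
and linkage are a documented choice (rank correlation pins down only the
similarity, not the agglomeration rule) and the linkage is configurable.

## Feature-anchored statistics

`metagene_profile()` uses literal 50-bp bins on fixed 2-kb flanks and
rescales each feature body to a fixed number of bins (default 60). A
uniform bin width cannot apply verbatim to bodies of different lengths
joined to fixed flanks; length-scaling the body is the standard
resolution and is recorded in the profile's attributes. Minus-strand
features are orientation-flipped before binning.

`select_msgs()` ranks genes by the proportion of MSC sites among their
classified sites and returns the genes strictly above the chosen
quantile (default 0.95) of that proportion. Selection is by value
threshold, not rank, so tie groups are never split: when every gene is
tied nothing exceeds the cut and the set is empty. Genes with fewer than
`min_sites` classified sites are ineligible. The cut value and the
eligible count are returned as attributes so "very few metastable genes"
situations are visible to the caller.

## Randomization tests

Both tests report three p-value forms: the raw one-sided empirical
fraction $\#\{\text{null} \ge \text{observed}\}/n$ (primary; this is the
"at least as extreme" convention, and it can be exactly zero), the
add-one smoothed estimate $(b+1)/(n+1)$, and — for the domain-contrast
test — the null probability of a *positive* difference, because that
literal reading of the contrast ("probability that compacted domains
exceed loose domains under the null") is also in circulation. The two
conventions agree whenever the observed difference is positive and
clearly outside the null; both are reported rather than adjudicated.

`csd_lsd_test()` permutes the domain sign labels over bins, preserving
the observed count of each sign. `msg_te_proximity_test()` draws gene
sets of the observed size uniformly without replacement from the
background; "near" means the gene interval extended by `near_dist`
(default 2 kb, consistent with the 2-kb flank convention used
throughout) overlaps any element. Both accept a `seed` and restore the
caller's RNG state.

Because both statistics are discrete, the raw empirical p-value is
slightly conservative (ties between null and observed count towards the
p-value). The calibration checks in the test suite therefore run at
scales where the discreteness is negligible: 500 replicates of a
100-bin continuous signal for the domain test, and gene sets of 500
drawn from 2000 background genes for the proximity test.

## The synthetic population generator

`simulate_population()` emulates the population structures a large
methylome panel exhibits, with four per-site models:

| model            | default mix | per-individual methylation rate        |
|------------------|-------------|----------------------------------------|
| `conserved_low`  | 0.70        | `theta_low` = 0.03                     |
| `conserved_high` | 0.20        | `theta_high` = 0.97                    |
| `intermediate`   | 0.08        | `theta_mid` = 0.5                      |
| `metastable`     | 0.02        | 0.97 or 0.03, high with prob. 0.5      |

Coverage is negative binomial with mean 30 and size 10 — moderate
overdispersion, chosen once as typical of per-site WGBS depth (size
`Inf` gives the Poisson limit); methylated counts are binomial.
Bisulfite conversion error is folded into `theta_low`/`theta_high`
rather than modelled separately. The synthetic chromosome embeds a
CG/CHG/CHH motif at every site (15/15/70% by default, the CHH-dominated
composition typical of a plant genome) in an A/T background so no
unintended cytosines arise. `simulate_annotations()` adds non-overlapping
genes, elements placed preferentially near planted metastable genes, and
an alternating-sign domain segmentation; `simulate_methylome_study()`
composes the two, biasing site models inside planted genes so the whole
scan-classify-select pipeline can be checked against ground truth.

What the generator does **not** emulate: spatial autocorrelation of
methylation along the chromosome, strand asymmetries, per-sample global
offsets (batch or tissue effects), conversion-rate variation, and
mapping artefacts. Passing tests on simulated data therefore validate
the estimator, the classifier and the interval statistics — not
robustness to those real-data pathologies.

## Classifier sensitivity and sample size

A property worth stating explicitly: with $s$ sampled methylomes, a
metastable site's high-state count is binomial $(s, 0.5)$, and at
saturating coverage its divergence is
$H_2(0.03 + 0.94k/s) - H_2(0.97)$ for $k$ high-state individuals. For
$s = 10$ this exceeds the 0.7-bit bar only for $k \in \{3,\dots,7\}$
($k = 3$ sits at 0.7011 bit, on the knife edge), so even a perfect
estimator classifies at most $\approx 91\%$ of middle-band metastable
sites as MSC, and finite coverage brings this to $\approx 84\%$. At
$s \approx 30$ the binomial concentrates and the rate rises above 98%.
The test suite records both regimes: the high-coverage, 100-sample check
confirms the closed-form limit, and the 10-sample desk-scale check
documents the small-panel sensitivity floor. Detecting metastability
reliably simply needs population panels of tens of methylomes — which is
why large public corpora are the method's natural habitat.

## Problem sizes used in the checks

The bundled suites run entirely on simulated data: 50,000 sites by 10
samples for the architecture-recovery check, 1,000 random count matrices
for the mutual-information oracle, 500 replicates for each permutation
calibration, and 10,000 uniform queries for the relative-distance
flatness check — sizes chosen so the whole suite completes in about a
minute while leaving the statistical assertions well-powered.

## Known limitations

- The plug-in estimator is biased at low coverage; no bias correction or
  uncertainty quantification is provided.
- Coverage weighting lets a single deep methylome dominate a site;
  inspect `samples_covered` and consider `weighting = "equal"`.
- Region queries on methylation tables filter a fully parsed file; for
  indexed random access over very large tables, pre-slice with tabix
  upstream.
- Context assignment trusts the reference; allele-specific sequence
  variation (e.g. a SNP destroying a CpG) is not modelled.
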