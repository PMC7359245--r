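# methdiv

Population-scale DNA methylation divergence via Jensen-Shannon entropy.

## What it is for

Whole-genome bisulfite sequencing gives, for every cytosine in every
sequenced individual, a pair of read counts: methylated and unmethylated.
When many methylomes from one population are available, the interesting
question is no longer "how methylated is this site" but "how *variable* is
this site across the population" — and which sites segregate into
methylated and unmethylated subpopulations (metastable epialleles).

`methdiv` scans a population of per-sample methylation tables
(MethylDackel-style bedGraph or a generic TSV) and computes, at every
covered cytosine, two statistics:

- **MET**, the weighted methylation level: total methylated reads over
  total reads, `μ̂ = Σⱼ n_j1 / n`;
- **JSD**, the plug-in Jensen-Shannon divergence in bits:

  ```
  D̂ = H(Σⱼ π̂ⱼ P̂ⱼ) − Σⱼ π̂ⱼ H(P̂ⱼ)
  ```

  where `P̂ⱼ` is methylome *j*'s count row normalised by its coverage,
  `π̂ⱼ = n_j / n` are coverage weights, and `H` is Shannon entropy with
  base-2 logs. JSD is the entropy of the pooled mixture minus the average
  within-methylome entropy — the information lost by pooling — and equals
  the mutual information between "which methylome" and "which methylation
  state" in the site's contingency table.

Each site then lands in the (MET, JSD) **phase plane**, bounded above by
the binary-entropy curve, and is classified: **LMC** (MET < 0.2), **HMC**
(MET > 0.8), and in the middle band **MMC**, or **MSC** (metastable,
JSD > 0.7 bit) where the population splits into two epigenetic states.

On top of the per-site scan the package provides the downstream genomic
statistics: CG/CHG/CHH context assignment from a reference FASTA,
genome-binned tracks, Spearman clustering of binned signals, metagene
profiles with fixed flanks, metastable-gene (MSG) selection,
relative-distance spatial association, a structural-domain (CSD/LSD)
sign-permutation test, and a gene-to-transposon proximity randomization
test — plus a synthetic methylome-population generator with known ground
truth so the whole pipeline is testable offline.

## Worked example

The single-site population of three methylomes with (methylated,
unmethylated) counts (15,0), (11,1), (5,4):

```r
library(methdiv)
counts <- rbind(c(15L, 0L), c(11L, 1L), c(5L, 4L))
site_terms(counts)
#>   methylome n_meth n_unmeth coverage p_meth weight entropy weighted_entropy
#> 1         1     15        0       15  1      0.417   0                0
#> 2         2     11        1       12  0.917  0.333   0.414            0.138
#> 3         3      5        4        9  0.556  0.25    0.991            0.248
site_divergence(counts)
#>     met   jsd h_mix h_avg coverage samples_covered k_states
#> 1 0.861 0.196 0.581 0.386       36               3        2
```

Reading: the three methylomes get coverage weights 0.42/0.33/0.25; the
pooled methylation level is 0.86; pooling costs
`0.581 − 0.386 ≈ 0.196` bits of information, so the site diverges mildly —
mostly because the third methylome is halfway between states.

A full simulated scan chains the same way:

```r
pop   <- simulate_population(n_samples = 10, n_sites = 2000, seed = 7)
stats <- scan_methylomes(pop$samples, context = pop$genome)
head(stats, 3)
#>   chrom pos    met    jsd  h_mix h_avg coverage samples_covered context ctype
#> 1 Chr1    2 0.954  0.0186 0.270  0.251      347              10 CG      HMC
#> 2 Chr1   22 0.980  0.0282 0.141  0.113      301              10 CHH     HMC
#> 3 Chr1   42 0.0300 0.0152 0.194  0.179      267              10 CHH     LMC
ctype_proportions(stats)      # percentages per context, summing to 100
plot_phase_plane(stats)       # sites under the binary-entropy envelope
```

From there: `bin_signal()` for chromosome tracks, `correlate_signals()`
for signal clustering, `metagene_profile()` for feature-anchored
profiles, `gene_ctype_counts() |> select_msgs()` for metastable genes,
and `csd_lsd_test()` / `msg_te_proximity_test()` for the randomization
tests (`tidy()`, `glance()` and `autoplot()` work on the results).

A thin command-line wrapper over the same functions ships in
`inst/cli/methdiv` (subcommands `scan`, `classify`, `bin`, `profile`,
`msg`, `reldist`, `test-csd`, `test-te`, `simulate`).

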