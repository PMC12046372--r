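---
title: "sweepscan: methods, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sweepscan: methods, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes

`sweepscan` detects candidate signatures of positive selection in phased
diploid resequencing data by combining four classic genome-scan
statistics on one shared sliding-window grid:

* **Pooled heterozygosity (Hp / ZHp)** — per window, with `S_maj` and
  `S_min` the sums over the window's SNPs of major- and minor-allele
  counts in a population,
  `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2`. A completed hard sweep
  drags linked variation to fixation and drives window Hp toward 0;
  extreme-low ZHp windows are sweep candidates. The original formulation
  pools sequencing reads; here the allele counts come from called
  genotypes, which is how the statistic is used on genotype data.
* **iHS** — per SNP, `ln(iHH_A / iHH_D)` where iHH is the area under the
  EHH decay curve (against genetic distance, trapezoidal rule, truncated
  where EHH first drops below a cutoff) for ancestral- and
  derived-allele carriers. Raw scores are standardized within
  derived-allele-frequency bins.
* **XP-EHH** — per SNP, `ln(iHH_pop1 / iHH_pop2)` with iHH computed over
  *all* haplotypes of each population under a shared stopping rule (the
  walk stops once both populations' EHH are below the cutoff, and both
  are integrated to that common boundary); standardized genome-wide.
* **Weir–Cockerham FST** — per SNP the 1984 variance-components
  estimator (r = 2 populations, locus-specific non-missing sample
  sizes), windowed with the weighted ratio-of-sums form
  `sum(a) / sum(a + b + c)`. Negative window estimates are reported
  as-is; clamping would bias the Z-standardization.

Windows are 20 kb sliding by 10 kb, anchored at position 1, 1-based
inclusive, and a window needs at least 20 member SNPs to be scored.
Those conventions reproduce the coordinate style of published candidate
tables (starts ≡ 1 mod 10 000). Unscored windows are excluded from the
mean/sd used by every Z-standardization.

Outlier windows are the extreme 0.1 % tail (`q = 0.001`) of each
track's empirical distribution — low tail for ZHp, high tail for window
iHS, ZFST and window XP-EHH — selected as the `k = max(1, ceiling(q*N))`
most extreme defined windows, boundary ties all included. Selected
windows are consolidated with bedtools-default semantics (book-ended
intervals merge at `max_gap = 0`), cross-tabulated across
methods/contrasts (regions supported by at least two combinations), and
intersected with a local gene table (1-bp overlap rule, 1-based
inclusive coordinates everywhere internally; BED I/O converts at the
boundary).

## Interpretation conventions that matter

* **Ancestral allele.** iHS needs an ancestral/derived orientation.
  The package records a per-variant flag on input (from a VCF `AA` INFO
  tag when present) and defaults to *REF is ancestral* otherwise, with
  `"major"` (population major allele) as an option. This choice flips
  iHS signs; it is a declared assumption, not an inference.
* **Window means of haplotype scores.** Per-SNP standardized scores are
  averaged per window as `mean(|z|)` by default. Published window-level
  iHS values well above any plausible signed mean of N(0,1) scores, and
  the explicit use of |XP-EHH_std| in the literature this pipeline
  mirrors, make the absolute-value reading the coherent one; a signed
  mode is retained.
* **Truncated cores.** A core SNP whose EHH never decays below the
  cutoff before the chromosome end is dropped (selscan convention).
  On short simulated chromosomes this is common — small samples contain
  genuinely identical haplotype pairs, whose EHH plateaus above the
  cutoff — so iHS coverage at desk scale is sparse, and XP-EHH is
  systematically undefined at a strong sweep (the swept population's
  EHH cannot decay). The pipeline treats score-less tracks as having no
  callable regions rather than failing. A `keep_truncated` option
  integrates to the chromosome end instead.
* **Exclusive QC thresholds.** Variants with MAF ≤ 0.05 or call rate
  ≤ 0.95 are excluded (boundaries excluded, matching the "≤ ...
  excluded" convention); LD pruning (greedy PLINK-style, 50-SNP window,
  step 5, r² > 0.1 on diploid dosages) is an explicit opt-in stage —
  it belongs to diversity/structure analyses, never implicitly to the
  selection scans.
* **Tail fraction, not percentile.** "Extreme 0.001 percentile" is read
  as tail fraction 0.001 (0.1 %). With ~10⁵ windows genome-wide this
  yields region counts of the observed magnitude, whereas the literal
  1e-5 quantile would select a single window. The literal reading
  remains available by setting `q = 1e-5`.

## Numerical choices

* Z-standardization and iHS bin standardization use the population sd
  (denominator N). At genome-wide window counts the distinction from
  the sample sd is negligible; fixing it makes results reproducible to
  the last digit.
* EHH is computed by partition refinement (exact, equals pairwise
  identity counting); curves include the first point below the cutoff,
  and iHH integrates that final segment. Genetic distance defaults to a
  constant 1 cM/Mb when no genetic map is supplied.
* A decay walk is skipped without stepping through it when the limiting
  EHH (identity partition over the full remaining span, precomputed
  once per population in O(n·m)) is still at or above the cutoff;
  by monotonicity this is exact, not an approximation.
* Monomorphic pairs in LD pruning have r² defined as 0; globally
  monomorphic sites have undefined (not zero) FST; windows whose
  denominator is non-positive are undefined.

## The synthetic world

`simulate_wf()` is a forward-in-time Wright–Fisher island model with
infinite-sites mutation, uniform crossover recombination and symmetric
migration, plus an optional hard sweep (additive fitness 1, 1+s, 1+2s)
confined to one deme. Forward simulation was chosen over coalescent
machinery for exact control of the sweep and zero external
dependencies; it is only honest at desk scale.

Defaults state the world the test-suite reasons about:

* 2 demes × 80 diploids, 20 sampled per deme, 300 kb chromosome,
  500 generations from a monomorphic start (diversity near
  equilibrium at this timescale);
* `mu = 2e-6`/bp/generation — deliberately scaled up (real vertebrate
  rates are ~1e-8) so a 300-kb chromosome carries a realistic sample
  density of ~4–5 SNPs/kb and 20-kb windows hold well over the 20-SNP
  scoring minimum;
* `rec = 1e-6`/bp/generation, so a sweep lasting ~75–85 generations
  leaves a hitchhiking footprint of roughly 1/(rec × time-while-rare)
  ≈ 30–50 kb per side — wide enough to dominate one to three 20-kb
  windows, narrow enough to stay localized;
* `migration = 0.006` per individual per generation (4Nm ≈ 2), giving a
  genome-background FST around 0.1–0.2 that is stable enough across
  windows for empirical outlier calling. Calibration during design
  showed both ends of this dial fail structurally: at m = 0.01 the
  post-fixation migrant influx refills the swept region's diversity
  before sampling (no trough left to detect), while at m ≤ 0.002 the
  demes are so isolated that per-window FST becomes drift-dominated
  noise spanning 0.2–0.7 and the outlier tail is meaningless;
* the sweep (s = 0.1) is introduced as a single copy 75 generations
  before sampling and re-attempted from a checkpoint with an
  incremented sub-seed until its final frequency reaches 0.9, so the
  sampled state is "established, recently completed", the regime the
  scan statistics target. Attempts that lose the allele abort
  immediately; this only skips simulating generations after the sweep
  has already failed.

What a green test does **not** establish: the generator has no
sequencing error, no ascertainment bias, no missing genotypes unless
injected, equal deme sizes, a single chromosome, and scaled rates — so
passing recovery tests demonstrates correct implementation of the scan
on data with the assumed statistical structure, not calibrated power on
real resequencing data.

## Known limitations

* iHS at desk scale scores few SNPs (truncation; see above), so its
  windowed track is sparse in the simulated world even though the
  per-SNP machinery is exact and oracle-checked.
* Two-population FST only (the estimator generalizes to r > 2, but the
  pipeline's contrasts are pairwise, mirroring the hot-vs-cold design).
* Sweep-recovery properties are stochastic by nature; they are asserted
  as majorities over seeded replicate sets, and individual replicates
  can and do miss.
* The CLI covers the documented subcommands with plain `--key value`
  parsing; it is a thin veneer over the R API, which is the primary
  interface.
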