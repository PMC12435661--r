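---
title: "Detecting population-specific selective sweeps with sweepscan"
author: "sweepscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting population-specific selective sweeps with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

A selective sweep — the rapid rise of a beneficial allele — strips linked
variation from the surrounding region. In the population that experienced
the sweep this leaves three correlated signatures: unusually long stretches
of haplotype homozygosity, reduced nucleotide diversity ($\pi$), and a
frequency spectrum skewed toward rare variants (negative Tajima's $D$).
Between populations it produces localized allele-frequency differentiation.

`sweepscan` implements a multi-statistic scan for *population-specific*
sweeps from phased, bi-allelic SNP genotypes of several populations — the
motivating design is a four-breed cattle panel (a focal indigenous breed of
8 diploids, a closely related breed of 17, and two more distant commercial
breeds of 10 each), but nothing in the code is species-specific. Three
complementary statistics are computed on genomic windows, outliers are
called by an empirical top-quantile rule, and outlier windows are annotated
with overlapping genes. Diversity statistics around candidate genes serve
as an independent validation of the sweep signature.

## The statistics

### Windowed Weir–Cockerham $F_{ST}$ and the four-population branch statistic

Per site, the Weir–Cockerham (1984) variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals) are computed from diploid sample sizes, allele frequencies and
observed heterozygote frequencies for a population pair. Window $F_{ST}$ is
the ratio of sums $\sum a / \sum (a+b+c)$ over in-window sites (the
"weighted" estimator of the common command-line tools; a mean-of-ratios
variant is exposed via `estimator = "mean_of_ratios"` since tools report
both). Windows are 50 kb with 20 kb steps, anchored at coordinate 1 per
chromosome.

Pairwise window $F_{ST}$ is transformed to an additive branch length

$$D_{A,B} = -\ln\!\left(1 - F_{ST}(A,B)\right),$$

with the natural logarithm (the convention of the population-branch-
statistic literature). Negative or missing window $F_{ST}$ values are
treated as undefined: $F_{ST} \le 0$ has no branch-length interpretation.
By default the *whole window* is dropped when any required pair is
undefined; `exclude = "pair"` instead clamps negative values to a zero
branch, for users who prefer to keep more windows.

With a focal population $F$, a sister population $S$, and outgroups $O_1$,
$O_2$, the four-population branch statistic per window is

$$\mathrm{PBS4} = \frac{2\,D_{F,S} + D_{F,O_1} + D_{F,O_2}
                        - D_{S,O_1} - D_{S,O_2}}{4}.$$

The sister term is doubled because $D_{F,S}$ is the only pair in which the
focal branch is measured against its closest relative; the two
outgroup-sister terms subtract the shared drift of the non-focal side. The
trailing 4 is a divisor over the whole numerator. When all five branch
lengths equal $d$ the statistic reduces to $d/2$, which the test suite
checks as an algebraic identity, and symmetric simulations confirm
empirically. Negative values are legitimate (a focal branch shorter than
expected) and are kept.

### XP-EHH

Extended haplotype homozygosity around a core SNP is the probability that
two random haplotypes from a population are identical over the core and
all SNPs out to a distance $x$:
$EHH(x) = \sum_g \binom{n_g}{2} / \binom{n}{2}$, computed outward SNP by
SNP. Extension stops when EHH drops below `ehh_cutoff` (0.05), at 1 Mb
(`max_extend`), at an inter-SNP gap above 200 kb (`max_gap`), or at the
chromosome end; these are the conventional defaults of the standard
haplotype-scan tools. Physical distance substitutes for genetic distance
throughout — no genetic map is shipped, and the statistic is robust to
this substitution at the 50 kb scale of interest.

The integrated haplotype homozygosity iHH is the trapezoidal integral of
the EHH decay over both directions, truncated at the last point at or above
the cutoff. The raw cross-population score at a core SNP is
$\ln(\mathrm{iHH}_{obs}/\mathrm{iHH}_{ref})$; positive values mean longer
homozygosity in the observed (focal) population. Cores with pooled minor
allele frequency below 0.05 are skipped, matching the upstream site QC.
Raw scores are standardized genome-wide in a single bin (mean 0, sd 1 over
all defined scores, population standard deviation), and each 50 kb
non-overlapping window is summarized by its *maximum* normalized score.
Normalizing per SNP genome-wide and then taking window maxima is the
conventional order for this scan; the window maximum, not the mean, is
thresholded. The inner decay loop is implemented in C++ (as every serious
EHH implementation is); everything else is plain R.

### Diversity validation

Per site, $\pi = 2 c_{ref} c_{alt} / (n_c (n_c - 1))$ on called allele
counts; windows report the per-bp sum so truncated terminal windows remain
comparable. Tajima's $D$ uses the canonical $a_1 \ldots e_2$ constants with
$n$ = two sequences per diploid with complete data in the window; windows
with fewer than `min_snps` (default 3) segregating sites are *undefined*,
never zero — near-monomorphic candidate regions legitimately yield no
value, and reporting 0 there would fake neutrality. The default of 3 is
configurable because the exact minimum used by the common implementation is
not documented.

Gene-local validation scans switch window sizes on gene length: genes over
100 kb get 50 kb/25 kb $\pi$ windows and 10 kb $D$ windows; shorter genes
get 1 kb/0.5 kb and 5 kb. The flank defaults to one $\pi$-window size on
each side of the gene; the margin is a presentation choice with no effect
on the statistics.

### Outlier calling and annotation

With $N$ windows carrying a defined score, the top-1% rule selects
$k = \lceil 0.01 N \rceil$ windows; the threshold is the $k$-th largest
value and ties at the threshold resolve by genomic order so exactly $k$
windows return. Ceiling rounding is the only rule consistent with the
published count tables this scan design derives from (e.g. 47,579 defined
windows select 476; 62,668 select 627). $N$ counts only defined windows:
an XP-EHH window with no scored SNP is not part of the distribution.

A selected window is annotated when it overlaps a gene span by at least
1 bp (1-based inclusive intersection; adjacency is not overlap), and genes
are deduplicated by id across windows. `merge_candidates()` builds the
final per-gene summary: the best score per method, with the contributing
reference populations recorded. Externally computed per-window score
tables (for instance a composite-likelihood scan run with an external
binary) can be read with `read_window_track()` and pass through the same
thresholding and annotation.

## Site QC, LD pruning and structure support

`filter_sites()` reproduces a standard WGS filter chain in the order HWE
(exact test, all samples pooled — the behaviour of the usual command-line
tool on a merged multi-population set, and deliberately so, although
pooling induces a Wahlund-effect het deficit at strongly differentiated
sites), then MAF $\ge$ 0.05 on called alleles, then call rate. The default
call-rate floor of 0.05 looks odd but is the documented meaning of the
`--max-missing 0.05` convention (minimum *proportion called* = 0.05, i.e.
very permissive); it is configurable. The HWE exact test uses the standard
two-sided conditional enumeration via the recurrence over heterozygote
counts, with no mid-p adjustment.

`ld_prune()` is the greedy 50-SNP/10-step/r² > 0.1 sliding-window rule on
dosage (composite) correlation, deterministic given input order.
`breed_specific_counts()` implements one defensible reading of
"breed-specific SNPs with Bonferroni correction": per site, each
population's allele counts are tested against all others pooled with
Fisher's exact test, the site is credited to the population with the
smallest p-value when it beats $\alpha$ divided by the number of sites.
The original tooling's exact test definition is not public, so this is an
interpretation and is documented as such.

The structure stack follows standard practice: p-distance
($\overline{|g_i - g_j|/2}$ over shared called sites), neighbor-joining
with the Saitou–Nei Q criterion (lowest-index tie-break for determinism;
negative branches clamped to zero with the deficit shifted to the sister
branch), a VanRaden-standardized GRM with eigen-decomposition, and the
three-population $f_3$ test with the finite-sample heterozygosity
correction on the target and a 5 Mb block jackknife (block size matters
little between 2 and 10 Mb, which the tests check).

## The synthetic-data generators

Three seeded generators make the whole pipeline testable without any
external download, and their defaults *are* the study conditions of the
motivating design:

* **Balding–Nichols genotypes** (`simulate_bn_genotypes()`): ancestral
  frequencies Uniform(0.05, 0.95) — sites below 5% would not survive QC —
  and per-population Beta-drifted frequencies with parameter $F = 0.1$, a
  typical cattle between-breed differentiation. $F$ equals the expected
  Weir–Cockerham intraclass correlation, so windowed $F_{ST}$ has a
  closed-form target and recovery can be tested (0.10 ± 0.02 at 2000
  sites/window).
* **Mosaic-founder haplotypes** (`simulate_sweep_haplotypes()`): per
  population, 8 founder haplotypes drawn from the population frequencies;
  sampled haplotypes switch founders at $10^{-5}$/bp, giving realistic
  local LD without a full recombination-graph simulator. The planted hard
  sweep collapses the focal founder pool to a single haplotype over a
  200 kb interval centered on a 20 Mb contig and injects singleton
  post-sweep mutations at $2 \times 10^{-4}$/bp. Population sizes default
  to 8/17/10/10 diploids so small-sample estimator behaviour stays
  realistic. Note the founder pool itself adds drift on top of the
  Balding–Nichols $F$ (realized pairwise $F_{ST}$ between haplotype
  populations is roughly $F + (1-F)/k$ for $k$ founders, about 0.2 at the
  defaults); calibration tests therefore use the genotype generator, while
  the haplotype generator is for relative contrasts.
* **Neutral coalescent** (`simulate_coalescent()`): constant-size,
  single-locus, infinite-sites, used to calibrate the diversity
  statistics against Watterson's $E[S] = \theta a_1$, Tajima's
  $E[\pi] = \theta$, and $E[D] \approx 0$.

What the generators do **not** emulate: realistic recombination-rate
variation, gene conversion, background selection, soft sweeps, sequencing
or phasing error, and genotype missingness structure. Passing tests
therefore demonstrate correctness of the statistics and the detection
machinery under a clean hard-sweep model, not field performance on real
resequencing data.

## The power experiment

`evaluate_sweep_power()` runs the complete scan — QC, all pairwise
$F_{ST}$, PBS4, XP-EHH against each of the three reference populations,
top-1% selection — on 50 seeded replicates of the default sweep
simulation and reports how often the window containing the sweep center is
selected. XP-EHH detection is counted as the union over the three
reference runs, mirroring a multi-reference study design in which
candidate regions from each reference-population run are pooled. Under the
defaults the sweep-center window reaches the PBS4 top-1% and the XP-EHH
top-1% (union) in effectively every replicate, focal $\pi$ inside the
sweep is well under a quarter of the genome background, and windowed
Tajima's $D$ inside the sweep is strongly negative. Problem sizes were
chosen so the full 50-replicate experiment runs in a few minutes on one
core: 20 Mb contig, 30,000 SNPs, 45 diploids.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere; BED input is converted at
  the boundary.
* Multi-allelic and non-SNP records are dropped on read, never split.
* Missing genotypes are allowed only unphased; phased analyses require
  complete data (phasing tools impute in practice).
* Windows with no informative sites are `NA` and excluded from outlier
  distributions; per-bp reporting makes truncated terminal windows
  comparable.
* `hwe_exact_p` works in log space and normalizes at the end, so counts in
  the hundreds are safe; the two-sided tail uses a `1 + 10^{-12}`
  tolerance when comparing configuration probabilities, the standard trick
  to make the enumeration robust to floating-point ties.
* NJ ties and top-1% threshold ties are both broken deterministically
  (lowest index / genomic order) so reruns are byte-identical.
* All generators consume a single integer seed; `set.seed` is called
  internally so identical configs give bit-identical output.

## Known limitations

* XP-EHH uses physical distance; on maps with strong recombination-rate
  variation, scores at hotspots/coldspots are biased relative to a
  genetic-map implementation.
* The pooled-HWE filter can remove strongly differentiated sites (Wahlund
  effect), slightly thinning the very signal the differentiation scans
  target; it is kept because it reproduces the standard merged-set QC, and
  the power experiment shows the signal survives it.
* The composite-likelihood cross-population scan is not implemented; its
  per-window scores are ingested from the shared window TSV and
  thresholded/annotated identically.
* GO-term enrichment of candidate genes is out of scope (external
  databases).
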