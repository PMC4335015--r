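---
title: "Methods: haplotype-based sweep scans and the founder-sweep simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based sweep scans and the founder-sweep simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepwatch)
```

# The analysis model

`sweepwatch` analyses a panel of phased biallelic chromosomes spanning a
targeted region that contains one designated *core variant* — a
putatively causal site with a known derived allele and a declared
inheritance mode for the phenotype it controls (recessive, as for
loss-of-function melanism alleles of *ASIP*, or dominant, as for
gain-of-function alleles of *MC1R*). Three signals of recent positive
selection are computed, each stratified by the allele carried at the
core:

1. **Windowed nucleotide diversity.** For a chromosome subset of size
   $n$ and a window of length $L$ bp,
   $$\pi = \frac{1}{\binom{n}{2}\,L} \sum_{i<j} k_{ij},$$
   with $k_{ij}$ the number of sites where chromosomes $i$ and $j$
   differ. The denominator is the window length in base pairs —
   monomorphic positions count implicitly — because that is the only
   convention under which diversity is meaningfully reported as a
   percentage of sequence (values of order 0.02–0.06% in small wild-cat
   populations). A per-variant-site denominator is exposed as a
   debugging option. Window lengths are taken exactly as supplied: if a
   capture target was repeat-masked, the user should pass the effective
   (masked) lengths; no masking is performed internally.

2. **Extended haplotype homozygosity.** For the class of chromosomes
   sharing one core allele, grouped by their allele strings over every
   site from the core to a target site inclusive,
   $$\mathrm{EHH}(x) = \frac{\sum_h \binom{c_h}{2}}{\binom{n}{2}},$$
   the probability that two randomly drawn class members are identical
   over the whole span. Because the core site itself is included,
   $\mathrm{EHH}(\text{core}) = 1$ exactly, and because groups can only
   refine as sites are added, EHH is non-increasing with distance — a
   property the test suite asserts on fuzzed inputs. EHH is evaluated at
   observed site positions only; plots join points linearly rather than
   interpolating. Two "relative" conventions exist in the literature;
   the package reports both distinctly: each class curve is already
   relative to its own core value (which is 1), and `rel_ehh` is the
   derived/ancestral ratio, left undefined (`NA`, never 0 or $\infty$)
   wherever the ancestral EHH has decayed to zero.

3. **Haplotype bifurcation trees.** Starting from the whole class at the
   core, each successive site splits every node's chromosome set by the
   allele carried there (children ordered allele 0 before 1). Node
   counts are conserved along the tree, and the per-depth quantity
   $\sum_h \binom{c_h}{2}/\binom{n}{2}$ reproduces the EHH curve — an
   internal consistency the tests check. Trees over hundreds of sites
   are mostly singleton paths, so `bifurcation_tree()` takes a
   `max_sites` cap (default 50 in `run_scan()`) for plotting.

## Stratification rules

A chromosome is *derived* or *ancestral* purely by its allele at the
core site; a heterozygous individual therefore contributes one
chromosome to each class. The by-individual stratification (both
chromosomes of every individual in a phenotype class) ignores
chromosome classes entirely; it is less sensitive — non-melanistic
individuals under a recessive model are a mixture of +/+ and +/m — but
allows comparison at loci unlinked to the core. Genotype–phenotype
combinations inconsistent with the declared mode (e.g. a melanistic
heterozygote under a recessive model) are listed in the report's
violations table and excluded from nothing.

## Association and Hardy–Weinberg prediction

The derived allele frequency is $q = (2\,\mathrm{hom} + \mathrm{het}) /
2n$ over all individuals in the supplied table. The predicted phenotype
frequency is $q^2$ (recessive) or $1-(1-q)^2$ (dominant). The
association statistic is the uncorrected Pearson chi-square on the 2×2
obtained by collapsing genotypes under the model (homozygous-derived vs
rest, or carrier vs non-carrier); without continuity correction a
perfectly associated table gives $\chi^2 = n$, which is how published
values of 18 ($n = 18$) and 16 ($n = 16$) arise. No exact test or
multiple-testing correction is applied: the variant is single and
prespecified. Which individuals enter the table is an explicit argument
— published tables sometimes exclude individuals (e.g. of unknown
geographic origin) from frequency rows while the chi-square uses all
genotyped animals, and the package takes the table as given rather than
guessing. Note that a dominant-model table of 16 + 7 individuals yields
$\chi^2 = 23$ under this convention; a published value of 16 for such a
table is not reproducible by an uncorrected Pearson statistic, and the
package does not attempt to match it. All frequencies are carried at
full precision; two-decimal rounding happens only in `*_rendered`
reporting columns.

## Capture arithmetic

Theoretical per-sample coverage is $(\text{reads} \times
\text{bp-per-read-pair}) / (\text{samples} \times \text{region size})$
(default 150 bp per pair, i.e. 75 bp aligned per end), and enrichment is
the ratio of unrounded coverages. Published summaries mix truncation
(0.79 from 0.79998, 2051 from 2051.5, 2564 from 2564.5) with rounding
(492 from 491.7), so `capture_summary()` exposes the full-precision
value plus both renderings and lets the report pin each cell.

# The founder-sweep simulator

The simulator generates the statistical structure the scan assumes,
with ground truth, so that every stage can be validated without
external data.

**Ancestral panel.** `k_founders` founder haplotypes are drawn
site-by-site: the derived count $m$ among founders follows the
neutral-like spectrum $P(m) \propto 1/m$ on $1..k-1$, and founder
alleles are i.i.d. Bernoulli$(m/k)$. Each ancestral chromosome is a
Li–Stephens-style mosaic that copies one founder and switches to a
uniformly chosen founder with per-bp probability `switch_rate`. This
gives tunable background LD — enough to make ancestral EHH decay, which
the derived/ancestral contrast requires — without the cost or
complexity of a full coalescent with recombination; the artifact tests
statistics, not demographic realism. Because two distinct chromosomes
carry independent uniform founders at any one site, the expected
diversity has the closed form
$$E(\pi_\text{site}) = \frac{(k-1)^2}{H_{k-1}\,k^2}, \qquad
H_{k-1} = \sum_{i=1}^{k-1} 1/i,$$
independent of `switch_rate`; `expected_ancestral_pi()` exposes it and
a Monte Carlo oracle in the test suite confirms it.

**Derived class.** One ancestral chromosome becomes the sweep founder
and receives the derived allele at the core (always a fresh column; the
ancestral panel never places a segregating site exactly at `core_pos`,
avoiding the ambiguous collision case). Each derived chromosome copies
the founder out to an Exponential(`rG`)-distributed breakpoint distance
on each side of the core — a single crossover per side, no gene
conversion — and a uniformly chosen ancestral chromosome beyond it,
then gains Poisson(`muG` × L) private mutations at new uniform
positions (new columns, ancestral chromosomes carrying code 0 there,
rather than toggles of existing sites). Under this model the expected
fraction of derived chromosomes unrecombined at distance $d$ is
$e^{-rG\,d}$ and, with `muG = 0`, derived EHH decays approximately as
$e^{-2\,rG\,d}$ — both recovered within 20% by regression in the tests.

**Pairing and phenotype labels.** `emit_dataset()` pairs chromosomes
into diploid individuals at requested genotype counts
(hom-ancestral/het/hom-derived) and assigns phenotypes from the
inheritance mode, so synthetic metadata follow the genetic model
exactly; counts that cannot be paired are an error.

## Default parameters (the simulated study conditions)

| parameter | default | why |
|---|---|---|
| `L` | 500 kb | the scale over which a strong sweep's diversity deficit extends in the motivating data |
| `core_pos` | 250 kb | mid-target, as a causal site inside (not at the edge of) a capture design |
| `n_anc`, `n_der` | 40 + 40 | 2× the chromosome counts of a 13–21-individual species sample, at the upper end typical for wild-felid studies |
| `n_sites` | 850 | chosen via the closed form so $E(\pi) \approx 0.05\%$ per bp, the middle of the 0.018–0.057% range observed in these populations |
| `k_founders` | 8 | enough founder lineages for realistic haplotype sharing (ancestral EHH plateau near $1/k$) |
| `switch_rate` | $10^{-5}$/bp | ~5 expected mosaic switches per 500 kb: background LD decays across, not within, windows |
| `rG` | $5 \times 10^{-6}$/bp | mean unrecombined tract of 200 kb per side, matching a sweep whose footprint spans most of the target |
| `muG` | $10^{-6}$/bp | ~0.5 private new mutations per derived chromosome — a young sweep; set to 0 in decay-rate recovery checks so recombination alone drives EHH |

No estimate of sweep age or local recombination rate exists for the
motivating populations, so `rG` and `muG` are free model parameters,
not species calibrations. Datasets are tiled into 9 equal windows by
default: an odd count centres the middle window on the default core
position, mirroring a design where the causal site lies inside a
fosmid, and avoiding the degenerate geometry of a core on a window
boundary (where a "core window" captures only one sweep flank).

# Numerical and design choices

- **Coordinates.** Windows are 0-based half-open (BED convention)
  internally; site and core positions are 1-based (VCF convention);
  conversion happens only at the boundary, so a site at `pos` is in
  `[start, end)` iff `start < pos <= end`.
- **Missing data.** Missing or unphased genotypes are hard errors, not
  imputed — phasing/imputation belongs to the upstream pipeline, and the
  matrix admits no missing entries. Ploidy is fixed at 2; multiallelic
  sites are rejected rather than split. All phased chromosomes are
  treated as equally trusted.
- **SEM.** The reported SEM is the standard deviation of per-pair
  per-site differences divided by $\sqrt{\binom{n}{2}}$. Pairs share
  chromosomes and are not independent, so this is a descriptive error
  bar, not a confidence interval; published diversity figures label
  their error bars SEM without defining the unit of replication, and
  this is the most literal reading.
- **Degenerate cells.** A class with fewer than two chromosomes yields
  `NA` diversity (undefined, never 0); a window with no sites counts one
  haplotype by convention; EHH for a class of fewer than two chromosomes
  is `NA`.
- **Density thinning.** `thin_variants()` partitions each window into
  1 kb bins from the window start and keeps the highest-quality site per
  bin (ties and missing qualities fall back to the smallest position),
  emulating the ~1-variant-per-kb filters applied in capture pipelines;
  off-target sites are dropped.
- **Determinism.** All randomness lives in the simulator and derives
  from the seed in its parameter object; `run_scan()` has no hidden
  state, records an md5 hash of its configuration, and writes
  byte-identical tables on reruns.

# What the synthetic data do and do not show

The generator reproduces the features the statistics rely on — a
low-diversity, high-EHH derived class against a structured ancestral
background, allele-frequency spectra of roughly neutral shape, phenotype
labels faithful to an inheritance model — and the test suite validates
the statistics against brute-force oracles, closed forms, and an
established diversity implementation (`ape`'s raw pairwise distances)
at agreement to at least six decimals. It does **not** emulate
demography (bottlenecks, structure, migration), gene conversion,
variable recombination or mutation rates, genotyping error, or
ascertainment from read depth. Passing tests therefore demonstrate the
correctness of the computations and the detectability of a founder
sweep under the stated model, not the power of the scan on any
particular real population.

Problem sizes used in the validation runs — 40 + 40 chromosomes
(200 derived for decay-rate recovery), ~850 sites over 500 kb, 10–20
simulator replicates per property — were chosen as the smallest panels
at which the Monte Carlo properties are stable.

# Known limitations

- Fst, Tajima's D, Watterson's θ, iHS/XP-EHH and genetic-map distances
  are out of scope; distances are physical bp.
- The bifurcation tree records splits at every site, so very long
  site runs produce large (if mostly path-shaped) trees; use
  `max_sites` for display.
- The chi-square relies on the asymptotic distribution; for the small
  perfectly associated tables it reproduces, the statistic (not the
  p-value) is the quantity of interest.
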