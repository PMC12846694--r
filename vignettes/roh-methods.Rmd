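---
title: "Methods: sliding-window ROH detection, FROH and island analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window ROH detection, FROH and island analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

# The model

A run of homozygosity (ROH) is a contiguous stretch of a diploid genome
where both haplotypes are identical, typically because they descend from a
common ancestor (autozygosity). On a medium-density SNP array an ROH is
observable only through the markers it covers, so detection must tolerate
occasional genotyping errors (isolated heterozygous calls inside a true
autozygous tract) and missing calls, while rejecting chance runs of
homozygosity that arise wherever allele frequencies are skewed.

`rohscan` implements the sliding-window heuristic popularized by PLINK.
Per individual and chromosome:

1. a window of `window_snps` consecutive markers slides one marker at a
   time; a window is *homozygous* when it contains at most `window_max_het`
   heterozygous and `window_max_missing` missing calls;
2. each marker is scored by the fraction of windows covering it that are
   homozygous, and becomes *eligible* when that fraction reaches
   `window_hit_threshold`;
3. maximal runs of consecutive eligible markers — split wherever adjacent
   markers lie more than `max_gap_bp` apart — become candidate segments;
4. candidates survive when they span at least `min_length_bp`, contain at
   least `min_segment_snps` markers, and keep at least one SNP per
   `min_density_bp_per_snp`.

The genomic inbreeding coefficient of an individual is

$$F_{ROH} = \frac{L_{ROH}}{L_{AUTO}},$$

where $L_{ROH}$ is the summed length of its ROH and $L_{AUTO}$ is the
autosomal span covered by the marker panel, computed per chromosome as
last minus first retained marker position plus one (1-based inclusive) and
summed. Because a segment can at most tile the covered span, $F_{ROH}$
lies in $[0, 1]$ and is additive in segments — properties the test suite
checks directly.

# Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `window_snps` | 50 | markers | standard window for ~50K arrays; smaller windows inflate chance runs |
| `window_max_het` | 1 | calls | tolerates one genotyping error per window |
| `window_max_missing` | 2 | calls | tolerates sparse missingness without breaking tracts |
| `min_length_bp` | 1 Mb | bp | suppresses short LD-driven homozygosity |
| `min_density_bp_per_snp` | 100 kb | bp/SNP | guards against segments spanned by few markers |
| `max_gap_bp` | 500 kb | bp | keeps distant regions from being merged |
| `window_hit_threshold` | 0.05 | fraction | PLINK's default window hit rate |
| `min_segment_snps` | 50 | markers | set equal to the window size; PLINK's separate per-segment minimum is configurable here |
| QC: `maf_min` | 0.05 | fraction | removes near-monomorphic markers that mimic homozygosity |
| QC: `snp_call_rate_min` | 0.90 | fraction | standard marker call-rate floor |
| QC: `sample_missing_max` | 0.10 | fraction | standard sample ceiling |
| QC: `breed_min_n` | 5 | individuals | breed-level summaries below this are dominated by noise |
| islands: `top_fraction` | 0.01 | fraction | hotspot SNPs are the top 1% of the ROH-incidence spectrum |
| annotation: `flank_bp` | 50 kb | bp | 100 kb windows (50 kb each side) around hotspot SNPs |

All of these are exposed as function arguments and echoed into the
pipeline manifest, so a run documents its own configuration.

# Numerical and design choices

Several points are under-determined by common practice; the package fixes
them explicitly:

* **Filter order.** QC applies sample missingness → SNP call rate → MAF →
  breed size, in that order, with MAF computed on non-missing calls of the
  retained samples. PLINK applies sample and marker filters jointly, so
  counts can differ at threshold boundaries; the chosen order is
  deterministic and idempotent (verified by test).
* **$L_{AUTO}$ timing.** The span is computed on post-QC markers — the
  denominator describes the panel actually scanned for ROH. Removing
  interior markers leaves it unchanged; removing a chromosome's extreme
  markers shrinks it.
* **Length classes.** The five reporting bins (1–5, 5–10, 10–20, 20–40,
  > 40 Mb) are half-open with boundaries assigned upward: exactly 5 Mb
  falls in 5–10. Shared endpoints in the conventional labels are otherwise
  ambiguous.
* **Hotspot ties.** The hotspot threshold is the $1 -$ `top_fraction`
  quantile (R type-7) of the incidence values, and *all* markers at or
  above it qualify. Including ties avoids an arbitrary choice among
  equally frequent markers, at the cost of occasionally returning more
  than exactly 1%; markers with zero incidence never qualify even when the
  quantile is zero.
* **Island construction.** Hotspot markers consecutive in map order with
  gaps ≤ 500 kb (the same bound as the ROH gap rule, in the absence of a
  separate convention) form one island; an isolated hotspot yields a
  degenerate island with start = end, which is retained.
* **Sharing.** Two islands are "shared" on ≥ 1 bp overlap, exposed as
  `min_overlap_bp`; no reciprocal-overlap fraction is imposed. Three-set
  (Venn) region counts are reported from each group's own perspective —
  a pairwise region count as seen from group A need not equal the count
  seen from B, and the headline numbers are taken from the first-listed
  group.
* **Segment polarity in PED text.** The text reader assigns allele A1 by
  first appearance per marker, so 0/2 polarity depends on sample order;
  hom/het/missing structure — all that ROH analysis consumes — is
  polarity-invariant. Binary input takes polarity from the BIM file and
  round-trips bit-exactly.
* **Short chromosomes.** A chromosome with fewer markers than one window
  is scanned with a single window covering the whole chromosome, so tiny
  test instances behave like a degenerate case of the same rule rather
  than a special path.
* **Coordinates.** 1-based inclusive throughout (PLINK convention); BED
  output converts to 0-based half-open on write.

# The brute-force oracle

`call_roh_bruteforce()` re-derives the same contract with naive
enumeration — every window recounted by slicing, every marker's covering
windows found by scanning, runs built by walking markers one at a time —
and shares no code with the fast scan (which uses cumulative sums and
vectorized hit-rate computation). The two paths are compared for set
equality of segments on hundreds of randomized instances spanning the
parameter grid (window 10–30 SNPs, 0–2 heterozygotes, 0–3 missing, gap
bounds 100–800 kb, length floors 0.5–2 Mb). Any divergence between an
optimization and the definition is caught by construction.

# What the simulator emulates — and what it does not

`simulate_panel()` produces a multi-breed diploid autosomal panel:
evenly spaced markers, per-breed per-marker allele frequencies drawn
uniformly from [0.05, 0.5], Hardy–Weinberg background genotypes, optional
missingness and hom↔het genotype error, and implanted autozygous tracts
(one founder haplotype drawn and doubled) whose coordinates are recorded
as truth *before* noise. Tract lengths default to a mixture over the five
length classes weighted like a worldwide 50K pig panel (~8/53/29/8/1%,
minimum 3 Mb — near the shortest segments such arrays resolve); random
tracts of one individual are kept ≥ 3 Mb apart so implanted segments stay
distinct under calling.

Deliberately **not** simulated: background linkage disequilibrium (markers
are independent given frequencies), recombination maps, admixture and
coalescent ancestry. Consequently chance homozygosity is rarer than in
real data and short-ROH behavior (≲ 2 Mb) is optimistic: passing recovery
tests demonstrates the machinery is correct, not that a real panel's short
segments are called with the same sensitivity. With independent markers at
these frequencies a 50-SNP window is essentially never homozygous by
chance, which the false-positive guard test (common-frequency background,
no tracts, zero called segments ≥ 2 Mb) confirms.

The default desk-scale panel is 2 chromosomes × 2,000 markers (one SNP per
50 kb, $L_{AUTO} \approx 200$ Mb) × 60 individuals in 4 breeds. The test
suite and the acceptance script use this scale throughout: it exercises
every stage, including island sharing across three population pools, in
seconds per run.

# Degenerate inputs and edge behavior

Empty segment sets yield zero-count summaries ($F_{ROH} = 0$), header-only
ROH tables and all-zero incidence tracks; an all-zero incidence track
yields an empty hotspot set with a warning; a breed of one individual has
undefined dispersion, reported as 0 with `sd_defined = FALSE`; a sample
with no non-missing calls has undefined heterozygosity and is always
flagged (never removed — heterozygosity screening is advisory, with a
configurable 3-SD flag). QC that removes everything raises an explicit
error rather than returning an empty panel.

Called segment boundaries are shaved by roughly two markers per side
relative to an implanted tract: a tract-edge marker is covered mostly by
windows that extend into the non-autozygous flank, so its hit rate falls
below the 5% threshold. At one SNP per 50 kb this is ~100 kb per
endpoint, well inside one window span; the recovery tests measure it.

# Known limitations

* The heuristic is a detector, not a likelihood model: no HMM-based
  posterior segmentation, no sequence-data support.
* PED text input cannot preserve 0/2 polarity without an external allele
  reference (BIM input does).
* Enrichment analysis is out of scope by design: the contract ends at
  reproducible, deduplicated gene lists per group, because GO/KEGG
  results depend on the release of an external service's databases.
* Island sharing is descriptive; no permutation null is attached to the
  overlap counts.
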