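---
title: "Methods: 4C-seq contact maps, permutation-FDR interaction calling and enhancer annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4C-seq contact maps and enhancer annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourcmap)
```

## The analysis

Circular chromosome conformation capture sequencing (4C-seq) measures the
genome-wide DNA contacts of one chosen viewpoint (the *bait*), typically a
gene promoter or enhancer. Chromatin is crosslinked, digested with a
frequent-cutting primary enzyme (a 4-cutter such as DpnII), religated so
that fragments in spatial proximity become covalently joined, digested
again with a secondary enzyme and circularised, and the ligation partners
of the bait fragment are amplified by inverse PCR from bait-specific
primers and sequenced. The per-fragment read counts of the resulting
library estimate the bait's contact frequency with every restriction
fragment of the genome.

`fourcmap` implements the full desk-side analysis of such an experiment:

1. **Restriction map** (`digest_genome()`, `flag_mappability()`): the
   genome is cut in silico at every occurrence of the primary motif; the
   fragments are the coordinate system of everything downstream.
2. **Bait demultiplexing** (`demultiplex()`, `trim_and_filter()`): read
   pairs are assigned to baits by exact (0-mismatch) primer match in the
   correct mate orientation, the primer is trimmed up to but excluding the
   digestion-site motif, 3' bases under Phred 20 are trimmed, and reads
   shorter than 30 bp are dropped.
3. **Quantification** (`align_exact()`, `count_per_fragment()`,
   `apply_filters()`): reads are aligned (uniquely and exactly, on the toy
   genomes the package targets; real data would use an external aligner
   and enter as pre-aligned loci), counted per fragment, and cleaned with
   the three standard artefact filters — self-ligated reads (the bait
   fragment itself), uncut reads (the two fragments index-adjacent to the
   bait), and every fragment with at least one read in the non-ligated
   control library.
4. **Profiles** (`rpm_normalize()`, `running_window_sum()`,
   `cumulative_distance_curve()`): the displayed contact profile is the
   reads-per-million-normalised sum over nine successive fragments.
5. **Interaction calling** (`call_bait()` and friends): permutation-FDR
   significance on 3-fragment window sums, with robustness categories.
6. **Annotation** (`intersect_replicates()`, `find_tf_clusters()`,
   `call_enhancer_candidates()`, ...): replicate reproducibility, domain
   counts, gene/promoter overlap, and enhancer candidates from
   transcription-factor co-binding clusters.

## The significance model

For one bait and one analysis region (a whole chromosome, or a
sub-interval such as the contact domain), let \(x_1, \dots, x_m\) be the
filtered read counts of the region's *mappable* fragments in genomic
order (unmappable fragments are excluded entirely, so their neighbours
become window-adjacent). The test statistic is the sliding window sum

\[ W_i = \sum_{j=i}^{i+w-1} x_j, \qquad w = 3 . \]

The null model treats the per-fragment counts as exchangeable: each
permutation uniformly shuffles the multiset \(\{x_j\}\) across the
region's mappable fragments and recomputes all window sums. Candidate
thresholds are the distinct observed window sums at or above the
\(1 - \texttt{fdr\_prob}\) empirical quantile of all observed window sums
(`fdr_prob = 0.05`: only the top fifth percentile of windows can become
significant). For each candidate \(T\),

\[ \widehat{\mathrm{FDR}}(T) \;=\;
   \frac{\frac{1}{B}\sum_{b=1}^{B} \#\{i : W^{(b)}_i \ge T\}}
        {\#\{i : W_i \ge T\}}, \qquad B = 1000, \]

and the calling threshold is the smallest candidate with
\(\widehat{\mathrm{FDR}}(T) < 0.01\). Windows at or above the threshold
are merged when they overlap or are adjacent in mappable-index space;
each merged run becomes one significant interval whose genomic extent is
the union of its member fragments.

Intuitively, this rewards *clustered* signal: a window of three elevated
fragments is far beyond what a random scatter of the same count multiset
produces, whereas a single high fragment is exactly as likely to appear
in a permuted window and therefore cannot, by itself, achieve a low FDR.

**Robustness categories.** Let \(m\) be the member fragment with the
highest count (ties to the lowest index). An interval is category 1 if
some member window still reaches the threshold with \(m\)'s count set to
0; category 2 if it reaches the threshold with \(m\)'s count replaced by
the mean of its two flanking mappable fragments; category 3 otherwise.
Category 3 intervals are driven by a single fragment and are discarded
before replicate overlap. Replicate-reproducible intervals (>= 1 bp
overlap between the two replicates; the reported span is the
intersection) are coloured red when both parents are category 1 and
orange otherwise. Categories are recomputed at the original threshold
rather than by re-running permutations: deterministic, and faithful to
"significant after removal" under a fixed criterion.

**Viewpoint-proximal exclusion.** The exchangeability assumption is
wrong near the viewpoint: cis contact frequency decays smoothly with
distance, so the bait-proximal profile is a genuine, reproducible,
contiguous elevation that the shuffle null always flags. Following
common 4C practice the caller therefore supports an exclusion radius
around the bait (`exclude_bp`; the packaged scenario uses 25 kb, the
default is 0 so that nothing is excluded unless asked for). The bait
fragment and its two index-adjacent neighbours are always excluded; they
were zeroed by the upstream filters in any case.

**Numerical choices.** The candidate floor uses the inverse-ECDF
(type 1) quantile, so candidates are always actual observed window sums;
ties in the FDR table are handled by taking the *smallest* qualifying
candidate; an estimated FDR with zero observed exceedances cannot occur
(candidates are observed sums). Counts are integers, so all window
arithmetic is exact and the implementation can be compared bit-for-bit
with a brute-force reference. The permutation stream is reproducible:
`set.seed(seed)` followed by one `sample.int()` per iteration, with one
recorded seed per (bait, region).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `w` | 3 fragments | calling window |
| `iterations` | 1000 | permutations per region |
| `fdr` | 0.01 | FDR cutoff |
| `fdr_prob` | 0.05 | candidate floor: top fifth percentile of window sums |
| `k` | 9 fragments | display profile window (windowed *sum*; `mean = TRUE` divides by the effective window size) |
| `qual_min` / `len_min` | 20 / 30 bp | 3' quality trim and minimum retained read length |
| `min_tfs` | 6 | distinct co-bound TFs required for an enhancer cluster |
| `max_dist` | 2000 bp | maximum gap between a cluster and a supporting interval |
| `promoter_ext` | 2000 bp | promoter window 5' of the TSS for gene overlap |

The RPM denominator is the *post-filter* retained read total of each
library, which makes replicate profiles comparable after their (slightly
different) blacklists; the pre-filter alternative differs only by a few
percent on realistic libraries.

## The synthetic scenario

Real 4C libraries are large and external; the package instead ships a
seeded generator whose outputs have known ground truth, and the test
suite validates the pipeline end to end against it
(`standard_scenario()`, `analyse_scenario()`).

The generator emulates, per library: bait-primer-anchored read pairs
whose forward mate runs through the primary digestion site into the
captured fragment; a self-ligated fraction (5%) mapping to the bait
fragment; an uncut fraction (5%) mapping to the bait's index-adjacent
fragments; mate order randomised (the demultiplexer re-normalises it);
constant high base qualities (the quality-trim path is exercised by
dedicated low-quality fixtures in the tests, not by the simulator). The
control library draws its captured fragments uniformly from a sparse
random 1.5% fragment subset — not a physical no-ligation chemistry
model; its only pipeline role is the blacklist filter, which this
suffices to exercise.

Captured fragments are drawn from the weight model

\[ w_j \;=\; \epsilon + \gamma_j\, \eta_j\, \beta^{\mathrm{cross}(j)}
   \left(1 + |mid_j - mid_{bait}|/s\right)^{-\alpha}, \]

with decay scale \(s = 100\) kb, exponent \(\alpha = 1\), background
\(\epsilon = 2\times 10^{-3}\), boundary attenuation \(\beta = 0.2\) for
fragments outside the 400 kb domain, a small uniform trans weight on the
second chromosome, and lognormal per-fragment efficiency noise
\(\eta_j\) (sdlog 0.45, mean 1, independent per library) on unplanted
fragments. The noise reflects the strong per-fragment overdispersion of
real 4C counts (fragment length, GC and ligation efficiency); it is also
what makes the permutation null calibrated on unplanted profiles —
without it the smooth decay envelope is an unrealistically clean signal
that any exchangeability test flags. Planted weights are left exact
because they are the controlled ground truth. The decay scale is chosen
relative to the 400 kb toy domain (the real counterpart spans about
1 Mb); it produces the expected domain-concentrated cumulative read
curve (about 85% of cis reads inside the domain) while leaving distal
within-domain contacts quantifiable.

The standard conditions are: a 500 kb main chromosome (about 2000 DpnII
fragments) plus a 120 kb trans chromosome; one bait at the active P1
promoter of a two-promoter gene; five planted enhancer loci at −70, −55,
−40, +40 and +70 kb from the P1 TSS, each a run of seven consecutive
mappable fragments with planted weight \(\gamma = 20\) (seven, so that a
single control-blacklist hit can never remove every complete calling
window of a locus); 2×10^5 reads per replicate and 2×10^4 control reads;
six-TF co-binding clusters at each planted locus, a five-TF decoy inside
the main chromosome and a six-TF decoy on the trans chromosome (never
near a called interval); Rad21 peaks without CTCF at two planted loci.

What passing tests on this scenario do **not** show about real data: no
PCR duplicates, GC bias or sequencing errors are modelled; alignment is
exact-unique rather than Bowtie-style; per-fragment efficiency noise is
independent between replicates (real efficiency is partly shared, which
would make reproducibility a weaker guard than it is here); and real
enhancer contacts are themselves subject to efficiency variation,
whereas planted weights are exact.

## Problem sizes used by the tests

The packaged validation runs at deliberately modest sizes chosen as
representative: the full standard scenario (2×10^5 reads per replicate)
once; the Poisson null calibration at 100 simulations of 300 fragments;
oracle equivalence of the caller on 60-fragment vectors at 1000
permutations; pipeline determinism on a 10^4-read demo configuration.

## Known limitations and open choices

* The mappability criterion (unique fragment-leading k-mer, both
  strands) is an intrinsic surrogate for an alignability track; real
  runs can override it with a mappable-fragment BED.
* Whether the original analyses applied the control blacklist per bait
  or globally is not documented; `apply_filters()` works per bait, with
  the control library demultiplexed identically.
* "Neighbouring fragments" in the category-2 rule means mappable-index
  neighbours, which may lie outside the interval.
* Trans (inter-chromosomal) calling beyond whole-configured-region mode
  is out of scope, as is automated domain-boundary detection — domains
  are user-supplied intervals.
* Manual additions to the enhancer set (elements adjacent to, but not
  meeting, the co-binding rule) are supported only via an explicit
  include list, never inferred.
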