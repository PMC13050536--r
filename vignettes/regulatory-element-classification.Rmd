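---
title: "Classifying cis-regulatory elements with a two-phase rule engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cis-regulatory elements with a two-phase rule engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creclass)
```

## The problem

Enhancers, promoters and CTCF-bound boundary elements cannot be measured
directly at scale; their identity is inferred from chromatin features.
Active promoters carry H3K4me3 (and H3K27ac), enhancers carry H3K4me1 (and
H3K27ac when active), and boundary elements are bound by CTCF. HMM-based
segmentation tools learn latent states from these marks and require a
manual state-to-label assignment afterwards. `creclass` takes the opposite
approach: a fixed, auditable decision rule over the **relative** strength of
the four marks at each candidate region. Every label can be explained by
pointing at the region's signal ranks.

The unit of annotation is the candidate region, not the genome: only loci
anchored by a chromatin-accessibility peak or a CTCF peak are classified.
Regions without such evidence of regulatory potential are never labelled,
which is why the pipeline starts from peak calls rather than from a
genome-wide tiling.

## Model and assumptions

For regions $r$ and tracks $t_1=\mathrm{H3K4me1}$, $t_2=\mathrm{H3K4me3}$,
$t_3=\mathrm{H3K27ac}$, $t_4=\mathrm{CTCF}$:

$$A_{rt} = 10^6\,\frac{auc(r \cap b_t)}{auc(\mathrm{genome})_t}$$

where $auc$ is summed per-base read coverage, $b_t$ the peak set of track
$t$, and $r \cap b_t$ their base-level intersection (possibly several
fragments, summed; possibly empty, giving exactly 0). Within each region the
four signals are ranked descending into $R_{rt}\in\{1,2,3,4\}$.

Phase 1 assigns the main class:

* **Enhancer** if $(R_{rt_1}{=}1 \wedge R_{rt_2}{=}2) \vee (R_{rt_1}{=}1
  \wedge R_{rt_3}{=}2) \vee (R_{rt_1}{=}2 \wedge R_{rt_3}{=}1) \vee
  (R_{rt_1}{=}1 \wedge A_{rt_2}{=}A_{rt_3}{=}A_{rt_4}{=}0)$
* **Promoter** — the mirror image with $t_2$ in place of $t_1$
* **CTCF** if $(R_{rt_4}{=}1 \wedge R_{rt_3}{=}2) \vee (R_{rt_4}{=}2 \wedge
  R_{rt_3}{=}1) \vee (R_{rt_4}{=}1 \wedge A_{rt_1}{=}A_{rt_2}{=}A_{rt_3}{=}0)$
* otherwise **Not assigned**.

Phase 2 detects CTCF co-occupancy and overrides phase 1 when it fires:
**Enhancer/CTCF** when CTCF and H3K4me1 hold the top two ranks (both
nonzero), or on the sign pattern $A_{rt_1}{\neq}0, A_{rt_2}{=}0,
A_{rt_3}{\neq}0, A_{rt_4}{\neq}0$; **Promoter/CTCF** mirror-wise with
H3K4me3. Enhancer-class regions are subclassed *active* when
$A_{rt_3}$ exceeds the activity threshold, else *inactive*.

The rule engine assumes the four tracks were processed comparably enough
that within-region rank comparisons are meaningful; the per-million
normalization removes depth differences (and the suite asserts exact
invariance under k-fold read duplication) but cannot correct antibody
efficiency or signal-to-noise differences between assays.

## Numerical and design choices

**Ranking ties.** The rank transform maps to strict $\{1,2,3,4\}$, but real
rows tie (most commonly at 0). Ties are broken by a fixed track priority,
H3K4me3 > H3K4me1 > CTCF > H3K27ac, chosen to favour the promoter-then-
enhancer reading of ambiguous rows and kept in one constant
(`tie_priority`) so the policy is swappable. An all-zero row is forced to
"Not assigned" *before* clause evaluation: its ranks are pure tie-break
artifacts and would otherwise satisfy an "only this track nonzero" clause
vacuously.

**Zero tests are exact.** $A_{rt} = 0$ iff the region has no peak-restricted
coverage at all, which the quantifier produces as an exact floating-point 0;
no tolerance is used, and no pseudocounts are added anywhere.

**auc = area, not read count.** `auc` is defined as summed per-base
coverage: it makes the numerator and the genome-wide denominator
dimensionally identical and is invariant to read fragmentation. A
read-count variant is available (`auc_mode = "read_count"`: reads
overlapping the intersection, per million mapped reads) behind the same
interface. Reads contribute their full CIGAR-consumed reference span;
soft-clips are excluded; duplicate and QC-fail reads are dropped by default.

**Union regions.** "Unique peaks" means exact-coordinate deduplication, not
interval merging: overlapping accessibility and CTCF peaks of different
extents stay separate candidates, because each region is quantified
independently and merging would silently change the region count. The
canonical region order is coordinate order; the H3K4me3−H3K4me1
coverage-difference ordering (from the bigWig coverage matrix) is exposed
separately and used only to stack metaplot rows. A config switch
(`anchor_mode`) restricts anchoring to accessibility peaks alone for
datasets where CTCF-only anchors are not wanted.

**Phase-2 scope.** Whether the hybrid clauses apply to every region or only
to regions phase 1 already labelled Enhancer/Promoter is genuinely open; the
default (`hybrid_scope = "all"`) lets Not-assigned rows gain a hybrid label
via the sign-pattern clauses, since those clauses express exactly the
"accessible + CTCF-bound + acetylated" configuration the hybrid classes
describe. The restricted behaviour is one option away. If both hybrid
clause sets ever fired simultaneously (impossible under strict ranks — the
two sign-pattern clauses contradict each other on the H3K4me1 zero status),
the larger of $A_{rt_1}$ vs $A_{rt_2}$ decides.

**Activity threshold.** No numeric H3K27ac activity cutoff is part of the
rule set; the default 0 reads as presence/absence and is a tunable
(`activity_threshold`, in the same per-million units as the signals).

**Blacklist.** Any overlap of ≥ 1 bp removes a candidate region whole;
nothing is trimmed. Coordinates are BED-convention 0-based half-open
throughout; GFF input is converted on read. No blacklist ships with the
package — any BED works.

**Distances.** A TSS is the gene's start on the forward strand and its last
covered base on the reverse strand. The per-element distance is the gap in
bp from the region edge to the nearest TSS, 0 when the TSS lies inside the
region, reported as $\log_{10}(d+1)$.

**Metaplots.** Windows of ±2000 bp around `floor((start+end)/2)`, mean
coverage per 10 bp bin (bin width is a rendering choice, configurable);
bases beyond chromosome ends read 0.

## What the synthetic data emulates

`simulate_dataset()` plants non-overlapping archetype regions (default
600 bp, 200 kb single-chromosome genome) and, per track, places fixed-length
50 bp single-end reads uniformly within each planted region, with count
Poisson around *intensity × reads_per_unit* (default 20, floored at one read
so a planted mark is never silent). The default profiles — Promoter
(1, 10, 6, 0), Enhancer (10, 1, 6, 0), CTCF (0, 0, 2, 10), Promoter/CTCF
(0, 8, 5, 9), Enhancer/CTCF (8, 0, 5, 9), Not assigned (0, 0, 0, 0) in
(H3K4me1, H3K4me3, H3K27ac, CTCF) units — give each class at least a 5×
separation on its discriminating marks and are validated against the rule
engine at construction rather than trusted. `noise_level` adds uniform
background reads in proportion to each track's planted reads; peaks are
emitted exactly at planted regions (plus optional decoys), and tracks no
archetype uses receive a handful of ambient reads so their normalization
denominator stays positive.

This emulates relative mark intensities, sequencing-depth variation and
background noise. It does **not** emulate fragment-size distributions, GC or
mappability bias, peak-caller boundary error, replicate structure, or the
scale of a real genome — so a passing recovery test demonstrates the
correctness of the quantification-ranking-classification chain, not
robustness to the full messiness of real ChIP-seq. Problem sizes in the
test-suite and acceptance script (60 planted regions noise-free; 20 seeds ×
30 regions at 10% noise; 20 random ≤ 100 kb genomes for the pileup oracle)
were chosen as the smallest sizes at which every class and clause is
exercised repeatedly.

## Validation strategy

Three independent oracles back the tests: (i) a table-driven clause
evaluator re-states the phase-1/phase-2 rules and is compared with the
implementation over every consistent combination of strict-rank permutation
and zero pattern; (ii) a brute-force per-base pileup computes every signal
entry on random toy genomes (agreement required to 1 part in 10⁹); (iii)
planted-truth recovery runs the full pipeline from files on disk — BAM,
bigWig and BED round-trip through Rsamtools/rtracklayer — and demands 100%
label recovery in the noise-free setting and ≥ 95% mean recovery at 10%
background noise over 20 seeds (the package's own regression bound).
Determinism is asserted as byte-identity of the output annotation across
reruns and across 1- vs 4-worker quantification.

## Known limitations

* Repressive and poised states (H3K27me3, H3K9me3) are outside the label
  set; a region dominated by them will read "Not assigned" or mislead via
  its accessible marks.
* The clause sets encode one cell-type-agnostic prior about mark order;
  they have no confidence measure, and near-tie rows flip labels on small
  signal changes.
* Stage outputs are recomputed on every run; the manifest records input
  checksums so reruns are verifiable, but no checksum-based stage cache is
  implemented — at the intended scales a rerun costs seconds.
* `workers > 1` uses `parallel::mclapply` (fork-based); on platforms
  without forking it falls back to serial behaviour inside one worker.
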