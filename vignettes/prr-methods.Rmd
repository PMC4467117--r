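---
title: "Methods: consensus regulatory regions, PRR discovery and allele-specific statistics"
author: "prrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus regulatory regions, PRR discovery and allele-specific statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prrtools)
```

This vignette is the package's own account of its models, parameters and
numerical choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The problem

Most trait-associated genetic variation is noncoding. A SNP inside an
enhancer or promoter can change a transcription-factor contact and thereby
alter target-gene expression. The package nominates such candidates — we
call them *polymorphic regulatory regions* (PRRs) — by combining three
genome-scale inputs: (i) per-cell-line chromatin peaks for histone marks
and open-chromatin assays, (ii) TF binding regions, and (iii) a SNP
catalog. It then supplies the quantitative statistics used downstream when
a candidate is taken to the bench: allele-specific binding (Fisher exact
test on allele quantifications), ΔΔCt expression, percent-input ChIP
enrichment, and response-element consensus-motif impact.

## 2. Consensus regulatory regions

For one marker and peak sets from $n$ cell lines, `build_consensus()`
applies:

1. **retain** — peak $P$ from cell line $i$ is kept iff some peak $Q$ from
   a cell line $j \ne i$ satisfies
   $\mathrm{overlap}(P, Q) \ge f \cdot |P|$ with $f =$
   `min_overlap_fraction` (default 0.5);
2. **concatenate** the retained peaks of all cell lines;
3. **sort and merge** them into disjoint regions (`merge_intervals()`).

Design choices where the procedure, as usually stated, leaves room:

- *"a second cell line" is existential*: any other cell line may supply
  the partner. A designated-pair reading is incoherent for $n > 2$.
  With `min_supporting_cell_lines` $= k > 2$, qualifying partners must
  come from at least $k-1$ distinct other lines.
- *The overlap fraction is relative to the candidate's own length*, so
  retention is asymmetric: for cellA $[100,200)$ and cellB $[150,300)$,
  A's peak is retained ($50/100 \ge 0.5$) but B's is not
  ($50/150 < 0.5$). The symmetric, stricter variant is available as
  `reciprocal = TRUE`. The threshold is $\ge$, because "at least 50%"
  includes equality.
- *Retention is single-pass*: the partner $Q$ need not itself be
  retained. An iterative (fixed-point) variant would be stricter; nothing
  in the stated procedure requires it, and single-pass keeps
  retained-set semantics simple ("has support elsewhere").
- *Book-ended intervals merge by default* (`merge_bookended = TRUE`):
  "sort and merge" does not say whether touching peaks coalesce; merging
  matches common peak-merge tooling, and the flag exposes the choice.
- *Strand is ignored*; histone and TF peaks are unstranded.
- *Coordinates are 0-based half-open everywhere* (BED convention); VCF
  positions are converted on ingest. Intervals live in
  `GenomicRanges::GRanges` internally; `granges0()`/`as_bed0()` convert.

Provenance (which cell lines' original peaks back each merged region) is
kept through the merge so consensus regions remain auditable.

## 3. Chromatin-state classification and PRR discovery

H3K4me1 without H3K4me3 marks enhancers; H3K4me1 with H3K4me3 marks
promoters. `classify_snp_context()` implements exactly that; positions in
neither (or in H3K4me3 alone) are `unclassified`. For full records,
`annotate_snps()` derives the class from the set of markers whose
consensus contains the SNP, with two further buckets for SNPs carrying
only acetylation (H3K9ac/H3K27ac → `acetylation`) or only open-chromatin
(DNase/FAIRE → `open_chromatin`) evidence; acetylation is checked first —
the order only matters for records lacking any methylation signal and is
a labelling convention, not a claim about biology.

TF attachment has two first-class semantics, because a summary count of
"SNPs in regions bound by a TF" does not pin down whether the TF peak
must cover the SNP itself:

- `region_overlap` (default): the TF peak overlaps (≥ 1 bp) a consensus
  region containing the SNP;
- `snp_in_peak`: the SNP position itself lies inside a TF peak.

`proximity_bp` (default 0 — strict containment) admits SNPs near a
region; the distance convention counts the first base beyond a region
edge as distance 1, so a SNP at position 205 is 6 bp from a region
ending at 200 (last inside base 199). The cross-tabulation
(`marker_crosstab()`) counts **distinct rsIDs** per marker row — with the
promoter pattern as the H3K4me1 ∩ H3K4me3 row and `Union` over the six
marker categories — per single-TF column and per all-TF intersection
column. Two invariants hold by construction and are asserted on every
generated instance: intersection ≤ min of single-TF columns (row-wise),
and each marker row ≤ the Union row (column-wise).

## 4. Allele-specific statistics

**Allele fraction.** $(A/(A+G)) \cdot 100$; complements sum to 100.

**Fisher exact test** (`fisher_allele_test()`): 2×2 table with rows
input/ChIP and columns A/G. The two-sided p-value follows the
probability-ordering definition — sum the hypergeometric masses, at the
observed margins, of all tables at most as probable as the observed one
(relative tolerance $1+10^{-7}$, the convention of conditional exact
tests). The reported odds ratio is the cross-product $(ad)/(bc)$ — not
the conditional MLE some software prints — with zero cells yielding
$\infty$, $0$ or `NaN` rather than an error. Quantification units must be
integers: electropherogram areas are continuous, so `allele_counts()`
exposes an explicit `scale` (multiply, then round; default 1) — p-values
depend on this choice, which is why a non-integer cell is an error that
points at the scaling decision instead of silently rounding. Sidedness is
not dictated by the source procedure; two-sided is the conservative
default.

**ΔΔCt** (`ddct_expression()`): replicate Cts are averaged per
(gene, condition); the reference Ct is the arithmetic mean of the
per-reference-gene means (equivalently the geometric mean of reference
quantities — the standard multi-reference rule; with GAPDH and B2M named
as references, a combination rule has to be chosen);
$\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{refs}$,
$\Delta\Delta Ct = \Delta Ct_{cond} - \Delta Ct_{ctrl}$, fold
$= 2^{-\Delta\Delta Ct}$ under the 2-fold-per-cycle assumption (no
efficiency correction). Replicate spread is reported as `sd_log2` but
never enters the point estimate. Adding any constant to every Ct leaves
the fold unchanged.

**Percent input** (`percent_input()`): with an input aliquot fraction $q$
(default 0.10), the input Ct is adjusted by $-\log_2 q$ (≈ +3.32 cycles
for 10%) and $\%input = 100 \cdot 2^{Ct_{input,adj} - Ct_{ChIP}}$; each
condition is finally expressed relative to the control condition (e.g.
vehicle/EtOH).

## 5. Motif scanning

Response elements are compared as plain IUPAC consensus strings (ARE
half-site `RGNACR`, ERE `RGGTCANNNTGASCY`) — match/mismatch counting
only, no PWM or information weighting, because the comparison being
reproduced is against consensus strings; the per-position mismatch report
lets a user see which contacts are non-consensus. Conventions:

- both strands are scanned; offsets are always reported in
  forward-strand query coordinates;
- a query `N` is an unknown base and matches nothing except a pattern
  `N` (pattern `N` matches everything);
- results sort by matches desc, then offset asc, then `+` before `-` —
  with an explicit strand key so ordering does not depend on the
  collation locale;
- `allele_impact()` substitutes each allele, restricts to sites covering
  the SNP, and reports $\Delta = matches(alt) - matches(ref)$ at the
  *shared best* covering site (the window maximising the better allelic
  score; ties by smaller offset, then `+`). Each allele's own best
  covering match is also returned. The default flank is ±25 bp — "short
  sequences surrounding the SNP" is otherwise unquantified, and ±25 bp
  comfortably contains any single response element.

## 6. The synthetic-data generators

`simulate_landscape()` emulates the *statistical structure* of the real
inputs (multi-cell-line ENCODE-style peak landscapes plus a dbSNP-style
catalog), not their content:

- one toy chromosome `chrS` (default 1 Mb; multi-chromosome handling is
  exercised by dedicated fixtures);
- `n_true_regions` (default 40) regulatory *elements*, 300–1000 bp,
  placed non-overlapping with a guard gap. Each carries H3K4me1;
  a `promoter_frac` = 0.4 subset also carries H3K4me3; each auxiliary
  mark (H3K9ac, H3K27ac, DNase, FAIRE) decorates an element independently
  with probability 0.5. Interpreting the region count as elements rather
  than per-marker counts is what makes enhancer/promoter truth labels
  coherent across markers;
- each of 5 cell lines re-detects an element's peak with probability 0.9,
  with Gaussian edge jitter (sd 20 bp, redrawn if start ≥ end) — peak
  callers disagree at boundaries — plus 20 uniformly placed noise peaks
  per line per marker, kept away from elements;
- TFs (AR, ER) cover each element with probability 0.6 (peaks pad the
  element by 20–100 bp), plus noise TF peaks;
- 200 SNPs, half inside elements. Background SNPs and noise peaks keep a
  guard band of $3\sigma_{jitter}$ from element edges so the planted
  labels stay unambiguous under jitter: a SNP a few bases outside an
  element is genuinely ambiguous once edges jitter, and the generator's
  job is to state a world with known answers. This band was fixed before
  any acceptance measurement;
- allele counts: input $\sim Binom(depth, 0.5)$, ChIP
  $\sim Binom(depth, \beta)$ with planted bias $\beta$ (defaults: depth
  200, $\beta = 0.5$, i.e. the null);
- Ct tables: $Ct = Ct_{base} - \log_2(fold) + N(0, 0.2)$ for the target,
  references constant up to noise;
- motif flanks: a concrete motif instance planted over the SNP, with the
  background redrawn until the planted site is the strict best
  SNP-covering window under either allele — again so the truth label
  (Δ < 0 at the planted site) is unambiguous.

Everything is drawn after `set.seed(cfg$seed)`; outputs (including files)
are byte-reproducible. Defaults not dictated by the emulated setting
(element count, lengths, jitter sd, mark probabilities, base Cts) were
chosen once as realistic for ENCODE-scale chromatin data and are not
tuned against test outcomes.

**What a green test does and does not establish.** The generator plants
clean, well-separated elements with independent noise; real peak
landscapes have correlated artifacts (mappability, copy number),
cell-type-specific biology, LD structure among SNPs, and far larger
scale. Recovery at ≥ 0.95 recall/precision on this world validates the
algorithmic chain (retention → merge → intersection → bookkeeping), not
the biological error rate on real ENCODE/dbSNP inputs.

## 7. Acceptance scope

The only genome-scale headline numbers attached to this method (the
marker × TF SNP counts, e.g. 591/553/41) were computed on the complete
January-2013 ENCODE peak compendium for 17 named cell lines and the full
dbSNP138 catalog — inputs of multi-gigabyte scale that are not shipped
and not downloadable in the offline test environment. They are therefore
*external* targets: `scripts/acceptance.R` emits no numeric claims about
them (an empty target object) and desk-scale acceptance is entirely
property- and simulation-based (`tests/testthat/test-acceptance.R`):
consensus equivalence against a base-by-base oracle on 500 random
instances, the worked retention example, planted-truth recovery over 20
seeds, cross-tab invariants (which the published summary table itself
satisfies), exact-test agreement with exhaustive enumeration for all
margins ≤ 30, type-I error in [0.03, 0.07] and power ≥ 0.9 for the
allele test, the allele-fraction formula, ΔΔCt/percent-input closed
forms with ±10% planted-fold recovery, and motif-scanner equivalence
with a positionwise brute-force scorer.

## 8. Known limitations

- No peak calling, IDR, signal-weighted merging, genome liftover,
  BigWig/BigBed or tabix support; inputs are plain BED/narrowPeak/VCF/TSV.
- Only SNVs are annotated; indels are skipped with a warning.
- No LD expansion, eQTL/GWAS joins or nearest-gene assignment.
- The Fisher test treats scaled quantification units as counts; the
  scale choice is the user's and materially affects p-values.
- Motif scoring is consensus-string matching; a PWM would rank degenerate
  positions more faithfully.
- The type-I/power calibration holds for the binomial sampling model of
  the generator; overdispersed real quantifications would be
  anti-conservative at the same nominal level.
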