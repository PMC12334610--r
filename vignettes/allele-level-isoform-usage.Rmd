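---
title: "Allele-level isoform usage from long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-level isoform usage from long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A heterozygous variant near a splice site may alter splicing of the
transcripts produced from its own allele while leaving the other allele
untouched. Long cDNA or direct-RNA reads make this directly observable:
a single read spans both the variant region and enough of the transcript
to reveal its full exon-intron structure, and -- when the read covers a
heterozygous single-nucleotide variant (an *allele-informative SNV*) --
the base it carries there assigns the read to one parental allele.
`isoallele` implements this analysis end to end: it filters candidate
splice-altering variants by their SpliceAI delta score, partitions
spanning reads into the two alleles, collapses reads into isoform groups
by their splice-junction chains, and tests whether isoform usage differs
between the alleles.

## Pipeline model

For each candidate splicing variant the pipeline:

1. **Derives a target region** spanning the minimal to maximal
   coordinates the SpliceAI sub-score offsets mark as affected, expanded
   to the containing gene's annotated span when available.
2. **Selects spanning reads**: primary alignments whose reference
   interval contains the variant position. Reads with supplementary
   segments outside the target region are chimeric (they map both within
   the gene and elsewhere) and are removed.
3. **Gates candidate allele-informative SNVs** inside the region: a site
   is usable when at least 10 spanning reads carry an actual base
   (A/C/G/T, i.e. the position is not spliced out or deleted in the
   read) with Phred quality >= 10, regardless of which allele the base
   supports. An exonic SNV splicing variant can act as its own
   informative site; an intronic one can too when intron-retention reads
   carry bases at its position.
4. **Partitions reads by allele** at each gated site. Bases matching
   neither the reference nor the alternate allele are base-call errors
   under a bi-allelic site and are discarded, which lowers the effective
   mis-partition rate below the Phred bound (see below). When two or
   more sites gate, reads covering them are additionally phased into a
   haplotype block by minimum error correction (MEC), yielding one more
   variant-site pair per variant.
5. **Collapses reads into isoform groups** by exact junction-chain
   identity (single-exon reads by reciprocal span overlap), keeping
   groups with >= 4 supporting reads, and counts group membership per
   allele.
6. **Tests each isoform against the rest** with a two-sided exact test
   on the isoform x allele 2x2 table, takes the minimum p across
   isoforms as the pair's p-value, and finally applies Bonferroni
   correction across the unique splicing variants that reached the test
   stage. Corrected p < 0.05 flags a variant as having allele-specific
   isoform usage.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `delta_threshold` | 0.5 | probability | moderate recall/precision; 0.2 favours recall, 0.8 precision. Retention is monotone in the threshold. |
| `min_informative_reads` | 10 | reads | with isoform support 4, two alleles expressing distinct isoforms need >= 8 reads; 10 is a deliberately permissive floor. |
| `min_base_quality` | 10 (amplicon: 15) | Phred | Q10 = 90% base reliability, below the accuracy of current nanopore chemistries; amplicon runs use 15 for extra stringency. |
| `min_isoform_support` | 4 | reads | isoform groups below this are alignment noise or fragments; their reads are left unassigned. |
| `alpha` | 0.05 | -- | family-wise level after Bonferroni. |
| `min_intron` | 20 | bp | reference skips shorter than this are treated as deletions mis-encoded as N, not introns. |
| `s_max` | 16 | sites | largest block phased exhaustively (2^(S-1) phasings); larger blocks use the greedy-plus-refinement heuristic. |

## The exact test

For isoform $i$ with counts $a$ (allele 1) and $c$ (allele 2) out of
allele totals $n_1, n_2$, the 2x2 table $[a, n_1 - a; c, n_2 - c]$ has,
with all margins fixed, a hypergeometric distribution over the possible
$a$. The two-sided p-value is the sum of point probabilities not
exceeding that of the observed table (the point-probability convention,
as in `fisher.test`). No mid-p or continuity correction is applied. The
Bonferroni denominator is the number of *unique* splicing variants
tested, not variant-site pairs: a variant separated by three different
SNVs is still one hypothesis about one variant (`pairs_level_correction`
switches to pairs-level counting for sensitivity analyses).

## MEC phasing

Reads covering $S \ge 2$ gated sites form a matrix of allele calls in
$\{0, 1, \mathrm{NA}\}$. The phaser seeks the haplotype vector $h$
(first site fixed at 0; haplotype 2 is the complement) minimizing the
MEC cost: the number of calls that must be flipped for every read to
match one of the two haplotypes, missing calls contributing nothing.
Blocks up to `s_max` sites are solved exactly by enumeration; beyond
that a deterministic greedy extension in genomic order is refined by
coordinate descent with restarts seeded from each distinct observed read
pattern. Reads are assigned to the nearer haplotype by Hamming distance
over their covered sites; equidistant reads are left unassigned rather
than placed arbitrarily, so that neither allele's isoform counts are
inflated by coin-flips. Phased blocks are reported as `0|1` / `1|0`
genotypes in a per-pair phased VCF; single-SNV separations carry no
haplotype information and emit none.

## What the simulator emulates -- and what it does not

`sim_scenario()` builds one gene per scenario: an exon-intron structure,
a heterozygous splicing variant with SpliceAI-style sub-scores, exonic
informative SNVs phased with it (all alternate alleles on haplotype 1),
and per-allele isoform mixtures. Reads are emitted *pre-aligned*: the
CIGAR is constructed from the true isoform (M across exons and retained
introns, N across spliced introns), bases are copied from the read's
haplotype with i.i.d. substitution errors, and Phred qualities are drawn
from a discretized normal (mean 20, sd 5, clipped to [2, 40]) --
roughly an older-chemistry nanopore quality profile. Substitution errors
are placed independently of the reported quality, so the quality gate
bounds but does not remove them. The seed fully determines every output
byte.

`mcardle_like_preset()` is the validation workhorse: a 14-exon gene with
an intronic acceptor-region variant 3 bp upstream of exon 13, whose
allele expresses exon-13 skipping (0.22), intron-12 retention (0.08) and
double retention of introns 12 and 13 (0.02) against a near-canonical
wild-type allele (0.97 canonical). These effect sizes mirror the
proportions reported for a glycogen-storage-myopathy splice variant in
the literature; the simulator's truth is its configured mixture, not any
patient's values. `null_twin()` sets both alleles to the wild-type
mixture -- the natural null in which the variant has no splicing effect.

The simulator deliberately does **not** model: alignment and
junction-correction artifacts (reads are emitted already aligned to the
truth), indel errors, quality-correlated error bursts, direct-RNA
homopolymer artifacts, PCR amplification bias, or transcript
degradation (an optional geometric 5' truncation was considered and left
out of v1). Passing tests therefore demonstrate the correctness of the
partitioning, collapse and testing machinery under a clean error model
-- not robustness to alignment error, which real data inherits from the
upstream aligner.

## Numerical and design choices

* **Coordinates.** VCF and GTF positions are 1-based; all internal
  interval arithmetic is 0-based half-open; conversions happen only at
  I/O boundaries.
* **SpliceAI reconciliation.** When several transcript records annotate
  one variant, the record with the maximal delta score is used,
  matching the "maximal probability of splicing alteration" definition
  of the delta score. Records whose ALLELE token matches the candidate
  alternate allele are preferred when present.
* **Multi-allelic records** are split into bi-allelic candidates before
  filtering; heterozygosity is evaluated per alternate allele. Indel
  splicing variants are accepted for region derivation but never serve
  as informative sites (base-at-position semantics are only well defined
  for SNVs).
* **Branch points.** The positional splice-region filter covers 1-3
  exonic and 3-8 intronic bases from each junction; a branch-point
  window upstream of acceptors is configurable (e.g. `c(18, 44)`) but
  disabled by default, since published branch-point definitions vary by
  annotation-tool version.
* **Junction matching** is exact by default (`fuzz = 0`): input
  alignments are assumed junction-corrected, and exact matching keeps
  group identity well defined. Representative isoform ends are medians
  of member alignment ends and are never adjusted to annotation.
  Single-exon reads cluster at >= 80% reciprocal overlap. Novel groups
  get deterministic `novel-k` ordinals.
* **Ties and degenerate inputs.** Equidistant reads in phasing:
  unassigned. Isoforms with zero counts in both alleles: excluded from
  testing. An allele with zero assigned reads: the pair is skipped with
  a reason code. An empty variant list: clean empty outputs with
  headers.
* **Determinism.** The pipeline itself consumes no randomness;
  per-variant tasks are independent and merged by a stable sort, so
  results are byte-identical across worker counts.
* **Mis-partition bound.** With per-base error rate $e$, a read
  mis-partitions only when its error matches the other allele's base
  (probability $e/3$); other error bases are discarded. At the Q10 gate
  the worst case is 10% mis-separation; the simulator's $e = 0.05$
  yields ~1.7%, and the acceptance suite verifies the observed rate.

## Validation problem sizes

The test suite validates the exact test against brute-force
hypergeometric enumeration over all 2x2 tables with both allele totals
up to 30; MEC phasing against exhaustive search on 200 random matrices
(up to 8 sites, 30 reads); and the CIGAR walkers against base-by-base
expansion on 1000 random spliced alignments. Operating characteristics
use the preset at 100 reads per allele and 5% base error: effect
recovery over 100 seeds (expected in >= 95), the false-positive rate
over 500 null replicates (bounded by 0.05 plus binomial margin), and the
mis-partition rate at 500 reads per allele. `scripts/acceptance.R`
recomputes the same surface at moderately reduced replicate counts (40
recovery seeds, 150 null replicates, enumeration to margin 20), sizes
chosen to keep a single-CPU rerun comfortably reproducible.

## Known limitations

* Junction matching has no tolerance by default, so uncorrected
  alignments with wobbly splice sites will fragment isoform groups;
  set `fuzz` or correct junctions upstream.
* The Bonferroni family is the set of tested variants within one run;
  combining runs requires re-correction.
* Minimum p across isoforms is a detection statistic, not an effect
  size; usage fractions in the per-pair isoform tables are the
  quantitative readout.
* The exact test treats reads as independent draws; UMI-free PCR
  amplicon data may violate this, which is one reason amplicon mode
  raises the base-quality gate rather than the coverage gate.
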