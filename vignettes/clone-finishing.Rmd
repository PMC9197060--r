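---
title: "Finishing pooled large-insert clones: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finishing pooled large-insert clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poreclone)
```

## The problem

Reference-quality sequence in ampliconic regions — euchromatic repeats of
greater than 99% identity over many kilobases — cannot be obtained from
shotgun data: short reads cannot tell paralogous repeat copies apart, and
noisy long reads blur them into an erroneous consensus. The clone-based
strategy this package implements sidesteps both problems. Each large-insert
clone (BAC or fosmid) is a single circular molecule: a shared cloning vector
followed by a 100–300 kb genomic insert. A pool of two dozen clones is
sequenced in one nanopore run; transposase chemistry is tuned so that most
circular molecules are cut exactly once, so a single read can traverse an
entire clone. Such a *full-length read* fixes the clone's structure — order,
orientation, and copy number of every internal repeat — with certainty,
while deep (~50×), accurate Illumina coverage fixes individual bases. The
rare *sequence family variants* (SFVs) that distinguish paralogous repeat
copies are the currency that ties the two together.

`poreclone` turns that strategy into a tested pipeline:

1. **Demultiplex** pooled reads to clones by alignment against per-clone
   draft assemblies — no barcodes needed, because reads carry enough unique
   sequence to be assigned even between clones sharing an amplicon.
2. **Identify full-length reads** by cloning-vector anchors at both read
   ends, **rotate** cut-in-insert reads to a canonical vector-first frame,
   and estimate clone length from the peak in the tail of the read-length
   distribution.
3. **Polish**: pick the best full-length read as backbone, build a windowed
   weighted column consensus from all long reads, then correct residual
   errors to the Illumina consensus.
4. **Resolve repeats**: detect near-identical internal units by
   self-alignment, call SFVs, partition short reads by their SFV alleles,
   polish each unit separately, and merge — with the overall structure
   anchored by the full-length reads throughout.

A synthetic clone-pool generator provides ground truth for every stage, so
each claim the pipeline makes is testable without any external data.

## The simulator and what it does (not) emulate

`make_clone_pool()` builds circular clones as a shared random vector
(default 3 kb) plus random inserts. A repeat specification plants `n_units`
near-identical units arranged as direct (tandem) or inverted (palindrome)
copies. Unit divergence is deterministic: a per-pair budget of
`floor(unit_len * (1 - unit_identity) * 0.8)` substitution columns, each
private to one unit, plus `sfv_per_unit` planted SFVs per unit. Every unit
pair therefore lands at a pairwise identity inside `[unit_identity, 1)` by
construction rather than in expectation — important because the detection
threshold sits at the same 0.99 boundary the amplicon definition uses.
Background divergence is substitution-only, which keeps unit columns
comparable; real amplicons also diverge by small indels, and resolving
indel-divergent units is correspondingly harder than what these simulations
exercise.

`simulate_nanopore_run()` draws each read from a uniformly chosen clone.
With probability `p_single_cut` (default 0.3) the molecule is cut once at a
uniform position and read full-length on a random strand; otherwise a
truncated fragment is emitted with an exponentially distributed length
(default mean 6 kb at desk scale — a modeling choice; run-level aggregates
are all the protocol reports, not a truncation law). Errors are applied per
base: substitutions at 4%, insertions at 3%, deletions at 3%, with indel
rates multiplied 6-fold inside homopolymer runs of length ≥ 3, where
nanopore basecalls concentrate their indel errors; inserted bases inside a
run duplicate the run base. The multiplier is a constant because only the
qualitative statement — indels cluster at homopolymers — is established; 6×
makes homopolymer undercalls the dominant residual error of the long-read
consensus, which is the regime the Illumina correction stage is designed
for. The simulator does not model pore current, quality strings, chimeras,
or host-cell contamination.

`simulate_illumina()` places fragments uniformly on the circle with
inward-pointing 150 bp mates and substitution-only errors (0.2%). Real
short-read data also carries indel errors (rarely) and coverage bias
(GC-dependent); passing tests therefore demonstrate correctness of the
*logic* under a realistic error budget, not robustness to every bias of
real flow cells.

`degrade_to_draft()` produces the collapsed draft the pipeline starts from:
tandem paralog groups merged into a single unit at the column-wise majority
base — the classic assembly collapse caused by multiple amplicon copies —
plus optional substitution noise and contig breaks.

Determinism: every operation takes a single integer seed; reads are drawn
sequentially, so the first *m* reads of an *n*-read run are identical to an
*m*-read run and adding reads never perturbs clone generation.

## The aligner

All stages share one aligner: canonical (strand-min) minimizers (long
preset k=15, w=10; short preset k=21, w=1), co-linear chaining by dynamic
programming with a concave gap cost and bounded lookback, and piecewise
banded affine-gap alignment (match +1, mismatch −2, gap open 4, extend 2 —
a gap of length L costs `open + L*extend`) between consecutive anchors,
with extension alignments past the terminal anchors and soft clips for
unaligned flanks. Between anchors the band widens with segment length,
because sparse anchors mean divergent sequence where the optimal path
wanders. If the optimal path touches the band edge the band is widened
once; a path still pinned to the edge is flagged low-confidence. On
sequences up to a few hundred bases with a covering band, the banded DP is
exactly the quadratic Needleman–Wunsch/Gotoh algorithm, which is how the
test suite checks it (against an independent implementation).

Demultiplexing ranks clones by chain score — the anchored-base score of the
best co-linear chain — and assigns a read to the top clone only when the
relative margin over the runner-up is at least `margin_frac` (default
0.05). Chain score rather than full extension keeps a 24,000-read pool
within minutes on one CPU; reads tied across clones (pure-vector reads, or
truncated reads wholly inside a shared amplicon) fall out as AMBIGUOUS
exactly as they should.

## Circularity

Reads come from circular molecules cut anywhere, so every pileup-based
stage aligns reads against a doubled reference and folds the column stack
back modulo the clone length; a read spanning the linearization origin then
aligns contiguously. Illumina polishing additionally runs one pass in a
half-rotated frame, because homopolymer regions that touch the origin are
edge-masked in the primary frame. After long-read polishing, and again at
the very end, the sequence is re-rotated so that vector base 0 is exactly
position 0: the backbone read's own rotation is only as accurate as a raw
nanopore alignment, and the vector-first frame is the coordinate system all
reports use.

## Polishing: thresholds and numerical choices

`polish_long()` (default 2 rounds, 500 bp windows) takes the weighted
majority base per column (weight = alignment identity), honours majority
insertions, and leaves zero-coverage windows at the backbone, flagged.
Insertions are accepted at 30% of junction-spanning support rather than a
majority: a read with its own deletion error near a backbone deletion
absorbs the missing base into mismatch columns (two mismatches cost less
than an insertion plus a deletion under affine scoring), so exact-position
insertion support is structurally diluted. A spurious insertion accepted
this way loses the majority-deletion vote in the next round and is also
removed by Illumina correction, so the asymmetry is safe.

`polish_short()` (defaults: `min_depth` 15, `min_agree` 0.9) aligns short
reads and edits wherever the Illumina consensus differs and clears both
thresholds, logging every edit as a discrepancy (`HOMOPOLYMER_INDEL` for
indels within or adjacent to runs ≥ 3 bp, `SUBSTITUTION` otherwise);
positions that differ but fail the thresholds are logged `UNRESOLVED` and
left unedited. Passes repeat until no edit applies, which makes the
operation idempotent. Three mechanisms beyond plain column votes matter:

* **Region votes.** A homopolymer run plus one flank base each side (merged
  when touching, boundaries snapped outward past any same-base run so that
  no cut point admits two equivalent indel placements) is edited as a unit:
  each spanning read contributes the exact string it aligns across the
  region. This captures run-length changes and non-run-base insertions at
  run boundaries in one decision. Because only reads spanning the whole
  region plus a flank can contribute — a systematically smaller pool than
  per-column depth — region votes use a scaled depth floor of
  `max(10, 2/3 * min_depth)`. For the insertion-agreement denominator,
  only junction-spanning reads count: a read whose alignment merely ends at
  a column carries no indel evidence.
* **Singleton removal and dominance.** A clone is a single molecule, so a
  region string observed in exactly one read is an individual read error,
  never a real second allele; singletons are dropped from region tallies.
  A region vote is accepted either at `min_agree` or when the top string
  dominates the runner-up 3:1 — alignment-placement jitter at short tandem
  repeats produces a dominant string with shifted low-count variants, while
  genuinely contested repeat regions show balanced support and are left
  alone. The dominance shortcut is disabled wherever reads of mixed unit
  origin are being used deliberately (the repeat-resolution cleanup pass).
* **Cluster re-votes.** Nearby interacting defects (a missing base a few
  bases from a mis-called run) depress each other's per-column agreement;
  clusters of unresolved positions within 12 bp are re-voted jointly over a
  snapped window.

## Repeat resolution

Repeat units are detected by self-alignment of the consensus: off-diagonal
minimizer chains (both strands, trivial diagonal excluded), with tandem
arrays of n ≥ 3 units decomposed at the chain period and adjacent arms cut
at the period so they stay in phase. Arm identity is measured on trimmed
cores because chain-end boundaries are ragged by up to ~(k+w) bp. Desk-scale
defaults are `min_len` 2 kb and `min_identity` 0.99 (the full-scale amplicon
definition uses 10 kb). The pipeline detects with a slack of 0.04 below the
nominal identity, because residual unresolved errors inside units depress
their mutual identity on the pre-resolution consensus; resolution then
restores the true identity.

`finish_repetitive()` proceeds in anchored-evidence order:

1. **Rebuild each unit's backbone** from the aligned segments of
   *structurally anchored* long reads — reads whose alignment extends into
   unique sequence outside the repeat region and whose placement is
   therefore positionally certain. This undoes any unit blur the pooled
   polishing introduced, at long-read accuracy.
2. **Re-call SFVs** on the rebuilt consensus and **partition** short reads
   by their alleles at validated marker columns. A marker requires every
   unit's claimed allele to be supported by the reads mapped to its own
   instance (agreement ≥ 0.55, depth ≥ 10): a residual consensus error
   masquerading as a distinguishing column has no support at its own
   instance and would otherwise systematically mislabel every read whose
   only evidence is that column. The partition is run twice, with the SFV
   columns refined to their partition majorities in between. A read must
   match at least one marker allele and contradict none; conflicted reads
   are set aside.
3. **Polish each unit** with its assigned reads plus *neutral* reads (reads
   covering no distinguishing column carry identical content in every unit
   and are safe evidence anywhere — they fill the coverage holes between
   SFV columns), then re-insert the units, tracking coordinate shifts.
4. **Cleanup.** One global Illumina pass with the dominance shortcut off:
   columns where units agree polish at full depth regardless of read
   origin, and genuinely distinguishing columns stay protected by the
   agreement threshold because mis-partitioned reads split their votes.
5. **Phase bimodal regions — the final word on repeat content.** A paralog
   difference blurred to identity before SFV calling is invisible to the
   partition: every position in it polls ~50/50 at full depth. Persistent
   bimodal votes (and confident-but-thin votes at instances so garbled that
   they repel their own reads) trigger a joint region decision. Triggering
   positions are merged generously (gaps up to 40 bp) because a fragmented
   divergent region yields windows with too few distinguishing bases for
   long reads to vote on. The two recurrent Illumina strings over the
   pooled instances are the candidate alleles; each unit instance is
   assigned the candidate preferred by the anchored long reads spanning it
   (edit-distance votes, ties abstaining, 70% of decided votes and at least
   4 required); the replacement string is taken from the instance's own
   phase-consistent short reads so it is natively in the instance's
   coordinate frame, falling back to splicing the picked candidate at the
   best-matching span when the instance has repelled its own reads.
   Iterated to a fixed point (at most 5 rounds).
6. **Junction validation.** Every unit boundary is annotated with the
   number of long reads spanning it by ≥ 200 bp on both sides; unit order
   and orientation are never altered by polishing — structure comes from
   the full-length reads alone. Units with no SFV-assignable reads are left
   at the long-read consensus and flagged `UNRESOLVED_UNIT`.

The whole detect-and-resolve block runs up to two passes (unit rebuild
only in the first), stopping at a fixed point.

Backbone policy for repetitive clones: reads classified full-length only by
their length (no vector anchor at both ends) are considered as backbones
only when no vector-anchored read exists, and not at all when the draft
already shows internal repeats — a mid-repeat cut cannot be rotated
unambiguously in a tandem array.

## Problem sizes

The packaged simulations are desk-scale by choice: 40 kb clones (3 kb
vector + 37 kb insert), 2.5–3 kb repeat units, ~60 nanopore reads per clone
at 10% error, and 50× Illumina coverage. All identity and structure
invariants are scale-free; the full-scale regime (100–300 kb inserts, 10 kb
amplicon units, hundreds of reads per clone) differs only in constants. The
acceptance evaluation simulates a six-clone tiling path with 12 kb overlaps
(one pair sharing a 2-unit tandem repeat) for the accuracy measurement, and
a balanced 24-clone pool with 24,000 reads for demultiplexing — the pool
size and per-clone read shares mirror a single pooled flow-cell run.

## Known limitations

* Unit divergence in the simulator is substitution-only; indel-divergent
  paralogs would stress the column-comparable assumptions of SFV calling
  and region phasing.
* Paralog groups with more than ~3 units thin out the per-unit read
  partition; with fixed total coverage, resolution quality degrades as
  copy number grows — consistent with short-read mapping getting harder as
  paralog count rises.
* A clone with no full-length read and a collapsed draft cannot be
  reconstructed: structure information is genuinely absent. The pipeline
  falls back to the draft, and the result surfaces as a `SHORT_CLONE` flag
  (the protocol's answer is to re-sequence the clone).
* SAM records are written and split with plain M operations (no =/X
  distinction), matching the operation-count workaround they exist for.
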