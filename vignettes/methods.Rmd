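---
title: "Methods: phase-aware diploid polishing and k-mer quality assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-aware diploid polishing and k-mer quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
assumptions each stage makes, and where the design was genuinely open.

## The polishing model

A draft diploid assembly carries residual base-level errors. The evidence
for correcting them is the pileup of long reads aligned back to the draft,
and the central statistical object is the per-column disagreement between
reads and assembly. Two failure modes shape the design:

* **Under-correction in falsely homozygous regions.** When a stretch where
  both haplotypes are represented identically exceeds the read length, the
  aligner assigns reads to a haplotype arbitrarily. Heterozygous
  corrections in such stretches are then invisible (each copy sees a ~50/50
  mixture) or applied to the wrong copy. The phasing stage exists to
  restore per-read haplotype assignment there, using ultra-long reads that
  bridge the stretch and its flanking heterozygous sites.
* **Over-correction.** Each proposed edit carries a confidence (GQ), and
  1 bp indel edits are empirically the most error-prone class, so the
  filter is class-specific: GQ ≥ 20 for 1 bp insertions, ≥ 12 for 1 bp
  deletions, ≥ 5 for everything else.

## Phase-aware reassignment

**Homozygous regions** are maximal runs of `=` columns in the
haplotype-vs-haplotype alignment strictly longer than `min_homo_len`
(default 20,000 bases, about one HiFi read). The comparison is strict
(`> 20,000`): a run of exactly 20,000 is excluded. The detector requires
extended CIGARs and rejects `M`, whose identity is ambiguous.

**Het candidates** are called per column from mismatch evidence under a
symmetric per-read error model with rate `error_rate` (default 0.01): the
three diploid genotypes are scored by binomial log-likelihood and
`GQ = 10·(log10 L_best − log10 L_second)`, capped at 99. Only heterozygous
calls with GQ ≥ 10 survive. Candidates are SNVs only; restricting to
substitutions keeps cross-haplotype projection of alleles exact
(width-1 images), and indel heterozygosity in the flanks contributes little
discriminating power relative to its bookkeeping cost. Reads with a
gap-compressed mismatch ratio above 0.02 (each indel run counted once,
mismatch columns individually) are excluded before calling, so diverged or
misplaced reads cannot seed spurious candidates.

**Phasing** joins variants co-covered by qualifying ultra-long reads
(≥ 100,000 bases); each adjacent pair's relative phase is the majority vote
of co-covering reads, and unlinked variants become singleton blocks. This
greedy chain phaser is exact when votes are consistent; the test suite
checks it against exhaustive enumeration over all phasings for blocks of up
to six variants. Within a block, the haplotype with more reference alleles
(ties to haplotype A) is the assembly-like one.

**Pseudo-polishing and scoring.** Variant blocks of width
`max(min_block, 2·span)` (default `min_block` 100) are centered on each
variant's reference span and merged when they overlap; the block start is
`floor(pos + span/2 − width/2)`, which is symmetric and stable under
merging. The paper-level description of which haplotype receives which
phased alleles is ambiguous, and the one reading under which the procedure
can discriminate reads at all is the split application: the selected
(assembly-like) phase haplotype's alternate alleles are applied to the
haplotype the variants were called on, and the complementary alleles to the
other haplotype at the projected positions. That is what `pharaoh()`
implements; `score_and_assign()` accepts any per-haplotype pseudo-edit
assignment, so the literal single-set application is also expressible. Each
read's merged projected blocks are compared against both pseudo-polished
haplotypes by Levenshtein distance (via `utils::adist`; the suite verifies
it against a hand-written dynamic program on 200 randomized instances), the
sums are compared, and ties keep the current assignment to avoid churn.
After reassignment the final alignment set is filtered at mismatch ratio
0.002.

## Candidate-window polishing

A position is a candidate iff at least `min_support = 3` distinct reads
("more than two") disagree with the assembly there — a mismatched base, a
deletion covering the position, or an insertion anchored immediately after
it; the rule counts disagreeing reads of any kind rather than reads per
allele, because the downstream consensus re-weighs the evidence anyway.
Candidates within `max_gap = 50` bases join a window while its span stays
within `max_span = 100`; the implementation scans each contig in one pass,
which trivially guarantees that windows are never split at scan-chunk
boundaries (the same property that 25 kb tiles with 1 kb overlap provide in
a streaming implementation).

Each window (± 15 bases of flanking context, which stabilizes indel
left-normalization at window edges) is featurized into one row per read —
deterministically subsampled to `depth_cap = 30` by a fixed hash of the
read name, so reruns are identical — and one column per reference position
plus one slot per distinct insertion locus. Channels are base (`-` for
deletion gaps), match flag, base quality and mapping quality.

The default predictor is a weighted pileup consensus: each read votes for
its allele with weight `1 − 10^(−baseq/10)`; the heaviest allele wins, and
an insertion is only emitted when its weight exceeds half the total weight
of reads covering its anchor. The predictor is a plug-in point
(`predictor =` argument): a trained sequence model consuming the same
tensor can replace it without touching any other stage. The per-record
`GQ = −10·log10(1 − support)` (capped at 99, minimized over the record's
positions) is likewise a property of this default core, not of the
interface; it is deliberately conservative — a single dissenting read among
30 caps a record at GQ ≈ 15, below the 1 bp-insertion cutoff.

Differences between predicted and assembly sequence become VCF records:
adjacent substitutions stay separate SNVs (never MNPs, which keeps the
INS1/DEL1/OTHER classification clean), runs mixing substitutions and indels
collapse into a single anchored record so REF spans can never overlap, and
indels are left-normalized. A property test verifies that applying the
emitted records reproduces the predicted sequence exactly on randomized
window pairs.

## Edit filtering and application

Filtering keeps an edit iff `GQ ≥ cutoff(class)`; the comparator is `≥` so
edits at exactly the printed optima (20/12/5) are retained. Application
substitutes ALT for REF with cumulative coordinate shifting; a REF string
that disagrees with the sequence is a hard error naming the locus, which is
the guard that has caught every coordinate bug in development. Overlapping
records (possible only when edits come from multiple sources) resolve to
the higher GQ, ties to the leftmost.

## K-mer evaluation

Both the read database and the assembly scan use canonical k-mers
(lexicographic minimum of a k-mer and its reverse complement, 2-bit
encoded, k ≤ 31), so strandedness never matters. An assembly k-mer absent
from the read set is an error k-mer; `B` of `T` total k-mers give
`E = 1 − (1 − B/T)^{1/k}`, `QV = −10·log10 E`, and
`errors/Mb = 10^{−QV/10}·10⁶`. With `B = 0` the QV is capped at 99 and
flagged rather than infinite. `ΔQV = −10·log10(after/before)` is additive
across successive polishing rounds by construction, and its error-reduction
reading is `1 − 10^{−ΔQV/10}`.

Fixed/induced/unchanged accounting projects the polished assembly's error
intervals onto the raw assembly through the raw-vs-polished alignment and
classifies by interval arithmetic; merged intervals are the bookkeeping
unit, and the lengths balance exactly (`fixed + unchanged = raw`,
`induced + unchanged = projected`). Polished intervals with no projection
image are counted as induced — the conservative choice — and flagged. The
GQ sweep estimates `errors_after = unchanged + induced(kept) +
fixes(dropped)` for every cutoff vector in the scenario grid and returns
the first optimum in ascending cutoff order, so ties resolve to the
lowest cutoffs; the suite checks it against an independent triple-loop
enumeration.

Context stratification counts error intervals overlapping k-mers with
GC > 0.70, homopolymer runs of ≥ 11 bases ("greater than 10 bp"), and
regions below 5× coverage using the quantized bands [0,5) [5,10) [10,150).
Gene impact follows three rules on coding sequence: a gap is a frameshift
iff its length is not a multiple of 3 **or** exceeds 30 bp; premature stops
are in-frame TAA/TAG/TGA strictly before the final codon; nonsynonymous
substitutions are codon changes that alter the encoded amino acid
(translation table from `Biostrings::GENETIC_CODE`).

## The synthetic diploid generator

`generate_diploid()` builds a base sequence per contig, scatters
heterozygous SNVs (default 10⁻³/bp, human-like) and 1–3 bp indels
(10⁻⁴/bp) outside designated loss-of-heterozygosity intervals, and assigns
each alternate allele to a random haplotype. LOH intervals (default 25 kb,
longer than a HiFi read) are het-free, so the haplotypes are exactly
identical across them — the situation the phasing stage exists for.
`corrupt_assembly()` injects draft errors (defaults 1.5×10⁻⁵ SNV +
5×10⁻⁶ indel per base ≈ one error per 50 kb, a draft around QV 47) and
records the repairing VCF edit for each; applying all truth edits restores
the genome byte-exactly, which is the conservation oracle used throughout
the suite. `simulate_reads()` draws uniform start positions (reads
truncated at contig ends, no circularity), truncated-normal lengths, and
per-base errors with the indel rate multiplied (default 8×) inside
homopolymer runs of ≥ 5 bases; each read's true alignment is emitted with
an extended CIGAR describing exactly the simulated errors. Base qualities
are constant per profile (HiFi-like Q30, ultra-long Q12), which keeps
featurization deterministic. HiFi-like defaults: mean 18 kb, capped below
25 kb, 10⁻³ substitutions and 2×10⁻⁴ indels per base — chosen so that a
read's gap-compressed mismatch ratio against its own haplotype
(≈ 1.2×10⁻³) passes the 0.002 final filter while staying realistic for
circular-consensus data. Ultra-long defaults: mean 150 kb, minimum 100 kb,
2 % substitutions, used only as phasing evidence.

What the generator does **not** emulate: chimeric reads and adapters,
GC-coverage bias, quality-score miscalibration, structural variation, and
repeat-induced mismapping. Passing the suite therefore demonstrates the
algorithmic chain is correct under its stated assumptions, not that the
default consensus core matches a trained model's accuracy on real data.

## Study conditions and problem sizes

The end-to-end synthetic study (used by the acceptance checks and
`scripts/acceptance.R`) runs on a 1 Mb diploid (two 1 Mb haplotypes) with
40× HiFi-like and 12× ultra-long coverage, draft errors at ~1/50 kb, and
five 25 kb LOH intervals. Five intervals rather than the minimum two: at
one error per 50 kb, an injected error lands inside a given interval with
probability ≈ 0.63 and can split its identical run below the strict
20,000-base detector, so a handful of intervals keeps at least one
detectable region for any seed — Poisson arithmetic on the stated rates,
fixed before any benchmarking. Pipeline QV is computed on contig interiors
(1 kb margin) because simulated coverage ramps at contig ends produce
k-mers absent from the read set for depth reasons, not accuracy — the
synthetic analogue of restricting QV to well-covered confident regions.
Unit tests use 5–300 kb genomes; oracle comparisons use ≤ 5 kb instances
where exhaustive dynamic programming is cheap.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; conversion to 1-based
  happens only in VCF records.
* Projection through an alignment clips to the alignment span, drops empty
  images, includes destination-only sequence (insertions) strictly inside
  an interval and excludes it at the edges; soft clips consume query but
  project nowhere; reverse-strand query output can be normalized to
  forward coordinates on request.
* Consensus ties prefer the assembly base, then lexicographic order;
  haplotype-selection ties choose haplotype A; assignment ties keep the
  current haplotype; sweep ties take the lowest cutoffs. Every tie-break is
  deterministic.
* Zero-coverage windows are skipped with a log entry; zero-coverage sites
  yield no genotype call; an empty edit list applies as the identity.
* Each public simulation entry point takes one integer seed and restores
  the caller's RNG state afterwards; identical seeds give byte-identical
  FASTA/FASTQ/SAM output.

## Known limitations

* The variant-mode reassignment handles one alignment per read per
  haplotype; split (supplementary) alignments are projected independently
  and secondary alignments are ignored.
* Het candidates are SNV-only (above); falsely homozygous indel
  heterozygosity is reassigned only insofar as flanking SNVs carry the
  signal.
* The mismatch-ratio filters apply per alignment record, not per read.
* The default consensus predictor has no learned error model; its GQ is a
  support fraction, informative but not calibrated to empirical error
  probability. The GQ-filter optimum transfers from the published setting
  rather than being re-derived for this core.
* K-mer QV inherits the known blindness of k-mer methods to errors in
  repetitive sequence whose k-mers occur elsewhere in the genome, and a
  read set with systematic bias (e.g. GC dropout) inflates the apparent
  error count; the context-stratification tools exist to quantify exactly
  these effects.
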