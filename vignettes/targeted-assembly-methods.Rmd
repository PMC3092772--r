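---
title: "Targeted localized assembly: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted localized assembly: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetasm)
```

## The problem and the approach

Whole-genome alignment or de novo assembly is wasteful when the question is
narrow: *is this particular variant present in this read set?* `targetasm`
answers such questions by **targeted localized assembly**. The user supplies
one or more short DNA *targets* — typically the two alleles of a candidate
SNV, a breakpoint junction, or a probe ending in an ambiguous base — and the
tool mines an arbitrarily large read set for exactly the reads that belong
to that sequence space, then assembles them stringently around the target.

The procedure has three stages:

1. **Word indexing.** Every length-`k` word (default `k = 15`) is extracted
   from the plus *and* minus strand of each target and stored in a hash
   table mapping word to `(target, strand, offset)`. A target of length
   $L$ contributes exactly $2(L - k + 1)$ hits. Fifteen-base words balance
   speed against specificity: a random 15-mer has a $4^{-15} \approx 10^{-9}$
   chance of matching a given word, so random reads are essentially never
   recruited, while every read truly overlapping the target by at least
   `k` bases at its start is caught.

2. **Prefix-anchored recruitment.** The read set is streamed once; a read
   is retained iff its **first `k` bases** exactly match an indexed word.
   Plus-strand words catch reads entering the target from the left;
   minus-strand words catch reads sequenced from the opposite strand.
   Anchoring to the prefix (rather than any internal word) is deliberate:
   it is what makes the flank-extension arithmetic below exact, and it
   keeps memory and time per read constant. Reads with `N` in the prefix,
   or shorter than `k`, are never recruited.

3. **Stringent placement and majority-rule extension.** Each candidate hit
   proposes a placement on the target coordinate axis (`start = offset`
   for a plus hit; `start = offset + k - read_length` for a minus hit, the
   oriented read's last `k` bases sitting over the word). A placement is
   accepted only if it overlaps the target by at least `m` bases and
   agrees with the target at **every** in-target position it covers — the
   perfect-agreement rule. Per-position base counts are tallied within and
   beyond the target; the in-target consensus therefore equals the target
   verbatim, and the consensus is extended outward one position at a time.
   A flank position is appended iff its depth is at least `o` **and** the
   most represented base accounts for at least fraction `r` of the depth;
   the first failure terminates that direction permanently.

Variants of one locus are supplied as separate targets, and a variant's
presence is read out from a successful assembly with spanning-read support
— exact-match assembly means reads carrying the other allele at the focal
base are excluded by construction, so ref/alt support separates cleanly.

## Parameters

| flag | meaning | default | notes |
|------|---------|---------|-------|
| `-k` | word size (nt) | 15 | below 11 a low-specificity warning is issued; low-complexity or long targets recruit more reads |
| `-m` | minimum in-target overlap (nt) | 15 | bounds flank extension at `read_length - m` per side; must be `>= k` |
| `-o` | minimum flank depth (reads) | 2 | extension stops at the first position below this depth |
| `-r` | minimum top-base ratio | 0.7 | `count(top)/depth`; see below |
| `-c` | minimum reported in-target depth | 1 | contig ends are trimmed inward until every reported in-target base reaches this depth |

**Ratio semantics.** `r` is interpreted as the fraction of the column depth
held by the most represented base (`count(top)/depth >= r`), the convention
of greedy-extension assemblers of this family. The alternative reading —
top count divided by the *second* base's count — is degenerate (any strict
majority passes at 0.7) and is not used.

**Tie-breaking.** If two bases tie for the top count the ratio is at most
0.5, so for any `r > 0.5` (including the default) extension simply
terminates. For `r <= 0.5` the alphabetically first base is chosen; this is
documented and tested but not recommended.

**`-c` trimming.** The reported contig is trimmed inward from each end
until every reported in-target position has depth at least `c`. Trimming is
ends-only: with the default `c = 1` it removes uncovered target margins; it
never rescues an interior coverage gap. A side whose in-target edge is
trimmed reports no flank extension.

**Conflicting placements.** When a read has several admissible placements
on one target (internal repeats), the largest in-target overlap wins, ties
broken by the smallest start, then by the plus strand. Reads hitting
several targets contribute independently to each — localized assemblies
are independent by design.

**`N` handling.** Input symbols outside `{A,C,G,T,N}` are mapped to `N` on
load. An `N` over the target is a mismatch (the read is rejected); an `N`
in a flank does not enter the base counts but the read still occupies the
span.

## The extension arithmetic

Prefix anchoring makes the maximum flank extension exactly
`read_length - m` per side: a read can only be recruited if its first `k`
bases lie within the target (possibly as a minus-strand word), and it must
keep at least `m` bases on the target, so at most `read_length - m` bases
can protrude. Hence 33-nt reads with `m = 15` extend a target by at most
18 nt per side, and 150-nt reads with a 150-nt target can produce a
`150 + 2 * 135 = 420` nt contig with 270 previously uncharacterized bases.
Extension is single-round by construction — a target shorter than two read
lengths captures all the extension the read length allows, which is why
targets should be at least as long as the reads and why longer reads yield
more novel flanking sequence.

Both bounds are *attained* only when the extreme flank positions satisfy
the `o`/`r` thresholds. The extreme position on each side is covered by
exactly one distinct placement (the read protruding maximally), so with
`o = 2` the bound requires at least two reads at that placement. The
deterministic tiling generator `tile_reads()` therefore emits two identical
reads per (start, strand) by default: this is the dense, error-free tiling
condition under which the analytic bounds are realized exactly, and it is
what the acceptance benchmarks use (500-nt and 1,500-nt references — sizes
chosen to keep the fixtures instant while leaving generous margins around
the embedded targets).

## Target design

* **SNV pairs** (`snv_target_pair()`): two targets of odd length (51 by
  convention) differing only at the centred focal base. Centring maximizes
  the number of words overlapping the base under scrutiny, so candidate
  reads carrying it at any offset can be recruited. Contexts shorter than
  `2k + 1` work but recruit less sensitively (warned).
* **Ambiguous-last-base probes** (`fusion_probe_set()`): four targets
  sharing a known prefix (37 nt by convention) and differing in the final
  base. Any read extending past the probe end must cover — and match —
  that final base, so exactly the probe matching the unknown neighbouring
  sequence extends, and its extension spells out the partner sequence.
* **Junction targets** (`junction_target()`): two arms concatenated across
  a putative breakpoint, the junction coordinate recorded for
  chimaeric-read counting. A spanning read with at least one base on each
  side is direct evidence for the event.

Support counting follows the spanning-read convention: a read *spans* a
focal position if it covers it; it counts as *interior* support only if the
focal base is at least 5 bases (configurable) from both read ends, where
base calls are reliable. The margin is read as "at least 5 bases from each
end": the opposite reading (only within 5 bases of an end) would keep
exactly the least reliable reads. Detection defaults to one interior
spanning read — a presence/absence readout; raise the threshold for
stricter screens.

## The read simulator

`simulate_reference()`, `implant_variant()` and `simulate_reads()` provide
fixtures with exact ground truth: uniform-random references; implanted
SNVs, deletions and fusions with recorded coordinates; uniform read starts;
configurable depth, read length, strand balance and per-base substitution
error; allele mixtures for heterozygotes. A single integer seed determines
everything.

What the simulator does *not* emulate: platform-specific error profiles and
quality scores (the assembler ignores qualities), indel sequencing errors
(the assembler is gapless, so they act like elevated substitution rates at
recruitment), non-uniform coverage, and paired-end structure. Passing the
synthetic suites therefore demonstrates algorithmic correctness — exact
recruitment, placement, extension arithmetic, allele separation — not
robustness to every artefact of real instruments.

The statistical validation runs at desk scale, with conditions chosen a
priori: heterozygote recovery uses a 50/50 SNV at 20x total depth and 1%
error over 50 seeded replicates, with 71-nt centred targets and 36-nt
reads (targets at least as long as the reads, per the design guidance
above; short-read length typical of early RNA-seq sets). A Poisson power
calculation at these settings predicts roughly five error-free interior
placements per allele, i.e. per-replicate both-allele recovery near 0.99,
against the >= 95% acceptance bar. Fusion discovery uses 25 seeds of
error-free 30x coverage over a 400 + 400 chimaera interrogated with the
four-probe design.

## Numerical and degenerate cases

* Empty recruitment, or no read passing placement, yields no contig —
  absence is a result (exit status stays 0).
* `c` larger than the available depth can trim a contig away entirely;
  this is reported as no contig.
* Duplicate read IDs across lanes are tolerated (identity is ID +
  source file + ordinal); duplicate *target* IDs are disambiguated with an
  ordinal suffix and a warning.
* FASTQ records are assumed 4-line; multi-line FASTA is accepted for both
  targets and reads; gzip input is auto-detected. Streaming is chunked
  (5,000 reads by default), so memory is a function of chunk size, not of
  read-set size; chunk fetches re-scan the file header-to-offset, trading
  parse time for the memory contract.
* Assembly is order-independent: any permutation of the input reads yields
  identical contigs (only the read-position file ordering may differ).

## Known limitations

* Gapless: an indel between read and target rejects the read rather than
  gapping the alignment; indel variants are interrogated via alternate
  targets carrying the edited sequence.
* Single-round extension: the extended consensus is not re-used to recruit
  further reads, so flanks are bounded by `read_length - m` regardless of
  depth.
* Adjacent variation not encoded in the target suppresses recruitment
  (stringency cuts both ways); supply one target per haplotype when
  nearby variants are known.
* Low-complexity targets recruit spurious reads and may extend through
  repeats; word multiplicity is retained, but no repeat resolution is
  attempted.
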