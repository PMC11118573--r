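---
title: "Reconciling DNA- and protein-based annotation lift-over"
author: "protlift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling DNA- and protein-based annotation lift-over}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protlift)
```

## The problem

When a genome is newly assembled, the fastest route to an annotation is
lift-over: transfer the gene models of a well-annotated reference genome onto
the new (target) genome by sequence homology. Two families of tools do this
with complementary failure modes:

* **DNA-based mapping** (Liftoff-style) aligns genomic DNA. It carries UTRs
  and non-coding genes along, but when the target diverges, it produces
  transcripts with broken reading frames or wrong splice sites, and its exon
  coordinates can encode frameshifts or premature stop codons.
* **Protein-to-genome alignment** (miniprot-style) aligns the reference
  protein, spliced, against target DNA. It is robust to synonymous
  divergence, but it cannot see UTRs or non-coding genes, may skip short
  exons separated by long introns, retains introns when a splice junction is
  missed, and happily aligns a protein onto a processed pseudogene.

`protlift` consumes both candidate annotations (as GFF3) plus the two
genomes and the reference annotation, and merges the candidates into a
single annotation whose proteins are as close as possible to the reference
proteins. Everything is organized around a single scalar: the
**gap-compressed protein identity** of a candidate transcript's translation
against the reference protein.

## Identity metrics

DNA identity is BLAST-style: matching bases over all alignment columns, with
gap columns in the denominator. The alignment is global Needleman–Wunsch
with affine gaps (match 1, mismatch −3, gap open 2 charged on the first gap
base, extension 2 per further base).

Protein identity uses a global BLOSUM62 alignment (gap open 11 on the first
gap residue, extension 2) with two modifications:

1. **Stop truncation.** Columns after the column holding the query protein's
   first `*` are discarded: everything a broken reading frame produces after
   a premature stop is meaningless sequence and is neither rewarded nor
   penalized per-residue.
2. **Gap compression.** Each maximal run of columns gapped in the
   *reference* row counts once in the denominator. A query protein that runs
   long (repeat expansion in the target, or a truncated reference protein)
   pays a single penalty per extension, not one per residue.

Two conventions the scoring needs that standard matrices do not pin down:
`X` (an N-containing codon) scores 0 against everything, and `*` scores +1
against `*` and −4 otherwise — the usual BLAST extension of BLOSUM62, except
that we use 0 rather than −1 for `X` so ambiguous bases are neutral.
Traceback ties break deterministically (diagonal > up > left), which makes
every identity in this package reproducible to the byte.

The windowed form of the metric (`partial_identity()`) restricts the same
formula to the alignment columns covering a span of reference and query
residues. One deliberate choice: stop truncation inside a window considers
only stops *inside that window*. If it were global, a premature stop in
block 2 of a transcript would zero the scores of blocks 3..n of that
candidate and the chaining algorithm below could never select the good
downstream blocks of an otherwise broken candidate — contradicting the
intended behavior of the worked example, where the DNA-based candidate wins
the blocks downstream of its own premature stop.

## Step 1: chaining

For each reference transcript, the paired DNA-based and protein-based
candidates are both translated and globally aligned to the reference
protein. Each candidate's CDS endpoints are then expressed in *reference
protein coordinates*: the endpoint is the number of complete codons
accumulated, carried through the alignment by a column walk (insertions in
the query consume no reference residues, so the boundary shifts exactly as
the cigar dictates).

CDSs are grouped 5′→3′: accumulate CDSs from both candidates until both
reach an endpoint with the same count of aligned reference amino acids; that
closes one comparison block. The final block is forced closed at the last
CDS of both candidates, and a block can be one-sided when a candidate has
run out of CDSs (the empty side scores 0 — absence must lose to any aligned
residue). Within each block the windowed identity decides the winner; ties
go to the DNA-based candidate so that UTRs and exon structure survive into
the output. The winning groups are concatenated into the merged CDS chain.

Two details make the concatenation safe:

* **Frame continuity.** Groups close at equal *amino acid* counts, but CDS
  endpoints are nucleotide positions and can sit mid-codon. When the merged
  chain switches source and the incoming group's codon phase disagrees with
  the accumulated chain length mod 3, the incoming group's first CDS is
  trimmed by up to 2 nt. CDS phases of the merged chain are recomputed from
  scratch (cumulative length mod 3), never copied from the sources.
* **Dominance guard.** The merged identity is recomputed from the merged
  chain's actual translation. If it ever falls below the better single
  candidate (conceivable when a mid-codon junction produces a chimeric
  residue), the chain falls back to that candidate wholesale. This makes
  "merged ≥ max(candidates)" an unconditional invariant of the
  implementation rather than a statistical tendency; on the package's
  fixture sweeps the guard never fires, but it turns a rare corner case
  into a guarantee.

If the two candidates map to different sequences or strands, chaining is
skipped and the DNA-based candidate wins outright.

## Step 2: ORF repair

After chaining, each transcript is compared with its reference: the CDS
chains are aligned as DNA and as protein, and the differences are
classified as `identical` (CDS DNA equal — exclusive of all others),
`synonymous`, `nonsynonymous`, `inframe_insertion`, `inframe_deletion`,
`frameshift`, `stop_gain`, `stop_loss`, `start_loss`. Conventions worth
stating: "identical" is decided on the spliced CDS chain (UTR-only changes
do not demote a transcript); indel detection uses a contiguity-preferring
gap cost (open 6, extend 2) because under the identity scoring
(open = extend = 2) a 3-nt gap can split into co-optimal 1+2 runs and
masquerade as a frameshift; substitution columns involving `*` belong to the
stop categories and are not additionally counted as nonsynonymous; and the
report records the mutations observed *before* repair — the repair changes
the annotation, not the fact that the target carries the mutation.

Transcripts with a deleterious category (`frameshift`, `stop_gain`,
`stop_loss`, `start_loss`) enter the ORF search: over the spliced transcript
(exons including UTRs when present, so new starts in the 5′ UTR and new
stops in the 3′ UTR are reachable; the bare CDS chain otherwise), the
longest ATG-initiated ORF is found in each of the three frames (ties:
leftmost start; an ORF without an in-frame stop runs to the sequence end,
covering stop-loss). The candidate with the highest protein identity to the
reference replaces the CDS chain **only if it strictly exceeds** the
current annotation's identity; identity ties prefer the current reading
frame, then frame 0 < 1 < 2. Post-repair identity is therefore monotonically
non-decreasing, which the pipeline enforces with a hard assertion.

A consequence of stop truncation worth understanding: a transcript
truncated *late* scores high (most columns before the stop match), so the
ORF search will not move a late premature stop — it simply keeps the
truncated protein, which is also what a curator would annotate. A stop
*early* in the protein scores low, and a downstream or upstream start that
recovers most of the protein wins. Both behaviors fall out of the metric;
no special-casing is involved.

## Copies, overlaps, pseudogenes

Accepted gene loci are tracked in an interval registry. Two loci may
overlap by at most 10% (shared bases over the shorter span) unless the
corresponding *reference* genes already overlap, in which case the overlap
is whitelisted. Strand is ignored for overlap: a locus blocks both strands
(conservative; the alternative admits antisense duplicates on flimsy
evidence).

Extra copies found by the DNA-based aligner (genes carrying
`extra_copy_number`) are admitted in descending DNA identity order, subject
to the identity threshold (`-sc`, default 0.95) and the overlap rule.
Protein-only candidates face stricter filters, because protein-to-genome
alignment is the classic way to annotate a retrocopy as a gene:

1. the overlap rule above;
2. an intronless candidate (single CDS) is admitted only if the reference
   gene also has a single-CDS isoform — an intronless copy of a multi-exon
   gene is the signature of a processed pseudogene;
3. the candidate's summed CDS length over the coding length of the
   reference gene's longest isoform must lie in [0.9, 1.5] — partial
   protein mappings and read-through fusions fall outside the band.

Accepted protein-only copies get a gene parent synthesized from the
reference gene record and carry no UTRs. Extra copies are numbered `_1`,
`_2`, ... by (seqid, start), with the first-mapped copy keeping the
reference id.

## The synthetic world generator

`make_world()` builds, from a list of seeded scenarios, a reference genome
with annotation, a mutated target genome, and the two candidate GFF3s —
emulating the aligners' failure modes by *corrupting coordinates*, not by
running aligners. Defaults describe a small but structurally realistic
world: genes of 3–5 exons, 10–16 codons per exon, introns of 24–45 nt
(multiples of 3 so an intron retention stays in frame), UTRs of 18–36 nt,
150 nt intergenic spacers; strands are drawn at random per gene. Scenario
seeds fully determine the output, byte for byte.

One design rule does most of the work: all filler sequence (spacers, UTRs,
introns) is drawn from the A-free alphabet {C,G,T}. A-free triplets can
encode neither ATG nor any stop codon in any reading frame, so the planted
starts and stops are provably the only ORF determinants, and each
repairable scenario has a unique intended repair whose post-repair identity
against the truth protein is exactly 1.0. The generator covers clean
transfer, in-frame indels, frameshifts with early stops, premature stops
with downstream starts, stop loss into the 3′ UTR, start loss repaired
downstream or from the 5′ UTR, missed splice junctions on either side,
exon skipping by the protein aligner, tandem duplicates (synonymous
third-position changes only), and processed pseudogenes plus a ratio-0.5
partial copy.

What a green test on these worlds does **not** establish: behavior on real
repeat structure, paralog families with high cross-identity, alternative
isoforms per gene (the generator plants one transcript per gene),
non-coding genes, or chromosome-scale inputs. The fixtures validate the
algorithmic machinery, not genome-scale recall.

## Numerical and degenerate-input choices

* Translation uses the standard genetic code only; codons containing
  non-ACGT characters translate to `X`; a trailing partial codon is
  ignored. The terminal stop codon is included inside CDS features
  (RefSeq convention).
* A protein-based candidate whose first CDS carries a nonzero GFF3 phase
  has that many bases skipped before translation.
* Identity comparisons use full double precision; the chaining tie rule
  (`>=` favoring the DNA candidate) is the only place equality matters.
* Empty sequences are alignment errors; an empty annotation writes a
  header-only GFF3; a transcript with no ATG anywhere yields no ORF
  candidates and the repair leaves it unchanged (logged, not an error).
* Coordinates are 1-based inclusive everywhere in the public surface;
  half-open arithmetic appears only inside operations.

## Known limitations

* Pairing assumes the protein-based candidate records its source transcript
  (a `Target` attribute or a `_copy<N>` id suffix); exotic id schemes need
  the `copy_regex` argument.
* Multi-isoform genes are processed per transcript; the locus registry
  operates on gene spans, so heavily nested isoform structures with
  legitimate >10% overlap across *different* genes rely on the reference
  whitelist.
* The mutation report is transcript-level and coding-centric; UTR-only
  differences are invisible to it (they do show up in the DNA identity).
* Only annotation reconciliation is implemented: running the underlying
  DNA and protein aligners is out of scope, as is chromosome-restricted
  two-pass mapping.
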