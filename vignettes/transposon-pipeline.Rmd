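---
title: "Characterizing Tc1/mariner transposons: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing Tc1/mariner transposons: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmariner)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the parameters that matter and their
defaults, what the synthetic-data generators do and do not emulate, and
the design choices made where the design was genuinely open.

## The biological object

Tc1/mariner elements are cut-and-paste DNA transposons. An autonomous
element is a single transposase ORF flanked by terminal inverted repeats
(TIRs); the transposase carries a DNA-binding domain with a GRPR-like
motif, a nuclear localization signal, and a catalytic triad of acidic
residues (DDE or DDD) whose spacing names the family — DD34E for the Tc1
group, DD37E for TRT, DDxD for pogo. Integration is strictly into TA
dinucleotides, which are duplicated on both flanks (the TA target site
duplication), and excision leaves a short footprint of a few base pairs
at the donor site. Young, recently expanded family members are
recognizable by intact structure, many near-identical genomic copies,
and low divergence from the family consensus.

## Structural annotation

**TIR detection** (`find_tirs()`) is an anchored terminal comparison: it
asks how far the element's 5' end matches the reverse complement of its
3' end, not whether any inverted repeat exists anywhere in the interior.
This is O(max_len) via a single cumulative match profile, and is the
right question for elements that have terminal TIRs by definition. The
reported arm is the longest length within `[min_len, max_len]` (defaults
20–250 bp) whose arm-to-arm identity is at least `min_identity`
(default 0.9), with one refinement: an arm must end on a matching base.
Without that trimming rule the "longest arm above the identity
threshold" is ill-posed — a perfect 201-bp arm could always be padded
with up to ~10% trailing mismatches and still clear a 0.9 threshold, so
the raw criterion would systematically overshoot planted truth.

**TSD checking** (`detect_tsd()`) compares the `tsd_len` bases (default
2) immediately flanking a copy; for Tc1/mariner the expected duplicated
text is `TA`, which is its own reverse complement, so the check is
strand-invariant. A copy at a contig edge yields `NA` with a warning
rather than an error: real copies do land near assembly edges and should
be reported, not crash a run.

**ORF finding** (`find_longest_orf()`) scans all six frames for
ATG-initiated, stop-terminated ORFs under the standard code, keeping the
longest at or above `min_aa` (default 300 — autonomous Tc1/mariner
transposases run roughly 300–400 aa; ZB's is 341 aa). The interval
includes the stop codon; the protein does not.

**Family classification** (`classify_catalytic_family()`) is a
constrained pattern scan, not an HMM or reference alignment: it
enumerates (D, D, D/E) triples with the first gap in 60–120 and the
second in 25–45 (both configurable) and keeps the triple with the
highest acidic-residue context score (fraction of D/E in the 11-residue
windows around the three positions). This is a deliberate
simplification: assigning families by D2–E spacing alone reproduces the
DD34E/DD37E/DDxD nomenclature without requiring curated reference
domains, but it cannot distinguish families that share a spacing, and
the context score is a crude surrogate for conservation. The GRPR and
NLS scans (`scan_simple_motifs()`) are likewise declared surrogates for
dedicated predictors: G-R-[PK]-R in the N-terminal third, and any
6-residue window with ≥4 K/R.

**Full-length copy clustering** (`cluster_full_length_copies()`): the
field's ">99% identity" convention for recent expansions is the default
identity threshold (0.99), and "full length" is defined numerically as
within 5% of the consensus length — no published numeric definition
exists, so the package fixes one and exposes it. Optionally both TIR
arms must also be detectable on the copy.

## Insertion-age profiling

Divergence of a copy from the family consensus is measured with the
Kimura two-parameter distance. With `P` and `Q` the transition and
transversion proportions over compared sites,

$$K = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

and the insertion age is $t = K / (2r)$ with the neutral substitution
rate $r$ per site per year (default $4.13 \times 10^{-9}$, the average
rate conventionally applied to zebrafish). Numerical choices:

* Gap and `N` columns are excluded **pairwise**, not list-wise; equal
  length inputs are compared positionally, unequal ones are globally
  aligned first (`Biostrings::pairwiseAlignment()`).
* When $1 - 2P - Q \le 0$ or $1 - 2Q \le 0$ the distance is
  **saturated**; such copies get `NA` and are carried into an explicit
  overflow bin of the age landscape rather than dropped, so landscape
  mass is conserved exactly (the sum over bins plus the overflow equals
  the summed copy lengths).
* Plain K2P is used, with no CpG adjustment — a documented limitation;
  the rate is quoted per synonymous site but applied to all sites of a
  copy, the standard simplification in repeat dating.
* $K \ge P + Q$ always (the multiple-hit correction only inflates),
  with equality only at $(0, 0)$; this is tested as a property and the
  implementation is cross-checked against an independent K80 distance
  (`ape::dist.dna`).

## Insertion-site calling from junction reads

A junction library read is `[TIR tag][genomic flank][linker]`. The
pipeline (`call_insertions()`) has three stages:

1. **Trimming** (`extract_genomic_fragment()`): the TIR tag must open
   the read within `max_mismatches` (default 1); the linker is stripped
   at its first match; an optional 3' quality trim (Phred threshold,
   default off — synthetic libraries are error-free and no published
   threshold exists to inherit) runs before the linker search. Fragments
   under `min_fragment_len` (default 25 bp) are rejected. Every
   rejection is categorized (`no_tag`, `too_short`, `all_linker`).
2. **Mapping** (`map_fragment()`): single-pass unique-best
   seed-and-extend against a keyed k-mer index (`seed_len` 16). Up to 8
   non-overlapping seeds per fragment nominate candidate starts on both
   strands — multiple seeds matter because one sequencing error in the
   single leading seed would otherwise lose the read — and candidates
   are verified by full-length mismatch counting. A hit is reported only
   if exactly one location attains the best mismatch count (≤ 4% of the
   fragment length by default) and the runner-up is worse by at least
   `margin` (default 2) mismatches; otherwise the fragment is
   `ambiguous`. This replaces iterative "cycling" mapping strategies
   with a deterministic, testable policy.
3. **Site building**: PCR duplicates (identical mapped start, strand and
   fragment length — the natural duplicate signature of a
   sonication-sheared library) collapse by default; reads then reduce to
   `(chrom, TA position, strand)` sites with read counts. No minimum
   read count is applied by default; `min_read_count` exposes one.

The site coordinate convention had to be fixed here: the reported locus
is the 1-based position of the **T of the TA on the forward strand**.
The genomic flank of a read begins with the duplicated TA, so a forward
mapping at start *s* places the T at *s*, and a reverse mapping ending
at *e* places it at *e* − 1; both element orientations at one site
therefore yield the same TA locus. Sites whose reference dinucleotide is
not TA are retained but flagged (`ta_validated = FALSE`) — they are
diagnostic of mismapping or non-canonical integration, and silently
dropping them would hide both.

## Target-site profiling

`build_pfm()` counts bases in an even `window` (default 60 bp, the
conventional logo window) centred on the TA; minus-strand site windows
are reverse-complemented before counting (orientation by element
strand), a behaviour that can be disabled to pool strands as-is —
published logos do not always state which was done, so both are
supported. Per-column information content is the plain Shannon form
`IC = 2 − H` with an additive pseudocount (default 0.5 per base for
stability; 0 wherever exact values are asserted); no small-sample
correction is applied. The palindrome score mirrors the window about its
centre and averages the cosine similarity between each left column and
the complement-permuted right column; the TA itself is its own reverse
complement, so a half-width of 1 always scores 1, and the planted
`ATATATAT` context scores > 0.99 while a deliberately non-palindromic
planting scores low. One subtlety worth knowing: with orientation
normalization on, a fixed genomic (non-strand-symmetric) context planted
at sites of mixed strand is re-symmetrized by the pooling itself —
asymmetry tests must fix the strand.

## Feature enrichment against a random null

Insertions are points (the TA); tracks are 0-based half-open intervals;
a point is inside iff it falls in any interval. The null is
`generate_random_loci()`: chromosomes drawn proportionally to usable
(non-excluded) length, positions uniform within, fully reproducible per
seed; 100,000 loci is the conventional null size. Fold change is the
sample fraction over the random fraction (the random expectation is 1 by
construction), reported linearly with log2 values alongside; features
are ordered by row-mean fold change rather than hierarchically
clustered. No significance testing is attached — a descriptive binomial
confidence interval on each sample fraction is emitted instead.
Gene-anatomy tracks (`derive_gene_feature_tracks()`) are derived
strand-awarely with a 2-kb default window for
upstream/downstream/TSS/TSE (no published window size exists to
inherit; 2 kb is the common promoter-scale choice and is configurable).
TSS/TSE windows are `[point − w, point + w)` around the 0-based
start/end boundary of the gene. Exon and intron fractions partition the
gene-body fraction exactly for point loci — a tested invariant.

## Germline-mobilization statistics

Litter frequencies are ratios of summed numerators and denominators —
never means of per-litter ratios, which differ and are a classic
aggregation error; the bundled 12-litter table is a case where the two
disagree. Reinsertion distances are `|pos − origin|` on the same
chromosome and undefined across chromosomes; rendering switches from
exact bp to one-decimal Mb at 1 Mb, matching the mixed style of
published tables. Event orientation (F/R) is carried verbatim, not
computed: its reference frame (gene vs chromosome) is not defined in the
source material. Footprint classification anchors the longest common
prefix/suffix of pre- and post-excision sequences (with a required
minimum flank) and reads the unmatched middle as the footprint — exact
matching suffices because footprints are ≤ 3 bp, and the computed length
is invariant to where an ambiguous boundary is placed. Junction TSD
validation checks the two bases 5' of the configured TIR-start text.

## The synthetic-data generators

The generators define the study conditions for every property test and
for the acceptance script:

* `sim_genome()`: i.i.d. bases, AT content tunable (default 0.5).
* `sim_plant_copies()`: copies mutated under a **single-hit** two-
  parameter model — each site substituted with probability *d*,
  transition with probability `tstv/(tstv+1)` (default ratio 2) — then
  inserted at TA positions with the TA duplicated, on random strands.
  Because the model is single-hit, the multiple-hit-corrected K2P
  estimate slightly exceeds *d* (about +3% at *d* = 0.05, +7% at
  *d* = 0.1); the 10% recovery tolerance accounts for this and the
  approximation is adequate for *d* ≤ 0.2. Indels are not simulated —
  the aging analysis concerns substitutions.
* `sim_junction_library()`: flank lengths uniform in 200–500 bp (the gel
  size-selection window of the emulated protocol), i.i.d. substitution
  errors, no quality degradation model.
* `sim_annotation_tracks()`: non-overlapping gene models with exons on a
  jittered grid, plus enhancer-like and open-chromatin interval sets
  placed to a target coverage; realized coverage is recounted exactly
  into the truth.
* `sim_footprint_pairs()`: donor flanks with 0–3 planted extra bases.

Every generator is a pure function of its parameters and seed
(`withr::with_seed`), and every emitted read/copy/interval appears in a
truth table, so precision and recall are computable exactly.

What passing tests on these data do **not** show: real genomes are not
i.i.d. (repeats create mapping ambiguity far beyond the simulated
level), real libraries have structured error and chimera modes,
insertion preferences are chromatin-conditioned rather than
track-planted, and real repeat copies accumulate indels and CpG-biased
substitutions that the aging model ignores. The synthetic suite
validates the machinery, not genome-scale biological claims.

## Problem sizes and determinism

The default test and acceptance runs use toy genomes of 0.2–1 Mb, 50
planted sites with 20 reads each (1,000 junction reads), 50 copies of
2 kb per divergence level, and 100,000-locus null sets — sizes chosen so
each suite completes in seconds to a few minutes on one CPU while
keeping binomial sampling error well inside the asserted tolerances
(e.g. a 100,000-locus null calibrates fold change to ±0.05 for tracks
covering ≥ 5% of the genome). All randomness flows from explicit seeds;
tests freeze seeds and the acceptance script derives all of its
sub-seeds from its `--seed` flag.

## Known limitations

* TIR detection is terminal-anchored; internally rearranged or
  truncated elements with displaced arms are not found.
* Family labels rest on triad spacing only; no phylogenetic placement.
* The mapper is single-pass unique-best; no split reads, pairs, or
  rescue of moderately ambiguous fragments.
* K2P without CpG adjustment slightly mis-dates CpG-rich elements.
* Enrichment is descriptive; no multiple-testing machinery is attached
  because no hypothesis test is performed.
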