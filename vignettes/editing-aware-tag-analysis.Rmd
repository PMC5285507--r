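---
title: "Editing-aware analysis of cross-linking tags: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Editing-aware analysis of cross-linking tags: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kredit)
```

## The problem

The mitochondrial genome (maxicircle) of *Trypanosoma brucei* encodes 18
protein-coding mRNAs, twelve of which are remodelled after transcription by
uridine (U) insertion/deletion editing. Guide RNAs direct the process in a
3'-to-5' wave along the transcript, so at steady state a transcript exists
as a population of preedited, partially edited and fully edited molecules.
The transcripts fall into three categories: *pan-edited* (extensive,
multi-guide editing), *minimally edited* (a single small edited region) and
*never-edited*.

When an RNA-binding protein is UV-cross-linked to its targets and the
protein-bound fragments are sequenced (an iCLIP-style experiment; the tags
are ~30-50 nt cDNAs), each tag may derive from the preedited or the edited
form of its transcript — and because editing inserts and deletes bases,
the two forms have different sequences. `kredit` resolves this with a
dual-reference design: tags are mapped against the maxicircle genome
(which *is* the preedited sequence) and against a catenated reference of
fully edited transcript sequences, and classified by which reference they
map to uniquely.

## The editing model

A transcript's editing is described by a set of events anchored on the
preedited sequence: each event sits immediately 3' of an anchor base
(0-based coordinates) and either inserts `n_u` uridines or deletes `n_u`
uridines that the preedited sequence carries at that point. Sequences are
stored in the DNA alphabet (U as T), since both the references and the
sequenced tags are DNA. Two invariants define a valid preedited/edited
pair:

* **Backbone conservation** — deleting every T from the preedited and the
  edited sequence yields the same string. Editing touches only uridines.
* **Round trip** — `count_editing_extent()` recovers, from the sequence
  pair alone, the per-kind totals of the event set that produced it.

`count_editing_extent()` computes the *minimal* U-only edit counts: with
all non-T characters forced to match, the optimal alignment compares the
T-run lengths gap by gap between consecutive backbone characters, counting
surplus Ts on the edited side as insertions and on the preedited side as
deletions. The test suite checks this against an independent dynamic
program over T-only indels.

One subtlety is worth recording: if a single T-run between two backbone
bases both received an insertion and donated a deletion, the two would
partially cancel under any minimal-distance criterion and the round trip
could not be exact. Real editing sites sit between non-U bases, so the
package's event generator anchors events at *distinct non-T bases* — at
most one event per backbone gap — which makes the round trip exact for
every generated event set. Event application is ordered from the highest
anchor down, so anchor coordinates never shift during application.

Events are anchored on the preedited sequence rather than the edited one
because that is the frame shared by the genome, the annotation and the
editing cascade; the edited-frame position of any site follows from the
net length change of the events 5' of it.

## References and coordinates

`build_reference_pair()` produces the two mapping targets: the genome
itself, and the fully edited sequences of the twelve editing-category
transcripts catenated with runs of 100 `N` characters between them. `N`
never matches any base, so within a mismatch budget of 2 no tag can align
across a junction; the spacer length is far beyond any tag length, which
makes junction artefacts structurally impossible rather than merely
unlikely. A coordinate map translates catenated positions back to
(transcript, position) pairs. Never-edited transcripts appear only in the
genome reference.

Coordinates are 0-based half-open internally (BED convention); SAM output
is 1-based per that standard. The maxicircle is circular, but transcripts
are not allowed to wrap the origin in this version — none of the analyses
the package implements require it.

## Preprocessing

Raw reads are processed in the order **trim → collapse → demultiplex**:

1. `trim_adapter()` removes the longest read suffix matching a prefix of
   the 3' adapter with at most 1 mismatch over at least 5 bases
   (both configurable). Trimmed reads shorter than the minimum insert
   (default 20 nt, deliberately below the expected 30-50 nt tag range so
   short genuine tags are not discarded) plus the 4-nt barcode are
   dropped and counted.
2. `collapse_duplicates()` collapses PCR duplicates by exact full-sequence
   identity — no UMIs are modelled, and base qualities are ignored for
   identity — recording the family size as the tag's multiplicity.
3. `demultiplex()` assigns tags by exact match of the first four bases
   against the barcode table and strips the barcode; unmatched prefixes go
   to an `unassigned` bin.

Read conservation (`input = assigned + short-discards + unassigned`,
counting multiplicities) is asserted inside `preprocess_library()` on
every run. Because barcodes are matched exactly and collapsing is by full
sequence, collapsing before or after demultiplexing gives identical
per-library unique-tag counts; the suite tests this reordering.

## Alignment and classification

The aligner is deliberately **ungapped and exact**: discrimination between
editing states comes from the dual references, not from gapped alignment.
A hit is any locus, on either strand, where the full tag aligns with at
most `max_mismatches` (default 2) mismatches and score at least
`min_score_fraction` (default 0.9) times the tag length, with score
`matches - penalty * mismatches` and a mismatch penalty of 1.

Candidate loci are found by pigeonhole seeding: the tag is cut into
`max_mismatches + 1` disjoint chunks, and any qualifying alignment must
leave at least one chunk mismatch-free, so looking up each chunk's leading
6-mer in a k-mer index of the reference and verifying every candidate
offset misses no qualifying locus. (A single fixed-length seed slid over
the tag would *not* be complete: for a 20-nt tag a mismatch at position 8
intersects every 12-nt window.) Tags shorter than three index k-mers fall
back to a brute-force scan; tags shorter than `seed_length` (default
12 nt) are unmapped by contract. The test suite compares hit sets against
an exhaustive all-offsets/all-strands scan on hundreds of random
instances.

Classification is sequential, mirroring the dual-reference design: tags
are mapped to the genome first; a tag with exactly one best-score locus is
`preedited` and is never re-mapped, tied best loci give `multimapped`
(also final), and only hit-less tags proceed to the edited reference,
where the same uniqueness rule yields `fully_edited` or `multimapped`.
Everything else is `unmapped`. "Unique" means exactly one best-score locus
across both strands of the searched reference; ties are discarded from all
binding counts rather than resolved.

`project_to_transcripts()` intersects genome hits with the annotation (a
hit belongs to the transcript containing its start, preferring one that
contains the whole hit when annotations overlap), flags hits outside any
annotation as `intergenic` and hits discordant with the annotated strand
as `antisense` — tags derive from mRNA, so only sense hits enter binding
counts. Edited-reference hits are translated through the coordinate map.

A tag from an unedited stretch of an editing-category transcript exists
identically in both references and is classified `preedited` by the stage
order; a tag from a partially edited molecule that spans the editing
boundary may match neither reference and legitimately ends `unmapped`.
This ambiguity is a property of short tags over a mixed molecule
population, and the pipeline reproduces it rather than resolving it.

## Quantification

All quantities count unique tags (deduplicated cDNAs, not read
multiplicities) with a sense, uniquely mapped assignment:

* per-transcript counts, with preedited and fully-edited tags combined
  into a total for editing-category transcripts;
* category shares (percent of assigned tags on pan-edited / minimally
  edited / never-edited transcripts);
* region shares (percent preedited vs fully edited, computed over
  editing-category transcripts only — never-edited tags are excluded from
  the denominator since the split is undefined for them);
* length-normalised density, implemented transparently as tags per
  kilonucleotide of preedited transcript length;
* per-position coverage tracks ("unique cDNA count") per transcript and
  frame, with bedGraph export;
* `five_prime_bias()`, the fraction of tag 5' ends in the 5' third of the
  transcript — a summary of the 5'-end accumulation seen on some
  transcripts; uniform starts give ≈ 1/3 (slightly above, because a tag
  must fit inside the transcript, which excludes the last few start
  positions);
* `correlate_with_editing_extent()`, the Pearson product-moment
  correlation between a transcript's total binding share and its editing
  extent (total Us inserted + deleted), over the pan-edited transcripts.
  Zero variance in either vector yields NA with a warning; fewer than
  three transcripts is an error.

The "total share" of a transcript is its combined preedited + fully-edited
tag count as a percentage of all assigned tags. Whether shares should use
raw unique-tag counts or length-normalised values is a genuine choice;
the package defaults to raw unique-tag counts and exposes the normalised
density alongside.

## qPCR enrichment math

Three closed forms, each with the amplification efficiency exposed as a
parameter (default 2, i.e. perfect doubling; no efficiency calibration is
modelled):

* `ddct_relative_abundance()`:
  `fold = E^-[(Ct_tgt,t - Ct_ref,t) - (Ct_tgt,c - Ct_ref,c)]`.
  Technical replicates are averaged before the differences by default; a
  `per_replicate` flag instead pairs replicates by index and reports the
  mean and SD of per-replicate folds. The default was chosen because
  replicate pairing across four Ct series is rarely meaningful for
  technical replicates; both conventions are available.
* `percent_input_enrichment()`:
  `%input = 100 * E^[(Ct_input - log_E(1/f)) - Ct_ip]` for an input
  reverse-transcribed from a fraction `f` of lysate. Mock-IP samples are
  computed identically and reported side by side; no background
  subtraction is applied.
* `pulldown_ratio()`: per-replicate ratios of aligned signal series with
  mean and SD (ratios are taken per replicate first, then averaged).

ΔΔCt antisymmetry (swapping treated and control inverts the fold) and
%input shift invariance (adding a constant to both Cts of a target changes
nothing) are verified on a thousand random tables in the suite.

## What the synthetic generator emulates — and what it does not

`simulate_maxicircle()` builds a random AT-rich ~20 kb genome carrying 18
non-overlapping transcripts (9 pan-edited, 3 minimally edited, 6
never-edited; the defaults use the canonical maxicircle gene names) of
400-900 nt on both strands. Pan-edited editing extents are laid out as
jittered evenly spaced values across 50-550 total Us, so that every
simulated dataset spans the range the real pan-edited mRNAs span rather
than clustering by chance; minimally edited extents cover 4-40, with about
10% of extent realised as deletions where the sequence allows.

`simulate_transcript_pool()` implements the 3'-to-5' cascade as
fixed-length blocks (default 50 nt of preedited sequence, a typical
single-guide footprint) consumed strictly from the 3' end: a molecule with
progress *p* is preedited 5' of its boundary and fully edited 3' of it.
The distribution of progress across molecules is not known from first
principles; the default is uniform over 0..n_blocks, exposed in the
configuration (`"none"` and `"full"` degenerate cases are available and
used by the tests).

`simulate_iclap_library()` samples tag inserts from the molecule pool
under one of three binding models — `extent_proportional` (expected tags
per transcript proportional to editing extent; never-edited transcripts
draw nothing), `five_prime_restricted` (uniform weights, insert 5' ends
confined to the 5' third) and `uniform` — assembles reads as
4-nt barcode + insert + 3' adapter truncated to the read length (default
75 nt), amplifies each unique cDNA into a geometric duplicate family
(geometric chosen as the simplest heavy-tailed family-size law; the rate
is configurable), and applies per-base substitution errors *after*
duplication. Cross-link truncation is modelled simply as the insert's 5'
end; there is no deletion-at-crosslink model, no realistic Illumina error
profile, and no nuclease sequence bias. `simulate_control_library()`
emits 483 structurally valid reads with random inserts, matching the size
of a near-empty mock-purification library.

Every read carries a ground-truth record (transcript, molecule progress,
coordinates, source segment relative to the editing boundary, duplicate
family, error flag), and all generator functions are deterministic given
the configuration seed.

Passing the pipeline's recovery tests on these data therefore shows that
the *computational* chain is correct — classification, counting and
correlation recover a known truth — not that the biological model is
complete. In particular, random sequence lacks the repeat structure and
extreme base composition of a real maxicircle (so multi-mapping rates are
lower than in real data), and the uniform progress distribution makes the
preedited/fully-edited split of the simulated libraries reflect that
choice rather than any steady-state biology.

## Problem sizes and numerical choices

The default study conditions used by the tests and the acceptance script
are: a 20 kb genome, 18 transcripts, 50,000 reads at 30% duplication and
0.1% error for the classification run; 20 independent seeds of 8,000
reads for correlation recovery; 5,000-read libraries for the 5'-bias
contrast; and 1,000 random cases each for the editing round trip and the
qPCR invariances. These sizes make every property measurable with
comfortable statistical margins while keeping a full run of the suite in
the low minutes on a single core.

Ties in best alignment score are never broken — they are classified
multimapped and excluded. Degenerate inputs follow one rule: undefined
ratios (no assigned tags, zero denominators) are NA, never silently
dropped, and invalid configurations (deletion without Us, events on
never-edited transcripts, duplicate barcodes) are errors that name the
offender.

## Known limitations

* Partially edited molecules are only attributable when a tag lies wholly
  on one side of the editing boundary; junction-spanning tags are
  unmapped. This mirrors the underlying identifiability limit of short
  tags rather than working around it.
* The aligner is ungapped by design; it is not a general-purpose read
  mapper and does not attempt local or spliced alignment.
* Gene-length normalisation is plain tags-per-kilonucleotide; no
  model-based differential-usage normalisation is implemented.
* Transcripts wrapping the circular origin are not supported.
* Densitometry is out of scope: the ratio functions consume user-supplied
  signal numbers.
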