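---
title: "Methods: upstream-ORF annotation of 5' UTR variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: upstream-ORF annotation of 5' UTR variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfann)
```

## The model

`uorfann` predicts the qualitative translational consequence of
single-nucleotide substitutions in a transcript leader under the standard
scanning model of cap-dependent initiation: the preinitiation complex scans 5′
to 3′ and initiates at the first AUG in an acceptable context. Three
assumptions delimit everything the package claims:

1. **AUG-only starts.** Near-cognate codons (CUG, GUG, ...) can initiate at
   low efficiency in vivo but are not scanned here; the classification is of
   AUG-gain/-loss mechanisms only.
2. **Geometry, not kinetics.** The output is a discrete classification plus a
   binary repression flag derived from ORF geometry and context strength. No
   attempt is made to predict the *magnitude* of repression — reporter-assay
   percentages are wet-lab quantities outside what sequence arithmetic can
   deliver.
3. **Single-exon leader.** Coordinates assume the leader and CDS are
   contiguous in the mRNA; intronic HGVS offsets (`c.-10+5G>A`) are rejected
   rather than mis-handled.

### Coordinates

Externally everything speaks HGVS c.: c.1 is the A of the start codon (sAUG),
c.-1 the last leader base, and position 0 does not exist. Internally the
package uses ordinary 1-based R indices (`c.-N ↔ L − N + 1`,
`c.M ↔ L + M` for a leader of length `L`); both directions are exact inverses
and the pair (c.-1, c.1) maps to adjacent indices. One consequence worth
stating: a uAUG at c.-N lies exactly `N` nt upstream of the sAUG, so frame
offset is `N mod 3`, and a leader stop at c.-s₁\_-s₃ gives the two published
distance conventions `s₃ − 1` (bases strictly between stop and sAUG,
"stop-end") and `s₁` (first stop base through c.-1, "stop-start"). These
differ by 3 for one and the same stop; reports carry both, and the repression
heuristic uses the stop-end convention.

### ORF delineation

From a leader AUG the scanner walks in-frame triplets. The first
`TAA`/`TAG`/`TGA` wholly inside the leader closes a
`uORF_terminating_in_leader`. An in-frame uAUG reaching c.1 without a stop is
an `inframe_readthrough_extension` adding `N/3` codons. An out-of-frame uAUG
whose ORF crosses into the CDS (including a stop straddling the leader/CDS
boundary — which can only happen out of frame) is an `overlapping_oORF`,
terminated at the first downstream stop. Codon counts are reported both
including and excluding the terminating stop, because both dialects are used
when uORF sizes are quoted; the `length_nt`/`codons_incl_stop` pair always
satisfies `length_nt = 3 × codons_incl_stop`.

### Kozak scoring

The initiation context is the 10-mer at −6..+4 (`N`-padded at sequence
edges). The default weights put 3 on a purine at −3 and on G at +4, and 0.5
on each remaining consensus position of `gccRccAUGG`. The 3/0.5 split is a
deliberate dominance design: the five minor positions together (2.5) can
never outvote one dominant determinant (3), so any two contexts that agree at
−3 and differ at +4 are strictly ordered regardless of their flanks. This is
what licenses the qualitative claim the package makes on its reference
fixture — the created −263 uAUG context (purine −3, G +4) outscores the sAUG
context (purine −3, non-G +4) whatever the unconstrained fill. The strength
class (`strong`/`adequate`/`weak`) is a function of −3/+4 alone; the score
orders contexts within a class. Weights are overridable
(`kozak_model(weights = ...)`, YAML via `read_kozak_config()`), under the
standing invariants that the consensus scores maximally and improving −3/+4
never lowers a score.

### Consequence classification and the repression flag

Per annotation unit (one variant or a cis set applied together), the
classifier diffs leader-AUG and in-frame-stop content against the reference
and reports the highest-impact event: uAUG created > uAUG destroyed > uORF
stop created > stop destroyed > nothing. When one edit creates several AUGs
the most 5′ one — met first by a scanning ribosome — defines the
classification and the rest are listed in `notes`.

The repression flag for a terminating uORF is:

- `predicted_repressive` if `codons_incl_stop ≥ 10` **or**
  `dist_stop_end < 200` nt,
- `predicted_tolerated` otherwise.

The two thresholds (defaults of `annotation_config()`) are operating points
of this package, not biological constants. They encode the two established
geometric determinants of uORF repressiveness — reinitiation after a long
uORF is inefficient, and reinitiation needs intercistronic distance to
re-acquire initiation competence — and were chosen so the engineered
construct series the package reproduces (68-codon/59-nt uORF and 61-codon
uORF repressive; 4-codon uORFs at 251 and 243 nt tolerated) sits comfortably
on the correct sides. Stated as a disjunction, the rule is monotone: moving a
uORF stop downstream (longer uORF, shorter distance) can never flip
repressive to tolerated. The published rule set left uORFs of intermediate
length (5–9 codons) at safe distance unaddressed; the disjunction resolves
them to tolerated, the less alarming default for a screening tool. In-frame
extensions are always flagged repressive with an explicit note that the
mechanism — an unstable extended protein versus suppressed sAUG initiation —
is not resolved by sequence analysis; overlapping oORFs are flagged
repressive since their stop lies downstream of the sAUG. Extension mass is
`codons × 110 Da` (average residue mass, configurable), reported raw and
rounded.

## The synthetic fixture

No transcript sequence ships with the package. `build_fixture()` generates a
300-nt leader plus a 60-nt CDS in which every position that the reference
analyses depend on is pinned:

- `CTG` at c.-263\_-261 and `GTG` at c.-255\_-253, each one substitution from
  AUG; `TGA` at c.-62\_-60 in frame with −263;
- stop-ready triplets `T` at c.-252 (T>A completes `TGA` at c.-254\_-252) and
  `CGA` at c.-246\_-244 and c.-75\_-73 (C>T completes `TGA`) — the two
  spellings match how the corresponding engineered constructs are named, by
  first stop base in one series and by edited base in the other;
- G at −3 of all three candidate starts (c.-266, c.-258, c.-3), G at +4 of
  the −263 uAUG (c.-260), a non-G at +4 of the sAUG (c.4);
- `G` at c.-281 with flanks chosen so that neither `G>T` nor `G>A` there can
  complete an AUG (the two alt alleles under which this variant has been
  written up);
- globally: no AUG anywhere in the wild-type leader, no stop in the −263
  frame before c.-62, none in the −255 frame before the CDS, and a first CDS
  stop ≥ 30 nt downstream of c.1 in every frame so overlapping ORFs always
  terminate but never trivially.

Unconstrained positions are filled iid at 60 % GC (these leaders are
typically GC-rich, which is also why they are poorly covered in capture
sequencing), then a repair pass rewrites free bases of any violating triplet
to C or G — edits that can never create an AUG or stop, so the pass converges
monotonically — and finally free A/T positions are promoted until the leader
GC floor of 0.60 holds. Leader length 300 is arbitrary (any length ≥ 283
hosts the constrained window); the true biological leader length is *not*
asserted. `validate_fixture()` re-checks every constraint independently and
is the contract for substituting a real transcript. The geometry — and hence
every number the acceptance analysis reports — is identical for every seed;
the seed only varies the free fill.

What the fixture does **not** emulate: real nucleotide composition beyond GC
content, secondary structure, conservation, and the actual reference
sequence. Tests passing on the fixture demonstrate correctness of the
*arithmetic and classification logic* under the published coordinate
geometry, not recovery of results from the real transcript.

## Verification design

Two independent code paths guard the scanner. The production path is
vectorised (`substring` over all in-frame codon starts); the oracle
(`orf_oracle`, also the label source for `spike_variants()`) is a deliberate
character-by-character walk. Property tests compare them on seeded random
transcripts — 1000 leaders of 50–400 nt in the acceptance suite, 200 in the
unit suite — and check the arithmetic identities
(`length_nt = 3 × codons = N − s₃ + 1`, `dist` conventions differing by 3,
frame consistency of uORF stops). The classifier is checked by
oracle-labelled spiked SNVs: on an AUG-bearing leader the stratified mixture
covers all seven classifications, and recovery must be exact. These problem
sizes keep the full suite under a minute on one CPU while exercising every
branch of the delineator many hundreds of times.

## Numerical and edge-case choices

- **Ties and degenerate inputs.** Overlapping AUG matches (`ATGATG`) are all
  reported; empty variant files yield empty reports with a warning, not an
  error; a failing annotation unit becomes an `ERROR` row carrying the
  message, so one bad line cannot sink a batch.
- **REF checking.** `apply_variants()` verifies every REF allele against the
  sequence and aborts on mismatch, naming position and both bases — the
  cheapest possible guard against annotating on the wrong transcript or
  leader-length declaration.
- **Allele spelling.** One historical variant in this gene's literature is
  spelled both `G>T` and `G>A` at c.-281 in different places; the package
  treats the genomic record (minus-strand `C>A`, hence `G>T`) as canonical
  and the fixture is safe under both alleles.
- **`N` handling.** `N` never matches AUG or stop patterns, scores 0 in
  Kozak windows, and triggers a load-time warning when present in a leader.
- **Determinism.** All randomness (fixture fill, random transcripts, spike
  sampling) flows through explicit seeds; reports are byte-identical across
  runs for fixed inputs and configuration.

## Limitations

Beyond the model assumptions above: no ribosome-profiling support, no
secondary-structure (ΔG) or IRES reasoning, no phasing inference (cis is
declared by input layout), no genome-wide GTF ingestion, and no liftover.
The package classifies molecular consequence; it never predicts penetrance
or phenotype.
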