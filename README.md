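# uorfann

Annotation of 5′ UTR single-nucleotide variants for predicted translational
consequence.

## The problem

Most eukaryotic mRNAs are translated by cap-dependent scanning: the 43S
preinitiation complex loads at the 5′ cap and scans the leader (5′ UTR) until
it meets the first AUG in an acceptable context. A variant that **creates an
upstream AUG (uAUG)** can therefore silence a gene without touching its coding
sequence: the ribosome initiates upstream instead of at the annotated start
codon (sAUG). Depending on the reading-frame geometry, the new start yields

- a **uORF** — an upstream ORF terminating at a stop codon within the leader;
  long uORFs and short uORF-to-sAUG distances suppress reinitiation at the
  main ORF and are repressive;
- an **in-frame N-terminal extension** — readthrough into the main ORF adding
  `N/3` residues to the protein (for a uAUG at c.-N with `N ≡ 0 (mod 3)`),
  typically unstable and/or competing with sAUG initiation;
- an **overlapping oORF** — an out-of-frame ORF crossing the sAUG, whose
  downstream stop precludes reinitiation.

For haploinsufficient disease genes this is a loss-of-function mechanism that
standard exome pipelines miss. `uorfann` gives variant analysts a tested,
transparent implementation of the whole interpretive chain: HGVS c. /
strand-aware genomic coordinates, in-silico mutagenesis, exhaustive uAUG
detection, ORF delineation with explicit length/distance conventions, Kozak
context scoring, and a qualitative repression-risk classification.

## The computation

For a leader of length `L` in HGVS c. coordinates (c.1 = A of the sAUG, no
position 0):

- a uAUG at c.-N is **in frame** with the main ORF iff `N ≡ 0 (mod 3)`;
- a uORF from c.-N to a stop at c.-s₁\_-s₃ has `length_nt = N − s₃ + 1`
  (`= 3 ×` codons including the stop) and sits `s₃ − 1` nt (stop-end
  convention) or `s₁` nt (stop-start convention) upstream of the sAUG — both
  conventions appear in the literature for the same stop, so both are
  reported;
- initiation context is the 10-mer at −6..+4 scored against the Kozak
  consensus `gccRccAUGG`; a purine at −3 and a G at +4 dominate (weight 3
  versus 0.5 for the minor consensus positions), and the strength class
  (`strong`/`adequate`/`weak`) depends on −3/+4 alone;
- a uORF is flagged `predicted_repressive` when it is ≥ 10 codons long
  (stop included) **or** ends < 200 nt upstream of the sAUG (both thresholds
  tunable via `annotation_config()`); in-frame extensions and overlapping
  oORFs are always flagged repressive, extensions with a predicted added mass
  of `codons × 110 Da`.

Because no reference sequence ships with the package, a constraint-driven
generator (`build_fixture()`) emits a synthetic leader reproducing the exact
coordinate geometry of the published TWIST1 case — reference `CTG` at
c.-263\_-261 and `GTG` at c.-255\_-253 (one substitution away from AUG), an
in-frame `TGA` at c.-62\_-60, engineered stop-ready triplets, and no AUG
anywhere in the wild-type leader — so every published number is recomputable
offline.

## Worked example

```r
library(uorfann)

tx <- build_fixture()
tx
#> <transcript_model> TWIST1like_synthetic
#>   length: 360 nt (leader 300 nt + CDS 60 nt)
#>   sAUG at index 301 (c.1_3)

rep <- annotate_variants(c("c.-281G>T,c.-263C>A", "c.-255G>A"), tx)
rep[, c("variants", "classification", "codons_incl_stop", "length_nt",
        "dist_stop_end", "extension_codons", "extension_mass_kda",
        "kozak_uaug_strength", "repression_flag")]
#>              variants                 classification codons_incl_stop length_nt
#> 1 c.-281G>T,c.-263C>A              UAUG_CREATED_UORF               68       204
#> 2           c.-255G>A UAUG_CREATED_INFRAME_EXTENSION               NA        NA
#>   dist_stop_end extension_codons extension_mass_kda kozak_uaug_strength
#> 1            59               NA                 NA              strong
#> 2            NA               85               9.35            adequate
#>        repression_flag
#> 1 predicted_repressive
#> 2 predicted_repressive
```

Reading the first row: the cis pair creates a uAUG at c.-263 whose ORF runs
204 nt (68 codons, stop included) to the TGA at c.-62\_-60, terminating 59 nt
upstream of the sAUG — a long uORF close to the start, in a strong Kozak
context, hence `predicted_repressive`. The second row is an in-frame uAUG:
readthrough would add 85 residues (≈ 9.35 kDa) to the protein, also flagged
repressive. `plot_leader(tx, rep)` draws the corresponding reading-frame
diagram, and `glance(rep)` summarises the batch.

A command-line wrapper lives at `inst/cli/uorfann.R`
(`annotate`, `scan` and `fixture` subcommands).

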