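---
title: "Methods: CRISPRi screen design and hit calling for pseudogenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPRi screen design and hit calling for pseudogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgscreen)
```

## The problem

CRISPRi silences a gene by parking a catalytically dead Cas9–KRAB
repressor on promoter-proximal DNA, so everything about a pooled
CRISPRi fitness screen hinges on knowing where transcription actually
starts and on placing guides close to it. Pseudogenes make this hard in
three specific ways that this package addresses end to end:

* their TSSs are poorly annotated, so CAGE evidence has to stand in for
  the annotation;
* they are near-copies of their parent genes, so read mapping,
  expression quantification, and guide uniqueness all need explicit
  homology handling;
* CRISPRi repression spreads over ~1 kb of chromatin, so a hit can be
  an artifact of a bidirectional promoter or of a guide's off-target
  site in the partner gene's promoter.

## TSS assignment from CAGE

CAGE tag clusters carry a transcription-initiation evidence score
(TIEScore), consumed here as input. A cluster is assigned as a TSS of a
transcript when it lies on the same chromosome and strand and its
summit falls within `max_offset_bp` (default 500 bp) of the annotated
5' end; a transcript with no qualifying cluster falls back to its
annotated 5' end with TIEScore 0, so design can proceed for every gene
while CAGE-supported TSSs still outrank fallbacks. Gene-level
assignments are the union over transcripts, one row per (gene, cluster)
keeping the smallest summit offset. The distance between two genes'
TSSs — used by the bidirectional filter — is the minimum over pairs of
CAGE-assigned TSSs and pairs of annotated TSSs, never mixing the two
families; genes on different chromosomes are infinitely far apart.

The assignment rule (summit proximity, one tunable offset) is the
package's own choice; boundary conditions are inclusive throughout.

## Guide design

Each assigned TSS defines a 500-bp design window centered on it. Every
20-mer followed by an NGG PAM on either strand, with spacer and PAM
fully inside the window, becomes a candidate. Candidates pass through
the filter cascade:

| filter | rule | boundary |
|---|---|---|
| `multi_mapping` | spacer+NGG occurs at more than one genomic site, both strands | exact occurrences only |
| `has_N` | any N in the spacer | — |
| `poly_T` | more than three consecutive T | `TTTT` flagged, `TTT` kept |
| `gc_extreme` | GC fraction ≥ 0.75 or < 0.10 | 0.75 flagged, 0.10 kept |
| `dedup_removed` | guides whose starts chain within 4 bp keep only the best score | `|Δ| ≤ 4` merges; ties keep the leftmost start |

The uniqueness check deliberately counts PAM-adjacent occurrences of
the spacer rather than bare 20-mers: only PAM-adjacent sites are
CRISPRi-competent. Deduplication chains are resolved greedily by score
with a leftmost-start tie-break, which makes the result independent of
input order and idempotent.

Per gene, up to `max_per_gene` (default 10) passing guides are chosen,
ordered first by the TIEScore of their TSS cluster (descending), then
score, then genomic start. Guide efficiency scoring is pluggable: the
default is a transparent linear position–nucleotide weight model
(`linear_score_model()`), and externally computed scores can be
supplied as a lookup table (`score_table_model()`); reproducing any
particular published weight matrix is out of scope. Library oligos are
always `linker5 + spacer + linker3`, bit-exactly, with the two linker
sequences exported as `pg_linkers`; no 5' G is prepended to spacers.

## Expression filtering with mappability-aware FPKM

Because a pseudogene shares most of its sequence with its parent, raw
gene length overstates the sequence a unique read can come from.
Position *p* is uniquely mappable at read length *k* (default 75 nt,
the screen's read length) when the *k*-mer starting there occurs
exactly once genome-wide counting both strands; *k*-mers with N never
map, and no full-length read starts within *k* of a chromosome 3' end.
The effective length of a gene is the count of mappable positions in
its genomic span (full span by default; an exon-union mode is
available), and

FPKM = count × 10⁹ / (effective length × total reads).

A gene is retained for the screen when FPKM ≥ 0.5 in at least one
cell line sample and it has at least three designed guides.

One property worth stating because it is easy to get backwards: a
unique *k*-mer stays unique when extended, so away from chromosome ends
effective length is monotone **non-decreasing** in read length; only
the 3'-edge positions lose with longer reads.

## Off-target search and the confound audit

The search is exhaustive and PAM-constrained: every genomic 20-mer with
an NGG PAM within Hamming distance `max_mismatches` (default 1) of the
spacer is a site; insertions and deletions (bulges) are never
considered, and genomic N never matches. The designed locus is marked
`is_intended_site` and excluded when counting a guide's off-targets.

A pseudogene/parent hit is *confounded* when it has one and only one
significant negatively selected sgRNA (p < 0.05 and log₂FC ≤
−log₂ 1.5) and that sgRNA has a predicted site within [−2 kb, +1 kb]
of its partner gene's TSS. The window is strand-oriented (upstream
means 5' of the partner), with inclusive boundaries — the package's
reading, since promoter-relative efficacy windows are the mechanism at
stake. The audit also reports how many significant guides remain after
removing offending ones.

## Read quantification

Screen reads (75 nt single-end) carry the spacer after a fixed vector
prefix; trimming 20 nt from the 5' end and 30 nt from the 3' end
leaves a 25-nt fragment. A fragment is assigned to the unique library
guide whose spacer occurs as a forward-orientation substring anywhere
in the fragment; fragments matching two or more spacers are dropped as
ambiguous, and reverse-complement matches never count. Matching
anywhere in the fragment (rather than at a fixed offset) tolerates
small priming jitter. Exact substring matching is the contract; an
optional ≤1-mismatch mode exists for noisy data. Per sample,
assigned + unassigned + ambiguous always equals the reads in.

## Screen statistics

`crispri_screen()` is the fitting function; it returns a classed object
with `print`, `summary`, `plot`, and `screen_hits` methods.

1. **Normalization** is median-of-ratios restricted to the
   negative-control guides: the size factor of sample *j* is the median
   over controls of count(i, j) divided by control *i*'s geometric mean
   across samples (zeros excluded from the geometric-mean set).
2. **Per-sgRNA statistics**: log₂((D21 + 1)/(D0 + 1)) on normalized
   counts per replicate pair, averaged over replicates (pseudocount 1).
   The depletion p-value is the add-one empirical percentile against
   the control guides' fold-change distribution:
   p = (1 + #{controls ≤ lfc}) / (n + 1).
3. **Gene-level test** is α-RRA with permutation: guides are ranked by
   fold change (ties broken by guide id so ranks are a permutation),
   normalized ranks u₍₁₎ ≤ … ≤ u₍ₖ₎ enter
   ρ = min over u₍ⱼ₎ ≤ α of BetaCDF(u₍ⱼ₎; j, k−j+1),
   and p = (1 + #{random size-k rank sets with ρ' ≤ ρ}) / (N + 1).
4. **Hit calling**: p < 0.05, Benjamini–Hochberg FDR < 0.25, and
   second-best lfc ≤ −log₂ 1.5 (the second most extreme guide in the
   selection direction; a single-guide gene represents itself).
   Positive selection is symmetric. Hits whose TSS lies within 1 kb
   (inclusive) of any other gene's TSS are flagged
   `excluded_bidirectional` and removed.

Two numerical choices deserve explanation:

* **ρ = 1 ties.** A gene with no guide rank in the top α fraction has
  ρ = 1 exactly; under a global null that is ~(1−α)ᵏ of all genes, an
  atom that would make permutation p-values pile up at 1. The
  permutation comparison therefore breaks ρ ties lexicographically by
  the gene's best normalized rank u₍₁₎. Hit calling is unaffected
  (hits have ρ ≪ 1), and null p-values are uniform, which the test
  suite checks by simulation.
* **Adaptive α.** With a fixed α = 0.05, a screen in which many guides
  are truly depleted leaves too few contributing ranks: truly
  essential genes crowd each other out of the top fraction and power
  collapses. The fit therefore defaults to
  α = max(0.05, fraction of guides with control-null p < 0.05),
  which reduces to 0.05 under a global null; a fixed α can still be
  passed explicitly, and `rra_gene_test()` always takes α as an
  argument.

## The synthetic fixture generator

`make_toy_genome()` builds the study conditions at desk scale: pairs of
parent and pseudogene on one chromosome, the pseudogene body a mutated
copy of the parent body at a configurable identity (default 0.85) with
an independent, divergent promoter (±250 bp of the TSS); a 20-bp CAGE
cluster with positive TIEScore and jittered summit (SD 10 bp) at every
5' end; one neighbor gene planted with its TSS 700 bp from a pseudogene
TSS to exercise the bidirectional filter; and one confound plant — a
protospacer in a pseudogene promoter whose one-mismatch copy sits in
the parent's [−2 kb, +1 kb] TSS window. The confound pseudogene's
design window is generated free of other PAMs and carries exactly three
protospacers (the confound guide plus two benign ones, the library's
minimum guide count), so the one-significant-sgRNA scenario the audit
must detect is identifiable by construction rather than by luck. The
registry of all plants is returned (and written as JSON) as ground
truth.

`simulate_screen()` emulates the pooled screen: D0 counts negative
binomial with mean `depth` (default 500, matching ~500× per-guide
coverage) and variance μ + φμ² (φ = 0.05, a standard pooled-screen
overdispersion), D21 means scaled by 2^(true lfc), three replicates,
and optionally 75-nt reads with the spacer placed where the trim
expects it plus 0–1 nt of prefix jitter.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: human sequence composition and
repeat structure beyond the planted homology, PCR and sequencing
errors, chromatin-dependent guide efficacy (all guides of a gene share
its true effect), copy-number effects, and cell-population dynamics
beyond a constant per-guide fold change.

## Problem sizes and runtimes

The test suite and the acceptance script use desk-scale problems chosen
to make every check exact or well-powered: fixture genomes of 1–8
gene pairs (10–70 kb), brute-force oracle comparisons on ≤ 30 kb
genomes, a 500-gene × 5-guide null screen with 2000 permutations for
calibration, a 220-gene screen with 20 spiked genes (true lfc −2,
500× depth) for power, and a full design → FASTQ → counts → hits run
on the 8-pair fixture. All seeds are fixed; every simulated quantity
asserted in a test is computed by the code under test or by an
independent oracle in the same run.

## Known limitations

* The off-target search is a vectorized exhaustive scan — right for
  fixture-to-small genomes, not an FM-index replacement for
  genome-scale libraries.
* sgRNA significance is an empirical percentile against controls, so
  its resolution is 1/(number of controls + 1); with few controls the
  p-values are coarse.
* The mappability mask holds whole chromosomes as logical vectors;
  fine at desk scale, memory-hungry for mammalian genomes.
* Exact substring counting assumes clean reads; the ≤1-mismatch mode
  is a slow fallback, not an aligner.
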