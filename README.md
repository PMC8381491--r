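# pgscreen

Design and analysis of pooled CRISPRi fitness screens targeting human
pseudogenes.

CRISPRi represses a gene by steering dCas9–KRAB to promoter-proximal
DNA, so a screening library stands or falls with accurate transcription
start sites and guides that bind nowhere else. Pseudogenes are the
worst case on both counts: their TSSs are poorly annotated and their
bodies are near-copies of their parent genes. `pgscreen` implements the
complete workflow for this setting, for genomicists building CRISPRi
libraries and analyzing the resulting screens:

* **TSS assignment** — CAGE tag clusters (with TIEScore) assigned to
  transcripts by strand-matched summit proximity, with annotated 5'
  ends as fallback.
* **Guide design** — SpCas9 protospacer scan (20-mer + NGG) in 500-bp
  windows centered on each TSS, a quality filter cascade
  (multi-mapping, N, >3 consecutive T, GC ≥ 0.75 or < 0.10), 4-bp
  positional deduplication, up to 10 guides per gene preferring
  higher-TIEScore clusters, and oligo assembly with fixed linkers.
* **Mappability-aware expression** — effective length = uniquely
  mappable positions of the gene span at a fixed read length;
  FPKM = count × 10⁹ / (effective length × total reads); library
  inclusion requires FPKM ≥ 0.5 in ≥ 1 sample and ≥ 3 guides.
* **Off-target audit** — exhaustive PAM-constrained Hamming search
  (≤ 1 mismatch, no bulges) and the parent/pseudogene confound test:
  a hit whose single significant guide has a site within
  [−2 kb, +1 kb] of its partner's TSS is flagged as confounded.
* **Screen quantification** — 75-nt reads end-trimmed (−5 20, −3 30)
  and assigned to the unique guide whose spacer is a forward substring
  of the fragment; ambiguous and reverse-complement matches are
  dropped.
* **Hit calling** — control-guide median-of-ratios normalization,
  per-guide log₂(D21/D0) with control-null empirical p-values, α-RRA
  gene scores with permutation p-values, BH FDR, second-best gene
  fold change, hit thresholds (p < 0.05, FDR < 0.25,
  lfc ≤ −log₂ 1.5), and exclusion of hits with another TSS within
  1 kb (bidirectional-promoter artifacts).
* **Synthetic fixtures** — a generator for toy genomes with
  parent/pseudogene pairs of tunable homology, planted CAGE clusters,
  a bidirectional neighbor, a planted off-target confound, and
  negative-binomial screen counts with known ground truth.

The gene-level statistic is α-RRA: for a gene with k guides ranked
among n, with normalized ranks u₍₁₎ ≤ … ≤ u₍ₖ₎,

    rho = min over u(j) <= alpha of  BetaCDF(u(j); j, k − j + 1)
    p   = (1 + #{random size-k rank sets with rho' <= rho}) / (N + 1)

with ρ = 1 ties broken by the best normalized rank (see the methods
vignette for why, and for the adaptive default of α).

## Worked example

```r
library(pgscreen)

## a desk-scale fixture: 8 parent/pseudogene pairs, CAGE track, truth
fx  <- make_toy_genome(fixture_config(n_pairs = 8, seed = 42))
asg <- assign_tss(fx$annotation, fx$cage)

## design the library and add non-targeting controls
sel  <- design_guides(fx$genome, fx$annotation, asg)
ctrl <- nontargeting_controls(fx$genome, n = 40, seed = 43)
man  <- assemble_library(sel, fx$annotation, ctrl)
manifest_composition(man)
#>        category n_guides n_genes
#> 1 non_targeting       40       0
#> 2        parent       90       9
#> 3    pseudogene       73       8

## simulate a screen where PSG04 and PSG05 are essential (true lfc −2)
ess <- vapply(strsplit(man$gene_ids, ","),
              function(g) any(g %in% c("PSG04", "PSG05")), logical(1))
truth <- setNames(ifelse(ess, -2, 0), man$guide_id)
sim <- simulate_screen(man, truth, depth = 500, seed = 44)

## fit the screen model
gm <- setNames(vapply(strsplit(man$gene_ids, ","),
                      function(g) if (length(g)) g[1] else "",
                      character(1)), man$guide_id)
fit <- crispri_screen(sim$counts, sim$samples, gm, ctrl$guide_id,
                      n_permutations = 1000, annotation = fx$annotation,
                      assignments = asg, seed = 45)
fit
#> CRISPRi screen fit
#>   sgRNAs: 203 ( 40 controls )
#>   genes tested: 17
#>   negative-selection hits: 2 ( 0 excluded as bidirectional )
screen_hits(fit)
#>    gene_id n_sgrnas          rho           p       lfc           q  hit excluded_bidirectional
#> 13   PSG04       10 7.734352e-10 0.000999001 -2.150221 0.008491508 TRUE                  FALSE
#> 14   PSG05       10 2.696802e-10 0.000999001 -2.306972 0.008491508 TRUE                  FALSE
```

Both spiked pseudogenes are recovered as negative-selection hits — the
permutation p is the smallest attainable at 1000 permutations, the
BH-adjusted q is far below the 0.25 bar, and the second-best guide
fold change sits at the simulated truth of −2. No null gene is called.

`plot(fit)` draws the volcano of second-best fold change against
permutation p with the hit thresholds marked; `summary(fit)` adds size
factors and the top genes.

A thin command-line front end over the same functions ships in
`inst/cli/pgscreen.R` (subcommands `annotate`, `design`, `mappability`,
`offtarget`, `count`, `stats`, `simulate`).

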