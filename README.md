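# splicescan

Tools for asking, at desk scale, whether an RNA-binding protein (RBP)
with a known exact sequence motif is positioned to regulate splicing —
and whether splicing actually shifts when conditions change.

The package targets the common situation where SELEX or CLIP work has
produced one or two short motif strings for an RBP, bulk RNA-seq exists
for wild-type and perturbed cells, and the analyst needs to connect the
two: does the motif concentrate at exon–intron junctions on the sense
strand? Which alternative-splicing (AS) event classes does it target,
and at what rate? And do percent-spliced-in (PSI) values of retained
introns and skipped exons move between conditions?

## What it computes

* **Gene model** — FASTA + GTF in, a validated exon/intron model in
  uniform 0-based half-open coordinates out.
* **AS events** — skipped exons (SE), retained introns (RI), mutually
  exclusive exons (MXE), and alternative 5′/3′ splice sites
  (A5SS/A3SS), enumerated from transcript pairs with SUPPA-style
  definitions and deduplicated by coordinate tuple.
* **Motif scan** — exact matches of a motif query on both strands;
  every hit classified per overlapping gene as exon / intron /
  junction-spanning / intergenic, sense vs antisense, with signed
  distances to the nearest splice site (donor vs acceptor).
* **Event targeting** — per class, the fraction of events with a sense
  hit within a window `W` of a splice site, with exact binomial
  confidence intervals; distance profiles per splice-site role; exact
  two-proportion comparisons between runs.
* **PSI & differential inclusion** — PSI from junction counts
  (`PSI = I / (I + S)` with two-junction read classes averaged), and a
  replicate-aware beta-binomial likelihood-ratio test for condition
  contrasts (falling back to the pooled exact test when no
  overdispersion is estimable), BH-corrected, with increased/decreased
  tallies per class. Exon-level RPKM for targeted region follow-up.
* **Synthetic data** — a seeded generator emitting toy genomes, GTFs
  and beta-binomial junction-count tables with planted motifs and known
  true PSI, so every estimator above is testable against ground truth.

See `vignettes/splicescan-methods.Rmd` for the definitions, the count
model behind PSI, and the reasoning behind each default.

## Worked example

A fully simulation-backed run (300 genes, default planting rates of
0.40 at A3SS/A5SS and 0.20 at SE/RI/MXE splice sites):

```r
library(splicescan)
cfg <- sim_config(seed = 42, n_genes = 300)
res <- run_splice_pipeline(list(simulate = cfg), "out42")
render_report("out42")
```

```
Alternative-splicing events by class:
  SE      108
  RI       74
  MXE      33
  A3SS     45
  A5SS     40

Motif hits:
  n_intron_hits        0
  n_exon_hits          0
  n_junction_hits     72
  n_intergenic_hits    0
  n_transcripts_hit  144
  n_genes_hit         72
  sense_fraction       1

Targeted proportions (window 50 bp):
  SE     18/ 108 = 0.167 [0.102, 0.251]
  RI     18/  74 = 0.243 [0.151, 0.357]
  MXE     7/  33 = 0.212 [0.090, 0.389]
  A3SS   15/  45 = 0.333 [0.200, 0.490]
  A5SS   14/  40 = 0.350 [0.206, 0.517]

Hit-to-splice-site distance peaks: donor -12 bp (n=5), acceptor -8 bp (n=6)
```

Reading it: all 72 motif hits are junction-spanning and sense-strand
(that is what the generator plants; on real data these rows are the
evidence for junction targeting). Per-class targeted fractions estimate
the planting probabilities — 0.33–0.35 at alternative splice sites
versus 0.17–0.24 elsewhere at n of a few dozen, with the exact binomial
intervals covering the true 0.40/0.20. The distance peaks sit within
one motif length upstream of the boundaries, as expected for hits that
straddle them. The differential section reports no calls because this
config simulates both conditions at the same true PSI; planting
condition-specific PSI (via `psi_true`) produces increased/decreased
tallies per class.

Every table behind the report (`events.tsv`, `hits.bed`,
`targeting.tsv`, `psi.tsv`, `differential.tsv`, ...) is written under
the output directory along with `manifest.json` recording all
parameters and file checksums; reruns with the same seed are
byte-identical.

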