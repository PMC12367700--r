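# pannac

Pan-genome analysis of plant transcription-factor gene families in R.

Single-reference gene-family surveys miss the presence/absence variation
that distinguishes accessions of a crop. Pan-genome surveys of families
such as the barley NAC transcription factors instead identify the family in
every accession, cluster the proteins into orthologous gene groups (OGGs),
and split those groups into a conserved core and a dispensable fraction
whose members evolve faster and carry adaptive variation. `pannac`
implements that analysis chain end to end, for anyone who has per-accession
protein/CDS FASTA, annotations and expression matrices — plus a seeded
synthetic pan-genome generator with recorded ground truth, so every stage
is testable without downloading twenty genomes.

The stages, and the statistics at their core:

* **Identification** — domain hits (E ≤ 1e-5, score ≥ 20) AND homology hits
  (E ≤ 1e-10, query coverage ≥ 70%); ProtParam-style protein properties
  (MW, pI, GRAVY, aliphatic and instability indices).
* **Orthogroup clustering** — greedy longest-first clustering at identity
  ≥ 95% (shorter-sequence denominator), coverage of the longer sequence
  ≥ 90%, alignment length ≥ 100 aa; the longest member represents each
  cluster.
* **Occupancy classes** — for *n* accessions: core = *n*, soft-core =
  ⌈0.9 *n*⌉…*n*−1, cloud = 1…⌊0.1 *n*⌋, shell = the rest (for *n* = 20:
  20 / 18–19 / 3–17 / 1–2), plus occupancy and copy-number matrices.
* **Structural variation** — strand-aware upstream/genic/downstream TE
  classification within a 2-kb window, three-letter-code tallies, PAV-gene
  overlap (0-based half-open), and tandem/proximal/dispersed/singleton
  duplication typing by gene-rank distance.
* **Selection** — Nei–Gojobori (1986) Ka/Ks with Jukes–Cantor correction,
  K<sub>a</sub>/K<sub>s</sub> = NA when K<sub>s</sub> = 0, and exact
  Mann–Whitney contrasts of core versus dispensable orthogroups.
* **Codon usage** — RSCU, Wright's ENC (with the expected curve
  ENC = 2 + s + 29/(s² + (1−s)²)), CAI, GC3s, third-position composition
  and PR2 coordinates, and optimal codons (RSCU<sub>high</sub> > 1,
  RSCU<sub>low</sub> < 1, ΔRSCU ≥ 0.3 between the lowest- and
  highest-10%-ENC gene sets).
* **Expression** — per-gene min-max tissue summaries; FPKM ≥ 10 filtering,
  z-scoring and fuzzy c-means (k = 10, m = 1.25) time-course clustering
  with `tidy()`/`glance()`/`autoplot()` support.
* **Network** — Pearson edges (r > 0.9, p < 0.01), FIMO-style PWM promoter
  scanning with exact DP p-values (hits at p ≤ 1e-4), and hypergeometric GO
  enrichment with BH correction.

Everything takes and returns tibbles, so stages chain with the pipe; the
`run_pipeline()` driver chains them all and writes a TSV report.

## Worked example

```r
library(pannac)

cfg <- synthetic_config(n_accessions = 5, n_core = 25, n_softcore = 0,
                        n_shell = 15, n_cloud = 10,
                        mean_cds_len_codons = 150, seed = 42)
bundle <- generate_pangenome(cfg, "example-bundle")
bundle
#> <pangenome_bundle> 5 accessions, 50 orthogroups, 198 genes
#>   dir: example-bundle

report <- run_pipeline(pipeline_config("example-bundle", "example-report",
                                       seed = 1))
dplyr::count(report$occupancy_classes, label)
#> # A tibble: 3 × 2
#>   label     n
#>   <fct> <int>
#> 1 core     25
#> 2 shell    15
#> 3 cloud    10
```

The 198 generated proteins cluster back into exactly the 50 planted
orthogroups, and the occupancy classes match the planted counts (no
soft-core is possible at five accessions). The selection contrast shows the
planted purifying-selection signal on core genes:

```r
report$kaks_contrast[, c("metric", "median_core", "median_dispensable", "p")]
#> # A tibble: 3 × 4
#>   metric median_core median_dispensable            p
#>   <chr>        <dbl>              <dbl>        <dbl>
#> 1 Ka          0.0113             0.0329 0.0000000972
#> 2 Ks          0.111              0.188  0.0000000972
#> 3 ratio       0.0988             0.163  0.00000239
```

Core orthogroups have roughly a third of the nonsynonymous divergence of
dispensable ones, and all three metrics differ at p « 0.05 by the exact
Mann–Whitney test. Downstream, the same report holds the codon-usage
profiles (mean ENC 55.17 across the 198 genes, 10 optimal codons at these
settings), the fuzzy time-course clustering (`tidy(report$fuzzy_fit)` gives
per-gene hard labels and memberships), and the regulatory network — here
112 co-expression edges to 34 promoter-motif-supported targets, including
all 30 planted regulatory targets.

Plot helpers: `plot_enc_gc3s()`, `plot_pr2()`, `plot_occupancy()`, and
`autoplot()` on a `fuzzy_cmeans` fit.

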