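---
title: "Methods: pan-genome analysis of a transcription-factor gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome analysis of a transcription-factor gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pannac implements the analysis chain used in pan-genome surveys of plant
transcription-factor families such as the barley NAC family: candidate
identification from domain and homology evidence, orthogroup clustering and
core/dispensable classification across accessions, structural variation
(presence/absence events and transposable elements) around gene loci,
selection-pressure contrasts from Ka/Ks, a codon-usage-bias suite, tissue and
stress time-course expression summaries, and a co-expression plus
promoter-motif regulatory network. This vignette records the models,
conventions and design choices behind each stage, and what the synthetic
pan-genome generator does and does not emulate.

## Candidate identification

A protein is accepted into the family when it carries at least one domain hit
with per-domain E-value $\le 10^{-5}$ and per-domain bit score $\ge 20$, and
at least one homology hit with E-value $\le 10^{-10}$ and query coverage
$\ge 70\%$. The two evidence tracks are combined with AND by default; a
`mode = "or"` switch is provided because either convention is seen in
practice. Coverage is computed from the best HSP's query coordinates only —
no HSP tiling — which is the simplest defensible reading and is stated here
so users with fragmented alignments know to pre-merge them.

Physicochemical properties follow the ProtParam conventions: average residue
masses plus one water; GRAVY as the mean Kyte–Doolittle hydropathy;
aliphatic index $X_{Ala} + 2.9 X_{Val} + 3.9 (X_{Ile} + X_{Leu})$ in mole
percent; pI by bisection (to $10^{-6}$ pH) on the Henderson–Hasselbalch net
charge under the Bjellqvist pKa set with residue-specific N-terminal values;
and the instability index from the published 400-entry dipeptide weight
table (Guruprasad et al. 1990).

## Orthogroup clustering

`greedy_cluster()` reproduces the greedy incremental strategy of
identity-based clusterers: records are sorted by length descending (ties by
identifier) and each record joins the first existing cluster whose
representative passes all of identity $\ge 0.95$, aligned coverage of the
longer sequence $\ge 0.90$ and alignment length $\ge 100$ residues, else it
founds a new cluster. Since founders are processed before their members,
every representative is a longest member (lexicographically smallest on
ties) and the partition is independent of input order.

Conventions that the thresholds depend on, made explicit:

* alignment is semiglobal with free end gaps (match $+1$, mismatch $-1$, gap
  open $-5$, gap extend $-1$), computed with `Biostrings::pairwiseAlignment`;
* identity divides identical aligned residues by the *shorter* sequence
  length (the global-identity convention of the emulated tool); this is the
  package default and documented rather than configurable per call;
* coverage is the aligned span on the longer sequence divided by its length;
  alignment length counts alignment columns excluding terminal free gaps.

A 5-mer containment prefilter (skip candidate representatives sharing
$< 20\%$ of 5-mers) plus an exact dependency-ordered batching of the
alignment calls accelerate the loop; `prefilter = FALSE` runs the plain
sequential reference path, and the test suite asserts both paths produce
identical partitions, as well as equality with an independently coded
brute-force implementation of the same rules on hundreds of random
instances. At these thresholds the prefilter cannot reject a true join: two
sequences at $\ge 95\%$ identity over $\ge 100$ residues share far more than
20% of their 5-mers.

## Occupancy classification

With $n$ accessions, an orthogroup present in all $n$ is core; in
$\lceil 0.9n \rceil \dots n-1$ soft-core; in $1 \dots \max(1,\lfloor 0.1n
\rfloor)$ cloud; and anything between is shell. For $n = 20$ this gives the
familiar 20 / 18–19 / 3–17 / 1–2 bands. The cloud band deliberately includes
occupancy 2 at $n = 20$: the stricter "exactly one accession" reading leaves
occupancy-2 groups without a class, and a classification must partition.
`strict_cloud = TRUE` restores the one-accession cloud, with occupancy 2
falling to shell so the partition stays total. Copy-number (CNV) and 0/1
occupancy matrices are built together; classification uses presence,
copy-number summaries use counts.

## Structural variation

All interval arithmetic is 0-based half-open; GFF3 input is converted on
read, so touching intervals never overlap. A TE overlapping the gene body is
genic regardless of flank overlap (an explicit priority rule); otherwise the
2-kb flank on the gene's 5′ side is upstream and the 3′ side downstream,
mirrored on minus-strand genes (`strand_aware = FALSE` gives the naive
left/right labelling). Three-letter TE codes map to order by their first
letter (R retrotransposon, D DNA transposon) and superfamily by letters 2–3;
malformed codes are tallied as unknown rather than dropped.

Duplication typing is the simplified rank-distance scheme: genes are ranked
along each chromosome; a gene with no same-cluster homolog is a singleton,
with a homolog at an adjacent rank tandem, within ten intervening genes
proximal, otherwise dispersed, taking the closest qualifying label. Homolog
pairs come from the orthogroup partition. Whole-genome/segmental duplicates
cannot be separated without collinearity blocks and are therefore absorbed
into the dispersed class; every output documents this.

## Selection: NG86 Ka/Ks and the core–dispensable contrast

`ng86()` implements the Nei–Gojobori (1986) approximate method. Synonymous
site fractions are averaged over the two sequences, with changes that create
a stop codon counted as nonsynonymous so that $S + N = 3 \times$ codons.
Codon pairs differing at 2–3 positions are averaged over all shortest
substitution pathways, excluding pathways through stop codons (if every
pathway is blocked, all are used with stop-creating steps counted as
nonsynonymous — a documented, rarely reached fallback). Both proportions
receive the Jukes–Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$,
undefined (NA) at $p \ge 3/4$; $K_a/K_s$ is NA when $K_s = 0$. Codon
alignments come from back-translating the semiglobal protein alignment and
dropping every gap column.

Pairing within an orthogroup is representative-versus-member, aggregated to
one value per orthogroup by the mean of defined pair values
(median or per-pair output available). The core-versus-dispensable contrast
(dispensable = soft-core ∪ shell ∪ cloud) uses a Mann–Whitney U test per
metric: exact two-sided p by full enumeration of group assignments when both
groups have $\le 8$ observations, else the normal approximation with tie and
continuity corrections. The exact branch handles ties correctly by
enumerating the observed values; at the branch point ($n = m = 8$) the
approximation tracks the exact p to about 0.01.

## Codon usage suite

Counting excludes the terminal stop, rejects internal stops, and skips
ambiguous codons with a counter. RSCU divides each codon's count by its
synonymous family's mean, so values in an observed family sum to the family
size; Met and Trp are excluded throughout. ENC is Wright's estimator from
per-family homozygosities $F = (n\sum p_i^2 - 1)/(n-1)$ over families with
$n > 1$ and $F > 0$, class means over the 2-, 3-, 4- and 6-fold degeneracy
classes, a missing 3-fold mean imputed as the average of the 2- and 4-fold
means, and the result clamped to $[20, 61]$. Six-fold families are treated
as single families by default (`sixfold_split = TRUE` splits them 2+4). The
ENC-expected reference line is Wright's mutation-only curve
$\mathrm{ENC} = 2 + s + 29/(s^2 + (1-s)^2)$ as a function of GC3s — the
only form of the curve that stays within $[20, 61]$ and so the only one that
can serve as the plot's no-selection reference.

CAI needs a reference set the source analyses rarely state; the default is
the pooled counts of the lowest-10%-ENC genes — the same high-expression
proxy used for optimal-codon calling — with zero pooled counts replaced by
0.5 before relative adaptiveness $w$ is formed, and the index computed as
the count-weighted geometric mean of $w$ over the gene's scorable codons.
Third-position composition (T3s/C3s/A3s/G3s, GC3s) and the PR2 coordinates
$x = G_3/(G_3{+}C_3)$, $y = A_3/(A_3{+}T_3)$ are tallied over synonymously
variable codons only. Optimal codons compare pooled RSCU between the
lowest- and highest-10%-ENC gene sets and flag codons with
$\mathrm{RSCU}_{high} > 1$, $\mathrm{RSCU}_{low} < 1$ and
$\Delta\mathrm{RSCU} \ge 0.3$.

## Expression

Tissue summaries min-max normalize each gene across conditions (a constant
row maps to all zeros — the convention is arbitrary but must be fixed) and
report group means on the raw FPKM scale. Before time-course clustering,
genes with mean FPKM $< 10$ are removed — the boundary is strict, so a mean
of exactly 10 survives — and survivors are z-scored per gene; zero-variance
survivors cannot be standardized and are dropped with a warning. Replicate
columns, if present, should be averaged per time point by the caller; the
clustering treats every column as one condition.

`fuzzy_cmeans()` is standard fuzzy c-means: memberships
$u_{ij} = 1/\sum_k (d_{ij}/d_{kj})^{2/(m-1)}$, centers as
$u^m$-weighted means, stopping when the largest center shift falls below
$10^{-6}$ or at 200 iterations, with the defaults $k = 10$ and $m = 1.25$
used in stress time-course work. Initial centers use maximin
(farthest-point) seeding over the sorted gene identifiers: the first center
is a seeded random gene, each next center the gene farthest from all chosen
ones. Purely random starts occasionally collapse two planted clusters into
one (a classic fuzzy c-means failure we observed directly); maximin removes
those degenerate optima and, because it works on the sorted identifier
list, makes the fit independent of row order. The per-iteration objective
$\sum u^m d^2$ is recorded and asserted non-increasing.

## Regulatory network

Co-expression edges connect a focal (family) gene to a non-focal gene when
the Pearson correlation across conditions has $r > 0.9$ and two-sided
$p < 0.01$ from $t = r\sqrt{(n-2)/(1-r^2)}$ — both strict inequalities, as
in the source thresholds. Promoter scanning scores the pseudocount-0.1
regularized PWM frequencies against a background estimated from the scanned
promoter set (overridable), on both strands at every offset; p-values are
exact tail probabilities of the score distribution under the background,
computed by dynamic programming over scores discretized at $10^{-3}$ bits,
and hits with $p \le 10^{-4}$ (the conventional scanner default) are
reported. The promoter is 2,000 bp upstream of the TSS by convention;
whatever sequences are supplied are scanned as-is. The network retains only
targets with both an edge and at least one motif hit, and GO enrichment of
the retained targets uses the upper-tail hypergeometric test with
Benjamini–Hochberg adjustment.

One property of these thresholds deserves emphasis: by the definition of a
p-value, about $10^{-4}$ of scanned background windows qualify as motif
hits, and with only four time points sample correlations are heavy-tailed,
so chance edge-plus-motif coincidences are structurally possible in any
data, real or synthetic. The planted-truth round-trip test therefore runs
the pipeline at motif $p \le 10^{-6}$, a regime where coincidences are
negligible and recovery of the planted targets is exact; at the default
thresholds the planted targets are still always recovered, alongside an
occasional coincidental target.

## The synthetic pan-genome generator

`generate_pangenome()` emulates the inputs of a 20-accession survey with
recorded ground truth. Its defaults are the study conditions used
throughout: 20 accessions; 30/10/10/10 core/soft-core/shell/cloud
orthogroups; CDS of ~300 codons (SD 15%, floor 115 so every
within-orthogroup alignment clears the 100-aa threshold); within-orthogroup
protein identity 0.97 and between-ancestor identity 0.25; per-orthogroup
GC3 targets drawn from [0.35, 0.85]; 60 TEs per accession (85% DNA
transposon codes, placed upstream/downstream/genic/far in roughly the
proportions seen in such surveys) with a 2-kb window; PAV deletions that
remove non-carrier accessions' loci relative to the reference accession,
plus intergenic insertions; five-tissue lognormal FPKM; a 4-point time
course with 10 planted sinusoidal clusters (log2 noise SD 0.25); 1-kb
promoters; and a sharp 12-bp binding-site PWM whose consensus is planted in
the promoters of 30 regulated background genes profiled as near-copies of a
focal family gene.

Choices worth knowing when interpreting test results:

* **Exact-count substitutions.** Derived members receive an exact
  (rounded) count of nonsynonymous and synonymous codon substitutions rather
  than binomial draws, so realized identities sit at their targets and
  cluster recovery is deterministic. Core orthogroups get multipliers 0.4
  (nonsynonymous) and 0.7 (synonymous) versus 1.2 and 1.1 for dispensable
  ones, planting the lower-Ka, lower-Ks, lower-ratio signal the selection
  contrast is meant to detect.
* **Founders are strictly longest.** Non-founder members are trimmed by 1–3
  C-terminal codons, so the orthogroup founder is the representative and
  member-to-representative identity equals the planted value.
* **Disjoint temporal clusters.** Family genes and background genes occupy
  disjoint halves of the planted cluster set, so high correlation with a
  family gene singles out the re-profiled regulated targets rather than
  cluster-mates.
* **What is not emulated.** No realistic chromosome structure, intron
  structure, recombination or TE sequence content (coordinates and labels
  only); no internal indels within proteins; iid Gaussian noise on the log2
  expression scale; promoters are iid random DNA. Passing the planted-truth
  tests therefore demonstrates correctness of the computations and
  conventions, not robustness to alignment ambiguity, annotation error or
  correlated biological noise.

Everything is driven by one seed through per-stream child seeds (so adding
accessions does not perturb earlier draws), and a fixed config plus seed
reproduces the bundle byte-for-byte.

## Numerical conventions and problem sizes

Ties in the greedy sort and in representative choice break lexicographically;
cluster identifiers follow founding order. PWM scores are discretized at
$10^{-3}$ bits both in the DP distribution and when scoring windows, so
reported p-values are exactly consistent with the distribution. The pI
bisection runs to $10^{-6}$ pH; fuzzy c-means stops at center shift
$< 10^{-6}$.

The test suite exercises the oracle-equivalence and recovery properties at
sizes chosen to keep a full run in a few minutes on one CPU: 200 clustering
instances of up to 50 proteins of 90–180 residues; 50 occupancy-recovery
pan-genomes generated at 130-codon mean CDS length (the clustering outcome
does not depend on length once above the 100-aa alignment floor); 100
random 100-codon NG86 pairs; a 500-gene, 1000-codon codon-usage corpus; and
a 5-accession, ~200-gene end-to-end bundle. Longer genes are used where
sampling noise would otherwise blur a planted contrast (the ENC-tail
selection effect: picking the highest-ENC genes selects for usage that
drifted toward uniform, which at short lengths can push a planted
below-parity RSCU above 1).

## Known limitations

Identity is representative-linked (single linkage to the founder), as in
the emulated clusterer — chains of just-below-threshold members are
possible in principle. The Ka/Ks pairing choice (representative versus
members, orthogroup mean) is one of several defensible units of
observation; the per-pair table is available for sensitivity analysis. The
instability index is reported as a descriptive statistic only. The network
stage inherits the coincidence floor discussed above; on real data its
specificity comes from the motif requirement and from biological
replication, not from the correlation threshold alone.
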