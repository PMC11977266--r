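---
title: "Methods: linking small RNAs, transposable elements and gene expression"
author: "srnalink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking small RNAs, transposable elements and gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnalink)
```

# The problem

Sperm-borne small RNAs — microRNAs (miRNAs) and PIWI-interacting RNAs
(piRNAs) — are candidates for carrying environmentally induced paternal
effects into the next generation. piRNAs silence transposable elements (TEs)
in the germ line through sequence complementarity; miRNAs tune gene
expression through seed pairing with 3'UTRs. A typical study design produces
three kinds of downstream tables: differential-expression (DE) results for
genes (DESeq2 dialect), family-level DE results for TEs (TEtranscripts
dialect), and mature small-RNA sequences. `srnalink` provides the
*integration* layer that connects them:

1. **piRNA → TE complementarity** (`match_pirnas_to_tes()`): which TE
   reference sequences carry exact complementary sites of a piRNA's 5' seed
   window, summarised by TE family and class.
2. **DE gene ↔ DE TE overlap and enrichment** (`fishtea()`): where DE genes
   and loci of DE TE families co-occur in the genome, and which genic
   regions carry significantly more DE-TE loci than chance.
3. **miRNA target ↔ DE gene linking** (`find_targets()`,
   `link_targets_to_de()`): which genes carry canonical miRNA seed sites in
   their 3'UTR, and whether DE genes are enriched among targets.

Everything upstream — read processing, alignment, DE calling, TE
quantification — is out of scope; `srnalink` starts from the standard output
formats of those tools.

# Statistical core

All enrichment statistics are computed exactly, in log-gamma space so that
genome-scale margins never overflow.

**Hypergeometric upper tail.** For a genic region overlapping $n$ annotated
TE loci of which $k$ belong to significantly DE families, with $K$ DE loci
among $N$ genome-wide,

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)}
\frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

evaluated by summing exponentials of log-binomials with a max-shift
(`hyper_upper_tail()`).

**Fisher exact test.** The 2×2 table crosses *targeted by a DE miRNA*
against *differentially expressed* over a background gene universe. The
two-sided p-value uses the point-probability method: the sum of the
probabilities of all tables with the observed margins whose point
probability is at most that of the observed table. A relative slack of
$10^{-7}$ absorbs floating-point rounding when comparing point
probabilities. The odds ratio is the sample cross-product estimate
$ad/bc$ ($+\infty$ when $bc = 0 < ad$; flagged undefined when both products
vanish), matching the convention of the scripting-stack Fisher
implementations that the field's reported values usually come from; a
Haldane–Anscombe (+0.5) variant is available behind the `haldane` flag.
The conditional-MLE estimate (as printed by `fisher.test()`) is deliberately
not used, but the test suite cross-checks our p-values against
`fisher.test()` and `phyper()` as independent oracles.

**Multiple testing.** Region-level enrichment reports raw p-values by
default, with significance called at a strict `p < alpha` (default 0.05) —
the convention of the tool family this package reimplements — and an
optional Benjamini–Hochberg mode (`correction = "bh"`, own step-up
implementation, cross-checked against `p.adjust`).

# Coordinate and matching conventions

* Internal coordinates are 0-based half-open; GTF (1-based inclusive) is
  converted on read and write. Half-open adjacency does not overlap.
* Overlap between genes and TE loci is strand-blind by default (TE
  insertions regulate genes from either strand); a `same_strand` switch
  exists. The minimum overlap is 1 bp — no biological rationale exists for
  a larger floor, and the engine takes `min_bp` if one is wanted.
* The pairwise overlap engine delegates to `GenomicRanges::findOverlaps()`;
  its output is contract-checked against a brute-force all-pairs scan in the
  test suite (200 random 1,000×1,000 instances).
* piRNA seed matching is exact, both orientations: a *sense* site is an
  occurrence of the reverse complement of the seed in the TE sequence, an
  *antisense* site an occurrence of the seed itself (the TE consensus strand
  in reference FASTAs is arbitrary). A TE counts once per piRNA no matter
  how many sites it carries. No mismatches and no G:U wobble — the seed
  window is the unit of evidence, not a thermodynamic duplex.
* The default piRNA seed window is positions 1–10 of the mature 5' end (the
  teleost convention); it is a parameter (`seed_start`, `seed_end`, floor of
  6 nt).
* miRNA sites are the canonical seed classes on the UTR read 5'→3': `6mer`
  (reverse complement of miRNA 2–7), `7mer-m8` (reverse complement of 2–8,
  the default rule), `7mer-A1` (6mer followed by A) and `8mer` (7mer-m8
  followed by A). Hits are additionally classified to their most specific
  class. Thermodynamic alignment scoring (miRanda-style) is intentionally
  not reproduced: the package's contribution is the linking statistic, and
  published scanners can be substituted upstream by supplying their hit
  table to `link_targets_to_de()`.

# TE taxonomy labelling

TEtranscripts-style inputs carry raw class tokens (`DNA`, `LTR`, `LINE`,
`SINE`, `RC`). `srnalink` groups them into DNA transposons (`DNA`, `RC`,
`Crypton`) and retroelements (`LTR`, `LINE`, `SINE`, `Retroposon`) and then
labels the groups under one of two nomenclatures:

* `paper` (default): DNA transposons are "Class I", retroelements
  "Class II" — the labelling used by the zebrafish sperm-sRNA study whose
  outputs this toolkit reproduces. Because this inverts the conventional
  taxonomy, the default announces itself with a message.
* `standard`: the conventional taxonomy (Class I = retroelements with an
  RNA intermediate).

Both labellings are computed from the same grouping; only the labels swap.

# The genic-region enrichment unit

The tested unit is the genic region of a significantly DE gene (the gene
interval, optionally flanked by `flank` bp and clipped to the chromosome)
that overlaps at least one annotated TE locus. Per region, $n$ counts all
overlapping annotated loci and $k$ those of significantly DE families;
$N$ and $K$ are taken genome-wide from the same annotation and are constant
within a run. This is the most direct reading of "enrichment of DE TEs and
DE genes in genic regions": the candidate-region construction is otherwise
under-determined (all genes? binned genome?), so the package makes the
choice explicit and records it here. Two caveats are deliberate and
documented behaviour:

* Overlapping genic regions are tested independently and may each count a
  shared locus; the per-region $(k, n)$ are not partitioned.
* TE DE status is family-level (TEtranscripts tests families, not loci), so
  `is_de` on a locus means "its family is DE", with the provenance carried
  in `family_padj`/`family_log2fc`. Locus-level DE is not implied.

The five pipeline stages run individually (`run_fishtea(step = 1..5)`) or as
one call, each step reading the previous step's TSV, and a full run is
byte-identical to the chained per-step run. Enrichment (stage 3) is computed
*before* the chromosomal layout (stage 4) because the layout marks
significant regions; the family/class count charts come last.

# The synthetic-data generator

`simulate_all()` is first-class, tested code, not a fixture: it emits every
input format (gene GTF, rmsk-dialect TE GTF, chrom.sizes, DESeq2-style and
TEtranscripts-style DE tables, TE/piRNA/miRNA/3'UTR FASTA) with planted
structure recorded in a truth object, under a single integer seed that makes
re-runs byte-identical.

Default dimensions follow the result shape of the zebrafish
paternal-social-stress design the package targets: 25 chromosomes of 8 Mb;
25,000 genes of 1–5 kb with 612 DE; 500 TE families (class mix 55% DNA,
20% LTR, 15% LINE, 5% SINE, 5% RC, log-normal abundance weights — DNA
transposons dominate, as in zebrafish) with 116 DE; 300,000 TE loci
(a scaled-down rmsk landscape); 12 enriched genic regions at a DE-locus
density multiplier of 8; 7 miRNAs and 3 piRNAs (seed window 1–10); ~1,466
targeted genes placed so the targeted-by-miRNA × DE odds ratio is 130 in
expectation with roughly 515 of the 612 DE genes targeted. All of these are
`sim_config()` fields, not constants.

What the generator emulates — and what it does not:

* `padj` values are drawn directly (DE members strictly below 0.05, others
  above, a 5% `NA` fraction mimicking independent filtering). DE calling is
  out of scope; only the output dialect matters. Consequently the generator
  says nothing about count noise, dispersion or fold-change shrinkage.
* Planted seed sites are inserted verbatim at recorded offsets (in disjoint
  per-sRNA zones so later insertions never destroy earlier ones), and
  *chance* occurrences of the planted patterns are excised from unselected
  sequences by window resampling. Matched sets therefore equal planted sets
  exactly, which is what makes exact truth-recovery tests possible; real
  references of course contain background complementarity. The excision
  covers the scanned site class (7mer-m8 for miRNAs; both orientations of
  the seed for piRNAs) — scanning a generated set under a *different* site
  rule will pick up chance hits.
* Gene placement is non-overlapping and uniform; TE loci are uniform with a
  density uplift of DE-family loci inside enriched regions. Real genomes
  cluster repeats (pericentromeres, the zebrafish chromosome-4 long arm);
  none of that spatial texture is emulated, so passing tests demonstrate
  statistical correctness of the pipeline, not realism of genome geography.
* The planted odds ratio is realised through per-gene Bernoulli targeting
  probabilities solved by `uniroot` from (background size, DE count,
  expected target count, odds ratio), so realised tables fluctuate around
  the planted value like a real experiment would.

# Numerical and design choices

* Discreteness of the hypergeometric: with only a handful of TE loci per
  region the attainable p-values are coarse and the test is conservative
  (the detected fraction under a true null sits *below* the nominal level).
  The calibration and planted-recovery test designs therefore use TE-dense
  regions (~350 loci per region, DE share ~0.5 over ≥ 1,900 regions) chosen
  so the null p-value distribution is nearly continuous and a two-sided
  binomial envelope around the nominal 0.05 is the right check. The
  module-level null test on sparse regions asserts super-uniformity only.
* Problem sizes in the test suite are scaled for a single CPU: exhaustive
  oracle equivalence for the exact tests runs over all hypergeometric
  parameter combinations with $N \le 30$ and all 2×2 tables with total
  $\le 40$; overlap and seed-site scanners are checked on 200 random
  1,000×1,000 interval instances and 1,000 random (seed, ≤ 5 kb target)
  pairs; odds-ratio recovery uses 20 seeds per planted value at a 20,000
  gene background. These sizes are the package's own choice of a thorough
  but quick regression net.
* Tie-breaking: enrichment results sort by p then region id; overlap
  results by (chromosome natural order, query start, subject start, names).
  Every output is deterministic given inputs, which the runners exploit to
  guarantee identical TSV checksums on re-runs.
* p-values at the `2e-16` magnitude printed by R-based pipelines are
  floors, not values; the Fisher implementation reports the exact number
  (which may underflow to 0 for genome-scale enrichments) and the package
  never treats a printed floor as a target.
* Degenerate inputs are defined, not fatal, where a real run can produce
  them: an empty DE table yields an `a = c = 0` contingency with a warning;
  `K = 0` (no DE TE locus) yields all-1 p-values with a warning; an
  all-zero 2×2 table is an error.

# Limitations

* Exact seed matching has no mismatch or wobble model; piRNA biology
  tolerates imperfect pairing outside the seed, so per-TE match counts are
  a lower bound on biological targeting.
* Family-level DE propagated to loci cannot distinguish which copies of a
  family are active.
* The Fisher linking treats genes as exchangeable; UTR length and
  expression biases of real target prediction are not modelled (they would
  enter through the user-supplied background).
* The CLI is a thin dispatch over the runner functions
  (`inst/cli/srnalink`); workflow-manager integration is out of scope.
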