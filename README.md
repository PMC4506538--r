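# areutr

Computational pipeline linking AU-rich element (ARE) content of mRNA
3' UTRs to gene-expression behaviour: during neural differentiation
(quantified from 3' end sequencing) and after knockout of the
ARE-binding repressor TTP/Zfp36 (quantified from replicate expression
matrices and an 81-tissue atlas). Written for transcriptomics analysts who
need each of these steps as a tested, reusable function rather than a
one-off script.

## What it computes

* **ARE annotation** — overlapping AUUUA pentamer and UAUUUAU heptamer
  counts per 3' UTR; each heptamer is *clustered* when it lies inside a
  maximal A/U run of ≥ 12 nt, else *isolated*.
* **PASS quantification** — from SAM alignments of 3' end reads: after an
  inclusive MAPQ ≥ 10 filter, a read is polyadenylation-site-supporting
  (PASS) iff its 3' soft-clip starts with ≥ 2 non-genomic A's in mRNA
  sense. PASS reads inside annotated 3' UTRs give per-gene counts,
  `RPM = count / total_PASS × 10⁶`, and between-condition
  `log2((RPM₁ + 1)/(RPM₂ + 1))` changes.
* **Motif-group comparison** — genes binned by pentamer count (0, 1–2,
  3–5, ≥ 6); fold-change distributions compared by two-sided
  Kolmogorov–Smirnov test, `D = sup|F_a − F_b|`.
* **Hit selection** — probe sets with |log2FC| > log2(10), BH-adjusted
  Welch-t p < 0.05, and direction-consistent deviation of every KO column
  from the WT mean; collapsed to gene sets.
* **Tissue-rank skew** — per gene, the rank of a focal tissue in the
  ascending ordering of its expression across T atlas tissues (1 = lowest
  anywhere, T = highest). A gene set's ranks are tested against the
  whole-atlas background with the one-sided KS statistic
  `D⁺ = sup(F_bg − F_set)`, `p = exp(−2 D⁺² nm/(n+m))`, per tissue;
  neural vs non-neural p-values are compared by one-sided Wilcoxon
  rank-sum.
* **Synthetic data** — seeded generators (`sim_config`, `gen_utrs`,
  `gen_sam_3reads`, `gen_ko_matrix`, `gen_atlas`) that plant exact motif
  counts, PASS-read truth tables, 16-fold KO rows and a neural-enriched
  atlas set, so every stage is testable offline.

## Worked example

```r
library(areutr)

cfg  <- sim_config(seed = 2)
utrs <- gen_utrs(cfg)                      # planted motif content
ann  <- annotate_ares(utrs, min_run = 12)
table(utrs$group, ann$n_pentamer)
#>         0   2   4   7
#>   >=6   0   0   0 100
#>   0   100   0   0   0
#>   1-2   0 100   0   0
#>   3-5   0   0 100   0

bed <- make_utr_bed(utrs)
gen_sam_3reads(cfg, bed, "sample.sam")
q <- quantify_3reads(read_sam_3p("sample.sam"), bed,
                     min_mapq = 10, min_a = 2)
q$accounting
#>  n_input  n_low_mapq  n_non_pass  n_pass_unassigned  n_pass_assigned ...
```

Every input read is accounted for exactly once (low-MAPQ, non-PASS,
PASS-unassigned, PASS-assigned), and on synthetic data the per-gene PASS
counts equal the planted truth exactly.

The full analysis, on synthetic inputs, is the numbered scripts:

```sh
Rscript analysis/01_simulate_inputs.R   # writes results/data/
Rscript analysis/02_annotate_ares.R
Rscript analysis/03_quantify_3reads.R
Rscript analysis/04_diffexpr_ko.R
Rscript analysis/05_tissue_rank.R
```

Representative output (seeded, so reproducible):

```
ARE-less vs >=6-pentamer group: KS D = 0.680, p = 1.66e-20 (n = 100 vs 100)
100 probe-set hits (50 up, 50 down); sensitivity on planted up rows: 100.0%
upregulated set median: WT 6.85 (transcriptome 7.01), KO 10.73 (transcriptome 7.00)
cortex rank right skew of the gene set: D+ = 0.590, one-sided p = 6.04e-24
neural vs non-neural skew p-values: Wilcoxon one-sided p = 1.72e-07
```

That is: ARE-rich genes are upregulated as a class in the differentiated
sample; the planted KO hits are recovered; the upregulated set sits below
the transcriptome median in WT and reaches it in KO; and its tissue ranks
skew hard towards neural tissues.

`run_pipeline(list(seed = 7), "outdir")` runs the same stages in one call
and writes a provenance manifest.

## Layout

```
R/                 package code (annotation, reads, stats, diffexpr,
                   tissue ranks, generators, pipeline)
analysis/          numbered narrative drivers over the package
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance test suites
vignettes/         methods vignette (models, parameters, design choices)
```
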