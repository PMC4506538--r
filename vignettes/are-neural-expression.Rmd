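---
title: "AU-rich elements, 3' end sequencing and tissue-specific expression ranks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AU-rich elements, 3' end sequencing and tissue-specific expression ranks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(areutr)
```

## The scientific question

AU-rich elements (AREs) are 3' UTR *cis*-elements — AUUUA pentamer cores,
often in the extended UAUUUAU spelling and embedded in longer A/U stretches —
that destabilize mRNAs by recruiting RNA-binding proteins such as
tristetraprolin (TTP/Zfp36). `areutr` implements the computational side of a
classic question about this pathway: do ARE-containing transcripts, as a
class, behave coherently during neural differentiation, and does removing
the repressor (TTP knockout) push a fibroblast transcriptome towards a
neural expression signature?

The package provides five analysis layers, each usable on its own:

1. **ARE annotation** (`annotate_ares`): overlapping AUUUA / UAUUUAU counts
   per UTR, with each heptamer classified *clustered* when its seven bases
   lie inside a maximal A/U run of at least `min_run` nucleotides (default
   12 nt) and *isolated* otherwise. Overlapping counting is deliberate:
   tandem arrays such as `UAUUUAUUUAU` contain two overlapping heptamers,
   and disjoint counting would undercount exactly the dense repeats that
   matter biologically.
2. **PASS quantification** (`quantify_3reads`): from 3' end sequencing
   alignments, a read qualifies as polyadenylation-site-supporting (PASS)
   when the soft-clip beyond its genome-matched 3' end *begins* with at
   least `min_a = 2` adenosines in mRNA sense. Reads first pass an
   inclusive MAPQ >= 10 filter; PASS reads falling inside annotated 3' UTR
   intervals are counted per gene and scaled to reads per million (RPM) of
   *total* PASS reads. Expression changes are log2 ratios of RPM with a
   symmetric pseudocount.
3. **Motif-group comparison** (`compare_motif_groups`): genes binned by
   pentamer count (default bins 0, 1–2, 3–5, >= 6) and their log2
   fold-change distributions compared pairwise with a two-sided
   Kolmogorov–Smirnov test.
4. **Hit selection** (`select_hits`): probe sets changing more than 10-fold
   between KO and WT replicate groups at Benjamini–Hochberg adjusted
   p < 0.05, with every KO column deviating from the WT mean in the same
   direction.
5. **Tissue-rank skew** (`per_tissue_scan`): for each gene, the rank of a
   focal tissue in the ascending ordering of its expression across a
   multi-tissue atlas (1 = lowest anywhere, T = highest anywhere); a gene
   set's rank distribution is tested for a right skew against the
   whole-atlas background with a one-sided KS statistic, per tissue, and
   neural vs non-neural p-values are compared by a one-sided Wilcoxon
   rank-sum test.

## Statistical kernels and numerical choices

**ECDF and KS machinery.** `ks_two_sided` evaluates both ECDFs over the
pooled breakpoints and returns `D = sup|F_a - F_b|`; the p-value uses the
asymptotic Kolmogorov series with effective sample size
`n_e = nm/(n+m)`. `ks_one_sided` returns `D+ = sup(F_background - F_set)`
(so a *right*-shifted set gives positive `D+`) with the one-sided
exponential bound `p = exp(-2 D+^2 n_e)`, clipped to (0, 1]. Exact
small-sample KS distributions are not implemented: the sets compared here
have tens to thousands of members, where the asymptotic forms are accurate
and the exponential bound is conservative (the null calibration tests show
rejection rates of 3–5% at nominal 5%).

**Ranks and ties.** Tissue ranks use a stable ascending sort: ties are
broken by atlas column order (`rank(ties.method = "first")`), keeping every
rank integral in 1..T. This matters only when atlas values tie exactly; on
the continuous synthetic atlas it never does, and on a real
gcrma-normalized atlas exact ties are rare.

**Wilcoxon branches.** `wilcoxon_rank_sum` enumerates exactly when the
pooled size is <= 20 and tie-free, else uses the normal approximation with
tie and continuity corrections. The two branches agree within 0.02 on
random tie-free samples of size 10 + 10 (tested).

**Welch t instead of a moderated t.** The historical microarray re-analysis
this package parallels used limma's empirical-Bayes moderated statistic.
Here each row gets an ordinary Welch (unequal-variance) t-test with
Welch–Satterthwaite degrees of freedom, computed in closed vectorized form
and cross-checked against `stats::t.test`. The package's test surface is
therefore *planted-truth recovery* (sensitivity >= 0.9 on 16-fold planted
rows, null safety on pure-noise matrices), not reproduction of a historical
hit list. Rows with zero overall variance are excluded from the BH family,
mirroring a variance filter; a row with both groups constant and equal
means returns p = 1, constant-but-different rows return p -> 0 and are
flagged `degenerate`.

**Consistency rule.** "Consistent across all KO samples" is operationalized
as: every KO column deviates from the *WT group mean* in the direction of
the overall log2 fold change. This is the simplest reading that makes the
filter monotone and auditable.

**Pseudocount.** Log2 RPM ratios use a symmetric pseudocount of 1 RPM, so
genes absent from both conditions give exactly 0 and the bias for genes
with counts >= 50 is below `|log2((x+1)/(y+1)) - log2(x/y)|`, which is
negligible at sequencing depth.

**UTR assignment ties.** A PASS read 3' end falling into several
overlapping UTRs is assigned to the gene with the nearest annotated 3'
terminus; exact ties go to the lexicographically smaller gene id, and the
number of ambiguous assignments is reported so users can audit them.

**Pentamer enrichment.** The published analyses used a separate motif
program whose internals are not restated here; `pentamer_enrichment` is
this package's own statistic, documented as such: per-UTR k-mer occurrence
rates (count / (length − k + 1)), a foreground-minus-background difference
of set means, and a label-permutation null giving a z-score and a one-sided
permutation p `(1 + #{null >= obs})/(n_perm + 1)`. K-mers are counted on
the sense strand only, since 3' UTRs are sense sequences.

## Coordinate and alphabet conventions

All genomic intervals are 0-based half-open internally (BED native; SAM POS
converted on load), which keeps the read-to-UTR containment test free of
off-by-one cases: a 3' end equal to the interval end is *outside*.
Sequences are normalized to the RNA alphabet (T -> U, case-folded) on
input, matching the UAUUUAU motif spelling; any other character is an error
naming the offending record. Reverse-strand alignments are
reverse-complemented to mRNA sense before the PASS rule is applied, so "two
or more non-genomic A's following the genome-encoded part" always reads the
clip in the 5'→3' direction of the transcript. Later non-A bases in the
clip (tail sequencing errors) do not disqualify a read; a non-A immediately
after the junction does.

## What the synthetic data emulates — and what it does not

`sim_config()` fixes the study conditions; its defaults are the conditions
under which every guarantee in the test suite is stated:

| parameter | default | meaning |
|---|---|---|
| `motif_plan` | 4 × 100 UTRs at 0 / 2 / 4 / 7 pentamers | motif-count bins, top bin clustered |
| `utr_length_range` | 150–400 nt | typical mammalian 3' UTR scale |
| `fc_effect`, `fc_noise_sd` | 0.5, 1.0 | per-bin log2 shift and biological noise |
| `reads_per_gene_range` | 50–200 | PASS reads per gene |
| `frac_pass` | 0.8 | remainder split across low-MAPQ, non-PASS, outside-UTR decoys |
| `n_tissues`, neural class | 81, 10 neural | atlas shape |
| `n_planted`, `neural_shift_sd` | 80 genes, +2 SD | planted neural-enriched set |
| `ko_plan` | 50 up + 50 down, 16-fold, 4 reps | planted differential rows |
| `ko_noise_sd` | 0.25 | log2 within-group SD |

Motif planting is *constructive with verification*: C-flanked motif blocks
(`CUAUUUAUUUUUUC` for a clustered heptamer inside an exactly-12 nt AU run,
`CUAUUUAUC` for an isolated one, `CAUUUAC` for bare pentamers) are
interleaved with AUUUA-free filler, and each candidate is re-annotated with
`annotate_ares` until the target counts hold exactly — so annotation tests
have integer ground truth rather than statistical targets. Decoy reads are
labelled in their names (`lowmapq`, `nonpass`, `outside`) so the
read-conservation identity `#input = low-MAPQ + non-PASS + unassigned +
assigned` can be audited class by class.

The generators are deliberately idealized. They do **not** model:
sequencing error in the genome-matched portion, internal priming artifacts,
alternative pA-site heterogeneity within a UTR, probe-level chip effects,
correlated expression across tissues, or heavy-tailed expression noise.
Atlas noise is i.i.d. Normal precisely because that makes the null rank
distribution provably uniform — a calibration property the tests rely on.
Passing tests therefore demonstrate correctness of the *computations* under
clean planted conditions, not robustness to every artifact of real
3'READS or microarray data.

## Problem sizes used by the tests and acceptance runs

Oracle agreement uses 1,000 random sequences of length <= 100; PASS round
trips use 20 genes at 10–40 reads per gene across three seeds; rank
calibration uses 500 random 100-gene sets against a 3,000-gene atlas; power
uses an 80-gene set shifted +2 SD in 10 neural tissues; hit-selection null
safety uses 200 replicate 2,000 × 6 pure-noise matrices. These sizes keep
every property estimate stable across seeds while the whole suite runs in
well under a minute on one CPU.

## Known limitations

* `ks_one_sided`'s exponential bound is conservative; at very small set
  sizes (< ~10) an exact test would be preferable, and the package refuses
  sets of fewer than 2 values rather than pretending accuracy.
* No pA-site clustering or internal-priming filter is applied: a read's 3'
  end is used directly, so closely spaced alternative pA sites within one
  UTR are aggregated per gene.
* No deduplication of multi-mapped reads beyond the MAPQ filter.
* `collapse_to_genes` is a simple any-probe rule with a discordant set;
  curated probe-to-gene mapping for a specific chip is out of scope.
* The pipeline ranks whatever row ids the atlas provides; collapsing
  several probe sets per gene before ranking is left to the caller.
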