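# pausepoint

Quantitative analysis of **3′ RNA polymerase II pausing** and
**transcriptional interference (TI) between closely spaced tandem genes**,
from ChIP-seq coverage tracks and RNA-seq differential-expression tables.

In many plant genomes, Pol II accumulates just downstream of the transcript
end site (TES) — 3′ pausing. When a highly expressed gene sits a short
distance upstream of another gene on the same strand, loss of 3′ pausing lets
the upstream polymerase intrude toward the downstream promoter and represses
it. `pausepoint` implements the statistics needed to detect and quantify this:

- **3′ pausing index** per gene:
  `PI = density(TES, TES + w] / density[TSS, TES)`,
  the ratio of mean per-bp coverage in a window of `w` bp immediately
  downstream of the TES to the mean coverage of the gene body (strand-aware;
  scale-invariant). Group differences in mean log2 PI are tested with a
  paired Student's t test, Benjamini–Hochberg (BH) adjusted across
  expression groups and antibodies (`pausing_index()`, `compare_pausing()`).
- **Winsorized metagene profiles** anchored on the TSS/TES or scaled over
  100 gene-body bins, with the most extreme 0.01% of pooled values capped at
  the 99.99th percentile and a 95% normal-approximation confidence band
  (`metagene_anchor()`, `metagene_genebody()`, `profile_argmax()`).
- **TES-shift estimation** between conditions, population-level (difference
  of the average-profile maxima) and per gene, with one-sided Wilcoxon
  signed-rank tests of group shifts against the all-genes baseline
  (`population_shift()`, `per_gene_shifts()`, `test_shift_groups()`).
- **Neighbor-context annotation**: tandem/divergent/convergent pair classes,
  intergenic distances, orientation fractions, intergenic-distance KS tests,
  upstream-neighbor expression Mann–Whitney tests, and gene-loop Fisher
  enrichment (`neighbor_contexts()`, `orientation_fractions()`,
  `distance_distribution_tests()`, `upstream_expression_test()`,
  `loop_enrichment()`).
- **Peak-to-feature annotation** with fixed precedence (promoter →
  immediate downstream → 5′UTR → 3′UTR → exon → intron → intergenic) and an
  empirical enrichment test against random genomic positions
  (`annotate_peaks()`, `random_position_enrichment()`).
- **Control-track quality tools**: a negative-binomial greylist of artifact
  regions from control ChIP samples, and nucleosome-free-region calling from
  MNase/H3 coverage (`build_blacklist()`, `call_nfr()`).
- **Light-modulated TI procedures**: threshold-exact selection of tandem
  gene pairs whose upstream gene is re-leveled by light, with Wilcoxon
  signed-rank tests of the downstream gene's log2(mutant/wild-type) ratio
  between dark and light, and the orientation × distance Mann–Whitney
  analysis of light-induced genes (`select_ti_up()`, `select_ti_relief()`,
  `ti_ratio_tests()`, `light_induced_distance_analysis()`).
- A **synthetic-data generator** with complete ground-truth bookkeeping
  (`sim_config()`, `gen_annotation()`, `gen_coverage()`, `gen_de_tables()`,
  `gen_loops()`), so every stage can be validated against planted truth.

Everything takes and returns tibbles (coverage lives in a light
`coverage_track` container), so analyses compose with the pipe. The named
tests (Wilcoxon signed-rank, Mann–Whitney U, two-sample KS, Fisher exact,
paired t, BH adjustment) are implemented in-package with exact enumeration on
small inputs, and are cross-checked against base R in the test suite.

## Worked example

Simulate a 500-gene genome in which the mutant halves the 3′ pausing bump
and shifts it 96 bp downstream, then recover both effects:

```r
library(pausepoint)

cfg <- sim_config(seed = 11, n_genes = 500,
                  mutant = list(amplitude_ratio = 0.5, shift_bp = 96,
                                shift_scope = "all"))
sim <- gen_annotation(cfg)
wt  <- gen_coverage(cfg, sim$genes, sim$truth, "wt",     "polii", seed = 101)
mut <- gen_coverage(cfg, sim$genes, sim$truth, "mutant", "polii", seed = 102)

population_shift(wt, mut, sim$genes)
#> # A tibble: 1 x 4
#>   offset_a offset_b shift n_genes
#>      <int>    <int> <int>   <int>
#> 1      103      191    88     500

expr <- tibble::tibble(gene_id = sim$truth$gene_id,
                       mean_expression = sim$truth$expression)
groups <- expression_groups(expr, n_groups = 9)
cmp <- compare_pausing(pausing_index(wt,  sim$genes, condition = "wt"),
                       pausing_index(mut, sim$genes, condition = "mutant"),
                       groups)
dplyr::select(cmp, expression_group, n, delta, statistic, padj)
#> # A tibble: 9 x 5
#>   expression_group     n delta statistic     padj
#>              <int> <int> <dbl>     <dbl>    <dbl>
#> 1                1    55 -1.71     -27.3 2.77e-33
#> 2                2    56 -1.78     -42.6 1.06e-43
#> 3                3    55 -1.77     -53.2 3.82e-48
#> # ... 6 more groups, all padj << 0.05
```

The recovered population shift (88 bp here; unbiased around 96 bp across
seeds) is the displacement of the TES-anchored average-profile maximum, and
`delta` is the drop in mean log2 pausing index in the mutant — strongly
negative in every expression group, as expected for a halved bump.

Profiles plot directly:

```r
autoplot(metagene_anchor(wt, sim$genes, anchor = "TES", flank_bp = 1000))
```

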