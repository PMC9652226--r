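# stallmpra

Pooled (massively parallel) reporter assays can measure how short
coding-sequence motifs change steady-state mRNA levels: thousands of
inserts — e.g. 8× tandem repeats of every possible codon pair — are
linked to random barcodes, integrated into cells, and each insert's
mRNA level is read out as the log2 ratio of its summed barcode counts
in mRNA versus genomic DNA. Dipeptide repeats that combine positively
charged (Lys/Arg) with bulky (Leu/Val/Ile/Tyr/Phe) residues, especially
in β-strand-prone contexts, slow ribosomes and destabilize the mRNA
that encodes them.

`stallmpra` is an R toolkit for designing, simulating, and analyzing
such assays, written for computational biologists who want a tested,
fully reproducible pipeline without access to raw sequencing data. It
provides:

* **Library design** — the 4096-member dicodon-repeat pool, repeat
  length/periodicity/combination variants, and VNN barcodes that
  exclude in-frame stops by construction.
* **Simulation** — linkage, gDNA/mRNA, sort-seq, decay-timecourse and
  luminescence data under an explicit generative model with
  ground-truth sidecars.
* **Linkage** — mismatch-tolerant insert matching plus the min-count,
  multi-insert and near-duplicate barcode filters.
* **Quantification** — per-insert levels
  `log2(mrna_sum/gdna_sum) − median` with a 200-read/6-barcode rule and
  barcode-bootstrap SEMs; spike-in-normalized decay curves; low-YFP
  sort enrichment.
* **Analyses** — positional codon/amino-acid effects; OLS models of
  level on mean pI, bulkiness, their interaction and β-strand
  propensity (`mRNA ≈ β₁·pI + β₂·bulk + β₃·pI·bulk + β₄·strand`);
  reading-frame correlations; Mann–Whitney group tests.
* **Proteome scan** — the destabilization score (adjacent K/R×bulky
  dipeptides + overlap bonus), maximal 16-aa windows per CDS, and
  composition-preserving reordered mutants.
* **Kinetics** — ribosome transit times as the X-intercept of the
  linear rise of luminescence traces.

## Worked example

Score peptide windows, scan a (toy) proteome, and design the
amino-acid-reordering mutant of the top hit:

```r
library(stallmpra)
peptide_score(c("KV", "VKV", strrep("VK", 8)))
#> [1]  1  3 29

scan <- scan_proteome(c(
  RQCB1 = paste0(strrep("A", 12), "SVKFRVKLSIYFRKVF", strrep("G", 12)),
  CTRL1 = strrep("AGSTNQ", 8)))
scan
#> # A tibble: 2 × 5
#>   gene_id window_start window_seq       score class
#>   <chr>          <int> <chr>            <int> <chr>
#> 1 RQCB1             12 ASVKFRVKLSIYFRKV    13 destabilizing
#> 2 CTRL1              1 AGSTNQAGSTNQAGST     0 control

m <- design_reordered_mutant(backtranslate_peptide(scan$window_seq[1]))
m
#> <reordered_mutant>
#>   wt : ASVKFRVKLSIYFRKV
#>   mut: KRKRKASSVFVLIYFV
peptide_score(m$peptide_mut)
#> [1] 0
```

`KV` scores 1 (one charged–bulky dipeptide); `VKV` scores 3 (two
dipeptides plus one overlap bonus); `(VK)₈` scores 29 (15 + 14). The
scan reports the leftmost maximal 16-residue window per sequence with
its 1-based start; scores above 9 are called destabilizing, below 3
control. The reordered mutant moves K/R codons 5′ and bulky codons 3′
without changing composition, and its score collapses to 0.

Simulate a 300-insert assay end to end and compare estimates with the
generative truth:

```r
lib <- enumerate_codon_pairs()
set.seed(1); lib_small <- lib[sample.int(4096, 300), ]
res <- run_pipeline(pipeline_config(seed = 2, design = lib_small,
                                    linkage_depth = 2e5,
                                    gdna_depth = 1e6, mrna_depth = 1e6,
                                    run_analyses = FALSE))
head(res$levels[res$levels$status == "ok", ], 3)
#> # A tibble: 3 × 7
#>   insert_id mrna_sum gdna_sum n_barcodes   level status    sem
#>   <chr>        <int>    <int>      <int>   <dbl> <chr>   <dbl>
#> 1 AAA_ATG       3852     3852         31  0.0195 ok     0.0375
#> 2 AAA_CAG       4323     4324         30  0.0192 ok     0.0284
#> 3 AAA_CCC       5216     6526         43 -0.304  ok     0.0218

j <- merge(res$levels, res$truth, by = "insert_id")
ok <- j$status == "ok"
cor(j$level[ok], j$true_level[ok], method = "spearman")
#> [1] 0.9947063
```

Each scoreable insert gets its median-normalized log2 level and a
bootstrap SEM over its barcodes; at these depths the estimated levels
track the simulated truth with Spearman ρ ≈ 0.99.

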