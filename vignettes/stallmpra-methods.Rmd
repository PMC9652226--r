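---
title: "Models and methods behind stallmpra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stallmpra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stallmpra)
```

# The assay and its quantification model

`stallmpra` models a pooled reporter assay in which short coding
inserts — tandem repeats of a codon pair, so 48 nt encoding a
16-residue dipeptide repeat — are placed in-frame in a constitutively
expressed reporter, each insert tagged by many random 24-nt barcodes.
Steady-state mRNA abundance of each insert is read out by sequencing
barcodes in cDNA and in genomic DNA from the same cells:

$$\mathrm{level}_i \;=\; \log_2 \frac{\sum_{b \in i} m_b}{\sum_{b \in i} g_b} \;-\; \mathrm{median},$$

where $m_b$ and $g_b$ are mRNA and gDNA read counts of barcode $b$, the
sums run over the barcodes linked to insert $i$, and the median over
scoreable inserts is subtracted so levels are expressed relative to the
library median. Dividing by the gDNA count cancels copy-number and
bottlenecking differences between inserts; summing over barcodes before
taking the ratio (rather than averaging per-barcode ratios) keeps the
estimator stable for low-count barcodes.

An insert is scoreable only with at least 200 reads and 6 barcodes
summed across the two samples and a nonzero gDNA sum; everything else
is reported `missing` rather than smoothed — no pseudocounts are used
anywhere, so exclusion semantics are explicit.

Uncertainty is estimated by a barcode bootstrap
(`bootstrap_sem()`): barcodes are resampled with replacement carrying
their paired (mRNA, gDNA) counts jointly, the level is recomputed per
replicate, and the SD over replicates is reported. The resampling unit
is the barcode because barcodes are the independent integrations of an
insert; resampling reads instead would understate the variance whenever
barcodes differ systematically (position effects, silencing).
Replicates with a zero resampled denominator are dropped and counted.
The default is 100 replicates for libraries above 1000 inserts and 1000
otherwise, mirroring common practice at the two scales.

# Barcode-to-insert linkage

Linkage reads carry the insert and its barcode at fixed offsets.
Insert regions are matched to the library allowing up to 2
substitutions and no indels (the regions are synthesized at fixed
length, so indels indicate artifacts better discarded). The matcher
splits each library insert into `m + 1` chunks, so any read within `m`
substitutions must match one chunk exactly; hash lookups then propose
candidates that are verified by Hamming distance. A read is discarded
when no insert is close enough or when two inserts tie at the minimum
distance — the tie rule plays the role of a mapping-quality filter.

Three filters then shape the barcode map, in order:

1. barcodes with fewer than `min_count = 4` total reads are dropped
   (sequencing noise; 4 is the lower end of the commonly used 4–10
   range and is exposed as an argument);
2. barcodes linked to two or more distinct inserts are dropped
   entirely (template switching or barcode collisions — ambiguous by
   construction);
3. among barcodes of the *same* insert within Hamming distance 2, only
   the highest-count member of each neighborhood is kept, visiting
   barcodes in decreasing count order (ties resolved against the
   lexicographically greater barcode). This greedy pass is
   deterministic, independent of read order, and guarantees that no two
   kept same-insert barcodes lie within the collision distance; the
   discarded member of each close pair is always the lower-count one,
   which is the natural reading of sequencing-error "echo" barcodes.

When counting sample reads against the kept map, an exact match is
required, with an optional single-substitution rescue to a *uniquely*
nearest kept barcode.

# The synthetic-data generator

Every input the pipeline consumes can be simulated under an explicit
generative model so that each downstream stage has a known truth to be
tested against:

* **True levels.** The log2 effect of an insert is a linear function of
  its dipeptide's mean isoelectric point, mean bulkiness, their
  product, and mean Chou–Fasman strand propensity
  (defaults 0.31, 0.20, −0.03, −0.52), plus a −2 log2 penalty for
  stop-containing inserts (a surrogate for nonsense-mediated decay) and
  Gaussian insert-level noise (`noise_sd = 0.3` log2 units, a typical
  scatter for integrated reporter assays). The coefficients serve as
  *simulation truth* for recovery tests; recovering the corresponding
  published regression values from real data is expressly not a claim
  this package can test.
* **Barcodes per insert.** Truncated geometric with median 15 and
  minimum 1. The median is the documented property of the cloning
  bottleneck; the geometric shape is a parsimonious choice for a
  colony-picking bottleneck and is not calibrated to data.
* **Counts.** Dirichlet-multinomial: gDNA weights are Gamma-perturbed
  around equal representation with dispersion 0.2 (amplicon-scale
  overdispersion), and mRNA weights are the gDNA weights times
  $2^{\mathrm{level}}$ — so the per-barcode gDNA variability cancels in
  the ratio exactly as it does in the real design.
* **Errors.** Uniform per-base substitutions at rate 0.001 with a
  constant quality string; no adapter or indel model. This suffices to
  exercise the mismatch-tolerant matching and the min-count filter,
  which is what the filters are for.
* **Sorting and decay.** The low-YFP sorted sample reweights inserts by
  a premature-termination probability (0.8 for stop-containing inserts,
  0.05 otherwise); the shutoff timecourse decays each insert with
  half-life $4 \cdot 2^{\mathrm{level}/2}$ hours against a
  constant-abundance spike-in barcode set, and curves are normalized by
  spike-in totals and then to the $t=0$ value.
* **Luminescence.** Signal $\max(0, r\,(t - \tau))$ plus Gaussian
  noise on a 10-s grid over 25 min; $\tau$ is the ribosome transit
  time, recovered as the X-intercept of a line fitted over a
  user-chosen window (e.g. 600–900 s).

What the simulator does **not** emulate: PCR jackpotting and chimeras,
indels, quality-score structure, UMI behavior, position-dependent
integration effects, or any coupling between termination and decay
beyond the generative formulas. Passing recovery tests therefore
demonstrates the correctness of the estimators under a plausible noise
model, not the biological accuracy of the model itself.

# Analyses

**Positional effects** average levels over all partners of a codon at
each of the two positions, and pool synonymous codons at the
amino-acid level with stop as a 21st class.

**Physicochemical model.** `fit_physicochemical_model()` is ordinary
least squares with an intercept (slopes are what the science is about;
the intercept absorbs the median normalization). Coefficients with
two-sided $p < 0.05$ form the `retained` set. Degenerate inputs are
handled explicitly: a collinear design is an error naming the terms, a
constant response retains nothing with $R^2_\mathrm{adj}$ pinned at 0,
and a zero-residual fit of a non-constant response reports
$R^2_\mathrm{adj} = 1$ with all slopes retained (its t statistics being
meaningless). Raw p-values are reported without multiplicity
correction, matching the reporting convention the analysis mirrors.

**Frame correlations.** Each codon pair's frameshift partner under a
shift of $s$ nucleotides is the left-rotation of its 6-mer by $s$; the
+3 shift swaps the codons. One design decision deserves note: classes
are formed at the unordered heterodipeptide level, but the frame-0
axis uses only one orientation per class (first residue alphabetically
smaller, i.e. reversed repeats excluded). If both orientations were
pooled, the +3 comparison would correlate a set of measurements with
itself and return $r = 1$ identically — even for pure noise. With the
restriction, +3 partner levels come from the independently measured
reversed-repeat inserts, so a high $r_{+3}$ is informative (it reflects
shared peptide chemistry), and the null behaves correctly (all three
$r$'s scatter around 0 for random levels). Pairs whose partner encodes
a stop are dropped, since stop-containing inserts are dominated by the
termination penalty rather than peptide chemistry.

**Group comparisons** are two-sided Mann–Whitney U tests, exact when
the two groups total at most 20 observations without ties, and the
tie-corrected normal approximation otherwise. Spearman propensity
correlations use the exact permutation distribution for $n \le 10$ and
the t approximation above that.

# Proteome scan

A dipeptide scores 1 when a positively charged residue (K/R) is
adjacent to a bulky one (L/V/I/Y/F) in either order; pairs within one
set score 0 (K–K, R–R and bulky–bulky pairs are not destabilizing).
Overlapping scoring dipeptides earn a bonus. Two readings of the
overlap rule are implemented: the default counts every adjacent
overlapping *pair* (a run of $L$ scoring dipeptides contributes
$L + (L-1)$, so $(VK)_8$ scores 29), and `overlap = "run"` awards a
single bonus per maximal run. The default is the literal per-pair
reading; both modes are exposed because the sentence defining the
bonus does not disambiguate chains of three or more.

Each CDS is scanned with a 16-residue window (cumulative sums make
this linear time), the maximum-score window is reported with leftmost
tie-breaking for determinism, and windows are classified destabilizing
($>9$) or control ($<3$) with strict inequalities. The
reordering mutant moves all K/R codons to the 5′ end and all bulky
codons to the 3′ end, each block keeping its internal order — a stable
partition that preserves the codon multiset exactly and can only leave
a single scoring dipeptide at the block junction.

# Numerical and testing conventions

All thresholds are strict (`>`), matching their verbal definitions.
All simulators accept a seed and are byte-reproducible; the pipeline
derives every stage from one configured seed. Tie-breaks (leftmost
window, lexicographic barcode order) are fixed so outputs are
independent of input order.

The test suite verifies operations against independent oracles:
translation against the Biostrings genetic-code table, window scores
against a brute-force enumerator, insert matching against an exhaustive
Hamming scan, the two-barcode bootstrap against exact enumeration over
the three resample multisets, and positional means against direct
group-by computation. Stochastic properties (type-I retention of the
$p<0.05$ filter, null frame correlations, uniformity of null
p-values) run under fixed seed banks with bands set from binomial
error before the tests were run.

Problem sizes used by the default test and acceptance runs: the full
4096-insert pool with a median of 15 barcodes per insert
(≈60,000–90,000 barcodes), 1.2 × 10⁶ linkage reads and 2 × 10⁶ reads
per count sample; the end-to-end run completes in about a minute on
one CPU. Smaller subsampled libraries are used where the property
under test does not need the full pool.

# Known limitations

* The generative model is linear in mean scale values of the encoded
  dipeptide; it cannot represent position-within-repeat effects or
  epistasis between non-adjacent residues.
* Insert matching ignores indels by design; a deletion-containing read
  is discarded rather than recovered.
* Secondary-structure probabilities are consumed from files produced by
  an external predictor; the package only classifies and correlates
  them.
* The measured-data regression coefficients, group p-values and
  transit-time differences reported for the original experiments
  depend on the study's sequencing and luminescence data and are out of
  scope for the simulation-based checks here.
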