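---
title: "Methods: quantifying intragenomic polymorphism in high-copy loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying intragenomic polymorphism in high-copy loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copyvar)
```

## The problem

Nuclear ribosomal DNA (nrDNA) and other tandemly repeated loci exist in
hundreds of near-identical copies per genome — on the order of 960 copies in
milkweeds. Concerted evolution homogenizes these copies imperfectly, so a
fraction of copies carries variant bases. Low-coverage whole-genome shotgun
sequencing ("genome skimming") samples the copy pool deeply at such loci:
with ~97x locus coverage, the reads covering a position are a random sample
of the copies, and the fraction of reads differing from the individual's
consensus base estimates the fraction of variant copies.

`copyvar` quantifies this intragenomic variation per individual and places
it in two wider contexts: position-level structure (cistron region and RNA
secondary structure) and phylogenetic signal across species.

## The per-sample pipeline

For one individual the chain is:

1. **Read preparation.** Exact-duplicate reads are collapsed to a single
   representative, keeping the copy with the highest mean Phred score
   (`collapse_duplicates()`). Reads with mean Phred < 20 are dropped and
   surviving bases with Phred < 20 masked to `N` (`quality_filter()`). Mean
   quality is computed on raw Phred values, matching common FASTQ toolkits.
2. **Consensus assembly.** Reads are mapped onto the group reference and the
   most frequent non-`N` base called per column; mapping and calling iterate
   (at most 5 rounds) until the sequence is stable (`build_consensus()`).
   Zero-coverage columns are marked unassembled. This majority-call
   iteration replaces a full reference-guided assembler: the pipeline needs
   the consensus and the position association, not contig building.
3. **Coordinate association.** The consensus is globally aligned to the
   group reference with affine gap costs (match +1, mismatch -1, gap open
   -4, gap extend -1) and the alignment converted to a coordinate map
   (`align_to_reference()`). Consensus positions with no reference partner
   (insertions) are discarded downstream so that positions remain
   homologous across samples; reference positions absent from the consensus
   surface as unassembled.
4. **Read mapping.** Reads are re-mapped onto the consensus by exhaustive
   ungapped search over every offset and both strands
   (`map_reads_ungapped()`). Mismatch caps depend on read length: 3 for an
   80 bp read and 4 for a 100 bp read under standard settings, 4 and 5 under
   relaxed settings, and 2 for reads under 50 bp; lengths in between take
   the nearest printed anchor (piecewise constant). A gapped mode allows a
   single indel of at most 5 bp, with the gap opening priced at one
   mismatch-equivalent (`map_reads_gapped()`). Alignments from an external
   mapper can be imported from SAM instead (`import_alignments()`).
5. **Polymorphism counting.** At every consensus position the reads are
   tallied by base (`tally_column()`); the differing fraction is the share
   of reads not carrying the consensus base. Positions with >= 2% differing
   reads are *polymorphic*, with >= 10% *highly polymorphic*; both cutoffs
   are inclusive. Calls are projected into reference coordinates and
   summarized per sample (`profile_sample()`, `profile_reads()`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `thresholds()$poly` | 0.02 | minimum differing-read fraction for a polymorphic call |
| `thresholds()$high` | 0.10 | minimum fraction for a highly polymorphic call |
| `thresholds()$min_coverage` | 0 | read-depth floor below which a position is unassembled |
| `max_mismatches(80)` | 3 | mismatch cap for 80 bp reads (standard) |
| `max_indel` | 5 bp | largest indel a gapped placement may contain |
| `sequence_reads()$coverage` | 97 | mean fold-coverage of the simulated locus |
| `sequence_reads()$read_length` | 80 bp | simulated read length |
| `sequence_reads()$error_rate` | 0.001 | per-base substitution error |
| `make_copy_pool()$n_copies` | 960 | copies in the simulated pool |

The 2% cutoff sits well above typical Illumina per-base error once reads
are quality-filtered, so single sequencing errors rarely masquerade as copy
variants at adequate coverage. The `min_coverage` floor defaults to 0 (no
floor) to match the original counting scheme, but note that below 50x a
single differing read already crosses 2%; the floor is exposed for users
who want to guard against that.

## Design decisions in the counting scheme

* **`N` handling.** Masked bases carry no call: they are excluded from both
  the numerator and the denominator of the differing fraction, and during
  mapping they neither match nor mismatch.
* **Multi-allelic sites.** The differing fraction aggregates *all*
  non-consensus bases, so a tri-allelic column counts every differing read.
* **Consensus ties.** An exact 50/50 column takes the lexicographically
  first base (A < C < G < T) as consensus; its differing fraction is then
  0.5 and the site is highly polymorphic.
* **Ambiguous placements.** A read whose best placement is achieved at more
  than one (strand, offset) is discarded rather than placed at random.
  Random placement is what BWA-style mappers do; discarding is a deliberate
  divergence that buys bit-reproducible output for testing. In gapped mode,
  placements are compared by (strand, offset, gap kind, gap length); a tie
  in the gap's position *within* the read (e.g., a deletion sliding along a
  homopolymer) is broken leftmost rather than treated as ambiguous, since
  those candidates describe the same event.
* **Indel polymorphisms.** A consensus position counts as indel-polymorphic
  when reads supporting one identical indel (same start, length, kind and
  inserted bases) reach the 2% support fraction among reads covering the
  position. The original counting rule was not published; this is the
  package's own rule, chosen to mirror the substitution threshold.
* **Fixed differences.** A base fixed in all copies but different from the
  group reference is *not* an intragenomic polymorphism: reads agree with
  the consensus there. Deletions fixed in an individual surface as
  unassembled reference positions (zero reads call a base).

## Region and structure statistics

`annotate_sites()` joins the locus region table (18S/ITS1/5.8S/ITS2/26S,
classed subunit vs spacer) with secondary structures parsed from
dot-bracket files (`parse_structure_file()`), labelling every position
paired (stem) or unpaired (loop). The parser accepts RNAfold-style 3-line
records, including co-folded two-strand records joined by `&`; pseudoknot
symbols are rejected, and the minimum free energy is retained as metadata
only.

Two models relate polymorphism to these labels:

* `fit_site_logistic()` — a two-factor logistic regression with interaction
  on the per-position indicator "polymorphic in at least one individual".
  The reference level is a paired spacer position; odds ratios below 1 mark
  categories that decrease polymorphism likelihood. Confidence intervals
  are Wald (estimate ± 1.96 SE exponentiated) — symmetric on the log scale,
  matching the convention of the tables this reproduces. Complete
  separation aborts with advice to use exact methods.
* `anova_sqrt_counts()` — a two-way ANOVA of square-root transformed counts
  of polymorphic individuals per position, with type III sums of squares
  computed under sum-to-zero contrasts (the appropriate convention for the
  unbalanced position design; results are contrast-dependent and therefore
  documented). Empty design cells are an error, because type III is
  undefined there. In the degenerate case of a perfect fit (zero residual
  sum of squares) the decomposition is computed directly from drop-one
  residual sums of squares, where the standard implementation refuses.

## Phylogenetic signal

Per-taxon polymorphic-site counts are treated as a continuous trait on a
time-calibrated phylogeny.

* **Tip preparation** (`prepare_tips()`): samples missing from the tree are
  dropped; multiple samples per tip are averaged; tips at zero patristic
  distance are collapsed into one tip carrying the mean over *all* their
  samples.
* **Squared-change parsimony** (`scp_ancestral_states()`): internal states
  minimize the sum of squared changes along branches. The objective is a
  quadratic form in the node states, so the minimizer is obtained exactly
  from one linear solve (the Schur complement of the graph Laplacian also
  yields the minimized tree length directly as a quadratic form in the tip
  values, which makes the permutation test cheap). The default is
  *unweighted* (branch lengths ignored), with a weighted option dividing
  each squared change by branch length; unweighted is the default because
  it is well-defined on trees with zero-length branches. Which convention
  the original desktop implementation used is ambiguous, so both are
  exposed.
* **Permutation test** (`permutation_signal_test()`): tip values are
  permuted uniformly (default 10,000 times) and the p-value is the
  fraction of permutations with a *strictly shorter* tree length than
  observed. No +1 correction is applied; a zero count is reported as
  `< 1/n_perm`. With constant tip values every permutation ties and the
  test is degenerate (reported, not hidden).
* **Pagel's lambda** (`lambda_transform()`, `fit_lambda()`,
  `lrt_lambda()`): lambda scales the off-diagonal phylogenetic covariances
  while leaving tip variances unchanged. The Brownian likelihood is
  profiled over the rate and root state and maximized over lambda in
  [0, 1] by bounded one-dimensional optimization (tolerance 1e-8, interval
  endpoints checked explicitly). The search is bounded at 1 because larger
  values can break positive-definiteness on non-ultrametric trees. The LRT
  against lambda = 0 uses a 1-df chi-square upper tail.
* **Brownian fit and bounded simulation** (`fit_bm()`,
  `simulate_bm_bounded()`): the rate and root are estimated on the
  lambda-transformed tree by multi-start optimization (the analytic GLS
  solution is always one start, so the result can never be worse than it;
  10,000 starts are honored via `n_starts` but 100 is the default — the
  likelihood surface is two-dimensional and unimodal in practice).
  Simulations draw increments branchwise and *reflect* at the lower bound
  of zero rather than truncating, so simulated counts stay non-negative
  without piling up mass at the bound.
* **Clade extremeness** (`clade_extremeness()`): for each internal node the
  observed parsimony state is compared with the simulated distribution of
  parsimony states; the count of more-extreme simulations is taken in the
  direction of the observed deviation from the simulation mean (strictly
  greater or strictly smaller; a two-sided option exists). The Bonferroni
  critical count is `floor(n_sims * alpha / n_clades)`, with `n_clades`
  the number of internal nodes of the (resolved) tree, including the root.

## What the synthetic generator emulates — and what it does not

`make_locus()`, `make_copy_pool()` and `sequence_reads()` generate data
with known ground truth under the study conditions this package targets: a
five-region cistron layout (5,839 bp by default), a pool of 960 copies with
planted per-site variant frequencies (realized counts within 1/n_copies of
the specification), 80 bp single-end reads at 97x mean coverage with a
uniform 0.1% substitution error, and constant Q40 qualities (a two-level
Q40/Q10 model is available to exercise the quality filter; constant Q40
keeps quality filtering a no-op so each pipeline stage can be tested in
isolation). Read starts are uniform with no wrap-around, so locus edges
receive lower coverage, as in real data. A separate flag plants copy-level
indels of at most 5 bp to exercise the indel counter; the default error
model is substitution-only because indel errors are secondary in the data
this emulates.

The generator deliberately omits: sequencing-quality decay along reads,
GC-coverage bias, chimeric reads, plastid or other contaminating reads,
pseudogenized copies evolving under different processes, and the
homogenization dynamics (unequal crossing-over, gene conversion) that
create the copy structure in the first place. Tests passing on synthetic
data therefore validate the *counting machinery* — that planted variant
frequencies are recovered and classified correctly — not the biological
interpretation of real read pools, where mapping bias and error structure
are richer.

`make_tree_and_traits()` generates random bifurcating trees with uniform
branch lengths and traits simulated under lambda-scaled Brownian motion
reflected at zero, providing ground truth for the signal machinery.

## Numerical choices and degenerate inputs

* Majority and consensus ties break in the fixed order A < C < G < T.
* The lambda search tolerance is 1e-8; profile likelihoods use Cholesky
  factorization and fail loudly on singular covariance matrices (e.g.,
  duplicated zero-distance tips — collapse them first with
  `prepare_tips()`).
* Constant traits: the Brownian rate is 0 and likelihoods are degenerate;
  `fit_bm()` returns the constant, `fit_lambda()` refuses.
* An empty pileup column has undefined differing fraction and is
  unassembled; empty read pools and unmappable pools raise errors rather
  than returning silent zeros.
* Alignment identity below 70% between a consensus and the reference
  triggers a non-homology warning. The original pipeline enforced 95% read
  identity inside its assembler, which has no exact analog here; 70% is
  this package's own conservative flag.

## Problem sizes used in the test suite

The shipped tests run the full pipeline on desk-scale instances chosen so
the suite completes in about a minute: loci of 200-400 bp at 40-500x
coverage for mapping/profiling tests, 100 pipeline replicates at 100x with
0.1% error for the planted-variant recovery checks, trees of 200 tips
(30-60 replicates) for lambda and rate recovery, and permutation tests of
200-2,000 permutations for calibration checks. These sizes are the
package's own testing choices; all defaults remain at the full study
conditions (5,839 bp locus, 960 copies, 97x, 10,000 permutations and
simulations).

## Known limitations

* The mapper is exhaustive and ungapped-first: it is exact and
  reproducible, but not suited to genome-scale references; for large data,
  map externally and use `import_alignments()`.
* Gapped placements allow a single indel per read.
* The consensus has the same length as the reference template (ungapped
  remapping cannot introduce length changes); copy-level indels are
  detected by the gapped mapper and the indel counter, not by the
  consensus itself. Samples whose true consensus differs in length from
  the reference are handled through the coordinate map.
* Positions entering the cross-sample statistics assume each sample
  contributes only where assembled; no imputation is attempted.
* The permutation p-value convention (strict less, no correction) makes
  `perm_p = 0` possible; it is printed as a bound, not as zero evidence.
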