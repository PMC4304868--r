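# copyvar

Intragenomic polymorphism detection in high-copy loci from shotgun reads.

## What this is for

Tandemly repeated loci — the classic case is the 18S–ITS1–5.8S–ITS2–26S
nuclear ribosomal DNA (nrDNA) cistron — exist in hundreds of near-identical
copies per genome (~960 in milkweeds). Concerted evolution homogenizes the
copies imperfectly, so within one individual a fraction of copies carries
variant bases. Because genome skimming (low-coverage whole-genome shotgun
sequencing) samples high-copy loci deeply, the reads covering a position are
a random sample of the copy pool, and the fraction of reads disagreeing with
the individual's consensus estimates the fraction of variant copies.

`copyvar` is for molecular systematists and evolutionary biologists who want
to quantify that intragenomic variation per individual, compare it across
many species in shared reference coordinates, relate it to locus structure
(subunit vs spacer, RNA stem vs loop), and test whether its abundance
carries phylogenetic signal.

## The core computation

For a position covered by reads with base counts `c_A, c_C, c_G, c_T`
(`N`-masked bases excluded), the consensus base is the plurality base and
the **differing fraction** is

    d = (coverage − c_consensus) / coverage .

A position is **polymorphic** when `d ≥ 0.02` and **highly polymorphic**
when `d ≥ 0.10` (both inclusive). Per-sample profiles are projected into
group-reference coordinates through a consensus-to-reference alignment, so
positions remain homologous across samples; insertions relative to the
reference are discarded and unassembled positions are excluded from
percentage denominators.

Downstream, per-position polymorphism is modeled on region class and
pairing state by two-factor logistic regression and by type III ANOVA of
square-root counts, and per-taxon polymorphic-site counts are analyzed on a
phylogeny via squared-change parsimony (ancestral states and a
10,000-permutation tree-length test), Pagel's λ with a 1-df likelihood
ratio test against λ = 0, and bounded Brownian-motion simulation for
per-clade extremeness with a Bonferroni correction.

## Worked example

Simulate a 300 bp locus whose copy pool carries one variant at 30%
frequency in 960 copies, sequence it at 100× with 80 bp reads and 0.1%
error, and run the full per-sample pipeline:

```r
library(copyvar)

loc  <- make_locus(c(`18S` = 100, ITS1 = 30, `5.8S` = 30, ITS2 = 30,
                     `26S` = 110), seed = 1)
site <- 150
alt  <- setdiff(c("A", "C", "G", "T"), substr(loc$sequence, site, site))[1]
pool <- make_copy_pool(loc, variant_spec(site, alt, 0.30),
                       n_copies = 960, seed = 2)
reads <- sequence_reads(pool, coverage = 100, read_length = 80,
                        error_rate = 0.001, seed = 3)

res <- profile_reads(reads, loc$sequence, sample_id = "demo")
res
#> sample demo - 5 polymorphic and 2 highly polymorphic of 299 sequenced positions
#>   (1.67% polymorphic, 0.67% highly polymorphic)

res$profile[site, ]
#>     ref_pos status  fraction coverage
#> 150     150   HIGH 0.3464567      127
```

The planted site is recovered as highly polymorphic with a differing
fraction near the planted 30%. The extra calls sit at the locus edges,
where coverage drops low enough that a single read crosses a threshold
(e.g., one HIGH call at coverage 8); a depth floor removes them:

```r
profile_reads(reads, loc$sequence, th = thresholds(min_coverage = 10),
              sample_id = "demo")
#> sample demo - 4 polymorphic and 1 highly polymorphic of 285 sequenced positions
#>   (1.40% polymorphic, 0.35% highly polymorphic)
```

The canonical single-column example: 10 reads, 7 `G` and 3 `C`.

```r
tally <- tally_column(rep(c("G", "C"), c(7, 3)))
tally$consensus_base          # "G"
100 * tally$differing_fraction  # 30
as.character(classify_site(tally))
#> [1] "HIGH"
```

And the likelihood-ratio arithmetic for phylogenetic signal, from a pair of
log-likelihoods (λ free vs λ = 0):

```r
lrt_lambda(-594.192, -597.863)
#> $lrt_stat [1] 7.342      $lrt_p [1] 0.006736185
```

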