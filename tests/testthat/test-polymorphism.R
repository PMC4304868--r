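test_that("tally_column counts bases, excludes N, and breaks ties A<C<G<T", {
  t1 <- tally_column(rep(c("G", "C"), c(7, 3)))
  expect_equal(t1$coverage, 10L)
  expect_equal(t1$consensus_base, "G")
  expect_equal(t1$differing_fraction, 0.30)

  t2 <- tally_column(rep("A", 10))
  expect_equal(t2$differing_fraction, 0)

  t3 <- tally_column(rep(c("A", "N"), c(5, 5)))
  expect_equal(t3$coverage, 5L)
  expect_equal(t3$n_count, 5L)
  expect_equal(t3$differing_fraction, 0)

  t4 <- tally_column(character(0))
  expect_equal(t4$coverage, 0L)
  expect_true(is.na(t4$differing_fraction))

  # 50/50 ties pick the lexicographically first base, fraction 0.5
  t5 <- tally_column(rep(c("T", "G"), c(5, 5)))
  expect_equal(t5$consensus_base, "G")
  expect_equal(t5$differing_fraction, 0.5)
})

test_that("classification thresholds are inclusive at 2% and 10%", {
  th <- thresholds()
  expect_equal(as.character(classify_site(0.019, th)), "MONO")
  expect_equal(as.character(classify_site(0.02, th)), "POLY")
  expect_equal(as.character(classify_site(0.0999, th)), "POLY")
  expect_equal(as.character(classify_site(0.10, th)), "HIGH")
  expect_equal(as.character(classify_site(0.30, th)), "HIGH")
  # coverage 50 with exactly one differing read sits exactly at 2%
  col <- rep(c("A", "G"), c(49, 1))
  expect_equal(as.character(classify_site(tally_column(col), th)), "POLY")
  expect_error(thresholds(poly = 0.5, high = 0.1), "poly <= high")
})

test_that("profiles recover planted variants and compute percentages", {
  loc <- make_locus(c(`18S` = 60, ITS1 = 20, `5.8S` = 20, ITS2 = 20,
                      `26S` = 80), seed = 1)
  sites <- c(40L, 90L, 150L)
  ref <- vapply(sites, function(p) substr(loc$sequence, p, p), "")
  alt <- vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  pool <- make_copy_pool(loc, variant_spec(sites, alt, rep(0.30, 3)),
                         n_copies = 100, seed = 2)
  rs <- sequence_reads(pool, coverage = 200, read_length = 40,
                       error_rate = 0, seed = 3)
  cons <- build_consensus(rs, loc$sequence)
  cm <- align_to_reference(cons, loc$sequence)
  aln <- map_reads_ungapped(rs, cons)
  prof <- profile_sample(aln, cons, cm, sample_id = "synthetic")
  expect_equal(attr(prof, "n_poly"), 3L)
  expect_equal(attr(prof, "n_high"), 3L)
  expect_setequal(prof$ref_pos[prof$status == "HIGH"], sites)
  expect_equal(attr(prof, "pct_poly"),
               100 * 3 / attr(prof, "n_sequenced"))
})

test_that("an all-identical read pool yields zero polymorphic sites", {
  set.seed(4)
  ref <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  starts <- seq(1, 61, by = 3)
  rs <- read_set(paste0("r", seq_along(starts)),
                 substring(ref, starts, starts + 39L), 40)
  res <- profile_reads(rs, ref, collapse = FALSE)
  expect_equal(attr(res$profile, "n_poly"), 0L)
  expect_equal(attr(res$profile, "pct_poly"), 0)
})

test_that("profile matches a brute-force recount on a toy instance", {
  loc <- make_locus(c(`18S` = 40, ITS1 = 20, `5.8S` = 20, ITS2 = 20,
                      `26S` = 50), seed = 5)
  pos <- 60L
  alt <- setdiff(c("A", "C", "G", "T"), substr(loc$sequence, pos, pos))[1]
  pool <- make_copy_pool(loc, variant_spec(pos, alt, 0.2), n_copies = 50,
                         seed = 6)
  rs <- sequence_reads(pool, coverage = 50, read_length = 30,
                       error_rate = 0.01, seed = 7)
  th <- thresholds()
  cons <- build_consensus(rs, loc$sequence)
  cm <- align_to_reference(cons, loc$sequence)
  aln <- map_reads_ungapped(rs, cons)
  prof <- profile_sample(aln, cons, cm, th)
  expect_equal(as.character(prof$status),
               oracle_profile(aln, nchar(cons$seq), cm, th))
})

test_that("raising thresholds never increases polymorphic counts", {
  loc <- make_locus(c(`18S` = 60, ITS1 = 20, `5.8S` = 20, ITS2 = 20,
                      `26S` = 80), seed = 8)
  sites <- c(30L, 120L)
  alt <- vapply(sites, function(p) {
    setdiff(c("A", "C", "G", "T"), substr(loc$sequence, p, p))[1]
  }, "")
  pool <- make_copy_pool(loc, variant_spec(sites, alt, c(0.05, 0.30)),
                         n_copies = 100, seed = 9)
  rs <- sequence_reads(pool, coverage = 150, read_length = 40,
                       error_rate = 0.005, seed = 10)
  cons <- build_consensus(rs, loc$sequence)
  cm <- align_to_reference(cons, loc$sequence)
  aln <- map_reads_ungapped(rs, cons)
  polys <- c(0.01, 0.02, 0.05, 0.10)
  n_poly <- vapply(polys, function(p) {
    attr(profile_sample(aln, cons, cm, thresholds(poly = p, high = 0.5)),
         "n_poly")
  }, integer(1))
  expect_true(all(diff(n_poly) <= 0))
  highs <- c(0.05, 0.10, 0.20)
  n_high <- vapply(highs, function(h) {
    attr(profile_sample(aln, cons, cm, thresholds(high = h)), "n_high")
  }, integer(1))
  expect_true(all(diff(n_high) <= 0))
})

test_that("per-position counts plus N reads conserve the overlapping reads", {
  loc <- make_locus(c(`18S` = 40, ITS1 = 20, `5.8S` = 20, ITS2 = 20,
                      `26S` = 50), seed = 11)
  pool <- make_copy_pool(loc, NULL, n_copies = 2, seed = 12)
  rs <- sequence_reads(pool, coverage = 40, read_length = 30,
                       quality = "two-level", low_frac = 0.2, seed = 13)
  rs <- quality_filter(rs)
  aln <- map_reads_ungapped(rs, loc$sequence)
  counts <- copyvar:::.pileup(aln, nchar(loc$sequence))
  overlap <- integer(nchar(loc$sequence))
  for (i in seq_len(nrow(aln))) {
    span <- aln$start[i]:(aln$start[i] + nchar(aln$seq[i]) - 1L)
    overlap[span] <- overlap[span] + 1L
  }
  expect_equal(unname(colSums(counts)), overlap)
})

test_that("indel polymorphisms are counted by shared-indel support", {
  set.seed(14)
  target <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  # no gapped reads -> 0
  rs0 <- read_set("plain", substr(target, 11, 70), 40)
  aln0 <- map_reads_gapped(rs0, target)
  expect_equal(count_indel_polymorphisms(aln0), 0L)

  # 10 of 100 covering reads share one 2 bp deletion -> 1 position
  plain <- substring(target, 31, 110)
  del <- paste0(substr(target, 31, 70), substr(target, 73, 112))
  rs <- read_set(paste0("r", 1:100),
                 c(rep_len(plain, 90), rep_len(del, 10)), 40)
  aln <- map_reads_gapped(rs, target)
  expect_equal(count_indel_polymorphisms(aln), 1L)
  # below the 2% support threshold the indel is not counted
  expect_equal(count_indel_polymorphisms(aln, thresholds(poly = 0.2,
                                                         high = 0.5)), 0L)
})

test_that("planted copy-level indels are detected end to end", {
  loc <- make_locus(c(`18S` = 60, ITS1 = 20, `5.8S` = 20, ITS2 = 20,
                      `26S` = 80), seed = 15)
  pool <- make_copy_pool(loc, NULL, n_copies = 50,
                         indels = data.frame(position = 100, kind = "ins",
                                             length = 3, bases = "TAG",
                                             frequency = 0.2),
                         seed = 16)
  rs <- sequence_reads(pool, coverage = 120, read_length = 40, error_rate = 0,
                       seed = 17)
  aln <- map_reads_gapped(rs, loc$sequence)
  expect_equal(count_indel_polymorphisms(aln), 1L)
})

test_that("cross-sample counts match a brute-force recount", {
  loc <- make_locus(c(`18S` = 60, ITS1 = 20, `5.8S` = 20, ITS2 = 20,
                      `26S` = 80), seed = 18)
  profiles <- lapply(1:3, function(k) {
    sites <- c(25L, 70L + 5L * k)
    alt <- vapply(sites, function(p) {
      setdiff(c("A", "C", "G", "T"), substr(loc$sequence, p, p))[1]
    }, "")
    pool <- make_copy_pool(loc, variant_spec(sites, alt, c(0.3, 0.15)),
                           n_copies = 60, seed = 20 + k)
    rs <- sequence_reads(pool, coverage = 120, read_length = 40,
                         error_rate = 0, seed = 30 + k)
    profile_reads(rs, loc$sequence, collapse = FALSE,
                  sample_id = paste0("s", k))$profile
  })
  cs <- cross_sample_matrix(profiles, loc$regions)
  brute_poly <- integer(200)
  brute_high <- integer(200)
  for (p in profiles) {
    brute_poly <- brute_poly + (p$status %in% c("POLY", "HIGH"))
    brute_high <- brute_high + (p$status == "HIGH")
  }
  expect_equal(cs$n_poly_individuals, brute_poly)
  expect_equal(cs$n_high_individuals, brute_high)
  expect_equal(nrow(cs$region_summary), 5L)

  expect_equal(cross_sample_matrix(list())$n_poly_individuals, integer(0))
  short <- profiles[[1]][1:100, ]
  class(short) <- class(profiles[[1]])
  expect_error(cross_sample_matrix(list(profiles[[1]], short)),
               "reference lengths")
})

test_that("maf_screen returns exactly the sites above the MAF threshold", {
  loc <- make_locus(c(`18S` = 60, ITS1 = 20, `5.8S` = 20, ITS2 = 20,
                      `26S` = 80), seed = 40)
  sites <- c(50L, 130L)
  alt <- vapply(sites, function(p) {
    setdiff(c("A", "C", "G", "T"), substr(loc$sequence, p, p))[1]
  }, "")
  pool <- make_copy_pool(loc, variant_spec(sites, alt, c(0.35, 0.12)),
                         n_copies = 100, seed = 41)
  rs <- sequence_reads(pool, coverage = 300, read_length = 40,
                       error_rate = 0, seed = 42)
  prof <- profile_reads(rs, loc$sequence, collapse = FALSE)$profile
  hits <- maf_screen(prof, 0.3)
  expect_equal(hits$ref_pos, 50L)
  # threshold 0 returns every covered position
  expect_equal(nrow(maf_screen(prof, 0)), attr(prof, "n_sequenced"))
  # biallelic sites cannot exceed 0.5 differing (consensus is the plurality)
  expect_equal(nrow(maf_screen(prof, 0.51)), 0L)
})
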