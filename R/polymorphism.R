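#' Classification thresholds for polymorphic sites
#'
#' A position is polymorphic when the fraction of reads differing from the
#' consensus base is at least `poly` (default 2%) and highly polymorphic when
#' it is at least `high` (default 10%); both cutoffs are inclusive.
#' `min_coverage` optionally marks positions below a read-depth floor as
#' unassembled (the default of 0 imposes no floor, matching the original
#' counting scheme; note that at coverage of 50 or less a single differing
#' read already crosses 2%).
#'
#' @param poly polymorphic cutoff, a fraction in `(0, 1]`.
#' @param high highly polymorphic cutoff, `poly <= high <= 1`.
#' @param min_coverage minimum read depth for a position to be classified.
#' @return An object of class `thresholds`.
#' @export
thresholds <- function(poly = 0.02, high = 0.10, min_coverage = 0L) {
  if (!(poly > 0 && poly <= high && high <= 1)) {
    stop("need 0 < poly <= high <= 1")
  }
  structure(list(poly = poly, high = high,
                 min_coverage = as.integer(min_coverage)),
            class = "thresholds")
}

.STATUS <- c("UNASSEMBLED", "MONO", "POLY", "HIGH")

# vectorized classification of differing fractions
.classify <- function(fraction, coverage, th) {
  status <- rep("MONO", length(fraction))
  status[!is.na(fraction) & fraction >= th$poly] <- "POLY"
  status[!is.na(fraction) & fraction >= th$high] <- "HIGH"
  status[is.na(fraction) | coverage == 0L | coverage < th$min_coverage] <-
    "UNASSEMBLED"
  factor(status, levels = .STATUS)
}

#' Tally the bases of one pileup column
#'
#' Counts the reads covering one consensus position by base. `N` bases are
#' excluded from both the counts and the coverage (they carry no call) but
#' are recorded separately. The consensus base is the most frequent base,
#' ties broken in the order A < C < G < T; the differing fraction aggregates
#' all non-consensus bases.
#'
#' @param bases character vector of read bases (`A`, `C`, `G`, `T`, `N`) at
#'   one position.
#' @return An object of class `position_tally`: list with `counts` (named
#'   A/C/G/T), `n_count`, `coverage`, `consensus_base` and
#'   `differing_fraction` (`NA` when coverage is 0).
#' @examples
#' tally_column(rep(c("G", "C"), c(7, 3)))$differing_fraction  # 0.3
#' @export
tally_column <- function(bases) {
  bases <- toupper(bases)
  stopifnot(all(bases %in% c(.BASES, "N")))
  counts <- tabulate(match(bases, .BASES), 4L)
  names(counts) <- .BASES
  coverage <- sum(counts)
  n_count <- sum(bases == "N")
  if (coverage == 0L) {
    cb <- NA_character_; frac <- NA_real_
  } else {
    cb <- .BASES[which.max(counts)]
    frac <- (coverage - counts[[cb]]) / coverage
  }
  structure(list(counts = counts, n_count = n_count, coverage = coverage,
                 consensus_base = cb, differing_fraction = frac),
            class = "position_tally")
}

#' Classify one position from its tally
#'
#' @param tally a [tally_column()] result (or a bare differing fraction, in
#'   which case coverage is assumed adequate).
#' @param th a [thresholds()] object.
#' @return One of `"UNASSEMBLED"`, `"MONO"`, `"POLY"`, `"HIGH"` (factor).
#' @examples
#' classify_site(tally_column(rep(c("G", "C"), c(7, 3))))  # HIGH
#' @export
classify_site <- function(tally, th = thresholds()) {
  if (inherits(tally, "position_tally")) {
    .classify(tally$differing_fraction, tally$coverage, th)
  } else {
    .classify(as.numeric(tally), rep(th$min_coverage + 1L, length(tally)), th)
  }
}

#' Per-sample polymorphism profile in reference coordinates
#'
#' The core per-sample computation: read bases are tallied at every consensus
#' position, differing fractions classified against the 2%/10% thresholds,
#' and the per-position calls projected into group-reference coordinates
#' through the coordinate map. Consensus positions with no reference partner
#' (insertions relative to the reference) are discarded; reference positions
#' absent from the consensus, or covered by no read, are reported as
#' unassembled. Percentages are computed over sequenced (non-unassembled)
#' positions.
#'
#' @param aln an `alignment_set` mapped onto the consensus underlying `cm`.
#' @param consensus the `consensus_sequence` (or string) reads were mapped to.
#' @param cm the [align_to_reference()] coordinate map for that consensus.
#' @param th a [thresholds()] object.
#' @param sample_id label stored with the profile.
#' @return A data.frame of class `polymorphism_profile` with columns
#'   `ref_pos`, `status`, `fraction`, `coverage`, and attributes `sample_id`,
#'   `n_poly`, `n_high`, `n_sequenced`, `pct_poly`, `pct_high`.
#' @export
profile_sample <- function(aln, consensus, cm, th = thresholds(),
                           sample_id = "sample") {
  cons <- .as_sequence(consensus)
  if (nchar(cons) != cm$cons_length) {
    stop("consensus length (", nchar(cons),
         ") does not match coordinate map (", cm$cons_length, ")")
  }
  counts <- .pileup(aln, cm$cons_length)
  base_counts <- counts[1:4, , drop = FALSE]
  cov <- colSums(base_counts)
  maxc <- do.call(pmax, as.data.frame(t(base_counts)))
  frac <- ifelse(cov > 0L, (cov - maxc) / cov, NA_real_)
  cpos <- cm$ref_to_cons
  fraction <- ifelse(is.na(cpos), NA_real_, frac[ifelse(is.na(cpos), 1L, cpos)])
  coverage <- ifelse(is.na(cpos), 0L, cov[ifelse(is.na(cpos), 1L, cpos)])
  status <- .classify(fraction, coverage, th)
  out <- data.frame(ref_pos = seq_len(cm$ref_length), status = status,
                    fraction = fraction, coverage = as.integer(coverage))
  n_seq <- sum(status != "UNASSEMBLED")
  n_poly <- sum(status %in% c("POLY", "HIGH"))
  n_high <- sum(status == "HIGH")
  structure(out,
            sample_id = sample_id, thresholds = th,
            n_poly = n_poly, n_high = n_high, n_sequenced = n_seq,
            pct_poly = if (n_seq > 0L) 100 * n_poly / n_seq else NA_real_,
            pct_high = if (n_seq > 0L) 100 * n_high / n_seq else NA_real_,
            class = c("polymorphism_profile", "data.frame"))
}

#' Summarize one or more profiles as a sample table
#'
#' Collects per-sample polymorphic and highly polymorphic site counts and
#' percentages into one row per sample (the layout of a published
#' polymorphic-site abundance table).
#'
#' @param profiles a `polymorphism_profile` or list of them.
#' @return data.frame with columns `sample`, `poly_n`, `poly_pct`, `high_n`,
#'   `high_pct`.
#' @export
profile_summary <- function(profiles) {
  if (inherits(profiles, "polymorphism_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample = attr(p, "sample_id"),
               poly_n = attr(p, "n_poly"), poly_pct = attr(p, "pct_poly"),
               high_n = attr(p, "n_high"), high_pct = attr(p, "pct_high"),
               stringsAsFactors = FALSE)
  }))
}

#' Count polymorphic indels
#'
#' Counts consensus positions at which reads supporting one identical indel
#' (same start, length, kind and inserted bases) make up at least the
#' polymorphic fraction (`th$poly`) of the reads covering that position.
#'
#' @param aln a gapped `alignment_set` (from [map_reads_gapped()] or
#'   [import_alignments()]).
#' @param th a [thresholds()] object.
#' @return Integer count of indel-polymorphic positions.
#' @export
count_indel_polymorphisms <- function(aln, th = thresholds()) {
  ind <- .alignment_indels(aln)
  if (nrow(ind) == 0L) return(0L)
  spans_start <- aln$start
  spans_end <- aln$start + .cigar_target_span(aln$cigar) - 1L
  key <- paste(ind$tpos, ind$len, ind$kind, ind$bases, sep = "\r")
  support <- table(key)
  qual_pos <- integer(0)
  for (k in names(support)) {
    tpos <- as.integer(strsplit(k, "\r", fixed = TRUE)[[1]][1])
    covering <- sum(spans_start <= tpos & spans_end >= tpos)
    if (covering > 0L && support[[k]] / covering >= th$poly) {
      qual_pos <- c(qual_pos, tpos)
    }
  }
  length(unique(qual_pos))
}

#' Cross-sample polymorphism counts per reference position
#'
#' For a set of profiles sharing one group reference, counts at every
#' reference position how many samples are polymorphic (including highly)
#' and how many are highly polymorphic; unassembled positions do not
#' contribute. Optionally summarizes, per annotated region, the fraction of
#' positions polymorphic in at least one sample.
#'
#' @param profiles list of `polymorphism_profile` objects on one reference.
#' @param regions optional region table (see [make_locus()]).
#' @return List with `n_poly_individuals` and `n_high_individuals` (integer
#'   vectors over reference positions), `any_poly`/`any_high` (logical), and
#'   `region_summary` (data.frame, when `regions` is supplied) with the
#'   percentage of positions polymorphic / highly polymorphic in at least
#'   one sample per region.
#' @export
cross_sample_matrix <- function(profiles, regions = NULL) {
  if (inherits(profiles, "polymorphism_profile")) profiles <- list(profiles)
  lens <- vapply(profiles, nrow, integer(1))
  if (length(profiles) > 0L && length(unique(lens)) != 1L) {
    stop("profiles use different reference lengths")
  }
  L <- if (length(profiles) > 0L) lens[1] else 0L
  n_poly <- integer(L); n_high <- integer(L)
  for (p in profiles) {
    n_poly <- n_poly + (p$status %in% c("POLY", "HIGH"))
    n_high <- n_high + (p$status == "HIGH")
  }
  out <- list(n_poly_individuals = n_poly, n_high_individuals = n_high,
              any_poly = n_poly > 0L, any_high = n_high > 0L)
  if (!is.null(regions)) {
    out$region_summary <- do.call(rbind, lapply(seq_len(nrow(regions)),
      function(i) {
        idx <- regions$start[i]:regions$end[i]
        data.frame(region = regions$region[i],
                   pct_any_poly = 100 * mean(out$any_poly[idx]),
                   pct_any_high = 100 * mean(out$any_high[idx]),
                   stringsAsFactors = FALSE)
      }))
  }
  out
}

#' Screen a profile for elevated minor-allele frequencies
#'
#' Returns the positions whose differing-read fraction reaches a
#' minor-allele-frequency threshold; profiles dominated by such positions
#' can flag hybrid or otherwise mixed ancestry.
#'
#' @param profile a `polymorphism_profile`.
#' @param maf_threshold minimum differing fraction (default 0.3).
#' @return data.frame with `ref_pos` and `fraction` for qualifying positions.
#' @export
maf_screen <- function(profile, maf_threshold = 0.3) {
  keep <- !is.na(profile$fraction) & profile$status != "UNASSEMBLED" &
    profile$fraction >= maf_threshold
  data.frame(ref_pos = profile$ref_pos[keep],
             fraction = profile$fraction[keep])
}

#' Write a polymorphism profile as TSV
#'
#' @param profile a `polymorphism_profile`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
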