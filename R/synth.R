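#' Generate a synthetic rDNA-like locus with a region layout
#'
#' Builds a random nucleotide sequence organized as the five regions of an
#' 18S-ITS1-5.8S-ITS2-26S cistron, in that order. The default lengths give a
#' 5,839 bp locus matching the size of a real milkweed nrDNA cistron used as
#' a group reference; the internal split among regions is a package choice.
#'
#' @param region_lengths named numeric vector of region lengths (bp), with
#'   names `18S`, `ITS1`, `5.8S`, `ITS2`, `26S` in that order.
#' @param seed optional integer seed for reproducibility.
#' @return A list with `sequence` (a single character string) and `regions`
#'   (a data.frame with columns `region`, `start`, `end`, `class`; 1-based
#'   inclusive coordinates). Subunit regions are 18S, 5.8S and 26S; spacer
#'   regions are ITS1 and ITS2.
#' @examples
#' loc <- make_locus(c(`18S` = 10, ITS1 = 5, `5.8S` = 5, ITS2 = 5, `26S` = 10),
#'                   seed = 1)
#' nchar(loc$sequence)
#' @export
make_locus <- function(region_lengths = c(`18S` = 1800, ITS1 = 250, `5.8S` = 160,
                                          ITS2 = 220, `26S` = 3409),
                       seed = NULL) {
  expected <- c("18S", "ITS1", "5.8S", "ITS2", "26S")
  if (!identical(names(region_lengths), expected)) {
    stop("region_lengths must be named ", paste(expected, collapse = ", "),
         " in that order")
  }
  region_lengths <- as.integer(region_lengths)
  if (any(region_lengths < 1L)) stop("all region lengths must be >= 1")
  .seed_guard(seed)
  total <- sum(region_lengths)
  sequence <- paste(sample(.BASES, total, replace = TRUE), collapse = "")
  ends <- cumsum(region_lengths)
  starts <- ends - region_lengths + 1L
  regions <- data.frame(
    region = expected,
    start = starts,
    end = ends,
    class = ifelse(expected %in% c("18S", "5.8S", "26S"), "subunit", "spacer"),
    stringsAsFactors = FALSE
  )
  list(sequence = sequence, regions = regions)
}

#' Specify planted variants for a synthetic copy pool
#'
#' @param position 1-based positions in the locus.
#' @param alt_base alternative base carried by a subset of copies; must differ
#'   from the locus base at that position.
#' @param frequency fraction of copies carrying the alternative base, in
#'   `[0, 1]`.
#' @return A data.frame of class `variant_spec`.
#' @export
variant_spec <- function(position, alt_base, frequency) {
  stopifnot(length(position) == length(alt_base),
            length(position) == length(frequency))
  alt_base <- toupper(alt_base)
  if (!all(alt_base %in% .BASES)) stop("alt_base must be one of A, C, G, T")
  if (any(frequency < 0 | frequency > 1)) stop("frequency must be in [0, 1]")
  if (anyDuplicated(position)) stop("variant positions must be unique")
  structure(data.frame(position = as.integer(position), alt_base = alt_base,
                       frequency = frequency, stringsAsFactors = FALSE),
            class = c("variant_spec", "data.frame"))
}

#' Generate a pool of locus copies with planted variant frequencies
#'
#' Emulates the many near-identical copies of a tandemly repeated locus within
#' one genome. Each planted variant is assigned to `round(frequency *
#' n_copies)` randomly chosen copies, so the realized frequency is within
#' `1/n_copies` of the specification. Optionally, copy-level insertions or
#' deletions (at most 5 bp) can be planted to exercise indel-aware mapping;
#' copies then differ in length.
#'
#' @param locus a locus sequence (string, or the list from [make_locus()]).
#' @param variants a [variant_spec()] data.frame, or `NULL` for none.
#' @param n_copies number of copies in the pool (default 960, a realistic
#'   plant nrDNA copy number).
#' @param indels optional data.frame with columns `position`, `kind`
#'   (`"ins"`/`"del"`), `length` (1-5), `bases` (inserted bases, for `ins`)
#'   and `frequency`. Insertions are placed after `position`; deletions remove
#'   `position .. position+length-1`.
#' @param seed optional integer seed.
#' @return A list of class `copy_pool` with elements `copies` (character
#'   vector), `locus`, `n_copies`, `variants`, `indels`.
#' @examples
#' loc <- make_locus(c(`18S` = 10, ITS1 = 5, `5.8S` = 5, ITS2 = 5, `26S` = 10),
#'                   seed = 1)
#' pool <- make_copy_pool(loc, variant_spec(7, "A", 0.3), n_copies = 10, seed = 2)
#' @export
make_copy_pool <- function(locus, variants = NULL, n_copies = 960L,
                           indels = NULL, seed = NULL) {
  locus <- .as_sequence(locus)
  L <- nchar(locus)
  n_copies <- as.integer(n_copies)
  stopifnot(n_copies >= 1L)
  .seed_guard(seed)
  copies <- rep(locus, n_copies)
  if (!is.null(variants) && nrow(variants) > 0L) {
    if (any(variants$frequency < 0 | variants$frequency > 1)) {
      stop("variant frequency must be in [0, 1]")
    }
    if (any(variants$position < 1L | variants$position > L)) {
      stop("variant positions must lie within the locus")
    }
    ref_at <- substring(locus, variants$position, variants$position)
    if (any(ref_at == variants$alt_base)) {
      stop("alt_base equals the locus base at some positions")
    }
    for (i in seq_len(nrow(variants))) {
      k <- round(variants$frequency[i] * n_copies)
      if (k > 0L) {
        idx <- sample.int(n_copies, k)
        substr(copies[idx], variants$position[i], variants$position[i]) <-
          variants$alt_base[i]
      }
    }
  }
  if (!is.null(indels) && nrow(indels) > 0L) {
    if (any(indels$length < 1L | indels$length > 5L)) {
      stop("planted indels must be 1-5 bp long")
    }
    for (i in seq_len(nrow(indels))) {
      k <- round(indels$frequency[i] * n_copies)
      if (k == 0L) next
      idx <- sample.int(n_copies, k)
      p <- indels$position[i]
      if (indels$kind[i] == "ins") {
        copies[idx] <- paste0(substr(copies[idx], 1L, p),
                              toupper(indels$bases[i]),
                              substr(copies[idx], p + 1L, nchar(copies[idx])))
      } else if (indels$kind[i] == "del") {
        copies[idx] <- paste0(substr(copies[idx], 1L, p - 1L),
                              substr(copies[idx], p + indels$length[i],
                                     nchar(copies[idx])))
      } else {
        stop("indel kind must be 'ins' or 'del'")
      }
    }
  }
  structure(list(copies = copies, locus = locus, n_copies = n_copies,
                 variants = variants, indels = indels),
            class = "copy_pool")
}

#' Simulate shotgun reads from a copy pool
#'
#' Draws single-end reads from uniformly sampled copies at uniform start
#' positions on either strand, applies a uniform per-base substitution error,
#' and assigns Phred qualities. The expected number of reads is
#' `coverage * locus_length / read_length`. Read starts are uniform within
#' each copy (no wrap-around), so positions near the locus ends receive lower
#' coverage, as in real shotgun data.
#'
#' @param pool a `copy_pool` (or plain character vector of copies).
#' @param coverage mean fold-coverage of the locus (default 97, the mean
#'   nrDNA coverage of the genome-skimming study conditions emulated here).
#' @param read_length read length in bp (default 80).
#' @param error_rate per-base substitution probability (default 0.001).
#' @param quality `"constant"` assigns `q_high` to every base; `"two-level"`
#'   assigns `q_low` to a fraction `low_frac` of bases and `q_high` otherwise.
#' @param q_high,q_low,low_frac quality model parameters.
#' @param seed optional integer seed.
#' @return A [read_set()] with an attached `"truth"` attribute: a data.frame
#'   with the originating copy, 1-based start on that copy, strand and number
#'   of simulated errors per read.
#' @export
sequence_reads <- function(pool, coverage = 97, read_length = 80L,
                           error_rate = 0.001,
                           quality = c("constant", "two-level"),
                           q_high = 40L, q_low = 10L, low_frac = 0.1,
                           seed = NULL) {
  quality <- match.arg(quality)
  copies <- if (inherits(pool, "copy_pool")) pool$copies else pool
  locus_len <- if (inherits(pool, "copy_pool")) nchar(pool$locus) else
    max(nchar(copies))
  read_length <- as.integer(read_length)
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (read_length > min(nchar(copies))) {
    stop("read_length exceeds the shortest copy in the pool")
  }
  .seed_guard(seed)
  n_reads <- round(coverage * locus_len / read_length)
  copy_idx <- sample.int(length(copies), n_reads, replace = TRUE)
  span <- nchar(copies)[copy_idx] - read_length + 1L
  start <- 1L + floor(runif(n_reads) * span)
  seqs <- substr(copies[copy_idx], start, start + read_length - 1L)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)

  mat <- .encode_dna_matrix(seqs)
  err <- which(matrix(runif(n_reads * read_length) < error_rate,
                      n_reads, read_length))
  if (length(err) > 0L) {
    # substitute each erroneous base by a uniformly chosen different base
    shift <- sample.int(3L, length(err), replace = TRUE)
    mat[err] <- 1L + (mat[err] - 1L + shift) %% 4L
  }
  n_err <- tabulate(((err - 1L) %% n_reads) + 1L, n_reads)
  seqs <- apply(mat, 1L, .decode_dna)
  rev_i <- strand == "-"
  if (any(rev_i)) seqs[rev_i] <- .revcomp(seqs[rev_i])

  if (quality == "constant") {
    qual <- as.integer(q_high)
  } else {
    qual <- lapply(seq_len(n_reads), function(i) {
      ifelse(runif(read_length) < low_frac, as.integer(q_low),
             as.integer(q_high))
    })
  }
  rs <- read_set(sprintf("read%06d", seq_len(n_reads)), seqs, qual)
  attr(rs, "truth") <- data.frame(
    id = rs$id, copy = copy_idx, start = start, strand = strand,
    n_errors = n_err, stringsAsFactors = FALSE)
  rs
}

#' Simulate a random tree with a trait evolved under lambda-scaled Brownian
#' motion
#'
#' Generates a random bifurcating tree with uniform branch lengths and
#' simulates a continuous trait (e.g., a polymorphic-site count) under
#' Brownian motion on the lambda-transformed tree, reflected at zero so the
#' trait stays non-negative (see [simulate_bm_bounded()]).
#'
#' @param n_tips number of tips (>= 2).
#' @param lambda Pagel's lambda in `[0, 1]` used to transform the tree before
#'   simulation.
#' @param sigma2 Brownian-motion rate (>= 0).
#' @param root_state trait value at the root (>= 0).
#' @param seed optional integer seed.
#' @return A [phylo_trait()] carrying the (untransformed) tree and one trait
#'   value per tip.
#' @export
make_tree_and_traits <- function(n_tips, lambda = 1, sigma2 = 1,
                                 root_state = 0, seed = NULL) {
  stopifnot(n_tips >= 2L)
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (root_state < 0) stop("root_state must be >= 0")
  .seed_guard(seed)
  tree <- ape::rtree(n_tips)
  ttree <- lambda_transform(tree, lambda)
  traits <- simulate_bm_bounded(ttree, sigma2, root_state, n_sims = 1L)[, 1L]
  phylo_trait(tree, traits)
}

#' Read and write region interval tables
#'
#' Region tables use 1-based, inclusive coordinates on the forward strand
#' (columns `region`, `start`, `end`, `class`), explicitly not the 0-based
#' half-open BED convention; the file header records the dialect.
#'
#' @param regions a region data.frame as produced by [make_locus()].
#' @param path file path.
#' @return `read_regions` returns the region data.frame; `write_regions`
#'   returns `path` invisibly.
#' @export
write_regions <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based, inclusive", con)
  utils::write.table(regions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
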