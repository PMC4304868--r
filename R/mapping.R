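#' Mismatch cap for a read length
#'
#' Piecewise-constant table reproducing the default and relaxed per-length
#' mismatch allowances of short-read mapping: under standard settings an
#' 80 bp read may carry up to 3 mismatches against the consensus and a
#' 100 bp read up to 4; relaxed settings allow 4 and 5, respectively. Reads
#' shorter than 50 bp get a cap of 2, reads of 50-89 bp the 80 bp cap, and
#' reads of 90 bp or more the 100 bp cap.
#'
#' @param read_length read length(s) in bp.
#' @param relaxed use the relaxed caps.
#' @return Integer vector of mismatch caps.
#' @examples
#' max_mismatches(80)                 # 3
#' max_mismatches(100, relaxed = TRUE) # 5
#' @export
max_mismatches <- function(read_length, relaxed = FALSE) {
  stopifnot(all(read_length >= 1))
  extra <- if (isTRUE(relaxed)) 1L else 0L
  ifelse(read_length < 50L, 2L,
         ifelse(read_length < 90L, 3L + extra, 4L + extra))
}

# empty alignment-set skeleton
.empty_alignments <- function(target_length) {
  structure(
    data.frame(read_id = character(0), start = integer(0),
               strand = character(0), seq = character(0),
               cigar = character(0), n_mismatch = integer(0),
               stringsAsFactors = FALSE),
    target_length = target_length, class = c("alignment_set", "data.frame"))
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("alignment_set:", nrow(x), "alignments on a",
      attr(x, "target_length"), "bp target\n")
  un <- attr(x, "unmapped")
  if (!is.null(un)) {
    cat("  unmapped:", sum(un$reason == "no_placement"),
        " ambiguous:", sum(un$reason == "ambiguous"), "\n")
  }
  invisible(x)
}

# mismatch counts of one encoded read against every window of the encoded
# target, for a block of reads sharing one length.
# Returns list(fwd, rev): n_reads x n_offsets matrices.
.mismatch_profiles <- function(rmat, tcode) {
  len <- ncol(rmat)
  L <- length(tcode)
  n_off <- L - len + 1L
  wcodes <- matrix(tcode[outer(seq_len(n_off), 0:(len - 1L), "+")], n_off, len)
  wind <- lapply(1:4, function(b) (wcodes == b) * 1)
  count_matches <- function(m) {
    M <- matrix(0, nrow(m), n_off)
    for (b in 1:4) M <- M + (m == b) %*% t(wind[[b]])
    M
  }
  non_n <- rowSums(rmat > 0L)
  rrev <- .revcomp_codes(rmat)
  list(fwd = non_n - count_matches(rmat),
       rev = non_n - count_matches(rrev))
}

#' Map reads onto a consensus by exhaustive ungapped search
#'
#' Each read (and its reverse complement) is scored at every offset of the
#' target; the placement with the fewest mismatches is retained if that count
#' is within the per-length cap (see [max_mismatches()]). `N` bases in a read
#' match nothing but are not counted as mismatches. Reads whose best
#' placement is achieved at more than one (strand, offset) are discarded as
#' ambiguous; reads longer than the target are reported unmapped.
#'
#' @param reads a [read_set()].
#' @param consensus target sequence (string or `consensus_sequence`).
#' @param relaxed use relaxed mismatch caps.
#' @param block_size number of reads scored per matrix block (memory knob).
#' @return An `alignment_set`: a data.frame with columns `read_id`, `start`
#'   (1-based on the target), `strand`, `seq` (bases in target orientation),
#'   `cigar`, `n_mismatch`, plus an `"unmapped"` attribute listing discarded
#'   reads and the reason (`no_placement` or `ambiguous`).
#' @export
map_reads_ungapped <- function(reads, consensus, relaxed = FALSE,
                               block_size = NULL) {
  stopifnot(inherits(reads, "read_set"))
  target <- .as_sequence(consensus)
  tcode <- .encode_dna(target)
  L <- length(tcode)
  if (L == 0L) stop("consensus must be non-empty")
  out <- .empty_alignments(L)
  unmapped <- data.frame(read_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (length(reads) == 0L) {
    attr(out, "unmapped") <- unmapped
    return(out)
  }

  rows <- vector("list", 0L)
  lens <- nchar(reads$seq)
  for (len in sort(unique(lens))) {
    sel <- which(lens == len)
    if (len > L) {
      unmapped <- rbind(unmapped, data.frame(
        read_id = reads$id[sel], reason = "no_placement",
        stringsAsFactors = FALSE))
      next
    }
    n_off <- L - len + 1L
    cap <- max_mismatches(len, relaxed)
    bs <- if (is.null(block_size)) max(1L, floor(5e6 / n_off)) else block_size
    for (chunk in split(sel, ceiling(seq_along(sel) / bs))) {
      rmat <- .encode_dna_matrix(reads$seq[chunk])
      prof <- .mismatch_profiles(rmat, tcode)
      bf <- apply(prof$fwd, 1L, min)
      br <- apply(prof$rev, 1L, min)
      best <- pmin(bf, br)
      n_best <- rowSums(prof$fwd == best) + rowSums(prof$rev == best)
      ok <- best <= cap & n_best == 1L
      amb <- best <= cap & n_best > 1L
      if (any(amb)) {
        unmapped <- rbind(unmapped, data.frame(
          read_id = reads$id[chunk[amb]], reason = "ambiguous",
          stringsAsFactors = FALSE))
      }
      if (any(!ok & !amb)) {
        unmapped <- rbind(unmapped, data.frame(
          read_id = reads$id[chunk[!ok & !amb]], reason = "no_placement",
          stringsAsFactors = FALSE))
      }
      if (!any(ok)) next
      iok <- which(ok)
      on_fwd <- bf[iok] <= br[iok]
      off <- integer(length(iok))
      off[on_fwd] <- max.col(-prof$fwd[iok[on_fwd], , drop = FALSE],
                             ties.method = "first")
      off[!on_fwd] <- max.col(-prof$rev[iok[!on_fwd], , drop = FALSE],
                              ties.method = "first")
      seqs <- reads$seq[chunk[iok]]
      seqs[!on_fwd] <- .revcomp(seqs[!on_fwd])
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = reads$id[chunk[iok]], start = off,
        strand = ifelse(on_fwd, "+", "-"), seq = seqs,
        cigar = paste0(len, "M"), n_mismatch = as.integer(best[iok]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) > 0L) {
    out <- structure(do.call(rbind, rows), target_length = L,
                     class = c("alignment_set", "data.frame"))
    out <- out[match(reads$id[reads$id %in% out$read_id], out$read_id), ]
    rownames(out) <- NULL
  }
  attr(out, "target_length") <- L
  attr(out, "unmapped") <- unmapped
  class(out) <- c("alignment_set", "data.frame")
  out
}

# one-gap placements for a single encoded read (one strand).
# Returns a data.frame of candidate placements: offset, kind, g, split,
# mismatches; only the best (minimum mismatch) candidates are returned.
.gap_candidates <- function(rcode, tcode, max_indel) {
  len <- length(rcode)
  L <- length(tcode)
  n_off <- L - len + 1L
  if (n_off < 1L) return(NULL)
  wcodes <- matrix(tcode[outer(seq_len(n_off), 0:(len - 1L), "+")], n_off, len)
  rrep <- matrix(rcode, n_off, len, byrow = TRUE)
  X <- (rrep > 0L) & (wcodes != rrep)
  U <- upper.tri(matrix(0, len, len), diag = TRUE) * 1
  pcum <- X %*% U                      # pcum[o, s] = mismatches of read[1..s]
  tot <- pcum[, len]
  best <- NULL
  push <- function(m, off, kind, g, split) {
    cand <- data.frame(offset = off, kind = kind, g = g, split = split,
                       mism = m, stringsAsFactors = FALSE)
    best <<- rbind(best, cand)
  }
  for (g in seq_len(max_indel)) {
    # deletion relative to the read: target consumes len + g bases
    if (n_off - g >= 1L && len >= 2L) {
      o <- seq_len(n_off - g)
      tmat <- pcum[o, seq_len(len - 1L), drop = FALSE] -
        pcum[o + g, seq_len(len - 1L), drop = FALSE] + tot[o + g]
      m <- apply(tmat, 1L, min)
      s <- max.col(-tmat, ties.method = "first")
      push(m, o, "D", g, s)
    }
    # insertion in the read: target consumes len - g bases
    if (len - g >= 2L && n_off - g >= 1L) {
      o <- seq(g + 1L, n_off)
      s_idx <- seq_len(len - g - 1L)
      tmat <- pcum[o, s_idx, drop = FALSE] -
        pcum[o - g, s_idx + g, drop = FALSE] + tot[o - g]
      m <- apply(tmat, 1L, min)
      s <- max.col(-tmat, ties.method = "first")
      push(m, o, "I", g, s)
    }
  }
  if (is.null(best)) return(NULL)
  best[best$mism == min(best$mism), , drop = FALSE]
}

#' Map reads allowing one short indel
#'
#' Extends [map_reads_ungapped()] with placements containing a single
#' insertion or deletion of at most `max_indel` bases (default 5). A gap
#' opening counts as one mismatch-equivalent in the placement score; the
#' mismatch cap applies to mismatches only. Reads that map unambiguously
#' without a gap keep their ungapped placement. Among gapped placements,
#' candidates are compared by distinct (strand, offset, gap kind, gap
#' length); ties in the gap's position within the read are broken leftmost.
#'
#' @inheritParams map_reads_ungapped
#' @param max_indel maximum indel length in bp.
#' @return An `alignment_set` (see [map_reads_ungapped()]); gapped placements
#'   carry CIGAR strings such as `30M2D50M`.
#' @export
map_reads_gapped <- function(reads, consensus, relaxed = FALSE,
                             max_indel = 5L) {
  target <- .as_sequence(consensus)
  tcode <- .encode_dna(target)
  ung <- map_reads_ungapped(reads, consensus, relaxed)
  un <- attr(ung, "unmapped")
  retry <- un$read_id[un$reason == "no_placement"]
  retry <- retry[retry %in% reads$id[nchar(reads$seq) <= length(tcode)]]
  if (length(retry) == 0L) return(ung)

  rows <- vector("list", 0L)
  still <- character(0)
  ambig <- character(0)
  for (id in retry) {
    i <- match(id, reads$id)
    len <- nchar(reads$seq[i])
    cap <- max_mismatches(len, relaxed)
    rcode <- .encode_dna(reads$seq[i])
    cand_f <- .gap_candidates(rcode, tcode, max_indel)
    cand_r <- .gap_candidates(.revcomp_codes(rcode), tcode, max_indel)
    if (!is.null(cand_f)) cand_f$strand <- "+"
    if (!is.null(cand_r)) cand_r$strand <- "-"
    cand <- rbind(cand_f, cand_r)
    if (is.null(cand) || nrow(cand) == 0L) { still <- c(still, id); next }
    cand <- cand[cand$mism == min(cand$mism), , drop = FALSE]
    if (cand$mism[1L] > cap) { still <- c(still, id); next }
    key <- unique(cand[, c("strand", "offset", "kind", "g")])
    if (nrow(key) > 1L) { ambig <- c(ambig, id); next }
    cc <- cand[1L, ]
    s <- cc$split
    cigar <- if (cc$kind == "D") {
      paste0(s, "M", cc$g, "D", len - s, "M")
    } else {
      paste0(s, "M", cc$g, "I", len - s - cc$g, "M")
    }
    sq <- if (cc$strand == "+") reads$seq[i] else .revcomp(reads$seq[i])
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = id, start = cc$offset, strand = cc$strand, seq = sq,
      cigar = cigar, n_mismatch = as.integer(cc$mism),
      stringsAsFactors = FALSE)
  }
  out <- ung
  if (length(rows) > 0L) {
    out <- structure(rbind(as.data.frame(ung), do.call(rbind, rows)),
                     class = c("alignment_set", "data.frame"))
    out <- out[match(reads$id[reads$id %in% out$read_id], out$read_id), ]
    rownames(out) <- NULL
    attr(out, "target_length") <- attr(ung, "target_length")
  }
  un <- un[!(un$read_id %in% c(vapply(rows, function(r) r$read_id, character(1)))), ,
           drop = FALSE]
  if (length(ambig) > 0L) {
    un$reason[un$read_id %in% ambig] <- "ambiguous"
  }
  attr(out, "unmapped") <- un
  out
}

# parse one CIGAR string into (lengths, ops)
.parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  list(lengths = lens, ops = ops)
}

# target span consumed by a CIGAR (M, D, =, X consume target)
.cigar_target_span <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- .parse_cigar(cg)
    sum(p$lengths[p$ops %in% c("M", "D", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# extract indels from an alignment set: one row per indel occurrence
# tpos: for D, first deleted target base; for I, target base preceding the
# inserted bases. bases: inserted read bases ("" for deletions).
.alignment_indels <- function(aln) {
  has <- grepl("[ID]", aln$cigar)
  if (!any(has)) {
    return(data.frame(row = integer(0), tpos = integer(0), len = integer(0),
                      kind = character(0), bases = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- vector("list", 0L)
  for (i in which(has)) {
    p <- .parse_cigar(aln$cigar[i])
    tpos <- aln$start[i]
    rpos <- 1L
    for (j in seq_along(p$ops)) {
      op <- p$ops[j]; n <- p$lengths[j]
      if (op %in% c("M", "=", "X")) { tpos <- tpos + n; rpos <- rpos + n }
      else if (op == "D") {
        out[[length(out) + 1L]] <- data.frame(
          row = i, tpos = tpos, len = n, kind = "del", bases = "",
          stringsAsFactors = FALSE)
        tpos <- tpos + n
      } else if (op == "I") {
        out[[length(out) + 1L]] <- data.frame(
          row = i, tpos = tpos - 1L, len = n, kind = "ins",
          bases = substr(aln$seq[i], rpos, rpos + n - 1L),
          stringsAsFactors = FALSE)
        rpos <- rpos + n
      }
    }
  }
  do.call(rbind, out)
}

#' Recount mismatches of alignments against a target sequence
#'
#' Walks each alignment's CIGAR and counts aligned read bases differing from
#' the target (`N` on either side is not counted).
#'
#' @param aln an `alignment_set`.
#' @param consensus the target sequence the alignments refer to.
#' @return Integer vector of mismatch counts, one per alignment.
#' @export
recount_mismatches <- function(aln, consensus) {
  tcode <- .encode_dna(.as_sequence(consensus))
  vapply(seq_len(nrow(aln)), function(i) {
    p <- .parse_cigar(aln$cigar[i])
    rcode <- .encode_dna(aln$seq[i])
    tpos <- aln$start[i]; rpos <- 1L; mm <- 0L
    for (j in seq_along(p$ops)) {
      op <- p$ops[j]; n <- p$lengths[j]
      if (op %in% c("M", "=", "X")) {
        r <- rcode[rpos:(rpos + n - 1L)]
        t <- tcode[tpos:(tpos + n - 1L)]
        # read N is neither match nor mismatch; target N never matches
        mm <- mm + sum(r > 0L & (t == 0L | r != t))
        tpos <- tpos + n; rpos <- rpos + n
      } else if (op == "D") tpos <- tpos + n
      else if (op == "I") rpos <- rpos + n
    }
    mm
  }, integer(1))
}
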