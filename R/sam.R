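#' Import read alignments from a SAM file
#'
#' Converts plain-text SAM records into an `alignment_set` so alignments
#' produced by an external mapper (e.g., bwa) can feed the polymorphism
#' counter. Unmapped, secondary and supplementary records are skipped.
#' Supported CIGAR operations are `M`, `I`, `D`, `S`, `=` and `X`; soft
#' clips are trimmed from the stored sequence and `=`/`X` runs are merged
#' into `M`. Records with any other operation are skipped with a warning.
#' Mismatch counts are taken from the `NM` tag (minus indel bases) when
#' present.
#'
#' @param path path to a SAM file, or a character vector of SAM lines.
#' @param target_name reference sequence name the records must use; records
#'   aligned to a different reference raise an error.
#' @param target_length target length; taken from the `@SQ` header when
#'   absent.
#' @return An `alignment_set` (see [map_reads_ungapped()]).
#' @export
import_alignments <- function(path, target_name, target_length = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  hdr <- lines[startsWith(lines, "@")]
  recs <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (is.null(target_length)) {
    sq <- hdr[startsWith(hdr, "@SQ")]
    for (h in sq) {
      f <- strsplit(h, "\t", fixed = TRUE)[[1]]
      sn <- sub("^SN:", "", f[startsWith(f, "SN:")])
      if (length(sn) == 1L && sn == target_name) {
        target_length <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")]))
      }
    }
  }
  rows <- vector("list", 0L)
  n_skipped <- 0L
  for (rec in recs) {
    f <- strsplit(rec, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next                    # unmapped
    if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) next
    if (f[3] != target_name) {
      stop("record aligned to '", f[3], "', expected '", target_name, "'")
    }
    cigar <- f[6]
    p <- .parse_cigar(cigar)
    if (!all(p$ops %in% c("M", "I", "D", "S", "=", "X"))) {
      n_skipped <- n_skipped + 1L
      next
    }
    seq <- toupper(f[10])
    # trim soft clips
    if (p$ops[1] == "S") {
      seq <- substr(seq, p$lengths[1] + 1L, nchar(seq))
      p$ops <- p$ops[-1]; p$lengths <- p$lengths[-1]
    }
    k <- length(p$ops)
    if (k > 0L && p$ops[k] == "S") {
      seq <- substr(seq, 1L, nchar(seq) - p$lengths[k])
      p$ops <- p$ops[-k]; p$lengths <- p$lengths[-k]
    }
    p$ops[p$ops %in% c("=", "X")] <- "M"
    # merge adjacent identical ops
    keep_ops <- character(0); keep_len <- integer(0)
    for (j in seq_along(p$ops)) {
      if (length(keep_ops) > 0L && keep_ops[length(keep_ops)] == p$ops[j]) {
        keep_len[length(keep_len)] <- keep_len[length(keep_len)] + p$lengths[j]
      } else {
        keep_ops <- c(keep_ops, p$ops[j]); keep_len <- c(keep_len, p$lengths[j])
      }
    }
    cigar <- paste0(keep_len, keep_ops, collapse = "")
    nm <- NA_integer_
    tag <- f[startsWith(f, "NM:i:")]
    if (length(tag) == 1L) {
      indel_bases <- sum(keep_len[keep_ops %in% c("I", "D")])
      nm <- max(0L, as.integer(sub("^NM:i:", "", tag)) - indel_bases)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = f[1], start = as.integer(f[4]),
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      seq = seq, cigar = cigar, n_mismatch = nm, stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " record(s) skipped: unsupported CIGAR operation")
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    as.data.frame(.empty_alignments(0L))
  if (is.null(target_length)) {
    target_length <- if (nrow(out) > 0L)
      max(out$start + .cigar_target_span(out$cigar) - 1L) else 0L
  }
  structure(out, target_length = as.integer(target_length),
            class = c("alignment_set", "data.frame"))
}

#' Export an alignment set as SAM
#'
#' Writes alignments in plain-text SAM (CIGAR restricted to `M`/`I`/`D`;
#' 1-based target coordinates). The stored sequence is already in target
#' orientation, matching the SAM convention. The `NM` tag records mismatches
#' plus inserted and deleted bases.
#'
#' @param aln an `alignment_set`.
#' @param path output file path.
#' @param target_name reference name written in the header and records.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, target_name = "consensus") {
  L <- attr(aln, "target_length")
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             paste0("@SQ\tSN:", target_name, "\tLN:", L))
  if (nrow(aln) > 0L) {
    indel_bases <- vapply(aln$cigar, function(cg) {
      p <- .parse_cigar(cg)
      sum(p$lengths[p$ops %in% c("I", "D")])
    }, integer(1), USE.NAMES = FALSE)
    nm <- ifelse(is.na(aln$n_mismatch), 0L, aln$n_mismatch) + indel_bases
    lines <- c(lines, paste(
      aln$read_id, ifelse(aln$strand == "-", 16L, 0L), target_name,
      aln$start, 255L, aln$cigar, "*", 0L, 0L, aln$seq, "*",
      paste0("NM:i:", nm), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
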