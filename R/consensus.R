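# Per-position base counts from an alignment set.
# Returns a 5 x L integer matrix with rows A, C, G, T, N.
.pileup <- function(aln, target_length) {
  counts <- matrix(0L, 5L, target_length,
                   dimnames = list(c(.BASES, "N"), NULL))
  if (nrow(aln) == 0L) return(counts)
  simple <- grepl("^[0-9]+M$", aln$cigar)
  if (any(simple)) {
    lens <- nchar(aln$seq[simple])
    pos <- sequence(lens) + rep(aln$start[simple] - 1L, lens)
    codes <- unlist(strsplit(aln$seq[simple], "", fixed = TRUE),
                    use.names = FALSE)
    codes <- match(codes, .BASES)
    codes[is.na(codes)] <- 5L
    key <- (pos - 1L) * 5L + codes
    counts[] <- counts + tabulate(key, 5L * target_length)
  }
  for (i in which(!simple)) {
    p <- .parse_cigar(aln$cigar[i])
    tpos <- aln$start[i]; rpos <- 1L
    chars <- strsplit(aln$seq[i], "", fixed = TRUE)[[1]]
    for (j in seq_along(p$ops)) {
      op <- p$ops[j]; n <- p$lengths[j]
      if (op %in% c("M", "=", "X")) {
        codes <- match(chars[rpos:(rpos + n - 1L)], .BASES)
        codes[is.na(codes)] <- 5L
        key <- (seq.int(tpos, length.out = n) - 1L) * 5L + codes
        counts[] <- counts + tabulate(key, 5L * target_length)
        tpos <- tpos + n; rpos <- rpos + n
      } else if (op == "D") tpos <- tpos + n
      else if (op == "I") rpos <- rpos + n
    }
  }
  counts
}

#' Build an individual consensus by iterative majority calling
#'
#' Reference-guided assembly reduced to its essence: reads are mapped onto
#' the current template, the most frequent non-`N` base is called in every
#' column (ties broken in the fixed order A < C < G < T), and mapping is
#' repeated against the new call until the sequence stops changing (at most
#' `max_iter` rounds). Columns covered by no read are marked `N` and treated
#' as unassembled.
#'
#' @param reads a [read_set()] (typically after [collapse_duplicates()] and
#'   [quality_filter()]).
#' @param reference initial template sequence (e.g., the group reference).
#' @param relaxed use relaxed mismatch caps during mapping.
#' @param max_iter maximum number of map-and-call iterations.
#' @return An object of class `consensus_sequence`: list with `seq` (string,
#'   `N` at unassembled positions), `coverage` (integer vector of non-`N`
#'   read depth) and `iterations`.
#' @export
build_consensus <- function(reads, reference, relaxed = FALSE, max_iter = 5L) {
  template <- .as_sequence(reference)
  L <- nchar(template)
  aln <- NULL
  for (it in seq_len(max_iter)) {
    aln <- map_reads_ungapped(reads, template, relaxed)
    if (nrow(aln) == 0L) stop("empty assembly: no reads mapped to the template")
    counts <- .pileup(aln, L)
    base_counts <- counts[1:4, , drop = FALSE]
    coverage <- colSums(base_counts)
    call <- max.col(t(base_counts), ties.method = "first")  # A < C < G < T
    call[coverage == 0L] <- 0L
    new_template <- .decode_dna(call)
    if (identical(new_template, template)) {
      return(structure(list(seq = template, coverage = as.integer(coverage),
                            iterations = it), class = "consensus_sequence"))
    }
    template <- new_template
  }
  aln <- map_reads_ungapped(reads, template, relaxed)
  counts <- .pileup(aln, L)
  coverage <- colSums(counts[1:4, , drop = FALSE])
  structure(list(seq = template, coverage = as.integer(coverage),
                 iterations = max_iter), class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat("consensus_sequence:", nchar(x$seq), "bp;",
      sum(x$coverage == 0L), "unassembled position(s); mean coverage",
      round(mean(x$coverage), 1), "\n")
  invisible(x)
}

#' Associate consensus positions with a group reference
#'
#' Globally aligns an individual consensus against the group reference
#' (match +1, mismatch -1, gap open -4, gap extend -1, via
#' [Biostrings::pairwiseAlignment()]) and derives the position association:
#' every reference position is either matched to a consensus position or
#' absent (deleted in the consensus); consensus positions with no reference
#' partner are recorded as insertions.
#'
#' @param consensus the individual consensus (string or
#'   `consensus_sequence`).
#' @param reference the group reference sequence.
#' @return An object of class `coordinate_map`: list with `ref_to_cons`
#'   (integer vector of length `ref_length`, `NA` where the reference
#'   position is absent from the consensus), `insertions` (consensus
#'   positions with no reference partner), `n_inserted`, `n_deleted`,
#'   `ref_length`, `cons_length` and `identity` (fraction of aligned columns
#'   that match). A warning is raised when identity falls below 70%,
#'   suggesting a non-homologous assembly.
#' @export
align_to_reference <- function(consensus, reference) {
  cons <- .as_sequence(consensus)
  ref <- .as_sequence(reference)
  if (!nzchar(cons) || !nzchar(ref)) stop("sequences must be non-empty")
  mat <- matrix(-1, 5, 5, dimnames = list(c(.BASES, "N"), c(.BASES, "N")))
  diag(mat) <- 1
  mat["N", ] <- -1; mat[, "N"] <- -1   # unassembled columns never reward
  pa <- Biostrings::pairwiseAlignment(
    pattern = cons, subject = ref, type = "global",
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  pr <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_len <- nchar(ref); cons_len <- nchar(cons)
  ref_to_cons <- rep(NA_integer_, ref_len)
  insertions <- integer(0)
  ri <- 0L; ci <- 0L; n_match <- 0L
  for (k in seq_along(pc)) {
    c_gap <- pc[k] == "-"; r_gap <- pr[k] == "-"
    if (!c_gap) ci <- ci + 1L
    if (!r_gap) ri <- ri + 1L
    if (!c_gap && !r_gap) {
      ref_to_cons[ri] <- ci
      if (pc[k] == pr[k]) n_match <- n_match + 1L
    } else if (!c_gap && r_gap) {
      insertions <- c(insertions, ci)
    }
  }
  identity <- n_match / length(pc)
  if (identity < 0.70) {
    warning("possible non-homologous assembly: alignment identity ",
            sprintf("%.1f%%", 100 * identity))
  }
  structure(list(ref_to_cons = ref_to_cons, insertions = insertions,
                 n_inserted = length(insertions),
                 n_deleted = sum(is.na(ref_to_cons)),
                 ref_length = ref_len, cons_length = cons_len,
                 identity = identity),
            class = "coordinate_map")
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat("coordinate_map:", x$ref_length, "bp reference <->", x$cons_length,
      "bp consensus;", x$n_inserted, "inserted,", x$n_deleted,
      "deleted position(s)\n")
  invisible(x)
}

#' Read and write coordinate maps as TSV
#'
#' The matched-position table has columns `ref_pos`, `cons_pos` (`.` where
#' the reference position is absent) and `flag` (`M` matched, `DEL` absent);
#' insertion positions are appended as `flag = INS` rows with `ref_pos = .`.
#' Coordinates are 1-based and inclusive.
#'
#' @param cm a `coordinate_map`.
#' @param path file path.
#' @return `read_coordinate_map` returns a `coordinate_map`;
#'   `write_coordinate_map` returns `path` invisibly.
#' @export
write_coordinate_map <- function(cm, path) {
  df <- data.frame(
    ref_pos = c(as.character(seq_len(cm$ref_length)),
                rep(".", length(cm$insertions))),
    cons_pos = c(ifelse(is.na(cm$ref_to_cons), ".",
                        as.character(cm$ref_to_cons)),
                 as.character(cm$insertions)),
    flag = c(ifelse(is.na(cm$ref_to_cons), "DEL", "M"),
             rep("INS", length(cm$insertions))),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# coordinates: 1-based, inclusive; cons_length=",
                    cm$cons_length), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coordinate_map
#' @export
read_coordinate_map <- function(path) {
  first <- readLines(path, n = 1L)
  cons_length <- as.integer(sub(".*cons_length=", "", first))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  m <- df[df$flag %in% c("M", "DEL"), ]
  ins <- as.integer(df$cons_pos[df$flag == "INS"])
  ref_to_cons <- ifelse(m$cons_pos == ".", NA, m$cons_pos)
  ref_to_cons <- as.integer(ref_to_cons)
  structure(list(ref_to_cons = ref_to_cons, insertions = ins,
                 n_inserted = length(ins),
                 n_deleted = sum(is.na(ref_to_cons)),
                 ref_length = length(ref_to_cons),
                 cons_length = cons_length, identity = NA_real_),
            class = "coordinate_map")
}
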