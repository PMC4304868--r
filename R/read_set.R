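#' Construct a set of sequencing reads
#'
#' A `read_set` holds single-end reads as parallel vectors: identifiers,
#' base strings over `{A,C,G,T,N}` and per-base Phred quality scores.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of base strings (same length as `id`).
#' @param qual list of integer vectors of Phred scores, one per read, each the
#'   same length as the corresponding base string. A single number is recycled
#'   to a constant quality for every base of every read.
#' @return An object of class `read_set`.
#' @examples
#' rs <- read_set(c("r1", "r2"), c("ACGT", "GGGT"), 40)
#' length(rs)
#' @export
read_set <- function(id, seq, qual = 40L) {
  stopifnot(is.character(id), is.character(seq), length(id) == length(seq))
  seq <- toupper(seq)
  if (!is.list(qual)) {
    stopifnot(is.numeric(qual), length(qual) == 1L)
    qual <- lapply(nchar(seq), function(n) rep(as.integer(qual), n))
  }
  stopifnot(length(qual) == length(seq))
  qual <- lapply(qual, as.integer)
  nb <- nchar(seq)
  nq <- lengths(qual)
  if (any(nb != nq)) stop("base and quality lengths differ for some reads")
  if (any(unlist(qual, use.names = FALSE) < 0L)) stop("Phred scores must be >= 0")
  structure(list(id = id, seq = seq, qual = qual), class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
`[.read_set` <- function(x, i) {
  out <- list(id = x$id[i], seq = x$seq[i], qual = x$qual[i])
  attr(out, "truth") <- attr(x, "truth")
  class(out) <- "read_set"
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", length(x), "reads")
  if (length(x) > 0L) {
    cat("; lengths", min(nchar(x$seq)), "-", max(nchar(x$seq)), "bp")
  }
  cat("\n")
  invisible(x)
}

.mean_quals <- function(reads) {
  vapply(reads$qual, function(q) if (length(q)) mean(q) else NA_real_, numeric(1))
}

#' Read and write FASTQ files
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] converting between FASTQ (Phred+33) and
#' [read_set()] objects.
#'
#' @param path file path.
#' @param reads a `read_set`.
#' @return `read_fastq` returns a `read_set`; `write_fastq` returns `path`
#'   invisibly.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  qual <- unname(lapply(quals, function(q) as.integer(charToRaw(q)) - 33L))
  ids <- sub("\\s.*$", "", names(x))
  read_set(ids, unname(as.character(x)), qual)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$id
  qstr <- vapply(reads$qual, function(q) rawToChar(as.raw(pmin(q, 93L) + 33L)),
                 character(1))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qstr))
  invisible(path)
}

#' Read and write FASTA files
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
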