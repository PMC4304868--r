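# Internal helpers shared across modules. Bases are encoded A=1, C=2, G=3,
# T=4; anything else (N, gap markers) is 0 and is treated as "no call".

.BASES <- c("A", "C", "G", "T")

.encode_dna <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- match(chars, .BASES)
  m[is.na(m)] <- 0L
  as.integer(m)
}

# many sequences at once -> integer matrix (one row per sequence); all
# sequences must share one length
.encode_dna_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) <= 1L)
  if (length(x) == 0L) return(matrix(integer(0), 0L, 0L))
  chars <- unlist(strsplit(toupper(x), "", fixed = TRUE), use.names = FALSE)
  m <- match(chars, .BASES)
  m[is.na(m)] <- 0L
  matrix(as.integer(m), nrow = length(x), byrow = TRUE)
}

.decode_dna <- function(codes) {
  paste(c(.BASES, "N")[ifelse(codes == 0L, 5L, codes)], collapse = "")
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTacgtn", "TGCAtgcaN", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# reverse complement on the integer encoding (0 stays 0)
.revcomp_codes <- function(m) {
  rc <- ifelse(m == 0L, 0L, 5L - m)
  if (is.matrix(rc)) rc[, rev(seq_len(ncol(rc))), drop = FALSE] else rev(rc)
}

.seed_guard <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

.as_sequence <- function(x) {
  if (is.list(x) && !is.null(x$sequence)) x <- x$sequence
  if (inherits(x, "consensus_sequence")) x <- x$seq
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  toupper(x)
}
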