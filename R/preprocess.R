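#' Collapse exact-duplicate reads
#'
#' Reduces reads with identical base strings to a single representative,
#' retaining the copy with the highest mean Phred quality (ties broken by
#' first occurrence). Qualities are ignored when deciding what counts as a
#' duplicate; `N` bases compare as literal `N`. Output order is the order of
#' first occurrence.
#'
#' @param reads a [read_set()].
#' @return A `read_set` with one record per distinct base string.
#' @examples
#' rs <- read_set(c("a", "b"), c("ACGT", "ACGT"), list(rep(32L, 4), rep(28L, 4)))
#' collapse_duplicates(rs)$id   # keeps "a", the higher-quality copy
#' @export
collapse_duplicates <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  if (length(reads) == 0L) return(reads)
  mq <- .mean_quals(reads)
  grp <- match(reads$seq, unique(reads$seq))
  # split() on the integer group keys orders groups 1..k, i.e. by first
  # occurrence, so `best` already follows first-occurrence order
  best <- vapply(split(seq_along(grp), grp),
                 function(ix) ix[which.max(mq[ix])], integer(1))
  reads[best]
}

#' Quality-filter and mask reads
#'
#' Removes reads whose mean Phred quality is strictly below `min_mean_q`, then
#' converts bases with quality strictly below `min_base_q` to `N` in the
#' surviving reads (their quality values are preserved). Mean quality is the
#' arithmetic mean of raw Phred scores.
#'
#' @param reads a [read_set()].
#' @param min_mean_q reads with mean Phred below this are dropped (default 20).
#' @param min_base_q bases with Phred below this are masked to `N`
#'   (default 20).
#' @return A filtered `read_set`.
#' @export
quality_filter <- function(reads, min_mean_q = 20, min_base_q = 20) {
  stopifnot(inherits(reads, "read_set"))
  if (length(reads) == 0L) return(reads)
  keep <- .mean_quals(reads) >= min_mean_q
  out <- reads[keep]
  if (length(out) == 0L) return(out)
  low <- vapply(out$qual, function(q) any(q < min_base_q), logical(1))
  if (any(low)) {
    out$seq[low] <- vapply(which(low), function(i) {
      chars <- strsplit(out$seq[i], "", fixed = TRUE)[[1]]
      chars[out$qual[[i]] < min_base_q] <- "N"
      paste(chars, collapse = "")
    }, character(1))
  }
  out
}
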