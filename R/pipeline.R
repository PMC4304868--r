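#' Full per-sample polymorphism pipeline
#'
#' Runs the complete single-sample chain: collapse exact-duplicate reads,
#' quality-filter and mask, build the individual consensus by iterative
#' majority calling against the group reference, associate consensus
#' positions with the reference, map the read pool back onto the consensus,
#' and profile every reference position against the polymorphism thresholds.
#'
#' @param reads a [read_set()] of raw reads for one individual.
#' @param reference the group reference sequence (string).
#' @param th a [thresholds()] object.
#' @param relaxed use relaxed mismatch caps throughout.
#' @param collapse collapse exact duplicates before assembly (default TRUE).
#' @param min_mean_q,min_base_q quality-filter settings (see
#'   [quality_filter()]).
#' @param sample_id label stored with the profile.
#' @return List of class `sample_result` with `profile`
#'   (a `polymorphism_profile`), `consensus`, `coordmap` and `alignments`.
#' @export
profile_reads <- function(reads, reference, th = thresholds(),
                          relaxed = FALSE, collapse = TRUE,
                          min_mean_q = 20, min_base_q = 20,
                          sample_id = "sample") {
  pool <- reads
  if (isTRUE(collapse)) pool <- collapse_duplicates(pool)
  pool <- quality_filter(pool, min_mean_q, min_base_q)
  cons <- build_consensus(pool, reference, relaxed = relaxed)
  cm <- align_to_reference(cons, reference)
  aln <- map_reads_ungapped(pool, cons, relaxed = relaxed)
  prof <- profile_sample(aln, cons, cm, th, sample_id)
  structure(list(profile = prof, consensus = cons, coordmap = cm,
                 alignments = aln), class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  p <- x$profile
  cat("sample", attr(p, "sample_id"), "-",
      attr(p, "n_poly"), "polymorphic and", attr(p, "n_high"),
      "highly polymorphic of", attr(p, "n_sequenced"),
      "sequenced positions\n")
  cat(sprintf("  (%.2f%% polymorphic, %.2f%% highly polymorphic)\n",
              attr(p, "pct_poly"), attr(p, "pct_high")))
  invisible(x)
}
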