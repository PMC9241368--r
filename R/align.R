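#' Local alignment statistics between a query and a subject sequence
#'
#' Computes the best affine-gap local alignment of `query` against `subject`
#' (defaults: match +1, mismatch -2, gap open -5, gap extend -2; a gap of
#' length L costs `gap_open + L * gap_extend`) and summarises it the way a
#' blastn user would read a hit table: percent identity over aligned columns
#' and percent coverage of the query. When `merge_hits = TRUE` the unaligned
#' query remainders flanking the best hit are re-aligned recursively against
#' the full subject, and non-overlapping (on the query) secondary hits are
#' merged into the coverage and identity totals. This models a fragmented old
#' element hit by several HSPs.
#'
#' @param query,subject DNA sequences (character or [Biostrings::DNAString]).
#' @param match,mismatch,gap_open,gap_extend Alignment scores; penalties are
#'   negative.
#' @param merge_hits Merge secondary non-overlapping hits into coverage.
#' @param min_hit_len Minimum query-remainder length worth re-aligning.
#' @param min_hit_score Minimum local score for a secondary hit to count;
#'   guards against spurious short matches in random sequence.
#' @param subject_coverage Also report coverage of the subject (for the
#'   reciprocal-coverage variant of the 80-80 rule).
#' @return A list with `identity_pct`, `coverage_pct`, `aln_length` (total
#'   aligned columns over merged hits), `score` (best single local hit),
#'   `n_hits`, and optionally `subject_coverage_pct`.
#' @examples
#' local_align_stats("ACGTACGTACGT", "ACGTACGTACGT")$identity_pct
#' @export
local_align_stats <- function(query, subject, match = 1, mismatch = -2,
                              gap_open = -5, gap_extend = -2,
                              merge_hits = TRUE, min_hit_len = 30L,
                              min_hit_score = 16, subject_coverage = FALSE) {
  q <- as_seq_chr(query)[1L]
  s <- as_seq_chr(subject)[1L]
  if (!nzchar(q) || !nzchar(s)) stop("query and subject must be non-empty")
  qlen <- nchar(q)

  # fast paths: exact equality / exact substring, the common case for
  # error-free simulations and identical SV calls
  if (q == s || grepl(q, s, fixed = TRUE)) {
    return(list(identity_pct = 100, coverage_pct = 100, aln_length = qlen,
                score = match * qlen, n_hits = 1L,
                subject_coverage_pct = if (subject_coverage)
                  100 * qlen / nchar(s) else NULL))
  }

  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA")

  align_one <- function(qseg) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = qseg, subject = s, type = "local",
      substitutionMatrix = submat,
      gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
    qr <- Biostrings::pattern(pa)
    list(score = Biostrings::score(pa),
         qstart = Biostrings::start(qr), qend = Biostrings::end(qr),
         sstart = Biostrings::start(Biostrings::subject(pa)),
         send = Biostrings::end(Biostrings::subject(pa)),
         nmatch = Biostrings::nmatch(pa),
         ncols = nchar(as.character(Biostrings::alignedPattern(pa))))
  }

  hits <- list()
  # recursively align query segments left/right of accepted hits
  stack <- list(c(1L, qlen))
  first <- TRUE
  while (length(stack)) {
    seg <- stack[[1L]]; stack <- stack[-1L]
    if (seg[2L] - seg[1L] + 1L < min_hit_len && !first) next
    h <- align_one(substr(q, seg[1L], seg[2L]))
    accept <- if (first) h$score > 0 else h$score >= min_hit_score
    first <- FALSE
    if (!accept || h$qend < h$qstart) next
    h$qstart <- h$qstart + seg[1L] - 1L
    h$qend <- h$qend + seg[1L] - 1L
    hits[[length(hits) + 1L]] <- h
    if (merge_hits) {
      if (h$qstart - seg[1L] >= min_hit_len)
        stack[[length(stack) + 1L]] <- c(seg[1L], h$qstart - 1L)
      if (seg[2L] - h$qend >= min_hit_len)
        stack[[length(stack) + 1L]] <- c(h$qend + 1L, seg[2L])
    }
  }

  if (!length(hits)) {
    return(list(identity_pct = 0, coverage_pct = 0, aln_length = 0L,
                score = 0, n_hits = 0L,
                subject_coverage_pct = if (subject_coverage) 0 else NULL))
  }
  qcov <- sum(vapply(hits, function(h) h$qend - h$qstart + 1L, integer(1)))
  ncols <- sum(vapply(hits, function(h) h$ncols, numeric(1)))
  nmatch <- sum(vapply(hits, function(h) h$nmatch, numeric(1)))
  scov <- NULL
  if (subject_coverage) {
    sint <- IRanges::reduce(IRanges::IRanges(
      start = vapply(hits, function(h) h$sstart, numeric(1)),
      end = vapply(hits, function(h) h$send, numeric(1))))
    scov <- 100 * sum(IRanges::width(sint)) / nchar(s)
  }
  list(identity_pct = 100 * nmatch / ncols,
       coverage_pct = 100 * qcov / qlen,
       aln_length = as.integer(ncols),
       score = hits[[1L]]$score,
       n_hits = length(hits),
       subject_coverage_pct = scov)
}
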