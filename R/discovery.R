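# Collation of per-reference SV calls into a nonredundant TIP locus set,
# and the aligned/unaligned region partition of the anchor genome.

#' Collate classified insertions into a nonredundant TIP locus set
#'
#' SVs (projected onto one anchor genome; a deletion in the anchor is the
#' same locus as the matching insertion carried by the other genome) are
#' merged when their anchor positions differ by at most `merge_window` bp
#' and their sequences reach `merge_similarity` percent identity over an
#' alignment covering at least that fraction of the shorter sequence. The
#' longest sequence represents each locus; `support` lists every
#' contributing (source genome, sv_type). Input order does not affect the
#' result: records are processed in (contig, position, sequence) order.
#'
#' @param svs data.frame with columns `source_genome`, `contig`, `position`
#'   (0-based insertion point), `sequence`, and optionally `sv_type`,
#'   `te_id`, `superfamily`.
#' @param merge_window Maximum position difference for merging (bp).
#' @param merge_similarity Minimum percent identity (and coverage of the
#'   shorter sequence) for merging.
#' @param known_contigs Optional contig names; SVs on other contigs raise an
#'   error listing the offenders.
#' @param gene_models Optional list of [gene_model()]s; when supplied each
#'   locus gets a genic `context`/`gene_id` and, unless
#'   `keep_intergenic = TRUE`, intergenic loci are dropped (the method
#'   tracks TIPs in genic regions: gene body plus 2 kb flanks).
#' @param flank Genic flank width passed to [assign_genic_context()].
#' @param keep_intergenic Keep intergenic loci when gene models are given.
#' @return data.frame of TIP loci sorted by (contig, position) with columns
#'   locus_id, contig, position, te_id, superfamily, te_length, sequence,
#'   support_count, sources, plus context/gene_id when annotated; the full
#'   support list is in `attr(x, "support")`.
#' @export
collate_insertions <- function(svs, merge_window = 100L,
                               merge_similarity = 80,
                               known_contigs = NULL, gene_models = NULL,
                               flank = 2000L, keep_intergenic = FALSE) {
  need <- c("source_genome", "contig", "position", "sequence")
  if (!all(need %in% names(svs)))
    stop("`svs` must have columns: ", paste(need, collapse = ", "))
  if (!is.null(known_contigs)) {
    bad <- setdiff(unique(svs$contig), known_contigs)
    if (length(bad))
      stop("SVs on unknown contigs: ", paste(bad, collapse = ", "))
  }
  svs$position <- as.integer(svs$position)
  if (!"sv_type" %in% names(svs)) svs$sv_type <- "insertion"
  if (!"te_id" %in% names(svs)) svs$te_id <- NA_character_
  if (!"superfamily" %in% names(svs)) svs$superfamily <- NA_character_

  svs <- svs[order(svs$contig, svs$position, svs$sequence), , drop = FALSE]

  loci <- list()   # each: contig, position, sequence, te_id, superfamily, support
  for (i in seq_len(nrow(svs))) {
    row <- svs[i, ]
    merged <- FALSE
    for (j in rev(seq_along(loci))) {       # recent loci are nearest in sort order
      loc <- loci[[j]]
      if (loc$contig != row$contig) break
      if (abs(loc$position - row$position) > merge_window) next
      if (sequences_similar(loc$sequence, row$sequence, merge_similarity)) {
        loc$support[[length(loc$support) + 1L]] <-
          list(source_genome = row$source_genome, sv_type = row$sv_type)
        if (nchar(row$sequence) > nchar(loc$sequence)) {
          loc$sequence <- row$sequence
          loc$position <- row$position
          loc$te_id <- row$te_id
          loc$superfamily <- row$superfamily
        }
        loci[[j]] <- loc
        merged <- TRUE
        break
      }
    }
    if (!merged)
      loci[[length(loci) + 1L]] <- list(
        contig = row$contig, position = row$position,
        sequence = row$sequence, te_id = row$te_id,
        superfamily = row$superfamily,
        support = list(list(source_genome = row$source_genome,
                            sv_type = row$sv_type)))
  }

  out <- data.frame(
    contig = vapply(loci, `[[`, character(1), "contig"),
    position = vapply(loci, `[[`, integer(1), "position"),
    te_id = vapply(loci, `[[`, character(1), "te_id"),
    superfamily = vapply(loci, `[[`, character(1), "superfamily"),
    sequence = vapply(loci, `[[`, character(1), "sequence"),
    support_count = vapply(loci, function(l) length(l$support), integer(1)),
    stringsAsFactors = FALSE)
  out$te_length <- nchar(out$sequence)
  ord <- order(out$contig, out$position)
  out <- out[ord, , drop = FALSE]
  support <- lapply(loci, `[[`, "support")[ord]
  out$sources <- vapply(support, function(s)
    paste(vapply(s, `[[`, character(1), "source_genome"), collapse = ";"),
    character(1))
  out$locus_id <- sprintf("TIP%05d", seq_len(nrow(out)))
  out <- out[, c("locus_id", "contig", "position", "te_id", "superfamily",
                 "te_length", "sequence", "support_count", "sources")]
  rownames(out) <- NULL

  if (!is.null(gene_models)) {
    ctx <- lapply(seq_len(nrow(out)), function(i)
      assign_genic_context(out$contig[i], out$position[i], gene_models,
                           flank = flank))
    out$context <- vapply(ctx, `[[`, character(1), "context")
    out$gene_id <- vapply(ctx, `[[`, character(1), "gene_id")
    if (!keep_intergenic) {
      keep <- out$context != "intergenic"
      support <- support[keep]
      out <- out[keep, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "support") <- support
  out
}

#' Do two SV sequences represent the same insertion?
#' @noRd
sequences_similar <- function(a, b, min_identity) {
  if (a == b) return(TRUE)
  shorter <- if (nchar(a) <= nchar(b)) a else b
  longer <- if (nchar(a) <= nchar(b)) b else a
  st <- local_align_stats(shorter, longer)
  st$identity_pct >= min_identity && st$coverage_pct >= min_identity
}

#' Read an aligned-region map from a BED file
#'
#' The BED intervals (0-based half-open) mark the parts of the anchor genome
#' covered by whole-genome alignment ("aligned regions"); everything else is
#' "unaligned". Malformed lines raise an error naming the line number.
#'
#' @param path BED file (>= 3 columns: contig, start, end).
#' @return A `region_map`: named list of [IRanges::IRanges] per contig.
#' @export
read_region_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  df <- list(contig = character(0), start = numeric(0), end = numeric(0))
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed BED at line ", i, ": fewer than 3 columns")
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || e <= s)
      stop("malformed BED at line ", i, ": bad interval [", f[2L], ", ",
           f[3L], ")")
    df$contig <- c(df$contig, f[1L])
    df$start <- c(df$start, s)
    df$end <- c(df$end, e)
  }
  region_map(data.frame(contig = df$contig, start = df$start, end = df$end,
                        stringsAsFactors = FALSE))
}

#' Build a region map from an interval data.frame
#'
#' @param intervals data.frame with `contig`, `start`, `end` (0-based
#'   half-open aligned intervals).
#' @return Named list of reduced, sorted [IRanges::IRanges] (1-based closed).
#' @export
region_map <- function(intervals) {
  out <- lapply(split(intervals, intervals$contig), function(d)
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end)))
  structure(out, class = "region_map")
}

#' Tag TIP loci as aligned or unaligned
#'
#' A locus is `aligned` iff its 0-based insertion point falls inside an
#' aligned interval of its contig; loci on contigs absent from the map are
#' `unaligned`.
#'
#' @param loci data.frame with `contig` and `position`.
#' @param map A `region_map` (see [region_map()], [read_region_bed()]).
#' @return Character vector "aligned"/"unaligned", one per locus.
#' @export
tag_region <- function(loci, map) {
  vapply(seq_len(nrow(loci)), function(i) {
    iv <- map[[loci$contig[i]]]
    if (is.null(iv)) return("unaligned")
    p <- loci$position[i] + 1L  # 0-based point -> 1-based base
    hit <- IRanges::countOverlaps(
      IRanges::IRanges(start = p, width = 1L), iv) > 0L
    if (hit) "aligned" else "unaligned"
  }, character(1))
}
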