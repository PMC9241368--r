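# TE classification of structural-variant sequences (the 80-80 rule),
# genic-context annotation, and SNP effect classification.

#' Normalise a TE library to (seqs, info) form
#' @noRd
as_te_library <- function(library) {
  if (is.list(library) && !is.null(library$seqs) && !is.null(library$info))
    return(library)
  seqs <- if (inherits(library, "DNAStringSet")) library
          else Biostrings::DNAStringSet(as_seq_chr(library))
  nm <- names(seqs)
  if (is.null(nm)) stop("TE library sequences must be named")
  m <- regmatches(nm, regexec("^([^#[:space:]]+)#?([^[:space:]]*)", nm))
  ids <- vapply(m, `[`, character(1), 2L)
  fams <- vapply(m, `[`, character(1), 3L)
  fams[!nzchar(fams)] <- "unknown"
  list(seqs = seqs,
       info = data.frame(te_id = ids, superfamily = fams,
                         length = Biostrings::width(seqs),
                         stringsAsFactors = FALSE))
}

#' Read / write a TE library FASTA
#'
#' Headers follow the `id#superfamily` convention (regex
#' `^([^#\\s]+)#?([^\\s]*)`); records without a `#` token get superfamily
#' "unknown".
#' @param path FASTA file.
#' @return A TE library list with `seqs` and `info`.
#' @export
read_te_library <- function(path) {
  as_te_library(Biostrings::readDNAStringSet(path))
}

#' @rdname read_te_library
#' @param library TE library (list or named DNAStringSet).
#' @export
write_te_library <- function(library, path) {
  lib <- as_te_library(library)
  seqs <- lib$seqs
  names(seqs) <- paste0(lib$info$te_id, "#", lib$info$superfamily)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Classify one SV sequence against a TE library under the 80-80 rule
#'
#' The sequence is a TE copy when the best library hit reaches both
#' `id_min` percent identity (over aligned columns) and `cov_min` percent
#' coverage of the SV (query) sequence. Ties between equally good hits are
#' broken by higher identity, then longer alignment, then lexicographic
#' te_id. Candidate elements are pre-screened by shared k-mer counts so only
#' promising library elements are aligned.
#'
#' @param sequence SV sequence (character or DNAString).
#' @param library TE library (see [read_te_library()]).
#' @param id_min,cov_min Thresholds in percent (defaults 80/80).
#' @param reciprocal If TRUE, also require `cov_min` coverage of the library
#'   element (reciprocal-coverage variant); default FALSE (query-only).
#' @param screen_k k-mer size for candidate screening.
#' @param max_candidates Maximum number of screened elements to align.
#' @return A one-row data.frame with `te_id`, `superfamily`, `identity_pct`,
#'   `coverage_pct`, `aln_length`, `classified` (logical) and `reason`
#'   (NA when classified).
#' @export
classify_te <- function(sequence, library, id_min = 80, cov_min = 80,
                        reciprocal = FALSE, screen_k = 13L,
                        max_candidates = 5L) {
  lib <- as_te_library(library)
  if (!length(lib$seqs)) stop("TE library is empty")
  seq <- as_seq_chr(sequence)[1L]
  none <- function(reason)
    data.frame(te_id = NA_character_, superfamily = NA_character_,
               identity_pct = NA_real_, coverage_pct = NA_real_,
               aln_length = NA_integer_, classified = FALSE, reason = reason,
               stringsAsFactors = FALSE)
  if (nchar(seq) < 50L) return(none("below minimum length"))

  cand <- screen_candidates(seq, lib, k = screen_k)
  if (!length(cand)) return(none("no hit"))
  cand <- cand[seq_len(min(length(cand), max_candidates))]

  hits <- lapply(cand, function(i) {
    st <- local_align_stats(seq, lib$seqs[[i]],
                            subject_coverage = reciprocal)
    ok <- st$identity_pct >= id_min && st$coverage_pct >= cov_min
    if (ok && reciprocal) ok <- st$subject_coverage_pct >= cov_min
    if (!ok) return(NULL)
    data.frame(te_id = lib$info$te_id[i],
               superfamily = lib$info$superfamily[i],
               identity_pct = st$identity_pct,
               coverage_pct = st$coverage_pct,
               aln_length = st$aln_length, classified = TRUE,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) return(none("no hit"))
  hits <- hits[order(-hits$identity_pct, -hits$aln_length, hits$te_id), ,
               drop = FALSE]
  hits[1L, , drop = FALSE]
}

#' Rank library elements by shared k-mers with the query
#' @noRd
screen_candidates <- function(seq, lib, k = 13L) {
  n <- nchar(seq)
  if (n < k) return(seq_along(lib$seqs))
  qk <- unique(substring(seq, 1:(n - k + 1L), k:n))
  counts <- vapply(seq_along(lib$seqs), function(i) {
    s <- as.character(lib$seqs[[i]])
    m <- nchar(s)
    if (m < k) return(0L)
    sum(qk %in% substring(s, 1:(m - k + 1L), k:m))
  }, integer(1))
  ord <- order(-counts, lib$info$te_id)
  ord[counts[ord] > 0L]
}

#' Classify a table of SV records
#'
#' Vectorised wrapper around [classify_te()] with an exact-sequence fast
#' path (identical SV sequences are classified once).
#'
#' @param svs data.frame with at least `sequence`; other columns are carried
#'   through.
#' @inheritParams classify_te
#' @return `svs` with classification columns bound on; unclassified rows
#'   have `classified = FALSE` and a `reason`.
#' @export
classify_sv_table <- function(svs, library, id_min = 80, cov_min = 80,
                              reciprocal = FALSE) {
  stopifnot(is.data.frame(svs), "sequence" %in% names(svs))
  uniq <- !duplicated(svs$sequence)
  res_u <- do.call(rbind, lapply(svs$sequence[uniq], classify_te,
                                 library = library, id_min = id_min,
                                 cov_min = cov_min, reciprocal = reciprocal))
  idx <- match(svs$sequence, svs$sequence[uniq])
  cbind(svs, res_u[idx, , drop = FALSE], row.names = NULL)
}

#' Construct a gene model
#'
#' Coordinates are 0-based half-open throughout. Exon and CDS intervals are
#' two-column matrices (start, end); intervals must be sorted and
#' non-overlapping and every CDS interval must lie inside an exon. Introns
#' are the gene span minus the exons.
#'
#' @param gene_id,contig,strand Gene identity; strand is "+" or "-".
#' @param start,end Gene span, 0-based half-open.
#' @param exons,cds Interval matrices; `cds` defaults to `exons`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, start, end,
                       exons = NULL, cds = NULL) {
  stopifnot(strand %in% c("+", "-"), end > start)
  if (is.null(exons)) exons <- matrix(c(start, end), ncol = 2L)
  if (is.null(cds)) cds <- exons
  check_iv <- function(iv, name) {
    iv <- matrix(as.integer(iv), ncol = 2L)
    if (any(iv[, 2L] <= iv[, 1L])) stop(name, " intervals must be non-empty")
    if (is.unsorted(iv[, 1L], strictly = TRUE) && nrow(iv) > 1L)
      stop(name, " intervals must be sorted")
    if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      stop(name, " intervals must be non-overlapping")
    if (any(iv[, 1L] < start) || any(iv[, 2L] > end))
      stop(name, " intervals must lie within the gene span")
    iv
  }
  exons <- check_iv(exons, "exon")
  cds <- check_iv(cds, "CDS")
  # every CDS interval inside some exon
  inside <- vapply(seq_len(nrow(cds)), function(i)
    any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L]), logical(1))
  if (!all(inside)) stop("CDS intervals must lie within exons")
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 exons = exons, cds = cds),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Converts gene/exon/CDS features into [gene_model()] objects (GFF 1-based
#' closed coordinates become 0-based half-open).
#' @param path GFF3 file.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  lapply(stats::setNames(seq_len(nrow(genes)), genes$ID), function(i) {
    g <- genes[i, ]
    # exons/CDS may be parented to an mRNA; accept any feature on the span
    sub <- df[df$seqnames == g$seqnames & df$start >= g$start &
                df$end <= g$end, , drop = FALSE]
    ex <- sub[sub$type == "exon", c("start", "end"), drop = FALSE]
    cd <- sub[sub$type == "CDS", c("start", "end"), drop = FALSE]
    to0 <- function(x) if (nrow(x))
      matrix(c(x$start - 1L, x$end), ncol = 2L)[order(x$start), , drop = FALSE]
      else NULL
    gene_model(g$ID, as.character(g$seqnames), as.character(g$strand),
               g$start - 1L, g$end, exons = to0(ex), cds = to0(cd))
  })
}

#' Assign genic context to a genomic position
#'
#' Classifies a 0-based insertion point as `CDS`, `intron`, `upstream2kb`,
#' `downstream2kb` or `intergenic` relative to a set of gene models, with
#' precedence CDS > intron > upstream2kb > downstream2kb when several apply.
#' Upstream/downstream are strand-aware. Positions inside the gene body that
#' fall in non-coding exon sequence (UTRs) are reported as `intron`
#' (gene-body non-coding). Among genes matching at equal precedence the one
#' with the nearest gene start wins.
#'
#' @param contig Contig name.
#' @param position 0-based point.
#' @param gene_models List of [gene_model()] objects.
#' @param flank Flank width in bp defining upstream/downstream (default 2000).
#' @param contig_lengths Optional named vector for bounds checking.
#' @return List with `context` and `gene_id` (NA for intergenic).
#' @export
assign_genic_context <- function(contig, position, gene_models,
                                 flank = 2000L, contig_lengths = NULL) {
  position <- as.integer(position)
  if (!is.null(contig_lengths)) {
    L <- contig_lengths[[contig]]
    if (is.null(L) || is.na(L) || position < 0L || position >= L)
      stop("position outside contig bounds")
  } else if (position < 0L) stop("position outside contig bounds")

  best <- NULL
  best_rank <- 5L
  best_dist <- Inf
  ranks <- c(CDS = 1L, intron = 2L, upstream2kb = 3L, downstream2kb = 4L)
  for (gm in gene_models) {
    if (gm$contig != contig) next
    ctx <- NULL
    if (position >= gm$start && position < gm$end) {
      in_cds <- any(gm$cds[, 1L] <= position & position < gm$cds[, 2L])
      ctx <- if (in_cds) "CDS" else "intron"
    } else {
      before <- position < gm$start && position >= gm$start - flank
      after <- position >= gm$end && position < gm$end + flank
      if (before) ctx <- if (gm$strand == "+") "upstream2kb" else "downstream2kb"
      if (after) ctx <- if (gm$strand == "+") "downstream2kb" else "upstream2kb"
    }
    if (is.null(ctx)) next
    rank <- ranks[[ctx]]
    dist <- abs(position - gm$start)
    if (rank < best_rank || (rank == best_rank && dist < best_dist)) {
      best <- list(context = ctx, gene_id = gm$gene_id)
      best_rank <- rank
      best_dist <- dist
    }
  }
  if (is.null(best)) list(context = "intergenic", gene_id = NA_character_)
  else best
}

#' Classify a SNP as synonymous / nonsynonymous / noncoding
#'
#' Translates the codon containing the site before and after the
#' substitution (strand-aware, standard nuclear code). A change preserving
#' the amino acid (including stop) is synonymous.
#'
#' @param contig Contig name.
#' @param pos 0-based position of the substituted base.
#' @param ref,alt Reference and alternate bases on the forward genome strand.
#' @param gene A [gene_model()].
#' @param genome Named character vector / DNAStringSet of contigs.
#' @return "synonymous", "nonsynonymous" or "noncoding".
#' @export
classify_snp_effect <- function(contig, pos, ref, alt, gene, genome) {
  genome <- as_seq_chr(genome)
  gseq <- genome[[contig]]
  pos <- as.integer(pos)
  base_at <- substr(gseq, pos + 1L, pos + 1L)
  if (base_at != toupper(ref))
    stop("ref base mismatch at position ", pos, ": genome has ", base_at)
  if (gene$contig != contig ||
      !any(gene$cds[, 1L] <= pos & pos < gene$cds[, 2L]))
    return("noncoding")

  widths <- gene$cds[, 2L] - gene$cds[, 1L]
  if (sum(widths) %% 3L != 0L)
    stop("CDS length of gene ", gene$gene_id, " is not divisible by 3")
  iv <- which(gene$cds[, 1L] <= pos & pos < gene$cds[, 2L])
  offset_fwd <- sum(widths[seq_len(iv - 1L)]) + (pos - gene$cds[iv, 1L])

  cds_fwd <- paste(substring(gseq, gene$cds[, 1L] + 1L, gene$cds[, 2L]),
                   collapse = "")
  if (gene$strand == "+") {
    cds <- cds_fwd
    cpos <- offset_fwd            # 0-based within CDS
    ref_c <- toupper(ref); alt_c <- toupper(alt)
  } else {
    cds <- revcomp_chr(cds_fwd)
    cpos <- sum(widths) - 1L - offset_fwd
    ref_c <- revcomp_chr(toupper(ref)); alt_c <- revcomp_chr(toupper(alt))
  }
  ci <- cpos %/% 3L
  within <- cpos %% 3L
  codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  stopifnot(substr(codon, within + 1L, within + 1L) == ref_c)
  codon_alt <- codon
  substr(codon_alt, within + 1L, within + 1L) <- alt_c
  aa <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  if (identical(aa, aa_alt)) "synonymous" else "nonsynonymous"
}

#' Nonsynonymous / synonymous SNP ratio
#'
#' @param effects Character vector of "synonymous"/"nonsynonymous" calls
#'   (other values are ignored).
#' @return List with `ratio` (NA when undefined), counts, and `status`:
#'   "ok", "undefined" (nonsynonymous present but no synonymous) or "empty".
#' @export
ns_s_ratio <- function(effects) {
  n_n <- sum(effects == "nonsynonymous")
  n_s <- sum(effects == "synonymous")
  if (n_n == 0L && n_s == 0L)
    return(list(ratio = NA_real_, n_nonsyn = 0L, n_syn = 0L,
                status = "empty"))
  if (n_s == 0L)
    return(list(ratio = NA_real_, n_nonsyn = n_n, n_syn = 0L,
                status = "undefined"))
  list(ratio = n_n / n_s, n_nonsyn = n_n, n_syn = n_s, status = "ok")
}
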