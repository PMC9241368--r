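# Genotyping of TIP loci from short paired-end reads.
#
# Every locus is genotyped against two small references: the "present"
# construct (up to 1 kb left flank + TE + up to 1 kb right flank) and the
# companion "absent" construct (the two flanks joined), so junction-spanning
# logic is symmetric for both alleles. Alignment intervals are 0-based
# half-open on the construct.

#' Build the genotyping construct for a TIP locus
#'
#' Extracts up to `flank` bp of anchor-genome sequence on each side of the
#' 0-based insertion point and concatenates left flank + TE + right flank.
#' Flanks are truncated (never padded) at contig ends and the realised
#' lengths recorded. `junctionL` is the 0-based offset of the first TE base,
#' `junctionR` the offset just past the TE. The companion TE-absent sequence
#' (flanks joined, junction at `absent_junction`) is carried along for
#' absence-evidence mapping.
#'
#' @param locus List or one-row data.frame with `locus_id`, `contig`,
#'   `position` (0-based) and `sequence` (the TE).
#' @param anchor_genome Named character vector / DNAStringSet of contigs.
#' @param flank Maximum flank length in bp (default 1000).
#' @return An object of class `locus_construct`.
#' @export
build_locus_construct <- function(locus, anchor_genome, flank = 1000L) {
  genome <- as_seq_chr(anchor_genome)
  te <- toupper(as.character(locus$sequence))
  if (!nzchar(te)) stop("TE sequence of locus ", locus$locus_id, " is empty")
  g <- genome[[locus$contig]]
  if (is.null(g) || is.na(g)) stop("contig ", locus$contig, " not in genome")
  L <- nchar(g)
  pos <- as.integer(locus$position)
  if (pos < 0L || pos > L) stop("locus position outside genome bounds")
  lf_start <- max(0L, pos - flank)
  rf_end <- min(L, pos + flank)
  left <- substr(g, lf_start + 1L, pos)
  right <- substr(g, pos + 1L, rf_end)
  lf <- nchar(left); rf <- nchar(right)
  structure(list(
    locus_id = locus$locus_id,
    sequence = paste0(left, te, right),
    absent_sequence = paste0(left, right),
    left_flank_len = lf, right_flank_len = rf,
    te_length = nchar(te),
    junctionL = lf, junctionR = lf + nchar(te),
    absent_junction = lf), class = "locus_construct")
}

#' Build an exact k-mer index over target sequences
#' @noRd
kmer_index <- function(seqs, k = 21L) {
  seqs <- as_seq_chr(seqs)
  stopifnot(!is.null(names(seqs)))
  parts <- lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[i])
    if (L < k) return(NULL)
    starts <- 1:(L - k + 1L)
    list(km = substring(seqs[i], starts, starts + k - 1L),
         tid = rep.int(i, length(starts)), pos = starts)
  })
  km <- unlist(lapply(parts, `[[`, "km"), use.names = FALSE)
  tid <- unlist(lapply(parts, `[[`, "tid"), use.names = FALSE)
  pos <- unlist(lapply(parts, `[[`, "pos"), use.names = FALSE)
  list(k = k, targets = names(seqs), seqs = unname(seqs),
       lengths = nchar(seqs), tid = tid, pos = pos,
       lookup = split(seq_along(km), km))
}

#' Map reads against an index: exact k-mer seeding + ungapped local extension
#'
#' Seeds at up to three offsets per read; candidate placements are verified
#' by direct comparison and trimmed to the maximal-scoring ungapped segment
#' (match +1 / mismatch -2). All co-optimal placements of a read are kept so
#' that reads from sequence shared between targets (e.g. a flank present in
#' both the TE-present and TE-absent constructs) contribute to each.
#'
#' @param index From `kmer_index()`.
#' @param reads Named character vector (names carry pair id + mate).
#' @param pair_id,mate Parallel vectors identifying read pairs.
#' @param min_aln Alignments with fewer matched bases than this are dropped.
#' @param max_mm_frac Maximum mismatch fraction within the trimmed segment.
#' @return data.frame: pair_id, mate, target, astart, aend (0-based
#'   half-open), aln_length (matched bases), n_mismatch.
#' @noRd
map_to_index <- function(index, reads, pair_id, mate, min_aln = 20L,
                         max_mm_frac = 0.10) {
  k <- index$k
  rl <- nchar(reads)
  empty <- data.frame(pair_id = character(0), mate = integer(0),
                      target = character(0), astart = integer(0),
                      aend = integer(0), aln_length = integer(0),
                      n_mismatch = integer(0), stringsAsFactors = FALSE)
  use <- which(rl >= max(k, min_aln))
  if (!length(use)) return(empty)

  offs <- cbind(1L, pmax(1L, (rl[use] - k) %/% 2L + 1L),
                pmax(1L, rl[use] - k + 1L))
  ridx <- rep(use, 3L)
  off <- as.integer(offs)
  keep <- !duplicated(cbind(ridx, off))
  ridx <- ridx[keep]; off <- off[keep]
  kms <- substring(reads[ridx], off, off + k - 1L)
  hits <- index$lookup[kms]
  nh <- lengths(hits)
  if (!sum(nh)) return(empty)
  e_r <- rep.int(ridx, nh)
  e_off <- rep.int(off, nh)
  e_hit <- unlist(hits, use.names = FALSE)
  tid <- index$tid[e_hit]
  start <- index$pos[e_hit] - e_off + 1L          # 1-based implied start

  key <- paste(e_r, tid, start, sep = "\r")
  keep <- !duplicated(key)
  e_r <- e_r[keep]; tid <- tid[keep]; start <- start[keep]

  Lt <- index$lengths[tid]
  s <- pmax(1L, start)
  e <- pmin(Lt, start + rl[e_r] - 1L)
  ok <- e - s + 1L >= min_aln
  e_r <- e_r[ok]; tid <- tid[ok]; start <- start[ok]; s <- s[ok]; e <- e[ok]
  if (!length(e_r)) return(empty)

  read_sub <- substr(reads[e_r], s - start + 1L, e - start + 1L)
  t_sub <- substring(index$seqs[tid], s, e)
  exact <- read_sub == t_sub

  astart <- s; aend <- e
  span <- e - s + 1L
  aln_length <- ifelse(exact, span, NA_integer_)
  n_mm <- ifelse(exact, 0L, NA_integer_)
  drop <- logical(length(e_r))
  for (i in which(!exact)) {
    mm <- charToRaw(read_sub[i]) != charToRaw(t_sub[i])
    seg <- max_score_segment(mm)
    if (is.null(seg)) { drop[i] <- TRUE; next }
    nmm <- sum(mm[seg[1L]:seg[2L]])
    len <- seg[2L] - seg[1L] + 1L
    if (len - nmm < min_aln || nmm / len > max_mm_frac) {
      drop[i] <- TRUE; next
    }
    astart[i] <- s[i] + seg[1L] - 1L
    aend[i] <- s[i] + seg[2L] - 1L
    aln_length[i] <- len - nmm
    n_mm[i] <- nmm
  }
  keep <- !drop & aln_length >= min_aln
  if (!any(keep)) return(empty)
  df <- data.frame(read_i = e_r[keep], target_i = tid[keep],
                   astart = astart[keep] - 1L, aend = aend[keep],
                   aln_length = aln_length[keep], n_mismatch = n_mm[keep],
                   stringsAsFactors = FALSE)

  # keep all co-optimal placements per read (score = matches - 2*mismatches)
  score <- df$aln_length - 2L * df$n_mismatch
  best <- tapply(score, df$read_i, max)
  df <- df[score == best[as.character(df$read_i)], , drop = FALSE]

  data.frame(pair_id = pair_id[df$read_i], mate = mate[df$read_i],
             target = index$targets[df$target_i], astart = df$astart,
             aend = df$aend, aln_length = df$aln_length,
             n_mismatch = df$n_mismatch, stringsAsFactors = FALSE)
}

#' Maximal-scoring contiguous segment under match +1 / mismatch -2 (Kadane)
#' @noRd
max_score_segment <- function(mismatch) {
  sc <- ifelse(mismatch, -2, 1)
  best <- 0; best_i <- 0L; best_j <- -1L
  cur <- 0; cur_i <- 1L
  for (j in seq_along(sc)) {
    if (cur <= 0) { cur <- 0; cur_i <- j }
    cur <- cur + sc[j]
    if (cur > best) { best <- cur; best_i <- cur_i; best_j <- j }
  }
  if (best_j < best_i) NULL else c(best_i, best_j)
}

#' Map a read set against one locus construct
#'
#' Maps reads (both mates of each pair) to the TE-present construct and its
#' TE-absent companion with exact 21-mer seeding and ungapped local
#' extension; alignments with fewer than `min_aln` matched bases are
#' dropped. Targets are named `present` and `absent`.
#'
#' @param reads List with `r1`/`r2` DNAStringSets (as from
#'   [simulate_reads()] / [read_fastq_pair()]) or a single DNAStringSet of
#'   unpaired reads.
#' @param construct A [build_locus_construct()] object.
#' @param min_aln Minimum matched bases (default 20).
#' @param k Seed k-mer size (default 21).
#' @return data.frame of alignments: pair_id, mate, target, astart, aend
#'   (0-based half-open construct interval), aln_length, n_mismatch.
#' @export
map_reads <- function(reads, construct, min_aln = 20L, k = 21L) {
  rr <- flatten_reads(reads)
  idx <- kmer_index(c(present = construct$sequence,
                      absent = construct$absent_sequence), k = k)
  map_to_index(idx, rr$seq, rr$pair_id, rr$mate, min_aln = min_aln)
}

#' Normalise read input to (seq, pair_id, mate)
#' @noRd
flatten_reads <- function(reads) {
  if (is.list(reads) && !is.null(reads$r1)) {
    r1 <- as_seq_chr(reads$r1); r2 <- as_seq_chr(reads$r2)
    ids1 <- sub("/[12]$", "", names(reads$r1))
    ids2 <- sub("/[12]$", "", names(reads$r2))
    list(seq = c(r1, r2), pair_id = c(ids1, ids2),
         mate = rep(1:2, c(length(r1), length(r2))))
  } else {
    r <- as_seq_chr(reads)
    nm <- names(r)
    if (is.null(nm)) nm <- sprintf("read%06d", seq_along(r))
    mate <- ifelse(grepl("/2$", nm), 2L, 1L)
    list(seq = r, pair_id = sub("/[12]$", "", nm), mate = mate)
  }
}

#' Ingest externally produced alignments from SAM/BAM
#'
#' Reads alignments (e.g. bwa-mem output against locus constructs) and
#' converts them to the same table [map_reads()] produces, applying the same
#' minimum-alignment-length filter. The matched-base count is the aligned
#' query length (CIGAR M/=/X) minus the NM edit distance when present.
#'
#' @param path SAM or BAM file.
#' @param min_aln Minimum matched bases.
#' @return data.frame: pair_id, mate, target, astart, aend, aln_length,
#'   n_mismatch.
#' @export
read_sam_alignments <- function(path, min_aln = 20L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag"), tag = "NM")
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  d <- as.data.frame(ga)
  ops <- GenomicAlignments::cigarOpTable(d$cigar)
  aligned <- rowSums(ops[, c("M", "=", "X"), drop = FALSE])
  nm <- d$NM
  if (is.null(nm)) nm <- rep(0L, nrow(d))
  nm[is.na(nm)] <- 0L
  aln_length <- aligned - nm
  mate <- ifelse(bitwAnd(d$flag, 128L) > 0L, 2L, 1L)
  df <- data.frame(pair_id = d$qname, mate = mate,
                   target = as.character(d$seqnames),
                   astart = d$start - 1L, aend = d$end,
                   aln_length = as.integer(aln_length),
                   n_mismatch = as.integer(nm), stringsAsFactors = FALSE)
  df[df$aln_length >= min_aln, , drop = FALSE]
}

#' Count presence / absence evidence for one locus
#' @noRd
evidence_counts <- function(aln, construct, min_aln = 20L,
                            insert_mean = NULL, insert_sd = NULL,
                            tol_sd = 4) {
  jL <- construct$junctionL; jR <- construct$junctionR
  aj <- construct$absent_junction
  pres <- aln[aln$target == "present", , drop = FALSE]
  abs_ <- aln[aln$target == "absent", , drop = FALSE]

  # junction-spanning reads: >= min_aln aligned bases on each side
  junc_p <- pres$pair_id[(pres$astart <= jL - min_aln & pres$aend >= jL + min_aln) |
                         (pres$astart <= jR - min_aln & pres$aend >= jR + min_aln)]
  # read pairs: one mate wholly in a flank, the other wholly inside the TE
  in_flank <- pres$aend <= jL | pres$astart >= jR
  in_te <- pres$astart >= jL & pres$aend <= jR
  pair_p <- intersect(unique(pres$pair_id[in_flank & pres$mate == 1L]),
                      unique(pres$pair_id[in_te & pres$mate == 2L]))
  pair_p2 <- intersect(unique(pres$pair_id[in_flank & pres$mate == 2L]),
                       unique(pres$pair_id[in_te & pres$mate == 1L]))
  n_presence <- length(unique(c(junc_p, pair_p, pair_p2)))

  junc_a <- abs_$pair_id[abs_$astart <= aj - min_aln & abs_$aend >= aj + min_aln]
  left_only <- abs_[abs_$aend <= aj, , drop = FALSE]
  right_only <- abs_[abs_$astart >= aj, , drop = FALSE]
  both <- intersect(unique(left_only$pair_id), unique(right_only$pair_id))
  both <- setdiff(both, abs_$pair_id[duplicated(paste(abs_$pair_id, abs_$mate))])
  if (length(both) && !is.null(insert_mean) && !is.null(insert_sd)) {
    spans <- vapply(both, function(p) {
      max(abs_$aend[abs_$pair_id == p]) - min(abs_$astart[abs_$pair_id == p])
    }, numeric(1))
    both <- both[abs(spans - insert_mean) <= tol_sd * insert_sd]
  }
  n_absence <- length(unique(c(junc_a, both)))
  list(n_presence = n_presence, n_absence = n_absence)
}

#' Genotype one locus in one accession from mapped reads
#'
#' Presence evidence: reads spanning either TE junction with at least
#' `min_aln` aligned bases on both sides, plus pairs with one mate in a
#' flank and the other inside the TE. Absence evidence: reads spanning the
#' flank-flank junction of the TE-absent companion construct, plus pairs
#' with mates in opposite flanks whose implied fragment is consistent with
#' no intervening TE (checked against `insert_mean`/`insert_sd` when
#' supplied). Decision: presence-only evidence gives CC, absence-only GG;
#' when both classes reach their thresholds the call is CG if the minority
#' evidence fraction is at least `het_fraction`, otherwise the majority
#' homozygote; with neither class of evidence the call is NN.
#'
#' @param alignments data.frame from [map_reads()] (or
#'   [read_sam_alignments()] with targets named `present`/`absent`) for one
#'   accession at one locus.
#' @param construct The locus [build_locus_construct()].
#' @param min_presence,min_absence Evidence thresholds (default 1 read each).
#' @param het_fraction Minimum minority evidence fraction for a CG call.
#' @param min_aln Junction anchoring requirement in bp.
#' @param insert_mean,insert_sd Optional genome-wide insert-size estimates
#'   used to screen absence pairs.
#' @return List with `genotype` ("CC","GG","CG","NN"), `n_presence`,
#'   `n_absence`.
#' @export
genotype_locus <- function(alignments, construct, min_presence = 1L,
                           min_absence = 1L, het_fraction = 0.2,
                           min_aln = 20L, insert_mean = NULL,
                           insert_sd = NULL) {
  ev <- evidence_counts(alignments, construct, min_aln = min_aln,
                        insert_mean = insert_mean, insert_sd = insert_sd)
  np <- ev$n_presence; na <- ev$n_absence
  gt <- if (np >= min_presence && na < min_absence) "CC"
  else if (na >= min_absence && np < min_presence) "GG"
  else if (np >= min_presence && na >= min_absence) {
    if (min(np, na) / (np + na) >= het_fraction) "CG"
    else if (np > na) "CC" else if (na > np) "GG" else "CG"
  } else "NN"
  list(genotype = gt, n_presence = np, n_absence = na)
}

#' Estimate the genome-wide insert size from pair spans
#'
#' Robust location/scale (median and MAD) so discordant pairs straddling
#' unrecognised insertions do not inflate the estimate.
#'
#' @param spans Numeric vector of observed outer fragment spans.
#' @return List with `mean` and `sd`.
#' @export
estimate_insert_size <- function(spans) {
  if (length(spans) < 20L)
    stop("need at least 20 pairs to estimate the insert size, got ",
         length(spans))
  list(mean = stats::median(spans), sd = stats::mad(spans))
}

#' Validate a TE insertion by paired-end insert sizes
#'
#' On the TE-absent reference, pairs straddling the insertion point of a
#' carrier show an apparent fragment of about `insert_mean + te_length`;
#' non-carrier pairs show about `insert_mean`. Each span is classified
#' accordingly within `tol_sd` standard deviations.
#'
#' @param spans Observed spans of straddling pairs on the TE-absent
#'   reference.
#' @param te_length TE length in bp.
#' @param insert_mean,insert_sd Genome-wide insert estimate (see
#'   [estimate_insert_size()]).
#' @param tol_sd Tolerance in standard deviations (default 3).
#' @return Character vector per span: "presence", "absence" or "ambiguous".
#' @export
insert_size_validate <- function(spans, te_length, insert_mean, insert_sd,
                                 tol_sd = 3) {
  out <- rep("ambiguous", length(spans))
  out[abs(spans - (insert_mean + te_length)) <= tol_sd * insert_sd] <- "presence"
  out[abs(spans - insert_mean) <= tol_sd * insert_sd] <- "absence"
  out
}

#' Genotype a population of accessions over a set of TIP loci
#'
#' Maps each accession's reads against all locus constructs (present and
#' absent companions share one k-mer index) and calls every locus with
#' [genotype_locus()]. The per-accession insert size is estimated from
#' concordant pairs when possible and used to screen absence pairs.
#'
#' @param constructs List of [build_locus_construct()] objects.
#' @param reads_by_accession Named list: accession -> list(r1, r2) (or NULL /
#'   empty for missing data, recorded as all-NN with a warning).
#' @param min_aln,k,min_presence,min_absence,het_fraction See
#'   [genotype_locus()] and [map_reads()].
#' @param estimate_insert Estimate insert size per accession from mapped
#'   concordant pairs (needs >= 20; otherwise no span screening).
#' @return List with `codes` (character matrix loci x accessions), `calls`
#'   (long data.frame with evidence counts) and `locus_stats` (missing rate,
#'   presence-allele frequency, polymorphic flag).
#' @export
genotype_population <- function(constructs, reads_by_accession,
                                min_aln = 20L, k = 21L, min_presence = 1L,
                                min_absence = 1L, het_fraction = 0.2,
                                estimate_insert = TRUE) {
  locus_ids <- vapply(constructs, `[[`, character(1), "locus_id")
  names(constructs) <- locus_ids
  accs <- names(reads_by_accession)
  if (is.null(accs)) stop("`reads_by_accession` must be a named list")

  targets <- c(stats::setNames(vapply(constructs, `[[`, character(1),
                                      "sequence"),
                               paste0(locus_ids, "||P")),
               stats::setNames(vapply(constructs, `[[`, character(1),
                                      "absent_sequence"),
                               paste0(locus_ids, "||A")))
  idx <- kmer_index(targets, k = k)

  codes <- matrix("NN", nrow = length(locus_ids), ncol = length(accs),
                  dimnames = list(locus_ids, accs))
  calls <- vector("list", length(accs))
  for (a in seq_along(accs)) {
    rd <- reads_by_accession[[a]]
    if (is.null(rd) || length(rd$r1) == 0L) {
      warning("accession ", accs[a], " has no reads; all calls NN")
      next
    }
    rr <- flatten_reads(rd)
    aln <- map_to_index(idx, rr$seq, rr$pair_id, rr$mate, min_aln = min_aln)
    locus <- sub("\\|\\|[PA]$", "", aln$target)
    aln$target <- ifelse(grepl("\\|\\|P$", aln$target), "present", "absent")

    ins <- list(mean = NULL, sd = NULL)
    if (estimate_insert) {
      pp <- paste(locus, aln$pair_id)
      tab <- split(seq_len(nrow(aln)), pp)
      spans <- vapply(tab, function(ii) {
        if (length(unique(aln$mate[ii])) < 2L) return(NA_real_)
        if (length(unique(aln$target[ii])) > 1L) return(NA_real_)
        max(aln$aend[ii]) - min(aln$astart[ii])
      }, numeric(1))
      spans <- spans[!is.na(spans)]
      if (length(spans) >= 20L) ins <- estimate_insert_size(spans)
    }

    by_locus <- split(seq_len(nrow(aln)), locus)
    res <- lapply(locus_ids, function(lid) {
      ii <- by_locus[[lid]]
      sub <- if (is.null(ii)) aln[0, , drop = FALSE]
             else aln[ii, , drop = FALSE]
      genotype_locus(sub, constructs[[lid]], min_presence = min_presence,
                     min_absence = min_absence, het_fraction = het_fraction,
                     min_aln = min_aln, insert_mean = ins$mean,
                     insert_sd = ins$sd)
    })
    codes[, a] <- vapply(res, `[[`, character(1), "genotype")
    calls[[a]] <- data.frame(
      accession = accs[a], locus_id = locus_ids,
      genotype = codes[, a],
      n_presence = vapply(res, `[[`, integer(1), "n_presence"),
      n_absence = vapply(res, `[[`, integer(1), "n_absence"),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)

  non_nn <- rowSums(codes != "NN")
  pres <- (2 * rowSums(codes == "CC") + rowSums(codes == "CG")) /
    pmax(1, 2 * non_nn)
  locus_stats <- data.frame(
    locus_id = locus_ids,
    missing_rate = rowMeans(codes == "NN"),
    presence_freq = ifelse(non_nn > 0, pres, NA_real_),
    polymorphic = apply(codes, 1L, function(x)
      length(unique(x[x != "NN"])) > 1L),
    stringsAsFactors = FALSE)
  list(codes = codes, calls = calls, locus_stats = locus_stats)
}
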