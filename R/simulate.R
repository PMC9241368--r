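# Synthetic pan-genome, TE library, read and genotype-matrix simulation.
# Everything is deterministic under an explicit seed so downstream stages can
# be validated against known truth without any real sequencing data.

TE_SUPERFAMILIES <- c("Copia", "Gypsy", "DTA", "DTC", "DTH", "DTM", "DTT",
                      "Helitron")

#' Simulate a TE library
#'
#' Draws `n` uniform-random ACGT elements with lengths uniform in
#' `length_range` and assigns each a superfamily label. Record names follow
#' the RepeatMasker-style `id#superfamily` convention so the library
#' round-trips through FASTA.
#'
#' @param n Number of elements.
#' @param length_range Length bounds in bp, within \[100, 20000\].
#' @param superfamilies Labels to sample from (LTR retrotransposon families
#'   Copia/Gypsy and the DNA-transposon superfamilies DTA, DTC, DTH, DTM,
#'   DTT, Helitron by default).
#' @param seed RNG seed; identical calls give byte-identical output.
#' @return List with `seqs` (a named [Biostrings::DNAStringSet]) and `info`
#'   (data.frame of te_id, superfamily, length).
#' @export
simulate_te_library <- function(n, length_range = c(3000, 6000),
                                superfamilies = TE_SUPERFAMILIES,
                                seed = NULL) {
  n <- check_count(n, "n", min = 1L)
  if (length(superfamilies) == 0L)
    stop("`superfamilies` must contain at least one label")
  if (length(length_range) != 2L || length_range[1] < 100 ||
      length_range[2] > 20000 || length_range[1] > length_range[2])
    stop("`length_range` must lie within [100, 20000]")
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    fams <- sample(superfamilies, n, replace = TRUE)
    ids <- sprintf("TE%04d", seq_len(n))
    seqs <- Biostrings::DNAStringSet(random_dna(lens))
    names(seqs) <- paste0(ids, "#", fams)
    list(seqs = seqs,
         info = data.frame(te_id = ids, superfamily = fams, length = lens,
                           stringsAsFactors = FALSE))
  })
}

#' Simulate a pan-genome of donor genomes carrying planted TE insertions
#'
#' Each donor genome equals the base genome with its carried TE copies
#' spliced in at known 0-based insertion points; the returned truth tables
#' drive validation of classification and genotyping. Insertion points are
#' kept at least `end_margin` bp from the contig ends (so 1 kb flanks exist)
#' and at least `min_spacing` bp apart (so locus constructs do not overlap).
#'
#' @param base Base genome: a single contig as character/DNAStringSet, or an
#'   integer length to draw a random one.
#' @param te_library Output of [simulate_te_library()] (or a named
#'   DNAStringSet with `id#superfamily` names).
#' @param n_accessions Number of donor genomes.
#' @param n_loci Number of insertion loci to plant.
#' @param carrier_frequency Per-locus probability that an accession carries
#'   the insertion.
#' @param positions Optional explicit 0-based insertion points (length
#'   `n_loci`); duplicated or out-of-margin positions are rejected.
#' @param min_spacing,end_margin Placement constraints in bp.
#' @param divergence Per-base substitution rate applied once to each planted
#'   copy (models a diverged insertion allele; 0 keeps exact library copies).
#' @param seed RNG seed.
#' @param contig Contig name of the base genome.
#' @return List with `base` (named character), `donors` (named character
#'   vector of donor genome sequences), `truth` (list: `loci` data.frame with
#'   locus_id/contig/position/te_id/superfamily/te_length/sequence, `carriers`
#'   logical loci x accessions matrix, `accessions`), and `sv` — the SV truth
#'   table, one row per (donor, insertion).
#' @export
simulate_pangenome <- function(base, te_library, n_accessions, n_loci,
                               carrier_frequency = 0.5, positions = NULL,
                               min_spacing = 2500L, end_margin = 1000L,
                               divergence = 0, seed = NULL,
                               contig = "chr1") {
  n_accessions <- check_count(n_accessions, "n_accessions", min = 1L)
  n_loci <- check_count(n_loci, "n_loci", min = 0L)
  stopifnot(carrier_frequency >= 0, carrier_frequency <= 1, divergence >= 0,
            divergence < 1)
  lib <- as_te_library(te_library)

  with_seed(seed, {
    if (is.numeric(base)) {
      base_seq <- random_dna(as.integer(base))
    } else {
      base_seq <- as_seq_chr(base)[1L]
    }
    L <- nchar(base_seq)

    if (is.null(positions) && n_loci > 0L) {
      need <- 2L * end_margin + (n_loci - 1L) * min_spacing
      if (need >= L)
        stop("base genome too short for requested loci/spacing")
      slack <- L - need
      u <- sort(sample.int(slack, n_loci, replace = TRUE))
      positions <- end_margin + (seq_len(n_loci) - 1L) * min_spacing + u
    }
    positions <- as.integer(positions)
    if (n_loci > 0L) {
      if (anyDuplicated(positions))
        stop("overlapping planted insertions: duplicated positions")
      if (any(positions < end_margin | positions > L - end_margin))
        stop("insertion points must lie within [end_margin, length - end_margin]")
      positions <- sort(positions)
    }

    te_idx <- if (n_loci > 0L)
      sample.int(nrow(lib$info), n_loci, replace = TRUE) else integer(0)
    te_seqs <- vapply(te_idx, function(i) as.character(lib$seqs[[i]]),
                      character(1))
    if (divergence > 0 && n_loci > 0L)
      te_seqs <- vapply(te_seqs, mutate_seq, character(1), rate = divergence,
                        USE.NAMES = FALSE)

    loci <- data.frame(
      locus_id = sprintf("TIP%05d", seq_len(n_loci)),
      contig = rep(contig, n_loci),
      position = positions,
      te_id = lib$info$te_id[te_idx],
      superfamily = lib$info$superfamily[te_idx],
      te_length = nchar(te_seqs),
      sequence = te_seqs,
      stringsAsFactors = FALSE)

    accs <- sprintf("acc%03d", seq_len(n_accessions))
    carriers <- matrix(stats::runif(n_loci * n_accessions) < carrier_frequency,
                       nrow = n_loci, ncol = n_accessions,
                       dimnames = list(loci$locus_id, accs))

    donors <- vapply(seq_len(n_accessions), function(a) {
      idx <- which(carriers[, a])
      splice_insertions(base_seq, positions[idx], te_seqs[idx])
    }, character(1))
    names(donors) <- accs

    sv <- do.call(rbind, lapply(seq_len(n_accessions), function(a) {
      idx <- which(carriers[, a])
      if (!length(idx)) return(NULL)
      data.frame(source_genome = accs[a], contig = contig,
                 position = positions[idx], sv_type = "insertion",
                 te_id = loci$te_id[idx], length = loci$te_length[idx],
                 sequence = te_seqs[idx], stringsAsFactors = FALSE)
    }))
    if (is.null(sv))
      sv <- data.frame(source_genome = character(0), contig = character(0),
                       position = integer(0), sv_type = character(0),
                       te_id = character(0), length = integer(0),
                       sequence = character(0), stringsAsFactors = FALSE)

    base_out <- stats::setNames(base_seq, contig)
    list(base = base_out, donors = donors,
         truth = list(loci = loci, carriers = carriers, accessions = accs),
         sv = sv)
  })
}

#' Splice insertion sequences into a genome at sorted 0-based points
#' @noRd
splice_insertions <- function(genome, positions, insertions) {
  if (!length(positions)) return(genome)
  o <- order(positions)
  positions <- positions[o]; insertions <- insertions[o]
  L <- nchar(genome)
  bounds <- c(0L, positions, L)
  pieces <- substring(genome, bounds[-length(bounds)] + 1L, bounds[-1L])
  out <- character(2L * length(positions) + 1L)
  out[seq(1L, length(out), by = 2L)] <- pieces
  out[seq(2L, length(out) - 1L, by = 2L)] <- insertions
  paste(out, collapse = "")
}

#' Simulate paired-end reads from a genome
#'
#' Fragment inserts are drawn from Normal(`insert_mean`, `insert_sd`)
#' truncated below at `read_length`; mate 2 is the reverse complement of the
#' fragment 3' end; substitution errors are applied per base at `error_rate`.
#' The number of pairs is `round(coverage * genome_length / (2 * read_length))`.
#'
#' @param genome Single-contig genome (character or DNAStringSet).
#' @param read_length,insert_mean,insert_sd,coverage,error_rate Standard
#'   short-read simulation parameters; `error_rate` must be in \[0, 0.1).
#' @param seed RNG seed.
#' @param id_prefix Read-name prefix.
#' @return List with `r1` and `r2` ([Biostrings::DNAStringSet], names carry
#'   the `/1` and `/2` mate suffixes) and `insert_sizes` (integer vector).
#' @export
simulate_reads <- function(genome, read_length = 150L, insert_mean = 500,
                           insert_sd = 50, coverage = 20, error_rate = 0,
                           seed = NULL, id_prefix = "read") {
  g <- as_seq_chr(genome)
  if (length(g) != 1L) stop("`genome` must be a single contig")
  g <- g[[1L]]
  L <- nchar(g)
  read_length <- check_count(read_length, "read_length", min = 1L)
  if (coverage <= 0) stop("`coverage` must be > 0")
  if (error_rate < 0 || error_rate >= 0.1)
    stop("`error_rate` must be in [0, 0.1)")
  if (insert_mean < read_length)
    stop("`insert_mean` must be >= read_length")
  if (L < insert_mean + 6 * insert_sd)
    stop("genome shorter than insert_mean + 6*insert_sd")

  n_pairs <- round(coverage * L / (2 * read_length))
  with_seed(seed, {
    isize <- pmax(read_length,
                  as.integer(round(stats::rnorm(n_pairs, insert_mean,
                                                insert_sd))))
    isize <- pmin(isize, L)
    start <- floor(stats::runif(n_pairs, min = 1, max = L - isize + 1 + 1))
    start <- pmin(as.integer(start), L - isize + 1L)
    r1 <- substring(g, start, start + read_length - 1L)
    r2 <- revcomp_chr(substring(g, start + isize - read_length,
                                start + isize - 1L))
    if (error_rate > 0) {
      r1 <- apply_read_errors(r1, error_rate)
      r2 <- apply_read_errors(r2, error_rate)
    }
    ids <- sprintf("%s%06d", id_prefix, seq_len(n_pairs))
    r1 <- Biostrings::DNAStringSet(r1)
    r2 <- Biostrings::DNAStringSet(r2)
    names(r1) <- paste0(ids, "/1")
    names(r2) <- paste0(ids, "/2")
    list(r1 = r1, r2 = r2, insert_sizes = isize)
  })
}

#' Apply per-base substitution errors to a character vector of reads
#' @noRd
apply_read_errors <- function(reads, rate) {
  rl <- nchar(reads)
  n_err <- stats::rbinom(length(reads), rl, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(rl[i], n_err[i])
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(bases, b), 1L), character(1), USE.NAMES = FALSE)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Write (or read) a simulated read pair as FASTQ
#'
#' @param reads List with `r1`/`r2` as returned by [simulate_reads()].
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with constant quality "I".
#' @return Invisibly, the two file paths.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (i in 1:2) {
    x <- reads[[c("r1", "r2")[i]]]
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
    Biostrings::writeXStringSet(x, paths[i], format = "fastq",
                                qualities = qual)
  }
  invisible(paths)
}

#' @rdname write_fastq_pair
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @export
read_fastq_pair <- function(path1, path2) {
  list(r1 = Biostrings::readDNAStringSet(path1, format = "fastq"),
       r2 = Biostrings::readDNAStringSet(path2, format = "fastq"))
}

#' Simulate a population genotype matrix with group-enriched loci
#'
#' Generates CC/GG codes (optionally CG and NN) for `n_loci` loci across
#' accessions organised into labelled groups. Neutral loci share one carrier
#' frequency across groups; enriched loci have per-group carrier frequencies
#' (e.g. 0.80 in a derived group vs 0.02 in the control), emulating a
#' selection contrast at matrix level.
#'
#' @param n_loci Total number of loci.
#' @param groups Named integer vector of group sizes, e.g.
#'   `c(heading = 329, nonheading = 195)`.
#' @param enriched Optional data.frame with column `locus` (index in
#'   `1:n_loci`) plus one carrier-frequency column per group label.
#' @param neutral_freq_range Range from which each neutral locus's shared
#'   carrier frequency is drawn.
#' @param cg_rate Probability that a carrier call is heterozygous (CG).
#' @param nn_rate Missingness probability applied to every call.
#' @param n_accessions Optional consistency check against `sum(groups)`.
#' @param seed RNG seed.
#' @return List with `codes` (character matrix, loci x accessions), `groups`
#'   (named character vector, accession -> group label) and `truth` (list
#'   with `enriched_loci` locus ids and the frequency design).
#' @export
simulate_population_matrix <- function(n_loci, groups, enriched = NULL,
                                       neutral_freq_range = c(0.1, 0.9),
                                       cg_rate = 0, nn_rate = 0,
                                       n_accessions = NULL, seed = NULL) {
  n_loci <- check_count(n_loci, "n_loci", min = 1L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("`groups` must be a named vector of group sizes")
  groups <- vapply(groups, check_count, integer(1), name = "groups", min = 1L)
  if (!is.null(n_accessions) && sum(groups) != n_accessions)
    stop("group sizes sum (", sum(groups), ") != n_accessions (",
         n_accessions, ")")

  acc_group <- rep(names(groups), groups)
  accs <- sprintf("%s_%03d", acc_group,
                  unlist(lapply(groups, seq_len), use.names = FALSE))
  locus_ids <- sprintf("L%04d", seq_len(n_loci))

  with_seed(seed, {
    # per-locus, per-group carrier frequencies
    freq <- matrix(stats::runif(n_loci, neutral_freq_range[1],
                                neutral_freq_range[2]),
                   nrow = n_loci, ncol = length(groups),
                   dimnames = list(locus_ids, names(groups)))
    enriched_ids <- character(0)
    if (!is.null(enriched)) {
      if (!all(names(groups) %in% names(enriched)))
        stop("`enriched` must have a frequency column per group label")
      freq[enriched$locus, ] <- as.matrix(enriched[, names(groups),
                                                   drop = FALSE])
      enriched_ids <- locus_ids[enriched$locus]
    }
    p <- freq[, acc_group, drop = FALSE]  # loci x accessions
    carrier <- matrix(stats::runif(length(p)) < p, nrow = n_loci)
    codes <- ifelse(carrier, "CC", "GG")
    if (cg_rate > 0)
      codes[carrier & matrix(stats::runif(length(p)) < cg_rate,
                             nrow = n_loci)] <- "CG"
    if (nn_rate > 0)
      codes[matrix(stats::runif(length(p)) < nn_rate, nrow = n_loci)] <- "NN"
    dimnames(codes) <- list(locus_ids, accs)
    list(codes = codes,
         groups = stats::setNames(acc_group, accs),
         truth = list(enriched_loci = enriched_ids, freq = freq))
  })
}
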