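fixture_locus <- function(seed = 50, te_len = 3000, genome_len = 20000,
                          pos = 9000) {
  set.seed(seed)
  base <- c(chr1 = rand_seq(genome_len))
  te <- rand_seq(te_len)
  locus <- list(locus_id = "TIP00001", contig = "chr1", position = pos,
                sequence = te)
  carrier <- c(chr1 = paste0(substr(base, 1, pos), te,
                             substr(base, pos + 1, genome_len)))
  list(base = base, te = te, locus = locus, carrier = carrier)
}

test_that("locus constructs have the stated junctions and truncate at ends", {
  fx <- fixture_locus(te_len = 4000)
  cons <- build_locus_construct(fx$locus, fx$base)
  expect_equal(nchar(cons$sequence), 6000L)
  expect_equal(cons$junctionL, 1000L)
  expect_equal(cons$junctionR, 5000L)
  # reconstructed construct is an exact substring of the carrier genome
  expect_true(grepl(cons$sequence, fx$carrier[[1]], fixed = TRUE))
  expect_true(grepl(cons$absent_sequence, fx$base[[1]], fixed = TRUE))

  near_end <- fx$locus
  near_end$position <- 400
  cons2 <- build_locus_construct(near_end, fx$base)
  expect_equal(cons2$left_flank_len, 400L)
  expect_equal(cons2$junctionL, 400L)

  bad <- fx$locus
  bad$sequence <- ""
  expect_error(build_locus_construct(bad, fx$base), "empty")
})

test_that("the mapper recovers exact placements and rejects noise", {
  fx <- fixture_locus()
  cons <- build_locus_construct(fx$locus, fx$base)
  # read equal to construct[101:250] (0-based [100, 250))
  read <- substr(cons$sequence, 101, 250)
  aln <- map_reads(stats::setNames(Biostrings::DNAStringSet(read), "r1/1"),
                   cons)
  pres <- aln[aln$target == "present", ]
  expect_equal(pres$astart, 100L)
  expect_equal(pres$aend, 250L)
  expect_equal(pres$aln_length, 150L)

  # 1000 random 150-mers: none map
  set.seed(51)
  rnd <- Biostrings::DNAStringSet(vapply(1:1000, function(i) rand_seq(150),
                                         character(1)))
  names(rnd) <- sprintf("n%04d/1", 1:1000)
  expect_equal(nrow(map_reads(rnd, cons)), 0L)

  # junction-spanning read with one substitution
  jread <- substr(cons$sequence, cons$junctionL - 74, cons$junctionL + 75)
  jread <- diverge_seq(jread, 1)
  aln2 <- map_reads(stats::setNames(Biostrings::DNAStringSet(jread), "j/1"),
                    cons)
  pres2 <- aln2[aln2$target == "present", ]
  expect_equal(nrow(pres2), 1L)
  expect_equal(pres2$n_mismatch, 1L)
})

test_that("mapper placements equal exact substring search on error-free reads", {
  fx <- fixture_locus(seed = 52)
  cons <- build_locus_construct(fx$locus, fx$base)
  set.seed(52)
  starts <- sample(seq_len(nchar(cons$sequence) - 150L), 40)
  reads <- Biostrings::DNAStringSet(substring(cons$sequence, starts,
                                              starts + 149L))
  names(reads) <- sprintf("s%03d/1", seq_along(starts))
  aln <- map_reads(reads, cons)
  pres <- aln[aln$target == "present", ]
  pres <- pres[match(sprintf("s%03d", seq_along(starts)), pres$pair_id), ]
  expect_equal(pres$astart, starts - 1L)
})

test_that("homozygous, missing and heterozygous patterns call correctly", {
  fx <- fixture_locus(seed = 53, te_len = 3500)
  cons <- build_locus_construct(fx$locus, fx$base)

  rd_carrier <- simulate_reads(fx$carrier, coverage = 20, seed = 54)
  aln <- map_reads(rd_carrier, cons)
  call <- genotype_locus(aln, cons)
  expect_equal(call$genotype, "CC")
  expect_gt(call$n_presence, 0)
  expect_equal(call$n_absence, 0)

  rd_absent <- simulate_reads(fx$base, coverage = 20, seed = 55)
  aln0 <- map_reads(rd_absent, cons)
  call0 <- genotype_locus(aln0, cons)
  expect_equal(call0$genotype, "GG")

  empty <- aln[0, , drop = FALSE]
  expect_equal(genotype_locus(empty, cons)$genotype, "NN")

  # 50:50 haplotype mixture -> CG
  half <- function(rd) list(r1 = rd$r1[seq(1, length(rd$r1), 2)],
                            r2 = rd$r2[seq(1, length(rd$r2), 2)])
  mix <- list(r1 = c(half(rd_carrier)$r1, half(rd_absent)$r1),
              r2 = c(half(rd_carrier)$r2, half(rd_absent)$r2))
  callh <- genotype_locus(map_reads(mix, cons), cons)
  expect_equal(callh$genotype, "CG")
})

test_that("evidence accumulation is monotone and never flips homozygotes directly", {
  fx <- fixture_locus(seed = 56)
  cons <- build_locus_construct(fx$locus, fx$base)
  rd <- simulate_reads(fx$carrier, coverage = 20, seed = 57)
  aln <- map_reads(rd, cons)
  # add batches of reads: evidence counts never decrease
  idx <- sample(nrow(aln))
  prev_p <- 0; prev_a <- 0
  for (frac in c(0.25, 0.5, 1)) {
    sub <- aln[sort(idx[seq_len(ceiling(frac * nrow(aln)))]), ]
    call <- genotype_locus(sub, cons)
    expect_gte(call$n_presence, prev_p)
    expect_gte(call$n_absence, prev_a)
    expect_true(call$genotype %in% c("NN", "CC", "CG"))
    prev_p <- call$n_presence; prev_a <- call$n_absence
  }
})

test_that("insert sizes separate carriers from non-carriers", {
  expect_equal(insert_size_validate(5319, te_length = 4819,
                                    insert_mean = 500, insert_sd = 50),
               "presence")
  expect_equal(insert_size_validate(500, te_length = 4819,
                                    insert_mean = 500, insert_sd = 50),
               "absence")
  expect_error(estimate_insert_size(rnorm(10, 500, 50)), "20")

  # simulated carrier library: straddling pairs support presence >= 95%
  fx <- fixture_locus(seed = 58, te_len = 3000)
  rd <- simulate_reads(fx$carrier, coverage = 30, seed = 59)
  est <- estimate_insert_size(rd$insert_sizes)
  # a fragment straddling the TE shows an apparent TE-absent span inflated
  # by te_length
  straddle <- rd$insert_sizes + 3000
  verdict <- insert_size_validate(straddle, te_length = 3000,
                                  insert_mean = est$mean, insert_sd = est$sd)
  expect_gte(mean(verdict == "presence"), 0.95)
})

test_that("population genotyping recovers the simulated truth at small scale", {
  cfg <- preset_config("tiny")
  fx <- build_population_fixture(cfg, seed = 60)
  truth <- fx$pangenome$truth
  cons <- lapply(seq_len(nrow(truth$loci)), function(i)
    build_locus_construct(truth$loci[i, ], fx$pangenome$base))
  gp <- genotype_population(cons, fx$reads)
  expect_equal(dim(gp$codes), dim(truth$carriers))
  want <- ifelse(truth$carriers, "CC", "GG")
  non_nn <- gp$codes != "NN"
  expect_gte(mean(gp$codes[non_nn] == want[non_nn]), 0.99)
  expect_lte(mean(!non_nn), 0.01)

  # an accession without reads is all NN with a warning
  rd2 <- fx$reads
  rd2[["acc001"]] <- NULL
  rd2 <- c(list(acc001 = NULL), rd2)
  expect_warning(gp2 <- genotype_population(cons, rd2), "acc001")
  expect_true(all(gp2$codes[, "acc001"] == "NN"))
})

test_that("SAM ingestion feeds the same genotype logic", {
  fx <- fixture_locus(seed = 61, te_len = 1500, genome_len = 8000,
                      pos = 4000)
  cons <- build_locus_construct(fx$locus, fx$base)
  # hand-written SAM: a junction-spanning read on the present construct
  read <- substr(cons$sequence, cons$junctionL - 74, cons$junctionL + 75)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:present\tLN:", nchar(cons$sequence)),
    paste0("@SQ\tSN:absent\tLN:", nchar(cons$absent_sequence)),
    paste("r1", 0, "present", cons$junctionL - 74, 60, "150M", "*", 0, 0,
          read, strrep("I", 150), "NM:i:0", sep = "\t")), sam)
  aln <- read_sam_alignments(sam)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$aln_length, 150L)
  call <- genotype_locus(aln, cons)
  expect_equal(call$genotype, "CC")
})
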