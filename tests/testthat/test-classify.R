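make_library <- function(seed = 30, n = 4, range = c(800, 1500)) {
  simulate_te_library(n, range, seed = seed)
}

test_that("exact copies classify to their own element at 100/100", {
  lib <- make_library()
  for (i in seq_along(lib$seqs)) {
    hit <- classify_te(lib$seqs[[i]], lib)
    expect_true(hit$classified)
    expect_equal(hit$te_id, lib$info$te_id[i])
    expect_equal(hit$identity_pct, 100)
    expect_equal(hit$coverage_pct, 100)
  }
})

test_that("coverage below 80% fails the 80-80 rule", {
  set.seed(31)
  lib <- make_library()
  el <- as.character(lib$seqs[[1]])
  n <- nchar(el)
  sv <- paste0(substr(el, 1, round(0.75 * n)), rand_seq(round(0.25 * n)))
  hit <- classify_te(sv, lib)
  expect_false(hit$classified)
})

test_that("identity near 85% passes and the short-sequence guard applies", {
  set.seed(32)
  lib <- make_library(range = c(2000, 3000))
  el <- as.character(lib$seqs[[2]])
  sv <- diverge_seq(el, round(0.15 * nchar(el)))
  hit <- classify_te(sv, lib)
  expect_true(hit$classified)
  expect_equal(hit$te_id, lib$info$te_id[2])
  expect_gte(hit$identity_pct, 80)
  # consistency with the aligner the rule is built on
  st <- local_align_stats(sv, lib$seqs[[2]])
  expect_equal(hit$identity_pct, st$identity_pct)

  short <- classify_te(substr(el, 1, 40), lib)
  expect_false(short$classified)
  expect_equal(short$reason, "below minimum length")
})

test_that("classification is monotone in the thresholds", {
  set.seed(33)
  lib <- make_library(range = c(1500, 2500))
  seqs <- c(as.character(lib$seqs[[1]]),
            diverge_seq(as.character(lib$seqs[[1]]), 250),
            diverge_seq(as.character(lib$seqs[[2]]), 500),
            rand_seq(1500))
  for (sq in seqs) {
    loose <- classify_te(sq, lib, id_min = 70, cov_min = 70)$classified
    mid <- classify_te(sq, lib, id_min = 80, cov_min = 80)$classified
    strict <- classify_te(sq, lib, id_min = 90, cov_min = 90)$classified
    expect_true(!strict || mid)   # classified at 90 => classified at 80
    expect_true(!mid || loose)
  }
})

toy_genes <- function() {
  list(
    gene_model("gA", "chr1", "+", 10000, 14000,
               exons = rbind(c(10000, 11000), c(12000, 14000)),
               cds = rbind(c(10200, 11000), c(12000, 13800))),
    gene_model("gB", "chr1", "-", 20000, 22000))
}

test_that("genic context follows distance, strand and precedence rules", {
  gm <- toy_genes()
  expect_equal(assign_genic_context("chr1", 8500, gm)$context, "upstream2kb")
  expect_equal(assign_genic_context("chr1", 11500, gm)$context, "intron")
  expect_equal(assign_genic_context("chr1", 10500, gm)$context, "CDS")
  expect_equal(assign_genic_context("chr1", 22001, gm)$context, "upstream2kb")
  expect_equal(assign_genic_context("chr1", 19000, gm)$context, "downstream2kb")
  far <- assign_genic_context("chr1", 24001, gm)  # > 2 kb past both genes
  expect_equal(far$context, "intergenic")
  expect_error(assign_genic_context("chr1", 999999, gm,
                                    contig_lengths = c(chr1 = 30000)),
               "bounds")
})

test_that("every in-bounds position receives exactly one context", {
  gm <- toy_genes()
  set.seed(34)
  pos <- sample(0:29999, 300)
  ctx <- vapply(pos, function(p)
    assign_genic_context("chr1", p, gm)$context, character(1))
  expect_true(all(ctx %in% c("CDS", "intron", "upstream2kb", "downstream2kb",
                             "intergenic")))
})

test_that("SNP effects follow the codon table on both strands", {
  # gene on +: CDS = GGG AAG -> place substitutions at known codon positions
  g <- paste0(rand_seq(10), "GGGAAG", rand_seq(10))
  genome <- c(chr1 = g)
  gm <- gene_model("g1", "chr1", "+", 10, 16)
  # GGG -> GGA (Gly -> Gly)
  expect_equal(classify_snp_effect("chr1", 12, substr(g, 13, 13), "A", gm,
                                   genome), "synonymous")
  # AAG -> GAG (Lys -> Glu)
  expect_equal(classify_snp_effect("chr1", 13, substr(g, 14, 14), "G", gm,
                                   genome), "nonsynonymous")
  # outside the CDS
  expect_equal(classify_snp_effect("chr1", 2, substr(g, 3, 3), "A", gm,
                                   genome), "noncoding")

  # minus-strand gene: forward genome CTTCCC, CDS strand reads GGG AAG.
  # Forward change C->T at the CDS-strand last base gives AAG -> AAA
  # (Lys -> Lys, synonymous)
  g2 <- paste0(rand_seq(6), "CTTCCC", rand_seq(6))
  genome2 <- c(chr1 = g2)
  gm2 <- gene_model("g2", "chr1", "-", 6, 12)
  expect_equal(classify_snp_effect("chr1", 6, "C", "T", gm2, genome2),
               "synonymous")
  # and CTT -> CTG complements AAG -> CAG (Lys -> Gln)
  expect_equal(classify_snp_effect("chr1", 8, "T", "G", gm2, genome2),
               "nonsynonymous")

  expect_error(classify_snp_effect("chr1", 12, "N", "A", gm, genome),
               "mismatch")
  gm_bad <- gene_model("g3", "chr1", "+", 10, 14)
  expect_error(classify_snp_effect("chr1", 11, substr(g, 12, 12), "A",
                                   gm_bad, genome), "divisible")
})

test_that("ns/s ratio handles counts, emptiness and undefined cases", {
  r <- ns_s_ratio(c("nonsynonymous", "nonsynonymous", "nonsynonymous",
                    "synonymous"))
  expect_equal(r$ratio, 3)
  expect_equal(ns_s_ratio(character(0))$status, "empty")
  u <- ns_s_ratio(rep("nonsynonymous", 3))
  expect_equal(u$status, "undefined")
  expect_true(is.na(u$ratio))
})

test_that("simulated SNP spectrum matches the codon-table expectation", {
  # oracle: exhaustive enumeration of all 9 single-base changes per codon
  codons <- names(Biostrings::GENETIC_CODE)
  n_ns <- 0L; n_total <- 0L
  for (cd in codons) {
    aa <- Biostrings::GENETIC_CODE[[cd]]
    for (i in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(cd, i, i))) {
      alt <- cd
      substr(alt, i, i) <- b
      n_total <- n_total + 1L
      if (Biostrings::GENETIC_CODE[[alt]] != aa) n_ns <- n_ns + 1L
    }
  }
  p_ns <- n_ns / n_total

  set.seed(35)
  cds_len <- 1200L
  g <- rand_seq(cds_len + 20L)
  genome <- c(chr1 = g)
  gm <- gene_model("g1", "chr1", "+", 10, 10 + cds_len)
  n_snp <- 1000L
  pos <- sample(10:(10 + cds_len - 1L), n_snp, replace = TRUE)
  eff <- vapply(pos, function(p) {
    ref <- substr(g, p + 1, p + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    classify_snp_effect("chr1", p, ref, alt, gm, genome)
  }, character(1))
  phat <- mean(eff == "nonsynonymous")
  se <- sqrt(p_ns * (1 - p_ns) / n_snp)
  expect_lt(abs(phat - p_ns), 4 * se)
  r <- ns_s_ratio(eff)
  expect_lt(abs(r$ratio - p_ns / (1 - p_ns)), 0.35)
})
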