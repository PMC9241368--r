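codes_from_counts <- function(cc, gg, cg = 0, nn = 0) {
  matrix(rep(c("CC", "GG", "CG", "NN"), c(cc, gg, cg, nn)), nrow = 1,
         dimnames = list("L1", sprintf("a%03d", seq_len(cc + gg + cg + nn))))
}

test_that("MAF uses presence alleles with NN excluded from the denominator", {
  expect_equal(unname(tip_maf(codes_from_counts(3, 97))), 0.03)
  expect_equal(unname(tip_maf(codes_from_counts(10, 90))), 0.10)
  # 5 CC / 90 GG / 5 NN -> 5/95
  expect_equal(unname(tip_maf(codes_from_counts(5, 90, nn = 5))), 5 / 95)
  # CG contributes one allele of each
  expect_equal(unname(tip_maf(codes_from_counts(1, 2, cg = 1))), 3 / 8)
})

test_that("maf_filter removes MAF <= threshold and is monotone", {
  m <- rbind(codes_from_counts(3, 97), codes_from_counts(10, 90),
             codes_from_counts(5, 90, nn = 5))
  rownames(m) <- c("low", "high", "edge")
  kept <- maf_filter(m, 0.05)
  expect_equal(rownames(kept), c("high", "edge"))   # 0.0526 survives 0.05
  expect_equal(attr(kept, "removed"), "low")
  strict <- maf_filter(m, 0.10)
  expect_true(all(rownames(strict) %in% rownames(kept)))
})

test_that("allele-sharing distances follow the mismatch rules", {
  m <- matrix("CC", nrow = 10, ncol = 3,
              dimnames = list(sprintf("L%02d", 1:10), c("a", "b", "c")))
  m[, "b"] <- "GG"
  m[1:2, "c"] <- "GG"
  d <- pairwise_distance(m)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["a", "b"], 1.0)
  expect_equal(d["a", "c"], 0.2)
  expect_equal(d, t(d))
  # heterozygote counts half
  m2 <- matrix(c("CC", "CG", "CC", "CC"), nrow = 2,
               dimnames = list(c("L1", "L2"), c("x", "y")))
  expect_equal(pairwise_distance(m2)["x", "y"], 0.25)
  m3 <- m
  m3[, "c"] <- "NN"
  expect_error(pairwise_distance(m3), "c")
})

test_that("neighbor joining recovers closed-form and additive trees", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- nj_tree(d)
  bl <- setNames(phy$edge.length[match(1:3, phy$edge[, 2])], phy$tip.label)
  expect_equal(bl, c(A = 1, B = 1, C = 3))

  set.seed(70)
  for (i in 1:5) {
    tr <- ape::rtree(5 + (i %% 3))
    dm <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(dm[order(rownames(dm)), order(colnames(dm))])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), rec)), 0)
    cm <- ape::cophenetic.phylo(rec)
    expect_equal(cm[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
  }

  dbad <- d; dbad[1, 2] <- 9
  expect_error(nj_tree(dbad), "symmetric")
})

test_that("two simulated groups come out monophyletic in the NJ tree", {
  sim <- simulate_population_matrix(
    60, c(red = 6, blue = 6),
    enriched = data.frame(locus = 1:30, red = 0.95, blue = 0.05),
    neutral_freq_range = c(0.45, 0.55), seed = 71)
  phy <- nj_tree(pairwise_distance(sim$codes))
  red_tips <- names(sim$groups)[sim$groups == "red"]
  expect_true(ape::is.monophyletic(phy, red_tips))
})

test_that("PCA separates groups and satisfies eigen properties", {
  sim <- simulate_population_matrix(
    80, c(g1 = 10, g2 = 10),
    enriched = data.frame(locus = 1:40, g1 = 0.95, g2 = 0.05),
    neutral_freq_range = c(0.45, 0.55), seed = 72)
  pc <- tip_pca(sim$codes, k = 5)
  s1 <- pc$coords[sim$groups == "g1", "PC1"]
  s2 <- pc$coords[sim$groups == "g2", "PC1"]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  expect_lte(sum(pc$explained), 1 + 1e-9)

  mono <- matrix("CC", 5, 4, dimnames = list(paste0("L", 1:5),
                                             paste0("a", 1:4)))
  pc0 <- suppressWarnings(tip_pca(mono, k = 5))
  expect_true(all(pc0$eigenvalues == 0))
})

test_that("fisher_exact_2x2 matches enumeration and handles edge tables", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), fisher_enum(3, 1, 1, 3))
  expect_warning(p0 <- fisher_exact_2x2(0, 0, 3, 4), "degenerate")
  expect_equal(p0, 1)

  set.seed(73)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.1, 1)))
    p <- suppressWarnings(do.call(fisher_exact_2x2, as.list(cells)))
    q <- suppressWarnings(
      stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value)
    expect_equal(p, q, tolerance = 1e-7)
  }
})

test_that("enrichment scan normalizes and ranks planted loci first", {
  sim <- simulate_population_matrix(
    100, c(derived = 60, control = 60),
    enriched = data.frame(locus = 1:3, derived = 0.9, control = 0.02),
    seed = 74)
  res <- enrichment_scan(sim$codes,
                         derived = names(sim$groups)[sim$groups == "derived"],
                         control = names(sim$groups)[sim$groups == "control"])
  expect_setequal(res$locus_id[1:3], sim$truth$enriched_loci)
  expect_equal(mean(res$z), 0, tolerance = 1e-10)
  expect_equal(sd(res$z), 1, tolerance = 1e-10)
  expect_equal(res$neg_log10_p, -log10(res$p))
  # identical frequencies give p = 1 and neg_log10_p = 0
  m <- rbind(L1 = rep(c("CC", "GG"), each = 10))
  colnames(m) <- sprintf("a%02d", 1:20)
  one <- enrichment_scan(m, derived = colnames(m)[c(1:5, 11:15)],
                         control = colnames(m)[c(6:10, 16:20)])
  expect_equal(one$p, 1)
  expect_equal(one$neg_log10_p, 0)
})

test_that("core-variant comparison reduces to the paired-t closed form", {
  set.seed(75)
  tip_p <- lapply(1:20, function(i) runif(sample(1:4, 1), 0, 0.2))
  names(tip_p) <- paste0("gene", 1:20)
  snp_p <- lapply(1:20, function(i) runif(sample(1:4, 1), 0, 0.4))
  names(snp_p) <- paste0("gene", 1:20)
  res <- core_variant_comparison(tip_p, snp_p)
  x <- vapply(tip_p, min, numeric(1))
  y <- vapply(snp_p, min, numeric(1))
  diffs <- x - y
  t_manual <- mean(diffs) / (sd(diffs) / sqrt(length(diffs)))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$df, 19L)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 19), tolerance = 1e-12)

  # identical columns: t = 0, p = 1
  same <- suppressWarnings(core_variant_comparison(tip_p, tip_p))
  expect_true(same$degenerate)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # constant nonzero differences flagged as degenerate with p -> 0
  shifted <- lapply(tip_p, function(v) v + 0.1)
  names(shifted) <- names(tip_p)
  single_tip <- lapply(tip_p, min)
  single_shift <- lapply(single_tip, function(v) v + 0.1)
  deg <- suppressWarnings(core_variant_comparison(single_tip, single_shift))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)

  # genes lacking SNPs are reported separately
  snp_p2 <- snp_p[1:15]
  res2 <- core_variant_comparison(tip_p, snp_p2)
  expect_setequal(res2$genes_without_snp, paste0("gene", 16:20))
  expect_error(core_variant_comparison(tip_p[1:2], snp_p[1:2]), "3")
})

test_that("cds_length_contrast is a plain 2x2 Fisher with p = 1 at equality", {
  expect_equal(cds_length_contrast(10, 10, 100, 100), 1.0)
  expect_equal(cds_length_contrast(145, 89, 3174, 3279),
               fisher_exact_2x2(145, 89, 3174, 3279))
})
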