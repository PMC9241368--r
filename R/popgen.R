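# Population analysis of a TIP genotype matrix: MAF filtering, allele-sharing
# distances, neighbor-joining, PCA, the Fisher's-exact selection scan and the
# core-TIP vs core-nonsynonymous-SNP comparison.

GENO_CODES <- c("CC", "GG", "CG", "NN")

#' Presence-allele dosage encoding of a code matrix
#' @noRd
code_dosage <- function(codes) {
  d <- matrix(NA_real_, nrow = nrow(codes), ncol = ncol(codes),
              dimnames = dimnames(codes))
  d[codes == "GG"] <- 0
  d[codes == "CG"] <- 1
  d[codes == "CC"] <- 2
  d
}

#' Minor allele frequency per TIP locus
#'
#' Alleles are presence/absence of the insertion; a CG call contributes one
#' of each, NN calls are excluded from the denominator (2 x non-missing
#' calls).
#'
#' @param codes Character matrix (loci x accessions) of CC/GG/CG/NN codes.
#' @return Numeric vector of per-locus MAF in \[0, 0.5\]; NA where all calls
#'   are missing.
#' @export
tip_maf <- function(codes) {
  pres <- 2 * rowSums(codes == "CC") + rowSums(codes == "CG")
  denom <- 2 * rowSums(codes != "NN")
  p <- ifelse(denom > 0, pres / denom, NA_real_)
  pmin(p, 1 - p)
}

#' Remove low-frequency homozygous loci
#'
#' Drops loci with MAF less than or equal to `threshold` (default 0.05,
#' the usual pre-analysis filter for TIP matrices).
#'
#' @param codes Genotype code matrix.
#' @param threshold MAF threshold; loci with `MAF <= threshold` are removed.
#' @return The filtered matrix; removed locus ids in `attr(x, "removed")`.
#' @export
maf_filter <- function(codes, threshold = 0.05) {
  maf <- tip_maf(codes)
  keep <- !is.na(maf) & maf > threshold
  out <- codes[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(codes)[!keep]
  out
}

#' Allele-sharing distance between accessions
#'
#' d(i, j) is the mean allele mismatch over loci where both accessions are
#' non-missing: opposite homozygotes count 1, homozygote vs heterozygote
#' 0.5, identical codes 0.
#'
#' @param codes Genotype code matrix (loci x accessions), >= 2 accessions.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(codes) {
  if (ncol(codes) < 2L) stop("need at least 2 accessions")
  d <- code_dosage(codes) / 2      # 0, 0.5, 1 presence fraction
  all_nn <- colSums(!is.na(d)) == 0L
  if (any(all_nn))
    stop("accession(s) with all calls missing: ",
         paste(colnames(codes)[all_nn], collapse = ", "))
  n <- ncol(d)
  out <- matrix(0, n, n, dimnames = list(colnames(d), colnames(d)))
  for (i in seq_len(n - 1L)) {
    diff <- abs(d[, (i + 1L):n, drop = FALSE] - d[, i])
    shared <- colSums(!is.na(diff))
    if (any(shared == 0L))
      stop("accession pairs sharing no genotyped loci: ", colnames(d)[i],
           " vs ", paste(colnames(d)[(i + 1L):n][shared == 0L],
                         collapse = ", "))
    val <- colMeans(diff, na.rm = TRUE)
    out[i, (i + 1L):n] <- val
    out[(i + 1L):n, i] <- val
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths
#' are clamped to zero with the deficit transferred to the sister edge so
#' path lengths between tips are preserved.
#'
#' @param d Symmetric distance matrix with zero diagonal, n >= 3.
#' @return An [ape] `phylo` object; write newick with [ape::write.tree()].
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  phy <- ape::nj(stats::as.dist(d))
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    parent <- phy$edge[e, 1L]
    sisters <- which(phy$edge[, 1L] == parent)
    sisters <- setdiff(sisters, e)
    if (length(sisters)) {
      s <- sisters[1L]
      phy$edge.length[s] <- phy$edge.length[s] + phy$edge.length[e]
    }
    phy$edge.length[e] <- 0
  }
  phy
}

#' Variance-standardized PCA of a TIP genotype matrix
#'
#' Encodes GG/CG/CC as dosages 0/1/2, centers each locus at `2p` and scales
#' by `sqrt(2p(1-p))` with `p` the presence-allele frequency (the plink
#' convention); missing calls are imputed to the locus mean. Coordinates are
#' the top-`k` eigenvectors of the accession covariance matrix; each
#' component's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param codes Genotype code matrix (ideally MAF-filtered).
#' @param k Number of components (default 20; truncated with a warning when
#'   `k >=` number of accessions).
#' @return List with `coords` (accessions x k), `eigenvalues`, and
#'   `explained` (fraction of total variance per component).
#' @export
tip_pca <- function(codes, k = 20L) {
  n <- ncol(codes)
  if (k >= n) {
    warning("k >= number of accessions; truncating to ", n - 1L)
    k <- n - 1L
  }
  dos <- code_dosage(codes)
  p <- rowMeans(dos, na.rm = TRUE) / 2
  informative <- !is.na(p) & p > 0 & p < 1
  dos <- dos[informative, , drop = FALSE]
  p <- p[informative]
  x <- (dos - 2 * p) / sqrt(2 * p * (1 - p))
  x[is.na(x)] <- 0
  if (!nrow(x)) {
    coords <- matrix(0, n, k,
                     dimnames = list(colnames(codes), paste0("PC", seq_len(k))))
    return(list(coords = coords, eigenvalues = rep(0, k),
                explained = rep(0, k)))
  }
  G <- crossprod(x) / nrow(x)
  eig <- eigen(G, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(codes), paste0("PC", seq_len(k)))
  list(coords = vecs, eigenvalues = vals[seq_len(k)],
       explained = if (sum(vals) > 0) vals[seq_len(k)] / sum(vals)
                   else rep(0, k))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test: the two-sided p-value sums the hypergeometric
#' probabilities of every table with the observed margins whose point
#' probability does not exceed that of the observed table (within relative
#' tolerance 1e-7). Computed in log space, so extreme tables (p ~ 1e-80)
#' are exact.
#'
#' @param a,b,c,d Cell counts: rows are the two groups, columns
#'   carrier / non-carrier.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)  # 34/70
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cnt <- vapply(list(a, b, c, d), check_count, integer(1), name = "count")
  a <- cnt[1]; b <- cnt[2]; c <- cnt[3]; d <- cnt[4]
  m <- a + b; n <- c + d; kk <- a + c
  if (m == 0L || n == 0L || kk == 0L || (b + d) == 0L) {
    warning("degenerate 2x2 table (zero margin); p = 1 by convention")
    return(1)
  }
  support <- max(0L, kk - n):min(kk, m)
  logp <- stats::dhyper(support, m, n, kk, log = TRUE)
  obs <- stats::dhyper(a, m, n, kk, log = TRUE)
  min(1, sum(exp(logp[logp <= obs + log1p(1e-7)])))
}

#' Fisher's-exact selection scan over a genotype matrix
#'
#' For every locus, counts insertion carriers (CC or CG) and non-carriers
#' (GG) in a derived and a control accession group (NN excluded), tests the
#' 2x2 table with [fisher_exact_2x2()], and normalizes: `neg_log10_p` is
#' -log10(p) and `z` its z-score across all scanned loci (all-zero when the
#' sd is zero). Loci with no genotyped accession in one group are skipped
#' with a warning.
#'
#' @param codes Genotype code matrix.
#' @param derived,control Disjoint, non-empty accession id vectors.
#' @return data.frame sorted by p: locus_id, a, b, c, d, p, neg_log10_p, z.
#' @export
enrichment_scan <- function(codes, derived, control) {
  if (!length(derived) || !length(control))
    stop("groups must be non-empty")
  if (length(intersect(derived, control)))
    stop("derived and control groups must be disjoint")
  missing_acc <- setdiff(c(derived, control), colnames(codes))
  if (length(missing_acc))
    stop("accessions not in matrix: ", paste(missing_acc, collapse = ", "))
  der <- codes[, derived, drop = FALSE]
  ctl <- codes[, control, drop = FALSE]
  a <- rowSums(der == "CC" | der == "CG")
  b <- rowSums(der == "GG")
  c_ <- rowSums(ctl == "CC" | ctl == "CG")
  d <- rowSums(ctl == "GG")
  ok <- (a + b) > 0 & (c_ + d) > 0
  if (any(!ok))
    warning(sum(!ok), " locus/loci with no genotyped accession in a group ",
            "skipped")
  p <- rep(NA_real_, nrow(codes))
  p[ok] <- vapply(which(ok), function(i)
    fisher_exact_2x2(a[i], b[i], c_[i], d[i]), numeric(1))
  nl <- -log10(p)
  s <- stats::sd(nl[ok])
  z <- if (is.na(s) || s == 0) rep(0, length(nl))
       else (nl - mean(nl[ok])) / s
  z[!ok] <- NA_real_
  out <- data.frame(locus_id = rownames(codes), a = a, b = b, c = c_, d = d,
                    p = p, neg_log10_p = nl, z = z,
                    stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  out[order(out$p, out$locus_id), , drop = FALSE]
}

#' Core-TIP vs core-nonsynonymous-SNP paired comparison
#'
#' Within each candidate gene the TIP (and nonsynonymous SNP) with the
#' smallest scan p-value is its core variant. Genes with at least one of
#' each enter a paired two-sided t-test on the per-gene core p-values (raw
#' p by default; `log10 = TRUE` compares -log10 p). Genes lacking SNPs are
#' reported separately.
#'
#' @param tip_p,snp_p Named lists: gene_id -> numeric vector of p-values.
#' @param log10 Compare -log10-transformed p-values instead of raw p.
#' @return List with `t`, `df`, `p`, `mean_tip`, `mean_snp`, `n`,
#'   `genes_without_snp`, `degenerate` (TRUE when the paired differences
#'   have zero variance) and `records` (per-gene core values).
#' @export
core_variant_comparison <- function(tip_p, snp_p, log10 = FALSE) {
  genes_tip <- names(tip_p)[vapply(tip_p, length, integer(1)) > 0L]
  genes_snp <- names(snp_p)[vapply(snp_p, length, integer(1)) > 0L]
  both <- intersect(genes_tip, genes_snp)
  without_snp <- setdiff(genes_tip, genes_snp)
  if (length(both) < 3L) stop("need at least 3 genes with both variant types")
  core_tip <- vapply(tip_p[both], min, numeric(1))
  core_snp <- vapply(snp_p[both], min, numeric(1))
  records <- data.frame(gene_id = both, core_tip_p = core_tip,
                        core_snp_p = core_snp, stringsAsFactors = FALSE)
  x <- if (log10) -log10(core_tip) else core_tip
  y <- if (log10) -log10(core_snp) else core_snp
  diffs <- x - y
  degenerate <- stats::sd(diffs) <=
    10 * .Machine$double.eps * max(1, abs(mean(diffs)))
  if (degenerate) {
    res <- if (isTRUE(all.equal(mean(diffs), 0))) list(t = 0, p = 1)
           else list(t = sign(mean(diffs)) * Inf, p = 0)
    warning("paired differences have zero variance; degenerate t-test")
    t_stat <- res$t; p_val <- res$p
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    t_stat <- unname(tt$statistic); p_val <- tt$p.value
  }
  list(t = t_stat, df = length(both) - 1L, p = p_val,
       mean_tip = mean(x), mean_snp = mean(y), n = length(both),
       genes_without_snp = without_snp, degenerate = degenerate,
       records = records)
}

#' CDS-length change contrast for TIP-containing genes
#'
#' Tests whether syntenic gene pairs carrying a TIP (in coding regions or
#' introns) are enriched for shortened CDS relative to all syntenic pairs:
#' Fisher's exact test on \[\[shorter_subset, longer_subset\],
#' \[shorter_all, longer_all\]\].
#'
#' @param shorter_subset,longer_subset Counts among TIP-containing pairs.
#' @param shorter_all,longer_all Counts among all syntenic pairs.
#' @return Two-sided Fisher p-value.
#' @export
cds_length_contrast <- function(shorter_subset, longer_subset,
                                shorter_all, longer_all) {
  fisher_exact_2x2(shorter_subset, longer_subset, shorter_all, longer_all)
}
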