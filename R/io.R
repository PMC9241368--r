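# Plain-text I/O for genotype matrices, group manifests and result tables.

#' Write / read a genotype code matrix as TSV
#'
#' Loci are rows (first column `locus_id`), accessions are columns, cells
#' are CC/GG/CG/NN.
#'
#' @param codes Character matrix (loci x accessions).
#' @param path Output file.
#' @export
write_genotype_matrix <- function(codes, path) {
  df <- data.frame(locus_id = rownames(codes), codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  bad <- !m %in% GENO_CODES
  if (any(bad))
    stop("invalid genotype codes in ", path, ": ",
         paste(unique(m[bad]), collapse = ", "))
  m
}

#' Export a genotype matrix as a minimal VCF
#'
#' Presence of the insertion is the ALT allele (`<INS:ME>`): CC becomes
#' `1/1`, GG `0/0`, CG `0/1`, NN `./.`.
#'
#' @param codes Genotype code matrix.
#' @param loci Optional data.frame with `locus_id`, `contig`, `position`
#'   (0-based) and `te_id`; defaults to placeholder coordinates.
#' @param path Output file.
#' @export
write_genotype_vcf <- function(codes, path, loci = NULL) {
  if (is.null(loci))
    loci <- data.frame(locus_id = rownames(codes), contig = "unknown",
                       position = seq_len(nrow(codes)) - 1L,
                       te_id = NA_character_, stringsAsFactors = FALSE)
  loci <- loci[match(rownames(codes), loci$locus_id), , drop = FALSE]
  gt <- c(CC = "1/1", GG = "0/0", CG = "0/1", NN = "./.")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=INS:ME,Description=\"Mobile element insertion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(codes)), collapse = "\t"))
  body <- vapply(seq_len(nrow(codes)), function(i) {
    info <- if (is.na(loci$te_id[i])) "SVTYPE=INS"
            else paste0("SVTYPE=INS;MEID=", loci$te_id[i])
    paste(c(loci$contig[i], loci$position[i] + 1L, rownames(codes)[i], "N",
            "<INS:ME>", ".", "PASS", info, "GT", gt[codes[i, ]]),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read an accession group manifest
#'
#' Two-column TSV (accession, group), with or without a header line.
#'
#' @param path TSV file.
#' @return Named character vector: accession -> group label.
#' @export
read_group_manifest <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (identical(tolower(df[1L, 1L]), "accession"))
    df <- df[-1L, , drop = FALSE]
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a result table as TSV with 6-significant-digit floats
#' @noRd
write_result_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
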