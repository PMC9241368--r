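# End-to-end orchestration: fixture presets, stage runner, run manifest.

#' Fixture preset parameters
#'
#' Three bundled synthetic designs: `tiny` (3 loci x 6 accessions, for smoke
#' tests), `demo` (50 loci x 60 accessions at 20x error-free coverage, the
#' genotyping-recovery benchmark) and `scan_only` (matrix-level design of
#' 500 loci across 329 derived + 195 control accessions with five loci
#' planted at carrier frequencies 0.80 vs 0.02, the selection-scan
#' benchmark).
#'
#' @param preset One of "tiny", "demo", "scan_only".
#' @return Named list of design parameters.
#' @export
preset_config <- function(preset = c("tiny", "demo", "scan_only")) {
  preset <- match.arg(preset)
  base <- list(
    read_length = 150L, insert_mean = 500, insert_sd = 50, coverage = 20,
    error_rate = 0, carrier_frequency = 0.5, te_length_range = c(3000, 6000),
    flank = 1000L, min_aln = 20L)
  switch(preset,
    tiny = c(base, list(preset = "tiny", base_length = 16000L, n_loci = 3L,
                        n_accessions = 6L, te_n = 3L, min_spacing = 2500L)),
    demo = c(base, list(preset = "demo", base_length = 125000L, n_loci = 50L,
                        n_accessions = 60L, te_n = 50L, min_spacing = 2300L)),
    scan_only = list(preset = "scan_only", n_loci = 500L,
                     groups = c(heading = 329L, nonheading = 195L),
                     n_enriched = 5L, enriched_freq = c(0.80, 0.02),
                     neutral_freq_range = c(0.1, 0.9)))
}

#' Build a pan-genome population fixture in memory
#'
#' Simulates the TE library, base genome, donor genomes and per-accession
#' paired reads for a sequence-level preset, returning everything needed to
#' exercise classification, collation and genotyping against known truth.
#'
#' @param cfg A [preset_config()] list (presets "tiny" or "demo").
#' @param seed Master seed; per-accession read seeds are derived from it.
#' @param with_reads Simulate reads (set FALSE to skip when only genomes and
#'   truth are needed).
#' @return List with `library`, `pangenome` (see [simulate_pangenome()]) and
#'   `reads` (named list accession -> list(r1, r2)).
#' @export
build_population_fixture <- function(cfg, seed = 1L, with_reads = TRUE) {
  lib <- simulate_te_library(cfg$te_n, cfg$te_length_range, seed = seed)
  pg <- simulate_pangenome(cfg$base_length, lib, cfg$n_accessions,
                           cfg$n_loci,
                           carrier_frequency = cfg$carrier_frequency,
                           min_spacing = cfg$min_spacing,
                           seed = seed + 1L)
  reads <- NULL
  if (with_reads) {
    reads <- lapply(seq_along(pg$donors), function(i)
      simulate_reads(pg$donors[[i]], read_length = cfg$read_length,
                     insert_mean = cfg$insert_mean,
                     insert_sd = cfg$insert_sd, coverage = cfg$coverage,
                     error_rate = cfg$error_rate, seed = seed + 1000L + i,
                     id_prefix = paste0(names(pg$donors)[i], "_")))
    names(reads) <- names(pg$donors)
  }
  list(library = lib, pangenome = pg, reads = reads)
}

#' Build the scan-only genotype matrix fixture
#'
#' @param cfg A [preset_config()] list (preset "scan_only").
#' @param seed RNG seed (also picks which loci are enriched).
#' @return As [simulate_population_matrix()].
#' @export
build_scan_matrix <- function(cfg, seed = 1L) {
  enriched_idx <- with_seed(seed,
                            sort(sample.int(cfg$n_loci, cfg$n_enriched)))
  enriched <- data.frame(locus = enriched_idx)
  for (i in seq_along(cfg$groups))
    enriched[[names(cfg$groups)[i]]] <- cfg$enriched_freq[i]
  simulate_population_matrix(cfg$n_loci, cfg$groups, enriched = enriched,
                             neutral_freq_range = cfg$neutral_freq_range,
                             seed = seed + 1L)
}

#' Write a synthetic fixture to disk
#'
#' Writes genomes (FASTA), reads (paired FASTQ), truth tables (TSV) and a
#' JSON manifest for a preset, or the genotype matrix + group manifest for
#' `scan_only`.
#'
#' @param preset Preset name (see [preset_config()]).
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @param with_reads Write per-accession FASTQ files (sequence presets).
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture <- function(preset, seed = 1L, dir, with_reads = TRUE) {
  cfg <- preset_config(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (preset == "scan_only") {
    sim <- build_scan_matrix(cfg, seed)
    files["matrix"] <- file.path(dir, "matrix.tsv")
    write_genotype_matrix(sim$codes, files["matrix"])
    files["groups"] <- file.path(dir, "groups.tsv")
    utils::write.table(data.frame(accession = names(sim$groups),
                                  group = unname(sim$groups)),
                       files["groups"], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files["truth"] <- file.path(dir, "truth_enriched.tsv")
    writeLines(c("locus_id", sim$truth$enriched_loci), files["truth"])
  } else {
    fx <- build_population_fixture(cfg, seed, with_reads = with_reads)
    files["library"] <- file.path(dir, "library.fa")
    write_te_library(fx$library, files["library"])
    files["base"] <- file.path(dir, "base.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(fx$pangenome$base), files["base"])
    files["donors"] <- file.path(dir, "donors.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(fx$pangenome$donors), files["donors"])
    files["loci"] <- file.path(dir, "truth_loci.tsv")
    utils::write.table(fx$pangenome$truth$loci, files["loci"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files["carriers"] <- file.path(dir, "truth_carriers.tsv")
    utils::write.table(fx$pangenome$truth$carriers, files["carriers"],
                       sep = "\t", quote = FALSE)
    files["sv"] <- file.path(dir, "sv_truth.tsv")
    utils::write.table(fx$pangenome$sv, files["sv"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (with_reads) {
      rdir <- file.path(dir, "reads")
      dir.create(rdir, showWarnings = FALSE)
      for (acc in names(fx$reads))
        write_fastq_pair(fx$reads[[acc]], file.path(rdir, acc))
      files["reads_dir"] <- rdir
    }
  }
  manifest <- list(preset = preset, seed = seed,
                   parameters = cfg, files = as.list(files),
                   md5 = as.list(tools::md5sum(
                     files[file.exists(files) & !dir.exists(files)])))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

RUN_CONFIG_DEFAULTS <- list(
  preset = "tiny", seed = 1L, out_dir = "tipscan_run",
  stages = c("simulate", "classify", "collate", "genotype", "scan"),
  id_min = 80, cov_min = 80, flank = 1000L, min_aln = 20L,
  maf_threshold = 0.05, merge_window = 100L, merge_similarity = 80,
  min_presence = 1L, min_absence = 1L, het_fraction = 0.2,
  matrix_path = NULL, groups_path = NULL, quiet = FALSE)

#' Load a pipeline run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the documented defaults.
#' @param path YAML file of `key: value` pairs.
#' @return Validated config list.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @noRd
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(RUN_CONFIG_DEFAULTS, cfg)
  bad <- setdiff(out$stages, c("simulate", "classify", "collate",
                               "genotype", "scan", "tree", "pca"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  out
}

#' Run the TIP pipeline end-to-end on a synthetic fixture
#'
#' Executes the selected stages in order (simulate -> classify -> collate ->
#' genotype -> scan, optionally tree and pca), writing one TSV per stage
#' plus `run.log` and a JSON manifest with the effective configuration and
#' output checksums. Reruns with an identical config reproduce identical
#' outputs. A standalone "scan" (or "tree"/"pca") run can start from a
#' genotype matrix given by `matrix_path` + `groups_path`.
#'
#' @param config List (see `load_run_config()` for keys and defaults).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (!cfg$quiet) message(msg)
  }
  logf("run_pipeline start; effective config: ",
       jsonlite::toJSON(cfg[setdiff(names(cfg), "stages")],
                        auto_unbox = TRUE))
  outputs <- character(0)
  state <- list()

  if ("simulate" %in% cfg$stages) {
    logf("stage simulate: preset ", cfg$preset, " seed ", cfg$seed)
    pc <- preset_config(cfg$preset)
    state$fixture <- build_population_fixture(pc, cfg$seed)
    state$preset <- pc
  }
  if ("classify" %in% cfg$stages) {
    if (is.null(state$fixture)) stop("stage classify needs stage simulate")
    logf("stage classify: 80-80 rule at ", cfg$id_min, "/", cfg$cov_min)
    state$classified <- classify_sv_table(state$fixture$pangenome$sv,
                                          state$fixture$library,
                                          id_min = cfg$id_min,
                                          cov_min = cfg$cov_min)
    p <- file.path(cfg$out_dir, "classified_svs.tsv")
    write_result_tsv(state$classified[, setdiff(names(state$classified),
                                                "sequence")], p)
    outputs <- c(outputs, p)
  }
  if ("collate" %in% cfg$stages) {
    if (is.null(state$classified)) stop("stage collate needs stage classify")
    keep <- state$classified[state$classified$classified %in% TRUE, ]
    logf("stage collate: ", nrow(keep), " classified SVs")
    state$loci <- collate_insertions(keep, merge_window = cfg$merge_window,
                                     merge_similarity = cfg$merge_similarity)
    p <- file.path(cfg$out_dir, "tip_loci.tsv")
    write_result_tsv(state$loci[, setdiff(names(state$loci), "sequence")], p)
    outputs <- c(outputs, p)
  }
  if ("genotype" %in% cfg$stages) {
    if (is.null(state$loci)) stop("stage genotype needs stage collate")
    logf("stage genotype: ", nrow(state$loci), " loci x ",
         length(state$fixture$reads), " accessions")
    constructs <- lapply(seq_len(nrow(state$loci)), function(i)
      build_locus_construct(state$loci[i, ], state$fixture$pangenome$base,
                            flank = cfg$flank))
    gp <- genotype_population(constructs, state$fixture$reads,
                              min_aln = cfg$min_aln,
                              min_presence = cfg$min_presence,
                              min_absence = cfg$min_absence,
                              het_fraction = cfg$het_fraction)
    state$codes <- gp$codes
    p <- file.path(cfg$out_dir, "genotypes.tsv")
    write_genotype_matrix(gp$codes, p)
    p2 <- file.path(cfg$out_dir, "genotype_evidence.tsv")
    write_result_tsv(gp$calls, p2)
    outputs <- c(outputs, p, p2)
  }
  if (any(c("scan", "tree", "pca") %in% cfg$stages)) {
    if (is.null(state$codes)) {
      if (is.null(cfg$matrix_path))
        stop("stage scan needs stage genotype or `matrix_path`")
      state$codes <- read_genotype_matrix(cfg$matrix_path)
    }
    filtered <- maf_filter(state$codes, cfg$maf_threshold)
    logf("MAF filter <= ", cfg$maf_threshold, ": ",
         length(attr(filtered, "removed")), " loci removed, ",
         nrow(filtered), " kept")
    if ("scan" %in% cfg$stages) {
      groups <- if (!is.null(cfg$groups_path))
        read_group_manifest(cfg$groups_path)
      else {
        acc <- colnames(state$codes)   # default contrast: first vs second half
        stats::setNames(rep(c("derived", "control"),
                            c(ceiling(length(acc) / 2),
                              floor(length(acc) / 2))), acc)
      }
      labs <- unique(groups)
      scan <- enrichment_scan(filtered,
                              derived = names(groups)[groups == labs[1L]],
                              control = names(groups)[groups == labs[2L]])
      p <- file.path(cfg$out_dir, "selection_scan.tsv")
      write_result_tsv(scan, p)
      outputs <- c(outputs, p)
      logf("stage scan: ", nrow(scan), " loci tested; min p = ",
           format(min(scan$p), digits = 3))
    }
    if ("tree" %in% cfg$stages) {
      phy <- nj_tree(pairwise_distance(filtered))
      p <- file.path(cfg$out_dir, "nj_tree.nwk")
      ape::write.tree(phy, p)
      outputs <- c(outputs, p)
      logf("stage tree: ", length(phy$tip.label), " tips")
    }
    if ("pca" %in% cfg$stages) {
      pc <- tip_pca(filtered)
      p <- file.path(cfg$out_dir, "pca_coords.tsv")
      write_result_tsv(data.frame(accession = rownames(pc$coords),
                                  pc$coords, check.names = FALSE), p)
      outputs <- c(outputs, p)
      logf("stage pca: top explained fraction ",
           format(pc$explained[1L], digits = 3))
    }
  }

  manifest <- list(config = cfg, outputs = as.list(outputs),
                   md5 = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("run_pipeline done; ", length(outputs), " outputs")
  invisible(manifest)
}
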