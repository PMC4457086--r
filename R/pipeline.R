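# Pipeline orchestration: a single YAML-serialisable run configuration
# driving simulate -> ingest -> pause -> motif -> errors -> genes, with
# deterministic seeds and a checksummed output manifest.

#' Default run configuration
#'
#' Every stochastic stage has an explicit seed; all values can be
#' overridden in the YAML config or by editing the returned list.
#' Thresholds follow the standard calling regimes: P(0.9, 100) for
#' bulk pausing and P(0.9, 50) for single-length analyses.
#'
#' @param seed master seed (mandatory in configs).
#' @return a named list (class `run_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    strain = "WT",
    simulate = list(
      n_bp = 20000L, gc = 0.5, n_genes = 20L, include_rrna = FALSE,
      n_pause_sites = 30L, motif_class = "WT_PIE",
      dwell_weight = 200,
      n_reads = 100000L
    ),
    alignments = NULL,   # path to SAM/BAM for real-data ingestion
    genome = NULL, annotation = NULL, tss = NULL,
    pause = list(phi_min = 0.9, delta_min = 100, length_class = "elong",
                 mapq_min = 10),
    motif = list(window = c(-15L, 5L), pseudocount = 0.25),
    errors = list(lengths = 14:18, unique_only = TRUE),
    genes = list(min_norm = 0.1, region_width = 50L),
    out_dir = "rnetseq_out"
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config a config list.
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  if (is.null(config$seed) || is.na(suppressWarnings(
    as.integer(config$seed)))) {
    v <- c(v, "seed is mandatory and must be an integer")
  }
  p <- config$pause
  if (!is.null(p)) {
    if (!is.null(p$phi_min) && (p$phi_min <= 0 || p$phi_min > 1)) {
      v <- c(v, "pause$phi_min must be in (0, 1]")
    }
    if (!is.null(p$delta_min) && p$delta_min < 1) {
      v <- c(v, "pause$delta_min must be >= 1")
    }
  }
  s <- config$simulate
  if (!is.null(s)) {
    if (!is.null(s$gc) && (s$gc < 0 || s$gc > 1)) {
      v <- c(v, "simulate$gc must be in [0, 1]")
    }
    if (!is.null(s$n_reads) && s$n_reads < 1) {
      v <- c(v, "simulate$n_reads must be >= 1")
    }
  }
  if (is.null(config$simulate) && is.null(config$alignments)) {
    v <- c(v, "either a simulate block or an alignments path is required")
  }
  v
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_config()),
                           yaml::read_yaml(path))
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config)[order(names(config))], f)
  # hash the serialised semantic content, not the list object identity
  yaml_f <- tempfile()
  on.exit(unlink(yaml_f), add = TRUE)
  yaml::write_yaml(unclass(config), yaml_f)
  unname(tools::md5sum(yaml_f))
}

write_tsv_with_header <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: simulate (or ingest
#' existing alignments), pileup and pause calling, motif matrix
#' construction, error profiling, and gene/region metrics, writing all
#' artifacts into `config$out_dir`. Each TSV carries a header comment
#' with the config hash; rerunning an identical config reproduces
#' identical checksums.
#'
#' @param config a run configuration (see [default_config()]).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return manifest data frame (`file`, `md5`), invisibly also written
#'   as `manifest.tsv`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  pth <- function(f) file.path(out_dir, f)

  if (!is.null(config$simulate)) {
    s <- config$simulate
    gen <- generate_genome(s$n_bp, s$gc, s$n_genes, seed = config$seed,
                           include_rrna = isTRUE(s$include_rrna))
    strain <- strain_profile(config$strain)
    mis <- s$misincorporation_rate %||%
      strain$default_misincorporation_rate
    planted <- plant_pauses(gen$genome, gen$genes, s$n_pause_sites,
                            motif_class = s$motif_class,
                            seed = config$seed + 1L,
                            dwell_weight = s$dwell_weight,
                            misincorporation_rate = mis)
    sim <- simulate_reads(planted$genome, gen$genes, planted$pauses,
                          strain, s$n_reads, seed = config$seed + 2L)
    write_genome_fasta(planted$genome, pth("genome.fa"))
    write_genes_gff3(gen$genes, planted$genome, pth("genes.gff3"))
    write_tss_table(gen$tss, pth("tss.tsv"))
    write_fastq(sim, pth("reads.fastq"))
    write_sam(sim, pth("alignments.sam"))
    write_truth(sim$truth, pth("truth.tsv"))
    genome <- planted$genome
    genes <- gen$genes
    tss <- gen$tss
    aln <- read_alignments(pth("alignments.sam"), genome = genome)
  } else {
    genome <- if (!is.null(config$genome)) {
      read_genome_fasta(config$genome)
    } else NULL
    genes <- read_genes_gff3(config$annotation)
    tss <- read_tss_table(config$tss)
    aln <- read_alignments(config$alignments, genome = genome)
    if (is.null(genome)) {
      stop("a genome FASTA is required for pileup and motif analysis",
           call. = FALSE)
    }
  }

  # pause calling
  track <- build_pileup(aln, genome,
                        length_class = config$pause$length_class)
  pauses <- call_pauses(track, config$pause$phi_min,
                        config$pause$delta_min)
  pauses <- filter_mapq(pauses, config$pause$mapq_min)$kept
  pause_out <- pauses
  pause_out$position <- pause_out$pos + 1L
  pause_out$pos <- NULL
  write_tsv_with_header(pause_out, pth("pauses.tsv"), hash)
  write_pause_bed(pauses, pth("pauses.bed"))

  # motif
  if (nrow(pauses) > 0) {
    wins <- extract_windows(pauses, genome, config$motif$window)
    pie <- frequency_matrix(wins, config$motif$window,
                            pseudocount = config$motif$pseudocount,
                            background = base_composition(genome$seq))
    write_pie_matrix(pie, pth("pie_matrix.tsv"))
  }

  # errors
  mats <- lapply(config$errors$lengths, function(L)
    accumulate_errors(aln, L, unique_only = config$errors$unique_only))
  names(mats) <- paste0("L", config$errors$lengths)
  write_error_matrices(mats, pth("error_matrices.tsv"))

  # gene metrics
  gcounts <- count_gene_reads(aln, genes)
  rcounts <- count_region_reads(aln, genes,
                                width = config$genes$region_width)
  write_tsv_with_header(gcounts, pth("gene_counts.tsv"), hash)
  write_tsv_with_header(rcounts, pth("region_counts.tsv"), hash)
  write_tsv_with_header(read_length_histogram(aln),
                        pth("read_lengths.tsv"), hash)

  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, pth("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
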