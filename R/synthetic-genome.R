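#' Generate a miniature annotated genome
#'
#' Builds a random single-replicon genome with non-overlapping genes on
#' both strands, per-gene transcription start sites (TSS), CDS bounds,
#' operon labels and log-normal expression levels. At least one
#' convergent (head-to-head) gene pair is always placed so that
#' antisense/convergent-transcription analyses can be exercised.
#' Optionally, seven identical ribosomal-RNA gene copies are written
#' into the sequence to mimic the multi-copy rRNA operons that defeat
#' unique read mapping.
#'
#' Coordinates are 0-based half-open internally; exported GFF3/TSV use
#' 1-based coordinates.
#'
#' @param n_bp genome length in bp (>= 2000).
#' @param gc GC content in `[0,1]`.
#' @param n_genes number of protein-coding genes to place.
#' @param seed integer seed; the output is byte-for-byte reproducible
#'   for a fixed seed.
#' @param include_rrna if `TRUE`, add 7 identical copies of one rRNA
#'   gene (`copy_number = 7`).
#' @param utr5_range integer range from which 5' UTR lengths are drawn.
#' @param cds_range integer range from which CDS lengths are drawn
#'   (rounded to codon multiples).
#' @param utr3_len 3' UTR length appended after the stop codon.
#' @param margin terminal genome margin kept gene-free; the simulator
#'   also never emits reads within this margin, so circular replicons
#'   need no origin-spanning logic.
#' @return a list with elements `genome` (class `sim_genome`: list of
#'   `replicon_id`, `seq`, `circular`, `gc_content`), `genes` (data
#'   frame, one row per gene copy) and `tss` (data frame with columns
#'   `replicon`, `pos`, `strand`; `pos` 0-based).
#' @export
generate_genome <- function(n_bp, gc = 0.5, n_genes = 20, seed,
                            include_rrna = FALSE,
                            utr5_range = c(20L, 60L),
                            cds_range = c(180L, 450L),
                            utr3_len = 30L,
                            margin = 50L) {
  stopifnot_scalar_number(n_bp, "n_bp")
  stopifnot_scalar_number(seed, "seed")
  if (n_bp < 2000) stop("n_bp must be >= 2000", call. = FALSE)
  if (gc < 0 || gc > 1) stop("gc must be in [0,1]", call. = FALSE)
  set.seed(as.integer(seed))

  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq_chars <- sample(BASES, n_bp, replace = TRUE, prob = probs)

  n_rrna <- if (include_rrna) 7L else 0L
  rrna_len <- 120L
  gap_range <- c(40L, 120L)

  # Draw gene geometries, then check they fit.
  n_total <- n_genes + n_rrna
  utr5 <- sample(seq(utr5_range[1], utr5_range[2]), n_total, replace = TRUE)
  cds_len <- 3L * (sample(seq(cds_range[1], cds_range[2]), n_total,
                          replace = TRUE) %/% 3L)
  span <- utr5 + cds_len + utr3_len
  if (n_rrna > 0) span[n_genes + seq_len(n_rrna)] <- rrna_len
  gaps <- sample(seq(gap_range[1], gap_range[2]), n_total, replace = TRUE)
  if (2L * margin + sum(span) + sum(gaps) > n_bp) {
    stop("n_genes incompatible with n_bp: annotation does not fit",
         call. = FALSE)
  }

  # Shuffle gene order so rRNA copies are interspersed, then lay out
  # left to right.
  ord <- sample.int(n_total)
  strand <- sample(c("+", "-"), n_total, replace = TRUE)
  # Guarantee one convergent head-to-head pair among the coding genes.
  coding_slots <- which(ord <= n_genes)
  if (length(coding_slots) >= 2L) {
    i <- coding_slots[1L]
    j <- coding_slots[2L]
    strand[i] <- "+"
    strand[j] <- "-"
  }

  lo <- integer(n_total)
  cursor <- margin
  for (k in seq_len(n_total)) {
    lo[k] <- cursor + gaps[k]
    cursor <- lo[k] + span[ord[k]]
  }

  idx <- ord  # idx[k] = which drawn geometry occupies slot k
  span_k <- span[idx]
  utr5_k <- utr5[idx]
  cds_k <- cds_len[idx]
  is_rrna <- idx > n_genes
  hi <- lo + span_k

  # Per-gene fields in transcription orientation.
  tss <- ifelse(strand == "+", lo, hi - 1L)
  cds_lo <- ifelse(is_rrna, lo,
                   ifelse(strand == "+", lo + utr5_k, lo + utr3_len))
  cds_hi <- ifelse(is_rrna, hi,
                   ifelse(strand == "+", lo + utr5_k + cds_k, hi - utr5_k))

  gene_id <- character(n_total)
  gene_id[!is_rrna] <- sprintf("gene%03d", idx[!is_rrna])
  gene_id[is_rrna] <- sprintf("rrnA_copy%d", idx[is_rrna] - n_genes)
  biotype <- ifelse(is_rrna, "rRNA", "mRNA")

  expr_by_geom <- stats::rlnorm(n_total, meanlog = log(4), sdlog = 0.7)
  expr <- expr_by_geom[idx]
  expr[is_rrna] <- stats::median(expr_by_geom)  # identical copies share level

  # Write the shared rRNA sequence into every copy.
  if (n_rrna > 0) {
    rrna_seq <- sample(BASES, rrna_len, replace = TRUE, prob = probs)
    for (k in which(is_rrna)) {
      s <- if (strand[k] == "+") rrna_seq else {
        rev(chartr("ACGT", "TGCA", rrna_seq))
      }
      seq_chars[(lo[k] + 1L):hi[k]] <- s
    }
  }

  genes <- data.frame(
    gene_id = gene_id,
    biotype = biotype,
    strand = strand,
    start = lo,
    end = hi,
    tss = tss,
    cds_lo = cds_lo,
    cds_hi = cds_hi,
    operon_id = paste0("op_", gene_id),
    operon_first = TRUE,
    copy_number = ifelse(is_rrna, 7L, 1L),
    expr_level = expr,
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  genome <- structure(list(
    replicon_id = "sim_chr",
    seq = paste(seq_chars, collapse = ""),
    circular = TRUE,
    gc_content = gc
  ), class = "sim_genome")

  tss_tab <- data.frame(replicon = genome$replicon_id,
                        pos = genes$tss, strand = genes$strand,
                        gene_id = genes$gene_id,
                        stringsAsFactors = FALSE)

  list(genome = genome, genes = genes, tss = tss_tab)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %s: %d bp, GC %.2f, %s\n", x$replicon_id,
              nchar(x$seq), x$gc_content,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

# Motif definitions on the non-template strand, keyed by offset from
# the pause 3'-end base (-1 convention, no offset 0).
pie_motif_bases <- function(motif_class) {
  switch(motif_class,
    WT_PIE   = c("-10" = "G", "-3" = "T", "-2" = "G", "-1" = "C", "+1" = "G"),
    dGre_PIE = c("-11" = "G", "-7" = "T", "-4" = "T"),
    none     = c(),
    stop("unknown motif_class: ", motif_class, call. = FALSE)
  )
}

#' Plant pause-inducing elements into a genome
#'
#' Edits the genome so that each planted site carries a pause motif on
#' the non-template strand, anchored at the intended 3'-end base
#' (offset -1). The `"WT_PIE"` motif is G at -10 with TGC at -3..-1 and
#' G at +1; the `"dGre_PIE"` motif is G at -11 with T at -4 and -7.
#' Sites with a non-zero `misincorporation_rate` additionally receive
#' the CpG error element C at -2, G at -1 (overriding any motif base at
#' those offsets), so that reads ending at the site expose a reference
#' G whose misreading as A is a bona fide G-to-A misincorporation.
#'
#' Sites are placed inside mRNA gene bodies on the gene strand, at
#' least `gene_margin` bp from the gene ends and at least `min_spacing`
#' bp apart (any strand).
#'
#' @param genome a `sim_genome`.
#' @param genes gene table from [generate_genome()].
#' @param n_sites number of sites to plant.
#' @param motif_class `"WT_PIE"`, `"dGre_PIE"` or `"none"`; recycled
#'   over sites.
#' @param seed integer seed.
#' @param dwell_weight relative occupancy multiplier of the site over
#'   the local elongation background (default 200).
#' @param misincorporation_rate per-site G-to-A misincorporation
#'   probability for backtracked reads ending at the site; recycled.
#' @param end_base `"auto"` (plant C-2/G-1 iff the site misincorporates),
#'   `"G"` (force a G at -1 without the CpG context) or `"motif"`
#'   (leave -1 to the motif/background).
#' @param state_distribution optional named probabilities over the five
#'   translocation states used for reads at the planted sites; default
#'   is a per-motif-class preset (see [strain_profile()]).
#' @param gene_margin,min_spacing placement constraints in bp.
#' @return list with the edited `genome` and a `pauses` data frame
#'   (columns `replicon`, `pos` (0-based 3'-end base), `strand`,
#'   `motif_class`, `dwell_weight`, `misincorporation_rate`, and the
#'   state probabilities `p_post`..`p_bt3`).
#' @export
plant_pauses <- function(genome, genes, n_sites,
                         motif_class = "WT_PIE",
                         seed,
                         dwell_weight = 200,
                         misincorporation_rate = 0,
                         end_base = c("auto", "G", "motif"),
                         state_distribution = NULL,
                         gene_margin = 30L,
                         min_spacing = 25L) {
  end_base <- match.arg(end_base)
  stopifnot_scalar_number(seed, "seed")
  set.seed(as.integer(seed))
  if (n_sites == 0) {
    return(list(genome = genome, pauses = empty_pause_plan()))
  }
  motif_class <- rep_len(motif_class, n_sites)
  misincorporation_rate <- rep_len(misincorporation_rate, n_sites)
  dwell_weight <- rep_len(dwell_weight, n_sites)

  body <- genes[genes$biotype == "mRNA", , drop = FALSE]
  if (nrow(body) == 0) stop("no mRNA genes to plant into", call. = FALSE)
  cand <- do.call(rbind, lapply(seq_len(nrow(body)), function(i) {
    lo <- body$start[i] + gene_margin
    hi <- body$end[i] - gene_margin
    if (hi <= lo) return(NULL)
    data.frame(pos = seq(lo, hi - 1L), strand = body$strand[i])
  }))
  if (is.null(cand) || nrow(cand) < n_sites) {
    stop("insufficient eligible positions for planting", call. = FALSE)
  }
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  chosen <- cand[0, , drop = FALSE]
  taken <- integer(0)
  for (i in seq_len(nrow(cand))) {
    p <- cand$pos[i]
    if (length(taken) == 0 || min(abs(taken - p)) >= min_spacing) {
      chosen <- rbind(chosen, cand[i, , drop = FALSE])
      taken <- c(taken, p)
      if (nrow(chosen) == n_sites) break
    }
  }
  if (nrow(chosen) < n_sites) {
    stop("insufficient eligible positions after spacing filter",
         call. = FALSE)
  }

  seq_chars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(n_sites)) {
    bases <- pie_motif_bases(motif_class[i])
    if ((end_base == "auto" && misincorporation_rate[i] > 0)) {
      bases <- c(bases[setdiff(names(bases), c("-2", "-1"))],
                 c("-2" = "C", "-1" = "G"))
    } else if (end_base == "G") {
      bases <- c(bases[setdiff(names(bases), "-1")], c("-1" = "G"))
    }
    if (length(bases) == 0) next
    off <- as.integer(names(bases))
    gpos <- offset_to_genomic(chosen$pos[i], chosen$strand[i], off)
    b <- unname(bases)
    if (chosen$strand[i] == "-") b <- complement_base(b)
    stopifnot(all(gpos >= 0), all(gpos < length(seq_chars)))
    seq_chars[gpos + 1L] <- b
  }
  genome$seq <- paste(seq_chars, collapse = "")

  sd_list <- lapply(seq_len(n_sites), function(i) {
    p <- state_distribution %||% planted_state_distribution(motif_class[i])
    check_state_distribution(p)
  })
  sd_mat <- do.call(rbind, sd_list)
  pauses <- data.frame(
    replicon = genome$replicon_id,
    pos = chosen$pos,
    strand = chosen$strand,
    motif_class = motif_class,
    dwell_weight = dwell_weight,
    misincorporation_rate = misincorporation_rate,
    stringsAsFactors = FALSE
  )
  pauses[paste0("p_", STATE_NAMES)] <- sd_mat[, STATE_NAMES]
  rownames(pauses) <- NULL
  list(genome = genome, pauses = pauses)
}

empty_pause_plan <- function() {
  out <- data.frame(replicon = character(0), pos = integer(0),
                    strand = character(0), motif_class = character(0),
                    dwell_weight = numeric(0),
                    misincorporation_rate = numeric(0),
                    stringsAsFactors = FALSE)
  out[paste0("p_", STATE_NAMES)] <- rep(list(numeric(0)), 5L)
  out
}
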