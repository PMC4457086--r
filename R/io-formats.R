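# Readers and writers for the standard formats touched by the
# pipeline, plus transcript-orientation alignment reconstruction from
# CIGAR/MD and a naive mapper for desk-scale synthetic genomes.
#
# Coordinates are 0-based half-open internally; 1-based in
# human-readable TSV reports; BED output is 0-based half-open.

#' Write a genome to FASTA
#' @param genome a `sim_genome`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(stats::setNames(genome$seq,
                                                  genome$replicon_id))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file; the first record is used as the replicon.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  structure(list(replicon_id = sub("\\s.*$", "", names(dss)[1]),
                 seq = as.character(dss[[1]]),
                 circular = FALSE,
                 gc_content = unname(sum(Biostrings::letterFrequency(
                   dss[[1]], c("G", "C"))) / length(dss[[1]]))),
            class = "sim_genome")
}

#' Write gene annotation to GFF3
#'
#' Genes are exported as `gene` features with `gene_id`, `biotype`,
#' `operon_id` and `copy_number` attributes; CDS bounds and TSS are
#' carried as additional attributes so the annotation round-trips.
#' @param genes gene table (0-based internal coordinates).
#' @param genome a `sim_genome` (for the replicon name and length).
#' @param path output file.
#' @export
write_genes_gff3 <- function(genes, genome, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genome$replicon_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "gene",
    ID = genes$gene_id,
    gene_id = genes$gene_id,
    biotype = genes$biotype,
    operon_id = genes$operon_id,
    copy_number = genes$copy_number,
    tss = genes$tss + 1L,
    cds_start = genes$cds_lo + 1L,
    cds_end = genes$cds_hi
  )
  GenomeInfoDb::seqlengths(gr) <- nchar(genome$seq)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene annotation from GFF3
#' @param path GFF3 file written by [write_genes_gff3()] (or any GFF3
#'   with `gene_id`, `biotype`, `tss`, `cds_start`, `cds_end`
#'   attributes).
#' @return gene table in internal 0-based coordinates.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  data.frame(
    gene_id = as.character(m$gene_id),
    biotype = as.character(m$biotype),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    tss = as.integer(m$tss) - 1L,
    cds_lo = as.integer(m$cds_start) - 1L,
    cds_hi = as.integer(m$cds_end),
    operon_id = as.character(m$operon_id),
    operon_first = TRUE,
    copy_number = as.integer(m$copy_number),
    expr_level = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Write / read a TSS table (TSV: replicon, 1-based position, strand)
#' @param tss TSS table with 0-based `pos`.
#' @param path file path.
#' @export
write_tss_table <- function(tss, path) {
  out <- data.frame(replicon = tss$replicon, position = tss$pos + 1L,
                    strand = tss$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_table
#' @export
read_tss_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(replicon = x$replicon, pos = x$position - 1L,
             strand = x$strand, stringsAsFactors = FALSE)
}

#' Write simulated reads to FASTQ (Phred+33, constant Q = 38)
#' @param sim an `rnet_sim` or an alignments data frame.
#' @param path output file.
#' @export
write_fastq <- function(sim, path) {
  aln <- if (inherits(sim, "rnet_sim")) sim$alignments else sim
  dss <- Biostrings::DNAStringSet(stats::setNames(aln$seq, aln$read_id))
  qual <- Biostrings::BStringSet(vapply(aln$length, function(n)
    strrep(rawToChar(as.raw(33L + 38L)), n), character(1)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a named character vector of sequences
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
}

#' Write / read the simulation truth table
#'
#' TSV with one row per read. `pos3` is written 1-based
#' (column `position`); all other columns are verbatim. The
#' write-then-read round trip reproduces the records exactly.
#' @param truth truth table from [simulate_reads()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$position <- out$pos3 + 1L
  out$pos3 <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(seq_error_offsets = "character",
                                        misinc_offset = "integer",
                                        protected_length = "integer",
                                        rnase_shift = "integer",
                                        slack5p = "integer"))
  x$pos3 <- x$position - 1L
  x$position <- NULL
  x$seq_error_offsets[is.na(x$seq_error_offsets)] <- ""
  cols <- c("read_id", "replicon", "pos3", "strand", "origin", "state",
            "protected_length", "rnase_shift", "slack5p", "length",
            "misincorporation", "misinc_offset", "seq_error_offsets",
            "planted")
  x[, cols]
}

#' Write lossless alignments to SAM
#'
#' Records carry all-match CIGARs with NM and MD tags reflecting every
#' mismatch between read and reference, so
#' [read_alignments()] reconstructs the transcript-orientation base
#' pairs exactly.
#' @param sim an `rnet_sim` or an alignments data frame.
#' @param path output SAM file.
#' @param seqlengths named integer vector of replicon lengths; derived
#'   from `sim$genome` when `sim` is an `rnet_sim`.
#' @export
write_sam <- function(sim, path, seqlengths = NULL) {
  if (inherits(sim, "rnet_sim")) {
    aln <- sim$alignments
    seqlengths <- stats::setNames(nchar(sim$genome$seq),
                                  sim$genome$replicon_id)
  } else {
    aln <- sim
    if (is.null(seqlengths)) stop("seqlengths required", call. = FALSE)
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                      as.integer(seqlengths)),
              "@PG\tID:rnetseq\tPN:rnetseq")
  minus <- aln$strand == "-"
  seq_top <- aln$seq
  ref_top <- aln$ref
  seq_top[minus] <- revcomp(seq_top[minus])
  ref_top[minus] <- revcomp(ref_top[minus])
  md <- md_tag(seq_top, ref_top)
  nm <- attr(md, "nm")
  qual <- strrep(rawToChar(as.raw(33L + 38L)), aln$length)
  records <- paste(aln$read_id, ifelse(minus, 16L, 0L), aln$replicon,
                   aln$ref_start + 1L, aln$mapq,
                   paste0(aln$length, "M"), "*", 0L, 0L,
                   seq_top, qual,
                   paste0("NM:i:", nm), paste0("MD:Z:", md),
                   sep = "\t")
  writeLines(c(header, records), path)
  invisible(path)
}

# MD tag and NM count for all-match alignments, from top-strand read
# and reference strings of equal length.
md_tag <- function(read_top, ref_top) {
  n <- length(read_top)
  md <- as.character(nchar(ref_top))
  nm <- integer(n)
  diff <- read_top != ref_top
  for (i in which(diff)) {
    r <- strsplit(read_top[i], "", fixed = TRUE)[[1]]
    f <- strsplit(ref_top[i], "", fixed = TRUE)[[1]]
    mm <- which(r != f)
    nm[i] <- length(mm)
    runs <- diff(c(0L, mm)) - 1L
    tail_run <- length(r) - mm[length(mm)]
    md[i] <- paste0(paste0(runs, f[mm], collapse = ""), tail_run)
  }
  attr(md, "nm") <- nm
  md
}

# Parse an MD tag for an all-match alignment: returns the top-strand
# reference string given the top-strand read string.
md_to_ref <- function(md, read_top) {
  if (grepl("^[0-9]+$", md)) return(read_top)
  tokens <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  ref <- strsplit(read_top, "", fixed = TRUE)[[1]]
  pos <- 0L
  for (tk in tokens) {
    if (grepl("^[0-9]+$", tk)) {
      pos <- pos + as.integer(tk)
    } else if (startsWith(tk, "^")) {
      stop("MD tag encodes a deletion; only substitution-only ",
           "alignments are supported", call. = FALSE)
    } else {
      pos <- pos + 1L
      if (pos > length(ref)) stop("malformed MD tag: ", md, call. = FALSE)
      ref[pos] <- tk
    }
  }
  if (pos > length(ref)) stop("malformed MD tag: ", md, call. = FALSE)
  paste(ref, collapse = "")
}

#' Read alignments from SAM/BAM into transcript orientation
#'
#' Loads single-end alignments, reconstructs the reference sequence of
#' each read from its MD tag (or, when MD is absent, from the supplied
#' genome), and flips minus-strand reads so that both the read and
#' reference sequences are reported in transcript orientation (the
#' non-template strand; offset -1 is the 3'-end base). Reads that are
#' unmapped, or whose CIGAR contains insertions, deletions or clipping,
#' are excluded and counted in the `skipped` attribute. Secondary
#' alignments are kept (multi-mapped reads are analysed at every
#' reported location); `n_hits` counts the locations per read name.
#'
#' @param path SAM or BAM file.
#' @param genome optional `sim_genome` for reference-base lookup when
#'   MD tags are missing.
#' @return data frame of alignments (0-based half-open coordinates,
#'   transcript-orientation `seq` and `ref`), with attribute `skipped`
#'   (named counts of excluded records).
#' @export
read_alignments <- function(path, genome = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("MD", "NM"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  flag <- x$flag
  skipped <- c(unmapped = 0L, supplementary = 0L, indel_or_clip = 0L,
               no_reference = 0L)
  keep <- rep(TRUE, n)
  unmapped <- bitwAnd(flag, 4L) > 0L
  suppl <- bitwAnd(flag, 2048L) > 0L
  skipped["unmapped"] <- sum(unmapped)
  skipped["supplementary"] <- sum(suppl & !unmapped)
  keep <- keep & !unmapped & !suppl
  simple <- grepl("^[0-9]+M$", x$cigar)
  skipped["indel_or_clip"] <- sum(keep & !simple)
  keep <- keep & simple

  idx <- which(keep)
  len <- as.integer(sub("M$", "", x$cigar[idx]))
  seq_top <- as.character(x$seq[idx])
  md <- x$tag$MD %||% rep(NA_character_, n)
  md <- md[idx]
  ref_top <- character(length(idx))
  have_md <- !is.na(md)
  # fast path: a purely numeric MD means a perfect match
  perfect <- have_md & grepl("^[0-9]+$", md)
  ref_top[perfect] <- seq_top[perfect]
  rest <- which(have_md & !perfect)
  if (length(rest)) {
    ref_top[rest] <- mapply(md_to_ref, md[rest], seq_top[rest],
                            USE.NAMES = FALSE)
  }
  if (any(!have_md)) {
    if (is.null(genome)) {
      stop("records lack MD tags and no genome was supplied for ",
           "reference-base lookup", call. = FALSE)
    }
    i <- which(!have_md)
    lo <- x$pos[idx][i] - 1L
    ref_top[i] <- span_at(genome$seq, lo, lo + len[i])
  }
  minus <- bitwAnd(flag[idx], 16L) > 0L
  seq_tx <- seq_top; ref_tx <- ref_top
  seq_tx[minus] <- revcomp(seq_tx[minus])
  ref_tx[minus] <- revcomp(ref_tx[minus])
  out <- data.frame(
    read_id = x$qname[idx],
    replicon = as.character(x$rname[idx]),
    strand = ifelse(minus, "-", "+"),
    ref_start = x$pos[idx] - 1L,
    ref_end = x$pos[idx] - 1L + len,
    length = len,
    mapq = as.integer(x$mapq[idx]),
    n_hits = 1L,
    seq = seq_tx,
    ref = ref_tx,
    stringsAsFactors = FALSE
  )
  f <- match(out$read_id, unique(out$read_id))
  out$n_hits <- tabulate(f)[f]
  attr(out, "skipped") <- skipped
  out
}

#' Transcript-orientation base pairs of alignments
#'
#' Expands alignments into one row per aligned base: offset from the
#' 3' end (-1 is the 3'-end base, -length the 5'-end base), with the
#' reference and read base in transcript orientation.
#' @param aln alignments data frame.
#' @return data frame with columns `read_id`, `offset`, `ref_base`,
#'   `read_base`.
#' @export
alignment_pairs <- function(aln) {
  if (nrow(aln) == 0) {
    return(data.frame(read_id = character(0), offset = integer(0),
                      ref_base = character(0), read_base = character(0)))
  }
  lens <- aln$length
  ref <- strsplit(aln$ref, "", fixed = TRUE)
  rd <- strsplit(aln$seq, "", fixed = TRUE)
  data.frame(
    read_id = rep(aln$read_id, lens),
    offset = unlist(lapply(lens, function(n) seq(-n, -1L))),
    ref_base = unlist(ref),
    read_base = unlist(rd),
    stringsAsFactors = FALSE
  )
}

#' Naive exact/near-exact mapper for desk-scale genomes
#'
#' Maps short reads against a small genome by exhaustive
#' mismatch-tolerant matching on both strands
#' ([Biostrings::matchPattern()]), reporting all hits at the minimal
#' mismatch count up to `max_mismatch`. Mapping quality follows a
#' documented convention: 42 for a unique best hit, 3 for 2-4 tied
#' best hits, 0 for more than 4. Results are ordered by (replicon,
#' position, strand). Reads shorter than `seed_k` are reported as
#' unmapped with a reason.
#'
#' @param reads named character vector of read sequences (transcript
#'   orientation), e.g. from [read_fastq()].
#' @param genome a `sim_genome`.
#' @param max_mismatch maximal number of substitutions (default 2).
#' @param seed_k minimal mappable read length (default 12).
#' @return alignments data frame (as [read_alignments()]), with
#'   attribute `unmapped` (data frame `read_id`, `reason`).
#' @export
naive_map <- function(reads, genome, max_mismatch = 2L, seed_k = 12L) {
  subject <- Biostrings::DNAString(genome$seq)
  ids <- names(reads) %||% sprintf("read_%05d", seq_along(reads))
  rows <- vector("list", length(reads))
  unmapped <- list()
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    if (nchar(rd) < seed_k) {
      unmapped[[length(unmapped) + 1L]] <-
        data.frame(read_id = ids[i], reason = "shorter_than_seed")
      next
    }
    hits <- list()
    for (s in c("+", "-")) {
      pat <- if (s == "+") rd else revcomp(rd)
      m <- Biostrings::matchPattern(pat, subject,
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m) == 0) next
      st <- BiocGenerics::start(m)
      nmis <- vapply(seq_along(m), function(k) {
        Biostrings::neditStartingAt(Biostrings::DNAString(pat), subject,
                                    starting.at = st[k])
      }, integer(1))
      hits[[s]] <- data.frame(strand = s, start = st, nmis = nmis)
    }
    hits <- do.call(rbind, hits)
    if (is.null(hits) || nrow(hits) == 0) {
      unmapped[[length(unmapped) + 1L]] <-
        data.frame(read_id = ids[i], reason = "no_hit")
      next
    }
    best <- hits[hits$nmis == min(hits$nmis), , drop = FALSE]
    nb <- nrow(best)
    mapq <- if (nb == 1L) 42L else if (nb <= 4L) 3L else 0L
    len <- nchar(rd)
    lo <- best$start - 1L
    ref_top <- span_at(genome$seq, lo, lo + len)
    ref_tx <- ifelse(best$strand == "-", revcomp(ref_top), ref_top)
    rows[[i]] <- data.frame(
      read_id = ids[i], replicon = genome$replicon_id,
      strand = best$strand, ref_start = lo, ref_end = lo + len,
      length = len, mapq = mapq, n_hits = nb,
      seq = rd, ref = ref_tx, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), replicon = character(0),
                      strand = character(0), ref_start = integer(0),
                      ref_end = integer(0), length = integer(0),
                      mapq = integer(0), n_hits = integer(0),
                      seq = character(0), ref = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$replicon, out$ref_start, out$strand), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "unmapped") <- if (length(unmapped)) do.call(rbind, unmapped)
    else data.frame(read_id = character(0), reason = character(0))
  out
}

#' Write pause sites to BED6
#'
#' Single-base intervals, 0-based half-open; the score column is
#' `round(1000 * phi)`.
#' @param pauses pause table from [call_pauses()].
#' @param path output file.
#' @export
write_pause_bed <- function(pauses, path) {
  if (nrow(pauses) == 0) {
    file.create(path)
    return(invisible(path))
  }
  lines <- paste(pauses$replicon, pauses$pos, pauses$pos + 1L,
                 sprintf("pause_%d", seq_len(nrow(pauses))),
                 round(1000 * pauses$phi), pauses$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
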