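# Strand-specific 3'-end pileups and the P(phi, delta) pause statistic.
#
# phi is the fraction of reads covering a position whose 3' end lies at
# that position; delta is the coverage depth of the length class. A
# pause site satisfies phi >= phi_min and delta >= delta_min.

# Length-class membership for aligned lengths.
class_filter <- function(length, length_class) {
  if (is.numeric(length_class)) return(length == as.integer(length_class))
  if (grepl("^L[0-9]+$", length_class)) {
    return(length == as.integer(sub("^L", "", length_class)))
  }
  switch(length_class,
    elong = length >= 14L & length <= 30L,
    ge21  = length >= 21L,
    sub   = length < 14L,
    all   = rep(TRUE, length(length)),
    stop("unknown length_class: ", length_class, call. = FALSE)
  )
}

#' Build strand-specific 3'-end pileup tracks
#'
#' For each (replicon, strand) tallies, over the alignments of one
#' length class, the coverage depth `delta`, the 3'-end counts, and
#' the mapping-quality sums of the 3'-end reads. Multi-mapped reads
#' contribute at every reported location. Each alignment has exactly
#' one 3' end, so the 3'-end counts sum to the number of class
#' alignments.
#'
#' @param aln alignments data frame (see [read_alignments()]).
#' @param seqlengths named integer vector of replicon lengths, or a
#'   `sim_genome`.
#' @param length_class `"elong"` (14-30 nt, default), `"ge21"` (bulk
#'   reads >= 21 nt), `"sub"` (< 14 nt sub-footprint reads), `"all"`,
#'   an exact length `"L14"`..`"L30"`, or a number.
#' @return named list of `pileup_track` objects, keyed
#'   `"replicon:strand"`.
#' @export
build_pileup <- function(aln, seqlengths, length_class = "elong") {
  if (inherits(seqlengths, "sim_genome")) {
    seqlengths <- stats::setNames(nchar(seqlengths$seq),
                                  seqlengths$replicon_id)
  }
  aln <- aln[class_filter(aln$length, length_class), , drop = FALSE]
  bad <- !(aln$replicon %in% names(seqlengths)) |
    aln$ref_start < 0L |
    aln$ref_end > seqlengths[aln$replicon]
  if (any(bad)) {
    stop("alignment outside replicon bounds: ",
         paste(utils::head(aln$read_id[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (repl in names(seqlengths)) {
    n <- as.integer(seqlengths[[repl]])
    for (s in c("+", "-")) {
      a <- aln[aln$replicon == repl & aln$strand == s, , drop = FALSE]
      if (nrow(a) > 0) {
        cov <- IRanges::coverage(
          IRanges::IRanges(start = a$ref_start + 1L, end = a$ref_end),
          width = n)
        depth <- as.integer(cov)
        pos3 <- if (s == "+") a$ref_end - 1L else a$ref_start
        end3 <- tabulate(pos3 + 1L, nbins = n)
        mapq_sum <- unname(rowsum_vector(a$mapq, pos3, n))
        mapq_n <- end3
      } else {
        depth <- integer(n); end3 <- integer(n)
        mapq_sum <- numeric(n); mapq_n <- integer(n)
      }
      out[[paste0(repl, ":", s)]] <- structure(list(
        replicon = repl, strand = s, length_class = length_class,
        depth = depth, end3 = end3,
        mapq_sum = mapq_sum, mapq_n = mapq_n
      ), class = "pileup_track")
    }
  }
  out
}

# Sum `values` into bins given 0-based positions; returns length-n vector.
rowsum_vector <- function(values, pos0, n) {
  out <- numeric(n)
  agg <- rowsum(as.numeric(values), pos0)
  out[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  out
}

#' @export
print.pileup_track <- function(x, ...) {
  cat(sprintf("<pileup_track> %s:%s class=%s, %d positions, %d 3' ends\n",
              x$replicon, x$strand, as.character(x$length_class),
              length(x$depth), sum(x$end3)))
  invisible(x)
}

#' Call pause sites with the P(phi, delta) criterion
#'
#' Returns exactly the positions whose 3'-end fraction
#' `phi = end3 / depth` is at least `phi_min` and whose depth is at
#' least `delta_min`. Adjacent qualifying positions are reported
#' independently (no merging). `mapq_mean` is the mean mapping quality
#' of the reads whose 3' ends define the site.
#'
#' @param tracks a `pileup_track` or a list of them.
#' @param phi_min minimal 3'-end fraction, in (0, 1].
#' @param delta_min minimal read depth (>= 1).
#' @param delta_on_end3 if `TRUE`, apply `delta_min` to the 3'-end
#'   count instead of the coverage depth (alternative reading of the
#'   depth parameter).
#' @return data frame with columns `replicon`, `pos` (0-based 3'-end
#'   base), `strand`, `phi`, `delta`, `mapq_mean`, `length_class`.
#' @export
call_pauses <- function(tracks, phi_min = 0.9, delta_min = 100,
                        delta_on_end3 = FALSE) {
  stopifnot(phi_min > 0, phi_min <= 1, delta_min >= 1)
  if (inherits(tracks, "pileup_track")) tracks <- list(tracks)
  res <- lapply(tracks, function(tr) {
    phi <- ifelse(tr$depth > 0, tr$end3 / tr$depth, 0)
    gate <- if (delta_on_end3) tr$end3 else tr$depth
    hit <- which(phi >= phi_min & gate >= delta_min)
    if (length(hit) == 0) return(NULL)
    data.frame(
      replicon = tr$replicon, pos = hit - 1L, strand = tr$strand,
      phi = phi[hit], delta = tr$depth[hit],
      mapq_mean = tr$mapq_sum[hit] / tr$mapq_n[hit],
      length_class = as.character(tr$length_class),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) out <- empty_pause_sites()
  rownames(out) <- NULL
  out
}

empty_pause_sites <- function() {
  data.frame(replicon = character(0), pos = integer(0),
             strand = character(0), phi = numeric(0), delta = integer(0),
             mapq_mean = numeric(0), length_class = character(0),
             stringsAsFactors = FALSE)
}

#' Filter pause sites on mean mapping quality
#'
#' @param pauses pause table from [call_pauses()].
#' @param threshold sites are kept iff `mapq_mean > threshold`.
#' @return list with elements `kept` and `rejected`.
#' @export
filter_mapq <- function(pauses, threshold = 10) {
  keep <- pauses$mapq_mean > threshold
  list(kept = pauses[keep, , drop = FALSE],
       rejected = pauses[!keep, , drop = FALSE])
}

#' Translocation state implied by a protected-fragment length
#'
#' 14 nt marks the post-translocated state, 15 nt pre-translocated,
#' and L > 15 a (L - 15)-bp backtracked state. Lengths below 14 nt are
#' sub-footprint species from initiation regions, not translocation
#' states.
#'
#' @param L read length(s) in nt, each in 6..30.
#' @return character vector of state labels.
#' @export
state_from_length <- function(L) {
  if (any(L < 6L | L > 30L)) {
    stop("read length outside the 6..30 nt range", call. = FALSE)
  }
  ifelse(L < 14L, "sub-footprint",
    ifelse(L == 14L, "post",
      ifelse(L == 15L, "pre", paste0("backtrack", L - 15L))))
}

#' 5'-flank base composition (RNase cleavage signature)
#'
#' Tallies the genomic base immediately 5' of each read start in
#' transcript orientation. An excess of G marks cleavage of GpN bonds
#' by RNase T1.
#'
#' @param aln alignments data frame.
#' @param genome a `sim_genome`.
#' @param by_length if `TRUE`, report one row per read length.
#' @return data frame of fractions over A/C/G/T (rows sum to 1), with
#'   a `length` column when `by_length = TRUE`.
#' @export
rnase_signature_fraction <- function(aln, genome, by_length = FALSE) {
  gpos <- ifelse(aln$strand == "+", aln$ref_start - 1L, aln$ref_end)
  b <- base_at(genome$seq, gpos)
  b <- ifelse(aln$strand == "-", complement_base(b), b)
  ok <- !is.na(b)
  tallies <- function(bb) {
    cnt <- table(factor(bb, levels = BASES))
    as.numeric(cnt) / sum(cnt)
  }
  if (!by_length) {
    out <- as.data.frame(t(tallies(b[ok])))
    names(out) <- BASES
    return(out)
  }
  lens <- sort(unique(aln$length))
  out <- do.call(rbind, lapply(lens, function(l) {
    sel <- ok & aln$length == l
    as.data.frame(t(tallies(b[sel])))
  }))
  names(out) <- BASES
  cbind(data.frame(length = lens), out)
}

#' Read-length histogram over 6..30 nt
#'
#' @param aln alignments data frame.
#' @return data frame `length`, `count`; counts sum to `nrow(aln)`.
#' @export
read_length_histogram <- function(aln) {
  counts <- tabulate(factor(aln$length, levels = 6:30), nbins = 25L)
  data.frame(length = 6:30, count = counts)
}
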