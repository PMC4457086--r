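# Pause-motif (PIE) matrices: non-template-strand windows anchored at
# pause 3' ends, base-frequency matrices, information content and a
# log-likelihood-ratio motif score.
#
# Offsets follow the -1 convention: -1 is the 3'-end base, +1 the next
# downstream base; there is no offset 0 (-1 abuts +1).

window_offsets <- function(window) {
  stopifnot(window[1] < 0, window[2] > 0)
  c(seq(window[1], -1L), seq(1L, window[2]))
}

#' Extract oriented sequence windows around pause 3' ends
#'
#' For a plus-strand pause the window is the top (non-template) strand
#' centred so the pause base sits at offset -1; for a minus-strand
#' pause the reverse complement. Sites too close to a sequence end for
#' the window to fit are skipped and counted in the `skipped`
#' attribute.
#'
#' @param pauses pause table (columns `pos` 0-based, `strand`).
#' @param genome a `sim_genome`.
#' @param window integer pair `c(upstream, downstream)`, default
#'   `c(-15, 5)`: offsets -15..-1 and +1..+5 (20 bases).
#' @return character vector of windows, with attribute `skipped`.
#' @export
extract_windows <- function(pauses, genome, window = c(-15L, 5L)) {
  u <- -window[1]; d <- window[2]
  L <- nchar(genome$seq)
  plus <- pauses$strand == "+"
  lo <- ifelse(plus, pauses$pos - u + 1L, pauses$pos - d)
  hi <- ifelse(plus, pauses$pos + d + 1L, pauses$pos + u)
  ok <- lo >= 0L & hi <= L
  out <- span_at(genome$seq, lo[ok], hi[ok])
  out[!plus[ok]] <- revcomp(out[!plus[ok]])
  attr(out, "skipped") <- sum(!ok)
  attr(out, "window") <- c(window[1], window[2])
  out
}

#' Build a base-frequency matrix from motif windows
#'
#' @param windows character vector of equal-length windows (typically
#'   from [extract_windows()]).
#' @param window offset bounds; taken from the `window` attribute of
#'   `windows` when present.
#' @param pseudocount pseudocount per base per column used when
#'   converting counts to probabilities (default 0.25).
#' @param background base probabilities used by [motif_score()];
#'   default uniform. Pass the genome composition
#'   ([base_composition()]) for composition-corrected scores.
#' @return object of class `pie_matrix`: counts (4 x width), offsets,
#'   `n_sites`, `pseudocount`, `background`.
#' @export
frequency_matrix <- function(windows, window = NULL, pseudocount = 0.25,
                             background = NULL) {
  if (length(windows) < 1) stop("need at least one window", call. = FALSE)
  if (length(unique(nchar(windows))) != 1) {
    stop("windows differ in length", call. = FALSE)
  }
  window <- window %||% attr(windows, "window") %||%
    c(-(nchar(windows[1]) - 5L), 5L)
  offs <- window_offsets(window)
  wlen <- nchar(windows[1])
  if (length(offs) != wlen) {
    stop("window bounds do not match window length", call. = FALSE)
  }
  m <- matrix(unlist(strsplit(windows, "", fixed = TRUE)),
              nrow = wlen)
  counts <- apply(m, 1L, function(col)
    as.integer(table(factor(col, levels = BASES))))
  dimnames(counts) <- list(BASES, as.character(offs))
  background <- background %||%
    stats::setNames(rep(0.25, 4), BASES)
  structure(list(
    counts = counts, offsets = offs, n_sites = length(windows),
    pseudocount = pseudocount, background = background[BASES]
  ), class = "pie_matrix")
}

#' @export
print.pie_matrix <- function(x, ...) {
  ic <- information_content(x)
  cat(sprintf("<pie_matrix> %d sites, offsets %d..%d, total IC %.1f bits\n",
              x$n_sites, min(x$offsets), max(x$offsets), ic$total))
  cons <- BASES[apply(x$counts, 2, which.max)]
  cat("  consensus:", paste(cons, collapse = ""), "\n")
  invisible(x)
}

# Pseudocounted per-offset base probabilities.
pie_probs <- function(m) {
  sweep(m$counts + m$pseudocount, 2,
        colSums(m$counts + m$pseudocount), "/")
}

#' Per-offset information content of a motif matrix
#'
#' `IC_j = 2 + sum_b p_jb log2 p_jb` bits against a uniform
#' background, using pseudocounted frequencies. The optional
#' small-sample correction subtracts `3 / (2 ln 2 n)` and floors at 0.
#'
#' @param m a `pie_matrix`.
#' @param small_sample_correction apply the correction (default FALSE).
#' @return list with `per_offset` (named numeric) and `total` (bits).
#' @export
information_content <- function(m, small_sample_correction = FALSE) {
  p <- pie_probs(m)
  plogp <- p * log2(p)
  plogp[p == 0] <- 0
  ic <- 2 + colSums(plogp)
  if (small_sample_correction) {
    ic <- pmax(0, ic - 3 / (2 * log(2) * m$n_sites))
  }
  list(per_offset = stats::setNames(ic, colnames(m$counts)),
       total = sum(ic))
}

#' Log-likelihood-ratio motif score (MAP-like)
#'
#' `score = sum_j sum_b n_jb log2(p_jb / q_b)` bits, with
#' pseudocounted frequencies `p` and background `q` taken from the
#' matrix. A matrix whose observed frequencies equal the background
#' scores 0 (up to the pseudocount).
#'
#' @param m a `pie_matrix`.
#' @return score in bits.
#' @export
motif_score <- function(m) {
  q <- m$background
  if (any(q <= 0)) stop("background probabilities must be > 0",
                        call. = FALSE)
  p <- pie_probs(m)
  term <- m$counts * log2(sweep(p, 1, q, "/"))
  term[m$counts == 0] <- 0  # 0 * log(0) contributes nothing
  sum(term)
}

#' Upstream-G position profile per length class
#'
#' For each length class, reports which of the offsets -9, -10, -11
#' carries the highest G frequency; in RNase-footprinted data this
#' position tracks the G-dC base pair at the upstream end of the
#' RNA-DNA hybrid (post-translocated, pre-translocated and 1-bp
#' backtracked registers respectively).
#'
#' @param matrices named list of `pie_matrix`, keyed by length class.
#' @param offsets candidate offsets (default -9, -10, -11).
#' @return data frame `length_class`, `g_offset`, `g_fraction`.
#' @export
g_position_profile <- function(matrices, offsets = c(-9L, -10L, -11L)) {
  rows <- lapply(names(matrices), function(cls) {
    m <- matrices[[cls]]
    sel <- as.character(offsets)
    gfrac <- m$counts["G", sel] / colSums(m$counts[, sel, drop = FALSE])
    k <- which.max(gfrac)
    data.frame(length_class = cls, g_offset = offsets[k],
               g_fraction = unname(gfrac[k]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Remove pause sites shared with another set
#'
#' @param setA,setB pause tables; returns the sites of `setB` whose
#'   (replicon, position, strand) does not occur in `setA`.
#' @export
exclude_shared_sites <- function(setA, setB) {
  keyA <- paste(setA$replicon, setA$pos, setA$strand)
  keyB <- paste(setB$replicon, setB$pos, setB$strand)
  setB[!(keyB %in% keyA), , drop = FALSE]
}

#' Partition pause sites by 3'-end G-to-A errors
#'
#' Considers the sites whose reference (non-template) base at offset
#' -1 is G, and splits them into those with at least one read carrying
#' a G-to-A mismatch at the 3'-end base and those with none. Builds a
#' motif matrix for each group. The partition is exhaustive and
#' disjoint over the G-ended sites.
#'
#' @param pauses pause table.
#' @param aln alignments data frame (transcript orientation).
#' @param genome a `sim_genome`.
#' @param window motif window (see [extract_windows()]).
#' @return list with `error_sites`, `clean_sites` (pause tables),
#'   `pie_error`, `pie_clean` (`pie_matrix` or NULL when a group is
#'   empty).
#' @export
split_by_3prime_error <- function(pauses, aln, genome,
                                  window = c(-15L, 5L)) {
  ref1 <- base_at(genome$seq, pauses$pos)
  ref1 <- ifelse(pauses$strand == "-", complement_base(ref1), ref1)
  g_sites <- pauses[!is.na(ref1) & ref1 == "G", , drop = FALSE]
  pos3 <- ifelse(aln$strand == "+", aln$ref_end - 1L, aln$ref_start)
  b3_read <- substring(aln$seq, aln$length, aln$length)
  b3_ref <- substring(aln$ref, aln$length, aln$length)
  err_key <- unique(paste(aln$replicon, pos3, aln$strand)[
    b3_ref == "G" & b3_read == "A"])
  key <- paste(g_sites$replicon, g_sites$pos, g_sites$strand)
  has_err <- key %in% err_key
  error_sites <- g_sites[has_err, , drop = FALSE]
  clean_sites <- g_sites[!has_err, , drop = FALSE]
  build <- function(sites) {
    if (nrow(sites) == 0) return(NULL)
    frequency_matrix(extract_windows(sites, genome, window))
  }
  list(error_sites = error_sites, clean_sites = clean_sites,
       pie_error = build(error_sites), pie_clean = build(clean_sites))
}

#' Write a motif matrix to TSV (counts and probabilities)
#'
#' Logo-ready long format: one row per (offset, base).
#' @param m a `pie_matrix`.
#' @param path output file.
#' @export
write_pie_matrix <- function(m, path) {
  p <- pie_probs(m)
  out <- data.frame(
    offset = rep(m$offsets, each = 4L),
    base = rep(BASES, times = length(m$offsets)),
    count = as.vector(m$counts),
    prob = as.vector(p)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
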