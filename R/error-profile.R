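# Per-read-position substitution matrices (all 12 types), indexed from
# the 3' end (-1 convention), stratified by read length.
#
# Rates are per-opportunity: the denominator for a ref->alt rate at an
# offset is the number of reads whose transcript-orientation reference
# base at that offset is `ref`. A `per-aligned-base` denominator is
# available as an alternative through error_rates().

#' Accumulate substitution errors for one read length
#'
#' Tallies, per offset -L..-1 and per ordered base pair (ref -> read,
#' ref != read), the mismatch counts and the opportunity counts (reads
#' whose reference base at the offset is `ref`). Every aligned base of
#' every retained read contributes exactly once. Multi-mapped reads
#' are excluded by default (mismatches at repeats are unreliable),
#' unlike in pileups where they are counted everywhere.
#'
#' @param aln alignments data frame (transcript orientation).
#' @param L exact aligned length of the reads to use.
#' @param unique_only drop reads with `n_hits > 1` (default TRUE).
#' @return object of class `error_matrix`: `L`, `mismatches` (array
#'   offset x ref x read), `opportunities` (offset x ref), `n_reads`,
#'   `n_skipped` (alignments of other lengths).
#' @export
accumulate_errors <- function(aln, L, unique_only = TRUE) {
  stopifnot_scalar_number(L, "L")
  sel <- aln$length == L
  n_skipped <- sum(!sel)
  a <- aln[sel, , drop = FALSE]
  if (unique_only && nrow(a) > 0) a <- a[a$n_hits == 1L, , drop = FALSE]
  offs <- seq(-L, -1L)
  mism <- array(0L, dim = c(L, 4L, 4L),
                dimnames = list(as.character(offs), BASES, BASES))
  opp <- matrix(0L, nrow = L, ncol = 4L,
                dimnames = list(as.character(offs), BASES))
  if (nrow(a) > 0) {
    refM <- matrix(unlist(strsplit(a$ref, "", fixed = TRUE)), nrow = L)
    readM <- matrix(unlist(strsplit(a$seq, "", fixed = TRUE)), nrow = L)
    for (rb in BASES) {
      isr <- refM == rb
      opp[, rb] <- rowSums(isr)
      for (ab in setdiff(BASES, rb)) {
        mism[, rb, ab] <- rowSums(isr & readM == ab)
      }
    }
  }
  storage.mode(mism) <- "integer"
  storage.mode(opp) <- "integer"
  structure(list(L = L, mismatches = mism, opportunities = opp,
                 n_reads = nrow(a), n_skipped = n_skipped),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("<error_matrix> L=%d, %d reads, %d mismatches\n",
              x$L, x$n_reads, sum(x$mismatches)))
  invisible(x)
}

#' Long-format substitution rates of an error matrix
#'
#' @param m an `error_matrix`.
#' @param per_aligned_base if `TRUE`, divide mismatch counts by the
#'   total number of reads at the offset instead of the
#'   reference-base-specific opportunity count.
#' @return data frame `L`, `offset`, `ref`, `alt`, `mismatches`,
#'   `opportunities`, `rate` (12 substitution types per offset).
#' @export
error_rates <- function(m, per_aligned_base = FALSE) {
  offs <- as.integer(rownames(m$opportunities))
  rows <- list()
  total_at_offset <- rowSums(m$opportunities)
  for (rb in BASES) for (ab in setdiff(BASES, rb)) {
    denom <- if (per_aligned_base) total_at_offset else m$opportunities[, rb]
    rows[[paste(rb, ab)]] <- data.frame(
      L = m$L, offset = offs, ref = rb, alt = ab,
      mismatches = m$mismatches[, rb, ab],
      opportunities = denom,
      rate = ifelse(denom > 0, m$mismatches[, rb, ab] / denom, 0),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Rate of one substitution type at one offset.
rate_at <- function(m, ref, alt, offset) {
  o <- as.character(offset)
  denom <- m$opportunities[o, ref]
  if (denom == 0) return(0)
  m$mismatches[o, ref, alt] / denom
}

#' Enrichment threshold for a substitution type
#'
#' Pools the per-offset rates of one substitution type over offsets
#' -12..-1 of the supplied length-stratified matrices (canonically the
#' 14- to 18-nt reads) and returns mean + 1 SD. A position is
#' "enriched" iff its rate exceeds the threshold.
#'
#' @param matrices list of `error_matrix` (e.g. lengths 14..18).
#' @param ref,alt substitution type (default G -> A).
#' @param offsets offsets pooled (default -12..-1).
#' @return list with `threshold`, `mean`, `sd`, and `rates` (the
#'   pooled per-(L, offset) rates).
#' @export
enrichment_threshold <- function(matrices, ref = "G", alt = "A",
                                 offsets = seq(-12L, -1L)) {
  rates <- unlist(lapply(matrices, function(m) {
    sel <- offsets[offsets >= -m$L]
    vapply(sel, function(o) rate_at(m, ref, alt, o), numeric(1))
  }))
  mu <- mean(rates)
  sdev <- stats::sd(rates)
  if (is.na(sdev)) sdev <- 0
  list(threshold = mu + sdev, mean = mu, sd = sdev, rates = rates)
}

#' 3'-end error rate versus read length (backtracking distance)
#'
#' Reports the rate of one substitution type at a fixed offset across
#' length classes, together with a Spearman rank correlation of rate
#' against length. In RNase-footprinted data, read length tracks the
#' backtracking distance, so a positive trend of the 3'-end G-to-A
#' rate links misincorporation to backtracking.
#'
#' @param matrices list of `error_matrix` (e.g. lengths 14..18).
#' @param ref,alt substitution type (default G -> A).
#' @param offset offset from the 3' end (default -1).
#' @return list with `table` (data frame `L`, `rate`, `mismatches`,
#'   `opportunities`), `spearman_rho` and `spearman_p` (NA when the
#'   rates are constant).
#' @export
error_rate_by_backtrack <- function(matrices, ref = "G", alt = "A",
                                    offset = -1L) {
  tab <- do.call(rbind, lapply(matrices, function(m) {
    o <- as.character(offset)
    data.frame(L = m$L,
               rate = rate_at(m, ref, alt, offset),
               mismatches = m$mismatches[o, ref, alt],
               opportunities = m$opportunities[o, ref])
  }))
  tab <- tab[order(tab$L), , drop = FALSE]
  rownames(tab) <- NULL
  if (stats::sd(tab$rate) == 0 || nrow(tab) < 3) {
    rho <- NA_real_; pval <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(tab$L, tab$rate, method = "spearman"))
    rho <- unname(ct$estimate); pval <- ct$p.value
  }
  list(table = tab, spearman_rho = rho, spearman_p = pval)
}

#' Write length-stratified error matrices to TSV
#' @param matrices list of `error_matrix`.
#' @param path output file.
#' @export
write_error_matrices <- function(matrices, path) {
  out <- do.call(rbind, lapply(matrices, error_rates))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
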