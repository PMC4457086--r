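#' Simulate RNase-protected nascent-transcript reads
#'
#' Draws reads whose 3'-end genomic positions follow a per-position
#' occupancy model (uniform elongation floor, per-gene expression
#' levels with read-through tails, and planted pause sites weighted by
#' `dwell_weight`), assigns each elongation read a translocation state,
#' and derives the protected fragment length as `14 + t` (t = 0 post,
#' 1 pre, 1 + b for b-bp backtracking). Four stochastic channels then
#' act on the read:
#'
#' * misincorporation: a backtracked read whose reference 3' base is G
#'   carries a G-to-A mismatch at its 3' terminus with the site's (or
#'   the strain's background) misincorporation rate;
#' * RNase T1 5' bias: with probability `rnase_t1_bias` the 5' trim
#'   point shifts up to 2 nt upstream to leave a G immediately 5' of
#'   the read start (T1 cuts GpN bonds), lengthening the read by <= 2;
#' * untrimmed 5' excess: with probability `p_untrimmed` the read keeps
#'   3-12 nt of untrimmed upstream RNA (capped at 30 nt total),
#'   producing the long reads without an RNase T1 signature;
#' * uniform sequencing substitutions at `sequencing_error_rate`.
#'
#' A fraction `p_initiation` of reads derives from initiation
#' complexes: 6-13 nt sub-footprint reads starting at a TSS.
#'
#' The returned alignments are lossless: position, strand, and the
#' transcript-orientation read and reference sequences are recorded
#' exactly, so [write_sam()] emits CIGAR all-match records whose MD
#' tags encode every planted mismatch.
#'
#' @param genome a `sim_genome` (possibly edited by [plant_pauses()]).
#' @param genes gene table from [generate_genome()].
#' @param pauses planted-pause table from [plant_pauses()] (may have
#'   zero rows).
#' @param strain a [strain_profile()].
#' @param n_reads number of reads (>= 1).
#' @param seed integer seed; identical inputs and seed give identical
#'   output.
#' @param extra_weights optional data frame (`strand`, `lo`, `hi`,
#'   `mult`): multiply the 3'-end weight of positions in `[lo, hi)` on
#'   `strand` by `mult` (used e.g. to plant region-specific dwell
#'   increases).
#' @param margin terminal margin of the replicon never emitting reads.
#' @return an object of class `rnet_sim`: list with `alignments` (data
#'   frame of lossless alignments, coordinates 0-based half-open,
#'   sequences in transcript orientation), `truth` (per-read ground
#'   truth), plus the inputs.
#' @export
simulate_reads <- function(genome, genes, pauses, strain, n_reads, seed,
                           extra_weights = NULL, margin = 50L) {
  stopifnot(inherits(genome, "sim_genome"), inherits(strain, "strain_profile"))
  stopifnot_scalar_number(n_reads, "n_reads")
  stopifnot_scalar_number(seed, "seed")
  if (n_reads < 1) stop("n_reads must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  L <- nchar(genome$seq)

  # ---- positional occupancy weights --------------------------------------
  w <- list("+" = rep(1, L), "-" = rep(1, L))
  jitter <- stats::rlnorm(nrow(genes), 0, strain$strain_jitter_sd)
  expr <- genes$expr_level * jitter
  runthrough_bp <- 100L
  for (i in seq_len(nrow(genes))) {
    s <- genes$strand[i]
    span <- (genes$start[i] + 1L):genes$end[i]
    w[[s]][span] <- w[[s]][span] + expr[i]
    rt <- if (s == "+") {
      seq(genes$end[i] + 1L, min(L, genes$end[i] + runthrough_bp))
    } else {
      seq(max(1L, genes$start[i] - runthrough_bp + 1L), genes$start[i])
    }
    if (length(rt)) w[[s]][rt] <- w[[s]][rt] + 0.3 * expr[i]
  }
  if (!is.null(extra_weights)) {
    for (i in seq_len(nrow(extra_weights))) {
      s <- extra_weights$strand[i]
      span <- (extra_weights$lo[i] + 1L):extra_weights$hi[i]
      w[[s]][span] <- w[[s]][span] * extra_weights$mult[i]
    }
  }
  site_key <- character(0)
  if (nrow(pauses) > 0) {
    for (i in seq_len(nrow(pauses))) {
      s <- pauses$strand[i]
      p <- pauses$pos[i] + 1L
      w[[s]][p] <- w[[s]][p] * pauses$dwell_weight[i]
    }
    site_key <- paste0(pauses$strand, ":", pauses$pos)
  }
  w[["+"]][c(seq_len(margin), (L - margin + 1L):L)] <- 0
  w[["-"]][c(seq_len(margin), (L - margin + 1L):L)] <- 0

  # ---- read class split ---------------------------------------------------
  is_init <- stats::runif(n_reads) < strain$p_initiation
  n_el <- sum(!is_init)
  n_in <- sum(is_init)

  # ---- elongation reads ---------------------------------------------------
  idx <- sample.int(2L * L, n_el, replace = TRUE, prob = c(w[["+"]], w[["-"]]))
  el_strand <- ifelse(idx <= L, "+", "-")
  el_pos3 <- ifelse(idx <= L, idx - 1L, idx - L - 1L)

  key <- paste0(el_strand, ":", el_pos3)
  site_ix <- match(key, site_key)  # NA for background positions

  # state per read
  bg <- strain$background_state_distribution[STATE_NAMES]
  state <- character(n_el)
  is_bg <- is.na(site_ix)
  if (any(is_bg)) {
    state[is_bg] <- sample(STATE_NAMES, sum(is_bg), replace = TRUE, prob = bg)
  }
  if (any(!is_bg)) {
    sd_mat <- as.matrix(pauses[paste0("p_", STATE_NAMES)])
    for (ix in unique(site_ix[!is_bg])) {
      sel <- which(!is_bg & site_ix == ix)
      state[sel] <- sample(STATE_NAMES, length(sel), replace = TRUE,
                           prob = sd_mat[ix, ])
    }
  }
  protected <- state_protected_length(state)

  # reference 3'-end base in transcript orientation
  ref3 <- base_at(genome$seq, el_pos3)
  ref3 <- ifelse(el_strand == "-", complement_base(ref3), ref3)

  # misincorporation channel (backtracked reads ending at reference G)
  mis_rate <- ifelse(is.na(site_ix), strain$default_misincorporation_rate,
                     pauses$misincorporation_rate[site_ix])
  eligible <- state %in% c("bt1", "bt2", "bt3") & ref3 == "G"
  misinc <- eligible & stats::runif(n_el) < mis_rate

  # untrimmed 5' excess vs RNase T1 bias shift
  untrimmed <- stats::runif(n_el) < strain$p_untrimmed
  slack <- integer(n_el)
  if (any(untrimmed)) {
    slack[untrimmed] <- pmin(sample(3:12, sum(untrimmed), replace = TRUE),
                             30L - protected[untrimmed])
  }
  shift <- integer(n_el)
  try_shift <- !untrimmed & stats::runif(n_el) < strain$rnase_t1_bias
  if (any(try_shift)) {
    # 5'-most genomic coordinate of the unshifted read
    start5 <- ifelse(el_strand == "+", el_pos3 - protected + 1L,
                     el_pos3 + protected - 1L)
    flank <- function(k) {
      # genomic base immediately 5' of the start when shifted by k
      gpos <- ifelse(el_strand == "+", start5 - k - 1L, start5 + k + 1L)
      b <- base_at(genome$seq, gpos)
      ifelse(el_strand == "-", complement_base(b), b)
    }
    f0 <- flank(0L); f1 <- flank(1L); f2 <- flank(2L)
    shift[try_shift & !is.na(f0) & f0 == "G"] <- 0L
    need1 <- try_shift & (is.na(f0) | f0 != "G")
    shift[need1 & !is.na(f1) & f1 == "G"] <- 1L
    need2 <- need1 & (is.na(f1) | f1 != "G")
    shift[need2 & !is.na(f2) & f2 == "G"] <- 2L
  }
  el_len <- protected + shift + slack

  # ---- initiation reads ---------------------------------------------------
  if (n_in > 0) {
    gi <- sample.int(nrow(genes), n_in, replace = TRUE, prob = expr)
    in_len <- sample(6:13, n_in, replace = TRUE)
    in_strand <- genes$strand[gi]
    in_pos3 <- ifelse(in_strand == "+", genes$tss[gi] + in_len - 1L,
                      genes$tss[gi] - in_len + 1L)
  } else {
    in_len <- integer(0); in_strand <- character(0); in_pos3 <- integer(0)
  }

  # ---- assemble ----------------------------------------------------------
  strand_all <- character(n_reads)
  pos3_all <- integer(n_reads)
  len_all <- integer(n_reads)
  strand_all[!is_init] <- el_strand; strand_all[is_init] <- in_strand
  pos3_all[!is_init] <- el_pos3;     pos3_all[is_init] <- in_pos3
  len_all[!is_init] <- el_len;       len_all[is_init] <- in_len
  if (any(len_all < 6L | len_all > 30L)) {
    stop("internal error: read length outside 6..30", call. = FALSE)
  }

  ref_start <- ifelse(strand_all == "+", pos3_all - len_all + 1L, pos3_all)
  ref_end <- ref_start + len_all
  stopifnot(all(ref_start >= 0L), all(ref_end <= L))

  ref_seq <- span_at(genome$seq, ref_start, ref_end)
  minus <- strand_all == "-"
  ref_seq[minus] <- revcomp(ref_seq[minus])
  read_seq <- ref_seq

  misinc_all <- logical(n_reads)
  misinc_all[!is_init] <- misinc
  if (any(misinc_all)) {
    i <- which(misinc_all)
    substr(read_seq[i], len_all[i], len_all[i]) <- "A"
  }

  # sequencing-substitution channel
  seq_err_off <- character(n_reads)
  if (strain$sequencing_error_rate > 0) {
    n_err <- stats::rbinom(n_reads, len_all, strain$sequencing_error_rate)
    hit <- which(n_err > 0)
    if (length(hit)) {
      sub <- read_seq[hit]
      offs <- character(length(hit))
      for (k in seq_along(hit)) {
        i <- hit[k]
        cols <- sample.int(len_all[i], n_err[i])
        for (j in cols) {
          old <- substr(sub[k], j, j)
          substr(sub[k], j, j) <- sample(setdiff(BASES, old), 1L)
        }
        offs[k] <- paste(sort(cols - len_all[i] - 1L), collapse = ",")
      }
      read_seq[hit] <- sub
      seq_err_off[hit] <- offs
    }
  }

  read_id <- sprintf("read_%07d", seq_len(n_reads))
  alignments <- data.frame(
    read_id = read_id,
    replicon = genome$replicon_id,
    strand = strand_all,
    ref_start = ref_start,
    ref_end = ref_end,
    length = len_all,
    mapq = 42L,
    n_hits = 1L,
    seq = read_seq,
    ref = ref_seq,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    read_id = read_id,
    replicon = genome$replicon_id,
    pos3 = pos3_all,
    strand = strand_all,
    origin = ifelse(is_init, "initiation", "elongation"),
    state = NA_character_,
    protected_length = NA_integer_,
    rnase_shift = NA_integer_,
    slack5p = NA_integer_,
    length = len_all,
    misincorporation = misinc_all,
    misinc_offset = ifelse(misinc_all, -1L, NA_integer_),
    seq_error_offsets = seq_err_off,
    planted = FALSE,
    stringsAsFactors = FALSE
  )
  truth$state[!is_init] <- state
  truth$protected_length[!is_init] <- protected
  truth$rnase_shift[!is_init] <- shift
  truth$slack5p[!is_init] <- slack
  truth$state[is_init] <- "initiation"
  truth$planted[!is_init] <- !is.na(site_ix)

  structure(list(
    genome = genome, genes = genes, pauses = pauses, strain = strain,
    alignments = alignments, truth = truth,
    n_reads = n_reads, seed = as.integer(seed)
  ), class = "rnet_sim")
}

#' @export
print.rnet_sim <- function(x, ...) {
  cat(sprintf("<rnet_sim> %d reads (%s strain), %d planted pause sites\n",
              x$n_reads, x$strain$name, nrow(x$pauses)))
  invisible(x)
}
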