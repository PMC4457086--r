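# Shared fixtures: memoised simulations under the package's default
# study conditions (20-kb genome, planted pause elements with dwell
# weight 200, strain-default state distributions and error rates), and
# independent brute-force oracles used to cross-check the vectorised
# implementations.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Wild-type simulation: WT pause elements, 250k reads.
sim_wt <- function() fixture("sim_wt", {
  gen <- generate_genome(20000, 0.5, 20, seed = 101, include_rrna = FALSE)
  pl <- plant_pauses(gen$genome, gen$genes, 30, motif_class = "WT_PIE",
                     seed = 102)
  sim <- simulate_reads(pl$genome, gen$genes, pl$pauses,
                        strain_profile("WT"), 250000, seed = 103)
  list(gen = gen, planted = pl, sim = sim)
})

# GreAB-deletion simulation: backtrack-prone pause elements carrying
# the CpG error element, strain-default misincorporation, 300k reads.
sim_dg <- function() fixture("sim_dg", {
  gen <- generate_genome(20000, 0.5, 20, seed = 101, include_rrna = FALSE)
  pl <- plant_pauses(gen$genome, gen$genes, 30, motif_class = "dGre_PIE",
                     seed = 102, misincorporation_rate = 8e-3)
  sim <- simulate_reads(pl$genome, gen$genes, pl$pauses,
                        strain_profile("dGreAB"), 350000, seed = 104)
  list(gen = gen, planted = pl, sim = sim)
})

# Mixed planting for the 3'-error motif split: half the sites carry
# the CpG misincorporation element, half only a G-ended pause.
sim_mixed_error <- function() fixture("sim_mixed_error", {
  gen <- generate_genome(20000, 0.5, 20, seed = 201)
  pl <- plant_pauses(gen$genome, gen$genes, 36, motif_class = "dGre_PIE",
                     seed = 202,
                     misincorporation_rate = rep(c(8e-3, 0), 18),
                     end_base = "auto")
  # force a plain G 3' end (no CpG context) at the non-misincorporating
  # sites so both groups are G-ended
  idx0 <- which(pl$pauses$misincorporation_rate == 0)
  g <- pl$genome
  chars <- strsplit(g$seq, "", fixed = TRUE)[[1]]
  for (i in idx0) {
    gpos <- rnetseq:::offset_to_genomic(pl$pauses$pos[i],
                                        pl$pauses$strand[i], -1L)
    b <- if (pl$pauses$strand[i] == "+") "G" else "C"
    chars[gpos + 1L] <- b
  }
  g$seq <- paste(chars, collapse = "")
  sim <- simulate_reads(g, gen$genes, pl$pauses,
                        strain_profile("dGreAB"), 200000, seed = 204)
  list(gen = gen, planted = list(genome = g, pauses = pl$pauses),
       sim = sim)
})

# Two-strain comparison with a planted Up-region dwell increase in
# strain B only. 80 genes so the cross-gene expression spread does not
# drown the planted effect in the unpaired comparison.
sim_two_strains <- function() fixture("sim_two_strains", {
  gen <- generate_genome(80000, 0.5, 80, seed = 301)
  no_sites <- plant_pauses(gen$genome, gen$genes, 0, seed = 302)
  up <- region_windows(gen$genes)
  up <- up[up$region == "Up", , drop = FALSE]
  boost <- data.frame(strand = up$strand, lo = up$lo, hi = up$hi, mult = 2)
  simA <- simulate_reads(gen$genome, gen$genes, no_sites$pauses,
                         strain_profile("WT"), 200000, seed = 303)
  simB <- simulate_reads(gen$genome, gen$genes, no_sites$pauses,
                         strain_profile("dGreAB"), 200000, seed = 304,
                         extra_weights = boost)
  list(gen = gen, simA = simA, simB = simB)
})

# A strain profile with every stochastic channel switched off and a
# fixed translocation state, for exact length checks.
quiet_strain <- function(state) {
  p <- stats::setNames(rep(0, 5), c("post", "pre", "bt1", "bt2", "bt3"))
  p[state] <- 1
  strain_profile("custom", background_state_distribution = p,
                 default_misincorporation_rate = 0,
                 rnase_t1_bias = 0, sequencing_error_rate = 0,
                 p_untrimmed = 0, p_initiation = 0,
                 strain_jitter_sd = 0)
}

# ---- independent oracles ------------------------------------------------

# Per-position recount of depth and 3'-end counts by looping over reads.
brute_pileup <- function(aln, n, strand) {
  depth <- integer(n); end3 <- integer(n)
  a <- aln[aln$strand == strand, , drop = FALSE]
  for (i in seq_len(nrow(a))) {
    span <- (a$ref_start[i] + 1L):a$ref_end[i]
    depth[span] <- depth[span] + 1L
    p3 <- if (strand == "+") a$ref_end[i] else a$ref_start[i] + 1L
    end3[p3] <- end3[p3] + 1L
  }
  list(depth = depth, end3 = end3)
}

# Exhaustive O(genome x read) scan for all minimal-mismatch hits.
brute_map <- function(read, genome, max_mismatch) {
  L <- nchar(genome$seq)
  n <- nchar(read)
  hits <- list()
  gchars <- strsplit(genome$seq, "", fixed = TRUE)[[1]]
  for (s in c("+", "-")) {
    pat <- if (s == "+") read else {
      paste(rev(strsplit(chartr("ACGT", "TGCA", read), "",
                         fixed = TRUE)[[1]]), collapse = "")
    }
    pchars <- strsplit(pat, "", fixed = TRUE)[[1]]
    for (lo in 0:(L - n)) {
      mm <- sum(gchars[(lo + 1):(lo + n)] != pchars)
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1L]] <-
          data.frame(strand = s, start = lo, nmis = mm)
      }
    }
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(hits)
  hits[hits$nmis == min(hits$nmis), , drop = FALSE]
}

# Tiny hand-rolled SAM writer for crafting edge-case records.
write_raw_sam <- function(records, path, replicon = "sim_chr",
                          len = 1000L) {
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", replicon, len),
               records), path)
  path
}
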