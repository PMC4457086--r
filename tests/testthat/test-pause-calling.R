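# Pileups, the P(phi, delta) statistic, translocation-state labels,
# RNase signature and length histograms.

class_ok <- function(len) len >= 14L & len <= 30L

toy_aln <- function(ref_start, ref_end, strand = "+", mapq = 42L,
                    n = 1L, id_prefix = "t") {
  k <- length(ref_start)
  data.frame(
    read_id = sprintf("%s%03d", id_prefix, seq_len(k)),
    replicon = "sim_chr", strand = strand,
    ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
    length = as.integer(ref_end - ref_start),
    mapq = as.integer(mapq), n_hits = as.integer(n),
    seq = strrep("A", ref_end - ref_start),
    ref = strrep("A", ref_end - ref_start),
    stringsAsFactors = FALSE)
}

test_that("single reads produce the expected depth and 3'-end counts", {
  sl <- c(sim_chr = 500L)
  a <- toy_aln(100, 121)
  tr <- build_pileup(a, sl, "elong")[["sim_chr:+"]]
  expect_identical(tr$depth[101:121], rep(1L, 21))
  expect_identical(sum(tr$depth), 21L)
  expect_identical(tr$end3[121], 1L)
  expect_identical(sum(tr$end3), 1L)
  # two identical reads: phi = 1 at the 3' end
  a2 <- toy_aln(c(100, 100), c(121, 121))
  tr2 <- build_pileup(a2, sl, "elong")[["sim_chr:+"]]
  expect_identical(tr2$depth[110], 2L)
  expect_identical(tr2$end3[121], 2L)
  p <- call_pauses(tr2, phi_min = 0.9, delta_min = 1)
  expect_identical(p$pos, 120L)
  expect_identical(p$phi, 1)
  # minus strand: 3' end at ref_start
  am <- toy_aln(100, 121, strand = "-")
  trm <- build_pileup(am, sl, "elong")[["sim_chr:-"]]
  expect_identical(trm$end3[101], 1L)
})

test_that("phi and delta thresholds behave exactly at the boundary", {
  sl <- c(sim_chr = 500L)
  # 100 reads cover position 199 (0-based); 95 end there
  enders <- toy_aln(rep(179, 95), rep(200, 95))
  passers <- toy_aln(rep(185, 5), rep(210, 5), id_prefix = "p")
  a <- rbind(enders, passers)
  tr <- build_pileup(a, sl, "elong")[["sim_chr:+"]]
  expect_identical(tr$depth[200], 100L)
  expect_identical(tr$end3[200], 95L)
  p <- call_pauses(tr, 0.9, 100)
  expect_identical(p$pos, 199L)
  expect_equal(p$phi, 0.95)
  # depth 99 fails delta_min = 100
  tr99 <- build_pileup(a[-1, ], sl, "elong")[["sim_chr:+"]]
  expect_identical(nrow(call_pauses(tr99, 0.9, 100)), 0L)
  expect_identical(call_pauses(tr99, 0.9, 99)$pos, 199L)
  # delta on 3'-end counts instead of coverage
  expect_identical(nrow(call_pauses(tr, 0.9, 100, delta_on_end3 = TRUE)),
                   0L)
  expect_identical(call_pauses(tr, 0.9, 95, delta_on_end3 = TRUE)$pos,
                   199L)
})

test_that("pileup matches a brute-force per-read recount", {
  gen <- generate_genome(4000, 0.5, 3, seed = 111)
  pl <- plant_pauses(gen$genome, gen$genes, 4, seed = 112)
  sim <- simulate_reads(pl$genome, gen$genes, pl$pauses,
                        strain_profile("dGreAB"), 3000, seed = 113)
  tracks <- build_pileup(sim$alignments, pl$genome, "elong")
  sel <- sim$alignments[class_ok(sim$alignments$length), ]
  for (s in c("+", "-")) {
    want <- brute_pileup(sel, 4000, s)
    tr <- tracks[[paste0("sim_chr:", s)]]
    expect_identical(tr$depth, want$depth)
    expect_identical(tr$end3, want$end3)
  }
  # calling equals an independent per-position recount
  called <- call_pauses(tracks, 0.9, 50)
  for (s in c("+", "-")) {
    want <- brute_pileup(sel, 4000, s)
    phi <- ifelse(want$depth > 0, want$end3 / want$depth, 0)
    manual <- which(phi >= 0.9 & want$depth >= 50) - 1L
    expect_identical(called$pos[called$strand == s], manual)
  }
})

test_that("3'-end conservation and threshold monotonicity hold", {
  x <- sim_wt()
  aln <- x$sim$alignments
  tracks <- build_pileup(aln, x$planted$genome, "elong")
  total_end3 <- sum(vapply(tracks, function(t) sum(t$end3), numeric(1)))
  expect_identical(as.integer(total_end3), sum(class_ok(aln$length)))
  # raising either threshold never adds a site
  set.seed(121)
  base <- call_pauses(tracks, 0.7, 50)
  for (i in 1:8) {
    phi <- stats::runif(1, 0.7, 1)
    delta <- sample(50:400, 1)
    a <- call_pauses(tracks, phi, delta)
    b <- call_pauses(tracks, min(1, phi + 0.05), delta)
    d <- call_pauses(tracks, phi, delta + 50)
    key <- function(p) paste(p$pos, p$strand)
    expect_true(all(key(b) %in% key(a)))
    expect_true(all(key(d) %in% key(a)))
    expect_true(all(key(a) %in% key(base)) || phi < 0.7)
  }
})

test_that("length classes stratify the pileup", {
  sl <- c(sim_chr = 500L)
  a <- rbind(toy_aln(c(100, 100), c(118, 118)),          # 18 nt
             toy_aln(c(96, 90), c(118, 118), id_prefix = "u"))  # 22, 28 nt
  t18 <- build_pileup(a, sl, "L18")[["sim_chr:+"]]
  expect_identical(sum(t18$end3), 2L)
  tge <- build_pileup(a, sl, "ge21")[["sim_chr:+"]]
  expect_identical(sum(tge$end3), 2L)
  expect_identical(t18$depth[100], 0L)
  expect_identical(tge$depth[100], 2L)  # both long reads cover 0-based 99
  expect_identical(build_pileup(a, sl, 22)[["sim_chr:+"]]$end3[118], 1L)
})

test_that("mapq filtering keeps sites strictly above the threshold", {
  sl <- c(sim_chr = 500L)
  a <- rbind(toy_aln(100, 118, mapq = 42L),
             toy_aln(100, 118, mapq = 0L, id_prefix = "m"))
  tr <- build_pileup(a, sl, "elong")[["sim_chr:+"]]
  p <- call_pauses(tr, 0.9, 1)
  expect_equal(p$mapq_mean, 21)  # arithmetic mean of 42 and 0
  expect_identical(nrow(filter_mapq(p, 10)$kept), 1L)
  expect_identical(nrow(filter_mapq(p, 21)$kept), 0L)  # strict >
  lowq <- p; lowq$mapq_mean <- 0
  expect_identical(nrow(filter_mapq(lowq, 10)$kept), 0L)
})

test_that("protected lengths map to translocation states", {
  expect_identical(state_from_length(14), "post")
  expect_identical(state_from_length(15), "pre")
  expect_identical(state_from_length(16), "backtrack1")
  expect_identical(state_from_length(17), "backtrack2")
  expect_identical(state_from_length(18), "backtrack3")
  expect_identical(state_from_length(23), "backtrack8")
  expect_identical(state_from_length(12), "sub-footprint")
  expect_error(state_from_length(5), "6..30")
  expect_error(state_from_length(31), "6..30")
})

test_that("RNase T1 bias shows up as a G-rich 5' flank", {
  gen <- generate_genome(10000, 0.5, 8, seed = 131)
  empty <- plant_pauses(gen$genome, gen$genes, 0, seed = 132)$pauses
  mk <- function(bias) {
    strain_profile("custom", rnase_t1_bias = bias,
                   sequencing_error_rate = 0, p_untrimmed = 0,
                   p_initiation = 0)
  }
  sims <- lapply(c(0, 0.5, 1), function(b)
    simulate_reads(gen$genome, gen$genes, empty, mk(b), 20000,
                   seed = 133))
  g <- vapply(sims, function(s)
    rnase_signature_fraction(s$alignments, gen$genome)$G, numeric(1))
  comp_g <- base_composition(gen$genome$seq)[["G"]]
  # bias 0: flank composition tracks the genome; monotone in bias
  expect_lt(abs(g[1] - comp_g), 0.02)
  expect_gt(g[2], g[1] + 0.05)
  expect_gt(g[3], g[2] + 0.02)
})

test_that("read-length histograms count every alignment", {
  empty <- data.frame()
  h0 <- read_length_histogram(data.frame(length = integer(0)))
  expect_true(all(h0$count == 0L))
  h3 <- read_length_histogram(data.frame(length = c(16L, 16L, 16L)))
  expect_identical(h3$count[h3$length == 16], 3L)
  expect_identical(sum(h3$count), 3L)
})

test_that("sub-footprint reads concentrate near transcription start sites", {
  x <- sim_wt()
  aln <- x$sim$alignments
  short <- aln[aln$length < 14L, ]
  pos3 <- ifelse(short$strand == "+", short$ref_end - 1L, short$ref_start)
  items <- data.frame(pos = pos3, strand = short$strand)
  prof <- tss_distance_profile(items, x$gen$tss, max_dist = 500, bin = 25)
  near <- sum(prof$count[prof$dist_lo >= 0 & prof$dist_lo < 25])
  expect_gt(near / sum(prof$count), 0.9)
})
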