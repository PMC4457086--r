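# Synthetic elongation-complex read generator: determinism, planted
# motifs, the protected-length law and the stochastic channels.

test_that("genome generation is deterministic, seed-sensitive and honours gc", {
  a <- generate_genome(20000, 0.5, 20, seed = 1)
  b <- generate_genome(20000, 0.5, 20, seed = 1)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$genes, b$genes)

  c2 <- generate_genome(20000, 0.5, 20, seed = 2)
  expect_false(identical(a$genome$seq, c2$genome$seq))

  at_only <- generate_genome(2000, 0, 1, seed = 2)
  expect_false(grepl("[GC]", at_only$genome$seq))
  expect_true(grepl("^[AT]+$", at_only$genome$seq))

  gc9 <- generate_genome(20000, 0.9, 5, seed = 3)
  comp <- base_composition(gc9$genome$seq)
  expect_gt(comp["G"] + comp["C"], 0.85)
})

test_that("generated annotation is internally consistent", {
  gen <- generate_genome(20000, 0.5, 20, seed = 7, include_rrna = TRUE)
  g <- gen$genes
  # genes do not overlap
  ord <- order(g$start)
  expect_true(all(g$start[ord][-1] >= g$end[ord][-nrow(g)]))
  # 5' UTR length >= 0: TSS at or upstream of the start codon
  plus <- g$strand == "+"
  expect_true(all(g$tss[plus] <= g$cds_lo[plus]))
  expect_true(all(g$tss[!plus] >= g$cds_hi[!plus] - 1L))
  # at least one convergent (head-to-head) pair
  conv <- any(vapply(seq_len(nrow(g) - 1L), function(i)
    g$strand[ord][i] == "+" && g$strand[ord][i + 1L] == "-", logical(1)))
  expect_true(conv)
  # 7 identical rRNA copies
  rr <- g[g$biotype == "rRNA", ]
  expect_identical(nrow(rr), 7L)
  expect_true(all(rr$copy_number == 7L))
  seqs <- vapply(seq_len(nrow(rr)), function(i) {
    s <- substring(gen$genome$seq, rr$start[i] + 1L, rr$end[i])
    if (rr$strand[i] == "-") rnetseq:::revcomp(s) else s
  }, character(1))
  expect_identical(length(unique(seqs)), 1L)
})

test_that("generation rejects annotations that cannot fit", {
  expect_error(generate_genome(2000, 0.5, 20, seed = 1), "incompatible")
})

test_that("planted motifs carry the expected non-template bases", {
  gen <- generate_genome(20000, 0.5, 20, seed = 11)
  pl <- plant_pauses(gen$genome, gen$genes, 10, motif_class = "WT_PIE",
                     seed = 12)
  offs <- c(seq(-15L, -1L), seq(1L, 5L))
  for (i in seq_len(nrow(pl$pauses))) {
    w <- extract_windows(pl$pauses[i, ], pl$genome)[1]
    base_at_off <- function(o) substr(w, which(offs == o), which(offs == o))
    expect_identical(base_at_off(-10L), "G")
    expect_identical(base_at_off(-3L), "T")
    expect_identical(base_at_off(-2L), "G")
    expect_identical(base_at_off(-1L), "C")
    expect_identical(base_at_off(1L), "G")
  }
  pld <- plant_pauses(gen$genome, gen$genes, 10, motif_class = "dGre_PIE",
                      seed = 12)
  for (i in seq_len(nrow(pld$pauses))) {
    w <- extract_windows(pld$pauses[i, ], pld$genome)[1]
    base_at_off <- function(o) substr(w, which(offs == o), which(offs == o))
    expect_identical(base_at_off(-11L), "G")
    expect_identical(base_at_off(-4L), "T")
    expect_identical(base_at_off(-7L), "T")
  }
  # CpG error element at misincorporating sites
  plc <- plant_pauses(gen$genome, gen$genes, 5, motif_class = "dGre_PIE",
                      seed = 13, misincorporation_rate = 8e-3)
  for (i in seq_len(nrow(plc$pauses))) {
    w <- extract_windows(plc$pauses[i, ], plc$genome)[1]
    base_at_off <- function(o) substr(w, which(offs == o), which(offs == o))
    expect_identical(base_at_off(-2L), "C")
    expect_identical(base_at_off(-1L), "G")
  }
})

test_that("planting zero sites leaves the genome unchanged", {
  gen <- generate_genome(20000, 0.5, 20, seed = 11)
  pl <- plant_pauses(gen$genome, gen$genes, 0, seed = 12)
  expect_identical(pl$genome$seq, gen$genome$seq)
  expect_identical(nrow(pl$pauses), 0L)
})

test_that("planting respects spacing and fails when space runs out", {
  gen <- generate_genome(20000, 0.5, 20, seed = 11)
  pl <- plant_pauses(gen$genome, gen$genes, 30, seed = 12)
  pos <- sort(pl$pauses$pos)
  expect_true(all(diff(pos) >= 25L))
  expect_error(plant_pauses(gen$genome, gen$genes, 5000, seed = 12),
               "insufficient")
})

test_that("protected length follows 14 + t(state) with channels off", {
  gen <- generate_genome(5000, 0.5, 4, seed = 21)
  empty <- plant_pauses(gen$genome, gen$genes, 0, seed = 22)$pauses
  expected <- c(post = 14L, pre = 15L, bt1 = 16L, bt2 = 17L, bt3 = 18L)
  for (state in names(expected)) {
    sim <- simulate_reads(gen$genome, gen$genes, empty,
                          quiet_strain(state), 200, seed = 23)
    expect_true(all(sim$alignments$length == expected[[state]]),
                info = state)
    expect_true(all(sim$truth$protected_length == expected[[state]]))
    expect_true(all(sim$truth$state == state))
  }
})

test_that("RNase bias lengthens reads by at most 2 nt over the footprint", {
  x <- sim_wt()
  tr <- x$sim$truth
  el <- tr[tr$origin == "elongation", ]
  expect_true(all(el$rnase_shift >= 0L & el$rnase_shift <= 2L))
  no_slack <- el[el$slack5p == 0L, ]
  expect_true(all(no_slack$length - no_slack$protected_length <= 2L))
  expect_true(all(el$length == el$protected_length + el$rnase_shift +
                    el$slack5p))
  # shifted reads expose a G immediately 5' of the read start
  shifted <- el$read_id[el$rnase_shift > 0L][1:200]
  a <- x$sim$alignments
  a <- a[a$read_id %in% shifted, ]
  sig <- rnase_signature_fraction(a, x$planted$genome)
  expect_gt(sig$G, 0.999)
})

test_that("read lengths stay within 6..30 and modal lengths differ by strain", {
  w <- sim_wt()$sim
  d <- sim_dg()$sim
  expect_true(all(w$alignments$length >= 6L & w$alignments$length <= 30L))
  hw <- read_length_histogram(w$alignments)
  hd <- read_length_histogram(d$alignments)
  mode_w <- hw$length[which.max(hw$count)]
  mode_d <- hd$length[which.max(hd$count)]
  expect_lt(mode_w, mode_d)
  expect_identical(mode_w, 16L)
  expect_identical(mode_d, 18L)
})

test_that("misincorporations hit backtracked G-ended reads at the set rate", {
  x <- sim_dg()
  tr <- x$sim$truth
  a <- x$sim$alignments
  # all misincorporated reads are backtracked (length >= 16 footprint)
  mis <- tr[tr$misincorporation, ]
  expect_true(all(mis$state %in% c("bt1", "bt2", "bt3")))
  expect_true(all(mis$protected_length >= 16L))
  # fraction of 18-nt reads (reference G at -1) carrying the error
  # matches the configured rate within 3 binomial SE
  is18 <- a$length == 18L
  refG <- substring(a$ref, a$length, a$length) == "G"
  n <- sum(is18 & refG)
  frac <- sum(tr$misincorporation[is18 & refG]) / n
  rate <- x$sim$strain$default_misincorporation_rate
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(frac - rate), 3 * se)
})

test_that("simulation is byte-identical under a fixed seed", {
  gen <- generate_genome(5000, 0.5, 4, seed = 31)
  pl <- plant_pauses(gen$genome, gen$genes, 5, seed = 32)
  s1 <- simulate_reads(pl$genome, gen$genes, pl$pauses,
                       strain_profile("WT"), 2000, seed = 33)
  s2 <- simulate_reads(pl$genome, gen$genes, pl$pauses,
                       strain_profile("WT"), 2000, seed = 33)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(s1, f1); write_sam(s2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  q1 <- tempfile(fileext = ".fastq"); q2 <- tempfile(fileext = ".fastq")
  write_fastq(s1, q1); write_fastq(s2, q2)
  expect_identical(unname(tools::md5sum(q1)), unname(tools::md5sum(q2)))
  s3 <- simulate_reads(pl$genome, gen$genes, pl$pauses,
                       strain_profile("WT"), 2000, seed = 34)
  expect_false(identical(s1$alignments$seq, s3$alignments$seq))
})

test_that("truth table round-trips through TSV", {
  gen <- generate_genome(5000, 0.5, 4, seed = 41)
  pl <- plant_pauses(gen$genome, gen$genes, 3, seed = 42)
  sim <- simulate_reads(pl$genome, gen$genes, pl$pauses,
                        strain_profile("dGreAB"), 500, seed = 43)
  f <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back, sim$truth[, names(back)])
  # empty table -> header-only file
  f0 <- tempfile(fileext = ".tsv")
  write_truth(sim$truth[0, ], f0)
  expect_identical(length(readLines(f0)), 1L)
  expect_identical(nrow(read_truth(f0)), 0L)
  # n reads -> n data rows
  f10 <- tempfile(fileext = ".tsv")
  write_truth(sim$truth[1:10, ], f10)
  expect_identical(length(readLines(f10)), 11L)
})

test_that("invalid generator inputs are rejected", {
  gen <- generate_genome(5000, 0.5, 4, seed = 51)
  pl <- plant_pauses(gen$genome, gen$genes, 0, seed = 52)
  expect_error(simulate_reads(gen$genome, gen$genes, pl$pauses,
                              strain_profile("WT"), 0, seed = 53),
               "n_reads")
  expect_error(strain_profile("custom",
    background_state_distribution = c(post = 0.5, pre = 0.6, bt1 = 0,
                                      bt2 = 0, bt3 = 0)),
    "sum to 1")
})
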