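# Gene- and region-level read accounting: strand-aware union counting,
# reads-per-million normalisation, Up/Head/Tail/Down windows, rRNA
# copy-number averaging, strain comparisons, sense/antisense
# correlation, pause categorisation and TSS-proximity profiles.

aln_granges <- function(aln) {
  GenomicRanges::GRanges(
    seqnames = aln$replicon,
    ranges = IRanges::IRanges(start = aln$ref_start + 1L, end = aln$ref_end),
    strand = aln$strand)
}

genes_granges <- function(genes, replicon) {
  GenomicRanges::GRanges(
    seqnames = replicon,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
}

# Strand-aware union rule: a read is assigned to a feature when its
# interval overlaps it and overlaps no other feature in the set;
# reads hitting >1 feature are ambiguous.
union_assign <- function(reads_gr, feat_gr) {
  hits <- GenomicRanges::findOverlaps(reads_gr, feat_gr,
                                      ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits)
  nper <- tabulate(q, nbins = length(reads_gr))
  uniq <- nper == 1L
  assigned <- rep(NA_integer_, length(reads_gr))
  sel <- q %in% which(uniq)
  assigned[q[sel]] <- S4Vectors::subjectHits(hits)[sel]
  list(assigned = assigned, n_ambiguous = sum(nper > 1L),
       n_unassigned = sum(nper == 0L))
}

#' Count reads per gene (sense and antisense)
#'
#' A read is assigned to a gene when its alignment interval overlaps
#' the gene on the same strand and overlaps no other same-strand gene;
#' reads overlapping several genes are dropped as ambiguous (strand-
#' aware union rule). Antisense counts apply the same rule with the
#' read strand inverted. Raw counts of multi-copy genes (rRNA) are
#' divided by their copy number to represent the average single copy.
#' Normalised counts are reads per million mapped:
#' `1e6 * raw / total_mapped`.
#'
#' @param aln alignments data frame.
#' @param genes gene table.
#' @param total_mapped total mapped reads used for normalisation
#'   (default `nrow(aln)`).
#' @return data frame per gene: `gene_id`, `biotype`, `raw_count`,
#'   `normalized_count`, `raw_antisense`, `normalized_antisense`; with
#'   attribute `assignment` (named counts: assigned, ambiguous,
#'   unassigned).
#' @export
count_gene_reads <- function(aln, genes, total_mapped = nrow(aln)) {
  rg <- aln_granges(aln)
  gg <- genes_granges(genes, if (nrow(aln)) aln$replicon[1] else "NA")
  sense <- union_assign(rg, gg)
  rg_flip <- rg
  BiocGenerics::strand(rg_flip) <- ifelse(aln$strand == "+", "-", "+")
  anti <- union_assign(rg_flip, gg)
  raw <- tabulate(sense$assigned[!is.na(sense$assigned)],
                  nbins = nrow(genes)) / genes$copy_number
  raw_as <- tabulate(anti$assigned[!is.na(anti$assigned)],
                     nbins = nrow(genes)) / genes$copy_number
  out <- data.frame(
    gene_id = genes$gene_id, biotype = genes$biotype,
    raw_count = raw,
    normalized_count = normalize_counts(raw, total_mapped),
    raw_antisense = raw_as,
    normalized_antisense = normalize_counts(raw_as, total_mapped),
    stringsAsFactors = FALSE
  )
  attr(out, "assignment") <- c(
    assigned = sum(!is.na(sense$assigned)),
    ambiguous = sense$n_ambiguous,
    unassigned = sense$n_unassigned)
  out
}

#' Reads-per-million normalisation
#'
#' `1e6 * raw / total_mapped`. Scale-free: doubling all raw counts and
#' the total leaves the result unchanged.
#' @param raw raw read counts.
#' @param total_mapped total mapped reads.
#' @export
normalize_counts <- function(raw, total_mapped) {
  if (total_mapped <= 0) stop("total_mapped must be > 0", call. = FALSE)
  1e6 * raw / total_mapped
}

#' Four 50-bp analysis windows per gene
#'
#' In transcription orientation: `Up` is the 50 bases immediately
#' upstream of the start codon, `Head` the first 50 bases of the CDS,
#' `Tail` the last 50 bases of the CDS, and `Down` the 50 bases just
#' downstream of the stop codon. Genes with a CDS shorter than 100 bp
#' have overlapping Head/Tail windows and are flagged.
#'
#' @param genes gene table.
#' @param width window width in bp (default 50).
#' @return data frame `gene_id`, `region`, `lo`, `hi` (0-based
#'   half-open), `strand`, `short_gene`.
#' @export
region_windows <- function(genes, width = 50L) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    short <- (g$cds_hi - g$cds_lo) < 2L * width
    if (g$strand == "+") {
      lo <- c(Up = g$cds_lo - width, Head = g$cds_lo,
              Tail = g$cds_hi - width, Down = g$cds_hi)
    } else {
      lo <- c(Up = g$cds_hi, Head = g$cds_hi - width,
              Tail = g$cds_lo, Down = g$cds_lo - width)
    }
    data.frame(gene_id = g$gene_id, region = names(lo),
               lo = unname(lo), hi = unname(lo) + width,
               strand = g$strand, short_gene = short,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

REGIONS <- c("Up", "Head", "Tail", "Down")

#' Count reads per gene region
#'
#' Applies the strand-aware union rule of [count_gene_reads()] within
#' each region class (Up/Head/Tail/Down windows from
#' [region_windows()]), for sense and antisense reads.
#'
#' @param aln alignments data frame.
#' @param genes gene table.
#' @param total_mapped total mapped reads for normalisation.
#' @param width region width (default 50).
#' @return data frame per gene x region: raw and normalised counts,
#'   sense and antisense.
#' @export
count_region_reads <- function(aln, genes, total_mapped = nrow(aln),
                               width = 50L) {
  win <- region_windows(genes, width)
  rg <- aln_granges(aln)
  rg_flip <- rg
  BiocGenerics::strand(rg_flip) <- ifelse(aln$strand == "+", "-", "+")
  repl <- if (nrow(aln)) aln$replicon[1] else "NA"
  rows <- lapply(REGIONS, function(region) {
    w <- win[win$region == region, , drop = FALSE]
    wg <- GenomicRanges::GRanges(
      seqnames = repl,
      ranges = IRanges::IRanges(start = w$lo + 1L, end = w$hi),
      strand = w$strand)
    sense <- union_assign(rg, wg)
    anti <- union_assign(rg_flip, wg)
    raw <- tabulate(sense$assigned[!is.na(sense$assigned)],
                    nbins = nrow(w))
    raw_as <- tabulate(anti$assigned[!is.na(anti$assigned)],
                       nbins = nrow(w))
    data.frame(gene_id = w$gene_id, region = region,
               raw_count = raw,
               normalized_count = normalize_counts(raw, total_mapped),
               raw_antisense = raw_as,
               normalized_antisense = normalize_counts(raw_as,
                                                       total_mapped),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare per-region pausing between two strains
#'
#' For each region (Up/Head/Tail/Down), a two-tailed t-test of the
#' normalised region counts between strains, over the mRNA genes whose
#' gene-level normalised count exceeds `min_norm` in both strains.
#' Welch's unequal-variance test is the default; a paired test is
#' available. p-values above 0.05 are labelled non-significant.
#'
#' @param regionsA,regionsB per-region counts ([count_region_reads()])
#'   for the two strains.
#' @param genesA,genesB gene-level counts ([count_gene_reads()]) used
#'   for the expression filter.
#' @param min_norm minimal gene-level normalised count (default 0.1).
#' @param paired use a paired t-test (default FALSE).
#' @return data frame `region`, `n_genes`, `p_value`, `significant`.
#' @export
compare_strains <- function(regionsA, regionsB, genesA, genesB,
                            min_norm = 0.1, paired = FALSE) {
  okA <- genesA$gene_id[genesA$biotype == "mRNA" &
                          genesA$normalized_count > min_norm]
  okB <- genesB$gene_id[genesB$biotype == "mRNA" &
                          genesB$normalized_count > min_norm]
  keep <- intersect(okA, okB)
  if (length(keep) < 2) stop("fewer than 2 genes pass the expression ",
                             "filter", call. = FALSE)
  rows <- lapply(REGIONS, function(region) {
    a <- regionsA[regionsA$region == region &
                    regionsA$gene_id %in% keep, , drop = FALSE]
    b <- regionsB[regionsB$region == region &
                    regionsB$gene_id %in% keep, , drop = FALSE]
    a <- a[match(keep, a$gene_id), ]
    b <- b[match(keep, b$gene_id), ]
    p <- if (isTRUE(all.equal(a$normalized_count, b$normalized_count))) {
      1
    } else {
      stats::t.test(a$normalized_count, b$normalized_count,
                    paired = paired, var.equal = FALSE)$p.value
    }
    data.frame(region = region, n_genes = length(keep), p_value = p,
               significant = p <= 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$label <- ifelse(out$significant, sprintf("p = %.3g", out$p_value),
                      "n.s.")
  out
}

#' Sense/antisense correlation over gene regions
#'
#' Pearson correlation of the normalised sense and antisense counts of
#' one region class across genes; a negative `r` is the signature of
#' interference between converging polymerases.
#'
#' @param regions per-region counts ([count_region_reads()]).
#' @param region region class (default `"Tail"`).
#' @return list with `r`, `p_value`, `n`, and `table` (the scatter
#'   data: `gene_id`, `sense`, `antisense`).
#' @export
sense_antisense_correlation <- function(regions, region = "Tail") {
  x <- regions[regions$region == region, , drop = FALSE]
  tab <- data.frame(gene_id = x$gene_id, sense = x$normalized_count,
                    antisense = x$normalized_antisense)
  ct <- suppressWarnings(stats::cor.test(tab$sense, tab$antisense,
                                         method = "pearson"))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(tab),
       table = tab)
}

#' Categorise pause sites by overlapping RNA type
#'
#' Assigns each pause position to one of mRNA CDS, 5' UTR, 3' UTR,
#' tRNA, rRNA, ncRNA, antisense, or intergenic. A same-strand feature
#' takes precedence over antisense, which takes precedence over
#' intergenic; among same-strand features the precedence is rRNA >
#' tRNA > ncRNA > mRNA. Within an mRNA the 5' UTR spans TSS to start
#' codon and the 3' UTR spans stop codon to the annotated gene end.
#'
#' @param pauses pause table.
#' @param genes gene table.
#' @return list with `categories` (per-pause labels) and `fractions`
#'   (named fractions summing to 1).
#' @export
categorize_pauses <- function(pauses, genes) {
  labels <- c("mRNA_CDS", "5'UTR", "3'UTR", "tRNA", "rRNA", "ncRNA",
              "antisense", "intergenic")
  prio <- c(rRNA = 1, tRNA = 2, ncRNA = 3, mRNA = 4)
  cat_one <- function(pos, strand) {
    inside <- genes$start <= pos & pos < genes$end
    same <- inside & genes$strand == strand
    if (any(same)) {
      g <- genes[same, , drop = FALSE]
      g <- g[order(prio[g$biotype]), , drop = FALSE][1, ]
      if (g$biotype != "mRNA") return(g$biotype)
      in_cds <- g$cds_lo <= pos & pos < g$cds_hi
      if (in_cds) return("mRNA_CDS")
      upstream <- if (g$strand == "+") pos < g$cds_lo else pos >= g$cds_hi
      return(if (upstream) "5'UTR" else "3'UTR")
    }
    if (any(inside)) return("antisense")
    "intergenic"
  }
  categories <- vapply(seq_len(nrow(pauses)), function(i)
    cat_one(pauses$pos[i], pauses$strand[i]), character(1))
  counts <- table(factor(categories, levels = labels))
  list(categories = categories,
       fractions = stats::setNames(
         as.numeric(counts) / max(1L, sum(counts)), labels))
}

#' TSS-proximity profile
#'
#' Histogram of the signed distance of items (pause sites or read 3'
#' ends) downstream of the nearest same-strand transcription start
#' site; items farther than `max_dist` from every TSS are excluded and
#' counted.
#'
#' @param items data frame with `pos` (0-based) and `strand`.
#' @param tss TSS table (`pos` 0-based, `strand`).
#' @param max_dist maximal absolute distance (default 500).
#' @param bin bin width in bp (default 25); bin `k` covers distances
#'   `[k * bin, (k + 1) * bin)`.
#' @return data frame `bin`, `dist_lo`, `count`, with attribute
#'   `n_excluded`.
#' @export
tss_distance_profile <- function(items, tss, max_dist = 500L, bin = 25L) {
  dist_one <- function(pos, strand) {
    cand <- tss[tss$strand == strand, , drop = FALSE]
    if (nrow(cand) == 0) return(NA_integer_)
    d <- if (strand == "+") pos - cand$pos else cand$pos - pos
    d[which.min(abs(d))]
  }
  d <- vapply(seq_len(nrow(items)), function(i)
    dist_one(items$pos[i], items$strand[i]), integer(1))
  ok <- !is.na(d) & abs(d) <= max_dist
  bins <- floor(d[ok] / bin)
  lv <- seq(floor(-max_dist / bin), floor(max_dist / bin))
  counts <- table(factor(bins, levels = lv))
  out <- data.frame(bin = lv, dist_lo = lv * bin,
                    count = as.integer(counts))
  attr(out, "n_excluded") <- sum(!ok)
  out
}
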