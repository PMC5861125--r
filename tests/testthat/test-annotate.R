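# hand-built annotation exercising every class on a 10 kb chromosome
toy_features <- function() {
  g <- function(start, end, strand, biotype, id) {
    dplyr::bind_rows(
      tibble::tibble(chrom = "chr1", start = start, end = end, strand = strand,
                     type = "gene", gene_id = id, transcript_id = NA,
                     gene_biotype = biotype, exon_number = NA_integer_),
      tibble::tibble(chrom = "chr1", start = start, end = end, strand = strand,
                     type = "transcript", gene_id = id,
                     transcript_id = paste0(id, ".t1"),
                     gene_biotype = biotype, exon_number = NA_integer_))
  }
  exon <- function(start, end, strand, id, n) {
    tibble::tibble(chrom = "chr1", start = start, end = end, strand = strand,
                   type = "exon", gene_id = id,
                   transcript_id = paste0(id, ".t1"),
                   gene_biotype = "protein_coding", exon_number = n)
  }
  utr <- function(start, end, strand, id, type) {
    tibble::tibble(chrom = "chr1", start = start, end = end, strand = strand,
                   type = type, gene_id = id,
                   transcript_id = paste0(id, ".t1"),
                   gene_biotype = "protein_coding", exon_number = NA_integer_)
  }
  dplyr::bind_rows(
    g(100L, 300L, "+", "rRNA", "rrna1"),
    tibble::tibble(chrom = "chr1", start = 100L, end = 300L, strand = "+",
                   type = "exon", gene_id = "rrna1",
                   transcript_id = "rrna1.t1", gene_biotype = "rRNA",
                   exon_number = 1L),
    g(500L, 900L, "-", "lincRNA", "nc1"),
    g(1000L, 1200L, "+", "processed_pseudogene", "ps1"),
    # coding gene: exons [2000,2300) and [2600,2900), 5'UTR, 3'UTR
    g(2000L, 2900L, "+", "protein_coding", "pc1"),
    exon(2000L, 2300L, "+", "pc1", 1L),
    exon(2600L, 2900L, "+", "pc1", 2L),
    utr(2000L, 2100L, "+", "pc1", "five_prime_utr"),
    utr(2800L, 2900L, "+", "pc1", "three_prime_utr")
  )
}

test_that("peaks take the highest-priority overlapping class", {
  idx <- build_annotation_index(toy_features())
  peak <- function(s, e, strand = "+") {
    tibble::tibble(chrom = "chr1", start = s, end = e, strand = strand)
  }
  # overlapping both an rRNA gene and (conceptually) lower classes
  both <- assign_target_class(
    dplyr::bind_rows(peak(250L, 2350L)), idx)
  expect_equal(as.character(both$target_class), "rRNA")
  expect_equal(as.character(
    assign_target_class(peak(5000L, 5100L), idx)$target_class), "intergenic")
  expect_equal(as.character(
    assign_target_class(peak(2350L, 2450L), idx)$target_class), "intron")
  expect_equal(as.character(
    assign_target_class(peak(2050L, 2060L), idx)$target_class), "5UTR")
  expect_equal(as.character(
    assign_target_class(peak(2850L, 2860L), idx)$target_class), "3UTR")
  expect_equal(as.character(
    assign_target_class(peak(2150L, 2250L), idx)$target_class), "exon")
  # only an opposite-strand exon under the peak -> antisense
  expect_equal(as.character(
    assign_target_class(peak(2100L, 2200L, strand = "-"), idx)$target_class),
    "antisense")
  expect_equal(as.character(
    assign_target_class(peak(600L, 700L, strand = "-"), idx)$target_class),
    "ncRNA")
})

test_that("class labels are exhaustive and exclusive", {
  idx <- build_annotation_index(toy_features())
  set.seed(61)
  peaks <- tibble::tibble(chrom = "chr1",
                          start = sample(0:5900, 200, replace = TRUE),
                          strand = sample(c("+", "-"), 200, replace = TRUE))
  peaks$end <- peaks$start + sample(10:80, 200, replace = TRUE)
  out <- assign_target_class(peaks, idx)
  expect_false(any(is.na(out$target_class)))
  expect_equal(sum(table(out$target_class)), nrow(peaks))
})

test_that("standardization extends to 41 nt about the midpoint and merges", {
  short <- tibble::tibble(chrom = "chr1", start = 100L, end = 110L,
                          strand = "+")
  std <- standardize_and_merge(short)
  expect_equal(std$end - std$start, 41)
  midpoint <- 105
  expect_true(std$start <= midpoint && midpoint < std$end)
  adjacent <- tibble::tibble(chrom = "chr1", start = c(0L, 41L),
                             end = c(41L, 82L), strand = "+")
  merged <- standardize_and_merge(adjacent)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(0, 82))
  long <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1100L,
                         strand = "+")
  expect_equal(standardize_and_merge(long)[, c("start", "end")],
               long[, c("start", "end")], ignore_attr = TRUE)
})

test_that("standardization is idempotent with non-adjacent >= 41 nt output", {
  set.seed(62)
  peaks <- tibble::tibble(chrom = "chr1",
                          start = sample(100:9000, 150, replace = TRUE),
                          strand = sample(c("+", "-"), 150, replace = TRUE))
  peaks$end <- peaks$start + sample(5:120, 150, replace = TRUE)
  once <- standardize_and_merge(peaks)
  twice <- standardize_and_merge(once)
  expect_equal(twice, once)
  expect_true(all(once$end - once$start >= 41))
  by_strand <- split(once, once$strand)
  for (s in by_strand) {
    if (nrow(s) > 1) expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }
})

test_that("overlap reports match a per-base oracle and partition the universe", {
  idx_peaks <- function(starts, widths) {
    tibble::tibble(chrom = "chr1", start = starts, end = starts + widths,
                   strand = ".")
  }
  a <- idx_peaks(c(100L, 500L), c(50L, 41L))
  expect_equal(overlap_sets(a = a, b = a)$n, 2)
  b <- idx_peaks(c(1000L, 2000L), c(41L, 41L))
  disjoint <- overlap_sets(a = a, b = b)
  expect_equal(sum(disjoint$n[disjoint$a & disjoint$b]), 0)
  set.seed(63)
  rnd <- function() {
    s <- sample(0:99000, 40, replace = TRUE)
    standardize_and_merge(idx_peaks(s, sample(41:200, 40, replace = TRUE)))
  }
  sets <- list(x = rnd(), y = rnd(), z = rnd())
  rep <- overlap_sets(sets)
  oracle <- overlap_oracle(sets)
  expect_equal(sum(rep$n), nrow(oracle))
  rep_counts <- dplyr::arrange(rep, x, y, z)
  oracle_counts <- dplyr::arrange(
    dplyr::count(tibble::as_tibble(oracle), x, y, z), x, y, z)
  expect_equal(rep_counts$n, oracle_counts$n)
})

test_that("peak-control proximity uses a strict 50 nt edge gap", {
  peak <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1041L,
                         strand = ".")
  read_at_gap <- function(gap) {
    tibble::tibble(chrom = "chr1", start = 1041L + gap, end = 1071L + gap,
                   strand = "+")
  }
  expect_equal(peak_control_proximity(peak, read_at_gap(51L))$fraction_far, 1)
  expect_equal(peak_control_proximity(peak, read_at_gap(50L))$fraction_far, 0)
  none <- peak_control_proximity(peak, read_at_gap(0L)[0, ])
  expect_equal(none$fraction_far, 1)
  overlapping <- peak_control_proximity(peak, read_at_gap(-20L))
  expect_equal(overlapping$fraction_far, 0)
})

test_that("motif scanning is IUPAC-aware and strand-oriented", {
  genome <- Biostrings::DNAStringSet(c(
    chrA = paste0(strrep("G", 50), "ACTAAC", strrep("G", 44)),
    chrB = strrep("G", 100)
  ))
  plus <- tibble::tibble(chrom = "chrA", start = 40L, end = 70L, strand = "+")
  hit <- motif_occurrence(plus, genome, "AYUAAY")
  expect_equal(hit$n_peaks_with_match, 1)
  allg <- motif_occurrence(
    tibble::tibble(chrom = "chrB", start = 0L, end = 100L, strand = "+"),
    genome, "AYUAAY")
  expect_equal(allg$total_matches, 0)
  # minus-strand peak whose reverse complement contains the motif
  rc_genome <- Biostrings::DNAStringSet(c(
    chrA = paste0(strrep("G", 50),
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString("ACTAAC"))), strrep("G", 44))))
  minus <- tibble::tibble(chrom = "chrA", start = 40L, end = 70L, strand = "-")
  expect_equal(motif_occurrence(minus, rc_genome, "AYUAAY")$n_peaks_with_match, 1)
  expect_equal(motif_occurrence(
    dplyr::mutate(minus, strand = "+"), rc_genome, "AYUAAY")$n_peaks_with_match, 0)
  expect_error(motif_occurrence(
    tibble::tibble(chrom = "chrA", start = 90L, end = 200L, strand = "+"),
    genome, "AYUAAY"), "bounds")
})

test_that("motif fractions survive a genome-wide strand flip with mirroring", {
  cfg <- sim_config(seed = 64, binding_mode = "motif", n_sites = 40)
  g <- make_genome(cfg)
  feats <- make_annotation(cfg, g$chrom_sizes)
  planted <- plant_sites(cfg, feats, g$genome)
  peaks <- dplyr::mutate(planted$sites, start = pmax(start - 10L, 0L),
                         end = end + 10L)
  frac <- motif_occurrence(peaks, planted$genome, cfg$motif)$fraction
  expect_equal(frac, 1)
  flipped_genome <- Biostrings::reverseComplement(planted$genome)
  names(flipped_genome) <- names(planted$genome)
  len <- setNames(g$chrom_sizes$size, g$chrom_sizes$chrom)
  mirrored <- dplyr::mutate(peaks,
                            new_start = len[chrom] - end,
                            end = len[chrom] - start,
                            start = new_start,
                            strand = ifelse(strand == "+", "-", "+"))
  frac2 <- motif_occurrence(mirrored, flipped_genome, cfg$motif)$fraction
  expect_equal(frac2, frac)
})
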