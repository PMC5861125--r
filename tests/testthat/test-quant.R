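sizes <- tibble::tibble(chrom = c("chr1", "chr2"), size = c(1000L, 500L))

event_at <- function(pos, chrom = "chr1", lib = NULL, n = 1L) {
  if (length(pos) == 1) pos <- rep(pos, n)
  out <- tibble::tibble(chrom = chrom, strand = "+",
                        crosslink_pos = as.integer(pos),
                        read_count = 1L)
  if (!is.null(lib)) out$library_name <- lib
  out
}

test_that("binning assigns each event to one anchored bin and conserves totals", {
  b <- bin_counts(event_at(150), sizes)
  expect_equal(b$start, 100)
  expect_equal(b$end, 200)
  expect_equal(b$count, 1)
  set.seed(3)
  pos <- sample(0:999, 500, replace = TRUE)
  b2 <- bin_counts(event_at(pos), sizes)
  expect_equal(sum(b2$count), 500)
  # integer-division oracle
  oracle <- table(100 * (pos %/% 100))
  expect_equal(b2$count, as.integer(oracle[as.character(b2$start)]))
  expect_error(bin_counts(event_at(5000), sizes), "beyond the chromosome end")
})

test_that("total enrichment is the ratio of event totals, with flagged infinity", {
  e <- total_enrichment(event_at(1, n = 1000), event_at(1, n = 100))
  expect_equal(e$ratio, 10)
  expect_equal(glance(total_enrichment(event_at(1, n = 5),
                                       event_at(2, n = 5)))$ratio, 1)
  z <- total_enrichment(list(event_at(1, n = 3)), event_at(1, n = 0))
  expect_true(is.infinite(z$ratio))
  expect_true(z$infinite)
})

test_that("MA tables honour the minimum-coverage rule and the median summary", {
  bins <- tibble::tibble(chrom = "chr1", start = seq(0, 900, 100),
                         end = seq(100, 1000, 100),
                         A = c(4L, 8L, 16L, 1L, 0L, 5L, 7L, 9L, 3L, 6L),
                         B = c(4L, 8L, 16L, 5L, 9L, 5L, 7L, 9L, 3L, 6L))
  identical_ma <- ma_table(bins, "A", "A")
  expect_true(all(identical_ma$log2fc == 0))
  expect_equal(attr(identical_ma, "median_log2fc"), 0)
  # bins with counts (1,5) and (0,9) are excluded
  ma <- ma_table(bins, "A", "B")
  expect_equal(nrow(ma), 8)
  doubled <- dplyr::mutate(bins, B = 2L * A)
  expect_equal(attr(ma_table(doubled, "A", "B"), "median_log2fc"), -1)
  # antisymmetry under swapping the libraries
  expect_equal(attr(ma_table(bins, "A", "B"), "median_log2fc"),
               -attr(ma_table(bins, "B", "A"), "median_log2fc"))
})

test_that("median-of-ratios factors recover planted scales exactly", {
  bins <- tibble::tibble(chrom = "chr1", start = seq(0, 400, 100),
                         end = seq(100, 500, 100),
                         A = c(10L, 20L, 30L, 40L, 50L))
  bins$B <- bins$A
  f <- median_ratio_factors(bins, c("A", "B"))
  expect_equal(f$size_factor, c(1, 1))
  scaled <- dplyr::mutate(bins, B = 3L * A)
  fs <- median_ratio_factors(scaled, c("A", "B"))
  # scale-equivariance: the c-fold library gets factor c/sqrt(c) relative
  # to the geometric-mean reference, i.e. ratios (1/sqrt(3), sqrt(3))
  expect_equal(fs$size_factor[2] / fs$size_factor[1], 3)
  worked <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                           A = 4L, B = 9L)
  fw <- median_ratio_factors(worked, c("A", "B"))
  expect_equal(fw$size_factor, c(4 / 6, 9 / 6))
  empty <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                          A = 0L, B = 9L)
  expect_error(median_ratio_factors(empty, c("A", "B")), "larger bins")
})

test_that("median-of-ratios agrees with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(13)
  m <- matrix(rpois(300, 20) + 1L, ncol = 3,
              dimnames = list(NULL, c("A", "B", "C")))
  bins <- dplyr::bind_cols(
    tibble::tibble(chrom = "chr1", start = seq_len(100) * 100L - 100L,
                   end = seq_len(100) * 100L),
    tibble::as_tibble(m))
  ours <- median_ratio_factors(bins, c("A", "B", "C"))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(ours$size_factor, unname(ref), tolerance = 1e-12)
})

test_that("bin correlations match direct formulas and refuse tiny inputs", {
  bins <- tibble::tibble(chrom = "chr1", start = seq(0, 900, 100),
                         end = seq(100, 1000, 100),
                         A = c(5L, 9L, 2L, 7L, 4L, 8L, 1L, 3L, 6L, 10L))
  bins$B <- bins$A
  expect_equal(correlate_bins(bins, "A", "B")$estimate, 1)
  bins$B <- 11L - bins$A
  expect_equal(correlate_bins(bins, "A", "B")$estimate, -1)
  set.seed(14)
  bins$B <- sample(bins$A)
  r <- correlate_bins(bins, "A", "B", method = "pearson")$estimate
  # textbook formula oracle
  x <- bins$A; y <- bins$B
  expect_equal(r, sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_warning(out <- correlate_bins(bins[1:2, ], "A", "B"), "undefined")
  expect_true(is.na(out$estimate))
})

test_that("relative standard deviation follows the sample-sd convention", {
  expect_equal(relative_std(c(5, 5, 5)), 0)
  expect_equal(relative_std(c(8, 12)), 100 * sd(c(8, 12)) / 10)
  expect_warning(single <- relative_std(7), "single value")
  expect_equal(single, 0)
  expect_warning(zero <- relative_std(c(-1, 1)), "mean is 0")
  expect_true(is.na(zero))
})

test_that("the enriched-bin caller finds planted bins and obeys monotonicity", {
  set.seed(15)
  n <- 50
  bins <- tibble::tibble(chrom = "chr1", start = seq_len(n) * 100L - 100L,
                         end = seq_len(n) * 100L,
                         signal = rpois(n, 5), control = rpois(n, 5))
  flat <- call_enriched_bins(dplyr::mutate(bins, signal = control),
                             "signal", "control")
  expect_equal(nrow(flat), 0)
  bins$signal[10] <- 100L
  bins$control[10] <- 1L
  peaks <- call_enriched_bins(bins, "signal", "control")
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$start, bins$start[10])
  expect_equal(nrow(call_enriched_bins(bins, "signal", "control",
                                       min_fold = Inf)), 0)
  # monotone non-increasing in min_fold and alpha
  n1 <- nrow(call_enriched_bins(bins, "signal", "control", min_fold = 1.5))
  n2 <- nrow(call_enriched_bins(bins, "signal", "control", min_fold = 3))
  expect_true(n2 <= n1)
  a1 <- nrow(call_enriched_bins(bins, "signal", "control", alpha = 0.1))
  a2 <- nrow(call_enriched_bins(bins, "signal", "control", alpha = 0.001))
  expect_true(a2 <= a1)
})

test_that("adjacent qualifying bins merge into one peak", {
  bins <- tibble::tibble(chrom = "chr1", start = c(0L, 100L, 200L, 500L),
                         end = c(100L, 200L, 300L, 600L),
                         signal = c(80L, 90L, 70L, 85L),
                         control = c(1L, 1L, 1L, 1L))
  # unit size factors: the libraries are notionally matched in depth
  peaks <- call_enriched_bins(bins, "signal", "control",
                              size_factors = c(signal = 1, control = 1))
  expect_equal(nrow(peaks), 2)
  expect_equal(peaks$end[1] - peaks$start[1], 300)
  expect_equal(peaks$n_bins, c(3L, 1L))
})

test_that("replicate event totals correlate on shared-site simulations", {
  pairs <- tibble::tibble(condition = c("a", "b", "c", "d"),
                          total_rep1 = c(100L, 2000L, 450L, 30L),
                          total_rep2 = c(100L, 2000L, 450L, 30L))
  conc <- event_total_concordance(pairs)
  expect_equal(conc$pearson_r, 1)
  expect_message(two <- event_total_concordance(pairs[1:2, ]),
                 "fewer than 3")
  expect_true(is.na(two$pearson_r))
  # stochastic replicates drawn from a shared site set
  cfg <- sim_config(seed = 51, n_molecules = 2000, error_rate = 0,
                    duplication = FALSE)
  sim <- simulate_experiment(cfg)
  aln <- simulate_alignments(sim$truth, seed = cfg$seed)
  ev <- call_events(aln)
  tot <- dplyr::count(ev, library_name)
  conds <- sub("_rep[0-9]+$", "", tot$library_name)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(tot, condition = conds,
                  rep = sub("^.*_", "", library_name)),
    id_cols = "condition", names_from = "rep", values_from = "n")
  expect_true(abs(wide$rep1[wide$condition == "signal"] -
                    wide$rep2[wide$condition == "signal"]) /
                wide$rep1[wide$condition == "signal"] < 0.2)
})
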