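#' Count crosslinking events in genomic bins
#'
#' Tiles every chromosome with fixed-width bins anchored at position 0
#' and increments, for each event, the single bin containing its
#' crosslinked nucleotide. Binning is strand-collapsed by default. When
#' the events carry a `library_name` column the result is a wide table
#' with one count column per library over the union of occupied bins
#' (unoccupied bins in the union get an explicit 0).
#'
#' @param events Event tibble with `crosslink_pos` (and optionally
#'   `library_name`).
#' @param chrom_sizes Tibble with `chrom` and `size`.
#' @param bin_size Bin width in nt (default 100).
#' @param stranded If `TRUE`, bins are kept separate per strand.
#' @return Tibble with `chrom`, `start`, `end` (and `strand` when
#'   stranded) plus one count column per library (or `count`).
#' @export
bin_counts <- function(events, chrom_sizes, bin_size = 100L, stranded = FALSE) {
  if (!"crosslink_pos" %in% names(events)) {
    events <- crosslink_position(events)
  }
  sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  bad <- is.na(sizes[events$chrom]) | events$crosslink_pos >= sizes[events$chrom]
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("event at %s:%d lies beyond the chromosome end",
                  events$chrom[i], events$crosslink_pos[i]))
  }
  keys <- c("chrom", if (stranded) "strand", "start")
  binned <- events %>%
    mutate(start = as.integer(bin_size * (.data$crosslink_pos %/% bin_size)))
  if ("library_name" %in% names(events)) {
    out <- binned %>%
      count(across(all_of(c("library_name", keys)))) %>%
      tidyr::pivot_wider(names_from = "library_name", values_from = "n",
                         values_fill = 0L)
  } else {
    out <- binned %>% count(across(all_of(keys)), name = "count")
  }
  out %>%
    mutate(end = as.integer(pmin(.data$start + bin_size,
                                 sizes[.data$chrom])), .after = "start") %>%
    arrange(across(all_of(keys)))
}

bin_count_columns <- function(bins) {
  setdiff(names(bins), c("chrom", "start", "end", "strand"))
}

#' Library-wide signal-to-control enrichment
#'
#' The total number of crosslinking events of the signal libraries
#' (replicates combined) divided by the total of the matched nonspecific
#' control libraries. Because multiplexed libraries are amplified and
#' sequenced jointly, this ratio reflects the RNA amounts and is
#' meaningful without normalization. A control total of 0 yields an
#' infinite ratio, reported with a flag rather than hidden by a
#' pseudocount.
#'
#' @param signal,control Event tibbles, or lists of event tibbles
#'   (replicates).
#' @return A `uvclap_enrichment` with `signal_total`, `control_total`,
#'   `ratio` and `infinite`; `glance()` returns it as a one-row tibble.
#' @export
total_enrichment <- function(signal, control) {
  total <- function(x) {
    if (is.data.frame(x)) x <- list(x)
    sum(vapply(x, nrow, integer(1)))
  }
  s <- total(signal)
  c0 <- total(control)
  structure(
    list(signal_total = s, control_total = c0,
         ratio = if (c0 == 0) Inf else s / c0,
         infinite = c0 == 0),
    class = "uvclap_enrichment"
  )
}

#' @export
print.uvclap_enrichment <- function(x, ...) {
  cat(sprintf("<uvclap_enrichment> signal %d / control %d events: ratio %s%s\n",
              x$signal_total, x$control_total, format(x$ratio, digits = 4),
              if (x$infinite) " (control empty)" else ""))
  invisible(x)
}

#' @export
glance.uvclap_enrichment <- function(x, ...) {
  tibble(signal_total = x$signal_total, control_total = x$control_total,
         ratio = x$ratio, infinite = x$infinite)
}

#' MA table for a replicate pair
#'
#' For each genomic bin covered by at least `min_events` crosslinking
#' events in both libraries, the mean log2 count and the log2 fold change
#' `log2(A/B)` are reported, together with the median log2 fold change
#' over the included bins. Raw counts are used by default (the comparison
#' of interest is between jointly amplified replicates); size factors can
#' be supplied to compare normalized counts.
#'
#' @param bins Wide bin-count table from [bin_counts()].
#' @param a,b Names of the two count columns to compare.
#' @param min_events Minimum events required in both libraries for a bin
#'   to be included (default 2).
#' @param size_factors Optional named vector of per-library size factors
#'   to divide counts by before comparison.
#' @return A `uvclap_ma` tibble (`mean_log2`, `log2fc` per bin) with
#'   attribute `median_log2fc`; see `glance()` and `autoplot()`.
#' @export
ma_table <- function(bins, a, b, min_events = 2L, size_factors = NULL) {
  ca <- bins[[a]]
  cb <- bins[[b]]
  keep <- ca >= min_events & cb >= min_events
  fa <- if (is.null(size_factors)) 1 else size_factors[[a]]
  fb <- if (is.null(size_factors)) 1 else size_factors[[b]]
  out <- bins[keep, intersect(c("chrom", "start", "end", "strand"), names(bins))]
  out$mean_log2 <- (log2(ca[keep] / fa) + log2(cb[keep] / fb)) / 2
  out$log2fc <- log2((ca[keep] / fa) / (cb[keep] / fb))
  attr(out, "median_log2fc") <- median(out$log2fc)
  attr(out, "libraries") <- c(a = a, b = b)
  class(out) <- c("uvclap_ma", class(out))
  out
}

#' @export
glance.uvclap_ma <- function(x, ...) {
  tibble(n_bins = nrow(x),
         median_log2fc = attr(x, "median_log2fc"),
         library_a = attr(x, "libraries")[["a"]],
         library_b = attr(x, "libraries")[["b"]])
}

#' @export
tidy.uvclap_ma <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "uvclap_ma")
  as_tibble(out)
}

#' Median-of-ratios library size factors
#'
#' The standard median-of-ratios estimator: for each bin with a nonzero
#' count in every library, the per-library count is divided by the
#' geometric mean of that bin's counts across libraries; a library's size
#' factor is the median of these ratios. The factor multiplies the
#' reference to give the library, so a library with twice the material
#' gets factor 2. Identical libraries get factor 1; scaling one library
#' by c scales its factor by exactly c.
#'
#' @param bins Wide bin-count table from [bin_counts()].
#' @param libraries Count columns to use (default: all).
#' @return A `uvclap_normalization` tibble with `library` and
#'   `size_factor`.
#' @export
median_ratio_factors <- function(bins, libraries = bin_count_columns(bins)) {
  if (length(libraries) < 2) abort("at least two libraries are required")
  m <- as.matrix(bins[, libraries])
  all_nonzero <- rowSums(m == 0) == 0
  if (!any(all_nonzero)) {
    abort(paste0("no bin has nonzero counts in every library; ",
                 "consider larger bins"))
  }
  logm <- log(m[all_nonzero, , drop = FALSE])
  log_geomean <- rowMeans(logm)
  factors <- apply(logm, 2, function(col) exp(median(col - log_geomean)))
  out <- tibble(library = libraries, size_factor = unname(factors))
  class(out) <- c("uvclap_normalization", class(out))
  out
}

#' Correlation of binned event counts
#'
#' Spearman or Pearson correlation of two libraries over genomic bins.
#' The inclusion rule is configurable: all bins of the table, bins with
#' at least `min_events` in either library (`"any"`, as used when
#' comparing control replicates on bins overlapping at least one
#' background event), or in both libraries (`"both"`).
#'
#' @inheritParams ma_table
#' @param method `"spearman"` or `"pearson"`.
#' @param include Bin inclusion rule (see Details).
#' @param min_events Event threshold for the inclusion rule.
#' @return One-row tibble with `method`, `n_regions`, `estimate`
#'   (`NA` with a warning when fewer than 3 regions are included).
#' @export
correlate_bins <- function(bins, a, b, method = c("spearman", "pearson"),
                           include = c("all", "any", "both"),
                           min_events = 1L) {
  method <- match.arg(method)
  include <- match.arg(include)
  ca <- bins[[a]]
  cb <- bins[[b]]
  keep <- switch(include,
                 all = rep(TRUE, length(ca)),
                 any = ca >= min_events | cb >= min_events,
                 both = ca >= min_events & cb >= min_events)
  n <- sum(keep)
  if (n < 3) {
    warn("fewer than 3 regions included; correlation is undefined")
    return(tibble(method = method, n_regions = n, estimate = NA_real_))
  }
  tibble(method = method, n_regions = n,
         estimate = cor(ca[keep], cb[keep], method = method))
}

#' Relative standard deviation (coefficient of variation)
#'
#' 100 times the sample standard deviation divided by the mean; used to
#' quantify how consistently different barcodes recover the same RNA.
#'
#' @param counts Numeric vector of event counts.
#' @return Percent relative standard deviation; 0 with a warning for a
#'   single value, `NA` with a warning for mean 0.
#' @export
relative_std <- function(counts) {
  if (length(counts) < 2) {
    warn("relative standard deviation of a single value is 0 by convention")
    return(0)
  }
  m <- mean(counts)
  if (m == 0) {
    warn("mean is 0; relative standard deviation undefined")
    return(NA_real_)
  }
  100 * sd(counts) / m
}

#' Call signal-enriched bins against the control
#'
#' A deliberately simple enriched-region caller used as pipeline
#' plumbing (production analyses should use a dedicated peak caller).
#' A bin qualifies when (i) its size-factor-normalized signal count is at
#' least `min_fold` times the normalized control count, (ii) it holds at
#' least `min_events` signal events, and (iii) a binomial test of the
#' signal count against the library-size expectation is significant at
#' `alpha` after Benjamini-Hochberg correction. Adjacent qualifying bins
#' are merged into peaks.
#'
#' @param bins Wide bin-count table.
#' @param signal,control Names of the signal and control count columns.
#' @param size_factors Optional `uvclap_normalization` (or named vector).
#'   The default is unit factors: jointly amplified libraries are
#'   directly comparable, and depth normalization would divide out the
#'   library-wide enrichment. Pass [median_ratio_factors()] output or
#'   library totals to normalize instead.
#' @param min_fold Minimum normalized fold change.
#' @param min_events Minimum raw signal events per bin.
#' @param alpha BH-adjusted significance threshold.
#' @return Peak tibble (`chrom`, `start`, `end`, `strand`, `n_bins`,
#'   `signal`, `control`, `min_padj`).
#' @export
call_enriched_bins <- function(bins, signal, control, size_factors = NULL,
                               min_fold = 2, min_events = 2L, alpha = 0.05) {
  s <- bins[[signal]]
  c0 <- bins[[control]]
  if (inherits(size_factors, "uvclap_normalization")) {
    size_factors <- setNames(size_factors$size_factor, size_factors$library)
  }
  if (is.null(size_factors)) {
    size_factors <- setNames(c(1, 1), c(signal, control))
  }
  fs <- size_factors[[signal]]
  fc <- size_factors[[control]]
  p0 <- fs / (fs + fc)
  tested <- s + c0 > 0
  pval <- rep(NA_real_, length(s))
  pval[tested] <- pbinom(s[tested] - 1L, s[tested] + c0[tested], p0,
                         lower.tail = FALSE)
  padj <- rep(NA_real_, length(s))
  padj[tested] <- p.adjust(pval[tested], method = "BH")
  qualifying <- tested &
    (s / fs) >= min_fold * (c0 / fc) &
    s >= min_events &
    !is.na(padj) & padj < alpha
  hits <- bins[qualifying, ]
  if (nrow(hits) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), n_bins = integer(),
                  signal = integer(), control = integer(),
                  min_padj = double()))
  }
  hits$padj <- padj[qualifying]
  hits$.s <- s[qualifying]
  hits$.c <- c0[qualifying]
  hits <- arrange(hits, .data$chrom, .data$start)
  new_run <- c(TRUE, hits$chrom[-1] != hits$chrom[-nrow(hits)] |
                 hits$start[-1] != hits$end[-nrow(hits)])
  hits$run <- cumsum(new_run)
  hits %>%
    group_by(.data$run) %>%
    summarise(chrom = .data$chrom[1],
              start = min(.data$start), end = max(.data$end),
              strand = ".",
              n_bins = dplyr::n(),
              signal = sum(.data$.s), control = sum(.data$.c),
              min_padj = min(.data$padj), .groups = "drop") %>%
    select(-"run")
}

#' Concordance of replicate event totals
#'
#' Compares the total number of crosslinking events between pairs of
#' biological replicates across conditions, the most direct check that
#' jointly amplified libraries preserve RNA quantities. The Pearson
#' correlation of the paired totals is computed when at least three pairs
#' are available.
#'
#' @param pairs Tibble with columns `condition`, `total_rep1`,
#'   `total_rep2` (or a named list of 2-element lists of event tibbles,
#'   from which totals are taken as row counts).
#' @return List with `totals` (tibble) and `pearson_r` (`NA` with a
#'   message when fewer than 3 pairs).
#' @export
event_total_concordance <- function(pairs) {
  if (!is.data.frame(pairs)) {
    pairs <- tibble(
      condition = names(pairs),
      total_rep1 = vapply(pairs, function(p) nrow(p[[1]]), integer(1)),
      total_rep2 = vapply(pairs, function(p) nrow(p[[2]]), integer(1))
    )
  }
  r <- if (nrow(pairs) >= 3) {
    cor(pairs$total_rep1, pairs$total_rep2, method = "pearson")
  } else {
    rlang::inform("fewer than 3 replicate pairs; correlation not computed")
    NA_real_
  }
  list(totals = pairs, pearson_r = r)
}
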