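# priority order for single-label peak annotation
TARGET_CLASS_PRIORITY <- c("rRNA", "ncRNA", "pseudogene", "3UTR", "5UTR",
                           "exon", "intron", "antisense", "intergenic")

# default mapping from GTF gene_biotype to a gene-level target class;
# anything not protein-coding, rRNA or pseudogene-like counts as ncRNA
biotype_class <- function(biotype) {
  case_when(
    biotype == "rRNA" ~ "rRNA",
    stringr::str_detect(biotype, "pseudogene") ~ "pseudogene",
    biotype == "protein_coding" ~ "coding",
    TRUE ~ "ncRNA"
  )
}

#' Build an interval index of genomic target classes
#'
#' Derives, from a gene annotation, the feature sets needed for
#' priority-based peak annotation: rRNA, ncRNA and pseudogene gene
#' bodies, 3'-UTRs, 5'-UTRs and exons of protein-coding genes, introns
#' (gene body minus exons), and all gene bodies (for the antisense
#' class).
#'
#' @param features Annotation tibble (see [read_gtf()] /
#'   [make_annotation()]) with columns `chrom`, `start`, `end`, `strand`,
#'   `type`, `gene_id`, `gene_biotype`.
#' @return A `uvclap_annotation_index`: named list of `GRanges`, one per
#'   feature class.
#' @export
build_annotation_index <- function(features) {
  genes <- filter(features, .data$type == "gene")
  genes$class <- biotype_class(genes$gene_biotype)
  gr <- function(x) features_to_granges(x[, c("chrom", "start", "end", "strand")])
  coding_ids <- genes$gene_id[genes$class == "coding"]
  exons <- filter(features, .data$type == "exon",
                  .data$gene_id %in% coding_ids)
  gene_bodies <- gr(genes)
  exon_gr <- gr(exons)
  idx <- list(
    rRNA = gr(filter(genes, .data$class == "rRNA")),
    ncRNA = gr(filter(genes, .data$class == "ncRNA")),
    pseudogene = gr(filter(genes, .data$class == "pseudogene")),
    `3UTR` = gr(filter(features, .data$type %in%
                         c("three_prime_utr", "3UTR", "three_prime_UTR"))),
    `5UTR` = gr(filter(features, .data$type %in%
                         c("five_prime_utr", "5UTR", "five_prime_UTR"))),
    exon = exon_gr,
    intron = GenomicRanges::setdiff(gr(genes[genes$class == "coding", ]),
                                    exon_gr, ignore.strand = FALSE),
    gene_body = gene_bodies
  )
  structure(idx, class = "uvclap_annotation_index")
}

#' @export
print.uvclap_annotation_index <- function(x, ...) {
  cat("<uvclap_annotation_index>\n")
  for (nm in names(x)) cat(sprintf("  %-10s %d intervals\n", nm, length(x[[nm]])))
  invisible(x)
}

peaks_to_granges <- function(peaks) {
  strand <- if ("strand" %in% names(peaks)) {
    ifelse(peaks$strand %in% c("+", "-"), peaks$strand, "*")
  } else {
    "*"
  }
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end),
                         strand = strand)
}

#' Assign each peak to a single genomic target class
#'
#' Every peak receives exactly one label, the highest-priority class
#' among the feature classes it overlaps by at least one nucleotide on
#' the same strand, in the fixed order rRNA, ncRNA, pseudogene, 3'-UTR,
#' 5'-UTR, exon, intron; a peak overlapping genes only on the opposite
#' strand is `antisense`, and a peak overlapping nothing is
#' `intergenic`. Unstranded peaks (strand `.` or `*`) match features on
#' either strand and can therefore never be antisense.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, optional
#'   `strand`).
#' @param index A [build_annotation_index()] result.
#' @return `peaks` with an added `target_class` factor ordered by
#'   priority.
#' @export
assign_target_class <- function(peaks, index) {
  pg <- peaks_to_granges(peaks)
  cls <- rep(NA_character_, length(pg))
  for (nm in c("rRNA", "ncRNA", "pseudogene", "3UTR", "5UTR", "exon", "intron")) {
    hit <- IRanges::overlapsAny(pg, index[[nm]], ignore.strand = FALSE)
    cls[is.na(cls) & hit] <- nm
  }
  anti <- IRanges::overlapsAny(pg, invertStrand_keep(index$gene_body),
                               ignore.strand = FALSE) &
    as.character(BiocGenerics::strand(pg)) %in% c("+", "-")
  cls[is.na(cls) & anti] <- "antisense"
  cls[is.na(cls)] <- "intergenic"
  peaks$target_class <- factor(cls, levels = TARGET_CLASS_PRIORITY)
  peaks
}

invertStrand_keep <- function(gr) {
  s <- as.character(BiocGenerics::strand(gr))
  BiocGenerics::strand(gr) <- ifelse(s == "+", "-", ifelse(s == "-", "+", s))
  gr
}

#' Standardize peak lengths and merge adjacent peaks
#'
#' For cross-method comparison, peaks shorter than `min_len` (default
#' 41 nt) are extended symmetrically about their midpoint to exactly
#' `min_len`; when the required extension is odd the extra base goes to
#' the 3' side (strand-aware; unstranded peaks are treated as plus).
#' Overlapping or abutting peaks (gap of at most `merge_gap`, default 0)
#' are then merged per chromosome and strand. The operation is
#' idempotent, and its output intervals are pairwise non-adjacent.
#'
#' @param peaks Peak tibble.
#' @param min_len Minimum standardized peak length in nt.
#' @param merge_gap Maximum gap between peaks that are still merged.
#' @return Sorted tibble of merged peaks, each at least `min_len` long
#'   (except where clamping at position 0 intervened).
#' @export
standardize_and_merge <- function(peaks, min_len = 41L, merge_gap = 0L) {
  if (nrow(peaks) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep(".", nrow(peaks))
  len <- peaks$end - peaks$start
  need <- pmax(min_len - len, 0L)
  left <- ifelse(strand == "-", ceiling(need / 2), need %/% 2)
  start <- pmax(peaks$start - as.integer(left), 0L)
  end <- start + pmax(len, min_len)
  gr <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(start + 1L, end),
                               strand = ifelse(strand %in% c("+", "-"),
                                               strand, "*"))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L,
                                  ignore.strand = FALSE)
  out <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(merged)),
    start = BiocGenerics::start(merged) - 1L,
    end = BiocGenerics::end(merged),
    strand = sub("\\*", ".", as.character(BiocGenerics::strand(merged)))
  )
  arrange(out, .data$chrom, .data$start, .data$strand)
}

#' Overlap counts between standardized peak sets
#'
#' Builds the merged universe of regions from the union of two or three
#' standardized peak sets and counts, for every combination of set
#' membership, the regions supported (overlapped by at least 1 nt) by
#' exactly that combination of sets -- the numbers behind a Venn diagram.
#' Strand is ignored, matching the comparison of peak sets from
#' different methods.
#'
#' @param ... Two or three peak tibbles, preferably named.
#' @return A `uvclap_overlap` tibble with one logical membership column
#'   per set and `n` regions; the counts partition the merged universe.
#' @export
overlap_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  if (length(sets) < 2 || length(sets) > 3) {
    abort("overlap_sets() expects two or three peak sets")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  grs <- lapply(sets, peaks_to_granges)
  universe <- GenomicRanges::reduce(do.call(c, unname(lapply(grs, function(g) {
    BiocGenerics::strand(g) <- "*"
    g
  }))))
  membership <- as_tibble(lapply(grs, function(g) {
    IRanges::overlapsAny(universe, g, ignore.strand = TRUE)
  }))
  out <- membership %>% count(across(dplyr::everything()), name = "n")
  attr(out, "n_regions") <- length(universe)
  class(out) <- c("uvclap_overlap", class(out))
  out
}

#' Fraction of peaks far from any control read
#'
#' For each peak, the edge-to-edge distance to the nearest control read
#' interval is computed (0 for overlapping or abutting intervals); a
#' peak is "far" when that distance is strictly greater than `distance`
#' nucleotides. Peaks with no control read on their chromosome are far.
#' Strand is ignored: a control read on either strand counts as nearby
#' background.
#'
#' @param peaks Peak tibble.
#' @param control_reads Interval tibble of control reads (or control
#'   events as 1-nt intervals).
#' @param distance Gap threshold in nt (default 50, strict `>`).
#' @return List with `fraction_far`, `n_far`, `n_peaks` and the per-peak
#'   `distances` tibble.
#' @export
peak_control_proximity <- function(peaks, control_reads, distance = 50L) {
  n <- nrow(peaks)
  if (n == 0) abort("no peaks supplied")
  if (nrow(control_reads) == 0) {
    d <- rep(Inf, n)
  } else {
    pg <- peaks_to_granges(peaks)
    cg <- peaks_to_granges(control_reads)
    hits <- GenomicRanges::distanceToNearest(pg, cg, ignore.strand = TRUE)
    d <- rep(Inf, n)
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  far <- d > distance
  list(
    fraction_far = mean(far),
    n_far = sum(far),
    n_peaks = n,
    distances = tibble(peak = seq_len(n), nearest_control_gap = d, far = far)
  )
}

#' Occurrence of an IUPAC consensus motif in peak sequences
#'
#' Scans the strand-oriented sequence of each peak (reverse complement
#' for minus-strand peaks) for windows matching a degenerate IUPAC motif
#' such as the QKI consensus `AYUAAY` (RNA `U` is read as `T`).
#'
#' @param peaks Peak tibble.
#' @param genome A `DNAStringSet` or path to a FASTA file.
#' @param motif IUPAC motif string.
#' @return List with `total_matches`, `n_peaks_with_match`, `fraction`
#'   and the per-peak `matches` tibble.
#' @export
motif_occurrence <- function(peaks, genome, motif = "AYUAAY") {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub(" .*", "", names(genome))
  if (any(peaks$end > Biostrings::width(genome)[match(peaks$chrom, names(genome))],
          na.rm = TRUE) || any(is.na(match(peaks$chrom, names(genome))))) {
    abort("peak lies beyond the genome sequence bounds")
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start = peaks$start[i] + 1L,
                                    end = peaks$end[i]))
  }, character(1)))
  minus <- if ("strand" %in% names(peaks)) peaks$strand == "-" else
    rep(FALSE, nrow(peaks))
  seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  pattern <- paste(iupac_letters(motif), collapse = "")
  counts <- Biostrings::vcountPattern(pattern, seqs, fixed = FALSE)
  list(
    total_matches = sum(counts),
    n_peaks_with_match = sum(counts > 0),
    fraction = mean(counts > 0),
    matches = tibble(peak = seq_len(nrow(peaks)), n_matches = counts)
  )
}
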