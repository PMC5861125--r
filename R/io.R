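#' Read and write FASTQ files
#'
#' Thin wrappers around Biostrings' FASTQ support, returning and
#' consuming plain tibbles. Files may be gzip-compressed.
#'
#' @param path FASTQ file path.
#' @return `read_fastq()`: tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' @rdname read_fastq
#' @param fastq1,fastq2 Paths to the two mates of a paired FASTQ set
#'   (records in matching order).
#' @return `read_fastq_pair()`: tibble with `read_id`, `mate1_seq`,
#'   `mate1_qual`, `mate2_seq`, `mate2_qual`.
#' @export
read_fastq_pair <- function(fastq1, fastq2) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (nrow(r1) != nrow(r2)) abort("mate files differ in record count")
  tibble(
    read_id = sub(" .*", "", r1$read_id),
    mate1_seq = r1$seq, mate1_qual = r1$qual,
    mate2_seq = r2$seq, mate2_qual = r2$qual
  )
}

#' @rdname read_fastq
#' @param ids,seqs,quals Read names, sequences, and quality strings
#'   (`NULL` qualities are written as constant maximum quality).
#' @export
write_fastq <- function(ids, seqs, quals = NULL, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  quals[nchar(quals) != nchar(seqs)] <-
    strrep("I", nchar(seqs)[nchar(quals) != nchar(seqs)])
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Read and write chromosome sizes
#'
#' Plain two-column TSV (`chrom`, `size`), the standard `chrom.sizes`
#' format.
#'
#' @param path File path.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "size"),
                  col_types = readr::cols(chrom = "c", size = "i"),
                  comment = "#")
}

#' @rdname read_chrom_sizes
#' @param sizes Tibble with `chrom` and `size`.
#' @export
write_chrom_sizes <- function(sizes, path) {
  readr::write_tsv(sizes[, c("chrom", "size")], path, col_names = FALSE)
  invisible(path)
}

# features tibble <-> GRanges. Internally all coordinates are 0-based
# half-open (BED convention); GRanges and GTF are 1-based closed, so the
# conversion happens here and only here.
features_to_granges <- function(x, seq_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*"
  )
  extra <- setdiff(names(x), c("chrom", "start", "end", "strand"))
  if (length(extra) > 0) {
    S4Vectors::mcols(gr) <- as.data.frame(x[, extra, drop = FALSE])
  }
  if (!is.null(seq_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seq_lengths)
    GenomeInfoDb::seqlengths(gr) <- seq_lengths
  }
  gr
}

granges_to_features <- function(gr) {
  out <- tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  )
  mc <- as_tibble(as.data.frame(S4Vectors::mcols(gr)))
  if (ncol(mc) > 0) out <- dplyr::bind_cols(out, mc)
  out
}

#' Read and write gene annotation as GTF
#'
#' Wrappers around `rtracklayer`; the tibble representation uses 0-based
#' half-open coordinates and the columns `chrom`, `start`, `end`,
#' `strand`, `type`, `gene_id`, `transcript_id`, `gene_biotype`,
#' `exon_number`.
#'
#' @param path GTF file path.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  out <- granges_to_features(gr)
  keep <- intersect(
    c("chrom", "start", "end", "strand", "type", "gene_id",
      "transcript_id", "gene_biotype", "exon_number"),
    names(out))
  out <- out[, keep]
  out$type <- as.character(out$type)
  if ("exon_number" %in% names(out)) {
    out$exon_number <- as.integer(out$exon_number)
  }
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' @rdname read_gtf
#' @param features Annotation tibble as produced by [make_annotation()]
#'   or [read_gtf()].
#' @export
write_gtf <- function(features, path) {
  gr <- features_to_granges(features)
  S4Vectors::mcols(gr)$source <- "uvclap"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED6 with 0-based half-open coordinates; the tibble columns are
#' `chrom`, `start`, `end`, `name`, `score`, `strand`.
#'
#' @param path BED file path.
#' @export
read_bed <- function(path) {
  readr::read_tsv(
    path, comment = "#",
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc"
  )
}

#' @rdname read_bed
#' @param x Tibble of intervals (missing BED columns are filled).
#' @export
write_bed <- function(x, path) {
  x <- mutate(
    x,
    name = if ("name" %in% names(x)) .data$name else ".",
    score = if ("score" %in% names(x)) .data$score else 0,
    strand = if ("strand" %in% names(x)) .data$strand else "."
  )
  lines <- "#chrom\tstart\tend\tname\tscore\tstrand"
  if (nrow(x) > 0) {
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                              x$chrom, as.integer(x$start), as.integer(x$end),
                              as.character(x$name), format(x$score, trim = TRUE),
                              x$strand))
  }
  writeLines(lines, path)
  invisible(path)
}
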