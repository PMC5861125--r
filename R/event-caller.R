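#' Keep uniquely mapped alignments
#'
#' Multi-mapping reads are removed before event calling. Multi-mapping
#' status is carried as the logical `multimap` column of the alignment
#' table; how it is derived is aligner-specific (for bowtie2 output it
#' corresponds to the presence of the `XS:i` secondary-score SAM tag).
#'
#' @param alignments Alignment tibble with columns `read_id`, `chrom`,
#'   `strand`, `mate1_start`, `mate2_start`, `aln_length`, `umi`,
#'   `multimap`.
#' @return The uniquely mapped subset, input order preserved.
#' @export
filter_unique <- function(alignments) {
  filter(alignments, !.data$multimap)
}

#' Collapse alignments into crosslinking events
#'
#' Alignments sharing the UMI and the start coordinates of both mates are
#' PCR copies of one captured RNA molecule and are combined into a single
#' crosslinking event whose `read_count` records the group size. The
#' result is coordinate-sorted and therefore independent of input order;
#' applying the collapse to its own output is a no-op.
#'
#' @param alignments Uniquely mapped alignment tibble (see
#'   [filter_unique()]); an optional `library_name` column partitions the
#'   collapse per library.
#' @return Event tibble with one row per distinct
#'   (`chrom`, `strand`, `mate1_start`, `mate2_start`, `umi`) and columns
#'   `read_count` and `aln_length`.
#' @export
collapse_to_events <- function(alignments) {
  keys <- intersect(c("library_name", "chrom", "strand", "mate1_start",
                      "mate2_start", "umi"), names(alignments))
  rc <- if ("read_count" %in% names(alignments)) {
    alignments$read_count
  } else {
    rep(1L, nrow(alignments))
  }
  alignments %>%
    mutate(.rc = rc) %>%
    group_by(across(all_of(keys))) %>%
    summarise(read_count = sum(.data$.rc),
              aln_length = max(.data$aln_length),
              .groups = "drop") %>%
    arrange(across(all_of(keys)))
}

#' Remove spurious events created by UMI errors
#'
#' Sequencing or amplification errors inside the UMI split one true event
#' into siblings at the same mapped position. Within each group of events
#' sharing (`chrom`, `strand`, `mate1_start`, `mate2_start`), events
#' supported by less than `threshold` (default 10%) of the reads of the
#' strongest event in the group are removed; the boundary is strict, so
#' an event at exactly the threshold is retained. The strongest event of
#' a group is never removed, and `threshold = 0` is the identity.
#'
#' @param events Event tibble from [collapse_to_events()].
#' @param threshold Fraction of the positional maximum below which an
#'   event is called spurious.
#' @return The retained subset of `events`.
#' @export
filter_spurious <- function(events, threshold = 0.10) {
  keys <- intersect(c("library_name", "chrom", "strand", "mate1_start",
                      "mate2_start"), names(events))
  events %>%
    group_by(across(all_of(keys))) %>%
    filter(.data$read_count >= threshold * max(.data$read_count)) %>%
    ungroup()
}

#' Assign the crosslinked nucleotide of each event
#'
#' Reverse transcription predominantly truncates at the crosslinked
#' nucleotide, which therefore sits immediately 5' of the cDNA. Under the
#' default `"upstream"` convention the crosslink is placed one nucleotide
#' upstream of the fragment 5' end in genome coordinates: `mate1_start - 1`
#' on the plus strand, and the position just past the fragment end on the
#' minus strand. The `"start"` convention instead reports the fragment 5'
#' end itself (read-start convention). Positions that would fall below 0
#' are clamped and flagged.
#'
#' @param events Event tibble carrying `strand`, `mate1_start`,
#'   `mate2_start` and `aln_length`.
#' @param convention `"upstream"` (default) or `"start"`.
#' @return `events` with columns `crosslink_pos` (0-based) and
#'   `clamped`.
#' @export
crosslink_position <- function(events, convention = c("upstream", "start")) {
  convention <- match.arg(convention)
  fstart <- pmin(events$mate1_start, events$mate2_start)
  fend <- fstart + events$aln_length # half-open end
  pos <- if (convention == "upstream") {
    ifelse(events$strand == "-", fend, fstart - 1L)
  } else {
    ifelse(events$strand == "-", fend - 1L, fstart)
  }
  events %>%
    mutate(crosslink_pos = pmax(as.integer(pos), 0L),
           clamped = pos < 0L)
}

#' Duplication rate as a function of cDNA length
#'
#' PCR amplifies cDNAs of different lengths with different efficiency; in
#' uvCLAP libraries the excess of duplicates is concentrated around cDNAs
#' of 40-60 nt. This table contrasts raw read counts with collapsed event
#' counts per alignment-length bin, with `duplicate_fraction = 1 -
#' events/reads`. Bins with no reads are omitted.
#'
#' @param alignments Uniquely mapped alignments of one library.
#' @param events Collapsed events of the same library.
#' @param binwidth Width of the alignment-length bins in nt (default 1:
#'   one bin per distinct length).
#' @return Tibble with `length_bin` (lower edge), `reads`, `events`,
#'   `duplicate_fraction`.
#' @export
duplication_by_length <- function(alignments, events, binwidth = 1L) {
  bin <- function(len) as.integer(binwidth * (len %/% binwidth))
  r <- alignments %>%
    count(length_bin = bin(.data$aln_length), name = "reads")
  e <- events %>%
    count(length_bin = bin(.data$aln_length), name = "events")
  r %>%
    left_join(e, by = "length_bin") %>%
    mutate(events = dplyr::coalesce(.data$events, 0L),
           duplicate_fraction = 1 - .data$events / .data$reads) %>%
    arrange(.data$length_bin)
}

#' Convert events to BED6 intervals
#'
#' Each event becomes a 1-nt interval at its crosslinked nucleotide
#' (0-based half-open) with the read count in the score column. Events at
#' the same position with distinct UMIs yield distinct records.
#'
#' @param events Event tibble with `crosslink_pos` (see
#'   [crosslink_position()]).
#' @param path Optional path; when given, the track is written with
#'   [write_bed()].
#' @return A sorted BED tibble (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`).
#' @export
events_to_bed <- function(events, path = NULL) {
  if (!"crosslink_pos" %in% names(events)) {
    events <- crosslink_position(events)
  }
  bed <- events %>%
    mutate(start = .data$crosslink_pos,
           end = .data$crosslink_pos + 1L,
           name = ".",
           score = .data$read_count) %>%
    select("chrom", "start", "end", "name", "score", "strand") %>%
    arrange(.data$chrom, .data$start, .data$strand)
  if (!is.null(path)) write_bed(bed, path)
  bed
}

#' Call crosslinking events from an alignment table
#'
#' Convenience pipeline: unique-read filtering, UMI/coordinate collapse,
#' spurious-event removal and crosslink assignment in one call, with the
#' bookkeeping totals attached.
#'
#' @inheritParams filter_unique
#' @inheritParams filter_spurious
#' @inheritParams crosslink_position
#' @return Event tibble with `crosslink_pos`; attribute `totals` records
#'   reads in, unique reads, events before and after the spurious filter.
#' @export
call_events <- function(alignments, threshold = 0.10,
                        convention = c("upstream", "start")) {
  unique_aln <- filter_unique(alignments)
  events <- collapse_to_events(unique_aln)
  kept <- filter_spurious(events, threshold)
  out <- crosslink_position(kept, convention)
  attr(out, "totals") <- tibble(
    reads_in = nrow(alignments),
    unique_reads = nrow(unique_aln),
    events = nrow(events),
    events_after_spurious_filter = nrow(kept)
  )
  out
}
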