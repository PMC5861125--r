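clip3 <- function(x, n) {
  substr(x, 1L, pmax(nchar(x) - n, 0L))
}

#' Split a read pair into barcode fields and raw inserts
#'
#' Slices the mate-1 prefix into its random (UMI) and condition-tag
#' positions according to the layout template, and the mate-2 prefix into
#' the observed semi-random 3' tag; the remainders are the raw inserts.
#' Reads shorter than the barcode prefix are flagged (`too_short`) rather
#' than dropped.
#'
#' @param reads Tibble with columns `read_id`, `mate1_seq`, `mate1_qual`,
#'   `mate2_seq`, `mate2_qual` (qualities optional).
#' @param layout A [barcode_layout()].
#' @return The input tibble with columns `observed_tag5`, `random5`,
#'   `observed_tag3`, `raw_insert1`, `raw_insert2` (and `_qual`
#'   counterparts when qualities are present) plus `too_short`.
#' @export
parse_read_architecture <- function(reads, layout = barcode_layout()) {
  p5 <- nchar(layout$five_prime)
  p3 <- nchar(layout$three_prime_pattern %||% "")
  slice_at <- function(seqs, positions) {
    if (length(seqs) == 0) return(character(0))
    m <- vapply(positions, function(i) substr(seqs, i, i), character(length(seqs)))
    if (length(seqs) == 1) m <- matrix(m, nrow = 1)
    apply(m, 1, paste0, collapse = "")
  }
  out <- reads %>%
    mutate(
      too_short = nchar(.data$mate1_seq) < p5 | nchar(.data$mate2_seq) < p3,
      raw_insert1 = substr(.data$mate1_seq, p5 + 1L, nchar(.data$mate1_seq)),
      observed_tag3 = ifelse(.data$too_short, NA_character_,
                             substr(.data$mate2_seq, 1L, p3)),
      raw_insert2 = substr(.data$mate2_seq, p3 + 1L, nchar(.data$mate2_seq))
    )
  out$random5 <- ifelse(out$too_short, NA_character_,
                        slice_at(out$mate1_seq, layout$random_positions))
  out$observed_tag5 <- ifelse(out$too_short, NA_character_,
                              slice_at(out$mate1_seq, layout$tag_positions))
  if ("mate1_qual" %in% names(reads)) {
    out$raw_insert1_qual <- substr(out$mate1_qual, p5 + 1L, nchar(out$mate1_qual))
    out$raw_insert2_qual <- substr(out$mate2_qual, p3 + 1L, nchar(out$mate2_qual))
  }
  out
}

#' Error-correcting condition-tag decoding
#'
#' Nearest-neighbour decoding against the codebook: an observed sequence
#' is assigned to the unique codebook tag within `max_edits` Levenshtein
#' edits, and left unassigned otherwise. For a codebook with minimum
#' pairwise distance `2 * max_edits + 1` (the design uses distance 3 and
#' `max_edits = 1`) decoding is guaranteed unique for any corruption by up
#' to `max_edits` substitutions or indels, so the observed sequence may be
#' shorter or longer than the tag length.
#'
#' @param observed Character vector of observed tag sequences.
#' @param codebook A `uvclap_tagset` or character vector of tags.
#' @param max_edits Maximum number of edits to correct.
#' @return A tibble with columns `observed`, `tag` (`NA` when
#'   unassigned), and `edits`.
#' @examples
#' ts <- generate_edit_distance_tags(5, 3, seed = 7)
#' correct_tag(sub("^.", "A", ts$tags[1]), ts)
#' @export
correct_tag <- function(observed, codebook, max_edits = 1L) {
  tags <- if (inherits(codebook, "uvclap_tagset")) codebook$tags else codebook
  uniq <- unique(observed[!is.na(observed)])
  decode_one <- function(obs) {
    d <- adist(obs, tags)[1, ]
    dmin <- min(d)
    if (dmin > max_edits || sum(d == dmin) > 1 || sum(d <= max_edits) > 1) {
      return(c(NA_character_, NA_integer_))
    }
    c(tags[which.min(d)], dmin)
  }
  dec <- vapply(uniq, decode_one, character(2))
  idx <- match(observed, uniq)
  tibble(
    observed = observed,
    tag = unname(dec[1, idx]),
    edits = as.integer(dec[2, idx])
  )
}

#' Assign a semi-random tag to its IUPAC pattern
#'
#' Each replicate pattern defines a per-position base class; an observed
#' 5-mer is assigned to the unique pattern it matches with at most
#' `max_mismatch` class violations. The default patterns `DRYYR` and
#' `DYRRY` disagree on four positions, so a single substitution can never
#' flip a tag from one pattern to the other.
#'
#' @param observed Character vector of observed semi-random tags.
#' @param patterns Character vector of IUPAC patterns (named or not).
#' @param max_mismatch Maximum tolerated class violations.
#' @return Character vector of pattern ids (`NA` = unassigned).
#' @examples
#' assign_pattern("AGCCG") # DRYYR
#' @export
assign_pattern <- function(observed, patterns = c("DRYYR", "DYRRY"),
                           max_mismatch = 1L) {
  ids <- if (is.null(names(patterns))) patterns else names(patterns)
  mm <- vapply(patterns, function(p) iupac_mismatches(observed, p),
               integer(length(observed)))
  if (length(observed) == 1) mm <- matrix(mm, nrow = 1)
  apply(mm, 1, function(v) {
    ok <- which(!is.na(v) & v <= max_mismatch)
    if (length(ok) != 1) NA_character_ else ids[ok]
  })
}

#' Clip barcode read-through from insert 3' ends
#'
#' Short inserts are read through into the barcode at the opposite end:
#' mate 1 runs into the 3' semi-random tag and mate 2 into the full 5'
#' prefix. The fixed clip lengths (5 and 10 nt for the default layout)
#' remove these bases; any genomic sequence removed is still present on
#' the other mate, so no information is lost.
#'
#' @param insert1,insert2 Character vectors of raw insert sequences.
#' @param layout A [barcode_layout()].
#' @return Tibble with clipped `insert1`, `insert2` and a `short_insert`
#'   flag marking inserts that were entirely consumed by clipping.
#' @export
clip_readthrough <- function(insert1, insert2, layout = barcode_layout()) {
  tibble(
    insert1 = clip3(insert1, layout$clip_mate1),
    insert2 = clip3(insert2, layout$clip_mate2),
    short_insert = nchar(insert1) <= layout$clip_mate1 |
      nchar(insert2) <= layout$clip_mate2
  )
}

# Decode the condition tag inside the full mate-1 prefix. An indel inside
# the tag shifts the tag/insert boundary, so slices one base shorter and
# longer than the nominal tag slot are also scored; the best-scoring
# hypothesis wins and its signed shift re-slices the trailing random bases
# and the insert. Distance ties between different tags are unassigned.
decode_tag5_in_context <- function(mate1_seq, layout, tags, max_edits = 1L) {
  tag_start <- min(layout$tag_positions)
  tag_len <- length(layout$tag_positions)
  # hypotheses ranked by (edit distance, |boundary shift|): a zero-shift
  # substitution explanation is preferred over an indel explanation of
  # the same cost, matching the predominance of substitution errors
  shifts <- if (max_edits >= 1) c(0L, -1L, 1L) else 0L
  n <- length(mate1_seq)
  best_tag <- rep(NA_character_, n)
  best_d <- rep(Inf, n)
  best_shift <- rep(99L, n)
  for (s in shifts) {
    slice <- substr(mate1_seq, tag_start, tag_start + tag_len - 1L + s)
    dec <- correct_tag(slice, tags, max_edits = max_edits)
    d <- ifelse(is.na(dec$edits), Inf, dec$edits)
    better <- !is.na(dec$tag) &
      (d < best_d | (d == best_d & abs(s) < abs(best_shift)))
    tie <- !is.na(dec$tag) & !is.na(best_tag) & d == best_d &
      abs(s) == abs(best_shift) & dec$tag != best_tag
    best_tag[better] <- dec$tag[better]
    best_shift[better] <- s
    best_d[better] <- d[better]
    best_tag[tie] <- NA_character_ # -1/+1 shift explain different tags equally
  }
  tibble(tag = best_tag,
         edits = as.integer(ifelse(is.finite(best_d) & !is.na(best_tag),
                                   best_d, NA_real_)),
         shift = ifelse(is.na(best_tag) | best_shift == 99L,
                        NA_integer_, best_shift))
}

#' Demultiplex decoded read pairs into libraries
#'
#' Full tri-barcode decoding of a table of paired reads: the condition
#' tag is error-corrected against the codebook (one substitution or indel
#' by default), the semi-random 3' tag is assigned to its replicate
#' pattern, read-through is clipped, and the UMI is assembled from the
#' five 5' random bases plus (by default) the realized 3' 5-mer. Reads
#' failing any step are retained with an `unassigned_reason`.
#'
#' @param reads Tibble with `read_id`, `mate1_seq`, `mate2_seq` (and
#'   optional `_qual` columns).
#' @param codebook A `uvclap_tagset` of condition tags.
#' @param sample_sheet Tibble with columns `library_name`,
#'   `condition_tag`, `replicate_pattern` (extra columns such as
#'   `size_fraction` and `pcr_index` are carried through).
#' @param layout A [barcode_layout()].
#' @param patterns Replicate-tag IUPAC patterns.
#' @param max_edits Condition-tag edits to correct.
#' @param max_pattern_mismatch Pattern class violations to tolerate.
#' @param umi_mode `"both"` (5' random bases + realized 3' tag, 10 nt) or
#'   `"five_prime"` (5 nt).
#' @return A `uvclap_demux` list with `reads` (decoded tibble: `library_name`,
#'   `umi`, `insert1`, `insert2`, `tag_edits`, `unassigned_reason`) and
#'   `stats` (per-library counts; `glance()`-able).
#' @export
demultiplex_reads <- function(reads, codebook, sample_sheet,
                              layout = barcode_layout(),
                              patterns = c("DRYYR", "DYRRY"),
                              max_edits = 1L, max_pattern_mismatch = 1L,
                              umi_mode = c("both", "five_prime")) {
  umi_mode <- match.arg(umi_mode)
  tags <- if (inherits(codebook, "uvclap_tagset")) codebook$tags else codebook
  ids <- if (is.null(names(patterns))) patterns else names(patterns)
  unknown <- setdiff(sample_sheet$condition_tag, tags)
  if (length(unknown) > 0) {
    abort(paste0("sample sheet references tags absent from the codebook: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!all(sample_sheet$replicate_pattern %in% ids)) {
    abort("sample sheet references unknown replicate patterns")
  }

  parsed <- parse_read_architecture(reads, layout)
  dec5 <- decode_tag5_in_context(parsed$mate1_seq, layout, tags, max_edits)
  pat <- assign_pattern(parsed$observed_tag3, patterns, max_pattern_mismatch)
  pat[parsed$too_short] <- NA_character_
  dec5$tag[parsed$too_short] <- NA_character_

  # re-slice the prefix when an indel shifted the tag/insert boundary
  p5 <- nchar(layout$five_prime)
  shift <- dplyr::coalesce(dec5$shift, 0L)
  lead_random <- substr(parsed$mate1_seq, 1L, min(layout$tag_positions) - 1L)
  tail_start <- max(layout$tag_positions) + 1L + shift
  n_tail <- p5 - max(layout$tag_positions)
  tail_random <- substr(parsed$mate1_seq, tail_start, tail_start + n_tail - 1L)
  insert1 <- substr(parsed$mate1_seq, p5 + 1L + shift, nchar(parsed$mate1_seq))
  random5 <- paste0(lead_random, tail_random)

  umi <- if (umi_mode == "both") paste0(random5, parsed$observed_tag3) else random5
  key <- paste(dec5$tag, pat, sep = "|")
  sheet_key <- paste(sample_sheet$condition_tag, sample_sheet$replicate_pattern,
                     sep = "|")
  library_name <- sample_sheet$library_name[match(key, sheet_key)]

  clipped1 <- clip3(insert1, layout$clip_mate1)
  clipped2 <- clip3(parsed$raw_insert2, layout$clip_mate2)

  decoded <- tibble(
    read_id = reads$read_id,
    library_name = library_name,
    umi = ifelse(is.na(library_name), NA_character_, umi),
    insert1 = clipped1,
    insert2 = clipped2,
    tag_edits = dec5$edits,
    tag_shift = dec5$shift,
    short_insert = nchar(insert1) <= layout$clip_mate1 |
      nchar(parsed$raw_insert2) <= layout$clip_mate2,
    unassigned_reason = case_when(
      parsed$too_short ~ "short_read",
      is.na(dec5$tag) ~ "tag_unassigned",
      is.na(pat) ~ "pattern_unassigned",
      is.na(library_name) ~ "no_library",
      TRUE ~ NA_character_
    )
  )
  if ("raw_insert1_qual" %in% names(parsed)) {
    decoded$insert1_qual <- clip3(
      substr(parsed$mate1_qual, p5 + 1L + shift, nchar(parsed$mate1_qual)),
      layout$clip_mate1)
    decoded$insert2_qual <- clip3(parsed$raw_insert2_qual, layout$clip_mate2)
  }

  counts <- decoded %>%
    mutate(library_name = dplyr::coalesce(.data$library_name, "UNASSIGNED")) %>%
    count(.data$library_name, name = "reads")
  edit_hist <- decoded %>%
    filter(!is.na(.data$tag_edits)) %>%
    count(.data$tag_edits, name = "reads")
  stats <- structure(
    list(input_reads = nrow(reads),
         library_counts = counts,
         unassigned = sum(is.na(decoded$library_name)),
         edit_histogram = edit_hist),
    class = "uvclap_demux_stats"
  )
  structure(list(reads = decoded, stats = stats), class = "uvclap_demux")
}

#' @export
print.uvclap_demux_stats <- function(x, ...) {
  cat(sprintf("<uvclap_demux_stats> %d reads in, %d unassigned\n",
              x$input_reads, x$unassigned))
  print(x$library_counts)
  invisible(x)
}

#' @export
glance.uvclap_demux_stats <- function(x, ...) {
  tibble(
    input_reads = x$input_reads,
    assigned_reads = x$input_reads - x$unassigned,
    unassigned_reads = x$unassigned,
    n_libraries = sum(x$library_counts$library_name != "UNASSIGNED")
  )
}

#' Demultiplex a multiplexed FASTQ pair into per-library FASTQ pairs
#'
#' File-level wrapper around [demultiplex_reads()]: reads the paired
#' FASTQs, decodes the tri-barcode, writes one FASTQ pair per library
#' (UMI appended to the read name) plus an `UNASSIGNED` pair for audit,
#' and returns the demultiplexing statistics. Adapter trimming is assumed
#' to have been performed upstream.
#'
#' @param fastq1,fastq2 Paths to the mate-1 and mate-2 FASTQ files
#'   (gzip-transparent).
#' @param codebook,sample_sheet,layout,patterns,... Passed to
#'   [demultiplex_reads()].
#' @param out_dir Output directory (created if missing).
#' @param umi_delimiter Separator between read name and UMI.
#' @return The `uvclap_demux_stats`, invisibly with attribute `files`.
#' @export
demultiplex_fastq <- function(fastq1, fastq2, codebook, sample_sheet,
                              layout = barcode_layout(),
                              patterns = c("DRYYR", "DYRRY"),
                              out_dir = ".", umi_delimiter = "_", ...) {
  reads <- read_fastq_pair(fastq1, fastq2)
  demux <- demultiplex_reads(reads, codebook, sample_sheet, layout,
                             patterns, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  decoded <- demux$reads %>%
    mutate(group = dplyr::coalesce(.data$library_name, "UNASSIGNED"),
           out_name = ifelse(is.na(.data$umi), .data$read_id,
                             paste0(.data$read_id, umi_delimiter, .data$umi)))
  files <- list()
  for (g in unique(decoded$group)) {
    d <- filter(decoded, .data$group == g)
    f1 <- file.path(out_dir, paste0(g, "_1.fastq"))
    f2 <- file.path(out_dir, paste0(g, "_2.fastq"))
    q1 <- if ("insert1_qual" %in% names(d)) d$insert1_qual else NULL
    q2 <- if ("insert2_qual" %in% names(d)) d$insert2_qual else NULL
    write_fastq(d$out_name, d$insert1, q1, f1)
    write_fastq(d$out_name, d$insert2, q2, f2)
    files[[g]] <- c(f1, f2)
  }
  out <- demux$stats
  attr(out, "files") <- files
  invisible(out)
}
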