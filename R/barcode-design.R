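#' Describe the tri-barcode read architecture
#'
#' The 5' end of mate 1 carries the condition tag interleaved with random
#' UMI bases following the template `NNNTTTTTNN` (three random bases, the
#' five tag bases, two random bases). The 5' end of mate 2 carries a
#' semi-random 5-mer drawn from an IUPAC pattern that identifies the
#' biological replicate and contributes further UMI capacity. Because the
#' barcodes sit at both ends of short inserts, each mate can read through
#' into the other end's barcode; `clip_mate1`/`clip_mate2` give the number
#' of bases to clip from the 3' ends (the clipped sequence is guaranteed
#' to be present on the other mate, so no insert information is lost).
#'
#' @param five_prime Template for the mate-1 prefix: `N` marks a random
#'   (UMI) base, `T` a condition-tag base.
#' @param three_prime_pattern IUPAC pattern of the mate-2 semi-random tag.
#' @param clip_mate1 Bases clipped from the 3' end of mate-1 inserts
#'   (length of the 3' semi-random tag).
#' @param clip_mate2 Bases clipped from the 3' end of mate-2 inserts
#'   (length of the full 5' prefix: tag plus random bases).
#' @return A `uvclap_layout` object.
#' @examples
#' barcode_layout()
#' @export
barcode_layout <- function(five_prime = "NNNTTTTTNN",
                           three_prime_pattern = "DRYYR",
                           clip_mate1 = nchar(three_prime_pattern),
                           clip_mate2 = nchar(five_prime)) {
  slots <- strsplit(toupper(five_prime), "")[[1]]
  if (!all(slots %in% c("N", "T"))) {
    abort("`five_prime` template may only contain N (random) and T (tag) slots")
  }
  if (!is.null(three_prime_pattern)) iupac_letters(three_prime_pattern)
  layout <- list(
    five_prime = toupper(five_prime),
    tag_positions = which(slots == "T"),
    random_positions = which(slots == "N"),
    three_prime_pattern = three_prime_pattern,
    clip_mate1 = as.integer(clip_mate1),
    clip_mate2 = as.integer(clip_mate2)
  )
  structure(layout, class = "uvclap_layout")
}

#' @export
print.uvclap_layout <- function(x, ...) {
  cat("<uvclap_layout>\n")
  cat("  mate-1 prefix:", x$five_prime,
      sprintf("(%d tag, %d random positions)\n",
              length(x$tag_positions), length(x$random_positions)))
  cat("  mate-2 prefix:", x$three_prime_pattern %||% "none", "\n")
  cat("  3' clipping  : mate1", x$clip_mate1, "nt, mate2", x$clip_mate2, "nt\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combinatorial UMI capacity of a barcode layout
#'
#' The number of distinguishable molecules per genomic position is the
#' number of random-base combinations on the 5' prefix (4^n for n random
#' positions; 1024 for the default layout) multiplied by the number of
#' realizations of the 3' semi-random pattern (48 for `DRYYR`), giving
#' 49,152 for the default layout.
#'
#' @param layout A [barcode_layout()].
#' @param include_three_prime If `FALSE`, count only the 5' random-base
#'   combinations.
#' @return A single number of combinations.
#' @examples
#' count_layout_combinations(barcode_layout(), include_three_prime = FALSE) # 1024
#' count_layout_combinations(barcode_layout()) # 49152
#' @export
count_layout_combinations <- function(layout = barcode_layout(),
                                      include_three_prime = TRUE) {
  n5 <- 4^length(layout$random_positions)
  n3 <- if (include_three_prime && !is.null(layout$three_prime_pattern)) {
    prod(lengths(IUPAC_DNA[iupac_letters(layout$three_prime_pattern)]))
  } else {
    1
  }
  n5 * n3
}

tag_distance_matrix <- function(a, b, metric = c("levenshtein", "hamming")) {
  metric <- match.arg(metric)
  if (metric == "levenshtein") {
    return(adist(a, b))
  }
  if (length(unique(nchar(c(a, b)))) != 1) {
    abort("hamming distance requires all tags to have equal length")
  }
  am <- do.call(rbind, strsplit(a, ""))
  bm <- do.call(rbind, strsplit(b, ""))
  d <- matrix(0L, nrow = length(a), ncol = length(b))
  for (k in seq_len(ncol(am))) {
    d <- d + outer(am[, k], bm[, k], "!=")
  }
  d
}

#' Minimum pairwise tag distance
#'
#' Exhaustive minimum Levenshtein or Hamming distance over all pairs drawn
#' from two tag sets (or over all distinct pairs within one set when
#' `setB` is omitted or identical to `setA`). Used to verify the two
#' guarantees of the tri-barcode design: condition-tag codebooks have
#' minimum Levenshtein distance 3 (one indel or substitution correctable)
#' and the two replicate-tag patterns are four substitutions apart.
#'
#' @param setA,setB Character vectors of tags.
#' @param metric `"levenshtein"` (edit distance) or `"hamming"`
#'   (substitutions only; requires equal lengths).
#' @return The minimum distance as an integer; for a set containing
#'   duplicated tags this is 0.
#' @examples
#' min_pairwise_distance(expand_iupac_pattern("DRYYR"),
#'                       expand_iupac_pattern("DYRRY"), metric = "hamming")
#' @export
min_pairwise_distance <- function(setA, setB = NULL,
                                  metric = c("levenshtein", "hamming")) {
  metric <- match.arg(metric)
  within <- is.null(setB) || identical(sort(setA), sort(setB))
  if (is.null(setB)) setB <- setA
  d <- tag_distance_matrix(setA, setB, metric)
  if (within) {
    if (length(setA) < 2) return(NA_integer_)
    diag(d) <- NA_integer_
    if (anyDuplicated(setA)) return(0L)
  }
  as.integer(min(d, na.rm = TRUE))
}

has_homopolymer_run <- function(x, run) {
  if (!is.finite(run) || run < 1) return(rep(FALSE, length(x)))
  stringr::str_detect(x, paste0("([ACGT])\\1{", run - 1, ",}"))
}

#' Generate an error-correcting condition-tag codebook
#'
#' Greedy construction of a set of fixed-length DNA tags whose pairwise
#' Levenshtein distances are all at least `min_dist`. A minimum distance
#' of 3 guarantees that one substitution or one indel can be corrected by
#' nearest-neighbour decoding. Candidates containing a homopolymer run of
#' `forbid_polybase_run` or more identical bases are excluded before the
#' greedy pass; optionally a candidate whose reverse complement is already
#' in the accepted set is rejected too (avoiding tag/reverse-complement
#' collisions during ligation). The candidate order is a seeded shuffle,
#' so the construction is deterministic for a given seed.
#'
#' @param length Tag length in nucleotides.
#' @param min_dist Minimum pairwise Levenshtein distance to enforce.
#' @param seed Integer seed for the candidate shuffle.
#' @param forbid_polybase_run Exclude candidates containing a run of this
#'   many identical bases (default 3); `Inf` disables the filter.
#' @param forbid_self_complement If `TRUE`, reject candidates whose
#'   reverse complement was already accepted.
#' @param n_max Stop after accepting this many tags.
#' @return A `uvclap_tagset`: list with `tags`, `min_distance` (the
#'   enforced bound), `length`, and the generation metadata.
#' @examples
#' ts <- generate_edit_distance_tags(5, 3, seed = 7)
#' min_pairwise_distance(ts$tags)
#' @export
generate_edit_distance_tags <- function(length = 5, min_dist = 3, seed = 1,
                                        forbid_polybase_run = 3,
                                        forbid_self_complement = FALSE,
                                        n_max = Inf) {
  stopifnot(length >= 1, min_dist >= 1)
  candidates <- expand_iupac_pattern(strrep("N", length))
  candidates <- candidates[!has_homopolymer_run(candidates, forbid_polybase_run)]
  set.seed(seed)
  candidates <- sample(candidates)
  accepted <- character(0)
  for (cand in candidates) {
    if (length(accepted) >= n_max) break
    if (length(accepted) > 0) {
      if (min(adist(cand, accepted)) < min_dist) next
      if (forbid_self_complement && revcomp(cand) %in% accepted) next
    }
    accepted <- c(accepted, cand)
  }
  structure(
    list(
      tags = accepted,
      min_distance = as.integer(min_dist),
      length = as.integer(length),
      seed = as.integer(seed),
      filters = list(forbid_polybase_run = forbid_polybase_run,
                     forbid_self_complement = forbid_self_complement)
    ),
    class = "uvclap_tagset"
  )
}

#' @export
print.uvclap_tagset <- function(x, ...) {
  cat(sprintf("<uvclap_tagset> %d tags of length %d, min Levenshtein distance >= %d (seed %d)\n",
              length(x$tags), x$length, x$min_distance, x$seed))
  cat(" ", paste(x$tags, collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.uvclap_tagset <- function(x, ...) {
  tibble(index = seq_along(x$tags), tag = x$tags)
}

#' @export
glance.uvclap_tagset <- function(x, ...) {
  tibble(
    n_tags = length(x$tags),
    tag_length = x$length,
    min_distance_enforced = x$min_distance,
    min_distance_observed = min_pairwise_distance(x$tags),
    seed = x$seed
  )
}

#' Filter candidate tags for sequencing robustness
#'
#' Applies the two post-design filters used on condition-tag candidates:
#' tags whose first two or last two bases are identical (nucleotide
#' repetitions at either end, problematic for cluster calling) are
#' removed, and among the remainder, tags whose reverse complement occurs
#' as a substring of the sequencing adapter are removed (such tags can
#' form adapter artefacts).
#'
#' @param tags Character vector of candidate tags.
#' @param adapter Adapter sequence to screen against; `""` disables the
#'   reverse-complement screen.
#' @return A `uvclap_filter_report`: tibble with columns `tag` and
#'   `removed_reason` (`NA` for surviving tags), in input order.
#'   `glance()` summarises the counts.
#' @export
filter_tags <- function(tags, adapter = "") {
  end_repeat <- stringr::str_detect(tags, "^([ACGT])\\1") |
    stringr::str_detect(tags, "([ACGT])\\1$")
  adapter_rc <- if (nzchar(adapter)) {
    !end_repeat & stringr::str_detect(toupper(adapter), stringr::fixed(revcomp(tags)))
  } else {
    rep(FALSE, length(tags))
  }
  out <- tibble(
    tag = tags,
    removed_reason = case_when(
      end_repeat ~ "end_repeat",
      adapter_rc ~ "adapter_revcomp",
      TRUE ~ NA_character_
    )
  )
  class(out) <- c("uvclap_filter_report", class(out))
  out
}

#' @export
glance.uvclap_filter_report <- function(x, ...) {
  tibble(
    input_count = nrow(x),
    removed_end_repeat_count = sum(x$removed_reason %in% "end_repeat"),
    removed_adapter_revcomp_count = sum(x$removed_reason %in% "adapter_revcomp"),
    surviving_count = sum(is.na(x$removed_reason))
  )
}

#' Check two-channel colour balance of a tag combination
#'
#' Two-channel Illumina chemistries must see, at every sequencing cycle,
#' at least one base from each colour channel across the multiplexed
#' tags. The base-to-channel assignment is configurable; the default
#' convention is red = {A, C} and green = {G, T}.
#'
#' @param tags Character vector of same-length tags sequenced together.
#' @param red,green Bases detected by each channel.
#' @return `TRUE` if every position sees both channels.
#' @examples
#' check_color_balance(c("AAAAA", "GGGGG")) # TRUE
#' check_color_balance(c("AAAAA", "CCCCC")) # FALSE
#' @export
check_color_balance <- function(tags, red = c("A", "C"), green = c("G", "T")) {
  stopifnot(length(unique(nchar(tags))) == 1)
  m <- do.call(rbind, strsplit(tags, ""))
  all(vapply(seq_len(ncol(m)), function(j) {
    any(m[, j] %in% red) && any(m[, j] %in% green)
  }, logical(1)))
}

#' Write or read a tag codebook as TSV
#'
#' The codebook format is a plain tab-separated file with `#`-prefixed
#' header lines recording the generation parameters, then one `tag<TAB>index`
#' row per tag.
#'
#' @param tagset A `uvclap_tagset` (or a character vector of tags).
#' @param path File path.
#' @return `write_codebook()` returns `path` invisibly; `read_codebook()`
#'   returns a `uvclap_tagset`.
#' @export
write_codebook <- function(tagset, path) {
  if (is.character(tagset)) {
    tagset <- structure(list(tags = tagset,
                             min_distance = min_pairwise_distance(tagset),
                             length = unique(nchar(tagset))[1],
                             seed = NA_integer_, filters = list()),
                        class = "uvclap_tagset")
  }
  header <- c(
    "# uvclap condition-tag codebook",
    sprintf("# length=%d min_distance=%d seed=%s",
            tagset$length, tagset$min_distance, tagset$seed),
    "# tag\tindex"
  )
  body <- sprintf("%s\t%d", tagset$tags, seq_along(tagset$tags))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  tags <- vapply(strsplit(body, "\t"), `[`, character(1), 1)
  params <- stringr::str_match(paste(meta, collapse = " "),
                               "length=(\\d+) min_distance=(\\d+)")
  structure(
    list(
      tags = tags,
      min_distance = if (!is.na(params[1, 3])) as.integer(params[1, 3])
                     else min_pairwise_distance(tags),
      length = if (!is.na(params[1, 2])) as.integer(params[1, 2])
               else unique(nchar(tags))[1],
      seed = NA_integer_,
      filters = list()
    ),
    class = "uvclap_tagset"
  )
}
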