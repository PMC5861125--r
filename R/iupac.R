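# IUPAC ambiguity codes over the DNA alphabet. The degenerate codes that
# matter for semi-random replicate tags are D (not C), R (purine), Y
# (pyrimidine) and N (any base); the full table is kept so arbitrary
# degenerate motifs (e.g. AYUAAY with U read as T) can be scanned.
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

iupac_letters <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  chars[chars == "U"] <- "T"
  bad <- setdiff(chars, names(IUPAC_DNA))
  if (length(bad) > 0) {
    abort(paste0("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", ")))
  }
  chars
}

#' Expand an IUPAC pattern into all matching DNA sequences
#'
#' Enumerates every DNA sequence compatible with a degenerate IUPAC
#' pattern, position by position. The semi-random replicate tags use the
#' patterns `DRYYR` and `DYRRY` (D = not C, R = purine, Y = pyrimidine),
#' each of which expands to 3 * 2 * 2 * 2 * 2 = 48 distinct 5-mers.
#'
#' @param pattern A single IUPAC string (RNA `U` is read as `T`).
#' @return A lexicographically sorted character vector of all distinct
#'   sequences matching the pattern; its length is the product of the
#'   per-position class sizes.
#' @examples
#' length(expand_iupac_pattern("DRYYR")) # 48
#' expand_iupac_pattern("RY")
#' @export
expand_iupac_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) >= 1)
  classes <- IUPAC_DNA[iupac_letters(pattern)]
  grid <- expand.grid(rev(classes), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(classes)), drop = FALSE], 1, paste0, collapse = ""))
}

#' Count per-position IUPAC class violations
#'
#' For each observed sequence, counts the positions whose base does not
#' belong to the IUPAC class of the pattern at that position. This is the
#' mismatch notion used to assign semi-random replicate tags to their
#' pattern: any `DRYYR` expansion differs from any `DYRRY` expansion in at
#' least the four R/Y positions.
#'
#' @param x Character vector of observed sequences, same length as the pattern.
#' @param pattern A single IUPAC string.
#' @return Integer vector of violation counts; `NA` for sequences whose
#'   length differs from the pattern length.
#' @export
iupac_mismatches <- function(x, pattern) {
  classes <- IUPAC_DNA[iupac_letters(pattern)]
  k <- length(classes)
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) != k) return(NA_integer_)
    b <- strsplit(toupper(s), "")[[1]]
    sum(vapply(seq_len(k), function(i) !(b[i] %in% classes[[i]]), logical(1)))
  }, integer(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
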