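# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (and utils::adist) so that distance and
# grouping logic can be verified against a second implementation.

# textbook dynamic-programming Levenshtein distance
lev_dp <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  prev <- 0:length(b)
  for (i in seq_along(a)) {
    cur <- numeric(length(b) + 1)
    cur[1] <- i
    for (j in seq_along(b)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[length(b) + 1]
}

# brute-force IUPAC expansion by nested recursion over a lookup table
expand_oracle <- function(pattern) {
  tab <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), D = c("A", "G", "T"),
              N = c("A", "C", "G", "T"))
  chars <- strsplit(pattern, "")[[1]]
  out <- ""
  for (ch in chars) {
    out <- as.vector(outer(out, tab[[ch]], paste0))
  }
  sort(out)
}

# every single-edit corruption (substitution, deletion, insertion) of a tag
all_single_edits <- function(tag) {
  alph <- c("A", "C", "G", "T")
  ch <- strsplit(tag, "")[[1]]
  n <- length(ch)
  subs <- unlist(lapply(seq_len(n), function(i) {
    vapply(setdiff(alph, ch[i]), function(b) {
      x <- ch; x[i] <- b; paste0(x, collapse = "")
    }, character(1))
  }))
  dels <- vapply(seq_len(n), function(i) paste0(ch[-i], collapse = ""),
                 character(1))
  ins <- unlist(lapply(0:n, function(i) {
    vapply(alph, function(b) {
      paste0(c(ch[seq_len(i)], b, ch[seq_len(n - i) + i]), collapse = "")
    }, character(1))
  }))
  unique(c(subs, dels, ins))
}

# hash-grouping oracle for event collapse: plain base-R table on a
# concatenated key
collapse_oracle <- function(aln) {
  key <- paste(aln$chrom, aln$strand, aln$mate1_start, aln$mate2_start,
               aln$umi, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    strand = vapply(parts, `[`, "", 2),
    mate1_start = as.integer(vapply(parts, `[`, "", 3)),
    mate2_start = as.integer(vapply(parts, `[`, "", 4)),
    umi = vapply(parts, `[`, "", 5),
    read_count = as.integer(tab)
  )
  out[order(out$chrom, out$strand, out$mate1_start, out$mate2_start,
            out$umi), ]
}

# per-base overlap oracle on a small genome: marks covered bases per set
# and counts membership combinations of the merged universe
overlap_oracle <- function(sets, genome_len = 1e5L) {
  cover <- lapply(sets, function(s) {
    v <- logical(genome_len)
    for (i in seq_len(nrow(s))) {
      v[(s$start[i] + 1):s$end[i]] <- TRUE
    }
    v
  })
  any_cover <- Reduce(`|`, cover)
  runs <- rle(any_cover)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  regions <- data.frame(start = starts[runs$values], end = ends[runs$values])
  member <- sapply(cover, function(v) {
    vapply(seq_len(nrow(regions)), function(i) {
      any(v[regions$start[i]:regions$end[i]])
    }, logical(1))
  })
  if (nrow(regions) == 1) member <- matrix(member, nrow = 1)
  colnames(member) <- names(sets)
  as.data.frame(member)
}

tiny_codebook <- function(seed = 101) {
  generate_edit_distance_tags(length = 5, min_dist = 3, seed = seed)
}
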