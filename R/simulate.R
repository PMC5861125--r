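#' Configuration for the synthetic uvCLAP experiment generator
#'
#' Collects every tunable of the simulator with defaults chosen to mirror
#' the structure of a real multiplexed uvCLAP run at desk scale: a small
#' random genome, a gene complement spanning all annotation classes used
#' by the priority annotator, point binding sites in one of three
#' biologically motivated modes (degenerate-motif binding, deposition
#' 20-30 nt upstream of exon-exon junctions as for the exon junction
#' complex, or 5'-UTR binding), paired signal/control libraries with a
#' planted molecular signal-to-control ratio, PCR duplication whose rate
#' is elevated for cDNAs of 40-60 nt, and the full tri-barcode read
#' architecture.
#'
#' All randomness derives from `seed`; the generator functions draw from
#' documented per-stage offsets of it (`make_genome`: seed,
#' `make_annotation`: seed + 1, `plant_sites`: seed + 2,
#' `simulate_library`: seed + 3, `simulate_alignments`: seed + 4), so each
#' stage is individually reproducible.
#'
#' @param seed Master seed.
#' @param ... Overrides for any default listed below.
#' @return A `uvclap_sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  config <- list(
    seed = as.integer(seed),
    # genome
    n_chrom = 2L, chrom_length = 100000L, gc = 0.5,
    # gene models
    n_coding = 20L, n_rRNA = 2L, n_ncRNA = 4L, n_pseudogene = 3L,
    exons_per_gene = 4L, exon_length = 150L, intron_length = 300L,
    utr5_length = 60L, utr3_length = 80L, noncoding_length = 400L,
    gene_gap = 400L,
    # binding sites
    binding_mode = "motif", motif = "AYUAAY", n_sites = 150L,
    # libraries
    n_replicates = 2L, n_molecules = 4000L, signal_control_ratio = 10,
    fragment_length_mean = 50, fragment_length_sd = 12,
    fragment_length_range = c(24L, 80L),
    # PCR duplication
    duplication = TRUE, dup_mean = 0.6,
    dup_bias_window = c(40L, 60L), dup_bias_factor = 4,
    # sequencing
    error_rate = 0.001,
    # control background
    rrna_background_weight = 0.2,
    # barcodes
    codebook_seed = 101L,
    layout = barcode_layout(),
    patterns = c("DRYYR", "DYRRY")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(config))
  if (length(unknown) > 0) {
    abort(paste0("unknown sim_config field(s): ", paste(unknown, collapse = ", ")))
  }
  config[names(dots)] <- dots
  structure(config, class = "uvclap_sim_config")
}

#' Default codebook and sample sheet for a simulated experiment
#'
#' Two conditions (signal and nonspecific control) times
#' `config$n_replicates` replicates; replicates are distinguished by the
#' semi-random patterns, conditions by codebook tags.
#'
#' @param config A [sim_config()].
#' @return List with `codebook` (a `uvclap_tagset`) and `sample_sheet`.
#' @export
default_sample_sheet <- function(config) {
  codebook <- generate_edit_distance_tags(
    length = length(config$layout$tag_positions),
    min_dist = 3, seed = config$codebook_seed)
  ids <- if (is.null(names(config$patterns))) config$patterns
         else names(config$patterns)
  if (config$n_replicates > length(ids)) {
    abort("more replicates than replicate patterns available")
  }
  sheet <- tidyr::expand_grid(
    condition = c("signal", "control"),
    replicate = seq_len(config$n_replicates)
  ) %>%
    mutate(
      library_name = paste0(.data$condition, "_rep", .data$replicate),
      condition_tag = codebook$tags[ifelse(.data$condition == "signal", 1L, 2L)],
      replicate_pattern = ids[.data$replicate],
      size_fraction = "M"
    ) %>%
    select("library_name", "condition", "replicate", "condition_tag",
           "replicate_pattern", "size_fraction")
  list(codebook = codebook, sample_sheet = sheet)
}

#' Generate a random genome
#'
#' Seeded i.i.d. sequence with configurable GC content.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`) and `chrom_sizes` tibble.
#' @export
make_genome <- function(config) {
  set.seed(config$seed)
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  seqs <- vapply(seq_len(config$n_chrom), function(i) {
    paste0(sample(names(p), config$chrom_length, replace = TRUE, prob = p),
           collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(config$n_chrom))
  list(genome = genome,
       chrom_sizes = tibble(chrom = names(genome),
                            size = Biostrings::width(genome)))
}

place_gene <- function(gene_id, biotype, chrom, strand, start, config) {
  tx <- paste0(gene_id, ".t1")
  if (biotype == "protein_coding") {
    k <- config$exons_per_gene
    exon_starts <- start +
      (seq_len(k) - 1L) * (config$exon_length + config$intron_length)
    exon_ends <- exon_starts + config$exon_length
    gene_end <- exon_ends[k]
    exon_num <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
    exons <- tibble(chrom = chrom, start = exon_starts, end = exon_ends,
                    strand = strand, type = "exon", gene_id = gene_id,
                    transcript_id = tx, gene_biotype = biotype,
                    exon_number = exon_num)
    # UTRs occupy the transcript-terminal ends of the terminal exons
    if (strand == "-") {
      utr5 <- tibble(chrom = chrom, start = exon_ends[k] - config$utr5_length,
                     end = exon_ends[k], strand = strand)
      utr3 <- tibble(chrom = chrom, start = exon_starts[1],
                     end = exon_starts[1] + config$utr3_length, strand = strand)
    } else {
      utr5 <- tibble(chrom = chrom, start = exon_starts[1],
                     end = exon_starts[1] + config$utr5_length, strand = strand)
      utr3 <- tibble(chrom = chrom, start = exon_ends[k] - config$utr3_length,
                     end = exon_ends[k], strand = strand)
    }
    utr5 <- mutate(utr5, type = "five_prime_utr", gene_id = gene_id,
                   transcript_id = tx, gene_biotype = biotype,
                   exon_number = NA_integer_)
    utr3 <- mutate(utr3, type = "three_prime_utr", gene_id = gene_id,
                   transcript_id = tx, gene_biotype = biotype,
                   exon_number = NA_integer_)
    body <- bind_rows(exons, utr5, utr3)
  } else {
    gene_end <- start + config$noncoding_length
    body <- tibble(chrom = chrom, start = start, end = gene_end,
                   strand = strand, type = "exon", gene_id = gene_id,
                   transcript_id = tx, gene_biotype = biotype,
                   exon_number = 1L)
  }
  tx_ids <- c(NA_character_, tx)
  header <- tibble(
    chrom = chrom, start = start, end = gene_end, strand = strand,
    type = c("gene", "transcript"), gene_id = gene_id,
    transcript_id = tx_ids,
    gene_biotype = biotype, exon_number = NA_integer_
  )
  bind_rows(header, body)
}

#' Generate a gene annotation on a simulated genome
#'
#' Places non-overlapping genes of each configured class along the
#' chromosomes, with multi-exon protein-coding genes carrying 5'- and
#' 3'-UTRs on their terminal exons, and single-exon rRNA, ncRNA and
#' pseudogene genes. Strands alternate, so both orientations are
#' exercised.
#'
#' @param config A [sim_config()].
#' @param chrom_sizes Tibble from [make_genome()].
#' @return Annotation tibble (GTF-convertible via [write_gtf()]).
#' @export
make_annotation <- function(config, chrom_sizes) {
  set.seed(config$seed + 1L)
  biotypes <- c(rep("protein_coding", config$n_coding),
                rep("rRNA", config$n_rRNA),
                rep("lincRNA", config$n_ncRNA),
                rep("processed_pseudogene", config$n_pseudogene))
  biotypes <- sample(biotypes)
  cursors <- setNames(rep(config$gene_gap, nrow(chrom_sizes)),
                      chrom_sizes$chrom)
  sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  rows <- list()
  chrom_i <- 1L
  for (i in seq_along(biotypes)) {
    span <- if (biotypes[i] == "protein_coding") {
      config$exons_per_gene * config$exon_length +
        (config$exons_per_gene - 1L) * config$intron_length
    } else {
      config$noncoding_length
    }
    placed <- FALSE
    for (try in seq_len(nrow(chrom_sizes))) {
      ch <- chrom_sizes$chrom[chrom_i]
      chrom_i <- chrom_i %% nrow(chrom_sizes) + 1L
      if (cursors[ch] + span + config$gene_gap <= sizes[ch]) {
        rows[[i]] <- place_gene(sprintf("gene%03d", i), biotypes[i], ch,
                                if (i %% 2 == 0) "-" else "+",
                                as.integer(cursors[ch]), config)
        cursors[ch] <- cursors[ch] + span + config$gene_gap
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("genome too small: could not place gene %d of %d",
                    i, length(biotypes)))
    }
  }
  bind_rows(rows) %>% arrange(.data$chrom, .data$start, .data$type)
}

#' Plant ground-truth binding sites
#'
#' Creates point binding sites according to the configured mode:
#' `"motif"` writes a concrete realization of the IUPAC motif into exonic
#' genome sequence and centres a site on it; `"junction_upstream"` places
#' site centres uniformly 20-30 nt upstream of exon-exon junctions (the
#' EJC deposition window); `"utr5"` places sites inside 5'-UTRs; `"none"`
#' returns no sites (control-only experiment).
#'
#' @param config A [sim_config()].
#' @param features Annotation from [make_annotation()].
#' @param genome `DNAStringSet` from [make_genome()].
#' @return List with `sites` (tibble: `site_id`, `chrom`, `strand`,
#'   `start`, `end`, `mode`) and `genome` (modified in motif mode).
#' @export
plant_sites <- function(config, features, genome) {
  set.seed(config$seed + 2L)
  n <- config$n_sites
  mode <- config$binding_mode
  empty <- tibble(site_id = integer(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  mode = character())
  if (mode == "none" || n == 0) {
    return(list(sites = empty, genome = genome))
  }
  if (mode == "junction_upstream") {
    junctions <- extract_junctions(features)
    if (nrow(junctions) == 0) abort("no junctions available for site planting")
    j <- junctions[sample(nrow(junctions), n, replace = TRUE), ]
    offset <- sample(20:30, n, replace = TRUE)
    centre <- ifelse(j$strand == "-", j$up_start + offset - 1L,
                     j$up_end - offset)
    sites <- tibble(site_id = seq_len(n), chrom = j$chrom, strand = j$strand,
                    start = as.integer(centre), end = as.integer(centre) + 1L,
                    mode = mode)
    return(list(sites = sites, genome = genome))
  }
  regions <- switch(
    mode,
    utr5 = filter(features, .data$type == "five_prime_utr"),
    motif = filter(features, .data$type == "exon",
                   .data$gene_biotype == "protein_coding"),
    abort(sprintf("unknown binding mode '%s'", mode))
  )
  if (nrow(regions) == 0) abort("no eligible regions for site planting")
  motif_len <- nchar(config$motif)
  margin <- if (mode == "motif") motif_len else 1L
  regions <- filter(regions, .data$end - .data$start > 2L * margin)
  if (mode == "motif") {
    # non-overlapping slots so planted motif instances cannot collide
    slots <- purrr::pmap_dfr(
      regions[, c("chrom", "strand", "start", "end")],
      function(chrom, strand, start, end) {
        pos <- seq.int(start + margin, end - 2L * margin, by = 2L * motif_len)
        tibble(chrom = chrom, strand = strand, start = pos)
      })
    if (nrow(slots) < n) {
      abort(sprintf("not enough eligible space: %d sites requested, %d slots",
                    n, nrow(slots)))
    }
    si <- sample(nrow(slots), n)
    sites <- tibble(site_id = seq_len(n), chrom = slots$chrom[si],
                    strand = slots$strand[si],
                    start = as.integer(slots$start[si]),
                    end = as.integer(slots$start[si]) + 1L, mode = mode)
  } else {
    ri <- sample(nrow(regions), n, replace = TRUE)
    pos <- regions$start[ri] + margin +
      floor(runif(n) * (regions$end[ri] - regions$start[ri] - 2L * margin))
    sites <- tibble(site_id = seq_len(n), chrom = regions$chrom[ri],
                    strand = regions$strand[ri], start = as.integer(pos),
                    end = as.integer(pos) + 1L, mode = mode)
  }
  if (mode == "motif") {
    classes <- IUPAC_DNA[iupac_letters(config$motif)]
    for (i in seq_len(n)) {
      realization <- paste0(vapply(classes, sample, character(1), size = 1),
                            collapse = "")
      instance <- if (sites$strand[i] == "-") revcomp(realization) else realization
      # motif occupies the site centre and downstream sequence
      at <- sites$start[i] + 1L
      Biostrings::subseq(genome[[sites$chrom[i]]],
                         start = at, width = motif_len) <-
        Biostrings::DNAString(instance)
    }
    sites$end <- sites$start + motif_len
  }
  list(sites = sites, genome = genome)
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    chars <- strsplit(seqs[i], "")[[1]]
    at <- sample(length(chars), n_err[i])
    chars[at] <- vapply(chars[at], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    seqs[i] <- paste0(chars, collapse = "")
  }
  seqs
}

#' Simulate multiplexed barcoded libraries
#'
#' Draws molecular crosslinking events for every library in the sample
#' sheet -- signal libraries at the planted sites, control libraries
#' uniformly over gene bodies with an rRNA-weighted component -- then
#' attaches fragments, UMIs, PCR duplicates (with the 40-60 nt length
#' bias) and sequencing errors, and assembles the paired reads with the
#' full tri-barcode architecture. Each mate reads through into the
#' barcode at the opposite end, exactly as for short real inserts, so the
#' fixed clipping of the demultiplexer recovers the genomic fragment.
#'
#' @param config A [sim_config()].
#' @param sites Site tibble from [plant_sites()].
#' @param genome `DNAStringSet` (use the one returned by
#'   [plant_sites()]).
#' @param features Annotation from [make_annotation()].
#' @param design Optional list with `codebook` and `sample_sheet`
#'   (default [default_sample_sheet()]).
#' @return List with `reads` (FASTQ-ready tibble), `truth` (per-read
#'   provenance: library, origin site, fragment coordinates, crosslink
#'   position, UMI, molecule id, duplicate flag), `codebook`,
#'   `sample_sheet`.
#' @export
simulate_library <- function(config, sites, genome, features, design = NULL) {
  set.seed(config$seed + 3L)
  if (is.null(design)) design <- default_sample_sheet(config)
  sheet <- design$sample_sheet
  sizes <- setNames(Biostrings::width(genome), names(genome))
  genes <- filter(features, .data$type == "gene")
  gene_w <- ifelse(genes$gene_biotype == "rRNA",
                   config$rrna_background_weight /
                     max(sum(genes$gene_biotype == "rRNA"), 1),
                   (1 - config$rrna_background_weight) /
                     max(sum(genes$gene_biotype != "rRNA"), 1))
  ids <- if (is.null(names(config$patterns))) config$patterns
         else names(config$patterns)
  pattern_pool <- lapply(setNames(config$patterns, ids), expand_iupac_pattern)

  lib_rows <- list()
  for (li in seq_len(nrow(sheet))) {
    lib <- sheet[li, ]
    is_signal <- lib$condition == "signal" && nrow(sites) > 0
    n_mol <- if (is_signal) config$n_molecules else
      max(1L, round(config$n_molecules / config$signal_control_ratio))
    if (is_signal) {
      si <- sample(nrow(sites), n_mol, replace = TRUE)
      crosslink <- sites$start[si] +
        floor(runif(n_mol) * (sites$end[si] - sites$start[si]))
      chrom <- sites$chrom[si]
      strand <- sites$strand[si]
      origin <- sites$site_id[si]
    } else {
      gi <- sample(nrow(genes), n_mol, replace = TRUE, prob = gene_w)
      crosslink <- genes$start[gi] +
        floor(runif(n_mol) * (genes$end[gi] - genes$start[gi]))
      chrom <- genes$chrom[gi]
      strand <- genes$strand[gi]
      origin <- NA_integer_
    }
    len <- as.integer(pmin(pmax(
      round(rnorm(n_mol, config$fragment_length_mean,
                  config$fragment_length_sd)),
      config$fragment_length_range[1]), config$fragment_length_range[2]))
    fstart <- ifelse(strand == "-", crosslink - len, crosslink + 1L)
    fstart <- pmax(fstart, 0L)
    fstart <- pmin(fstart, sizes[chrom] - len)
    fend <- fstart + len
    # truth crosslink recomputed from the (possibly clamped) fragment
    crosslink <- as.integer(ifelse(strand == "-", fend, fstart - 1L))

    random5 <- vapply(seq_len(n_mol), function(i) {
      paste0(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = "")
    }, character(1))
    tag3 <- sample(pattern_pool[[lib$replicate_pattern]], n_mol, replace = TRUE)

    bias <- len >= config$dup_bias_window[1] & len <= config$dup_bias_window[2]
    mu <- config$dup_mean * ifelse(bias, config$dup_bias_factor, 1)
    copies <- if (config$duplication) 1L + rgeom(n_mol, 1 / (1 + mu)) else
      rep(1L, n_mol)

    lib_rows[[li]] <- tibble(
      library_name = lib$library_name,
      condition = lib$condition,
      molecule_id = paste0(lib$library_name, "_m", seq_len(n_mol)),
      origin_site = origin,
      chrom = chrom, strand = strand,
      fragment_start = as.integer(fstart), fragment_length = len,
      crosslink_pos = crosslink,
      random5 = random5, tag3 = tag3,
      umi = paste0(random5, tag3),
      condition_tag = lib$condition_tag,
      n_copies = copies
    )
  }
  truth <- bind_rows(lib_rows) %>%
    tidyr::uncount(.data$n_copies, .remove = FALSE, .id = "copy") %>%
    mutate(read_id = paste0(.data$molecule_id, "_c", .data$copy),
           duplicate = .data$copy > 1L)

  # assemble reads: NNNTTTTTNN prefix, insert, reverse-complemented 3' tag
  insert <- vapply(seq_len(nrow(truth)), function(i) {
    as.character(Biostrings::subseq(genome[[truth$chrom[i]]],
                                    start = truth$fragment_start[i] + 1L,
                                    width = truth$fragment_length[i]))
  }, character(1))
  insert <- ifelse(truth$strand == "-", revcomp(insert), insert)
  prefix <- paste0(substr(truth$random5, 1, 3), truth$condition_tag,
                   substr(truth$random5, 4, 5))
  mate1 <- paste0(prefix, insert, revcomp(truth$tag3))
  mate2 <- revcomp(mate1)
  mate1 <- inject_errors(mate1, config$error_rate)
  mate2 <- inject_errors(mate2, config$error_rate)
  reads <- tibble(
    read_id = truth$read_id,
    mate1_seq = mate1, mate1_qual = strrep("I", nchar(mate1)),
    mate2_seq = mate2, mate2_qual = strrep("I", nchar(mate2))
  )
  list(reads = reads, truth = truth,
       codebook = design$codebook, sample_sheet = sheet)
}

#' Derive an alignment table from simulation ground truth
#'
#' The aligner-free testing path: perfect alignments constructed directly
#' from the truth coordinates, with a configurable fraction flagged as
#' multi-mapping.
#'
#' @param truth Truth tibble from [simulate_library()].
#' @param multimap_fraction Fraction of reads flagged `multimap`.
#' @param seed Seed for the multimap draw (default: documented offset of
#'   the truth's generation is not needed here; pass the config seed).
#' @param umi Optional replacement UMI vector (e.g. the demultiplexer's
#'   observed UMIs), matched by `read_id`.
#' @return Alignment tibble suitable for [call_events()].
#' @export
simulate_alignments <- function(truth, multimap_fraction = 0, seed = 1L,
                                umi = NULL) {
  set.seed(seed + 4L)
  out <- tibble(
    read_id = truth$read_id,
    library_name = truth$library_name,
    chrom = truth$chrom,
    strand = truth$strand,
    mate1_start = truth$fragment_start,
    mate2_start = truth$fragment_start,
    aln_length = truth$fragment_length,
    umi = truth$umi,
    multimap = runif(nrow(truth)) < multimap_fraction
  )
  if (!is.null(umi)) {
    out$umi <- umi[match(out$read_id, names(umi))]
  }
  out
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper chaining [make_genome()], [make_annotation()],
#' [plant_sites()] and [simulate_library()].
#'
#' @param config A [sim_config()].
#' @return List with `genome`, `chrom_sizes`, `features`, `sites`,
#'   `codebook`, `sample_sheet`, `reads`, `truth`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  g <- make_genome(config)
  features <- make_annotation(config, g$chrom_sizes)
  planted <- plant_sites(config, features, g$genome)
  design <- default_sample_sheet(config)
  lib <- simulate_library(config, planted$sites, planted$genome, features,
                          design)
  list(genome = planted$genome, chrom_sizes = g$chrom_sizes,
       features = features, sites = planted$sites,
       codebook = lib$codebook, sample_sheet = lib$sample_sheet,
       reads = lib$reads, truth = lib$truth)
}
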