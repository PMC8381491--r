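#' Configuration for the toy parent/pseudogene fixture
#'
#' The generator emulates the structural features the workflow depends
#' on: parent/pseudogene pairs with tunable body homology but divergent
#' promoters, CAGE clusters near annotated 5' ends, one planted
#' bidirectional-promoter neighbor (TSS within 1 kb of a pseudogene
#' TSS), and one planted parent-promoter off-target site shared at one
#' mismatch with a pseudogene-promoter protospacer (the confound
#' plant).
#'
#' @param n_pairs Number of parent/pseudogene pairs.
#' @param homology Body sequence identity of pseudogene vs parent,
#'   in [0, 1].
#' @param body_length Gene body length in bp.
#' @param block_size Genomic block per pair in bp.
#' @param cage_offset_sd SD (bp) of the CAGE summit around the
#'   annotated 5' end.
#' @param tie_range TIEScore range for planted clusters.
#' @param bidirectional_pair Pair index receiving a neighbor gene with
#'   a TSS ~700 bp from the pseudogene TSS (0 = none).
#' @param confound_pair Pair index receiving the off-target confound
#'   plant (0 = none).
#' @param seed Mandatory RNG seed.
#' @return List of class `pg_fixture_config`.
#' @export
fixture_config <- function(n_pairs = 8L, homology = 0.85,
                           body_length = 600L, block_size = 8000L,
                           cage_offset_sd = 10, tie_range = c(10, 50),
                           bidirectional_pair = 1L, confound_pair = 2L,
                           seed) {
  if (missing(seed)) stop("fixture seed is mandatory")
  stopifnot(homology >= 0, homology <= 1, n_pairs >= 1,
            body_length > 500L)
  structure(list(n_pairs = as.integer(n_pairs), homology = homology,
                 body_length = as.integer(body_length),
                 block_size = as.integer(block_size),
                 cage_offset_sd = cage_offset_sd, tie_range = tie_range,
                 bidirectional_pair = as.integer(bidirectional_pair),
                 confound_pair = as.integer(confound_pair),
                 seed = as.integer(seed)),
            class = "pg_fixture_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random sequence free of GG and CC dinucleotides, hence free of NGG
# PAMs on either strand (used to isolate a planted protospacer)
pam_sparse_dna <- function(n) {
  ch <- character(n)
  prev <- ""
  for (i in seq_len(n)) {
    allowed <- setdiff(c("A", "C", "G", "T"),
                       if (prev %in% c("C", "G")) prev else NULL)
    ch[i] <- sample(allowed, 1)
    prev <- ch[i]
  }
  paste(ch, collapse = "")
}

mutate_seq <- function(seq, identity) {
  if (identity >= 1) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) > identity
  ch[hit] <- vapply(ch[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

splice_in <- function(seq, at, piece) {
  # overwrite seq[at .. at+nchar(piece)-1] (1-based)
  paste0(substr(seq, 1, at - 1L), piece,
         substr(seq, at + nchar(piece), nchar(seq)))
}

# Planted confound protospacer: moderate GC, no poly-T, and free of
# GG/CC dinucleotides so it cannot spawn overlapping candidates.
.CONFOUND_SPACER <- "ACGTTAGCACGATTGACTAC"
.CONFOUND_PAM <- "TGG"

#' Generate the toy genome, annotation, CAGE track, and ground truth
#'
#' Layout (one chromosome): each pair occupies one block; the parent
#' TSS sits at block + 1000 and the pseudogene TSS at block + 4500,
#' both on the plus strand, each gene spanning `body_length` bp from
#' its TSS. The pseudogene body beyond the 250-bp promoter is a
#' mutated copy of the parent body at the configured identity; the
#' promoters are independent random sequence. A CAGE cluster (20 bp,
#' jittered summit, positive TIEScore) is planted at every 5' end.
#'
#' @param config A `pg_fixture_config`.
#' @param out_dir Optional directory; writes genome.fa, genes.gtf,
#'   cage.bed, truth.json.
#' @return List of class `pg_fixture`: genome, annotation, cage, truth.
#' @export
make_toy_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pg_fixture_config"))
  set.seed(config$seed)
  np <- config$n_pairs
  B <- config$block_size
  body <- config$body_length
  L <- np * B + 2000L
  chrom <- "chr1"
  seq <- rand_dna(L)

  genes <- list(); tx <- list(); cage <- list()
  pairs <- data.frame(parent_id = character(np), pseudo_id = character(np),
                      parent_tss = integer(np), pseudo_tss = integer(np),
                      stringsAsFactors = FALSE)
  homolog <- list()
  add_gene <- function(id, name, biotype, strand, start, end, parent = NA) {
    genes[[length(genes) + 1]] <<- data.frame(
      gene_id = id, gene_name = name, biotype = biotype, chrom = chrom,
      strand = strand, start = start, end = end, parent_gene_id = parent,
      stringsAsFactors = FALSE)
    tx[[length(tx) + 1]] <<- data.frame(
      transcript_id = paste0(id, ".t1"), gene_id = id, chrom = chrom,
      strand = strand, start = start, end = end,
      five_prime_end = if (strand == "+") start else end,
      stringsAsFactors = FALSE)
  }
  add_cage <- function(id, tss, strand, jitter = TRUE) {
    off <- if (jitter) round(stats::rnorm(1, 0, config$cage_offset_sd)) else 0
    s <- max(12L, as.integer(tss + off))
    cage[[length(cage) + 1]] <<- data.frame(
      cluster_id = id, chrom = chrom, strand = strand,
      start = s - 10L, end = s + 9L, summit = s,
      tie_score = round(stats::runif(1, config$tie_range[1],
                                     config$tie_range[2]), 1),
      stringsAsFactors = FALSE)
  }

  classes <- c("processed_pseudogene", "unprocessed_pseudogene",
               "unitary_pseudogene")
  for (i in seq_len(np)) {
    b <- (i - 1L) * B
    p_tss <- b + 1000L; q_tss <- b + 4500L
    pid <- sprintf("PARENT%02d", i); qid <- sprintf("PSG%02d", i)
    # homologous body beyond the promoter half-window
    parent_body <- substr(seq, p_tss + 250L, p_tss + body - 1L)
    seq <- splice_in(seq, q_tss + 250L, mutate_seq(parent_body,
                                                   config$homology))
    add_gene(pid, pid, "protein_coding", "+", p_tss, p_tss + body - 1L)
    add_gene(qid, qid, classes[(i - 1) %% 3 + 1], "+", q_tss,
             q_tss + body - 1L, parent = pid)
    add_cage(paste0("cage_", pid), p_tss, "+")
    # the confound pseudogene keeps an exact summit so the planted
    # protospacer below stays at the design-window edge
    add_cage(paste0("cage_", qid), q_tss, "+",
             jitter = (i != config$confound_pair))
    pairs[i, ] <- list(pid, qid, p_tss, q_tss)
    homolog[[i]] <- data.frame(parent_start = p_tss + 250L,
                               pseudo_start = q_tss + 250L,
                               length = body - 250L)
  }

  truth <- list(seed = config$seed, chrom = chrom, chrom_length = L,
                pairs = pairs, homologous = do.call(rbind, homolog))

  if (config$bidirectional_pair >= 1L) {
    i <- config$bidirectional_pair
    q_tss <- pairs$pseudo_tss[i]
    n_tss <- q_tss + 700L
    add_gene("NBR01", "NBR01", "protein_coding", "-", n_tss - 400L, n_tss)
    add_cage("cage_NBR01", n_tss, "-")
    truth$bidirectional <- list(gene_id = pairs$pseudo_id[i],
                                neighbor_id = "NBR01",
                                tss_distance = 700L)
  }

  if (config$confound_pair >= 1L) {
    i <- config$confound_pair
    q_tss <- pairs$pseudo_tss[i]; p_tss <- pairs$parent_tss[i]
    # The confound pseudogene's whole 500-bp design window is rebuilt
    # from PAM-free sequence carrying exactly three protospacers: the
    # confound guide plus two benign ones, i.e. the library's minimum
    # guide count. A single noisy extra guide cannot then blur the
    # one-significant-sgRNA scenario the audit must detect. Fillers
    # start/end with A/T so no GG/CC can form across junctions.
    safe_filler <- function(n) paste0("A", pam_sparse_dna(n - 2L), "T")
    benign_spacer <- function() {
      repeat {
        sp <- paste0("A", pam_sparse_dna(19L))
        gc <- gc_fraction(sp)
        if (!has_polyT(sp) && gc >= 0.10 && gc < 0.75 &&
            sp != .CONFOUND_SPACER) return(sp)
      }
    }
    b1 <- benign_spacer(); b2 <- benign_spacer()
    promoter <- paste0(safe_filler(37L), .CONFOUND_SPACER, .CONFOUND_PAM,
                      safe_filler(90L), b1, "AGG",
                      safe_filler(127L), b2, "AGG",
                      safe_filler(177L))
    stopifnot(nchar(promoter) == 500L)
    seq <- splice_in(seq, q_tss - 250L, promoter)
    q_at <- q_tss - 213L
    # one-mismatch copy in the parent [-2 kb, +1 kb] TSS window
    mm_spacer <- .CONFOUND_SPACER
    substr(mm_spacer, 5, 5) <- "G"   # T -> G at position 5
    p_at <- p_tss - 500L
    seq <- splice_in(seq, p_at, paste0(mm_spacer, .CONFOUND_PAM))
    truth$confound <- list(gene_id = pairs$pseudo_id[i],
                           partner_id = pairs$parent_id[i],
                           spacer = .CONFOUND_SPACER,
                           intended = list(chrom = chrom, start = q_at,
                                           strand = "+"),
                           offtarget = list(chrom = chrom, start = p_at,
                                            strand = "+",
                                            mismatch_count = 1L))
  }

  genome <- genome_from_strings(stats::setNames(seq, chrom))
  annotation <- structure(list(genes = do.call(rbind, genes),
                               transcripts = do.call(rbind, tx)),
                          class = "pg_annotation")
  cage_df <- do.call(rbind, cage)
  cage_df <- cage_df[order(cage_df$chrom, cage_df$start), ]
  rownames(cage_df) <- NULL

  fx <- structure(list(genome = genome, annotation = annotation,
                       cage = cage_df, truth = truth,
                       config = config), class = "pg_fixture")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unclass(genome)),
      file.path(out_dir, "genome.fa"))
    write_annotation(annotation, file.path(out_dir, "genes.gtf"))
    write_cage_clusters(cage_df, file.path(out_dir, "cage.bed"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  fx
}

#' Non-targeting control spacers absent from a genome
#'
#' @param genome `pg_genome`.
#' @param n Number of controls.
#' @param seed RNG seed.
#' @return Data frame guide_id, spacer, category = "non_targeting".
#' @export
nontargeting_controls <- function(genome, n = 50L, seed = 1L) {
  set.seed(seed)
  seqs <- unclass(genome)
  out <- character(0)
  while (length(out) < n) {
    sp <- rand_dna(20L)
    present <- any(vapply(seqs, function(s)
      grepl(sp, s, fixed = TRUE) || grepl(revcomp(sp), s, fixed = TRUE),
      logical(1)))
    if (!present && !has_polyT(sp)) out <- unique(c(out, sp))
  }
  data.frame(guide_id = sprintf("NTC%03d", seq_len(n)),
             spacer = out[seq_len(n)], category = "non_targeting",
             stringsAsFactors = FALSE)
}

#' Simulate pooled-screen counts (and optionally reads)
#'
#' D0 counts are negative binomial around `depth` reads per guide
#' (variance mu + dispersion * mu^2); D21 means are scaled by
#' 2^truth_lfc. Reads are 75 nt: a vector prefix of 20 (+ jitter)
#' bases, the spacer, and vector suffix, so the default 20/30 end-trim
#' leaves a 25-nt fragment containing the full spacer.
#'
#' @param manifest Library manifest (guide_id, spacer).
#' @param truth_lfc Named numeric: guide id -> true log2 depletion (0
#'   for nulls and controls).
#' @param n_replicates Replicates per timepoint (default 3).
#' @param depth Mean D0 coverage per guide (default 500).
#' @param dispersion NB dispersion phi, variance mu + phi mu^2
#'   (default 0.05).
#' @param jitter Max extra prefix bases, sampled uniformly from
#'   0..jitter per read (default 1).
#' @param reads If TRUE, also generate read sequences per sample.
#' @param seed RNG seed.
#' @return List of class `pg_sim_screen`: `counts` (guides x samples),
#'   `samples` (sample sheet), `truth_lfc`, and `reads` (named list of
#'   character vectors) when requested.
#' @export
simulate_screen <- function(manifest, truth_lfc, n_replicates = 3L,
                            depth = 500, dispersion = 0.05, jitter = 1L,
                            reads = FALSE, seed = 1L) {
  stopifnot(all(manifest$guide_id %in% names(truth_lfc)))
  set.seed(seed)
  lfc <- truth_lfc[manifest$guide_id]
  samples <- data.frame(
    sample = c(paste0("D0_r", seq_len(n_replicates)),
               paste0("D21_r", seq_len(n_replicates))),
    timepoint = rep(c("D0", "D21"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2),
    stringsAsFactors = FALSE)
  ng <- nrow(manifest)
  counts <- matrix(0L, ng, nrow(samples),
                   dimnames = list(manifest$guide_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- if (samples$timepoint[j] == "D0") rep(depth, ng)
          else depth * 2^lfc
    counts[, j] <- if (dispersion > 0)
      stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
    else stats::rpois(ng, mu)
  }
  out <- list(counts = counts, samples = samples,
              truth_lfc = lfc)
  if (reads) {
    pre <- pg_linkers$linker5
    suf <- pg_linkers$linker3
    out$reads <- lapply(seq_len(nrow(samples)), function(j) {
      n_per <- counts[, j]
      idx <- rep.int(seq_len(ng), n_per)
      jit <- sample.int(jitter + 1L, length(idx), replace = TRUE) - 1L
      prefix <- substring(pre, nchar(pre) - 19L - jit, nchar(pre))
      core <- paste0(prefix, manifest$spacer[idx])
      paste0(core, substring(suf, 1L, 75L - nchar(core)))
    })
    names(out$reads) <- samples$sample
  }
  structure(out, class = "pg_sim_screen")
}

#' Write simulated reads as FASTQ
#' @param sim `pg_sim_screen` with reads.
#' @param out_dir Output directory; one `<sample>.fastq` per sample.
#' @return Named vector of file paths.
#' @export
write_sim_fastq <- function(sim, out_dir) {
  stopifnot(!is.null(sim$reads))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$reads), function(s) {
    rd <- sim$reads[[s]]
    p <- file.path(out_dir, paste0(s, ".fastq"))
    writeLines(paste0("@", s, "_", seq_along(rd), "\n", rd, "\n+\n",
                      strrep("I", nchar(rd))), p)
    p
  }, character(1))
  paths
}
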