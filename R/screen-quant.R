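#' Trim fixed lengths off both read ends
#'
#' The screen protocol sequences 75-nt single-end reads in which the
#' 20-nt spacer sits after 20 nt of vector sequence; trimming 20 nt from
#' the 5' end and 30 nt from the 3' end leaves a 25-nt fragment
#' containing the spacer.
#'
#' @param reads Character vector of read sequences.
#' @param trim5,trim3 Bases removed from the 5'/3' ends (defaults 20/30).
#' @return List with `fragments` (trimmed sequences; too-short reads
#'   yield NA) and `discarded` (logical).
#' @export
trim_reads <- function(reads, trim5 = 20L, trim3 = 30L) {
  stopifnot(trim5 >= 0, trim3 >= 0)
  L <- nchar(reads)
  ok <- L > trim5 + trim3
  frags <- rep(NA_character_, length(reads))
  frags[ok] <- substr(reads[ok], trim5 + 1L, L[ok] - trim3)
  list(fragments = frags, discarded = !ok)
}

match_spacers <- function(fragments, spacers, max_mismatch = 0L) {
  # returns a list: fragment -> integer indices of matching spacers
  frags <- Biostrings::DNAStringSet(fragments)
  if (max_mismatch == 0L) {
    pd <- Biostrings::PDict(spacers)
    hits <- Biostrings::vwhichPDict(pd, frags)
    lapply(hits, unique)
  } else {
    hit_mat <- vapply(spacers, function(sp) {
      Biostrings::vcountPattern(sp, frags, max.mismatch = max_mismatch) > 0
    }, logical(length(frags)))
    if (length(frags) == 1L) hit_mat <- matrix(hit_mat, nrow = 1)
    apply(hit_mat, 1, which, simplify = FALSE)
  }
}

#' Count screen reads into an sgRNA x sample matrix
#'
#' Reads are end-trimmed and each fragment is assigned to the unique
#' library guide whose spacer occurs as a forward-orientation substring
#' of the fragment. Fragments matching two or more distinct spacers are
#' tallied `ambiguous` and dropped (the unique-mapping contract);
#' reverse-complement matches are not searched (the forward-strand
#' contract); non-matching or too-short reads are `unassigned`. Per
#' sample, assigned + unassigned + ambiguous equals the number of input
#' reads.
#'
#' @param reads_by_sample Named list: sample -> character vector of
#'   reads, or path(s) to FASTQ files (plain or gzipped).
#' @param manifest Library manifest (needs guide_id and spacer; spacers
#'   must be unique).
#' @param trim5,trim3 End trims (defaults 20/30).
#' @param max_mismatch Allowed mismatches within a spacer match
#'   (default 0 = exact substring).
#' @return List of class `pg_count_matrix`: `counts` (integer matrix,
#'   guides x samples) and `qc` (per-sample tallies).
#' @export
quantify_reads <- function(reads_by_sample, manifest, trim5 = 20L,
                           trim3 = 30L, max_mismatch = 0L) {
  if (nrow(manifest) == 0) stop("empty manifest")
  if (anyDuplicated(manifest$spacer))
    stop("manifest spacers must be unique")
  samples <- names(reads_by_sample)
  if (is.null(samples)) stop("reads_by_sample must be named by sample")
  counts <- matrix(0L, nrow(manifest), length(samples),
                   dimnames = list(manifest$guide_id, samples))
  qc <- data.frame(sample = samples, total = 0L, assigned = 0L,
                   unassigned = 0L, ambiguous = 0L,
                   stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    reads <- reads_by_sample[[j]]
    if (is.character(reads) && length(reads) <= 4 &&
        all(file.exists(reads))) {
      reads <- unlist(lapply(reads, function(p)
        as.character(Biostrings::readDNAStringSet(p, format = "fastq"))))
    }
    tr <- trim_reads(reads, trim5, trim3)
    frags <- tr$fragments[!tr$discarded]
    n_short <- sum(tr$discarded)
    if (length(frags)) {
      hits <- match_spacers(frags, manifest$spacer, max_mismatch)
      nhit <- lengths(hits)
      amb <- nhit >= 2L
      uni <- nhit == 1L
      tab <- table(factor(unlist(hits[uni]), levels = seq_len(nrow(manifest))))
      counts[, j] <- as.integer(tab)
      qc$assigned[j] <- sum(uni)
      qc$ambiguous[j] <- sum(amb)
      qc$unassigned[j] <- sum(nhit == 0L) + n_short
    } else {
      qc$unassigned[j] <- n_short
    }
    qc$total[j] <- length(reads)
  }
  structure(list(counts = counts, qc = qc), class = "pg_count_matrix")
}

#' @export
print.pg_count_matrix <- function(x, ...) {
  cat("sgRNA count matrix:", nrow(x$counts), "guides x",
      ncol(x$counts), "samples\n")
  print(x$qc, row.names = FALSE)
  invisible(x)
}

#' Write a count matrix as TSV (sgRNA rows, sample columns)
#' @param cm `pg_count_matrix` or plain matrix.
#' @param path Output path.
#' @export
write_counts <- function(cm, path) {
  m <- if (inherits(cm, "pg_count_matrix")) cm$counts else cm
  df <- data.frame(sgrna = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
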