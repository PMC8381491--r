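#' Read a genome FASTA into a named sequence set
#'
#' Sequences are uppercased and validated against the {A,C,G,T,N} alphabet.
#' All downstream coordinates are 1-based inclusive.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return Named character vector of chromosome sequences, class
#'   `pg_genome`.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  genome_from_strings(stats::setNames(as.character(dss), names(dss)))
}

#' Build a genome object from in-memory sequences
#'
#' @param seqs Named character vector, one element per chromosome.
#' @return Named character vector of class `pg_genome`.
#' @export
genome_from_strings <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every chromosome needs a name")
  seqs <- vapply(seqs, function(s) toupper(s), character(1))
  # FASTA headers may carry descriptions; keep the first token as the name
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)
  if (any(nchar(seqs) == 0L)) stop("zero-length chromosome sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("disallowed characters in chromosome(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  structure(seqs, class = "pg_genome")
}

#' @export
print.pg_genome <- function(x, ...) {
  cat("genome:", length(x), "chromosome(s),",
      format(sum(nchar(x)), big.mark = ","), "bp total\n")
  invisible(x)
}

.BIOTYPES <- c("protein_coding", "processed_pseudogene",
               "unprocessed_pseudogene", "unitary_pseudogene")

map_biotype <- function(gene_type) {
  ifelse(gene_type %in% .BIOTYPES, gene_type, "other")
}

#' Read a GENCODE-dialect GTF into gene and transcript models
#'
#' Parses `gene` and `transcript` feature rows. Each transcript gets a
#' strand-correct 5' end (interval start on `+`, interval end on `-`).
#' `gene_type` values outside the recognized classes (protein_coding and
#' the processed/unprocessed/unitary pseudogene classes) map to `other`.
#' Optional `parent_id` attributes record a pseudogene's parent gene.
#'
#' @param path Path to a GTF file (1-based inclusive coordinates).
#' @return A list of class `pg_annotation` with elements `genes` and
#'   `transcripts` (data frames).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("GTF parse error at line ", idx[which(nf < 9L)[1]],
         ": expected 9 tab-separated fields")
  feat <- vapply(fields, `[[`, character(1), 3L)
  use <- feat %in% c("gene", "transcript")
  fields <- fields[use]; idx <- idx[use]; feat <- feat[use]

  attr_val <- function(attrs, key) {
    pat <- paste0(key, ' "([^"]*)"')
    m <- regexpr(pat, attrs)
    out <- rep(NA_character_, length(attrs))
    hit <- m != -1L
    out[hit] <- sub(pat, "\\1", regmatches(attrs, m))
    out
  }
  attrs <- vapply(fields, `[[`, character(1), 9L)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[[`, character(1), 4L))
  end <- as.integer(vapply(fields, `[[`, character(1), 5L))
  strand <- vapply(fields, `[[`, character(1), 7L)
  if (any(!strand %in% c("+", "-")))
    stop("GTF parse error at line ", idx[which(!strand %in% c("+", "-"))[1]],
         ": strand must be + or -")

  gene_id <- attr_val(attrs, "gene_id")
  if (anyNA(gene_id))
    stop("GTF parse error at line ", idx[which(is.na(gene_id))[1]],
         ": missing gene_id attribute")
  gene_type <- attr_val(attrs, "gene_type")
  if (anyNA(gene_type))
    stop("GTF parse error at line ", idx[which(is.na(gene_type))[1]],
         ": missing gene_type attribute")

  gi <- feat == "gene"
  genes <- data.frame(
    gene_id = gene_id[gi],
    gene_name = ifelse(is.na(attr_val(attrs[gi], "gene_name")),
                       gene_id[gi], attr_val(attrs[gi], "gene_name")),
    biotype = map_biotype(gene_type[gi]),
    chrom = chrom[gi], strand = strand[gi],
    start = start[gi], end = end[gi],
    parent_gene_id = attr_val(attrs[gi], "parent_id"),
    stringsAsFactors = FALSE
  )
  ti <- feat == "transcript"
  transcript_id <- attr_val(attrs, "transcript_id")
  if (any(ti & is.na(transcript_id)))
    stop("GTF parse error at line ", idx[which(ti & is.na(transcript_id))[1]],
         ": missing transcript_id attribute")
  transcripts <- data.frame(
    transcript_id = transcript_id[ti],
    gene_id = gene_id[ti],
    chrom = chrom[ti], strand = strand[ti],
    start = start[ti], end = end[ti],
    five_prime_end = ifelse(strand[ti] == "+", start[ti], end[ti]),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, transcripts = transcripts),
            class = "pg_annotation")
}

#' @export
print.pg_annotation <- function(x, ...) {
  cat("annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts\n")
  tab <- table(x$genes$biotype)
  cat(paste0("  ", names(tab), ": ", tab, collapse = "\n"), "\n")
  invisible(x)
}

#' Write gene/transcript models as a GENCODE-dialect GTF
#' @param annotation A `pg_annotation`.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes
  gene_attr <- paste0('gene_id "', g$gene_id, '"; gene_type "', g$biotype,
                      '"; gene_name "', g$gene_name, '";',
                      ifelse(is.na(g$parent_gene_id), "",
                             paste0(' parent_id "', g$parent_gene_id, '";')))
  gl <- paste(g$chrom, "pgscreen", "gene", g$start, g$end, ".", g$strand,
              ".", gene_attr, sep = "\t")
  tx <- annotation$transcripts
  bt <- g$biotype[match(tx$gene_id, g$gene_id)]
  tx_attr <- paste0('gene_id "', tx$gene_id, '"; transcript_id "',
                    tx$transcript_id, '"; gene_type "', bt, '";')
  tl <- paste(tx$chrom, "pgscreen", "transcript", tx$start, tx$end, ".",
              tx$strand, ".", tx_attr, sep = "\t")
  # keep each gene's transcripts after its gene row
  ord <- order(c(match(g$gene_id, g$gene_id),
                 match(tx$gene_id, g$gene_id) + 0.5))
  writeLines(c(gl, tl)[ord], path)
}

#' Read CAGE clusters from a BED6+1 file
#'
#' Column 7 carries the TIEScore (transcription initiation evidence
#' score). BED coordinates (0-based half-open) are converted to 1-based
#' inclusive. The cluster summit defaults to the interval midpoint,
#' `start0 + floor((end0 - start0)/2)` in BED terms.
#'
#' @param path Path to a BED6+1 file.
#' @return Data frame of clusters sorted by (chrom, start) with columns
#'   cluster_id, chrom, strand, start, end, summit, tie_score.
#' @export
read_cage_clusters <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start0", "end0", "name",
                                         "score", "strand", "tie_score"))
  if (any(!bed$strand %in% c("+", "-")))
    stop("CAGE parse error: strand must be + or - (row ",
         which(!bed$strand %in% c("+", "-"))[1], ")")
  if (any(bed$start0 >= bed$end0))
    stop("CAGE parse error: start must be < end (row ",
         which(bed$start0 >= bed$end0)[1], ")")
  if (any(bed$tie_score < 0))
    stop("CAGE parse error: negative TIEScore (row ",
         which(bed$tie_score < 0)[1], ")")
  cl <- data.frame(
    cluster_id = bed$name,
    chrom = bed$chrom, strand = bed$strand,
    start = bed$start0 + 1L, end = bed$end0,
    summit = bed$start0 + (bed$end0 - bed$start0) %/% 2L + 1L,
    tie_score = bed$tie_score,
    stringsAsFactors = FALSE
  )
  cl[order(cl$chrom, cl$start), , drop = FALSE]
}

#' Write CAGE clusters back to BED6+1
#' @param clusters Data frame as returned by [read_cage_clusters()].
#' @param path Output path.
#' @export
write_cage_clusters <- function(clusters, path) {
  bed <- data.frame(clusters$chrom, clusters$start - 1L, clusters$end,
                    clusters$cluster_id, 0L, clusters$strand,
                    clusters$tie_score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Assign CAGE clusters to transcripts as TSSs
#'
#' A cluster is assigned to a transcript when it lies on the same
#' chromosome and strand and its summit is within `max_offset_bp` of the
#' transcript 5' end. Transcripts with no assigned cluster fall back to
#' their annotated 5' end (`source = "annotated"`, tie_score 0) so that
#' library design can proceed for every gene. Gene-level assignments are
#' the union over the gene's transcripts; each (gene, cluster) pair
#' appears once, keeping the smallest summit offset.
#'
#' @param annotation A `pg_annotation`.
#' @param clusters CAGE cluster data frame.
#' @param max_offset_bp Maximum |summit - 5' end| distance (default 500).
#' @return Data frame with columns gene_id, transcript_id, source, tss,
#'   cluster_id, tie_score, offset; ordered per gene by descending
#'   tie_score (CAGE-supported TSSs first).
#' @export
assign_tss <- function(annotation, clusters, max_offset_bp = 500L) {
  stopifnot(max_offset_bp > 0)
  tx <- annotation$transcripts
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    sel <- clusters$chrom == t$chrom & clusters$strand == t$strand &
      abs(clusters$summit - t$five_prime_end) <= max_offset_bp
    if (any(sel)) {
      cc <- clusters[sel, , drop = FALSE]
      out[[i]] <- data.frame(
        gene_id = t$gene_id, transcript_id = t$transcript_id,
        source = "cage", tss = cc$summit, cluster_id = cc$cluster_id,
        tie_score = cc$tie_score,
        offset = abs(cc$summit - t$five_prime_end),
        stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(
        gene_id = t$gene_id, transcript_id = t$transcript_id,
        source = "annotated", tss = t$five_prime_end,
        cluster_id = NA_character_, tie_score = 0, offset = 0L,
        stringsAsFactors = FALSE)
    }
  }
  asg <- do.call(rbind, out)
  # one row per (gene, cluster): keep smallest offset, then higher tie_score
  key <- ifelse(is.na(asg$cluster_id),
                paste0(asg$gene_id, "\r", asg$transcript_id, "\rann"),
                paste0(asg$gene_id, "\r", asg$cluster_id))
  ord <- order(key, asg$offset, -asg$tie_score)
  asg <- asg[ord, , drop = FALSE]
  asg <- asg[!duplicated(key[ord]), , drop = FALSE]
  asg <- asg[order(asg$gene_id, -asg$tie_score, asg$offset), , drop = FALSE]
  rownames(asg) <- NULL
  asg
}

gene_tss_set <- function(gene_id, annotation, assignments, source) {
  if (source == "cage") {
    a <- assignments[assignments$gene_id == gene_id &
                       assignments$source == "cage", ]
    unique(a$tss)
  } else {
    unique(annotation$transcripts$five_prime_end[
      annotation$transcripts$gene_id == gene_id])
  }
}

#' Minimum TSS distance between two genes
#'
#' The distance is the minimum over all pairs of CAGE-assigned TSSs of
#' the two genes and all pairs of annotated TSSs (the two families are
#' never mixed). Genes on different chromosomes get `Inf`.
#'
#' @param gene_a,gene_b Gene ids.
#' @param annotation A `pg_annotation`.
#' @param assignments Output of [assign_tss()].
#' @return Non-negative distance in bp, or `Inf`.
#' @export
tss_distance <- function(gene_a, gene_b, annotation, assignments) {
  g <- annotation$genes
  ca <- g$chrom[g$gene_id == gene_a]; cb <- g$chrom[g$gene_id == gene_b]
  if (length(ca) == 0 || length(cb) == 0) stop("unknown gene id")
  if (ca != cb) return(Inf)
  dmin <- function(x, y) {
    if (length(x) == 0 || length(y) == 0) return(Inf)
    min(abs(outer(x, y, "-")))
  }
  min(dmin(gene_tss_set(gene_a, annotation, assignments, "cage"),
           gene_tss_set(gene_b, annotation, assignments, "cage")),
      dmin(gene_tss_set(gene_a, annotation, assignments, "annotated"),
           gene_tss_set(gene_b, annotation, assignments, "annotated")))
}

#' 500-bp design window centered on a TSS
#'
#' Returns the 1-based inclusive interval `[tss - half, tss + half - 1]`
#' (500 bp for the default `half = 250`), clipped at chromosome ends.
#'
#' @param tss 1-based TSS coordinate.
#' @param chrom_length Chromosome length in bp.
#' @param half Half-width in bp (default 250).
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
design_window <- function(tss, chrom_length, half = 250L) {
  stopifnot(tss >= 1, tss <= chrom_length)
  c(start = max(1L, as.integer(tss) - as.integer(half)),
    end = min(as.integer(chrom_length), as.integer(tss) + as.integer(half) - 1L))
}
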