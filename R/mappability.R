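#' Unique-mappability mask at a fixed read length
#'
#' Position p of a chromosome is mappable iff the `read_length`-mer
#' starting there occurs exactly once genome-wide, counting both strands
#' (a k-mer whose reverse complement occurs elsewhere is not unique;
#' a reverse-complement palindrome counts itself twice and is never
#' unique). K-mers containing N are non-mappable. Positions within
#' `read_length` of a chromosome 3' end are FALSE: no full-length read
#' starts there.
#'
#' @param genome `pg_genome`.
#' @param read_length Read length in bp (default 75, matching 75-nt
#'   single-end sequencing).
#' @return Named list of logical vectors (one per chromosome, full
#'   chromosome length), with attribute `read_length`.
#' @export
mappability_mask <- function(genome, read_length = 75L) {
  stopifnot(read_length >= 1)
  k <- as.integer(read_length)
  seqs <- unclass(genome)
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  })
  fwd <- unlist(kmers, use.names = FALSE)
  fcount <- table(fwd)
  mask <- lapply(names(seqs), function(ch) {
    L <- nchar(seqs[[ch]])
    m <- logical(L)
    km <- kmers[[ch]]
    if (length(km) == 0) return(m)
    rc <- revcomp(km)
    occ <- as.integer(fcount[km])
    occ_rc <- as.integer(fcount[rc])
    occ_rc[is.na(occ_rc)] <- 0L
    m[seq_along(km)] <- (occ + occ_rc) == 1L &
      !grepl("N", km, fixed = TRUE)
    m
  })
  names(mask) <- names(seqs)
  attr(mask, "read_length") <- k
  mask
}

#' Effective (uniquely mappable) length of a gene
#'
#' Counts the mappable positions within the gene's genomic span. The
#' span is the full genomic extent of the gene, not the exon union;
#' pass exon intervals via `intervals` to use an exon-union length.
#'
#' @param gene One-row data frame with chrom, start, end (1-based
#'   inclusive), as in `pg_annotation$genes`.
#' @param mask Output of [mappability_mask()].
#' @param intervals Optional data frame chrom/start/end replacing the
#'   gene span (exon-union mode).
#' @return Effective length in bp.
#' @export
effective_length <- function(gene, mask, intervals = NULL) {
  iv <- if (is.null(intervals))
    data.frame(chrom = gene$chrom, start = gene$start, end = gene$end)
  else intervals
  sum(vapply(seq_len(nrow(iv)), function(i) {
    m <- mask[[iv$chrom[i]]]
    sum(m[iv$start[i]:min(iv$end[i], length(m))])
  }, numeric(1)))
}

#' Effective-length FPKM for pseudogene expression
#'
#' `count * 1e9 / (effective_length_bp * total_reads)` — fragments per
#' kilobase of uniquely mappable gene length per million total reads.
#' A zero effective length yields NA (expression undefined), never a
#' division error.
#'
#' @param count Gene-level read count (non-negative).
#' @param effective_length_bp Uniquely mappable length in bp.
#' @param total_reads Per-sample total read count (> 0).
#' @return FPKM value(s); NA where effective length is 0.
#' @export
fpkm <- function(count, effective_length_bp, total_reads) {
  if (any(count < 0) || any(effective_length_bp < 0) || any(total_reads <= 0))
    stop("fpkm: counts/lengths must be non-negative and totals positive")
  out <- count * 1e9 / (effective_length_bp * total_reads)
  out[effective_length_bp == 0] <- NA_real_
  out
}

#' Expression / guide-count library inclusion filter
#'
#' A gene is retained iff its FPKM reaches `min_fpkm` in at least one
#' sample (i.e. it is not lowly expressed in every cell line) AND it has
#' at least `min_guides` designed sgRNAs. Genes absent from the FPKM
#' table count as 0 in all samples.
#'
#' @param fpkm_by_sample Numeric matrix or data frame, genes x samples,
#'   rownames = gene ids.
#' @param guides_per_gene Named integer vector of designed-guide counts.
#' @param min_fpkm FPKM threshold (default 0.5).
#' @param min_guides Minimum designed sgRNAs (default 3).
#' @return Character vector of retained gene ids.
#' @export
expression_filter <- function(fpkm_by_sample, guides_per_gene,
                              min_fpkm = 0.5, min_guides = 3L) {
  genes <- names(guides_per_gene)
  fm <- as.matrix(fpkm_by_sample)
  expr <- vapply(genes, function(g) {
    if (!g %in% rownames(fm)) return(FALSE)
    any(fm[g, ] >= min_fpkm, na.rm = TRUE)
  }, logical(1))
  genes[expr & guides_per_gene >= min_guides]
}

#' Export a mappability mask as BedGraph
#' @param mask Output of [mappability_mask()].
#' @param path Output path.
#' @export
write_mask_bedgraph <- function(mask, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(mask)) {
    m <- mask[[ch]]
    r <- rle(as.integer(m))
    ends <- cumsum(r$lengths)
    starts0 <- c(0L, ends[-length(ends)])
    writeLines(paste(ch, starts0, ends, r$values, sep = "\t"), con)
  }
}
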