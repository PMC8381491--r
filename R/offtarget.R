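hamming_to <- function(spacer, others) {
  # N in the genome never matches a spacer base
  sp <- strsplit(spacer, "")[[1]]
  mat <- do.call(rbind, strsplit(others, ""))
  rowSums(sweep(mat, 2, sp, "!=") | mat == "N")
}

#' PAM-constrained mismatch search for a spacer
#'
#' Reports every genomic 20-mer followed by an NGG PAM (both strands)
#' within `max_mismatches` Hamming distance of the spacer. No bulges
#' (insertions/deletions) are considered. The designed locus, when
#' given, is marked `is_intended_site` and excluded from off-target
#' counting by [count_offtargets()].
#'
#' @param spacer 20-nt guide sequence.
#' @param genome `pg_genome`, or a precomputed site table from
#'   [scan_protospacers()] (reused across many spacers).
#' @param max_mismatches Maximum Hamming distance (default 1; bulges
#'   are never allowed).
#' @param intended Optional list/row with chrom, start, strand of the
#'   designed locus.
#' @return Data frame: chrom, strand, start, end, pam, mismatch_count,
#'   is_intended_site.
#' @export
find_sites <- function(spacer, genome, max_mismatches = 1L,
                       intended = NULL) {
  if (nchar(spacer) != 20L) stop("spacer must be 20 nt")
  stopifnot(max_mismatches >= 0)
  sites <- if (inherits(genome, "pg_genome"))
    scan_protospacers(genome, drop_N = FALSE)
  else genome
  if (nrow(sites) == 0)
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      pam = character(), mismatch_count = integer(),
                      is_intended_site = logical()))
  mm <- hamming_to(spacer, sites$spacer)
  hit <- sites[mm <= max_mismatches, , drop = FALSE]
  hit$mismatch_count <- as.integer(mm[mm <= max_mismatches])
  hit$is_intended_site <- rep(FALSE, nrow(hit))
  if (!is.null(intended)) {
    hit$is_intended_site <- hit$chrom == intended$chrom &
      hit$start == intended$start & hit$strand == intended$strand
  }
  hit <- hit[order(hit$chrom, hit$start, hit$strand),
             c("chrom", "strand", "start", "end", "pam",
               "mismatch_count", "is_intended_site")]
  rownames(hit) <- NULL
  hit
}

#' Number of additional (off-target) sites of a guide
#' @param sites Output of [find_sites()].
#' @return Count of sites that are not the intended locus.
#' @export
count_offtargets <- function(sites) sum(!sites$is_intended_site)

#' Sites falling in a partner gene's promoter window
#'
#' The window is strand-oriented: [TSS - 2 kb, TSS + 1 kb] on a `+`
#' strand partner (2 kb upstream, 1 kb downstream), mirrored to
#' [TSS - 1 kb, TSS + 2 kb] on `-`. Boundaries inclusive; a site is in
#' the window when its interval overlaps it.
#'
#' @param sites Output of [find_sites()].
#' @param partner_chrom,partner_tss,partner_strand Partner gene TSS
#'   (CAGE-assigned preferred, else annotated).
#' @param upstream,downstream Window extents in bp (defaults 2000/1000).
#' @return Subset of `sites` overlapping the window.
#' @export
partner_window_hits <- function(sites, partner_chrom, partner_tss,
                                partner_strand, upstream = 2000L,
                                downstream = 1000L) {
  if (partner_strand == "+") {
    lo <- partner_tss - upstream; hi <- partner_tss + downstream
  } else {
    lo <- partner_tss - downstream; hi <- partner_tss + upstream
  }
  sel <- sites$chrom == partner_chrom & sites$start <= hi & sites$end >= lo
  sites[sel, , drop = FALSE]
}

#' Audit a screen hit for the partner off-target confound
#'
#' A hit is confounded when it has one and only one significant
#' negatively selected sgRNA (p below `p_thresh`, log2 fold change at or
#' below `lfc_thresh`) and that sgRNA harbors a predicted off-target
#' site within the partner gene's [-2 kb, +1 kb] TSS window. The report
#' also gives how many significant sgRNAs remain after removing all
#' offending ones.
#'
#' @param hit_gene Gene id of the screen hit.
#' @param sgrna_stats Data frame with columns sgrna, gene_id, lfc, p
#'   (as produced by [sgrna_stats()]).
#' @param partner_window_sites Named list: sgrna id -> data frame of
#'   that guide's sites inside the partner window (possibly 0-row).
#' @param p_thresh,lfc_thresh Significance thresholds (defaults 0.05
#'   and -log2(1.5)).
#' @return List of class `pg_confound_report`.
#' @export
audit_confounded_hits <- function(hit_gene, sgrna_stats,
                                  partner_window_sites,
                                  p_thresh = 0.05,
                                  lfc_thresh = -log2(1.5)) {
  st <- sgrna_stats[sgrna_stats$gene_id == hit_gene, , drop = FALSE]
  if (nrow(st) == 0) stop("hit gene has no sgRNAs: ", hit_gene)
  sig <- st$p < p_thresh & st$lfc <= lfc_thresh
  sig_ids <- st$sgrna[sig]
  offending <- sig_ids[vapply(sig_ids, function(id) {
    s <- partner_window_sites[[id]]
    !is.null(s) && nrow(s) > 0
  }, logical(1))]
  confounded <- sum(sig) == 1L && length(offending) == 1L
  structure(list(
    gene_id = hit_gene,
    n_significant_sgrnas = sum(sig),
    significant_sgrnas = sig_ids,
    offending_sgrnas = offending,
    confounded = confounded,
    n_significant_after_removal = sum(sig) - length(offending)
  ), class = "pg_confound_report")
}

#' @export
print.pg_confound_report <- function(x, ...) {
  cat("confound audit for", x$gene_id, "\n",
      " significant negatively selected sgRNAs:", x$n_significant_sgrnas, "\n",
      " with partner-window off-target site:", length(x$offending_sgrnas), "\n",
      " confounded:", x$confounded, "\n",
      " significant after removing offenders:",
      x$n_significant_after_removal, "\n")
  invisible(x)
}
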