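# Shared low-level sequence helpers. N is kept distinct everywhere: it
# never matches any base and never counts toward GC.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

gc_fraction <- function(x) {
  (nchar(gsub("[^GC]", "", x))) / nchar(x)
}

has_polyT <- function(x, run = 4L) {
  grepl(strrep("T", run), x, fixed = TRUE)
}

#' Enumerate all SpCas9 protospacers in a genome or region
#'
#' A protospacer is a 20-mer immediately followed by an NGG PAM; both
#' strands are scanned. For a minus-strand site the reported `spacer` is
#' the guide sequence (reverse complement of the plus-strand slice) and
#' the interval still refers to plus-strand coordinates of the 20-mer.
#'
#' @param genome `pg_genome`.
#' @param chrom Restrict to one chromosome (default all).
#' @param start,end 1-based inclusive bounds of the scanned region; a
#'   site is reported only if spacer and PAM both lie inside.
#' @param drop_N Drop sites whose 20-mer contains N (TRUE for design;
#'   the off-target search keeps them, counting N as a mismatch). The
#'   two PAM G positions must be literal G either way.
#' @return Data frame: spacer, pam, chrom, strand, start, end (1-based
#'   inclusive interval of the 20-nt protospacer).
#' @export
scan_protospacers <- function(genome, chrom = NULL, start = NULL, end = NULL,
                              drop_N = TRUE) {
  chroms <- if (is.null(chrom)) names(genome) else chrom
  out <- list()
  for (ch in chroms) {
    seq <- unclass(genome)[[ch]]
    lo <- if (is.null(start)) 1L else max(1L, as.integer(start))
    hi <- if (is.null(end)) nchar(seq) else min(nchar(seq), as.integer(end))
    if (hi - lo + 1L < 23L) next
    w <- substr(seq, lo, hi)
    n <- nchar(w)
    # + strand: spacer at i..i+19, PAM i+20..i+22 with GG at i+21,i+22
    ig <- which(strsplit(w, "")[[1]] == "G")
    plus_pam <- ig[ig >= 2 & (ig - 1) %in% ig]  # positions p where w[p-1]=w[p]="G"
    plus_i <- (plus_pam - 22L)                  # spacer start for GG at (i+21,i+22)
    plus_i <- plus_i[plus_i >= 1L]
    ic <- which(strsplit(w, "")[[1]] == "C")
    minus_cc <- ic[(ic + 1) %in% ic]            # p where w[p]=w[p+1]="C"
    minus_i <- minus_cc                         # PAM at i..i+2 (revcomp NGG), spacer i+3..i+22
    minus_i <- minus_i[minus_i + 22L <= n]
    rows <- list()
    if (length(plus_i)) {
      sp <- substring(w, plus_i, plus_i + 19L)
      pam <- substring(w, plus_i + 20L, plus_i + 22L)
      ok <- if (drop_N) !grepl("N", sp, fixed = TRUE) else rep(TRUE, length(sp))
      rows$plus <- data.frame(spacer = sp[ok], pam = pam[ok], chrom = ch,
                              strand = "+", start = lo + plus_i[ok] - 1L,
                              end = lo + plus_i[ok] + 18L,
                              stringsAsFactors = FALSE)
    }
    if (length(minus_i)) {
      sp_plus <- substring(w, minus_i + 3L, minus_i + 22L)
      pam_plus <- substring(w, minus_i, minus_i + 2L)
      ok <- if (drop_N) !grepl("N", sp_plus, fixed = TRUE)
            else rep(TRUE, length(sp_plus))
      if (any(ok)) {
        rows$minus <- data.frame(spacer = revcomp(sp_plus[ok]),
                                 pam = revcomp(pam_plus[ok]), chrom = ch,
                                 strand = "-",
                                 start = lo + minus_i[ok] + 2L,
                                 end = lo + minus_i[ok] + 21L,
                                 stringsAsFactors = FALSE)
      }
    }
    out[[ch]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(spacer = character(), pam = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Genome-wide census of protospacer 20-mers (for the uniqueness filter):
# named integer vector, spacer string -> number of PAM-adjacent sites.
protospacer_census <- function(genome) {
  sites <- scan_protospacers(genome)
  table(sites$spacer)
}
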