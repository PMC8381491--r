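# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own scanning/counting code paths.

naive_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Brute-force Hamming scan over every PAM-adjacent genomic position.
naive_site_scan <- function(seqs, spacer, max_mm) {
  spc <- strsplit(spacer, "")[[1]]
  hits <- list()
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    L <- nchar(s)
    if (L < 23) next
    for (i in 1:(L - 22)) {
      seg <- substr(s, i, i + 22)
      if (substr(seg, 22, 23) == "GG") {
        sc <- strsplit(substr(seg, 1, 20), "")[[1]]
        mm <- sum(sc != spc | sc == "N")
        if (mm <= max_mm)
          hits[[length(hits) + 1]] <- data.frame(
            chrom = ch, strand = "+", start = i, end = i + 19L,
            mismatch_count = mm, stringsAsFactors = FALSE)
      }
      if (substr(seg, 1, 2) == "CC") {
        sc <- strsplit(naive_revcomp(substr(seg, 4, 23)), "")[[1]]
        mm <- sum(sc != spc | sc == "N")
        if (mm <= max_mm)
          hits[[length(hits) + 1]] <- data.frame(
            chrom = ch, strand = "-", start = i + 3L, end = i + 22L,
            mismatch_count = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      mismatch_count = integer()))
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$start, out$strand), ]
}

# Brute-force k-mer occurrence count (both strands) via countPattern.
naive_kmer_occurrences <- function(seqs, kmer) {
  sum(vapply(seqs, function(s) {
    subj <- Biostrings::DNAString(s)
    Biostrings::countPattern(kmer, subj, fixed = TRUE) +
      Biostrings::countPattern(kmer, Biostrings::reverseComplement(subj),
                               fixed = TRUE)
  }, numeric(1)))
}

# Brute-force mappability: position-by-position census.
naive_mask <- function(seqs, k) {
  lapply(seqs, function(s) {
    L <- nchar(s)
    m <- logical(L)
    if (L >= k) {
      for (i in 1:(L - k + 1)) {
        km <- substr(s, i, i + k - 1)
        m[i] <- !grepl("N", km, fixed = TRUE) &&
          naive_kmer_occurrences(seqs, km) == 1
      }
    }
    m
  })
}

# Exhaustive alpha-RRA p-value over all size-k rank subsets, with the
# same lexicographic (rho, u1) ordering, computed independently.
exhaustive_rra_p <- function(ranks, n_total, alpha) {
  k <- length(ranks)
  score <- function(r) {
    u <- sort(r) / n_total
    j <- which(u <= alpha)
    c(if (length(j)) min(stats::pbeta(u[j], j, k - j + 1)) else 1, u[1])
  }
  s0 <- score(ranks)
  sc <- apply(utils::combn(n_total, k), 2, score)
  mean(sc[1, ] < s0[1] | (sc[1, ] == s0[1] & sc[2, ] <= s0[2]))
}

# A tiny deterministic genome with named landmarks for targeted tests.
landmark_genome <- function() {
  set.seed(404)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  spacer <- "GATTACAGATTACAGATTCA"       # moderate GC, no TTTT
  list(spacer = spacer,
       genome = genome_from_strings(c(
         chrA = paste0(bg(200), spacer, "AGG", bg(200)),
         chrB = paste0(bg(100), naive_revcomp(paste0(spacer, "TGG")),
                       bg(100)))))
}

# Synthetic stats-only manifest: n_genes x guides_per_gene targeting
# guides plus n_controls controls, with a gene map and truth lfc.
stats_fixture <- function(n_genes, guides_per_gene, n_controls,
                          ess_genes = character(0), ess_lfc = -2) {
  gids <- paste0("G", seq_len(n_genes))
  man <- data.frame(
    guide_id = c(paste0("g", seq_len(n_genes * guides_per_gene)),
                 paste0("ctl", seq_len(n_controls))),
    spacer = "", category = "x", stringsAsFactors = FALSE)
  gene_map <- stats::setNames(
    c(rep(gids, each = guides_per_gene), rep("", n_controls)),
    man$guide_id)
  truth <- stats::setNames(
    ifelse(gene_map[man$guide_id] %in% ess_genes, ess_lfc, 0),
    man$guide_id)
  list(manifest = man, gene_map = gene_map, truth = truth,
       controls = paste0("ctl", seq_len(n_controls)), genes = gids)
}
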