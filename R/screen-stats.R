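#' Control-guide median-of-ratios normalization
#'
#' Size factor for sample j = median over control sgRNAs i of
#' count(i, j) / geomean_i, where geomean_i is the geometric mean of
#' control i's counts across samples with zeros excluded from the
#' geometric-mean set. Normalized count = raw / size factor, so after
#' normalization the median control ratio to the reference is 1.
#'
#' @param counts Integer matrix, sgRNAs x samples (rownames = guide
#'   ids).
#' @param control_ids Character vector of control guide ids.
#' @return List of class `pg_norm_counts`: `norm` (numeric matrix),
#'   `size_factors`, `control_ids`.
#' @export
normalize_control <- function(counts, control_ids) {
  ctrl <- intersect(control_ids, rownames(counts))
  if (length(ctrl) < 2) stop("need at least 2 control sgRNAs in the matrix")
  cm <- counts[ctrl, , drop = FALSE]
  if (any(colSums(cm) == 0))
    stop("all control sgRNAs are zero in sample(s): ",
         paste(colnames(cm)[colSums(cm) == 0], collapse = ", "))
  geo <- apply(cm, 1, function(x) {
    x <- x[x > 0]
    if (!length(x)) return(NA_real_)
    exp(mean(log(x)))
  })
  ratios <- cm / geo
  sf <- apply(ratios, 2, function(r) stats::median(r, na.rm = TRUE))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("non-positive control size factor")
  structure(list(norm = sweep(counts, 2, sf, "/"),
                 size_factors = sf, control_ids = ctrl),
            class = "pg_norm_counts")
}

#' Per-sgRNA log2 fold changes and control-null p-values
#'
#' For each replicate pair (D0, D21 matched by position),
#' lfc_r = log2((norm_d21 + pc) / (norm_d0 + pc)); the guide lfc is the
#' mean across replicates. The depletion p-value is the add-one
#' empirical percentile against the control guides' lfc distribution:
#' p = (1 + #controls with lfc <= guide lfc) / (n_controls + 1).
#'
#' @param nc `pg_norm_counts` from [normalize_control()].
#' @param d0_samples,d21_samples Sample names, paired by index.
#' @param gene_map Named character vector: guide id -> gene id (controls
#'   may be absent or map to "").
#' @param pseudocount Added to normalized counts (default 1).
#' @return Data frame: sgrna, gene_id, lfc, p (one-sided depletion).
#' @export
sgrna_stats <- function(nc, d0_samples, d21_samples, gene_map,
                        pseudocount = 1) {
  stopifnot(inherits(nc, "pg_norm_counts"), pseudocount > 0)
  if (length(d0_samples) != length(d21_samples))
    stop("mismatched replicate counts between D0 and D21")
  m <- nc$norm
  lfc_reps <- vapply(seq_along(d0_samples), function(r) {
    log2((m[, d21_samples[r]] + pseudocount) /
           (m[, d0_samples[r]] + pseudocount))
  }, numeric(nrow(m)))
  lfc <- rowMeans(lfc_reps)
  ctrl_lfc <- lfc[nc$control_ids]
  nctl <- length(ctrl_lfc)
  p <- vapply(lfc, function(x) (1 + sum(ctrl_lfc <= x)) / (nctl + 1),
              numeric(1))
  gid <- gene_map[rownames(m)]
  gid[is.na(gid)] <- ""
  data.frame(sgrna = rownames(m), gene_id = unname(gid),
             lfc = unname(lfc), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Second-best gene-level log2 fold change
#'
#' Represents a gene by the second most extreme sgRNA fold change in the
#' selection direction (second most negative for depletion), which is
#' robust to a single outlier guide. A single-guide gene returns its own
#' lfc.
#'
#' @param lfcs Numeric vector of a gene's sgRNA lfcs.
#' @param direction "negative" (depletion) or "positive".
#' @return Scalar lfc.
#' @export
gene_secondbest_lfc <- function(lfcs, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (!length(lfcs)) stop("no sgRNA lfcs")
  s <- sort(lfcs, decreasing = (direction == "positive"))
  if (length(s) == 1) s[1] else s[2]
}

# rho statistic of alpha-RRA: minimum Beta order-statistic probability
# over the gene's top-of-list normalized ranks. Returns c(rho, u1);
# u1 (the best normalized rank) breaks ties between genes sharing
# rho = 1 (no guide in the top alpha fraction), which keeps the
# permutation p-value continuous under the null instead of leaving an
# atom at p = 1.
rra_rho <- function(ranks, n_total, alpha) {
  k <- length(ranks)
  u <- sort(ranks) / n_total
  contrib <- which(u <= alpha)
  rho <- if (!length(contrib)) 1
         else min(stats::pbeta(u[contrib], contrib, k - contrib + 1))
  c(rho = rho, u1 = u[1])
}

rra_less_equal <- function(null_mat, rho, u1) {
  null_mat[, 1] < rho | (null_mat[, 1] == rho & null_mat[, 2] <= u1)
}

# permutation null of (rho, u1) for genes with k guides among n_total
# ranks; rows = permutations
rra_null_rhos <- function(k, n_total, alpha, n_permutations) {
  t(vapply(seq_len(n_permutations), function(i)
    rra_rho(sample.int(n_total, k), n_total, alpha), numeric(2)))
}

#' Permutation-based alpha-RRA gene test
#'
#' Given the (tie-free) ranks of a gene's k sgRNAs among `n_total`
#' ranked sgRNAs, computes the alpha-RRA score
#' rho = min over contributing order statistics u_(j) <= alpha of
#' BetaCDF(u_(j); j, k - j + 1), and a permutation p-value
#' p = (1 + #permuted size-k rank sets with rho' <= rho) /
#' (n_permutations + 1).
#'
#' @param ranks Integer ranks (1 = most depleted) of the gene's sgRNAs.
#' @param n_total Total number of ranked sgRNAs.
#' @param alpha Top-fraction cutoff on normalized ranks (default 0.05).
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Optional RNG seed for the permutations.
#' @param null_rhos Optional precomputed null matrix for this k from
#'   the internal permutation sampler (shared across genes for speed).
#' @return List with `rho` and `p`.
#' @details Genes with no guide in the top alpha fraction share
#'   rho = 1; their permutation comparison is tie-broken by the best
#'   normalized rank u_(1), so null p-values stay uniform instead of
#'   piling up at 1.
#' @export
rra_gene_test <- function(ranks, n_total, alpha = 0.05,
                          n_permutations = 1000L, seed = NULL,
                          null_rhos = NULL) {
  k <- length(ranks)
  if (k == 0) stop("gene has no sgRNA ranks")
  stopifnot(n_permutations >= 100, all(ranks >= 1), all(ranks <= n_total),
            !anyDuplicated(ranks))
  s <- rra_rho(ranks, n_total, alpha)
  if (is.null(null_rhos)) {
    if (!is.null(seed)) set.seed(seed)
    null_rhos <- rra_null_rhos(k, n_total, alpha, n_permutations)
  }
  p <- (1 + sum(rra_less_equal(null_rhos, s[["rho"]], s[["u1"]]))) /
    (nrow(null_rhos) + 1)
  list(rho = unname(s[["rho"]]), p = p)
}

#' Benjamini-Hochberg q-values
#' @param pvalues Numeric vector of p-values.
#' @return Step-up q-values (monotone-enforced).
#' @export
bh_fdr <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Call screen hits at the standard thresholds
#'
#' A gene is a negative-selection hit iff p < `p_max`, q < `fdr_max`,
#' and second-best lfc <= `lfc_max` (default -log2(1.5)); positive
#' selection is symmetric with lfc >= +log2(1.5).
#'
#' @param gene_stats Data frame with columns p, q, lfc.
#' @param p_max,fdr_max P-value / FDR thresholds (defaults 0.05, 0.25).
#' @param lfc_max Fold-change threshold (default -log2(1.5)).
#' @param direction "negative" or "positive".
#' @return Logical hit vector aligned with `gene_stats` rows.
#' @export
call_hits <- function(gene_stats, p_max = 0.05, fdr_max = 0.25,
                      lfc_max = -log2(1.5),
                      direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  lfc_ok <- if (direction == "negative") gene_stats$lfc <= lfc_max
            else gene_stats$lfc >= abs(lfc_max)
  gene_stats$p < p_max & gene_stats$q < fdr_max & lfc_ok
}

#' Exclude hits with a bidirectional-promoter neighbor
#'
#' CRISPRi repression spreads over promoter-proximal chromatin, so a
#' gene whose TSS lies within `max_distance` (default 1 kb, inclusive)
#' of any other gene's TSS can score as a false positive. Such hits are
#' flagged `excluded_bidirectional` and removed from the hit set. TSS
#' distance is the minimum over CAGE-assigned and annotated TSS pairs
#' ([tss_distance()]).
#'
#' @param gene_stats Gene-stats data frame with `gene_id` and `hit`.
#' @param annotation `pg_annotation` (all genes, not only tested ones).
#' @param assignments Output of [assign_tss()].
#' @param max_distance Exclusion distance in bp (default 1000).
#' @return `gene_stats` with `excluded_bidirectional` and updated `hit`.
#' @export
bidirectional_filter <- function(gene_stats, annotation, assignments,
                                 max_distance = 1000L) {
  gene_stats$excluded_bidirectional <- FALSE
  g <- annotation$genes
  for (i in which(gene_stats$hit)) {
    gid <- gene_stats$gene_id[i]
    same_chr <- g$gene_id[g$chrom == g$chrom[g$gene_id == gid] &
                            g$gene_id != gid]
    d <- vapply(same_chr, function(o)
      tss_distance(gid, o, annotation, assignments), numeric(1))
    if (length(d) && min(d) <= max_distance)
      gene_stats$excluded_bidirectional[i] <- TRUE
  }
  gene_stats$hit <- gene_stats$hit & !gene_stats$excluded_bidirectional
  gene_stats
}

#' Fit the pooled CRISPRi screen model
#'
#' The fitting function for the whole screen analysis: control-guide
#' normalization, per-sgRNA log2 fold changes and control-null
#' p-values, alpha-RRA gene scores with permutation p-values,
#' Benjamini-Hochberg FDR, second-best gene lfc, hit calls, and (when
#' annotation is supplied) the bidirectional-promoter exclusion.
#'
#' @param counts Integer matrix, sgRNAs x samples.
#' @param samples Sample sheet data frame with columns sample,
#'   timepoint ("D0"/"D21"), replicate.
#' @param gene_map Named character vector guide id -> gene id.
#' @param control_ids Control guide ids (the negative-control list).
#' @param alpha alpha-RRA top-fraction cutoff. The default (NULL) is
#'   adaptive: the fraction of tested sgRNAs significantly depleted
#'   against the control null (p < 0.05), floored at 0.05, so that in
#'   a screen with many truly depleted guides every affected gene can
#'   contribute its guides to the rank aggregation.
#' @param n_permutations Permutations for the gene test (default 1000).
#' @param pseudocount Pseudocount on normalized counts (default 1).
#' @param p_max,fdr_max,lfc_max Hit thresholds (defaults 0.05, 0.25,
#'   -log2(1.5)).
#' @param annotation,assignments Optional; enables the bidirectional
#'   filter.
#' @param max_tss_distance Bidirectional exclusion distance (1000 bp).
#' @param seed RNG seed for the permutation null.
#' @return Object of class `crispri_screen` with components `sgrna`
#'   (per-guide stats), `genes` (per-gene stats incl. `hit`), `norm`,
#'   and `params`.
#' @export
crispri_screen <- function(counts, samples, gene_map, control_ids,
                           alpha = NULL, n_permutations = 1000L,
                           pseudocount = 1, p_max = 0.05,
                           fdr_max = 0.25, lfc_max = -log2(1.5),
                           annotation = NULL, assignments = NULL,
                           max_tss_distance = 1000L, seed = 1L) {
  stopifnot(all(c("sample", "timepoint", "replicate") %in% names(samples)))
  d0 <- samples$sample[samples$timepoint == "D0"][
    order(samples$replicate[samples$timepoint == "D0"])]
  d21 <- samples$sample[samples$timepoint == "D21"][
    order(samples$replicate[samples$timepoint == "D21"])]
  nc <- normalize_control(counts, control_ids)
  st <- sgrna_stats(nc, d0, d21, gene_map, pseudocount)
  tested <- st[!(st$sgrna %in% nc$control_ids) & nzchar(st$gene_id), ,
               drop = FALSE]
  # tie-free depletion ranks: by lfc, ties broken by guide id
  ord <- order(tested$lfc, tested$sgrna)
  tested$rank <- NA_integer_
  tested$rank[ord] <- seq_len(nrow(tested))
  n_total <- nrow(tested)
  if (is.null(alpha))
    alpha <- max(0.05, mean(tested$p < 0.05))

  set.seed(seed)
  by_gene <- split(tested, tested$gene_id)
  ks <- sort(unique(lengths(lapply(by_gene, function(g) g$rank))))
  nulls <- lapply(ks, function(k)
    rra_null_rhos(k, n_total, alpha, n_permutations))
  names(nulls) <- as.character(ks)

  genes <- do.call(rbind, lapply(names(by_gene), function(gid) {
    g <- by_gene[[gid]]
    k <- nrow(g)
    res <- rra_gene_test(g$rank, n_total, alpha, n_permutations,
                         null_rhos = nulls[[as.character(k)]])
    data.frame(gene_id = gid, n_sgrnas = k, rho = res$rho, p = res$p,
               lfc = gene_secondbest_lfc(g$lfc, "negative"),
               stringsAsFactors = FALSE)
  }))
  genes$q <- bh_fdr(genes$p)
  genes$hit <- call_hits(genes, p_max, fdr_max, lfc_max, "negative")
  if (!is.null(annotation) && !is.null(assignments))
    genes <- bidirectional_filter(genes, annotation, assignments,
                                  max_tss_distance)
  else
    genes$excluded_bidirectional <- FALSE
  rownames(genes) <- NULL
  structure(list(sgrna = st, genes = genes, norm = nc,
                 params = list(alpha = alpha,
                               n_permutations = n_permutations,
                               pseudocount = pseudocount, p_max = p_max,
                               fdr_max = fdr_max, lfc_max = lfc_max,
                               seed = seed, d0 = d0, d21 = d21)),
            class = "crispri_screen")
}

#' @export
print.crispri_screen <- function(x, ...) {
  cat("CRISPRi screen fit\n")
  cat("  sgRNAs:", nrow(x$sgrna),
      "(", length(x$norm$control_ids), "controls )\n")
  cat("  genes tested:", nrow(x$genes), "\n")
  cat("  negative-selection hits:", sum(x$genes$hit),
      "(", sum(x$genes$excluded_bidirectional),
      "excluded as bidirectional )\n")
  invisible(x)
}

#' @method summary crispri_screen
#' @export
summary.crispri_screen <- function(object, ...) {
  g <- object$genes
  out <- list(
    n_sgrnas = nrow(object$sgrna),
    n_genes = nrow(g),
    n_hits = sum(g$hit),
    n_excluded_bidirectional = sum(g$excluded_bidirectional),
    size_factors = object$norm$size_factors,
    top_hits = utils::head(g[order(g$p, g$lfc), ], 10)
  )
  class(out) <- "summary.crispri_screen"
  out
}

#' @export
print.summary.crispri_screen <- function(x, ...) {
  cat("CRISPRi screen summary:", x$n_genes, "genes,", x$n_sgrnas,
      "sgRNAs\n")
  cat("hits:", x$n_hits, "| excluded (bidirectional):",
      x$n_excluded_bidirectional, "\n")
  cat("size factors:\n")
  print(round(x$size_factors, 3))
  cat("top genes by p:\n")
  print(x$top_hits, row.names = FALSE)
  invisible(x)
}

#' @method plot crispri_screen
#' @export
plot.crispri_screen <- function(x, ...) {
  g <- x$genes
  plot(g$lfc, -log10(g$p),
       xlab = expression(log[2] ~ "fold change (second-best sgRNA)"),
       ylab = expression(-log[10] ~ "permutation p"),
       pch = 19, col = ifelse(g$hit, "red",
                              ifelse(g$excluded_bidirectional,
                                     "orange", "grey40")), ...)
  abline(h = -log10(x$params$p_max), v = x$params$lfc_max, lty = 2)
  invisible(x)
}

#' Extract called hits from a screen fit
#' @param object `crispri_screen` fit.
#' @return Data frame of hit genes.
#' @export
screen_hits <- function(object) {
  stopifnot(inherits(object, "crispri_screen"))
  object$genes[object$genes$hit, , drop = FALSE]
}
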