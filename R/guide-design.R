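#' Linker sequences used to build library oligos
#'
#' Every oligo in the manifest is `linker5 + spacer + linker3`, exactly.
#' @export
pg_linkers <- list(
  linker5 = "CTTTATATATCTTGTGGAAAGGACGAAACACCG",
  linker3 = "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCG"
)

#' Transparent linear position-nucleotide score model
#'
#' Score = intercept + sum over spacer positions of `weights[base, pos]`.
#' Higher is better. This is the default, fully transparent stand-in for
#' an on-target efficiency scorer; externally computed scores can be
#' supplied instead via [score_table_model()].
#'
#' @param weights 4 x 20 numeric matrix, rownames A,C,G,T.
#' @param intercept Scalar added to every score.
#' @export
linear_score_model <- function(weights = matrix(0, 4, 20,
                                                dimnames = list(c("A", "C", "G", "T"), NULL)),
                               intercept = 0) {
  stopifnot(nrow(weights) == 4, ncol(weights) == 20,
            identical(rownames(weights), c("A", "C", "G", "T")))
  structure(list(weights = weights, intercept = intercept),
            class = c("pg_linear_score", "pg_score_model"))
}

#' Imported spacer-to-score lookup model
#' @param table Named numeric vector, names are 20-nt spacers.
#' @export
score_table_model <- function(table) {
  stopifnot(is.numeric(table), !is.null(names(table)))
  structure(list(table = table),
            class = c("pg_table_score", "pg_score_model"))
}

#' Score guide candidates
#' @param candidates Candidate data frame with a `spacer` column.
#' @param model A score model from [linear_score_model()] or
#'   [score_table_model()].
#' @return `candidates` with a numeric `score` column.
#' @export
score_candidates <- function(candidates, model) {
  if (inherits(model, "pg_table_score")) {
    miss <- setdiff(unique(candidates$spacer), names(model$table))
    if (length(miss))
      stop("spacer(s) absent from imported score table: ",
           paste(utils::head(miss, 3), collapse = ", "))
    candidates$score <- unname(model$table[candidates$spacer])
    return(candidates)
  }
  stopifnot(inherits(model, "pg_linear_score"))
  mat <- do.call(rbind, strsplit(candidates$spacer, ""))
  sc <- rep(model$intercept, nrow(candidates))
  for (j in seq_len(20L)) {
    w <- model$weights[, j]
    sc <- sc + ifelse(mat[, j] %in% names(w), w[mat[, j]], 0)
  }
  candidates$score <- as.numeric(sc)
  candidates
}

#' Apply the spacer quality filter cascade
#'
#' Flags (a candidate passes iff no flag is set):
#' \itemize{
#'   \item `multi_mapping`: the 20-nt spacer immediately followed by NGG
#'     occurs at more than one genomic site (both strands).
#'   \item `has_N`: any N in the spacer.
#'   \item `poly_T`: four or more consecutive T (more than three).
#'   \item `gc_extreme`: GC fraction >= 0.75 or < 0.10.
#' }
#'
#' @param candidates Candidate data frame.
#' @param genome `pg_genome` used for the genome-wide uniqueness census,
#'   or a precomputed census (`table` of spacer occurrence counts).
#' @return `candidates` with logical flag columns added.
#' @export
filter_candidates <- function(candidates, genome) {
  census <- if (inherits(genome, "pg_genome")) protospacer_census(genome)
            else genome
  occ <- as.integer(census[candidates$spacer])
  occ[is.na(occ)] <- 0L
  candidates$multi_mapping <- occ > 1L
  candidates$has_N <- grepl("N", candidates$spacer, fixed = TRUE)
  candidates$poly_T <- has_polyT(candidates$spacer)
  gc <- gc_fraction(candidates$spacer)
  candidates$gc_extreme <- gc >= 0.75 | gc < 0.10
  candidates
}

guide_passes <- function(candidates) {
  !(candidates$multi_mapping | candidates$has_N | candidates$poly_T |
      candidates$gc_extreme)
}

#' Remove near-duplicate guides within 4 bp
#'
#' Within each maximal chain of passing candidates whose interval start
#' coordinates are pairwise-linked by |delta start| <= 4 bp (same
#' chromosome, either strand), only the highest-scoring candidate is
#' kept; ties keep the leftmost start. The result is independent of the
#' input row order, and the operation is idempotent.
#'
#' @param candidates Filtered, scored candidate data frame.
#' @param max_gap Chain-link distance in bp (default 4).
#' @return `candidates` with a logical `dedup_removed` column.
#' @export
dedup_nearby <- function(candidates, max_gap = 4L) {
  candidates$dedup_removed <- FALSE
  pass <- guide_passes(candidates)
  idx <- which(pass)
  if (length(idx) < 2L) return(candidates)
  key <- paste(candidates$chrom[idx], candidates$start[idx],
               candidates$strand[idx])
  first <- !duplicated(key)           # distinct genomic sites only
  gidx <- idx[first]
  ord <- gidx[order(candidates$chrom[gidx], candidates$start[gidx])]
  ch <- candidates$chrom[ord]; st <- candidates$start[ord]
  newchain <- c(TRUE, ch[-1] != ch[-length(ch)] | diff(st) > max_gap)
  chain <- cumsum(newchain)
  keep_site <- logical(length(ord))
  for (cid in unique(chain)) {
    members <- ord[chain == cid]
    sc <- candidates$score[members]
    best <- members[order(-sc, candidates$start[members],
                          candidates$strand[members])][1]
    keep_site[ord %in% members] <- FALSE
    keep_site[ord == best] <- TRUE
  }
  removed_sites <- paste(candidates$chrom[ord], candidates$start[ord],
                         candidates$strand[ord])[!keep_site]
  all_key <- paste(candidates$chrom, candidates$start, candidates$strand)
  candidates$dedup_removed <- pass & all_key %in% removed_sites
  candidates
}

#' Select up to `max_per_gene` guides per gene
#'
#' Passing, non-deduplicated candidates of each gene are ordered by the
#' TIEScore of their TSS cluster (descending; CAGE clusters with more
#' initiation evidence are preferred), then by score (descending), then
#' by genomic start (ascending), and the first `max_per_gene` are kept.
#'
#' @param candidates Candidate data frame carrying `gene_id` and
#'   `tie_score` columns (filter flags set, deduplicated).
#' @param max_per_gene Per-gene cap (default 10).
#' @return Selected candidates; attribute `n_designed` gives the
#'   per-gene selected counts (used by the >= 3-guide inclusion rule).
#' @export
select_per_gene <- function(candidates, max_per_gene = 10L) {
  stopifnot(max_per_gene >= 1)
  ok <- guide_passes(candidates) & !candidates$dedup_removed
  cc <- candidates[ok, , drop = FALSE]
  # a guide reachable from several TSSs of one gene counts once,
  # attributed to the best-evidence cluster
  cc <- cc[order(cc$gene_id, -cc$tie_score, -cc$score, cc$start), , drop = FALSE]
  site <- paste(cc$gene_id, cc$chrom, cc$start, cc$strand)
  cc <- cc[!duplicated(site), , drop = FALSE]
  sel <- do.call(rbind, lapply(split(cc, cc$gene_id), function(g) {
    utils::head(g, max_per_gene)
  }))
  rownames(sel) <- NULL
  n <- table(sel$gene_id)
  attr(sel, "n_designed") <- stats::setNames(as.integer(n), names(n))
  sel
}

#' Design guides for every gene from its assigned TSSs
#'
#' Runs the whole cascade: 500-bp windows around each assigned TSS,
#' protospacer scan, scoring, quality filters, 4-bp deduplication, and
#' per-gene selection.
#'
#' @param genome `pg_genome`.
#' @param annotation `pg_annotation`.
#' @param assignments Output of [assign_tss()].
#' @param score_model Score model (default all-zero linear model).
#' @param max_per_gene Per-gene cap (default 10).
#' @param window_half Window half-width in bp (default 250).
#' @return Selected candidate data frame (see [select_per_gene()]).
#' @export
design_guides <- function(genome, annotation, assignments,
                          score_model = linear_score_model(),
                          max_per_gene = 10L, window_half = 250L) {
  chrom_len <- stats::setNames(nchar(unclass(genome)), names(genome))
  gene_chrom <- stats::setNames(annotation$genes$chrom,
                                annotation$genes$gene_id)
  rows <- vector("list", nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    ch <- gene_chrom[[a$gene_id]]
    win <- design_window(a$tss, chrom_len[[ch]], half = window_half)
    cand <- scan_protospacers(genome, chrom = ch,
                              start = win[["start"]], end = win[["end"]])
    if (nrow(cand) == 0) next
    cand$gene_id <- a$gene_id
    cand$cluster_id <- a$cluster_id
    cand$tss_source <- a$source
    cand$tie_score <- a$tie_score
    rows[[i]] <- cand
  }
  cand <- do.call(rbind, rows)
  if (is.null(cand) || nrow(cand) == 0)
    stop("no protospacers found in any design window")
  cand <- score_candidates(cand, score_model)
  cand <- filter_candidates(cand, genome)
  cand <- dedup_nearby(cand)
  select_per_gene(cand, max_per_gene = max_per_gene)
}

#' Assemble the library manifest
#'
#' One record per distinct spacer; a spacer lying in the design windows
#' of several genes carries all gene annotations on one record. Oligos
#' are `linker5 + spacer + linker3`, bit-exactly.
#'
#' @param selected Output of [design_guides()]/[select_per_gene()].
#' @param annotation `pg_annotation` (for gene biotypes).
#' @param controls Optional data frame with columns guide_id, spacer,
#'   category (e.g. non_targeting, AAVS1, positive_control, auxiliary).
#' @return Manifest data frame with columns guide_id, spacer, category,
#'   gene_ids, chrom, start, end, strand, pam, score, flags, oligo.
#' @export
assemble_library <- function(selected, annotation, controls = NULL) {
  bt <- stats::setNames(annotation$genes$biotype, annotation$genes$gene_id)
  sp <- split(seq_len(nrow(selected)), selected$spacer)
  recs <- lapply(sp, function(ii) {
    r <- selected[ii[1], ]
    gids <- sort(unique(selected$gene_id[ii]))
    cat <- if (any(grepl("pseudogene", bt[gids]))) "pseudogene" else "parent"
    data.frame(guide_id = paste0("sg_", gids[1], "_", r$start),
               spacer = r$spacer, category = cat,
               gene_ids = paste(gids, collapse = ","),
               chrom = r$chrom, start = r$start, end = r$end,
               strand = r$strand, pam = r$pam, score = r$score,
               flags = "", stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, recs)
  if (!is.null(controls)) {
    stopifnot(all(c("guide_id", "spacer", "category") %in% names(controls)))
    ctrl <- data.frame(guide_id = controls$guide_id,
                       spacer = controls$spacer,
                       category = controls$category,
                       gene_ids = "", chrom = "", start = NA_integer_,
                       end = NA_integer_, strand = "", pam = "",
                       score = NA_real_, flags = "",
                       stringsAsFactors = FALSE)
    man <- rbind(man, ctrl)
  }
  if (anyDuplicated(man$guide_id))
    stop("duplicate guide_id in manifest: ",
         man$guide_id[duplicated(man$guide_id)][1])
  man$oligo <- paste0(pg_linkers$linker5, man$spacer, pg_linkers$linker3)
  rownames(man) <- NULL
  man
}

#' Write / read a library manifest as TSV
#' @param manifest Manifest data frame.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = c(guide_id = "character",
                                   spacer = "character",
                                   category = "character",
                                   gene_ids = "character",
                                   chrom = "character",
                                   start = "integer", end = "integer",
                                   strand = "character",
                                   pam = "character", score = "numeric",
                                   flags = "character",
                                   oligo = "character"),
                    fill = TRUE)
}

#' Tally manifest records by category
#'
#' @param manifest Manifest data frame.
#' @return Data frame with columns category, n_guides, n_genes (distinct
#'   gene ids annotated on records of that category), plus a `total` row
#'   attribute `total_guides`.
#' @export
manifest_composition <- function(manifest) {
  sp <- split(manifest, manifest$category)
  out <- do.call(rbind, lapply(names(sp), function(cat) {
    m <- sp[[cat]]
    genes <- unique(unlist(strsplit(m$gene_ids[nzchar(m$gene_ids)], ",")))
    data.frame(category = cat, n_guides = nrow(m),
               n_genes = length(genes), stringsAsFactors = FALSE)
  }))
  attr(out, "total_guides") <- nrow(manifest)
  out
}
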