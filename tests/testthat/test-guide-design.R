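test_that("protospacer scan reports NGG sites on both strands only", {
  lm <- landmark_genome()
  sites <- scan_protospacers(lm$genome)
  # the planted + strand site on chrA
  plus <- sites[sites$chrom == "chrA" & sites$start == 201, ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$spacer, lm$spacer)
  expect_equal(plus$pam, "AGG")
  expect_equal(plus$strand, "+")
  # the planted - strand site on chrB (revcomp of spacer+TGG)
  minus <- sites[sites$chrom == "chrB" & sites$spacer == lm$spacer, ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$strand, "-")
  expect_equal(minus$pam, "TGG")
  # a 20-mer followed by AAG is not a site
  g2 <- genome_from_strings(c(c1 = paste0(strrep("A", 5), lm$spacer, "AAG",
                                          strrep("A", 5))))
  expect_false(lm$spacer %in% scan_protospacers(g2)$spacer)
})

test_that("genome re-slicing reproduces every candidate's spacer and PAM", {
  fx <- make_toy_genome(fixture_config(n_pairs = 3, seed = 5))
  sites <- scan_protospacers(fx$genome)
  seqs <- unclass(fx$genome)
  for (i in sample(nrow(sites), 50)) {
    s <- sites[i, ]
    slice <- substr(seqs[[s$chrom]], s$start, s$end)
    pam_slice <- if (s$strand == "+")
      substr(seqs[[s$chrom]], s$end + 1, s$end + 3)
    else substr(seqs[[s$chrom]], s$start - 3, s$start - 1)
    if (s$strand == "+") {
      expect_equal(slice, s$spacer)
      expect_equal(pam_slice, s$pam)
    } else {
      expect_equal(naive_revcomp(slice), s$spacer)
      expect_equal(naive_revcomp(pam_slice), s$pam)
    }
  }
})

test_that("scoring supports linear models and imported tables", {
  cand <- data.frame(spacer = c("ACGTACGTACGTACGTACGT",
                                "TTTTTTTTTTTTTTTTTTTT"),
                     stringsAsFactors = FALSE)
  expect_equal(score_candidates(cand, linear_score_model())$score, c(0, 0))
  w <- matrix(0, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
  w["A", 1] <- 0.5
  expect_equal(score_candidates(cand, linear_score_model(w))$score,
               c(0.5, 0))
  tbl <- score_table_model(c(ACGTACGTACGTACGTACGT = 0.73,
                             TTTTTTTTTTTTTTTTTTTT = -1))
  expect_equal(score_candidates(cand, tbl)$score, c(0.73, -1))
  expect_error(score_candidates(
    data.frame(spacer = "GGGGGGGGGGGGGGGGGGGG"), tbl),
    "GGGGGGGGGGGGGGGGGGGG")
})

test_that("the filter cascade flags exactly the rule boundaries", {
  sp <- c(
    polyT4   = "ACGTTTTACGTACGTACGTA",  # four consecutive T
    polyT3   = "ACGTTTACGTACGTACGTAC",  # only three -> passes
    gc75     = paste0(strrep("GC", 7), "G", "AAAAA"),       # GC 15/20
    gc10     = paste0("GC", strrep("AT", 9)),               # GC 2/20
    gc05     = paste0("G", strrep("AT", 9), "A"),           # GC 1/20
    withN    = "ACGTNCGTACGTACGTACGT")
  cand <- data.frame(spacer = unname(sp), stringsAsFactors = FALSE)
  census <- table(character(0))
  f <- filter_candidates(cand, census)
  expect_true(f$poly_T[1]); expect_false(f$poly_T[2])
  expect_true(f$gc_extreme[3])    # exactly 0.75 flagged
  expect_false(f$gc_extreme[4])   # exactly 0.10 kept
  expect_true(f$gc_extreme[5])    # below 0.10 flagged
  expect_true(f$has_N[6])
})

test_that("multi-mapping is flagged iff the spacer+NGG site is non-unique", {
  set.seed(77)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  dup <- "CATGACCATAGACCATAGAC"
  uniq <- "GTACCGATTGACCGTATGAC"
  g <- genome_from_strings(c(
    c1 = paste0(bg(80), dup, "AGG", bg(50), dup, "TGG", bg(80)),
    c2 = paste0(bg(60), uniq, "CGG", bg(60))))
  cand <- data.frame(spacer = c(dup, uniq), stringsAsFactors = FALSE)
  f <- filter_candidates(cand, g)
  expect_true(f$multi_mapping[1])
  expect_false(f$multi_mapping[2])
  # oracle: naive occurrence counts over every PAM-adjacent position
  expect_equal(nrow(naive_site_scan(unclass(g), dup, 0)), 2)
  expect_equal(nrow(naive_site_scan(unclass(g), uniq, 0)), 1)
  # a revcomp placement also counts as a second site
  g3 <- genome_from_strings(c(
    c1 = paste0(bg(40), uniq, "AGG", bg(40),
                naive_revcomp(paste0(uniq, "GGG")), bg(40))))
  f3 <- filter_candidates(data.frame(spacer = uniq), g3)
  expect_true(f3$multi_mapping[1])
})

dedup_frame <- function(starts, scores, strand = "+") {
  data.frame(spacer = strrep("A", 20), pam = "AGG", chrom = "c1",
             strand = strand, start = starts, end = starts + 19,
             score = scores, multi_mapping = FALSE, has_N = FALSE,
             poly_T = FALSE, gc_extreme = FALSE, stringsAsFactors = FALSE)
}

test_that("4-bp dedup keeps the best-scoring guide per chain", {
  d <- dedup_nearby(dedup_frame(c(100, 103), c(0.9, 0.4)))
  expect_equal(d$dedup_removed, c(FALSE, TRUE))
  d2 <- dedup_nearby(dedup_frame(c(100, 105), c(0.9, 0.4)))
  expect_equal(d2$dedup_removed, c(FALSE, FALSE))
  # equal scores: leftmost start wins
  d3 <- dedup_nearby(dedup_frame(c(104, 100), c(0.5, 0.5)))
  expect_equal(d3$dedup_removed[d3$start == 100], FALSE)
  expect_equal(d3$dedup_removed[d3$start == 104], TRUE)
  # chains extend transitively: 100-104-108 is one chain
  d4 <- dedup_nearby(dedup_frame(c(100, 104, 108), c(0.1, 0.9, 0.5)))
  expect_equal(d4$dedup_removed, c(TRUE, FALSE, TRUE))
  # flagged candidates do not participate
  f <- dedup_frame(c(100, 103), c(0.9, 0.4))
  f$poly_T[1] <- TRUE
  d5 <- dedup_nearby(f)
  expect_equal(d5$dedup_removed, c(FALSE, FALSE))
})

test_that("dedup is idempotent and input-order-invariant", {
  set.seed(31)
  f <- dedup_frame(sort(sample(1:300, 40)), runif(40))
  a <- dedup_nearby(f)
  expect_equal(dedup_nearby(a)$dedup_removed, a$dedup_removed)
  perm <- sample(nrow(f))
  b <- dedup_nearby(f[perm, ])
  expect_equal(b$dedup_removed[order(perm)], a$dedup_removed)
})

test_that("per-gene selection caps at 10 and prefers higher-TIEScore clusters", {
  base <- dedup_frame(seq(100, by = 30, length.out = 14),
                      seq(0.14, 0.01, by = -0.01))
  base$dedup_removed <- FALSE
  base$gene_id <- "G1"
  base$cluster_id <- c(rep("cHi", 6), rep("cLo", 8))
  base$tie_score <- c(rep(30, 6), rep(20, 8))
  sel <- select_per_gene(base, max_per_gene = 10)
  expect_equal(nrow(sel), 10)
  # all 6 from the tie 30 cluster, top 4 by score from the tie 20 cluster
  expect_equal(sum(sel$cluster_id == "cHi"), 6)
  lo <- base[base$cluster_id == "cLo", ]
  expect_setequal(sel$start[sel$cluster_id == "cLo"],
                  lo$start[order(-lo$score)][1:4])
  # 12 passing single-cluster candidates -> top 10 by score
  one <- dedup_frame(seq(1000, by = 30, length.out = 12), runif(12))
  one$dedup_removed <- FALSE; one$gene_id <- "G2"
  one$cluster_id <- "c"; one$tie_score <- 10
  sel2 <- select_per_gene(one, max_per_gene = 10)
  expect_equal(nrow(sel2), 10)
  expect_setequal(sel2$start, one$start[order(-one$score)][1:10])
  # a 2-guide gene is reported below the 3-sgRNA minimum
  two <- dedup_frame(c(5000, 5100), c(0.2, 0.1))
  two$dedup_removed <- FALSE; two$gene_id <- "G3"
  two$cluster_id <- "c"; two$tie_score <- 5
  n <- attr(select_per_gene(two), "n_designed")
  expect_equal(unname(n["G3"]), 2)
  expect_lt(n[["G3"]], 3)
})

test_that("manifest assembly builds exact oligos and merges shared spacers", {
  fx <- make_toy_genome(fixture_config(n_pairs = 2, seed = 9))
  asg <- assign_tss(fx$annotation, fx$cage)
  sel <- design_guides(fx$genome, fx$annotation, asg)
  ctrl <- data.frame(guide_id = c("NT1", "NT2"),
                     spacer = c("AAAACCCCGGGGAAAACCCC",
                                "CCCCAAAAGGGGCCCCAAAA"),
                     category = "non_targeting")
  man <- assemble_library(sel, fx$annotation, ctrl)
  expect_equal(man$oligo,
               paste0("CTTTATATATCTTGTGGAAAGGACGAAACACCG", man$spacer,
                      "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCG"))
  expect_equal(sum(man$category == "non_targeting"), 2)
  expect_equal(nrow(man), length(unique(man$spacer)))
  # duplicate guide ids are rejected
  bad <- rbind(ctrl, ctrl[1, ])
  expect_error(assemble_library(sel, fx$annotation, bad), "duplicate")
  # a spacer in two genes' windows gets one record with both annotations
  sel2 <- sel[1:2, ]
  sel2$spacer <- sel$spacer[1]
  sel2$gene_id <- c("GX", "GY")
  man2 <- assemble_library(sel2, fx$annotation)
  expect_equal(nrow(man2), 1)
  expect_equal(man2$gene_ids, "GX,GY")
  # manifest round-trips through TSV
  p <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(man, p)
  man_rt <- read_manifest(p)
  expect_equal(man_rt, man, ignore_attr = TRUE)
})

test_that("every designed guide passes all filters and respects the cap", {
  fx <- make_toy_genome(fixture_config(n_pairs = 4, seed = 3))
  asg <- assign_tss(fx$annotation, fx$cage)
  sel <- design_guides(fx$genome, fx$annotation, asg)
  expect_true(all(guide_passes <- !(sel$multi_mapping | sel$has_N |
                                      sel$poly_T | sel$gc_extreme |
                                      sel$dedup_removed)))
  expect_true(all(table(sel$gene_id) <= 10))
})
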