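gtf_lines <- function() c(
  'chr1\tx\tgene\t1001\t2000\t.\t+\t.\tgene_id "GA"; gene_type "protein_coding"; gene_name "GeneA";',
  'chr1\tx\ttranscript\t1001\t2000\t.\t+\t.\tgene_id "GA"; transcript_id "GA.t1"; gene_type "protein_coding";',
  'chr1\tx\tgene\t1001\t2000\t.\t-\t.\tgene_id "GB"; gene_type "processed_pseudogene"; parent_id "GA";',
  'chr1\tx\ttranscript\t1001\t2000\t.\t-\t.\tgene_id "GB"; transcript_id "GB.t1"; gene_type "processed_pseudogene";',
  'chr2\tx\tgene\t500\t900\t.\t+\t.\tgene_id "GC"; gene_type "TEC";',
  'chr2\tx\ttranscript\t500\t900\t.\t+\t.\tgene_id "GC"; transcript_id "GC.t1"; gene_type "TEC";'
)

test_that("GTF parsing sets strand-correct 5' ends and mapped biotypes", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf_lines(), p)
  ann <- read_annotation(p)
  expect_equal(nrow(ann$genes), 3)
  tx <- ann$transcripts
  expect_equal(tx$five_prime_end[tx$transcript_id == "GA.t1"], 1001)
  expect_equal(tx$five_prime_end[tx$transcript_id == "GB.t1"], 2000)
  bt <- setNames(ann$genes$biotype, ann$genes$gene_id)
  expect_equal(bt[["GA"]], "protein_coding")
  expect_equal(bt[["GB"]], "processed_pseudogene")
  expect_equal(bt[["GC"]], "other")
  expect_equal(ann$genes$parent_gene_id[ann$genes$gene_id == "GB"], "GA")
})

test_that("GTF records missing mandatory attributes fail with the line number", {
  p <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_lines()[1],
               'chr1\tx\tgene\t10\t20\t.\t+\t.\tgene_name "Broken";'), p)
  expect_error(read_annotation(p), "line 2.*gene_id")
  writeLines(c('# a header comment',
               'chr1\tx\tgene\t10\t20\t.\t+\t.\tgene_id "X";'), p)
  expect_error(read_annotation(p), "line 2.*gene_type")
})

test_that("CAGE BED6+1 parsing converts coordinates and defaults the summit", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t150\tc1\t0\t+\t32.5",
               "chr1\t50\t70\tc0\t0\t+\t12"), p)
  cl <- read_cage_clusters(p)
  # sorted by start; BED [100,150) midpoint 125 (0-based) = 126 (1-based)
  expect_equal(cl$cluster_id, c("c0", "c1"))
  expect_equal(cl$start[2], 101)
  expect_equal(cl$end[2], 150)
  expect_equal(cl$summit[2], 126)
  expect_equal(cl$tie_score[2], 32.5)
  writeLines("chr1\t100\t150\tc1\t0\t.\t5", p)
  expect_error(read_cage_clusters(p), "strand")
  writeLines("chr1\t150\t100\tc1\t0\t+\t5", p)
  expect_error(read_cage_clusters(p), "start")
})

test_that("annotation and CAGE fixtures round-trip through their writers", {
  fx <- make_toy_genome(fixture_config(n_pairs = 3, seed = 11))
  gtf <- withr::local_tempfile(fileext = ".gtf")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_annotation(fx$annotation, gtf)
  write_cage_clusters(fx$cage, bed)
  ann2 <- read_annotation(gtf)
  expect_equal(ann2$genes[order(ann2$genes$gene_id), ],
               fx$annotation$genes[order(fx$annotation$genes$gene_id), ],
               ignore_attr = TRUE)
  expect_equal(ann2$transcripts[order(ann2$transcripts$transcript_id), ],
               fx$annotation$transcripts[
                 order(fx$annotation$transcripts$transcript_id), ],
               ignore_attr = TRUE)
  cl2 <- read_cage_clusters(bed)
  expect_equal(cl2, fx$cage, ignore_attr = TRUE)
})

make_ann <- function(tss_list) {
  # tss_list: gene_id -> list(strand, tss, chrom)
  genes <- do.call(rbind, lapply(names(tss_list), function(g) {
    x <- tss_list[[g]]
    data.frame(gene_id = g, gene_name = g, biotype = "protein_coding",
               chrom = x$chrom, strand = x$strand,
               start = min(x$tss), end = max(x$tss) + 100,
               parent_gene_id = NA_character_, stringsAsFactors = FALSE)
  }))
  tx <- do.call(rbind, lapply(names(tss_list), function(g) {
    x <- tss_list[[g]]
    data.frame(transcript_id = paste0(g, ".t", seq_along(x$tss)),
               gene_id = g, chrom = x$chrom, strand = x$strand,
               start = ifelse(x$strand == "+", x$tss, x$tss - 100),
               end = ifelse(x$strand == "+", x$tss + 100, x$tss),
               five_prime_end = x$tss, stringsAsFactors = FALSE)
  }))
  structure(list(genes = genes, transcripts = tx), class = "pg_annotation")
}

cage_row <- function(id, summit, strand, tie, chrom = "chr1") {
  data.frame(cluster_id = id, chrom = chrom, strand = strand,
             start = summit - 10, end = summit + 9, summit = summit,
             tie_score = tie, stringsAsFactors = FALSE)
}

test_that("TSS assignment follows strand, offset, and TIEScore ordering", {
  ann <- make_ann(list(GA = list(strand = "+", tss = 1000, chrom = "chr1")))
  cl <- rbind(cage_row("c1", 950, "+", 35),   # 50 bp upstream
              cage_row("c2", 1010, "+", 20),
              cage_row("c3", 1000, "-", 99),  # opposite strand
              cage_row("c4", 1700, "+", 50))  # beyond max offset
  asg <- assign_tss(ann, cl, max_offset_bp = 500)
  expect_setequal(asg$cluster_id[asg$source == "cage"], c("c1", "c2"))
  # ranked by tie_score for the gene
  ga <- asg[asg$gene_id == "GA" & asg$source == "cage", ]
  expect_equal(ga$cluster_id, c("c1", "c2"))
  expect_equal(ga$tie_score, c(35, 20))
  # opposite strand cluster only -> annotated fallback
  asg2 <- assign_tss(ann, cl[3, , drop = FALSE])
  expect_equal(asg2$source, "annotated")
  expect_equal(asg2$tss, 1000)
  expect_equal(asg2$tie_score, 0)
  # order-independence of input record order
  asg3 <- assign_tss(ann, cl[sample(nrow(cl)), ])
  expect_equal(asg, asg3, ignore_attr = TRUE)
  # every cage assignment is within max_offset of a transcript 5' end
  fp <- ann$transcripts$five_prime_end
  for (i in which(asg$source == "cage"))
    expect_lte(min(abs(asg$tss[i] - fp)), 500)
})

test_that("TSS distance is the minimum over CAGE and annotated pairs", {
  ann <- make_ann(list(GA = list(strand = "+", tss = 1000, chrom = "chr1"),
                       GB = list(strand = "+", tss = 1800, chrom = "chr1"),
                       GC = list(strand = "+", tss = 500, chrom = "chr2")))
  # no CAGE: annotated distance
  asg0 <- assign_tss(ann, cage_row("cx", 99999, "+", 1))
  expect_equal(tss_distance("GA", "GB", ann, asg0), 800)
  # CAGE-assigned pair closer than annotated
  cl <- rbind(cage_row("ca", 1000, "+", 30), cage_row("cb", 1500, "+", 30))
  asg <- assign_tss(ann, cl, max_offset_bp = 400)
  expect_equal(tss_distance("GA", "GB", ann, asg), 500)
  expect_equal(tss_distance("GA", "GA", ann, asg), 0)
  expect_equal(tss_distance("GA", "GC", ann, asg), Inf)
  # symmetry and triangle inequality on a same-chromosome triple
  ann3 <- make_ann(list(A = list(strand = "+", tss = 100, chrom = "chr1"),
                        B = list(strand = "+", tss = 900, chrom = "chr1"),
                        C = list(strand = "+", tss = 2500, chrom = "chr1")))
  asg3 <- assign_tss(ann3, cage_row("c", 99999, "+", 1))
  dAB <- tss_distance("A", "B", ann3, asg3)
  dBC <- tss_distance("B", "C", ann3, asg3)
  dAC <- tss_distance("A", "C", ann3, asg3)
  expect_equal(dAB, tss_distance("B", "A", ann3, asg3))
  expect_lte(dAC, dAB + dBC)
})

test_that("design windows are 500 bp, centered, and clipped at ends", {
  w <- design_window(10000, 100000)
  expect_equal(unname(w), c(9750, 10249))
  expect_equal(w[["end"]] - w[["start"]] + 1, 500)
  wc <- design_window(100, 100000)
  expect_equal(unname(wc), c(1, 349))
  g <- genome_from_strings(c(chr = strrep("ACGT", 300)))
  wg <- design_window(600, nchar(unclass(g)[[1]]))
  seq <- substr(unclass(g)[[1]], wg[["start"]], wg[["end"]])
  expect_equal(nchar(seq), wg[["end"]] - wg[["start"]] + 1)
})
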