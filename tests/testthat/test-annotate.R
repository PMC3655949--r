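mk_markers <- function(pos, chrom = "1", p = NULL) {
  df <- data.frame(marker_id = sprintf("m%03d", seq_along(pos)), chrom = chrom,
                   pos = as.integer(pos), stringsAsFactors = FALSE)
  if (!is.null(p)) df$p_combined <- p
  df
}

test_that("intragenic assignment is half-open with an inclusive start", {
  genes <- gene_set(id = "g1", chrom = "1", start = 100L, end = 200L)
  # gene covers 1-based positions 101..200
  expect_equal(nrow(intragenic_hits(mk_markers(101), genes)), 1L)  # first base
  expect_equal(nrow(intragenic_hits(mk_markers(200), genes)), 1L)  # last base
  expect_equal(nrow(intragenic_hits(mk_markers(201), genes)), 0L)  # 1 bp past end
  expect_equal(nrow(intragenic_hits(mk_markers(100), genes)), 0L)
})

test_that("intragenic hits match the quadratic scan oracle on random fixtures", {
  set.seed(44)
  genes <- gene_set(id = sprintf("g%02d", 1:50), chrom = sample(1:3, 50, TRUE),
                    start = (s <- sample.int(1e6, 50)), end = s + sample.int(5e4, 50))
  mks <- mk_markers(sample.int(1.1e6, 1000), chrom = sample(1:3, 1000, TRUE))
  hits <- intragenic_hits(mks, genes)
  oracle <- do.call(rbind, lapply(seq_len(nrow(mks)), function(i) {
    inside <- genes$chrom == mks$chrom[i] & genes$start <= mks$pos[i] - 1 &
      mks$pos[i] - 1 < genes$end
    if (!any(inside)) return(NULL)
    data.frame(marker_id = mks$marker_id[i], gene_id = genes$id[inside])
  }))
  key <- function(d) sort(paste(d$marker_id, d$gene_id))
  expect_identical(key(hits), key(oracle))
})

test_that("peak clustering is single-linkage with the configured gap", {
  cl <- cluster_peaks(mk_markers(c(1e6, 1.4e6), p = c(0.1, 0.2)))
  expect_equal(nrow(cl), 1L)                      # 400 kb apart: one cluster
  cl2 <- cluster_peaks(mk_markers(c(1e6, 1.6e6), p = c(0.1, 0.2)))
  expect_equal(nrow(cl2), 2L)                     # 600 kb apart: two clusters
  expect_equal(cl$top_marker, "m001")
  set.seed(8)
  pos <- sort(sample.int(1e7, 60))
  cl3 <- cluster_peaks(mk_markers(pos, p = runif(60)), cluster_gap_bp = 2e5)
  # brute-force gap partition oracle
  brk <- cumsum(c(TRUE, diff(pos) > 2e5))
  expect_equal(nrow(cl3), max(brk))
  expect_equal(cl3$n_markers, unname(as.vector(table(brk))))
  # top member belongs to its cluster span
  expect_true(all(cl3$start <= cl3$end))
})

test_that("closest gene minimizes distance with deterministic tie-breaks", {
  genes <- gene_set(id = c("gB", "gA"), chrom = "1",
                    start = c(1000L, 3000L), end = c(2000L, 4000L))
  expect_equal(closest_gene(mk_markers(1500), genes)$distance, 0)
  # marker at 2500 (0-based 2499): 500 bp from both genes -> lower start wins
  res <- closest_gene(mk_markers(2500), genes)
  expect_equal(res$gene_id, "gB")
  expect_equal(res$distance, -500)                # upstream gene: negative
  res2 <- closest_gene(mk_markers(2600), genes)
  expect_equal(res2$gene_id, "gA")
  expect_gt(res2$distance, 0)
  expect_true(is.na(closest_gene(mk_markers(100, chrom = "9"), genes)$gene_id))
  set.seed(3)
  g2 <- gene_set(id = sprintf("g%02d", 1:30), chrom = "1",
                 start = (s <- sort(sample.int(1e6, 30))), end = s + 1000L)
  for (pos in sample.int(1.1e6, 25)) {
    got <- closest_gene(mk_markers(pos), g2)
    d <- vapply(seq_len(30), function(j) {
      p0 <- pos - 1
      if (p0 < g2$start[j]) g2$start[j] - p0
      else if (p0 >= g2$end[j]) p0 - g2$end[j] + 1 else 0L
    }, 0)
    expect_equal(abs(got$distance), min(d))
  }
})

test_that("LD windows capture overlapping genes and report their size", {
  cl <- cluster_peaks(mk_markers(5e5, p = 0.01))
  genes <- gene_set(id = c("in1", "edge", "out"), chrom = "1",
                    start = c(450000L, 600001L, 700000L),
                    end = c(460000L, 610000L, 710000L))
  res <- ld_window_genes(cl, genes, flank_bp = 100000L)
  expect_equal(res$windows$width, 200001L)        # singleton cluster window
  expect_true("in1" %in% res$hits$gene_id)
  expect_false("edge" %in% res$hits$gene_id)      # abuts the window, no overlap
  expect_false("out" %in% res$hits$gene_id)
})

test_that("strategy-1 hits are contained in strategy-3 windows", {
  set.seed(10)
  pos <- sort(sample.int(5e6, 40))
  mks <- mk_markers(pos, p = runif(40))
  genes <- gene_set(id = sprintf("g%02d", 1:25), chrom = "1",
                    start = (s <- sort(sample.int(5e6, 25))), end = s + 20000L)
  s1 <- intragenic_hits(mks, genes)
  cl <- cluster_peaks(mks)
  s3 <- ld_window_genes(cl, genes)
  expect_true(all(s1$gene_id %in% s3$hits$gene_id))
})

test_that("gene models round-trip through BED input", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tgeneA\t0\t+", "2\t500\t900\tgeneB\t0\t-"), bed)
  gs <- read_genes(bed)
  expect_equal(gs$start, c(100L, 500L))           # 0-based half-open preserved
  expect_equal(gs$end, c(200L, 900L))
  expect_equal(gs$name, c("geneA", "geneB"))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneA;Name=alpha",
               "1\tsrc\texon\t101\t150\t.\t+\t.\tID=exon1;Parent=geneA"), gff)
  gs2 <- read_genes(gff)
  expect_equal(nrow(gs2), 1L)                     # exon rows dropped
  expect_equal(gs2$start, 100L)                   # converted to 0-based
  expect_equal(gs2$end, 200L)
})
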