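test_that("count tables round-trip and enforce their contract", {
  x <- tiny_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(x, path)
  y <- read_counts(path, paste0(path, ".meta.tsv"))
  expect_identical(y$counts, x$counts)
  expect_identical(y$meta, x$meta)

  # sample missing from metadata, named in the error
  meta_bad <- x$meta[x$meta$sample != "s6", ]
  expect_error(count_matrix(x$counts, meta_bad), "s6")

  # negative count reported with coordinates
  m <- x$counts; m["g2", "s3"] <- -4
  expect_error(count_matrix(m, x$meta), "g2.*s3")
  m <- x$counts; m["g1", "s1"] <- 1.5
  expect_error(count_matrix(m, x$meta), "non-integer")

  expect_error(count_matrix(rbind(x$counts, g1 = x$counts[1, ]), x$meta),
               "duplicate")
})

test_that("DEG tables recompute status from thresholds and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcondition\ttimepoint\tlog2FC\tFDR",
               "g1\tWF\t14\t2.3\t0.001",
               "g2\tWF\t14\t0.9\t0.001",
               "g3\tWF\t14\t-1.2\t0.05"), path)
  d <- read_deg_table(path)
  expect_equal(d$status, c("up", "ns", "down"))

  writeLines(c("gene\tcondition\ttimepoint\tlog2FC\tFDR",
               "g1\tWF\t14\t2.3\t1.2"), path)
  expect_error(read_deg_table(path), "FDR")
  writeLines(c("gene\tcondition\ttimepoint\tlog2FC\tFDR",
               "g1\tWF\t14\tabc\t0.2"), path)
  expect_error(read_deg_table(path), "log2FC")

  # status always equals recomputation from (log2FC, fdr), property-wise
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    d <- deg_table(gene_id = paste0("g", 1:n), condition = "c",
                   timepoint = seq_len(n), log2FC = rnorm(n, 0, 2),
                   fdr = runif(n))
    expect_identical(d$status, call_deg_status(d$log2FC, d$fdr))
  }
})

test_that("BED and GFF3 coordinates unify to 1-based inclusive", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr8\t99\t200\tg1\t0\t+", bed)
  cat_bed <- read_gene_coords(bed, "bed")
  expect_equal(cat_bed$start, 100)
  expect_equal(cat_bed$end, 200)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr8\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1;family=PR-2"),
             gff)
  cat_gff <- read_gene_coords(gff, "gff3")
  expect_equal(cat_gff$start, 100)
  expect_equal(cat_gff$end, 200)
  expect_equal(cat_gff$family, "PR-2")

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr8\tsrc\tgene\t300\t200\t.\t+\t.\tID=g1"), bad)
  expect_error(read_gene_coords(bad, "gff3"))

  # BED -> internal -> GFF3 preserves interval lengths
  set.seed(2)
  starts <- sort(sample(1e6, 10))
  widths <- sample(500:5000, 10)
  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\tg%d", starts, starts + widths, 1:10), bed2)
  cat2 <- read_gene_coords(bed2, "bed", family = "PR-9")
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_gene_coords(cat2, gff2, "gff3")
  cat3 <- read_gene_coords(gff2, "gff3")
  m <- match(cat2$gene_id, cat3$gene_id)
  expect_equal(cat3$end[m] - cat3$start[m], cat2$end - cat2$start)
})

test_that("trees are species-tagged, rooted, and round-trip", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((Mes_a,Mes_b),Ptr_c);", path)
  tr <- read_tree(path)
  expect_equal(length(tr$tip.label), 3)
  expect_setequal(unique(attr(tr, "species")), c("Mes", "Ptr"))

  writeLines("((Mes_a,x1),Ptr_c);", path)
  expect_error(read_tree(path), "x1")

  # round-trip preserves topology
  tr1 <- tag_tree_species(ape::read.tree(text = "((Mes_a,Mes_b),(Ptr_c,Mes_d));"))
  write_tree(tr1, path)
  tr2 <- read_tree(path)
  expect_true(ape::all.equal.phylo(tr1, tr2, use.edge.length = FALSE))

  # species_map translation and unknown-prefix error
  tr3 <- tag_tree_species(ape::read.tree(text = "(Mes_a,Ptr_b);"),
                          species_map = c(Mes = "cassava", Ptr = "poplar"))
  expect_equal(attr(tr3, "species"), c("cassava", "poplar"))
  expect_error(tag_tree_species(ape::read.tree(text = "(Osa_a,Ptr_b);"),
                                species_map = c(Ptr = "poplar")), "Osa")
})

test_that("catalog invariants are enforced", {
  expect_error(gene_catalog(c("a", "a"), "PR-1"), "duplicate")
  expect_error(gene_catalog("a", "PR-1", chromosome = "chr1",
                            start = 200, end = 100), "start > end")
  cat <- gene_catalog(c("a", "b"), "PR-1", chromosome = c("chr1", NA),
                      start = c(1, NA), end = c(10, NA))
  expect_equal(cat$chromosome[2], "unplaced")
})
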