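test_that("expansion detection follows the >= 3 focal-paralog rule", {
  tr <- tag_tree_species(ape::read.tree(text = "(((Mes_a,Mes_b),Mes_c),Ptr_d);"))
  ex <- detect_expansions(tr, "Mes")
  expect_equal(nrow(ex), 1)
  expect_equal(ex$members, "a,b,c")
  expect_equal(ex$size, 3)

  tr2 <- tag_tree_species(ape::read.tree(text = "((Mes_a,Mes_b),Ptr_c);"))
  expect_equal(nrow(detect_expansions(tr2, "Mes")), 0)

  # maximality: nested qualifying clades report only the largest
  tr3 <- tag_tree_species(ape::read.tree(
    text = "((((Mes_a,Mes_b),Mes_c),Mes_d),Ptr_e);"))
  ex3 <- detect_expansions(tr3, "Mes")
  expect_equal(nrow(ex3), 1)
  expect_equal(ex3$members, "a,b,c,d")

  expect_error(detect_expansions(tr, "Osa"), "absent")
})

test_that("expansion detection equals exhaustive clade enumeration", {
  set.seed(11)
  for (i in 1:25) {
    tr <- random_species_tree(sample(6:40, 1))
    got <- sort(detect_expansions(tr, "Mes")$members)
    expect_identical(got, expansions_brute(tr, "Mes"))
    # disjointness: no gene in two expansions
    genes <- unlist(strsplit(got, ","))
    expect_false(anyDuplicated(genes) > 0)
  }
})

test_that("nomenclature renders family + clade letter + L infix + index", {
  # four single-gene clades off the root; clade d's gene never a DEG
  tr <- tag_tree_species(ape::read.tree(
    text = "(Mes_a1,Mes_b1,Mes_c1,Mes_d1);"))
  nm <- assign_nomenclature(tr, "PR-1",
                            deg_history = c(a1 = TRUE, b1 = TRUE, c1 = TRUE))
  expect_equal(nm$name[nm$gene_id == "d1"], "PR-1dL1")
  expect_equal(nm$clade, letters[1:4])

  # clade e, eighth gene, ever-DEG -> PR-2e8
  big <- paste0("(", paste0("Mes_e", 1:9, collapse = ","), ")")
  tr2 <- tag_tree_species(ape::read.tree(text = paste0(
    "(Mes_a1,Mes_b1,Mes_c1,Mes_d1,", big, ");")))
  hist <- setNames(rep(TRUE, 13), c("a1", "b1", "c1", "d1", paste0("e", 1:9)))
  nm2 <- assign_nomenclature(tr2, "PR-2", hist)
  expect_equal(nm2$name[nm2$gene_id == "e8"], "PR-2e8")

  # bijection within the family and stability under tip-order permutation
  expect_false(anyDuplicated(nm2$name) > 0)
  expect_false(anyDuplicated(nm2$gene_id) > 0)
  tr2b <- tag_tree_species(ape::read.tree(text = sprintf(
    "((%s),Mes_d1,Mes_c1,Mes_b1,Mes_a1);",
    paste0("Mes_e", 9:1, collapse = ","))))
  nm2b <- assign_nomenclature(tr2b, "PR-2", hist)
  m <- match(nm2$gene_id, nm2b$gene_id)
  expect_identical(nm2$name, nm2b$name[m])

  # idempotent: re-running gives the identical table
  expect_identical(nm2, assign_nomenclature(tr2, "PR-2", hist))

  # letters extend past z
  expect_equal(clade_letters(28)[27:28], c("aa", "ab"))
})

test_that("physical clustering respects gap and intervening-gene limits", {
  cat <- gene_catalog(
    gene_id = c("a1", "a2", "b1", "c1", "c2"),
    family = c("PR-2", "PR-2", "PR-9", "PR-5", "PR-5"),
    chromosome = c("chr1", "chr1", "chr1", "chr2", "chr3"),
    start = c(1000, 13000, 5000, 100, 100),
    end = c(2000, 14000, 5500, 200, 200))
  cl <- detect_physical_clusters(cat)
  # two PR-2 genes 11 kb apart with one intervening gene: one 2-gene cluster
  expect_equal(nrow(cl), 1)
  expect_equal(cl$members, "a1,a2")
  # same-family genes on different chromosomes stay singletons
  expect_false(any(grepl("c1", cl$members)))

  # gap limit: pushing a2 400 kb away dissolves the cluster
  cat2 <- cat; cat2$start[2] <- 4e5; cat2$end[2] <- 4e5 + 1000
  expect_equal(nrow(detect_physical_clusters(cat2)), 0)

  # intervening limit
  inter <- gene_catalog(
    gene_id = c("x1", paste0("f", 1:6), "x2"),
    family = c("PR-2", rep("PR-9", 6), "PR-2"),
    chromosome = "chr1",
    start = seq(1000, by = 2000, length.out = 8),
    end = seq(1000, by = 2000, length.out = 8) + 500)
  expect_equal(nrow(detect_physical_clusters(inter, max_intervening = 5)), 1)
  expect_equal(detect_physical_clusters(inter, max_intervening = 5)$members[1],
               "f1,f2,f3,f4,f5,f6")  # the six PR-9s chain; PR-2 pair has 6 between
  expect_equal(nrow(detect_physical_clusters(inter, max_intervening = 6)), 2)

  # unplaced genes skipped with a message; every gene is cluster xor singleton
  cat3 <- rbind(as.data.frame(cat),
                data.frame(gene_id = "u1", family = "PR-2", clade = NA,
                           chromosome = "unplaced", start = NA, end = NA,
                           strand = NA))
  class(cat3) <- class(cat)
  expect_message(cl3 <- detect_physical_clusters(cat3), "unplaced")
  clustered <- unlist(strsplit(cl3$members, ","))
  expect_false(anyDuplicated(clustered) > 0)
  expect_true(all(clustered %in% cat3$gene_id))
})

test_that("cluster summaries compute rounded clustered fractions", {
  cat <- gene_catalog(paste0("g", 1:59), "PR-15/16")
  none <- detect_physical_clusters(gene_catalog("solo", "PR-1",
                                                chromosome = "chr1",
                                                start = 1, end = 2))
  expect_equal(cluster_summary(none, cat)$overall_pct, 0)
  # 29 clustered of 59 -> 49%
  fake <- data.frame(cluster_id = 1:3, family = "PR-15/16", chromosome = "chr8",
                     n = c(20, 5, 4), span = 1,
                     members = c(paste(paste0("g", 1:20), collapse = ","),
                                 paste(paste0("g", 21:25), collapse = ","),
                                 paste(paste0("g", 26:29), collapse = ",")),
                     stringsAsFactors = FALSE)
  s <- cluster_summary(fake, cat)
  expect_equal(s$per_family$n_clustered, 29)
  expect_equal(s$per_family$pct, 49)
  # all genes in one cluster -> 100%
  all_in <- data.frame(cluster_id = 1, family = "PR-15/16", chromosome = "chr8",
                       n = 59, span = 1,
                       members = paste(paste0("g", 1:59), collapse = ","))
  expect_equal(cluster_summary(all_in, cat)$overall_pct, 100)
})
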