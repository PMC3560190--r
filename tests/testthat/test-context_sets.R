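# Grouping schemes, query matching, leaf building and naming.

test_that("operon grouping follows the intergenic-distance rule", {
  # gap = start2 - end1 - 1 = 416 - 400 - 1 = 15 <= 20: one grouping
  g <- mk_genome(c(100, 416), c(400, 900))
  ops <- group_operons(g, 20)
  expect_length(ops, 1L)
  expect_equal(nrow(ops[[1]]$genes), 2L)

  # strand flip breaks the run regardless of gap
  g <- mk_genome(c(100, 416), c(400, 900), strand = c("+", "-"))
  expect_length(group_operons(g, 20), 2L)

  # gap 99 > 20: two singletons
  g <- mk_genome(c(100, 500), c(400, 900))
  expect_length(group_operons(g, 20), 2L)

  # contig change always breaks
  g <- mk_genome(c(100, 416), c(400, 900), contig = c("c1", "c2"))
  expect_length(group_operons(g, 20), 2L)
})

test_that("strand-distance grouping chains transitively and admits overlaps", {
  # consecutive gaps 50 and 60, D = 75: one grouping of 3
  g <- mk_genome(c(100, 451, 1012), c(400, 951, 1500))
  expect_equal(c(451 - 400 - 1, 1012 - 951 - 1), c(50, 60))
  expect_length(group_strand_distance(g, 75), 1L)

  # gaps 50 and 80: sizes 2 and 1
  g <- mk_genome(c(100, 451, 1032), c(400, 951, 1500))
  sizes <- sort(vapply(group_strand_distance(g, 75),
                       function(x) nrow(x$genes), integer(1)))
  expect_equal(sizes, c(1L, 2L))

  # overlapping genes (negative gap) chain even at D = 0
  g <- mk_genome(c(100, 350), c(400, 900))
  expect_length(group_strand_distance(g, 0), 1L)
})

test_that("groupings are exact partitions, monotone in threshold, and scheme-equivalent", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      g <- random_genome(n = sample(5:30, 1))
      t1 <- sample(0:60, 1); t2 <- t1 + sample(0:80, 1)
      p1 <- group_operons(g, t1)
      p2 <- group_operons(g, t2)

      # partition: every gene in exactly one grouping
      expect_identical(partition_gene_ids(p1), sort(g$features$gene_id))

      # monotone: each grouping at t1 lies inside exactly one at t2
      for (grp in p1) {
        containing <- Filter(function(h) all(grp$genes$gene_id %in%
                                             h$genes$gene_id), p2)
        expect_length(containing, 1L)
      }

      # shared kernel: operon and strand-distance schemes coincide
      expect_identical(p1, group_strand_distance(g, t1))
    }
  })
})

test_that("queries match by annotation substring or exact cluster ID", {
  g1 <- mk_genome(c(100, 600), c(400, 900),
                  annotation = c("gamma-glutamyl transpeptidase", "kinase"),
                  cluster = c(7L, 9L), species = "spA")
  g2 <- mk_genome(c(100, 600), c(400, 900),
                  annotation = c("KINASE subunit", "other"),
                  cluster = c(7L, 2L), species = "spB")
  genomes <- list(spA = g1, spB = g2)

  m <- match_query(genomes, NULL, context_query("annotation_text", "transpeptidase"))
  expect_equal(m$gene_id, "g1")

  # case folding is on by default
  m <- match_query(genomes, NULL, context_query("annotation_text", "kinase"))
  expect_equal(nrow(m), 2L)
  m <- match_query(genomes, NULL,
                   context_query("annotation_text", "kinase", case_sensitive = TRUE))
  expect_equal(m$species_name, "spA")

  m <- match_query(genomes, NULL, context_query("homology_cluster_id", 7))
  expect_equal(m$species_name, c("spA", "spB"))

  # cluster query without any cluster information is a usage error
  bare <- list(spA = mk_genome(100, 400))
  expect_error(match_query(bare, NULL, context_query("homology_cluster_id", 7)),
               class = "ct_usage_error")
})

test_that("leaf naming joins species to a per-species genomic-order serial", {
  expect_equal(name_leaf("Klebsiella_oxytoca", 1), "Klebsiella_oxytoca-1")
  expect_equal(name_leaf("E coli K12", 2), "E_coli_K12-2")

  g <- mk_genome(c(100, 2000), c(400, 2500), cluster = c(7L, 7L))
  leaves <- build_context_leaves(list(spA = g), NULL,
                                 context_query("homology_cluster_id", 7),
                                 context_set("sg", "single_gene"))
  expect_equal(vapply(leaves, function(l) l$leaf_name, character(1)),
               c("spA-1", "spA-2"))
})

test_that("build_context_leaves honors each scheme and deduplicates groupings", {
  # two query genes inside one operon-scale run -> one leaf
  g <- mk_genome(c(100, 416, 950), c(400, 930, 1400),
                 cluster = c(7L, 7L, 3L))
  q <- context_query("homology_cluster_id", 7)
  leaves <- build_context_leaves(list(spA = g), NULL, q,
                                 context_set("d75", "strand_distance", distance = 75))
  expect_length(leaves, 1L)
  expect_equal(nrow(leaves[[1]]$genes), 3L)
  expect_equal(leaves[[1]]$leaf_name, "spA-1")

  # single_gene: one leaf per match, containing only the match
  leaves <- build_context_leaves(list(spA = g), NULL, q,
                                 context_set("sg", "single_gene"))
  expect_length(leaves, 2L)
  expect_true(all(vapply(leaves, function(l) nrow(l$genes), integer(1)) == 1L))

  # gene_window k = 1: match plus both neighbors
  g2 <- mk_genome(c(100, 600, 1200), c(400, 900, 1500), cluster = c(1L, 7L, 2L))
  leaves <- build_context_leaves(list(spA = g2), NULL, q,
                                 context_set("w", "gene_window", k = 1))
  expect_equal(nrow(leaves[[1]]$genes), 3L)

  # nt_window w = 0: only genes overlapping the match itself
  leaves <- build_context_leaves(list(spA = g2), NULL, q,
                                 context_set("nt", "nt_window", window = 0))
  expect_equal(leaves[[1]]$genes$gene_id, "g2")

  # zero matches: empty result, not an error
  expect_length(build_context_leaves(list(spA = g2), NULL,
                                     context_query("homology_cluster_id", 99),
                                     context_set("sg", "single_gene")), 0L)
})

test_that("leaf names within one build are unique and reruns are identical", {
  withr::with_seed(5, g <- random_genome(30))
  g$features$cluster <- rep(c(7L, 1L, 2L), length.out = 30)
  q <- context_query("homology_cluster_id", 7)
  cs <- context_set("d75", "strand_distance", distance = 75)
  l1 <- build_context_leaves(list(spR = g), NULL, q, cs)
  l2 <- build_context_leaves(list(spR = g), NULL, q, cs)
  nms <- vapply(l1, function(l) l$leaf_name, character(1))
  expect_false(anyDuplicated(nms) > 0)
  expect_identical(l1, l2)
})
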