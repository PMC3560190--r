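# Multidendrogram construction, linkage arithmetic, Newick export.

test_that("two leaves merge into a root with a degenerate band", {
  m <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t <- cluster_multidendrogram(m, "single")
  expect_length(t$root$children, 2L)
  expect_equal(t$root$band_low, 0.4)
  expect_equal(t$root$band_high, 0.4)
  expect_equal(to_newick(t), "(A:0.4,B:0.4);")
})

test_that("mutually equidistant leaves merge simultaneously into one multifurcation", {
  for (k in c(3L, 5L)) {
    t <- cluster_multidendrogram(generate_tie_block(k, 1.0), "average_unweighted")
    expect_length(t$root$children, k)
    expect_equal(t$root$band_low, 1.0)
    expect_equal(t$root$band_high, 1.0)
  }
  expect_equal(to_newick(cluster_multidendrogram(generate_tie_block(3, 1.0), "complete")),
               "(T1:1,T2:1,T3:1);")
})

test_that("tie-free matrices reproduce the standard pair-group oracle", {
  method_map <- c(single = "single", complete = "complete",
                  average_unweighted = "average")
  withr::with_seed(51, {
    for (i in 1:30) {
      n <- sample(4:12, 1)
      m <- random_dissimilarity(n)
      for (mine in names(method_map)) {
        t <- cluster_multidendrogram(m, mine)
        h <- stats::hclust(stats::as.dist(m), method = method_map[[mine]])
        expect_equal(tree_signature(t), hclust_signature(h, rownames(m)),
                     label = sprintf("%s n=%d rep=%d", mine, n, i))
      }
    }
  })
})

test_that("single-linkage merge heights equal the MST edge weights", {
  skip_if_not_installed("vegan")
  withr::with_seed(61, {
    for (i in 1:10) {
      n <- sample(5:12, 1)
      m <- random_dissimilarity(n)
      t <- cluster_multidendrogram(m, "single")
      heights <- sort(vapply(contexttrees:::tree_nodes(t),
                             function(nd) nd$band_low, numeric(1)))
      mst <- sort(as.numeric(vegan::spantree(stats::as.dist(m))$dist))
      expect_equal(heights, mst, tolerance = 1e-12)
    }
  })
})

test_that("linkage_update implements the per-method combination rules", {
  expect_equal(linkage_update("single", c(0.2, 0.7)), 0.2)
  expect_equal(linkage_update("complete", c(0.2, 0.7)), 0.7)
  expect_equal(linkage_update("average_unweighted", c(0.3, 0.6), sizes = c(2, 1)),
               (2 * 0.3 + 1 * 0.6) / 3)
  expect_equal(linkage_update("average_weighted", c(0.3, 0.6)), 0.45)
  expect_error(linkage_update("joint_between_within", c(0.3, 0.6)),
               class = "ct_usage_error")
  expect_error(linkage_update("nope", 0.5), class = "ct_usage_error")
})

test_that("joint between-within linkage pools squared dissimilarities over the union", {
  # 3 leaves: A-B merge first at 0.1; d({A,B}, C) must be the root mean
  # square over all pairs of {A, B, C}
  m <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  m["A", "B"] <- m["B", "A"] <- 0.1
  m["A", "C"] <- m["C", "A"] <- 0.5
  m["B", "C"] <- m["C", "B"] <- 0.7
  t <- cluster_multidendrogram(m, "joint_between_within")
  expected <- sqrt(mean(c(0.1, 0.5, 0.7)^2))
  expect_equal(t$root$band_low, expected)
})

test_that("permuting the leaves yields an identical tree (order invariance)", {
  withr::with_seed(71, {
    for (i in 1:10) {
      n <- sample(4:9, 1)
      m <- random_dissimilarity(n)
      # force some exact ties to exercise the variable-group path
      m[1, 2] <- m[2, 1] <- m[min(3, n - 1), n] <- m[n, min(3, n - 1)] <- 0.05
      for (method in c("single", "complete", "average_unweighted",
                       "joint_between_within")) {
        ref <- cluster_multidendrogram(m, method)
        perm <- sample(n)
        mp <- m[perm, perm]
        t2 <- cluster_multidendrogram(mp, method)
        expect_equal(tree_signature(t2), tree_signature(ref),
                     label = sprintf("%s rep=%d", method, i))
        expect_identical(to_newick(t2), to_newick(ref))
      }
    }
  })
})

test_that("every internal node satisfies band_low <= band_high and leaves are conserved", {
  withr::with_seed(81, {
    m <- random_dissimilarity(10)
    m[2, 5] <- m[5, 2] <- m[3, 7] <- m[7, 3] <- 0.05  # tie
    for (method in c("single", "complete", "average_unweighted",
                     "average_weighted", "joint_between_within")) {
      t <- cluster_multidendrogram(m, method)
      expect_setequal(t$root$leaves, rownames(m))
      for (nd in contexttrees:::tree_nodes(t)) {
        expect_true(nd$band_low <= nd$band_high + 1e-12)
        expect_gte(length(nd$children), 2L)
      }
    }
  })
})

test_that("band heights are monotone from root to leaves for monotone linkages", {
  withr::with_seed(91, {
    m <- random_dissimilarity(9)
    for (method in c("single", "complete", "average_unweighted")) {
      t <- cluster_multidendrogram(m, method)
      check <- function(node, parent_low) {
        if (!is.null(node$leaf_name)) return(invisible(NULL))
        expect_lte(node$band_low, parent_low + 1e-12)
        for (ch in node$children) check(ch, node$band_low)
      }
      check(t$root, Inf)
    }
  })
})

test_that("Newick export carries heights, multifurcations, and survives a reference parser", {
  skip_if_not_installed("ape")
  # nested tree: merge at 0.2 then root at 0.5 -> inner branch length 0.3
  m <- matrix(c(0, 0.2, 0.5, 0.2, 0, 0.5, 0.5, 0.5, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  t <- cluster_multidendrogram(m, "average_unweighted")
  nwk <- to_newick(t)
  expect_equal(nwk, "((A:0.2,B:0.2):0.3,C:0.5);")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, LETTERS[1:3])
  # leaf depths in the parsed tree equal the root height (ultrametric)
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(unname(depths), rep(0.5, 3))

  # multifurcation round-trips through the reference parser
  t3 <- cluster_multidendrogram(generate_tie_block(4, 0.9), "single")
  ph3 <- ape::read.tree(text = to_newick(t3))
  expect_equal(length(ph3$tip.label), 4L)
  expect_equal(ph3$Nnode, 1L)
})

test_that("band midpoints are available as alternative node heights", {
  m <- generate_tie_block(3, 1.0)
  m["T1", "T2"] <- m["T2", "T1"] <- 0.999999999999  # still within tolerance
  t <- cluster_multidendrogram(m, "complete")
  expect_length(t$root$children, 3L)
  expect_match(to_newick(t, height_mode = "band_mid"), "^\\(T1:")
})

test_that("leaf selection filters by case-insensitive substring", {
  t <- cluster_multidendrogram(
    matrix(c(0, .5, .5, 0), 2, 2,
           dimnames = list(c("Klebsiella_oxytoca-1", "Ecoli-1"),
                           c("Klebsiella_oxytoca-1", "Ecoli-1"))), "single")
  expect_equal(select_leaves(t, "oxytoca"), "Klebsiella_oxytoca-1")
  expect_equal(select_leaves(t, "OXYTOCA"), "Klebsiella_oxytoca-1")
  expect_setequal(select_leaves(t, ""), c("Klebsiella_oxytoca-1", "Ecoli-1"))
  expect_length(select_leaves(t, "zzz"), 0L)
})

test_that("invalid matrices are rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(cluster_multidendrogram(m, "single"), class = "ct_usage_error")
  m2 <- matrix(c(0.1, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(cluster_multidendrogram(m2, "single"), class = "ct_usage_error")
})

test_that("tree JSON dump carries agglomeration bands", {
  t <- cluster_multidendrogram(generate_tie_block(3, 0.8), "single")
  js <- jsonlite::fromJSON(tree_to_json(t), simplifyVector = FALSE)
  expect_equal(js$band_low, 0.8)
  expect_equal(js$band_high, 0.8)
  expect_length(js$children, 3L)
})
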