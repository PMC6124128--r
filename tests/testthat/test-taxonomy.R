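test_that("rescaled node heights follow the classification-level formula", {
  # raw formula (L_c - L_s) * C, normalized by L_c
  expect_equal(rescale_node_height(4, 1, 0.5), (4 - 1) * 0.5 / 4)
  expect_equal(rescale_node_height(10, 7, 0.2), 0.06)
  # tip-level node is at zero for any clade age
  expect_equal(rescale_node_height(3, 3, 0.9), 0)
  expect_equal(rescale_node_height(5, 5, 0.1), 0)
  # clade ancestor sits at C
  expect_equal(rescale_node_height(4, 0, 0.7), 0.7)
  # monotone decreasing in L_s
  h <- rescale_node_height(5, 0:5, 0.6)
  expect_true(all(diff(h) < 0))
  # error contracts
  expect_error(rescale_node_height(3, 4, 0.5), "L_s exceeds")
  expect_error(rescale_node_height(3, 1, 0), "C must be > 0")
  expect_error(rescale_node_height(3, 1, 1.2), "C must be <= 1")
})

test_that("the six-tip fixture matches the hand-enumerated height table", {
  fx <- fixture_taxonomy()
  tree <- build_hierarchy(fx$taxonomy, fx$clades)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, fx$taxonomy$tip_id)
  # ultrametric with root height 1
  depths <- ape::node.depth.edgelength(tree)
  tip_depth <- depths[seq_along(tree$tip.label)]
  expect_lt(max(abs(tip_depth - 1)), 1e-9)
  # every pairwise MRCA height equals the hand table
  H <- fixture_mrca_heights()
  node_h <- 1 - depths
  for (i in 1:5) {
    for (j in (i + 1):6) {
      ti <- tree$tip.label[i]; tj <- tree$tip.label[j]
      m <- ape::getMRCA(tree, c(ti, tj))
      expect_equal(node_h[m], H[ti, tj], tolerance = 1e-9,
                   label = paste("MRCA height", ti, tj))
    }
  }
})

test_that("similarity equals the brute-force shared-path oracle", {
  fx <- fixture_taxonomy()
  tree <- build_hierarchy(fx$taxonomy, fx$clades)
  P <- phylo_similarity(tree)
  expect_equal(P, oracle_phylo_similarity(tree)[rownames(P), colnames(P)],
               tolerance = 1e-9)
  # cherry entries: 1 - MRCA height
  expect_equal(P["b1", "b2"], 1 - 0.4 / 6, tolerance = 1e-9)
  # cross-clade pairs share nothing
  expect_equal(P["a1", "b3"], 0, tolerance = 1e-9)
  # diagonal and symmetry
  expect_equal(diag(P), setNames(rep(1, 6), rownames(P)))
  expect_equal(P, t(P))
})

test_that("star-like and degenerate topologies behave as documented", {
  # two clades at C = 1 join directly at the root: similarity 0 between
  tax <- data.frame(
    tip_id = c("t1", "t2", "t3", "t4"),
    language_code = paste0("l", 1:4),
    clade_id = c("A", "A", "B", "B"),
    path = c("p|p1", "p|p2", "q|q1", "q|q2"),
    sample_level = 2L)
  cl <- data.frame(clade_id = c("A", "B"), relative_height = 1,
                   max_level = 2L, n_languages = 2L)
  P <- phylo_similarity(build_hierarchy(tax, cl))
  expect_equal(P["t1", "t3"], 0, tolerance = 1e-9)
  expect_equal(P["t1", "t2"], 0.5, tolerance = 1e-9) # MRCA at C/2

  # single-tip clade: warning, not error
  tax2 <- rbind(tax, data.frame(tip_id = "t5", language_code = "l5",
                                clade_id = "C", path = "r", sample_level = 1L))
  cl2 <- rbind(cl, data.frame(clade_id = "C", relative_height = 0.5,
                              max_level = 1L, n_languages = 1L))
  expect_warning(build_hierarchy(tax2, cl2), "single tip")

  # all tips one language: similarity all ones off-diagonal, flagged
  tax3 <- data.frame(tip_id = c("u1", "u2", "u3"),
                     language_code = "l1", clade_id = "A",
                     path = "p|p1", sample_level = 2L)
  cl3 <- data.frame(clade_id = "A", relative_height = 1, max_level = 2L,
                    n_languages = 1L)
  tr3 <- build_hierarchy(tax3, cl3)
  expect_warning(P3 <- phylo_similarity(tr3), "non-identifiable")
  expect_true(all(P3[upper.tri(P3)] > 0.7))
})

test_that("invalid taxonomies are rejected with informative errors", {
  fx <- fixture_taxonomy()
  bad <- fx$taxonomy
  bad$tip_id[2] <- "a1"
  expect_error(build_hierarchy(bad, fx$clades), "duplicate tip_id")
  bad2 <- fx$taxonomy
  bad2$clade_id[1] <- "Z"
  expect_error(build_hierarchy(bad2, fx$clades), "unknown clade")
  bad3 <- fx$taxonomy
  bad3$path[3] <- "x|x2|x2a|x2aa"
  bad3$sample_level[3] <- 4L
  expect_error(build_hierarchy(bad3, fx$clades), "exceeds clade max level")
  expect_error(phylo_similarity(ape::read.tree(text = "((a:1,b:2):1,c:3);")),
               "not ultrametric")
})

test_that("built trees are ultrametric and serialize losslessly", {
  for (seed in c(1, 7, 23, 99)) {
    tax <- simulate_taxonomy(25, 5, seed = seed)
    tree <- suppressWarnings(build_hierarchy(tax$taxonomy, tax$clades))
    depths <- ape::node.depth.edgelength(tree)
    expect_lt(max(abs(depths[seq_along(tree$tip.label)] - 1)), 1e-9)
    # Newick round trip preserves topology and heights
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tree, f)
    tree2 <- read_newick(f)
    expect_setequal(tree2$tip.label, tree$tip.label)
    d1 <- ape::cophenetic.phylo(tree)
    d2 <- ape::cophenetic.phylo(tree2)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
  }
})

test_that("within-clade similarity exceeds between-clade similarity", {
  fx <- fixture_taxonomy()
  P <- phylo_similarity(build_hierarchy(fx$taxonomy, fx$clades))
  within_a <- c(P["a1", "a2"], P["a1", "a3"], P["a2", "a3"])
  within_b <- c(P["b1", "b2"], P["b1", "b3"], P["b2", "b3"])
  between <- as.vector(P[c("a1", "a2", "a3"), c("b1", "b2", "b3")])
  expect_true(min(c(within_a, within_b)) > max(between))
})
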