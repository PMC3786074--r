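# Parsimony mapping: Hartigan-Fitch counts against exhaustive enumeration,
# Dollo gain/loss reconstruction, clade delimitation and the genus census.

test_that("Fitch count matches hand-checked four-leaf cases", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_identical(fitch_min_changes(t1, c(A = 1, B = 1, C = 0, D = 0)), 1L)
  expect_identical(fitch_min_changes(t1, c(A = 0, B = 0, C = 0, D = 0)), 0L)
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_identical(fitch_min_changes(t2, c(A = 1, B = 1, C = 0, D = 0)), 2L)
  expect_error(fitch_min_changes(t1, c(A = 1, B = 1, C = 0)), "input error")
})

test_that("Fitch count equals the exhaustive minimum on random trees", {
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    labels <- LETTERS[seq_len(n)]
    tree <- if (rep %% 2 == 0) {
      random_polytomy_tree(labels)
    } else {
      ape::rtree(n, tip.label = labels)
    }
    states <- setNames(sample(0:1, n, replace = TRUE), labels)
    expect_identical(fitch_min_changes(tree, states),
                     oracle_min_changes(tree, states),
                     info = paste("rep", rep))
  }
})

test_that("resolving a polytomy never increases the change count", {
  # a resolution refines the topology, so any labeling of the polytomous
  # tree projects onto it with the same cost; the minimum cannot grow
  # (it can shrink, e.g. a star over leaves 1,1,0,0 costs 2 but its
  # ((1,1),(0,0)) resolution costs 1)
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    labels <- LETTERS[seq_len(n)]
    poly <- random_polytomy_tree(labels)
    states <- setNames(sample(0:1, n, replace = TRUE), labels)
    resolved <- ape::multi2di(poly)
    expect_lte(fitch_min_changes(resolved, states),
               fitch_min_changes(poly, states))
    expect_identical(fitch_min_changes(resolved, states),
                     oracle_min_changes(resolved, states))
  }
  star <- ape::read.tree(text = "(A,B,C,D);")
  expect_identical(fitch_min_changes(star, c(A = 1, B = 1, C = 0, D = 0)), 2L)
  res <- ape::read.tree(text = "((A,B),(C,D));")
  expect_identical(fitch_min_changes(res, c(A = 1, B = 1, C = 0, D = 0)), 1L)
})

test_that("Fitch count agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    labels <- LETTERS[seq_len(n)]
    tree <- ape::rtree(n, tip.label = labels)
    states <- setNames(sample(0:1, n, replace = TRUE), labels)
    dat <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                   dimnames = list(labels, NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_identical(fitch_min_changes(tree, states),
                     as.integer(phangorn::parsimony(tree, dat)),
                     info = paste("rep", rep))
  }
})

test_that("Dollo reconstruction finds the gain node and maximal losses", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  d1 <- dollo_reconstruction(t1, c(A = 1, B = 1, C = 0, D = 0))
  expect_identical(d1$gain_node, ape::getMRCA(t1, c("A", "B")))
  expect_identical(d1$n_losses, 0L)
  expect_setequal(d1$clade_tips, c("A", "B"))
  # gain above A,B,C with one loss (the B subtree)
  t2 <- ape::read.tree(text = "(((A,B),C),D);")
  d2 <- dollo_reconstruction(t2, c(A = 1, B = 0, C = 1, D = 0))
  expect_identical(d2$gain_node, ape::getMRCA(t2, c("A", "C")))
  expect_identical(d2$n_losses, 1L)
  # chain of positives, no negatives under the MRCA
  t3 <- ladder_tree(paste0("P", 1:7))
  d3 <- dollo_reconstruction(t3, setNames(rep(1, 7), paste0("P", 1:7)))
  expect_identical(d3$n_losses, 0L)
  expect_error(dollo_reconstruction(t1, c(A = 0, B = 0, C = 0, D = 0)),
               "no leaf")
})

test_that("losses are zero exactly when positives form one clade", {
  set.seed(53)
  for (rep in 1:30) {
    n <- sample(5:9, 1)
    labels <- LETTERS[seq_len(n)]
    tree <- ape::rtree(n, tip.label = labels)
    npos <- sample(2:(n - 1), 1)
    pos <- sample(labels, npos)
    states <- setNames(as.integer(labels %in% pos), labels)
    d <- dollo_reconstruction(tree, states)
    is_clade <- setequal(ape::extract.clade(
      tree, ape::getMRCA(tree, pos))$tip.label, pos)
    expect_identical(d$n_losses == 0L, is_clade, info = paste("rep", rep))
    # one Fitch change iff the positives or their complement form a clade
    neg <- setdiff(labels, pos)
    neg_clade <- length(neg) >= 2L &&
      setequal(ape::extract.clade(tree, ape::getMRCA(tree, neg))$tip.label, neg)
    if (length(neg) == 1L) neg_clade <- TRUE
    expect_identical(fitch_min_changes(tree, states) == 1L,
                     is_clade || neg_clade, info = paste("rep", rep))
  }
})

test_that("clade delimitation on the packaged survey recovers 29 genera", {
  t1 <- load_table1()
  outgroups <- c("Nicotiana tabacum", "Atropa belladonna", "Hyoscyamus niger",
                 "Lycium barbarum", "Jaborosa integrifolia", "Nolana humifusa",
                 "Juanulloa mexicana")
  tree <- ladder_tree(c(outgroups, "CLADE"))
  tree <- ape::bind.tree(tree, ladder_tree(t1$rows$taxon),
                         where = which(tree$tip.label == "CLADE"))
  states <- rbind(fixture_states(),
                  data.frame(taxon = outgroups, copy_number = 0L))
  cm <- character_map(states, tree)
  report <- delimit_clade(cm)
  expect_true(report$single_origin)
  expect_identical(report$n_gains, 1L)
  expect_identical(report$n_losses_dollo, 0L)
  expect_length(report$clade_taxa, nrow(t1$rows))
  expect_length(report$clade_genera, 29L)
  # without the spelling correction the misprint inflates the census
  expect_length(unique(genus_of(t1$rows$taxon)), 30L)
})

test_that("single positive leaf delimits itself; scattered positives break single origin", {
  tree <- ape::read.tree(text = "((A_x,B_x),(C_x,D_x));")
  cm1 <- character_map(c("A x" = 3, "B x" = 0, "C x" = 0, "D x" = 0), tree)
  r1 <- delimit_clade(cm1)
  expect_true(r1$single_origin)
  expect_identical(r1$clade_taxa, "A x")
  expect_identical(r1$clade_genera, "A")
  # positives scattered across three separate clades
  t2 <- ladder_tree(paste0("T", 1:8))
  st <- setNames(c(1, 0, 1, 0, 1, 0, 0, 0), paste0("T", 1:8))
  cm2 <- character_map(st, t2)
  r2 <- delimit_clade(cm2)
  expect_identical(r2$n_gains, oracle_min_changes(t2, st))
  expect_gt(r2$n_gains, 1L)
  expect_false(r2$single_origin)
})

test_that("genus census is idempotent and order-independent", {
  taxa <- c("Solanum lycopersicum", "Solanum tuberosum", "Capsicum annuum",
            "Jalotmata procumbens")
  corr <- c(Jalotmata = "Jaltomata")
  g1 <- sort(unique(genus_of(taxa, corr)))
  g2 <- sort(unique(genus_of(rev(taxa), corr)))
  expect_identical(g1, g2)
  expect_identical(sort(unique(genus_of(g1, corr))), g1)
})

test_that("character maps prune stateless tips with a warning", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  expect_warning(cm <- character_map(c(A = 1, B = 2, C = 0), tree),
                 "pruning")
  expect_identical(sort(names(cm$states)), c("A", "B", "C"))
  expect_identical(cm$dropped_tips, "D")
  # NA states are unknown, not absent
  expect_warning(cm2 <- character_map(c(A = 1, B = 2, C = 0, D = NA), tree),
                 "pruning")
  expect_false("D" %in% names(cm2$states))
})

test_that("annotated trees round-trip through newick", {
  tree <- ape::read.tree(text = "((A_a,B_b),(C_c,D_d));")
  cm <- character_map(c("A a" = 2, "B b" = 3, "C c" = 0, "D d" = 0), tree)
  report <- delimit_clade(cm)
  ann <- annotate_tree(cm, report)
  expect_identical(sum(ann$tree$node.label == "PSI_GAIN"), 1L)
  expect_identical(ann$table$copy_number[ann$table$taxon == "A a"], 2L)
  nwk <- tempfile(fileext = ".nwk")
  ape::write.tree(ann$tree, nwk)
  back <- ape::read.tree(nwk)
  expect_true(grepl("PSI_GAIN", paste(back$node.label, collapse = "")))
  expect_setequal(back$tip.label, ann$tree$tip.label)
  # topology identical: same splits
  expect_true(ape::all.equal.phylo(back, ann$tree, use.edge.length = FALSE))
})
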