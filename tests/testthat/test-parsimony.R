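test_that("fitch_length handles the textbook cases", {
  sm <- c(t1 = "A", t2 = "A", t3 = "C", t4 = "C")
  tr1 <- read_newick("((t1,t2),(t3,t4));")
  tr2 <- read_newick("((t1,t3),(t2,t4));")
  expect_equal(fitch_length(tr1, sm), 1)
  expect_equal(fitch_length(tr2, sm), 2)
  # identical rows: zero length
  expect_equal(fitch_length(tr2, c(t1 = "ACG", t2 = "ACG", t3 = "ACG",
                                   t4 = "ACG")), 0)
  # weights scale linearly
  seqs <- random_seqs(4, 12, seed = 1)
  expect_equal(fitch_length(tr1, seqs, weights = rep(2, 12)),
               2 * fitch_length(tr1, seqs))
  expect_error(fitch_length(tr1, c(t1 = "A", t2 = "A", t3 = "A")),
               "leaf absent")
})

test_that("fitch_length matches brute-force assignment enumeration", {
  set.seed(11)
  n_checked <- 0
  for (rep in 1:60) {
    n <- sample(4:6, 1)
    tree <- ape::rtree(n)
    tree$tip.label <- paste0("t", 1:n)
    # single column, occasionally with a missing leaf state
    states <- sample(1:4, n, replace = TRUE)
    col <- c("A", "C", "G", "T")[states]
    leaf_states <- lapply(states, function(s) s)
    if (rep %% 5 == 0) { col[1] <- "?"; leaf_states[[1]] <- 1:4 }
    names(leaf_states) <- paste0("t", 1:n)
    seqs <- stats::setNames(col, paste0("t", 1:n))
    expect_equal(fitch_length(tree, seqs),
                 oracle_fitch_column(tree, leaf_states))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 60)
})

test_that("fitch_length is invariant to rerooting and leaf permutation", {
  seqs <- random_seqs(7, 25, seed = 5)
  tree <- ape::rtree(7)
  tree$tip.label <- names(seqs)
  base <- fitch_length(tree, seqs)
  for (t in tree$tip.label[1:4]) {
    rr <- ape::root(tree, outgroup = t, resolve.root = TRUE)
    expect_equal(fitch_length(rr, seqs), base)
  }
  perm <- seqs[sample(names(seqs))]
  expect_equal(fitch_length(tree, perm), base)
  # cross-check against the phangorn engine on the same matrix
  d <- barcodeval:::as_phydat(seqs)
  expect_equal(base, phangorn::parsimony(tree, d, method = "fitch"))
})

test_that("stepwise addition yields valid seeded start trees", {
  seqs <- random_seqs(3, 10, seed = 2)
  tr <- stepwise_addition(seqs, seed = 1)
  expect_equal(sort(tr$tip.label), sort(names(seqs)))  # unique 3-taxon tree
  seqs6 <- random_seqs(6, 40, seed = 3)
  t1 <- stepwise_addition(seqs6, seed = 9)
  t2 <- stepwise_addition(seqs6, seed = 9)
  expect_equal(topology_key(t1), topology_key(t2))  # deterministic
  expect_error(stepwise_addition(seqs[1:2], 1), "at least 3")
})

test_that("SPR search reaches the exhaustive optimum on small matrices", {
  for (seed in c(2, 4, 8)) {
    seqs <- random_seqs(5, 20, seed = seed)
    ex <- exhaustive_search(seqs)
    res <- spr_search(stepwise_addition(seqs, seed), seqs)
    expect_equal(res$length, ex$length)
  }
})

test_that("SPR search retains equally parsimonious topologies as a set", {
  # a no-signal taxon ties every placement; exhaustive search is the oracle
  seqs <- c(a = "AAAATTTT", b = "AAAATTTA", c = "CCCCTTTT",
            d = "CCCCAAAA", e = "????????")
  ex <- exhaustive_search(seqs)
  expect_gte(length(ex$trees), 2)
  res <- spr_search(stepwise_addition(seqs, 1), seqs, collect_ties = TRUE)
  expect_equal(res$length, ex$length)
  expect_setequal(vapply(res$trees, topology_key, character(1)),
                  vapply(ex$trees, topology_key, character(1)))
  lens <- vapply(res$trees, fitch_length, numeric(1), x = seqs)
  expect_true(all(lens == res$length))
})

test_that("the ratchet matches exhaustive search and logs monotone lengths", {
  for (seed in c(1, 5)) {
    seqs <- random_seqs(6, 25, seed = seed)
    ex <- exhaustive_search(seqs)
    rr <- parsimony_ratchet(seqs, search_params(ratchet_iterations = 6,
                                                n_start_trees = 2,
                                                seed = seed))
    expect_equal(rr$length, ex$length)
    expect_true(all(diff(rr$log$length) <= 0))
    # reproducible given the seed
    rr2 <- parsimony_ratchet(seqs, search_params(ratchet_iterations = 6,
                                                 n_start_trees = 2,
                                                 seed = seed))
    expect_equal(sort(vapply(rr$trees, topology_key, character(1))),
                 sort(vapply(rr2$trees, topology_key, character(1))))
  }
  # all-identical matrix: length 0
  same <- stats::setNames(rep("ACGTACGT", 5), paste0("t", 1:5))
  rr <- parsimony_ratchet(same, search_params(ratchet_iterations = 2,
                                              seed = 1))
  expect_equal(rr$length, 0)
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- read_newick("((a,b),(c,d));")
  expect_equal(sort(tree_splits(strict_consensus(list(t1)))),
               sort(tree_splits(t1)))
  t2 <- read_newick("((a,c),(b,d));")
  star <- strict_consensus(list(t1, t2))
  expect_length(tree_splits(star), 0)
  expect_error(strict_consensus(list(t1, read_newick("((a,b),(c,e));"))),
               "differing leaf sets")
  # idempotence
  set.seed(3)
  trees <- lapply(1:4, function(i) {
    tr <- ape::rtree(8); tr$tip.label <- paste0("x", 1:8); tr
  })
  cons <- strict_consensus(trees)
  expect_equal(sort(tree_splits(strict_consensus(list(cons)))),
               sort(tree_splits(cons)))
  # every consensus bipartition is present in every input (oracle check)
  for (tr in trees)
    expect_true(all(tree_splits(cons) %in% oracle_splits(tr)))
})

test_that("tree_splits agrees with the BFS edge-cut oracle", {
  set.seed(21)
  for (i in 1:10) {
    tr <- ape::rtree(sample(5:9, 1))
    tr$tip.label <- paste0("t", seq_len(ape::Ntip(tr)))
    expect_equal(tree_splits(tr), oracle_splits(tr))
  }
})

test_that("Newick round trips preserve bipartitions", {
  tr <- read_newick("(a,b,(c,d));")
  expect_equal(tree_splits(read_newick(write_newick(tr))), tree_splits(tr))
  quoted <- read_newick("('sp one','sp two',('a b','c d'));")
  expect_true("sp one" %in% quoted$tip.label)
  set.seed(8)
  for (i in 1:20) {
    tr <- ape::rtree(20)
    tr$tip.label <- paste0("t", 1:20)
    path <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, path)
    expect_equal(tree_splits(read_newick(path = path)), tree_splits(tr))
  }
  expect_error(read_newick("((a,b),(c,d);"), "unclosed")
  expect_error(read_newick("(a,b))"), "offset")
})
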