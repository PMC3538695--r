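test_that("bipartition monophyly matches direct reading of small trees", {
  tr <- read_newick("(a,b,(c,d));")
  expect_true(bipartition_monophyly(tr, c("c", "d")))
  expect_false(bipartition_monophyly(tr, c("b", "c")))
  expect_true(bipartition_monophyly(tr, "a"))             # singleton
  expect_true(bipartition_monophyly(tr, c("a", "b", "c")))  # complement of leaf
  expect_error(bipartition_monophyly(tr, c("a", "zz")), "not a leaf")
})

test_that("monophyly agrees with the rooted-MRCA oracle on random trees", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(6:10, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", 1:n)
    members <- sample(tr$tip.label, sample(2:(n - 2), 1))
    expect_equal(bipartition_monophyly(tr, members),
                 oracle_monophyletic(tr, members),
                 info = paste("seed case", i))
  }
})

test_that("monophyly works on multifurcating consensus trees", {
  tr <- read_newick("(a,b,c,(d,e));")
  expect_true(bipartition_monophyly(tr, c("d", "e")))
  expect_false(bipartition_monophyly(tr, c("a", "b")))
})

test_that("diagnostic sites follow the member/other ambiguity rules", {
  sm <- c(m1 = "GAAT", m2 = "GAAT", o1 = "AAAT", o2 = "ACAT")
  expect_equal(diagnostic_sites(sm, c("m1", "m2"), c("o1", "o2")), 1L)
  # ambiguity or missing in a member blocks the column
  sm2 <- c(m1 = "GAAT", m2 = "?AAT", o1 = "AAAT")
  expect_length(diagnostic_sites(sm2, c("m1", "m2"), "o1"), 0)
  # a single other specimen sharing the base blocks it
  sm3 <- c(m1 = "GAAT", m2 = "GAAT", o1 = "AAAT", o2 = "GAAT")
  expect_false(1L %in% diagnostic_sites(sm3, c("m1", "m2"), c("o1", "o2")))
  # missing/ambiguous cells in others do not block
  sm4 <- c(m1 = "GAAT", m2 = "GAAT", o1 = "?AAT", o2 = "RAAT")
  expect_equal(diagnostic_sites(sm4, c("m1", "m2"), c("o1", "o2")), 1L)
  expect_error(diagnostic_sites(sm, character(), "o1"), "empty member")
  expect_error(diagnostic_sites(sm, "m1", c("m1", "o1")), "disjoint")
})

test_that("diagnostic sites equal a per-column brute-force scan", {
  set.seed(13)
  alphabet <- c("A", "C", "G", "T", "-", "?", "N")
  for (rep in 1:15) {
    n <- 8; L <- 30
    seqs <- stats::setNames(vapply(1:n, function(i)
      paste(sample(alphabet, L, TRUE, prob = c(rep(.22, 4), rep(.04, 3))),
            collapse = ""), character(1)), paste0("s", 1:n))
    members <- paste0("s", 1:3); others <- paste0("s", 4:8)
    mrows <- lapply(seqs[members], function(x) strsplit(x, "")[[1]])
    orows <- lapply(seqs[others], function(x) strsplit(x, "")[[1]])
    expected <- integer()
    for (j in 1:L) {
      mv <- vapply(mrows, `[`, "", j)
      ov <- vapply(orows, `[`, "", j)
      if (all(mv %in% c("A", "C", "G", "T")) && length(unique(mv)) == 1 &&
          !(mv[1] %in% ov))
        expected <- c(expected, j)
    }
    expect_equal(diagnostic_sites(seqs, members, others), expected)
  }
})

test_that("species resolution combines monophyly and diagnosability", {
  ds <- tiny_library()
  sm <- concatenate(ds, c("rbcL", "ITS2"), rule = "all_markers")
  # tree grouping conspecifics correctly
  tr <- read_newick("((s1,s2),(s3,s4),(s5,s6));")
  rep <- species_resolution(tr, sm, ds)
  expect_true(all(rep$species$resolved))
  expect_equal(rep$summary$overall_percent, 100)
  expect_true(all(rep$species$resolved <= rep$species$monophyletic))
  # genus class comes from the metadata
  expect_equal(rep$species$genus_class[rep$species$genus == "B"], "monotypic")
  expect_equal(sum(rep$species$genus_class == "polytypic"), 2)

  # indistinguishable taxa: identical sequences across two species
  ds2 <- ds
  ds2$alignments$rbcL$seqs[c("s3", "s4")] <-
    ds2$alignments$rbcL$seqs[c("s1", "s2")]
  ds2$alignments$ITS2$seqs[c("s3", "s4")] <-
    ds2$alignments$ITS2$seqs[c("s1", "s2")]
  sm2 <- concatenate(ds2, c("rbcL", "ITS2"), rule = "all_markers")
  rep2 <- species_resolution(tr, sm2, ds2)
  unresolved <- rep2$species$species[!rep2$species$resolved]
  expect_setequal(unresolved, c("A x", "A y"))
})

test_that("adding other species' specimens never unresolves a clean species", {
  ds <- tiny_library()
  sm <- concatenate(ds, c("rbcL", "ITS2"), rule = "all_markers")
  tr <- read_newick("((s1,s2),(s3,s4),(s5,s6));")
  before <- species_resolution(tr, sm, ds)$species
  # constructed case: drop species B entirely and rescore A-species
  ds_small <- barcodeval:::subset_dataset(ds, c("s1", "s2", "s3", "s4"))
  sm_small <- concatenate(ds_small, c("rbcL", "ITS2"), rule = "all_markers")
  tr_small <- read_newick("((s1,s2),(s3,s4));")
  small <- species_resolution(tr_small, sm_small, ds_small)$species
  for (sp in small$species[small$resolved])
    expect_true(before$resolved[before$species == sp])
})

test_that("marker combination comparison tracks which combo resolves what", {
  p <- simulation_params(n_families = 3, seed = 12)
  lib <- simulate_library(p, anomalies = FALSE)
  cmp <- marker_combination_compare(
    lib$dataset, list("rbcL", c("rbcL", "ITS2")),
    params = search_params(ratchet_iterations = 3, n_start_trees = 2,
                           seed = 4, collect_ties = FALSE))
  expect_equal(cmp$table$combo, c("rbcL", "rbcL+ITS2"))
  # adding an informative marker never hurts on clean data
  expect_gte(cmp$table$overall_percent[2], cmp$table$overall_percent[1])
  expect_true(all(rownames(cmp$resolved_by) %in%
                    lib$dataset$specimens$species))
})

test_that("a zero-rate marker alone resolves no polytypic species", {
  mk <- default_markers()
  mk$rate[1] <- 0
  p <- simulation_params(n_families = 2, markers = mk, seed = 6,
                         diagnostic_tags = FALSE)
  lib <- simulate_library(p, anomalies = FALSE)
  sm <- concatenate(lib$dataset, "rbcL", rule = "any_marker")
  rr <- parsimony_ratchet(sm, search_params(ratchet_iterations = 2,
                                            n_start_trees = 2, seed = 2,
                                            collect_ties = FALSE))
  rep <- species_resolution(strict_consensus(rr$trees), sm, lib$dataset)
  expect_equal(rep$summary$polytypic_percent, 0)
})
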