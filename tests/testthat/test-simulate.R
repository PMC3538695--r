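test_that("taxonomy skeleton honours the structural knobs", {
  p <- simulation_params(n_families = 1, genera_per_family = c(1, 1),
                         monotypic_fraction = 0, polytypic_extra_lambda = 1,
                         seed = 2)
  sk <- simulate_taxonomy(p)
  expect_equal(length(unique(sk$species$genus)), 1L)
  expect_gte(nrow(sk$species), 2L)  # polytypic by construction

  p1 <- simulation_params(n_families = 4, monotypic_fraction = 1, seed = 3)
  sk1 <- simulate_taxonomy(p1)
  expect_true(all(table(sk1$species$genus) == 1L))

  # specimens-per-species range respected; metadata consistent
  p2 <- simulation_params(seed = 5)
  sk2 <- simulate_taxonomy(p2)
  expect_true(all(sk2$species$n_specimens >= 2 & sk2$species$n_specimens <= 5))
  expect_silent(validate_specimens(sk2$specimens))
})

test_that("the monotypic fraction is calibrated (binomial check)", {
  p <- simulation_params(n_families = 300, genera_per_family = c(3, 3),
                         monotypic_fraction = 0.6, seed = 8)
  sk <- simulate_taxonomy(p)
  n_gen <- length(unique(sk$species$genus))
  frac <- mean(table(sk$species$genus) == 1L)
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / n_gen))
})

test_that("a zero rate multiplier freezes a marker", {
  mk <- default_markers()
  mk$rate[1] <- 0
  p <- simulation_params(n_families = 1, genera_per_family = c(2, 2),
                         markers = mk, seed = 4, diagnostic_tags = FALSE)
  lib <- simulate_library(p, anomalies = FALSE)
  expect_equal(length(unique(lib$dataset$alignments$rbcL$seqs)), 1L)
  expect_gt(length(unique(lib$dataset$alignments$ITS2$seqs)), 1L)
})

test_that("coding markers are ORF-clean by construction", {
  p <- simulation_params(seed = 21)
  lib <- simulate_library(p, anomalies = FALSE)
  for (m in c("rbcL", "matK"))
    expect_equal(nrow(orf_check(lib$dataset$alignments[[m]],
                                frame_offset = 0)), 0L)
})

test_that("default rates reproduce the marker MPD ordering", {
  p <- simulation_params(seed = 33)
  lib <- simulate_library(p, anomalies = FALSE)
  means <- vapply(c("rbcL", "matK", "ITS2"), function(m)
    mean(mpd_by_family(lib$dataset, m)$mpd_percent), numeric(1))
  expect_true(means["rbcL"] < means["matK"] && means["matK"] < means["ITS2"])
})

test_that("herbarium dropout rates land within binomial bounds", {
  p <- simulation_params(n_families = 30, herbarium_fraction = 1,
                         dropout_herbarium = c(rbcL = 0.2, matK = 0.5,
                                               ITS2 = 0.1),
                         seed = 14)
  lib <- simulate_library(p)
  rec <- lib$dataset$recovery
  matk <- rec[rec$marker == "matK", ]
  n <- nrow(matk)
  fail <- mean(matk$status == "attempted_failed")
  expect_lt(abs(fail - 0.5), 3 * sqrt(0.25 / n))
  expect_gte(n, 200)
  # recovery_stats reports the complement
  st <- recovery_stats(lib$dataset)
  herb_matk <- st$by_source[st$by_source$marker == "matK", ]
  expect_equal(herb_matk$success_percent, 100 * (1 - fail))
})

test_that("anomaly-free parameters leave the dataset unchanged", {
  p <- simulation_params(seed = 9, herbarium_fraction = 0,
                         dropout_fresh = c(rbcL = 0, matK = 0, ITS2 = 0))
  sk <- simulate_taxonomy(p)
  clean <- simulate_sequences(sk, p)
  res <- inject_anomalies(clean, sk, p)
  expect_equal(nrow(res$truth$anomalies), 0L)
  for (m in names(clean$alignments))
    expect_equal(res$dataset$alignments[[m]]$seqs,
                 clean$alignments[[m]]$seqs)
})

test_that("each planted anomaly appears exactly once in the truth", {
  p <- simulation_params(seed = 26, n_paralogs = 3, n_pseudogenes = 2,
                         n_contaminants = 2, n_misidentifications = 3,
                         n_introgressed_genera = 1)
  lib <- simulate_library(p)
  an <- lib$truth$anomalies
  expect_equal(sum(an$type == "paralog"), 3L)
  expect_equal(sum(an$type == "pseudogene"), 2L)
  expect_equal(sum(an$type == "contaminant"), 2L)
  expect_equal(sum(an$type == "misidentification"), 3L)
  expect_equal(sum(an$type == "introgression"), 1L)
  ids <- an$specimen_id[an$type != "introgression"]
  expect_equal(anyDuplicated(paste(ids, an$marker[an$type != "introgression"])), 0L)
  # a planted single-base deletion is caught by the ORF screen
  ps <- an[an$type == "pseudogene", ]
  for (i in seq_len(nrow(ps))) {
    fl <- orf_check(lib$dataset$alignments[[ps$marker[i]]])
    expect_true(ps$specimen_id[i] %in%
                  fl$specimen_id[fl$flag_type == "pseudogene_frameshift"])
  }
})

test_that("introgression truth matches the planted chloroplast sharing", {
  p <- simulation_params(seed = 41, n_introgressed_genera = 1,
                         herbarium_fraction = 0)
  lib <- simulate_library(p, resolvable_combos = list(c("rbcL", "matK")))
  gen <- lib$truth$introgressed_genera
  sp <- unique(lib$dataset$specimens$species[
    lib$dataset$specimens$genus == gen])
  expect_length(sp, 9L)
  er <- lib$truth$expected_resolvable[["rbcL+matK"]]
  in_gen <- er[er$species %in% sp, ]
  expect_equal(sum(in_gen$resolvable), 1L)
  expect_equal(in_gen$species[in_gen$resolvable], lib$truth$holdout_species)
  # sharers literally share one haplotype
  sharers <- setdiff(sp, lib$truth$holdout_species)
  ids <- lib$dataset$specimens$specimen_id[
    lib$dataset$specimens$species %in% sharers]
  haps <- unique(lib$dataset$alignments$rbcL$seqs[
    intersect(ids, names(lib$dataset$alignments$rbcL$seqs))])
  expect_length(haps, 1L)
})

test_that("emission round trips and is byte-identical across reruns", {
  p <- simulation_params(n_families = 3, seed = 18, n_paralogs = 1,
                         n_misidentifications = 2)
  lib <- simulate_library(p)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_library(lib$dataset, lib$truth, d1)
  back <- read_library(d1)
  for (m in names(lib$dataset$alignments))
    expect_equal(back$alignments[[m]]$seqs[
      sort(names(lib$dataset$alignments[[m]]$seqs))],
      lib$dataset$alignments[[m]]$seqs[
        sort(names(lib$dataset$alignments[[m]]$seqs))])
  expect_setequal(back$specimens$specimen_id,
                  lib$dataset$specimens$specimen_id)
  # regenerate from the same seed: byte-identical files
  lib2 <- simulate_library(simulation_params(n_families = 3, seed = 18,
                                             n_paralogs = 1,
                                             n_misidentifications = 2))
  emit_library(lib2$dataset, lib2$truth, d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d2, f))),
                 unname(tools::md5sum(file.path(d1, f))),
                 info = f)
  }
  # truth JSON is valid and carries the planted anomalies
  tr <- jsonlite::read_json(file.path(d1, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(tr$anomalies), nrow(lib$truth$anomalies))
})
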