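test_that("ORF screen flags frameshifts and internal stops", {
  clean <- paste(rep("ATGGCT", 4), collapse = "")  # 24 bp, stop-free
  aln <- marker_alignment("matK", c(
    s1 = clean, s2 = clean,
    s3 = paste0(substr(clean, 2, 24), "-"),            # 1-base deletion
    s4 = paste0(substr(clean, 1, 6), "TAA",
                substr(clean, 10, 24))))               # in-frame stop
  flags <- orf_check(aln, frame_offset = 0)
  expect_setequal(flags$specimen_id[flags$flag_type == "pseudogene_frameshift"],
                  "s3")
  stop_rows <- flags[flags$flag_type == "pseudogene_stop", ]
  expect_true("s4" %in% stop_rows$specimen_id)
  expect_match(stop_rows$evidence[stop_rows$specimen_id == "s4"], "codon 3")
  expect_false("s1" %in% flags$specimen_id)
  expect_error(orf_check(aln, coding = FALSE), "not protein-coding")
})

test_that("ORF screen infers the frame and translates like a codon-scan oracle", {
  set.seed(17)
  base <- barcodeval:::random_root(90, coding = TRUE)
  seqs <- stats::setNames(
    vapply(1:6, function(i)
      barcodeval:::int_to_seq(barcodeval:::jc_evolve(base, 0.01)),
      character(1)), paste0("s", 1:6))
  # force a stop into s6 mid-sequence (codon 10)
  substr(seqs["s6"], 28, 30) <- "TGA"
  aln <- marker_alignment("rbcL", seqs)
  flags <- orf_check(aln)  # frame inferred from the modal sequence
  # oracle: scan frame-0 codons for stops
  oracle_has_stop <- vapply(seqs, function(s) {
    codons <- substring(s, seq(1, 87, 3), seq(3, 89, 3))
    any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  flagged <- names(seqs) %in%
    flags$specimen_id[flags$flag_type == "pseudogene_stop"]
  expect_equal(unname(flagged), unname(oracle_has_stop))
})

test_that("k-mer containment screen separates contaminants with a margin", {
  set.seed(23)
  plant <- stats::setNames(
    vapply(1:2, function(i) barcodeval:::int_to_seq(
      sample.int(4, 120, TRUE)), character(1)), c("p1", "p2"))
  fungus <- stats::setNames(
    vapply(1:2, function(i) barcodeval:::int_to_seq(
      sample.int(4, 120, TRUE)), character(1)), c("f1", "f2"))
  aln <- marker_alignment("ITS2", c(
    good = plant[["p1"]],
    bad = fungus[["f1"]],
    chimera = paste0(substr(plant[["p1"]], 1, 60),
                     substr(fungus[["f1"]], 61, 120))))
  flags <- contaminant_screen(aln, plant, fungus)
  expect_equal(flags$specimen_id, "bad")
  # 50/50 chimera has near-equal containments: below the margin
  expect_false("chimera" %in% flags$specimen_id)
  expect_error(contaminant_screen(aln, plant, character()), "non-empty")
  # brute-force containment check for the flagged sequence
  kms <- function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - 7), 8:n))
  }
  q <- kms(fungus[["f1"]])
  best_c <- max(mean(q %in% kms(fungus[["f1"]])), mean(q %in% kms(fungus[["f2"]])))
  best_p <- max(mean(q %in% kms(plant[["p1"]])), mean(q %in% kms(plant[["p2"]])))
  expect_match(flags$evidence, sprintf("contaminant %.3f vs plant %.3f",
                                       best_c, best_p), fixed = TRUE)
})

nn_fixture <- function() {
  meta <- data.frame(
    specimen_id = paste0("s", 1:6),
    species = c("A x", "A x", "A x", "B y", "B y", "C z"),
    genus = c("A", "A", "A", "B", "B", "C"),
    family = "F", stringsAsFactors = FALSE)
  aln <- marker_alignment("rbcL", c(
    s1 = "AAAAAAAA", s2 = "AAAAAAAA", s3 = "AAAAAAAT",
    s4 = "CCCCCCCC", s5 = "CCCCCCCA", s6 = "GGGGGGGG"))
  link_dataset(list(aln), meta)
}

test_that("nearest-neighbour conflict states cover all cases", {
  ds <- nn_fixture()
  expect_equal(nn_conflict(ds, "rbcL", "s1")$status, "concordant")
  expect_equal(nn_conflict(ds, "rbcL", "s6")$status, "no_conspecific")
  # specimen identical to another species, far from conspecifics
  ds2 <- ds
  ds2$alignments$rbcL$seqs["s3"] <- "CCCCCCCC"
  r <- nn_conflict(ds2, "rbcL", "s3")
  expect_equal(r$status, "conflict")
  expect_equal(r$nearest_het_species, "B y")
  # an exact distance tie is concordant
  ds3 <- ds
  ds3$alignments$rbcL$seqs <- c(s1 = "AAAAAAAA", s2 = "AAAAAAAT",
                                s3 = "AAAAAAAT", s4 = "AAAAAATT",
                                s5 = "CCCCCCCC", s6 = "GGGGGGGG")
  # s1: nearest conspecific at d=1/8 (s2,s3), nearest het s4 at d=2/8
  expect_equal(nn_conflict(ds3, "rbcL", "s1")$status, "concordant")
  ds3$alignments$rbcL$seqs["s4"] <- "AAAAAAAT"  # ties s2/s3
  expect_equal(nn_conflict(ds3, "rbcL", "s1")$status, "concordant")
})

test_that("paralogy requires nuclear conflict with chloroplast concordance", {
  meta <- data.frame(
    specimen_id = paste0("s", 1:6),
    species = rep(c("A x", "B y"), each = 3),
    genus = rep(c("A", "B"), each = 3),
    family = "F", stringsAsFactors = FALSE)
  rbcL <- marker_alignment("rbcL", c(
    s1 = "AAAAAAAA", s2 = "AAAAAAAA", s3 = "AAAAAAAA",
    s4 = "CCCCCCCC", s5 = "CCCCCCCC", s6 = "CCCCCCCC"))
  its <- marker_alignment("ITS2", c(
    s1 = "TTTTTTTT", s2 = "TTTTTTTT", s3 = "GGGGGGGG",  # s3: foreign copy
    s4 = "GGGGGGGG", s5 = "GGGGGGGG", s6 = "GGGGGGGG"))
  ds <- link_dataset(list(rbcL, its), meta)
  pf <- paralogy_flags(ds, "ITS2", "rbcL")
  expect_equal(pf$specimen_id, "s3")
  expect_equal(pf$flag_type, "paralogy")

  # conflicting ITS2 AND conflicting rbcL is not paralogy
  ds2 <- ds
  ds2$alignments$rbcL$seqs["s3"] <- "CCCCCCCC"
  expect_equal(nrow(paralogy_flags(ds2, "ITS2", "rbcL")), 0L)
  # ...but it is a misidentification, with the true species implicated
  mf <- misidentification_flags(ds2)
  expect_equal(mf$specimen_id, "s3")
  expect_match(mf$evidence, "B y")
  # the two flag sets are disjoint by construction
  expect_length(intersect(paralogy_flags(ds2)$specimen_id,
                          mf$specimen_id), 0)
})

test_that("single-marker misidentification is flagged with a support note", {
  meta <- data.frame(
    specimen_id = paste0("s", 1:4),
    species = c("A x", "A x", "B y", "B y"),
    genus = c("A", "A", "B", "B"),
    family = "F", stringsAsFactors = FALSE)
  its <- marker_alignment("ITS2", c(
    s1 = "TTTTTTTT", s2 = "GGGGGGGG",  # s2 sits with B
    s3 = "GGGGGGGG", s4 = "GGGGGGGG"))
  ds <- link_dataset(list(its), meta)
  mf <- misidentification_flags(ds)
  expect_equal(mf$specimen_id, "s2")
  expect_match(mf$evidence, "low support")
})
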