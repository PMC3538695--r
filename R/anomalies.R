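# Planted anomalies and ground truth: introgression (shared chloroplast
# haplotype), ITS2 paralogy, pseudogenes (single-base deletion),
# contamination, misidentification (cross-genus label rotation) and
# herbarium marker dropout; plus the independent diagnosability oracle used
# to compute expected resolvability.

#' @noRd
chloroplast_markers_of <- function(params) {
  params$markers$name[params$markers$name != params$nuclear_marker]
}

#' Inject anomalies into a clean simulated library
#'
#' Planting rules (constraints keep each anomaly unambiguously detectable at
#' default divergences, and target specimen sets disjoint across types):
#' \itemize{
#' \item herbarium dropout: a seeded fraction of specimens is marked
#'   herbarium and markers are removed with per-source, per-marker failure
#'   probabilities, recorded in the recovery table (applied first, so later
#'   anomalies target surviving sequences);
#' \item introgression: in each target genus, one species' chloroplast
#'   haplotype is copied verbatim to all specimens of every other species
#'   except one divergent holdout;
#' \item paralogy: the nuclear sequence of a specimen (species with >= 3
#'   nuclear records; one per species) is replaced by a sequence evolved
#'   from a different genus's nuclear ancestor;
#' \item pseudogene: one base is deleted from a coding sequence (columns
#'   shift left, a gap pads the end);
#' \item contamination: a nuclear sequence is replaced by a mutated copy of
#'   a synthetic contaminant reference;
#' \item misidentification: species labels of specimens from different
#'   genera are rotated; the intraspecific variation of each affected
#'   species is first collapsed to a single haplotype (the typical plastid
#'   situation), which makes the label conflict unambiguous.
#' }
#'
#' @param dataset Clean \code{barcode_library} from
#'   \code{\link{simulate_sequences}}.
#' @param skeleton The matching taxonomy skeleton.
#' @param params The matching \code{\link{simulation_params}}.
#' @return List with \code{dataset} (modified library) and \code{truth}
#'   (class \code{ground_truth}): \code{anomalies} data frame,
#'   \code{introgressed_genera}, \code{holdout_species}, \code{true_species}
#'   (for relabelled specimens), \code{plant_refs},
#'   \code{contaminant_refs}, \code{seed}.
#' @export
inject_anomalies <- function(dataset, skeleton, params) {
  internals <- attr(dataset, "sim_internals")
  if (is.null(internals))
    stop("dataset lacks simulation internals; use simulate_sequences()")
  nuc <- params$nuclear_marker
  chl <- chloroplast_markers_of(params)
  mk <- params$markers
  anomalies <- data.frame(specimen_id = character(), marker = character(),
                          type = character(), detail = character(),
                          stringsAsFactors = FALSE)
  note <- function(id, marker, type, detail) {
    anomalies <<- rbind(anomalies, data.frame(
      specimen_id = id, marker = marker, type = type, detail = detail,
      stringsAsFactors = FALSE))
  }
  taken_species <- character()  # species already carrying a planted anomaly
  with_seed(substream(params$seed, "anomalies"), {
    meta <- dataset$specimens

    ## herbarium dropout -----------------------------------------------------
    n <- nrow(meta)
    n_herb <- round(params$herbarium_fraction * n)
    herb <- sample(meta$specimen_id, n_herb)
    meta$source <- ifelse(meta$specimen_id %in% herb, "herbarium", "fresh")
    meta$collection_year <- ifelse(meta$specimen_id %in% herb,
                                   2009L - sample(1:40, n, replace = TRUE),
                                   2009L)
    rec <- dataset$recovery
    for (m in mk$name) {
      p_fail <- ifelse(meta$source == "herbarium",
                       params$dropout_herbarium[[m]] %||% 0,
                       params$dropout_fresh[[m]] %||% 0)
      fail <- meta$specimen_id[stats::runif(n) < p_fail]
      if (length(fail)) {
        dataset$alignments[[m]]$seqs <-
          dataset$alignments[[m]]$seqs[
            !names(dataset$alignments[[m]]$seqs) %in% fail]
        rec$status[rec$marker == m & rec$specimen_id %in% fail] <-
          "attempted_failed"
      }
    }
    dataset$recovery <- rec

    has_marker <- function(id, m) id %in% names(dataset$alignments[[m]]$seqs)

    ## introgression ----------------------------------------------------------
    holdouts <- character()
    for (gen in skeleton$introgression_targets) {
      sp <- sort(skeleton$species$species[skeleton$species$genus == gen])
      donor <- sp[1L]
      holdout <- sp[length(sp)]
      holdouts <- c(holdouts, holdout)
      sharers <- setdiff(sp, holdout)
      for (m in chl) {
        hap <- int_to_seq(internals[[m]]$species_seq[[donor]])
        ids <- meta$specimen_id[meta$species %in% sharers]
        ids <- ids[vapply(ids, has_marker, TRUE, m = m)]
        dataset$alignments[[m]]$seqs[ids] <- hap
      }
      note(NA_character_, paste(chl, collapse = ","), "introgression",
           sprintf("genus %s: %d species share the %s chloroplast haplotype; holdout %s",
                   gen, length(sharers), donor, holdout))
      taken_species <- c(taken_species, sp)
    }

    ## paralogy ---------------------------------------------------------------
    sp_nuc_counts <- table(meta$species[
      meta$specimen_id %in% names(dataset$alignments[[nuc]]$seqs)])
    cand_sp <- setdiff(names(sp_nuc_counts)[sp_nuc_counts >= 3L],
                       taken_species)
    if (params$n_paralogs > length(cand_sp))
      stop("not enough eligible species for ", params$n_paralogs, " paralogs")
    par_sp <- if (params$n_paralogs) sample(cand_sp, params$n_paralogs)
              else character()
    nuc_rate <- mk$rate[mk$name == nuc]
    for (sp in par_sp) {
      ids <- meta$specimen_id[meta$species == sp &
                                vapply(meta$specimen_id, has_marker, TRUE,
                                       m = nuc)]
      id <- sample(ids, 1L)
      gen <- meta$genus[meta$specimen_id == id]
      donor_gen <- sample(setdiff(names(internals[[nuc]]$genus_anc),
                                  c(gen, unique(meta$genus[
                                    meta$species %in% taken_species]))), 1L)
      seq_int <- jc_evolve(internals[[nuc]]$genus_anc[[donor_gen]],
                           params$intraspecific_depth * nuc_rate)
      dataset$alignments[[nuc]]$seqs[[id]] <- int_to_seq(seq_int)
      note(id, nuc, "paralog",
           sprintf("%s copy evolved from ancestor of %s", nuc, donor_gen))
      taken_species <- c(taken_species, sp)
    }

    ## pseudogenes ------------------------------------------------------------
    coding_markers <- mk$name[mk$coding]
    cand <- meta$specimen_id[!meta$species %in% taken_species]
    cand <- cand[vapply(cand, function(id)
      any(vapply(coding_markers, has_marker, TRUE, id = id)), TRUE)]
    if (params$n_pseudogenes > length(cand))
      stop("not enough eligible specimens for pseudogenes")
    ps_ids <- if (params$n_pseudogenes) sample(cand, params$n_pseudogenes)
              else character()
    for (j in seq_along(ps_ids)) {
      id <- ps_ids[j]
      ms <- coding_markers[vapply(coding_markers, has_marker, TRUE, id = id)]
      m <- ms[1L + (j - 1L) %% length(ms)]
      s <- dataset$alignments[[m]]$seqs[[id]]
      pos <- sample.int(nchar(s), 1L)
      dataset$alignments[[m]]$seqs[[id]] <-
        paste0(substr(s, 1L, pos - 1L),
               substr(s, pos + 1L, nchar(s)), "-")
      note(id, m, "pseudogene", sprintf("single-base deletion at column %d",
                                        pos))
      taken_species <- c(taken_species,
                         meta$species[meta$specimen_id == id])
    }

    ## contamination ----------------------------------------------------------
    nuc_len <- mk$length[mk$name == nuc]
    contaminant_refs <- stats::setNames(
      vapply(seq_len(params$n_contaminant_refs), function(i)
        int_to_seq(sample.int(4L, nuc_len, replace = TRUE)), character(1)),
      sprintf("synthetic_contaminant_%d", seq_len(params$n_contaminant_refs)))
    plant_refs <- stats::setNames(
      vapply(internals[[nuc]]$family_root, int_to_seq, character(1)),
      paste0("plant_ref_", names(internals[[nuc]]$family_root)))
    cand <- meta$specimen_id[!meta$species %in% taken_species]
    cand <- cand[vapply(cand, has_marker, TRUE, m = nuc)]
    if (params$n_contaminants > length(cand))
      stop("not enough eligible specimens for contaminants")
    ct_ids <- if (params$n_contaminants) sample(cand, params$n_contaminants)
              else character()
    for (id in ct_ids) {
      ref <- sample(names(contaminant_refs), 1L)
      seq_int <- jc_evolve(encode_resolved(
        contaminant_refs[ref])[1L, ] |> match(.single_bits), 0.02)
      dataset$alignments[[nuc]]$seqs[[id]] <- int_to_seq(seq_int)
      note(id, nuc, "contaminant", sprintf("replaced by mutated %s", ref))
      taken_species <- c(taken_species,
                         meta$species[meta$specimen_id == id])
    }

    ## misidentification ------------------------------------------------------
    # source species need >= 3 specimens: after one is relabelled away its
    # siblings must still have a true label-conspecific, so the NN rule
    # cannot false-flag them
    sp_counts <- table(meta$species)
    cand_sp <- setdiff(names(sp_counts)[sp_counts >= 3L], taken_species)
    cand_gen <- unique(meta$genus[meta$species %in% cand_sp])
    if (params$n_misidentifications > 0 &&
        length(cand_gen) < max(2L, params$n_misidentifications))
      stop("not enough eligible genera for misidentifications")
    true_species <- character()
    if (params$n_misidentifications > 0) {
      k <- max(2L, params$n_misidentifications)
      gens <- sample(cand_gen, k)
      pick <- vapply(gens, function(g) {
        sp <- sample(intersect(cand_sp, meta$species[meta$genus == g]), 1L)
        sample(meta$specimen_id[meta$species == sp], 1L)
      }, character(1))
      # collapse intraspecific variation of each affected species
      for (id in pick) {
        sp <- meta$species[meta$specimen_id == id]
        sp_ids <- meta$specimen_id[meta$species == sp]
        for (m in mk$name) {
          hap <- int_to_seq(internals[[m]]$species_seq[[sp]])
          present <- sp_ids[vapply(sp_ids, has_marker, TRUE, m = m)]
          dataset$alignments[[m]]$seqs[present] <- hap
        }
        taken_species <- c(taken_species, sp)
      }
      old <- meta[match(pick, meta$specimen_id),
                  c("species", "genus", "family", "order")]
      new_idx <- c(seq_along(pick)[-1L], 1L)
      for (j in seq_len(params$n_misidentifications)) {
        id <- pick[j]
        tgt <- old[new_idx[j], ]
        true_species[id] <- old$species[j]
        meta[meta$specimen_id == id,
             c("species", "genus", "family", "order")] <- tgt
        note(id, paste(mk$name, collapse = ","), "misidentification",
             sprintf("labelled %s, true species %s", tgt$species,
                     old$species[j]))
      }
    }

    dataset$specimens <- meta
    truth <- structure(list(
      anomalies = anomalies,
      introgressed_genera = skeleton$introgression_targets,
      holdout_species = holdouts,
      true_species = true_species,
      plant_refs = plant_refs,
      contaminant_refs = contaminant_refs,
      seed = params$seed), class = "ground_truth")
    attr(dataset, "sim_internals") <- internals
    list(dataset = dataset, truth = truth)
  })
}

# ---- independent diagnosability oracle --------------------------------------

#' Expected resolvability by the diagnosability oracle
#'
#' An independent, loop-based re-derivation of which species carry at least
#' one diagnostic column in a marker combination, used as ground truth for
#' the pipeline.  Inclusion mimics the combined-analysis rule (nuclear plus
#' at least one chloroplast marker when the combination spans both genomes,
#' any marker otherwise); missing partitions are treated as uninformative.
#'
#' @param dataset A \code{barcode_library}.
#' @param markers Character vector of marker names.
#' @param nuclear_marker Nuclear marker name.
#' @return Data frame \code{species}, \code{resolvable}.
#' @export
oracle_resolvable <- function(dataset, markers, nuclear_marker = "ITS2") {
  meta <- dataset$specimens
  nuc <- intersect(nuclear_marker, markers)
  chl <- setdiff(markers, nuclear_marker)
  included <- character()
  for (id in meta$specimen_id) {
    have <- vapply(markers, function(m)
      id %in% names(dataset$alignments[[m]]$seqs), TRUE)
    ok <- if (length(nuc) && length(chl))
      have[nuc] && any(have[chl]) else any(have)
    if (isTRUE(ok)) included <- c(included, id)
  }
  rows <- lapply(included, function(id) {
    unlist(lapply(markers, function(m) {
      s <- dataset$alignments[[m]]$seqs
      width <- dataset$alignments[[m]]$columns
      if (id %in% names(s)) chars_of(s[[id]]) else rep("?", width)
    }))
  })
  names(rows) <- included
  sp_of <- stats::setNames(meta$species, meta$specimen_id)
  out <- lapply(sort(unique(sp_of[included])), function(sp) {
    members <- included[sp_of[included] == sp]
    others <- setdiff(included, members)
    resolvable <- FALSE
    if (length(others)) {
      L <- length(rows[[1L]])
      for (j in seq_len(L)) {
        vals <- vapply(members, function(id) rows[[id]][j], "")
        if (any(!vals %in% .base_chars)) next
        if (length(unique(vals)) != 1L) next
        other_vals <- vapply(others, function(id) rows[[id]][j], "")
        if (!vals[1L] %in% other_vals) { resolvable <- TRUE; break }
      }
    }
    data.frame(species = sp, resolvable = resolvable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# ---- one-call generator and file round trip ---------------------------------

#' Simulate a complete synthetic barcode library
#'
#' @param params A \code{\link{simulation_params}} object.
#' @param anomalies Apply \code{\link{inject_anomalies}} (planted anomalies
#'   and herbarium dropout)?  With \code{FALSE} the clean library is
#'   returned with an empty truth record.
#' @param resolvable_combos Marker combinations for which the
#'   diagnosability oracle is evaluated into the truth record (default: the
#'   full marker set).
#' @return List with \code{dataset}, \code{truth} and \code{skeleton}.
#' @export
simulate_library <- function(params = simulation_params(), anomalies = TRUE,
                             resolvable_combos =
                               list(params$markers$name)) {
  skeleton <- simulate_taxonomy(params)
  dataset <- simulate_sequences(skeleton, params)
  if (anomalies) {
    res <- inject_anomalies(dataset, skeleton, params)
    dataset <- res$dataset
    truth <- res$truth
  } else {
    truth <- structure(list(
      anomalies = data.frame(specimen_id = character(), marker = character(),
                             type = character(), detail = character()),
      introgressed_genera = character(), holdout_species = character(),
      true_species = character(), plant_refs = character(),
      contaminant_refs = character(), seed = params$seed),
      class = "ground_truth")
  }
  # resolvability truth is computed after removing planted pseudogene and
  # contaminant sequences, mirroring their stated exclusion from analysis
  oracle_input <- dataset
  excl <- truth$anomalies[truth$anomalies$type %in%
                            c("pseudogene", "contaminant"), , drop = FALSE]
  for (i in seq_len(nrow(excl))) {
    m <- excl$marker[i]
    s <- oracle_input$alignments[[m]]$seqs
    oracle_input$alignments[[m]]$seqs <- s[names(s) != excl$specimen_id[i]]
  }
  truth$expected_resolvable <- stats::setNames(
    lapply(resolvable_combos, function(cmb)
      oracle_resolvable(oracle_input, cmb, params$nuclear_marker)),
    vapply(resolvable_combos, paste, "", collapse = "+"))
  list(dataset = dataset, truth = truth, skeleton = skeleton)
}

#' Write a simulated library to disk
#'
#' Emits one aligned FASTA per marker, \code{metadata.tsv},
#' \code{recovery.tsv}, \code{truth.json} and the synthetic reference FASTA
#' files for the contamination screen.  Output is deterministic: re-running
#' with the same seed gives byte-identical files.
#'
#' @param dataset A \code{barcode_library}.
#' @param truth The matching \code{ground_truth} (optional).
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
emit_library <- function(dataset, truth = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(dataset$alignments))
    write_marker_fasta(dataset$alignments[[m]],
                       file.path(out_dir, paste0(m, ".fasta")))
  write_metadata(dataset$specimens, file.path(out_dir, "metadata.tsv"))
  if (!is.null(dataset$recovery)) {
    rec <- dataset$recovery[order(dataset$recovery$specimen_id,
                                  dataset$recovery$marker), ]
    utils::write.table(rec, file.path(out_dir, "recovery.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth)) {
    if (length(truth$plant_refs))
      write_marker_fasta(marker_alignment("plant_refs", truth$plant_refs),
                         file.path(out_dir, "plant_refs.synthetic.fasta"))
    if (length(truth$contaminant_refs))
      write_marker_fasta(
        marker_alignment("contaminant_refs", truth$contaminant_refs),
        file.path(out_dir, "contaminant_refs.synthetic.fasta"))
    tr <- truth
    class(tr) <- NULL
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(out_dir)
}

#' Read a library directory written by \code{\link{emit_library}}
#'
#' @param dir Directory containing per-marker FASTA files,
#'   \code{metadata.tsv} and optionally \code{recovery.tsv}.
#' @param markers Marker names (default: all non-reference \code{.fasta}
#'   files in the directory).
#' @return A \code{barcode_library}.
#' @export
read_library <- function(dir, markers = NULL) {
  if (is.null(markers)) {
    fa <- list.files(dir, pattern = "\\.fasta$")
    fa <- fa[!grepl("synthetic", fa)]
    markers <- sub("\\.fasta$", "", fa)
  }
  alignments <- lapply(markers, function(m)
    read_marker_fasta(file.path(dir, paste0(m, ".fasta")), m))
  specimens <- read_metadata(file.path(dir, "metadata.tsv"))
  rec_path <- file.path(dir, "recovery.tsv")
  recovery <- if (file.exists(rec_path)) read_recovery(rec_path) else NULL
  link_dataset(alignments, specimens, recovery = recovery)
}
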