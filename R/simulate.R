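# Synthetic barcode-library generator: taxonomy skeleton, Jukes-Cantor
# sequence evolution along grafted family/genus trees, planted anomalies
# (introgression, ITS2 paralogy, pseudogenes, contamination,
# misidentification, herbarium dropout) and the ground-truth record.

#' Default marker specification
#'
#' Three markers mirroring a northern vascular-plant library: a slow coding
#' chloroplast marker (rbcL, 552 bp), a faster coding chloroplast marker
#' (matK, 800 bp) and a fast non-coding nuclear spacer (ITS2, 350 bp).
#' Rate multipliers scale the substitution depth per marker.
#'
#' @return Data frame with columns \code{name}, \code{length}, \code{rate},
#'   \code{coding}.
#' @export
default_markers <- function() {
  data.frame(name = c("rbcL", "matK", "ITS2"),
             length = c(552L, 800L, 350L),
             rate = c(1, 2.4, 7),
             coding = c(TRUE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}

#' Simulation parameters
#'
#' Defaults emulate the design of a local-flora barcode library: tens of
#' genera with a 0.6 monotypic fraction, 2-5 specimens per species, three
#' markers with rate ordering rbcL < matK < ITS2, a 0.05 expected
#' substitutions/site interspecific depth and 0.002 intraspecific depth, a
#' 40\% herbarium fraction and length-dependent herbarium dropout.
#'
#' @param n_families Number of families.
#' @param genera_per_family Integer range \code{c(min, max)}.
#' @param monotypic_fraction Probability that a genus has a single species.
#' @param polytypic_extra_lambda Poisson mean of extra species beyond 2 in
#'   polytypic genera.
#' @param specimens_per_species Integer range \code{c(min, max)}.
#' @param markers Marker specification (see \code{\link{default_markers}}).
#' @param interspecific_depth Expected substitutions/site (rate multiplier
#'   1) from family root to species tips.
#' @param species_stem Guaranteed private branch length per species,
#'   ensuring established species are distinct at default rates.
#' @param intraspecific_depth Expected substitutions/site separating two
#'   conspecific specimens.
#' @param diagnostic_tags Add a conserved diagnostic block: a reserved
#'   column per species, fixed to C library-wide, in which that species
#'   alone carries a G.  This emulates the species-diagnostic substitutions
#'   at otherwise conserved positions that make real barcode markers
#'   diagnosable, and makes every species' resolvability deterministic on
#'   clean data.
#' @param n_introgressed_genera Number of genera given a shared chloroplast
#'   haplotype (all species but one holdout).
#' @param introgressed_genus_size Forced species count of introgressed
#'   genera.
#' @param n_paralogs,n_pseudogenes,n_contaminants,n_misidentifications
#'   Numbers of planted anomalies of each type.
#' @param herbarium_fraction Fraction of specimens marked herbarium.
#' @param dropout_fresh,dropout_herbarium Named per-marker probabilities of
#'   sequencing failure by tissue source.
#' @param n_contaminant_refs Number of synthetic contaminant reference
#'   sequences generated.
#' @param nuclear_marker Name of the nuclear marker used for paralog and
#'   contamination planting.
#' @param seed Integer seed; all generator randomness flows from it through
#'   named substreams.
#' @return List of class \code{simulation_params}.
#' @export
simulation_params <- function(n_families = 10L,
                              genera_per_family = c(1L, 5L),
                              monotypic_fraction = 0.6,
                              polytypic_extra_lambda = 1,
                              specimens_per_species = c(2L, 5L),
                              markers = default_markers(),
                              interspecific_depth = 0.05,
                              species_stem = interspecific_depth / 4,
                              intraspecific_depth = 0.002,
                              diagnostic_tags = TRUE,
                              n_introgressed_genera = 0L,
                              introgressed_genus_size = 9L,
                              n_paralogs = 0L,
                              n_pseudogenes = 0L,
                              n_contaminants = 0L,
                              n_misidentifications = 0L,
                              herbarium_fraction = 0.4,
                              dropout_fresh = c(rbcL = 0.05, matK = 0.17,
                                                ITS2 = 0.11),
                              dropout_herbarium = c(rbcL = 0.15, matK = 0.47,
                                                    ITS2 = 0.12),
                              n_contaminant_refs = 3L,
                              nuclear_marker = "ITS2",
                              seed = 1L) {
  stopifnot(n_families >= 1, monotypic_fraction >= 0, monotypic_fraction <= 1,
            interspecific_depth > 0, intraspecific_depth >= 0,
            herbarium_fraction >= 0, herbarium_fraction <= 1,
            all(markers$rate >= 0), all(markers$length >= 1))
  structure(as.list(environment()), class = "simulation_params")
}

# ---- taxonomy ---------------------------------------------------------------

#' Simulate a taxonomy skeleton
#'
#' Families, genera (monotypic with the stated probability), species and
#' specimen counts; naming is deterministic given the seed.  When
#' introgression is requested, the first \code{n_introgressed_genera} genera
#' are forced to \code{introgressed_genus_size} species and recorded as
#' targets.
#'
#' @param params A \code{\link{simulation_params}} object.
#' @return List of class \code{taxonomy_skeleton} with \code{specimens}
#'   (metadata data frame), \code{species} (per-species summary) and
#'   \code{introgression_targets} (genus names).
#' @export
simulate_taxonomy <- function(params) {
  with_seed(substream(params$seed, "taxonomy"), {
    gen_counter <- 0L
    sp_rows <- list()
    intro_targets <- character()
    for (fi in seq_len(params$n_families)) {
      fam <- sprintf("Family%02d", fi)
      ord <- sprintf("Order%02d", (fi - 1L) %/% 3L + 1L)
      n_gen <- sample(seq(params$genera_per_family[1L],
                          params$genera_per_family[2L]), 1L)
      for (gi in seq_len(n_gen)) {
        gen_counter <- gen_counter + 1L
        gen <- sprintf("Genus%03d", gen_counter)
        if (length(intro_targets) < params$n_introgressed_genera) {
          n_sp <- params$introgressed_genus_size
          intro_targets <- c(intro_targets, gen)
        } else if (stats::runif(1) < params$monotypic_fraction) {
          n_sp <- 1L
        } else {
          n_sp <- 2L + stats::rpois(1L, params$polytypic_extra_lambda)
        }
        for (si in seq_len(n_sp)) {
          sp <- sprintf("%s sp%d", gen, si)
          n_spec <- sample(seq(params$specimens_per_species[1L],
                               params$specimens_per_species[2L]), 1L)
          sp_rows[[length(sp_rows) + 1L]] <- data.frame(
            order = ord, family = fam, genus = gen, species = sp,
            n_specimens = n_spec, stringsAsFactors = FALSE)
        }
      }
    }
    species <- do.call(rbind, sp_rows)
    n_total <- sum(species$n_specimens)
    specimen_id <- sprintf("SPM%04d", seq_len(n_total))
    specimens <- data.frame(
      specimen_id = specimen_id,
      species = rep(species$species, species$n_specimens),
      genus = rep(species$genus, species$n_specimens),
      family = rep(species$family, species$n_specimens),
      order = rep(species$order, species$n_specimens),
      source = "fresh", collection_year = NA_integer_,
      stringsAsFactors = FALSE)
    structure(list(specimens = specimens, species = species,
                   introgression_targets = intro_targets),
              class = "taxonomy_skeleton")
  })
}

# ---- sequence evolution -----------------------------------------------------

.base_chars <- c("A", "C", "G", "T")
# frame-0 codon ids (16*(b1-1) + 4*(b2-1) + b3) of TAA, TAG, TGA
.stop_codon_ids <- c(49L, 51L, 57L)

#' @noRd
int_to_seq <- function(v) paste(.base_chars[v], collapse = "")

# Exact Jukes-Cantor transition sampling along a branch of length b
# (expected substitutions/site); integer-coded sequences (1..4).
#' @noRd
jc_evolve <- function(seq_int, b) {
  if (b <= 0) return(seq_int)
  p_same <- 0.25 + 0.75 * exp(-4 * b / 3)
  mut <- stats::runif(length(seq_int)) > p_same
  if (any(mut)) {
    shift <- sample.int(3L, sum(mut), replace = TRUE)
    seq_int[mut] <- ((seq_int[mut] - 1L + shift) %% 4L) + 1L
  }
  seq_int
}

# Replace any frame-0 stop codon by the ancestral codon (ancestor assumed
# stop-free), keeping coding markers ORF-clean on anomaly-free data.
#' @noRd
fix_stops <- function(seq_int, anc_int) {
  n_codon <- length(seq_int) %/% 3L
  if (n_codon == 0L) return(seq_int)
  i1 <- 3L * (seq_len(n_codon) - 1L) + 1L
  ids <- 16L * (seq_int[i1] - 1L) + 4L * (seq_int[i1 + 1L] - 1L) +
    seq_int[i1 + 2L]
  bad <- which(ids %in% .stop_codon_ids)
  for (j in bad) {
    idx <- (3L * (j - 1L) + 1L):(3L * j)
    seq_int[idx] <- anc_int[idx]
  }
  seq_int
}

#' @noRd
evolve_branch <- function(seq_int, b, coding) {
  out <- jc_evolve(seq_int, b)
  if (coding) out <- fix_stops(out, seq_int)
  out
}

# Random root sequence; coding roots are sampled codon-wise excluding stops.
#' @noRd
random_root <- function(len, coding) {
  if (!coding) return(sample.int(4L, len, replace = TRUE))
  n_codon <- len %/% 3L
  rest <- len - 3L * n_codon
  repeat_draw <- function(n) {
    ids <- sample.int(64L, n, replace = TRUE)
    while (any(ids %in% .stop_codon_ids))
      ids[ids %in% .stop_codon_ids] <- sample.int(64L,
        sum(ids %in% .stop_codon_ids), replace = TRUE)
    ids
  }
  ids <- repeat_draw(n_codon) - 1L
  codons <- rbind(ids %/% 16L, (ids %% 16L) %/% 4L, ids %% 4L) + 1L
  c(as.vector(codons), sample.int(4L, rest, replace = TRUE))
}

# Evolve sequences for the tips of an ultrametric genus tree, returning a
# named list of integer sequences.
#' @noRd
evolve_along_tree <- function(tree, root_seq, rate, coding) {
  tr <- stats::reorder(tree, "cladewise")
  n_node <- max(tr$edge)
  seqs <- vector("list", n_node)
  root <- ape::Ntip(tr) + 1L
  seqs[[root]] <- root_seq
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    seqs[[ch]] <- evolve_branch(seqs[[p]], tr$edge.length[e] * rate, coding)
  }
  stats::setNames(seqs[seq_len(ape::Ntip(tr))], tr$tip.label)
}

#' Simulate clean sequences over a taxonomy skeleton
#'
#' Per marker: a random family root (stop-free codons for coding markers), a
#' branch to each genus ancestor, a pure-birth species tree within each
#' genus (depth \code{interspecific_depth / 2}) plus a guaranteed private
#' species stem, and a terminal branch of \code{intraspecific_depth / 2} per
#' specimen.  Branch lengths are multiplied by the marker's rate.
#' Substitutions follow exact Jukes-Cantor transition probabilities; there
#' are no indels, so sequences are trivially aligned.
#'
#' @param skeleton A \code{\link{simulate_taxonomy}} result.
#' @param params The matching \code{\link{simulation_params}}.
#' @return A clean \code{barcode_library}; internal ancestral sequences are
#'   attached for use by \code{\link{inject_anomalies}}.
#' @export
simulate_sequences <- function(skeleton, params) {
  with_seed(substream(params$seed, "sequences"), {
    mk <- params$markers
    specs <- skeleton$specimens
    species_tab <- skeleton$species
    fams <- unique(species_tab$family)
    alignments <- list()
    internals <- list()
    for (i in seq_len(nrow(mk))) {
      marker <- mk$name[i]; len <- mk$length[i]
      rate <- mk$rate[i]; coding <- mk$coding[i]
      genus_anc <- list(); species_seq <- list(); family_root <- list()
      for (fam in fams) {
        root <- random_root(len, coding)
        family_root[[fam]] <- root
        for (gen in unique(species_tab$genus[species_tab$family == fam])) {
          anc <- evolve_branch(root, params$interspecific_depth * rate,
                               coding)
          genus_anc[[gen]] <- anc
          sp <- species_tab$species[species_tab$genus == gen]
          if (length(sp) == 1L) {
            tip_seqs <- stats::setNames(
              list(evolve_branch(anc, (params$interspecific_depth / 2) * rate,
                                 coding)), sp)
          } else {
            tr <- ape::rphylo(length(sp), birth = 1, death = 0)
            tr$tip.label <- sp
            depth <- max(ape::node.depth.edgelength(tr))
            tr$edge.length <- tr$edge.length *
              (params$interspecific_depth / 2) / depth
            tip_seqs <- evolve_along_tree(tr, anc, rate, coding)
          }
          for (s in names(tip_seqs))
            species_seq[[s]] <- evolve_branch(tip_seqs[[s]],
                                              params$species_stem * rate,
                                              coding)
        }
      }
      if (isTRUE(params$diagnostic_tags)) {
        # conserved diagnostic block: reserved column i is C library-wide
        # except in species i, which carries a private G (stop-safe: no T
        # can appear in these codons)
        n_res <- min(nrow(species_tab), len)
        res_cols <- seq_len(n_res)
        tag_col <- stats::setNames(res_cols,
                                   species_tab$species[seq_len(n_res)])
        fix_block <- function(seq_int, sp = NULL) {
          seq_int[res_cols] <- 2L  # C
          if (!is.null(sp) && !is.na(tag_col[sp]))
            seq_int[tag_col[[sp]]] <- 3L  # G
          seq_int
        }
        family_root <- lapply(family_root, fix_block)
        genus_anc <- lapply(genus_anc, fix_block)
        species_seq <- stats::setNames(
          lapply(names(species_seq), function(sp)
            fix_block(species_seq[[sp]], sp)), names(species_seq))
      }
      seqs <- vapply(seq_len(nrow(specs)), function(j) {
        base <- species_seq[[specs$species[j]]]
        out <- evolve_branch(base, (params$intraspecific_depth / 2) * rate,
                             coding)
        if (isTRUE(params$diagnostic_tags)) {
          n_res <- min(nrow(species_tab), len)
          out[seq_len(n_res)] <- base[seq_len(n_res)]
        }
        int_to_seq(out)
      }, character(1))
      names(seqs) <- specs$specimen_id
      alignments[[marker]] <- marker_alignment(marker, seqs)
      internals[[marker]] <- list(family_root = family_root,
                                  genus_anc = genus_anc,
                                  species_seq = species_seq)
    }
    recovery <- data.frame(
      specimen_id = rep(specs$specimen_id, nrow(mk)),
      marker = rep(mk$name, each = nrow(specs)),
      status = "succeeded", stringsAsFactors = FALSE)
    dataset <- link_dataset(alignments, specs, recovery = recovery)
    attr(dataset, "sim_internals") <- internals
    dataset
  })
}
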