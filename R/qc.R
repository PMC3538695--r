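# Quality-control flags: pseudogenes (frameshift length changes, internal
# stop codons), contamination (k-mer containment against reference sets),
# and nearest-neighbour conflict rules for ITS2 paralogy and specimen
# misidentification.

.stop_codons <- list(standard = c("TAA", "TAG", "TGA"),
                     plastid = c("TAA", "TAG", "TGA"))

#' @noRd
qc_flag <- function(specimen_id, marker, flag_type, evidence) {
  data.frame(specimen_id = specimen_id, marker = marker,
             flag_type = flag_type, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' @noRd
empty_flags <- function() {
  data.frame(specimen_id = character(), marker = character(),
             flag_type = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

#' @noRd
degap <- function(seq) gsub("[-?]", "", seq)

# Internal stop-codon positions (codon index, 1-based) of an ungapped
# sequence read from frame_offset; the final complete codon is terminal, not
# internal.  Codons with ambiguity never count as stops.
#' @noRd
internal_stops <- function(seq, frame_offset, stops) {
  n <- nchar(seq)
  n_codons <- (n - frame_offset) %/% 3L
  if (n_codons < 2L) return(integer())
  starts <- frame_offset + 1L + 3L * (seq_len(n_codons - 1L) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  which(codons %in% stops)
}

#' Open-reading-frame screen for a protein-coding marker
#'
#' Flags putative pseudogenes and editing errors in a coding alignment:
#' \code{pseudogene_frameshift} when a sequence's ungapped length differs
#' from the modal ungapped length by a non-multiple of 3, and
#' \code{pseudogene_stop} when the stated reading frame contains one or more
#' internal stop codons.  The modal-length reference is recomputed once
#' after excluding stop-flagged rows.
#'
#' @param aln A \code{marker_alignment} for a coding marker.
#' @param frame_offset Reading-frame offset (0, 1 or 2), or \code{NULL} to
#'   infer it as the frame minimising internal stops over the modal
#'   sequence.
#' @param genetic_code \code{"plastid"} (default) or \code{"standard"};
#'   both use the stop set TAA/TAG/TGA.
#' @param coding Set \code{FALSE} to signal a non-coding marker (error).
#' @return A flags data frame (\code{specimen_id}, \code{marker},
#'   \code{flag_type}, \code{evidence}), zero rows if clean.
#' @export
orf_check <- function(aln, frame_offset = NULL,
                      genetic_code = c("plastid", "standard"),
                      coding = TRUE) {
  genetic_code <- match.arg(genetic_code)
  if (!coding)
    stop("marker '", aln$marker, "' is not protein-coding; skip the ORF screen")
  stops <- .stop_codons[[genetic_code]]
  ungapped <- vapply(aln$seqs, degap, character(1))
  lens <- nchar(ungapped)
  if (is.null(frame_offset)) {
    modal_len <- as.integer(names(which.max(table(lens))))
    modal_seq <- ungapped[lens == modal_len][
      which.max(table(ungapped[lens == modal_len])[
        ungapped[lens == modal_len]])]
    n_stops <- vapply(0:2, function(f)
      length(internal_stops(modal_seq, f, stops)), 0L)
    frame_offset <- which.min(n_stops) - 1L
  }
  stopifnot(frame_offset %in% 0:2)
  flags <- empty_flags()
  stop_flagged <- character()
  for (id in names(ungapped)) {
    pos <- internal_stops(ungapped[[id]], frame_offset, stops)
    if (length(pos)) {
      stop_flagged <- c(stop_flagged, id)
      flags <- rbind(flags, qc_flag(id, aln$marker, "pseudogene_stop",
        sprintf("internal stop codon(s) at codon %s (frame %d, %s code)",
                paste(pos, collapse = ","), frame_offset, genetic_code)))
    }
  }
  # modal length from rows without internal stops, iterated once
  ref_lens <- lens[setdiff(names(lens), stop_flagged)]
  if (length(ref_lens) == 0L) ref_lens <- lens
  modal_len <- as.integer(names(which.max(table(ref_lens))))
  for (id in names(ungapped)) {
    delta <- lens[[id]] - modal_len
    if (delta %% 3L != 0L) {
      flags <- rbind(flags, qc_flag(id, aln$marker, "pseudogene_frameshift",
        sprintf("ungapped length %d differs from modal %d by %+d (not a multiple of 3)",
                lens[[id]], modal_len, delta)))
    }
  }
  flags
}

#' @noRd
kmer_set <- function(seq, k) {
  seq <- toupper(degap(seq))
  n <- nchar(seq)
  if (n < k) return(character())
  km <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  unique(km[!grepl("[^ACGT]", km)])
}

#' @noRd
containment <- function(query_kmers, ref_kmers) {
  if (length(query_kmers) == 0L) return(0)
  mean(query_kmers %in% ref_kmers)
}

#' Reference-based contamination screen
#'
#' Classifies each sequence by maximum k-mer containment similarity against
#' a plant reference set and a contaminant (e.g. fungal/algal) reference
#' set; a sequence is flagged \code{contaminant} when its best contaminant
#' similarity exceeds its best plant similarity by at least \code{delta}.
#'
#' @param aln A \code{marker_alignment}.
#' @param plant_refs,contaminant_refs Named character vectors of reference
#'   sequences (non-empty).
#' @param k k-mer size (default 8).
#' @param delta Required similarity margin (default 0.1).
#' @return A flags data frame, zero rows if clean.
#' @export
contaminant_screen <- function(aln, plant_refs, contaminant_refs, k = 8L,
                               delta = 0.1) {
  if (length(plant_refs) == 0L || length(contaminant_refs) == 0L)
    stop("both reference sets must be non-empty")
  pk <- lapply(plant_refs, kmer_set, k = k)
  ck <- lapply(contaminant_refs, kmer_set, k = k)
  flags <- empty_flags()
  for (id in names(aln$seqs)) {
    q <- kmer_set(aln$seqs[[id]], k)
    best_p <- max(vapply(pk, containment, 0, query_kmers = q))
    best_c <- max(vapply(ck, containment, 0, query_kmers = q))
    if (best_c - best_p >= delta) {
      flags <- rbind(flags, qc_flag(id, aln$marker, "contaminant",
        sprintf("k-mer containment: contaminant %.3f vs plant %.3f (k=%d)",
                best_c, best_p, k)))
    }
  }
  flags
}

#' Nearest-neighbour conflict status of a specimen for one marker
#'
#' \code{conflict} when the nearest heterospecific specimen (p-distance,
#' pairwise deletion) is strictly closer than the nearest conspecific;
#' distance ties are \code{concordant}.  \code{no_data} when the specimen
#' lacks the marker (or no distance is defined), \code{no_conspecific} when
#' no conspecific specimen carries the marker.
#'
#' @param dataset A \code{barcode_library}.
#' @param marker Marker name.
#' @param specimen_id Specimen to evaluate.
#' @param dist An optional precomputed p-distance matrix over the marker's
#'   sequences (from \code{barcodeval:::distance_matrix}); computed on the
#'   fly otherwise.
#' @return List: \code{status} (one of the four states), \code{nearest_het}
#'   (specimen ID or NA), \code{nearest_het_species}, \code{d_con},
#'   \code{d_het}.
#' @export
nn_conflict <- function(dataset, marker, specimen_id, dist = NULL) {
  aln <- dataset$alignments[[marker]]
  res <- list(status = "no_data", nearest_het = NA_character_,
              nearest_het_species = NA_character_, d_con = NA_real_,
              d_het = NA_real_)
  if (is.null(aln) || !(specimen_id %in% names(aln$seqs))) return(res)
  meta <- dataset$specimens
  ids <- intersect(meta$specimen_id, names(aln$seqs))
  if (is.null(dist)) dist <- distance_matrix(aln$seqs[ids], "p")
  sp_of <- stats::setNames(meta$species, meta$specimen_id)
  self_sp <- sp_of[[specimen_id]]
  others <- setdiff(ids, specimen_id)
  con <- others[sp_of[others] == self_sp]
  het <- others[sp_of[others] != self_sp]
  d_con <- if (length(con)) dist[specimen_id, con] else numeric()
  d_con <- d_con[!is.na(d_con)]
  if (length(d_con) == 0L) {
    res$status <- if (length(con)) "no_data" else "no_conspecific"
    return(res)
  }
  d_het <- if (length(het)) dist[specimen_id, het] else numeric()
  d_het <- d_het[!is.na(d_het)]
  if (length(d_het) == 0L) { res$status <- "concordant"; return(res) }
  i <- which.min(d_het)
  res$d_con <- min(d_con)
  res$d_het <- unname(d_het[i])
  res$nearest_het <- names(d_het)[i]
  res$nearest_het_species <- unname(sp_of[[res$nearest_het]])
  res$status <- if (res$d_het < res$d_con) "conflict" else "concordant"
  res
}

# Conflict status for every specimen x marker (internal, reuses distance
# matrices).
#' @noRd
nn_status_table <- function(dataset, markers) {
  out <- list()
  for (m in markers) {
    aln <- dataset$alignments[[m]]
    if (is.null(aln)) next
    ids <- intersect(dataset$specimens$specimen_id, names(aln$seqs))
    if (length(ids) < 2L) next
    dm <- distance_matrix(aln$seqs[ids], "p")
    for (id in ids) {
      r <- nn_conflict(dataset, m, id, dist = dm)
      out[[length(out) + 1L]] <- data.frame(
        specimen_id = id, marker = m, status = r$status,
        nearest_het_species = r$nearest_het_species,
        d_con = r$d_con, d_het = r$d_het, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(specimen_id = character(), marker = character(),
                      status = character(),
                      nearest_het_species = character(),
                      d_con = numeric(), d_het = numeric()))
  do.call(rbind, out)
}

#' Flag putative ITS2 paralogs
#'
#' A specimen's nuclear sequence is flagged \code{paralogy} when its
#' nearest-neighbour placement conflicts with its species label while every
#' chloroplast marker with an informative status supports the label
#' (at least one informative chloroplast marker is required, so the call is
#' never made on nuclear evidence alone).
#'
#' @param dataset A \code{barcode_library}.
#' @param nuclear_marker Nuclear marker name (default \code{"ITS2"}).
#' @param chloroplast_markers Chloroplast marker names present in the
#'   dataset.
#' @return A flags data frame.
#' @export
paralogy_flags <- function(dataset, nuclear_marker = "ITS2",
                           chloroplast_markers = c("rbcL", "matK")) {
  chloroplast_markers <- intersect(chloroplast_markers,
                                   names(dataset$alignments))
  tab <- nn_status_table(dataset, c(nuclear_marker, chloroplast_markers))
  flags <- empty_flags()
  nuc <- tab[tab$marker == nuclear_marker & tab$status == "conflict", ,
             drop = FALSE]
  for (i in seq_len(nrow(nuc))) {
    id <- nuc$specimen_id[i]
    chl <- tab[tab$specimen_id == id & tab$marker %in% chloroplast_markers &
                 tab$status %in% c("conflict", "concordant"), , drop = FALSE]
    if (nrow(chl) >= 1L && all(chl$status == "concordant")) {
      flags <- rbind(flags, qc_flag(id, nuclear_marker, "paralogy",
        sprintf("%s nearest neighbour is %s (d=%.4g) vs conspecific d=%.4g; chloroplast concordant (%s)",
                nuclear_marker, nuc$nearest_het_species[i], nuc$d_het[i],
                nuc$d_con[i], paste(chl$marker, collapse = ","))))
    }
  }
  flags
}

#' Flag putative specimen misidentifications
#'
#' A specimen is flagged \code{misidentification} when every marker with an
#' informative nearest-neighbour status returns a conflict and the nearest
#' heterospecific species agrees across those markers.  With a single
#' informative marker the flag is still raised and the evidence notes the
#' low marker support.
#'
#' @param dataset A \code{barcode_library}.
#' @param markers Markers to use (default: all in the dataset).
#' @return A flags data frame; the evidence names the implicated species.
#' @export
misidentification_flags <- function(dataset,
                                    markers = names(dataset$alignments)) {
  tab <- nn_status_table(dataset, markers)
  flags <- empty_flags()
  informative <- tab[tab$status %in% c("conflict", "concordant"), ,
                     drop = FALSE]
  for (id in unique(informative$specimen_id)) {
    sub <- informative[informative$specimen_id == id, , drop = FALSE]
    if (nrow(sub) == 0L || any(sub$status != "conflict")) next
    implicated <- unique(sub$nearest_het_species)
    if (length(implicated) != 1L) next
    note <- if (nrow(sub) == 1L)
      sprintf(" (single informative marker %s: low support)", sub$marker[1L])
    else ""
    flags <- rbind(flags, qc_flag(id, paste(sub$marker, collapse = ","),
      "misidentification",
      sprintf("all informative markers place specimen with %s%s",
              implicated, note)))
  }
  flags
}
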