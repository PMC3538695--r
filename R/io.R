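# Domain types and file I/O: per-marker alignments (FASTA), specimen
# metadata (TSV), optional recovery-status table, and the linked library
# dataset that the rest of the pipeline consumes.

#' Construct a marker alignment
#'
#' A marker alignment is a set of equal-length, aligned sequences keyed by
#' specimen ID, for a single barcode marker (e.g. \code{"rbcL"}).  Sequences
#' may contain IUPAC ambiguity codes plus \code{'-'} (gap) and \code{'?'}
#' (no data); both of the latter are treated as missing downstream.
#'
#' @param marker Marker name.
#' @param seqs Named character vector of aligned sequences; names are
#'   specimen IDs.
#' @return An object of class \code{marker_alignment} with elements
#'   \code{marker}, \code{seqs} (uppercase) and \code{columns}.
#' @export
marker_alignment <- function(marker, seqs) {
  if (length(seqs) < 1L) stop("alignment for '", marker, "' has no sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named by specimen ID")
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("duplicate specimen ID in '", marker, "' alignment: ",
         paste(unique(dup), collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- names(seqs)[lens != lens[1L]][1L]
    stop(sprintf(
      "unequal sequence lengths in '%s' alignment: '%s' has %d columns, expected %d",
      marker, bad, nchar(seqs[[bad]]), lens[1L]))
  }
  encode_states(seqs)  # alphabet validation; errors name id and position
  structure(list(marker = marker, seqs = seqs, columns = unname(lens[1L])),
            class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("<marker_alignment> %s: %d sequences x %d columns\n",
              x$marker, length(x$seqs), x$columns))
  invisible(x)
}

#' Read a per-marker aligned FASTA file
#'
#' Record IDs are the first whitespace-delimited token of each header.
#' All sequences must have equal length; characters are validated against
#' the nucleotide alphabet (IUPAC codes, \code{'-'}, \code{'?'}) and
#' normalised to uppercase.
#'
#' @param path FASTA file path.
#' @param marker Marker name to attach; defaults to the file base name.
#' @return A \code{\link{marker_alignment}}.
#' @export
read_marker_fasta <- function(path, marker = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  marker <- marker %||% sub("\\.[^.]*$", "", basename(path))
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "DNA")
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  marker_alignment(marker, seqs)
}

#' Write a marker alignment as FASTA
#' @param aln A \code{marker_alignment}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_marker_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "marker_alignment"))
  ids <- sort(names(aln$seqs))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0(">", ids), unname(aln$seqs[ids]))),
             con, sep = "\n")
  invisible(path)
}

.req_meta_cols <- c("specimen_id", "species", "genus", "family")

#' Read the specimen metadata table
#'
#' Tab-delimited with a header row.  Required columns: \code{specimen_id},
#' \code{species}, \code{genus}, \code{family}; optional: \code{order},
#' \code{source} (\code{fresh}/\code{herbarium}), \code{collection_year}.
#' Metadata is authoritative for taxonomy: each species must map to exactly
#' one genus and each genus to one family across all rows.
#'
#' @param path TSV file path.
#' @return A data frame of specimen records (one row per specimen).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          na.strings = c("NA", ""), quote = "",
                          check.names = TRUE, fileEncoding = "UTF-8")
  validate_specimens(df)
}

#' Validate a specimen metadata data frame
#' @param df Data frame with the metadata columns.
#' @return The validated, normalised data frame.
#' @export
validate_specimens <- function(df) {
  missing_cols <- setdiff(.req_meta_cols, names(df))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"order" %in% names(df)) df$order <- NA_character_
  if (!"source" %in% names(df)) {
    df$source <- NA_character_
    warning("metadata has no 'source' column; source-stratified statistics disabled",
            call. = FALSE)
  }
  if (!"collection_year" %in% names(df)) df$collection_year <- NA
  df$collection_year <- suppressWarnings(as.integer(df$collection_year))
  df <- df[, c(.req_meta_cols, "order", "source", "collection_year")]
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup))
    stop("duplicate specimen_id in metadata: ", paste(unique(dup), collapse = ", "))
  bad_src <- stats::na.omit(setdiff(unique(df$source), c("fresh", "herbarium")))
  if (length(bad_src))
    stop("source must be 'fresh' or 'herbarium'; found: ",
         paste(bad_src, collapse = ", "))
  sp2gen <- tapply(df$genus, df$species, function(g) length(unique(g)))
  if (any(sp2gen > 1L))
    stop("taxonomy inconsistency: species mapped to multiple genera: ",
         paste(names(sp2gen)[sp2gen > 1L], collapse = ", "))
  gen2fam <- tapply(df$family, df$genus, function(f) length(unique(f)))
  if (any(gen2fam > 1L))
    stop("taxonomy inconsistency: genus mapped to multiple families: ",
         paste(names(gen2fam)[gen2fam > 1L], collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write specimen metadata as TSV
#' @param specimens Specimen data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_metadata <- function(specimens, path) {
  df <- specimens[order(specimens$specimen_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

.recovery_levels <- c("attempted_failed", "succeeded", "not_attempted")

#' Read a recovery-status table
#'
#' Tab-delimited with columns \code{specimen_id}, \code{marker},
#' \code{status} (\code{attempted_failed}, \code{succeeded},
#' \code{not_attempted}).
#' @param path TSV file path.
#' @return Data frame of recovery records.
#' @export
read_recovery <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  need <- c("specimen_id", "marker", "status")
  if (!all(need %in% names(df)))
    stop("recovery table needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$status), .recovery_levels)
  if (length(bad))
    stop("unknown recovery status: ", paste(bad, collapse = ", "))
  df[, need]
}

#' Link marker alignments to specimen metadata
#'
#' Builds the central library object.  Sequence IDs absent from the metadata
#' are reported as orphans (warning) and dropped; a specimen may lack any
#' given marker.  Metadata is authoritative for taxonomy.
#'
#' @param alignments Named list of \code{marker_alignment} objects (names are
#'   ignored; each alignment carries its marker).
#' @param specimens Specimen metadata data frame (see
#'   \code{\link{read_metadata}}).
#' @param recovery Optional recovery-status data frame.
#' @return An object of class \code{barcode_library} with elements
#'   \code{specimens}, \code{alignments}, \code{recovery}, \code{orphans}.
#' @export
link_dataset <- function(alignments, specimens, recovery = NULL) {
  if (length(alignments) < 1L) stop("at least one alignment is required")
  specimens <- validate_specimens(specimens)
  alignments <- stats::setNames(alignments,
                                vapply(alignments, `[[`, "", "marker"))
  orphans <- list()
  any_linked <- FALSE
  for (m in names(alignments)) {
    ids <- names(alignments[[m]]$seqs)
    keep <- ids %in% specimens$specimen_id
    if (any(keep)) any_linked <- TRUE
    if (any(!keep)) {
      orphans[[m]] <- ids[!keep]
      alignments[[m]]$seqs <- alignments[[m]]$seqs[keep]
      if (length(alignments[[m]]$seqs) == 0L)
        stop("no sequence in '", m, "' alignment matches the metadata")
    }
  }
  if (!any_linked)
    stop("link error: no sequence ID in any alignment matches the metadata")
  if (length(orphans))
    warning("dropped orphan sequence IDs with no metadata: ",
            paste(unlist(orphans), collapse = ", "), call. = FALSE)
  structure(list(specimens = specimens, alignments = alignments,
                 recovery = recovery, orphans = orphans),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf(
    "<barcode_library> %d specimens, %d species, %d genera, %d families\n",
    nrow(x$specimens), length(unique(x$specimens$species)),
    length(unique(x$specimens$genus)), length(unique(x$specimens$family))))
  for (m in names(x$alignments))
    cat(sprintf("  %s: %d sequences x %d columns\n", m,
                length(x$alignments[[m]]$seqs), x$alignments[[m]]$columns))
  if (!is.null(x$recovery))
    cat(sprintf("  recovery table: %d records\n", nrow(x$recovery)))
  invisible(x)
}

#' Per-specimen marker presence matrix
#' @param dataset A \code{barcode_library}.
#' @return Logical matrix, specimens x markers.
#' @export
marker_presence <- function(dataset) {
  stopifnot(inherits(dataset, "barcode_library"))
  ids <- dataset$specimens$specimen_id
  out <- sapply(dataset$alignments,
                function(a) ids %in% names(a$seqs))
  out <- matrix(out, nrow = length(ids),
                dimnames = list(ids, names(dataset$alignments)))
  out
}

# Restrict a dataset to a subset of specimen IDs (internal).
#' @noRd
subset_dataset <- function(dataset, ids) {
  keep <- dataset$specimens$specimen_id %in% ids
  specimens <- dataset$specimens[keep, , drop = FALSE]
  alignments <- lapply(dataset$alignments, function(a) {
    a$seqs <- a$seqs[names(a$seqs) %in% ids]
    a
  })
  alignments <- Filter(function(a) length(a$seqs) > 0L, alignments)
  structure(list(specimens = specimens, alignments = alignments,
                 recovery = dataset$recovery, orphans = dataset$orphans),
            class = "barcode_library")
}
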