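# Concatenated character matrices ("profiled alignments") with per-marker
# partitions and specimen-inclusion rules.

#' Specimen-inclusion rules for concatenation
#'
#' \code{inclusion_rule("paper")} is the three-gene rule used for combined
#' analyses of rbcL + matK + ITS2 libraries: a specimen is included when it
#' has ITS2 plus at least one of the chloroplast markers.  When applied to a
#' marker combination that lacks either the nuclear or the chloroplast side,
#' the rule degrades gracefully to "any marker of the combination".
#'
#' @param rule One of \code{"all_markers"}, \code{"any_marker"},
#'   \code{"paper"}.
#' @param nuclear Name of the nuclear marker (default \code{"ITS2"}).
#' @param chloroplast Names of the chloroplast markers.
#' @return A predicate \code{function(present, markers)} where
#'   \code{present} is a named logical vector of marker presence for one
#'   specimen, restricted to \code{markers}.
#' @export
inclusion_rule <- function(rule = c("paper", "any_marker", "all_markers"),
                           nuclear = "ITS2",
                           chloroplast = c("rbcL", "matK")) {
  rule <- match.arg(rule)
  switch(rule,
    all_markers = function(present, markers) all(present[markers]),
    any_marker  = function(present, markers) any(present[markers]),
    paper = function(present, markers) {
      nuc <- intersect(nuclear, markers)
      chl <- intersect(chloroplast, markers)
      if (length(nuc) == 0L || length(chl) == 0L)
        return(any(present[markers]))
      all(present[nuc]) && any(present[chl])
    })
}

#' Concatenate marker alignments into a supermatrix
#'
#' Specimens failing the inclusion rule are excluded.  An included specimen
#' that lacks a marker has that partition filled with \code{'?'} (no data; a
#' missing state for parsimony, distinct from the alignment gap \code{'-'}
#' at file level).
#'
#' @param dataset A \code{barcode_library}.
#' @param markers Ordered character vector of marker names (default: the
#'   dataset's markers in their stored order).
#' @param rule An inclusion predicate from \code{\link{inclusion_rule}}, or a
#'   rule name.
#' @return An object of class \code{supermatrix}: list with \code{seqs}
#'   (named character vector of concatenated rows) and \code{partitions}
#'   (data frame \code{marker}, \code{start}, \code{end}; 0-based half-open
#'   column intervals in declared marker order).
#' @export
concatenate <- function(dataset, markers = names(dataset$alignments),
                        rule = "paper") {
  stopifnot(inherits(dataset, "barcode_library"))
  missing_m <- setdiff(markers, names(dataset$alignments))
  if (length(missing_m))
    stop("marker(s) not in dataset: ", paste(missing_m, collapse = ", "))
  if (is.character(rule)) rule <- inclusion_rule(rule)
  pres <- marker_presence(dataset)
  keep <- vapply(rownames(pres), function(id) {
    isTRUE(rule(pres[id, ], markers))
  }, logical(1))
  ids <- rownames(pres)[keep]
  if (length(ids) == 0L)
    stop("empty matrix: no specimen satisfies the inclusion rule")
  widths <- vapply(markers, function(m) dataset$alignments[[m]]$columns, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths
  rows <- vapply(ids, function(id) {
    paste(vapply(markers, function(m) {
      s <- dataset$alignments[[m]]$seqs
      if (id %in% names(s)) unname(s[[id]])
      else strrep("?", dataset$alignments[[m]]$columns)
    }, character(1)), collapse = "")
  }, character(1))
  structure(list(
    seqs = rows,
    partitions = data.frame(marker = markers, start = unname(starts),
                            end = unname(ends), stringsAsFactors = FALSE)),
    class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d specimens x %d columns; partitions: %s\n",
              length(x$seqs), sm_columns(x),
              paste(sprintf("%s[%d,%d)", x$partitions$marker,
                            x$partitions$start, x$partitions$end),
                    collapse = " ")))
  invisible(x)
}

#' Total column count of a supermatrix
#' @param sm A \code{supermatrix}.
#' @return Integer column count.
#' @export
sm_columns <- function(sm) {
  if (nrow(sm$partitions) == 0L) return(0L)
  max(sm$partitions$end)
}

#' Extract one marker's partition from a supermatrix
#'
#' Slicing every partition and re-concatenating in order reproduces the
#' supermatrix exactly.
#'
#' @param sm A \code{supermatrix}.
#' @param marker Marker name present in the partition table.
#' @return A \code{marker_alignment} over the included specimens (missing
#'   specimens appear as all-\code{'?'} rows).
#' @export
partition_slice <- function(sm, marker) {
  i <- match(marker, sm$partitions$marker)
  if (is.na(i)) stop("marker '", marker, "' not in supermatrix partitions")
  start <- sm$partitions$start[i]
  end <- sm$partitions$end[i]
  seqs <- vapply(sm$seqs, substr, character(1), start + 1L, end)
  marker_alignment(marker, seqs)
}

#' Write a supermatrix as FASTA plus a partitions file
#'
#' The partitions file uses the common RAxML-style dialect, one line per
#' marker: \code{"DNA, <marker> = <start>-<end>"} with 1-based inclusive
#' coordinates.
#'
#' @param sm A \code{supermatrix}.
#' @param fasta_path Output FASTA path.
#' @param partitions_path Output partitions text path (default: alongside
#'   \code{fasta_path} with extension \code{.partitions}).
#' @return \code{fasta_path}, invisibly.
#' @export
write_supermatrix <- function(sm, fasta_path,
                              partitions_path =
                                paste0(tools::file_path_sans_ext(fasta_path),
                                       ".partitions")) {
  ids <- sort(names(sm$seqs))
  con <- file(fasta_path, "wb")
  writeLines(as.vector(rbind(paste0(">", ids), unname(sm$seqs[ids]))),
             con, sep = "\n")
  close(con)
  con <- file(partitions_path, "wb")
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$marker,
                     sm$partitions$start + 1L, sm$partitions$end),
             con, sep = "\n")
  close(con)
  invisible(fasta_path)
}
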