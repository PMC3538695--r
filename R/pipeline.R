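# End-to-end orchestration: QC screen -> exclusion of flagged sequences ->
# supermatrix / ratchet / consensus / resolution per marker combination ->
# distance statistics -> paralogy and misidentification flags -> report
# bundle on disk.  Stages are plain functions so that staged execution and
# the single-shot runner produce identical artifacts for the same seed.

#' Pipeline run configuration
#'
#' @param dataset A \code{barcode_library}, or \code{NULL} when
#'   \code{input_dir} is given.
#' @param input_dir Directory readable by \code{\link{read_library}}.
#' @param coding_markers Markers subject to the ORF screen.
#' @param nuclear_marker,chloroplast_markers Marker roles for the paralogy
#'   rule.
#' @param combos Marker combinations to compare (default: chloroplast pair,
#'   chloroplast-plus-nuclear pairs and the full set, intersected with the
#'   available markers).
#' @param rule Inclusion rule (see \code{\link{inclusion_rule}}).
#' @param distance_model \code{"p"} or \code{"k2p"}.
#' @param search \code{\link{search_params}} template; per-combination seeds
#'   are derived from \code{seed}.
#' @param plant_refs,contaminant_refs Reference sets for the contamination
#'   screen (named character vectors); screen skipped when \code{NULL}.
#' @param keep_flagged Keep pseudogene/contaminant-flagged sequences in the
#'   analysis instead of excluding them.
#' @param out_dir Output directory for the report bundle (\code{NULL}: no
#'   files written).
#' @param seed Top-level seed; stage substreams are derived from it.
#' @param log_timestamps Write ISO timestamps into the run log.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(dataset = NULL, input_dir = NULL,
                       coding_markers = c("rbcL", "matK"),
                       nuclear_marker = "ITS2",
                       chloroplast_markers = c("rbcL", "matK"),
                       combos = NULL, rule = "paper",
                       distance_model = "p",
                       search = search_params(),
                       plant_refs = NULL, contaminant_refs = NULL,
                       keep_flagged = FALSE, out_dir = NULL, seed = 1L,
                       log_timestamps = TRUE) {
  if (is.null(dataset) && is.null(input_dir))
    stop("supply 'dataset' or 'input_dir'")
  structure(as.list(environment()), class = "run_config")
}

#' QC screen stage: ORF check and contamination screen
#'
#' @param dataset A \code{barcode_library}.
#' @param config A \code{\link{run_config}}.
#' @return Flags data frame (possibly zero rows).
#' @export
qc_screen <- function(dataset, config) {
  flags <- list()
  for (m in intersect(config$coding_markers, names(dataset$alignments)))
    flags[[length(flags) + 1L]] <- orf_check(dataset$alignments[[m]])
  if (!is.null(config$plant_refs) && !is.null(config$contaminant_refs) &&
      config$nuclear_marker %in% names(dataset$alignments))
    flags[[length(flags) + 1L]] <- contaminant_screen(
      dataset$alignments[[config$nuclear_marker]],
      config$plant_refs, config$contaminant_refs)
  out <- do.call(rbind, flags)
  if (is.null(out)) empty_flags() else out
}

#' Exclude flagged sequences from a dataset
#'
#' Removes each flagged (specimen, marker) sequence; the specimen record
#' stays so that other markers remain usable.
#'
#' @param dataset A \code{barcode_library}.
#' @param flags Flags data frame from \code{\link{qc_screen}}.
#' @return The reduced \code{barcode_library}.
#' @export
exclude_flagged <- function(dataset, flags) {
  if (nrow(flags) == 0L) return(dataset)
  for (i in seq_len(nrow(flags))) {
    m <- flags$marker[i]
    if (!m %in% names(dataset$alignments)) next
    s <- dataset$alignments[[m]]$seqs
    dataset$alignments[[m]]$seqs <- s[names(s) != flags$specimen_id[i]]
  }
  dataset
}

#' @noRd
default_combos <- function(markers, nuclear, chloroplast) {
  chl <- intersect(chloroplast, markers)
  nuc <- intersect(nuclear, markers)
  combos <- list()
  if (length(chl) >= 2L) combos <- c(combos, list(chl))
  if (length(nuc) && length(chl))
    combos <- c(combos, lapply(chl[1L], function(c1) c(c1, nuc)))
  if (length(markers) >= 2L) combos <- c(combos, list(markers))
  unique(combos)
}

#' Run the full evaluation pipeline
#'
#' Executes QC (ORF and contamination screens), excludes flagged sequences
#' (unless \code{keep_flagged}), builds a supermatrix per marker
#' combination, runs the parsimony ratchet and strict consensus, scores
#' species resolution, computes the distance statistics and the paralogy /
#' misidentification flags, and (when \code{out_dir} is set) writes the
#' report bundle: per-combination Newick trees and resolution tables, MPD
#' and correlation tables, recovery tables, a flags table, a JSON summary
#' and a run log.
#'
#' @param config A \code{\link{run_config}}.
#' @return The report bundle (list), invisibly containing all artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    stamp <- if (isTRUE(config$log_timestamps))
      paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ") else ""
    log_lines <<- c(log_lines, paste0(stamp, sprintf(fmt, ...)))
  }
  dataset <- config$dataset %||% read_library(config$input_dir)
  say("pipeline start: seed %d, %d specimens, markers %s", config$seed,
      nrow(dataset$specimens),
      paste(names(dataset$alignments), collapse = ","))

  ## stage: qc screen + exclusion
  qc_flags <- qc_screen(dataset, config)
  say("qc: %d flags (%s)", nrow(qc_flags),
      paste(names(table(qc_flags$flag_type)), table(qc_flags$flag_type),
            sep = "=", collapse = ", "))
  analysed <- if (isTRUE(config$keep_flagged)) dataset
              else exclude_flagged(dataset, qc_flags)

  ## stage: trees + resolution per combination
  markers <- names(analysed$alignments)
  combos <- config$combos %||%
    default_combos(markers, config$nuclear_marker,
                   config$chloroplast_markers)
  search <- config$search
  search$seed <- substream(config$seed, "search")
  comparison <- marker_combination_compare(analysed, combos, params = search,
                                           rule = config$rule)
  for (i in seq_len(nrow(comparison$table)))
    say("combo %s: length %s, %d optimal trees, overall %.1f%%",
        comparison$table$combo[i], format(comparison$table$tree_length[i]),
        comparison$table$n_optimal_trees[i],
        comparison$table$overall_percent[i])

  ## stage: distance statistics
  mpd <- stats::setNames(lapply(markers, function(m)
    mpd_by_family(analysed, m, config$distance_model)), markers)
  correlations <- list()
  if (length(markers) >= 2L) {
    prs <- utils::combn(markers, 2L, simplify = FALSE)
    for (pr in prs) {
      res <- tryCatch(mpd_correlation(mpd[[pr[1L]]], mpd[[pr[2L]]]),
                      error = function(e) NULL)
      if (!is.null(res)) correlations[[paste(pr, collapse = "/")]] <- res
    }
  }
  intraspecific <- stats::setNames(lapply(markers, function(m)
    intraspecific_variation(analysed, m)), markers)
  recovery <- tryCatch(recovery_stats(dataset), error = function(e) NULL)

  ## stage: label-conflict flags on the cleaned dataset
  conflict_flags <- rbind(
    paralogy_flags(analysed, config$nuclear_marker,
                   config$chloroplast_markers),
    misidentification_flags(analysed))
  say("conflict flags: %d paralogy, %d misidentification",
      sum(conflict_flags$flag_type == "paralogy"),
      sum(conflict_flags$flag_type == "misidentification"))

  bundle <- list(config_seed = config$seed, qc_flags = qc_flags,
                 conflict_flags = conflict_flags, comparison = comparison,
                 mpd = mpd, correlations = correlations,
                 intraspecific = intraspecific, recovery = recovery,
                 log = log_lines)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a pipeline report bundle to a directory
#' @param bundle Result of \code{\link{run_pipeline}}.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(rbind(bundle$qc_flags, bundle$conflict_flags),
            file.path(out_dir, "flags.tsv"))
  cmp <- bundle$comparison
  write_tsv(cmp$table, file.path(out_dir, "combo_comparison.tsv"))
  rb <- data.frame(species = rownames(cmp$resolved_by), cmp$resolved_by,
                   check.names = FALSE)
  write_tsv(rb, file.path(out_dir, "resolved_by.tsv"))
  for (cname in names(cmp$reports)) {
    tag <- gsub("[^A-Za-z0-9]+", "_", cname)
    write_newick(cmp$trees[[cname]],
                 file.path(out_dir, paste0("tree_", tag, ".nwk")))
    write_tsv(cmp$reports[[cname]]$species,
              file.path(out_dir, paste0("resolution_", tag, ".tsv")))
  }
  for (m in names(bundle$mpd))
    write_tsv(bundle$mpd[[m]], file.path(out_dir, paste0("mpd_", m, ".tsv")))
  if (length(bundle$correlations)) {
    cor_df <- do.call(rbind, lapply(bundle$correlations, function(x)
      data.frame(marker_a = x$marker_a, marker_b = x$marker_b, r = x$r,
                 n_families = x$n_families, p_value = x$p_value)))
    write_tsv(cor_df, file.path(out_dir, "mpd_correlations.tsv"))
  }
  for (m in names(bundle$intraspecific))
    write_tsv(bundle$intraspecific[[m]],
              file.path(out_dir, paste0("intraspecific_", m, ".tsv")))
  if (!is.null(bundle$recovery)) {
    write_tsv(bundle$recovery$by_source,
              file.path(out_dir, "recovery_by_source.tsv"))
    write_tsv(bundle$recovery$by_age,
              file.path(out_dir, "recovery_by_age.tsv"))
  }
  summary <- list(
    seed = bundle$config_seed,
    combos = stats::setNames(lapply(names(cmp$reports), function(cn)
      cmp$reports[[cn]]$summary), names(cmp$reports)),
    mpd_mean_percent = lapply(bundle$mpd, function(t)
      if (nrow(t)) mean(t$mpd_percent) else NA),
    correlations = lapply(bundle$correlations, function(x)
      list(r = x$r, n_families = x$n_families, p_value = x$p_value)),
    n_qc_flags = nrow(bundle$qc_flags),
    n_conflict_flags = nrow(bundle$conflict_flags))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
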